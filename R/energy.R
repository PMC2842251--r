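PAIR_CODES <- c("CG", "GC", "GU", "UG", "AU", "UA")

#' Load duplex nearest-neighbor energy parameters
#'
#' Reads a versioned parameter TSV with rows \code{term = "stack"} (columns
#' \code{pair1}, \code{pair2}, \code{dg37}; physical orientation, see the
#' bundled file header), \code{term = "duplex_init"} and
#' \code{term = "terminal_au"}.  The bundled set is the Turner 2004 table
#' at 37 degrees C with \code{duplex_init = 0}: energies are reported on
#' the scale customary for duplex screening tools, which omit the
#' bimolecular initiation term.  Pass \code{duplex_init = 4.1} to work on
#' the full Turner scale instead.
#'
#' @param path parameter file; default is the bundled Turner 2004 set.
#' @param duplex_init,terminal_au optional overrides (kcal/mol).
#' @return list of class \code{energy_params}: \code{stack} (6x6 matrix
#'   over pair codes CG/GC/GU/UG/AU/UA), \code{duplex_init},
#'   \code{terminal_au}, \code{parameter_set_id}.
#' @export
read_energy_params <- function(path = system.file("extdata",
                                                  "energy_turner2004.tsv",
                                                  package = "uaugscan"),
                               duplex_init = NULL, terminal_au = NULL) {
  if (!file.exists(path)) stop("energy parameter file not found: ", path)
  header <- readLines(path, n = 1)
  id <- if (grepl("parameter_set_id:", header)) {
    trimws(sub(".*parameter_set_id:", "", header))
  } else "unversioned"
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  st <- tab[tab$term == "stack", ]
  mat <- matrix(NA_real_, 6, 6, dimnames = list(PAIR_CODES, PAIR_CODES))
  mat[cbind(st$pair1, st$pair2)] <- st$dg37
  if (anyNA(mat) || any(!is.finite(mat))) {
    stop("stack table must cover all 36 pair doublets with finite energies")
  }
  init <- tab$dg37[tab$term == "duplex_init"]
  term <- tab$dg37[tab$term == "terminal_au"]
  out <- list(stack = mat,
              duplex_init = if (is.null(duplex_init)) init else duplex_init,
              terminal_au = if (is.null(terminal_au)) term else terminal_au,
              parameter_set_id = id)
  class(out) <- "energy_params"
  out
}

#' @rdname read_energy_params
#' @export
default_energy_params <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- read_energy_params()
    cache
  }
})

#' Free energy of a fully paired antiparallel RNA duplex at 37 C
#'
#' Both strands are given 5' to 3' and must have equal length;
#' position k of \code{motif_sub} pairs position L+1-k of \code{half_sub}.
#' Every position must form a Watson-Crick or G:U pair.  The energy is
#' \code{duplex_init} + the sum of nearest-neighbor stack terms + a
#' \code{terminal_au} penalty for each helix end closed by A:U or G:U.
#'
#' @param motif_sub,half_sub the two strands (RNA strings, equal length).
#' @param params an \code{energy_params} object.
#' @return free energy in kcal/mol (more negative = more stable).
#' @examples
#' duplex_free_energy("GGGGGGG", "CCCCCCC")
#' @export
duplex_free_energy <- function(motif_sub, half_sub,
                               params = default_energy_params()) {
  if (nchar(motif_sub) != nchar(half_sub)) {
    stop("logic error: strands of a fully paired duplex must have equal ",
         "length")
  }
  m <- strsplit(motif_sub, "", fixed = TRUE)[[1]]
  h <- rev(strsplit(half_sub, "", fixed = TRUE)[[1]])
  codes <- paste0(m, h)
  if (!all(codes %in% PAIR_CODES)) {
    k <- which(!codes %in% PAIR_CODES)[1]
    stop("logic error: unpairable position ", k, " (", codes[k], ")")
  }
  L <- length(codes)
  dg <- params$duplex_init
  if (L > 1) {
    dg <- dg + sum(params$stack[cbind(codes[-L], codes[-1])])
  }
  weak <- c("AU", "UA", "GU", "UG")
  dg + params$terminal_au * ((codes[1] %in% weak) + (codes[L] %in% weak))
}
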