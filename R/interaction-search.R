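#' Search parameters for the two-step complementarity screen
#'
#' @param dg_cutoff duplex free-energy cutoff in kcal/mol; a candidate is
#'   kept only if its stretch energy is at or below this value.
#' @param min_stretch minimum number of consecutive paired positions.
#' @param max_gu_5p,max_gu_3p maximum number of G:U wobbles allowed inside
#'   the stretch for 5'-half and 3'-half interactions respectively.
#'   Genome-wide runs use the same allowance for both ends (0 or 1); the
#'   gene-level meta-analysis uses one wobble at the 3' end and none at the
#'   5' end.
#' @return list of class \code{search_params}.
#' @export
search_params <- function(dg_cutoff = -14, min_stretch = 7, max_gu_5p = 0,
                          max_gu_3p = 0) {
  stopifnot(dg_cutoff < 0, min_stretch >= 1, max_gu_5p >= 0, max_gu_3p >= 0)
  out <- list(dg_cutoff = dg_cutoff, min_stretch = as.integer(min_stretch),
              max_gu_5p = as.integer(max_gu_5p),
              max_gu_3p = as.integer(max_gu_3p))
  class(out) <- "search_params"
  out
}

#' @noRd
max_gu_for_end <- function(params, end) {
  ifelse(end == "5p", params$max_gu_5p, params$max_gu_3p)
}

#' Longest consecutive complementary stretch between a motif and a half
#'
#' Finds the maximum-length run of consecutive paired positions between the
#' motif (read 5' to 3') and the miRNA half (antiparallel, 3' to 5') where
#' every position is Watson-Crick (A:U, G:C) or a G:U wobble, with at most
#' \code{max_gu} wobbles.  Ties are broken by fewer wobbles, then smaller
#' motif start, then smaller half start, making the result deterministic.
#'
#' @param motif_seq,half_seq RNA strings (both written 5' to 3').
#' @param max_gu maximum number of G:U pairs inside the stretch.
#' @return list with \code{stretch_len}, \code{gu_count}, and 0-based
#'   half-open \code{motif_span} and \code{half_span} (both \code{NULL}
#'   when \code{stretch_len} is 0).
#' @examples
#' longest_complementary_stretch("CUAUGCAAC", "GUUGCAUAGUU", 0)$stretch_len
#' @export
longest_complementary_stretch <- function(motif_seq, half_seq, max_gu = 0) {
  if (nchar(motif_seq) == 0 || nchar(half_seq) == 0) {
    stop("both sequences must be non-empty")
  }
  check_alphabet(c(motif_seq, half_seq), what = "stretch input")
  r <- .best_stretch_cpp(encode_rna(motif_seq), encode_rna(half_seq),
                         as.integer(max_gu))
  if (r[1] == 0) {
    return(list(stretch_len = 0L, gu_count = 0L, motif_span = NULL,
                half_span = NULL))
  }
  list(stretch_len = r[1], gu_count = r[2],
       motif_span = c(r[3], r[3] + r[1]),
       half_span = c(r[4], r[4] + r[1]))
}

#' Two-step hit test for one motif against one miRNA half
#'
#' Applies the conjunctive filter: the best stretch must reach
#' \code{min_stretch} under the end's wobble allowance, and its duplex free
#' energy must pass \code{dg_cutoff}.
#'
#' @param motif motif sequence (character) or one-row motif data frame.
#' @param half list or one-row data frame with \code{sequence},
#'   \code{end} (\code{"5p"}/\code{"3p"}) and \code{parent_name}.
#' @param params a \code{search_params} object.
#' @param energy an \code{energy_params} object.
#' @return one-row hit data frame, or \code{NULL} if either criterion
#'   fails.
#' @export
find_hit <- function(motif, half, params = search_params(),
                     energy = default_energy_params()) {
  mseq <- if (is.character(motif)) motif else motif$sequence
  s <- longest_complementary_stretch(mseq, half$sequence,
                                     max_gu_for_end(params, half$end))
  if (s$stretch_len < params$min_stretch) return(NULL)
  dg <- duplex_free_energy(
    substr(mseq, s$motif_span[1] + 1, s$motif_span[2]),
    substr(half$sequence, s$half_span[1] + 1, s$half_span[2]),
    energy)
  if (dg > params$dg_cutoff) return(NULL)
  data.frame(gene = if (is.character(motif) || is.null(motif$gene_id)) NA_character_ else motif$gene_id,
             motif = mseq,
             motif_start = if (is.character(motif)) NA_integer_ else motif$aug_start,
             conserved_motif = if (is.character(motif)) NA else motif$conserved,
             mirna = half$parent_name, end = half$end,
             mirna_conserved = if (is.null(half$mirna_conserved)) NA else half$mirna_conserved,
             stretch_len = s$stretch_len, gu_count = s$gu_count,
             dg37 = dg, stringsAsFactors = FALSE)
}

#' Scan motifs against a miRNA catalog
#'
#' Runs the two-step screen for every (motif occurrence, miRNA, end)
#' triple.  Each triple appears at most once; output order is
#' deterministic (gene, motif start, miRNA, 5p before 3p).
#'
#' @param motifs motif data frame from \code{\link{extract_all}} (or
#'   \code{\link{scan_gene}}'s window table).
#' @param catalog a \code{catalog_partition}, \code{mirna_records}, or a
#'   halves data frame from \code{\link{catalog_halves}}.
#' @param params a \code{search_params} object.
#' @param energy an \code{energy_params} object.
#' @return hit data frame (possibly 0-row) with columns \code{gene},
#'   \code{motif}, \code{motif_start}, \code{conserved_motif},
#'   \code{mirna}, \code{end}, \code{mirna_conserved}, \code{stretch_len},
#'   \code{gu_count}, \code{dg37}.
#' @export
scan_hits <- function(motifs, catalog, params = search_params(),
                      energy = default_energy_params()) {
  halves <- if (is.data.frame(catalog) && "end" %in% names(catalog)) {
    catalog
  } else {
    catalog_halves(catalog)
  }
  empty <- data.frame(gene = character(0), motif = character(0),
                      motif_start = integer(0), conserved_motif = logical(0),
                      mirna = character(0), end = character(0),
                      mirna_conserved = logical(0), stretch_len = integer(0),
                      gu_count = integer(0), dg37 = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(motifs) == 0 || nrow(halves) == 0) return(empty)
  menc <- lapply(motifs$sequence, encode_rna)
  henc <- lapply(halves$sequence, encode_rna)
  raw <- .scan_cpp(menc, henc,
                   as.integer(max_gu_for_end(params, halves$end)),
                   params$min_stretch, energy$stack, energy$duplex_init,
                   energy$terminal_au, params$dg_cutoff)
  if (nrow(raw) == 0) return(empty)
  hits <- data.frame(
    gene = motifs$gene_id[raw$motif_i],
    motif = motifs$sequence[raw$motif_i],
    motif_start = motifs$aug_start[raw$motif_i],
    conserved_motif = motifs$conserved[raw$motif_i],
    mirna = halves$parent_name[raw$half_i],
    end = halves$end[raw$half_i],
    mirna_conserved = halves$mirna_conserved[raw$half_i],
    stretch_len = raw$stretch_len, gu_count = raw$gu_count,
    dg37 = raw$dg37, stringsAsFactors = FALSE)
  order_hits(hits)
}
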