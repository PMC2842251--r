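#' Classify focal-species miRNAs as conserved or non-conserved
#'
#' A focal miRNA is conserved iff a miRNA with the same base name (name with
#' the species prefix stripped; compared case-insensitively and exactly,
#' including any arm suffix such as -3p/-5p) exists under a different
#' species prefix in \code{all_species}.  Nucleotide-level identity is not
#' required.
#'
#' @param focal \code{mirna_records} for one species.
#' @param all_species \code{mirna_records} over all species (may include
#'   the focal records themselves).
#' @return list of class \code{catalog_partition} with elements
#'   \code{conserved} and \code{non_conserved} (disjoint
#'   \code{mirna_records} whose union is \code{focal}).
#' @examples
#' recs <- mirna_records(c("hsa-let-7d", "mmu-let-7d", "hsa-miR-944"),
#'                       c("AGAGGUAGUAGGUUGCAUAGUU",
#'                         "AGAGGUAGUAGGUUGCAUAGUU",
#'                         "AAAUUAUUGUACAUCGGAUGAG"))
#' p <- classify_mirna_conservation(recs[recs$species_prefix == "hsa", ], recs)
#' p$conserved$name
#' @export
classify_mirna_conservation <- function(focal, all_species) {
  if (length(unique(focal$species_prefix)) > 1) {
    stop("focal records must share one species prefix")
  }
  if (nrow(all_species) == 0) {
    warning("empty all-species catalog: classifying every miRNA as ",
            "non-conserved")
    conserved <- rep(FALSE, nrow(focal))
  } else {
    key_all <- tolower(all_species$base_name)
    conserved <- vapply(seq_len(nrow(focal)), function(i) {
      any(key_all == tolower(focal$base_name[i]) &
            all_species$species_prefix != focal$species_prefix[i])
    }, logical(1))
  }
  out <- list(conserved = focal[conserved, , drop = FALSE],
              non_conserved = focal[!conserved, , drop = FALSE])
  class(out) <- "catalog_partition"
  out
}

#' Split a mature miRNA into its 5' and 3' halves
#'
#' The 5' half takes the first ceiling(L/2) nucleotides (so the seed,
#' positions 2-7, stays in the 5' half for every mature length); the 3'
#' half takes the remainder.
#'
#' @param sequence character vector of mature sequences (length >= 2 nt).
#' @return data frame with columns \code{five_p}, \code{three_p}.
#' @examples
#' split_halves("AGAGGUAGUAGGUUGCAUAGUU")
#' @export
split_halves <- function(sequence) {
  len <- nchar(sequence)
  if (any(len < 2)) stop("value error: mature sequence shorter than 2 nt")
  cut <- ceiling(len / 2)
  data.frame(five_p = substr(sequence, 1, cut),
             three_p = substr(sequence, cut + 1, len),
             stringsAsFactors = FALSE)
}

#' Flatten a catalog partition into one row per miRNA half
#'
#' @param partition a \code{catalog_partition} (or \code{mirna_records},
#'   treated as all-conserved = NA).
#' @return data frame with columns \code{parent_name}, \code{end}
#'   (\code{"5p"}/\code{"3p"}), \code{sequence}, \code{mirna_conserved}.
#' @export
catalog_halves <- function(partition) {
  if (inherits(partition, "catalog_partition")) {
    recs <- rbind(partition$conserved, partition$non_conserved)
    cons <- rep(c(TRUE, FALSE), c(nrow(partition$conserved),
                                  nrow(partition$non_conserved)))
  } else {
    recs <- partition
    cons <- rep(NA, nrow(recs))
  }
  h <- split_halves(recs$sequence)
  data.frame(parent_name = rep(recs$name, 2),
             end = rep(c("5p", "3p"), each = nrow(recs)),
             sequence = c(h$five_p, h$three_p),
             mirna_conserved = rep(cons, 2),
             stringsAsFactors = FALSE)
}

#' Composition-preserving miRNA shuffle
#'
#' Returns a uniformly random permutation of the mature sequence's letters
#' (mononucleotide shuffle), drawn from R's RNG stream; seed the stream for
#' reproducibility.  Halves are re-derived from the shuffled full sequence
#' downstream, matching the documented shuffle-then-split order.
#'
#' @param record one-row \code{mirna_records} data frame, or a plain
#'   character sequence.
#' @return same shape as the input, with the sequence permuted and
#'   \code{"|shuffled"} appended to the name (record input only).
#' @export
shuffle_mirna <- function(record) {
  if (is.character(record)) return(shuffle_sequence(record))
  record$sequence <- vapply(record$sequence, shuffle_sequence, character(1),
                            USE.NAMES = FALSE)
  record$name <- paste0(record$name, "|shuffled")
  record
}

#' @noRd
shuffle_sequence <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  paste(ch[sample.int(length(ch))], collapse = "")
}
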