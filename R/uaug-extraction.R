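#' Find all AUG occurrences in an ungapped 5'-UTR
#'
#' Every AUG triplet in the leader counts as a uAUG, including overlapping
#' occurrences; no Kozak-context filtering is applied.
#'
#' @param utr_ungapped RNA string over A/C/G/U.
#' @return integer vector of 0-based start indices of the A, ascending.
#' @examples
#' find_uaugs("CAUAAUGGGGU")  # 4
#' @export
find_uaugs <- function(utr_ungapped) {
  if (nchar(utr_ungapped) < 3) return(integer(0))
  check_alphabet(utr_ungapped, what = "5'-UTR")
  hits <- gregexpr("(?=AUG)", utr_ungapped, perl = TRUE)[[1]]
  if (hits[1] == -1) return(integer(0))
  as.integer(hits) - 1L
}

#' Extract the uAUG-centered motif window
#'
#' Cuts the window from 4 nt upstream of the A through 4 nt downstream of
#' the G (positions -4..+7 with the A as +1), clipped to the sequence
#' bounds.  Clipping removes flanks only; the AUG itself is always intact.
#' Windows shorter than 7 nt are discarded.
#'
#' @param utr_ungapped RNA string.
#' @param aug_start 0-based index of the A of an AUG in \code{utr_ungapped}.
#' @return one-row motif data frame (columns \code{aug_start},
#'   \code{sequence}, \code{length}, \code{aug_offset}, \code{mutant}), or
#'   \code{NULL} if the clipped window is shorter than 7 nt.
#' @examples
#' extract_motif("GCAUAAUGGGGUC", 5)  # "CAUAAUGGGGU"
#' @export
extract_motif <- function(utr_ungapped, aug_start) {
  n <- nchar(utr_ungapped)
  if (aug_start < 0 || aug_start + 3 > n ||
      substr(utr_ungapped, aug_start + 1, aug_start + 3) != "AUG") {
    stop("logic error: no AUG at 0-based position ", aug_start)
  }
  lo <- max(0L, aug_start - 4L)
  hi <- min(n, aug_start + 7L)
  if (hi - lo < 7L) return(NULL)
  data.frame(aug_start = as.integer(aug_start),
             sequence = substr(utr_ungapped, lo + 1, hi),
             length = hi - lo,
             aug_offset = as.integer(aug_start - lo),
             mutant = FALSE, stringsAsFactors = FALSE)
}

# alignment column index (1-based) of every ungapped position
#' @noRd
ungapped_columns <- function(aligned) {
  which(strsplit(aligned, "", fixed = TRUE)[[1]] != "-")
}

#' Classify a motif as conserved between human and mouse
#'
#' A motif is conserved iff, over the alignment columns covering its human
#' positions, the mouse sequence is identical at every column and carries
#' neither a gap at any motif column nor an insertion (mouse base over a
#' human gap) inside the span.  This is the strict 100%-identity call.
#'
#' @param pair one row of a \code{utr_alignment_pairs} data frame.
#' @param motif one-row motif data frame from \code{\link{extract_motif}}.
#' @return logical.
#' @export
classify_motif_conservation <- function(pair, motif) {
  hchars <- strsplit(pair$human_aligned, "", fixed = TRUE)[[1]]
  mchars <- strsplit(pair$mouse_aligned, "", fixed = TRUE)[[1]]
  cols <- ungapped_columns(pair$human_aligned)
  lo <- motif$aug_start - motif$aug_offset  # 0-based window start
  idx <- (lo + 1):(lo + motif$length)       # 1-based ungapped positions
  if (max(idx) > length(cols)) {
    stop("logic error: motif positions not mappable to alignment columns")
  }
  span <- cols[idx]
  full <- span[1]:span[length(span)]
  if (any(mchars[span] != hchars[span])) return(FALSE)       # mismatch/gap
  ins <- setdiff(full, span)                                  # human gaps
  if (length(ins) && any(mchars[ins] != "-")) return(FALSE)   # insertion
  TRUE
}

#' Extract and classify all uAUG motifs from alignment pairs
#'
#' Runs \code{\link{find_uaugs}} and \code{\link{extract_motif}} on the
#' gap-stripped human sequence of every pair and classifies each motif's
#' conservation against the mouse row.  Duplicate motif sequences are
#' retained as separate occurrences.
#'
#' @param pairs a \code{utr_alignment_pairs} data frame.
#' @return list with \code{motifs} (data frame: \code{gene_id},
#'   \code{aug_start}, \code{sequence}, \code{length}, \code{aug_offset},
#'   \code{conserved}, \code{mutant}) and \code{summary} (a
#'   \code{\link{motif_summary}}).
#' @export
extract_all <- function(pairs) {
  per_gene <- vector("list", nrow(pairs))
  for (g in seq_len(nrow(pairs))) {
    pair <- pairs[g, ]
    utr <- strip_gaps(pair$human_aligned)
    rows <- lapply(find_uaugs(utr), function(s) extract_motif(utr, s))
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) {
      df <- do.call(rbind, rows)
      df$conserved <- vapply(seq_len(nrow(df)), function(i) {
        classify_motif_conservation(pair, df[i, ])
      }, logical(1))
      df <- cbind(gene_id = pair$gene_id, df, stringsAsFactors = FALSE)
      per_gene[[g]] <- df
    }
  }
  per_gene <- per_gene[!vapply(per_gene, is.null, logical(1))]
  motifs <- if (length(per_gene)) {
    df <- do.call(rbind, per_gene)
    rownames(df) <- NULL
    df
  } else {
    data.frame(gene_id = character(0), aug_start = integer(0),
               sequence = character(0), length = integer(0),
               aug_offset = integer(0), conserved = logical(0),
               mutant = logical(0), stringsAsFactors = FALSE)
  }
  list(motifs = motifs, summary = motif_summary(motifs, pairs$gene_id))
}

#' Summarize uAUG counts and conservation by motif length
#'
#' @param motifs motif data frame from \code{\link{extract_all}}.
#' @param gene_ids all input gene ids (so UTRs without any uAUG contribute
#'   to the zero bin of the histogram).
#' @return list of class \code{motif_summary}: \code{uaug_counts_per_utr}
#'   (named vector, uAUGs-per-UTR value -> number of UTRs) and
#'   \code{conserved_fraction_by_n} (length 7..11 -> conserved fraction,
#'   \code{NaN} where no motif of that length exists).
#' @export
motif_summary <- function(motifs, gene_ids) {
  counts <- table(factor(motifs$gene_id, levels = gene_ids))
  hist <- table(as.integer(counts))
  frac <- vapply(7:11, function(n) {
    sel <- motifs$length == n
    sum(motifs$conserved[sel]) / sum(sel)
  }, numeric(1))
  out <- list(uaug_counts_per_utr = setNames(as.integer(hist), names(hist)),
              conserved_fraction_by_n = setNames(frac, 7:11))
  class(out) <- "motif_summary"
  out
}

#' Write motif and summary tables
#'
#' @param extraction result of \code{\link{extract_all}}.
#' @param motif_path,summary_path output TSV paths.
#' @return invisibly, the two paths.
#' @export
write_motif_tables <- function(extraction, motif_path, summary_path) {
  m <- extraction$motifs
  out <- data.frame(gene = m$gene_id, position = m$aug_start + 1L,
                    sequence = m$sequence, length = m$length,
                    conserved = m$conserved, stringsAsFactors = FALSE)
  write.table(out, motif_path, sep = "\t", quote = FALSE, row.names = FALSE)
  s <- extraction$summary
  sm <- rbind(
    data.frame(statistic = "uaugs_per_utr", key = names(s$uaug_counts_per_utr),
               value = as.vector(s$uaug_counts_per_utr)),
    data.frame(statistic = "conserved_fraction",
               key = names(s$conserved_fraction_by_n),
               value = as.vector(s$conserved_fraction_by_n)))
  write.table(sm, summary_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(motif_path, summary_path))
}
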