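#' Build a motif table from explicit uAUG windows
#'
#' Gene-level analyses often start from published uAUG windows (7-11 nt)
#' rather than a full 5'-UTR.  Wild-type windows must contain an intact
#' AUG; mutant windows (experimentally mutated variants) need not, and are
#' flagged so reports can distinguish them, but they pass through the
#' generic scan unchanged — no special-casing in the search path.
#'
#' @param label window labels (e.g. \code{"uAUG7"}, \code{"m7"}).
#' @param sequence 7-11 nt RNA windows.
#' @param mutant logical; \code{TRUE} for mutated windows.
#' @param gene_id gene identifier attached to every window.
#' @return motif data frame compatible with \code{\link{scan_hits}}.
#' @export
uaug_windows <- function(label, sequence, mutant = FALSE, gene_id = NA) {
  sequence <- normalize_rna(sequence)
  check_alphabet(sequence, what = "uAUG windows")
  len <- nchar(sequence)
  if (any(len < 7 | len > 11)) {
    stop("value error: uAUG windows must be 7-11 nt")
  }
  mutant <- rep_len(mutant, length(sequence))
  offset <- rep(NA_integer_, length(sequence))
  for (i in which(!mutant)) {
    pos <- find_uaugs(sequence[i])
    ok <- pos[pos <= 4 & len[i] - pos >= 3]
    if (!length(ok)) {
      stop("value error: wild-type window ", sQuote(label[i]),
           " contains no AUG placeable in the -4..+7 frame")
    }
    # prefer the canonical centered placement (A at offset 4)
    offset[i] <- if (4L %in% ok) 4L else ok[1]
  }
  data.frame(gene_id = gene_id, label = label,
             aug_start = seq_along(sequence) - 1L,  # report ordering key
             sequence = sequence, length = len, aug_offset = offset,
             conserved = NA, mutant = mutant, stringsAsFactors = FALSE)
}

#' Scan one gene's uAUG windows against conserved miRNAs
#'
#' Gene-level policy: conserved miRNAs only, one G:U wobble allowed for 3'
#' half interactions and none for 5' half interactions.  The input is
#' either a full 5'-UTR (from which windows are extracted) or an explicit
#' window table, plus optional mutant windows.
#'
#' @param utr optional 5'-UTR sequence; its uAUG windows are extracted.
#' @param windows optional motif table from \code{\link{uaug_windows}}.
#' @param mutants optional data frame with columns \code{label},
#'   \code{sequence} of mutated 7-11 nt windows.
#' @param partition a \code{catalog_partition}; only the conserved class is
#'   scanned.
#' @param params,energy search and energy parameters.
#' @param gene_id identifier used in the report.
#' @return hit data frame (see \code{\link{scan_hits}}).
#' @export
scan_gene <- function(utr = NULL, windows = NULL, mutants = NULL, partition,
                      params = search_params(max_gu_5p = 0, max_gu_3p = 1),
                      energy = default_energy_params(), gene_id = "gene") {
  motifs <- NULL
  if (!is.null(utr)) {
    utr <- normalize_rna(utr)
    rows <- lapply(find_uaugs(utr), function(s) extract_motif(utr, s))
    rows <- rows[!vapply(rows, is.null, logical(1))]
    if (length(rows)) {
      df <- do.call(rbind, rows)
      motifs <- uaug_windows(paste0("uAUG", seq_len(nrow(df))), df$sequence,
                             gene_id = gene_id)
      motifs$aug_start <- df$aug_start
    }
  }
  if (!is.null(windows)) {
    windows$gene_id <- gene_id
    motifs <- rbind(motifs, windows)
  }
  if (!is.null(mutants)) {
    motifs <- rbind(motifs,
                    uaug_windows(mutants$label, mutants$sequence,
                                 mutant = TRUE, gene_id = gene_id))
  }
  if (is.null(motifs) || nrow(motifs) == 0) {
    stop("no uAUG windows to scan")
  }
  motifs$aug_start <- seq_len(nrow(motifs)) - 1L  # stable ordering key
  conserved_only <- partition
  conserved_only$non_conserved <-
    partition$non_conserved[0, , drop = FALSE]
  hits <- scan_hits(motifs, conserved_only, params, energy)
  # report by window label rather than position
  hits$label <- motifs$label[match(paste(hits$motif, hits$motif_start),
                                   paste(motifs$sequence, motifs$aug_start))]
  hits$mutant <- motifs$mutant[match(hits$label, motifs$label)]
  hits
}

#' Join expression evidence onto predicted hits
#'
#' Each hit is annotated with whether the predicted miRNA is expressed in
#' the given cell line: \code{TRUE}/\code{FALSE} from the evidence table,
#' \code{NA} (unknown) when no record exists.
#'
#' @param hits hit data frame.
#' @param expression \code{expression_records} data frame.
#' @param cell_line cell line to look up.
#' @return \code{hits} with added \code{expressed} and \code{source}
#'   columns.
#' @export
join_expression <- function(hits, expression, cell_line) {
  sel <- expression[expression$cell_line == cell_line, , drop = FALSE]
  idx <- match(hits$mirna, sel$mirna)
  hits$expressed <- sel$expressed[idx]
  hits$source <- sel$source[idx]
  hits$cell_line <- if (nrow(hits)) cell_line else character(0)
  hits
}

#' Per-gene report of uAUG windows, predictions and evidence
#'
#' One row per (window, predicted miRNA); windows with no predicted miRNA
#' get a single row with \code{mirna = NA} (the "None" rows of a published
#' gene table).  Fold annotations (1x-6x repression strength, transcribed
#' from reporter experiments) are data, not computation.
#'
#' @param hits hit data frame from \code{\link{scan_gene}}.
#' @param windows window table from \code{\link{uaug_windows}}.
#' @param annotations optional data frame with columns \code{label},
#'   \code{fold} (integer 1-6).
#' @param expression optional \code{expression_records}.
#' @param cell_line cell line for the expression join.
#' @return data frame of class \code{gene_report}: \code{gene},
#'   \code{label}, \code{motif}, \code{fold}, \code{mirna}, \code{end},
#'   \code{expressed}, \code{source}.
#' @export
gene_report <- function(hits, windows, annotations = NULL,
                        expression = NULL, cell_line = NA) {
  if (!is.null(expression) && !is.na(cell_line)) {
    hits <- join_expression(hits, expression, cell_line)
  } else {
    hits$expressed <- rep(NA, nrow(hits))
    hits$source <- rep(NA_character_, nrow(hits))
  }
  rows <- lapply(seq_len(nrow(windows)), function(i) {
    lab <- windows$label[i]
    h <- hits[hits$label == lab, , drop = FALSE]
    if (nrow(h) == 0) {
      data.frame(gene = windows$gene_id[i], label = lab,
                 motif = windows$sequence[i], mirna = NA_character_,
                 end = NA_character_, expressed = NA,
                 source = NA_character_, stringsAsFactors = FALSE)
    } else {
      data.frame(gene = windows$gene_id[i], label = lab, motif = h$motif,
                 mirna = h$mirna, end = h$end, expressed = h$expressed,
                 source = h$source, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$fold <- if (is.null(annotations)) NA_integer_ else {
    annotations$fold[match(out$label, annotations$label)]
  }
  out <- out[c("gene", "label", "motif", "fold", "mirna", "end",
               "expressed", "source")]
  class(out) <- c("gene_report", "data.frame")
  out
}

#' Repression fold versus expressed-miRNA interaction summary
#'
#' @param report a \code{gene_report} (rows annotated with folds).
#' @return data frame with one row per fold value present: \code{fold},
#'   \code{n_motifs} (distinct windows), \code{n_with_expressed_hit}
#'   (windows with at least one predicted, expressed miRNA).
#' @export
summarize_fold_association <- function(report) {
  r <- report[!is.na(report$fold), , drop = FALSE]
  if (nrow(r) == 0) {
    return(data.frame(fold = integer(0), n_motifs = integer(0),
                      n_with_expressed_hit = integer(0)))
  }
  folds <- sort(unique(r$fold))
  do.call(rbind, lapply(folds, function(f) {
    rf <- r[r$fold == f, , drop = FALSE]
    labs <- unique(rf$label)
    hit <- vapply(labs, function(l) {
      any(!is.na(rf$mirna[rf$label == l]) &
            rf$expressed[rf$label == l] %in% TRUE)
    }, logical(1))
    data.frame(fold = f, n_motifs = length(labs),
               n_with_expressed_hit = sum(hit))
  }))
}
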