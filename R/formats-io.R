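#' Read paired human/mouse 5'-UTR alignments
#'
#' Reads the two-record aligned-FASTA dialect used for pairwise 5'-UTR
#' alignments: for each gene, a record \code{">geneid|human"} immediately
#' followed by \code{">geneid|mouse"}, both carrying the gapped (\code{-})
#' aligned sequence.  DNA input is accepted; \code{T} is mapped to \code{U}
#' and case is folded to upper.
#'
#' @param path path to the aligned FASTA file.
#' @param dialect input dialect; only \code{"two_record_fasta"} is built in.
#'   Other dialects can be converted up front and fed through this reader.
#' @return a data frame of class \code{utr_alignment_pairs} with columns
#'   \code{gene_id}, \code{human_aligned}, \code{mouse_aligned} and
#'   \code{source_line} (line of the human record header, for error
#'   reporting).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">geneX|human", "ACG-U", ">geneX|mouse", "ACGAU"), fa)
#' read_alignment_pairs(fa)
#' @export
read_alignment_pairs <- function(path, dialect = c("two_record_fasta")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("alignment file not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0) stop("no records in ", path)
  if (length(seqs) %% 2 != 0) {
    stop("pairing error: odd number of records (", length(seqs), ") in ",
         path, "; expected human/mouse pairs")
  }
  header_lines <- grep("^>", readLines(path))
  ids <- sub("\\s.*", "", names(seqs))
  parts <- strsplit(ids, "|", fixed = TRUE)
  bad <- lengths(parts) != 2
  if (any(bad)) {
    stop("malformed header ", sQuote(ids[which(bad)[1]]),
         " at line ", header_lines[which(bad)[1]],
         "; expected 'geneid|human' or 'geneid|mouse'")
  }
  gene <- vapply(parts, `[`, character(1), 1)
  org <- vapply(parts, `[`, character(1), 2)
  hi <- seq(1, length(seqs), by = 2)
  mi <- hi + 1L
  ok <- org[hi] == "human" & org[mi] == "mouse" & gene[hi] == gene[mi]
  if (any(!ok)) {
    k <- which(!ok)[1]
    stop("pairing error near line ", header_lines[hi[k]], ": records ",
         sQuote(ids[hi[k]]), " / ", sQuote(ids[mi[k]]),
         " are not a human/mouse pair for one gene")
  }
  human <- normalize_rna(as.character(seqs[hi]))
  mouse <- normalize_rna(as.character(seqs[mi]))
  for (k in seq_along(hi)) {
    where <- paste0("gene ", sQuote(gene[hi[k]]), " (line ",
                    header_lines[hi[k]], ")")
    check_alphabet(c(human[k], mouse[k]), allow_gap = TRUE, what = where)
    if (nchar(human[k]) != nchar(mouse[k])) {
      stop("structural error for ", where, ": aligned lengths differ (",
           nchar(human[k]), " vs ", nchar(mouse[k]), ")")
    }
    if (nchar(strip_gaps(human[k])) == 0 || nchar(strip_gaps(mouse[k])) == 0) {
      stop("structural error for ", where, ": empty ungapped sequence")
    }
  }
  out <- data.frame(gene_id = unname(gene[hi]),
                    human_aligned = unname(human),
                    mouse_aligned = unname(mouse),
                    source_line = header_lines[hi],
                    stringsAsFactors = FALSE)
  class(out) <- c("utr_alignment_pairs", "data.frame")
  out
}

#' Write alignment pairs in the two-record aligned-FASTA dialect
#'
#' @param pairs a \code{utr_alignment_pairs} data frame.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_alignment_pairs <- function(pairs, path) {
  lines <- as.vector(rbind(paste0(">", pairs$gene_id, "|human"),
                           pairs$human_aligned,
                           paste0(">", pairs$gene_id, "|mouse"),
                           pairs$mouse_aligned))
  writeLines(lines, path)
  invisible(path)
}

#' Read mature miRNA sequences from miRBase-style FASTA
#'
#' The first whitespace-delimited token of each header must be a
#' miRBase-style name with a three-letter species prefix
#' (e.g. \code{hsa-let-7d}).  \code{T} is mapped to \code{U}.
#'
#' @param path path to the FASTA file.
#' @return data frame of class \code{mirna_records} with columns
#'   \code{name}, \code{species_prefix}, \code{base_name}, \code{sequence},
#'   \code{length}.
#' @export
read_mirna_fasta <- function(path) {
  if (!file.exists(path)) stop("miRNA FASTA not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  names <- sub("\\s.*", "", names(seqs))
  bad <- !grepl("^[A-Za-z]{3}-.", names)
  if (any(bad)) {
    stop("parse error: header ", sQuote(names(seqs)[which(bad)[1]]),
         " lacks a miRBase-style 'xxx-' species prefix")
  }
  if (anyDuplicated(names)) {
    stop("duplicate miRNA name(s): ",
         paste(unique(names[duplicated(names)]), collapse = ", "))
  }
  sequence <- normalize_rna(as.character(seqs))
  if (any(nchar(sequence) == 0)) {
    stop("alphabet error: empty sequence for ",
         names[which(nchar(sequence) == 0)[1]])
  }
  check_alphabet(sequence, what = "miRNA sequences")
  mirna_records(name = names, sequence = unname(sequence))
}

#' Construct a miRNA record table
#'
#' @param name miRBase-style names (\code{<species>-<base_name>}).
#' @param sequence mature RNA sequences.
#' @return data frame of class \code{mirna_records}.
#' @export
mirna_records <- function(name, sequence) {
  stopifnot(length(name) == length(sequence))
  sequence <- normalize_rna(sequence)
  check_alphabet(sequence, what = "miRNA sequences")
  out <- data.frame(name = name,
                    species_prefix = sub("-.*", "", name),
                    base_name = sub("^[A-Za-z0-9]*-", "", name),
                    sequence = sequence,
                    length = nchar(sequence),
                    stringsAsFactors = FALSE)
  class(out) <- c("mirna_records", "data.frame")
  out
}

#' Write miRNA records as FASTA
#'
#' @param records a \code{mirna_records} data frame.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_mirna_fasta <- function(records, path) {
  writeLines(as.vector(rbind(paste0(">", records$name), records$sequence)),
             path)
  invisible(path)
}

#' Read a miRNA expression evidence table
#'
#' Tab-delimited with header columns \code{mirna}, \code{cell_line},
#' \code{expressed} (one of Yes/No/Y/N/1/0, case-insensitive) and
#' \code{source} (citation tag).
#'
#' @param path path to the TSV file.
#' @return data frame of class \code{expression_records} with a logical
#'   \code{expressed} column.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("expression table not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("mirna", "cell_line", "expressed", "source")
  missing <- setdiff(need, names(tab))
  if (length(missing)) {
    stop("schema error: expression table lacks column(s) ",
         paste(missing, collapse = ", "))
  }
  tab <- tab[need]
  if (nrow(tab)) {
    tok <- tolower(as.character(tab$expressed))
    val <- c(yes = TRUE, y = TRUE, "1" = TRUE, no = FALSE, n = FALSE,
             "0" = FALSE)[tok]
    if (anyNA(val)) {
      stop("value error: unknown 'expressed' token ",
           sQuote(tab$expressed[which(is.na(val))[1]]),
           "; expected Yes/No/Y/N/1/0")
    }
    tab$expressed <- unname(val)
    key <- paste(tab$mirna, tab$cell_line, tab$source, sep = "\r")
    if (anyDuplicated(key)) {
      stop("duplicate (mirna, cell_line, source) row: ",
           gsub("\r", " / ", key[duplicated(key)][1]))
    }
  } else {
    tab$expressed <- logical(0)
  }
  class(tab) <- c("expression_records", "data.frame")
  tab
}

HITS_COLUMNS <- c("gene", "motif", "motif_start", "conserved_motif",
                  "mirna", "end", "stretch_len", "gu_count", "dG37")

# stable report order: gene, motif_start, mirna, end (5p before 3p)
#' @noRd
order_hits <- function(hits) {
  hits[order(hits$gene, hits$motif_start, hits$mirna,
             match(hits$end, c("5p", "3p"))), , drop = FALSE]
}

#' Write a duplex hit table
#'
#' Writes hits as TSV with stable column order and deterministic row order
#' (gene, motif start, miRNA, end with 5p before 3p).  Positions are written
#' 1-based; in-memory hit tables use 0-based starts.
#'
#' @param hits a hit data frame as returned by \code{\link{scan_hits}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_hits_table <- function(hits, path) {
  out <- data.frame(gene = character(0), motif = character(0),
                    motif_start = integer(0), conserved_motif = logical(0),
                    mirna = character(0), end = character(0),
                    stretch_len = integer(0), gu_count = integer(0),
                    dG37 = numeric(0))
  if (!is.null(hits) && nrow(hits)) {
    out <- data.frame(gene = hits$gene, motif = hits$motif,
                      motif_start = hits$motif_start + 1L,
                      conserved_motif = hits$conserved_motif,
                      mirna = hits$mirna, end = hits$end,
                      stretch_len = hits$stretch_len,
                      gu_count = hits$gu_count, dG37 = hits$dg37,
                      stringsAsFactors = FALSE)
    out <- out[order(out$gene, out$motif_start, out$mirna,
                     match(out$end, c("5p", "3p"))), , drop = FALSE]
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a duplex hit table written by \code{write_hits_table}
#'
#' @param path path to the TSV file.
#' @return hit data frame with 0-based \code{motif_start}.
#' @export
read_hits_table <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(gene = "character", mirna = "character"))
  missing <- setdiff(HITS_COLUMNS, names(tab))
  if (length(missing)) {
    stop("schema error: hits table lacks column(s) ",
         paste(missing, collapse = ", "))
  }
  data.frame(gene = tab$gene, motif = tab$motif,
             motif_start = tab$motif_start - 1L,
             conserved_motif = tab$conserved_motif, mirna = tab$mirna,
             end = tab$end, stretch_len = tab$stretch_len,
             gu_count = tab$gu_count, dg37 = tab$dG37,
             stringsAsFactors = FALSE)
}
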