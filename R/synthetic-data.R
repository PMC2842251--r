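#' Configuration for the synthetic dataset generator
#'
#' Defaults describe the reference study conditions used throughout the
#' package's validation: 200 UTRs of 50-300 nt with on average 2.05 uAUGs
#' each (the motifs-per-UTR mean of the curated human/mouse alignment set),
#' per-column human/mouse conservation 0.97 (so an 11-mer is fully
#' conserved with probability ~0.72), and 70 focal miRNAs of 20-22 nt of
#' which an expected 5/7 are conserved (present in a second species).
#' \code{plant_rate} is the probability that a given full-window uAUG gets
#' a planted reverse-complement binding site for a conserved miRNA 3' half.
#'
#' @param n_utrs number of UTR alignment pairs.
#' @param utr_length_range min/max UTR length (nt).
#' @param column_conservation_rate per-column probability that the mouse
#'   base equals the human base.
#' @param uaug_rate expected (Poisson) uAUGs injected per UTR.
#' @param n_mirnas number of focal-species miRNAs.
#' @param mirna_length_range min/max mature miRNA length (nt).
#' @param conserved_mirna_fraction per-miRNA probability of being
#'   duplicated under a second species prefix (with ~10% nucleotide
#'   divergence).
#' @param plant_rate per-uAUG planting probability.
#' @param gc_content GC fraction of the uniform background composition.
#' @param seed integer master seed; all generator randomness derives from
#'   it.
#' @return list of class \code{generator_config}.
#' @export
generator_config <- function(n_utrs = 200, utr_length_range = c(50, 300),
                             column_conservation_rate = 0.97,
                             uaug_rate = 2.05, n_mirnas = 70,
                             mirna_length_range = c(20, 22),
                             conserved_mirna_fraction = 5 / 7,
                             plant_rate = 0.2, gc_content = 0.5, seed = 1) {
  stopifnot(column_conservation_rate >= 0, column_conservation_rate <= 1,
            conserved_mirna_fraction >= 0, conserved_mirna_fraction <= 1,
            plant_rate >= 0, plant_rate <= 1, uaug_rate >= 0,
            utr_length_range[1] >= 20,
            utr_length_range[2] >= utr_length_range[1],
            mirna_length_range[1] >= 16,
            mirna_length_range[2] >= mirna_length_range[1],
            gc_content > 0, gc_content < 1, seed + 400 < 2^31)
  out <- list(n_utrs = as.integer(n_utrs),
              utr_length_range = as.integer(utr_length_range),
              column_conservation_rate = column_conservation_rate,
              uaug_rate = uaug_rate, n_mirnas = as.integer(n_mirnas),
              mirna_length_range = as.integer(mirna_length_range),
              conserved_mirna_fraction = conserved_mirna_fraction,
              plant_rate = plant_rate, gc_content = gc_content,
              seed = as.integer(seed))
  class(out) <- "generator_config"
  out
}

#' @noRd
base_probs <- function(gc) c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2,
                             U = (1 - gc) / 2)

#' @noRd
random_rna <- function(n, gc) {
  paste(sample(RNA_BASES, n, replace = TRUE, prob = base_probs(gc)),
        collapse = "")
}

# replace the middle base of every AUG occurrence not in `keep` with C
# (C cannot complete a new AUG), until the sequence is clean
#' @noRd
scrub_augs <- function(chars, keep = integer(0)) {
  repeat {
    s <- paste(chars, collapse = "")
    occ <- find_uaugs(s)
    occ <- setdiff(occ, keep)
    if (!length(occ)) return(chars)
    chars[occ + 2L] <- "C"
  }
}

#' Generate a multi-species miRNA catalog
#'
#' Focal-species ("hsa") records get random sequences (no structure is
#' imposed, so unplanted catalogs are exchangeable with their shuffles);
#' a Bernoulli draw with \code{conserved_mirna_fraction} decides whether
#' each base name is duplicated under the "mmu" prefix with ~10% of
#' positions substituted (conservation is by name, irrespective of
#' nucleotide identity).
#'
#' @param config a \code{generator_config}.
#' @return \code{mirna_records} for both species, with attribute
#'   \code{"intended_conserved"} (named logical over focal names).
#' @export
gen_mirna_catalog <- function(config) {
  set.seed(config$seed + 101L)
  n <- config$n_mirnas
  lens <- sample(seq(config$mirna_length_range[1],
                     config$mirna_length_range[2]), n, replace = TRUE)
  seqs <- vapply(lens, random_rna, character(1), gc = config$gc_content)
  names <- sprintf("hsa-miR-s%03d", seq_len(n))
  conserved <- runif(n) < config$conserved_mirna_fraction
  mmu <- lapply(which(conserved), function(i) {
    chars <- strsplit(seqs[i], "", fixed = TRUE)[[1]]
    mut <- runif(length(chars)) < 0.1
    chars[mut] <- vapply(chars[mut], function(b) {
      sample(setdiff(RNA_BASES, b), 1)
    }, character(1))
    c(sub("^hsa", "mmu", names[i]), paste(chars, collapse = ""))
  })
  all_names <- c(names, vapply(mmu, `[`, character(1), 1))
  all_seqs <- c(seqs, vapply(mmu, `[`, character(1), 2))
  out <- mirna_records(all_names, all_seqs)
  attr(out, "intended_conserved") <- setNames(conserved, names)
  out
}

#' Generate human/mouse 5'-UTR alignment pairs with injected uAUGs
#'
#' Human sequences are uniform random RNA with all background AUGs removed
#' and a Poisson(\code{uaug_rate}) number of AUG triplets injected at
#' random positions (spaced >= 3 nt).  The mouse row is a copy with
#' per-column substitutions at rate 1 - \code{column_conservation_rate};
#' no indels are introduced, so alignments are gap-free.
#'
#' @param config a \code{generator_config}.
#' @return a \code{utr_alignment_pairs} data frame.
#' @export
gen_utr_alignments <- function(config) {
  set.seed(config$seed + 202L)
  n <- config$n_utrs
  out <- vector("list", n)
  for (g in seq_len(n)) {
    len <- sample(seq(config$utr_length_range[1],
                      config$utr_length_range[2]), 1)
    chars <- strsplit(random_rna(len, config$gc_content), "",
                      fixed = TRUE)[[1]]
    chars <- scrub_augs(chars)
    k <- rpois(1, config$uaug_rate)
    placed <- integer(0)
    if (k > 0) {
      cand <- sample.int(len - 2)  # 1-based starts, random order
      for (p in cand) {
        if (length(placed) >= k) break
        if (all(abs(placed - p) >= 3)) placed <- c(placed, p)
      }
      for (p in placed) chars[p:(p + 2)] <- c("A", "U", "G")
      chars <- scrub_augs(chars, keep = placed - 1L)
    }
    human <- paste(chars, collapse = "")
    mut <- runif(len) >= config$column_conservation_rate
    mchars <- chars
    mchars[mut] <- vapply(chars[mut], function(b) {
      sample(setdiff(RNA_BASES, b), 1)
    }, character(1))
    out[[g]] <- data.frame(gene_id = sprintf("g%04d", g),
                           human_aligned = human,
                           mouse_aligned = paste(mchars, collapse = ""),
                           source_line = 2L * g - 1L,
                           stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, out)
  class(pairs) <- c("utr_alignment_pairs", "data.frame")
  pairs
}

# Feasible AUG placements for planting a 3' half.  The planted site is the
# full reverse complement of the half, laid on the UTR so that one of its
# AUG occurrences coincides with the uAUG.  An offset o (0-based position
# of that AUG within the reverse complement) is feasible when the overlap
# between the planted site and the -4..+7 motif window reaches min_stretch
# and the overlap duplex passes the energy screen, so every planted site
# is recoverable by construction.  Returns integer offsets (possibly none).
#' @noRd
plant_offsets_for_half <- function(half, params, energy) {
  Lh <- nchar(half)
  rc <- rna_revcomp(half)
  offs <- integer(0)
  for (o in find_uaugs(rc)) {
    lo <- max(-4L, -o)               # overlap bounds relative to the AUG's A
    hi <- min(7L, Lh - o)
    ol <- hi - lo
    if (ol < params$min_stretch) next
    rc_sub <- substr(rc, o + lo + 1, o + hi)
    # rc index r pairs half index Lh - 1 - r (both 0-based)
    h_sub <- substr(half, Lh - (o + hi) + 1, Lh - (o + lo))
    if (duplex_free_energy(rc_sub, h_sub, energy) > params$dg_cutoff) next
    offs <- c(offs, o)
  }
  offs
}

#' Plant reverse-complement binding sites on uAUGs
#'
#' For each uAUG whose full -4..+7 window lies inside the UTR, with
#' probability \code{plant_rate} the surrounding sequence is overwritten
#' with the exact reverse complement of a randomly chosen eligible
#' conserved miRNA 3' half, laid so that one of the site's AUG triplets
#' coincides with the uAUG (see \code{plant_offsets_for_half}; eligibility
#' guarantees the motif-window overlap reaches the stretch and energy
#' criteria, so every planted triple is recoverable).  The mouse row is
#' synchronized over the affected span, keeping planted motifs conserved.
#' Flanks outside the planted span are untouched.
#'
#' @param alignments a \code{utr_alignment_pairs} data frame (gap-free, as
#'   produced by \code{\link{gen_utr_alignments}}).
#' @param partition a \code{catalog_partition} of the focal species.
#' @param config a \code{generator_config}.
#' @param params,energy screen parameters used for the eligibility check.
#' @return list with modified \code{alignments} and \code{ground_truth}
#'   (data frame: \code{gene_id}, \code{aug_start} 0-based, \code{mirna},
#'   \code{end}, \code{site_start} 0-based start of the planted reverse
#'   complement).
#' @export
plant_sites <- function(alignments, partition, config,
                        params = search_params(),
                        energy = default_energy_params()) {
  set.seed(config$seed + 303L)
  cons <- partition$conserved
  halves <- split_halves(cons$sequence)
  offsets <- lapply(halves$three_p, plant_offsets_for_half, params = params,
                    energy = energy)
  eligible <- which(lengths(offsets) > 0)
  skipped <- nrow(cons) - length(eligible)
  empty_gt <- data.frame(gene_id = character(0), aug_start = integer(0),
                         mirna = character(0), end = character(0),
                         site_start = integer(0))
  if (length(eligible) == 0) {
    if (config$plant_rate > 0 && nrow(cons) > 0) {
      warning("no eligible conserved miRNA 3' half; nothing planted")
    }
    return(list(alignments = alignments, ground_truth = empty_gt,
                skipped_mirnas = skipped))
  }
  gt <- list()
  for (g in seq_len(nrow(alignments))) {
    human <- strsplit(alignments$human_aligned[g], "", fixed = TRUE)[[1]]
    mouse <- strsplit(alignments$mouse_aligned[g], "", fixed = TRUE)[[1]]
    len <- length(human)
    planted_pos <- integer(0)
    for (a in find_uaugs(paste(human, collapse = ""))) {
      if (a - 4 < 0 || a + 7 > len) next        # need the full motif window
      if (runif(1) >= config$plant_rate) next
      if (paste(human[a + 1:3], collapse = "") != "AUG") next  # stale pos
      pick <- eligible[sample.int(length(eligible), 1)]
      o <- offsets[[pick]][sample.int(length(offsets[[pick]]), 1)]
      rc <- rna_revcomp(halves$three_p[pick])
      site_start <- a - o                        # 0-based
      if (site_start < 0 || site_start + nchar(rc) > len) next
      # synchronized span: planted site plus the full motif window
      span <- (min(site_start, a - 4) + 1):(max(site_start + nchar(rc),
                                                a + 7))
      if (any(span %in% planted_pos)) next       # keep plants disjoint
      human[site_start + seq_len(nchar(rc))] <-
        strsplit(rc, "", fixed = TRUE)[[1]]
      mouse[span] <- human[span]
      planted_pos <- c(planted_pos, span)
      gt[[length(gt) + 1]] <- data.frame(gene_id = alignments$gene_id[g],
                                         aug_start = a,
                                         mirna = cons$name[pick],
                                         end = "3p",
                                         site_start = site_start,
                                         stringsAsFactors = FALSE)
    }
    alignments$human_aligned[g] <- paste(human, collapse = "")
    alignments$mouse_aligned[g] <- paste(mouse, collapse = "")
  }
  ground_truth <- if (length(gt)) do.call(rbind, gt) else empty_gt
  list(alignments = alignments, ground_truth = ground_truth,
       skipped_mirnas = skipped)
}

#' Generate a random expression evidence table
#'
#' @param records \code{mirna_records} (focal species).
#' @param cell_lines character vector of cell line names.
#' @param rate per-(miRNA, cell line) probability of an "expressed" call.
#' @param seed integer seed.
#' @return \code{expression_records} data frame.
#' @export
gen_expression_table <- function(records, cell_lines = c("HeLa", "N2A"),
                                 rate = 0.5, seed = 1) {
  set.seed(seed)
  grid <- expand.grid(mirna = records$name, cell_line = cell_lines,
                      stringsAsFactors = FALSE)
  out <- data.frame(grid, expressed = runif(nrow(grid)) < rate,
                    source = "synthetic", stringsAsFactors = FALSE)
  class(out) <- c("expression_records", "data.frame")
  out
}

#' Generate a complete synthetic dataset with ground truth
#'
#' Chains \code{\link{gen_mirna_catalog}}, conservation classification,
#' \code{\link{gen_utr_alignments}} and \code{\link{plant_sites}}.  Fixed
#' seed implies full determinism.
#'
#' @param config a \code{generator_config}.
#' @param params,energy screen parameters used for plant eligibility.
#' @return list: \code{alignments}, \code{records} (all species),
#'   \code{partition} (focal species), \code{ground_truth},
#'   \code{config}.
#' @export
simulate_dataset <- function(config = generator_config(),
                             params = search_params(),
                             energy = default_energy_params()) {
  records <- gen_mirna_catalog(config)
  focal <- records[records$species_prefix == "hsa", , drop = FALSE]
  class(focal) <- class(records)
  partition <- classify_mirna_conservation(focal, records)
  alignments <- gen_utr_alignments(config)
  planted <- plant_sites(alignments, partition, config, params, energy)
  list(alignments = planted$alignments, records = records,
       partition = partition, ground_truth = planted$ground_truth,
       skipped_mirnas = planted$skipped_mirnas, config = config)
}

#' Write a synthetic dataset in the formats the readers consume
#'
#' @param dataset result of \code{\link{simulate_dataset}}.
#' @param dir output directory (created if needed).
#' @return named character vector of the written paths.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(alignments = file.path(dir, "alignments.fa"),
             mirnas = file.path(dir, "mirnas.fa"),
             ground_truth = file.path(dir, "ground_truth.tsv"))
  write_alignment_pairs(dataset$alignments, paths["alignments"])
  write_mirna_fasta(dataset$records, paths["mirnas"])
  gt <- dataset$ground_truth
  gt$aug_start <- gt$aug_start + 1L  # 1-based on disk
  write.table(gt, paths["ground_truth"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths
}
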