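#' Count interactions in a stratum
#'
#' A stratum is a conjunction of optional filters on the miRNA end, the
#' miRNA conservation class and the motif conservation class; \code{NA}
#' leaves a dimension unrestricted.
#'
#' @param hits hit data frame from \code{\link{scan_hits}}.
#' @param end \code{"5p"}, \code{"3p"} or \code{NA}.
#' @param mirna_conserved,motif_conserved logical or \code{NA}.
#' @return integer count of (motif occurrence, miRNA, end) triples.
#' @export
count_interactions <- function(hits, end = NA, mirna_conserved = NA,
                               motif_conserved = NA) {
  keep <- rep(TRUE, nrow(hits))
  if (!is.na(end)) keep <- keep & hits$end == end
  if (!is.na(mirna_conserved)) {
    keep <- keep & hits$mirna_conserved %in% mirna_conserved
  }
  if (!is.na(motif_conserved)) {
    keep <- keep & hits$conserved_motif %in% motif_conserved
  }
  sum(keep)
}

#' Default stratum table for genome-wide runs
#'
#' Ends crossed with miRNA conservation (motif class unrestricted), plus
#' ends crossed with motif conservation restricted to conserved miRNAs:
#' the eight strata examined per wobble configuration.
#'
#' @return data frame with columns \code{end}, \code{mirna_conserved},
#'   \code{motif_conserved}.
#' @export
default_strata <- function() {
  rbind(expand.grid(end = c("5p", "3p"), mirna_conserved = c(TRUE, FALSE),
                    motif_conserved = NA, stringsAsFactors = FALSE),
        expand.grid(end = c("5p", "3p"), mirna_conserved = TRUE,
                    motif_conserved = c(TRUE, FALSE),
                    stringsAsFactors = FALSE))
}

# stratum counts from the (motif class) x (half class) count matrix:
# motif classes 1/2 = conserved/non-conserved motif,
# half classes 1..4 = (5p,3p) x (conserved, non-conserved miRNA)
#' @noRd
strata_from_cells <- function(cells, strata) {
  vapply(seq_len(nrow(strata)), function(k) {
    mi <- if (is.na(strata$motif_conserved[k])) 1:2 else {
      if (strata$motif_conserved[k]) 1L else 2L
    }
    ends <- if (is.na(strata$end[k])) c("5p", "3p") else strata$end[k]
    mcons <- if (is.na(strata$mirna_conserved[k])) c(TRUE, FALSE) else {
      strata$mirna_conserved[k]
    }
    hj <- outer(match(ends, c("5p", "3p")) - 1,
                match(mcons, c(TRUE, FALSE)), function(e, c) e * 2 + c)
    sum(cells[mi, as.vector(hj), drop = FALSE])
  }, numeric(1))
}

#' @noRd
half_class_of <- function(halves) {
  (match(halves$end, c("5p", "3p")) - 1L) * 2L +
    match(halves$mirna_conserved, c(TRUE, FALSE))
}

# one stratum-count evaluation used by both the observed data and the null
#' @noRd
scan_stratum_counts <- function(menc, motif_class, henc, halves, params,
                                energy, strata) {
  cells <- .scan_count_cpp(menc, henc,
                           as.integer(max_gu_for_end(params, halves$end)),
                           params$min_stretch, energy$stack,
                           energy$duplex_init, energy$terminal_au,
                           params$dg_cutoff, motif_class, 2L,
                           half_class_of(halves), 4L)
  strata_from_cells(cells, strata)
}

#' Shuffle-null distribution of interaction counts
#'
#' Per iteration every focal miRNA's full mature sequence is permuted
#' (composition-preserving mononucleotide shuffle), halves are re-derived
#' from the shuffled sequence, the scan is re-run and stratum counts are
#' recorded.  Iteration i uses the derived seed \code{seed + i}, so the
#' null is fully reproducible and independent of execution order.
#'
#' @param motifs motif data frame.
#' @param partition a \code{catalog_partition}.
#' @param params,energy search and energy parameters.
#' @param iterations number of shuffle iterations (>= 2).
#' @param seed integer base seed.
#' @param strata stratum table (see \code{\link{default_strata}}).
#' @return list of \code{null_model} objects (one per stratum row), each
#'   with \code{iterations}, \code{seed}, \code{counts}, \code{mean},
#'   \code{sd} (sample SD, n-1 denominator).
#' @export
null_distribution <- function(motifs, partition, params = search_params(),
                              energy = default_energy_params(),
                              iterations = 1000, seed = 1,
                              strata = default_strata()) {
  if (iterations < 2) stop("value error: iterations must be >= 2")
  if (seed + iterations >= 2^31) stop("seed too large")
  halves <- catalog_halves(partition)
  recs <- rbind(partition$conserved, partition$non_conserved)
  renc <- lapply(recs$sequence, encode_rna)
  cut <- ceiling(nchar(recs$sequence) / 2)
  menc <- lapply(motifs$sequence, encode_rna)
  motif_class <- ifelse(motifs$conserved, 1L, 2L)
  counts <- matrix(0, iterations, nrow(strata))
  for (it in seq_len(iterations)) {
    set.seed(seed + it)
    shuf <- lapply(renc, function(e) e[sample.int(length(e))])
    henc <- c(lapply(seq_along(shuf), function(i) shuf[[i]][seq_len(cut[i])]),
              lapply(seq_along(shuf), function(i) {
                shuf[[i]][seq(cut[i] + 1, length(shuf[[i]]))]
              }))
    counts[it, ] <- scan_stratum_counts(menc, motif_class, henc, halves,
                                        params, energy, strata)
  }
  lapply(seq_len(nrow(strata)), function(k) {
    out <- list(iterations = as.integer(iterations), seed = as.integer(seed),
                counts = counts[, k], mean = mean(counts[, k]),
                sd = sd(counts[, k]), stratum = strata[k, ])
    class(out) <- "null_model"
    out
  })
}

#' Z-test of an observed count against a shuffle null
#'
#' One-sided upper-tail test under a normal assumption for the null counts.
#' With a degenerate null (\code{sd == 0}) the p-value is 0 above the mean,
#' 1 below, and 0.5 at the mean, and the result is flagged.
#'
#' @param observed observed interaction count.
#' @param null a \code{null_model}.
#' @return list with \code{z}, \code{p_one_sided}, \code{degenerate}.
#' @examples
#' z_test(10, list(mean = 4, sd = 3))
#' @export
z_test <- function(observed, null) {
  if (null$sd == 0) {
    p <- if (observed > null$mean) 0 else if (observed < null$mean) 1 else 0.5
    return(list(z = if (observed == null$mean) 0 else
      sign(observed - null$mean) * Inf, p_one_sided = p, degenerate = TRUE))
  }
  z <- (observed - null$mean) / null$sd
  list(z = z, p_one_sided = pnorm(z, lower.tail = FALSE), degenerate = FALSE)
}

#' Genome-wide interaction analysis with shuffle-null significance
#'
#' For each wobble configuration (the same allowance applied to both miRNA
#' ends) the scan is run, interactions are counted in each stratum, and a
#' shuffle null (\code{\link{null_distribution}}) provides the Z-test.
#' No multiple-testing correction is applied across strata by default;
#' set \code{bonferroni = TRUE} to add an adjusted p column.
#'
#' @param motifs motif data frame from \code{\link{extract_all}}.
#' @param partition a \code{catalog_partition}.
#' @param energy an \code{energy_params} object.
#' @param iterations shuffle iterations.
#' @param seed base seed.
#' @param wobbles integer vector of wobble allowances to evaluate.
#' @param dg_cutoff,min_stretch screen parameters.
#' @param strata stratum table.
#' @param bonferroni add Bonferroni-adjusted p-values.
#' @return data frame with one row per (wobble, stratum): observed count,
#'   null mean and SD, z and one-sided p.
#' @export
run_interaction_analysis <- function(motifs, partition,
                                     energy = default_energy_params(),
                                     iterations = 1000, seed = 1,
                                     wobbles = c(0L, 1L), dg_cutoff = -14,
                                     min_stretch = 7,
                                     strata = default_strata(),
                                     bonferroni = FALSE) {
  res <- lapply(wobbles, function(w) {
    params <- search_params(dg_cutoff = dg_cutoff, min_stretch = min_stretch,
                            max_gu_5p = w, max_gu_3p = w)
    hits <- scan_hits(motifs, partition, params, energy)
    nulls <- null_distribution(motifs, partition, params, energy,
                               iterations, seed, strata)
    obs <- vapply(seq_len(nrow(strata)), function(k) {
      count_interactions(hits, strata$end[k], strata$mirna_conserved[k],
                         strata$motif_conserved[k])
    }, numeric(1))
    zt <- lapply(seq_along(obs), function(k) z_test(obs[k], nulls[[k]]))
    data.frame(max_gu = w, strata,
               observed = as.integer(obs),
               null_mean = vapply(nulls, `[[`, numeric(1), "mean"),
               null_sd = vapply(nulls, `[[`, numeric(1), "sd"),
               z = vapply(zt, `[[`, numeric(1), "z"),
               p = vapply(zt, `[[`, numeric(1), "p_one_sided"),
               degenerate = vapply(zt, `[[`, logical(1), "degenerate"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  if (bonferroni) out$p_bonferroni <- pmin(1, out$p * nrow(out))
  rownames(out) <- NULL
  out
}
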