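test_that("catalog generator hits the requested conserved fraction", {
  cfg <- generator_config(n_mirnas = 200, conserved_mirna_fraction = 0.5,
                          seed = 11)
  recs <- gen_mirna_catalog(cfg)
  focal <- recs[recs$species_prefix == "hsa", ]
  part <- classify_mirna_conservation(focal, recs)
  k <- nrow(part$conserved)
  # binomial 99% interval around 100 of 200
  expect_gte(k, qbinom(0.005, 200, 0.5))
  expect_lte(k, qbinom(0.995, 200, 0.5))
  # classification recovers the generator's intent exactly
  intended <- attr(recs, "intended_conserved")
  expect_setequal(part$conserved$name, names(intended)[intended])

  all1 <- gen_mirna_catalog(generator_config(n_mirnas = 30,
                                             conserved_mirna_fraction = 1,
                                             seed = 2))
  p1 <- classify_mirna_conservation(all1[all1$species_prefix == "hsa", ],
                                    all1)
  expect_equal(nrow(p1$non_conserved), 0)
  all0 <- gen_mirna_catalog(generator_config(n_mirnas = 30,
                                             conserved_mirna_fraction = 0,
                                             seed = 2))
  expect_warning(
    p0 <- classify_mirna_conservation(all0[all0$species_prefix == "hsa", ],
                                      all0[0, ]))
  expect_equal(nrow(p0$conserved), 0)
})

test_that("UTR generator injects Poisson-many uAUGs and controls conservation", {
  cfg <- generator_config(n_utrs = 400, uaug_rate = 2, plant_rate = 0,
                          seed = 19)
  pairs <- gen_utr_alignments(cfg)
  ex <- extract_all(pairs)
  per_utr <- table(factor(ex$motifs$gene_id, levels = pairs$gene_id))
  # windows shorter than 7 nt are dropped by extraction, so compare AUG
  # occurrence counts directly against the Poisson mean
  occ <- vapply(pairs$human_aligned, function(s) length(find_uaugs(s)),
                numeric(1))
  expect_lt(abs(mean(occ) - 2), 3 * sqrt(2 / length(occ)))

  # full conservation when the mouse row is a perfect copy
  full <- gen_utr_alignments(generator_config(
    n_utrs = 30, column_conservation_rate = 1, plant_rate = 0, seed = 3))
  exf <- extract_all(full)
  expect_true(all(exf$motifs$conserved))

  # rate 0 yields no uAUGs at all (background AUGs are scrubbed)
  none <- gen_utr_alignments(generator_config(n_utrs = 30, uaug_rate = 0,
                                              plant_rate = 0, seed = 4))
  expect_equal(nrow(extract_all(none)$motifs), 0)
})

test_that("planting writes exact reverse complements with closed ground truth", {
  cfg <- generator_config(n_utrs = 80, n_mirnas = 30, plant_rate = 0.3,
                          seed = 55)
  ds <- simulate_dataset(cfg)
  gt <- ds$ground_truth
  expect_gt(nrow(gt), 10)
  halves <- split_halves(ds$partition$conserved$sequence)
  rownames(halves) <- ds$partition$conserved$name
  for (i in seq_len(nrow(gt))) {
    utr <- ds$alignments$human_aligned[ds$alignments$gene_id == gt$gene_id[i]]
    h <- halves[gt$mirna[i], "three_p"]
    # the planted span is the exact reverse complement of the 3' half and
    # one of its AUGs sits on the recorded uAUG
    site <- substr(utr, gt$site_start[i] + 1, gt$site_start[i] + nchar(h))
    expect_equal(site, rna_revcomp(h))
    expect_equal(substr(utr, gt$aug_start[i] + 1, gt$aug_start[i] + 3),
                 "AUG")
  }
  # every planted triple is recovered by the scan (ground-truth closure)
  motifs <- extract_all(ds$alignments)$motifs
  hits <- scan_hits(motifs, ds$partition, search_params())
  hkey <- paste(hits$gene, hits$motif_start, hits$mirna, hits$end)
  gkey <- paste(gt$gene_id, gt$aug_start, gt$mirna, gt$end)
  expect_true(all(gkey %in% hkey))

  # determinism and the plant_rate = 0 edge
  ds2 <- simulate_dataset(cfg)
  expect_identical(ds$alignments, ds2$alignments)
  expect_identical(ds$ground_truth, ds2$ground_truth)
  none <- simulate_dataset(generator_config(n_utrs = 10, n_mirnas = 6,
                                            plant_rate = 0, seed = 5))
  expect_equal(nrow(none$ground_truth), 0)
})

test_that("datasets round-trip through the on-disk formats", {
  ds <- simulate_dataset(generator_config(n_utrs = 8, n_mirnas = 6,
                                          plant_rate = 0, seed = 13))
  dir <- tempfile()
  paths <- write_dataset(ds, dir)
  back <- read_alignment_pairs(paths["alignments"])
  expect_equal(back$gene_id, ds$alignments$gene_id)
  expect_equal(back$human_aligned, ds$alignments$human_aligned)
  recs <- read_mirna_fasta(paths["mirnas"])
  expect_equal(recs$sequence, ds$records$sequence)
  gt <- read.delim(paths["ground_truth"])
  expect_equal(nrow(gt), nrow(ds$ground_truth))
})
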