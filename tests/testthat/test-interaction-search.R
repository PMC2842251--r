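test_that("stretch finder handles the canonical and degenerate cases", {
  # let-7d 3' half against its published 9-mer motif: full-length pairing
  s <- longest_complementary_stretch("CUAUGCAAC", "GUUGCAUAGUU", 0)
  expect_equal(s$stretch_len, 9L)
  expect_equal(s$gu_count, 0L)
  expect_equal(s$motif_span, c(0L, 9L))
  expect_equal(s$half_span, c(0L, 9L))

  # A cannot pair with A
  expect_equal(longest_complementary_stretch("AAAAAAA", "AAAAAAA", 1)$stretch_len, 0L)
  # all-GU diagonals: a second consecutive wobble exceeds max_gu = 1
  s <- longest_complementary_stretch("GGGGGGG", "UUUUUUU", 1)
  expect_equal(s$stretch_len, 1L)
  expect_equal(s$gu_count, 1L)
  expect_error(longest_complementary_stretch("", "ACGU", 0), "non-empty")
})

test_that("stretch finder agrees with the exhaustive-enumeration oracle", {
  set.seed(101)
  for (i in 1:300) {
    m <- random_rna_string(sample(4:12, 1))
    h <- random_rna_string(sample(4:12, 1))
    for (g in 0:2) {
      got <- longest_complementary_stretch(m, h, g)
      want <- oracle_stretch(m, h, g)
      label <- paste(m, h, g)
      expect_equal(got$stretch_len, unname(want["len"]), label = label)
      if (got$stretch_len > 0) {
        expect_equal(got$gu_count, unname(want["gu"]), label = label)
        expect_equal(got$motif_span[1], unname(want["ms"]), label = label)
        expect_equal(got$half_span[1], unname(want["hs"]), label = label)
      }
    }
  }
})

test_that("stretch length is invariant under reverse-complementing both strands", {
  # holds for Watson-Crick pairing (max_gu = 0): complementing both
  # strands maps a G:U wobble to the unpairable A:C, so wobble stretches
  # are deliberately excluded
  set.seed(7)
  for (i in 1:60) {
    m <- random_rna_string(sample(5:12, 1))
    h <- random_rna_string(sample(5:12, 1))
    a <- longest_complementary_stretch(m, h, 0)
    b <- longest_complementary_stretch(rna_revcomp(h), rna_revcomp(m), 0)
    expect_equal(a$stretch_len, b$stretch_len)
    expect_equal(a$gu_count, b$gu_count)
  }
})

test_that("duplex energies follow the nearest-neighbor model", {
  # frozen hand-sums over the bundled Turner 2004 table (independent
  # arithmetic: stack doublets summed by hand from the TSV)
  expect_equal(duplex_free_energy("GGGGGGG", "CCCCCCC"), -19.8)
  expect_equal(duplex_free_energy("AUAUAUA", "UAUAUAU"), -6.2)
  expect_equal(duplex_free_energy("AACUAUG", "CAUAGUU"), -9.2)
  expect_equal(duplex_free_energy("CUAUGCAAC", "GUUGCAUAG"), -15.2)
  # 7 GC pairs clear the screen with any standard parameter set
  expect_lte(duplex_free_energy("GGGGGGG", "CCCCCCC"), -14)
  # AU-only helix is less stable than the all-GC one
  expect_gt(duplex_free_energy("AUAUAUA", "UAUAUAU"),
            duplex_free_energy("GGGGGGG", "CCCCCCC"))
  # a single pair is never stabilizing on the screening scale
  expect_gte(duplex_free_energy("G", "C"), 0)
  expect_error(duplex_free_energy("AAA", "GGG"), "unpairable")
  expect_error(duplex_free_energy("AA", "UUU"), "equal length")
})

test_that("energies match RNAduplex (Turner 2004 with initiation) exactly", {
  # G/C-closed helices only: RNAduplex's MFE structure can open a weak
  # (A:U/G:U) terminal pair in favor of dangling ends, which the
  # fully-paired stretch model deliberately does not represent
  params <- read_energy_params(duplex_init = 4.1)
  set.seed(23)
  for (i in 1:12) {
    m <- paste0(sample(c("G", "C"), 1), random_rna_string(sample(4:9, 1)),
                sample(c("G", "C"), 1))
    h <- rna_revcomp(m)
    expect_equal(duplex_free_energy(m, h, params), rnaduplex_dg(m, h),
                 tolerance = 1e-6, label = m)
  }
})

test_that("adding a GC pair at the end never destabilizes the duplex", {
  set.seed(31)
  for (i in 1:30) {
    m <- random_rna_string(8)
    h <- rna_revcomp(m)
    base <- duplex_free_energy(m, h)
    ext <- duplex_free_energy(paste0(m, "G"), paste0("C", h))
    expect_lte(ext, base)
  }
})

test_that("find_hit applies the conjunctive length + energy filter", {
  params <- search_params()
  # a perfect 7-mer stretch that fails the energy screen is not a hit
  half_weak <- list(parent_name = "x", end = "3p",
                    sequence = rna_revcomp("AUAUAUA"))
  expect_null(find_hit("AUAUAUA", half_weak, params))
  expect_gte(longest_complementary_stretch(
    "AUAUAUA", half_weak$sequence, 0)$stretch_len, 7)

  # a GC-rich 8-mer passes both criteria
  half_strong <- list(parent_name = "y", end = "3p",
                      sequence = rna_revcomp("GGCGAUGC"))
  hit <- find_hit("GGCGAUGC", half_strong, params)
  expect_equal(hit$stretch_len, 8L)
  expect_lte(hit$dg37, -14)

  # a half shorter than min_stretch can never produce a hit
  expect_null(find_hit("GGCGAUGCCGG",
                       list(parent_name = "z", end = "3p", sequence = "GGC"),
                       params))
})

test_that("scan is deterministic, conjunctive, and monotone in the wobble allowance", {
  set.seed(47)
  cfg <- generator_config(n_utrs = 60, n_mirnas = 30, plant_rate = 0.3,
                          seed = 12)
  ds <- simulate_dataset(cfg)
  motifs <- extract_all(ds$alignments)$motifs
  p0 <- search_params(max_gu_5p = 0, max_gu_3p = 0)
  p1 <- search_params(max_gu_5p = 1, max_gu_3p = 1)
  h0 <- scan_hits(motifs, ds$partition, p0)
  h1 <- scan_hits(motifs, ds$partition, p1)
  key <- function(h) paste(h$gene, h$motif_start, h$mirna, h$end)
  # triples unique
  expect_equal(anyDuplicated(key(h0)), 0)
  # wobble superset property
  expect_true(all(key(h0) %in% key(h1)))
  # every output satisfies both criteria
  expect_true(all(h1$stretch_len >= 7))
  expect_true(all(h1$dg37 <= -14))
  expect_true(all(h1$gu_count <= 1))
  expect_true(all(h0$gu_count == 0))
  # scan agrees with per-pair find_hit
  halves <- catalog_halves(ds$partition)
  slow <- do.call(rbind, lapply(seq_len(nrow(motifs)), function(i) {
    do.call(rbind, lapply(seq_len(nrow(halves)), function(j) {
      find_hit(motifs[i, ], halves[j, ], p1)
    }))
  }))
  expect_gt(nrow(h1), 0)
  expect_equal(nrow(h1), nrow(slow))
  expect_setequal(key(h1), paste(slow$gene, slow$motif_start, slow$mirna,
                                 slow$end))
  # rerunning the scan reproduces it byte for byte
  expect_identical(h1, scan_hits(motifs, ds$partition, p1))
})
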