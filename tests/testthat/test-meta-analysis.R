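klf9_windows <- function() {
  tab <- read.delim(extdata("klf9_uaugs.tsv"), stringsAsFactors = FALSE)
  uaug_windows(tab$label, tab$sequence, gene_id = "KLF9")
}

snapshot_partition <- function() {
  recs <- read_mirna_fasta(extdata("mirna_snapshot_synthetic.fa"))
  classify_mirna_conservation(recs[recs$species_prefix == "hsa", ], recs)
}

test_that("window builder validates lengths and AUG placement", {
  w <- uaug_windows(c("w1", "w2"), c("CAUAAUGGGGU", "AUGCCCC"))
  expect_equal(w$aug_offset, c(4L, 0L))
  expect_error(uaug_windows("w", "AUGCC"), "7-11 nt")
  expect_error(uaug_windows("w", "CCCCCCCCC"), "no AUG")
  # mutants need no AUG and are flagged
  m <- uaug_windows("m7", "GAGAAAGCCGG", mutant = TRUE)
  expect_true(m$mutant)
  expect_true(is.na(m$aug_offset))
})

test_that("gene scan treats mutants through the generic search path", {
  part <- snapshot_partition()
  mut <- read.delim(extdata("klf9_mutants.tsv"), stringsAsFactors = FALSE)
  hits <- scan_gene(windows = klf9_windows(), mutants = mut,
                    partition = part, gene_id = "KLF9")
  # a mutant window's hits equal a wild-type-style scan of the same string
  m7 <- hits[hits$label == "m7", ]
  direct <- scan_hits(
    data.frame(gene_id = "KLF9", aug_start = 0L, sequence = "GAGAAAGCCGG",
               length = 11L, aug_offset = NA, conserved = NA, mutant = TRUE),
    part, search_params(max_gu_5p = 0, max_gu_3p = 1))
  expect_equal(sort(paste(m7$mirna, m7$end)),
               sort(paste(direct$mirna, direct$end)))
  # only conserved miRNAs are scanned
  expect_true(all(hits$mirna %in%
                    c(part$conserved$name,
                      sub("^hsa", "mmu", part$conserved$name))))
})

test_that("expression join flags hits expressed / absent / unknown", {
  expression <- read_expression_table(extdata("expression_evidence.tsv"))
  hits <- data.frame(gene = "MDM2", label = "MDM2-uAUG1",
                     motif = "AAAGAUGGAGC", motif_start = 0L,
                     conserved_motif = NA,
                     mirna = c("hsa-miR-363", "hsa-miR-556-3p",
                               "hsa-miR-unknown"),
                     end = "3p", mirna_conserved = TRUE, stretch_len = 8L,
                     gu_count = 0L, dg37 = -15, stringsAsFactors = FALSE)
  j <- join_expression(hits, expression, "HeLa")
  expect_equal(j$expressed, c(TRUE, FALSE, NA))
  expect_equal(j$source[1], "ref42")
  # empty evidence: everything unknown
  j0 <- join_expression(hits, expression[0, ], "HeLa")
  expect_true(all(is.na(j0$expressed)))
})

test_that("gene report emits None rows and fold association counts", {
  windows <- uaug_windows(c("u1", "u2"), c("UAUCAUGUUAA", "GGCGAUGCCGC"))
  hits <- data.frame(gene = "toy", label = "u2", motif = "GGCGAUGCCGC",
                     motif_start = 1L, conserved_motif = NA,
                     mirna = "hsa-miR-strong", end = "3p",
                     mirna_conserved = TRUE, stretch_len = 9L,
                     gu_count = 0L, dg37 = -18, mutant = FALSE,
                     stringsAsFactors = FALSE)
  expression <- data.frame(mirna = "hsa-miR-strong", cell_line = "HeLa",
                           expressed = TRUE, source = "synthetic")
  ann <- data.frame(label = c("u1", "u2"), fold = c(1L, 3L))
  rep <- gene_report(hits, windows, ann, expression, "HeLa")
  expect_equal(nrow(rep), 2)
  expect_true(is.na(rep$mirna[rep$label == "u1"]))  # the "None" row
  fa <- summarize_fold_association(rep)
  expect_equal(fa$fold, c(1L, 3L))
  expect_equal(fa$n_motifs, c(1L, 1L))
  expect_equal(fa$n_with_expressed_hit, c(0L, 1L))

  # without fold annotations the summary is empty
  rep2 <- gene_report(hits, windows)
  expect_equal(nrow(summarize_fold_association(rep2)), 0)
})

test_that("least-repressive uAUGs in the transcribed gene fixture lack expressed hits", {
  tab <- read.delim(extdata("genes_repression_uaugs.tsv"),
                    stringsAsFactors = FALSE)
  expression <- read_expression_table(extdata("expression_evidence.tsv"))
  part <- snapshot_partition()
  for (gene in unique(tab$gene)) {
    gt <- tab[tab$gene == gene, ]
    windows <- uaug_windows(gt$label, gt$sequence, gene_id = gene)
    hits <- scan_gene(windows = windows, partition = part, gene_id = gene)
    rep <- gene_report(hits, windows,
                       data.frame(label = gt$label, fold = gt$fold),
                       expression, gt$cell_line[1])
    fa <- summarize_fold_association(rep)
    if (1L %in% fa$fold) {
      expect_equal(fa$n_with_expressed_hit[fa$fold == 1L], 0L,
                   label = gene)
    }
  }
})

test_that("gene reports are byte-identical across reruns", {
  part <- snapshot_partition()
  mut <- read.delim(extdata("klf9_mutants.tsv"), stringsAsFactors = FALSE)
  one <- function() {
    hits <- scan_gene(windows = klf9_windows(), mutants = mut,
                      partition = part, gene_id = "KLF9")
    gene_report(hits, klf9_windows())
  }
  expect_identical(one(), one())
})
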