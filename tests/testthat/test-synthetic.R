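small_params <- function(seed = 1, ...) {
  args <- utils::modifyList(list(seed = seed, n_chrom = 2, chrom_len = 2e6,
                                 n_genes = 50, identity_fraction = 0.1),
                            list(...))
  do.call(simulation_params, args)
}

test_that("generators are pure functions of (params, seed)", {
  p <- small_params(seed = 7)
  g1 <- simulate_genome(p); g2 <- simulate_genome(p)
  expect_identical(start(g1$genes), start(g2$genes))
  t1 <- simulate_truth(p, g1$genes); t2 <- simulate_truth(p, g2$genes)
  expect_identical(t1, t2)
  r1 <- simulate_mark_reads(p, g1$layout, g1$genes, t1)
  r2 <- simulate_mark_reads(p, g1$layout, g1$genes, t1)
  expect_identical(start(r1$reads[[1]]), start(r2$reads[[1]]))
  n1 <- simulate_grn(p, g1$genes, t1); n2 <- simulate_grn(p, g1$genes, t1)
  expect_identical(n1$edge_idx, n2$edge_idx)
  m1 <- simulate_motifs_loops(p, g1$layout, g1$genes, t1)
  m2 <- simulate_motifs_loops(p, g1$layout, g1$genes, t1)
  expect_identical(start(m1$sites), start(m2$sites))
  ## a different seed changes the draw
  g3 <- simulate_genome(small_params(seed = 8))
  expect_false(identical(start(g1$genes), start(g3$genes)))
})

test_that("simulated genomes keep genes apart by at least 25 kb", {
  g <- simulate_genome(small_params(seed = 3))
  for (ch in g$layout$chroms) {
    gg <- g$genes[as.character(seqnames(g$genes)) == ch]
    if (length(gg) > 1) {
      gaps <- start(gg)[-1] - end(gg)[-length(gg)] - 1
      expect_true(all(gaps >= 25000))
    }
  }
  expect_true(all(end(g$genes) <= g$layout$lengths[as.character(seqnames(g$genes))]))
  ## n_genes = 0: empty table, valid layout
  g0 <- simulate_genome(simulation_params(seed = 1, n_genes = 0))
  expect_length(g0$genes, 0)
  expect_s3_class(g0$layout, "genome_layout")
  ## infeasible packing errors out
  expect_error(simulate_genome(simulation_params(seed = 1, n_chrom = 1,
                                                 chrom_len = 1e6,
                                                 n_genes = 100)),
               "packing")
})

test_that("perfect cross-mark correlation plants identical widths across marks", {
  p <- small_params(seed = 5, cross_mark_correlation = 1)
  g <- simulate_genome(p)
  t <- simulate_truth(p, g$genes)
  w <- t$planted_breadth[t$planted_breadth[, 1] > 0, ]
  expect_true(all(abs(w - w[, 1]) <= 1))  # equal up to rounding
  ## independent marks decorrelate the log widths
  p0 <- small_params(seed = 5, cross_mark_correlation = 0, n_genes = 400,
                     n_chrom = 4, chrom_len = 4e6)
  g0 <- simulate_genome(p0)
  t0 <- simulate_truth(p0, g0$genes)
  ## sharp-peak genes share one base width, so any correlation must come
  ## from the latent factor alone
  sharp <- setdiff(t0$expressed_genes, t0$identity_genes)
  w0 <- t0$planted_breadth[sharp, ]
  r <- cor(log(w0[, 1]), log(w0[, 2]))
  expect_lt(abs(r), 0.35)
})

test_that("planted domains carry the expected Poisson read mass", {
  p <- small_params(seed = 9)
  g <- simulate_genome(p)
  t <- simulate_truth(p, g$genes)
  rd <- simulate_mark_reads(p, g$layout, g$genes, t)
  mk <- p$marks[1]
  id <- t$identity_genes[1]
  gene <- g$genes[g$genes$gene_id == id]
  w <- t$planted_breadth[id, mk]
  reads <- rd$reads[[mk]]
  near <- sum(as.character(seqnames(reads)) == as.character(seqnames(gene)) &
                start(reads) >= start(gene) - 16000 &
                end(reads) <= end(gene) + 16000)
  lam <- w / 1000 * p$reads_per_kb_signal
  expect_gt(near, lam - 4 * sqrt(lam) - 5)
  expect_lt(near, lam + 4 * sqrt(lam) + 20)
})

test_that("hub-structured GRNs concentrate edges on identity genes", {
  p <- small_params(seed = 13, n_genes = 200, chrom_len = 4e6, n_chrom = 2)
  g <- simulate_genome(p)
  t <- simulate_truth(p, g$genes)
  grn <- simulate_grn(p, g$genes, t)
  deg <- tabulate(as.vector(grn$edge_idx), nbins = length(grn$nodes))
  names(deg) <- grn$nodes
  hub_mean <- mean(deg[t$identity_genes])
  bg_mean <- mean(deg[setdiff(grn$nodes, t$identity_genes)])
  expect_gt(hub_mean, 4 * bg_mean)
  expect_true(all(t$identity_genes %in% grn$tfs))
})

test_that("loop overlap rates in the two conditions track their parameters", {
  p <- simulation_params(seed = 17, n_chrom = 4, chrom_len = 5e6,
                         n_genes = 300, identity_fraction = 0.2,
                         motif_background_rate = 0.05,
                         loop_overlap_rate_conditionA = 0.3,
                         loop_overlap_rate_conditionB = 0.05,
                         n_background_loops = 0)
  g <- simulate_genome(p)
  t <- simulate_truth(p, g$genes)
  ml <- simulate_motifs_loops(p, g$layout, g$genes, t)
  fa <- loop_overlap_fraction(ml$sites, ml$loops_A)
  fb <- loop_overlap_fraction(ml$sites, ml$loops_B)
  n <- length(ml$sites)
  sig_a <- sqrt(0.3 * 0.7 / n); sig_b <- sqrt(0.05 * 0.95 / n)
  expect_lt(abs(fa$percent / 100 - 0.3), 3 * sig_a + 0.02)
  expect_lt(abs(fb$percent / 100 - 0.05), 3 * sig_b + 0.02)
  expect_gt(fa$percent, fb$percent)
})

test_that("differential table respects the filter contract and identity placement", {
  p <- small_params(seed = 19, n_genes = 300, chrom_len = 6e6)
  g <- simulate_genome(p)
  t <- simulate_truth(p, g$genes)
  de <- simulate_de_table(p, g$genes, t)
  f <- filter_differential(read_back <- transform(de, fpkm_max = pmax(fpkm_wt, fpkm_ko)))
  expect_true(all(t$identity_genes %in% f$up))
  expect_equal(length(f$up), round(p$frac_up * 300))
  expect_equal(length(f$down), round(p$frac_down * 300))
  ## identity fold changes look like other upregulated fold changes
  lfc_id <- de$log2fc[de$gene_id %in% t$identity_genes]
  lfc_up <- de$log2fc[de$gene_id %in% setdiff(f$up, t$identity_genes)]
  expect_gt(suppressWarnings(ks.test(lfc_id, lfc_up))$p.value, 1e-4)
})

test_that("a written bundle reloads consistently through the file formats", {
  dir <- tempfile("bundle")
  p <- small_params(seed = 23)
  b <- simulate_bundle(p, dir)
  lay <- read_genome_layout(b$paths$genome)
  expect_equal(lay$lengths, b$layout$lengths)
  genes <- read_gene_models(b$paths$genes, "bed12", lay)
  expect_setequal(genes$gene_id, b$genes$gene_id)
  tags <- read_tags_bed(b$paths$marks[[1]], lay)
  expect_equal(length(tags), length(b$reads[[1]]))
  sets <- read_gmt(b$paths$pathways)
  expect_true(any(grepl("endothelial", names(sets))))
  truth <- jsonlite::read_json(b$paths$truth, simplifyVector = TRUE)
  expect_setequal(truth$identity_genes, b$truth$identity_genes)
})
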