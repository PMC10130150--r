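consensus_pwm <- function(consensus = "ACGTAC") {
  bases <- strsplit(consensus, "")[[1]]
  m <- matrix(0, 4, length(bases), dimnames = list(c("A", "C", "G", "T"), NULL))
  ## near-indicator columns (probabilities must sum to 1)
  for (j in seq_along(bases)) {
    m[, j] <- 0.01
    m[bases[j], j] <- 0.97
  }
  motif_pwm(m, name = "consensus")
}

test_that("an indicator PWM at its maximum score hits exactly the consensus", {
  pwm <- consensus_pwm("ACGTAC")
  maxscore <- sum(apply(pwm$log_odds, 2, max))
  seqs <- c(s1 = "TTTACGTACTTTTTTACGTACTT")
  hits <- scan_pwm(seqs, pwm, maxscore)
  fw <- hits[as.character(GenomicRanges::strand(hits)) == "+"]
  expect_equal(start(fw), c(4, 16))
  ## the reverse complement GTACGT appears on the minus strand at the same spots
  rc_hits <- scan_pwm(c(s1 = "TTGTACGTTT"), pwm, maxscore)
  expect_equal(as.character(GenomicRanges::strand(rc_hits)), "-")
  expect_equal(start(rc_hits), 3)
})

test_that("reverse-complementing the sequence flips strands, not the site set", {
  set.seed(19)
  pwm <- consensus_pwm("GATTAC")
  s <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  h1 <- scan_pwm(c(x = s), pwm, 5)
  h2 <- scan_pwm(c(x = rc), pwm, 5)
  expect_equal(length(h1), length(h2))
  ## positions map via L - (start + w - 1) + 1 with strands flipped
  remapped <- sort(400 - (start(h2) + pwm$width - 1) + 1)
  expect_equal(sort(start(h1)), remapped)
  s1 <- as.character(GenomicRanges::strand(h1))
  s2 <- as.character(GenomicRanges::strand(h2))
  expect_equal(sum(s1 == "+"), sum(s2 == "-"))
  expect_equal(sum(s1 == "-"), sum(s2 == "+"))
})

test_that("scanning equals the exhaustive per-window scorer (with N handling)", {
  set.seed(29)
  pwm <- consensus_pwm("ACGTA")
  chars <- sample(c("A", "C", "G", "T", "N"), 600, TRUE,
                  prob = c(0.24, 0.24, 0.24, 0.24, 0.04))
  s <- paste(chars, collapse = "")
  got <- scan_pwm(c(x = s), pwm, 3)
  ref <- oracle_scan(s, pwm, 3)
  key_got <- paste(start(got), as.character(GenomicRanges::strand(got)))
  key_ref <- paste(ref$start, ref$strand)
  expect_setequal(key_got, key_ref)
  expect_equal(got$score[order(key_got)], ref$score[order(key_ref)],
               tolerance = 1e-12)
})

test_that("MEME-minimal PWM files parse with background frequencies", {
  path <- tmpfile_with(c(
    "MEME version 4", "", "ALPHABET= ACGT", "",
    "Background letter frequencies",
    "A 0.30 C 0.20 G 0.20 T 0.30", "",
    "MOTIF TESTMOTIF",
    "letter-probability matrix: alength= 4 w= 3 nsites= 20 E= 0",
    " 0.90 0.05 0.03 0.02",
    " 0.05 0.85 0.05 0.05",
    " 0.10 0.10 0.10 0.70"), ext = ".meme")
  pwm <- read_meme_pwm(path)
  expect_equal(pwm$name, "TESTMOTIF")
  expect_equal(pwm$width, 3)
  expect_equal(pwm$background, c(0.3, 0.2, 0.2, 0.3))
  expect_equal(unname(pwm$mat["A", 1]), 0.9)
  ## FASTA input path: scan via Biostrings
  fa <- tmpfile_with(c(">s1", "TTACTTT"), ext = ".fa")
  hits <- scan_pwm(fa, pwm, sum(apply(pwm$log_odds, 2, max)) - 1e-9)
  expect_equal(start(hits[as.character(GenomicRanges::strand(hits)) == "+"]), 3)
})

test_that("promoter motif window is strand-aware, upstream-only, 5 kb", {
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(50001, 120001),
                                                           c(60000, 130000)),
                                  strand = c("+", "-"))
  genes$gene_id <- c("plus", "minus")
  site_at <- function(pos) GenomicRanges::GRanges("chr1",
                                                  IRanges::IRanges(pos, pos + 9))
  ## 4,900 bp upstream of the + TSS (50001): included
  expect_equal(promoter_motif_gene_set(site_at(45101), genes), "plus")
  ## 5,100 bp upstream: excluded
  expect_length(promoter_motif_gene_set(site_at(44800), genes), 0)
  ## downstream of the + TSS: excluded
  expect_length(promoter_motif_gene_set(site_at(50500), genes), 0)
  ## minus-strand gene: upstream means right of the TSS at 130000
  expect_equal(promoter_motif_gene_set(site_at(133000), genes), "minus")
  expect_length(promoter_motif_gene_set(site_at(128000), genes), 0)
})

test_that("cumulative distance enrichment is monotone and saturates at fold 1", {
  set.seed(37)
  n <- 60
  starts <- seq(2e5, by = 1e5, length.out = 2 * n)
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(starts, starts + 5000),
                                  strand = "+")
  genes$gene_id <- sprintf("g%03d", seq_along(genes))
  targets <- genes$gene_id[seq_len(n)]
  background <- genes$gene_id[n + seq_len(n)]
  ## plant sites within 2 kb of every target TSS, none near background
  tpos <- starts[seq_len(n)] + sample(-2000:2000, n, TRUE)
  sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(tpos, tpos + 9))
  grid <- c(2000, 10000, 50000, 1e8)
  cur <- cumulative_distance_enrichment(sites, genes, targets, background, grid)
  expect_true(all(diff(cur$n_target_hit) >= 0))
  expect_true(all(diff(cur$n_background_hit) >= 0))
  expect_equal(cur$n_target_hit[1], n)
  expect_lt(cur$p[1], 1e-6)
  ## genome-covering distance: both hit rates 1, fold 1
  expect_equal(cur$fold[4], 1)
  expect_equal(cur$n_background_hit[4], n)
  expect_error(cumulative_distance_enrichment(sites, genes, targets,
                                              character(0), grid),
               "background")
  expect_error(cumulative_distance_enrichment(sites, genes, targets,
                                              c(targets[1], background), grid),
               "disjoint")
})

test_that("loop overlap counts half-open boundaries correctly and once per site", {
  ## 0-based site [100,150) vs anchor [140,200): overlapping
  a <- loop_set(GenomicRanges::GRanges("chr1", IRanges::IRanges(141, 200)),
                GenomicRanges::GRanges("chr1", IRanges::IRanges(5141, 5200)))
  s_in <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 150))
  s_out <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 140))
  expect_equal(loop_overlap_fraction(s_in, a)$n_overlapping, 1)
  expect_equal(loop_overlap_fraction(s_out, a)$n_overlapping, 0)
  ## a site touching both anchors of both of two duplicate loops counts once
  dup <- loop_set(c(a$anchor1, a$anchor1), c(a$anchor2, a$anchor2))
  both <- c(s_in, GenomicRanges::GRanges("chr1", IRanges::IRanges(5150, 5160)))
  f <- loop_overlap_fraction(both, dup)
  expect_equal(f$n_overlapping, 2)
  expect_equal(f$percent, 100)
  expect_error(loop_overlap_fraction(GenomicRanges::GRanges(), a), "sites")
})

test_that("loop overlap is invariant to loop duplication and anchor order", {
  set.seed(43)
  s <- sample.int(1e6, 300)
  sites <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s, s + 9))
  a1p <- sample.int(1e6, 40); a2p <- sample.int(1e6, 40)
  l1 <- loop_set(GenomicRanges::GRanges("chr1", IRanges::IRanges(a1p, a1p + 999)),
                 GenomicRanges::GRanges("chr1", IRanges::IRanges(a2p, a2p + 999)))
  base <- loop_overlap_fraction(sites, l1)
  swapped <- loop_set(GenomicRanges::GRanges("chr1", IRanges::IRanges(a2p, a2p + 999)),
                      GenomicRanges::GRanges("chr1", IRanges::IRanges(a1p, a1p + 999)))
  expect_equal(loop_overlap_fraction(sites, swapped), base)
  dup <- loop_set(c(l1$anchor1, l1$anchor1), c(l1$anchor2, l1$anchor2))
  expect_equal(loop_overlap_fraction(sites, dup), base)
})

test_that("two-sample Poisson test matches enumeration and its symmetries", {
  expect_equal(two_sample_poisson_test(7, 1000, 7, 1000), 1)
  expect_equal(two_sample_poisson_test(0, 100, 0, 50), 1)
  p <- two_sample_poisson_test(132, 1000, 59, 1000)
  expect_equal(p, oracle_binom_p(132, 191, 0.5), tolerance = 1e-12)
  expect_lt(p, 1e-6)
  ## exchanging samples leaves p unchanged
  expect_equal(two_sample_poisson_test(59, 1000, 132, 1000), p,
               tolerance = 1e-12)
  ## unequal exposures against the oracle
  p2 <- two_sample_poisson_test(30, 400, 50, 1600)
  expect_equal(p2, oracle_binom_p(30, 80, 400 / 2000), tolerance = 1e-12)
  expect_error(two_sample_poisson_test(10, 5, 1, 10), "k <= n")
})
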