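test_that("reads extend 200 bp from their 5' end in the strand direction", {
  lay <- genome_layout("chr1", 1e4)
  ## 0-based [100,136) + and [500,536) - in 1-based closed form
  reads <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(101, 501), c(136, 536)),
                                  strand = c("+", "-"))
  ext <- extend_reads(reads, 200, lay)
  expect_equal(start(ext), c(101, 337))
  expect_equal(end(ext), c(300, 536))

  ## minus read near the chromosome start clips at 1
  near0 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 86), strand = "-")
  expect_equal(start(extend_reads(near0, 200, lay)), 1)
  expect_equal(end(extend_reads(near0, 200, lay)), 86)

  ## plus read near the chromosome end clips at the length
  nearE <- GenomicRanges::GRanges("chr1", IRanges::IRanges(9950, 9985), strand = "+")
  expect_equal(end(extend_reads(nearE, 200, lay)), 1e4)

  star <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 36), strand = "*")
  expect_error(extend_reads(star, 200, lay), "strand")
})

test_that("binned coverage is the mean per-bp depth and conserves read bp", {
  lay <- genome_layout("chr1", 1000)
  one <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 300), strand = "+")
  tr <- coverage_track(one, lay, 10)
  expect_equal(tr$values$chr1[11:30], rep(1, 20))
  expect_equal(sum(tr$values$chr1 > 0), 20)

  two <- c(one, one)
  tr2 <- coverage_track(two, lay, 10)
  expect_equal(tr2$values$chr1[11:30], rep(2, 20))

  ## conservation: sum(bins) * bin_size = total covered bp, off-grid reads too
  set.seed(3)
  s <- sample.int(900, 200)
  rnd <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(s, s + sample.int(80, 200, replace = TRUE)),
                                strand = "+")
  trr <- coverage_track(rnd, lay, 10)
  expect_equal(sum(trr$values$chr1) * 10, sum(width(rnd)))
})

test_that("depth normalization scales bins by norm_total / n_reads", {
  tr <- make_track(list(chr1 = c(1, 2, 0, 4)))
  up <- normalize_track(tr, 5e6, 25e6)
  expect_equal(up$values$chr1, c(5, 10, 0, 20))
  id <- normalize_track(tr, 25e6, 25e6)
  expect_equal(id$values$chr1, tr$values$chr1)
  expect_error(normalize_track(tr, 0), "n_mapped_reads")
})

test_that("input subtraction clamps at zero and requires a shared grid", {
  chip <- make_track(list(chr1 = c(3, 1, 5)))
  input <- make_track(list(chr1 = c(1, 2, 0)))
  out <- subtract_input(chip, input)
  expect_equal(out$values$chr1, c(2, 0, 5))
  zero <- make_track(list(chr1 = numeric(3)))
  expect_equal(subtract_input(chip, zero)$values$chr1, chip$values$chr1)
  other <- make_track(list(chr1 = numeric(4)))
  expect_error(subtract_input(chip, other), "grids")
})

test_that("seed-and-extend segmentation matches hand-derived cases", {
  p <- caller_params(background_lambda = 1)
  ## lone spike: neighbours at 1 have tail P(X>=1|1) = 0.63 > 1e-3
  t1 <- make_track(list(chr1 = c(1, 1, 50, 1, 1)))
  r1 <- call_enriched_regions(t1, p)
  expect_length(r1, 1)
  expect_equal(width(r1), 10)
  expect_equal(start(r1), 21)

  ## 9-flanked spike: P(X>=9|1) ~ 1.1e-7 <= 1e-3, so one 30-bp region
  t2 <- make_track(list(chr1 = c(0, 9, 50, 9, 0)))
  r2 <- call_enriched_regions(t2, p)
  expect_length(r2, 1)
  expect_equal(width(r2), 30)
  expect_equal(r2$max_signal, 50)
  expect_equal(r2$seed_p, ppois(49, 1, lower.tail = FALSE))

  ## uniform track at lambda: nothing passes 1e-5
  t3 <- make_track(list(chr1 = rep(1, 100)))
  expect_length(call_enriched_regions(t3, p), 0)

  ## empty track: empty result, not an error
  t4 <- make_track(list(chr1 = numeric(50)))
  expect_length(call_enriched_regions(t4, caller_params()), 0)
})

test_that("peak calls are invariant to k-fold read duplication after renormalization", {
  lay <- genome_layout("chr1", 1e5)
  set.seed(7)
  s <- sample.int(9e4, 400)
  reads <- GenomicRanges::GRanges("chr1", IRanges::IRanges(s, s + 35),
                                  strand = sample(c("+", "-"), 400, TRUE))
  peak_s <- sample.int(500, 150) + 40000
  reads <- c(reads, GenomicRanges::GRanges("chr1",
                                           IRanges::IRanges(peak_s, peak_s + 35),
                                           strand = "+"))
  base <- call_regions_from_tags(reads, lay,
                                 caller_params(norm_total = length(reads)))
  for (k in c(2, 4)) {
    dup <- rep(reads, k)
    res <- call_regions_from_tags(dup, lay,
                                  caller_params(norm_total = length(reads)))
    expect_equal(start(res$regions), start(base$regions))
    expect_equal(end(res$regions), end(base$regions))
  }
})

test_that("raising a bin never removes a region or shrinks the one containing it", {
  set.seed(21)
  for (rep in 1:20) {
    vals <- rpois(200, 1)
    spikes <- sample(200, 3)
    vals[spikes] <- vals[spikes] + rpois(3, 40)
    tr <- make_track(list(chr1 = vals))
    p <- caller_params(background_lambda = 1)
    before <- call_enriched_regions(tr, p)
    i <- sample(200, 1)
    vals2 <- vals
    vals2[i] <- vals2[i] + sample(1:50, 1)
    after <- call_enriched_regions(make_track(list(chr1 = vals2)), p)
    expect_gte(length(after), length(before))
    bin_start <- (i - 1) * 10 + 1
    containing <- which(start(after) <= bin_start & end(after) >= bin_start)
    for (j in seq_along(before)) {
      if (start(before)[j] <= bin_start && end(before)[j] >= bin_start) {
        expect_true(length(containing) == 1)
        expect_lte(start(after)[containing], start(before)[j])
        expect_gte(end(after)[containing], end(before)[j])
      }
    }
  }
})

test_that("p_ext = p_seed degenerates to thresholded-run segmentation", {
  set.seed(5)
  lambda <- 2
  kmin <- qpois(1e-4, lambda, lower.tail = FALSE) + 1
  for (rep in 1:10) {
    vals <- rpois(300, lambda)
    spikes <- sample(300, 10)
    vals[spikes] <- vals[spikes] + rpois(10, 25)
    p <- caller_params(p_seed = 1e-4, p_ext = 1e-4, background_lambda = lambda)
    got <- call_enriched_regions(make_track(list(chr1 = vals)), p)
    ## run-length oracle on the plain count threshold
    r <- rle(floor(vals + 0.5) >= kmin)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    exp_bins <- cbind(starts[r$values], ends[r$values])
    expect_equal(start(got), (exp_bins[, 1] - 1) * 10 + 1)
    expect_equal(end(got), exp_bins[, 2] * 10)
  }
})

test_that("regions are disjoint, sorted, and bounded by the genome", {
  set.seed(9)
  vals <- rpois(500, 1)
  vals[sample(500, 20)] <- 60
  tr <- make_track(list(chr1 = vals))
  r <- call_enriched_regions(tr, caller_params(background_lambda = 1))
  expect_true(all(diff(start(r)) > 0))
  if (length(r) > 1) expect_true(all(start(r)[-1] > end(r)[-length(r)]))
  expect_lte(sum(width(r)), 5000)
  expect_true(all(width(r) %% 10 == 0))
})
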