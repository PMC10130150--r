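## Independent reference implementations ("oracles") used to validate the
## package's fast paths.  These deliberately share no code with R/: the
## Poisson tail is computed by direct mass summation, Fisher and binomial
## two-tailed p values by exhaustive enumeration over lchoose/dbinom, the
## segmentation by per-bin labeling and a linear scan, PWM scanning by an
## explicit per-window double loop, and overlaps by a quadratic scan.

## Poisson upper tail P(X >= k) by direct summation of masses
oracle_pois_tail <- function(k, lambda) {
  if (k <= 0) return(1)
  j <- seq(k, k + max(200, ceiling(10 * lambda)))
  sum(exp(-lambda + j * log(lambda) - lfactorial(j)))
}

## brute-force seed/extend/merge segmentation on a bin-value vector;
## returns a matrix of (first_bin, last_bin) rows
oracle_call_bins <- function(values, lambda, p_seed = 1e-5, p_ext = 1e-3) {
  k <- floor(values + 0.5)
  uk <- sort(unique(k))
  tail_p <- vapply(uk, oracle_pois_tail, numeric(1), lambda = lambda)[match(k, uk)]
  seed <- tail_p <= p_seed
  ext <- tail_p <= p_ext
  regions <- NULL
  i <- 1
  n <- length(values)
  while (i <= n) {
    if (ext[i]) {
      j <- i
      while (j < n && ext[j + 1]) j <- j + 1
      if (any(seed[i:j])) regions <- rbind(regions, c(i, j))
      i <- j + 1
    } else i <- i + 1
  }
  if (is.null(regions)) matrix(numeric(0), ncol = 2) else regions
}

## exhaustive two-tailed Fisher p for the 2x2 table rbind(c(a, b), c(c, d)),
## by enumerating all hypergeometric masses; ties within relative 1e-7 are
## included, matching the standard minimum-likelihood convention
oracle_fisher_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  x <- max(0, k - n):min(k, m)
  logp <- lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)
  obs <- logp[x == a]
  min(1, sum(exp(logp[logp <= obs + log(1 + 1e-7)])))
}

## exhaustive two-tailed binomial p at observed k of n with success prob p
oracle_binom_p <- function(k, n, p) {
  mass <- dbinom(0:n, n, p)
  min(1, sum(mass[mass <= mass[k + 1] * (1 + 1e-7)]))
}

## exhaustive PWM scan: score every window of both strands one base at a
## time; returns data.frame(start, strand, score) for score >= threshold
oracle_scan <- function(seq, pwm, threshold) {
  revcomp <- function(s) chartr("ACGTN", "TGCAN",
                                paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  score1 <- function(s, lom) {
    ch <- strsplit(s, "")[[1]]
    tot <- 0
    for (j in seq_along(ch)) {
      if (ch[j] %in% c("A", "C", "G", "T")) tot <- tot + lom[ch[j], j]
    }
    tot
  }
  w <- pwm$width
  L <- nchar(seq)
  out <- NULL
  for (s in seq_len(L - w + 1)) {
    win <- substr(seq, s, s + w - 1)
    fs <- score1(win, pwm$log_odds)
    if (fs >= threshold) out <- rbind(out, data.frame(start = s, strand = "+",
                                                      score = fs))
    rs <- score1(revcomp(win), pwm$log_odds)
    if (rs >= threshold) out <- rbind(out, data.frame(start = s, strand = "-",
                                                      score = rs))
  }
  if (is.null(out)) data.frame(start = integer(0), strand = character(0),
                               score = numeric(0))
  else out[order(out$start, out$strand), ]
}

## quadratic interval-overlap scan (1-based closed coordinates)
oracle_overlaps_any <- function(chrom_a, s_a, e_a, chrom_b, s_b, e_b) {
  vapply(seq_along(s_a), function(i) {
    any(chrom_b == chrom_a[i] & s_b <= e_a[i] & e_b >= s_a[i])
  }, logical(1))
}

## exhaustive count of length-2 simple paths u - g - w centered on each node
oracle_path_counts <- function(edge_mat, n_nodes) {
  adj <- matrix(FALSE, n_nodes, n_nodes)
  adj[edge_mat] <- TRUE
  adj[edge_mat[, 2:1, drop = FALSE]] <- TRUE
  out <- numeric(n_nodes)
  for (g in seq_len(n_nodes)) {
    nb <- which(adj[g, ])
    cnt <- 0
    for (u in nb) for (w in nb) if (u < w) cnt <- cnt + 1
    out[g] <- cnt
  }
  out
}

## build a signal_track from a plain list of bin-value vectors
make_track <- function(values, bin_size = 10) {
  if (is.null(names(values)))
    names(values) <- sprintf("chr%d", seq_along(values))
  layout <- genome_layout(names(values), lengths(values) * bin_size)
  signal_track(values, layout, bin_size)
}

## random 2x2 table with total N; returns c(a, b, c, d)
random_table <- function(N) {
  m <- sample(1:(N - 1), 1)            # top margin
  k <- sample(1:(N - 1), 1)            # set margin
  lo <- max(0, k - (N - m))
  hi <- min(k, m)
  a <- sample(lo:hi, 1)
  c(a, m - a, k - a, N - m - k + a)
}

## write lines to a temp file and return its path
tmpfile_with <- function(lines, ext = ".bed") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
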