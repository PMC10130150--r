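## Motif machinery: MEME-minimal PWM parsing, log-odds scanning of both
## strands, promoter-window motif gene sets, and cumulative motif-to-TSS
## distance enrichment.

#' Position weight matrix constructor
#'
#' @param mat 4 x w numeric matrix of per-position base probabilities, rows
#'   A, C, G, T; every column must sum to 1 (tolerance 1e-9).
#' @param background background base frequencies (A, C, G, T).
#' @param name motif identifier.
#' @param pseudocount probability mass added to every cell before the
#'   log-odds transform (must be > 0).
#' @return Object of class `motif_pwm` with a precomputed `log_odds`
#'   (log2) matrix.
#' @export
motif_pwm <- function(mat, background = rep(0.25, 4), name = "motif",
                      pseudocount = 1e-3) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4) stop("PWM must have 4 rows (A, C, G, T)")
  rownames(mat) <- c("A", "C", "G", "T")
  if (any(abs(colSums(mat) - 1) > 1e-9))
    stop("PWM columns must each sum to 1")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  if (length(background) != 4 || abs(sum(background) - 1) > 1e-6)
    stop("background must be 4 frequencies summing to 1")
  p <- (mat + pseudocount) / (1 + 4 * pseudocount)
  lo <- log2(p / background)
  structure(list(mat = mat, background = background, name = name,
                 pseudocount = pseudocount, log_odds = lo,
                 width = ncol(mat)),
            class = "motif_pwm")
}

#' @export
print.motif_pwm <- function(x, ...) {
  cat(sprintf("motif_pwm '%s': width %d, max log-odds %.2f\n",
              x$name, x$width, sum(apply(x$log_odds, 2, max))))
  invisible(x)
}

#' Read a PWM from MEME-minimal text
#'
#' Parses the first motif of a minimal MEME file: `MOTIF` name line,
#' optional `Background letter frequencies` line, and the
#' `letter-probability matrix` block.
#'
#' @param path input file.
#' @param pseudocount see [motif_pwm()].
#' @return A [motif_pwm()].
#' @export
read_meme_pwm <- function(path, pseudocount = 1e-3) {
  lines <- readLines(path, warn = FALSE)
  bg <- rep(0.25, 4)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i)) {
    toks <- strsplit(trimws(lines[bg_i[1] + 1]), "\\s+")[[1]]
    freq <- suppressWarnings(as.numeric(toks))
    labs <- toks[is.na(freq)]
    vals <- freq[!is.na(freq)]
    if (length(labs) >= 4 && length(vals) >= 4)
      bg <- vals[match(c("A", "C", "G", "T"), labs)]
  }
  m_i <- grep("^MOTIF", lines)
  if (!length(m_i)) stop(sprintf("%s: no MOTIF record", path))
  name <- strsplit(trimws(lines[m_i[1]]), "\\s+")[[1]][2]
  lp_i <- grep("^letter-probability matrix", lines)
  lp_i <- lp_i[lp_i > m_i[1]][1]
  if (is.na(lp_i)) stop(sprintf("%s: no letter-probability matrix", path))
  w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[lp_i]))
  rows <- lapply(lines[(lp_i + 1):(lp_i + w)], function(l)
    as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
  if (any(lengths(rows) != 4))
    stop(sprintf("%s: letter-probability rows must have 4 columns", path))
  motif_pwm(t(do.call(rbind, rows)), background = bg, name = name,
            pseudocount = pseudocount)
}

encode_dna <- function(s) {
  x <- match(strsplit(toupper(s), "", fixed = TRUE)[[1]],
             c("A", "C", "G", "T"))
  x
}

## score every window start on one strand; N (NA code) contributes 0
window_scores <- function(code, lom) {
  w <- ncol(lom)
  n <- length(code) - w + 1
  if (n < 1) return(numeric(0))
  sc <- numeric(n)
  for (j in seq_len(w)) {
    v <- unname(lom[, j][code[j:(j + n - 1)]])
    v[is.na(v)] <- 0
    sc <- sc + v
  }
  sc
}

#' Scan sequences for motif instances
#'
#' Scores every window of both strands with the PWM's log-2 odds against the
#' background and reports windows scoring at or above `threshold`.  Sites
#' are reported in forward-strand coordinates; `N` bases score as
#' background (log-odds contribution 0).
#'
#' @param sequences a named character vector, `DNAStringSet`, or path to a
#'   FASTA file.
#' @param pwm a [motif_pwm()].
#' @param threshold minimum log2-odds score for a reported site.
#' @return `GRanges` (seqnames = sequence names) with `score` and strand.
#' @export
scan_pwm <- function(sequences, pwm, threshold) {
  if (is.character(sequences) && length(sequences) == 1 &&
      file.exists(sequences))
    sequences <- readDNAStringSet(sequences)
  if (inherits(sequences, "DNAStringSet")) {
    nms <- names(sequences)
    sequences <- as.character(sequences)
    names(sequences) <- nms
  }
  if (is.null(names(sequences))) stop("sequences must be named")
  lom <- pwm$log_odds
  lom_rc <- lom[4:1, ncol(lom):1]  # reverse complement scan on fwd coords
  rownames(lom_rc) <- c("A", "C", "G", "T")
  out <- lapply(names(sequences), function(nm) {
    code <- encode_dna(sequences[[nm]])
    fw <- window_scores(code, lom)
    rv <- window_scores(code, lom_rc)
    hf <- which(fw >= threshold)
    hr <- which(rv >= threshold)
    if (!length(hf) && !length(hr)) return(NULL)
    GRanges(nm, IRanges(c(hf, hr), width = pwm$width),
            strand = rep(c("+", "-"), c(length(hf), length(hr))),
            score = c(fw[hf], rv[hr]))
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) {
    gr <- GRanges()
    gr$score <- numeric(0)
    return(gr)
  }
  BiocGenerics::sort(combine_granges(out, names(sequences)),
                     ignore.strand = TRUE)
}

#' Genes with a motif site in the upstream promoter window
#'
#' A gene is included when at least one site overlaps the strand-aware
#' window from 5 kb upstream up to (but excluding) the TSS.
#'
#' @param sites motif-site `GRanges`.
#' @param genes gene-model `GRanges` with `gene_id`.
#' @param window upstream window size in bp (default 5000).
#' @return character vector of gene ids.
#' @export
promoter_motif_gene_set <- function(sites, genes, window = 5000) {
  if (!length(genes)) return(character(0))
  tss <- gene_tss(genes)
  minus <- as.character(strand(genes)) == "-"
  ws <- ifelse(minus, tss + 1, tss - window)
  we <- ifelse(minus, tss + window, tss - 1)
  ok <- we >= 1 & ws <= we
  ws <- pmax(ws, 1)
  win <- GRanges(seqnames(genes)[ok], IRanges(ws[ok], we[ok]))
  win$gene_id <- genes$gene_id[ok]
  hits <- findOverlaps(win, sites, ignore.strand = TRUE)
  sort(unique(win$gene_id[queryHits(hits)]))
}

#' Cumulative motif-to-TSS distance enrichment
#'
#' For each distance `d` of an ascending grid, genes are dichotomized by
#' whether a motif site lies within `d` bp of their TSS (unsigned, either
#' side, 0 when overlapping) and the 2x2 table target-vs-background x
#' hit-vs-not is tested with the two-tailed Fisher exact test.  The curve is
#' cumulative in `d`.
#'
#' @param sites motif-site `GRanges`.
#' @param genes gene-model `GRanges` with `gene_id`.
#' @param target_genes,background_genes disjoint character vectors of gene
#'   ids present in `genes`.
#' @param distance_grid ascending distances in bp.
#' @return data.frame with columns `distance`, `n_target_hit`,
#'   `n_background_hit`, `fold`, `p`.
#' @export
cumulative_distance_enrichment <- function(sites, genes, target_genes,
                                           background_genes,
                                           distance_grid = 10^seq(3, 6, 0.5)) {
  if (!length(background_genes)) stop("background gene set is empty")
  if (length(intersect(target_genes, background_genes)))
    stop("target and background gene sets must be disjoint")
  if (is.unsorted(distance_grid)) stop("distance_grid must be ascending")
  tss <- tss_granges(genes)
  dmin <- rep(Inf, length(genes))
  if (length(sites)) {
    nh <- distanceToNearest(tss, sites, ignore.strand = TRUE)
    dmin[queryHits(nh)] <- mcols(nh)$distance
  }
  names(dmin) <- genes$gene_id
  dt <- dmin[target_genes]
  db <- dmin[background_genes]
  if (any(is.na(dt)) || any(is.na(db)))
    stop("target/background gene absent from the gene table")
  nt <- length(dt); nb <- length(db)
  rows <- lapply(distance_grid, function(d) {
    ht <- sum(dt <= d); hb <- sum(db <= d)
    tab <- matrix(c(ht, nt - ht, hb, nb - hb), nrow = 2)
    p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
    fold <- if (hb == 0) Inf else (ht / nt) / (hb / nb)
    data.frame(distance = d, n_target_hit = ht, n_background_hit = hb,
               fold = fold, p = p)
  })
  do.call(rbind, rows)
}
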