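## Broad-domain calling from aligned tags: strand-directed read extension,
## binned mean coverage, depth normalization, input subtraction, and
## two-threshold Poisson seed-and-extend segmentation of enriched regions.

#' Signal track constructor
#'
#' A binned per-chromosome signal: bin `i` covers base pairs
#' `[(i-1)*bin_size+1, i*bin_size]`.  A trailing partial bin is treated as a
#' full bin for segmentation purposes.
#'
#' @param values named list of non-negative numeric vectors, one per
#'   chromosome.
#' @param layout a [genome_layout()].
#' @param bin_size bin width in bp (default 10).
#' @return An object of class `signal_track` with elements `values`,
#'   `bin_size`, `layout`, `total_signal`.
#' @export
signal_track <- function(values, layout, bin_size = 10) {
  if (!setequal(names(values), layout$chroms))
    stop("track chromosomes must match the genome layout")
  values <- values[layout$chroms]
  nbin <- ceiling(layout$lengths / bin_size)
  ok <- lengths(values) == nbin
  if (!all(ok))
    stop(sprintf("chromosome '%s': %d bins supplied, %d expected",
                 layout$chroms[!ok][1], lengths(values)[!ok][1],
                 nbin[!ok][1]))
  if (any(vapply(values, function(v) any(v < 0), logical(1))))
    stop("signal values must be non-negative")
  structure(list(values = values, bin_size = bin_size, layout = layout,
                 total_signal = sum(vapply(values, sum, numeric(1)))),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track: %d chromosome(s), bin %d bp, total signal %.4g\n",
              length(x$values), x$bin_size, x$total_signal))
  invisible(x)
}

#' Caller parameters
#'
#' Bundles the segmentation constants: 200-bp 3' read extension, depth
#' normalization to 25 million mapped reads, 10-bp bins, Poisson tail
#' thresholds 1e-5 for seeding and 1e-3 for extension.
#'
#' @param extend_len read extension length in bp.
#' @param norm_total depth-normalization target in mapped reads.
#' @param p_seed Poisson upper-tail threshold nucleating a region.
#' @param p_ext laxer tail threshold through which seeds extend
#'   (`p_ext >= p_seed`).
#' @param bin_size bin width in bp.
#' @param background_lambda expected signal per bin under background; when
#'   `NULL` it is estimated as the genome-wide mean bin value of the track
#'   being segmented.
#' @return list of class `caller_params`.
#' @export
caller_params <- function(extend_len = 200, norm_total = 25e6,
                          p_seed = 1e-5, p_ext = 1e-3, bin_size = 10,
                          background_lambda = NULL) {
  if (extend_len <= 0) stop("extend_len must be > 0")
  if (p_ext < p_seed) stop("p_ext must be >= p_seed")
  if (bin_size <= 0) stop("bin_size must be > 0")
  structure(list(extend_len = extend_len, norm_total = norm_total,
                 p_seed = p_seed, p_ext = p_ext, bin_size = bin_size,
                 background_lambda = background_lambda),
            class = "caller_params")
}

#' Extend reads at the 3' end
#'
#' Each read is replaced by an interval starting at its 5' end and spanning
#' `extend_len` bp in the strand direction, clipped at chromosome bounds.
#'
#' @param reads `GRanges` with `+`/`-` strands.
#' @param extend_len target fragment length in bp.
#' @param layout optional [genome_layout()] used for clipping (otherwise any
#'   seqlengths on `reads` are used; without either, only the lower bound 1
#'   is enforced).
#' @return `GRanges` of extended fragments, order preserved.
#' @export
extend_reads <- function(reads, extend_len = 200, layout = NULL) {
  if (!length(reads)) return(reads)
  st <- as.character(strand(reads))
  if (any(!st %in% c("+", "-")))
    stop("strandless read: extension requires +/- strand")
  plus <- st == "+"
  new_start <- ifelse(plus, start(reads), end(reads) - extend_len + 1)
  new_end <- ifelse(plus, start(reads) + extend_len - 1, end(reads))
  lens <- if (!is.null(layout)) layout$lengths[as.character(seqnames(reads))]
          else seqlengths(reads)[as.character(seqnames(reads))]
  new_start <- pmax(new_start, 1)
  if (!all(is.na(lens))) new_end <- pmin(new_end, lens, na.rm = TRUE)
  out <- GRanges(seqnames(reads), IRanges(new_start, new_end), strand = st)
  if (!is.null(layout)) out <- with_layout(out, layout)
  out
}

#' Binned mean coverage of extended reads
#'
#' Bin value = mean per-bp read coverage within the bin, so one read fully
#' covering a bin contributes 1.0 and coverage is additive over reads.
#'
#' @param extended_reads `GRanges` (typically from [extend_reads()]).
#' @param layout a [genome_layout()].
#' @param bin_size bin width in bp.
#' @return A [signal_track()].
#' @export
coverage_track <- function(extended_reads, layout, bin_size = 10) {
  if (length(extended_reads)) check_within_layout(extended_reads, layout, "read")
  gr <- with_layout(GRanges(seqnames(extended_reads),
                            IRanges(start(extended_reads), end(extended_reads))),
                    layout)
  cov <- coverage(gr)
  vals <- lapply(layout$chroms, function(ch) {
    v <- as.numeric(cov[[ch]])
    nbin <- ceiling(length(v) / bin_size)
    pad <- nbin * bin_size - length(v)
    if (pad) v <- c(v, numeric(pad))
    .colMeans(v, bin_size, nbin)
  })
  names(vals) <- layout$chroms
  signal_track(vals, layout, bin_size)
}

#' Depth-normalize a track
#'
#' Scales every bin by `norm_total / n_mapped_reads` so libraries of
#' different depth are comparable.
#'
#' @param track a [signal_track()].
#' @param n_mapped_reads mapped-read count of the library (> 0).
#' @param norm_total normalization target (default 25 million reads).
#' @return The scaled [signal_track()].
#' @export
normalize_track <- function(track, n_mapped_reads, norm_total = 25e6) {
  if (is.na(n_mapped_reads) || n_mapped_reads <= 0)
    stop("n_mapped_reads must be > 0")
  f <- norm_total / n_mapped_reads
  signal_track(lapply(track$values, `*`, f), track$layout, track$bin_size)
}

#' Subtract an input (control) track from a ChIP track
#'
#' Per-bin `max(chip - input, 0)`.  Both tracks must share the bin grid and
#' should be normalized to the same total beforehand.
#'
#' @param chip_track,input_track [signal_track()]s on identical grids.
#' @return The input-subtracted [signal_track()].
#' @export
subtract_input <- function(chip_track, input_track) {
  if (chip_track$bin_size != input_track$bin_size ||
      !identical(chip_track$layout$lengths, input_track$layout$lengths))
    stop("chip and input tracks are on different bin grids")
  vals <- mapply(function(a, b) pmax(a - b, 0),
                 chip_track$values, input_track$values, SIMPLIFY = FALSE)
  signal_track(vals, chip_track$layout, chip_track$bin_size)
}

## deterministic half-up rounding (R's round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

## smallest integer count whose Poisson upper tail P(X >= k) <= p
min_signif_count <- function(p, lambda) {
  k <- qpois(p, lambda, lower.tail = FALSE) + 1
  while (k > 1 && ppois(k - 2, lambda, lower.tail = FALSE) <= p) k <- k - 1
  k
}

#' Call enriched regions by Poisson seed-and-extend segmentation
#'
#' A bin whose rounded value `k` has Poisson upper-tail probability
#' `P(X >= k | lambda) <= p_seed` nucleates a region; the region extends
#' bin-by-bin in both directions through bins with tail probability
#' `<= p_ext`; touching or overlapping extended regions merge.  Each region
#' reports its width, maximum bin signal, and the minimal tail probability
#' attained inside it.
#'
#' @param track a [signal_track()] (normalized and input-subtracted as
#'   appropriate).
#' @param params a [caller_params()].
#' @return `GRanges` sorted by coordinate with metadata columns
#'   `max_signal` and `seed_p`; empty when no bin is significant.
#' @export
call_enriched_regions <- function(track, params = caller_params()) {
  lambda <- params$background_lambda
  if (is.null(lambda)) {
    nb <- sum(lengths(track$values))
    lambda <- if (nb) track$total_signal / nb else 0
  }
  if (lambda <= 0) return(empty_regions())
  k_seed <- min_signif_count(params$p_seed, lambda)
  k_ext <- min_signif_count(params$p_ext, lambda)
  bs <- track$bin_size
  out <- lapply(names(track$values), function(ch) {
    v <- track$values[[ch]]
    k <- round_half_up(v)
    ext <- k >= k_ext
    if (!any(ext)) return(NULL)
    r <- rle(ext)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    runs <- which(r$values)
    res <- lapply(runs, function(i) {
      b0 <- starts[i]; b1 <- ends[i]
      kmax <- max(k[b0:b1])
      if (kmax < k_seed) return(NULL)
      c(b0, b1, max(v[b0:b1]), kmax)
    })
    res <- do.call(rbind, res)
    if (is.null(res)) return(NULL)
    chrom_len <- track$layout$lengths[[ch]]
    GRanges(ch, IRanges(start = (res[, 1] - 1) * bs + 1,
                        end = pmin(res[, 2] * bs, chrom_len)),
            max_signal = res[, 3],
            seed_p = ppois(res[, 4] - 1, lambda, lower.tail = FALSE))
  })
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty_regions())
  BiocGenerics::sort(combine_granges(out, names(track$values)),
                     ignore.strand = TRUE)
}

empty_regions <- function() {
  gr <- GRanges()
  gr$max_signal <- numeric(0)
  gr$seed_p <- numeric(0)
  gr
}

#' Run the full tag-to-region stage for one mark
#'
#' Convenience wrapper: extend reads, bin coverage, normalize, optionally
#' subtract a matched input, and call enriched regions.
#'
#' @param tags read `GRanges` (from [read_tags_bed()]).
#' @param layout a [genome_layout()].
#' @param params a [caller_params()].
#' @param input_tags optional control reads; when supplied the input track is
#'   normalized to the same total as the ChIP track and subtracted.
#' @return list with elements `regions` (`GRanges`) and `track`
#'   (the segmented [signal_track()]).
#' @export
call_regions_from_tags <- function(tags, layout, params = caller_params(),
                                   input_tags = NULL) {
  ext <- extend_reads(tags, params$extend_len, layout)
  track <- coverage_track(ext, layout, params$bin_size)
  track <- normalize_track(track, max(length(tags), 1), params$norm_total)
  if (!is.null(input_tags) && length(input_tags)) {
    iext <- extend_reads(input_tags, params$extend_len, layout)
    itrack <- coverage_track(iext, layout, params$bin_size)
    itrack <- normalize_track(itrack, length(input_tags), params$norm_total)
    track <- subtract_input(track, itrack)
  }
  list(regions = call_enriched_regions(track, params), track = track)
}

#' Export a signal track as bedGraph
#'
#' Runs of equal-valued adjacent bins are merged; zero bins are omitted, so
#' an all-zero track yields an empty body.
#'
#' @param track a [signal_track()].
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  bs <- track$bin_size
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    r <- rle(v)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    keep <- r$values != 0
    if (!any(keep)) next
    chrom_len <- track$layout$lengths[[ch]]
    df <- data.frame(ch, (starts[keep] - 1) * bs,
                     pmin(ends[keep] * bs, chrom_len),
                     format(r$values[keep], digits = 15, trim = TRUE,
                            scientific = FALSE))
    write.table(df, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a bedGraph file back onto a bin grid
#'
#' Inverse of [write_bedgraph()] for records aligned to the grid.
#'
#' @param path bedGraph file.
#' @param layout a [genome_layout()].
#' @param bin_size bin width in bp.
#' @return A [signal_track()].
#' @export
read_bedgraph <- function(path, layout, bin_size = 10) {
  vals <- lapply(layout$lengths, function(L) numeric(ceiling(L / bin_size)))
  body <- read_body_lines(path)
  if (length(body$lines)) {
    fields <- split_fields(body, 4L, "bedGraph", path)
    chrom <- field_col(fields, 1)
    s <- as_coord(field_col(fields, 2), body, path, "start")
    e <- as_coord(field_col(fields, 3), body, path, "end")
    val <- as.numeric(field_col(fields, 4))
    if (any(is.na(val)))
      stop(sprintf("%s: non-numeric value at line %d", path,
                   body$lineno[which(is.na(val))[1]]))
    for (i in seq_along(chrom)) {
      b0 <- s[i] %/% bin_size + 1
      b1 <- ceiling(e[i] / bin_size)
      vals[[chrom[i]]][b0:b1] <- val[i]
    }
  }
  signal_track(vals, layout, bin_size)
}

#' Export called regions as BED6
#'
#' Name = region index; score = `-log10(seed_p) * 10`, capped at 1000.
#'
#' @param regions `GRanges` from [call_enriched_regions()].
#' @param path output path.
#' @export
write_regions_bed <- function(regions, path) {
  gr <- regions
  gr$name <- sprintf("region%d", seq_along(gr))
  gr$score <- pmin(round(-log10(pmax(gr$seed_p, 1e-300)) * 10), 1000)
  write_bed6(gr, path)
}
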