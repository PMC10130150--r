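## Chromatin-loop anchor overlap and the exact two-sample Poisson rate
## comparison.

#' Fraction of sites overlapping chromatin-loop anchors
#'
#' A site counts once if it overlaps (>= 1 bp) either anchor of at least one
#' loop; intervals are half-open on disk, so a site ending where an anchor
#' begins does not overlap.
#'
#' @param sites `GRanges` of target sites (e.g. motif instances).
#' @param loops a [loop_set()].
#' @return list with `n_overlapping`, `n_total`, `percent`.
#' @export
loop_overlap_fraction <- function(sites, loops) {
  if (!length(sites)) stop("no sites supplied (n_total = 0)")
  anchors <- combine_granges(list(
    GRanges(seqnames(loops$anchor1),
            IRanges(start(loops$anchor1), end(loops$anchor1))),
    GRanges(seqnames(loops$anchor2),
            IRanges(start(loops$anchor2), end(loops$anchor2)))))
  ov <- countOverlaps(GRanges(seqnames(sites),
                              IRanges(start(sites), end(sites))),
                      anchors, ignore.strand = TRUE) > 0
  list(n_overlapping = sum(ov), n_total = length(sites),
       percent = 100 * sum(ov) / length(sites))
}

#' Exact two-sample Poisson rate comparison
#'
#' Tests equality of rates k1/n1 and k2/n2 with the exact conditional
#' construction: given `k1 + k2`, `k1 ~ Binomial(k1 + k2, n1/(n1 + n2))`
#' under the null; the two-tailed p sums all binomial masses not exceeding
#' the observed one (minimum-likelihood summation, as in `binom.test`).
#'
#' @param k1,k2 event counts (`k <= n`).
#' @param n1,n2 exposure totals.
#' @return Two-tailed p value; 1 when `k1 + k2 == 0`.
#' @export
two_sample_poisson_test <- function(k1, n1, k2, n2) {
  if (any(c(k1, k2, n1, n2) < 0) || k1 > n1 || k2 > n2)
    stop("need 0 <= k <= n for both samples")
  if (k1 + k2 == 0) return(1)
  stats::binom.test(k1, k1 + k2, p = n1 / (n1 + n2),
                    alternative = "two.sided")$p.value
}
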