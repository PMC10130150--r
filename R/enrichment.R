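## Positive-set construction, differential filtering, and Fisher exact
## enrichment of gene sets among top-ranked genes.

#' Filter a differential-expression table
#'
#' A gene is called differential when its FDR-adjusted q value is smaller
#' than `q_max` and its FPKM exceeds `fpkm_min` in at least one sample; the
#' sign of the log2 fold change splits up from down.
#'
#' @param table data.frame with columns `gene_id`, `log2fc`, `qvalue` and
#'   `fpkm_max` (or `fpkm_*` sample columns), as from [read_de_table()].
#' @param q_max q-value cutoff (exclusive; default 0.05).
#' @param fpkm_min FPKM floor (exclusive; default 1).
#' @return list with character vectors `up` and `down`.
#' @export
filter_differential <- function(table, q_max = 0.05, fpkm_min = 1) {
  need <- c("gene_id", "log2fc", "qvalue")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop(sprintf("missing column(s): %s", paste(miss, collapse = ", ")))
  if (is.null(table$fpkm_max)) {
    fcols <- grep("^fpkm", names(table), value = TRUE)
    if (!length(fcols)) stop("missing column(s): fpkm_max (or fpkm_* samples)")
    table$fpkm_max <- do.call(pmax, table[fcols])
  }
  pass <- table$qvalue < q_max & table$fpkm_max > fpkm_min
  list(up = table$gene_id[pass & table$log2fc > 0],
       down = table$gene_id[pass & table$log2fc < 0])
}

#' Intersect keyword-matched pathways with upregulated genes
#'
#' Builds a positive-regulator set: the union of members of every pathway
#' whose name contains `keyword` (case-insensitive substring), intersected
#' with the upregulated gene set.
#'
#' @param pathway_sets named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param keyword substring to match against pathway names.
#' @param up_set character vector of upregulated gene ids.
#' @return character vector (possibly empty, with a warning when no pathway
#'   matches).
#' @export
intersect_positive_set <- function(pathway_sets, keyword, up_set) {
  hit <- grepl(keyword, names(pathway_sets), ignore.case = TRUE, fixed = FALSE)
  if (!any(hit)) {
    warning(sprintf("no pathway name matches keyword '%s'", keyword))
    return(character(0))
  }
  intersect(unique(unlist(pathway_sets[hit], use.names = FALSE)), up_set)
}

#' Fisher exact enrichment of a gene set among the top-n ranked genes
#'
#' Builds the 2x2 table top/not-top x in-set/not over the gene universe and
#' tests it with the two-tailed Fisher exact test (minimum-likelihood
#' summation, as implemented in R's `fisher.test`).  Fold enrichment is
#' `(overlap/n) / (set size/universe size)`.
#'
#' @param ranking character vector of gene ids ordered best-first, covering
#'   the universe.
#' @param gene_set character vector, a subset of `universe`.
#' @param n top-list size.
#' @param universe character vector of all gene ids (default: `ranking`).
#' @return list of class `enrichment_result`: `n_universe`, `n_set`,
#'   `n_top`, `n_overlap`, `p_two_tailed`, `fold`, `overlap_members`.
#' @export
fisher_top_n <- function(ranking, gene_set, n, universe = ranking) {
  if (!all(gene_set %in% universe))
    stop("gene_set contains genes absent from the universe; restrict it first")
  if (!setequal(ranking, universe))
    stop("ranking must cover exactly the gene universe")
  if (n > length(universe)) stop("n exceeds the universe size")
  top <- ranking[seq_len(n)]
  n_overlap <- sum(top %in% gene_set)
  N <- length(universe); K <- length(unique(gene_set))
  tab <- matrix(c(n_overlap, n - n_overlap,
                  K - n_overlap, N - n - K + n_overlap), nrow = 2)
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  structure(list(n_universe = N, n_set = K, n_top = n, n_overlap = n_overlap,
                 p_two_tailed = p,
                 fold = (n_overlap / n) / (K / N),
                 overlap_members = top[top %in% gene_set]),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment_result: %d/%d of top %d in set (|set| %d, universe %d)\n  fold = %.3g, two-tailed Fisher p = %.3g\n",
    x$n_overlap, x$n_set, x$n_top, x$n_set, x$n_universe, x$fold,
    x$p_two_tailed))
  invisible(x)
}

#' Enrichment as a cumulative function of the top-list size
#'
#' One [fisher_top_n()] per cutoff; cutoffs are cumulative top-n lists, not
#' disjoint bins.
#'
#' @inheritParams fisher_top_n
#' @param thresholds ascending integer cutoffs; values beyond the universe
#'   size are clipped with a warning.
#' @return data.frame with columns `n`, `n_overlap`, `fold`, `p`.
#' @export
enrichment_curve <- function(ranking, gene_set, thresholds,
                             universe = ranking) {
  if (is.unsorted(thresholds)) stop("thresholds must be ascending")
  if (any(thresholds > length(universe))) {
    warning("thresholds beyond the universe size were clipped")
    thresholds <- unique(pmin(thresholds, length(universe)))
  }
  rows <- lapply(thresholds, function(n) {
    r <- fisher_top_n(ranking, gene_set, n, universe)
    data.frame(n = n, n_overlap = r$n_overlap, fold = r$fold,
               p = r$p_two_tailed)
  })
  do.call(rbind, rows)
}
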