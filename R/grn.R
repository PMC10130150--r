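## Gene-regulatory-network scoring: internal/incident edge counts of gene
## groups, transcription-factor counts, length-2 path centrality, and the
## seeded random-group comparison.

#' Construct a GRN graph
#'
#' Edges are treated as undirected and deduplicated; self-loops are dropped.
#'
#' @param edges data.frame with columns `source`, `target` (extra columns
#'   ignored), or a two-column matrix.
#' @param nodes optional character vector of the gene universe; defaults to
#'   the genes appearing in `edges` plus `tfs`.
#' @param tfs character vector of genes flagged as transcription factors.
#' @return Object of class `grn_graph`: list with `nodes`, `edge_idx`
#'   (2-column integer matrix), `tfs`, and the underlying `igraph` object.
#' @export
grn_graph <- function(edges, nodes = NULL, tfs = character(0)) {
  edges <- as.data.frame(edges)
  if (ncol(edges) < 2) stop("edges needs source and target columns")
  src <- as.character(edges[[1]]); tgt <- as.character(edges[[2]])
  keep <- src != tgt
  src <- src[keep]; tgt <- tgt[keep]
  if (is.null(nodes)) nodes <- sort(unique(c(src, tgt, tfs)))
  if (any(!c(src, tgt) %in% nodes)) stop("edge endpoint not in node universe")
  a <- match(src, nodes); b <- match(tgt, nodes)
  lo <- pmin(a, b); hi <- pmax(a, b)
  dup <- duplicated(paste(lo, hi))
  em <- cbind(lo[!dup], hi[!dup])
  g <- igraph::make_empty_graph(n = length(nodes), directed = FALSE)
  g <- igraph::add_edges(g, t(em))
  g <- igraph::set_vertex_attr(g, "name", value = nodes)
  structure(list(nodes = nodes, edge_idx = em,
                 tfs = intersect(tfs, nodes), graph = g),
            class = "grn_graph")
}

#' @export
print.grn_graph <- function(x, ...) {
  cat(sprintf("grn_graph: %d nodes, %d undirected edges, %d TFs\n",
              length(x$nodes), nrow(x$edge_idx), length(x$tfs)))
  invisible(x)
}

#' Count GRN edges inside (or incident to) a gene group
#'
#' `mode = "internal"` counts edges with both endpoints in the group;
#' `"incident"` counts edges touching the group with at least one endpoint.
#' Group members absent from the network are ignored with a warning.
#'
#' @param group character vector of gene ids.
#' @param grn a [grn_graph()].
#' @param mode `"internal"` (default) or `"incident"`.
#' @return Integer edge count.
#' @export
internal_edge_count <- function(group, grn, mode = c("internal", "incident")) {
  mode <- match.arg(mode)
  if (!length(group)) {
    warning("empty gene group")
    return(0L)
  }
  missing <- setdiff(group, grn$nodes)
  if (length(missing))
    warning(sprintf("%d group gene(s) absent from the GRN were ignored",
                    length(missing)))
  mem <- logical(length(grn$nodes))
  mem[match(intersect(group, grn$nodes), grn$nodes)] <- TRUE
  a <- mem[grn$edge_idx[, 1]]; b <- mem[grn$edge_idx[, 2]]
  if (mode == "internal") sum(a & b) else sum(a | b)
}

#' Count transcription factors in a gene group
#'
#' @inheritParams internal_edge_count
#' @return `|group intersect tf_flags|`.
#' @export
tf_count <- function(group, grn) length(intersect(group, grn$tfs))

#' Length-2 path centrality of a gene
#'
#' The number of unique simple paths u - g - w centered on gene `g`, i.e.
#' `choose(degree(g), 2)`.  A hub connected to many regulators/targets
#' scores high; a degree-1 gene scores 0.
#'
#' @param gene a gene id present in the network.
#' @param grn a [grn_graph()].
#' @return Numeric path count.
#' @export
path_centrality <- function(gene, grn) {
  if (!gene %in% grn$nodes) stop(sprintf("gene '%s' absent from the GRN", gene))
  d <- sum(grn$edge_idx == match(gene, grn$nodes))
  choose(d, 2)
}

#' Rank all transcription factors by path centrality
#'
#' @param grn a [grn_graph()].
#' @return data.frame with columns `gene_id`, `degree`, `path_centrality`,
#'   sorted descending by centrality (ties lexicographic by gene id).
#' @export
rank_tf_centrality <- function(grn) {
  if (!length(grn$tfs)) return(data.frame(gene_id = character(0),
                                          degree = integer(0),
                                          path_centrality = numeric(0)))
  deg <- tabulate(as.vector(grn$edge_idx), nbins = length(grn$nodes))
  i <- match(grn$tfs, grn$nodes)
  df <- data.frame(gene_id = grn$tfs, degree = deg[i],
                   path_centrality = choose(deg[i], 2))
  df <- df[order(-df$path_centrality, df$gene_id), ]
  rownames(df) <- NULL
  df
}

#' Compare top-k gene groups against seeded random baselines
#'
#' For each named ranking the top-k group is scored by internal edge count
#' and TF count; `n_random` uniform draws of k genes from the universe give
#' an empirical null, and the empirical p is
#' `(1 + #\{random >= observed\}) / (n_random + 1)`.
#'
#' @param grn a [grn_graph()].
#' @param rankings named list of character vectors, each an ordering of the
#'   gene universe (best first).
#' @param k group size (default 400).
#' @param n_random number of random groups (default 1000).
#' @param seed integer RNG seed; all randomness in this function flows from
#'   it.
#' @param universe gene universe to draw random groups from; defaults to the
#'   first ranking.
#' @return data.frame with one row per ranking plus a `"random"` baseline
#'   row: `name`, `internal_edges`, `tf_count`, `p_edges` (empirical).
#' @export
compare_rankings <- function(grn, rankings, k = 400, n_random = 1000,
                             seed = 1, universe = NULL) {
  if (is.null(universe)) universe <- rankings[[1]]
  if (k > length(universe)) stop("k exceeds the universe size")
  set.seed(seed)
  node_idx <- match(universe, grn$nodes)
  e1 <- grn$edge_idx[, 1]; e2 <- grn$edge_idx[, 2]
  count_internal <- function(ids) {
    mem <- logical(length(grn$nodes))
    mem[stats::na.omit(match(ids, grn$nodes))] <- TRUE
    sum(mem[e1] & mem[e2])
  }
  rnd <- vapply(seq_len(n_random), function(i)
    count_internal(universe[sample.int(length(universe), k)]), numeric(1))
  rows <- lapply(names(rankings), function(nm) {
    grp <- rankings[[nm]][seq_len(k)]
    obs <- count_internal(grp)
    data.frame(name = nm, internal_edges = obs, tf_count = tf_count(grp, grn),
               p_edges = (1 + sum(rnd >= obs)) / (n_random + 1))
  })
  out <- do.call(rbind, rows)
  out <- rbind(out, data.frame(name = "random",
                               internal_edges = mean(rnd),
                               tf_count = NA_real_,
                               p_edges = NA_real_))
  rownames(out) <- NULL
  out
}
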