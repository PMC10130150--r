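## End-to-end orchestration: YAML config -> peak calling per mark -> breadth
## ranking -> gene-set enrichment -> GRN scoring -> motif and loop
## statistics, with one TSV per stage and a JSON summary.

pipeline_defaults <- function() {
  list(bin_size = 10, extend_len = 200, p_seed = 1e-5, p_ext = 1e-3,
       norm_total = 25e6, flank = 10000, top_n = 1000, grn_k = 400,
       promoter_window = 5000, n_random = 1000, seed = 7,
       q_max = 0.05, fpkm_min = 1, keyword = "endothelial",
       multi_assign = "all",
       distance_grid = as.numeric(10^seq(3, 6, 0.5)))
}

#' Load a pipeline configuration from YAML
#'
#' The file holds two mappings: `inputs` (paths) and `params`
#' (pipeline constants).  Parameters omitted from the file take their
#' defaults (bin 10 bp, extension 200 bp, seed p 1e-5, extension p 1e-3,
#' normalization total 25 million, flank 10 kb, top 1000, GRN group 400,
#' promoter window 5 kb).  Unknown keys are rejected rather than silently
#' ignored.
#'
#' @param path YAML file; an empty/absent mapping yields pure defaults.
#' @return list of class `pipeline_config` with elements `inputs`, `params`.
#' @export
load_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), c("inputs", "params", "out_dir"))
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  pipeline_config(inputs = raw$inputs, params = raw$params,
                  out_dir = raw$out_dir)
}

#' @rdname load_pipeline_config
#' @param inputs named list of input paths (`genes`, `genome`, `marks` (a
#'   named mapping mark -> tag BED), `input`, `de_table`, `grn`, `tfs`,
#'   `motifs`, `loops_a`, `loops_b`, `pathways`); unused stages may be
#'   omitted and are skipped.
#' @param params named list overriding [pipeline_defaults]; `norm_total`
#'   may be the string `"observed"` to normalize each library to its own
#'   observed read total (scale 1).
#' @param out_dir directory for stage outputs (optional).
#' @export
pipeline_config <- function(inputs = list(), params = list(),
                            out_dir = NULL) {
  if (is.null(inputs)) inputs <- list()
  if (is.null(params)) params <- list()
  def <- pipeline_defaults()
  unknown <- setdiff(names(params), names(def))
  if (length(unknown))
    stop(sprintf("unknown parameter key(s): %s", paste(unknown, collapse = ", ")))
  params <- utils::modifyList(def, params)
  known_inputs <- c("genes", "genes_dialect", "genome", "marks", "input",
                    "de_table", "grn", "tfs", "motifs", "loops_a", "loops_b",
                    "pathways", "positive_set")
  unknown <- setdiff(names(inputs), known_inputs)
  if (length(unknown))
    stop(sprintf("unknown input key(s): %s", paste(unknown, collapse = ", ")))
  for (nm in setdiff(names(inputs), c("marks", "genes_dialect"))) {
    if (!file.exists(inputs[[nm]]))
      stop(sprintf("input '%s' does not exist: %s", nm, inputs[[nm]]))
  }
  for (mk in names(inputs$marks)) {
    if (!file.exists(inputs$marks[[mk]]))
      stop(sprintf("tag file for mark '%s' does not exist: %s",
                   mk, inputs$marks[[mk]]))
  }
  structure(list(inputs = inputs, params = params, out_dir = out_dir),
            class = "pipeline_config")
}

stage_msg <- function(fmt, ...) {
  message(sprintf("[broadscape %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

#' Run the full prioritization pipeline
#'
#' Executes, for every configured stage: enriched-region calling per mark,
#' gene-breadth ranking combined across marks, differential filtering and
#' positive-set construction, Fisher enrichment of the top-ranked genes, GRN
#' group comparison and TF centrality, promoter motif gene set, cumulative
#' motif-distance enrichment, and loop-anchor overlap with the two-sample
#' Poisson comparison.  Progress goes to stderr; results are returned and,
#' when `out_dir` is set, written as one TSV per stage plus `summary.json`.
#'
#' @param config a `pipeline_config`.
#' @return list of class `pipeline_result` with elements `regions`,
#'   `breadth_table`, `ranking`, `differential`, `positive_set`,
#'   `enrichment`, `grn_comparison`, `tf_centrality`,
#'   `promoter_motif_genes`, `motif_distance`, `loops`, `params`.
#' @export
run_pipeline <- function(config) {
  inp <- config$inputs
  par <- config$params
  if (is.null(inp$genome)) stop("config must name a genome layout file")
  if (is.null(inp$genes)) stop("config must name a gene-model file")
  layout <- read_genome_layout(inp$genome)
  dialect <- if (is.null(inp$genes_dialect)) "bed12" else inp$genes_dialect
  genes <- read_gene_models(inp$genes, dialect, layout)
  universe <- genes$gene_id
  stage_msg("loaded %d genes on %d chromosome(s)", length(genes),
            length(layout$chroms))

  input_tags <- if (!is.null(inp$input)) read_tags_bed(inp$input, layout)
  regions <- list()
  for (mk in names(inp$marks)) {
    tags <- read_tags_bed(inp$marks[[mk]], layout)
    if (!length(tags)) stop(sprintf("mark '%s': no reads", mk))
    norm_total <- par$norm_total
    if (identical(norm_total, "observed")) norm_total <- length(tags)
    cp <- caller_params(extend_len = par$extend_len, norm_total = norm_total,
                        p_seed = par$p_seed, p_ext = par$p_ext,
                        bin_size = par$bin_size)
    res <- call_regions_from_tags(tags, layout, cp, input_tags)
    regions[[mk]] <- res$regions
    stage_msg("mark %s: %d reads -> %d enriched regions", mk, length(tags),
              length(res$regions))
  }

  breadth <- NULL; ranking <- NULL
  if (length(regions)) {
    breadth <- gene_breadth_table(regions, genes, flank = par$flank,
                                  multi_assign = par$multi_assign)
    ranking <- breadth$gene_id
    stage_msg("breadth ranking over %d genes (%d marks)", nrow(breadth),
              length(regions))
  }

  differential <- NULL; positive <- NULL; enr <- NULL
  if (!is.null(inp$de_table)) {
    de <- read_de_table(inp$de_table)
    differential <- filter_differential(de, par$q_max, par$fpkm_min)
    stage_msg("differential filter: %d up / %d down",
              length(differential$up), length(differential$down))
  }
  if (!is.null(inp$pathways) && !is.null(differential)) {
    pathways <- read_gmt(inp$pathways)
    positive <- intersect_positive_set(pathways, par$keyword,
                                       differential$up)
    stage_msg("positive set: %d genes (keyword '%s')", length(positive),
              par$keyword)
  } else if (!is.null(inp$positive_set)) {
    positive <- read_gmt(inp$positive_set)[[1]]
  }
  if (!is.null(ranking) && length(positive)) {
    n_top <- min(par$top_n, length(universe))
    if (n_top < par$top_n)
      warning("top_n clipped to the universe size")
    enr <- fisher_top_n(ranking, intersect(positive, universe), n_top,
                        universe)
    stage_msg("enrichment: overlap %d/%d, fold %.2f, p %.3g",
              enr$n_overlap, enr$n_set, enr$fold, enr$p_two_tailed)
  }

  grn_cmp <- NULL; tf_rank <- NULL; grn <- NULL
  if (!is.null(inp$grn)) {
    tfs <- if (!is.null(inp$tfs)) read_tf_list(inp$tfs) else character(0)
    grn <- grn_graph(read_grn_edges(inp$grn), nodes = universe, tfs = tfs)
    rankings <- list()
    if (!is.null(ranking)) rankings$breadth <- ranking
    if (!is.null(inp$de_table)) {
      de <- read_de_table(inp$de_table)
      de <- de[match(universe, de$gene_id), ]
      rankings$expression <- universe[order(-de$fpkm_wt)]
      rankings$differential <- universe[order(-de$log2fc)]
    }
    if (length(rankings)) {
      k <- min(par$grn_k, length(universe))
      grn_cmp <- compare_rankings(grn, rankings, k = k,
                                  n_random = par$n_random, seed = par$seed,
                                  universe = universe)
      stage_msg("GRN comparison at k = %d over %d random groups", k,
                par$n_random)
    }
    tf_rank <- rank_tf_centrality(grn)
  }

  motif_genes <- NULL; motif_dist <- NULL; loops_res <- NULL
  sites <- if (!is.null(inp$motifs)) read_tags_bed_lenient(inp$motifs, layout)
  if (!is.null(sites)) {
    motif_genes <- promoter_motif_gene_set(sites, genes, par$promoter_window)
    if (!is.null(differential)) {
      targets <- union(differential$up, differential$down)
      background <- setdiff(universe, targets)
      if (length(background))
        motif_dist <- cumulative_distance_enrichment(sites, genes, targets,
                                                background,
                                                par$distance_grid)
    }
    stage_msg("motifs: %d sites, %d genes with promoter motif",
              length(sites), length(motif_genes))
  }
  if (!is.null(sites) && !is.null(inp$loops_a) && !is.null(inp$loops_b)) {
    la <- read_bedpe(inp$loops_a, layout)
    lb <- read_bedpe(inp$loops_b, layout)
    fa <- loop_overlap_fraction(sites, la)
    fb <- loop_overlap_fraction(sites, lb)
    loops_res <- list(
      condition_A = fa, condition_B = fb,
      p_two_tailed = two_sample_poisson_test(fa$n_overlapping, fa$n_total,
                                             fb$n_overlapping, fb$n_total))
    stage_msg("loop overlap: %.2f%% (A) vs %.2f%% (B), Poisson p %.3g",
              fa$percent, fb$percent, loops_res$p_two_tailed)
  }

  result <- structure(
    list(regions = regions, breadth_table = breadth, ranking = ranking,
         differential = differential, positive_set = positive,
         enrichment = enr, grn_comparison = grn_cmp,
         tf_centrality = tf_rank, promoter_motif_genes = motif_genes,
         motif_distance = motif_dist, loops = loops_res, params = par),
    class = "pipeline_result")
  if (!is.null(config$out_dir)) write_pipeline_result(result, config)
  result
}

## motif-site BED files may legitimately carry fewer than 6 columns or '.'
## strands; fall back to a BED3+ read
read_tags_bed_lenient <- function(path, layout = NULL) {
  body <- read_body_lines(path)
  if (!length(body$lines)) return(GRanges())
  fields <- split_fields(body, 3L, "BED", path)
  gr <- GRanges(field_col(fields, 1),
                IRanges(as_coord(field_col(fields, 2), body, path, "start") + 1,
                        as_coord(field_col(fields, 3), body, path, "end")))
  if (!is.null(layout)) {
    check_within_layout(gr, layout, "site")
    gr <- with_layout(gr, layout)
  }
  gr
}

write_pipeline_result <- function(result, config) {
  dir <- config$out_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (mk in names(result$regions))
    write_regions_bed(result$regions[[mk]],
                      file.path(dir, sprintf("regions_%s.bed", mk)))
  if (!is.null(result$breadth_table))
    write_breadth_table(result$breadth_table, file.path(dir, "breadth.tsv"))
  if (!is.null(result$grn_comparison))
    write.table(result$grn_comparison, file.path(dir, "grn_comparison.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$tf_centrality))
    write.table(result$tf_centrality, file.path(dir, "tf_centrality.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(result$motif_distance))
    write.table(result$motif_distance, file.path(dir, "motif_distance.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  summary <- list(
    package_version = as.character(utils::packageVersion("broadscape")),
    seed = result$params$seed,
    params = result$params[setdiff(names(result$params), "distance_grid")],
    n_regions = lapply(result$regions, length),
    enrichment = if (!is.null(result$enrichment))
      result$enrichment[c("n_universe", "n_set", "n_top", "n_overlap",
                          "p_two_tailed", "fold")],
    loops = result$loops)
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("broadscape pipeline result\n")
  if (length(x$regions))
    cat(sprintf("  regions: %s\n",
                paste(sprintf("%s=%d", names(x$regions),
                              vapply(x$regions, length, integer(1))),
                      collapse = ", ")))
  if (!is.null(x$enrichment))
    cat(sprintf("  top-%d enrichment: overlap %d, fold %.2f, p %.3g\n",
                x$enrichment$n_top, x$enrichment$n_overlap,
                x$enrichment$fold, x$enrichment$p_two_tailed))
  if (!is.null(x$loops))
    cat(sprintf("  loop overlap: %.2f%% vs %.2f%%, p %.3g\n",
                x$loops$condition_A$percent, x$loops$condition_B$percent,
                x$loops$p_two_tailed))
  invisible(x)
}
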