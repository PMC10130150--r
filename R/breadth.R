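## Gene-level breadth: assign called regions to genes, sum widths, rank per
## mark, and average ranks across marks into the prioritization list.

#' Assign enriched regions to genes
#'
#' A region is assigned to a gene when it overlaps the gene body by at least
#' 1 bp, or when it is intergenic (overlaps no gene body in the table) and
#' lies within `flank` bp of the gene's TSS or TTS (minimal gap between
#' interval ends; 0 when touching).  With `multi_assign = "all"` a region
#' may be assigned to every qualifying gene; `"nearest"` keeps only the
#' closest gene.
#'
#' @param regions `GRanges` of enriched regions.
#' @param genes gene-model `GRanges` with a `gene_id` column.
#' @param flank intergenic assignment distance in bp (default 10,000).
#' @param multi_assign `"all"` (default) or `"nearest"`.
#' @return data.frame with columns `gene_id`, `region` (index into
#'   `regions`), `width`.
#' @export
assign_regions_to_genes <- function(regions, genes, flank = 10000,
                                    multi_assign = c("all", "nearest")) {
  multi_assign <- match.arg(multi_assign)
  if (!length(regions) || !length(genes))
    return(data.frame(gene_id = character(0), region = integer(0),
                      width = integer(0)))
  regions <- GRanges(seqnames(regions), IRanges(start(regions), end(regions)))
  body_hits <- findOverlaps(regions, genes, ignore.strand = TRUE)
  genic <- countOverlaps(regions, genes, ignore.strand = TRUE) > 0
  df <- data.frame(gene_id = genes$gene_id[subjectHits(body_hits)],
                   region = queryHits(body_hits),
                   dist = numeric(length(body_hits)))
  inter <- which(!genic)
  if (length(inter)) {
    ends <- c(tss_granges(genes), tts_granges(genes))
    end_hits <- findOverlaps(regions[inter], ends, maxgap = flank,
                             ignore.strand = TRUE)
    if (length(end_hits)) {
      d <- distance(regions[inter][queryHits(end_hits)],
                    ends[subjectHits(end_hits)], ignore.strand = TRUE)
      idf <- data.frame(gene_id = ends$gene_id[subjectHits(end_hits)],
                        region = inter[queryHits(end_hits)],
                        dist = d)
      ## one row per (gene, region): keep the smaller of the TSS/TTS gaps
      idf <- idf[order(idf$dist), ]
      idf <- idf[!duplicated(idf[c("gene_id", "region")]), ]
      df <- rbind(df, idf)
    }
  }
  if (multi_assign == "nearest" && nrow(df)) {
    df <- df[order(df$dist, df$gene_id), ]
    df <- df[!duplicated(df$region), ]
  }
  df <- df[order(df$region, df$gene_id), c("gene_id", "region")]
  df$width <- width(regions)[df$region]
  rownames(df) <- NULL
  df
}

#' Gene-level breadth
#'
#' Breadth of a gene = sum of the widths of all regions assigned to it;
#' genes with no assigned region have breadth 0.
#'
#' @param assignment data.frame from [assign_regions_to_genes()].
#' @param genes gene-model `GRanges` defining the gene universe.
#' @return Named numeric vector of breadths (bp) over the full universe.
#' @export
gene_breadth <- function(assignment, genes) {
  b <- setNames(numeric(length(genes)), genes$gene_id)
  if (nrow(assignment)) {
    s <- tapply(assignment$width, assignment$gene_id, sum)
    b[names(s)] <- s
  }
  b
}

#' Rank genes by breadth
#'
#' Rank 1 = broadest.  Ties (including all zero-breadth genes) receive the
#' average of the ranks they span.
#'
#' @param breadths named numeric vector over the gene universe.
#' @return Named numeric vector of ranks.
#' @export
rank_by_breadth <- function(breadths) {
  if (!length(breadths)) stop("empty gene universe")
  rank(-breadths, ties.method = "average")
}

#' Combine per-mark ranks into a single prioritization list
#'
#' The combined rank of a gene is the arithmetic mean of its per-mark ranks;
#' the final ordering is ascending by combined rank with lexicographic
#' `gene_id` tie-break.
#'
#' @param rank_table numeric matrix or data.frame of per-mark ranks
#'   (rows = genes, rownames = gene ids, columns = marks).  All marks must
#'   rank the identical universe.
#' @return list with `combined_rank` (named numeric) and `ordering`
#'   (character vector of gene ids, best first).
#' @export
combine_ranks <- function(rank_table) {
  m <- as.matrix(rank_table)
  if (is.null(rownames(m))) stop("rank_table needs gene ids as rownames")
  if (any(is.na(m)))
    stop("mark is missing ranks for some genes: universes must match")
  combined <- rowMeans(m)
  ord <- order(combined, rownames(m))
  list(combined_rank = combined, ordering = rownames(m)[ord])
}

#' Build the full gene-breadth table across marks
#'
#' Runs [assign_regions_to_genes()] + [gene_breadth()] +
#' [rank_by_breadth()] per mark and [combine_ranks()] across marks.
#'
#' @param regions_by_mark named list of region `GRanges`, one per mark.
#' @param genes gene-model `GRanges`.
#' @param flank intergenic assignment distance (bp).
#' @param multi_assign see [assign_regions_to_genes()].
#' @return data.frame of class `gene_breadth_table` with one row per gene:
#'   `gene_id`, `breadth_<mark>`, `rank_<mark>`, `combined_rank`, sorted by
#'   combined rank (ties lexicographic by gene id).
#' @export
gene_breadth_table <- function(regions_by_mark, genes, flank = 10000,
                               multi_assign = "all") {
  if (is.null(names(regions_by_mark)) || any(!nzchar(names(regions_by_mark))))
    stop("regions_by_mark must be a named list (one element per mark)")
  breadths <- lapply(regions_by_mark, function(r)
    gene_breadth(assign_regions_to_genes(r, genes, flank, multi_assign), genes))
  ranks <- lapply(breadths, rank_by_breadth)
  rk <- do.call(cbind, ranks)
  comb <- combine_ranks(rk)
  df <- data.frame(gene_id = genes$gene_id, check.names = FALSE)
  for (mk in names(regions_by_mark)) {
    df[[paste0("breadth_", mk)]] <- unname(breadths[[mk]])
    df[[paste0("rank_", mk)]] <- unname(ranks[[mk]])
  }
  df$combined_rank <- unname(comb$combined_rank[df$gene_id])
  df <- df[match(comb$ordering, df$gene_id), ]
  rownames(df) <- NULL
  class(df) <- c("gene_breadth_table", "data.frame")
  df
}

#' @export
print.gene_breadth_table <- function(x, n = 6, ...) {
  cat(sprintf("gene_breadth_table: %d genes x %d marks\n", nrow(x),
              sum(grepl("^rank_", names(x)))))
  print.data.frame(head(as.data.frame(x), n))
  invisible(x)
}

#' Serialize / read a gene-breadth table as TSV
#' @param table a `gene_breadth_table` (or any data.frame).
#' @param path output path.
#' @export
write_breadth_table <- function(table, path) {
  write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_breadth_table
#' @export
read_breadth_table <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  class(df) <- c("gene_breadth_table", "data.frame")
  df
}
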