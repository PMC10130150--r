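#' Genome layout
#'
#' A minimal description of a genome: an ordered set of chromosome names and
#' their lengths in base pairs.  Used to bound coordinates, size signal
#' tracks, and seed the synthetic generators.
#'
#' @param chroms character vector of unique chromosome names.
#' @param lengths numeric vector of positive chromosome lengths (bp), one per
#'   chromosome.
#' @return An object of class `genome_layout`: a list with elements `chroms`
#'   and `lengths` (named numeric).
#' @examples
#' genome_layout(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genome_layout <- function(chroms, lengths) {
  chroms <- as.character(chroms)
  lengths <- as.numeric(lengths)
  if (length(chroms) != length(lengths))
    stop("chroms and lengths must have equal length")
  if (anyDuplicated(chroms)) stop("chromosome names must be unique")
  if (length(lengths) && any(!is.finite(lengths) | lengths <= 0))
    stop("chromosome lengths must be positive")
  structure(list(chroms = chroms, lengths = setNames(lengths, chroms)),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("genome_layout: %d chromosome(s), %s bp total\n",
              length(x$chroms), format(sum(x$lengths), big.mark = ",")))
  invisible(x)
}

genome_size <- function(layout) sum(layout$lengths)

## attach seqlengths so GRanges operations can bounds-check
with_layout <- function(gr, layout) {
  seqlevels(gr) <- layout$chroms
  seqlengths(gr) <- layout$lengths
  gr
}

## concatenate GRanges after harmonizing seqlevels (avoids noisy Seqinfo
## merge warnings when pieces cover different chromosome subsets)
combine_granges <- function(grl, chroms = NULL) {
  grl <- grl[vapply(grl, length, integer(1)) > 0]
  if (!length(grl)) return(GRanges())
  if (is.null(chroms))
    chroms <- unique(unlist(lapply(grl, function(g) as.character(seqlevels(g)))))
  grl <- lapply(grl, function(g) {
    seqlevels(g) <- chroms
    g
  })
  do.call(c, grl)
}

check_within_layout <- function(gr, layout, what = "interval") {
  bad_chr <- !(as.character(seqnames(gr)) %in% layout$chroms)
  if (any(bad_chr))
    stop(sprintf("%s on unknown chromosome '%s'", what,
                 as.character(seqnames(gr))[which(bad_chr)[1]]))
  lens <- layout$lengths[as.character(seqnames(gr))]
  bad <- start(gr) < 1 | end(gr) > lens
  if (any(bad))
    stop(sprintf("%s out of chromosome bounds at %s:%d-%d", what,
                 as.character(seqnames(gr))[which(bad)[1]],
                 start(gr)[which(bad)[1]], end(gr)[which(bad)[1]]))
  invisible(gr)
}

#' Strand-aware gene ends
#'
#' The transcription start site (TSS) is the strand-aware 5' end of a gene
#' model and the transcription termination site (TTS) its 3' end: for a
#' plus-strand gene TSS = start and TTS = end; for a minus-strand gene TSS =
#' end and TTS = start (1-based coordinates).
#'
#' @param genes a `GRanges` of gene models with a `gene_id` metadata column
#'   and `+`/`-` strands.
#' @return Integer vector of positions, named by `gene_id`.
#' @export
gene_tss <- function(genes) {
  pos <- ifelse(as.character(strand(genes)) == "-", end(genes), start(genes))
  setNames(as.integer(pos), genes$gene_id)
}

#' @rdname gene_tss
#' @export
gene_tts <- function(genes) {
  pos <- ifelse(as.character(strand(genes)) == "-", start(genes), end(genes))
  setNames(as.integer(pos), genes$gene_id)
}

tss_granges <- function(genes) {
  p <- gene_tss(genes)
  gr <- GRanges(seqnames(genes), IRanges(p, width = 1))
  gr$gene_id <- genes$gene_id
  gr
}

tts_granges <- function(genes) {
  p <- gene_tts(genes)
  gr <- GRanges(seqnames(genes), IRanges(p, width = 1))
  gr$gene_id <- genes$gene_id
  gr
}
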