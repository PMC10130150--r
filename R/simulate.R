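## Synthetic data with planted ground truth.  The generators emulate the
## statistical structure the pipeline assumes: identity genes carry broad
## (kb-scale) domains of every activating mark with correlated breadth,
## other expressed genes carry sharp promoter peaks, identity genes sit as
## hubs in the GRN, motif sites concentrate near identity-gene TSSs, and
## loop anchors overlap planted sites at a condition-dependent rate.  Every
## generator is a deterministic function of (params, seed).

#' Simulation parameters
#'
#' Defaults define the reference synthetic study: a 40-Mb four-chromosome
#' genome, 1,000 genes of which 5% are identity genes, five activating
#' histone marks with broad (5 kb) identity domains versus sharp (0.5 kb)
#' promoter peaks, strong cross-mark breadth correlation, a hub-structured
#' GRN, motif placement near identity TSSs, and loop overlap rates echoing a
#' two-condition contrast.
#'
#' @param seed integer seed; every generator derives its stream from it.
#' @param n_chrom,chrom_len chromosome count and uniform length (bp).
#' @param n_genes number of genes.
#' @param identity_fraction fraction of genes planted as identity genes.
#' @param expressed_fraction fraction of non-identity genes expressed (these
#'   get sharp promoter peaks and positive FPKM).
#' @param marks character vector of mark names.
#' @param breadth_broad,breadth_sharp mean planted domain widths (bp) for
#'   identity and expressed non-identity genes.
#' @param breadth_cv lognormal dispersion (sdlog) of planted widths.
#' @param cross_mark_correlation correlation of log widths across marks,
#'   induced by a shared per-gene latent factor (in `[0, 1]`).
#' @param reads_per_kb_signal,background_reads_per_kb Poisson read densities
#'   inside planted domains and genome-wide background.
#' @param read_len sequenced read length (bp) before 3' extension.
#' @param grn_hub_degree,grn_background_degree mean GRN degree of identity
#'   versus other genes.
#' @param n_tf_background non-identity genes additionally flagged as TFs.
#' @param motif_near_target_rate probability an identity gene receives a
#'   motif site within 2 kb of its TSS.
#' @param motif_background_rate background motif sites per kb of genome.
#' @param motif_width motif site width (bp).
#' @param loop_overlap_rate_conditionA,loop_overlap_rate_conditionB
#'   probability a motif site is covered by a loop anchor in each condition.
#' @param n_background_loops loops unrelated to motif sites per condition.
#' @param loop_anchor_width loop anchor width (bp).
#' @param frac_up,frac_down fractions of genes up-/down-regulated in the
#'   differential table (identity genes are always upregulated, with fold
#'   changes exchangeable with other upregulated genes).
#' @return list of class `simulation_params`.
#' @export
simulation_params <- function(seed = 0,
                              n_chrom = 4, chrom_len = 1e7,
                              n_genes = 1000,
                              identity_fraction = 0.05,
                              expressed_fraction = 0.7,
                              marks = c("H3K4me3", "H3K27ac", "H3K4me1",
                                        "H3K9ac", "H3K4me2"),
                              breadth_broad = 5000, breadth_sharp = 500,
                              breadth_cv = 0.3,
                              cross_mark_correlation = 0.8,
                              reads_per_kb_signal = 100,
                              background_reads_per_kb = 0.5,
                              read_len = 36,
                              grn_hub_degree = 30, grn_background_degree = 4,
                              n_tf_background = 50,
                              motif_near_target_rate = 0.8,
                              motif_background_rate = 0.01,
                              motif_width = 10,
                              loop_overlap_rate_conditionA = 0.13,
                              loop_overlap_rate_conditionB = 0.06,
                              n_background_loops = 100,
                              loop_anchor_width = 2000,
                              frac_up = 0.35, frac_down = 0.30) {
  p <- as.list(environment())
  rates <- c(identity_fraction, expressed_fraction, cross_mark_correlation,
             motif_near_target_rate, loop_overlap_rate_conditionA,
             loop_overlap_rate_conditionB, frac_up, frac_down)
  if (any(rates < 0 | rates > 1)) stop("fractions/rates must lie in [0, 1]")
  if (breadth_broad <= 0 || breadth_sharp <= 0) stop("widths must be > 0")
  if (frac_up + frac_down > 1) stop("frac_up + frac_down must be <= 1")
  structure(p, class = "simulation_params")
}

## fixed per-generator seed offsets keep the streams decoupled while the
## whole bundle remains a pure function of params$seed
seed_for <- function(params, offset) set.seed(params$seed + offset)

#' Simulate a genome and non-overlapping gene models
#'
#' Genes are packed sequentially with intergenic gaps of at least 25 kb so
#' the 10-kb flank assignment logic is exercised unambiguously.
#'
#' @param params a [simulation_params()].
#' @return list with `layout` ([genome_layout()]) and `genes` (`GRanges`
#'   with `gene_id`, `tss`, `tts`).
#' @export
simulate_genome <- function(params) {
  seed_for(params, 0)
  layout <- genome_layout(sprintf("chr%d", seq_len(params$n_chrom)),
                          rep(params$chrom_len, params$n_chrom))
  n <- params$n_genes
  if (n == 0) {
    genes <- GRanges()
    genes$gene_id <- character(0)
    return(list(layout = layout, genes = with_layout(genes, layout)))
  }
  lens <- round(pmin(pmax(rlnorm(n, log(4000), 0.4), 1000), 20000))
  gaps <- round(25000 + rexp(n, 1 / 3000))
  if (sum(lens) + sum(gaps) > genome_size(layout) - params$n_chrom * 25000)
    stop("infeasible packing: genes + gaps exceed the genome size")
  chrom <- character(n); starts <- numeric(n)
  ci <- 1; pos <- 1
  for (i in seq_len(n)) {
    repeat {
      s <- pos + gaps[i]
      if (s + lens[i] - 1 <= layout$lengths[ci] - 1000) break
      ci <- ci + 1
      pos <- 1
      if (ci > params$n_chrom)
        stop("infeasible packing: ran out of chromosomes")
    }
    chrom[i] <- layout$chroms[ci]
    starts[i] <- s
    pos <- s + lens[i] - 1
  }
  genes <- GRanges(chrom, IRanges(starts, width = lens),
                   strand = sample(c("+", "-"), n, replace = TRUE))
  genes$gene_id <- sprintf("g%04d", seq_len(n))
  genes <- with_layout(genes, layout)
  genes$tss <- unname(gene_tss(genes))
  genes$tts <- unname(gene_tts(genes))
  list(layout = layout, genes = genes)
}

#' Plant the ground truth
#'
#' Fixes which genes are identity genes, which are expressed, and the
#' planted per-mark domain widths.  Log widths share a per-gene latent
#' factor so their cross-mark correlation equals
#' `cross_mark_correlation`.
#'
#' @param params a [simulation_params()].
#' @param genes gene models from [simulate_genome()].
#' @return list of class `synthetic_truth`: `identity_genes`,
#'   `expressed_genes`, `planted_breadth` (gene x mark matrix, bp; 0 for
#'   unexpressed genes).
#' @export
simulate_truth <- function(params, genes) {
  seed_for(params, 1)
  ids <- genes$gene_id
  n <- length(ids)
  n_identity <- round(params$identity_fraction * n)
  identity <- sort(sample(ids, n_identity))
  others <- setdiff(ids, identity)
  expressed <- sort(c(identity,
                      sample(others, round(params$expressed_fraction *
                                             length(others)))))
  base <- ifelse(ids %in% identity, params$breadth_broad,
                 ifelse(ids %in% expressed, params$breadth_sharp, 0))
  rho <- sqrt(params$cross_mark_correlation)
  z <- rnorm(n)
  w <- matrix(0, n, length(params$marks),
              dimnames = list(ids, params$marks))
  for (m in seq_along(params$marks)) {
    e <- rnorm(n)
    lat <- rho * z + sqrt(1 - rho^2) * e
    w[, m] <- base * exp(params$breadth_cv * lat)
  }
  w[base == 0, ] <- 0
  w <- round(w)
  structure(list(identity_genes = identity, expressed_genes = expressed,
                 planted_breadth = w),
            class = "synthetic_truth")
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d identity / %d expressed genes, %d mark(s)\n",
              length(x$identity_genes), length(x$expressed_genes),
              ncol(x$planted_breadth)))
  invisible(x)
}

## planted domain interval for one gene: identity domains centered on the
## gene body, sharp peaks centered on the TSS; clipped to gene +- 10 kb and
## to the chromosome
planted_domains <- function(genes, truth, mark, layout, flank = 10000) {
  w <- truth$planted_breadth[genes$gene_id, mark]
  keep <- w > 0
  g <- genes[keep]
  w <- w[keep]
  is_identity <- g$gene_id %in% truth$identity_genes
  center <- ifelse(is_identity, (start(g) + end(g)) / 2, g$tss)
  s <- round(center - w / 2)
  e <- s + w - 1
  s <- pmax(s, start(g) - flank, 1)
  e <- pmin(e, end(g) + flank, layout$lengths[as.character(seqnames(g))])
  dom <- GRanges(seqnames(g), IRanges(s, e))
  dom$gene_id <- g$gene_id
  dom
}

## uniform background fragments over the genome; returns 5'-anchored reads
background_reads <- function(layout, rate_per_kb, read_len, extend_len) {
  n <- rpois(1, genome_size(layout) / 1000 * rate_per_kb)
  if (n == 0) return(GRanges())
  chrom <- sample(layout$chroms, n, replace = TRUE,
                  prob = layout$lengths / genome_size(layout))
  f <- floor(runif(n, 1, layout$lengths[chrom] - extend_len))
  reads_from_fragments(chrom, f, read_len, extend_len)
}

## a fragment [f, f+extend_len-1] sequenced from a random end: the read is
## the first read_len bp in strand orientation, so 3'-extension recovers
## the fragment
reads_from_fragments <- function(chrom, f, read_len, extend_len) {
  n <- length(f)
  st <- sample(c("+", "-"), n, replace = TRUE)
  s <- ifelse(st == "+", f, f + extend_len - read_len)
  GRanges(chrom, IRanges(s, width = read_len), strand = st)
}

#' Simulate per-mark read tracks and a matched input
#'
#' Reads are Poisson-placed fragments: `reads_per_kb_signal` per kb inside
#' each planted domain plus `background_reads_per_kb` genome-wide; the input
#' library contains background only.
#'
#' @param params a [simulation_params()].
#' @param layout,genes from [simulate_genome()].
#' @param truth from [simulate_truth()].
#' @return list with `reads` (named list of `GRanges` per mark) and
#'   `input` (`GRanges`).
#' @export
simulate_mark_reads <- function(params, layout, genes, truth) {
  seed_for(params, 2)
  ext <- 200
  reads <- lapply(params$marks, function(mk) {
    dom <- planted_domains(genes, truth, mk, layout)
    out <- list()
    if (length(dom)) {
      nd <- rpois(length(dom), width(dom) / 1000 * params$reads_per_kb_signal)
      chrom <- rep(as.character(seqnames(dom)), nd)
      lo <- rep(start(dom), nd)
      hi <- rep(pmax(end(dom) - ext + 1, start(dom)), nd)
      f <- floor(runif(length(chrom), lo, hi + 1))
      out$signal <- reads_from_fragments(chrom, f, params$read_len, ext)
    }
    out$bg <- background_reads(layout, params$background_reads_per_kb,
                               params$read_len, ext)
    gr <- combine_granges(unname(out), layout$chroms)
    gr <- with_layout(gr, layout)
    gr$name <- sprintf("r%d", seq_along(gr))
    gr
  })
  names(reads) <- params$marks
  input <- background_reads(layout, params$background_reads_per_kb,
                            params$read_len, ext)
  input <- with_layout(input, layout)
  input$name <- sprintf("i%d", seq_along(input))
  list(reads = reads, input = input)
}

#' Simulate a hub-structured GRN
#'
#' Configuration-style pairing: identity genes draw Poisson degrees with
#' mean `grn_hub_degree`, all others with mean `grn_background_degree`;
#' stubs are shuffled and paired, then self-loops and duplicate edges are
#' dropped.  TF flags = identity genes plus `n_tf_background` random other
#' genes.
#'
#' @inheritParams simulate_mark_reads
#' @return A [grn_graph()] over the full gene universe.
#' @export
simulate_grn <- function(params, genes, truth) {
  seed_for(params, 3)
  ids <- genes$gene_id
  deg <- ifelse(ids %in% truth$identity_genes,
                rpois(length(ids), params$grn_hub_degree),
                rpois(length(ids), params$grn_background_degree))
  stubs <- rep(seq_along(ids), deg)
  if (length(stubs) %% 2 == 1) stubs <- c(stubs, sample(seq_along(ids), 1))
  stubs <- sample(stubs)
  m <- matrix(stubs, ncol = 2)
  tfs <- sort(c(truth$identity_genes,
                sample(setdiff(ids, truth$identity_genes),
                       min(params$n_tf_background,
                           length(ids) - length(truth$identity_genes)))))
  grn_graph(data.frame(source = ids[m[, 1]], target = ids[m[, 2]]),
            nodes = ids, tfs = tfs)
}

#' Simulate motif sites and two-condition chromatin loops
#'
#' Each identity gene receives, with probability `motif_near_target_rate`,
#' a motif site within 2 kb of its TSS; background sites fall uniformly at
#' `motif_background_rate` per kb.  In each condition a site is covered by a
#' loop anchor with the condition's overlap rate, and `n_background_loops`
#' unrelated loops are added.
#'
#' @inheritParams simulate_mark_reads
#' @return list with `sites` (`GRanges`), `loops_A`, `loops_B`
#'   ([loop_set()]s), and `site_looped` (logical matrix, site x condition).
#' @export
simulate_motifs_loops <- function(params, layout, genes, truth) {
  seed_for(params, 4)
  w <- params$motif_width
  idg <- genes[genes$gene_id %in% truth$identity_genes]
  planted <- GRanges()
  if (length(idg)) {
    take <- runif(length(idg)) < params$motif_near_target_rate
    idg <- idg[take]
    if (length(idg)) {
      center <- gene_tss(idg) + round(runif(length(idg), -2000, 2000))
      s <- pmax(center - floor(w / 2), 1)
      planted <- GRanges(seqnames(idg), IRanges(s, width = w))
    }
  }
  nbg <- rpois(1, genome_size(layout) / 1000 * params$motif_background_rate)
  bg <- GRanges()
  if (nbg) {
    chrom <- sample(layout$chroms, nbg, replace = TRUE,
                    prob = layout$lengths / genome_size(layout))
    s <- floor(runif(nbg, 1, layout$lengths[chrom] - w))
    bg <- GRanges(chrom, IRanges(s, width = w))
  }
  sites <- BiocGenerics::sort(combine_granges(list(planted, bg),
                                              layout$chroms),
                              ignore.strand = TRUE)
  sites$name <- sprintf("site%d", seq_along(sites))
  make_loops <- function(rate) {
    looped <- runif(length(sites)) < rate
    a1 <- GRanges(); a2 <- GRanges()
    if (any(looped)) {
      s <- sites[looped]
      aw <- params$loop_anchor_width
      c1 <- round((start(s) + end(s)) / 2)
      off <- round(runif(length(s), 5e4, 5e5)) *
        sample(c(-1, 1), length(s), replace = TRUE)
      c2 <- pmin(pmax(c1 + off, aw),
                 layout$lengths[as.character(seqnames(s))] - aw)
      a1 <- GRanges(seqnames(s), IRanges(pmax(c1 - aw %/% 2, 1), width = aw))
      a2 <- GRanges(seqnames(s), IRanges(pmax(c2 - aw %/% 2, 1), width = aw))
    }
    nb <- params$n_background_loops
    if (nb) {
      aw <- params$loop_anchor_width
      chrom <- sample(layout$chroms, nb, replace = TRUE,
                      prob = layout$lengths / genome_size(layout))
      b1 <- floor(runif(nb, 1, layout$lengths[chrom] - 6e5))
      b2 <- b1 + round(runif(nb, 5e4, 5e5))
      a1 <- combine_granges(list(a1, GRanges(chrom, IRanges(b1, width = aw))),
                            layout$chroms)
      a2 <- combine_granges(list(a2, GRanges(chrom, IRanges(b2, width = aw))),
                            layout$chroms)
    }
    list(loops = loop_set(a1, a2), looped = looped)
  }
  la <- make_loops(params$loop_overlap_rate_conditionA)
  lb <- make_loops(params$loop_overlap_rate_conditionB)
  list(sites = sites, loops_A = la$loops, loops_B = lb$loops,
       site_looped = cbind(A = la$looped, B = lb$looped))
}

#' Simulate a differential-expression table
#'
#' Identity genes are always upregulated; their log2 fold changes are drawn
#' from the same distribution as other upregulated genes, so fold-change
#' rank carries no extra information about identity.
#'
#' @inheritParams simulate_mark_reads
#' @return data.frame with columns `gene_id`, `log2fc`, `qvalue`,
#'   `fpkm_wt`, `fpkm_ko`.
#' @export
simulate_de_table <- function(params, genes, truth) {
  seed_for(params, 5)
  ids <- genes$gene_id
  n <- length(ids)
  n_up <- round(params$frac_up * n)
  n_down <- round(params$frac_down * n)
  pool <- setdiff(ids, truth$identity_genes)
  up <- c(truth$identity_genes,
          sample(pool, max(n_up - length(truth$identity_genes), 0)))
  down <- sample(setdiff(ids, up), min(n_down, n - length(up)))
  lfc <- rnorm(n, 0, 0.15)
  q <- runif(n, 0.1, 1)
  iu <- ids %in% up; idn <- ids %in% down
  lfc[iu] <- 0.25 + stats::rgamma(sum(iu), shape = 2, rate = 1.2)
  lfc[idn] <- -(0.25 + stats::rgamma(sum(idn), shape = 2, rate = 1.2))
  q[iu | idn] <- runif(sum(iu | idn), 0, 0.04)
  expressed <- ids %in% truth$expressed_genes | iu | idn
  fpkm_wt <- ifelse(expressed, rlnorm(n, log(10), 1.2), runif(n, 0, 0.5))
  fpkm_wt[iu | idn] <- pmax(fpkm_wt[iu | idn], 1.5)
  fpkm_ko <- fpkm_wt * 2^(-lfc)
  data.frame(gene_id = ids, log2fc = lfc, qvalue = q,
             fpkm_wt = fpkm_wt, fpkm_ko = fpkm_ko)
}

#' Simulate GO-like pathway gene sets
#'
#' One pathway whose name carries the keyword `endothelial` contains the
#' identity genes plus random extras; decoy pathways contain random genes.
#'
#' @inheritParams simulate_mark_reads
#' @return named list of character vectors.
#' @export
simulate_pathways <- function(params, genes, truth) {
  seed_for(params, 6)
  ids <- genes$gene_id
  extras <- sample(setdiff(ids, truth$identity_genes),
                   min(30, length(ids) - length(truth$identity_genes)))
  sets <- list("synthetic endothelial identity program" =
                 sort(c(truth$identity_genes, extras)))
  for (i in 1:5)
    sets[[sprintf("synthetic housekeeping module %d", i)]] <-
      sort(sample(ids, min(40, length(ids))))
  sets
}

#' Generate and write the full synthetic bundle
#'
#' Runs every generator and serializes the standard file set: genome.tsv,
#' genes.bed12, tags_<mark>.bed, input.bed, grn.tsv, tfs.txt, motifs.bed,
#' loops_A.bedpe, loops_B.bedpe, de_table.tsv, pathways.gmt, truth.json.
#'
#' @param params a [simulation_params()].
#' @param dir output directory (created if needed); `NULL` keeps everything
#'   in memory only.
#' @return Invisibly, a list with all simulated objects (`layout`, `genes`,
#'   `truth`, `reads`, `input`, `grn`, `motifs`, `de_table`, `pathways`)
#'   and, when `dir` is given, the file `paths`.
#' @export
simulate_bundle <- function(params = simulation_params(), dir = NULL) {
  gen <- simulate_genome(params)
  truth <- simulate_truth(params, gen$genes)
  rd <- simulate_mark_reads(params, gen$layout, gen$genes, truth)
  grn <- simulate_grn(params, gen$genes, truth)
  ml <- simulate_motifs_loops(params, gen$layout, gen$genes, truth)
  de <- simulate_de_table(params, gen$genes, truth)
  pw <- simulate_pathways(params, gen$genes, truth)
  res <- list(layout = gen$layout, genes = gen$genes, truth = truth,
              reads = rd$reads, input = rd$input, grn = grn, motifs = ml,
              de_table = de, pathways = pw, params = params)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(genome = file.path(dir, "genome.tsv"),
                  genes = file.path(dir, "genes.bed12"),
                  input = file.path(dir, "input.bed"),
                  grn = file.path(dir, "grn.tsv"),
                  tfs = file.path(dir, "tfs.txt"),
                  motifs = file.path(dir, "motifs.bed"),
                  loops_a = file.path(dir, "loops_A.bedpe"),
                  loops_b = file.path(dir, "loops_B.bedpe"),
                  de_table = file.path(dir, "de_table.tsv"),
                  pathways = file.path(dir, "pathways.gmt"),
                  truth = file.path(dir, "truth.json"))
    write_genome_layout(gen$layout, paths$genome)
    write_genes_bed12(gen$genes, paths$genes)
    paths$marks <- setNames(file.path(dir, sprintf("tags_%s.bed", params$marks)),
                            params$marks)
    for (mk in params$marks) write_bed6(rd$reads[[mk]], paths$marks[[mk]])
    write_bed6(rd$input, paths$input)
    write.table(data.frame(source = grn$nodes[grn$edge_idx[, 1]],
                           target = grn$nodes[grn$edge_idx[, 2]]),
                paths$grn, sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(grn$tfs, paths$tfs)
    write_bed6(ml$sites, paths$motifs)
    write_bedpe(ml$loops_A, paths$loops_a)
    write_bedpe(ml$loops_B, paths$loops_b)
    write.table(de, paths$de_table, sep = "\t", quote = FALSE,
                row.names = FALSE)
    write_gmt(pw, paths$pathways)
    jsonlite::write_json(
      list(identity_genes = truth$identity_genes,
           expressed_genes = truth$expressed_genes,
           planted_breadth = as.data.frame(truth$planted_breadth)),
      paths$truth, digits = NA)
    res$paths <- paths
  }
  invisible(res)
}

#' Read / write a genome layout TSV (chrom, length)
#' @param layout a [genome_layout()].
#' @param path file path.
#' @export
write_genome_layout <- function(layout, path) {
  write.table(data.frame(chrom = layout$chroms,
                         length = format(layout$lengths, scientific = FALSE,
                                         trim = TRUE)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genome_layout
#' @export
read_genome_layout <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  genome_layout(df$chrom, as.numeric(df$length))
}
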