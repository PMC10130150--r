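# broadscape

Prioritizing cell identity genes from broad epigenomic domains.

## The problem

The regulators that establish and maintain a cell lineage — for example the
transcription factors behind endothelial identity — are hard to find by
expression alone: housekeeping genes are just as highly expressed. What sets
identity genes apart is their chromatin: they sit under exceptionally
**broad** domains of activating marks (kilobase-scale H3K4me3 across
promoter and gene body, super-enhancer-scale H3K27ac/H3K4me1, broad H3K9ac,
H3K4me2 and open chromatin), while most other active genes carry sharp
promoter peaks. broadscape implements that observation as a tested,
end-to-end prioritization pipeline for computational biologists working
from aligned ChIP-seq/DNase-seq tags, gene models, a gene regulatory
network, motif sites and chromatin loops.

## The method

1. **Domain calling.** Reads (BED6) are extended 200 bp from the 5' end,
   binned at 10 bp, depth-normalized, optionally input-subtracted, and
   segmented with a two-threshold Poisson rule: bins with upper-tail
   probability ≤ 1e−5 under the background rate λ seed regions, which
   extend through bins with tail ≤ 1e−3 and merge when touching.
2. **Breadth ranking.** Each region is assigned to genes it overlaps (or,
   if intergenic, genes whose TSS/TTS lie within 10 kb); gene breadth =
   total assigned width. Genes are ranked per mark (descending, average
   ties) and the per-mark ranks are averaged into one list:
   `combined_rank(g) = mean_m rank_m(g)`.
3. **Enrichment.** The overlap of a positive gene set with the top-n list
   is tested by the two-tailed Fisher exact test; fold enrichment is
   `(overlap/n) / (|set|/|universe|)`.
4. **Network scoring.** Top-k groups are compared by the number of GRN
   edges internal to the group against seeded random groups; per-TF
   centrality is the number of length-2 paths through the gene,
   `choose(degree, 2)`.
5. **Motifs and loops.** PWM scanning (log2-odds, both strands), cumulative
   motif-to-TSS distance enrichment, promoter-window (TSS to 5 kb upstream)
   motif gene sets, and the fraction of sites overlapping loop anchors,
   compared between conditions with an exact two-sample Poisson test.

A synthetic-data module plants ground truth (identity genes with broad,
cross-mark-correlated domains; GRN hubs; motif proximity; condition-
dependent loop overlap) so every stage is testable without downloads.

## Worked example

Simulate the default study (1,000 genes, 50 planted identity genes, five
marks) and run the pipeline on the written files:

```r
library(broadscape)

params <- simulation_params(seed = 0)
bundle <- simulate_bundle(params, "ec_sim")

cfg <- pipeline_config(
  inputs = list(genome  = "ec_sim/genome.tsv",
                genes   = "ec_sim/genes.bed12",
                marks   = as.list(bundle$paths$marks),
                input   = "ec_sim/input.bed",
                de_table = "ec_sim/de_table.tsv",
                grn     = "ec_sim/grn.tsv",
                tfs     = "ec_sim/tfs.txt",
                motifs  = "ec_sim/motifs.bed",
                loops_a = "ec_sim/loops_A.bedpe",
                loops_b = "ec_sim/loops_B.bedpe",
                pathways = "ec_sim/pathways.gmt"),
  params = list(norm_total = "observed", top_n = 50, grn_k = 400, seed = 7))

res <- run_pipeline(cfg)
res
#> broadscape pipeline result
#>   regions: H3K4me3=717, H3K27ac=719, H3K4me1=718, H3K9ac=718, H3K4me2=715
#>   top-50 enrichment: overlap 50, fold 16.95, p 1.33e-75
#>   loop overlap: 13.90% vs 7.44%, p 0.00667
```

~718 enriched domains are called per mark (50 broad identity domains plus
sharp peaks at expressed genes). The head of the combined ranking:

```r
head(as.data.frame(res$breadth_table)[,
  c("gene_id", "breadth_H3K4me3", "rank_H3K4me3", "combined_rank")], 5)
#>   gene_id breadth_H3K4me3 rank_H3K4me3 combined_rank
#> 1   g0874            7140            4           3.2
#> 2   g0037            6560            7           4.0
#> 3   g0554            7080            5           4.1
#> 4   g0277            7600            1           5.2
#> 5   g0836            6780            6           5.5
```

Breadths are in bp (identity domains ~5–8 kb after calling, sharp peaks
~0.5–1 kb), and `combined_rank` is the mean of the five per-mark ranks. All
50 of the top-50 genes belong to the keyword-derived positive set of 59
(fold 16.9, Fisher p = 1.3e−75):

```r
res$enrichment
#> enrichment_result: 50/59 of top 50 in set (|set| 59, universe 1000)
#>   fold = 16.9, two-tailed Fisher p = 1.33e-75
```

The breadth-ranked top-400 group carries 746 internal GRN edges versus
420 for random groups of the same size (empirical p = 1/1001, the floor at
1000 random draws), while expression-ranked groups do no better than
random:

```r
res$grn_comparison
#>           name internal_edges tf_count     p_edges
#> 1      breadth        746.000       62 0.000999001
#> 2   expression        345.000       34 0.984015984
#> 3 differential        732.000       63 0.000999001
#> 4       random        420.425       NA          NA
```

Finally, motif sites overlap loop anchors in 13.90% of cases in condition A
versus 7.44% in condition B (two-sample Poisson p = 0.0067), recovering the
planted two-condition contrast.

A thin CLI wrapper ships in `inst/scripts/broadscape`
(`broadscape simulate`, `broadscape run --config pipeline.yaml`).

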