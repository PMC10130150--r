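---
title: "Methods: breadth-based prioritization of cell identity genes"
author: "broadscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: breadth-based prioritization of cell identity genes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(broadscape)
```

## The model

Cell identity genes — the transcription factors and effectors that define a
lineage — tend to sit under exceptionally *broad* domains of activating
chromatin marks: kilobase-scale H3K4me3 spanning promoter and gene body,
super-enhancer-scale H3K27ac and H3K4me1, broad H3K9ac and H3K4me2, and
broad open chromatin. Most other active genes, including highly expressed
housekeeping genes, show sharp promoter peaks instead. broadscape turns that
contrast into a ranking statistic: the **gene-level breadth** of each mark
(total width, in bp, of the enriched regions assigned to a gene), ranked per
mark and averaged across marks.

### Enriched-region calling

The caller operates on binned signal. Reads are extended 200 bp from their
5' end in the strand direction (the typical ChIP fragment size), coverage is
averaged in 10-bp bins, libraries are depth-normalized (by default to 25
million mapped reads), and a matched input track, normalized to the same
total, may be subtracted with clamping at zero.

Segmentation is a two-threshold Poisson seed-and-extend rule. With
background rate $\lambda$ (signal per bin), a bin whose rounded value $k$
satisfies $P(X \ge k \mid \lambda) \le 10^{-5}$ nucleates a region; the
region grows bin-by-bin through neighbours with tail probability
$\le 10^{-3}$, and touching regions merge. Because the Poisson tail is
monotone in $k$, this is implemented as two integer count thresholds, which
makes the segmentation exactly equivalent to per-bin tail evaluation (the
test suite checks this against a brute-force per-bin reference).

Choices the procedure leaves open, fixed here:

* **Background rate.** $\lambda$ defaults to the genome-wide mean bin value
  of the track being segmented. A global Poisson background is the simplest
  reproducible choice; a locally estimated background is out of scope.
* **Rounding.** Bin values are rounded half-up before the tail test —
  Poisson support is integral and half-up is deterministic (R's `round()`
  rounds half to even).
* **Merging.** Regions separated by zero bins merge; there is no gap
  bridging parameter.
* **Replicates** are pooled before calling; no replicate variance model is
  fitted.
* **Smoothing** is a no-op (smooth width 0 bp).

### Depth normalization and the Poisson model

The Poisson background applies on the count scale. Real ~25M-read libraries
normalized to 25M keep a scale factor near 1, so the normalized values stay
count-like. The synthetic studies shipped with the package have far fewer
reads, so their pipeline configurations normalize each library to its own
observed total (`norm_total: "observed"`, scale 1): multiplying sparse
counts by a large factor would break the Poisson calibration without adding
information for a single-sample comparison. Peak calls are invariant to
duplicating a library $k$-fold and renormalizing, which the suite checks.

### Gene-level breadth and rank combination

A region is assigned to a gene if it overlaps the gene body by at least
1 bp, or if it is intergenic (overlaps no gene body) and lies within 10 kb
of the gene's TSS or TTS, measured as the minimal gap between interval ends.
A region may count toward several genes (`multi_assign = "all"`, with a
`"nearest"` alternative); breadth is monotone under region widening either
way. Isoforms are collapsed to the maximal genomic span before assignment,
so ranking is strictly gene-level.

Per mark, genes are ranked by descending breadth with average ties — all
zero-breadth genes share one averaged rank, so unmarked genes are not
ordered arbitrarily. The combined rank is the arithmetic mean of the
per-mark ranks (five activating marks by default), with deterministic
lexicographic tie-break on gene id in the final ordering.

### Enrichment, network, motif and loop statistics

* **Gene-set enrichment** of the top-$n$ genes uses the two-tailed Fisher
  exact test (`stats::fisher.test`, minimum-likelihood summation) on the
  top/not-top × in-set/not table, with fold enrichment
  $(o/n)/(K/N)$. The suite validates the p value against an independent
  hypergeometric enumeration to $10^{-12}$ relative error.
* **Positive sets** are built as (union of pathways whose name contains a
  keyword, case-insensitive substring) ∩ (upregulated genes), where the
  differential filter keeps genes with $q < 0.05$ and FPKM $> 1$ in at
  least one sample.
* **GRN scoring** treats edges as undirected and deduplicated. A group's
  internal edge count (both endpoints inside; an incident mode is also
  provided — the field's figure legends are ambiguous between the two) is
  compared with uniform random groups of the same size; the empirical p is
  $(1 + \#\{\text{random} \ge \text{obs}\})/(n_{\text{random}} + 1)$.
  Path centrality of a gene is the number of length-2 simple paths centered
  on it, $\binom{\deg}{2}$; "paths through a gene and its neighbours" admits
  longer-path readings, but the length-2 count is the simplest consistent
  one and is what the package implements throughout.
* **Motif scanning** scores every window of both strands with a log2-odds
  PWM (pseudocount $10^{-3}$ per cell before the log; `N` scores as
  background, contributing 0) and reports sites at or above a threshold in
  forward-strand coordinates.
* **Cumulative distance enrichment** dichotomizes target and background
  genes by whether a motif site lies within distance $d$ of the TSS
  (unsigned, either side) and applies the Fisher test at each $d$ of an
  ascending grid — a cumulative curve, not sliding bins. Both fold and p
  are emitted, since either may be the quantity of interest. The
  promoter-window gene set instead uses a strand-aware, upstream-only
  window: 5 kb upstream up to, and excluding, the TSS.
* **Loop overlap** counts a site once if it overlaps (≥ 1 bp, half-open on
  disk) either anchor of at least one loop. Two conditions are compared
  with the exact conditional two-sample Poisson test: given $k_1 + k_2$,
  $k_1 \sim \mathrm{Binomial}(k_1+k_2,\, n_1/(n_1+n_2))$ under the null,
  two-tailed by minimum-likelihood summation (`stats::binom.test`).

## The synthetic study

The generators plant ground truth that mirrors the statistical structure
the method assumes, so recovery can be scored exactly. The default study
(all values fixed once, chosen to be realistic at desk scale):

| parameter | default | why |
|---|---|---|
| genome | 4 × 10 Mb | large enough for 1,000 genes with ≥ 25 kb gaps, so the 10-kb flank rule is unambiguous |
| genes | 1,000; 5% identity; 70% of the rest expressed | a workable universe with a small planted positive class |
| marks | H3K4me3, H3K27ac, H3K4me1, H3K9ac, H3K4me2 | the five activating marks whose breadths co-vary most strongly |
| planted widths | broad 5 kb (identity, centered on the gene body) vs sharp 0.5 kb (expressed, at the TSS); lognormal, sdlog 0.3 | an order-of-magnitude breadth contrast at realistic domain scales |
| cross-mark correlation | 0.8 via a shared per-gene latent factor | broad domains co-occur across marks on the same genes |
| reads | 100/kb inside domains vs 0.5/kb background; 36-bp reads, Poisson-placed fragments | strong but noisy enrichment over a sparse background |
| GRN | hub degree 30 (identity) vs 4 (others), configuration-model pairing | identity regulators sit as hubs |
| motifs | 80% of identity genes get a site within 2 kb of the TSS; 0.01 background sites/kb | TF binding concentrates near targets |
| loops | anchor covers a site with probability 0.13 (condition A) vs 0.06 (condition B); 2-kb anchors; 100 background loops | a two-condition overlap contrast of the magnitude seen in real loop data |
| differential table | 35% up / 30% down; identity genes always up, fold changes exchangeable with other up genes | a distant-cell-type comparison; fold-change magnitude carries no identity information |

Every generator is a pure function of `(params, seed)`; each derives its
stream from the seed with a fixed offset so the bundle is reproducible
bit-for-bit.

What the generator deliberately does **not** emulate: nucleosome-level
signal shape, mappability and GC bias, overdispersed (non-Poisson) read
placement, overlapping genes, correlated expression and identity, and
directed regulatory edges. Passing the recovery tests therefore shows the
pipeline's logic is correct and calibrated under its own model — not that
real ChIP-seq meets that model.

### Group-size regimes for the network comparison

The network comparison contrasts the top-400 breadth group with groups of
equal size ranked by expression, by fold change, and at random. Fold-change
ranking dilutes the identity genes only when the differential set is larger
than the group size — the regime real data are in, where thousands of genes
change between distant cell types. The packaged network-pattern check
therefore runs on a 2,000-gene universe (identity fraction 2.5%, 700 up /
600 down), keeping $k/N$ and $k/N_{\mathrm{up}}$ in that regime; at the
1,000-gene default the upregulated set (350) would sit entirely inside any
top-400 list and the comparison would degenerate.

### Problem sizes used by the shipped checks

The test suite runs the full default study once (1,000 genes, five marks,
~80k reads per mark), the null calibration on a 1-chromosome 10-Mb genome,
the empirical-p calibration over 200 replicate seeds with 499 random groups
each, and the network pattern over 100 seeds. Oracle-equivalence checks use
100 random tracks (≤ 1,000 bins), 500 random 2×2 tables (N ≤ 200), 100
random graphs (≤ 50 nodes), one 10-kb scanned sequence, and 1,000 random
sites against a quadratic overlap scan.

## Numerical and degenerate-input choices

* Poisson count thresholds come from `qpois` and are verified against
  `ppois` in both directions, so threshold equality cases follow the tail
  test exactly.
* An empty track, or a track whose estimated background is zero, yields an
  empty region set, not an error; an empty gene universe is an error.
* `fisher_top_n` requires the gene set to be inside the universe and the
  ranking to cover it exactly; silent restriction would change the table.
* Fold enrichment is 0 for empty overlap and `Inf` when the background hit
  rate is 0 in the distance curve; both are reported as computed.
* The two-sample Poisson test returns p = 1 when both counts are zero.
* Trailing partial bins (chromosome length not a multiple of the bin size)
  are treated as full bins for segmentation; region ends are clipped to the
  chromosome.

## Limitations

* The global Poisson background understates local variation (input is
  subtracted, but domain-scale covariates are not modelled); on real data a
  matched input is strongly recommended.
* Breadth is assigned to every qualifying gene, so nested or adjacent genes
  share credit; `multi_assign = "nearest"` is available but changes the
  monotonicity guarantees for shared regions.
* The centrality statistic is degree-based (length-2 paths); it does not
  capture betweenness-style global position.
* The cumulative distance curve conditions on gene TSSs only; enhancer
  assignment by chromatin contact is consumed (as loops), not inferred.
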