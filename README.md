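# adipodyn

Comparative transcriptomic and epigenomic analysis of differentiation time
courses, built around the brown-versus-white adipogenesis setting: brown
adipocytes (BA) differentiating from mesenchymal stem cells via BMP7-driven
lineage commitment, compared against white adipocytes (WA) differentiating
from committed preadipocytes, each sampled at five stages (BA: d-3, d0, 6h,
d2, d7; WA: d-4/d-2, d0, 6h, d2, d7).

The package is for computational biologists who have per-stage expression
tables (FPKM for coding genes and lncRNAs, array signal for microRNAs),
per-stage histone-mark peak sets and read positions (H3K27ac, H3K4me3,
H3K4me1, H3K27me3), and TF ChIP-seq peaks, and who want to ask: which genes
and which enhancers act at which stage, which are lineage-specific, where
are the super-enhancers and what do they regulate, and where does a given
TF bind relative to all of that. A synthetic-data generator with planted,
recorded ground truth makes the whole pipeline testable end to end without
any external download.

## The methods at the core

**Stage-specificity entropy.** For a feature with abundance `E_i` across
`N` ordered stages, relative expression is `R_i = E_i / sum(E)` and

```
H = - sum_i R_i * log2(R_i),      0 <= H <= log2(N)
```

`H = 0` means single-stage expression, `H = log2(N)` means uniform
expression. A coding gene is assigned to stage *s* when `H < 2`, its FPKM
exceeds 5 in *s*, and FPKM > 5 is seen in at most three additional stages
(lncRNAs use 0.5 instead of 5; quantile-normalized miRNAs use a strict
two-fold variation rule with argmax-stage assignment).

**Day-7 lineage classes.** Pooled d7 stage-specific genes are BA-specific
when BA d7 FPKM >= 3 x WA d7 FPKM and WA d7 FPKM < 10 (mirrored for WA;
the rest are shared adipogenic genes); lncRNAs use a plain 5-fold rule,
and optional tissue / primary-cell expression can confirm calls at
2.5-fold.

**Enhancers.** Candidate enhancers are pooled H3K27ac regions that overlap
neither pooled H3K4me3 regions nor any TSS +/- 2.5 kb window. Per-stage
H3K27ac reads are extended to 300 bp, quantified as RPKM over the
candidate regions, and z-score normalized; a region is a stage-specific
enhancer in *s* when z > 1 in *s* and z > 0 in at most three additional
stages.

**Super-enhancers.** Active enhancers (z > 0) within 12.5 kb are stitched;
stitched spans larger than 12.5 kb are ranked by their re-quantified RPKM,
and the calls above the slope > 0.5 crossing of the scaled rank-signal
curve are super-enhancers (SEs). Day-7 SEs overlapping any early-stage SE
are removed to give late-specific SEs. Targets are expressed genes
(FPKM > 1) within 100 kb whose expression profile correlates with SE
activity at Pearson r > 0.75 (or the single best gene at r > 0.5 as a
fallback); TF-defined SEs instead take the nearest gene.

**Promoter chromatin state and TF binding.** Promoter z-RPKM of each mark
is compared between lineages per gene group with Welch t-tests; TF peaks
are classified by midpoint (promoter > exon > intron > TTS-proximal >
intergenic) and their signal summed over each group's H3K27ac-defined
regulatory space.

## Worked example

```r
library(adipodyn)

## entropy of a sharply d-3-specific profile
entropy_score(c(120, 0.4, 0.2, 0.3, 0.1))$H
#> [1] 0.08426159

## stage assignment: a late-induced gene lands on d2 and d7, a uniformly
## expressed cycling gene is assigned nowhere
m <- rbind(Ucp1_like = c(0.3, 0.4, 0.2, 6.1, 162.0),
           Cycling   = c(88, 85, 91, 84, 90))
colnames(m) <- c("d-3", "d0", "6h", "d2", "d7")
select_stage_specific(m, "coding")
#>   feature_id  class stage         H  expr
#> 1  Ucp1_like coding    d2 0.2798428   6.1
#> 2  Ucp1_like coding    d7 0.2798428 162.0
```

The one-command demo generates the default synthetic fixture (2,000 genes,
200 planted stage-specific genes per lineage, 200 planted stage-specific
enhancers per lineage, 20 super-enhancer loci per lineage with co-varying
target genes), runs the full pipeline, and scores recovery against the
planted truth:

```r
d <- run_demo(seed = 1, out = "demo_out")
round(unlist(d$report[1:11]), 3)
#>    stage_gene_recall stage_gene_precision     stage_lnc_recall
#>                0.996                0.989                1.000
#>  stage_lnc_precision       lineage_recall    lineage_precision
#>                1.000                1.000                0.993
#>      enhancer_recall   enhancer_precision            se_recall
#>                1.000                1.000                1.000
#>     se_target_recall        se_decoy_rate
#>                1.000                0.000
```

`demo_out/` then holds every table the pipeline writes (stage-specific
gene / lncRNA / miRNA lists, lineage calls, enhancer calls and BED tracks,
ranked SE curves, SE target assignments, TF annotation and enrichment, a
run manifest echoing every threshold, and the recovery report). Recall and
precision are measured against the expected calls implied by the
generator's noise-free profiles; a recall of 1.000 means every planted
element was recovered from the noisy data.

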