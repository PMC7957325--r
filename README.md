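# germfate

Analysis toolkit for studying how zebrafish primordial germ cells (PGCs)
diverge from somatic cells across early development — transcriptionally,
in chromatin accessibility, in DNA methylation, and in germ-granule
geometry. It is aimed at developmental and regulatory genomicists who work
with staged, cell-sorted RNA-seq/ATAC-seq/RRBS designs (two cell types ×
five stages from 256-cell to prim-5, in duplicate) and want the bespoke
statistics of such a study as tested, reusable functions rather than
one-off scripts.

Everything runs on synthetic data with ground truth: a seeded generator
module emulates the full study design (maternal/zygotic transcript
classes, germ-plasm-stabilized transcripts, replicate-reproducible and
irreproducible ATAC elements, stage-dependent enhancer demethylation in
soma only, granule–nucleus contact geometry), so every analysis stage can
be validated end to end without any downloads.

## What it computes

**RNA.** Median-of-ratios size factors; TPM; the zygotic-gene rule
(TPM < 2 at the pre-ZGA stage *and* rising at the next stage); absolute
RNA quantification from ERCC spike-ins by ordinary least squares in
log10–log10 space, *y = a + bX* with X = log10 concentration and
y = log10 RPKM, after discarding spike-ins with RPKM < 1; and a simplified
negative-binomial Wald test for differential counts (common
method-of-moments dispersion, BH adjustment).

**Intron retention.** The IR ratio of an intron with intronic depth *D*
and splice-site reads *SS5*, *SS3* is

    IR = D / (max(SS5, SS3) + D)

a proxy for nascent transcription. Gene-level IR is the coverage-weighted
mean across introns, and a permutation test (default 10,000 draws of
same-size random gene sets, two-sided p with the +1 correction, 95% null
interval, companion Welch t-test) asks whether a gene subgroup shifts its
IR between stages more than chance.

**Chromatin.** Paired-end fragments are converted to Tn5 cut sites with
the standard offset correction (start + 5, end − 4; MAPQ ≥ 10;
chromosomes 1–25, mitochondrial excluded; duplicates kept), extended by
±25 bp (browser tracks) or ±5 bp (PCA/SOM signal). A global-background
Poisson window scan calls peaks; a two-component Gaussian copula mixture
fitted on rank-transformed replicate scores gives each peak a local and
global irreproducible discovery rate (IDR); and the candidate-enhancer
cascade keeps IDR ≤ 0.05 peaks, drops those within 500 bp of a TSS or
wider than 1 kb, union-merges conditions and re-filters width, logging
survivor counts at every step. Accessibility signal in 601-bp windows
feeds PCA (column-centered SVD) and a 3×3 batch self-organizing map (nine
clusters) on log-fold-change profiles. Differential accessibility uses
|logFC| > 1, padj < 0.05 and fold enrichment > 4.

**Methylation.** Bismark-dialect CpG tables filtered at coverage ≥ 6,
coverage-weighted region summaries, and per-CpG Fisher exact tests on
pooled group counts with a BH-adjusted differential fraction.

**Granules.** From labeled masks: region areas/perimeters by edge
counting, and the granule–nucleus contact ratio — boundary length
adjacent to the nucleus divided by the total granule area of the cell —
compared across conditions with Wilcoxon rank-sum tests.

## Worked example

```r
library(germfate)

cfg <- simConfig(seed = 1)            # the default staged study design
sim <- simulateExpression(cfg)        # counts + ground-truth labels
ce  <- sim$counts                     # a CountExperiment (SummarizedExperiment)

sizeFactors(ce)[1:4]
#> PGC_256-cell_1 PGC_256-cell_2     PGC_high_1     PGC_high_2
#>          1.210          1.223          1.261          1.275

tp <- tpm(ce)
genes <- rownames(ce)[!SummarizedExperiment::rowData(ce)$spike_in]
cd <- SummarizedExperiment::colData(ce)
tpmByStage <- vapply(stages(cfg), function(st)
    rowMeans(tp[genes, cd$cell_type == "PGC" & cd$stage == st, drop = FALSE]),
    numeric(length(genes)))
calls <- classifyZygotic(tpmByStage, stages(cfg))
table(calls)
#> calls
#> not_zygotic     zygotic
#>        1721         279

mean(calls[sim$truth$geneClass[genes] == "zygotic"] == "zygotic")
#> [1] 0.962            # classifier sensitivity against the planted truth

irRatio(10, 30, 20)
#> [1] 0.25             # intronic depth 10 against 30 splice-site reads
```

The size factors hover near 1 because all samples were simulated at the
same depth; the 279 zygotic calls recover 96% of the genes planted as
zygotically activated, with the remainder missed where sampling noise
put a stray pre-ZGA read above threshold. `runEndToEnd(cfg)` drives the
same dataset through every stage (chromatin, methylation, granules
included) and returns a report with per-stage truth-recovery metrics.

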