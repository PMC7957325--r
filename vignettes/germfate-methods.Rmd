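---
title: "Methods and design of the germfate pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of the germfate pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

germfate quantifies how zebrafish primordial germ cells (PGCs) diverge
from somatic cells across the first day of development. This vignette
explains each statistical component, the assumptions it rests on, the
parameters that matter, and the design decisions taken where more than
one reasonable implementation existed. It states no empirical result that
the package's tests and acceptance script do not themselves compute.

# The study design being modelled

The object of study is a two-cell-type (PGC, soma) by five-stage
(256-cell, high, dome, 10-somites, prim-5) by two-replicate design.
The first stage precedes zygotic genome activation (ZGA); divergence
between the cell types grows across the series and is assayed on three
molecular layers (RNA, chromatin accessibility, CpG methylation) plus a
geometric one (germ-granule position relative to the nucleus).

# RNA components

**Size factors** are median-of-ratios: for features with no zero count, a
per-feature geometric-mean pseudo-reference is built and each sample's
factor is the median ratio to it. Factors are renormalized to geometric
mean one, which makes them unique and keeps the data on its original
scale; the estimator assumes most features are not differential.

**Zygotic classification** is a two-point rule on staged TPM profiles:
expression below 2 TPM at the pre-ZGA stage and strictly rising at the
next analysed stage. Both inequalities are strict, so ties are classified
as not zygotic. The 2-TPM threshold is exposed (`tpmThreshold`). The rule
uses only the first two stages by construction; later stages cannot
change a call.

**ERCC calibration** regresses log10 observed RPKM on log10 known
concentration (attomoles/µL) after discarding spike-ins below 1 RPKM —
points near the detection floor are dominated by count discreteness and
would bend the line. RPKM uses total mapped reads including spike-ins as
denominator (a documented convention; the alternative, genes-only
denominators, changes the intercept but not the slope). Inverting the
fitted line converts an observed RPKM into an absolute concentration.
The normal equations are solved directly, so the fit is exact for
noiseless input.

**Differential counts** use a negative-binomial Wald test with one
dispersion for all features, estimated by the method of moments on
normalized within-group variances (10%-trimmed mean across features with
signal, floored at zero). The log fold change uses a pseudocount of 0.5
to stay defined at zero means; standard errors follow the delta method,
`Var(log mean) ≈ (1/mu + alpha)/n` per group. This is a deliberate
simplification of shrinkage-based frameworks: no per-feature dispersion,
no outlier handling. Its type-I calibration at the simulated design
(n = 3 vs 3, dispersion 0.05) is asserted by the test suite. For
chromatin use, a significance call additionally requires the element's
peak fold enrichment over background to exceed 4.

# Intron retention

The IR ratio of one intron is `D / (max(SS5, SS3) + D)`: intronic depth
against the better-supported splice site. It is undefined (NA) when all
three numbers are zero. Gene-level IR is the mean of intron IRs weighted
by each intron's own denominator, so well-covered introns dominate;
the aggregation rule is a package decision (the upstream tooling it
replaces does not document one), and the weight equals the evidence
supporting the ratio.

The permutation test compares a subgroup's mean IR shift between two
stages to shifts of random same-size gene sets drawn without replacement
from all genes with defined IR in both stages. The default 10,000 draws
give a p-value resolution of about 1e-4; the +1 correction keeps p
strictly positive. Two-sided p is used, matching the symmetric 95% null
interval reported alongside. A mean statistic is the default; a median
option exists because the choice is not dictated by anything deeper than
robustness taste. A Welch t-test of subgroup post- vs pre-stage IR is
reported as a companion, not as the primary inference.

# Chromatin components

**Tn5 correction.** A fragment [start, end) in 0-based half-open
coordinates yields cut sites start + 5 and end − 4, the standard
correction for the transposase's 9-bp duplication. Fragments whose
corrected sites collapse (shorter than 10 bp) are skipped and counted.
Filters: MAPQ ≥ 10, chromosomes 1–25 only, mitochondrial excluded, no
duplicate removal. Both "chr1" and "1" spellings are accepted; "chrM"
and "MT" are mitochondrial aliases. Cut sites are extended ±25 bp for
browser-style tracks and ±5 bp for PCA/SOM signal; each retained
fragment therefore contributes exactly two (2·extension + 1)-bp windows,
a conservation law the tests assert.

**Peak calling** is a global-background Poisson scan, the no-local-lambda
regime of the tool it replaces: non-overlapping windows are scored by the
Poisson upper tail of their cut-site event count against
`totalEvents / genomeSize × window`; touching significant windows merge.
Two numerical points matter. First, the tested statistic is the window
coverage sum divided by the per-cut-site footprint (2·extension + 1) —
raw extended-coverage sums are autocorrelated and badly overdispersed
relative to Poisson. Second, tail probabilities are computed in log
space; deep peaks otherwise underflow to p = 0 and tie at a saturated
score, which would destroy the rank-based reproducibility analysis
downstream. The genome-size parameter scales the background exactly as
the conventional `-g` option does (1.412e9 for the real zebrafish
assembly; the summed track chromosome lengths by default for synthetic
genomes). One caveat is inherent to paired cut sites: the two sites of
one fragment are one insert length apart, so windows wider than the
typical insert see correlated events and the Poisson null is mildly
anticonservative there; calibration tests use windows narrower than the
insert.

**IDR.** Matched replicate peak scores (overlap ≥ 1 bp, greedy
best-score matching, each peak used once) enter through their ranks
`u = rank/(n+1)` and are modelled as a two-component Gaussian copula
mixture: independent standard-normal noise versus a reproducible
component with mean (mu, mu), s.d. sigma and correlation rho. EM from
the fixed start (p, rho, mu, sigma) = (0.5, 0.8, 1, 1) recomputes the
pseudo-data `z = G⁻¹(u)` from the current mixture marginal each
iteration; because that EM path ignores the Jacobian of the marginal
transform, the estimate is finished by quasi-Newton maximization of the
exact copula pseudo-likelihood (`idrCopulaLogLik`), giving a single
well-defined objective that a brute-force grid search can verify.
Convergence is 1e-6 on either the log-likelihood or the maximum
parameter change; non-convergence is flagged, not fatal. A peak's local
irreproducibility is the posterior of the noise component; global IDR is
the running mean of local values along the ranking, non-decreasing by
construction, with the conventional 5% passing threshold. In the
end-to-end driver, pre-IDR peak calling is deliberately permissive
(p < 1e-2): reproducibility, not the caller threshold, decides survival,
which both matches accepted IDR practice and keeps the mixture's noise
component populated.

**Enhancer cascade.** Per condition: IDR filter, then removal of
elements whose nearest edge lies within 500 bp of any TSS (inclusive —
an element exactly at 500 bp is removed), then a 1-kb width cap; across
conditions: union merge (bookended intervals merge) and a final width
cap, since merging can push elements past 1 kb. Survivor counts are
logged at every step, and replaying the cascade on its own output is a
fixed point, which the tests assert. Matched replicate peaks contribute
the union span of the pair as the element interval.

**Signal, PCA, SOM.** Element signal is the extended cut-site coverage
summed in a 601-bp window on the element midpoint, divided by library
size (total retained cut sites). PCA log-transforms (pseudocount = the
smallest positive value, keeping zeros finite without dominating the
scale), column-centers per sample, and embeds samples by the right
singular vectors scaled by singular values; duplicated samples provably
coincide. The SOM additionally row-centers, so it clusters
log-fold-change profiles. It is a batch SOM on a 3×3 grid (nine
clusters): codebook initialized from random data rows under a seed,
Gaussian neighborhood shrinking linearly to zero over the first two
thirds of 100 epochs, plain Lloyd iteration afterwards — so the tail of
the quantization-error trace is provably non-increasing even though the
neighborhood phase need not be monotone. Ties in unit assignment break
to the first unit. Because a biological pattern typically occupies a
*set* of units, `cutSomUnits` groups units by complete-linkage
clustering of codebook vectors when a hard k-cluster reading is needed.
The grid geometry behind "nine clusters" is not dictated by anything in
the data; 3×3 is the assumed default and is configurable.

# Methylation

CpG records follow the bismark coverage dialect; coverage below 6 reads
is discarded at load (the assay's conventional floor), and the percent
column is recomputed from counts, warning at discrepancies above half a
percentage point. Region summaries are coverage-weighted means, which
makes them exactly additive under region splitting. Differential testing
pools replicates within group by position (appropriate at low per-sample
coverage), applies Fisher's exact test per matched CpG and BH
adjustment, and calls a CpG differential at q < 0.01 with at least a
25-point methylation difference — both thresholds are package defaults
in the tradition of the standard RRBS toolchain, exposed as arguments.
Testing is per-CpG; region tiling was considered and deliberately not
conflated with per-CpG results, since the two are not equivalent and the
per-CpG fraction is the quantity the pipeline reports.

# Granule geometry

Masks are labeled integer grids with 4-connected regions; area is pixel
count × spacing², perimeter is exposed-edge count × spacing. A granule's
contact length is the summed length of boundary edges whose facing pixel
lies within `adjacencyDistance` (default 1, i.e. the facing pixel is
nucleus) of the nucleus; "adjacent" had to be operationalized because
the original regions of interest were drawn by hand, and the
edge-within-one-pixel rule is exact on axis-aligned geometry. The
primary score divides each granule's contact length by the *total*
granule area of the cell, so per-granule ratios of one cell share a
denominator; a per-cell sum is available as a secondary summary. Ratios
are translation-invariant and scale as 1/spacing (length over area).
Conditions are compared against a designated control by two-sample
Wilcoxon rank-sum tests at alpha 0.05; groups under three observations
are flagged untestable rather than tested.

# The synthetic-data module

The generators are first-class, tested code, and their defaults *are*
the study conditions every acceptance property is evaluated under.

* **Genome**: 25 numbered chromosomes of 400 kb plus a 16.6-kb
  mitochondrial chromosome — a ~10-Mb stand-in chosen so the full
  pipeline runs in seconds while keeping per-window depths in realistic
  proportion to real data.
* **Expression**: 2,000 genes in five classes (maternal 35%, zygotic
  15%, maternal/zygotic 25%, germ-plasm-stabilized 5%, housekeeping
  20%), lognormal baselines, class-specific stage profiles (zygotic
  genes near zero pre-ZGA then rising; germ-plasm transcripts decaying
  only in soma after ZGA), negative-binomial counts with
  variance = mu + alpha·mu² at alpha = 0.3 (alpha = 0 gives exactly
  Poisson), 300k reads per sample, and 40 ERCC-like spike-ins log-spaced
  over six orders of magnitude contributing ~2% of reads.
* **Introns**: splice-site reads Poisson around a 100-read coverage;
  intronic depth drawn conditionally so the realized IR ratio has
  expectation equal to the gene's true nascent fraction (exactly zero
  depth at fraction zero).
* **ATAC**: 120k background fragments per sample (≈2.4 per 200 bp —
  the same background density per element width as ~50M reads on a
  1.4-Gb genome), 5% mitochondrial, 5% low-MAPQ; 240 planted 200-bp
  elements in four classes (pgc_open, soma_open, shared,
  irreproducible_noise at 30/30/20/20%), enriched 10-fold in the
  matching samples. Each element carries a lognormal strength (sdlog
  0.6) shared across samples and replicates — this shared variation is
  what makes replicate peak scores correlated, i.e. the very signal the
  IDR mixture detects; without it replicate scores are independent
  Poisson noise and the reproducible component genuinely has rho = 0.
  A tenth of elements are planted within 500 bp of a TSS to exercise
  the cascade's proximity filter.
* **Methylation**: 200 regions, half promoter-like (8% methylation
  everywhere), half enhancer-like (soma demethylating linearly from 90%
  to 20% across stages, PGC constant at 85%), binomial counts at
  Poisson-20 coverage with a 5% low-coverage fraction to exercise the
  cutoff.
* **Granules**: 64×64 masks, one square nucleus, 3–6 square granules
  per cell; control cells place granules flush against a nucleus edge
  with probability 0.7 (axis-aligned, so the analytic expected ratio is
  exact), the knockdown-like condition with probability 0.2 and larger
  granules, emulating reaggregation away from the nuclear envelope.

Where the emulated study does not state effect sizes, these defaults
were chosen once for testability and realism and are not tuned
thereafter. What passing tests show is therefore that each method
recovers structure *of the planted kind at the planted strength* — they
do not certify performance on real libraries, which add alignment
artifacts, GC and accessibility biases, non-uniform background, and
fragment-size structure that the generators deliberately omit (no
read-level sequences, no aligner emulation).

# Orchestration

`runEndToEnd(config, outdir, seed)` drives simulate → RNA → IR →
chromatin → methylation → granules, writes intermediates in their
standard text formats, and serializes a report (config echo, per-stage
status, truth-recovery metrics) as JSON that reloads losslessly. A stage
failure marks the stage and skips its dependents without aborting the
run. Configuration is an S4 object constructible from a YAML file — YAML
rather than another structured format because a parser is a standard
part of the R stack this package sits on. The package is a library: its
functions, this vignette and `scripts/acceptance.R` are the command
surface, and the acceptance script doubles as the canonical end-to-end
invocation.

# Known limitations

* The differential count test's single pooled dispersion is honest for
  the simulated homoscedastic design but will be miscalibrated on data
  with strong mean–dispersion trends; it is a stand-in, not a
  replacement, for shrinkage-based tools.
* The Poisson scan has no local background model, so copy-number or
  mappability structure in real data would inflate calls.
* The IDR mixture assumes one reproducible component; heterogeneous
  reproducibility (e.g. two element classes with different replicate
  noise) is absorbed into the parameters rather than modelled.
* Granule analysis consumes already-labeled masks; segmentation itself
  (thresholding, median filtering, 3D stacks) is out of scope.
* Methylation positions are assumed strand-merged CpG-resolved upstream.
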