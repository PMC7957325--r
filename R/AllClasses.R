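#' @import methods
#' @importFrom S4Vectors metadata DataFrame
#' @importFrom GenomicRanges GRanges
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' Configuration for the synthetic study design
#'
#' `SimConfig` holds every knob of the synthetic-data generators: the study
#' layout (two cell types across five developmental stages in duplicate,
#' mirroring a zebrafish PGC/soma time course from 256-cell to prim-5),
#' genome geometry, sequencing depths, and effect sizes. A single integer
#' seed fully determines the output of every generator.
#'
#' @slot nGenes number of simulated genes (spike-ins excluded)
#' @slot nElements number of true open-chromatin elements
#' @slot stages ordered developmental stage labels (first = pre-ZGA)
#' @slot cellTypes cell type labels
#' @slot nReplicates biological replicates per condition
#' @slot nbDispersion negative-binomial dispersion alpha (variance
#'   `mu + alpha * mu^2`); 0 gives Poisson counts
#' @slot librarySize expected RNA-seq reads per sample
#' @slot erccConcentrations named vector of spike-in concentrations
#'   (attomoles/uL), spanning six orders of magnitude
#' @slot erccLengths spike-in transcript lengths (bp)
#' @slot chromLengths named vector of chromosome lengths (bp); includes a
#'   mitochondrial chromosome named `"chrM"`
#' @slot atacStages stages at which ATAC samples are generated
#' @slot fragmentsPerSample expected ATAC fragments per sample
#' @slot elementWidth width (bp) of true elements
#' @slot atacEnrichment fold enrichment of fragment rate at true elements
#' @slot mitoFraction fraction of background fragments on the mitochondrial
#'   chromosome
#' @slot lowMapqFraction fraction of fragments below the MAPQ-10 filter
#' @slot nTss number of synthetic transcript start sites
#' @slot intronCoverage mean splice-site read depth for intron simulation
#' @slot nRegions number of methylation regions
#' @slot cpgsPerRegion CpGs per methylation region
#' @slot methCoverage mean CpG read coverage
#' @slot nCellsPerCondition granule mask cells per condition
#' @slot maskSize side length (pixels) of granule masks
#' @slot seed integer seed determining all generator output
#' @export
setClass("SimConfig", representation(
    nGenes = "integer", nElements = "integer",
    stages = "character", cellTypes = "character", nReplicates = "integer",
    nbDispersion = "numeric", librarySize = "numeric",
    erccConcentrations = "numeric", erccLengths = "numeric",
    chromLengths = "numeric",
    atacStages = "character", fragmentsPerSample = "numeric",
    elementWidth = "integer", atacEnrichment = "numeric",
    mitoFraction = "numeric", lowMapqFraction = "numeric", nTss = "integer",
    intronCoverage = "numeric",
    nRegions = "integer", cpgsPerRegion = "integer", methCoverage = "numeric",
    nCellsPerCondition = "integer", maskSize = "integer",
    seed = "integer"
))

setValidity("SimConfig", function(object) {
    msg <- character()
    if (object@nGenes <= 0L) msg <- c(msg, "nGenes must be positive")
    if (object@librarySize <= 0) msg <- c(msg, "librarySize must be positive")
    if (length(object@stages) == 0L) msg <- c(msg, "stages must be non-empty")
    if (anyDuplicated(object@stages)) msg <- c(msg, "stages must be unique")
    if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
    if (object@nbDispersion < 0) msg <- c(msg, "nbDispersion must be >= 0")
    if (is.null(names(object@chromLengths)) || any(object@chromLengths <= 0))
        msg <- c(msg, "chromLengths must be named and positive")
    if (!all(object@atacStages %in% object@stages))
        msg <- c(msg, "atacStages must be a subset of stages")
    if (length(object@erccConcentrations) &&
        length(object@erccConcentrations) != length(object@erccLengths))
        msg <- c(msg, "erccConcentrations and erccLengths must have equal length")
    if (object@mitoFraction < 0 || object@mitoFraction > 1)
        msg <- c(msg, "mitoFraction must be in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Gene-by-sample count container with lengths and sample metadata
#'
#' Thin subclass of [SummarizedExperiment::SummarizedExperiment] enforcing the
#' contract every counting stage relies on: a single integer `counts` assay,
#' positive feature lengths in `rowData(x)$length`, and complete
#' `cell_type` / `stage` / `replicate` columns in `colData`.
#'
#' @export
setClass("CountExperiment", contains = "SummarizedExperiment")

setValidity("CountExperiment", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        return("assay 'counts' is required")
    cts <- SummarizedExperiment::assay(object, "counts")
    if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
    rd <- SummarizedExperiment::rowData(object)
    if (!"length" %in% colnames(rd) || any(rd$length <= 0))
        msg <- c(msg, "rowData(x)$length must be present and positive")
    cd <- SummarizedExperiment::colData(object)
    need <- c("cell_type", "stage", "replicate")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
        msg <- c(msg, paste0("colData missing: ", paste(miss, collapse = ", ")))
    else if (any(vapply(need, function(f) anyNA(cd[[f]]), logical(1))))
        msg <- c(msg, "sample metadata must be complete (no NA)")
    if (length(msg)) msg else TRUE
})

#' Extended Tn5 cut-site coverage
#'
#' Per-chromosome run-length-encoded coverage of Tn5 cut sites after the
#' +5/-4 offset correction, each cut site extended symmetrically so that one
#' retained fragment contributes two (2 * extension + 1)-bp windows.
#'
#' @slot coverage `SimpleRleList`, one run-length vector per chromosome
#' @slot chromLengths named chromosome lengths (bp)
#' @slot extension symmetric extension (bp) applied to each cut site
#' @slot librarySize number of retained cut sites (2 per retained fragment)
#' @slot nFragments retained fragment count
#' @slot nSkipped fragments dropped because the corrected cut sites collapsed
#' @slot normalized whether coverage was divided by `librarySize`
#' @export
setClass("CutSiteTrack", representation(
    coverage = "ANY", chromLengths = "numeric", extension = "integer",
    librarySize = "numeric", nFragments = "integer", nSkipped = "integer",
    normalized = "logical"
))

#' Two-component copula-mixture IDR fit
#'
#' Parameters and per-peak posteriors of the reproducibility mixture fitted
#' by EM on rank-transformed replicate peak scores: an uncorrelated
#' standard-normal noise component and a correlated reproducible component
#' with mean `mu`, s.d. `sigma` and correlation `rho`.
#'
#' @slot p mixture proportion of the reproducible component
#' @slot rho correlation of the reproducible component
#' @slot mu mean of the reproducible component (copula space)
#' @slot sigma s.d. of the reproducible component
#' @slot localIdr per-peak posterior probability of the noise component
#' @slot globalIdr per-peak expected irreproducibility among all peaks ranked
#'   at least as well
#' @slot logLik final observed-data log-likelihood
#' @slot iterations EM iterations used
#' @slot converged whether EM reached the log-likelihood tolerance
#' @export
setClass("IdrFit", representation(
    p = "numeric", rho = "numeric", mu = "numeric", sigma = "numeric",
    localIdr = "numeric", globalIdr = "numeric",
    logLik = "numeric", iterations = "integer", converged = "logical"
))

setValidity("IdrFit", function(object) {
    msg <- character()
    if (object@p <= 0 || object@p >= 1) msg <- c(msg, "p must be in (0, 1)")
    if (object@rho <= 0 || object@rho >= 1) msg <- c(msg, "rho must be in (0, 1)")
    if (any(object@localIdr < 0 | object@localIdr > 1))
        msg <- c(msg, "localIdr must lie in [0, 1]")
    if (any(object@globalIdr < 0 | object@globalIdr > 1))
        msg <- c(msg, "globalIdr must lie in [0, 1]")
    if (length(msg)) msg else TRUE
})

#' Candidate regulatory elements with cascade provenance
#'
#' Result of the enhancer filtering cascade: reproducible (IDR-passing),
#' TSS-distal, width-limited open-chromatin elements merged across
#' conditions, together with a log of survivor counts at every step.
#'
#' @slot elements `GRanges` of final candidate elements; `mcols()$conditions`
#'   records the contributing condition(s)
#' @slot cascadeLog data.frame with columns `step`, `condition`, `count`
#' @export
setClass("ElementSet", representation(
    elements = "GRanges", cascadeLog = "data.frame"
))

#' Element-by-sample accessibility signal matrix
#'
#' Fixed-width window sums of extended cut-site signal around element
#' centers, with the transform state tracked so that downstream PCA/SOM can
#' assert their preconditions (log transform, column and row centering).
#'
#' @slot values numeric matrix, elements x samples
#' @slot window window width (bp) centered on element midpoints
#' @slot transform one or more of `"raw"`, `"log"`, `"column-centered"`,
#'   `"row-centered"`, in application order
#' @slot truncated logical per element: window clipped at a chromosome end
#' @export
setClass("SignalMatrix", representation(
    values = "matrix", window = "integer", transform = "character",
    truncated = "logical"
))

#' Batch self-organizing-map fit
#'
#' @slot grid SOM grid dimensions (rows, cols)
#' @slot codebook unit-by-feature codebook matrix
#' @slot assignment best-matching unit per input row
#' @slot qerror mean squared quantization error per epoch
#' @slot seed seed used for codebook initialization
#' @export
setClass("SomFit", representation(
    grid = "integer", codebook = "matrix", assignment = "integer",
    qerror = "numeric", seed = "integer"
))

#' ERCC spike-in log-log calibration fit
#'
#' Ordinary least squares of log10 observed RPKM on log10 known
#' concentration, after discarding spike-ins with RPKM below the detection
#' floor. The inverse of the fitted line converts an RPKM into an absolute
#' concentration estimate.
#'
#' @slot intercept fitted intercept a in y = a + b X
#' @slot slope fitted slope b
#' @slot n number of spike-ins retained in the fit
#' @slot retained data.frame of the retained (concentration, rpkm) pairs
#' @slot rpkmFloor exclusion threshold applied to observed RPKM
#' @export
setClass("ErccFit", representation(
    intercept = "numeric", slope = "numeric", n = "integer",
    retained = "data.frame", rpkmFloor = "numeric"
))

#' Permutation test result for an intron-retention shift
#'
#' @slot observed mean IR shift (post minus pre) of the gene subgroup
#' @slot null null statistics from random same-size gene sets
#' @slot p two-sided permutation p with the +1 correction
#' @slot tTestP Welch t-test p comparing subgroup post vs pre IR
#' @slot interval 2.5th and 97.5th percentiles of the null
#' @slot nPerm number of permutations
#' @slot seed seed used for the draws
#' @export
setClass("IrPermutation", representation(
    observed = "numeric", null = "numeric", p = "numeric", tTestP = "numeric",
    interval = "numeric", nPerm = "integer", seed = "integer"
))

setValidity("IrPermutation", function(object) {
    msg <- character()
    if (object@p <= 0 || object@p > 1) msg <- c(msg, "p must be in (0, 1]")
    if (length(object@null) != object@nPerm)
        msg <- c(msg, "null length must equal nPerm")
    if (object@interval[1] > object@interval[2])
        msg <- c(msg, "interval bounds out of order")
    if (length(msg)) msg else TRUE
})

#' Nucleus and granule geometry of one segmented cell
#'
#' A labeled integer grid: 0 is background, `nucleusLabel` is the nucleus,
#' every other positive label is one germ granule. Regions are 4-connected;
#' `spacing` converts pixels into physical length units.
#'
#' @slot mask integer matrix of region labels
#' @slot nucleusLabel label of the nucleus region
#' @slot spacing physical length per pixel edge
#' @export
setClass("CellGeometry", representation(
    mask = "matrix", nucleusLabel = "integer", spacing = "numeric"
))

setValidity("CellGeometry", function(object) {
    msg <- character()
    if (any(object@mask < 0)) msg <- c(msg, "mask labels must be >= 0")
    if (object@spacing <= 0) msg <- c(msg, "spacing must be positive")
    if (length(msg)) msg else TRUE
})
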