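#' Build a synthetic-study configuration
#'
#' Defaults encode the study layout the generators emulate: two cell types
#' (PGC, soma) sampled at five stages from 256-cell to prim-5 in biological
#' duplicate; a scaled-down genome of 25 numbered chromosomes plus a
#' mitochondrial chromosome; ERCC-like spike-ins spanning six orders of
#' magnitude of concentration; ATAC sampling restricted to the two stages
#' flanking the divergence window (high, prim-5).
#'
#' @param nGenes,nElements problem sizes (genes; true open-chromatin elements)
#' @param stages ordered stage labels; the first stage is pre-ZGA
#' @param cellTypes cell type labels
#' @param nReplicates replicates per condition
#' @param nbDispersion NB dispersion alpha (variance `mu + alpha mu^2`)
#' @param librarySize expected reads per RNA sample
#' @param erccConcentrations named spike-in concentrations (attomoles/uL);
#'   default 40 spike-ins log-spaced over 1e-2..1e4
#' @param erccLengths spike-in lengths (bp)
#' @param chromLengths named chromosome lengths; default 25 x 400 kb + chrM
#' @param atacStages stages with ATAC samples
#' @param fragmentsPerSample expected ATAC fragments per sample
#' @param elementWidth true element width (bp)
#' @param atacEnrichment fold enrichment of cut-site rate at true elements
#' @param mitoFraction fraction of background fragments on chrM
#' @param lowMapqFraction fraction of fragments with MAPQ below 10
#' @param nTss number of synthetic TSS positions
#' @param intronCoverage mean splice-site depth in the intron simulator
#' @param nRegions,cpgsPerRegion,methCoverage methylation design
#' @param nCellsPerCondition,maskSize granule mask design
#' @param seed integer seed; fully determines all generator output
#' @return a validated [SimConfig-class] object
#' @examples
#' cfg <- simConfig(seed = 1)
#' stages(cfg)
#' @export
simConfig <- function(nGenes = 2000L, nElements = 240L,
                      stages = c("256-cell", "high", "dome", "10-somites", "prim-5"),
                      cellTypes = c("PGC", "soma"), nReplicates = 2L,
                      nbDispersion = 0.3, librarySize = 3e5,
                      erccConcentrations = NULL, erccLengths = NULL,
                      chromLengths = NULL,
                      atacStages = c("high", "prim-5"),
                      fragmentsPerSample = 1.2e5, elementWidth = 200L,
                      atacEnrichment = 10, mitoFraction = 0.05,
                      lowMapqFraction = 0.05, nTss = 300L,
                      intronCoverage = 100, nRegions = 200L,
                      cpgsPerRegion = 8L, methCoverage = 20,
                      nCellsPerCondition = 30L, maskSize = 64L,
                      seed = 1L) {
    if (is.null(erccConcentrations)) {
        erccConcentrations <- 10^seq(-2, 4, length.out = 40)
        names(erccConcentrations) <- sprintf("ERCC-%05d", seq_len(40))
    }
    if (is.null(erccLengths)) {
        # deterministic catalogue: lengths cycle over a plausible range
        erccLengths <- rep(c(500, 750, 1000, 1250, 1500), length.out =
                               length(erccConcentrations))
        names(erccLengths) <- names(erccConcentrations)
    }
    if (is.null(chromLengths)) {
        chromLengths <- c(stats::setNames(rep(4e5, 25), paste0("chr", 1:25)),
                          chrM = 16596)
    }
    new("SimConfig",
        nGenes = as.integer(nGenes), nElements = as.integer(nElements),
        stages = stages, cellTypes = cellTypes,
        nReplicates = as.integer(nReplicates),
        nbDispersion = nbDispersion, librarySize = librarySize,
        erccConcentrations = erccConcentrations, erccLengths = erccLengths,
        chromLengths = chromLengths, atacStages = atacStages,
        fragmentsPerSample = fragmentsPerSample,
        elementWidth = as.integer(elementWidth),
        atacEnrichment = atacEnrichment, mitoFraction = mitoFraction,
        lowMapqFraction = lowMapqFraction, nTss = as.integer(nTss),
        intronCoverage = intronCoverage, nRegions = as.integer(nRegions),
        cpgsPerRegion = as.integer(cpgsPerRegion), methCoverage = methCoverage,
        nCellsPerCondition = as.integer(nCellsPerCondition),
        maskSize = as.integer(maskSize), seed = as.integer(seed))
}

#' Read a SimConfig from a YAML file
#'
#' Every key of the YAML document is passed to [simConfig()] as the
#' argument of the same name; missing keys take the defaults.
#'
#' @param path path to a YAML configuration file
#' @return a [SimConfig-class]
#' @export
readSimConfig <- function(path) {
    args <- yaml::read_yaml(path)
    if (!is.null(args$erccConcentrations))
        args$erccConcentrations <- unlist(args$erccConcentrations)
    if (!is.null(args$chromLengths))
        args$chromLengths <- unlist(args$chromLengths)
    do.call(simConfig, args)
}

#' Construct a CountExperiment
#'
#' @param counts integer matrix, features x samples
#' @param lengths feature lengths (bp)
#' @param cellType,stage,replicate per-sample metadata
#' @param rowData optional extra per-feature columns (data.frame)
#' @return a [CountExperiment-class]
#' @examples
#' ce <- CountExperiment(matrix(1:4, 2, dimnames = list(c("g1", "g2"), NULL)),
#'                       lengths = c(1000, 2000),
#'                       cellType = c("PGC", "soma"),
#'                       stage = c("high", "high"), replicate = c(1, 1))
#' featureLengths(ce)
#' @export
CountExperiment <- function(counts, lengths, cellType, stage, replicate,
                            rowData = NULL) {
    counts <- as.matrix(counts)
    storage.mode(counts) <- "integer"
    rd <- S4Vectors::DataFrame(length = as.numeric(lengths))
    if (!is.null(rowData)) rd <- cbind(rd, S4Vectors::DataFrame(rowData))
    rownames(rd) <- rownames(counts)
    cd <- S4Vectors::DataFrame(cell_type = cellType, stage = stage,
                               replicate = replicate)
    if (is.null(colnames(counts)))
        colnames(counts) <- paste(cellType, stage, replicate, sep = "_")
    rownames(cd) <- colnames(counts)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(counts = counts), rowData = rd, colData = cd)
    new("CountExperiment", se)
}
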