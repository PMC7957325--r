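#' Run the full synthetic study end to end
#'
#' Generates a seeded synthetic dataset (expression, introns, ATAC
#' fragments, CpG methylation, granule masks) and drives every analysis
#' stage over it: size factors, TPM, zygotic-gene classification, ERCC
#' calibration, the intron-retention permutation test, Tn5 cut-site
#' processing, peak calling, IDR filtering, the candidate-enhancer cascade,
#' the PCA/SOM accessibility clustering, differential accessibility,
#' differential CpG methylation, and the granule contact-ratio comparison.
#' Because the generators carry ground truth, the report includes
#' truth-recovery metrics (sensitivity / false-positive rates) for the
#' classification stages. A stage failure marks that stage failed, skips
#' stages depending on it, and is reflected in the report.
#'
#' @param config a [SimConfig-class] (default `simConfig()`); its seed is
#'   overridden by `seed` when given
#' @param outdir optional directory: when set, intermediate files are
#'   written in their standard text formats and the report as JSON
#' @param seed optional integer seed overriding `config@seed`
#' @return the run report (a nested list; serializable losslessly with
#'   [writeRunReport()])
#' @export
runEndToEnd <- function(config = simConfig(), outdir = NULL, seed = NULL) {
    if (!is.null(seed)) config@seed <- as.integer(seed)
    report <- list(config = list(seed = config@seed,
                                 nGenes = config@nGenes,
                                 nElements = config@nElements,
                                 stages = config@stages,
                                 cellTypes = config@cellTypes,
                                 nReplicates = config@nReplicates),
                   constants = list(tpmThreshold = 2, tssExclusion = 500,
                                    maxWidth = 1000, signalWindow = 601,
                                    idrThreshold = 0.05, nPerm = 10000,
                                    lfcThreshold = 1, padjThreshold = 0.05,
                                    foldEnrichmentThreshold = 4,
                                    minCoverage = 6),
                   stages = list())
    if (!is.null(outdir) && !dir.exists(outdir))
        dir.create(outdir, recursive = TRUE)
    runStage <- function(name, fun) {
        res <- tryCatch(list(status = "ok", value = fun()),
                        error = function(e)
                            list(status = "failed",
                                 value = NULL, error = conditionMessage(e)))
        report$stages[[name]] <<- c(list(status = res$status),
                                    if (res$status == "failed")
                                        list(error = res$error))
        res$value
    }

    ## --- expression ---------------------------------------------------
    expr <- runStage("simulate_expression",
                     function() simulateExpression(config))
    rna <- NULL
    if (!is.null(expr)) rna <- runStage("expression", function() {
        ce <- expr$counts
        sf <- sizeFactors(ce)
        tpmAll <- tpm(ce)
        spike <- rowData(ce)$spike_in
        genes <- rownames(ce)[!spike]
        # stage profile in PGCs (mean over replicates) for the classifier
        cd <- colData(ce)
        pgcCols <- which(cd$cell_type == config@cellTypes[1])
        tpmByStage <- vapply(config@stages, function(st)
            rowMeans(tpmAll[genes, pgcCols[cd$stage[pgcCols] == st],
                            drop = FALSE]), numeric(length(genes)))
        calls <- classifyZygotic(tpmByStage, config@stages)
        truthZyg <- expr$truth$geneClass[genes] == "zygotic"
        sens <- mean(calls[truthZyg] == "zygotic")
        fpr <- mean(calls[expr$truth$geneClass[genes] %in%
                              c("maternal", "housekeeping")] == "zygotic")
        # ERCC calibration on the first sample
        rp <- rpkm(ce)[, 1]
        fit <- erccCalibrate(expr$truth$erccConcentration,
                             rp[names(expr$truth$erccConcentration)])
        if (!is.null(outdir)) writeCountsTsv(ce, file.path(outdir, "counts.tsv"))
        list(sizeFactors = sf, zygoticCalls = calls,
             zygoticSensitivity = sens, zygoticFPR = fpr,
             erccIntercept = fit@intercept, erccSlope = fit@slope,
             erccN = fit@n)
    })
    if (!is.null(rna)) report$stages$expression$metrics <-
        list(zygotic_sensitivity = rna$zygoticSensitivity,
             zygotic_fpr = rna$zygoticFPR,
             ercc_slope = rna$erccSlope, ercc_intercept = rna$erccIntercept)

    ## --- intron retention ---------------------------------------------
    ir <- NULL
    if (!is.null(expr)) ir <- runStage("intron_retention", function() {
        introns <- simulateIntrons(config, expr$truth)
        if (!is.null(outdir)) writeIntronTsv(introns,
                                             file.path(outdir, "introns.tsv"))
        soma <- config@cellTypes[2]
        pre <- introns[introns$sample ==
                           paste(soma, config@stages[1], sep = "_"), ]
        post <- introns[introns$sample ==
                            paste(soma, config@stages[3], sep = "_"), ]
        irPre <- geneIR(pre)
        irPost <- geneIR(post)
        sub <- names(which(expr$truth$geneClass == "germ_plasm_stabilized"))
        sub <- intersect(sub, intersect(names(irPre), names(irPost)))
        test <- irPermutationTest(irPre, irPost, sub,
                                  nPerm = 10000L, seed = config@seed)
        list(observed = test@observed, p = test@p, tTestP = test@tTestP,
             interval = test@interval)
    })
    if (!is.null(ir)) report$stages$intron_retention$metrics <-
        list(ir_shift = ir$observed, permutation_p = ir$p,
             t_test_p = ir$tTestP)

    ## --- chromatin -----------------------------------------------------
    atac <- runStage("simulate_atac", function() simulateAtac(config))
    chrom <- NULL
    if (!is.null(atac)) chrom <- runStage("chromatin", function() {
        tracks25 <- lapply(atac$fragments, prepareCutSites,
                           chromLengths = config@chromLengths,
                           extension = 25L)
        # permissive pre-IDR calling (the reproducibility filter, not the
        # caller threshold, decides what survives)
        peaks <- lapply(tracks25, callPeaks, window = 200L,
                        pCutoff = 1e-2)
        conds <- expand.grid(stage = config@atacStages,
                             cell_type = config@cellTypes,
                             stringsAsFactors = FALSE)
        peaksets <- lapply(seq_len(nrow(conds)), function(i) {
            pre <- paste(conds$cell_type[i], conds$stage[i], sep = "_")
            peaks[paste(pre, 1:2, sep = "_")]
        })
        names(peaksets) <- paste(conds$cell_type, conds$stage, sep = "_")
        cascade <- enhancerCascade(peaksets, atac$tss)
        el <- elements(cascade)
        tracks5 <- lapply(atac$fragments, prepareCutSites,
                          chromLengths = config@chromLengths,
                          extension = 5L)
        sm <- signalMatrix(el, tracks5)
        smL <- logTransform(sm)
        pca <- pcaEmbed(centerColumns(smL), nComponents = 2)
        som <- somCluster(centerRows(centerColumns(smL)), seed = config@seed)
        # differential accessibility on element cut-site counts, prim-5
        lastStage <- config@atacStages[length(config@atacStages)]
        rawCounts <- signalMatrix(el, tracks25, window = 601L,
                                  normalize = FALSE)
        m <- round(signalValues(rawCounts) / (2 * 25L + 1))
        storage.mode(m) <- "integer"
        rownames(m) <- paste0("el", seq_len(nrow(m)))
        groupA <- grep(paste0("^PGC_", lastStage), colnames(m), value = TRUE)
        groupB <- grep(paste0("^soma_", lastStage), colnames(m), value = TRUE)
        da <- differentialCounts(m, groupA, groupB)
        # truth recovery for differential accessibility
        hits <- GenomicRanges::findOverlaps(el, atac$elements)
        trueClass <- rep("none", length(el))
        trueClass[S4Vectors::queryHits(hits)] <-
            atac$elements$class[S4Vectors::subjectHits(hits)]
        isDiff <- trueClass %in% c("pgc_open", "soma_open")
        sens <- if (any(isDiff)) mean(da$significant[isDiff]) else NA
        fpr <- if (any(trueClass == "shared"))
            mean(da$significant[trueClass == "shared"]) else NA
        if (!is.null(outdir)) {
            writeNarrowPeak(peaks[[1]], file.path(outdir, "peaks_rep1.narrowPeak"))
            utils::write.table(cascadeLog(cascade),
                               file.path(outdir, "cascade_log.tsv"),
                               sep = "\t", quote = FALSE, row.names = FALSE)
        }
        list(nPeaks = vapply(peaks, length, integer(1)),
             cascadeLog = cascadeLog(cascade),
             nCandidates = length(el),
             pcaVariance = pca$varianceExplained[1:2],
             somUnits = prod(som@grid),
             somOccupied = length(unique(somAssignment(som))),
             daSensitivity = sens, daFPR = fpr,
             elementTruthClass = trueClass)
    })
    if (!is.null(chrom)) report$stages$chromatin$metrics <-
        list(n_candidate_enhancers = chrom$nCandidates,
             som_units = chrom$somUnits,
             pca_var_pc1 = chrom$pcaVariance[1],
             da_sensitivity = chrom$daSensitivity,
             da_fpr = chrom$daFPR)

    ## --- methylation ----------------------------------------------------
    meth <- runStage("methylation", function() {
        sim <- simulateMethylation(config)
        filtered <- lapply(sim$cpgs, filterCpGs, minCoverage = 6)
        lastStage <- config@stages[length(config@stages)]
        pgc <- do.call(rbind, filtered[grep(paste0("^PGC_", lastStage),
                                            names(filtered))])
        soma <- do.call(rbind, filtered[grep(paste0("^soma_", lastStage),
                                             names(filtered))])
        dm <- differentialCpGs(pgc, soma)
        regMeans <- regionMethylation(rbind(pgc, soma), sim$regions)
        enh <- sim$regions$class == "enhancer_like"
        if (!is.null(outdir))
            writeBismarkCoverage(filtered[[1]],
                                 file.path(outdir, "cpg_coverage.cov"))
        list(differentialFraction = dm$fraction,
             nDifferential = sum(dm$table$differential),
             nMatched = nrow(dm$table),
             enhancerDeltaPGCminusSoma =
                 mean(regMeans[enh, grep("^PGC", colnames(regMeans))],
                      na.rm = TRUE) -
                 mean(regMeans[enh, grep("^soma", colnames(regMeans))],
                      na.rm = TRUE))
    })
    if (!is.null(meth)) report$stages$methylation$metrics <-
        list(differential_cpg_fraction = meth$differentialFraction,
             n_differential = meth$nDifferential,
             enhancer_delta = meth$enhancerDeltaPGCminusSoma)

    ## --- granules -------------------------------------------------------
    gran <- runStage("granules", function() {
        sim <- simulateGranuleMasks(config)
        ratios <- lapply(sim$cells, function(cg) {
            cr <- contactRatio(cg)
            cr$granules$ratio
        })
        byCond <- split(ratios, sim$condition)
        pooled <- lapply(byCond, function(l) unlist(l))
        cmp <- compareGroups(pooled, control = "control")
        if (!is.null(outdir))
            writeMaskGrid(sim$cells[[1]], file.path(outdir, "mask_001.txt"))
        list(meanRatioByCondition = vapply(pooled, mean, numeric(1)),
             comparison = cmp)
    })
    if (!is.null(gran)) report$stages$granules$metrics <-
        list(mean_ratio = as.list(gran$meanRatioByCondition),
             kd_vs_control_p = gran$comparison$p[1])

    report$values <- list(rna = rna, ir = ir, chromatin = chrom,
                          methylation = meth, granules = gran)
    if (!is.null(outdir))
        writeRunReport(report, file.path(outdir, "report.json"))
    report
}

#' Serialize / reload a run report as JSON
#'
#' Only the serializable summary (config echo, per-stage status and
#' metrics) is written; the heavyweight `values` component is dropped.
#'
#' @param report a report from [runEndToEnd()]
#' @param path JSON path
#' @return `path` invisibly / the reloaded report list
#' @export
writeRunReport <- function(report, path) {
    slim <- report[c("config", "constants", "stages")]
    jsonlite::write_json(slim, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    invisible(path)
}

#' @rdname writeRunReport
#' @export
readRunReport <- function(path) {
    jsonlite::read_json(path, simplifyVector = TRUE)
}
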