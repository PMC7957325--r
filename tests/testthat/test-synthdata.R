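test_that("all generators are bit-identical under the same seed", {
    cfg <- smallConfig(seed = 5L)
    e1 <- simulateExpression(cfg); e2 <- simulateExpression(cfg)
    expect_identical(counts(e1$counts), counts(e2$counts))
    expect_identical(e1$truth, e2$truth)
    expect_identical(simulateIntrons(cfg, e1$truth),
                     simulateIntrons(cfg, e2$truth))
    a1 <- simulateAtac(cfg); a2 <- simulateAtac(cfg)
    expect_identical(a1$fragments, a2$fragments)
    m1 <- simulateMethylation(cfg); m2 <- simulateMethylation(cfg)
    expect_identical(m1$cpgs, m2$cpgs)
    g1 <- simulateGranuleMasks(cfg); g2 <- simulateGranuleMasks(cfg)
    expect_identical(lapply(g1$cells, function(x) x@mask),
                     lapply(g2$cells, function(x) x@mask))
    # a different seed changes the data
    e3 <- simulateExpression(smallConfig(seed = 6L))
    expect_false(identical(counts(e1$counts), counts(e3$counts)))
})

test_that("zero dispersion gives Poisson counts (variance equals mean)", {
    # >= 1000 replicate draws of each gene at fixed expected counts
    mk <- function(alpha) smallConfig(
        nGenes = 30L, nbDispersion = alpha, nReplicates = 600L,
        stages = c("256-cell", "high"), atacStages = "high",
        librarySize = 2e4)
    e0 <- simulateExpression(mk(0))
    cd <- SummarizedExperiment::colData(e0$counts)
    cols <- cd$cell_type == "PGC" & cd$stage == "high"
    x <- counts(e0$counts)[!SummarizedExperiment::rowData(e0$counts)$spike_in,
                           cols]
    m <- rowMeans(x); v <- apply(x, 1, var)
    ratio <- v[m > 5] / m[m > 5]
    expect_lt(abs(mean(ratio) - 1), 0.1)   # index of dispersion ~ 1
    # positive dispersion inflates the variance well beyond Poisson
    e1 <- simulateExpression(mk(0.3))
    x1 <- counts(e1$counts)[
        !SummarizedExperiment::rowData(e1$counts)$spike_in, cols]
    m1 <- rowMeans(x1); v1 <- apply(x1, 1, var)
    big <- m1 > 50
    expect_gt(mean(v1[big] / m1[big]), 2)
})

test_that("class profiles satisfy the study design", {
    cfg <- simConfig(seed = 2L)
    e <- simulateExpression(cfg)
    expect_equal(unique(SummarizedExperiment::colData(e$counts)$stage),
                 c("256-cell", "high", "dome", "10-somites", "prim-5"))
    tp <- tpm(e$counts)
    cls <- e$truth$geneClass
    cd <- SummarizedExperiment::colData(e$counts)
    stage1 <- rowMeans(tp[names(cls), cd$stage == "256-cell"])
    stage2 <- rowMeans(tp[names(cls), cd$stage == "high"])
    zyg <- cls == "zygotic"
    expect_lt(median(stage1[zyg]), 2)
    expect_gt(mean(stage2[zyg] > stage1[zyg]), 0.95)
    # germ-plasm transcripts persist in PGCs but decay in late soma
    gp <- names(cls)[cls == "germ_plasm_stabilized"]
    pgcLate <- rowMeans(tp[gp, cd$cell_type == "PGC" &
                               cd$stage == "prim-5", drop = FALSE])
    somaLate <- rowMeans(tp[gp, cd$cell_type == "soma" &
                                cd$stage == "prim-5", drop = FALSE])
    expect_gt(median(pgcLate + 1), median(somaLate + 1))
    # ERCC counts track concentration over the detectable range
    sp <- SummarizedExperiment::rowData(e$counts)$spike_in
    ec <- counts(e$counts)[sp, 1]
    expected <- e$truth$erccConcentration * cfg@erccLengths
    top <- expected >= median(expected)   # dim spike-ins drop out entirely
    expect_gt(cor(log10(ec[top] + 1), log10(expected[top])), 0.95)
})

test_that("intron generator hits the target nascent fraction in expectation", {
    cfg <- smallConfig()
    e <- simulateExpression(cfg)
    # deep-coverage check at f = 0.5 over 1000 genes
    truth <- e$truth
    truth$nascentFraction[] <- 0.5
    cfg2 <- smallConfig(intronCoverage = 500)
    tab <- simulateIntrons(cfg2, truth)
    ir <- irRatio(tab$depth, tab$ss5, tab$ss3)
    expect_gt(mean(ir), 0.45); expect_lt(mean(ir), 0.55)
    # zero nascent fraction -> zero intronic depth everywhere
    truth0 <- e$truth; truth0$nascentFraction[] <- 0
    tab0 <- simulateIntrons(cfg, truth0)
    expect_true(all(tab0$depth == 0))
    # default truth: pre-ZGA IR below post-ZGA IR
    tabD <- simulateIntrons(cfg, e$truth)
    irD <- irRatio(tabD$depth, tabD$ss5, tabD$ss3)
    pre <- mean(irD[grepl("256-cell", tabD$sample)], na.rm = TRUE)
    post <- mean(irD[grepl("dome", tabD$sample)], na.rm = TRUE)
    expect_lt(pre, post)
    expect_error(simulateIntrons(cfg, list()), "truth")
})

test_that("ATAC generator plants recoverable, replicate-consistent elements", {
    cfg <- simConfig(seed = 3L)
    a <- simulateAtac(cfg)
    # intervals valid, counts non-negative, both chromosome dialect fields
    for (fr in a$fragments) {
        expect_true(all(fr$start < fr$end))
        expect_true(all(fr$mapq >= 0))
    }
    expect_true(any(a$fragments[[1]]$chrom == "chrM"))
    expect_true(any(a$fragments[[1]]$mapq < 10))
    # a pgc_open element is recovered in both PGC replicates
    tr1 <- prepareCutSites(a$fragments[["PGC_prim-5_1"]], cfg@chromLengths)
    tr2 <- prepareCutSites(a$fragments[["PGC_prim-5_2"]], cfg@chromLengths)
    pk1 <- callPeaks(tr1, window = 200L, pCutoff = 1e-4)
    pk2 <- callPeaks(tr2, window = 200L, pCutoff = 1e-4)
    pgcEl <- a$elements[a$elements$class == "pgc_open"]
    rec1 <- mean(GenomicRanges::countOverlaps(pgcEl, pk1) > 0)
    rec2 <- mean(GenomicRanges::countOverlaps(pgcEl, pk2) > 0)
    expect_gte(rec1, 0.8); expect_gte(rec2, 0.8)
    # capacity guard
    expect_error(simulateAtac(smallConfig(nElements = 100000L)),
                 "capacity")
})

test_that("near-pure background yields at most the nominal false-positive count", {
    cfg <- smallConfig(nElements = 1L, seed = 8L)
    a <- simulateAtac(cfg)
    fr <- a$fragments[[1]]
    tr <- prepareCutSites(fr, cfg@chromLengths, extension = 0L)
    # windows narrower than the cut-site pair separation keep window
    # counts Poisson; discreteness makes the test conservative, so only
    # the upper bound is asserted here (the sharp two-sided calibration
    # lives in the peak-caller tests)
    pk <- callPeaks(tr, window = 100L, pCutoff = 0.01)
    nW <- attr(pk, "nWindows")
    expect_lt(attr(pk, "nSignificant"), 2 * 0.01 * nW + 5)
})

test_that("methylation generator follows the planted trajectories", {
    cfg <- simConfig(seed = 4L)
    m <- simulateMethylation(cfg)
    expect_true(any((m$cpgs[[1]]$coverage) < 6))   # low-coverage records exist
    enh <- m$regions$class == "enhancer_like"
    somaHigh <- m$cpgs[["soma_high_1"]]
    somaPrim <- m$cpgs[["soma_prim-5_1"]]
    rmH <- regionMethylation(somaHigh, m$regions)
    rmP <- regionMethylation(somaPrim, m$regions)
    expect_lt(mean(rmP[enh, 1], na.rm = TRUE),
              mean(rmH[enh, 1], na.rm = TRUE))
    # PGC enhancer-like regions stay hypermethylated at prim-5
    pgcPrim <- regionMethylation(m$cpgs[["PGC_prim-5_1"]], m$regions)
    expect_gt(mean(pgcPrim[enh, 1], na.rm = TRUE), 0.7)
})

test_that("granule masks carry exact analytic expected ratios", {
    cfg <- smallConfig(seed = 9L)
    g <- simulateGranuleMasks(cfg)
    expect_equal(length(g$cells), 2L * cfg@nCellsPerCondition)
    for (i in seq_along(g$cells)) {
        cr <- contactRatio(g$cells[[i]])
        expect_equal(sort(cr$granules$ratio), sort(g$expected[[i]]),
                     tolerance = 1e-12)
        # nucleus and granules disjoint by construction of the labels
        expect_true(all(table(g$cells[[i]]@mask[g$cells[[i]]@mask > 0]) > 0))
    }
    # the knockdown-like condition scores lower on average
    pooled <- split(unlist(g$expected),
                    rep(g$condition, lengths(g$expected)))
    expect_lt(mean(pooled$tdrd7_KD), mean(pooled$control))
})
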