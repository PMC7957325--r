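test_that("size factors reproduce the median-of-ratios hand computation", {
    # identical columns -> unit factors
    m <- cbind(a = c(5L, 8L, 12L), b = c(5L, 8L, 12L))
    expect_equal(unname(sizeFactors(m)), c(1, 1))
    # one column doubled: ratios to the geometric-mean reference are
    # 1/sqrt(2) and sqrt(2)
    m2 <- cbind(s1 = c(10L, 30L, 50L), s2 = c(20L, 60L, 100L))
    expect_equal(unname(sizeFactors(m2)), c(1 / sqrt(2), sqrt(2)),
                 tolerance = 1e-4)
    # a feature with a zero is excluded from the reference but the sample
    # is still normalized
    m3 <- rbind(m2, c(0L, 7L))
    expect_equal(sizeFactors(m3), sizeFactors(m2))
    expect_error(sizeFactors(cbind(c(0L, 1L), c(1L, 0L))), "pseudo-reference")
})

test_that("size factors agree with DESeq2 up to the geometric-mean rescale", {
    skip_if_not_installed("DESeq2")
    set.seed(11)
    m <- matrix(rnbinom(600, mu = 60, size = 5), ncol = 4)
    ours <- sizeFactors(m)
    ref <- DESeq2::estimateSizeFactorsForMatrix(m)
    ref <- ref / exp(mean(log(ref)))
    expect_equal(unname(ours), unname(ref), tolerance = 1e-12)
})

test_that("size factors are scale-equivariant", {
    set.seed(3)
    m <- matrix(rpois(300, 50) + 1L, ncol = 3)
    sf <- sizeFactors(m)
    m2 <- m; m2[, 2] <- m2[, 2] * 4L
    sf2 <- sizeFactors(m2)
    # after the geometric-mean renormalization, ratios between samples
    # change by exactly the applied scale
    expect_equal(sf2[2] / sf2[1], 4 * sf[2] / sf[1], tolerance = 1e-12)
})

test_that("TPM follows the length-normalized formula and sums to 1e6", {
    out <- tpm(matrix(c(100, 300), 2), lengths = c(1000, 3000))
    expect_equal(as.numeric(out), c(5e5, 5e5))
    set.seed(5)
    m <- matrix(rpois(200, 30), ncol = 2)
    lens <- sample(200:5000, 100)
    res <- tpm(m, lens)
    expect_equal(unname(colSums(res)), rep(1e6, 2), tolerance = 1e-6)
    # equal lengths -> proportional to counts
    resEq <- tpm(m, rep(1000, 100))
    expect_equal(resEq[, 1], m[, 1] / sum(m[, 1]) * 1e6)
    expect_error(tpm(cbind(c(0, 0)), lengths = c(100, 100)), "all-zero")
})

test_that("zygotic classification applies the 2-TPM rise rule strictly", {
    m <- cbind(`256-cell` = c(0.5, 5, 0.5, 1, 2),
               high = c(10, 10, 0.4, 1, 5),
               dome = c(0, 0, 0, 0, 0))
    rownames(m) <- paste0("g", 1:5)
    calls <- classifyZygotic(m, c("256-cell", "high", "dome"))
    expect_equal(unname(calls),
                 c("zygotic",        # low then rising
                   "not_zygotic",    # maternal contribution (>= 2 TPM)
                   "not_zygotic",    # no increase
                   "not_zygotic",    # tie
                   "not_zygotic"))   # exactly at threshold
    # invariant to gene order and to stages after the second
    perm <- sample(5)
    expect_equal(classifyZygotic(m[perm, ], c("256-cell", "high"))[rownames(m)],
                 calls)
    expect_error(classifyZygotic(m[, 1, drop = FALSE], "256-cell"),
                 "two stages")
})

test_that("ERCC calibration recovers exact fits, excludes dim spike-ins and matches the normal equations", {
    conc <- 10^seq(-1, 4, length.out = 12)
    fit <- erccCalibrate(conc, 10^(2 + 0.5 * log10(conc)))
    expect_equal(fit@intercept, 2, tolerance = 1e-12)
    expect_equal(fit@slope, 0.5, tolerance = 1e-12)
    expect_equal(predictConcentration(fit, 10^(2 + 0.5 * 2)), 100,
                 tolerance = 1e-9)
    # rpkm below 1 dropped
    rp <- 10^(2 + 0.5 * log10(conc)); rp[1] <- 0.5
    expect_equal(erccCalibrate(conc, rp)@n, 11L)
    expect_error(erccCalibrate(c(1, 10), c(0.5, 0.2)), "fewer than 2")
    # noisy fit equals the brute-force normal-equations solution
    # (concentrations chosen so every point clears the rpkm >= 1 floor)
    set.seed(9)
    X <- runif(50, 0.5, 4); y <- 1.5 + 0.8 * X + rnorm(50, 0, 0.1)
    fit2 <- erccCalibrate(10^X, 10^y)
    A <- cbind(1, X)
    beta <- solve(t(A) %*% A, t(A) %*% y)
    expect_equal(c(fit2@intercept, fit2@slope), as.numeric(beta),
                 tolerance = 1e-10)
})

test_that("differential counts: identical groups yield no calls; planted folds are found", {
    set.seed(21)
    base <- matrix(rnbinom(500 * 3, mu = 100, size = 20), ncol = 3)
    m <- cbind(base, base)
    colnames(m) <- paste0("s", 1:6)
    res <- differentialCounts(m, paste0("s", 1:3), paste0("s", 4:6))
    expect_true(all(res$logFC == 0))
    expect_false(any(res$significant))
    expect_error(differentialCounts(m, paste0("s", 1:3), paste0("s", 3:5)),
                 "overlap")
    # planted 4-fold features
    set.seed(22)
    mu <- rep(100, 1000); up <- 1:50
    mA <- matrix(rnbinom(1000 * 3, mu = mu, size = 20), ncol = 3)
    muB <- mu; muB[up] <- muB[up] * 4
    mB <- matrix(rnbinom(1000 * 3, mu = muB, size = 20), ncol = 3)
    m2 <- cbind(mA, mB); colnames(m2) <- paste0("s", 1:6)
    res2 <- differentialCounts(m2, paste0("s", 1:3), paste0("s", 4:6))
    called <- which(res2$significant)
    expect_gte(mean(up %in% called), 0.8)                       # sensitivity
    expect_lte(mean(!(called %in% up)), 0.1)                    # FDR
})

test_that("fold-enrichment gating removes weakly enriched features", {
    set.seed(23)
    mA <- matrix(rnbinom(100 * 2, mu = 50, size = 20), ncol = 2)
    mB <- matrix(rnbinom(100 * 2, mu = c(rep(250, 20), rep(50, 80)),
                         size = 20), ncol = 2)
    m <- cbind(mA, mB); colnames(m) <- paste0("s", 1:4)
    fe <- rep(10, 100); fe[1:10] <- 1   # half the planted set fails FE > 4
    res <- diffAccessibility(m, paste0("s", 1:2), paste0("s", 3:4),
                             foldEnrichment = fe)
    expect_false(any(res$significant[1:10]))
})
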