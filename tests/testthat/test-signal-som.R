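test_that("signal windows sum extended cut-site coverage around element centers", {
    # one fragment whose first cut site lands exactly on the element center
    frags <- data.frame(chrom = "chr1", start = 995, end = 2000, mapq = 30)
    tr <- prepareCutSites(frags, c(chr1 = 5000), chroms = "chr1",
                          extension = 5L)
    # cut sites at 1000 and 1996 (0-based); element centered on 1000
    el <- gr("chr1", 901, 1101)   # midpoint 1001 (1-based) = 0-based 1000
    sm <- signalMatrix(el, list(s1 = tr), window = 601L, normalize = FALSE)
    expect_equal(as.numeric(signalValues(sm)), 11)  # 2*5+1
    # normalization makes the column invariant to fragment duplication
    tr2 <- prepareCutSites(rbind(frags, frags), c(chr1 = 5000),
                           chroms = "chr1", extension = 5L)
    n1 <- signalValues(signalMatrix(el, list(s1 = tr), window = 601L))
    n2 <- signalValues(signalMatrix(el, list(s1 = tr2), window = 601L))
    expect_equal(n1, n2)
})

test_that("windows past the chromosome end are truncated and flagged", {
    frags <- data.frame(chrom = "chr1", start = 50, end = 250, mapq = 30)
    tr <- prepareCutSites(frags, c(chr1 = 400), chroms = "chr1",
                          extension = 5L)
    el <- gr("chr1", 1, 199)
    sm <- signalMatrix(el, list(s1 = tr), window = 601L)
    expect_true(sm@truncated[1])
})

test_that("centering transforms meet their invariants to 1e-9", {
    set.seed(51)
    sm <- new("SignalMatrix", values = matrix(rexp(200), 50, 4),
              window = 601L, transform = "raw", truncated = logical(50))
    smL <- logTransform(sm)
    smC <- centerColumns(smL)
    expect_lt(max(abs(colMeans(signalValues(smC)))), 1e-9)
    smR <- centerRows(smC)
    expect_lt(max(abs(rowMeans(signalValues(smR)))), 1e-9)
    expect_equal(transformState(smR),
                 c("raw", "log", "column-centered", "row-centered"))
})

test_that("PCA gives duplicated samples identical coordinates and a valid spectrum", {
    set.seed(52)
    v <- matrix(rexp(300), 100, 3)
    vals <- cbind(v, v[, 3])   # duplicate sample
    sm <- new("SignalMatrix", values = vals, window = 601L,
              transform = "raw", truncated = logical(100))
    p <- pcaEmbed(centerColumns(logTransform(sm)), nComponents = 2)
    expect_equal(p$coordinates[3, ], p$coordinates[4, ], tolerance = 1e-10)
    ve <- p$varianceExplained
    expect_lte(sum(ve), 1 + 1e-12)
    expect_true(all(diff(ve) <= 1e-12))
    # reconstruction from the full SVD reproduces the centered matrix
    sv <- p$svd
    rec <- sv$u %*% diag(sv$d) %*% t(sv$v)
    centered <- sweep(log(vals + min(vals[vals > 0])), 2,
                      colMeans(log(vals + min(vals[vals > 0]))))
    expect_lt(max(abs(rec - centered)), 1e-8)
})

test_that("PCA refuses a matrix that was never log-transformed", {
    sm <- new("SignalMatrix", values = matrix(1:12, 4, 3), window = 601L,
              transform = "raw", truncated = logical(4))
    expect_error(pcaEmbed(sm), "log-transformed")
})

test_that("SOM separates planted accessibility patterns into distinct unit sets", {
    skip_if_not_installed("mclust")
    set.seed(53)
    pat <- rep(1:3, each = 100)
    centers <- rbind(c(2, 2, -2, -2, 0, 0, 0, 0),    # PGC-up
                     c(-2, -2, 2, 2, 0, 0, 0, 0),    # soma-up
                     c(2, -2, 2, -2, 0, 0, 0, 0))    # stage-flip
    X <- centers[pat, ] + matrix(rnorm(300 * 8, 0, 0.3), 300)
    X <- sweep(X, 2, colMeans(X)); X <- sweep(X, 1, rowMeans(X))
    fit <- somCluster(X, grid = c(3, 3), epochs = 100, seed = 1)
    expect_equal(prod(fit@grid), 9L)   # default grid: 9 clusters
    # every unit is pure: it hosts rows from a single pattern
    tab <- table(pat, somAssignment(fit))
    expect_true(all(colSums(tab > 0) == 1))
    meta <- cutSomUnits(fit, 3)
    expect_gte(mclust::adjustedRandIndex(pat, meta), 0.8)
    # determinism under the seed
    fit2 <- somCluster(X, grid = c(3, 3), epochs = 100, seed = 1)
    expect_identical(somAssignment(fit), somAssignment(fit2))
})

test_that("SOM quantization error decreases overall and is monotone in the Lloyd tail", {
    set.seed(54)
    X <- matrix(rnorm(200 * 6), 200, 6)
    fit <- somCluster(X, grid = c(3, 3), epochs = 90, seed = 2)
    qe <- fit@qerror
    expect_lt(qe[length(qe)], qe[1])
    # after the neighborhood reaches zero the update is Lloyd iteration
    tail_ <- qe[ceiling(2 * 90 / 3):90]
    expect_true(all(diff(tail_) <= 1e-6))
})

test_that("SOM rejects a grid larger than the data", {
    expect_error(somCluster(matrix(rnorm(12), 4, 3), grid = c(3, 3)),
                 "more units")
})
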