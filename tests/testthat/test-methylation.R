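writeCovFixture <- function(rows, path = tempfile(fileext = ".cov")) {
    writeLines(rows, path)
    path
}

test_that("bismark coverage reader applies the coverage-6 cutoff and validates percent", {
    p <- writeCovFixture(c(
        "chr1\t100\t101\t60\t3\t2",     # coverage 5 -> dropped
        "chr1\t200\t201\t100\t6\t0",    # retained, 100%
        "chr1\t300\t301\t25\t2\t6"))    # retained, 25%
    out <- readBismarkCoverage(p)
    expect_equal(nrow(out), 2L)
    expect_equal(out$percent, c(100, 25))
    # malformed numeric field errors with the line number
    p2 <- writeCovFixture(c("chr1\t100\t101\t50\t5\t5",
                            "chr1\t200\t201\t50\tfive\t5"))
    expect_error(readBismarkCoverage(p2), "line 2")
    # percent disagreeing with the counts warns
    p3 <- writeCovFixture("chr1\t100\t101\t90\t5\t5")
    expect_warning(readBismarkCoverage(p3), "disagrees")
})

test_that("region methylation is the coverage-weighted mean and NA without CpGs", {
    cpgs <- data.frame(chrom = "chr1",
                       start = c(100, 150, 900),
                       end = c(101, 151, 901),
                       methylated = c(9, 1, 5), unmethylated = c(1, 9, 5),
                       sample = "s1")
    regions <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(50, 500, 2000), c(300, 1000, 2100)))
    names(regions) <- c("r1", "r2", "r3")
    m <- regionMethylation(cpgs, regions)
    expect_equal(m["r1", "s1"], 0.5)      # (9+1)/(10+10)
    expect_equal(m["r2", "s1"], 0.5)      # single CpG = its own fraction
    expect_true(is.na(m["r3", "s1"]))
    # invariant to CpG ordering
    m2 <- regionMethylation(cpgs[c(3, 1, 2), ], regions)
    expect_equal(m, m2)
})

test_that("region methylation recombines additively under region splitting", {
    set.seed(61)
    cpgs <- data.frame(chrom = "chr1", start = sort(sample(1000:1999, 30)),
                       methylated = rbinom(30, 20, 0.4),
                       unmethylated = 0, sample = "s1")
    cpgs$unmethylated <- 20 - cpgs$methylated
    cpgs$end <- cpgs$start + 1
    whole <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1000, 2000))
    halves <- GenomicRanges::GRanges("chr1",
        IRanges::IRanges(c(1000, 1501), c(1500, 2000)))
    mw <- regionMethylation(cpgs, whole)[1, 1]
    mh <- regionMethylation(cpgs, halves)
    cov <- vapply(1:2, function(i) {
        inR <- cpgs$start + 1 >= GenomicRanges::start(halves)[i] &
            cpgs$start + 1 <= GenomicRanges::end(halves)[i]
        sum(cpgs$methylated[inR] + cpgs$unmethylated[inR])
    }, numeric(1))
    expect_equal(sum(mh[, 1] * cov) / sum(cov), unname(mw),
                 tolerance = 1e-12)
})

test_that("differential CpG testing equals the hypergeometric oracle and flags planted sites", {
    # identical pooled counts -> p 1, nothing differential
    g <- data.frame(chrom = "chr1", start = c(10, 20), end = c(11, 21),
                    methylated = c(5, 8), unmethylated = c(5, 2),
                    sample = "x")
    same <- differentialCpGs(g, g)
    expect_true(all(same$table$p == 1))
    expect_equal(same$fraction, 0)
    # extreme 2x2 is strongly significant
    a <- data.frame(chrom = "chr1", start = 10, end = 11,
                    methylated = 10, unmethylated = 0, sample = "a")
    b <- data.frame(chrom = "chr1", start = 10, end = 11,
                    methylated = 0, unmethylated = 10, sample = "b")
    res <- differentialCpGs(a, b)
    expect_lt(res$table$p, 1e-4)
    # Fisher p equals brute-force hypergeometric enumeration on random
    # tables with margins <= 50
    set.seed(62)
    for (i in 1:25) {
        m1 <- sample(0:25, 1); u1 <- sample(0:25, 1)
        m2 <- sample(0:25, 1); u2 <- sample(0:25, 1)
        if (m1 + u1 == 0 || m2 + u2 == 0) next
        a <- data.frame(chrom = "c", start = 1, end = 2,
                        methylated = m1, unmethylated = u1, sample = "a")
        b <- data.frame(chrom = "c", start = 1, end = 2,
                        methylated = m2, unmethylated = u2, sample = "b")
        p <- differentialCpGs(a, b)$table$p
        # enumerate all tables with the same margins; two-sided p sums
        # the probabilities of tables no more likely than the observed
        n <- m1 + u1 + m2 + u2; k <- m1 + m2; r <- m1 + u1
        support <- max(0, k - (n - r)):min(k, r)
        probs <- dhyper(support, r, n - r, k)
        pObs <- dhyper(m1, r, n - r, k)
        oracle <- sum(probs[probs <= pObs * (1 + 1e-7)])
        expect_equal(p, oracle, tolerance = 1e-9)
    }
})

test_that("the differential fraction is invariant under group relabeling", {
    set.seed(63)
    mk <- function(shift) {
        pos <- seq(100, 1090, by = 10)
        pm <- rbinom(100, 30, 0.5 + shift * (seq_len(100) <= 10))
        data.frame(chrom = "chr1", start = pos, end = pos + 1,
                   methylated = pm, unmethylated = 30 - pm, sample = "s")
    }
    a <- mk(0); b <- mk(0.45)
    r1 <- differentialCpGs(a, b)
    r2 <- differentialCpGs(b, a)
    expect_equal(r1$fraction, r2$fraction)
    expect_equal(r1$table$p, r2$table$p)
    expect_equal(r1$table$difference, -r2$table$difference)
})
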