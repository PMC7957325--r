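# shared fixtures, all generated in code

# small config for fast generator tests
smallConfig <- function(seed = 1L, ...) {
    args <- utils::modifyList(
        list(nGenes = 200L, nElements = 40L, librarySize = 5e4,
             fragmentsPerSample = 3e4, nRegions = 40L,
             nCellsPerCondition = 10L, nTss = 60L, seed = seed),
        list(...))
    do.call(simConfig, args)
}

# synthetic paired IDR scores: proportion p from a correlated component
simIdrScores <- function(n, p, mu = 2, rho = 0.8, seed = 1) {
    withr::with_seed(seed, {
        rep_ <- runif(n) < p
        z1 <- ifelse(rep_, mu + rnorm(n), rnorm(n))
        z2 <- ifelse(rep_, mu + rho * (z1 - mu) + sqrt(1 - rho^2) * rnorm(n),
                     rnorm(n))
        list(s1 = z1, s2 = z2, reproducible = rep_)
    })
}

# uniform background fragments on one chromosome
simBackgroundFragments <- function(n, chromLen, seed = 1, chrom = "chr1") {
    withr::with_seed(seed, {
        start <- floor(runif(n) * (chromLen - 200))
        data.frame(chrom = chrom, start = start, end = start + 150,
                   mapq = 30L)
    })
}

# GRanges peak list helper (1-based closed)
gr <- function(chrom, start, end, score = 1) {
    GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end),
                           score = score)
}

# Hand-built cascade fixture. TSS at chr1:20750 (+ strand).
# Condition A peaks (identical in both replicates):
#   A1 chr1 [10000,10400]  survivor
#   A2 chr1 [20000,20250]  edge exactly 500 bp from the TSS -> dropped
#   A3 chr1 [30000,31200]  width 1201 -> dropped
#   A4 chr2 [10000,10500]  survivor (merges with B2)
#   A5 chr2 [50000,50400]  survivor (duplicate of B3)
#   A6 chr2 [80000,80600]  survivor (merges with B6 into width 1002)
# Condition B peaks:
#   B1 chr1 [40000,40400]  survivor
#   B2 chr2 [10451,10900]  overlaps A4 by 50 bp
#   B3 chr2 [50000,50400]  identical to A5
#   B4 chr1 [60000,61050]  width 1051 -> dropped
#   B5 chr1 [70000,70200]  survivor
#   B6 chr2 [80551,81001]  overlaps A6 by 50 bp
# Hand enumeration: A filters 6 -> 5 -> 4; B filters 6 -> 6 -> 5;
# union merges the 9 survivors into 6 elements; the A6+B6 merge has width
# 1002 > 1000 and is dropped -> 5 final candidates.
makeCascadeFixture <- function() {
    tss <- GenomicRanges::GRanges("chr1", IRanges::IRanges(20750, 20750),
                                  strand = "+")
    a <- gr(c("chr1", "chr1", "chr1", "chr2", "chr2", "chr2"),
            c(10000, 20000, 30000, 10000, 50000, 80000),
            c(10400, 20250, 31200, 10500, 50400, 80600),
            score = 6:1)
    b <- gr(c("chr1", "chr2", "chr2", "chr1", "chr1", "chr2"),
            c(40000, 10451, 50000, 60000, 70000, 80551),
            c(40400, 10900, 50400, 61050, 70200, 81001),
            score = 6:1)
    list(peaksets = list(condA = list(a, a), condB = list(b, b)), tss = tss)
}
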