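test_that("Tn5 offsets place cut sites at start+5 and end-4", {
    cs <- tn5CutSites(data.frame(chrom = "chr1", start = 100, end = 200))
    expect_equal(cs$cut1, 105)
    expect_equal(cs$cut2, 196)
    # degenerate fragment: corrected sites collapse
    cs2 <- tn5CutSites(data.frame(chrom = "chr1", start = 0, end = 9))
    expect_true(is.na(cs2$cut1))
    expect_error(tn5CutSites(data.frame(chrom = "c", start = 5, end = 5)),
                 "start < end")
})

test_that("prepareCutSites filters MAPQ and mitochondrial fragments and conserves counts", {
    frags <- data.frame(
        chrom = c("chr1", "chr1", "chrM", "1", "chr26"),
        start = c(100, 300, 100, 500, 100),
        end = c(200, 450, 250, 700, 300),
        mapq = c(30, 5, 30, 30, 30))
    lens <- c(setNames(rep(1000, 25), paste0("chr", 1:25)), chrM = 1000)
    tr <- prepareCutSites(frags, lens, extension = 25L)
    # mapq 5 dropped, chrM dropped, chr26 dropped; "1" accepted as chr1
    expect_equal(tr@nFragments, 2L)
    expect_equal(tr@librarySize, 4)
    # total signal = 2 fragments x 2 cut sites x 51 bp (no edge clipping)
    expect_equal(trackTotalSignal(tr), 2 * 2 * 51)
    # the 51-bp window of cut1=105 covers 0-based [80, 131)
    r <- tr@coverage[["chr1"]]
    expect_equal(as.integer(r[81]), 1L)   # 1-based 81 = 0-based 80
    expect_equal(as.integer(r[80]), 0L)
    expect_equal(as.integer(r[131]), 1L)
    expect_equal(as.integer(r[132]), 0L)
})

test_that("extension windows are 2*extension+1 bp wide", {
    frags <- data.frame(chrom = "chr1", start = 400, end = 600, mapq = 30)
    lens <- c(chr1 = 2000)
    for (ext in c(5L, 25L)) {
        tr <- prepareCutSites(frags, lens, chroms = "chr1", extension = ext)
        expect_equal(trackTotalSignal(tr), 2 * (2 * ext + 1))
    }
})

test_that("fragments with collapsing cut sites are skipped and logged", {
    frags <- data.frame(chrom = "chr1", start = c(100, 200), end = c(108, 400),
                        mapq = 30)
    tr <- prepareCutSites(frags, c(chr1 = 1000), chroms = "chr1")
    expect_equal(tr@nSkipped, 1L)
    expect_equal(tr@nFragments, 1L)
})

test_that("peak caller is near-calibrated on homogeneous background and finds a planted element", {
    lens <- c(chr1 = 5e5)
    frags <- simBackgroundFragments(1e5, 5e5, seed = 41)
    tr <- prepareCutSites(frags, lens, chroms = "chr1", extension = 0L)
    # the two cut sites of a 150-bp fragment sit 141 bp apart, so windows
    # narrower than that see independent events and the Poisson null is
    # exact up to discreteness; the background is deep (lambda = 40)
    pk <- callPeaks(tr, window = 100L, pCutoff = 0.01)
    fpr <- attr(pk, "nSignificant") / attr(pk, "nWindows")
    expect_lte(fpr, 2 * 0.01)
    expect_gte(fpr, 0.01 / 2)
    # fold enrichment of background calls stays modest
    if (length(pk)) expect_true(all(pk$foldEnrichment < 2))
    # planted element at 10x local rate
    el <- simBackgroundFragments(800, 400, seed = 42)
    el$start <- el$start + 250000; el$end <- el$end + 250000
    tr2 <- prepareCutSites(rbind(frags, el), lens, chroms = "chr1",
                           extension = 0L)
    pk2 <- callPeaks(tr2, window = 100L, pCutoff = 1e-4)
    hit <- GenomicRanges::findOverlaps(
        gr("chr1", 250001, 250600), pk2)
    expect_equal(length(unique(S4Vectors::subjectHits(hit))), 1L)
    ov <- pk2[S4Vectors::subjectHits(hit)[1]]
    expect_gte(ov$foldEnrichment, 4)
})

test_that("empty track yields an empty peak list", {
    tr <- prepareCutSites(
        data.frame(chrom = "chr2", start = 1, end = 100, mapq = 0),
        c(chr1 = 1000), chroms = "chr1")
    expect_equal(length(callPeaks(tr)), 0L)
})
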