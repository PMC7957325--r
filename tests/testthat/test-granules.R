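test_that("region measurement counts areas and exposed edges", {
    m <- matrix(0L, 4, 4); m[2, 2] <- 1L
    r <- measureRegions(m)
    expect_equal(r$area, 1)
    expect_equal(r$perimeter, 4)
    # 10x10 solid square
    m2 <- matrix(0L, 20, 20); m2[5:14, 5:14] <- 1L
    r2 <- measureRegions(m2)
    expect_equal(r2$area, 100)
    expect_equal(r2$perimeter, 40)
    # two labels -> two records ordered by label; area survives relabeling
    m2[1, 1] <- 7L
    r3 <- measureRegions(m2)
    expect_equal(r3$label, c(1L, 7L))
    m3 <- m2; m3[m3 == 1L] <- 9L
    expect_equal(sum(measureRegions(m3)$area), sum(r3$area))
    # spacing scales area quadratically and perimeter linearly
    r4 <- measureRegions(m2, spacing = 2)
    expect_equal(r4$area, r3$area * 4)
    expect_equal(r4$perimeter, r3$perimeter * 2)
    expect_equal(nrow(measureRegions(matrix(0L, 3, 3))), 0L)
})

test_that("contact ratio matches analytic geometry for flush and detached granules", {
    # single 10x10 granule flush against a straight nucleus edge
    m <- matrix(0L, 40, 40)
    m[1:10, 1:30] <- 1L
    m[11:20, 5:14] <- 2L
    cr <- contactRatio(cellGeometry(m))
    expect_equal(cr$granules$contactLength, 10)
    expect_equal(cr$totalArea, 100)
    expect_equal(cr$granules$ratio, 0.1)
    # detached granule scores zero
    m[30:33, 30:33] <- 3L
    cr2 <- contactRatio(cellGeometry(m))
    expect_equal(cr2$granules$ratio[cr2$granules$label == 3L], 0)
    # two 10x10 granules, one flush: the shared denominator halves the ratio
    m3 <- matrix(0L, 60, 60)
    m3[1:10, 1:30] <- 1L
    m3[11:20, 5:14] <- 2L
    m3[40:49, 40:49] <- 3L
    cr3 <- contactRatio(cellGeometry(m3))
    expect_equal(cr3$granules$ratio, c(10 / 200, 0))
})

test_that("contact plus exposed edges equals the perimeter for a nucleus-only contact", {
    m <- matrix(0L, 40, 40)
    m[1:10, 1:30] <- 1L
    m[11:16, 8:13] <- 2L     # 6x6 granule flush against the nucleus
    cr <- contactRatio(cellGeometry(m))
    per <- measureRegions(m)$perimeter[2]
    # one full 6-px side touches the nucleus; the remaining edges are
    # exposed, and together they exhaust the perimeter
    expect_equal(cr$granules$contactLength, 6)
    expect_equal(cr$granules$contactLength + (per - 6), per)
    expect_equal(per, 24)
})

test_that("ratios are translation-invariant and scale as 1/spacing", {
    m <- matrix(0L, 50, 50)
    m[10:19, 10:29] <- 1L
    m[20:25, 12:17] <- 2L
    base <- contactRatio(cellGeometry(m))
    shifted <- matrix(0L, 50, 50)
    shifted[15:24, 13:32] <- 1L
    shifted[25:30, 15:20] <- 2L
    expect_equal(contactRatio(cellGeometry(shifted))$granules$ratio,
                 base$granules$ratio)
    scaled <- contactRatio(cellGeometry(m, spacing = 2))
    expect_equal(scaled$granules$ratio, base$granules$ratio / 2)
})

test_that("a cell without granules is flagged empty", {
    m <- matrix(0L, 10, 10); m[3:6, 3:6] <- 1L
    cr <- contactRatio(cellGeometry(m))
    expect_true(cr$empty)
    expect_equal(nrow(cr$granules), 0L)
    expect_error(contactRatio(cellGeometry(matrix(0L, 5, 5))), "nucleus")
})

test_that("group comparison flags a shifted condition and handles small groups", {
    withr::with_seed(71, {
        ctrl <- runif(30, 0.05, 0.15)
        kd <- ctrl * 0.5
        same <- ctrl + rnorm(30, 0, 1e-4)
    })
    res <- compareGroups(list(control = ctrl, kd = kd, same = same,
                              tiny = c(0.1, 0.2)),
                         control = "control")
    expect_true(res$significant[res$condition == "kd"])
    expect_lt(res$p[res$condition == "kd"], 0.05)
    expect_gt(res$p[res$condition == "same"], 0.5)
    expect_true(is.na(res$p[res$condition == "tiny"]))
    expect_error(compareGroups(list(a = 1:5), control = "b"), "not found")
})
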