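#' Read and filter a bismark-style CpG coverage file
#'
#' Expects the bismark coverage dialect: tab-separated columns
#' chrom, start, end, percent methylation, count methylated,
#' count unmethylated. Records with coverage (methylated + unmethylated)
#' below `minCoverage` are dropped. The percent column is recomputed from
#' the counts; a discrepancy above 0.5 percentage points raises a warning
#' naming the line.
#'
#' @param path path to the coverage file
#' @param minCoverage minimum read coverage to keep a CpG (default 6)
#' @param sample sample id attached to the records (default the file name)
#' @return data.frame with columns `chrom`, `start`, `end`, `methylated`,
#'   `unmethylated`, `coverage`, `percent`, `sample`
#' @export
readBismarkCoverage <- function(path, minCoverage = 6,
                                sample = basename(path)) {
    raw <- utils::read.table(path, sep = "\t", header = FALSE,
                             colClasses = "character")
    if (ncol(raw) < 6) stop("expected 6 columns in bismark coverage file")
    num <- suppressWarnings(lapply(raw[, c(2, 3, 4, 5, 6)], as.numeric))
    badLine <- which(vapply(seq_len(nrow(raw)), function(i)
        any(is.na(vapply(num, `[`, numeric(1), i))), logical(1)))
    if (length(badLine))
        stop("malformed (non-numeric) row at line ", badLine[1],
             " of ", path)
    df <- data.frame(chrom = raw[[1]], start = num[[1]], end = num[[2]],
                     percent = num[[3]], methylated = num[[4]],
                     unmethylated = num[[5]])
    df$coverage <- df$methylated + df$unmethylated
    recomputed <- ifelse(df$coverage > 0,
                         100 * df$methylated / df$coverage, 0)
    off <- which(abs(recomputed - df$percent) > 0.5)
    if (length(off))
        warning("percent column disagrees with counts by > 0.5 at line(s) ",
                paste(utils::head(off, 5), collapse = ", "))
    df$percent <- recomputed
    df <- df[df$coverage >= minCoverage, , drop = FALSE]
    df$sample <- sample
    rownames(df) <- NULL
    df[, c("chrom", "start", "end", "methylated", "unmethylated",
           "coverage", "percent", "sample")]
}

#' Filter CpG records by coverage
#'
#' @param cpgs data.frame with `methylated` and `unmethylated` columns
#' @param minCoverage minimum coverage (default 6)
#' @return the filtered data.frame
#' @export
filterCpGs <- function(cpgs, minCoverage = 6) {
    cov <- cpgs$methylated + cpgs$unmethylated
    cpgs[cov >= minCoverage, , drop = FALSE]
}

#' Region-level mean methylation
#'
#' Coverage-weighted mean methylation fraction per region per sample:
#' `sum(methylated) / sum(coverage)` over the CpGs falling in the region.
#' Regions without any covered CpG are `NA`.
#'
#' @param cpgs data.frame of CpG records (as from [readBismarkCoverage()]),
#'   possibly several samples stacked
#' @param regions `GRanges` of regions (1-based); names become row names
#' @return matrix regions x samples of methylation fractions in \[0, 1\]
#' @export
regionMethylation <- function(cpgs, regions) {
    samples <- unique(cpgs$sample)
    out <- matrix(NA_real_, length(regions), length(samples),
                  dimnames = list(names(regions), samples))
    cpgGr <- GenomicRanges::GRanges(
        cpgs$chrom, IRanges::IRanges(cpgs$start + 1L, cpgs$start + 1L))
    hits <- GenomicRanges::findOverlaps(cpgGr, regions)
    if (!length(hits)) return(out)
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    sampIdx <- match(cpgs$sample[qi], samples)
    cov <- cpgs$methylated[qi] + cpgs$unmethylated[qi]
    key <- (si - 1L) * length(samples) + sampIdx
    num <- tapply(cpgs$methylated[qi], key, sum)
    den <- tapply(cov, key, sum)
    k <- as.integer(names(num))
    out[cbind((k - 1L) %/% length(samples) + 1L,
              (k - 1L) %% length(samples) + 1L)] <- num / den
    out
}

#' Per-CpG differential methylation between two groups
#'
#' Replicates are pooled by position within each group; matched positions
#' are tested with Fisher's exact test on the 2x2
#' (methylated/unmethylated x group) table, adjusted by Benjamini-Hochberg.
#' A CpG is called differential when `q < qThreshold` and the absolute
#' methylation difference is at least `minDiff` percentage points. The
#' differential fraction (differential / matched CpGs) summarizes the
#' genome-wide extent of divergence.
#'
#' @param groupA,groupB data.frames of CpG records (several samples stacked
#'   per group)
#' @param qThreshold BH q-value threshold (default 0.01)
#' @param minDiff minimum absolute difference in percentage points
#'   (default 25)
#' @return list with `table` (per-CpG data.frame: `chrom`, `start`,
#'   `difference` in percentage points, `p`, `q`, `differential`) and
#'   `fraction` (differential CpGs / matched CpGs)
#' @export
differentialCpGs <- function(groupA, groupB, qThreshold = 0.01,
                             minDiff = 25) {
    poolGroup <- function(g) {
        key <- paste(g$chrom, g$start)
        data.frame(key = unique(key),
                   chrom = g$chrom[!duplicated(key)],
                   start = g$start[!duplicated(key)],
                   methylated = as.numeric(
                       tapply(g$methylated, key, sum)[unique(key)]),
                   unmethylated = as.numeric(
                       tapply(g$unmethylated, key, sum)[unique(key)]))
    }
    a <- poolGroup(groupA)
    b <- poolGroup(groupB)
    common <- intersect(a$key, b$key)
    if (!length(common)) stop("no CpG positions matched across groups")
    a <- a[match(common, a$key), ]
    b <- b[match(common, b$key), ]
    n <- length(common)
    p <- vapply(seq_len(n), function(i) {
        tab <- matrix(c(a$methylated[i], a$unmethylated[i],
                        b$methylated[i], b$unmethylated[i]), 2)
        stats::fisher.test(tab)$p.value
    }, numeric(1))
    q <- stats::p.adjust(p, method = "BH")
    fracA <- a$methylated / (a$methylated + a$unmethylated)
    fracB <- b$methylated / (b$methylated + b$unmethylated)
    diff <- 100 * (fracB - fracA)
    differential <- q < qThreshold & abs(diff) >= minDiff
    list(table = data.frame(chrom = a$chrom, start = a$start,
                            difference = diff, p = p, q = q,
                            differential = differential),
         fraction = mean(differential))
}
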