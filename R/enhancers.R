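#' @importFrom GenomicRanges seqnames start end width reduce findOverlaps
#' @importFrom GenomeInfoDb seqlevels
NULL

# distance from an interval to the nearest point in `points` (per chrom):
# 0 when a point falls inside the (1-based, closed) interval, otherwise the
# number of bp from the nearest interval edge to the point.
.tssDistance <- function(gr, tss) {
    d <- rep(Inf, length(gr))
    if (!length(tss) || !length(gr)) return(d)
    tchr <- as.character(GenomicRanges::seqnames(tss))
    gchr <- as.character(GenomicRanges::seqnames(gr))
    for (cname in unique(gchr)) {
        pts <- sort(GenomicRanges::start(tss)[tchr == cname])
        gi <- which(gchr == cname)
        if (!length(pts)) next
        s <- GenomicRanges::start(gr)[gi]
        e <- GenomicRanges::end(gr)[gi]
        # nearest point below the start and above the end
        lo <- findInterval(s - 1L, pts)        # index of last pt < s
        hi <- findInterval(e, pts) + 1L        # index of first pt > e
        inside <- findInterval(e, pts) - findInterval(s - 1L, pts) > 0
        dlo <- ifelse(lo >= 1, s - pts[pmax(lo, 1L)], Inf)
        dhi <- ifelse(hi <= length(pts), pts[pmin(hi, length(pts))] - e, Inf)
        d[gi] <- ifelse(inside, 0, pmin(dlo, dhi))
    }
    d
}

#' Candidate-enhancer filtering cascade
#'
#' For each condition (a pair of replicate peak lists): match peaks across
#' replicates, keep those passing the global IDR threshold, drop elements
#' lying within `tssExclusion` bp of any transcript start site (inclusive,
#' measured from the nearest element edge), and drop elements wider than
#' `maxWidth`. The per-condition survivors are then merged into a union
#' (overlapping or bookended intervals collapse into one) and the width
#' filter is applied once more to the merged elements. Survivor counts at
#' every step are logged.
#'
#' @param peaksets named list: condition -> list of two (or more) replicate
#'   `GRanges` peak lists with `score` columns
#' @param tss `GRanges` (width-1) of transcript start sites
#' @param idrThreshold global IDR ceiling (default 0.05)
#' @param tssExclusion TSS proximity filter in bp (default 500, inclusive)
#' @param maxWidth maximum element width in bp (default 1000)
#' @return an [ElementSet-class]; `mcols(elements(x))$conditions` lists the
#'   contributing condition(s) per merged element
#' @export
enhancerCascade <- function(peaksets, tss, idrThreshold = 0.05,
                            tssExclusion = 500, maxWidth = 1000) {
    stopifnot(is.list(peaksets), length(peaksets) >= 1L)
    # harmonize seqlevels so cross-condition set operations are silent
    allLv <- unique(unlist(lapply(peaksets, function(reps)
        lapply(reps, function(g) GenomeInfoDb::seqlevels(g)))))
    peaksets <- lapply(peaksets, function(reps) lapply(reps, function(g) {
        GenomeInfoDb::seqlevels(g) <- allLv
        g
    }))
    logRows <- list()
    addLog <- function(step, condition, count)
        logRows[[length(logRows) + 1L]] <<-
            data.frame(step = step, condition = condition, count = count)
    survivors <- list()
    for (cond in names(peaksets)) {
        reps <- peaksets[[cond]]
        if (length(reps) < 2L)
            stop("condition '", cond, "' needs two replicates")
        m <- matchPeaks(reps[[1]], reps[[2]])
        if (nrow(m$pairs) == 0L) {
            addLog("idr", cond, 0L)
            addLog("tss_filter", cond, 0L)
            addLog("width_filter", cond, 0L)
            survivors[[cond]] <- GenomicRanges::GRanges()
            next
        }
        # element interval = span of the matched replicate pair
        span <- GenomicRanges::punion(reps[[1]][m$pairs$i1],
                                      reps[[2]][m$pairs$i2],
                                      fill.gap = TRUE)
        if (nrow(m$pairs) >= 20L) {
            fit <- idrFit(m$scores1, m$scores2)
            keep <- idrPass(fit, idrThreshold)
        } else {
            keep <- rep(TRUE, nrow(m$pairs))  # too few pairs to model
        }
        el <- span[keep]
        addLog("idr", cond, length(el))
        d <- .tssDistance(el, tss)
        el <- el[d > tssExclusion]
        addLog("tss_filter", cond, length(el))
        el <- el[GenomicRanges::width(el) <= maxWidth]
        addLog("width_filter", cond, length(el))
        survivors[[cond]] <- el
    }
    pooled <- unlist(methods::as(survivors, "GRangesList"))
    merged <- GenomicRanges::reduce(pooled)   # bookended intervals merge
    addLog("union_merge", "all", length(merged))
    final <- merged[GenomicRanges::width(merged) <= maxWidth]
    addLog("final_width_filter", "all", length(final))
    # provenance: conditions contributing to each merged element
    conds <- rep("", length(final))
    for (cond in names(survivors)) {
        hit <- unique(S4Vectors::queryHits(
            GenomicRanges::findOverlaps(final, survivors[[cond]])))
        conds[hit] <- ifelse(conds[hit] == "", cond,
                             paste(conds[hit], cond, sep = ","))
    }
    S4Vectors::mcols(final)$conditions <- conds
    new("ElementSet", elements = final,
        cascadeLog = do.call(rbind, logRows))
}

#' Annotate elements by genomic feature and TSS distance
#'
#' Each element is labeled by its midpoint with precedence
#' promoter (within 1 kb up- or downstream of a TSS) > exon > intron >
#' intergenic, and annotated with the signed distance from its midpoint to
#' the closest TSS (negative = upstream of the TSS, using TSS strand).
#'
#' @param elements `GRanges` of elements (or an [ElementSet-class])
#' @param tss `GRanges` width-1 TSS positions (strand used to sign distances)
#' @param exons optional `GRanges` of exons
#' @param genes optional `GRanges` of gene bodies (midpoints inside a gene
#'   but not in an exon are introns)
#' @param promoterWindow half-width of the promoter window (default 1000 bp)
#' @return data.frame with columns `feature` and `tssDistance`; the
#'   empirical cumulative distribution of |distance| is attached as
#'   attribute `"ecdf"`
#' @export
annotateElements <- function(elements, tss, exons = NULL, genes = NULL,
                             promoterWindow = 1000) {
    if (is(elements, "ElementSet")) elements <- elements(elements)
    n <- length(elements)
    mid <- (GenomicRanges::start(elements) + GenomicRanges::end(elements)) %/% 2L
    midGr <- GenomicRanges::GRanges(GenomicRanges::seqnames(elements),
                                    IRanges::IRanges(mid, mid))
    dist <- rep(Inf, n)
    if (length(tss)) {
        tchr <- as.character(GenomicRanges::seqnames(tss))
        mchr <- as.character(GenomicRanges::seqnames(midGr))
        tpos <- GenomicRanges::start(tss)
        tstr <- as.character(GenomicRanges::strand(tss))
        for (cname in unique(mchr)) {
            ti <- which(tchr == cname)
            gi <- which(mchr == cname)
            if (!length(ti)) next
            o <- order(tpos[ti]); ti <- ti[o]
            pts <- tpos[ti]
            m <- mid[gi]
            k <- findInterval(m, pts)
            cand <- cbind(pmax(k, 1L), pmin(k + 1L, length(pts)))
            dd <- abs(m - pts[cand[, 1]])
            dd2 <- abs(m - pts[cand[, 2]])
            best <- ifelse(dd2 < dd, cand[, 2], cand[, 1])
            signed <- m - pts[best]
            flip <- tstr[ti][best] == "-"
            dist[gi] <- ifelse(flip, -signed, signed)
        }
    }
    feature <- rep("intergenic", n)
    if (!is.null(genes) && length(genes)) {
        inGene <- S4Vectors::queryHits(
            GenomicRanges::findOverlaps(midGr, genes))
        feature[unique(inGene)] <- "intron"
    }
    if (!is.null(exons) && length(exons)) {
        inExon <- S4Vectors::queryHits(
            GenomicRanges::findOverlaps(midGr, exons))
        feature[unique(inExon)] <- "exon"
    }
    feature[abs(dist) <= promoterWindow] <- "promoter"
    out <- data.frame(feature = feature, tssDistance = dist)
    finite <- is.finite(dist)
    attr(out, "ecdf") <- if (any(finite)) stats::ecdf(abs(dist[finite]))
                         else NULL
    out
}
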