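#' @importFrom IRanges IRanges Views viewSums viewWhichMaxs coverage
#' @importFrom S4Vectors Rle runValue
NULL

# Chromosome-name handling: both "chr1" and "1" dialects are accepted;
# "chrM" and "MT" are mitochondrial aliases.
.normChrom <- function(chrom) {
    x <- sub("^chr", "", as.character(chrom))
    ifelse(x %in% c("M", "MT"), "chrM", paste0("chr", x))
}

#' Standard nuclear chromosome set
#'
#' The 25 numbered chromosomes (zebrafish karyotype), excluding the
#' mitochondrial chromosome and any unplaced contigs.
#'
#' @return character vector `chr1` .. `chr25`
#' @export
nuclearChroms <- function() paste0("chr", 1:25)

#' Tn5-corrected cut sites of paired-end fragments
#'
#' The transposase inserts with a 9-bp stagger, so the two cut sites of a
#' fragment \[start, end) in 0-based half-open coordinates are obtained by
#' adding 5 bp to the fragment start and subtracting 4 bp from the fragment
#' end: `start + 5` and `end - 4`.
#'
#' @param fragments data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open) and optionally `mapq`
#' @return data.frame with columns `chrom`, `cut1`, `cut2` (0-based
#'   positions); fragments whose corrected sites collapse
#'   (`end - 4 <= start + 5`) get `NA` sites
#' @examples
#' tn5CutSites(data.frame(chrom = "chr1", start = 100, end = 200))
#' # cut1 = 105, cut2 = 196
#' @export
tn5CutSites <- function(fragments) {
    stopifnot(all(c("chrom", "start", "end") %in% names(fragments)))
    if (any(fragments$start >= fragments$end))
        stop("fragments must satisfy start < end")
    cut1 <- fragments$start + 5
    cut2 <- fragments$end - 4
    bad <- cut2 <= cut1
    cut1[bad] <- NA_integer_
    cut2[bad] <- NA_integer_
    data.frame(chrom = fragments$chrom, cut1 = cut1, cut2 = cut2)
}

#' Build an extended cut-site coverage track
#'
#' Filters fragments by mapping quality and chromosome (nuclear chromosomes
#' only, mitochondrial excluded), applies the Tn5 +5/-4 offset correction,
#' and extends each cut site symmetrically by `extension` bp into a
#' `2 * extension + 1`-bp window. Duplicate fragments are retained.
#' Fragments whose corrected cut sites collapse are skipped and counted.
#'
#' @param fragments data.frame with `chrom`, `start`, `end` (0-based
#'   half-open) and `mapq`
#' @param chromLengths named chromosome lengths (bp); defines the track span
#' @param minMapq minimum mapping quality (default 10; fragments below are
#'   dropped)
#' @param chroms chromosomes to keep (default the 25 nuclear chromosomes);
#'   both `"chr1"` and `"1"` spellings are accepted in the input
#' @param extension symmetric extension in bp (25 for browser-style tracks,
#'   5 for PCA/SOM signal)
#' @return a [CutSiteTrack-class]
#' @export
prepareCutSites <- function(fragments, chromLengths, minMapq = 10,
                            chroms = nuclearChroms(), extension = 25L) {
    stopifnot(all(c("chrom", "start", "end") %in% names(fragments)))
    extension <- as.integer(extension)
    if (!is.null(names(chromLengths)))
        names(chromLengths) <- .normChrom(names(chromLengths))
    chrom <- .normChrom(fragments$chrom)
    keep <- chrom %in% .normChrom(chroms)
    if ("mapq" %in% names(fragments))
        keep <- keep & fragments$mapq >= minMapq
    fr <- fragments[keep, , drop = FALSE]
    chrom <- chrom[keep]
    cs <- tn5CutSites(data.frame(chrom = chrom, start = fr$start,
                                 end = fr$end))
    skipped <- sum(is.na(cs$cut1))
    ok <- !is.na(cs$cut1)
    cuts <- data.frame(chrom = rep(cs$chrom[ok], 2L),
                       pos = c(cs$cut1[ok], cs$cut2[ok]))
    useChroms <- intersect(.normChrom(chroms), names(chromLengths))
    cov <- lapply(useChroms, function(cname) {
        len <- chromLengths[[cname]]
        p <- cuts$pos[cuts$chrom == cname]
        if (!length(p)) return(Rle(0L, len))
        # 0-based window [pos - ext, pos + ext + 1) -> 1-based IRanges
        ir <- IRanges(start = pmax(p - extension + 1L, 1L),
                      end = pmin(p + extension + 1L, len))
        coverage(ir, width = len)
    })
    names(cov) <- useChroms
    new("CutSiteTrack", coverage = methods::as(cov, "SimpleRleList"),
        chromLengths = chromLengths[useChroms], extension = extension,
        librarySize = 2 * sum(ok), nFragments = sum(ok),
        nSkipped = as.integer(skipped), normalized = FALSE)
}

#' Total signal in a cut-site track
#'
#' For an unnormalized track away from chromosome ends this equals
#' `2 * fragments * (2 * extension + 1)`.
#'
#' @param track a [CutSiteTrack-class]
#' @return total summed coverage
#' @export
trackTotalSignal <- function(track) {
    sum(vapply(track@coverage, function(r) sum(as.numeric(r)), numeric(1)))
}

#' Poisson sliding-window peak caller
#'
#' A deliberately simple global-background caller in the spirit of a
#' no-local-lambda MACS2 run: the genome is tiled into `window`-bp windows,
#' each scored by the Poisson upper-tail probability of the number of
#' cut-site events it contains against the global rate
#' `totalSignal / genomeSize * window`. The extended coverage in a window
#' is converted back to events by dividing by the per-cut-site footprint
#' `2 * extension + 1`, so the tested counts are Poisson under a
#' homogeneous background. Significant windows that touch are merged into
#' peaks.
#'
#' @param track an unnormalized [CutSiteTrack-class]
#' @param genomeSize effective genome size used for the background rate;
#'   defaults to the summed chromosome lengths of the track (for the real
#'   zebrafish assembly the conventional value is 1.412e9)
#' @param window window width in bp (default 300)
#' @param pCutoff Poisson p-value threshold (default 1e-3)
#' @return `GRanges` of peaks with metadata columns `score` (-log10 best
#'   window p), `foldEnrichment` (best window observed/expected) and
#'   `summit` (1-based position of maximum coverage). Attributes `nWindows`
#'   and `nSignificant` on the result record the scan size for calibration.
#' @export
callPeaks <- function(track, genomeSize = NULL, window = 300L,
                      pCutoff = 1e-3) {
    if (track@normalized) stop("callPeaks requires an unnormalized track")
    window <- as.integer(window)
    if (is.null(genomeSize)) genomeSize <- sum(track@chromLengths)
    total <- trackTotalSignal(track)
    if (total == 0) {
        out <- GenomicRanges::GRanges()
        attr(out, "nWindows") <- 0L
        attr(out, "nSignificant") <- 0L
        return(out)
    }
    footprint <- 2 * track@extension + 1
    lambda <- total / footprint / genomeSize * window
    allPeaks <- list()
    nW <- 0L; nSig <- 0L
    for (cname in names(track@coverage)) {
        r <- track@coverage[[cname]]
        len <- length(r)
        nwin <- len %/% window
        if (nwin == 0L) next
        starts <- seq.int(1L, by = window, length.out = nwin)
        v <- Views(r, start = starts, width = window)
        obs <- round(viewSums(v) / footprint)
        # log-space tail probability: deep peaks would underflow double
        # precision and saturate (tie) the scores otherwise
        logpv <- stats::ppois(obs - 1, lambda, lower.tail = FALSE,
                              log.p = TRUE)
        sig <- logpv < log(pCutoff)
        nW <- nW + nwin
        nSig <- nSig + sum(sig)
        if (!any(sig)) next
        idx <- which(sig)
        grp <- cumsum(c(1L, diff(idx) != 1L))
        first <- tapply(idx, grp, min)
        last <- tapply(idx, grp, max)
        best <- as.integer(tapply(idx, grp,
                                  function(w) w[which.min(logpv[w])]))
        s <- starts[first]
        e <- starts[last] + window - 1L
        summit <- viewWhichMaxs(Views(r, start = s, end = e))
        allPeaks[[length(allPeaks) + 1L]] <- data.frame(
            chrom = cname, start = s, end = e,
            score = -logpv[best] / log(10),
            foldEnrichment = obs[best] / lambda,
            summit = summit)
    }
    if (!length(allPeaks)) {
        out <- GenomicRanges::GRanges()
    } else {
        df <- do.call(rbind, allPeaks)
        out <- GenomicRanges::GRanges(
            df$chrom, IRanges(df$start, df$end),
            score = df$score, foldEnrichment = df$foldEnrichment,
            summit = df$summit)
    }
    attr(out, "nWindows") <- nW
    attr(out, "nSignificant") <- nSig
    out
}
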