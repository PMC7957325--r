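#' Median-of-ratios size factors
#'
#' Per-sample scaling factors computed as the median ratio of each sample's
#' counts to a per-feature geometric-mean pseudo-reference, using only
#' features with no zero count. Factors are renormalized to geometric mean 1
#' so the overall scale of the data is preserved.
#'
#' @param counts integer count matrix (features x samples) or a
#'   [CountExperiment-class]
#' @return named numeric vector of positive size factors, one per sample
#' @examples
#' m <- cbind(s1 = c(10, 30, 50), s2 = c(20, 60, 100))
#' sizeFactors(m)  # c(0.7071, 1.4142)
#' @export
sizeFactors <- function(counts) {
    if (is(counts, "CountExperiment")) counts <- counts(counts)
    counts <- as.matrix(counts)
    keep <- rowSums(counts == 0) == 0L
    if (!any(keep))
        stop("no feature has nonzero counts in all samples; ",
             "cannot build a pseudo-reference")
    logref <- rowMeans(log(counts[keep, , drop = FALSE]))
    logratios <- log(counts[keep, , drop = FALSE]) - logref
    sf <- exp(apply(logratios, 2, stats::median))
    sf <- sf / exp(mean(log(sf)))
    stats::setNames(sf, colnames(counts))
}

#' Normalize counts by median-of-ratios size factors
#'
#' @inheritParams sizeFactors
#' @param factors optional precomputed size factors
#' @return numeric matrix of normalized counts (`count / factor`)
#' @export
normalizeCounts <- function(counts, factors = NULL) {
    if (is(counts, "CountExperiment")) counts <- counts(counts)
    if (is.null(factors)) factors <- sizeFactors(counts)
    sweep(as.matrix(counts), 2, factors, "/")
}

#' Transcripts per million
#'
#' Per sample: `rate = count / length_kb`, `tpm = rate / sum(rate) * 1e6`.
#' Every column of the result sums to one million.
#'
#' @param counts count matrix or [CountExperiment-class]
#' @param lengths feature lengths in bp (taken from the object if omitted)
#' @return TPM matrix with the input's dimnames
#' @examples
#' tpm(matrix(c(100, 300), 2), lengths = c(1000, 3000))  # both 5e5
#' @export
tpm <- function(counts, lengths = NULL) {
    if (is(counts, "CountExperiment")) {
        if (is.null(lengths)) lengths <- featureLengths(counts)
        counts <- counts(counts)
    }
    counts <- as.matrix(counts)
    if (is.null(lengths)) stop("feature lengths are required")
    if (length(lengths) != nrow(counts))
        stop("lengths must match the number of features")
    rate <- counts / (lengths / 1000)
    tot <- colSums(rate)
    if (any(tot == 0))
        stop("TPM undefined for all-zero sample column(s): ",
             paste(colnames(counts)[tot == 0], collapse = ", "))
    sweep(rate, 2, tot, "/") * 1e6
}

#' Reads per kilobase per million mapped reads
#'
#' The denominator is the total mapped reads of the sample including
#' spike-ins.
#'
#' @inheritParams tpm
#' @return RPKM matrix
#' @export
rpkm <- function(counts, lengths = NULL) {
    if (is(counts, "CountExperiment")) {
        if (is.null(lengths)) lengths <- featureLengths(counts)
        counts <- counts(counts)
    }
    counts <- as.matrix(counts)
    tot <- colSums(counts)
    sweep(counts / (lengths / 1000), 2, tot / 1e6, "/")
}

#' Classify genes as zygotically transcribed
#'
#' A gene is called zygotic when its expression at the first (pre-ZGA) stage
#' is below `tpmThreshold` TPM and it increases at the next analysed stage;
#' both inequalities are strict, so a gene with no maternal contribution but
#' no rise (or a tie) is not called. Stages after the second are ignored.
#'
#' @param tpmByStage TPM matrix, genes x stages (columns named by stage)
#' @param stageOrder ordered stage labels; the first is pre-ZGA
#' @param tpmThreshold pre-ZGA expression ceiling (default 2 TPM)
#' @return character vector per gene, `"zygotic"` or `"not_zygotic"`
#' @examples
#' m <- cbind(`256-cell` = c(0.5, 5, 0.5), high = c(10, 10, 0.4))
#' rownames(m) <- c("a", "b", "c")
#' classifyZygotic(m, c("256-cell", "high"))  # zygotic, not, not
#' @export
classifyZygotic <- function(tpmByStage, stageOrder, tpmThreshold = 2) {
    if (length(stageOrder) < 2L)
        stop("at least two stages are required")
    miss <- setdiff(stageOrder[1:2], colnames(tpmByStage))
    if (length(miss))
        stop("stage(s) missing from the TPM matrix: ",
             paste(miss, collapse = ", "))
    s1 <- tpmByStage[, stageOrder[1]]
    s2 <- tpmByStage[, stageOrder[2]]
    zyg <- s1 < tpmThreshold & s2 > s1
    stats::setNames(ifelse(zyg, "zygotic", "not_zygotic"),
                    rownames(tpmByStage))
}

#' Calibrate absolute RNA concentration from ERCC spike-ins
#'
#' Spike-ins with observed RPKM below `rpkmFloor` are discarded; on the
#' rest, ordinary least squares fits `y = a + b X` with
#' `X = log10(known concentration)` and `y = log10(observed rpkm)`. The
#' normal equations are solved directly.
#'
#' @param concentration known spike-in concentrations (attomoles/uL)
#' @param observedRpkm observed RPKM for the same spike-ins
#' @param rpkmFloor detection floor below which spike-ins are dropped
#' @return an [ErccFit-class]
#' @seealso [predictConcentration()]
#' @examples
#' fit <- erccCalibrate(10^(0:3), 10^(2 + 0.5 * (0:3)))
#' fit@intercept; fit@slope  # 2 and 0.5
#' @export
erccCalibrate <- function(concentration, observedRpkm, rpkmFloor = 1) {
    if (length(concentration) != length(observedRpkm))
        stop("concentration and observedRpkm must have equal length")
    keep <- observedRpkm >= rpkmFloor
    if (sum(keep) < 2L)
        stop("fewer than 2 spike-ins at rpkm >= ", rpkmFloor,
             "; cannot fit the calibration line")
    X <- log10(concentration[keep])
    y <- log10(observedRpkm[keep])
    xb <- mean(X); yb <- mean(y)
    b <- sum((X - xb) * (y - yb)) / sum((X - xb)^2)
    a <- yb - b * xb
    new("ErccFit", intercept = a, slope = b, n = sum(keep),
        retained = data.frame(concentration = concentration[keep],
                              rpkm = observedRpkm[keep]),
        rpkmFloor = rpkmFloor)
}

#' Estimate absolute concentration from an ERCC fit
#'
#' Inverts the calibration line: `X = (y - a) / b` with `y = log10(rpkm)`.
#'
#' @param fit an [ErccFit-class]
#' @param rpkm observed RPKM values
#' @return estimated concentrations (attomoles/uL)
#' @export
predictConcentration <- function(fit, rpkm) {
    if (fit@slope == 0) stop("degenerate fit: zero slope")
    10^((log10(rpkm) - fit@intercept) / fit@slope)
}

#' Simplified negative-binomial differential count test
#'
#' Size-factor-normalized group means, a per-feature Wald test of the log
#' fold change under a negative-binomial model with a single
#' method-of-moments dispersion pooled across features, and
#' Benjamini-Hochberg adjustment. This is a deliberately compact stand-in
#' for a full shrinkage-based differential framework: one common dispersion,
#' no outlier filtering.
#'
#' @param counts count matrix or [CountExperiment-class]
#' @param groupA,groupB column names or indices of the two sample groups
#'   (disjoint, at least two samples each)
#' @param lfcThreshold,padjThreshold significance thresholds
#'   (default |logFC| > 1 and padj < 0.05)
#' @param foldEnrichment optional per-feature fold enrichment (e.g. peak
#'   enrichment over background); when supplied, significance additionally
#'   requires `foldEnrichment > feThreshold`
#' @param feThreshold fold-enrichment threshold (default 4)
#' @param pseudocount added to group means in the log fold change
#' @return data.frame with columns `feature`, `meanA`, `meanB`, `logFC`,
#'   `p`, `padj`, `significant` (and `foldEnrichment` when given)
#' @export
differentialCounts <- function(counts, groupA, groupB,
                               lfcThreshold = 1, padjThreshold = 0.05,
                               foldEnrichment = NULL, feThreshold = 4,
                               pseudocount = 0.5) {
    if (is(counts, "CountExperiment")) counts <- counts(counts)
    counts <- as.matrix(counts)
    if (is.character(groupA)) groupA <- match(groupA, colnames(counts))
    if (is.character(groupB)) groupB <- match(groupB, colnames(counts))
    if (anyNA(groupA) || anyNA(groupB)) stop("unknown sample name(s)")
    if (length(intersect(groupA, groupB)))
        stop("groupA and groupB overlap")
    if (length(groupA) < 2L || length(groupB) < 2L)
        stop("each group needs at least two samples")
    sub <- counts[, c(groupA, groupB), drop = FALSE]
    norm <- normalizeCounts(sub)
    A <- norm[, seq_along(groupA), drop = FALSE]
    B <- norm[, length(groupA) + seq_along(groupB), drop = FALSE]
    mA <- rowMeans(A); mB <- rowMeans(B)
    vA <- apply(A, 1, stats::var); vB <- apply(B, 1, stats::var)
    nA <- ncol(A); nB <- ncol(B)
    # common NB dispersion by method of moments, pooled across features:
    # per-feature (var - mean) / mean^2, averaged over features with signal
    m <- (mA + mB) / 2
    v <- (vA * (nA - 1) + vB * (nB - 1)) / (nA + nB - 2)
    ok <- m > 1
    alphaF <- (v[ok] - m[ok]) / m[ok]^2
    alpha <- max(mean(alphaF, trim = 0.1), 0)
    lfcE <- log(mB + pseudocount) - log(mA + pseudocount)
    se <- sqrt((1 / (mA + pseudocount) + alpha) / nA +
               (1 / (mB + pseudocount) + alpha) / nB)
    z <- lfcE / se
    p <- 2 * stats::pnorm(-abs(z))
    padj <- stats::p.adjust(p, method = "BH")
    logFC <- lfcE / log(2)
    sig <- abs(logFC) > lfcThreshold & padj < padjThreshold
    res <- data.frame(
        feature = if (is.null(rownames(counts))) seq_len(nrow(counts))
                  else rownames(counts),
        meanA = mA, meanB = mB, logFC = logFC, p = p, padj = padj,
        row.names = NULL)
    if (!is.null(foldEnrichment)) {
        res$foldEnrichment <- foldEnrichment
        sig <- sig & foldEnrichment > feThreshold
    }
    res$significant <- sig
    attr(res, "dispersion") <- alpha
    res
}
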