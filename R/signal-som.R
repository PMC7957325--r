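#' Element-by-sample accessibility signal matrix
#'
#' For every element, sums the extended cut-site signal of each sample's
#' track in a fixed-width window centered on the element midpoint and
#' divides by the track's library size (total retained cut sites). Windows
#' reaching past a chromosome end are truncated and flagged.
#'
#' @param elements `GRanges` or [ElementSet-class] of elements
#' @param tracks named list of [CutSiteTrack-class], one per sample (built
#'   with the short 5-bp extension for PCA/SOM use)
#' @param window odd window width in bp (default 601)
#' @param normalize divide by library size (default TRUE)
#' @return a [SignalMatrix-class]
#' @export
signalMatrix <- function(elements, tracks, window = 601L, normalize = TRUE) {
    if (is(elements, "ElementSet")) elements <- elements(elements)
    window <- as.integer(window)
    half <- window %/% 2L
    chroms <- as.character(GenomicRanges::seqnames(elements))
    mid <- (GenomicRanges::start(elements) + GenomicRanges::end(elements)) %/% 2L
    n <- length(elements)
    vals <- matrix(0, n, length(tracks),
                   dimnames = list(NULL, names(tracks)))
    truncated <- logical(n)
    for (j in seq_along(tracks)) {
        tr <- tracks[[j]]
        for (cname in unique(chroms)) {
            if (!cname %in% names(tr@coverage)) next
            r <- tr@coverage[[cname]]
            idx <- which(chroms == cname)
            s <- mid[idx] - half
            e <- mid[idx] + half
            trunc <- s < 1L | e > length(r)
            truncated[idx] <- truncated[idx] | trunc
            v <- IRanges::Views(r, start = pmax(s, 1L),
                                end = pmin(e, length(r)))
            vals[idx, j] <- IRanges::viewSums(v)
        }
        if (normalize) vals[, j] <- vals[, j] / tr@librarySize
    }
    new("SignalMatrix", values = vals, window = window,
        transform = "raw", truncated = truncated)
}

#' Log-transform a signal matrix
#'
#' @param x a [SignalMatrix-class]
#' @param pseudocount added before taking logs (signal can be zero)
#' @return the matrix with `log(x + pseudocount)` values
#' @export
logTransform <- function(x, pseudocount = NULL) {
    stopifnot(is(x, "SignalMatrix"))
    if ("log" %in% x@transform) stop("already log-transformed")
    if (is.null(pseudocount)) {
        pos <- x@values[x@values > 0]
        pseudocount <- if (length(pos)) min(pos) else 1
    }
    x@values <- log(x@values + pseudocount)
    x@transform <- c(x@transform, "log")
    x
}

#' Center the columns (samples) of a signal matrix
#'
#' @param x a [SignalMatrix-class]
#' @return matrix with each column mean subtracted
#' @export
centerColumns <- function(x) {
    stopifnot(is(x, "SignalMatrix"))
    x@values <- sweep(x@values, 2, colMeans(x@values))
    x@transform <- c(x@transform, "column-centered")
    x
}

#' Center the rows (elements) of a signal matrix
#'
#' After column then row centering the values behave as log-fold changes of
#' each element across samples.
#'
#' @param x a [SignalMatrix-class]
#' @return matrix with each row mean subtracted
#' @export
centerRows <- function(x) {
    stopifnot(is(x, "SignalMatrix"))
    x@values <- sweep(x@values, 1, rowMeans(x@values))
    x@transform <- c(x@transform, "row-centered")
    x
}

#' PCA embedding of samples from an accessibility signal matrix
#'
#' Column-centers the (log-transformed) element-by-sample matrix and
#' computes the SVD; samples are embedded by the right singular vectors
#' scaled by the singular values.
#'
#' @param x a log-transformed [SignalMatrix-class]
#' @param nComponents components to return (clipped to the matrix rank with
#'   a warning)
#' @return list with `coordinates` (samples x components),
#'   `varianceExplained` (per component, sums to at most 1) and the full
#'   `svd`
#' @export
pcaEmbed <- function(x, nComponents = 2L) {
    stopifnot(is(x, "SignalMatrix"))
    if (!"log" %in% x@transform)
        stop("pcaEmbed expects a log-transformed matrix")
    if (!"column-centered" %in% x@transform) x <- centerColumns(x)
    m <- x@values
    sv <- svd(m)
    pos <- sum(sv$d > sv$d[1] * 1e-12)
    if (nComponents > pos) {
        warning("nComponents clipped to rank ", pos)
        nComponents <- pos
    }
    coords <- sv$v[, seq_len(nComponents), drop = FALSE] %*%
        diag(sv$d[seq_len(nComponents)], nComponents)
    rownames(coords) <- colnames(m)
    colnames(coords) <- paste0("PC", seq_len(nComponents))
    list(coordinates = coords,
         varianceExplained = sv$d^2 / sum(sv$d^2),
         svd = sv)
}

#' Batch self-organizing map of accessibility patterns
#'
#' A standard batch SOM on the rows of a column- and row-centered
#' log-signal matrix (i.e. on log-fold-change profiles): the codebook is
#' initialized from random data rows, and each epoch assigns every row to
#' its best-matching unit and recomputes every unit as the
#' Gaussian-neighborhood-weighted mean of the data. The neighborhood width
#' shrinks linearly to zero over the first two thirds of the epochs, after
#' which the update is plain Lloyd iteration, so the tail of the
#' quantization-error trace is non-increasing.
#'
#' @param x a [SignalMatrix-class] (log-transformed, column- and
#'   row-centered) or a plain numeric matrix
#' @param grid SOM grid rows and columns (default `c(3, 3)`, i.e. 9 units)
#' @param epochs training epochs (default 100)
#' @param seed seed for codebook initialization
#' @return a [SomFit-class]
#' @export
somCluster <- function(x, grid = c(3L, 3L), epochs = 100L, seed = 1L) {
    if (is(x, "SignalMatrix")) {
        if (!all(c("log", "column-centered", "row-centered") %in% x@transform))
            stop("somCluster expects a log-transformed, column- and ",
                 "row-centered matrix")
        m <- x@values
    } else m <- as.matrix(x)
    nUnits <- prod(grid)
    if (nUnits > nrow(m))
        stop("grid has more units than input rows")
    gridPos <- as.matrix(expand.grid(row = seq_len(grid[1]),
                                     col = seq_len(grid[2])))
    unitDist2 <- as.matrix(stats::dist(gridPos))^2
    codebook <- withr::with_seed(seed,
        m[sample.int(nrow(m), nUnits), , drop = FALSE])
    sigma0 <- max(grid) / 2
    shrinkEpochs <- ceiling(2 * epochs / 3)
    qerror <- numeric(epochs)
    assignment <- integer(nrow(m))
    x2 <- rowSums(m^2)
    for (ep in seq_len(epochs)) {
        # BMU assignment via squared distances
        cross <- m %*% t(codebook)
        c2 <- rowSums(codebook^2)
        d2 <- outer(x2, c2, "+") - 2 * cross
        assignment <- max.col(-d2, ties.method = "first")
        qerror[ep] <- mean(d2[cbind(seq_len(nrow(m)), assignment)])
        sigma <- if (ep < shrinkEpochs)
            sigma0 * (1 - (ep - 1) / shrinkEpochs) else 0
        if (sigma > 0) {
            h <- exp(-unitDist2 / (2 * sigma^2))
        } else {
            h <- diag(nUnits)
        }
        w <- h[assignment, , drop = FALSE]      # rows x units
        denom <- colSums(w)
        upd <- t(w) %*% m / denom
        nonempty <- denom > 0
        codebook[nonempty, ] <- upd[nonempty, , drop = FALSE]
    }
    new("SomFit", grid = as.integer(grid), codebook = codebook,
        assignment = assignment, qerror = qerror, seed = as.integer(seed))
}

#' Group SOM units into meta-clusters by codebook similarity
#'
#' A pattern of accessibility typically occupies a contiguous *set* of SOM
#' units rather than a single one. This helper applies complete-linkage
#' hierarchical clustering to the codebook vectors and cuts the tree at
#' `k` groups, returning the meta-cluster of every input row.
#'
#' @param fit a [SomFit-class]
#' @param k number of meta-clusters
#' @return integer vector: meta-cluster per input row
#' @export
cutSomUnits <- function(fit, k) {
    hc <- stats::hclust(stats::dist(fit@codebook), method = "complete")
    unitGroup <- stats::cutree(hc, k = k)
    unitGroup[fit@assignment]
}

#' Differential chromatin accessibility
#'
#' Applies the negative-binomial differential count test to per-element
#' cut-site counts and additionally requires the element's peak fold
#' enrichment over background to exceed `feThreshold` for a significance
#' call (the logFC > 1, padj < 0.05, fold enrichment > 4 regime).
#'
#' @param peakCounts count matrix or [CountExperiment-class] of cut-site
#'   counts per element per sample
#' @param groupA,groupB sample groups
#' @param foldEnrichment per-element fold enrichment from the peak caller
#' @param lfcThreshold,padjThreshold,feThreshold significance thresholds
#' @return data.frame as [differentialCounts()]
#' @export
diffAccessibility <- function(peakCounts, groupA, groupB,
                              foldEnrichment = NULL,
                              lfcThreshold = 1, padjThreshold = 0.05,
                              feThreshold = 4) {
    differentialCounts(peakCounts, groupA, groupB,
                       lfcThreshold = lfcThreshold,
                       padjThreshold = padjThreshold,
                       foldEnrichment = foldEnrichment,
                       feThreshold = feThreshold)
}
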