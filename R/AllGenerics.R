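#' @importFrom SummarizedExperiment assay rowData colData assayNames
NULL

#' Accessors for germfate objects
#'
#' Small accessor generics so that user code never reaches into slots:
#' `counts()` and `featureLengths()` for [CountExperiment-class],
#' `elements()`/`cascadeLog()` for [ElementSet-class],
#' `localIdr()`/`globalIdr()` for [IdrFit-class],
#' `signalValues()`/`transformState()` for [SignalMatrix-class],
#' `stages()` for [SimConfig-class].
#'
#' @param x an object of the documented class
#' @return the stored component
#' @name accessors
#' @aliases counts featureLengths elements cascadeLog localIdr globalIdr
#'   signalValues transformState stages somAssignment
NULL

#' @rdname accessors
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))
#' @rdname accessors
#' @export
setMethod("counts", "CountExperiment", function(x) assay(x, "counts"))

#' @rdname accessors
#' @export
setGeneric("featureLengths", function(x) standardGeneric("featureLengths"))
#' @rdname accessors
#' @export
setMethod("featureLengths", "CountExperiment",
          function(x) stats::setNames(rowData(x)$length, rownames(x)))

#' @rdname accessors
#' @export
setGeneric("elements", function(x) standardGeneric("elements"))
#' @rdname accessors
#' @export
setMethod("elements", "ElementSet", function(x) x@elements)

#' @rdname accessors
#' @export
setGeneric("cascadeLog", function(x) standardGeneric("cascadeLog"))
#' @rdname accessors
#' @export
setMethod("cascadeLog", "ElementSet", function(x) x@cascadeLog)

#' @rdname accessors
#' @export
setGeneric("localIdr", function(x) standardGeneric("localIdr"))
#' @rdname accessors
#' @export
setMethod("localIdr", "IdrFit", function(x) x@localIdr)

#' @rdname accessors
#' @export
setGeneric("globalIdr", function(x) standardGeneric("globalIdr"))
#' @rdname accessors
#' @export
setMethod("globalIdr", "IdrFit", function(x) x@globalIdr)

#' @rdname accessors
#' @export
setGeneric("signalValues", function(x) standardGeneric("signalValues"))
#' @rdname accessors
#' @export
setMethod("signalValues", "SignalMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("transformState", function(x) standardGeneric("transformState"))
#' @rdname accessors
#' @export
setMethod("transformState", "SignalMatrix", function(x) x@transform)

#' @rdname accessors
#' @export
setGeneric("stages", function(x) standardGeneric("stages"))
#' @rdname accessors
#' @export
setMethod("stages", "SimConfig", function(x) x@stages)

#' @rdname accessors
#' @export
setGeneric("somAssignment", function(x) standardGeneric("somAssignment"))
#' @rdname accessors
#' @export
setMethod("somAssignment", "SomFit", function(x) x@assignment)

setMethod("show", "SimConfig", function(object) {
    cat("SimConfig:", object@nGenes, "genes,", object@nElements,
        "elements;", length(object@stages), "stages x",
        length(object@cellTypes), "cell types x", object@nReplicates,
        "replicates; seed", object@seed, "\n")
})

setMethod("show", "CutSiteTrack", function(object) {
    cat("CutSiteTrack:", object@nFragments, "fragments ->",
        object@librarySize, "cut sites, extension", object@extension,
        "bp,", length(object@coverage), "chromosomes",
        if (object@normalized) "(normalized)" else "(raw)", "\n")
})

setMethod("show", "IdrFit", function(object) {
    cat(sprintf(
        "IdrFit: p = %.3f, rho = %.3f, mu = %.3f, sigma = %.3f (%s, %d it.)\n",
        object@p, object@rho, object@mu, object@sigma,
        if (object@converged) "converged" else "NOT converged",
        object@iterations))
    cat("  peaks at global IDR <= 0.05:", sum(object@globalIdr <= 0.05),
        "of", length(object@globalIdr), "\n")
})

setMethod("show", "ElementSet", function(object) {
    cat("ElementSet:", length(object@elements), "candidate elements\n")
    cat("  cascade steps:", nrow(object@cascadeLog), "\n")
})

setMethod("show", "SignalMatrix", function(object) {
    cat("SignalMatrix:", nrow(object@values), "elements x",
        ncol(object@values), "samples; window", object@window, "bp;",
        "transform:", paste(object@transform, collapse = " -> "), "\n")
})

setMethod("show", "SomFit", function(object) {
    cat("SomFit:", object@grid[1], "x", object@grid[2], "grid;",
        length(object@assignment), "rows;",
        length(object@qerror), "epochs; final QE",
        signif(utils::tail(object@qerror, 1), 4), "\n")
})

setMethod("show", "ErccFit", function(object) {
    cat(sprintf("ErccFit: y = %.4f + %.4f X on %d spike-ins (rpkm >= %g)\n",
                object@intercept, object@slope, object@n, object@rpkmFloor))
})

setMethod("show", "IrPermutation", function(object) {
    cat(sprintf(
        "IrPermutation: observed %.4f, p = %.4g (%d permutations)\n",
        object@observed, object@p, object@nPerm))
    cat(sprintf("  95%% null interval [%.4f, %.4f]; Welch t p = %.4g\n",
                object@interval[1], object@interval[2], object@tTestP))
})

setMethod("show", "CellGeometry", function(object) {
    nl <- setdiff(unique(as.vector(object@mask)), c(0L, object@nucleusLabel))
    cat("CellGeometry:", paste(dim(object@mask), collapse = "x"),
        "mask;", length(nl), "granules; spacing", object@spacing, "\n")
})
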