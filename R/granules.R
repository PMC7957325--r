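#' Construct a CellGeometry from a labeled mask
#'
#' @param mask integer matrix; 0 = background, `nucleusLabel` = nucleus,
#'   other positive labels = granules
#' @param nucleusLabel label of the nucleus region (default 1)
#' @param spacing physical length per pixel edge (default 1)
#' @return a [CellGeometry-class]
#' @export
cellGeometry <- function(mask, nucleusLabel = 1L, spacing = 1) {
    mask <- as.matrix(mask)
    storage.mode(mask) <- "integer"
    new("CellGeometry", mask = mask, nucleusLabel = as.integer(nucleusLabel),
        spacing = spacing)
}

# out[i, j] = m[i + dr, j + dc], out-of-bounds neighbors take `fill`
.shifted <- function(m, dr, dc, fill = 0L) {
    nr <- nrow(m); nc <- ncol(m)
    out <- matrix(fill, nr, nc)
    ri <- seq_len(nr); ci <- seq_len(nc)
    okr <- ri + dr >= 1 & ri + dr <= nr
    okc <- ci + dc >= 1 & ci + dc <= nc
    out[ri[okr], ci[okc]] <- m[ri[okr] + dr, ci[okc] + dc]
    out
}

#' Area and perimeter of every labeled region
#'
#' Area is the pixel count times `spacing^2`; perimeter is the number of
#' pixel edges exposed to a different label (or the grid boundary) times
#' `spacing`. Regions are reported in increasing label order.
#'
#' @param mask integer matrix of labels (0 = background)
#' @param spacing physical length per pixel edge (default 1)
#' @return data.frame with columns `label`, `area`, `perimeter`
#' @examples
#' m <- matrix(0L, 4, 4); m[2, 2] <- 1L
#' measureRegions(m)  # area 1, perimeter 4
#' @export
measureRegions <- function(mask, spacing = 1) {
    mask <- as.matrix(mask)
    labels <- sort(setdiff(unique(as.vector(mask)), 0L))
    if (!length(labels))
        return(data.frame(label = integer(), area = numeric(),
                          perimeter = numeric()))
    shifts <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
    res <- lapply(labels, function(lb) {
        reg <- mask == lb
        area <- sum(reg)
        exposed <- 0L
        for (s in shifts) {
            nb <- .shifted(mask, s[1], s[2], fill = 0L)
            exposed <- exposed + sum(reg & nb != lb)
        }
        data.frame(label = lb, area = area * spacing^2,
                   perimeter = exposed * spacing)
    })
    do.call(rbind, res)
}

#' Germ-granule/nucleus contact ratio
#'
#' For every granule, the contact length is the summed length of granule
#' boundary edges whose facing pixel lies within `adjacencyDistance` pixels
#' of the nucleus region; the granule's contact ratio is that length
#' divided by the *total* granule area of the cell, so the per-granule
#' ratios of one cell share a denominator and sum to (total contact) /
#' (total area).
#'
#' @param cell a [CellGeometry-class]
#' @param adjacencyDistance pixels: a boundary edge counts as contact when
#'   the pixel across it is within this distance of the nucleus (default 1,
#'   i.e. the facing pixel is a nucleus pixel)
#' @return list with `granules` (data.frame: `label`, `area`,
#'   `contactLength`, `ratio`), `totalArea`, and `empty` flag (TRUE when the
#'   cell has no granules, in which case `granules` has zero rows)
#' @examples
#' m <- matrix(0L, 30, 30)
#' m[1:10, 1:20] <- 1L           # nucleus
#' m[11:20, 1:10] <- 2L          # granule flush against nucleus bottom edge
#' contactRatio(cellGeometry(m))$granules$ratio  # 10 / 100 = 0.1
#' @export
contactRatio <- function(cell, adjacencyDistance = 1L) {
    stopifnot(is(cell, "CellGeometry"))
    mask <- cell@mask
    spacing <- cell@spacing
    nuc <- mask == cell@nucleusLabel
    if (!any(nuc)) stop("no nucleus region in mask")
    labels <- sort(setdiff(unique(as.vector(mask)),
                           c(0L, cell@nucleusLabel)))
    if (!length(labels))
        return(list(granules = data.frame(label = integer(),
                                          area = numeric(),
                                          contactLength = numeric(),
                                          ratio = numeric()),
                    totalArea = 0, empty = TRUE))
    # pixels within (adjacencyDistance - 1) of the nucleus, by repeated
    # 4-neighborhood dilation; with distance 1 the facing pixel itself must
    # be nucleus
    near <- nuc
    d <- as.integer(adjacencyDistance) - 1L
    shifts <- list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
    if (d > 0) for (i in seq_len(d)) {
        grown <- near
        for (s in shifts)
            grown <- grown | .shifted(near, s[1], s[2], fill = FALSE) > 0
        near <- grown
    }
    totalArea <- sum(mask %in% labels) * spacing^2
    rows <- lapply(labels, function(lb) {
        reg <- mask == lb
        contact <- 0L
        for (s in shifts) {
            facing <- .shifted(near, s[1], s[2], fill = FALSE) > 0
            contact <- contact + sum(reg & facing)
        }
        area <- sum(reg) * spacing^2
        clen <- contact * spacing
        data.frame(label = lb, area = area, contactLength = clen,
                   ratio = clen / totalArea)
    })
    list(granules = do.call(rbind, rows), totalArea = totalArea,
         empty = FALSE)
}

#' Compare contact-ratio distributions against a control condition
#'
#' Two-sample Wilcoxon rank-sum test of every condition against the
#' control, flagged significant at alpha = 0.05. Conditions with fewer than
#' three observations are flagged untestable (`NA` p).
#'
#' @param ratiosByCondition named list of numeric contact-ratio vectors
#' @param control name of the control condition
#' @param alpha significance level (default 0.05)
#' @return data.frame with `condition`, `n`, `p`, `significant`
#' @export
compareGroups <- function(ratiosByCondition, control, alpha = 0.05) {
    if (!control %in% names(ratiosByCondition))
        stop("control condition '", control, "' not found")
    ctrl <- ratiosByCondition[[control]]
    others <- setdiff(names(ratiosByCondition), control)
    rows <- lapply(others, function(cond) {
        x <- ratiosByCondition[[cond]]
        if (length(x) < 3L || length(ctrl) < 3L)
            return(data.frame(condition = cond, n = length(x),
                              p = NA_real_, significant = NA))
        p <- stats::wilcox.test(x, ctrl, exact = FALSE)$p.value
        data.frame(condition = cond, n = length(x), p = p,
                   significant = p < alpha)
    })
    do.call(rbind, rows)
}
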