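#' Intron-retention ratio
#'
#' The IR ratio of one intron is the intronic sequencing depth divided by
#' the larger of the two splice-site read counts plus the intronic depth:
#' `D / (max(SS5, SS3) + D)`. It is a proxy for nascent (unspliced)
#' transcription: 0 for a fully spliced intron, 1 when only intronic signal
#' is seen. When depth and both splice-site counts are all zero the ratio is
#' undefined and `NA` is returned.
#'
#' @param depth intronic depth D (mean per-base read depth)
#' @param ss5,ss3 reads mapping to the 5' and 3' splice sites
#' @return numeric vector of ratios in \[0, 1\] (NA where undefined)
#' @examples
#' irRatio(10, 30, 20)  # 0.25
#' @export
irRatio <- function(depth, ss5, ss3) {
    if (any(depth < 0, na.rm = TRUE) || any(ss5 < 0, na.rm = TRUE) ||
        any(ss3 < 0, na.rm = TRUE))
        stop("depth and splice-site reads must be non-negative")
    denom <- pmax(ss5, ss3) + depth
    out <- ifelse(denom == 0, NA_real_, depth / denom)
    out
}

#' Coverage-weighted per-gene IR
#'
#' Aggregates intron-level IR ratios to genes with weights
#' `max(SS5, SS3) + D` (the ratio's own denominator, i.e. the evidence
#' supporting each intron). Genes whose introns carry no evidence at all are
#' absent from the result.
#'
#' @param measurements data.frame with columns `gene`, `depth`, `ss5`, `ss3`
#'   (one row per intron; an `intron` id column may be present)
#' @return named numeric vector of per-gene IR values
#' @examples
#' tab <- data.frame(gene = c("g", "g"), depth = c(25, 300),
#'                   ss5 = c(75, 75), ss3 = c(60, 0))
#' geneIR(tab)  # weighted mean of 0.25 (w=100) and 0.8 (w=375)
#' @export
geneIR <- function(measurements) {
    stopifnot(all(c("gene", "depth", "ss5", "ss3") %in% names(measurements)))
    w <- pmax(measurements$ss5, measurements$ss3) + measurements$depth
    ir <- irRatio(measurements$depth, measurements$ss5, measurements$ss3)
    keep <- w > 0
    if (!any(keep)) return(stats::setNames(numeric(0), character(0)))
    num <- tapply(ir[keep] * w[keep], measurements$gene[keep], sum)
    den <- tapply(w[keep], measurements$gene[keep], sum)
    out <- num / den
    stats::setNames(as.numeric(out), names(out))
}

#' Permutation test for an IR shift in a gene subgroup
#'
#' Tests whether a subgroup of genes changes its intron retention between
#' two stages more than random gene sets of the same size. The observed
#' statistic is the mean over the subgroup of `IR_post - IR_pre`. The null
#' is built from `nPerm` random same-size gene sets drawn without
#' replacement from all genes with a defined IR at both stages; the
#' two-sided p-value uses the +1 correction,
#' `p = (1 + #{|null| >= |observed|}) / (nPerm + 1)`, and is therefore never
#' exactly zero. A Welch t-test of the subgroup's post vs pre IR values is
#' reported alongside.
#'
#' @param irPre,irPost named per-gene IR vectors for the two stages
#' @param subgroup gene ids forming the subgroup of interest
#' @param nPerm number of permutations (default 10000)
#' @param seed integer seed for the permutation draws
#' @param statistic `"mean"` (default) or `"median"` of the subgroup shifts
#' @return an [IrPermutation-class] with the observed statistic, null
#'   distribution, p-value and the 95% null interval
#' @export
irPermutationTest <- function(irPre, irPost, subgroup, nPerm = 10000L,
                              seed = 1L, statistic = c("mean", "median")) {
    statistic <- match.arg(statistic)
    if (nPerm < 100L) stop("nPerm must be at least 100")
    common <- intersect(names(irPre), names(irPost))
    common <- common[!is.na(irPre[common]) & !is.na(irPost[common])]
    miss <- setdiff(subgroup, common)
    if (length(miss))
        stop("subgroup gene(s) missing from the eligible background: ",
             paste(utils::head(miss, 5), collapse = ", "))
    shift <- irPost[common] - irPre[common]
    k <- length(subgroup)
    statFun <- if (statistic == "mean") mean else stats::median
    observed <- statFun(shift[subgroup])
    n <- length(shift)
    null <- withr::with_seed(seed, {
        vapply(seq_len(nPerm),
               function(i) statFun(shift[sample.int(n, k)]), numeric(1))
    })
    p <- (1 + sum(abs(null) >= abs(observed))) / (nPerm + 1)
    tt <- stats::t.test(irPost[subgroup], irPre[subgroup])
    new("IrPermutation", observed = observed, null = null, p = p,
        tTestP = tt$p.value,
        interval = unname(stats::quantile(null, c(0.025, 0.975))),
        nPerm = as.integer(nPerm), seed = as.integer(seed))
}
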