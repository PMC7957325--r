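#' Fit the reproducibility mixture (IDR) to paired peak scores
#'
#' Replicate peak scores enter only through their ranks,
#' `u = rank / (n + 1)`, and are modelled with a two-component Gaussian
#' copula mixture: an irreproducible noise component with independent
#' standard-normal margins and a reproducible component with mean
#' `(mu, mu)`, standard deviation `sigma` and correlation `rho`. Each EM
#' iteration recomputes the pseudo-data `z = G^{-1}(u)` from the current
#' mixture marginal `G`, then takes an expectation and maximization step;
#' the starting point is (p, rho, mu, sigma) = (0.5, 0.8, 1, 1). Because
#' the EM path treats the pseudo-data as fixed within each iteration, its
#' fixed point can sit slightly off the optimum of the exact copula
#' pseudo-likelihood (which carries the Jacobian of the marginal
#' transform), so the estimate is finished by quasi-Newton maximization of
#' [idrCopulaLogLik()] from the EM solution. The local irreproducibility of
#' a peak is the posterior probability of the noise component; the global
#' IDR is the running mean of local values over all peaks ranked at least
#' as well (ascending local irreproducibility), non-decreasing along that
#' ranking by construction.
#'
#' @param scores1,scores2 paired peak scores from two replicates (same
#'   peaks, matched upstream); higher = stronger
#' @param maxIter maximum EM warm-start iterations (default 100)
#' @param tol convergence tolerance (default 1e-6), applied to the larger
#'   of the pseudo log-likelihood change and the maximum parameter change;
#'   the pseudo log-likelihood alone is not monotone because the pseudo-data
#'   move with the parameters
#' @return an [IdrFit-class]
#' @seealso [matchPeaks()] to pair replicate peak lists, [idrPass()]
#' @export
idrFit <- function(scores1, scores2, maxIter = 100L, tol = 1e-6) {
    n <- length(scores1)
    if (length(scores2) != n) stop("score vectors must be paired")
    if (n < 20L) stop("at least 20 matched peaks are required")
    u1 <- rank(scores1, ties.method = "average") / (n + 1)
    u2 <- rank(scores2, ties.method = "average") / (n + 1)
    p <- 0.5; rho <- 0.8; mu <- 1; sigma <- 1
    ll <- -Inf; converged <- FALSE; it <- 0L
    gamma <- rep(0.5, n)
    for (it in seq_len(maxIter)) {
        z1 <- .mixQuantile(u1, p, mu, sigma)
        z2 <- .mixQuantile(u2, p, mu, sigma)
        f1 <- .dbvnorm(z1, z2, mu, sigma, rho)
        f0 <- stats::dnorm(z1) * stats::dnorm(z2)
        num <- p * f1
        den <- num + (1 - p) * f0
        den[den == 0] <- .Machine$double.xmin
        gamma <- num / den
        llNew <- sum(log(den))
        # M step
        old <- c(p, rho, mu, sigma)
        sg <- sum(gamma)
        p <- min(max(sg / n, 1e-4), 1 - 1e-4)
        mu <- sum(gamma * (z1 + z2)) / (2 * sg)
        sigma2 <- sum(gamma * ((z1 - mu)^2 + (z2 - mu)^2)) / (2 * sg)
        sigma <- sqrt(max(sigma2, 1e-6))
        rho <- sum(gamma * (z1 - mu) * (z2 - mu)) / (sg * sigma2)
        rho <- min(max(rho, 1e-4), 1 - 1e-4)
        delta <- max(abs(c(p, rho, mu, sigma) - old))
        if (is.finite(ll) && (abs(llNew - ll) < tol || delta < tol)) {
            ll <- llNew
            converged <- TRUE
            break
        }
        ll <- llNew
    }
    # polish: quasi-Newton maximization of the exact copula
    # pseudo-likelihood (the EM path above ignores the dependence of the
    # marginal transform on the parameters, so its fixed point can sit
    # slightly off the optimum)
    obj <- function(theta) {
        pp <- min(max(stats::plogis(theta[1]), 1e-4), 1 - 1e-4)
        rr <- min(max(stats::plogis(theta[2]), 1e-4), 1 - 1e-4)
        mm <- min(max(theta[3], -20), 20)
        ss <- min(max(exp(theta[4]), 1e-3), 1e3)
        -.idrCopulaLogLik(u1, u2, pp, rr, mm, ss)
    }
    opt <- stats::optim(c(stats::qlogis(p), stats::qlogis(rho), mu,
                          log(sigma)),
                        obj, method = "BFGS",
                        control = list(maxit = 200, reltol = 1e-10))
    p <- min(max(stats::plogis(opt$par[1]), 1e-4), 1 - 1e-4)
    rho <- min(max(stats::plogis(opt$par[2]), 1e-4), 1 - 1e-4)
    mu <- min(max(opt$par[3], -20), 20)
    sigma <- min(max(exp(opt$par[4]), 1e-3), 1e3)
    z1 <- .mixQuantile(u1, p, mu, sigma)
    z2 <- .mixQuantile(u2, p, mu, sigma)
    f1 <- .dbvnorm(z1, z2, mu, sigma, rho)
    f0 <- stats::dnorm(z1) * stats::dnorm(z2)
    den <- p * f1 + (1 - p) * f0
    den[den == 0] <- .Machine$double.xmin
    gamma <- p * f1 / den
    converged <- converged || opt$convergence == 0L
    local <- 1 - gamma
    ord <- order(local)
    global <- numeric(n)
    global[ord] <- cumsum(local[ord]) / seq_len(n)
    global <- pmin(global, 1)
    new("IdrFit", p = p, rho = rho, mu = mu, sigma = sigma,
        localIdr = local, globalIdr = global, logLik = -opt$value,
        iterations = it, converged = converged)
}

#' Copula pseudo-log-likelihood of the IDR mixture
#'
#' The likelihood of the rank data under the two-component Gaussian copula
#' mixture: joint mixture density of the pseudo-data `z = G^{-1}(u)`
#' divided by the product of the mixture marginal densities (the Jacobian
#' of the marginal transform). Exposed for oracle-style verification.
#'
#' @param u1,u2 rank-based uniforms, `rank / (n + 1)`
#' @param p,rho,mu,sigma mixture parameters
#' @return the pseudo-log-likelihood (a scalar)
#' @export
idrCopulaLogLik <- function(u1, u2, p, rho, mu, sigma) {
    .idrCopulaLogLik(u1, u2, p, rho, mu, sigma)
}

.idrCopulaLogLik <- function(u1, u2, p, rho, mu, sigma) {
    z1 <- .mixQuantile(u1, p, mu, sigma)
    z2 <- .mixQuantile(u2, p, mu, sigma)
    f1 <- .dbvnorm(z1, z2, mu, sigma, rho)
    f0 <- stats::dnorm(z1) * stats::dnorm(z2)
    g1 <- p * stats::dnorm((z1 - mu) / sigma) / sigma +
        (1 - p) * stats::dnorm(z1)
    g2 <- p * stats::dnorm((z2 - mu) / sigma) / sigma +
        (1 - p) * stats::dnorm(z2)
    sum(log(pmax(p * f1 + (1 - p) * f0, .Machine$double.xmin))) -
        sum(log(pmax(g1, .Machine$double.xmin))) -
        sum(log(pmax(g2, .Machine$double.xmin)))
}

# quantile function of the mixture marginal
# G(z) = p Phi((z - mu)/sigma) + (1 - p) Phi(z), by monotone interpolation
.mixQuantile <- function(u, p, mu, sigma) {
    qlo <- stats::qnorm(min(u)); qhi <- stats::qnorm(max(u))
    lo <- min(qlo, mu + sigma * qlo) - 1
    hi <- max(qhi, mu + sigma * qhi) + 1
    grid <- seq(lo, hi, length.out = 4096)
    G <- p * stats::pnorm((grid - mu) / sigma) + (1 - p) * stats::pnorm(grid)
    stats::approx(G, grid, xout = u, rule = 2, ties = "ordered")$y
}

# bivariate normal density with equal margins N(mu, sigma^2), correlation rho
.dbvnorm <- function(z1, z2, mu, sigma, rho) {
    d1 <- (z1 - mu) / sigma
    d2 <- (z2 - mu) / sigma
    q <- (d1^2 - 2 * rho * d1 * d2 + d2^2) / (1 - rho^2)
    exp(-q / 2) / (2 * pi * sigma^2 * sqrt(1 - rho^2))
}

#' Peaks passing a global IDR threshold
#'
#' @param fit an [IdrFit-class]
#' @param threshold global IDR ceiling (default 0.05, i.e. "5% IDR")
#' @return logical vector over the matched peaks
#' @export
idrPass <- function(fit, threshold = 0.05) {
    fit@globalIdr <= threshold
}

#' Match peaks across two replicates for IDR
#'
#' Peaks are matched by interval overlap of at least one bp; when a peak
#' overlaps several, the partner with the highest score wins, and each peak
#' is used at most once (greedy, best matches first).
#'
#' @param peaks1,peaks2 `GRanges` peak lists with a `score` metadata column
#' @return list with `pairs` (data.frame of matched indices `i1`, `i2`),
#'   `scores1`, `scores2` (paired score vectors)
#' @export
matchPeaks <- function(peaks1, peaks2) {
    hits <- GenomicRanges::findOverlaps(peaks1, peaks2)
    if (!length(hits))
        return(list(pairs = data.frame(i1 = integer(), i2 = integer()),
                    scores1 = numeric(), scores2 = numeric()))
    i1 <- S4Vectors::queryHits(hits)
    i2 <- S4Vectors::subjectHits(hits)
    s <- peaks1$score[i1] + peaks2$score[i2]
    ord <- order(-s)
    used1 <- logical(length(peaks1)); used2 <- logical(length(peaks2))
    keep <- logical(length(ord))
    for (k in ord) {
        if (!used1[i1[k]] && !used2[i2[k]]) {
            keep[k] <- TRUE
            used1[i1[k]] <- TRUE
            used2[i2[k]] <- TRUE
        }
    }
    pairs <- data.frame(i1 = i1[keep], i2 = i2[keep])
    list(pairs = pairs,
         scores1 = peaks1$score[pairs$i1],
         scores2 = peaks2$score[pairs$i2])
}
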