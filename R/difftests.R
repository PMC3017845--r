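#' Benjamini-Hochberg step-up adjustment
#'
#' Thin, validated wrapper around `stats::p.adjust(method = "BH")`: sorts the
#' p-values ascending, forms q_i = min over j >= i of (m * p_(j) / j) capped
#' at 1, and returns them in the input order. Controls the false discovery
#' rate for independent or positively dependent tests.
#'
#' @param p numeric vector of p-values in \[0, 1\]
#' @return adjusted values, same length and order as `p`
#' @export
bhAdjust <- function(p) {
    if (!is.numeric(p) || anyNA(p) || any(p < 0 | p > 1))
        stop("p-values must be finite numbers in [0, 1]", call. = FALSE)
    stats::p.adjust(p, method = "BH")
}

## ---- internal statistics -------------------------------------------------

## Rank-sum test on two numeric vectors.
## * no ties, both n <= 25: exact via stats::wilcox.test
## * ties, total n <= exactMax: exact permutation distribution of the rank
##   sum over all choose(N, n1) group-1 assignments (midranks; two-sided
##   p = P(|W - EW| >= |w - EW|), valid because the midrank multiset is
##   symmetric under reflection)
## * otherwise: normal approximation with tie correction, no continuity
##   correction (so that the squared statistic matches its chi-square use in
##   the two-part test)
## `idx` optionally carries a precomputed combn(N, n1) matrix so callers
## looping over features of equal shape pay for it once.
.rankSumTest <- function(v1, v2, exactMax = 16L, idx = NULL) {
    n1 <- length(v1); n2 <- length(v2); N <- n1 + n2
    v <- c(v1, v2)
    r <- rank(v)
    W <- sum(r[seq_len(n1)])
    mu <- n1 * (N + 1) / 2
    tieTab <- table(v)
    hasTies <- any(tieTab > 1)
    sigma2 <- n1 * n2 / 12 *
        ((N + 1) - sum(tieTab^3 - tieTab) / (N * (N - 1)))
    z <- if (sigma2 > 0) (W - mu) / sqrt(sigma2) else 0
    if (!hasTies && n1 <= 25 && n2 <= 25) {
        p <- stats::wilcox.test(v1, v2, exact = TRUE)$p.value
    } else if (hasTies && N <= exactMax && sigma2 > 0) {
        if (is.null(idx)) idx <- utils::combn(N, n1)
        Wall <- colSums(matrix(r[idx], nrow = n1))
        p <- mean(abs(Wall - mu) >= abs(W - mu) - 1e-9)
    } else if (sigma2 == 0) {
        p <- 1
    } else {
        p <- 2 * stats::pnorm(-abs(z))
    }
    list(statistic = z, p = min(p, 1))
}

## Tie-corrected rank-sum z only (no p), for use as the continuous part of
## the two-part chi-square.
.rankSumZ <- function(v1, v2) {
    n1 <- length(v1); n2 <- length(v2); N <- n1 + n2
    v <- c(v1, v2)
    r <- rank(v)
    W <- sum(r[seq_len(n1)])
    mu <- n1 * (N + 1) / 2
    tieTab <- table(v)
    sigma2 <- n1 * n2 / 12 *
        ((N + 1) - sum(tieTab^3 - tieTab) / (N * (N - 1)))
    if (sigma2 > 0) (W - mu) / sqrt(sigma2) else 0
}

## Welch (default) or pooled-variance t on the natural-log nonzero values.
.logTTest <- function(nz1, nz2, pooledVar = FALSE) {
    if (length(nz1) < 2 || length(nz2) < 2) return(NULL)
    l1 <- log(nz1); l2 <- log(nz2)
    if (stats::sd(l1) == 0 && stats::sd(l2) == 0) {
        t <- if (mean(l1) == mean(l2)) 0 else sign(mean(l1) - mean(l2)) * Inf
        return(list(statistic = t, p = if (t == 0) 1 else 0))
    }
    tt <- stats::t.test(l1, l2, var.equal = pooledVar)
    list(statistic = unname(tt$statistic), p = tt$p.value)
}

## Two-proportion z on the zero proportions, pooled variance.
## NULL when undefined (no zeros at all, or all values zero).
.zeroPropTest <- function(x1, x2) {
    n1 <- length(x1); n2 <- length(x2)
    p1 <- mean(x1 == 0); p2 <- mean(x2 == 0)
    pp <- (sum(x1 == 0) + sum(x2 == 0)) / (n1 + n2)
    if (pp <= 0 || pp >= 1) return(NULL)
    z <- (p1 - p2) / sqrt(pp * (1 - pp) * (1 / n1 + 1 / n2))
    list(statistic = z, p = 2 * stats::pnorm(-abs(z)))
}

## One-sample empirical log-likelihood ratio statistic for mean mu
## (Owen): 2 * sum log(1 + lambda * (x - mu)), lambda solved by uniroot.
.elOneSample <- function(x, mu) {
    d <- x - mu
    if (all(d == 0)) return(0)
    if (min(d) >= 0 || max(d) <= 0) return(Inf)  # mu outside the data hull
    eps <- 1e-10
    lo <- -1 / max(d) + eps
    hi <- -1 / min(d) - eps
    g <- function(lam) sum(d / (1 + lam * d))
    glo <- g(lo); ghi <- g(hi)
    if (!is.finite(glo) || !is.finite(ghi) || glo * ghi > 0) return(Inf)
    lam <- stats::uniroot(g, c(lo, hi), tol = 1e-10)$root
    2 * sum(log1p(lam * d))
}

## Two-sample empirical likelihood ratio test of equal mixture means
## (zeros enter as genuine observations on the amplitude scale). The
## profiled common mean lies between the two sample means; -2 log R is
## calibrated against chi-square with 1 df.
.elrTest <- function(x1, x2) {
    m1 <- mean(x1); m2 <- mean(x2)
    W <- function(mu) {
        v <- .elOneSample(x1, mu) + .elOneSample(x2, mu)
        if (is.finite(v)) v else 1e10  # keep the profile finite for optimize
    }
    if (m1 == m2) {
        stat <- W(m1)
    } else {
        lo <- min(m1, m2); hi <- max(m1, m2)
        opt <- stats::optimize(W, c(lo, hi), tol = 1e-8)
        stat <- min(opt$objective, W(lo), W(hi))
    }
    if (!is.finite(stat)) stat <- .Machine$double.xmax
    list(statistic = stat, p = stats::pchisq(stat, df = 1,
                                             lower.tail = FALSE))
}

## ---- per-feature dispatcher ---------------------------------------------

.testMethods <- c("t", "wilcoxon", "two_part_t", "two_part_wilcoxon", "elrt")

.testOne <- function(x1, x2, method, pooledVar = FALSE, exactMax = 16L,
                     idx = NULL) {
    res <- list(method = method, statistic = NA_real_, df = NA_integer_,
                p_raw = NA_real_, stat_prop = NA_real_, stat_cont = NA_real_,
                untestable = FALSE)
    nz1 <- x1[x1 > 0]; nz2 <- x2[x2 > 0]
    if (method == "t") {
        tt <- .logTTest(nz1, nz2, pooledVar)
        if (is.null(tt)) { res$untestable <- TRUE; return(res) }
        res$statistic <- tt$statistic; res$p_raw <- tt$p
    } else if (method == "wilcoxon") {
        rs <- .rankSumTest(x1, x2, exactMax, idx)
        res$statistic <- rs$statistic; res$p_raw <- rs$p
    } else if (method %in% c("two_part_t", "two_part_wilcoxon")) {
        zb <- .zeroPropTest(x1, x2)
        zc <- if (method == "two_part_t") .logTTest(nz1, nz2, pooledVar)
              else if (length(nz1) >= 2 && length(nz2) >= 2)
                  list(statistic = .rankSumZ(nz1, nz2))
              else NULL
        parts <- c(if (!is.null(zb)) zb$statistic,
                   if (!is.null(zc)) zc$statistic)
        if (!length(parts)) { res$untestable <- TRUE; return(res) }
        x2stat <- sum(parts^2)
        res$statistic <- x2stat
        res$df <- length(parts)
        res$p_raw <- stats::pchisq(x2stat, df = length(parts),
                                   lower.tail = FALSE)
        if (!is.null(zb)) res$stat_prop <- zb$statistic
        if (!is.null(zc)) res$stat_cont <- zc$statistic
    } else if (method == "elrt") {
        if (length(unique(c(x1, x2))) == 1L) {
            res$statistic <- 0; res$df <- 1L; res$p_raw <- 1
            return(res)
        }
        el <- .elrTest(x1, x2)
        res$statistic <- el$statistic; res$df <- 1L; res$p_raw <- el$p
    } else stop("unknown test method: ", method, call. = FALSE)
    res
}

#' Differential test for a single feature
#'
#' Runs one of the five two-group tests on a feature of a point-mass
#' mixture matrix:
#' \describe{
#'   \item{`t`}{Welch two-sample t on the natural-log nonzero amplitudes
#'     (pooled-variance variant via `pooledVar = TRUE`).}
#'   \item{`wilcoxon`}{two-sided rank-sum on all values; zeros enter as ties
#'     at the common minimum, which only makes the test conservative. Exact
#'     for small samples (enumeration when ties are present), tie-corrected
#'     normal approximation otherwise.}
#'   \item{`two_part_t`, `two_part_wilcoxon`}{the two-part chi-square: a
#'     pooled two-proportion z on the zero proportions plus a continuous-part
#'     statistic (Welch t, or normal-approximated rank-sum) on the nonzero
#'     values; X^2 = sum of the squared defined parts, df = number of
#'     defined parts (a part is dropped when its data are degenerate:
#'     no zeros anywhere, or fewer than two nonzero values in a group).}
#'   \item{`elrt`}{two-sample empirical likelihood ratio test of equal
#'     mixture means, zeros included as observations; -2 log R against
#'     chi-square df 1. A permutation calibration is available through
#'     [testAll()]'s `calibrate` argument.}
#' }
#'
#' @param x a [PeptideSet-class] with two groups
#' @param feature feature id or index
#' @param method one of `"t"`, `"wilcoxon"`, `"two_part_t"`,
#'   `"two_part_wilcoxon"`, `"elrt"`
#' @param pooledVar use pooled-variance t instead of Welch
#' @return a list with `feature_id`, `method`, `statistic`, `df`, `p_raw`,
#'   component statistics `stat_prop`/`stat_cont` (two-part methods), and an
#'   `untestable` flag
#' @export
runTest <- function(x, feature, method = .testMethods, pooledVar = FALSE) {
    method <- match.arg(method)
    g <- .checkTwoGroups(x)
    amp <- amplitudes(x)
    if (is.character(feature) && !feature %in% rownames(amp))
        stop("feature not present: ", feature, call. = FALSE)
    v <- amp[feature, ]
    lev <- levels(g)
    res <- .testOne(v[g == lev[1]], v[g == lev[2]], method, pooledVar)
    c(list(feature_id = if (is.character(feature)) feature
           else rownames(amp)[feature]), res)
}

#' Differential tests for every feature, with BH adjustment
#'
#' Applies [runTest()]'s method to each feature and fills in BH-adjusted
#' p-values over the family of testable features. Untestable features (both
#' mixture parts degenerate) are returned flagged, with `NA` p-values, and
#' are excluded from the adjustment family.
#'
#' @inheritParams runTest
#' @param calibrate p-value calibration for `elrt`. The default
#'   `"permutation"` permutes the group labels `B` times and pools the
#'   permuted statistics across features (valid because the statistic is
#'   asymptotically pivotal); the faster `"chisq"` asymptotic calibration is
#'   noticeably anticonservative for heavily skewed intensity
#'   distributions at realistic sample sizes, so it is opt-in here (and is
#'   what the single-feature [runTest()] reports).
#' @param B permutation count when `calibrate = "permutation"`; with
#'   pooling, `B * nrow(x)` draws form the reference distribution
#' @param seed RNG seed for the permutation calibration (an internal fixed
#'   seed is used when `NULL`, so results are reproducible by default)
#' @return a data.frame with one row per feature: `feature_id`, `method`,
#'   `statistic`, `df`, `p_raw`, `p_adj`, `stat_prop`, `stat_cont`,
#'   `untestable`
#' @export
testAll <- function(x, method = .testMethods, pooledVar = FALSE,
                    calibrate = c("permutation", "chisq"), B = 60,
                    seed = NULL) {
    method <- match.arg(method)
    calibrate <- match.arg(calibrate)
    g <- .checkTwoGroups(x)
    amp <- amplitudes(x)
    lev <- levels(g)
    i1 <- which(g == lev[1]); i2 <- which(g == lev[2])
    N <- length(i1) + length(i2)
    ## share the enumeration index across features of identical shape
    idx <- if (method == "wilcoxon" && N <= 16L) utils::combn(N, length(i1))
           else NULL
    rows <- lapply(seq_len(nrow(amp)), function(i)
        .testOne(amp[i, i1], amp[i, i2], method, pooledVar, idx = idx))
    out <- data.frame(
        feature_id = rownames(amp),
        method = method,
        statistic = vapply(rows, `[[`, 0, "statistic"),
        df = vapply(rows, `[[`, 0L, "df"),
        p_raw = vapply(rows, `[[`, 0, "p_raw"),
        stat_prop = vapply(rows, `[[`, 0, "stat_prop"),
        stat_cont = vapply(rows, `[[`, 0, "stat_cont"),
        untestable = vapply(rows, `[[`, TRUE, "untestable"),
        stringsAsFactors = FALSE)
    if (method == "elrt" && calibrate == "permutation")
        out$p_raw <- .elrtPermutation(amp, i1, i2, out$statistic, B, seed)
    out$p_adj <- NA_real_
    ok <- !out$untestable
    if (any(ok)) out$p_adj[ok] <- bhAdjust(out$p_raw[ok])
    out
}

## Permutation calibration for the ELRT: pool the permuted statistics over
## all features (the statistic is asymptotically pivotal).
.elrtPermutation <- function(amp, i1, i2, observed, B, seed) {
    set.seed(if (is.null(seed)) 0L else seed)
    n1 <- length(i1)
    cols <- c(i1, i2)
    perm <- matrix(0, nrow = nrow(amp), ncol = B)
    for (b in seq_len(B)) {
        sh <- sample(cols)
        j1 <- sh[seq_len(n1)]; j2 <- sh[-seq_len(n1)]
        perm[, b] <- vapply(seq_len(nrow(amp)), function(i)
            .elrTest(amp[i, j1], amp[i, j2])$statistic, 0)
    }
    ref <- as.vector(perm)
    vapply(observed, function(s) (sum(ref >= s) + 1) / (length(ref) + 1), 0)
}

#' Validate training-set markers on an independent test set
#'
#' Re-tests each candidate marker, alone, on an independent matrix and
#' reports how many remain significant. Candidates default to the features
#' whose BH-adjusted (or raw, `trainAdjusted = FALSE`) training p-value is
#' below `level`. On the test side the default re-applies BH within the
#' candidate subset; `testAdjust = "none"` tests each marker alone at the
#' raw level, the literal per-marker reading.
#'
#' @param train a `testAll()` result on the training matrix, or a character
#'   vector of candidate feature ids
#' @param testSet the independent [PeptideSet-class]
#' @param method test to use on the test set (default: same as training)
#' @param level significance/FDR level (default 0.05)
#' @param trainAdjusted define candidates by `p_adj` (TRUE) or `p_raw`
#' @param testAdjust `"bh"` or `"none"` on the test side
#' @return a list: `candidates`, `confirmed` (ids), `n_candidates`,
#'   `n_confirmed`, `fraction` (0 when there are no candidates), and
#'   `missing` (candidates absent from the test matrix, counted
#'   unconfirmed)
#' @export
validateMarkers <- function(train, testSet, method = NULL, level = 0.05,
                            trainAdjusted = TRUE,
                            testAdjust = c("bh", "none")) {
    testAdjust <- match.arg(testAdjust)
    if (is.data.frame(train)) {
        pcol <- if (trainAdjusted) train$p_adj else train$p_raw
        cand <- train$feature_id[!is.na(pcol) & pcol < level]
        if (is.null(method)) method <- train$method[1]
    } else {
        cand <- as.character(train)
        if (is.null(method)) stop("method required when candidates are ids",
                                  call. = FALSE)
    }
    present <- cand[cand %in% rownames(testSet)]
    missing <- setdiff(cand, present)
    confirmed <- character()
    if (length(present)) {
        res <- testAll(testSet[present, ], method = method)
        p <- if (testAdjust == "bh") res$p_adj else res$p_raw
        confirmed <- res$feature_id[!is.na(p) & p < level]
    }
    list(candidates = cand, confirmed = confirmed,
         n_candidates = length(cand), n_confirmed = length(confirmed),
         fraction = if (length(cand)) length(confirmed) / length(cand) else 0,
         missing = missing)
}
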