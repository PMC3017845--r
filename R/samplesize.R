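#' Estimate the null proportion pi0 from a p-value distribution
#'
#' Fits the two-component mixture f(p) = pi0 + (1 - pi0) fA(p) by maximum
#' likelihood, where the null density is Uniform(0,1) and the alternative
#' density fA is the decreasing Beta(a, 1) density a p^(a-1) with 0 < a < 1
#' (the beta-uniform mixture). pi0 is the proportion of truly
#' non-differential features and feeds the average per-test level of
#' [alphaAve()].
#'
#' @details The mixture weight is not identifiable at the null boundary: as
#' the Beta shape a approaches 1 the alternative density degenerates to the
#' uniform and the likelihood becomes flat along a ridge of (pi0, a) pairs.
#' The estimator therefore profiles the likelihood over pi0 and reports the
#' largest pi0 whose profile log-likelihood is within 0.5 units of the
#' maximum. Away from the ridge (a genuine enrichment of small p-values)
#' this coincides with the MLE; on a pure null it resolves the flat ridge
#' to the conservative end, so pi0 is over- rather than under-estimated —
#' the safe direction for the downstream per-test level.
#'
#' @param p numeric vector of at least 50 p-values in \[0, 1\]
#' @return a `Pi0Model` list: `pi0`, `shape` (the Beta shape a at the
#'   reported pi0), `logLik`, `n`
#' @export
estimatePi0 <- function(p) {
    if (length(p) < 50) stop("need at least 50 p-values", call. = FALSE)
    if (anyNA(p) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]", call. = FALSE)
    if (length(unique(p)) == 1L)
        stop("degenerate input: all p-values identical", call. = FALSE)
    pc <- pmin(pmax(p, 1e-12), 1)  # p = 0 would make the Beta density infinite
    nll <- function(pi0, a) -sum(log(pi0 + (1 - pi0) * a * pc^(a - 1)))
    profile <- function(pi0) stats::optimize(function(a) nll(pi0, a),
                                             c(1e-6, 1 - 1e-6))
    grid <- seq(0.001, 0.999, length.out = 150)
    prof <- lapply(grid, profile)
    obj <- vapply(prof, `[[`, 0, "objective")
    best <- min(obj)
    keep <- max(which(obj <= best + 0.5))
    structure(list(pi0 = grid[keep], shape = prof[[keep]]$minimum,
                   logLik = -obj[keep], n = length(p)),
              class = "Pi0Model")
}

#' @export
print.Pi0Model <- function(x, ...) {
    cat(sprintf("Pi0Model: pi0 = %.4f, Beta shape a = %.4f (m = %d, logLik = %.1f)\n",
                x$pi0, x$shape, x$n, x$logLik))
    invisible(x)
}

#' Average per-test significance level equivalent to FDR control
#'
#' Conducting every single test at
#' alpha_ave = (1 - beta)_ave * q / (1 + (1 - q) * pi0 / (1 - pi0))
#' is on average equivalent to controlling the FDR at q, given the average
#' per-marker power (1 - beta)_ave and the null proportion pi0. The level
#' shrinks to 0 as pi0 approaches 1 and equals (1 - beta)_ave * q when
#' pi0 = 0.
#'
#' @param pi0 null proportion in \[0, 1\] (a `Pi0Model` is also accepted)
#' @param q expected FDR
#' @param powerAve average per-marker power (1 - beta)_ave
#' @return the per-test level alpha_ave
#' @export
alphaAve <- function(pi0, q = 0.05, powerAve = 0.9) {
    if (inherits(pi0, "Pi0Model")) pi0 <- pi0$pi0
    if (any(c(pi0, q, powerAve) < 0) || any(c(q, powerAve) > 1) || pi0 > 1)
        stop("inputs must lie in [0, 1]", call. = FALSE)
    if (pi0 == 1) return(0)
    powerAve * q / (1 + (1 - q) * pi0 / (1 - pi0))
}

#' Bootstrap power curves from pilot data
#'
#' For each requested per-group size n, draws `B` datasets of n samples per
#' group by resampling whole pilot columns with replacement within group
#' (preserving within-sample peptide correlation), runs the differential
#' test on each feature at per-test level `alpha`, and estimates power as
#' the rejection fraction N/B. By default the estimate is discounted by the
#' factor 0.95, treating 5% of the rejections as false positives; set
#' `discount = FALSE` for the raw rejection rate.
#'
#' @param pilot a pilot [PeptideSet-class] (two groups, >= 2 samples each)
#' @param sizes per-group sample-size grid
#' @param B bootstrap replicates per size (>= 100)
#' @param alpha per-test level, typically [alphaAve()]'s output
#' @param method differential test
#' @param features ids to evaluate (default: all pilot features)
#' @param discount apply the 0.95 false-positive discount
#' @param seed RNG seed
#' @return list of `PowerCurve`s, one per feature: `feature_id`, `sizes`,
#'   `power`, plus the run parameters
#' @export
bootstrapPower <- function(pilot, sizes = seq(10, 120, 5), B = 2000,
                           alpha = 0.05, method = "wilcoxon",
                           features = NULL, discount = TRUE, seed = 1) {
    stopifnot(B >= 100)
    if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)",
                                       call. = FALSE)
    g <- .checkTwoGroups(pilot)
    if (is.null(features)) features <- rownames(pilot)
    amp <- amplitudes(pilot)[features, , drop = FALSE]
    lev <- levels(g)
    i1 <- which(g == lev[1]); i2 <- which(g == lev[2])
    set.seed(seed)
    rej <- array(0, dim = c(length(features), length(sizes)))
    for (s in seq_along(sizes)) {
        n <- sizes[s]
        idx <- if (2 * n <= 16L) utils::combn(2 * n, n) else NULL
        for (b in seq_len(B)) {
            j1 <- sample(i1, n, replace = TRUE)
            j2 <- sample(i2, n, replace = TRUE)
            for (f in seq_along(features)) {
                r <- .testOne(amp[f, j1], amp[f, j2], method, idx = idx)
                if (!r$untestable && !is.na(r$p_raw) && r$p_raw < alpha)
                    rej[f, s] <- rej[f, s] + 1
            }
        }
    }
    fac <- if (discount) 0.95 else 1
    lapply(seq_along(features), function(f)
        structure(list(feature_id = features[f], sizes = sizes,
                       power = fac * rej[f, ] / B, B = B, alpha = alpha,
                       method = method, discount = discount),
                  class = "PowerCurve"))
}

#' @export
print.PowerCurve <- function(x, ...) {
    cat(sprintf("PowerCurve %s (%s, alpha = %.4g, B = %d)\n", x$feature_id,
                x$method, x$alpha, x$B))
    print(stats::setNames(round(x$power, 3), x$sizes))
    invisible(x)
}

#' Differential sample size from a power curve
#'
#' The smallest per-group n on the curve's grid whose estimated power
#' reaches the target.
#'
#' @param curve a `PowerCurve` from [bootstrapPower()]
#' @param targetPower required power (default 0.9)
#' @return the per-group n, or `NA` with attribute `unattained = TRUE` when
#'   no grid size reaches the target
#' @export
ndiff <- function(curve, targetPower = 0.9) {
    stopifnot(length(curve$sizes) > 0)
    ok <- which(curve$power >= targetPower)
    if (!length(ok)) return(structure(NA_integer_, unattained = TRUE))
    as.integer(curve$sizes[min(ok)])
}

#' Classifier learning-curve points
#'
#' For each training size n and repetition: subsample n samples per group
#' from the training set, select features inside the subsample (unadjusted
#' Wilcoxon at `selectAlpha`), train the classifier, and evaluate on the
#' fixed independent test set. Records AAC = 1 - AUC and MER = 1 - accuracy.
#'
#' @param train,testSet training and independent test [PeptideSet-class]s
#' @param classifier classifier spec, see [trainAndEval()]
#' @param sizes per-group training sizes
#' @param reps repetitions per size
#' @param selectAlpha unadjusted selection level
#' @param seed RNG seed
#' @return data.frame: `n_train`, `rep`, `aac`, `mer` (NA rows record
#'   subsamples where selection or training failed)
#' @export
learningCurve <- function(train, testSet, classifier = "svm",
                          sizes = c(7, 10, 15, 20, 30, 45, 65), reps = 20,
                          selectAlpha = 0.05, seed = 1) {
    g <- .checkTwoGroups(train)
    lev <- levels(g)
    if (any(sizes > min(table(g))))
        stop("requested size exceeds training capacity", call. = FALSE)
    set.seed(seed)
    out <- expand.grid(n_train = sizes, rep = seq_len(reps))
    out$aac <- NA_real_; out$mer <- NA_real_
    for (i in seq_len(nrow(out))) {
        keep <- unlist(lapply(lev, function(l)
            sample(which(g == l), out$n_train[i])))
        sub <- train[, keep]
        ev <- try({
            feats <- selectFeatures(sub, alpha = selectAlpha)
            if (!length(feats)) stop("empty selection")
            trainAndEval(sub, testSet, classifier, feats)
        }, silent = TRUE)
        if (!inherits(ev, "try-error")) {
            out$aac[i] <- ev$aac
            out$mer[i] <- ev$mer
        }
    }
    out
}

#' Fit an inverse power-law learning curve
#'
#' Nonlinear least squares of E(Y) = Gamma + beta * N^(-gamma) with all three
#' parameters constrained nonnegative: `Gamma` is the asymptotic (Bayes)
#' error floor, `beta` the scale and `gamma` the learning rate. By default
#' the curve is fitted to the mean metric per training size; set
#' `onMeans = FALSE` to fit all raw points.
#'
#' @param points data.frame with a size column `n_train` and a metric column
#'   (`aac` or `mer`, chosen by `metric`; a column named `value` also works)
#' @param metric which metric column to fit
#' @param onMeans fit per-size means (default) or raw points
#' @return a `PowerLawFit`: `gammaFloor`, `scale`, `rate`, `metric`,
#'   `points`, `residuals`, `degenerate` (TRUE when the fitted curve is
#'   essentially flat: `scale` or `rate` ~ 0)
#' @export
fitPowerLaw <- function(points, metric = c("aac", "mer", "value"),
                        onMeans = TRUE) {
    metric <- match.arg(metric)
    ycol <- if (metric %in% colnames(points)) metric else "value"
    df <- data.frame(n = points$n_train, y = points[[ycol]])
    df <- df[stats::complete.cases(df), ]
    if (length(unique(df$n)) < 3)
        stop("need at least 3 distinct sizes", call. = FALSE)
    if (onMeans) {
        agg <- stats::aggregate(y ~ n, df, mean)
        df <- agg
    }
    best <- NULL
    gMin <- max(min(df$y), 0)
    for (g0 in c(0.2, 0.5, 0.7, 1, 1.5)) {
        for (G0 in unique(c(0, 0.5 * gMin, 0.9 * gMin))) {
            b0 <- max((df$y[which.min(df$n)] - G0) * min(df$n)^g0, 1e-3)
            fit <- try(minpack.lm::nlsLM(
                y ~ G + b * n^(-g), data = df,
                start = list(G = G0, b = b0, g = g0),
                lower = c(0, 0, 0), upper = c(Inf, Inf, Inf),
                control = minpack.lm::nls.lm.control(maxiter = 200)),
                silent = TRUE)
            if (inherits(fit, "try-error")) next
            rss <- sum(stats::resid(fit)^2)
            if (is.null(best) || rss < best$rss)
                best <- list(fit = fit, rss = rss)
        }
    }
    if (is.null(best))
        stop("inverse power-law fit did not converge", call. = FALSE)
    cf <- stats::coef(best$fit)
    powerLawFit(cf[["G"]], cf[["b"]], cf[["g"]], metric = metric,
                points = df, residuals = stats::resid(best$fit))
}

#' Build a PowerLawFit from known coefficients
#'
#' Wraps coefficients of E(Y) = Gamma + beta * N^(-gamma) — e.g. a published
#' fitted curve — into the object [ndisc()] consumes.
#'
#' @param gammaFloor asymptotic error floor Gamma (>= 0)
#' @param scale beta (>= 0)
#' @param rate learning rate gamma (>= 0)
#' @param metric metric label
#' @param points,residuals optional fit provenance
#' @return a `PowerLawFit`
#' @export
powerLawFit <- function(gammaFloor, scale, rate, metric = "aac",
                        points = NULL, residuals = NULL) {
    stopifnot(gammaFloor >= 0, scale >= 0, rate >= 0)
    structure(list(gammaFloor = unname(gammaFloor), scale = unname(scale),
                   rate = unname(rate), metric = metric, points = points,
                   residuals = residuals,
                   degenerate = scale < 1e-8 || rate < 1e-8),
              class = "PowerLawFit")
}

#' @export
print.PowerLawFit <- function(x, ...) {
    cat(sprintf("PowerLawFit (%s): E(Y) = %.4g + %.4g * N^(-%.4g)%s\n",
                x$metric, x$gammaFloor, x$scale, x$rate,
                if (x$degenerate) "  [degenerate: flat]" else ""))
    invisible(x)
}

#' @export
predict.PowerLawFit <- function(object, n, ...) {
    object$gammaFloor + object$scale * n^(-object$rate)
}

#' Discriminative sample size from a learning-curve fit
#'
#' Solves Gamma + beta * N^(-gamma) = target for N:
#' N = ((target - Gamma) / beta)^(-1 / gamma), rounded to the nearest
#' integer (or up, with `rounding = "ceiling"`).
#'
#' @param fit a `PowerLawFit`
#' @param target target metric value; must exceed the Bayes floor Gamma
#' @param rounding `"nearest"` (default) or `"ceiling"`
#' @return per-group training size N
#' @export
ndisc <- function(fit, target, rounding = c("nearest", "ceiling")) {
    rounding <- match.arg(rounding)
    if (fit$degenerate)
        stop("degenerate (flat) learning curve: ndisc undefined",
             call. = FALSE)
    if (target <= fit$gammaFloor)
        stop(sprintf("target %.4g is at or below the Bayes floor %.4g",
                     target, fit$gammaFloor), call. = FALSE)
    n <- ((target - fit$gammaFloor) / fit$scale)^(-1 / fit$rate)
    if (rounding == "nearest") as.integer(round(n)) else as.integer(ceiling(n))
}
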