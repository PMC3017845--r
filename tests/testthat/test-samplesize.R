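test_that("estimatePi0 recovers known p-value mixtures", {
    set.seed(1)
    expect_gte(estimatePi0(runif(5000))$pi0, 0.95)

    p <- c(runif(2500), rbeta(2500, 0.1, 1))
    fit <- estimatePi0(p)
    expect_lt(abs(fit$pi0 - 0.5), 0.05)

    expect_error(estimatePi0(runif(20)), "at least 50")
    expect_error(estimatePi0(rep(0.5, 100)), "degenerate")
})

test_that("estimatePi0 never materially underestimates on pure nulls", {
    # the ridge-resolving rule reports the conservative (large-pi0) end of
    # the likelihood plateau, so on uniform p-values the estimate sits
    # within a couple of percent of 1 at any m
    set.seed(2)
    biasAt <- function(m) mean(sapply(1:8, function(i)
        estimatePi0(runif(m))$pi0)) - 1
    expect_gte(biasAt(200), -0.03)
    expect_gte(biasAt(5000), -0.03)
})

test_that("alphaAve evaluates the average-level formula with its limits", {
    expect_equal(alphaAve(0, q = 0.05, powerAve = 0.9), 0.045)
    expect_equal(alphaAve(1, q = 0.05, powerAve = 0.9), 0)
    expect_equal(alphaAve(0.5652831, q = 0.05, powerAve = 0.9), 0.02013125,
                 tolerance = 1e-6)
    expect_error(alphaAve(1.2), "\\[0, 1\\]")

    # strictly decreasing in pi0, increasing in q and in average power
    pi0s <- seq(0.05, 0.95, 0.1)
    expect_true(all(diff(sapply(pi0s, alphaAve)) < 0))
    qs <- seq(0.01, 0.2, 0.02)
    expect_true(all(diff(sapply(qs, function(q) alphaAve(0.5, q))) > 0))
    expect_true(all(diff(sapply(qs, function(pw)
        alphaAve(0.5, powerAve = pw))) > 0))
})

test_that("bootstrap power is flat at the discounted level for a null feature", {
    set.seed(10)
    vals <- exp(rnorm(40, 2))
    a <- rbind(f = c(vals, vals))  # both groups carry the same pilot values
    pilot <- PeptideSet(a, group = rep(c("a", "b"), each = 40))
    cur <- bootstrapPower(pilot, sizes = c(15, 30), B = 400, alpha = 0.05,
                          method = "t", seed = 3)[[1]]
    expect_true(all(abs(cur$power - 0.95 * 0.05) < 0.04))
    expect_error(bootstrapPower(pilot, B = 400, alpha = 1.5), "alpha")
})

test_that("bootstrap power tracks closed-form two-sample normal power", {
    # deterministic pilot embodying N(delta, 1) vs N(0, 1) log intensities
    n <- 200
    qs <- qnorm(ppoints(n))
    a <- rbind(f = exp(c(qs + 1, qs)))
    pilot <- PeptideSet(a, group = rep(c("hi", "lo"), each = n))
    sizes <- c(10, 20, 30)
    cur <- bootstrapPower(pilot, sizes = sizes, B = 400, alpha = 0.00223,
                          method = "t", discount = FALSE, seed = 7)[[1]]
    ref <- sapply(sizes, function(nn)
        power.t.test(n = nn, delta = 1, sd = 1,
                     sig.level = 0.00223)$power)
    expect_true(all(abs(cur$power - ref) < 0.05))

    # monotone nondecreasing in n for this non-null feature, deterministic
    expect_true(all(diff(cur$power) >= -0.02))
    cur2 <- bootstrapPower(pilot, sizes = sizes, B = 400, alpha = 0.00223,
                           method = "t", discount = FALSE, seed = 7)[[1]]
    expect_identical(cur$power, cur2$power)
})

test_that("ndiff reads the smallest adequate size off the curve", {
    cur <- structure(list(feature_id = "f", sizes = c(10, 20, 30),
                          power = c(0.5, 0.8, 0.95)), class = "PowerCurve")
    expect_equal(ndiff(cur, 0.9), 30)
    expect_equal(ndiff(cur, 0.8), 20)
    low <- cur; low$power <- c(0.1, 0.2, 0.3)
    expect_true(is.na(ndiff(low, 0.9)))
    expect_true(attr(ndiff(low, 0.9), "unattained"))
})

test_that("stronger effects need fewer samples", {
    n <- 150
    qs <- qnorm(ppoints(n))
    nd <- sapply(c(0.8, 1.2, 1.8), function(d) {
        pilot <- PeptideSet(rbind(f = exp(c(qs + d, qs))),
                            group = rep(c("hi", "lo"), each = n))
        cur <- bootstrapPower(pilot, sizes = seq(5, 80, 5), B = 250,
                              alpha = 0.01, method = "t", seed = 5)[[1]]
        ndiff(cur, 0.9)
    })
    expect_true(all(diff(nd) <= 0))
})

test_that("fitPowerLaw recovers noiseless curves exactly and survives noise", {
    sizes <- 7:65
    pts <- data.frame(n_train = sizes,
                      aac = 0.03 + 1.39 * sizes^(-0.716))
    fit <- fitPowerLaw(pts, metric = "aac")
    expect_equal(fit$gammaFloor, 0.03, tolerance = 1e-6)
    expect_equal(fit$scale, 1.39, tolerance = 1e-6)
    expect_equal(fit$rate, 0.716, tolerance = 1e-6)
    expect_equal(ndisc(fit, 0.10), 65)

    # noisy recovery of the learning rate
    set.seed(12)
    rates <- sapply(1:10, function(s) {
        noisy <- data.frame(
            n_train = rep(sizes, 20),
            aac = pmax(0.001, 0.03 + 1.39 * rep(sizes, 20)^(-0.716) +
                           rnorm(length(sizes) * 20, 0, 0.02)))
        fitPowerLaw(noisy, metric = "aac")$rate
    })
    expect_true(all(abs(rates - 0.716) < 0.15))

    # flat curve flagged degenerate
    flat <- data.frame(n_train = sizes, aac = 0.2)
    ffit <- fitPowerLaw(flat, metric = "aac")
    expect_true(ffit$degenerate)
    expect_error(ndisc(ffit, 0.1), "degenerate")
    expect_error(fitPowerLaw(pts[1:2, ], metric = "aac"), "3 distinct")
})

test_that("ndisc solves the inverse power law with documented rounding", {
    expect_equal(ndisc(powerLawFit(0.03, 1.39, 0.716), 0.10), 65)
    expect_equal(ndisc(powerLawFit(0.02, 1.052, 0.597, metric = "mer"),
                       0.10), 75)
    # target = Gamma + beta is the N = 1 solution
    expect_equal(ndisc(powerLawFit(0.05, 0.5, 0.8), 0.55), 1)
    expect_error(ndisc(powerLawFit(0.1, 1, 0.5), 0.08), "Bayes floor")
    expect_equal(ndisc(powerLawFit(0.02, 1.052, 0.597), 0.10,
                       rounding = "ceiling"), 75)

    # round trip: fit on noiseless points, then solve back any target
    sizes <- c(5, 10, 20, 40, 80)
    pts <- data.frame(n_train = sizes, value = 0.05 + 0.9 * sizes^(-0.5))
    fit <- fitPowerLaw(pts, metric = "value")
    for (tgt in c(0.5, 0.2, 0.15))
        expect_equal(ndisc(fit, tgt),
                     as.integer(round(((tgt - 0.05) / 0.9)^(-2))))
})

test_that("learning-curve points improve with training size on a real effect", {
    spec <- makeEffectSpec(80, pi0 = 0.5, nPerGroup = 40, seed = 77,
                           deltaRange = c(0.8, 2))
    tr <- simulateMatrix(spec)
    te <- simulateMatrix(reseed(spec, 78))
    colnames(te) <- paste0("T", colnames(te))
    pts <- learningCurve(tr, te, classifier = "glm",
                         sizes = c(7, 15, 30), reps = 4, seed = 5)
    expect_true(all(pts$aac >= 0 & pts$aac <= 1, na.rm = TRUE))
    expect_true(all(pts$mer >= 0 & pts$mer <= 1, na.rm = TRUE))
    agg <- aggregate(aac ~ n_train, pts, mean)
    expect_lt(agg$aac[agg$n_train == 30], agg$aac[agg$n_train == 7] + 0.05)
    expect_error(learningCurve(tr, te, sizes = c(7, 100)), "capacity")
})
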