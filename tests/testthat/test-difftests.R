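test_that("bhAdjust equals the step-up oracle and is order-equivariant", {
    expect_equal(bhAdjust(0.05), 0.05)
    expect_equal(bhAdjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_error(bhAdjust(c(0.2, 1.3)), "\\[0, 1\\]")

    # exhaustive over sorted grid combinations of length <= 6 (BH is
    # permutation-equivariant, checked separately below)
    grid <- c(0.001, 0.01, 0.04, 0.2, 0.5, 1)
    for (k in 1:6) {
        combos <- utils::combn(length(grid) + k - 1, k)  # multisets via stars&bars
        for (j in seq_len(ncol(combos))) {
            p <- grid[combos[, j] - seq_len(k) + 1]
            expect_equal(bhAdjust(p), bhOracle(p))
        }
    }
    set.seed(1)
    for (i in 1:20) {
        p <- runif(8)
        o <- sample(8)
        expect_equal(bhAdjust(p)[o], bhAdjust(p[o]))
        expect_equal(bhAdjust(p), bhOracle(p))
        expect_true(all(bhAdjust(p) >= p))
    }
})

test_that("Wilcoxon matches exact enumeration, with and without ties", {
    ps <- PeptideSet(rbind(x = 1:6), group = rep(c("a", "b"), each = 3))
    expect_equal(runTest(ps, "x", "wilcoxon")$p_raw, 0.10)

    set.seed(7)
    for (i in 1:25) {
        n1 <- sample(2:4, 1); n2 <- sample(2:4, 1)
        # zeros force ties at the minimum
        v <- round(c(rep(0, sample(0:3, 1)),
                     rexp(n1 + n2))[seq_len(n1 + n2)], 1)
        v <- sample(v)
        v1 <- v[seq_len(n1)]; v2 <- v[-seq_len(n1)]
        a <- rbind(f = c(v1, v2))
        psi <- PeptideSet(a, group = rep(c("g1", "g2"), c(n1, n2)))
        expect_equal(runTest(psi, "f", "wilcoxon")$p_raw,
                     rankSumEnumOracle(v1, v2))
    }
})

test_that("two-part statistics combine the defined parts with matching df", {
    # identical groups: X^2 = 0, p = 1
    ps <- PeptideSet(rbind(f = rep(c(0, 2, 3, 5), 2)),
                     group = rep(c("a", "b"), each = 4))
    r <- runTest(ps, "f", "two_part_wilcoxon")
    expect_equal(r$statistic, 0)
    expect_equal(r$p_raw, 1)

    # proportion part only: group 1 all zero, group 2 all nonzero
    ps2 <- PeptideSet(rbind(f = c(rep(0, 10), exp(rnorm(10, 3)))),
                      group = rep(c("a", "b"), each = 10))
    r2 <- runTest(ps2, "f", "two_part_wilcoxon")
    expect_equal(r2$df, 1)
    expect_equal(sqrt(r2$statistic), 1 / sqrt(0.25 * (1 / 10 + 1 / 10)),
                 tolerance = 1e-12)
    expect_equal(r2$statistic, 20)
    expect_equal(r2$p_raw, pchisq(20, 1, lower.tail = FALSE))
    expect_true(is.na(r2$stat_cont))

    # both parts present: df = 2 and X^2 = ZB^2 + ZC^2
    set.seed(3)
    v <- c(rep(0, 4), exp(rnorm(16, 2)))
    ps3 <- PeptideSet(rbind(f = sample(v)), group = rep(c("a", "b"), 10))
    r3 <- runTest(ps3, "f", "two_part_t")
    expect_equal(r3$df, 2)
    expect_equal(r3$statistic, r3$stat_prop^2 + r3$stat_cont^2)

    # untestable: all zeros everywhere
    ps4 <- PeptideSet(rbind(f = rep(0, 8)), group = rep(c("a", "b"), each = 4))
    expect_true(runTest(ps4, "f", "two_part_wilcoxon")$untestable)
})

test_that("with no zeros the two-part tests collapse to their single-part versions", {
    set.seed(11)
    a <- rbind(f = exp(c(rnorm(30, 1), rnorm(30, 1.6))))
    ps <- PeptideSet(a, group = rep(c("a", "b"), each = 30))
    t1 <- runTest(ps, "f", "t")
    tp <- runTest(ps, "f", "two_part_t")
    expect_equal(tp$df, 1)
    expect_equal(tp$statistic, t1$statistic^2)
    w1 <- runTest(ps, "f", "wilcoxon")
    wp <- runTest(ps, "f", "two_part_wilcoxon")
    expect_equal(wp$df, 1)
    expect_equal(wp$statistic, w1$statistic^2)
    expect_equal(wp$p_raw, w1$p_raw)  # both use the normal approximation here
})

test_that("ELRT is zero for identical groups and grows with separation", {
    ps <- PeptideSet(rbind(f = rep(c(1, 2, 3), 2)),
                     group = rep(c("a", "b"), each = 3))
    r <- runTest(ps, "f", "elrt")
    expect_equal(r$statistic, 0, tolerance = 1e-6)
    expect_equal(r$p_raw, 1, tolerance = 1e-6)

    set.seed(5)
    x <- exp(rnorm(40, 1))
    stat <- sapply(c(0.3, 0.8, 1.5), function(sh) {
        psi <- PeptideSet(rbind(f = c(x, x * exp(sh))),  # pure scale shift
                          group = rep(c("a", "b"), each = 40))
        runTest(psi, "f", "elrt")$statistic
    })
    expect_true(all(diff(stat) > 0))

    # chi-square calibration sanity on a quick null (details in the
    # acceptance suite)
    m <- simulateMatrix(makeNullSpec(200, nPerGroup = 40, seed = 13))
    r0 <- testAll(m, "elrt")
    expect_lt(mean(r0$p_raw < 0.05), 0.12)
})

test_that("testAll adjusts within the testable family and is deterministic", {
    m <- simulateMatrix(makeEffectSpec(120, nPerGroup = 15, seed = 21))
    r1 <- testAll(m, "wilcoxon")
    r2 <- testAll(m, "wilcoxon")
    expect_identical(r1, r2)
    ok <- !r1$untestable
    expect_equal(r1$p_adj[ok], bhOracle(r1$p_raw[ok]))
    expect_true(all(is.na(r1$p_adj[!ok])))
})

test_that("two-part tests dominate their single-part counterparts on consonant alternatives", {
    # fixed grid of consonant effects in the regime the two-part
    # construction targets: the signal is split between the detection
    # probability and a modest continuous shift, so a single-part test
    # sees only a diluted version of either component
    rej <- matrix(0, 2, 2, dimnames = list(c("single", "two_part"),
                                           c("wilcoxon", "t")))
    set.seed(31)
    for (i in 1:200) {
        n <- 25
        g1 <- rbinom(n, 1, 0.9) * exp(rnorm(n, 0.8, 1))
        g2 <- rbinom(n, 1, 0.5) * exp(rnorm(n, 0.5, 1))
        ps <- PeptideSet(rbind(f = c(g1, g2)),
                         group = rep(c("a", "b"), each = n))
        rej["single", "wilcoxon"] <- rej["single", "wilcoxon"] +
            (runTest(ps, "f", "wilcoxon")$p_raw < 0.05)
        rej["two_part", "wilcoxon"] <- rej["two_part", "wilcoxon"] +
            (runTest(ps, "f", "two_part_wilcoxon")$p_raw < 0.05)
        rej["single", "t"] <- rej["single", "t"] +
            (runTest(ps, "f", "t")$p_raw < 0.05)
        rej["two_part", "t"] <- rej["two_part", "t"] +
            (runTest(ps, "f", "two_part_t")$p_raw < 0.05)
    }
    expect_gte(rej["two_part", "wilcoxon"], rej["single", "wilcoxon"])
    expect_gte(rej["two_part", "t"], rej["single", "t"])
})

test_that("validateMarkers confirms more markers under a real effect than under the null", {
    # trivial contracts first
    empty <- validateMarkers(character(),
                             simulateMatrix(makeNullSpec(10, 10, 1)),
                             method = "wilcoxon")
    expect_equal(empty$n_confirmed, 0)
    expect_equal(empty$fraction, 0)

    fracs <- sapply(1:10, function(s) {
        eff <- makeEffectSpec(150, pi0 = 0.5, nPerGroup = 30, seed = s,
                              deltaRange = c(0.8, 2))
        tr <- simulateMatrix(eff)
        te <- simulateMatrix(reseed(eff, s + 1000L))
        colnames(te) <- paste0("T", colnames(te))
        nul <- makeNullSpec(150, nPerGroup = 30, seed = s)
        trN <- simulateMatrix(nul)
        teN <- simulateMatrix(reseed(nul, s + 1000L))
        colnames(teN) <- paste0("T", colnames(teN))
        rEff <- testAll(tr, "wilcoxon")
        rNul <- testAll(trN, "wilcoxon")
        c(eff = validateMarkers(rEff, te, level = 0.05)$fraction,
          nul = validateMarkers(rNul, teN, level = 0.05,
                                trainAdjusted = FALSE)$fraction)
    })
    expect_gt(mean(fracs["eff", ]), mean(fracs["nul", ]))

    # a candidate absent from the test matrix counts unconfirmed, flagged
    eff <- simulateMatrix(makeEffectSpec(50, pi0 = 0.3, nPerGroup = 30,
                                         seed = 2, deltaRange = c(1, 2)))
    te <- simulateMatrix(makeEffectSpec(50, pi0 = 0.3, nPerGroup = 30,
                                        seed = 3, deltaRange = c(1, 2)))
    colnames(te) <- paste0("T", colnames(te))
    v <- validateMarkers(c("ft00001", "ghost"), te[-1, ],
                         method = "wilcoxon")
    expect_true(all(c("ft00001", "ghost") %in% v$missing))
    expect_equal(v$n_candidates, 2)
})
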