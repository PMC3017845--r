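#' Per-feature, per-group summaries of the point-mass mixture
#'
#' For each feature and each of the two groups, computes the sample count
#' `n`, the nonzero (detected) count `m`, the zero proportion `1 - m/n`, and
#' the mean and SD of the natural-log nonzero amplitudes. Zeros are excluded
#' from the continuous-component moments: below-LOD values are censored, not
#' imputed. Also classifies the between-group difference
#' ([classifyDifference()]) and attaches the standardized effect size delta
#' ([effectSize()]).
#'
#' @param x a [PeptideSet-class] with two groups
#' @return a data.frame with one row per feature: columns `n_1, m_1,
#'   zero_prop_1, mean_log_1, sd_log_1` (and `_2` for the second group),
#'   `diff_class`, `delta`, and `degenerate` (TRUE when a group has no
#'   nonzero values so the continuous mean is undefined). Group 1 is the
#'   reference (first factor level).
#' @export
featureSummaries <- function(x) {
    g <- .checkTwoGroups(x)
    amp <- amplitudes(x)
    lev <- levels(g)
    out <- data.frame(feature_id = rownames(amp), stringsAsFactors = FALSE)
    st <- lapply(lev, function(l) .groupStats(amp[, g == l, drop = FALSE]))
    for (k in 1:2) {
        s <- st[[k]]
        out[[paste0("n_", k)]] <- s$n
        out[[paste0("m_", k)]] <- s$m
        out[[paste0("zero_prop_", k)]] <- s$zero_prop
        out[[paste0("mean_log_", k)]] <- s$mean_log
        out[[paste0("sd_log_", k)]] <- s$sd_log
    }
    out$degenerate <- st[[1]]$m == 0L | st[[2]]$m == 0L
    out$diff_class <- classifyDifference(out$zero_prop_1, out$zero_prop_2,
                                         out$mean_log_1, out$mean_log_2)
    out$delta <- .deltaFromStats(st[[1]], st[[2]])
    attr(out, "groups") <- lev
    out
}

.groupStats <- function(a) {
    nz <- a > 0
    m <- rowSums(nz)
    n <- ncol(a)
    la <- log(a)
    la[!nz] <- NA
    mean_log <- rowMeans(la, na.rm = TRUE)
    mean_log[m == 0] <- NA_real_
    sd_log <- apply(la, 1, stats::sd, na.rm = TRUE)
    sd_log[m < 2] <- NA_real_
    list(n = n, m = as.integer(m), zero_prop = 1 - m / n,
         mean_log = mean_log, sd_log = sd_log)
}

#' Classify a between-group difference as consonant, dissonant or
#' no-point-mass
#'
#' A difference is *consonant* when the group with the (strictly) higher
#' proportion of zeros also has the smaller mean in the continuous
#' component, *dissonant* when that group has the larger continuous mean,
#' and *no_point_mass* when neither group contains zeros. Consonant markers
#' dominate real data because peptides with means near the limit of
#' detection are both less detectable and less abundant.
#'
#' Tie rules: equal zero proportions (with at least one nonzero) are
#' classified consonant, the conservative choice; when a group has no
#' nonzero values its continuous mean is undefined and the feature is
#' classified by zero proportions alone (higher zero proportion = consonant
#' side).
#'
#' @param zeroProp1,zeroProp2 zero proportions per group (vectors)
#' @param meanLog1,meanLog2 mean natural-log nonzero amplitude per group
#' @return character vector in `{"consonant", "dissonant", "no_point_mass"}`
#' @export
classifyDifference <- function(zeroProp1, zeroProp2, meanLog1, meanLog2) {
    n <- length(zeroProp1)
    out <- character(n)
    for (i in seq_len(n)) {
        z1 <- zeroProp1[i]; z2 <- zeroProp2[i]
        m1 <- meanLog1[i]; m2 <- meanLog2[i]
        if (z1 == 0 && z2 == 0) { out[i] <- "no_point_mass"; next }
        if (is.na(m1) || is.na(m2)) { out[i] <- "consonant"; next }
        ## orient so that 'hi' is the group with more zeros
        if (z1 >= z2) { mhi <- m1; mlo <- m2 } else { mhi <- m2; mlo <- m1 }
        out[i] <- if (mhi > mlo) "dissonant" else "consonant"
    }
    out
}

#' Standardized effect size on the log scale
#'
#' delta = (mean log nonzero amplitude in group 1 - group 2) / pooled SD of
#' the log nonzero amplitudes. Group 1 is the reference (first factor
#' level), so the sign convention is group 1 minus group 2. Requires at
#' least two nonzero observations per group; otherwise `NA` (the feature
#' remains testable through its zero-proportion part).
#'
#' @param x a [PeptideSet-class] with two groups
#' @param feature optional feature id(s) or indices; default all features
#' @return named numeric vector of effect sizes
#' @export
effectSize <- function(x, feature = NULL) {
    s <- featureSummaries(if (is.null(feature)) x else x[feature, ])
    stats::setNames(s$delta, s$feature_id)
}

.deltaFromStats <- function(s1, s2) {
    ok <- s1$m >= 2L & s2$m >= 2L
    pooled <- sqrt(((s1$m - 1) * s1$sd_log^2 + (s2$m - 1) * s2$sd_log^2) /
                       (s1$m + s2$m - 2))
    d <- (s1$mean_log - s2$mean_log) / pooled
    d[!ok] <- NA_real_
    d[ok & pooled == 0 & s1$mean_log == s2$mean_log] <- 0
    d[ok & pooled == 0 & s1$mean_log != s2$mean_log] <- NA_real_
    d
}
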