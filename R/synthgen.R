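#' SyntheticSpec: a recipe for two-group point-mass mixture matrices
#'
#' Each feature is generated as `Bernoulli(detect_prob) * exp(Normal(log_mean,
#' log_sd))`, after which amplitudes below the limit of detection (`lod`) are
#' set to 0. This reproduces the distribution shape seen in real CE-MS
#' peptide profiles: a point mass at zero (peptide absent, or present below
#' the LOD) plus a roughly Gaussian hump on the natural-log intensity scale.
#'
#' @slot features data.frame with one row per feature: `feature_id`,
#'   `detect_prob_1`, `detect_prob_2`, `log_mean_1`, `log_mean_2`,
#'   `log_sd_1`, `log_sd_2`, `lod`, `intended_class` (one of `null`,
#'   `consonant`, `dissonant`, `no_point_mass`), `delta` (intended
#'   standardized log effect, group 1 minus group 2)
#' @slot nPerGroup samples per group
#' @slot groupLabels the two group labels (first = reference)
#' @slot seed RNG seed; the same spec always yields the same matrix
#' @slot blockSize when > 0, features are grouped into equicorrelated blocks
#'   of this size on the latent log scale
#' @slot rho within-block latent correlation
#' @export
setClass("SyntheticSpec",
         representation(features = "data.frame", nPerGroup = "integer",
                        groupLabels = "character", seed = "integer",
                        blockSize = "integer", rho = "numeric"))

setValidity("SyntheticSpec", function(object) {
    f <- object@features
    msg <- character()
    pr <- c(f$detect_prob_1, f$detect_prob_2)
    if (any(pr < 0 | pr > 1)) msg <- c(msg, "detection probabilities in [0,1]")
    if (any(c(f$log_sd_1, f$log_sd_2) <= 0)) msg <- c(msg, "log sds must be > 0")
    if (any(f$lod < 0)) msg <- c(msg, "lod must be >= 0")
    if (object@nPerGroup < 2L) msg <- c(msg, "need >= 2 samples per group")
    if (length(object@groupLabels) != 2L) msg <- c(msg, "exactly two groups")
    if (object@rho < 0 || object@rho >= 1) msg <- c(msg, "rho in [0,1)")
    if (length(msg)) msg else TRUE
})

setMethod("show", "SyntheticSpec", function(object) {
    cat(sprintf("SyntheticSpec: %d features, 2 x %d samples, seed %d\n",
                nrow(object@features), object@nPerGroup, object@seed))
    print(table(object@features$intended_class))
    invisible(NULL)
})

#' A null spec: identical mixtures in both groups
#'
#' Defaults describe a typical filtered urinary-peptidome feature: detected
#' in 70% of samples, natural-log amplitudes centred at 5 with SD 1, no
#' explicit LOD censoring beyond the point mass itself.
#'
#' @param mFeatures number of features
#' @param nPerGroup samples per group
#' @param seed RNG seed stored in the spec
#' @param detectProb,logMean,logSd,lod shared mixture parameters
#' @param groupLabels two group labels
#' @param blockSize,rho optional equicorrelated latent blocks
#' @return a [SyntheticSpec-class]
#' @export
makeNullSpec <- function(mFeatures, nPerGroup = 67, seed = 1,
                         detectProb = 0.7, logMean = 5, logSd = 1, lod = 0,
                         groupLabels = c("A", "B"), blockSize = 0, rho = 0) {
    f <- data.frame(
        feature_id = sprintf("ft%05d", seq_len(mFeatures)),
        detect_prob_1 = detectProb, detect_prob_2 = detectProb,
        log_mean_1 = logMean, log_mean_2 = logMean,
        log_sd_1 = logSd, log_sd_2 = logSd, lod = lod,
        intended_class = "null", delta = 0, stringsAsFactors = FALSE)
    methods::new("SyntheticSpec", features = f,
                 nPerGroup = as.integer(nPerGroup),
                 groupLabels = groupLabels, seed = as.integer(seed),
                 blockSize = as.integer(blockSize), rho = rho)
}

#' An effect spec: a mixture of null and differential features
#'
#' A fraction `pi0` of features is null; the rest receive a group difference
#' realizing a standardized log effect drawn from `deltaRange` (random sign)
#' and a difference class drawn from `classMix`. Consonant features give the
#' group with the smaller continuous mean the lower detection probability
#' (the realistic LOD mechanism), dissonant features the higher one, and
#' no-point-mass features are detected everywhere with only a mean shift.
#' The default class mix mirrors the composition observed in real urinary
#' peptidome data, where consonant differences dominate.
#'
#' @inheritParams makeNullSpec
#' @param pi0 proportion of null features
#' @param deltaRange range of |delta| for differential features
#' @param classMix named probabilities for `consonant`, `dissonant`,
#'   `no_point_mass`
#' @param detectShift detection-probability offset realizing the point-mass
#'   difference
#' @return a [SyntheticSpec-class]; ground truth is in `spec@features`
#' @export
makeEffectSpec <- function(mFeatures, pi0 = 0.565, deltaRange = c(0.2, 2),
                           classMix = c(consonant = 0.961, dissonant = 0.031,
                                        no_point_mass = 0.008),
                           nPerGroup = 67, seed = 1, detectProb = 0.7,
                           logMean = 5, logSd = 1, detectShift = 0.15,
                           groupLabels = c("A", "B"), blockSize = 0,
                           rho = 0) {
    stopifnot(pi0 >= 0, pi0 <= 1, all(deltaRange > 0))
    classMix <- classMix / sum(classMix)
    if (any(classMix < 0) || !all(names(classMix) %in%
            c("consonant", "dissonant", "no_point_mass")))
        stop("infeasible class mix", call. = FALSE)
    if (detectProb - detectShift <= 0 || detectProb + detectShift > 1)
        stop("detectProb +/- detectShift must stay in (0, 1]", call. = FALSE)
    spec <- makeNullSpec(mFeatures, nPerGroup, seed, detectProb, logMean,
                         logSd, 0, groupLabels, blockSize, rho)
    f <- spec@features
    set.seed(seed)
    mAlt <- round((1 - pi0) * mFeatures)
    if (mAlt > 0) {
        alt <- sample.int(mFeatures, mAlt)
        cls <- sample(names(classMix), mAlt, replace = TRUE, prob = classMix)
        delta <- stats::runif(mAlt, deltaRange[1], deltaRange[2]) *
            sample(c(-1, 1), mAlt, replace = TRUE)
        f$intended_class[alt] <- cls
        f$delta[alt] <- delta
        ## group 1 minus group 2 on the standardized log scale
        f$log_mean_2[alt] <- logMean - delta * logSd
        lowMeanIs2 <- delta > 0
        for (k in seq_along(alt)) {
            i <- alt[k]
            if (cls[k] == "no_point_mass") {
                f$detect_prob_1[i] <- 1; f$detect_prob_2[i] <- 1
            } else {
                sgn <- if (cls[k] == "consonant") -1 else 1
                if (lowMeanIs2[k])
                    f$detect_prob_2[i] <- detectProb + sgn * detectShift
                else
                    f$detect_prob_1[i] <- detectProb + sgn * detectShift
            }
        }
    }
    spec@features <- f
    methods::validObject(spec)
    spec
}

#' Re-seed a SyntheticSpec
#'
#' Returns a copy of the spec with a new RNG seed but identical ground
#' truth, so that independent train/test draws can be taken from one
#' feature recipe.
#'
#' @param spec a [SyntheticSpec-class]
#' @param seed new seed
#' @return the re-seeded spec
#' @export
reseed <- function(spec, seed) {
    spec@seed <- as.integer(seed)
    methods::validObject(spec)
    spec
}

#' Simulate a PeptideSet from a SyntheticSpec
#'
#' Amplitude = detection indicator x lognormal intensity, then values below
#' the feature's LOD are censored to 0. Feature metadata (mass, CE time) are
#' drawn from plausible CE-MS ranges. Fully reproducible: the spec's seed
#' drives the whole stream.
#'
#' @param spec a [SyntheticSpec-class]
#' @return a [PeptideSet-class] whose rows match `spec@features`
#' @export
simulateMatrix <- function(spec) {
    methods::validObject(spec)
    f <- spec@features
    m <- nrow(f); n <- spec@nPerGroup
    set.seed(spec@seed + 1L)  # offset from the spec-construction stream
    amp <- matrix(0, m, 2 * n)
    for (k in 1:2) {
        cols <- seq_len(n) + (k - 1L) * n
        mu <- f[[paste0("log_mean_", k)]]
        sdv <- f[[paste0("log_sd_", k)]]
        pr <- f[[paste0("detect_prob_", k)]]
        z <- matrix(stats::rnorm(m * n), m, n)
        if (spec@blockSize > 0L && spec@rho > 0) {
            blk <- rep(seq_len(ceiling(m / spec@blockSize)),
                       each = spec@blockSize)[seq_len(m)]
            shared <- matrix(stats::rnorm(max(blk) * n), max(blk), n)
            z <- sqrt(spec@rho) * shared[blk, , drop = FALSE] +
                sqrt(1 - spec@rho) * z
        }
        lat <- exp(mu + sdv * z)
        det <- matrix(stats::rbinom(m * n, 1L, rep(pr, n)), m, n)
        a <- det * lat
        a[a < f$lod] <- 0
        amp[, cols] <- a
    }
    rownames(amp) <- f$feature_id
    colnames(amp) <- c(sprintf("%s%03d", spec@groupLabels[1], seq_len(n)),
                       sprintf("%s%03d", spec@groupLabels[2], seq_len(n)))
    group <- factor(rep(spec@groupLabels, each = n),
                    levels = spec@groupLabels)
    mass <- stats::runif(m, 800, 15000)
    ceT <- stats::runif(m, 19, 45)
    PeptideSet(amp, group = group, mass = mass, ceTime = ceT)
}
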