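#' Resampling stability selection of biomarkers
#'
#' Repeatedly holds out a fraction of the training samples (stratified by
#' group), re-runs the differential test with BH adjustment on the retained
#' samples, and records how often each feature comes out significant. The
#' selection frequency defines nested marker tiers: features significant in
#' at least 100%, 80% and 50% of the resamples. High-frequency markers are
#' the ones most likely to hold up in an independent test set.
#'
#' With `nResamples = 0` no resampling is done and all tiers equal the
#' full-data significant set.
#'
#' @param x training [PeptideSet-class] (two groups)
#' @param nResamples number of resamples N (>= 0)
#' @param holdoutFraction fraction of samples held out per group, in \[0, 1)
#' @param method differential test, see [testAll()]
#' @param fdrLevel BH FDR level declaring significance inside a resample
#' @param seed RNG seed (resampling is deterministic given the seed)
#' @param thresholds selection-frequency tier thresholds
#' @return a `StabilityReport` list: `selectionFrequency` (named, denominator
#'   N), `tiers` (named list of feature-id sets, nested), `fullSignificant`,
#'   and the run parameters
#' @export
stabilitySelect <- function(x, nResamples = 30, holdoutFraction = 0.30,
                            method = "wilcoxon", fdrLevel = 0.05,
                            seed = 1, thresholds = c(1, 0.8, 0.5)) {
    stopifnot(nResamples >= 0, holdoutFraction >= 0, holdoutFraction < 1)
    g <- .checkTwoGroups(x)
    thresholds <- sort(thresholds, decreasing = TRUE)
    full <- testAll(x, method = method)
    fullSig <- full$feature_id[!is.na(full$p_adj) & full$p_adj < fdrLevel]
    ids <- rownames(x)
    if (nResamples == 0) {
        freq <- stats::setNames(as.numeric(ids %in% fullSig), ids)
        tiers <- stats::setNames(rep(list(fullSig), length(thresholds)),
                                 sprintf("f(%d%%)", round(100 * thresholds)))
    } else {
        lev <- levels(g)
        keepN <- vapply(lev, function(l) round((1 - holdoutFraction) *
                                                   sum(g == l)), 0)
        if (any(keepN < 2)) stop("resample smaller than 2 per group",
                                 call. = FALSE)
        set.seed(seed)
        hits <- matrix(0, nrow(x), nResamples, dimnames = list(ids, NULL))
        for (b in seq_len(nResamples)) {
            keep <- unlist(lapply(seq_along(lev), function(k)
                sample(which(g == lev[k]), keepN[k])))
            res <- testAll(x[, keep], method = method)
            hits[, b] <- !is.na(res$p_adj) & res$p_adj < fdrLevel
        }
        freq <- rowMeans(hits)
        tiers <- lapply(thresholds, function(t) ids[freq >= t - 1e-9])
        names(tiers) <- sprintf("f(%d%%)", round(100 * thresholds))
    }
    structure(list(nResamples = nResamples,
                   holdoutFraction = holdoutFraction, method = method,
                   fdrLevel = fdrLevel, thresholds = thresholds, seed = seed,
                   selectionFrequency = freq, tiers = tiers,
                   fullSignificant = fullSig),
              class = "StabilityReport")
}

#' @export
print.StabilityReport <- function(x, ...) {
    cat(sprintf("StabilityReport: N=%d resamples, %.0f%% holdout, %s/BH %.2g\n",
                x$nResamples, 100 * x$holdoutFraction, x$method, x$fdrLevel))
    for (nm in names(x$tiers))
        cat(sprintf("  %s: %d features\n", nm, length(x$tiers[[nm]])))
    invisible(x)
}

#' Test-set concordance of stability tiers
#'
#' For each frequency tier, counts how many members remain significant when
#' re-tested on an independent test set (same validation convention as
#' [validateMarkers()]).
#'
#' @param report a `StabilityReport` from [stabilitySelect()]
#' @param testSet the independent [PeptideSet-class]
#' @param method test method (default: the report's)
#' @param level significance level on the test set
#' @param testAdjust `"bh"` (within-tier adjustment) or `"none"`
#' @return data.frame: `tier`, `size`, `confirmed`, `fraction`
#' @export
tierConcordance <- function(report, testSet, method = report$method,
                            level = report$fdrLevel,
                            testAdjust = c("bh", "none")) {
    testAdjust <- match.arg(testAdjust)
    rows <- lapply(names(report$tiers), function(nm) {
        ids <- report$tiers[[nm]]
        if (!length(ids))
            return(data.frame(tier = nm, size = 0L, confirmed = 0L,
                              fraction = 0))
        v <- validateMarkers(ids, testSet, method = method, level = level,
                             testAdjust = testAdjust)
        data.frame(tier = nm, size = length(ids), confirmed = v$n_confirmed,
                   fraction = v$fraction)
    })
    do.call(rbind, rows)
}
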