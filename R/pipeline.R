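#' Run the full biomarker-definition workflow from one configuration
#'
#' Executes the canonical stage chain — input (read or simulate) ->
#' detection-frequency filter -> differential testing + BH -> any of the
#' optional downstream stages (stability selection, differential sample
#' size, discriminative sample size, classification) — writing TSV/JSON
#' outputs and a structured log. Identical config + seed gives identical
#' outputs: every stochastic stage draws from a seed derived
#' deterministically from the root seed.
#'
#' @param config a named list (or path to a JSON file holding one) with
#'   elements:
#'   \describe{
#'     \item{`seed`}{root RNG seed (required)}
#'     \item{`out_dir`}{output directory (created if absent)}
#'     \item{`input`}{list(`matrix`, `sample_sheet`) paths, or}
#'     \item{`simulate`}{list(`type` = "null"/"effect", `m_features`,
#'       `n_per_group`, and [makeEffectSpec()] arguments); a paired test set
#'       is simulated from the same spec with a shifted seed}
#'     \item{`filter`}{list(`threshold`), default 0.30}
#'     \item{`test`}{list(`method`, `fdr_level`), default wilcoxon / 0.05}
#'     \item{`stability`}{optional: list(`n_resamples`, `holdout`)}
#'     \item{`ndiff`}{optional: list(`sizes`, `B`, `q`, `power_ave`,
#'       `target_power`, `n_features`)}
#'     \item{`ndisc`}{optional: list(`classifier`, `sizes`, `reps`,
#'       `metric`, `target`, `select_alpha`)}
#'     \item{`classify`}{optional: list(`classifier`, `select_alpha`,
#'       `loocv`)}
#'     \item{`test_input`}{list(`matrix`, `sample_sheet`) for the
#'       independent test set (needed by stability concordance, ndisc and
#'       classify when the input is not simulated)}
#'   }
#' @return invisibly, a report bundle: the objects every executed stage
#'   produced, plus `log` (one line per stage with its seed and parameters)
#' @export
runPipeline <- function(config) {
    if (is.character(config)) config <- jsonlite::read_json(config,
                                                            simplifyVector = TRUE)
    if (is.null(config$seed)) stop("config$seed is required", call. = FALSE)
    seed <- as.integer(config$seed)
    stageSeed <- function(k) (seed + 7919L * k) %% .Machine$integer.max
    outDir <- config$out_dir
    if (!is.null(outDir) && !dir.exists(outDir))
        dir.create(outDir, recursive = TRUE)
    emit <- function(name, obj, writer) {
        if (!is.null(outDir)) writer(file.path(outDir, name))
        invisible(obj)
    }
    bundle <- list(log = character())
    logLine <- function(...) {
        line <- sprintf(...)
        bundle$log <<- c(bundle$log, line)
        if (!is.null(outDir))
            cat(line, "\n", sep = "", file = file.path(outDir, "run.log"),
                append = TRUE)
    }
    runStage <- function(name, expr) {
        tryCatch(expr, error = function(e)
            stop("stage '", name, "' failed: ", conditionMessage(e),
                 call. = FALSE))
    }

    ## ---- input ----
    testSet <- NULL
    m <- runStage("input", {
        if (!is.null(config$input)) {
            pth <- config$input
            if (is.null(pth$matrix) || !file.exists(pth$matrix))
                stop("input matrix path missing or not found")
            readPeptideMatrix(pth$matrix, sampleSheet = pth$sample_sheet)
        } else if (!is.null(config$simulate)) {
            sc <- config$simulate
            mk <- function(s) {
                args <- sc[setdiff(names(sc), "type")]
                names(args)[names(args) == "m_features"] <- "mFeatures"
                names(args)[names(args) == "n_per_group"] <- "nPerGroup"
                names(args)[names(args) == "delta_range"] <- "deltaRange"
                names(args)[names(args) == "class_mix"] <- "classMix"
                args$seed <- s
                fun <- if (identical(sc$type, "null")) makeNullSpec
                       else makeEffectSpec
                simulateMatrix(do.call(fun, args))
            }
            trainSet <- mk(stageSeed(1L))
            testSet <- mk(stageSeed(2L))
            colnames(testSet) <- paste0("T", colnames(testSet))
            trainSet
        } else stop("config needs either 'input' or 'simulate'")
    })
    if (is.null(testSet) && !is.null(config$test_input))
        testSet <- runStage("input", readPeptideMatrix(
            config$test_input$matrix,
            sampleSheet = config$test_input$sample_sheet))
    logLine("input: %d features x %d samples (seed %d)", nrow(m), ncol(m),
            seed)

    ## ---- filter ----
    thr <- if (is.null(config$filter$threshold)) 0.30
           else config$filter$threshold
    m <- runStage("filter", frequencyFilter(m, thr))
    logLine("filter: threshold %.2f -> %d features", thr, nrow(m))
    emit("filtered.csv", m, function(p) writePeptideMatrix(m, p))
    bundle$filtered <- m

    ## ---- test ----
    method <- if (is.null(config$test$method)) "wilcoxon"
              else config$test$method
    fdr <- if (is.null(config$test$fdr_level)) 0.05
           else config$test$fdr_level
    res <- runStage("test", {
        r <- testAll(m, method = method)
        s <- featureSummaries(m)
        r$diff_class <- s$diff_class[match(r$feature_id, s$feature_id)]
        r
    })
    logLine("test: %s, %d BH-significant at %.2g", method,
            sum(res$p_adj < fdr, na.rm = TRUE), fdr)
    emit("results.tsv", res, function(p)
        utils::write.table(res, p, sep = "\t", row.names = FALSE,
                           quote = FALSE))
    bundle$test <- res

    ## ---- stability ----
    if (!is.null(config$stability)) {
        sc <- config$stability
        stab <- runStage("stability", stabilitySelect(
            m, nResamples = if (is.null(sc$n_resamples)) 30
                            else sc$n_resamples,
            holdoutFraction = if (is.null(sc$holdout)) 0.30 else sc$holdout,
            method = method, fdrLevel = fdr, seed = stageSeed(3L)))
        bundle$stability <- stab
        logLine("stability: N=%d, tiers %s (seed %d)", stab$nResamples,
                paste(vapply(stab$tiers, length, 0L), collapse = "/"),
                stageSeed(3L))
        if (!is.null(testSet)) {
            conc <- runStage("stability", tierConcordance(stab, testSet))
            bundle$concordance <- conc
            emit("stability.tsv", conc, function(p)
                utils::write.table(conc, p, sep = "\t", row.names = FALSE,
                                   quote = FALSE))
        }
    }

    ## ---- differential sample size ----
    if (!is.null(config$ndiff)) {
        nd <- config$ndiff
        out <- runStage("ndiff", {
            pi0 <- estimatePi0(res$p_raw[!res$untestable])
            aa <- alphaAve(pi0,
                           q = if (is.null(nd$q)) 0.05 else nd$q,
                           powerAve = if (is.null(nd$power_ave)) 0.9
                                      else nd$power_ave)
            sig <- res$feature_id[!is.na(res$p_adj) & res$p_adj < fdr]
            feats <- utils::head(sig, if (is.null(nd$n_features)) 5
                                      else nd$n_features)
            if (!length(feats)) stop("no significant features to power")
            curves <- bootstrapPower(
                m, sizes = if (is.null(nd$sizes)) seq(10, 120, 5)
                           else nd$sizes,
                B = if (is.null(nd$B)) 2000 else nd$B,
                alpha = aa, method = method, features = feats,
                seed = stageSeed(4L))
            tp <- if (is.null(nd$target_power)) 0.9 else nd$target_power
            data.frame(feature_id = feats,
                       pi0 = pi0$pi0, alpha_ave = aa,
                       ndiff = vapply(curves, ndiff, 0L,
                                      targetPower = tp))
        })
        bundle$ndiff <- out
        logLine("ndiff: pi0 %.4f, alpha_ave %.4g (seed %d)", out$pi0[1],
                out$alpha_ave[1], stageSeed(4L))
        emit("ndiff.tsv", out, function(p)
            utils::write.table(out, p, sep = "\t", row.names = FALSE,
                               quote = FALSE))
    }

    ## ---- discriminative sample size ----
    if (!is.null(config$ndisc)) {
        if (is.null(testSet)) stop("stage 'ndisc' failed: no test set",
                                   call. = FALSE)
        nd <- config$ndisc
        out <- runStage("ndisc", {
            pts <- learningCurve(
                m, testSet,
                classifier = if (is.null(nd$classifier)) "svm"
                             else nd$classifier,
                sizes = if (is.null(nd$sizes)) c(7, 15, 25, 40, 65)
                        else nd$sizes,
                reps = if (is.null(nd$reps)) 20 else nd$reps,
                selectAlpha = if (is.null(nd$select_alpha)) 0.05
                              else nd$select_alpha,
                seed = stageSeed(5L))
            metric <- if (is.null(nd$metric)) "aac" else nd$metric
            fit <- fitPowerLaw(pts, metric = metric)
            target <- if (is.null(nd$target)) 0.10 else nd$target
            list(points = pts, fit = fit,
                 ndisc = ndisc(fit, target), target = target)
        })
        bundle$ndisc <- out
        logLine("ndisc: %s fit (%.3g, %.3g, %.3g) -> N = %d (seed %d)",
                out$fit$metric, out$fit$gammaFloor, out$fit$scale,
                out$fit$rate, out$ndisc, stageSeed(5L))
        emit("ndisc.json", out, function(p)
            jsonlite::write_json(list(gamma_floor = out$fit$gammaFloor,
                                      scale = out$fit$scale,
                                      rate = out$fit$rate,
                                      target = out$target,
                                      ndisc = out$ndisc),
                                 p, auto_unbox = TRUE, digits = NA))
    }

    ## ---- classification ----
    if (!is.null(config$classify)) {
        if (is.null(testSet)) stop("stage 'classify' failed: no test set",
                                   call. = FALSE)
        cc <- config$classify
        out <- runStage("classify", {
            alpha <- if (is.null(cc$select_alpha)) 0.05 else cc$select_alpha
            feats <- selectFeatures(m, alpha = alpha)
            if (!length(feats)) stop("empty feature selection")
            ev <- trainAndEval(m, testSet,
                               classifier = if (is.null(cc$classifier)) "svm"
                                            else cc$classifier,
                               features = feats, seed = stageSeed(6L))
            if (isTRUE(cc$loocv))
                ev$loocvAccuracy <- as.numeric(loocv(
                    m, classifier = if (is.null(cc$classifier)) "svm"
                                    else cc$classifier,
                    selectAlpha = alpha, seed = stageSeed(7L)))
            ev
        })
        bundle$classify <- out
        logLine("classify: %s, holdout acc %.3f, AUC %.3f (seed %d)",
                out$classifier, out$accuracy, out$auc, stageSeed(6L))
        emit("eval.json", out, function(p)
            jsonlite::write_json(list(classifier = out$classifier,
                                      accuracy = out$accuracy,
                                      mer = out$mer, auc = out$auc,
                                      aac = out$aac,
                                      loocv_accuracy = out$loocvAccuracy,
                                      features = out$features,
                                      roc = out$roc),
                                 p, auto_unbox = TRUE, digits = NA))
    }
    invisible(bundle)
}
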