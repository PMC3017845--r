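#' Unadjusted (or BH-adjusted) Wilcoxon feature selection
#'
#' The canonical pre-classification filter: a Wilcoxon rank-sum test per
#' feature on the training set, keeping features with p below `alpha`
#' (raw by default; BH-adjusted with `adjusted = TRUE`).
#'
#' @param train training [PeptideSet-class]
#' @param alpha selection level
#' @param adjusted select on BH-adjusted p-values instead of raw
#' @param method differential test (default `"wilcoxon"`)
#' @return character vector of selected feature ids (possibly empty)
#' @export
selectFeatures <- function(train, alpha = 0.05, adjusted = FALSE,
                           method = "wilcoxon") {
    if (alpha <= 0) return(character())
    res <- testAll(train, method = method)
    p <- if (adjusted) res$p_adj else res$p_raw
    res$feature_id[!is.na(p) & p < alpha]
}

## ---- classifier adapters -------------------------------------------------
## Each adapter returns list(model, score(newX) -> numeric oriented so that
## larger = more like the positive class, class(newX) -> factor labels).
## Inputs are natural-log amplitudes; zeros are mapped to log of a
## pseudo-amplitude (half the smallest nonzero training value).

.classifierDefaults <- list(
    svm = list(kernel = "radial", cost = 1),
    random_forest = list(ntree = 500),
    adaboost = list(nRounds = 100),
    tree = list(),
    glm = list(),
    hb = list(lambda = 1))

.resolveClassifier <- function(classifier) {
    if (is.character(classifier))
        classifier <- list(name = classifier, params = list())
    stopifnot(is.list(classifier), !is.null(classifier$name))
    known <- names(.classifierDefaults)
    if (!classifier$name %in% known && is.null(classifier$fit))
        stop("unknown classifier '", classifier$name, "'; known: ",
             paste(known, collapse = ", "),
             " (or supply fit/predictScore functions)", call. = FALSE)
    defaults <- .classifierDefaults[[classifier$name]]
    classifier$params <- utils::modifyList(if (is.null(defaults)) list()
                                           else defaults,
                                           if (is.null(classifier$params))
                                               list() else classifier$params)
    classifier
}

.fitClassifier <- function(spec, X, y) {
    y <- droplevels(factor(y))
    pos <- levels(y)[2]
    p <- spec$params
    orient <- function(score, trainScore) {
        ## orientation decided on training scores only
        if (mean(trainScore[y == pos]) < mean(trainScore[y != pos])) -1 else 1
    }
    if (!is.null(spec$fit)) {           # pluggable slot
        model <- spec$fit(X, y)
        return(list(
            score = function(newX) spec$predictScore(model, newX),
            class = function(newX) {
                s <- spec$predictScore(model, newX)
                factor(levels(y)[(s > 0.5) + 1], levels = levels(y))
            }))
    }
    switch(spec$name,
        svm = {
            model <- e1071::svm(X, y, kernel = p$kernel, cost = p$cost)
            tr <- as.numeric(attr(stats::predict(model, X,
                                                 decision.values = TRUE),
                                  "decision.values"))
            o <- orient(NULL, tr)
            list(score = function(newX) {
                     o * as.numeric(attr(stats::predict(model, newX,
                                                        decision.values = TRUE),
                                         "decision.values"))
                 },
                 class = function(newX) stats::predict(model, newX))
        },
        random_forest = {
            model <- randomForest::randomForest(X, y, ntree = p$ntree)
            list(score = function(newX)
                     stats::predict(model, newX, type = "prob")[, pos],
                 class = function(newX) stats::predict(model, newX))
        },
        adaboost = {
            model <- .adaboostFit(X, y, p$nRounds)
            list(score = function(newX) .adaboostScore(model, newX),
                 class = function(newX)
                     factor(levels(y)[(.adaboostScore(model, newX) > 0) + 1],
                            levels = levels(y)))
        },
        tree = {
            df <- data.frame(X, y = y, check.names = FALSE)
            model <- rpart::rpart(y ~ ., df, method = "class")
            list(score = function(newX)
                     stats::predict(model,
                                    data.frame(newX, check.names = FALSE),
                                    type = "prob")[, pos],
                 class = function(newX)
                     stats::predict(model,
                                    data.frame(newX, check.names = FALSE),
                                    type = "class"))
        },
        glm = {
            df <- data.frame(X, y = y, check.names = FALSE)
            model <- suppressWarnings(stats::glm(y ~ ., df,
                                                 family = stats::binomial()))
            scoreFun <- function(newX)
                suppressWarnings(stats::predict(
                    model, data.frame(newX, check.names = FALSE),
                    type = "response"))
            list(score = scoreFun,
                 class = function(newX)
                     factor(levels(y)[(scoreFun(newX) > 0.5) + 1],
                            levels = levels(y)))
        },
        hb = {
            ## reference implementation for the hierarchical-Bayes slot:
            ## MAP Bayesian logistic regression under a shared Gaussian
            ## shrinkage prior on the coefficients (= ridge-penalized
            ## logistic regression). Not a canonical published model.
            model <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                                    lambda = p$lambda)
            scoreFun <- function(newX)
                as.numeric(stats::predict(model, newX, type = "response"))
            list(score = scoreFun,
                 class = function(newX)
                     factor(levels(y)[(scoreFun(newX) > 0.5) + 1],
                            levels = levels(y)))
        },
        stop("unhandled classifier", call. = FALSE))
}

## Minimal AdaBoost.M1 over depth-1 rpart stumps (no boosting-specific
## package is assumed): weights updated multiplicatively, additive score
## F(x) = sum alpha_t h_t(x) with h in {-1, +1} (+1 = positive class).
.adaboostFit <- function(X, y, nRounds) {
    yy <- ifelse(y == levels(y)[2], 1, -1)
    n <- nrow(X)
    w <- rep(1 / n, n)
    df <- data.frame(X, check.names = FALSE)
    stumps <- list(); alphas <- numeric()
    for (t in seq_len(nRounds)) {
        dat <- df
        dat$.y <- factor(yy, levels = c(-1, 1))
        fit <- rpart::rpart(.y ~ ., data = dat,
                            weights = w, method = "class",
                            control = rpart::rpart.control(
                                maxdepth = 1, cp = -1, minsplit = 2,
                                xval = 0))
        pred <- as.numeric(as.character(stats::predict(fit, df,
                                                       type = "class")))
        err <- sum(w * (pred != yy))
        if (err <= 0) { stumps[[t]] <- fit; alphas[t] <- 10; break }
        if (err >= 0.5) break
        a <- 0.5 * log((1 - err) / err)
        stumps[[t]] <- fit; alphas[t] <- a
        w <- w * exp(-a * yy * pred)
        w <- w / sum(w)
    }
    if (!length(stumps)) {  # no usable stump: constant majority score
        return(list(stumps = list(), alphas = numeric(),
                    majority = sign(sum(yy) + 0.5)))
    }
    list(stumps = stumps, alphas = alphas, majority = 0)
}

.adaboostScore <- function(model, newX) {
    df <- data.frame(newX, check.names = FALSE)
    if (!length(model$stumps)) return(rep(model$majority, nrow(df)))
    s <- rep(0, nrow(df))
    for (t in seq_along(model$stumps)) {
        pred <- as.numeric(as.character(
            stats::predict(model$stumps[[t]], df, type = "class")))
        s <- s + model$alphas[t] * pred
    }
    s
}

## ---- ROC -----------------------------------------------------------------

#' ROC curve and trapezoid AUC from scores
#'
#' Sweeps the decision threshold over the scores (ties grouped), producing a
#' nondecreasing curve from (0,0) to (1,1); AUC by the trapezoid rule,
#' which equals the rank (Mann-Whitney) statistic and is invariant under
#' strictly monotone score transformations.
#'
#' @param scores numeric decision scores, larger = more positive
#' @param labels true labels (factor or logical); `positive` names the
#'   positive level (default: second factor level)
#' @param positive positive class label
#' @return list: `roc` data.frame of (`fpr`, `tpr`) points, `auc`
#' @export
rocCurve <- function(scores, labels, positive = NULL) {
    labels <- factor(labels)
    if (is.null(positive)) positive <- levels(labels)[length(levels(labels))]
    isPos <- labels == positive
    nP <- sum(isPos); nN <- sum(!isPos)
    stopifnot(nP > 0, nN > 0, length(scores) == length(labels))
    ord <- order(scores, decreasing = TRUE)
    s <- scores[ord]; y <- isPos[ord]
    grp <- cumsum(!duplicated(s))
    tp <- cumsum(y); fp <- cumsum(!y)
    last <- !duplicated(grp, fromLast = TRUE)  # end of each tie block
    tpr <- c(0, tp[last] / nP); fpr <- c(0, fp[last] / nN)
    auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
    list(roc = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

## ---- train / evaluate ----------------------------------------------------

.logInputs <- function(trainAmp, testAmp = NULL) {
    nz <- trainAmp[trainAmp > 0]
    pseudo <- if (length(nz)) min(nz) / 2 else 1
    tr <- t(log(pmax(trainAmp, pseudo)))
    te <- if (is.null(testAmp)) NULL else t(log(pmax(testAmp, pseudo)))
    list(train = tr, test = te, pseudo = pseudo)
}

#' Train a classifier on selected features and evaluate on a holdout set
#'
#' Trains on the natural-log amplitudes of the selected features (zeros are
#' mapped to half the smallest nonzero training amplitude) and evaluates on
#' the independent test set: accuracy, MER = 1 - accuracy, the ROC curve by
#' sweeping the decision score, AUC by trapezoid, and AAC = 1 - AUC.
#' Training and test sample ids must be disjoint; an overlap is treated as
#' information leakage and aborts.
#'
#' @param train,testSet training and test [PeptideSet-class]s
#' @param classifier name (`"svm"`, `"random_forest"`, `"adaboost"`,
#'   `"tree"`, `"glm"`, `"hb"`) or a list with `name`, optional `params`,
#'   or a pluggable `fit(X, y)` / `predictScore(model, X)` pair
#' @param features selected feature ids (must exist in both sets)
#' @param seed RNG seed for stochastic learners
#' @return a `ClassifierEval` list: classifier name + hyperparameters,
#'   per-group training sizes, `features`, `accuracy`, `mer`, `auc`, `aac`,
#'   `roc` points, `pseudoAmplitude`
#' @export
trainAndEval <- function(train, testSet, classifier = "svm", features,
                         seed = NULL) {
    spec <- .resolveClassifier(classifier)
    if (length(intersect(colnames(train), colnames(testSet))))
        stop("train/test sample ids overlap: leakage", call. = FALSE)
    if (!length(features)) stop("no features selected", call. = FALSE)
    if (!all(features %in% rownames(train)) ||
        !all(features %in% rownames(testSet)))
        stop("selected features missing from train or test matrix",
             call. = FALSE)
    gTr <- .checkTwoGroups(train)
    gTe <- factor(sampleGroups(testSet), levels = levels(gTr))
    if (anyNA(gTe)) stop("test groups do not match training groups",
                         call. = FALSE)
    if (!is.null(seed)) set.seed(seed)
    inp <- .logInputs(amplitudes(train)[features, , drop = FALSE],
                      amplitudes(testSet)[features, , drop = FALSE])
    cl <- .fitClassifier(spec, inp$train, gTr)
    scores <- cl$score(inp$test)
    pred <- cl$class(inp$test)
    acc <- mean(pred == gTe)
    rc <- rocCurve(scores, gTe, positive = levels(gTr)[2])
    structure(list(classifier = spec$name, params = spec$params,
                   nTrain = table(gTr), features = features,
                   accuracy = acc, mer = 1 - acc,
                   auc = rc$auc, aac = 1 - rc$auc, roc = rc$roc,
                   pseudoAmplitude = inp$pseudo),
              class = "ClassifierEval")
}

#' @export
print.ClassifierEval <- function(x, ...) {
    cat(sprintf("ClassifierEval: %s on %d features (train n = %s)\n",
                x$classifier, length(x$features),
                paste(as.integer(x$nTrain), collapse = "+")))
    cat(sprintf("  holdout accuracy %.3f (MER %.3f), AUC %.3f (AAC %.3f)\n",
                x$accuracy, x$mer, x$auc, x$aac))
    invisible(x)
}

#' Leave-one-out cross-validated accuracy
#'
#' Fits one model per left-out training sample and reports the fraction of
#' held-out samples correctly labelled. With `reselect = TRUE` ("complete"
#' LOOCV, the default) feature selection is re-run inside every fold, the
#' only version free of selection bias. With `reselect = FALSE` features
#' are selected once on the full training set — the leaky shortcut whose
#' wildly optimistic accuracy on small samples this package exists to
#' demonstrate.
#'
#' @param train training [PeptideSet-class] (>= 3 samples per group)
#' @param classifier see [trainAndEval()]
#' @param selectAlpha unadjusted Wilcoxon selection level per fold
#' @param reselect re-run selection inside each fold (complete LOOCV)
#' @param features optional fixed feature set (implies `reselect = FALSE`)
#' @param seed RNG seed
#' @return LOOCV accuracy in \[0, 1\]; attribute `folds` holds per-fold
#'   predictions (`NA` where selection came up empty)
#' @export
loocv <- function(train, classifier = "svm", selectAlpha = 0.05,
                  reselect = TRUE, features = NULL, seed = NULL) {
    spec <- .resolveClassifier(classifier)
    g <- .checkTwoGroups(train, minPerGroup = 3L)
    if (!is.null(features)) reselect <- FALSE
    if (!reselect && is.null(features))
        features <- selectFeatures(train, alpha = selectAlpha)
    if (!is.null(seed)) set.seed(seed)
    n <- ncol(train)
    pred <- factor(rep(NA_character_, n), levels = levels(g))
    for (i in seq_len(n)) {
        feats <- if (reselect) selectFeatures(train[, -i],
                                              alpha = selectAlpha)
                 else features
        if (!length(feats)) next
        inp <- .logInputs(amplitudes(train)[feats, -i, drop = FALSE],
                          amplitudes(train)[feats, i, drop = FALSE])
        cl <- .fitClassifier(spec, inp$train, g[-i])
        pred[i] <- cl$class(inp$test)
    }
    ## folds with an empty selection count as errors
    acc <- sum(!is.na(pred) & pred == g) / n
    structure(acc, folds = pred)
}
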