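#' PeptideSet: a two-group peptide amplitude matrix
#'
#' `PeptideSet` extends [SummarizedExperiment::SummarizedExperiment] to hold a
#' features x samples matrix of nonnegative peptide amplitudes, where 0 means
#' "not detected" (the peptide is absent or below the limit of detection).
#' Feature metadata (molecular mass in Da, normalized CE migration time in
#' minutes) live in `rowData`; the per-sample group label lives in
#' `colData$group`.
#'
#' @slot . inherits all slots from `SummarizedExperiment`; the single assay is
#'   named `"amplitude"`.
#'
#' @details Amplitudes must be nonnegative and finite; feature and sample
#' identifiers must be unique; every sample must carry a group label. Most
#' analyses additionally require exactly two group levels with at least two
#' samples each; this is checked at analysis time, not at construction, so
#' that partially labelled matrices can still be read and subset.
#'
#' @seealso [readPeptideMatrix()], [frequencyFilter()], [featureSummaries()]
#' @export
setClass("PeptideSet", contains = "SummarizedExperiment")

setValidity("PeptideSet", function(object) {
    msg <- character()
    if (!"amplitude" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'amplitude' is required")
    else {
        a <- SummarizedExperiment::assay(object, "amplitude")
        if (!is.numeric(a))
            msg <- c(msg, "amplitudes must be numeric")
        else if (any(!is.finite(a)))
            msg <- c(msg, "amplitudes must be finite (use 0 for not detected)")
        else if (any(a < 0))
            msg <- c(msg, "amplitudes must be nonnegative")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "feature ids must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample ids must be present and unique")
    if (!"group" %in% colnames(SummarizedExperiment::colData(object)))
        msg <- c(msg, "colData must contain a 'group' column")
    else if (anyNA(object$group))
        msg <- c(msg, "every sample needs a group label")
    if (length(msg)) msg else TRUE
})

#' Construct a PeptideSet
#'
#' @param amplitude numeric matrix, features x samples; 0 = not detected.
#'   Row and column names are used as feature/sample identifiers.
#' @param group factor or character vector of group labels, one per sample.
#'   Converted to a factor; by default levels are sorted lexicographically.
#'   The first level is the reference group for effect-size signs.
#' @param mass numeric vector of molecular masses (Da), one per feature.
#' @param ceTime numeric vector of CE migration times (min), one per feature.
#'
#' @return a validated [PeptideSet-class] object.
#' @examples
#' a <- matrix(c(10, 0, 3, 5, 0, 8, 2, 9), nrow = 2,
#'             dimnames = list(c("p1", "p2"), c("F1", "F2", "M1", "M2")))
#' ps <- PeptideSet(a, group = c("F", "F", "M", "M"))
#' ps
#' @export
PeptideSet <- function(amplitude, group,
                       mass = rep(NA_real_, nrow(amplitude)),
                       ceTime = rep(NA_real_, nrow(amplitude))) {
    amplitude <- as.matrix(amplitude)
    if (is.null(rownames(amplitude)))
        rownames(amplitude) <- sprintf("ft%05d", seq_len(nrow(amplitude)))
    if (is.null(colnames(amplitude)))
        colnames(amplitude) <- sprintf("S%03d", seq_len(ncol(amplitude)))
    if (!is.factor(group)) group <- factor(group)
    group <- droplevels(group)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(amplitude = amplitude),
        rowData = S4Vectors::DataFrame(mass_da = as.numeric(mass),
                                       ce_time_min = as.numeric(ceTime),
                                       row.names = rownames(amplitude)),
        colData = S4Vectors::DataFrame(group = group,
                                       row.names = colnames(amplitude)))
    methods::new("PeptideSet", se)
}

#' @describeIn PeptideSet amplitude matrix accessor
#' @param x a PeptideSet
#' @export
amplitudes <- function(x) SummarizedExperiment::assay(x, "amplitude")

#' @describeIn PeptideSet group labels (factor, one per sample)
#' @export
sampleGroups <- function(x) x$group

#' @describeIn PeptideSet molecular masses in Da
#' @export
featureMass <- function(x) SummarizedExperiment::rowData(x)$mass_da

#' @describeIn PeptideSet CE migration times in minutes
#' @export
ceTime <- function(x) SummarizedExperiment::rowData(x)$ce_time_min

setMethod("show", "PeptideSet", function(object) {
    cat(sprintf("PeptideSet: %d features x %d samples\n",
                nrow(object), ncol(object)))
    tab <- table(sampleGroups(object))
    cat("groups:", paste(sprintf("%s (n=%d)", names(tab), as.integer(tab)),
                         collapse = ", "), "\n")
    a <- amplitudes(object)
    cat(sprintf("zero fraction: %.3f\n", mean(a == 0)))
    invisible(NULL)
})

## internal: check the two-group analysis contract
.checkTwoGroups <- function(x, minPerGroup = 2L) {
    g <- sampleGroups(x)
    if (nlevels(g) != 2L)
        stop("analysis requires exactly two group levels, got ",
             nlevels(g), call. = FALSE)
    tab <- table(g)
    if (any(tab < minPerGroup))
        stop("each group needs at least ", minPerGroup, " samples",
             call. = FALSE)
    invisible(g)
}
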