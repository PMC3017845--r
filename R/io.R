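#' Read a peptide amplitude matrix from delimited text
#'
#' The canonical on-disk layout mirrors the wide "pivot table" format common
#' in CE-MS studies: a header row naming the samples, then one row per
#' peptide with columns `feature_id, mass_da, ce_time_min` followed by one
#' amplitude column per sample. Missing cells are read as 0 (not detected).
#'
#' @param matrixPath path to the CSV/TSV matrix file (delimiter sniffed from
#'   the extension: `.tsv`/`.txt` = tab, otherwise comma).
#' @param sampleSheet either a path to a two-column `sample_id,group` CSV, a
#'   data.frame with those columns, or `NULL` to use `groupRule`.
#' @param groupRule when no sample sheet is given, how to derive groups from
#'   sample names. `"prefix"` (default) takes the leading run of letters of
#'   each sample id (so `M12` and `F3` map to groups `M` and `F`).
#'   Alternatively a function mapping sample ids to labels.
#' @param reference optional group label to use as reference (first factor
#'   level); effect-size signs follow this order.
#'
#' @return a [PeptideSet-class].
#' @export
readPeptideMatrix <- function(matrixPath, sampleSheet = NULL,
                              groupRule = "prefix", reference = NULL) {
    if (!file.exists(matrixPath))
        stop("matrix file not found: ", matrixPath, call. = FALSE)
    sep <- if (grepl("\\.(tsv|txt)$", matrixPath)) "\t" else ","
    df <- utils::read.table(matrixPath, header = TRUE, sep = sep,
                            check.names = FALSE, stringsAsFactors = FALSE)
    need <- c("feature_id", "mass_da", "ce_time_min")
    if (!all(need %in% colnames(df)))
        stop("matrix header must start with columns ",
             paste(need, collapse = ", "), call. = FALSE)
    ids <- as.character(df$feature_id)
    if (anyDuplicated(ids))
        stop("duplicate feature ids in matrix file", call. = FALSE)
    ampCols <- setdiff(colnames(df), need)
    amp <- as.matrix(df[, ampCols, drop = FALSE])
    if (!is.numeric(amp))
        stop("non-numeric amplitude values in matrix file", call. = FALSE)
    amp[is.na(amp)] <- 0
    rownames(amp) <- ids

    group <- .resolveGroups(ampCols, sampleSheet, groupRule)
    if (!is.null(reference)) group <- stats::relevel(group, ref = reference)
    PeptideSet(amp, group = group, mass = df$mass_da, ceTime = df$ce_time_min)
}

.resolveGroups <- function(sampleIds, sampleSheet, groupRule) {
    if (!is.null(sampleSheet)) {
        sh <- if (is.character(sampleSheet) && length(sampleSheet) == 1L)
            utils::read.csv(sampleSheet, stringsAsFactors = FALSE)
        else as.data.frame(sampleSheet)
        if (!all(c("sample_id", "group") %in% colnames(sh)))
            stop("sample sheet needs columns sample_id, group", call. = FALSE)
        idx <- match(sampleIds, sh$sample_id)
        if (anyNA(idx))
            stop("samples without a group label: ",
                 paste(sampleIds[is.na(idx)], collapse = ", "), call. = FALSE)
        return(factor(sh$group[idx]))
    }
    labels <- if (is.function(groupRule)) groupRule(sampleIds)
    else if (identical(groupRule, "prefix")) sub("^([A-Za-z]+).*$", "\\1",
                                                 sampleIds)
    else stop("unknown group rule", call. = FALSE)
    if (any(labels == "" | is.na(labels)))
        stop("could not derive a group label for every sample", call. = FALSE)
    factor(labels)
}

#' Write a PeptideSet to delimited text
#'
#' Writes the matrix in the canonical layout read by [readPeptideMatrix()],
#' and optionally a `sample_id,group` sheet. Amplitudes are written with full
#' precision (round trips are bit-identical for values representable in
#' decimal; `format` uses 17 significant digits).
#'
#' @param x a [PeptideSet-class]
#' @param matrixPath output path for the matrix CSV
#' @param sampleSheetPath optional output path for the sample sheet CSV
#' @return invisibly, `matrixPath`
#' @export
writePeptideMatrix <- function(x, matrixPath, sampleSheetPath = NULL) {
    amp <- amplitudes(x)
    df <- data.frame(feature_id = rownames(amp),
                     mass_da = featureMass(x),
                     ce_time_min = ceTime(x),
                     check.names = FALSE)
    num <- as.data.frame(amp, check.names = FALSE)
    for (j in seq_along(num)) num[[j]] <- format(num[[j]], digits = 17,
                                                 trim = TRUE,
                                                 scientific = FALSE)
    utils::write.table(cbind(df, num), matrixPath, sep = ",", quote = FALSE,
                       row.names = FALSE)
    if (!is.null(sampleSheetPath))
        utils::write.csv(data.frame(sample_id = colnames(amp),
                                    group = as.character(sampleGroups(x))),
                         sampleSheetPath, row.names = FALSE, quote = FALSE)
    invisible(matrixPath)
}

#' Keep features detected frequently enough in at least one group
#'
#' A peptide seen in only a small fraction of both groups can hardly be
#' called associated with the phenotype, so the standard pre-filter keeps a
#' feature only if its nonzero (detection) frequency reaches `threshold` in
#' group 1 OR group 2. The default 0.30 is the conventional 30% rule.
#'
#' The operation is idempotent and preserves feature order.
#'
#' @param x a [PeptideSet-class] with two groups
#' @param threshold detection-frequency threshold in \[0, 1\]
#' @return the filtered [PeptideSet-class]
#' @export
frequencyFilter <- function(x, threshold = 0.30) {
    stopifnot(threshold >= 0, threshold <= 1)
    if (nrow(x) == 0L) return(x)
    g <- .checkTwoGroups(x)
    amp <- amplitudes(x)
    keep <- rep(FALSE, nrow(amp))
    for (lev in levels(g)) {
        freq <- rowMeans(amp[, g == lev, drop = FALSE] > 0)
        keep <- keep | freq >= threshold
    }
    x[keep, ]
}
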