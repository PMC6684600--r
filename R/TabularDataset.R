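#' Construct a TabularDataset
#'
#' Builds a [TabularDataset-class] from a samples-by-features numeric matrix
#' and a label per sample.  Missing values are rejected unless
#' \code{impute = "mean"} is given, in which case each missing entry is
#' replaced by its feature's mean over the non-missing samples.
#'
#' @param values numeric matrix, n samples x d features (d >= 2).
#' @param labels vector of length n with the class label of each sample;
#'   coerced to factor.
#' @param featureIds optional character vector of d feature names; defaults to
#'   the column names of \code{values} or \code{f1..fd}.
#' @param sampleIds optional character vector of n sample names; defaults to
#'   the row names of \code{values} or \code{s1..sn}.
#' @param impute \code{"none"} (reject missing values, the default) or
#'   \code{"mean"}.
#' @return A [TabularDataset-class].
#' @examples
#' ds <- TabularDataset(matrix(rnorm(40), 10, 4), rep(c("a", "b"), 5))
#' dim(sampleValues(ds))
#' @export
TabularDataset <- function(values, labels, featureIds = NULL,
                           sampleIds = NULL, impute = c("none", "mean")) {
    impute <- match.arg(impute)
    values <- as.matrix(values)
    storage.mode(values) <- "double"
    if (nrow(values) != length(labels))
        stop("'labels' must have one entry per sample (row of 'values')")
    if (anyNA(values)) {
        if (impute == "none")
            stop("'values' contains missing values; pass impute = \"mean\" ",
                 "to impute them")
        mu <- colMeans(values, na.rm = TRUE)
        idx <- which(is.na(values), arr.ind = TRUE)
        values[idx] <- mu[idx[, 2L]]
    }
    if (is.null(featureIds))
        featureIds <- colnames(values)
    if (is.null(featureIds))
        featureIds <- paste0("f", seq_len(ncol(values)))
    if (is.null(sampleIds))
        sampleIds <- rownames(values)
    if (is.null(sampleIds))
        sampleIds <- paste0("s", seq_len(nrow(values)))
    assay <- t(values)                       # features x samples
    dimnames(assay) <- list(featureIds, sampleIds)
    se <- SummarizedExperiment::SummarizedExperiment(
        assays = list(values = assay),
        colData = S4Vectors::DataFrame(label = factor(labels),
                                       row.names = sampleIds))
    methods::new("TabularDataset", se)
}

#' @describeIn TabularDataset number of samples.
#' @param x,object a [TabularDataset-class].
#' @export
nSamples <- function(x) ncol(SummarizedExperiment::assay(x, "values"))

#' @describeIn TabularDataset number of features.
#' @export
nFeatures <- function(x) nrow(SummarizedExperiment::assay(x, "values"))

#' @describeIn TabularDataset samples-by-features numeric matrix (n x d).
#' @export
sampleValues <- function(x) t(SummarizedExperiment::assay(x, "values"))

#' @describeIn TabularDataset factor of per-sample class labels.
#' @export
sampleLabels <- function(x) SummarizedExperiment::colData(x)$label

#' @describeIn TabularDataset feature identifiers, in order.
#' @export
featureIds <- function(x) rownames(SummarizedExperiment::assay(x, "values"))

#' @describeIn TabularDataset sample identifiers, in order.
#' @export
sampleIds <- function(x) colnames(SummarizedExperiment::assay(x, "values"))

#' Feature-space view of a dataset
#'
#' Returns the d x n matrix whose row j is feature j described by its profile
#' across the n samples — the transpose of the samples-by-features table.
#' This is the point set that [embedFeatures()] places in the plane.
#'
#' @param x a [TabularDataset-class].
#' @return numeric matrix, features x samples.
#' @export
featureSpace <- function(x) {
    stopifnot(methods::is(x, "TabularDataset"))
    SummarizedExperiment::assay(x, "values")
}

#' Subset a dataset by sample indices
#'
#' @param x a [TabularDataset-class].
#' @param idx integer vector of 1-based sample indices.
#' @return A [TabularDataset-class] with the selected samples.
#' @export
subsetSamples <- function(x, idx) {
    stopifnot(methods::is(x, "TabularDataset"))
    x[, idx]
}

setMethod("show", "TabularDataset", function(object) {
    lab <- sampleLabels(object)
    cat("TabularDataset:", nSamples(object), "samples x",
        nFeatures(object), "features\n")
    cat("classes:", paste(levels(lab), collapse = ", "), "\n")
})

#' Read / write a labeled delimited table
#'
#' The on-disk format is a delimited text file with a header row: one column
#' per feature plus one label column, one row per sample.  Row names (sample
#' ids) are stored in the first column when written and recovered when read.
#'
#' @param path file path.
#' @param labelColumn name of the label column (default \code{"label"}).
#' @param sep field separator (default comma).
#' @param impute passed to [TabularDataset()].
#' @return \code{readTabular}: a [TabularDataset-class].
#' @export
readTabular <- function(path, labelColumn = "label", sep = ",",
                        impute = c("none", "mean")) {
    df <- read.csv(path, sep = sep, check.names = FALSE, row.names = 1L)
    if (!labelColumn %in% colnames(df))
        stop("label column '", labelColumn, "' not found in ", path)
    labels <- df[[labelColumn]]
    values <- as.matrix(df[, setdiff(colnames(df), labelColumn), drop = FALSE])
    TabularDataset(values, labels, sampleIds = rownames(df), impute = impute)
}

#' @rdname readTabular
#' @param x a [TabularDataset-class] to write.
#' @export
writeTabular <- function(x, path, labelColumn = "label", sep = ",") {
    stopifnot(methods::is(x, "TabularDataset"))
    df <- as.data.frame(sampleValues(x), check.names = FALSE)
    df[[labelColumn]] <- as.character(sampleLabels(x))
    utils::write.table(df, path, sep = sep, row.names = TRUE,
                       col.names = NA, quote = FALSE)
    invisible(path)
}
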