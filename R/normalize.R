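#' Fit min-max normalization statistics on a training set
#'
#' Two variants, both mapping feature values into [0, 1] so they can act as
#' image shades:
#' \describe{
#'   \item{norm1}{features are treated as independent: each is normalized by
#'     its own training minimum and maximum.}
#'   \item{norm2}{one shared affine map for the whole matrix, shifting by the
#'     global training minimum and dividing by the global training range —
#'     this retains the relative topology of values across features.}
#' }
#' Statistics are fitted from the training split only; applying them to
#' held-out samples never refits them.
#'
#' @param train a [TabularDataset-class] or samples-by-features matrix
#'   (training split only).
#' @param kind \code{"norm1"} or \code{"norm2"}.
#' @return A [NormalizationParams-class].
#' @examples
#' p <- fitNorm(matrix(c(2, 4, 6), 3, 1), "norm1")
#' applyNorm(p, matrix(c(2, 4, 6, 8), 4, 1))
#' @export
fitNorm <- function(train, kind = c("norm1", "norm2")) {
    kind <- match.arg(kind)
    X <- asMatrixSamples(train)
    if (kind == "norm1") {
        methods::new("NormalizationParams", kind = "norm1",
                     featureMin = apply(X, 2L, min),
                     featureMax = apply(X, 2L, max),
                     globalMin = NA_real_, globalMax = NA_real_)
    } else {
        methods::new("NormalizationParams", kind = "norm2",
                     featureMin = numeric(0), featureMax = numeric(0),
                     globalMin = min(X), globalMax = max(X))
    }
}

#' Apply fitted normalization
#'
#' Maps samples into [0, 1] using training statistics.  Values outside the
#' training range (possible for held-out samples) are clipped to [0, 1].
#' A feature that was constant in training (min = max) maps to 0 under norm1.
#'
#' @param params a [NormalizationParams-class] from [fitNorm()].
#' @param samples a [TabularDataset-class] or samples-by-features matrix with
#'   the same feature count the params were fitted on.
#' @return numeric matrix of the same shape with entries in [0, 1].
#' @export
applyNorm <- function(params, samples) {
    stopifnot(methods::is(params, "NormalizationParams"))
    X <- asMatrixSamples(samples)
    if (params@kind == "norm1") {
        d <- length(params@featureMin)
        if (ncol(X) != d)
            stop("samples have ", ncol(X), " features but params were ",
                 "fitted on ", d)
        rng <- params@featureMax - params@featureMin
        out <- sweep(X, 2L, params@featureMin)
        out <- sweep(out, 2L, ifelse(rng > 0, rng, 1), "/")
        out[, rng == 0] <- 0        # constant training feature -> 0 shade
    } else {
        rng <- params@globalMax - params@globalMin
        out <- if (rng > 0) (X - params@globalMin) / rng
               else matrix(0, nrow(X), ncol(X))
    }
    out[out < 0] <- 0
    out[out > 1] <- 1
    out
}
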