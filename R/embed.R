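#' Embed features into a 2D plane
#'
#' Places each feature at a Cartesian point so that features with similar
#' profiles across the training samples land close together — the element
#' arrangement step that precedes image rendering.  Two embeddings are
#' offered: exact t-SNE (the default, good at pulling correlated feature
#' blocks into tight clusters) and kernel PCA via \pkg{kernlab}.
#'
#' t-SNE details: perplexity defaults to \code{min(30, (d - 1) / 3)} and is
#' lowered automatically when it exceeds what \code{d} supports; exactly
#' duplicated feature profiles are jittered by \code{1e-10 * N(0, 1)} before
#' embedding (duplicate points make the perplexity search degenerate).
#' Results are bit-reproducible for a fixed seed.
#'
#' kPCA details: the default kernel is a Gaussian RBF whose inverse width
#' \code{sigma} is set deterministically to the reciprocal of the median
#' squared pairwise distance between feature profiles; pass
#' \code{params = list(kernel = "vanilladot")} for a linear kernel (ordinary
#' PCA) or \code{params = list(sigma = ...)} to override the width.
#'
#' @param x a [TabularDataset-class] or a features-by-samples numeric matrix
#'   (one row per feature, as returned by [featureSpace()]).
#' @param method \code{"tsne"} or \code{"kpca"}.
#' @param params list of method parameters.  t-SNE: \code{perplexity},
#'   \code{max_iter}, \code{eta}.  kPCA: \code{kernel} (\code{"rbfdot"} or
#'   \code{"vanilladot"}), \code{sigma}.
#' @param seed integer seed.
#' @return A [FeatureCoordinates-class] with one row per feature.
#' @examples
#' ds <- generateRingnorm(100, seed = 1)
#' fc <- embedFeatures(ds, method = "kpca", seed = 1)
#' dim(coords(fc))
#' @export
embedFeatures <- function(x, method = c("tsne", "kpca"), params = list(),
                          seed = 1L) {
    method <- match.arg(method)
    G <- if (methods::is(x, "TabularDataset")) featureSpace(x) else {
        m <- as.matrix(x); storage.mode(m) <- "double"; m
    }
    d <- nrow(G)
    if (d < 2L) stop("at least 2 features are required for an embedding")
    if (!all(is.finite(G))) stop("feature profiles must be finite")
    Y <- if (method == "tsne") embedTsne(G, params, seed)
         else embedKpca(G, params, seed)
    rownames(Y) <- rownames(G)
    methods::new("FeatureCoordinates", coords = Y, method = method,
                 seed = as.integer(seed), params = params)
}

#' @describeIn embedFeatures coordinate matrix accessor (features x 2).
#' @export
coords <- function(x) {
    stopifnot(methods::is(x, "FeatureCoordinates"))
    x@coords
}

embedTsne <- function(G, params, seed) {
    d <- nrow(G)
    if (d < 3L)
        stop("t-SNE needs at least 3 features (no valid perplexity exists ",
             "for d < 3); use method = \"kpca\" instead")
    perplexity <- params$perplexity %||% min(30, (d - 1) / 3)
    if (perplexity >= (d - 1))
        perplexity <- (d - 1) / 3
    max_iter <- params$max_iter %||% 500L
    eta <- params$eta %||% 100
    withSeed(seed, {
        dup <- duplicated(G) | duplicated(G, fromLast = TRUE)
        if (any(dup))
            G[dup, ] <- G[dup, , drop = FALSE] +
                1e-10 * rnorm(sum(dup) * ncol(G))
        tsneEmbed(G, perplexity = perplexity, max_iter = max_iter, eta = eta)
    })
}

embedKpca <- function(G, params, seed) {
    kernel <- params$kernel %||% "rbfdot"
    kpar <- if (kernel == "rbfdot") {
        sigma <- params$sigma %||% {
            med <- stats::median(dist(G)^2)
            if (!is.finite(med) || med <= 0) 1 else 1 / med
        }
        list(sigma = sigma)
    } else list()
    # kernlab warns when the centered kernel has rank < 2 (e.g. two
    # features); the missing component is padded with zeros below
    fit <- withSeed(seed, suppressWarnings(
        kernlab::kpca(G, kernel = kernel, kpar = kpar, features = 2L)))
    # kernlab scales projections by sqrt(n) relative to PCA scores (its
    # eigenvalues are of K/n); undo so a linear kernel reproduces PCA exactly
    Y <- kernlab::rotated(fit)[, 1:2, drop = FALSE] / sqrt(nrow(G))
    # kernlab drops components with near-zero eigenvalue; pad if needed,
    # and zero out non-finite projections from rank-deficient kernels
    if (ncol(Y) < 2L)
        Y <- cbind(Y, matrix(0, nrow(Y), 2L - ncol(Y)))
    Y[!is.finite(Y)] <- 0
    unname(Y)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
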