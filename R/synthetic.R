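#' Generate the ringnorm two-class Gaussian benchmark
#'
#' Breiman's classic 20-dimensional two-class problem: class 1 is drawn from
#' a multivariate normal with zero mean and covariance four times the
#' identity; class 2 from a multivariate normal with per-dimension mean
#' a = 2 / sqrt(20) and identity covariance.  Classes are balanced 50/50.
#' The full benchmark has 7400 samples; smaller draws from the same
#' generative model are useful for scaled-down runs.
#'
#' @param nSamples even number of samples (default 7400).
#' @param seed integer seed; draws are bit-reproducible.
#' @param nFeatures dimensionality (default 20).
#' @return A [TabularDataset-class] with labels \code{class1}/\code{class2}.
#' @examples
#' ds <- generateRingnorm(200, seed = 1)
#' table(sampleLabels(ds))
#' @export
generateRingnorm <- function(nSamples = 7400L, seed = 1L, nFeatures = 20L) {
    nSamples <- as.integer(nSamples)
    if (nSamples < 2L || nSamples %% 2L != 0L)
        stop("'nSamples' must be an even number >= 2 (balanced classes)")
    d <- as.integer(nFeatures)
    n1 <- nSamples %/% 2L
    a <- 2 / sqrt(d)
    withSeed(seed, {
        x1 <- matrix(rnorm(n1 * d, mean = 0, sd = 2), n1, d)
        x2 <- matrix(rnorm(n1 * d, mean = a, sd = 1), n1, d)
    })
    TabularDataset(rbind(x1, x2),
                   labels = rep(c("class1", "class2"), each = n1),
                   featureIds = paste0("f", seq_len(d)))
}

#' Misclassification rate of the exact ringnorm Bayes rule
#'
#' Classifies samples by the true Gaussian log-density ratio of the two
#' ringnorm class distributions (known parameters, no estimation) and
#' returns the percent misclassified.  This is the irreducible-error
#' reference for the benchmark: no classifier can beat it in expectation.
#'
#' @param dataset a [TabularDataset-class] from [generateRingnorm()].
#' @return misclassification rate in percent.
#' @export
ringnormBayesError <- function(dataset) {
    X <- sampleValues(dataset)
    d <- ncol(X)
    a <- 2 / sqrt(d)
    # log N(0, 4I) - log N(a*1, I), constants included
    ll1 <- -0.5 * rowSums(X^2) / 4 - 0.5 * d * log(4)
    ll2 <- -0.5 * rowSums(sweep(X, 2L, a)^2)
    pred <- ifelse(ll1 > ll2, "class1", "class2")
    100 * mean(pred != as.character(sampleLabels(dataset)))
}

#' Generate a Madelon-like nonlinear two-class problem
#'
#' Emulates the construction behind the Madelon benchmark: informative
#' features are Gaussian clusters placed on the vertices of a hypercube with
#' an XOR-style (parity) label assignment, so no linear classifier can
#' separate the classes; redundant features are random linear combinations
#' of the informative ones; the remaining features are pure Gaussian noise.
#' This is an emulation of that style of problem, not a reconstruction of
#' the published benchmark instance.
#'
#' @param nSamples number of samples.
#' @param nInformative informative dimensions (clusters live on the
#'   \code{2^nInformative} hypercube vertices; keep this small).
#' @param nRedundant linear combinations of informative features.
#' @param nNoise independent N(0, 1) features.
#' @param seed integer seed.
#' @param clusterSep distance of hypercube vertices from the origin per
#'   dimension (default 2); cluster noise is N(0, 1).
#' @return A [TabularDataset-class] with labels \code{classA}/\code{classB}.
#' @export
generateMadelonLike <- function(nSamples = 2600L, nInformative = 5L,
                                nRedundant = 5L, nNoise = 10L, seed = 1L,
                                clusterSep = 2) {
    n <- as.integer(nSamples)
    ni <- as.integer(nInformative)
    stopifnot(n >= 2L, ni >= 1L, nRedundant >= 0L, nNoise >= 0L)
    withSeed(seed, {
        # hypercube vertex per sample, label = parity of positive signs
        signs <- matrix(sample(c(-1, 1), n * ni, replace = TRUE), n, ni)
        parity <- rowSums(signs > 0) %% 2L
        inform <- signs * clusterSep + matrix(rnorm(n * ni), n, ni)
        X <- inform
        if (nRedundant > 0L) {
            B <- matrix(rnorm(ni * nRedundant), ni, nRedundant)
            X <- cbind(X, inform %*% B)
        }
        if (nNoise > 0L)
            X <- cbind(X, matrix(rnorm(n * nNoise), n, nNoise))
    })
    ids <- c(paste0("inf", seq_len(ni)),
             if (nRedundant > 0L) paste0("red", seq_len(nRedundant)),
             if (nNoise > 0L) paste0("noise", seq_len(nNoise)))
    TabularDataset(X, labels = ifelse(parity == 1L, "classA", "classB"),
                   featureIds = ids)
}

#' Generate a dataset with blocks of correlated features
#'
#' Features within a block share a latent Gaussian factor so that every
#' within-block pair has correlation approximately \code{withinCorr}
#' (construction: \code{sqrt(rho) * factor + sqrt(1 - rho) * noise}).
#' Blocks are mutually independent.  If \code{classShift} is nonzero, class 2
#' shifts the mean of the first block's features by that amount, providing a
#' class signal carried by one correlated block.  This is the fixture for
#' the neighborhood property: an embedding that places similar features
#' together should co-locate each block's features in the image.
#'
#' @param nSamples number of samples (split evenly between two classes).
#' @param nBlocks number of feature blocks.
#' @param featuresPerBlock features in each block.
#' @param withinCorr target within-block correlation in [0, 1).
#' @param classShift mean shift applied to block 1 for class 2.
#' @param seed integer seed.
#' @return A [TabularDataset-class]; feature ids are \code{b<block>.<k>}.
#' @export
generateBlockCorrelated <- function(nSamples = 500L, nBlocks = 3L,
                                    featuresPerBlock = 20L,
                                    withinCorr = 0.95, classShift = 0,
                                    seed = 1L) {
    n <- as.integer(nSamples)
    stopifnot(withinCorr >= 0, withinCorr < 1, n >= 2L)
    nb <- as.integer(nBlocks)
    fb <- as.integer(featuresPerBlock)
    lab <- rep(c("class1", "class2"), length.out = n)
    withSeed(seed, {
        X <- matrix(0, n, nb * fb)
        for (b in seq_len(nb)) {
            factor_b <- rnorm(n)
            noise <- matrix(rnorm(n * fb), n, fb)
            X[, (b - 1L) * fb + seq_len(fb)] <-
                sqrt(withinCorr) * factor_b + sqrt(1 - withinCorr) * noise
        }
        if (classShift != 0)
            X[lab == "class2", seq_len(fb)] <-
                X[lab == "class2", seq_len(fb)] + classShift
    })
    ids <- paste0("b", rep(seq_len(nb), each = fb), ".",
                  rep(seq_len(fb), nb))
    TabularDataset(X, labels = lab, featureIds = ids)
}

#' Split a dataset 80:10:10 into train / validation / test
#'
#' Returns disjoint, exhaustive index sets in 80:10:10 proportion (sizes
#' within one sample of the exact proportions).  With \code{stratified =
#' TRUE} (the default) the class proportions of each split match the full
#' dataset within one sample per class, using largest-remainder allocation.
#'
#' @param dataset a [TabularDataset-class] with at least 10 samples.
#' @param seed integer seed; membership is deterministic given the seed.
#' @param stratified preserve per-class proportions (default TRUE); errors
#'   if any class has fewer than 3 samples.
#' @return A [SplitIndices-class].
#' @examples
#' sp <- splitDataset(generateRingnorm(1000, seed = 1), seed = 2)
#' lengths(list(trainIdx(sp), valIdx(sp), testIdx(sp)))
#' @export
splitDataset <- function(dataset, seed = 1L, stratified = TRUE) {
    stopifnot(methods::is(dataset, "TabularDataset"))
    n <- nSamples(dataset)
    if (n < 10L) stop("at least 10 samples are required for an 80:10:10 split")
    n_val <- round(0.1 * n)
    n_test <- round(0.1 * n)
    lab <- as.character(sampleLabels(dataset))
    idx <- withSeed(seed, {
        if (stratified) {
            counts <- table(lab)
            if (any(counts < 3L))
                stop("stratified split requires >= 3 samples per class ",
                     "(class '", names(counts)[which.min(counts)],
                     "' has ", min(counts), ")")
            pool <- lapply(split(seq_len(n), lab), sample)
            q_val <- largestRemainder(counts / n * n_val, n_val)
            q_test <- largestRemainder(counts / n * n_test, n_test)
            val <- test <- train <- integer(0)
            for (k in seq_along(pool)) {
                p <- pool[[k]]
                val <- c(val, utils::head(p, q_val[k]))
                p <- utils::tail(p, length(p) - q_val[k])
                test <- c(test, utils::head(p, q_test[k]))
                train <- c(train, utils::tail(p, length(p) - q_test[k]))
            }
            list(train = train, val = val, test = test)
        } else {
            p <- sample(n)
            list(train = p[seq_len(n - n_val - n_test)],
                 val = p[n - n_val - n_test + seq_len(n_val)],
                 test = p[n - n_test + seq_len(n_test)])
        }
    })
    methods::new("SplitIndices",
                 trainIdx = sort(as.integer(idx$train)),
                 valIdx = sort(as.integer(idx$val)),
                 testIdx = sort(as.integer(idx$test)),
                 seed = as.integer(seed), stratified = stratified)
}

# integer allocation matching fractional quotas: floor everything, then give
# the leftover units to the largest remainders (ties by order)
largestRemainder <- function(quota, total) {
    base <- floor(quota)
    left <- as.integer(round(total - sum(base)))
    if (left > 0) {
        extra <- order(quota - base, decreasing = TRUE)[seq_len(left)]
        base[extra] <- base[extra] + 1
    }
    as.integer(base)
}

#' @describeIn splitDataset training indices.
#' @param x a [SplitIndices-class].
#' @export
trainIdx <- function(x) x@trainIdx

#' @describeIn splitDataset validation indices.
#' @export
valIdx <- function(x) x@valIdx

#' @describeIn splitDataset test indices.
#' @export
testIdx <- function(x) x@testIdx

setMethod("show", "SplitIndices", function(object) {
    cat("SplitIndices: train", length(object@trainIdx),
        "/ val", length(object@valIdx),
        "/ test", length(object@testIdx),
        if (object@stratified) "(stratified)" else "", "\n")
})
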