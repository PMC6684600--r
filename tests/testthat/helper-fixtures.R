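# Shared fixtures and independent oracles used across the suite.

# two-class Gaussian blob: 60 features, the first 20 informative via a
# 2-sigma mean shift for class 2, the rest independent noise
makeBlobDataset <- function(nSamples = 500L, seed = 11L) {
    generateBlockCorrelated(nSamples = nSamples, nBlocks = 3L,
                            featuresPerBlock = 20L, withinCorr = 0,
                            classShift = 2, seed = seed)
}

# brute-force minimum-area rectangle: for every hull-edge orientation,
# rotate *all* points into that frame and take the axis-aligned bounding
# box; return the minimal area.  Independent of the package's calipers code
# path (works on raw points, no tie-breaking, no rectangle construction).
minRectAreaOracle <- function(points) {
    h <- grDevices::chull(points)
    H <- points[h, , drop = FALSE]
    nh <- nrow(H)
    e <- H[c(2:nh, 1L), ] - H
    thetas <- atan2(e[, 2L], e[, 1L])
    best <- Inf
    for (th in thetas) {
        R <- matrix(c(cos(-th), sin(-th), -sin(-th), cos(-th)), 2L, 2L)
        P <- points %*% t(R)
        a <- diff(range(P[, 1L])) * diff(range(P[, 2L]))
        if (a < best) best <- a
    }
    best
}

# direct group-by-pixel mean of normalized values, built from the rounding
# formula itself rather than the package's aggregation matrix
imageOracle <- function(map, zrow) {
    m <- map@frameRows
    n <- map@frameCols
    img <- matrix(0, m, n)
    key <- paste(map@pixelRow, map@pixelCol, sep = ",")
    for (k in unique(key)) {
        members <- which(key == k)
        rc <- as.integer(strsplit(k, ",")[[1L]])
        img[rc[1L] + 1L, rc[2L] + 1L] <- mean(zrow[members])
    }
    img
}

# mean within-block vs between-block distances for the 3-block fixture
blockDistanceGap <- function(D, blockId) {
    same <- outer(blockId, blockId, "==") & upper.tri(D)
    diff <- outer(blockId, blockId, "!=") & upper.tri(D)
    c(within = mean(D[same]), between = mean(D[diff]))
}

# small CNN configuration used wherever architecture details don't matter
tinyCnnConfig <- function(...) {
    args <- list(branches = 2L, convBlocksPerBranch = 2L,
                 filtersPerBlock = c(4L, 8L), kernelSizePerBranch = c(3L, 5L),
                 fcUnits = 16L, learningRate = 0.02, batchSize = 16L,
                 maxEpochs = 5L, seed = 7L)
    extra <- list(...)
    args[names(extra)] <- extra
    do.call(cnnConfig, args)
}
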