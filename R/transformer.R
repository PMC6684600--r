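#' Fit the tabular-to-image transformer on a training set
#'
#' Learns the sample-independent transformation that turns a feature vector
#' into a grayscale image: (1) view each feature as a point described by its
#' profile across the training samples, (2) embed the features into a 2D
#' plane ([embedFeatures()]), (3) enclose them in the minimum-area rectangle
#' via the convex hull ([minAreaRectangle()]), (4) rotate the plane by the
#' negative rectangle angle so the frame is horizontal/vertical, (5) rescale
#' and round the coordinates into an m x n pixel frame
#' ([coordsToPixelMap()]).  Both normalization variants are fitted alongside
#' so either can be selected later by validation error.
#'
#' The fitted object is immutable: transforming held-out samples never
#' changes any fitted parameter.
#'
#' @param train a [TabularDataset-class] — the training split only.
#' @param frameRows,frameCols pixel frame size; the default is 120 x 120
#'   (200 x 200 is recommended for very high-dimensional inputs such as
#'   full-transcriptome expression, where a small frame forces heavy
#'   collision averaging).
#' @param method embedding method, \code{"tsne"} (default) or \code{"kpca"}.
#' @param params embedding parameters, see [embedFeatures()].
#' @param seed integer seed controlling the embedding.
#' @return An [ImageTransformer-class].
#' @examples
#' ds <- generateRingnorm(200, seed = 1)
#' tr <- fitTransformer(ds, frameRows = 32, frameCols = 32,
#'                      method = "kpca", seed = 1)
#' stack <- transformSamples(tr, ds, norm = "norm1")
#' dim(imagePixels(stack))
#' @export
fitTransformer <- function(train, frameRows = 120L, frameCols = 120L,
                           method = c("tsne", "kpca"), params = list(),
                           seed = 1L) {
    stopifnot(methods::is(train, "TabularDataset"))
    method <- match.arg(method)
    fc <- embedFeatures(train, method = method, params = params, seed = seed)
    rect <- minAreaRectangle(coords(fc))
    rotated <- rotateCoordinates(coords(fc), -rect@angle)
    map <- coordsToPixelMap(rotated, frameRows, frameCols)
    map@rotationAngle <- -rect@angle
    methods::new("ImageTransformer",
                 coordinates = fc, rectangle = rect, locationMap = map,
                 norm1 = fitNorm(train, "norm1"),
                 norm2 = fitNorm(train, "norm2"),
                 featureIds = featureIds(train),
                 config = list(frameRows = as.integer(frameRows),
                               frameCols = as.integer(frameCols),
                               method = method, params = params,
                               seed = as.integer(seed)))
}

#' @describeIn fitTransformer the fitted [LocationMap-class].
#' @param transformer an [ImageTransformer-class].
#' @export
locationMap <- function(transformer) {
    stopifnot(methods::is(transformer, "ImageTransformer"))
    transformer@locationMap
}

#' @describeIn fitTransformer the fitted [NormalizationParams-class] of the
#'   requested kind.
#' @param kind \code{"norm1"} or \code{"norm2"}.
#' @export
normParams <- function(transformer, kind = c("norm1", "norm2")) {
    stopifnot(methods::is(transformer, "ImageTransformer"))
    kind <- match.arg(kind)
    if (kind == "norm1") transformer@norm1 else transformer@norm2
}

setMethod("show", "ImageTransformer", function(object) {
    cat("ImageTransformer:", length(object@featureIds), "features ->",
        paste0(object@config$frameRows, "x", object@config$frameCols),
        "frame\n")
    cat("embedding:", object@config$method,
        "| rectangle angle:", signif(object@rectangle@angle, 4), "rad\n")
})

#' Render samples as grayscale images
#'
#' Applies a fitted transformer to samples: normalizes them with the chosen
#' training statistics, then writes each normalized value to its feature's
#' pixel; where several features share a pixel (a collision group) their
#' arithmetic mean is used.  Pixels with no feature hold the background
#' value 0.
#'
#' @param transformer an [ImageTransformer-class] from [fitTransformer()].
#' @param samples a [TabularDataset-class] or samples-by-features matrix with
#'   the same features (count and order) as the training set.
#' @param norm which fitted normalization to use, \code{"norm1"} or
#'   \code{"norm2"}.
#' @return An [ImageStack-class] of dimension m x n x N with values in [0, 1].
#' @export
transformSamples <- function(transformer, samples,
                             norm = c("norm1", "norm2")) {
    stopifnot(methods::is(transformer, "ImageTransformer"))
    norm <- match.arg(norm)
    X <- asMatrixSamples(samples)
    d <- length(transformer@featureIds)
    if (ncol(X) != d)
        stop("samples have ", ncol(X), " features but the transformer ",
             "expects ", d)
    Z <- applyNorm(normParams(transformer, norm), X)     # N x d in [0,1]
    map <- transformer@locationMap
    m <- map@frameRows
    n <- map@frameCols
    # aggregation matrix A (pixels x d): image vector = A %*% sample
    groups <- map@collisionGroups
    feat <- unlist(groups, use.names = FALSE)
    pix_lin <- rep.int(
        map@pixelRow[vapply(groups, `[`, 1L, 1L)] +
            m * map@pixelCol[vapply(groups, `[`, 1L, 1L)] + 1L,
        lengths(groups))
    w <- rep.int(1 / lengths(groups), lengths(groups))
    A <- matrix(0, m * n, d)
    A[cbind(pix_lin, feat)] <- w
    img <- A %*% t(Z)                                    # (m*n) x N
    ids <- if (methods::is(samples, "TabularDataset")) sampleIds(samples)
           else rownames(X) %||% paste0("s", seq_len(nrow(X)))
    methods::new("ImageStack",
                 pixels = array(img, dim = c(m, n, ncol(img))),
                 sampleIds = as.character(ids))
}

#' @describeIn transformSamples pixel array accessor (m x n x N).
#' @param stack an [ImageStack-class].
#' @export
imagePixels <- function(stack) {
    stopifnot(methods::is(stack, "ImageStack"))
    stack@pixels
}

#' @describeIn transformSamples number of images in a stack.
#' @export
nImages <- function(stack) {
    stopifnot(methods::is(stack, "ImageStack"))
    dim(stack@pixels)[3L]
}

setMethod("show", "ImageStack", function(object) {
    d <- dim(object@pixels)
    cat("ImageStack:", d[3L], "images of", paste0(d[1L], "x", d[2L]),
        "pixels in [0,1]\n")
})

#' Save / load a fitted transformer
#'
#' The transformer is serialized as a single versioned archive (RDS) holding
#' the embedding coordinates, rectangle, location map, both normalization
#' statistics, configuration and seed.  A round trip is exact: images
#' produced after reloading are bit-identical.
#'
#' @param transformer an [ImageTransformer-class].
#' @param path file path of the archive.
#' @return \code{loadTransformer}: the restored [ImageTransformer-class].
#' @export
saveTransformer <- function(transformer, path) {
    stopifnot(methods::is(transformer, "ImageTransformer"))
    saveRDS(list(format = "tabimage.transformer", version = 1L,
                 object = transformer), path)
    invisible(path)
}

#' @rdname saveTransformer
#' @export
loadTransformer <- function(path) {
    x <- readRDS(path)
    if (!is.list(x) || !identical(x$format, "tabimage.transformer"))
        stop("'", path, "' is not a transformer archive")
    x$object
}

#' Write an image stack as 8-bit grayscale PNG files
#'
#' Each pixel value v in [0, 1] becomes the 8-bit level round(255 * v).
#'
#' @param stack an [ImageStack-class].
#' @param dir output directory (created if missing); one file per sample,
#'   named \code{<sampleId>.png}.
#' @return invisibly, the written file paths.
#' @export
writeImagePNG <- function(stack, dir) {
    stopifnot(methods::is(stack, "ImageStack"))
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    px <- stack@pixels
    paths <- character(nImages(stack))
    for (i in seq_len(nImages(stack))) {
        img <- roundHalfUp(255 * px[, , i]) / 255
        paths[i] <- file.path(dir, paste0(stack@sampleIds[i], ".png"))
        png::writePNG(img, paths[i])
    }
    invisible(paths)
}
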