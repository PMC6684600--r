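#' @import methods
#' @importFrom stats dist rnorm runif predict sd cor var
#' @importFrom utils head read.csv write.csv
#' @importFrom graphics polygon
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
#' @useDynLib tabimage, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Labeled tabular dataset
#'
#' A \code{TabularDataset} holds a numeric samples-by-features table together
#' with a class label per sample.  Internally it extends
#' \linkS4class{SummarizedExperiment} with the Bioconductor orientation:
#' features in rows, samples in columns, labels in \code{colData} under
#' \code{label}.  The feature-space view used for embedding (one point per
#' feature, described by its profile across training samples) is therefore
#' simply the assay matrix; the samples-by-features view is its transpose.
#'
#' @slot ... inherited from \linkS4class{SummarizedExperiment}; the single
#'   assay is named \code{"values"}.
#'
#' @seealso [TabularDataset()], [featureSpace()], [sampleValues()]
#' @export
setClass("TabularDataset", contains = "SummarizedExperiment")

setValidity("TabularDataset", function(object) {
    msg <- NULL
    if (!("values" %in% SummarizedExperiment::assayNames(object)))
        msg <- c(msg, "assay 'values' is required")
    else {
        v <- SummarizedExperiment::assay(object, "values")
        if (!is.numeric(v))
            msg <- c(msg, "assay 'values' must be numeric")
        if (anyNA(v))
            msg <- c(msg, "assay 'values' must not contain missing values")
        if (nrow(v) < 2L)
            msg <- c(msg, "at least 2 features are required")
    }
    if (!("label" %in% colnames(SummarizedExperiment::colData(object))))
        msg <- c(msg, "colData column 'label' is required")
    if (is.null(msg)) TRUE else msg
})

#' 2D feature coordinates from an embedding
#'
#' One Cartesian point per feature, produced by [embedFeatures()].  Row order
#' matches the feature order of the dataset the embedding was fitted on.
#'
#' @slot coords numeric matrix, features x 2.
#' @slot method character, \code{"tsne"} or \code{"kpca"}.
#' @slot seed integer seed the embedding was computed under.
#' @slot params list of embedding parameters actually used.
#' @export
setClass("FeatureCoordinates",
    representation(coords = "matrix", method = "character",
                   seed = "integer", params = "list"))

setValidity("FeatureCoordinates", function(object) {
    msg <- NULL
    if (ncol(object@coords) != 2L)
        msg <- c(msg, "coords must have exactly 2 columns")
    if (!all(is.finite(object@coords)))
        msg <- c(msg, "all coordinates must be finite")
    if (!object@method %in% c("tsne", "kpca"))
        msg <- c(msg, "method must be 'tsne' or 'kpca'")
    if (is.null(msg)) TRUE else msg
})

#' Minimum-area enclosing rectangle
#'
#' A rectangle of arbitrary orientation described by its center, half-extents
#' and rotation angle.  The angle is reported modulo pi/2 (a rectangle's
#' orientation has a quarter-turn symmetry).
#'
#' @slot center numeric length-2 center point.
#' @slot halfExtents numeric length-2 non-negative half side lengths along the
#'   rectangle's own axes.
#' @slot angle numeric, radians in [0, pi/2): rotation of the rectangle's
#'   first axis relative to the x-axis.
#' @export
setClass("RotatedRectangle",
    representation(center = "numeric", halfExtents = "numeric",
                   angle = "numeric"))

setValidity("RotatedRectangle", function(object) {
    msg <- NULL
    if (length(object@center) != 2L) msg <- c(msg, "center must be length 2")
    if (length(object@halfExtents) != 2L || any(object@halfExtents < 0))
        msg <- c(msg, "halfExtents must be length 2 and non-negative")
    if (length(object@angle) != 1L || object@angle < 0 ||
        object@angle >= pi / 2 + 1e-12)
        msg <- c(msg, "angle must be a scalar in [0, pi/2)")
    if (is.null(msg)) TRUE else msg
})

#' Fitted feature-to-pixel assignment
#'
#' The sample-independent transformation learned from the training set only:
#' every feature is assigned one pixel of an m x n frame; features whose
#' rotated coordinates round to the same pixel form a collision group whose
#' normalized values are averaged at transform time.  Pixel indices are
#' 0-based (row 0 is the top row of the image).
#'
#' @slot frameRows,frameCols integer frame size m, n.
#' @slot pixelRow,pixelCol integer vectors (length d) of 0-based pixel indices.
#' @slot collisionGroups named list: \code{"row,col"} -> integer vector of
#'   1-based feature indices sharing that pixel.
#' @slot rotationAngle numeric, radians the coordinates were rotated by
#'   (negative of the enclosing-rectangle angle).
#' @slot xBounds,yBounds numeric length-2 post-rotation min/max used for
#'   scaling coordinates into the frame.
#' @export
setClass("LocationMap",
    representation(frameRows = "integer", frameCols = "integer",
                   pixelRow = "integer", pixelCol = "integer",
                   collisionGroups = "list", rotationAngle = "numeric",
                   xBounds = "numeric", yBounds = "numeric"))

setValidity("LocationMap", function(object) {
    msg <- NULL
    d <- length(object@pixelRow)
    if (length(object@pixelCol) != d)
        msg <- c(msg, "pixelRow and pixelCol must have equal length")
    if (object@frameRows < 1L || object@frameCols < 1L)
        msg <- c(msg, "frame size must be at least 1 x 1")
    if (d > 0) {
        if (any(object@pixelRow < 0L) || any(object@pixelRow >= object@frameRows))
            msg <- c(msg, "pixelRow out of frame")
        if (any(object@pixelCol < 0L) || any(object@pixelCol >= object@frameCols))
            msg <- c(msg, "pixelCol out of frame")
        members <- sort(unlist(object@collisionGroups, use.names = FALSE))
        if (!identical(as.integer(members), seq_len(d)))
            msg <- c(msg, "collisionGroups must partition the feature indices")
    }
    if (is.null(msg)) TRUE else msg
})

#' Min-max normalization parameters
#'
#' Statistics fitted from the training set only.  \code{norm1} treats features
#' independently (per-feature min and max); \code{norm2} applies one shared
#' affine map using the global min and max of the whole training matrix, which
#' preserves the relative topology of feature values across features.
#'
#' @slot kind character, \code{"norm1"} or \code{"norm2"}.
#' @slot featureMin,featureMax numeric length-d vectors (norm1; empty for norm2).
#' @slot globalMin,globalMax numeric scalars (norm2; NA for norm1).
#' @export
setClass("NormalizationParams",
    representation(kind = "character", featureMin = "numeric",
                   featureMax = "numeric", globalMin = "numeric",
                   globalMax = "numeric"))

setValidity("NormalizationParams", function(object) {
    msg <- NULL
    if (!object@kind %in% c("norm1", "norm2"))
        msg <- c(msg, "kind must be 'norm1' or 'norm2'")
    if (object@kind == "norm1") {
        if (length(object@featureMin) != length(object@featureMax))
            msg <- c(msg, "featureMin/featureMax length mismatch")
        if (any(object@featureMax < object@featureMin))
            msg <- c(msg, "featureMax must be >= featureMin elementwise")
    } else if (object@kind == "norm2") {
        if (length(object@globalMin) != 1L || length(object@globalMax) != 1L ||
            is.na(object@globalMin) || is.na(object@globalMax))
            msg <- c(msg, "norm2 requires scalar globalMin/globalMax")
        else if (object@globalMax < object@globalMin)
            msg <- c(msg, "globalMax must be >= globalMin")
    }
    if (is.null(msg)) TRUE else msg
})

#' Stack of grayscale images
#'
#' N grayscale m x n images with values in [0, 1], one per sample.  Pixels not
#' assigned to any feature hold the background value 0.
#'
#' @slot pixels numeric array with dim (m, n, N): \code{pixels[, , i]} is the
#'   image of sample i, row 1 at the top.
#' @slot sampleIds character length N.
#' @export
setClass("ImageStack",
    representation(pixels = "array", sampleIds = "character"))

setValidity("ImageStack", function(object) {
    msg <- NULL
    if (length(dim(object@pixels)) != 3L)
        msg <- c(msg, "pixels must be a 3D array (rows, cols, samples)")
    else if (dim(object@pixels)[3] != length(object@sampleIds))
        msg <- c(msg, "third dimension must match sampleIds length")
    rng <- range(object@pixels)
    if (is.finite(rng[1]) && (rng[1] < -1e-12 || rng[2] > 1 + 1e-12))
        msg <- c(msg, "pixel values must lie in [0, 1]")
    if (is.null(msg)) TRUE else msg
})

#' Fitted tabular-to-image transformer
#'
#' The full fitted transformation: feature embedding, minimum-area rectangle,
#' pixel location map, and both normalization variants.  Fitted on the
#' training split only; applying it to new samples never modifies it.
#'
#' @slot coordinates [FeatureCoordinates-class] of the training features.
#' @slot rectangle [RotatedRectangle-class] enclosing the embedded features.
#' @slot locationMap [LocationMap-class] feature-to-pixel assignment.
#' @slot norm1,norm2 [NormalizationParams-class] fitted on the training set.
#' @slot featureIds character, expected feature names in order.
#' @slot config list: frame size, embedding method/params, seed.
#' @export
setClass("ImageTransformer",
    representation(coordinates = "FeatureCoordinates",
                   rectangle = "RotatedRectangle",
                   locationMap = "LocationMap",
                   norm1 = "NormalizationParams",
                   norm2 = "NormalizationParams",
                   featureIds = "character",
                   config = "list"))

#' Parallel CNN configuration
#'
#' Hyperparameters of the multi-branch convolutional network.  Each branch is
#' a chain of blocks (2D convolution, batch normalization, ReLU, 2x2 max
#' pooling); branches use different kernel sizes so that several filter scales
#' see the image; branch outputs are concatenated into one fully connected
#' layer followed by softmax.
#'
#' @slot branches integer number of parallel branches.
#' @slot convBlocksPerBranch integer blocks per branch.
#' @slot filtersPerBlock integer vector, one filter count per block.
#' @slot kernelSizePerBranch integer vector, one (odd) kernel size per branch;
#'   sizes must be pairwise distinct.
#' @slot poolSize integer max-pooling window (and stride).
#' @slot fcUnits integer units of the fully connected layer.
#' @slot learningRate,momentum numeric SGD settings.
#' @slot batchSize,maxEpochs integer training loop settings.
#' @slot seed integer seed for initialization and batch shuffling.
#' @export
setClass("CnnConfig",
    representation(branches = "integer", convBlocksPerBranch = "integer",
                   filtersPerBlock = "integer",
                   kernelSizePerBranch = "integer", poolSize = "integer",
                   fcUnits = "integer", learningRate = "numeric",
                   momentum = "numeric", batchSize = "integer",
                   maxEpochs = "integer", seed = "integer"))

setValidity("CnnConfig", function(object) {
    msg <- NULL
    if (object@branches < 1L) msg <- c(msg, "branches must be >= 1")
    if (object@convBlocksPerBranch < 1L)
        msg <- c(msg, "convBlocksPerBranch must be >= 1")
    if (length(object@filtersPerBlock) != object@convBlocksPerBranch)
        msg <- c(msg, "filtersPerBlock must have one entry per block")
    if (any(object@filtersPerBlock < 1L))
        msg <- c(msg, "filter counts must be positive")
    if (length(object@kernelSizePerBranch) != object@branches)
        msg <- c(msg, "kernelSizePerBranch must have one entry per branch")
    if (object@branches > 1L &&
        anyDuplicated(object@kernelSizePerBranch))
        msg <- c(msg, "kernel sizes must differ across branches")
    if (any(object@kernelSizePerBranch %% 2L == 0L))
        msg <- c(msg, "kernel sizes must be odd (same-padding convolution)")
    if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
    if (object@momentum < 0 || object@momentum >= 1)
        msg <- c(msg, "momentum must be in [0, 1)")
    if (object@batchSize < 1L || object@maxEpochs < 1L ||
        object@fcUnits < 1L || object@poolSize < 2L)
        msg <- c(msg, "batchSize, maxEpochs, fcUnits >= 1 and poolSize >= 2")
    if (is.null(msg)) TRUE else msg
})

#' An (un)trained parallel CNN
#'
#' Weights plus architecture metadata.  Produced untrained by
#' [buildParallelCnn()] and trained by [trainCnn()].
#'
#' @slot config [CnnConfig-class].
#' @slot weights list of per-branch conv/batch-norm parameters and the fully
#'   connected head.
#' @slot imageShape integer length-2 input frame size.
#' @slot classes character class labels (empty until trained).
#' @slot chosenNorm character, \code{"norm1"}, \code{"norm2"} or NA until set.
#' @slot history data.frame with per-epoch train/validation loss and error
#'   (empty until trained).
#' @slot bestEpoch integer epoch whose weights are stored (0 until trained).
#' @export
setClass("ParallelCnn",
    representation(config = "CnnConfig", weights = "list",
                   imageShape = "integer", classes = "character",
                   chosenNorm = "character", history = "data.frame",
                   bestEpoch = "integer"))

#' Train/validation/test split indices
#'
#' Disjoint, exhaustive 1-based indices in 80:10:10 proportion (within one
#' sample per split), optionally stratified by class.
#'
#' @slot trainIdx,valIdx,testIdx integer index vectors.
#' @slot seed integer seed used.
#' @slot stratified logical.
#' @export
setClass("SplitIndices",
    representation(trainIdx = "integer", valIdx = "integer",
                   testIdx = "integer", seed = "integer",
                   stratified = "logical"))

setValidity("SplitIndices", function(object) {
    all_idx <- c(object@trainIdx, object@valIdx, object@testIdx)
    n <- length(all_idx)
    msg <- NULL
    if (anyDuplicated(all_idx))
        msg <- c(msg, "splits must be disjoint")
    if (!identical(sort(all_idx), seq_len(n)))
        msg <- c(msg, "splits must be exhaustive over 1..n")
    if (abs(length(object@valIdx) - 0.1 * n) > 1 + 1e-9 ||
        abs(length(object@testIdx) - 0.1 * n) > 1 + 1e-9 ||
        abs(length(object@trainIdx) - 0.8 * n) > 2 + 1e-9)
        msg <- c(msg, "split sizes must be within one sample of 80:10:10")
    if (is.null(msg)) TRUE else msg
})
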