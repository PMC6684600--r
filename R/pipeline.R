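#' End-to-end pipeline: fit the transformer
#'
#' Loads or generates a dataset, splits it 80:10:10, fits the tabular-to-
#' image transformer on the training split only, and writes a versioned
#' transformer archive plus a feature-location diagnostic plot and a
#' provenance file (full config and seeds) into the output directory.
#'
#' The \code{config} list understands:
#' \describe{
#'   \item{input}{path to a delimited dataset ([readTabular()]), or}
#'   \item{generator}{list(name = "ringnorm"|"madelon"|"blocks", args = list(...))}
#'   \item{frameRows, frameCols}{pixel frame (default 120 x 120)}
#'   \item{method, params}{embedding method (default "tsne") and parameters}
#'   \item{splitSeed, fitSeed}{seeds for the split and the embedding}
#'   \item{outputDir}{artifact directory (created)}
#' }
#'
#' @param config named list, see Details.
#' @return invisibly, a list with the transformer, the split, the dataset
#'   and the archive path.
#' @export
runFit <- function(config) {
    config <- fillRunDefaults(config)
    dir.create(config$outputDir, showWarnings = FALSE, recursive = TRUE)
    ds <- loadRunInput(config)
    split <- splitDataset(ds, seed = config$splitSeed,
                          stratified = config$stratified)
    train <- subsetSamples(ds, trainIdx(split))
    tr <- fitTransformer(train, frameRows = config$frameRows,
                         frameCols = config$frameCols,
                         method = config$method, params = config$params,
                         seed = config$fitSeed)
    tr@config$splitSeed <- config$splitSeed
    archive <- file.path(config$outputDir, "transformer.rds")
    saveTransformer(tr, archive)
    saveRDS(split, file.path(config$outputDir, "split.rds"))
    writeRunConfig(config, file.path(config$outputDir, "run_config.rds"))
    plotFeatureLocations(tr, file.path(config$outputDir,
                                       "feature_locations.png"))
    logMsg(config, "fit: d=", nFeatures(ds), " frame=", config$frameRows,
           "x", config$frameCols, " angle=",
           signif(tr@rectangle@angle, 4), " rad seed=", config$fitSeed)
    invisible(list(transformer = tr, split = split, dataset = ds,
                   archive = archive))
}

#' End-to-end pipeline: train and evaluate the classifier
#'
#' Resumes from a [runFit()] output directory: renders train/validation/test
#' image stacks with the fitted transformer, trains the parallel CNN (under
#' the \code{"auto"} norm policy both normalization variants are trained and
#' the one with the lower validation error is kept; a fixed policy trains a
#' single arm), then touches the test split exactly once to compute the
#' final accuracy and confusion table.  The metrics report and confusion
#' table are written as delimited text, the model as a checkpoint archive.
#'
#' Additional \code{config} fields: \code{normPolicy} ("auto", "norm1" or
#' "norm2"), \code{cnn} (a [CnnConfig-class] or argument list for
#' [cnnConfig()]), and optionally \code{searchSpace} + \code{budget} to run
#' [tuneHyperparameters()] first.
#'
#' @param config named list as in [runFit()] plus the fields above.
#' @param fitDir directory produced by [runFit()] (defaults to
#'   \code{config$outputDir}).
#' @return invisibly, a list with the trained model, the report data.frame
#'   and the evaluation.
#' @export
runTrain <- function(config, fitDir = config$outputDir) {
    config <- fillRunDefaults(config)
    tr <- loadTransformer(file.path(fitDir, "transformer.rds"))
    split <- readRDS(file.path(fitDir, "split.rds"))
    if (!identical(tr@config$splitSeed, config$splitSeed))
        stop("transformer was fitted under split seed ", tr@config$splitSeed,
             " but config requests ", config$splitSeed,
             "; refusing to mix splits")
    ds <- loadRunInput(config)
    train <- subsetSamples(ds, trainIdx(split))
    val <- subsetSamples(ds, valIdx(split))
    cnn <- config$cnn
    if (!methods::is(cnn, "CnnConfig"))
        cnn <- do.call(cnnConfig, as.list(cnn))
    if (!is.null(config$searchSpace)) {
        trStack <- transformSamples(tr, train, norm = "norm1")
        vaStack <- transformSamples(tr, val, norm = "norm1")
        tuned <- tuneHyperparameters(config$searchSpace,
                                     config$budget %||% 5L,
                                     trStack, sampleLabels(train),
                                     vaStack, sampleLabels(val),
                                     seed = config$fitSeed,
                                     baseConfig = cnn)
        cnn <- tuned$best
        utils::write.table(tuned$trials,
                           file.path(config$outputDir, "tuning_trials.tsv"),
                           sep = "\t", row.names = FALSE, quote = FALSE)
    }
    testAccess <- 0L
    if (config$normPolicy == "auto") {
        sel <- selectNormalization(tr, train, val, cnn)
        model <- sel$models[[sel$chosen]]
        chosen <- sel$chosen
        valError <- sel$valError
        logMsg(config, "train: norm policy auto -> chose ", chosen,
               " (val errors: norm1=", signif(valError[["norm1"]], 4),
               ", norm2=", signif(valError[["norm2"]], 4), ")")
    } else {
        chosen <- config$normPolicy
        trStack <- transformSamples(tr, train, norm = chosen)
        vaStack <- transformSamples(tr, val, norm = chosen)
        model <- buildParallelCnn(cnn, dim(imagePixels(trStack))[1:2],
                                  nlevels(factor(sampleLabels(train))))
        model <- trainCnn(model, trStack, sampleLabels(train),
                          vaStack, sampleLabels(val))
        model@chosenNorm <- chosen
        valError <- c(norm1 = NA_real_, norm2 = NA_real_)
        valError[[chosen]] <- min(model@history$valError)
        logMsg(config, "train: norm policy ", chosen, " (single arm)")
    }
    # the test split is rendered and evaluated exactly once, after freezing
    test <- subsetSamples(ds, testIdx(split))
    teStack <- transformSamples(tr, test, norm = chosen)
    testAccess <- testAccess + 1L
    ev <- evaluateClassifier(model, teStack, sampleLabels(test))
    trStack <- transformSamples(tr, train, norm = chosen)
    vaStack <- transformSamples(tr, val, norm = chosen)
    trainAcc <- evaluateClassifier(model, trStack, sampleLabels(train))$accuracy
    valAcc <- evaluateClassifier(model, vaStack, sampleLabels(val))$accuracy
    report <- data.frame(
        metric = c("trainAccuracy", "valAccuracy", "testAccuracy",
                   "chosenNorm", "valErrorNorm1", "valErrorNorm2",
                   "bestEpoch", "testAccessCount"),
        value = c(signif(trainAcc, 6), signif(valAcc, 6),
                  signif(ev$accuracy, 6), chosen,
                  signif(valError[["norm1"]], 6),
                  signif(valError[["norm2"]], 6),
                  model@bestEpoch, testAccess))
    utils::write.table(report, file.path(config$outputDir, "metrics.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(as.data.frame.matrix(ev$confusion),
                       file.path(config$outputDir, "confusion.tsv"),
                       sep = "\t", row.names = TRUE, col.names = NA,
                       quote = FALSE)
    utils::write.table(model@history,
                       file.path(config$outputDir, "history.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    saveRDS(list(format = "tabimage.model", version = 1L, object = model),
            file.path(config$outputDir, "model.rds"))
    invisible(list(model = model, report = report, evaluation = ev,
                   chosen = chosen, valError = valError,
                   testAccessCount = testAccess))
}

#' End-to-end pipeline: render samples as images
#'
#' Applies a saved transformer to a dataset and writes the image stack (RDS
#' archive) and, optionally, one 8-bit grayscale PNG per sample.
#'
#' @param transformerPath path to a transformer archive from [runFit()].
#' @param samples a [TabularDataset-class], matrix, or path to a delimited
#'   dataset.
#' @param outputDir output directory.
#' @param norm normalization to apply.
#' @param writePng also write per-sample PNG files.
#' @return invisibly, the [ImageStack-class].
#' @export
runTransform <- function(transformerPath, samples, outputDir,
                         norm = c("norm1", "norm2"), writePng = FALSE) {
    norm <- match.arg(norm)
    tr <- loadTransformer(transformerPath)
    if (is.character(samples)) samples <- readTabular(samples)
    stack <- transformSamples(tr, samples, norm = norm)
    dir.create(outputDir, showWarnings = FALSE, recursive = TRUE)
    saveRDS(stack, file.path(outputDir, "images.rds"))
    if (writePng) writeImagePNG(stack, file.path(outputDir, "png"))
    invisible(stack)
}

fillRunDefaults <- function(config) {
    defaults <- list(frameRows = 120L, frameCols = 120L, method = "tsne",
                     params = list(), splitSeed = 1L, fitSeed = 1L,
                     stratified = TRUE, normPolicy = "auto",
                     cnn = cnnConfig(), outputDir = tempfile("tabimage_run_"),
                     verbose = FALSE)
    for (nm in names(defaults))
        if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
    if (!config$normPolicy %in% c("auto", "norm1", "norm2"))
        stop("normPolicy must be 'auto', 'norm1' or 'norm2'")
    config
}

loadRunInput <- function(config) {
    if (!is.null(config$dataset)) return(config$dataset)
    if (!is.null(config$input)) return(readTabular(config$input))
    if (is.null(config$generator))
        stop("config needs 'input' (file), 'dataset' or 'generator'")
    g <- config$generator
    args <- g$args %||% list()
    switch(g$name,
        ringnorm = do.call(generateRingnorm, args),
        madelon = do.call(generateMadelonLike, args),
        blocks = do.call(generateBlockCorrelated, args),
        stop("unknown generator '", g$name, "'"))
}

writeRunConfig <- function(config, path) {
    saveRDS(config[setdiff(names(config), "dataset")], path)
    invisible(path)
}

logMsg <- function(config, ...) {
    line <- paste0(format(Sys.time(), "%H:%M:%S "), paste0(..., collapse = ""))
    cat(line, "\n", file = file.path(config$outputDir, "run.log"),
        append = TRUE, sep = "")
    if (isTRUE(config$verbose)) message(line)
}

# scatter of embedded feature locations with the enclosing rectangle;
# skipped silently if no graphics device is available
plotFeatureLocations <- function(transformer, path) {
    ok <- tryCatch({
        grDevices::png(path, width = 600, height = 600)
        on.exit(grDevices::dev.off())
        co <- coords(transformer@coordinates)
        plot(co, pch = 20, cex = 0.6, xlab = "dim 1", ylab = "dim 2",
             main = "embedded feature locations", asp = 1)
        corners <- rectangleCorners(transformer@rectangle)
        graphics::polygon(corners, border = "red")
        TRUE
    }, error = function(e) FALSE)
    invisible(ok)
}
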