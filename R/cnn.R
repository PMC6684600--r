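#' Create a parallel-CNN configuration
#'
#' Defaults follow the architecture used throughout this package: two
#' parallel branches, four blocks per branch (each block = 2D convolution
#' with same padding, batch normalization, ReLU, 2x2 max pooling), kernel
#' sizes 3 and 5 so the branches see different filter scales, filter counts
#' 16/32/64/128 across the blocks, one fully connected layer and a softmax
#' head.  Training uses SGD with momentum and keeps the weights of the epoch
#' with the lowest validation error.
#'
#' @param branches number of parallel branches.
#' @param convBlocksPerBranch conv blocks per branch.
#' @param filtersPerBlock integer vector of filter counts, one per block.
#' @param kernelSizePerBranch odd kernel sizes, one per branch, pairwise
#'   distinct.
#' @param poolSize max-pooling window and stride.
#' @param fcUnits fully connected layer width.
#' @param learningRate,momentum SGD settings.
#' @param batchSize,maxEpochs training loop settings.
#' @param seed integer seed for weight initialization and batch shuffling.
#' @return A [CnnConfig-class].
#' @export
cnnConfig <- function(branches = 2L, convBlocksPerBranch = 4L,
                      filtersPerBlock = c(16L, 32L, 64L, 128L),
                      kernelSizePerBranch = c(3L, 5L), poolSize = 2L,
                      fcUnits = 128L, learningRate = 0.01, momentum = 0.9,
                      batchSize = 32L, maxEpochs = 20L, seed = 1L) {
    methods::new("CnnConfig", branches = as.integer(branches),
                 convBlocksPerBranch = as.integer(convBlocksPerBranch),
                 filtersPerBlock = as.integer(filtersPerBlock),
                 kernelSizePerBranch = as.integer(kernelSizePerBranch),
                 poolSize = as.integer(poolSize),
                 fcUnits = as.integer(fcUnits),
                 learningRate = as.numeric(learningRate),
                 momentum = as.numeric(momentum),
                 batchSize = as.integer(batchSize),
                 maxEpochs = as.integer(maxEpochs), seed = as.integer(seed))
}

# spatial size trace through the pooling cascade; NULL if infeasible
pooledSizes <- function(size, pool, blocks) {
    out <- integer(blocks)
    s <- size
    for (b in seq_len(blocks)) {
        s <- s %/% pool
        if (s < 1L) return(NULL)
        out[b] <- s
    }
    out
}

#' Build an untrained parallel CNN
#'
#' Initializes weights (He initialization, seeded) for the architecture in
#' \code{config}.  Fails if the frame is too small for the pooling cascade:
#' each block halves (floor) the spatial size, which must stay at least 1.
#'
#' @param config a [CnnConfig-class].
#' @param imageShape integer length-2, the (rows, cols) of input images.
#' @param nClasses number of output classes (>= 2).
#' @return An untrained [ParallelCnn-class].
#' @examples
#' model <- buildParallelCnn(cnnConfig(maxEpochs = 1L), c(120, 120), 2)
#' @export
buildParallelCnn <- function(config, imageShape, nClasses) {
    stopifnot(methods::is(config, "CnnConfig"))
    methods::validObject(config)
    imageShape <- as.integer(imageShape)
    nClasses <- as.integer(nClasses)
    if (nClasses < 2L) stop("at least 2 classes are required")
    nb <- config@convBlocksPerBranch
    minFrame <- config@poolSize^nb
    for (s in imageShape)
        if (is.null(pooledSizes(s, config@poolSize, nb)))
            stop("frame ", imageShape[1L], "x", imageShape[2L],
                 " is too small for ", nb, " pooling blocks; the minimum ",
                 "feasible frame is ", minFrame, "x", minFrame)
    rows <- pooledSizes(imageShape[1L], config@poolSize, nb)
    cols <- pooledSizes(imageShape[2L], config@poolSize, nb)
    weights <- withSeed(config@seed, {
        branchList <- lapply(seq_len(config@branches), function(br) {
            k <- config@kernelSizePerBranch[br]
            cin <- 1L
            blocks <- vector("list", nb)
            for (bl in seq_len(nb)) {
                f <- config@filtersPerBlock[bl]
                blocks[[bl]] <- list(
                    W = array(rnorm(k * k * cin * f,
                                    sd = sqrt(2 / (k * k * cin))),
                              dim = c(k, k, cin, f)),
                    b = numeric(f), gamma = rep(1, f), beta = numeric(f),
                    runMean = numeric(f), runVar = rep(1, f))
                cin <- f
            }
            blocks
        })
        p_branch <- rows[nb] * cols[nb] * config@filtersPerBlock[nb]
        P <- p_branch * config@branches
        list(branches = branchList,
             fc = list(W1 = matrix(rnorm(config@fcUnits * P,
                                         sd = sqrt(2 / P)),
                                   config@fcUnits, P),
                       b1 = numeric(config@fcUnits),
                       W2 = matrix(rnorm(nClasses * config@fcUnits,
                                         sd = sqrt(2 / config@fcUnits)),
                                   nClasses, config@fcUnits),
                       b2 = numeric(nClasses)))
    })
    methods::new("ParallelCnn", config = config, weights = weights,
                 imageShape = imageShape, classes = character(0),
                 chosenNorm = NA_character_,
                 history = data.frame(), bestEpoch = 0L)
}

bnEps <- 1e-5

# forward pass; returns logits (K x N) and, when backprop = TRUE, all caches
cnnForward <- function(model, images, train = FALSE, backprop = FALSE) {
    cfg <- model@config
    d <- dim(images)
    X0 <- array(images, dim = c(d[1L], d[2L], 1L, d[3L]))
    caches <- vector("list", cfg@branches)
    feats <- vector("list", cfg@branches)
    w <- model@weights
    for (br in seq_len(cfg@branches)) {
        X <- X0
        bcache <- vector("list", cfg@convBlocksPerBranch)
        for (bl in seq_len(cfg@convBlocksPerBranch)) {
            blk <- w$branches[[br]][[bl]]
            Xc <- cpp_conv_fw(X, blk$W, blk$b)
            if (train) {
                st <- cpp_channel_stats(Xc)
                mu <- st$mean
                v <- st$var
                blk$runMean <- 0.9 * blk$runMean + 0.1 * mu
                blk$runVar <- 0.9 * blk$runVar + 0.1 * v
                w$branches[[br]][[bl]] <- blk
            } else {
                mu <- blk$runMean
                v <- blk$runVar
            }
            istd <- 1 / sqrt(v + bnEps)
            head <- cpp_block_head_fw(Xc, blk$gamma, blk$beta, mu, istd,
                                      cfg@poolSize)
            if (backprop)
                bcache[[bl]] <- list(Xin = X, xhat = head$xhat,
                                     istd = istd, poolIdx = head$idx)
            X <- head$Y
        }
        caches[[br]] <- bcache
        feats[[br]] <- matrix(X, ncol = d[3L])
    }
    Z <- do.call(rbind, feats)
    H1 <- w$fc$W1 %*% Z + w$fc$b1
    H1r <- H1 * (H1 > 0)
    logits <- w$fc$W2 %*% H1r + w$fc$b2
    list(logits = logits, Z = Z, H1r = H1r, caches = caches,
         featRows = vapply(feats, nrow, 1L), weights = w)
}

softmaxCols <- function(logits) {
    e <- exp(sweep(logits, 2L, apply(logits, 2L, max)))
    sweep(e, 2L, colSums(e), "/")
}

# full backward pass; returns gradients in the same structure as weights
cnnBackward <- function(model, fw, dlogits) {
    cfg <- model@config
    w <- fw$weights
    g <- list(branches = vector("list", cfg@branches), fc = list())
    g$fc$W2 <- dlogits %*% t(fw$H1r)
    g$fc$b2 <- rowSums(dlogits)
    dH1 <- t(w$fc$W2) %*% dlogits
    dH1[fw$H1r <= 0] <- 0
    g$fc$W1 <- dH1 %*% t(fw$Z)
    g$fc$b1 <- rowSums(dH1)
    dZ <- t(w$fc$W1) %*% dH1
    offset <- 0L
    for (br in seq_len(cfg@branches)) {
        nr <- fw$featRows[br]
        dX <- dZ[offset + seq_len(nr), , drop = FALSE]
        offset <- offset + nr
        gblocks <- vector("list", cfg@convBlocksPerBranch)
        for (bl in rev(seq_len(cfg@convBlocksPerBranch))) {
            cache <- fw$caches[[br]][[bl]]
            blk <- w$branches[[br]][[bl]]
            dPool <- as.numeric(dX)
            bnb <- cpp_block_head_bw(dPool, cache$poolIdx, cache$xhat,
                                     blk$gamma, blk$beta, cache$istd)
            cv <- cpp_conv_bw(cache$Xin, blk$W, bnb$dX)
            gblocks[[bl]] <- list(W = cv$dW, b = cv$db,
                                  gamma = bnb$dgamma, beta = bnb$dbeta)
            dX <- cv$dX
        }
        g$branches[[br]] <- gblocks
    }
    g
}

sgdUpdate <- function(weights, grads, vel, lr, mom) {
    upd <- function(wp, gp, vp) {
        v <- mom * vp - lr * gp
        list(w = wp + v, v = v)
    }
    for (br in seq_along(weights$branches)) {
        for (bl in seq_along(weights$branches[[br]])) {
            for (nm in c("W", "b", "gamma", "beta")) {
                u <- upd(weights$branches[[br]][[bl]][[nm]],
                         grads$branches[[br]][[bl]][[nm]],
                         vel$branches[[br]][[bl]][[nm]])
                weights$branches[[br]][[bl]][[nm]] <- u$w
                vel$branches[[br]][[bl]][[nm]] <- u$v
            }
        }
    }
    for (nm in c("W1", "b1", "W2", "b2")) {
        u <- upd(weights$fc[[nm]], grads$fc[[nm]], vel$fc[[nm]])
        weights$fc[[nm]] <- u$w
        vel$fc[[nm]] <- u$v
    }
    list(weights = weights, vel = vel)
}

zeroVelocity <- function(weights) {
    z <- weights
    for (br in seq_along(z$branches))
        for (bl in seq_along(z$branches[[br]]))
            for (nm in c("W", "b", "gamma", "beta"))
                z$branches[[br]][[bl]][[nm]] <-
                    z$branches[[br]][[bl]][[nm]] * 0
    for (nm in c("W1", "b1", "W2", "b2")) z$fc[[nm]] <- z$fc[[nm]] * 0
    z
}

#' Predict class probabilities
#'
#' Runs the network in inference mode (batch normalization uses running
#' statistics).  Each output row is a probability vector over the classes
#' (softmax), summing to 1.
#'
#' @param model a [ParallelCnn-class].
#' @param images an [ImageStack-class] or m x n x N array.
#' @param batchSize evaluation chunk size.
#' @return N x K matrix of class probabilities; columns named after the
#'   training classes once the model is trained.
#' @export
predictCnn <- function(model, images, batchSize = 256L) {
    stopifnot(methods::is(model, "ParallelCnn"))
    px <- if (methods::is(images, "ImageStack")) imagePixels(images)
          else images
    N <- dim(px)[3L]
    out <- NULL
    for (start in seq(1L, N, by = batchSize)) {
        sel <- start:min(start + batchSize - 1L, N)
        fw <- cnnForward(model, px[, , sel, drop = FALSE], train = FALSE)
        out <- rbind(out, t(softmaxCols(fw$logits)))
    }
    if (length(model@classes)) colnames(out) <- model@classes
    out
}

#' Train a parallel CNN
#'
#' Minibatch SGD with momentum on the softmax cross-entropy.  After every
#' epoch the validation loss and error are computed in inference mode; the
#' returned model carries the weights of the epoch with the lowest
#' validation error (ties go to the earlier epoch), so its validation error
#' is never worse than the final epoch's.  Bit-reproducible for fixed data,
#' config and seed.
#'
#' @param model an untrained [ParallelCnn-class] from [buildParallelCnn()].
#' @param trainImages,valImages [ImageStack-class] stacks with disjoint
#'   sample ids.
#' @param trainLabels,valLabels label vectors (>= 2 classes in training).
#' @param verbose print per-epoch progress.
#' @return A trained [ParallelCnn-class] with \code{history} and
#'   \code{bestEpoch} filled in.
#' @export
trainCnn <- function(model, trainImages, trainLabels, valImages, valLabels,
                     verbose = FALSE) {
    stopifnot(methods::is(model, "ParallelCnn"),
              methods::is(trainImages, "ImageStack"),
              methods::is(valImages, "ImageStack"))
    cfg <- model@config
    trainLabels <- factor(trainLabels)
    if (nlevels(trainLabels) < 2L)
        stop("training labels must contain at least 2 classes")
    classes <- levels(trainLabels)
    valLabels <- factor(valLabels, levels = classes)
    if (anyNA(valLabels))
        stop("validation labels contain classes unseen in training")
    if (length(intersect(trainImages@sampleIds, valImages@sampleIds)) > 0L)
        stop("train and validation stacks share sample ids")
    K <- length(classes)
    if (nrow(model@weights$fc$W2) != K)
        stop("model was built for ", nrow(model@weights$fc$W2),
             " classes but labels have ", K)
    Xtr <- imagePixels(trainImages)
    N <- dim(Xtr)[3L]
    if (N != length(trainLabels))
        stop("trainLabels length must match the image stack")
    y <- as.integer(trainLabels)
    Yhot <- matrix(0, K, N)
    Yhot[cbind(y, seq_len(N))] <- 1
    weights <- model@weights
    vel <- zeroVelocity(weights)
    best <- list(err = Inf, epoch = 0L, weights = weights)
    hist <- vector("list", cfg@maxEpochs)
    withSeed(cfg@seed + 1L, {
        for (epoch in seq_len(cfg@maxEpochs)) {
            perm <- sample(N)
            tot_loss <- 0
            tot_correct <- 0L
            for (start in seq(1L, N, by = cfg@batchSize)) {
                sel <- perm[start:min(start + cfg@batchSize - 1L, N)]
                nb <- length(sel)
                model@weights <- weights
                fw <- cnnForward(model, Xtr[, , sel, drop = FALSE],
                                 train = TRUE, backprop = TRUE)
                weights <- fw$weights          # updated BN running stats
                probs <- softmaxCols(fw$logits)
                loss <- -mean(log(pmax(probs[cbind(y[sel],
                                                   seq_len(nb))], 1e-12)))
                if (!is.finite(loss))
                    stop("non-finite training loss at epoch ", epoch,
                         "; lower the learning rate")
                tot_loss <- tot_loss + loss * nb
                tot_correct <- tot_correct +
                    sum(max.col(t(probs)) == y[sel])
                dlogits <- (probs - Yhot[, sel, drop = FALSE]) / nb
                grads <- cnnBackward(model, fw, dlogits)
                u <- sgdUpdate(weights, grads, vel,
                               cfg@learningRate, cfg@momentum)
                weights <- u$weights
                vel <- u$vel
            }
            model@weights <- weights
            model@classes <- classes
            vp <- predictCnn(model, valImages)
            vy <- as.integer(valLabels)
            vloss <- -mean(log(pmax(vp[cbind(seq_len(nrow(vp)), vy)],
                                    1e-12)))
            verr <- mean(max.col(vp) != vy)
            hist[[epoch]] <- data.frame(
                epoch = epoch, trainLoss = tot_loss / N,
                trainError = 1 - tot_correct / N,
                valLoss = vloss, valError = verr)
            if (verbose)
                message(sprintf(
                    "epoch %d: train loss %.4f err %.3f | val loss %.4f err %.3f",
                    epoch, tot_loss / N, 1 - tot_correct / N, vloss, verr))
            if (verr < best$err - 1e-12) {
                best <- list(err = verr, epoch = epoch, weights = weights)
            }
        }
    })
    model@weights <- best$weights
    model@classes <- classes
    model@history <- do.call(rbind, hist)
    model@bestEpoch <- best$epoch
    model
}

#' @describeIn trainCnn per-epoch training history (data.frame).
#' @export
trainingHistory <- function(model) {
    stopifnot(methods::is(model, "ParallelCnn"))
    model@history
}

setMethod("show", "ParallelCnn", function(object) {
    cfg <- object@config
    cat("ParallelCnn:", cfg@branches, "branches x",
        cfg@convBlocksPerBranch, "conv blocks, kernels",
        paste(cfg@kernelSizePerBranch, collapse = "/"), "\n")
    if (object@bestEpoch > 0L)
        cat("trained:", nrow(object@history), "epochs, best epoch",
            object@bestEpoch, "| classes:",
            paste(object@classes, collapse = ", "), "\n")
    else cat("untrained\n")
})

#' Evaluate a trained classifier
#'
#' Classification accuracy is the percentage of test samples whose predicted
#' class matches the label; the confusion table cross-tabulates true labels
#' (rows) against predictions (columns).
#'
#' @param model a trained [ParallelCnn-class].
#' @param images an [ImageStack-class] of held-out samples.
#' @param labels true labels; must all be classes seen in training.
#' @return list with \code{accuracy} (percent) and \code{confusion} (table).
#' @export
evaluateClassifier <- function(model, images, labels) {
    stopifnot(methods::is(model, "ParallelCnn"))
    if (!length(model@classes)) stop("model is untrained")
    labels <- as.character(labels)
    unknown <- setdiff(unique(labels), model@classes)
    if (length(unknown))
        stop("labels contain classes unseen in training: ",
             paste(unknown, collapse = ", "))
    probs <- predictCnn(model, images)
    pred <- model@classes[max.col(probs)]
    truth <- factor(labels, levels = model@classes)
    predf <- factor(pred, levels = model@classes)
    list(accuracy = 100 * mean(pred == labels),
         confusion = table(truth = truth, predicted = predf))
}

# validation-error argmin with the documented tie-break toward norm1
chooseNorm <- function(valErrors) {
    stopifnot(all(c("norm1", "norm2") %in% names(valErrors)))
    if (valErrors[["norm2"]] < valErrors[["norm1"]]) "norm2" else "norm1"
}

#' Select the normalization by validation error
#'
#' Trains one model per normalization variant with identical configuration
#' and seed (a paired comparison), evaluates both on the validation split,
#' and returns the variant with the lower validation error; an exact tie
#' goes to \code{norm1}.
#'
#' @param transformer an [ImageTransformer-class] fitted on the training
#'   split only.
#' @param train,val [TabularDataset-class] training and validation splits.
#' @param config a [CnnConfig-class] used for both arms.
#' @return list: \code{chosen} (\code{"norm1"} or \code{"norm2"}),
#'   \code{valError} (named numeric, fraction misclassified per arm),
#'   \code{models} (both trained [ParallelCnn-class] objects, with
#'   \code{chosenNorm} set on the winner).
#' @export
selectNormalization <- function(transformer, train, val, config) {
    stopifnot(methods::is(transformer, "ImageTransformer"),
              methods::is(train, "TabularDataset"),
              methods::is(val, "TabularDataset"))
    arms <- c("norm1", "norm2")
    models <- list()
    valError <- c(norm1 = NA_real_, norm2 = NA_real_)
    for (arm in arms) {
        trStack <- transformSamples(transformer, train, norm = arm)
        vaStack <- transformSamples(transformer, val, norm = arm)
        model <- buildParallelCnn(config, dim(imagePixels(trStack))[1:2],
                                  nlevels(factor(sampleLabels(train))))
        fit <- tryCatch(
            trainCnn(model, trStack, sampleLabels(train),
                     vaStack, sampleLabels(val)),
            error = function(e) stop("training failed for ", arm, ": ",
                                     conditionMessage(e)))
        valError[[arm]] <- min(fit@history$valError)
        models[[arm]] <- fit
    }
    chosen <- chooseNorm(valError)
    models[[chosen]]@chosenNorm <- chosen
    list(chosen = chosen, valError = valError, models = models)
}

#' Seeded random search over CNN hyperparameters
#'
#' Samples \code{budget} configurations from a declared search space,
#' evaluates each (by default: train on the training stack, measure the best
#' validation error) and returns the winner with the full trial log.  The
#' sampling sequence is a pure function of the seed, so reruns reproduce the
#' identical trials.  A custom \code{objective(config)} can be injected,
#' e.g. to plug in a Bayesian optimizer's surrogate or a cheap proxy.
#'
#' @param searchSpace named list describing the space.  Each element is
#'   either a vector/list of discrete choices, or \code{list(min =, max =,
#'   log = FALSE)} for a continuous range (log-uniform when \code{log =
#'   TRUE}).  Names must be \code{cnnConfig()} arguments.
#' @param budget number of configurations to try (>= 1).
#' @param trainImages,trainLabels,valImages,valLabels data for the default
#'   objective; may be omitted when \code{objective} is supplied.
#' @param seed integer seed for the sampling sequence.
#' @param baseConfig a [CnnConfig-class] providing unsampled fields.
#' @param objective optional function(CnnConfig) -> numeric validation error.
#' @return list: \code{best} ([CnnConfig-class]), \code{bestError},
#'   \code{trials} (data.frame log with one row per trial).
#' @export
tuneHyperparameters <- function(searchSpace, budget, trainImages = NULL,
                                trainLabels = NULL, valImages = NULL,
                                valLabels = NULL, seed = 1L,
                                baseConfig = cnnConfig(),
                                objective = NULL) {
    if (length(searchSpace) == 0L) stop("search space is empty")
    if (is.null(names(searchSpace)) || any(names(searchSpace) == ""))
        stop("search space entries must be named")
    budget <- as.integer(budget)
    stopifnot(budget >= 1L)
    if (is.null(objective)) {
        if (is.null(trainImages) || is.null(valImages))
            stop("supply train/validation data or an objective function")
        objective <- function(cfg) {
            model <- buildParallelCnn(
                cfg, dim(imagePixels(trainImages))[1:2],
                nlevels(factor(trainLabels)))
            fit <- trainCnn(model, trainImages, trainLabels,
                            valImages, valLabels)
            min(fit@history$valError)
        }
    }
    samples <- withSeed(seed, {
        lapply(seq_len(budget), function(i)
            lapply(searchSpace, sampleSpaceEntry))
    })
    errs <- numeric(budget)
    cfgs <- vector("list", budget)
    for (i in seq_len(budget)) {
        cfgs[[i]] <- modifyConfig(baseConfig, samples[[i]])
        errs[i] <- objective(cfgs[[i]])
    }
    bestIdx <- which.min(errs)
    trials <- data.frame(
        trial = seq_len(budget), valError = errs,
        config = vapply(samples, function(s)
            paste(names(s), vapply(s, function(v)
                paste(signif(unlist(v), 4), collapse = "/"), ""),
                sep = "=", collapse = "; "), ""))
    list(best = cfgs[[bestIdx]], bestError = errs[bestIdx], trials = trials)
}

sampleSpaceEntry <- function(entry) {
    if (is.list(entry) && !is.null(entry$min)) {
        if (isTRUE(entry$log))
            exp(runif(1L, log(entry$min), log(entry$max)))
        else runif(1L, entry$min, entry$max)
    } else {
        entry[[sample.int(length(entry), 1L)]]
    }
}

modifyConfig <- function(baseConfig, fields) {
    args <- list(branches = baseConfig@branches,
                 convBlocksPerBranch = baseConfig@convBlocksPerBranch,
                 filtersPerBlock = baseConfig@filtersPerBlock,
                 kernelSizePerBranch = baseConfig@kernelSizePerBranch,
                 poolSize = baseConfig@poolSize,
                 fcUnits = baseConfig@fcUnits,
                 learningRate = baseConfig@learningRate,
                 momentum = baseConfig@momentum,
                 batchSize = baseConfig@batchSize,
                 maxEpochs = baseConfig@maxEpochs,
                 seed = baseConfig@seed)
    for (nm in names(fields)) {
        if (!nm %in% names(args)) stop("unknown config field '", nm, "'")
        args[[nm]] <- fields[[nm]]
    }
    do.call(cnnConfig, args)
}
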