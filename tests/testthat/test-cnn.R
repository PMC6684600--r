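test_that("configuration invariants are enforced", {
    expect_error(cnnConfig(kernelSizePerBranch = c(3L, 3L)),
                 "differ across branches")
    expect_error(cnnConfig(kernelSizePerBranch = c(4L, 6L)), "odd")
    expect_error(cnnConfig(learningRate = 0), "learningRate")
    expect_error(cnnConfig(filtersPerBlock = c(16L, 32L)),
                 "one entry per block")
    expect_s4_class(cnnConfig(), "CnnConfig")
})

test_that("the default architecture has two branches of four conv blocks", {
    model <- buildParallelCnn(cnnConfig(), c(120, 120), 2)
    expect_length(model@weights$branches, 2L)
    expect_length(model@weights$branches[[1]], 4L)
    expect_length(model@weights$branches[[2]], 4L)
    # each block carries conv + batch-norm parameters
    expect_named(model@weights$branches[[1]][[1]],
                 c("W", "b", "gamma", "beta", "runMean", "runVar"))
    # one fully connected layer and one softmax head
    expect_named(model@weights$fc, c("W1", "b1", "W2", "b2"))
    # branch kernel sizes differ
    expect_equal(dim(model@weights$branches[[1]][[1]]$W)[1], 3L)
    expect_equal(dim(model@weights$branches[[2]][[1]]$W)[1], 5L)
})

test_that("pooling feasibility is traced through the blocks", {
    cfg <- cnnConfig()
    expect_s4_class(buildParallelCnn(cfg, c(16, 16), 2), "ParallelCnn")
    expect_error(buildParallelCnn(cfg, c(8, 8), 2), "minimum feasible.*16")
    expect_error(buildParallelCnn(cfg, c(120, 8), 2), "too small")
})

test_that("untrained network outputs lie on the probability simplex", {
    model <- buildParallelCnn(tinyCnnConfig(), c(16, 16), 3)
    set.seed(20)
    imgs <- array(runif(16 * 16 * 5), dim = c(16, 16, 5))
    probs <- predictCnn(model, imgs)
    expect_equal(dim(probs), c(5L, 3L))
    expect_true(all(probs >= 0))
    expect_equal(rowSums(probs), rep(1, 5), tolerance = 1e-6)
})

test_that("backpropagation matches numerical gradients", {
    set.seed(21)
    cfg <- tinyCnnConfig(batchSize = 4L)
    model <- buildParallelCnn(cfg, c(8, 8), 2)
    N <- 4L
    X <- array(runif(8 * 8 * N), dim = c(8, 8, N))
    y <- c(1L, 2L, 1L, 2L)
    Yhot <- matrix(0, 2, N); Yhot[cbind(y, 1:N)] <- 1
    lossOf <- function(m) {
        fw <- tabimage:::cnnForward(m, X, train = TRUE, backprop = TRUE)
        p <- tabimage:::softmaxCols(fw$logits)
        list(loss = -mean(log(p[cbind(y, 1:N)])), fw = fw, p = p)
    }
    base <- lossOf(model)
    g <- tabimage:::cnnBackward(model, base$fw, (base$p - Yhot) / N)
    paths <- list(
        list(get = function(m) m@weights$branches[[1]][[1]]$W,
             set = function(m, i, v) { m@weights$branches[[1]][[1]]$W[i] <- v; m },
             grad = g$branches[[1]][[1]]$W),
        list(get = function(m) m@weights$branches[[2]][[2]]$gamma,
             set = function(m, i, v) { m@weights$branches[[2]][[2]]$gamma[i] <- v; m },
             grad = g$branches[[2]][[2]]$gamma),
        list(get = function(m) m@weights$fc$W1,
             set = function(m, i, v) { m@weights$fc$W1[i] <- v; m },
             grad = g$fc$W1))
    for (p in paths) {
        w0 <- p$get(model)
        for (i in sample(length(w0), 3)) {
            eps <- 1e-5
            lp <- lossOf(p$set(model, i, w0[i] + eps))$loss
            lm <- lossOf(p$set(model, i, w0[i] - eps))$loss
            num <- (lp - lm) / (2 * eps)
            expect_equal(p$grad[i], num, tolerance = 1e-4)
        }
    }
})

test_that("a small network overfits a separable 20-image stack", {
    ds <- makeBlobDataset(nSamples = 40, seed = 22)
    tr <- fitTransformer(ds, 16, 16, method = "kpca", seed = 1)
    idx_train <- 1:20
    idx_val <- 21:40
    trS <- transformSamples(tr, subsetSamples(ds, idx_train), "norm1")
    vaS <- transformSamples(tr, subsetSamples(ds, idx_val), "norm1")
    cfg <- tinyCnnConfig(maxEpochs = 20L, batchSize = 10L,
                         learningRate = 0.05)
    model <- buildParallelCnn(cfg, c(16, 16), 2)
    fit <- trainCnn(model, trS, sampleLabels(ds)[idx_train],
                    vaS, sampleLabels(ds)[idx_val])
    hist <- trainingHistory(fit)
    expect_equal(min(hist$trainError), 0)
    # best-epoch selection: returned state is never worse than the final one
    expect_lte(min(hist$valError), hist$valError[nrow(hist)])
})

test_that("training is reproducible and rejects degenerate inputs", {
    ds <- makeBlobDataset(nSamples = 30, seed = 23)
    tr <- fitTransformer(ds, 16, 16, method = "kpca", seed = 2)
    trS <- transformSamples(tr, subsetSamples(ds, 1:20), "norm1")
    vaS <- transformSamples(tr, subsetSamples(ds, 21:30), "norm1")
    cfg <- tinyCnnConfig(maxEpochs = 3L)
    run <- function() {
        m <- buildParallelCnn(cfg, c(16, 16), 2)
        trainCnn(m, trS, sampleLabels(ds)[1:20],
                 vaS, sampleLabels(ds)[21:30])
    }
    a <- run(); b <- run()
    expect_identical(trainingHistory(a), trainingHistory(b))
    expect_identical(a@bestEpoch, b@bestEpoch)
    expect_identical(a@weights, b@weights)

    m <- buildParallelCnn(cfg, c(16, 16), 2)
    expect_error(trainCnn(m, trS, rep("a", 20), vaS, rep("a", 10)),
                 "at least 2 classes")
    expect_error(trainCnn(m, trS, sampleLabels(ds)[1:20],
                          trS, sampleLabels(ds)[1:20]),
                 "share sample ids")
})

test_that("normalization choice is the validation-error argmin, ties to norm1", {
    expect_equal(tabimage:::chooseNorm(c(norm1 = 0.10, norm2 = 0.20)), "norm1")
    expect_equal(tabimage:::chooseNorm(c(norm1 = 0.30, norm2 = 0.05)), "norm2")
    expect_equal(tabimage:::chooseNorm(c(norm1 = 0.15, norm2 = 0.15)), "norm1")

    ds <- makeBlobDataset(nSamples = 60, seed = 24)
    tr <- fitTransformer(subsetSamples(ds, 1:40), 16, 16,
                         method = "kpca", seed = 3)
    sel <- selectNormalization(tr, subsetSamples(ds, 1:40),
                               subsetSamples(ds, 41:60),
                               tinyCnnConfig(maxEpochs = 3L))
    expect_true(sel$chosen %in% c("norm1", "norm2"))
    expect_equal(sel$chosen, tabimage:::chooseNorm(sel$valError))
    expect_equal(sel$models[[sel$chosen]]@chosenNorm, sel$chosen)
    expect_length(sel$models, 2L)
})

test_that("random search is seeded and finds the injected optimum", {
    space <- list(learningRate = list(min = 1e-4, max = 1, log = TRUE),
                  batchSize = c(8L, 16L, 32L))
    oracle <- function(cfg) abs(cfg@learningRate - 0.01)

    one <- tuneHyperparameters(space, budget = 1, seed = 30,
                               objective = oracle)
    expect_s4_class(one$best, "CnnConfig")
    expect_equal(nrow(one$trials), 1L)

    a <- tuneHyperparameters(space, budget = 8, seed = 31, objective = oracle)
    b <- tuneHyperparameters(space, budget = 8, seed = 31, objective = oracle)
    expect_identical(a$trials, b$trials)
    expect_equal(a$best@learningRate, b$best@learningRate)
    # the winner is the sampled rate closest to 0.01
    expect_equal(a$bestError, min(a$trials$valError))

    expect_error(tuneHyperparameters(list(), 3, objective = oracle), "empty")
})

test_that("accuracy equals the counting oracle and errors on unknown labels", {
    ds <- makeBlobDataset(nSamples = 40, seed = 25)
    tr <- fitTransformer(subsetSamples(ds, 1:30), 16, 16,
                         method = "kpca", seed = 4)
    trS <- transformSamples(tr, subsetSamples(ds, 1:20), "norm1")
    vaS <- transformSamples(tr, subsetSamples(ds, 21:30), "norm1")
    model <- buildParallelCnn(tinyCnnConfig(maxEpochs = 2L), c(16, 16), 2)
    fit <- trainCnn(model, trS, sampleLabels(ds)[1:20],
                    vaS, sampleLabels(ds)[21:30])
    teS <- transformSamples(tr, subsetSamples(ds, 31:40), "norm1")
    probs <- predictCnn(fit, teS)
    pred <- fit@classes[max.col(probs)]

    ev_match <- evaluateClassifier(fit, teS, pred)      # labels == predictions
    expect_equal(ev_match$accuracy, 100)
    expect_equal(sum(ev_match$confusion) - sum(diag(ev_match$confusion)), 0)

    flipped <- ifelse(pred == fit@classes[1], fit@classes[2], fit@classes[1])
    ev_flip <- evaluateClassifier(fit, teS, flipped)
    expect_equal(ev_flip$accuracy, 0)
    expect_equal(sum(diag(ev_flip$confusion)), 0)
    expect_equal(sum(ev_flip$confusion), 10)

    truth <- sampleLabels(ds)[31:40]
    ev <- evaluateClassifier(fit, teS, truth)
    expect_equal(ev$accuracy, 100 * mean(pred == as.character(truth)))
    expect_equal(sum(ev$confusion), 10)

    expect_error(evaluateClassifier(fit, teS, rep("mystery", 10)),
                 "unseen in training")
})
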