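test_that("ringnorm moments match the generative model", {
    ds <- generateRingnorm(10000, seed = 7)
    X <- sampleValues(ds)
    lab <- sampleLabels(ds)
    expect_equal(dim(X), c(10000L, 20L))
    expect_equal(unname(table(lab)[["class1"]]), 5000L)

    v1 <- apply(X[lab == "class1", ], 2, var)
    expect_true(all(v1 > 3.7 & v1 < 4.3))
    m1 <- colMeans(X[lab == "class1", ])
    expect_true(all(abs(m1) < 0.1))
    m2 <- colMeans(X[lab == "class2", ])
    expect_true(all(abs(m2 - 2 / sqrt(20)) < 0.05))
    v2 <- apply(X[lab == "class2", ], 2, var)
    expect_true(all(v2 > 0.9 & v2 < 1.1))
})

test_that("the exact Bayes rule error matches its frozen reference", {
    ds <- generateRingnorm(10000, seed = 7)
    err <- ringnormBayesError(ds)
    # frozen from the closed-form log-density-ratio rule on this draw; the
    # separability reference for pipeline accuracy expectations
    expect_equal(err, 1.15, tolerance = 1e-12)
    expect_lt(err, 3)
})

test_that("generators are bit-reproducible and validate their inputs", {
    expect_identical(sampleValues(generateRingnorm(100, seed = 2)),
                     sampleValues(generateRingnorm(100, seed = 2)))
    expect_error(generateRingnorm(101, seed = 1), "even")
    expect_identical(
        sampleValues(generateMadelonLike(50, seed = 3)),
        sampleValues(generateMadelonLike(50, seed = 3)))
    expect_identical(
        sampleValues(generateBlockCorrelated(50, seed = 4)),
        sampleValues(generateBlockCorrelated(50, seed = 4)))
})

test_that("madelon-like labels are nonlinear: trees beat linear models", {
    skip_if_not_installed("rpart")
    ds <- generateMadelonLike(nSamples = 600, nInformative = 2,
                              nRedundant = 0, nNoise = 0, seed = 1)
    df <- data.frame(sampleValues(ds), y = sampleLabels(ds))
    lin <- stats::glm(y ~ ., data = df, family = binomial)
    lin_acc <- mean((predict(lin, type = "response") > 0.5) ==
                        (df$y == levels(df$y)[2]))
    tree <- rpart::rpart(y ~ ., data = df,
                         control = rpart::rpart.control(maxdepth = 4))
    tree_acc <- mean(predict(tree, type = "class") == df$y)
    expect_lt(lin_acc, 0.65)    # linear stays near chance
    expect_gt(tree_acc, 0.85)   # a shallow tree finds the XOR structure
})

test_that("redundant madelon features are linear images of informative ones", {
    ds <- generateMadelonLike(nSamples = 300, nInformative = 3,
                              nRedundant = 4, nNoise = 2, seed = 2)
    X <- sampleValues(ds)
    inf <- X[, 1:3]
    for (j in 4:7) {
        fit <- stats::lm(X[, j] ~ inf)
        r2 <- 1 - sum(resid(fit)^2) / sum((X[, j] - mean(X[, j]))^2)
        expect_gt(r2, 0.99)
    }
})

test_that("block-correlated features have the requested correlation", {
    ds <- generateBlockCorrelated(nSamples = 2000, nBlocks = 3,
                                  featuresPerBlock = 10, withinCorr = 0.95,
                                  seed = 5)
    C <- cor(sampleValues(ds))
    blk <- rep(1:3, each = 10)
    within <- C[outer(blk, blk, "==") & upper.tri(C)]
    between <- C[outer(blk, blk, "!=") & upper.tri(C)]
    expect_gt(mean(within), 0.9)
    expect_lt(mean(within), 1.0)
    expect_lt(mean(abs(between)), 0.1)

    ds0 <- generateBlockCorrelated(nSamples = 2000, nBlocks = 3,
                                   featuresPerBlock = 10, withinCorr = 0,
                                   seed = 6)
    C0 <- cor(sampleValues(ds0))
    expect_lt(mean(abs(C0[upper.tri(C0)])), 0.1)
})

test_that("zero class shift carries no class signal", {
    ds <- generateBlockCorrelated(nSamples = 400, nBlocks = 2,
                                  featuresPerBlock = 10, withinCorr = 0.5,
                                  classShift = 0, seed = 7)
    X <- sampleValues(ds)
    lab <- sampleLabels(ds)
    obs <- abs(mean(X[lab == "class1", 1:10]) - mean(X[lab == "class2", 1:10]))
    set.seed(1)
    perm <- replicate(200, {
        p <- sample(lab)
        abs(mean(X[p == "class1", 1:10]) - mean(X[p == "class2", 1:10]))
    })
    expect_gt(mean(perm >= obs), 0.01)   # observed gap is unremarkable
})

test_that("splits are 80:10:10, disjoint, exhaustive and seeded", {
    ds <- generateRingnorm(1000, seed = 1)
    sp <- splitDataset(ds, seed = 2)
    expect_length(trainIdx(sp), 800L)
    expect_length(valIdx(sp), 100L)
    expect_length(testIdx(sp), 100L)
    all_idx <- c(trainIdx(sp), valIdx(sp), testIdx(sp))
    expect_equal(sort(all_idx), 1:1000)

    # odd n: within one sample of the exact proportions
    ds103 <- TabularDataset(matrix(rnorm(103 * 4), 103, 4),
                            rep(c("a", "b"), length.out = 103))
    sp103 <- splitDataset(ds103, seed = 3)
    expect_lte(abs(length(trainIdx(sp103)) - 82.4), 1)
    expect_lte(abs(length(valIdx(sp103)) - 10.3), 1)
    expect_lte(abs(length(testIdx(sp103)) - 10.3), 1)
    expect_equal(sort(c(trainIdx(sp103), valIdx(sp103), testIdx(sp103))),
                 1:103)

    # determinism and reshuffling
    expect_identical(trainIdx(splitDataset(ds, seed = 2)), trainIdx(sp))
    sp2 <- splitDataset(ds, seed = 9)
    expect_false(identical(trainIdx(sp2), trainIdx(sp)))
    expect_length(trainIdx(sp2), 800L)
})

test_that("stratified splits preserve class proportions within one sample", {
    labels <- rep(c("a", "b"), times = c(300, 200))
    ds <- TabularDataset(matrix(rnorm(500 * 3), 500, 3), labels)
    sp <- splitDataset(ds, seed = 4, stratified = TRUE)
    lab <- as.character(sampleLabels(ds))
    for (idx in list(trainIdx(sp), valIdx(sp), testIdx(sp))) {
        na <- sum(lab[idx] == "a")
        expect_lte(abs(na - 0.6 * length(idx)), 1)
    }
    tiny <- TabularDataset(matrix(rnorm(24), 12, 2),
                           c(rep("a", 10), "b", "b"))
    expect_error(splitDataset(tiny, seed = 1, stratified = TRUE),
                 ">= 3 samples per class")
})
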