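test_that("linear-kernel kPCA preserves distances of a rank-2 configuration", {
    set.seed(2)
    basis <- matrix(rnorm(2 * 30), 2, 30)
    G <- matrix(rnorm(10 * 2), 10, 2) %*% basis  # 10 profiles in a 2D subspace
    fc <- embedFeatures(G, method = "kpca",
                        params = list(kernel = "vanilladot"), seed = 1)
    expect_lt(max(abs(dist(coords(fc)) - dist(G))), 1e-6)
})

test_that("identical feature profiles embed to identical coordinates", {
    set.seed(3)
    G <- matrix(rnorm(8 * 25), 8, 25)
    G <- rbind(G, G[2, ])
    fc <- embedFeatures(G, method = "kpca", seed = 1)
    expect_identical(coords(fc)[2, ], coords(fc)[9, ])
})

test_that("t-SNE pulls correlated feature blocks into clusters", {
    ds <- generateBlockCorrelated(nSamples = 500, nBlocks = 3,
                                  featuresPerBlock = 20, withinCorr = 0.95,
                                  seed = 1)
    fc <- embedFeatures(ds, method = "tsne", seed = 0)
    gap <- blockDistanceGap(as.matrix(dist(coords(fc))),
                            rep(1:3, each = 20))
    expect_lt(gap[["within"]], gap[["between"]])
})

test_that("embeddings are bit-reproducible under a fixed seed", {
    ds <- generateBlockCorrelated(nSamples = 100, nBlocks = 2,
                                  featuresPerBlock = 10, withinCorr = 0.8,
                                  seed = 4)
    a <- embedFeatures(ds, method = "tsne", seed = 9)
    b <- embedFeatures(ds, method = "tsne", seed = 9)
    expect_identical(coords(a), coords(b))
    ka <- embedFeatures(ds, method = "kpca", seed = 9)
    kb <- embedFeatures(ds, method = "kpca", seed = 9)
    expect_identical(coords(ka), coords(kb))
})

test_that("coordinate matrix is finite with one ordered row per feature", {
    ds <- generateRingnorm(80, seed = 6)
    fc <- embedFeatures(ds, method = "tsne", seed = 2)
    co <- coords(fc)
    expect_equal(dim(co), c(20L, 2L))
    expect_true(all(is.finite(co)))
    expect_identical(rownames(co), featureIds(ds))
})

test_that("t-SNE refuses fewer than 3 features and points at kPCA", {
    G <- matrix(rnorm(2 * 10), 2, 10)
    expect_error(embedFeatures(G, method = "tsne", seed = 1), "kpca")
    expect_silent(fc <- embedFeatures(G, method = "kpca", seed = 1))
    expect_equal(nrow(coords(fc)), 2L)
})
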