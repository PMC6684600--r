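test_that("fitting on ringnorm yields an in-frame location map", {
    ds <- generateRingnorm(200, seed = 1)
    tr <- fitTransformer(ds, frameRows = 120, frameCols = 120,
                         method = "tsne", seed = 0)
    map <- locationMap(tr)
    pa <- pixelAssignments(map)
    expect_equal(nrow(pa), 20L)
    expect_true(all(pa$row >= 0 & pa$row < 120))
    expect_true(all(pa$col >= 0 & pa$col < 120))
    expect_lte(length(collisionGroups(map)), 20L)
})

test_that("refitting with identical data, config and seed is bit-identical", {
    ds <- generateRingnorm(150, seed = 2)
    a <- fitTransformer(ds, 32, 32, method = "tsne", seed = 5)
    b <- fitTransformer(ds, 32, 32, method = "tsne", seed = 5)
    expect_identical(pixelAssignments(locationMap(a)),
                     pixelAssignments(locationMap(b)))
    expect_identical(imagePixels(transformSamples(a, ds, "norm1")),
                     imagePixels(transformSamples(b, ds, "norm1")))
})

test_that("a serialized transformer reproduces bit-identical images", {
    ds <- generateRingnorm(100, seed = 3)
    tr <- fitTransformer(ds, 24, 24, method = "kpca", seed = 4)
    path <- withr::local_tempfile(fileext = ".rds")
    saveTransformer(tr, path)
    back <- loadTransformer(path)
    expect_identical(imagePixels(transformSamples(back, ds, "norm2")),
                     imagePixels(transformSamples(tr, ds, "norm2")))
    expect_error(loadTransformer(withr::local_tempfile(fileext = ".rds") |>
                                     (\(p) { saveRDS(1:3, p); p })()),
                 "not a transformer archive")
})

test_that("collision pixels hold the mean of their group", {
    # two features with identical profiles share a pixel; mean is forced
    set.seed(16)
    prof <- rnorm(30)
    X <- cbind(prof, prof, rnorm(30), rnorm(30))
    ds <- TabularDataset(X, rep(c("a", "b"), 15))
    tr <- fitTransformer(ds, 8, 8, method = "kpca", seed = 1)
    map <- locationMap(tr)
    expect_true(any(lengths(collisionGroups(map)) >= 2))

    # replace the shared-pixel features' normalized values by construction:
    # a sample whose normalized values are v1, v2 at one pixel gives (v1+v2)/2
    z <- applyNorm(normParams(tr, "norm1"), ds)
    img <- imagePixels(transformSamples(tr, ds, "norm1"))[, , 1]
    oracle <- imageOracle(map, z[1, ])
    expect_equal(img, oracle, tolerance = 1e-12)
})

test_that("occupied pixels of a uniform sample share its value", {
    ds <- generateRingnorm(60, seed = 6)
    tr <- fitTransformer(ds, 16, 16, method = "kpca", seed = 2)
    # craft a sample halfway between training min and max of every feature
    p <- normParams(tr, "norm1")
    mid <- (p@featureMin + p@featureMax) / 2
    img <- imagePixels(transformSamples(tr, rbind(mid), "norm1"))[, , 1]
    occupied <- img[img != 0]
    expect_true(all(abs(occupied - 0.5) < 1e-12))
    # and the training minimum maps to an all-background image
    img0 <- imagePixels(transformSamples(tr, rbind(p@featureMin), "norm1"))
    expect_true(all(img0 == 0))
})

test_that("images match a group-by-pixel oracle on random samples", {
    set.seed(17)
    ds <- TabularDataset(matrix(rnorm(40 * 50), 40, 50),
                         rep(c("a", "b"), 20))
    tr <- fitTransformer(ds, 8, 8, method = "tsne", seed = 3)
    z <- applyNorm(normParams(tr, "norm2"), ds)
    stack <- transformSamples(tr, ds, "norm2")
    for (i in c(1, 17, 40))
        expect_equal(imagePixels(stack)[, , i],
                     imageOracle(locationMap(tr), z[i, ]), tolerance = 1e-12)
    expect_true(all(imagePixels(stack) >= 0 & imagePixels(stack) <= 1))
})

test_that("transforming held-out samples never mutates the fitted state", {
    ds <- generateRingnorm(120, seed = 7)
    sp <- splitDataset(ds, seed = 8)
    tr <- fitTransformer(subsetSamples(ds, trainIdx(sp)), 16, 16,
                         method = "kpca", seed = 9)
    before <- serialize(tr, NULL)
    invisible(transformSamples(tr, subsetSamples(ds, testIdx(sp)), "norm1"))
    invisible(transformSamples(tr, subsetSamples(ds, valIdx(sp)), "norm2"))
    expect_identical(serialize(tr, NULL), before)
})

test_that("dimension mismatches are rejected with the expected d", {
    ds <- generateRingnorm(50, seed = 1)
    tr <- fitTransformer(ds, 16, 16, method = "kpca", seed = 1)
    expect_error(transformSamples(tr, matrix(0, 2, 7), "norm1"),
                 "expects 20")
})
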