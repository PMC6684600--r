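test_that("convex hull finds the extreme points counter-clockwise", {
    sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5))
    h <- convexHull(sq)
    expect_setequal(h, 1:4)
    tri <- rbind(c(0, 0), c(2, 0), c(1, 3))
    expect_setequal(convexHull(tri), 1:3)
    # counter-clockwise: positive signed area
    expect_gt(tabimage:::signedArea(sq[h, ]), 0)
})

test_that("every point satisfies the hull half-plane inequalities", {
    set.seed(10)
    r <- sqrt(runif(200))
    th <- runif(200, 0, 2 * pi)
    P <- cbind(r * cos(th), r * sin(th))
    h <- convexHull(P)
    H <- P[h, , drop = FALSE]
    nh <- nrow(H)
    for (i in seq_len(nh)) {      # CCW edge: interior on the left
        a <- H[i, ]
        b <- H[if (i == nh) 1L else i + 1L, ]
        cross <- (b[1] - a[1]) * (P[, 2] - a[2]) -
                 (b[2] - a[2]) * (P[, 1] - a[1])
        expect_true(all(cross >= -1e-9))
    }
})

test_that("degenerate point sets raise a typed geometry error", {
    line <- cbind(1:5, 2 * (1:5) + 1)
    expect_error(convexHull(line), class = "degenerateGeometryError")
    expect_error(convexHull(rbind(c(0, 0), c(1, 1))),
                 class = "degenerateGeometryError")
    expect_error(minAreaRectangle(line), class = "degenerateGeometryError")
})

test_that("minimum rectangle of squares has the expected area and angle", {
    sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
    r <- minAreaRectangle(sq)
    expect_equal(rectangleArea(r), 1, tolerance = 1e-9)
    expect_equal(r@angle %% (pi / 2), 0, tolerance = 1e-9)

    rot45 <- rotateCoordinates(sq, pi / 4)
    r45 <- minAreaRectangle(rot45)
    expect_equal(rectangleArea(r45), 1, tolerance = 1e-9)
    expect_equal(r45@angle, pi / 4, tolerance = 1e-9)
    expect_true(rectangleContains(r45, rot45))
})

test_that("calipers area matches the edge-sweep oracle on random clouds", {
    set.seed(11)
    for (rep in 1:20) {
        n <- sample(3:120, 1)
        P <- cbind(rnorm(n), rnorm(n))
        if (inherits(try(convexHull(P), silent = TRUE), "try-error")) next
        r <- minAreaRectangle(P)
        expect_equal(rectangleArea(r), minRectAreaOracle(P),
                     tolerance = 1e-9)
        expect_true(rectangleContains(r, P))
        expect_lte(rectangleArea(r),
                   diff(range(P[, 1])) * diff(range(P[, 2])) + 1e-9)
    }
})

test_that("rotation is an isometry and behaves on canonical cases", {
    expect_equal(drop(rotateCoordinates(rbind(c(1, 0)), pi / 2)), c(0, 1),
                 tolerance = 1e-12)
    P <- cbind(rnorm(40), rnorm(40))
    expect_equal(rotateCoordinates(P, 0), P)
    Q <- rotateCoordinates(P, 0.7)
    expect_lt(max(abs(dist(P) - dist(Q))), 1e-9)
})

test_that("rotating by the negative rectangle angle squares up the cloud", {
    set.seed(12)
    P <- cbind(rnorm(50), rnorm(50)) %*% matrix(c(2, 1, 0.5, 1), 2)
    r <- minAreaRectangle(P)
    Pr <- rotateCoordinates(P, -r@angle)
    # the axis-aligned bounding box of the rotated points has minimal area
    expect_equal(diff(range(Pr[, 1])) * diff(range(Pr[, 2])),
                 rectangleArea(r), tolerance = 1e-9)
})
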