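#' Convex hull of a 2D point set
#'
#' Returns the indices of the hull vertices in counter-clockwise order.
#' Degenerate inputs (fewer than 3 distinct points, or all points collinear)
#' raise a \code{degenerateGeometryError} advising a kPCA embedding or a
#' small jitter, rather than silently perturbing the geometry.
#'
#' @param points numeric matrix with 2 columns (x, y), one row per point.
#' @return integer vector of 1-based row indices of \code{points}, ordered
#'   counter-clockwise around the hull.
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0.5, 0.5))
#' convexHull(sq)   # the four corners
#' @export
convexHull <- function(points) {
    points <- as.matrix(points)
    if (ncol(points) != 2L) stop("'points' must have 2 columns")
    if (nrow(points) < 3L)
        degenerateGeometryError(
            "convex hull needs at least 3 points; jitter the coordinates or use a kPCA embedding")
    h <- grDevices::chull(points[, 1L], points[, 2L])
    if (length(h) < 3L || polygonArea(points[h, , drop = FALSE]) <= 0)
        degenerateGeometryError(
            "all points are collinear or coincident; add a tiny jitter or use a kPCA embedding")
    # chull returns clockwise order; reverse for counter-clockwise
    if (signedArea(points[h, , drop = FALSE]) < 0) h <- rev(h)
    h
}

signedArea <- function(P) {
    n <- nrow(P)
    j <- c(2:n, 1L)
    sum(P[, 1L] * P[j, 2L] - P[j, 1L] * P[, 2L]) / 2
}

polygonArea <- function(P) abs(signedArea(P))

#' Rotate 2D coordinates about the origin
#'
#' An exact isometry: all pairwise distances are preserved.
#'
#' @param coordsMat numeric matrix with 2 columns.
#' @param angle rotation angle in radians (counter-clockwise).
#' @return rotated matrix of the same shape.
#' @export
rotateCoordinates <- function(coordsMat, angle) {
    coordsMat <- as.matrix(coordsMat)
    R <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L, 2L)
    out <- coordsMat %*% t(R)
    dimnames(out) <- dimnames(coordsMat)
    out
}

#' Minimum-area enclosing rectangle
#'
#' Finds the smallest-area rectangle (of arbitrary orientation) containing
#' all points, by the rotating-calipers principle: the optimal rectangle has
#' one side collinear with a convex-hull edge, so it suffices to sweep the
#' hull-edge orientations and take the best axis-aligned bounding box in each
#' rotated frame.  Ties in area are broken toward the smaller angle so the
#' result is deterministic.
#'
#' @param points numeric matrix with 2 columns; at least 3 non-collinear
#'   points.
#' @return A [RotatedRectangle-class] with angle in [0, pi/2).
#' @examples
#' sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
#' rectangleArea(minAreaRectangle(sq))   # 1
#' @export
minAreaRectangle <- function(points) {
    points <- as.matrix(points)
    h <- convexHull(points)               # errors on degenerate input
    H <- points[h, , drop = FALSE]
    nh <- nrow(H)
    edges <- H[c(2:nh, 1L), ] - H
    angles <- atan2(edges[, 2L], edges[, 1L]) %% (pi / 2)
    angles <- sort(unique(round(angles, 12L)))
    best <- NULL
    for (th in angles) {
        Hr <- rotateCoordinates(H, -th)
        w <- diff(range(Hr[, 1L]))
        hgt <- diff(range(Hr[, 2L]))
        area <- w * hgt
        if (is.null(best) || area < best$area - 1e-12) {
            cr <- c(mean(range(Hr[, 1L])), mean(range(Hr[, 2L])))
            best <- list(area = area, angle = th,
                         half = c(w, hgt) / 2,
                         center = drop(rotateCoordinates(rbind(cr), th)))
        }
    }
    methods::new("RotatedRectangle", center = best$center,
                 halfExtents = best$half, angle = best$angle %% (pi / 2))
}

#' @describeIn minAreaRectangle area of a [RotatedRectangle-class].
#' @param rect a [RotatedRectangle-class].
#' @export
rectangleArea <- function(rect) {
    stopifnot(methods::is(rect, "RotatedRectangle"))
    4 * rect@halfExtents[1L] * rect@halfExtents[2L]
}

#' @describeIn minAreaRectangle the four corner points (counter-clockwise) of
#'   a [RotatedRectangle-class].
#' @export
rectangleCorners <- function(rect) {
    stopifnot(methods::is(rect, "RotatedRectangle"))
    hx <- rect@halfExtents[1L]
    hy <- rect@halfExtents[2L]
    base <- rbind(c(-hx, -hy), c(hx, -hy), c(hx, hy), c(-hx, hy))
    sweep(rotateCoordinates(base, rect@angle), 2L, rect@center, "+")
}

#' @describeIn minAreaRectangle does the rectangle contain the points (within
#'   tolerance)?
#' @param tol containment tolerance.
#' @export
rectangleContains <- function(rect, points, tol = 1e-9) {
    stopifnot(methods::is(rect, "RotatedRectangle"))
    P <- rotateCoordinates(sweep(as.matrix(points), 2L, rect@center),
                           -rect@angle)
    all(abs(P[, 1L]) <= rect@halfExtents[1L] + tol &
        abs(P[, 2L]) <= rect@halfExtents[2L] + tol)
}
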