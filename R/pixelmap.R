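#' Discretize Cartesian feature coordinates to a pixel frame
#'
#' Linearly rescales the (already rotated) feature coordinates into an
#' m x n pixel grid and rounds (half away from zero) to 0-based pixel
#' indices, using the image convention that row 0 is the top of the frame
#' (the y axis is flipped).  The x and y axes are scaled independently so the
#' point cloud fills the frame.  Features rounding to the same pixel form a
#' collision group; their normalized values are averaged at transform time.
#'
#' Degenerate spans are mapped, not errored: if all x (or y) coordinates
#' coincide, every feature gets the central column \code{floor((n-1)/2)}
#' (or central row \code{floor((m-1)/2)}).
#'
#' @param rotatedCoords numeric matrix, features x 2, after rotation by the
#'   negative enclosing-rectangle angle.
#' @param frameRows,frameCols frame size m, n (>= 1).
#' @param xBounds,yBounds optional length-2 min/max used for scaling; default
#'   to the ranges of \code{rotatedCoords} (pass the training bounds when
#'   mapping new coordinates).
#' @return A [LocationMap-class].
#' @examples
#' co <- rbind(c(0, 0), c(1, 1))
#' m <- coordsToPixelMap(co, 120, 120)
#' pixelAssignments(m)
#' @export
coordsToPixelMap <- function(rotatedCoords, frameRows, frameCols,
                             xBounds = NULL, yBounds = NULL) {
    P <- as.matrix(rotatedCoords)
    stopifnot(ncol(P) == 2L, frameRows >= 1L, frameCols >= 1L,
              all(is.finite(P)))
    m <- as.integer(frameRows)
    n <- as.integer(frameCols)
    if (is.null(xBounds)) xBounds <- range(P[, 1L])
    if (is.null(yBounds)) yBounds <- range(P[, 2L])
    xspan <- xBounds[2L] - xBounds[1L]
    yspan <- yBounds[2L] - yBounds[1L]
    col <- if (xspan <= 0) rep(floor((n - 1L) / 2), nrow(P))
           else roundHalfUp((P[, 1L] - xBounds[1L]) / xspan * (n - 1L))
    row <- if (yspan <= 0) rep(floor((m - 1L) / 2), nrow(P))
           else roundHalfUp((yBounds[2L] - P[, 2L]) / yspan * (m - 1L))
    # out-of-range coordinates (new samples beyond training bounds) clamp
    row <- pmin(pmax(as.integer(row), 0L), m - 1L)
    col <- pmin(pmax(as.integer(col), 0L), n - 1L)
    key <- paste(row, col, sep = ",")
    groups <- split(seq_len(nrow(P)), key)
    methods::new("LocationMap", frameRows = m, frameCols = n,
                 pixelRow = row, pixelCol = col,
                 collisionGroups = groups, rotationAngle = 0,
                 xBounds = as.numeric(xBounds), yBounds = as.numeric(yBounds))
}

#' @describeIn coordsToPixelMap data.frame of 0-based (row, col) pixel
#'   assignments, one row per feature.
#' @param map a [LocationMap-class].
#' @export
pixelAssignments <- function(map) {
    stopifnot(methods::is(map, "LocationMap"))
    data.frame(row = map@pixelRow, col = map@pixelCol)
}

#' @describeIn coordsToPixelMap list of collision groups (1-based feature
#'   indices sharing a pixel).
#' @export
collisionGroups <- function(map) {
    stopifnot(methods::is(map, "LocationMap"))
    map@collisionGroups
}

#' @describeIn coordsToPixelMap frame size c(m, n).
#' @export
frameSize <- function(map) {
    stopifnot(methods::is(map, "LocationMap"))
    c(map@frameRows, map@frameCols)
}

setMethod("show", "LocationMap", function(object) {
    d <- length(object@pixelRow)
    cat("LocationMap:", d, "features ->",
        length(object@collisionGroups), "occupied pixels in a",
        paste0(object@frameRows, "x", object@frameCols), "frame\n")
})
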