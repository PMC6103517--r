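## Internal geometry helpers. Pixel (i, j) (1-based) has center
## ((j-1)*px, (i-1)*px) um; see AllClasses.R for the convention.

## x (um) coordinates of the columns and y of the rows of a rows x cols image
.pixelXY <- function(dims, px) {
    list(x = (seq_len(dims[2L]) - 1) * px, y = (seq_len(dims[1L]) - 1) * px)
}

## logical rows x cols mask of pixel centers inside rectangle (closed bounds)
.rectMask <- function(dims, px, rect) {
    co <- .pixelXY(dims, px)
    inX <- co$x >= rect[1L] & co$x <= rect[3L]
    inY <- co$y >= rect[2L] & co$y <= rect[4L]
    outer(inY, inX, "&")
}

.rectMean <- function(img, px, rect) {
    m <- .rectMask(dim(img), px, rect)
    if (!any(m))
        stop("rectangle [", paste(signif(rect, 4), collapse = ", "),
             "] um contains no pixel centers")
    mean(img[m])
}

## Signed perpendicular distance of points from the directed midline, and
## position along it measured from the segment midpoint. Left of the
## directed midline is negative.
.midlineCoords <- function(xs, ys, midline) {
    p0 <- midline[1L, ]; p1 <- midline[2L, ]
    v <- p1 - p0
    len <- sqrt(sum(v^2))
    u <- v / len
    dx <- xs - p0[1L]; dy <- ys - p0[2L]
    along <- dx * u[1L] + dy * u[2L]
    ## cross product z-component: positive to the right of direction u,
    ## so the left side of the directed midline comes out negative
    perp <- dx * u[2L] - dy * u[1L]
    list(dist = perp, along = along - len / 2, length = len)
}

## same, for every pixel center of a rows x cols image
.midlineCoordsImage <- function(dims, px, midline) {
    co <- .pixelXY(dims, px)
    xs <- matrix(co$x, dims[1L], dims[2L], byrow = TRUE)
    ys <- matrix(co$y, dims[1L], dims[2L])
    .midlineCoords(xs, ys, midline)
}

## bilinear interpolation of img (rows x cols) at points (x, y) in um;
## points outside the grid return NA
.bilinear <- function(img, px, x, y) {
    cj <- x / px + 1  # fractional column index
    ri <- y / px + 1
    d <- dim(img)
    j0 <- floor(cj); i0 <- floor(ri)
    fj <- cj - j0; fi <- ri - i0
    ok <- j0 >= 1 & i0 >= 1 & j0 + 1 <= d[2L] & i0 + 1 <= d[1L]
    ## clamp exact far edges into the last cell
    edgeJ <- j0 == d[2L] & fj == 0; edgeI <- i0 == d[1L] & fi == 0
    j0[edgeJ] <- j0[edgeJ] - 1; fj[edgeJ] <- 1
    i0[edgeI] <- i0[edgeI] - 1; fi[edgeI] <- 1
    ok <- ok | ((j0 >= 1 & j0 + 1 <= d[2L]) & (i0 >= 1 & i0 + 1 <= d[1L]))
    out <- rep(NA_real_, length(x))
    if (any(ok)) {
        i0k <- i0[ok]; j0k <- j0[ok]; fik <- fi[ok]; fjk <- fj[ok]
        v00 <- img[cbind(i0k, j0k)]
        v01 <- img[cbind(i0k, j0k + 1)]
        v10 <- img[cbind(i0k + 1, j0k)]
        v11 <- img[cbind(i0k + 1, j0k + 1)]
        out[ok] <- v00 * (1 - fik) * (1 - fjk) + v01 * (1 - fik) * fjk +
            v10 * fik * (1 - fjk) + v11 * fik * fjk
    }
    out
}

## unit direction, unit normal, and the direction of positive signed
## distance (`dplus`, consistent with .midlineCoords) of a 2-point path
.pathFrame <- function(path) {
    v <- path[2L, ] - path[1L, ]
    len <- sqrt(sum(v^2))
    if (len <= 0) stop("path must have positive length")
    u <- v / len
    list(u = u, n = c(-u[2L], u[1L]), dplus = c(u[2L], -u[1L]),
         length = len)
}
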