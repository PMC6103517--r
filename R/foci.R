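## Automated counting of fluorescent puncta (centrosome/centriole foci)
## and intestinal nuclei: Gaussian smoothing, robust-threshold local
## maxima, and minimum-separation suppression.

## robust scale with a dynamic-range floor: on (near-)noiseless images the
## MAD of a mostly-flat background is ~0 and would admit numerical ripples
## and far Gaussian tails, so never let the scale drop below 2% of the
## range above the median
.robustScale <- function(x) {
    max(mad(x), 0.02 * (max(x) - median(x)), 1e-12)
}

## strict-on-threshold local maxima of a matrix: pixel >= its 8 neighbors
## and above thr
.localMaxima <- function(m, thr) {
    d <- dim(m)
    pad <- matrix(-Inf, d[1L] + 2L, d[2L] + 2L)
    pad[2:(d[1L] + 1L), 2:(d[2L] + 1L)] <- m
    ok <- m > thr
    for (di in -1:1) for (dj in -1:1) {
        if (di == 0L && dj == 0L) next
        nb <- pad[(2:(d[1L] + 1L)) + di, (2:(d[2L] + 1L)) + dj]
        ok <- ok & m >= nb
    }
    which(ok, arr.ind = TRUE)
}

#' Count fluorescent puncta
#'
#' Smooths the image with a Gaussian of width `sigma`, finds local
#' maxima above a robust background threshold (median + `kSD` robust
#' SDs, both over the smoothed image), and suppresses maxima closer
#' than `minSeparation`, keeping the brighter of each pair.
#'
#' @param img numeric matrix, or an [ImageStack-class] (its brightest
#'   plane is used).
#' @param pixelSize um per pixel (taken from the stack if given one).
#' @param minSeparation minimum center separation (um); closer detections
#'   merge into the brighter one.
#' @param sigma Gaussian smoothing width (um).
#' @param kSD threshold multiplier over the robust background SD.
#' @return A list with `count`, `centers` (n x 2 matrix, um) and
#'   `intensity` (smoothed peak heights).
#' @examples
#' tr <- GroundTruth(fociCount = 3L)
#' sim <- simulateFociImage(SceneParams(), tr, seed = 1)
#' countFoci(sim$image)$count
#' @export
countFoci <- function(img, pixelSize = NULL, minSeparation = 1,
                      sigma = 0.25, kSD = 5) {
    stopifnot(minSeparation > 0, sigma > 0, kSD > 0)
    if (is(img, "ImageStack")) {
        if (is.null(pixelSize)) pixelSize <- pixelSize(img)
        z <- selectFocusPlane(img)
        img <- imgData(img)[z, , ]
    }
    if (is.null(pixelSize)) stop("pixelSize is required for a bare matrix")
    s <- EBImage::gblur(img, sigma = max(sigma / pixelSize, 0.5))
    thr <- median(s) + kSD * .robustScale(s)
    pk <- .localMaxima(s, thr)
    if (nrow(pk) == 0L)
        return(list(count = 0L, centers = matrix(numeric(), 0L, 2L),
                    intensity = numeric()))
    val <- s[pk]
    o <- order(val, decreasing = TRUE)
    pk <- pk[o, , drop = FALSE]; val <- val[o]
    cen <- cbind(x = (pk[, 2L] - 1) * pixelSize,
                 y = (pk[, 1L] - 1) * pixelSize)
    keep <- logical(nrow(cen))
    for (i in seq_len(nrow(cen))) {
        if (!any(keep)) { keep[i] <- TRUE; next }
        prev <- cen[keep, , drop = FALSE]
        dmin <- min(sqrt((prev[, 1L] - cen[i, 1L])^2 +
                         (prev[, 2L] - cen[i, 2L])^2))
        keep[i] <- dmin >= minSeparation
    }
    list(count = sum(keep), centers = cen[keep, , drop = FALSE],
         intensity = val[keep])
}

#' Count intestinal nuclei
#'
#' [countFoci()] with presets for the larger, softer nuclear blobs:
#' wider smoothing and separation.
#'
#' @inheritParams countFoci
#' @return As [countFoci()].
#' @export
countNuclei <- function(img, pixelSize = NULL, minSeparation = 1.2,
                        sigma = 0.35, kSD = 4) {
    countFoci(img, pixelSize = pixelSize, minSeparation = minSeparation,
              sigma = sigma, kSD = kSD)
}
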