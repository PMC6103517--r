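## Plane selection, projection, background estimation/subtraction, and
## photobleaching correction -- applied before any quantification.

#' Select the in-focus plane of a z-stack
#'
#' Returns the (1-based) index of the z-plane with the highest mean
#' intensity inside a rectangular ROI; in practice the ROI is placed on
#' the tubulin reference channel to find the plane of the intestinal
#' midline. Ties break toward the lower index.
#'
#' @param stack an [ImageStack-class].
#' @param roi rectangle `c(x0, y0, x1, y1)` in micrometers; defaults to
#'   the whole field.
#' @return Integer plane index (1-based).
#' @examples
#' st <- ImageStack(array(c(1, 5, 2), c(3, 4, 4)), pixelSize = 0.11)
#' selectFocusPlane(st)  # 2
#' @export
selectFocusPlane <- function(stack, roi = NULL) {
    d <- dim(imgData(stack))
    if (is.null(roi)) {
        mask <- matrix(TRUE, d[2L], d[3L])
    } else {
        mask <- .rectMask(d[2:3], pixelSize(stack), roi)
        if (!any(mask)) stop("empty ROI: no pixel centers inside")
    }
    means <- vapply(seq_len(d[1L]),
                    function(z) mean(imgData(stack)[z, , ][mask]), 0)
    which.max(means)  # which.max returns the first maximum: lower index
}

#' Sum-project slices around a center plane
#'
#' Pixelwise sum of `nSlices` z-planes centered on `center`; the window
#' is clipped at the stack boundaries rather than padded, so no data are
#' fabricated at the edges. Total intensity over the window is conserved
#' exactly.
#'
#' @param stack an [ImageStack-class].
#' @param center 1-based center plane index.
#' @param nSlices odd window size (default 3).
#' @return A numeric matrix (rows x cols).
#' @export
sumProject <- function(stack, center, nSlices = 3L) {
    d <- dim(imgData(stack))
    if (nSlices %% 2L != 1L) stop("nSlices must be odd")
    if (center < 1L || center > d[1L])
        stop("center plane ", center, " out of range 1..", d[1L])
    h <- (nSlices - 1L) %/% 2L
    zz <- max(1L, center - h):min(d[1L], center + h)
    plane <- matrix(0, d[2L], d[3L])
    for (z in zz) plane <- plane + imgData(stack)[z, , ]
    plane
}

#' Estimate slide background from three rectangles
#'
#' The unweighted mean of the three rectangle means, following the
#' convention of drawing three variable-size rectangles outside the
#' embryo.
#'
#' @param img numeric matrix (e.g. a sum projection).
#' @param bgRects list of three rectangles `c(x0, y0, x1, y1)` um.
#' @param pixelSize um per pixel.
#' @return Scalar background estimate.
#' @export
estimateSlideBackground <- function(img, bgRects, pixelSize) {
    if (length(bgRects) < 3L)
        stop("three background rectangles are required")
    mean(vapply(bgRects, function(r) .rectMean(img, pixelSize, r), 0))
}

#' Subtract a scalar background
#'
#' Pixelwise subtraction; negative values are retained (not clipped) so
#' that downstream ROI means stay unbiased.
#'
#' @param img numeric matrix/array, [ImageStack-class] or
#'   [TimeLapse-class].
#' @param value finite scalar to subtract.
#' @return Same type as `img`.
#' @export
subtractScalar <- function(img, value) {
    if (!is.finite(value)) stop("background value must be finite")
    if (is(img, "ImageStack") || is(img, "TimeLapse")) {
        img@data <- img@data - value
        return(img)
    }
    img - value
}

#' Correct a movie for photobleaching
#'
#' `simple_ratio` rescales every frame so its mean equals the first
#' frame's mean (the corrected frame-mean sequence is exactly constant,
#' and the operation is idempotent). `exponential_fit` fits the frame
#' means to A exp(-k t) + B by least squares and divides each frame by
#' its fitted decay relative to frame 1; if the fit does not converge it
#' falls back to `simple_ratio` with a warning.
#'
#' @param movie a [TimeLapse-class].
#' @param method `"simple_ratio"` (default) or `"exponential_fit"`.
#' @return A corrected [TimeLapse-class].
#' @export
bleachCorrect <- function(movie, method = c("simple_ratio",
                                            "exponential_fit")) {
    method <- match.arg(method)
    dat <- imgData(movie)
    nF <- dim(dat)[1L]
    fm <- vapply(seq_len(nF), function(k) mean(dat[k, , ]), 0)
    if (any(fm <= 0)) stop("nonpositive frame mean; cannot bleach-correct")
    if (max(fm) - min(fm) < 1e-12 * mean(fm)) return(movie)  # no decay
    if (method == "exponential_fit") {
        if (nF < 3L) stop("exponential_fit needs at least 3 frames")
        tt <- (seq_len(nF) - 1L) * frameInterval(movie)
        ## Levenberg-Marquardt: unlike stats::nls it converges on
        ## zero-residual (exact-decay) data
        fit <- tryCatch({
            k0 <- if (fm[nF] < fm[1L])
                log(fm[1L] / fm[nF]) / max(tt[nF], 1e-9) else 0.01
            minpack.lm::nlsLM(fm ~ A * exp(-k * tt) + B,
                start = list(A = max(fm[1L] - min(fm), 1e-6), k = k0,
                             B = min(fm) * 0.5),
                control = minpack.lm::nls.lm.control(maxiter = 200))
        }, error = function(e) NULL)
        if (is.null(fit)) {
            warning("exponential fit did not converge; ",
                    "falling back to simple_ratio")
            return(bleachCorrect(movie, "simple_ratio"))
        }
        pred <- stats::predict(fit)
        scale <- pred[1L] / pred
    } else {
        scale <- fm[1L] / fm
    }
    for (k in seq_len(nF)) dat[k, , ] <- dat[k, , ] * scale[k]
    movie@data <- dat
    movie
}
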