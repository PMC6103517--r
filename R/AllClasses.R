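#' @import methods
#' @importFrom stats coef lm median nls mad sd pt qt rnorm rpois runif rexp
#' @importFrom utils write.csv read.csv packageVersion
NULL

## Physical coordinate convention used throughout:
## pixel (i, j) of a row x col array (1-based R indices) has its center at
## x = (j - 1) * pixelSize, y = (i - 1) * pixelSize, in micrometers.
## Rectangles are c(x0, y0, x1, y1) in micrometers; a pixel belongs to a
## rectangle when its center lies inside (closed bounds).

#' SceneParams: imaging geometry of a synthetic acquisition
#'
#' Describes the field of view and physical calibration shared by all
#' generated images of one experiment: the size of the intestinal
#' primordium, the pixel pitch, the z sampling, and (for movies) the frame
#' interval.
#'
#' @slot primordiumLength numeric, length of the primordium along the
#'   midline (micrometers).
#' @slot primordiumHalfWidth numeric, half-width of the primordium on either
#'   side of the midline (micrometers).
#' @slot pixelSize numeric, micrometers per pixel.
#' @slot zStep numeric, spacing between optical sections (micrometers).
#' @slot frameInterval numeric, time between movie frames (seconds);
#'   \code{NA} for still acquisitions.
#' @slot imageShape integer of length 2, rows and columns of the field.
#' @slot fieldMargin numeric, embryo-free border (micrometers) kept around
#'   the primordium so that an external background box fits outside it.
#' @slot nZ integer, number of optical sections in a generated z-stack.
#' @slot sigmaZ numeric, axial extent (micrometers) of the Gaussian focus
#'   falloff that makes the central slice brightest.
#'
#' @seealso [SceneParams()] for the user constructor.
#' @exportClass SceneParams
setClass("SceneParams", representation(
    primordiumLength = "numeric",
    primordiumHalfWidth = "numeric",
    pixelSize = "numeric",
    zStep = "numeric",
    frameInterval = "numeric",
    imageShape = "integer",
    fieldMargin = "numeric",
    nZ = "integer",
    sigmaZ = "numeric"
))

setValidity("SceneParams", function(object) {
    msg <- character()
    pos <- c(primordiumLength = object@primordiumLength,
             primordiumHalfWidth = object@primordiumHalfWidth,
             pixelSize = object@pixelSize,
             zStep = object@zStep,
             fieldMargin = object@fieldMargin,
             sigmaZ = object@sigmaZ)
    bad <- names(pos)[!is.finite(pos) | pos <= 0]
    if (length(bad))
        msg <- c(msg, paste0("strictly positive value required for: ",
                             paste(bad, collapse = ", ")))
    if (length(object@imageShape) != 2L || any(object@imageShape < 8L))
        msg <- c(msg, "imageShape must be two integers >= 8")
    if (object@nZ < 1L) msg <- c(msg, "nZ must be >= 1")
    if (!is.na(object@frameInterval) && object@frameInterval <= 0)
        msg <- c(msg, "frameInterval must be positive when set")
    ## the primordium plus margin must fit in the field
    if (length(msg) == 0L) {
        fy <- (object@imageShape[1L] - 1L) * object@pixelSize
        fx <- (object@imageShape[2L] - 1L) * object@pixelSize
        if (object@primordiumLength + 2 * object@fieldMargin > fy ||
            2 * object@primordiumHalfWidth + 2 * object@fieldMargin > fx)
            msg <- c(msg, "primordium plus fieldMargin does not fit in imageShape")
    }
    if (length(msg)) msg else TRUE
})

#' GroundTruth: hidden parameters of a synthetic scene
#'
#' Holds every quantity that the analysis pipeline later estimates, so
#' that recovery can be checked against construction. Intensities are in
#' arbitrary camera units; lengths in micrometers, times in seconds.
#'
#' @slot enrichmentRatio numeric, apical plateau over cytoplasmic plateau
#'   of the marker (background-free); must be >= 1.
#' @slot cytoLevel numeric, cytoplasmic marker plateau intensity.
#' @slot depletionFraction numeric in [0, 1], fraction of the gut marker
#'   removed in degraded embryos.
#' @slot hazeLevel numeric, spatially uniform out-of-focus additive term
#'   from non-degraded marker in neighboring tissues.
#' @slot autofluoLevel numeric, gut-restricted autofluorescence additive
#'   term.
#' @slot slideBg numeric, slide background intensity.
#' @slot tubulinLevel numeric, cytoplasmic plateau of the tubulin
#'   reference channel.
#' @slot cometSpeed numeric, plus-end comet speed (micrometers/second).
#' @slot cometSpeedSD numeric, per-comet speed standard deviation.
#' @slot cometRate numeric, expected number of comets crossing one 5-um
#'   line at the standard 3-um offset within a 10-s window.
#' @slot cometAmplitude numeric, peak intensity of one comet above
#'   background.
#' @slot fociCount integer, number of planted puncta.
#' @slot nucleusCount integer, number of planted nuclei.
#' @slot bleachRate numeric, photobleaching rate (1/second).
#' @slot poissonGain numeric, scaling of the Poisson shot-noise model
#'   (variance = mean/poissonGain); larger gain means less noise.
#' @slot readSD numeric, additive Gaussian read noise SD.
#'
#' @seealso [GroundTruth()] for the user constructor.
#' @exportClass GroundTruth
setClass("GroundTruth", representation(
    enrichmentRatio = "numeric",
    cytoLevel = "numeric",
    depletionFraction = "numeric",
    hazeLevel = "numeric",
    autofluoLevel = "numeric",
    slideBg = "numeric",
    tubulinLevel = "numeric",
    cometSpeed = "numeric",
    cometSpeedSD = "numeric",
    cometRate = "numeric",
    cometAmplitude = "numeric",
    fociCount = "integer",
    nucleusCount = "integer",
    bleachRate = "numeric",
    poissonGain = "numeric",
    readSD = "numeric"
))

setValidity("GroundTruth", function(object) {
    msg <- character()
    if (object@enrichmentRatio < 1)
        msg <- c(msg, "enrichmentRatio must be >= 1")
    if (object@depletionFraction < 0 || object@depletionFraction > 1)
        msg <- c(msg, "depletionFraction must lie in [0, 1]")
    nonneg <- c(cytoLevel = object@cytoLevel, hazeLevel = object@hazeLevel,
                autofluoLevel = object@autofluoLevel, slideBg = object@slideBg,
                tubulinLevel = object@tubulinLevel,
                cometSpeed = object@cometSpeed,
                cometSpeedSD = object@cometSpeedSD,
                cometRate = object@cometRate,
                cometAmplitude = object@cometAmplitude,
                bleachRate = object@bleachRate, readSD = object@readSD)
    bad <- names(nonneg)[!is.finite(nonneg) | nonneg < 0]
    if (length(bad))
        msg <- c(msg, paste0("nonnegative value required for: ",
                             paste(bad, collapse = ", ")))
    if (object@poissonGain <= 0) msg <- c(msg, "poissonGain must be positive")
    if (object@fociCount < 0L || object@nucleusCount < 0L)
        msg <- c(msg, "fociCount and nucleusCount must be >= 0")
    if (length(msg)) msg else TRUE
})

#' EmbryoAnnotation: midline and measurement ROIs for one embryo
#'
#' The midline is a directed segment (two endpoints in micrometers); all
#' boxes are axis-aligned rectangles \code{c(x0, y0, x1, y1)} in
#' micrometers. Widths follow the measurement conventions: the apical and
#' cytoplasmic boxes are 2 um wide, the gut box 10 um wide, the external
#' box lies entirely in the embryo-free margin, and the three slide
#' background rectangles lie outside the embryo.
#'
#' @slot midline 2x2 numeric matrix, rows = the two endpoints (x, y).
#' @slot gutBox,externalBox,apicalBox,cytoBox numeric length-4 rectangles.
#' @slot bgRects list of three numeric length-4 rectangles.
#' @slot fociCenters,nucleusCenters optional n x 2 matrices of planted
#'   point coordinates (ground truth; may have zero rows).
#'
#' @exportClass EmbryoAnnotation
setClass("EmbryoAnnotation", representation(
    midline = "matrix",
    gutBox = "numeric",
    externalBox = "numeric",
    apicalBox = "numeric",
    cytoBox = "numeric",
    bgRects = "list",
    fociCenters = "matrix",
    nucleusCenters = "matrix"
))

.rectOK <- function(r) length(r) == 4L && all(is.finite(r)) &&
    r[1L] <= r[3L] && r[2L] <= r[4L]

## a measurement box has one prescribed width; the other side is its
## variable length
.hasWidth <- function(r, w, tol = 1e-6)
    abs(r[3L] - r[1L] - w) < tol || abs(r[4L] - r[2L] - w) < tol

setValidity("EmbryoAnnotation", function(object) {
    msg <- character()
    if (!all(dim(object@midline) == c(2L, 2L)) ||
        !all(is.finite(object@midline)))
        msg <- c(msg, "midline must be a finite 2x2 matrix of endpoints")
    else if (sqrt(sum((object@midline[2L, ] - object@midline[1L, ])^2)) <= 0)
        msg <- c(msg, "midline must have positive length")
    for (nm in c("gutBox", "externalBox", "apicalBox", "cytoBox"))
        if (!.rectOK(slot(object, nm)))
            msg <- c(msg, paste0(nm, " must be c(x0, y0, x1, y1) with x0<=x1, y0<=y1"))
    if (length(object@bgRects) != 3L || !all(vapply(object@bgRects, .rectOK, TRUE)))
        msg <- c(msg, "bgRects must be a list of 3 valid rectangles")
    if (length(msg) == 0L) {
        if (!.hasWidth(object@apicalBox, 2))
            msg <- c(msg, "apicalBox width must be 2 um")
        if (!.hasWidth(object@cytoBox, 2))
            msg <- c(msg, "cytoBox width must be 2 um")
        if (!.hasWidth(object@externalBox, 2))
            msg <- c(msg, "externalBox width must be 2 um")
        if (!.hasWidth(object@gutBox, 10))
            msg <- c(msg, "gutBox width must be 10 um")
    }
    if (length(msg)) msg else TRUE
})

#' ImageStack: a calibrated z-stack of one channel
#'
#' @slot data numeric array z x rows x cols of nonnegative intensities.
#' @slot pixelSize numeric, micrometers per pixel.
#' @slot zStep numeric, micrometers between sections.
#' @slot channel character, label of the imaged marker.
#'
#' @exportClass ImageStack
setClass("ImageStack", representation(
    data = "array", pixelSize = "numeric", zStep = "numeric",
    channel = "character"
))

setValidity("ImageStack", function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L || any(dim(object@data) < 1L))
        msg <- c(msg, "data must be a z x rows x cols array with all dims >= 1")
    if (!all(is.finite(object@data)))
        msg <- c(msg, "intensities must be finite")
    if (object@pixelSize <= 0 || object@zStep <= 0)
        msg <- c(msg, "pixelSize and zStep must be positive")
    if (length(msg)) msg else TRUE
})

#' TimeLapse: a calibrated single-plane movie
#'
#' @slot data numeric array t x rows x cols.
#' @slot pixelSize numeric, micrometers per pixel.
#' @slot frameInterval numeric, seconds between frames.
#' @slot channel character label.
#'
#' @exportClass TimeLapse
setClass("TimeLapse", representation(
    data = "array", pixelSize = "numeric", frameInterval = "numeric",
    channel = "character"
))

setValidity("TimeLapse", function(object) {
    msg <- character()
    if (length(dim(object@data)) != 3L || any(dim(object@data) < 1L))
        msg <- c(msg, "data must be a t x rows x cols array")
    if (!all(is.finite(object@data)))
        msg <- c(msg, "intensities must be finite")
    if (object@pixelSize <= 0 || object@frameInterval <= 0)
        msg <- c(msg, "pixelSize and frameInterval must be positive")
    if (length(msg)) msg else TRUE
})

#' Kymograph: intensity along a path versus time
#'
#' Rows are frames, columns are unit-pixel steps along the path; each
#' entry averages the movie across \code{lineWidth} pixels perpendicular
#' to the path (bilinear interpolation at sub-pixel positions).
#'
#' @slot data numeric matrix, time x path-distance.
#' @slot path 2x2 numeric matrix of path endpoints (micrometers).
#' @slot lineWidth integer, odd perpendicular averaging width in pixels.
#' @slot frameInterval numeric, seconds per row.
#' @slot pixelSize numeric, micrometers per column step.
#'
#' @exportClass Kymograph
setClass("Kymograph", representation(
    data = "matrix", path = "matrix", lineWidth = "integer",
    frameInterval = "numeric", pixelSize = "numeric"
))

setValidity("Kymograph", function(object) {
    msg <- character()
    if (!all(is.finite(object@data)))
        msg <- c(msg, "kymograph intensities must be finite")
    if (object@lineWidth < 1L || object@lineWidth %% 2L == 0L)
        msg <- c(msg, "lineWidth must be odd and >= 1")
    if (sqrt(sum((object@path[2L, ] - object@path[1L, ])^2)) <= 0)
        msg <- c(msg, "path must have positive length")
    if (length(msg)) msg else TRUE
})
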