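#' Construct imaging scene parameters
#'
#' Defaults describe a polarized E16 intestinal primordium imaged on a
#' spinning-disk system: 0.11 um pixels (100x objective with a 1.5x
#' magnifying lens on a typical EM-CCD), 0.5 um z sampling, and a
#' 256 x 256 field. All values are configurable; none is hard-coded
#' downstream.
#'
#' @param primordiumLength length of the primordium along the midline (um).
#' @param primordiumHalfWidth half-width of the primordium (um).
#' @param pixelSize um per pixel.
#' @param zStep um between optical sections.
#' @param frameInterval seconds between movie frames (NA for stills).
#' @param imageShape integer rows, cols of the field.
#' @param fieldMargin embryo-free border (um).
#' @param nZ number of optical sections per z-stack.
#' @param sigmaZ axial Gaussian focus falloff (um).
#' @return A [SceneParams-class] object.
#' @examples
#' sc <- SceneParams()
#' pixelSize(sc)
#' @export
SceneParams <- function(primordiumLength = 14, primordiumHalfWidth = 5.5,
                        pixelSize = 0.11, zStep = 0.5, frameInterval = 0.1,
                        imageShape = c(256L, 256L), fieldMargin = 3,
                        nZ = 7L, sigmaZ = 1.0) {
    new("SceneParams", primordiumLength = primordiumLength,
        primordiumHalfWidth = primordiumHalfWidth, pixelSize = pixelSize,
        zStep = zStep, frameInterval = as.numeric(frameInterval),
        imageShape = as.integer(imageShape), fieldMargin = fieldMargin,
        nZ = as.integer(nZ), sigmaZ = sigmaZ)
}

#' Construct ground-truth parameters for a synthetic scene
#'
#' Defaults are the operating point of the study conditions: a marker
#' 2-fold enriched at the apical midline over a cytoplasmic plateau of
#' 100 camera units, modest uniform haze and gut autofluorescence,
#' EM-CCD-like noise (Poisson shot noise at unit gain plus read noise of
#' 3 units), comets at 0.558 um/s with mild photobleaching.
#'
#' @param enrichmentRatio apical/cytoplasmic plateau ratio (>= 1).
#' @param cytoLevel cytoplasmic marker plateau (camera units).
#' @param depletionFraction fraction of gut marker removed in degraded
#'   embryos, in [0, 1].
#' @param hazeLevel uniform out-of-focus additive intensity.
#' @param autofluoLevel gut-restricted autofluorescence intensity.
#' @param slideBg slide background intensity.
#' @param tubulinLevel cytoplasmic plateau of the tubulin channel.
#' @param cometSpeed comet speed (um/s).
#' @param cometSpeedSD per-comet speed SD (um/s).
#' @param cometRate expected comets crossing one 5-um line at 3 um offset
#'   per 10 s.
#' @param cometAmplitude comet peak intensity above background.
#' @param fociCount,nucleusCount planted spot counts.
#' @param bleachRate photobleaching rate (1/s).
#' @param poissonGain shot-noise gain (variance = mean/gain).
#' @param readSD additive Gaussian read noise SD.
#' @return A [GroundTruth-class] object.
#' @examples
#' tr <- GroundTruth(enrichmentRatio = 1.67)
#' enrichmentRatio(tr)
#' @export
GroundTruth <- function(enrichmentRatio = 2, cytoLevel = 100,
                        depletionFraction = 0, hazeLevel = 20,
                        autofluoLevel = 10, slideBg = 50,
                        tubulinLevel = 120, cometSpeed = 0.558,
                        cometSpeedSD = 0.05, cometRate = 5,
                        cometAmplitude = 60, fociCount = 0L,
                        nucleusCount = 0L, bleachRate = 0.02,
                        poissonGain = 1, readSD = 3) {
    new("GroundTruth", enrichmentRatio = enrichmentRatio,
        cytoLevel = cytoLevel, depletionFraction = depletionFraction,
        hazeLevel = hazeLevel, autofluoLevel = autofluoLevel,
        slideBg = slideBg, tubulinLevel = tubulinLevel,
        cometSpeed = cometSpeed, cometSpeedSD = cometSpeedSD,
        cometRate = cometRate, cometAmplitude = cometAmplitude,
        fociCount = as.integer(fociCount),
        nucleusCount = as.integer(nucleusCount), bleachRate = bleachRate,
        poissonGain = poissonGain, readSD = readSD)
}

#' Construct an embryo annotation
#'
#' @param midline 2x2 matrix of segment endpoints (um), directed from the
#'   first to the second row.
#' @param gutBox,externalBox,apicalBox,cytoBox rectangles c(x0,y0,x1,y1) um.
#' @param bgRects list of three rectangles outside the embryo.
#' @param fociCenters,nucleusCenters optional n x 2 matrices (um).
#' @return An [EmbryoAnnotation-class] object.
#' @export
EmbryoAnnotation <- function(midline, gutBox, externalBox, apicalBox,
                             cytoBox, bgRects,
                             fociCenters = matrix(numeric(), 0L, 2L),
                             nucleusCenters = matrix(numeric(), 0L, 2L)) {
    new("EmbryoAnnotation", midline = unname(midline),
        gutBox = unname(gutBox), externalBox = unname(externalBox),
        apicalBox = unname(apicalBox), cytoBox = unname(cytoBox),
        bgRects = lapply(bgRects, unname),
        fociCenters = fociCenters, nucleusCenters = nucleusCenters)
}

#' Construct a calibrated image stack
#'
#' @param data z x rows x cols array, or a matrix (promoted to one plane).
#' @param pixelSize um per pixel.
#' @param zStep um between sections.
#' @param channel marker label.
#' @return An [ImageStack-class] object.
#' @export
ImageStack <- function(data, pixelSize, zStep = 0.5, channel = "marker") {
    if (is.matrix(data)) data <- array(data, c(1L, dim(data)))
    new("ImageStack", data = data, pixelSize = pixelSize, zStep = zStep,
        channel = channel)
}

#' Construct a calibrated time lapse
#'
#' @param data t x rows x cols array.
#' @param pixelSize um per pixel.
#' @param frameInterval seconds between frames.
#' @param channel marker label.
#' @return A [TimeLapse-class] object.
#' @export
TimeLapse <- function(data, pixelSize, frameInterval, channel = "marker") {
    new("TimeLapse", data = data, pixelSize = pixelSize,
        frameInterval = frameInterval, channel = channel)
}
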