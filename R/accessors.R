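#' Accessors for mtocQuant containers
#'
#' Small generic accessors so user code never touches slots directly.
#'
#' @param x an mtocQuant S4 object.
#' @return The corresponding field: a numeric array for `imgData`,
#'   scalars for the calibration accessors, a 2x2 matrix for `midline`.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("imgData", function(x) standardGeneric("imgData"))
#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))
#' @rdname accessors
#' @export
setGeneric("zStep", function(x) standardGeneric("zStep"))
#' @rdname accessors
#' @export
setGeneric("channel", function(x) standardGeneric("channel"))
#' @rdname accessors
#' @export
setGeneric("midline", function(x) standardGeneric("midline"))
#' @rdname accessors
#' @export
setGeneric("enrichmentRatio", function(x) standardGeneric("enrichmentRatio"))
#' @rdname accessors
#' @export
setGeneric("cometSpeed", function(x) standardGeneric("cometSpeed"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))

#' @rdname accessors
setMethod("imgData", "ImageStack", function(x) x@data)
#' @rdname accessors
setMethod("imgData", "TimeLapse", function(x) x@data)
#' @rdname accessors
setMethod("imgData", "Kymograph", function(x) x@data)
#' @rdname accessors
setMethod("pixelSize", "ImageStack", function(x) x@pixelSize)
#' @rdname accessors
setMethod("pixelSize", "TimeLapse", function(x) x@pixelSize)
#' @rdname accessors
setMethod("pixelSize", "Kymograph", function(x) x@pixelSize)
#' @rdname accessors
setMethod("pixelSize", "SceneParams", function(x) x@pixelSize)
#' @rdname accessors
setMethod("frameInterval", "TimeLapse", function(x) x@frameInterval)
#' @rdname accessors
setMethod("frameInterval", "Kymograph", function(x) x@frameInterval)
#' @rdname accessors
setMethod("frameInterval", "SceneParams", function(x) x@frameInterval)
#' @rdname accessors
setMethod("zStep", "ImageStack", function(x) x@zStep)
#' @rdname accessors
setMethod("zStep", "SceneParams", function(x) x@zStep)
#' @rdname accessors
setMethod("channel", "ImageStack", function(x) x@channel)
#' @rdname accessors
setMethod("channel", "TimeLapse", function(x) x@channel)
#' @rdname accessors
setMethod("midline", "EmbryoAnnotation", function(x) x@midline)
#' @rdname accessors
setMethod("enrichmentRatio", "GroundTruth", function(x) x@enrichmentRatio)
#' @rdname accessors
setMethod("cometSpeed", "GroundTruth", function(x) x@cometSpeed)
#' @rdname accessors
setMethod("nFrames", "TimeLapse", function(x) dim(x@data)[1L])

setMethod("show", "SceneParams", function(object) {
    cat("SceneParams:", object@imageShape[1L], "x", object@imageShape[2L],
        "px @", object@pixelSize, "um/px\n")
    cat("  primordium", object@primordiumLength, "x",
        2 * object@primordiumHalfWidth, "um; margin", object@fieldMargin,
        "um\n")
    cat("  z:", object@nZ, "slices @", object@zStep, "um; frame interval:",
        object@frameInterval, "s\n")
})

setMethod("show", "GroundTruth", function(object) {
    cat("GroundTruth:\n")
    cat("  enrichment", object@enrichmentRatio, "x; cyto",
        object@cytoLevel, "; depletion", object@depletionFraction, "\n")
    cat("  haze", object@hazeLevel, "; autofluo", object@autofluoLevel,
        "; slide bg", object@slideBg, "\n")
    cat("  comets:", object@cometSpeed, "um/s (SD", object@cometSpeedSD,
        "), rate", object@cometRate, "/line/10s\n")
    cat("  noise: gain", object@poissonGain, ", read SD", object@readSD,
        "; bleach", object@bleachRate, "/s\n")
})

setMethod("show", "EmbryoAnnotation", function(object) {
    len <- sqrt(sum((object@midline[2L, ] - object@midline[1L, ])^2))
    cat("EmbryoAnnotation: midline", round(len, 2), "um;",
        nrow(object@fociCenters), "foci,",
        nrow(object@nucleusCenters), "nuclei recorded\n")
})

setMethod("show", "ImageStack", function(object) {
    d <- dim(object@data)
    cat("ImageStack [", object@channel, "]: ", d[1L], " z x ", d[2L], " x ",
        d[3L], " px @ ", object@pixelSize, " um/px, z-step ",
        object@zStep, " um\n", sep = "")
})

setMethod("show", "TimeLapse", function(object) {
    d <- dim(object@data)
    cat("TimeLapse [", object@channel, "]: ", d[1L], " frames x ", d[2L],
        " x ", d[3L], " px @ ", object@pixelSize, " um/px, ",
        object@frameInterval, " s/frame\n", sep = "")
})

setMethod("show", "Kymograph", function(object) {
    d <- dim(object@data)
    cat("Kymograph: ", d[1L], " frames x ", d[2L], " steps, width ",
        object@lineWidth, " px\n", sep = "")
})
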