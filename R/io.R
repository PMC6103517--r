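## Disk formats: multi-page TIFF (one page per z or per t) with a
## plain-text key-value sidecar carrying the physical calibration,
## annotations and ground truth as JSON (units in um), event logs as CSV.

.sidecarPath <- function(path) paste0(sub("\\.tiff?$", "", path), ".txt")

.writeSidecar <- function(path, fields) {
    writeLines(paste0(names(fields), " = ", vapply(fields, format, "")),
               .sidecarPath(path))
}

.readSidecar <- function(path) {
    ln <- readLines(.sidecarPath(path))
    kv <- strsplit(ln, " = ", fixed = TRUE)
    stats::setNames(lapply(kv, `[`, 2L), vapply(kv, `[`, "", 1L))
}

#' Write a calibrated image to multi-page TIFF plus sidecar
#'
#' Writes one 32-bit page per z-plane (or frame, or kymograph row
#' block); TIFF stores values in [0, 1], so intensities are divided by
#' an `intensity_scale` recorded in the plain-text sidecar
#' (`<path>.txt`) along with the pixel size and z-step or frame
#' interval.
#'
#' @param x an [ImageStack-class], [TimeLapse-class] or
#'   [Kymograph-class].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
writeCalibrated <- function(x, path) {
    if (is(x, "Kymograph")) {
        dat <- array(imgData(x), c(1L, dim(imgData(x))))
        fields <- list(type = "Kymograph",
                       frame_interval_s = x@frameInterval,
                       pixel_size_um = x@pixelSize,
                       line_width_px = x@lineWidth)
    } else if (is(x, "TimeLapse")) {
        dat <- imgData(x)
        fields <- list(type = "TimeLapse", channel = channel(x),
                       pixel_size_um = pixelSize(x),
                       frame_interval_s = frameInterval(x))
    } else {
        dat <- imgData(x)
        fields <- list(type = "ImageStack", channel = channel(x),
                       pixel_size_um = pixelSize(x), z_step_um = zStep(x))
    }
    lo <- min(dat); hi <- max(dat)
    scale <- max(hi - lo, 1e-12)
    fields$intensity_scale <- scale
    fields$intensity_offset <- lo
    fields$n_pages <- dim(dat)[1L]
    pages <- lapply(seq_len(dim(dat)[1L]),
                    function(k) (dat[k, , ] - lo) / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L)
    .writeSidecar(path, fields)
    invisible(path)
}

#' Read a calibrated image written by [writeCalibrated()]
#'
#' @param path TIFF path (the `<path>.txt` sidecar must sit beside it).
#' @return An [ImageStack-class], [TimeLapse-class] or plain matrix
#'   (for a stored kymograph), per the sidecar `type`.
#' @export
readCalibrated <- function(path) {
    sc <- .readSidecar(path)
    pages <- tiff::readTIFF(path, all = TRUE)
    scale <- as.numeric(sc$intensity_scale)
    off <- as.numeric(sc$intensity_offset)
    dat <- array(0, c(length(pages), dim(pages[[1L]])))
    for (k in seq_along(pages)) dat[k, , ] <- pages[[k]] * scale + off
    switch(sc$type,
        ImageStack = ImageStack(dat, as.numeric(sc$pixel_size_um),
                                as.numeric(sc$z_step_um), sc$channel),
        TimeLapse = TimeLapse(dat, as.numeric(sc$pixel_size_um),
                              as.numeric(sc$frame_interval_s), sc$channel),
        Kymograph = dat[1L, , ],
        stop("unknown sidecar type: ", sc$type))
}

#' Write / read an embryo annotation as JSON (units: um)
#'
#' @param ann an [EmbryoAnnotation-class].
#' @param path JSON path.
#' @return `path` invisibly; `readAnnotation` returns the object.
#' @export
writeAnnotation <- function(ann, path) {
    obj <- list(units = "um",
                midline = unname(apply(ann@midline, 1L, c,
                                       simplify = FALSE)),
                gutBox = ann@gutBox, externalBox = ann@externalBox,
                apicalBox = ann@apicalBox, cytoBox = ann@cytoBox,
                bgRects = ann@bgRects,
                fociCenters = if (nrow(ann@fociCenters))
                    unname(apply(ann@fociCenters, 1L, c,
                                 simplify = FALSE)) else list(),
                nucleusCenters = if (nrow(ann@nucleusCenters))
                    unname(apply(ann@nucleusCenters, 1L, c,
                                 simplify = FALSE)) else list())
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeAnnotation
#' @export
readAnnotation <- function(path) {
    o <- jsonlite::read_json(path, simplifyVector = TRUE)
    toMat <- function(x) if (length(x))
        matrix(unlist(x), ncol = 2L, byrow = !is.matrix(x))
        else matrix(numeric(), 0L, 2L)
    ml <- if (is.matrix(o$midline)) o$midline else
        do.call(rbind, o$midline)
    EmbryoAnnotation(midline = ml, gutBox = o$gutBox,
                     externalBox = o$externalBox, apicalBox = o$apicalBox,
                     cytoBox = o$cytoBox,
                     bgRects = if (is.matrix(o$bgRects))
                         lapply(seq_len(nrow(o$bgRects)),
                                function(i) o$bgRects[i, ])
                         else o$bgRects,
                     fociCenters = toMat(o$fociCenters),
                     nucleusCenters = toMat(o$nucleusCenters))
}

#' Write / read ground truth as JSON
#'
#' @param truth a [GroundTruth-class].
#' @param path JSON path.
#' @return `path` invisibly; `readGroundTruth` returns the object.
#' @export
writeGroundTruth <- function(truth, path) {
    sl <- slotNames("GroundTruth")
    obj <- stats::setNames(lapply(sl, function(s) slot(truth, s)), sl)
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
    invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
    o <- jsonlite::read_json(path, simplifyVector = TRUE)
    do.call(GroundTruth, o[setdiff(names(o),
                                   c("fociCount", "nucleusCount"))] |>
        c(list(fociCount = as.integer(o$fociCount),
               nucleusCount = as.integer(o$nucleusCount))))
}

#' Write a comet event log as CSV
#'
#' Columns: `time_s`, `side`, `lateral_um`, `angle_rad`, `speed_um_s`.
#'
#' @param events the `events` data.frame from [simulateCometMovie()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
writeEventLog <- function(events, path) {
    write.csv(events, path, row.names = FALSE)
    invisible(path)
}
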