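## Synthetic-microscopy generator. Every image carries a GroundTruth so
## downstream estimators can be validated by parameter recovery.

## enrichment of the tubulin reference channel; fixed so midline detection
## works even when the marker itself is unenriched
.TUB_RATIO <- 2.5

## run code under a temporary RNG seed, restoring the caller's stream
.withSeed <- function(seed, fun) {
    if (is.null(seed)) return(fun())
    genv <- globalenv()
    had <- exists(".Random.seed", envir = genv, inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = genv) else NULL
    on.exit({
        if (had) assign(".Random.seed", old, envir = genv)
        else if (exists(".Random.seed", envir = genv, inherits = FALSE))
            rm(".Random.seed", envir = genv)
    })
    set.seed(seed)
    fun()
}

## piecewise-linear apical profile: r at |d| <= 1 um, 1 at |d| >= 2.5 um,
## linear in between; chosen so the 2-um box estimators recover r exactly
## in the noiseless case
.apicalShape <- function(d, r) {
    ad <- abs(d)
    g <- rep(1, length(d))
    g[ad <= 1] <- r
    mid <- ad > 1 & ad < 2.5
    g[mid] <- 1 + (r - 1) * (2.5 - ad[mid]) / 1.5
    g
}

## EM-CCD noise model: scaled-Poisson shot noise plus Gaussian read noise
.applyNoise <- function(meanImg, gain, readSD) {
    n <- length(meanImg)
    out <- rpois(n, gain * pmax(meanImg, 0)) / gain
    if (readSD > 0) out <- out + rnorm(n, 0, readSD)
    array(out, dim(meanImg))
}

.fieldCenter <- function(scene) {
    c(x = (scene@imageShape[2L] - 1L) * scene@pixelSize / 2,
      y = (scene@imageShape[1L] - 1L) * scene@pixelSize / 2)
}

#' Default annotation for a generated primordium
#'
#' Places the midline vertically through the field center and all
#' measurement boxes consistently with the measurement conventions:
#' apical box (2 um wide) centered on the midline, cytoplasmic box (2 um)
#' fully within 2.5-4.5 um of it, gut box 10 um wide inside the
#' primordium, external box (2 um) in the embryo-free margin, and three
#' slide-background rectangles near the field corners.
#'
#' @param scene a [SceneParams-class] object.
#' @return An [EmbryoAnnotation-class] object.
#' @examples
#' defaultAnnotation(SceneParams())
#' @export
defaultAnnotation <- function(scene) {
    ctr <- .fieldCenter(scene)
    hw <- scene@primordiumHalfWidth
    if (hw < 4.5)
        stop("geometry error: cytoplasmic box (2.5-4.5 um from midline) ",
             "does not fit inside primordiumHalfWidth = ", hw)
    if (hw < 5)
        stop("geometry error: 10-um-wide gut box does not fit inside ",
             "primordiumHalfWidth = ", hw)
    L <- scene@primordiumLength
    ml <- rbind(c(ctr["x"], ctr["y"] - L / 2), c(ctr["x"], ctr["y"] + L / 2))
    dimnames(ml) <- NULL
    aLen <- 0.6 * L
    fy <- (scene@imageShape[1L] - 1L) * scene@pixelSize
    fx <- (scene@imageShape[2L] - 1L) * scene@pixelSize
    ## the external box must sit entirely in the embryo-free margin,
    ## just left of the primordium edge
    ex1 <- ctr["x"] - hw - scene@pixelSize / 2
    ex0 <- ex1 - 2
    if (ex0 < -1e-9)
        stop("geometry error: no room for the 2-um external box in the ",
             "margin left of the primordium")
    EmbryoAnnotation(
        midline = ml,
        gutBox = c(ctr["x"] - 5, ctr["y"] - 0.35 * L,
                   ctr["x"] + 5, ctr["y"] + 0.35 * L),
        externalBox = c(ex0, ctr["y"] - 0.35 * L, ex1,
                        ctr["y"] + 0.35 * L),
        apicalBox = c(ctr["x"] - 1, ctr["y"] - aLen / 2,
                      ctr["x"] + 1, ctr["y"] + aLen / 2),
        cytoBox = c(ctr["x"] + 2.5, ctr["y"] - aLen / 2,
                    ctr["x"] + 4.5, ctr["y"] + aLen / 2),
        bgRects = list(c(0.3, 0.3, 2.0, 2.0),
                       c(fx - 2.0, 0.3, fx - 0.3, 2.0),
                       c(fx - 2.0, fy - 2.0, fx - 0.3, fy - 0.3)))
}

## noiseless single-plane mean images for both channels
.meanImages <- function(scene, truth, degraded = FALSE, noGFP = FALSE) {
    dims <- scene@imageShape
    ann <- defaultAnnotation(scene)
    mc <- .midlineCoordsImage(dims, scene@pixelSize, ann@midline)
    inGut <- abs(mc$dist) <= scene@primordiumHalfWidth &
        abs(mc$along) <= mc$length / 2
    g <- array(.apicalShape(mc$dist, truth@enrichmentRatio), dims)
    cm <- truth@cytoLevel * (if (degraded) 1 - truth@depletionFraction else 1)
    if (noGFP) cm <- 0
    haze <- if (noGFP) 0 else truth@hazeLevel
    marker <- truth@slideBg + haze +
        inGut * (truth@autofluoLevel + cm * g)
    gt <- array(.apicalShape(mc$dist, .TUB_RATIO), dims)
    tubulin <- truth@slideBg + inGut * truth@tubulinLevel * gt
    list(marker = marker, tubulin = tubulin, annotation = ann)
}

## expand a 2-D mean image into a z-stack with a Gaussian focus falloff;
## the slide background does not defocus, so the central slice is brightest
.zExpand <- function(meanImg, scene, slideBg) {
    zc <- (scene@nZ + 1) / 2
    w <- exp(-(((seq_len(scene@nZ) - zc) * scene@zStep)^2) /
                 (2 * scene@sigmaZ^2))
    out <- array(0, c(scene@nZ, dim(meanImg)))
    for (z in seq_len(scene@nZ))
        out[z, , ] <- slideBg + w[z] * (meanImg - slideBg)
    out
}

#' Simulate a two-channel primordium z-stack
#'
#' Generates a marker channel (apically enriched, with uniform haze and
#' gut autofluorescence over slide background) and a tubulin reference
#' channel sharing the same midline geometry, as z-stacks whose central
#' slice is brightest. Noise is scaled-Poisson shot noise plus Gaussian
#' read noise.
#'
#' @param scene a [SceneParams-class].
#' @param truth a [GroundTruth-class].
#' @param seed integer seed (identical inputs give bit-identical output);
#'   `NULL` uses the current RNG stream.
#' @param degraded logical; scale the gut marker component by
#'   (1 - depletionFraction)?
#' @param noGFP logical; autofluorescence-only control embryo (marker
#'   component and haze absent, autofluorescence retained)?
#' @param noise logical; apply the noise model?
#' @return A list with elements `marker` and `tubulin`
#'   ([ImageStack-class]), `annotation` ([EmbryoAnnotation-class]) and
#'   `truth` ([GroundTruth-class]).
#' @examples
#' sim <- simulatePrimordium(SceneParams(), GroundTruth(), seed = 1)
#' sim$marker
#' @export
simulatePrimordium <- function(scene, truth, seed = NULL, degraded = FALSE,
                               noGFP = FALSE, noise = TRUE) {
    mi <- .meanImages(scene, truth, degraded = degraded, noGFP = noGFP)
    mk <- .zExpand(mi$marker, scene, truth@slideBg)
    tb <- .zExpand(mi$tubulin, scene, truth@slideBg)
    if (noise) {
        res <- .withSeed(seed, function() list(
            mk = .applyNoise(mk, truth@poissonGain, truth@readSD),
            tb = .applyNoise(tb, truth@poissonGain, truth@readSD)))
        mk <- res$mk; tb <- res$tb
    }
    list(marker = ImageStack(mk, scene@pixelSize, scene@zStep, "marker"),
         tubulin = ImageStack(tb, scene@pixelSize, scene@zStep, "tubulin"),
         annotation = mi$annotation, truth = truth)
}

#' Simulate sibling cohorts for percent-depletion analysis
#'
#' Generates degraded ("gut(-)") embryos whose gut marker component is
#' scaled by (1 - depletionFraction), non-degraded ("gut(+)") siblings,
#' and autofluorescence-only controls carrying no fluorophore. Haze,
#' autofluorescence and slide background are identical in distribution
#' across the two sibling cohorts.
#'
#' @param scene,truth see [simulatePrimordium()].
#' @param nMinus,nPlus number of degraded / non-degraded embryos (>= 1).
#' @param nControls number of no-fluorophore control embryos.
#' @param seed integer seed.
#' @param noise logical; apply the noise model?
#' @return A list with elements `minus`, `plus`, `controls` (lists of
#'   [simulatePrimordium()] results) and `truth`.
#' @export
simulateDepletionCohort <- function(scene, truth, nMinus, nPlus,
                                    nControls = 5L, seed = NULL,
                                    noise = TRUE) {
    stopifnot(nMinus >= 1L, nPlus >= 1L, nControls >= 1L)
    .withSeed(seed, function() list(
        minus = lapply(seq_len(nMinus), function(i)
            simulatePrimordium(scene, truth, degraded = TRUE, noise = noise)),
        plus = lapply(seq_len(nPlus), function(i)
            simulatePrimordium(scene, truth, noise = noise)),
        controls = lapply(seq_len(nControls), function(i)
            simulatePrimordium(scene, truth, noGFP = TRUE, noise = noise)),
        truth = truth))
}

## birth rate (events/s, one side, whole midline length) calibrated so the
## expected number of comets crossing a lineLength line at `offset` within
## `window` seconds equals `rate`
.midlineBirthRate <- function(rate, v, midLen, lineLength = 5, offset = 3,
                              window = 10) {
    travel <- if (v > 0) offset / v else Inf
    eff <- max(window - travel, 0)
    if (eff <= 0) eff <- window  # uncrossable geometry: rate per window
    rate / ((lineLength / midLen) * eff)
}

#' Simulate a plus-end comet time-lapse movie
#'
#' Comets are isotropic Gaussian spots born on a Poisson process and
#' moving at constant per-comet speed over a uniform background; the
#' whole frame decays as exp(-bleachRate t) and then receives the noise
#' model. Two geometries are supported: `"midline"` (births on either
#' side of the apical midline, motion perpendicular to it, rate
#' calibrated so the expected number of comets crossing a 5-um line at
#' 3 um offset in 10 s equals `cometRate(truth)` per side) and
#' `"radial"` (births at a central point source, motion outward at a
#' uniform random angle, `cometRate` expected births per 10 s).
#'
#' @param scene,truth see [simulatePrimordium()]; `frameInterval(scene)`
#'   must be set.
#' @param duration movie length in seconds (> 0).
#' @param seed integer seed.
#' @param geometry `"midline"` or `"radial"`.
#' @param spotSigma Gaussian comet radius (um).
#' @param noise logical; apply bleaching-plus-noise model (bleaching is
#'   applied regardless; `noise = FALSE` skips the stochastic part).
#' @return A list with elements `movie` ([TimeLapse-class]), `annotation`,
#'   `truth`, and `events`, a data.frame with one row per comet birth:
#'   `time_s`, `side` (-1 left / +1 right; 0 for radial), `lateral_um`
#'   (position along the midline; for radial geometry the birth angle in
#'   radians is in `angle_rad`), `speed_um_s`.
#' @examples
#' sc <- SceneParams(imageShape = c(128L, 128L))
#' sim <- simulateCometMovie(sc, GroundTruth(cometRate = 3), duration = 5,
#'                           seed = 1)
#' nrow(sim$events)
#' @export
simulateCometMovie <- function(scene, truth, duration = 10, seed = NULL,
                               geometry = c("midline", "radial"),
                               spotSigma = 0.15, noise = TRUE) {
    geometry <- match.arg(geometry)
    if (!is.finite(scene@frameInterval) || scene@frameInterval <= 0)
        stop("frameInterval must be set in the scene for movies")
    if (duration <= 0) stop("duration must be positive")
    .withSeed(seed, function() {
        dt <- scene@frameInterval
        ## inclusive endpoint: frames at 0, dt, ..., duration
        nF <- max(2L, as.integer(round(duration / dt)) + 1L)
        dims <- scene@imageShape
        px <- scene@pixelSize
        ann <- defaultAnnotation(scene)
        ctr <- .fieldCenter(scene)
        midLen <- scene@primordiumLength
        v <- truth@cometSpeed

        if (geometry == "midline") {
            R <- .midlineBirthRate(truth@cometRate, v, midLen)
            nL <- rpois(1L, R * duration); nR <- rpois(1L, R * duration)
            events <- data.frame(
                time_s = c(runif(nL, 0, duration), runif(nR, 0, duration)),
                side = c(rep(-1, nL), rep(1, nR)),
                lateral_um = runif(nL + nR, -midLen / 2, midLen / 2),
                angle_rad = rep(NA_real_, nL + nR),
                speed_um_s = pmax(rnorm(nL + nR, v, truth@cometSpeedSD), 0))
        } else {
            nB <- rpois(1L, truth@cometRate * duration / 10)
            events <- data.frame(
                time_s = runif(nB, 0, duration),
                side = rep(0, nB),
                lateral_um = rep(NA_real_, nB),
                angle_rad = runif(nB, 0, 2 * pi),
                speed_um_s = pmax(rnorm(nB, v, truth@cometSpeedSD), 0))
        }
        events <- events[order(events$time_s), , drop = FALSE]
        rownames(events) <- NULL

        bg <- truth@slideBg + truth@hazeLevel
        xs <- (seq_len(dims[2L]) - 1) * px
        ys <- (seq_len(dims[1L]) - 1) * px
        mov <- array(0, c(nF, dims))
        win <- ceiling(4 * spotSigma / px)
        for (k in seq_len(nF)) {
            t <- (k - 1L) * dt
            frame <- matrix(bg, dims[1L], dims[2L])
            act <- events[events$time_s <= t, , drop = FALSE]
            if (nrow(act)) {
                d <- act$speed_um_s * (t - act$time_s)
                if (geometry == "midline") {
                    cx <- ctr["x"] + act$side * d
                    cy <- ctr["y"] + act$lateral_um
                } else {
                    cx <- ctr["x"] + d * cos(act$angle_rad)
                    cy <- ctr["y"] + d * sin(act$angle_rad)
                }
                for (e in seq_len(nrow(act))) {
                    j0 <- floor(cx[e] / px) + 1L; i0 <- floor(cy[e] / px) + 1L
                    jj <- max(1L, j0 - win):min(dims[2L], j0 + win)
                    ii <- max(1L, i0 - win):min(dims[1L], i0 + win)
                    if (!length(jj) || !length(ii)) next
                    gx <- exp(-((xs[jj] - cx[e])^2) / (2 * spotSigma^2))
                    gy <- exp(-((ys[ii] - cy[e])^2) / (2 * spotSigma^2))
                    frame[ii, jj] <- frame[ii, jj] +
                        truth@cometAmplitude * outer(gy, gx)
                }
            }
            frame <- frame * exp(-truth@bleachRate * t)
            mov[k, , ] <- if (noise)
                .applyNoise(frame, truth@poissonGain, truth@readSD)
            else frame
        }
        list(movie = TimeLapse(mov, px, dt, "EB1"), annotation = ann,
             truth = truth, events = events)
    })
}

#' Simulate an image with planted puncta or nuclei
#'
#' Plants Gaussian spots of known amplitude and position on the gut
#' background, recording the centers as ground truth in the annotation.
#'
#' @param scene,truth see [simulatePrimordium()]; the number of spots is
#'   `fociCount(truth)` (or `nucleusCount` for `what = "nuclei"`).
#' @param spotSigma Gaussian spot radius (um); defaults to 0.25 um for
#'   puncta and 0.5 um for nuclei (condensed histone-marked nuclei).
#' @param seed integer seed.
#' @param what `"foci"` or `"nuclei"` (larger, dimmer blobs).
#' @param centers optional n x 2 matrix of explicit centers (um),
#'   overriding random placement (use to deliberately plant spots closer
#'   than `minSeparation`).
#' @param amplitude spot peak intensity above background; default is 10x
#'   the background noise SD.
#' @param minSeparation minimum center-to-center distance (um) enforced
#'   for random placement.
#' @param noise logical; apply the noise model?
#' @return A list with elements `image` ([ImageStack-class], one plane),
#'   `annotation` (with `fociCenters`/`nucleusCenters` filled in) and
#'   `truth`.
#' @export
simulateFociImage <- function(scene, truth, spotSigma = NULL, seed = NULL,
                              what = c("foci", "nuclei"), centers = NULL,
                              amplitude = NULL, minSeparation = 1,
                              noise = TRUE) {
    what <- match.arg(what)
    if (is.null(spotSigma)) spotSigma <- if (what == "foci") 0.25 else 0.5
    k <- if (what == "foci") truth@fociCount else truth@nucleusCount
    bgLevel <- truth@slideBg + truth@autofluoLevel + truth@cytoLevel
    if (is.null(amplitude))
        amplitude <- 10 * sqrt(bgLevel / truth@poissonGain + truth@readSD^2)
    .withSeed(seed, function() {
        dims <- scene@imageShape; px <- scene@pixelSize
        ann <- defaultAnnotation(scene)
        ctr <- .fieldCenter(scene)
        hw <- scene@primordiumHalfWidth; L <- scene@primordiumLength
        if (is.null(centers)) {
            if (what == "nuclei" && k > 0L) {
                ## nuclei sit in two regular tiers flanking the midline;
                ## a jittered grid reproduces that packing
                nCol <- ceiling(k / 2)
                yy <- ctr["y"] + seq(-L / 2 + 1, L / 2 - 1,
                                     length.out = max(nCol, 2L))[seq_len(nCol)]
                xx <- ctr["x"] + c(-hw / 2, hw / 2)
                grid <- cbind(rep(xx, each = nCol), rep(yy, 2L))[seq_len(k), ,
                                                                drop = FALSE]
                jit <- min(0.1, minSeparation / 4)
                pts <- grid + matrix(runif(2L * k, -jit, jit), k)
            } else {
                pts <- matrix(numeric(), 0L, 2L)
                guard <- 0L
                while (nrow(pts) < k && guard < 10000L) {
                    cand <- c(ctr["x"] + runif(1, -hw + 1, hw - 1),
                              ctr["y"] + runif(1, -L / 2 + 1, L / 2 - 1))
                    if (nrow(pts) == 0L ||
                        min(sqrt(rowSums(sweep(pts, 2L, cand)^2))) >=
                            minSeparation)
                        pts <- rbind(pts, cand)
                    guard <- guard + 1L
                }
                if (nrow(pts) < k)
                    stop("could not place ", k, " spots at minSeparation = ",
                         minSeparation, " um inside the primordium")
            }
            centers <- pts
        } else {
            centers <- as.matrix(centers)
            k <- nrow(centers)
        }
        rownames(centers) <- NULL
        img <- matrix(bgLevel, dims[1L], dims[2L])
        xs <- (seq_len(dims[2L]) - 1) * px
        ys <- (seq_len(dims[1L]) - 1) * px
        for (e in seq_len(k)) {
            gx <- exp(-((xs - centers[e, 1L])^2) / (2 * spotSigma^2))
            gy <- exp(-((ys - centers[e, 2L])^2) / (2 * spotSigma^2))
            img <- img + amplitude * outer(gy, gx)
        }
        if (noise) img <- .applyNoise(img, truth@poissonGain, truth@readSD)
        if (what == "foci") ann@fociCenters <- centers
        else ann@nucleusCenters <- centers
        validObject(ann)
        list(image = ImageStack(img, px, scene@zStep, what),
             annotation = ann, truth = truth)
    })
}
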