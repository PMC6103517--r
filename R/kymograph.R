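## Kymograph construction and slope-based comet speed estimation, with
## the per-embryo averaging and exclusion rules used for genotype
## comparisons.

#' Build a kymograph along a path
#'
#' Samples the movie at unit-pixel steps along the path; at each step
#' the intensity is the mean over `width` pixels perpendicular to the
#' path, interpolated bilinearly at sub-pixel positions. Rows are
#' frames, columns are steps along the path.
#'
#' @param movie a [TimeLapse-class].
#' @param path 2x2 matrix of path endpoints (um).
#' @param width odd perpendicular averaging width in pixels (default 5).
#' @return A [Kymograph-class].
#' @export
makeKymograph <- function(movie, path, width = 5L) {
    width <- as.integer(width)
    if (width < 1L || width %% 2L == 0L) stop("width must be odd and >= 1")
    px <- pixelSize(movie)
    d <- dim(imgData(movie))
    fr <- .pathFrame(path)
    nS <- floor(fr$length / px) + 1L
    sPos <- (seq_len(nS) - 1L) * px
    wOff <- (seq_len(width) - (width + 1L) / 2) * px
    ## sample grid: nS steps x width perpendicular offsets
    gx <- outer(sPos, rep(1, width)) * fr$u[1L] + path[1L, 1L] +
        outer(rep(1, nS), wOff) * fr$n[1L]
    gy <- outer(sPos, rep(1, width)) * fr$u[2L] + path[1L, 2L] +
        outer(rep(1, nS), wOff) * fr$n[2L]
    lim <- c((d[3L] - 1) * px, (d[2L] - 1) * px)
    if (any(gx < -1e-9 | gx > lim[1L] + 1e-9 |
            gy < -1e-9 | gy > lim[2L] + 1e-9))
        stop("kymograph path (plus width) exits the field")
    nF <- d[1L]
    out <- matrix(0, nF, nS)
    for (k in seq_len(nF)) {
        v <- .bilinear(imgData(movie)[k, , ], px, as.vector(gx),
                       as.vector(gy))
        out[k, ] <- rowMeans(matrix(v, nS, width))
    }
    new("Kymograph", data = out, path = path, lineWidth = width,
        frameInterval = frameInterval(movie), pixelSize = px)
}

#' Estimate comet speeds from kymograph streaks
#'
#' Thresholds the kymograph at a robust background level (median +
#' `kSD` robust SDs), extracts connected streak components spanning at
#' least `minStreakFrames` frames, and fits each component's per-frame
#' intensity-weighted centroid position against time by least squares.
#' Rows where the streak touches the kymograph edge are dropped (the
#' spot is partially outside the path there, which drags its centroid),
#' and the fit is refined by `refit` rounds of residual trimming so
#' that a second comet briefly merging into the streak does not tilt
#' the slope. Components whose final fit has R-squared below `minR2`
#' are discarded; components with (numerically) constant position are
#' stationary spots and report speed 0. Speeds are |slope| in um/s.
#'
#' @param kymo a [Kymograph-class].
#' @param minStreakFrames minimum temporal extent of a streak (frames).
#' @param kSD threshold multiplier.
#' @param minR2 minimum R-squared of the distance-time fit.
#' @param refit rounds of trimmed least-squares refinement (residuals
#'   beyond 2.5 robust SDs dropped).
#' @return Numeric vector of speeds (um/s), possibly empty, with a
#'   `details` attribute data.frame (`speed`, `r2`, `nFrames`).
#' @export
estimateSpeeds <- function(kymo, minStreakFrames = 5L, kSD = 4,
                           minR2 = 0.8, refit = 2L) {
    dat <- imgData(kymo)
    if (nrow(dat) < minStreakFrames)
        stop("kymograph has fewer than minStreakFrames rows")
    empty <- function() {
        out <- numeric()
        attr(out, "details") <- data.frame(speed = numeric(),
                                           r2 = numeric(),
                                           nFrames = integer())
        out
    }
    thr <- median(dat) + kSD * .robustScale(dat)
    mask <- dat > thr
    if (!any(mask)) return(empty())
    ## dilate before labelling so that streaks moving > 1 px/frame stay
    ## connected, then label the original pixels
    dil <- EBImage::dilate(EBImage::Image(mask * 1),
                           EBImage::makeBrush(3, "box"))
    lab <- EBImage::bwlabel(dil)
    lab <- as.matrix(EBImage::imageData(lab)) * mask
    px <- pixelSize(kymo); dt <- frameInterval(kymo)
    speeds <- numeric(); r2s <- numeric(); nfs <- integer()
    for (cc in setdiff(unique(as.vector(lab)), 0)) {
        idx <- which(lab == cc, arr.ind = TRUE)
        fr <- sort(unique(idx[, 1L]))
        if (length(fr) < minStreakFrames) next
        cen <- numeric(length(fr)); clip <- logical(length(fr))
        for (i in seq_along(fr)) {
            cols <- idx[idx[, 1L] == fr[i], 2L]
            w <- dat[cbind(fr[i], cols)] - thr
            cen[i] <- sum(cols * w) / sum(w)
            clip[i] <- min(cols) == 1L || max(cols) == ncol(dat)
        }
        fr <- fr[!clip]; cen <- cen[!clip]
        if (length(fr) < minStreakFrames) next
        if (sd(cen) < 1e-9) {  # stationary spot: vertical streak
            speeds <- c(speeds, 0); r2s <- c(r2s, 1)
            nfs <- c(nfs, length(fr)); next
        }
        keep <- rep(TRUE, length(fr))
        fit <- NULL
        for (it in 0:refit) {
            fit <- lm(cen[keep] ~ fr[keep])
            if (it == refit) break
            res <- cen - (coef(fit)[1L] + coef(fit)[2L] * fr)
            s <- mad(res[keep])
            if (s < 1e-9) break
            keep2 <- abs(res) < 2.5 * s
            if (sum(keep2) < minStreakFrames || all(keep2 == keep)) break
            keep <- keep2
        }
        cenK <- cen[keep]
        sst <- sum((cenK - mean(cenK))^2)
        r2 <- if (sst < 1e-12) 1 else 1 - sum(stats::resid(fit)^2) / sst
        if (!is.finite(r2) || r2 < minR2) next
        speeds <- c(speeds, abs(coef(fit)[2L]) * px / dt)
        r2s <- c(r2s, r2); nfs <- c(nfs, sum(keep))
    }
    out <- unname(speeds)
    attr(out, "details") <- data.frame(speed = out, r2 = r2s, nFrames = nfs)
    out
}

#' Measure all comet speeds in one embryo movie
#'
#' Automates the manual practice of drawing a kymograph line along each
#' visible comet and measuring that comet's slope: trajectories are
#' detected ([detectTrajectories()]), a kymograph path is laid through
#' each trajectory's course (for `"midline"` geometry, perpendicular to
#' the midline at the trajectory's lateral position; for `"radial"`,
#' outward from the field-center source along the trajectory's
#' direction), streak slopes are measured on the kymograph
#' ([estimateSpeeds()]), and the streak whose speed agrees with the
#' trajectory's own coarse displacement rate is reported -- one comet
#' per kymograph, so streaks of neighboring comets grazing the same
#' line are not attributed to it. Paths that coincide are measured
#' once.
#'
#' @param movie a [TimeLapse-class] (bleach-corrected).
#' @param annotation the embryo's [EmbryoAnnotation-class].
#' @param geometry `"midline"` or `"radial"`.
#' @param width kymograph line width in pixels.
#' @param pathStart distance from the midline (or source) at which
#'   measurement paths begin (um); skipping the birth zone keeps newly
#'   born comets of neighboring tracks out of the streak being fit.
#' @param minTrackFrames minimum trajectory length used to place a path.
#' @param minDisplacement minimum net trajectory displacement (um).
#' @param sigma,kSD,vMax detection parameters, see
#'   [detectTrajectories()].
#' @param minStreakFrames,minR2 streak-fit parameters, see
#'   [estimateSpeeds()].
#' @return Numeric vector of comet speeds (um/s) for the embryo.
#' @export
measureCometSpeeds <- function(movie, annotation,
                               geometry = c("midline", "radial"),
                               width = 5L, pathStart = 0.8,
                               minTrackFrames = 5L,
                               minDisplacement = 0.5, sigma = 0.15,
                               kSD = 5, vMax = 1.5, minStreakFrames = 5L,
                               minR2 = 0.8) {
    geometry <- match.arg(geometry)
    px <- pixelSize(movie)
    d <- dim(imgData(movie))
    lim <- c((d[3L] - 1) * px, (d[2L] - 1) * px)
    trj <- detectTrajectories(movie, sigma = sigma, kSD = kSD, vMax = vMax)
    if (!nrow(trj)) return(numeric())
    ml <- midline(annotation)
    mlMid <- (ml[1L, ] + ml[2L, ]) / 2
    fr <- .pathFrame(ml)
    paths <- list()
    vTracks <- numeric()
    keys <- character()
    for (id in unique(trj$track)) {
        tk <- trj[trj$track == id, , drop = FALSE]
        if (nrow(tk) < minTrackFrames) next
        disp <- sqrt((tk$x[nrow(tk)] - tk$x[1L])^2 +
                     (tk$y[nrow(tk)] - tk$y[1L])^2)
        if (disp < minDisplacement) next
        ## coarse displacement rate of this comet, used to pick its own
        ## streak on the kymograph: |distance from the midline| for
        ## midline comets, radius from the source for radial ones
        rr <- if (geometry == "midline")
            abs(.midlineCoords(tk$x, tk$y, ml)$dist)
        else sqrt((tk$x - mlMid[1L])^2 + (tk$y - mlMid[2L])^2)
        vTrack <- abs(unname(coef(lm(rr ~ tk$time_s))[2L]))
        if (geometry == "midline") {
            mc <- .midlineCoords(tk$x, tk$y, ml)
            side <- sign(mean(mc$dist))
            if (side == 0) side <- 1
            u0 <- median(mc$along)
            u0 <- max(min(u0, fr$length / 2), -fr$length / 2)
            dirv <- side * fr$dplus
            p0 <- mlMid + u0 * fr$u + pathStart * dirv
            key <- paste0(side, "@", round(u0 * 2) / 2)
        } else {
            dx <- tk$x[nrow(tk)] - tk$x[1L]; dy <- tk$y[nrow(tk)] - tk$y[1L]
            th <- atan2(dy, dx)
            dirv <- c(cos(th), sin(th))
            p0 <- mlMid + pathStart * dirv  # field-center source
            key <- paste0("r@", round(th / (pi / 36)))  # 5-degree bins
        }
        if (key %in% keys) next
        ## longest path from p0 along dirv staying inside the field,
        ## leaving room for the perpendicular averaging width
        marg <- (as.integer(width) %/% 2L + 1L) * px
        reach <- Inf
        for (i in 1:2) {
            if (abs(dirv[i]) > 1e-12) {
                cand <- c((lim[i] - marg - p0[i]) / dirv[i],
                          (marg - p0[i]) / dirv[i])
                reach <- min(reach, max(cand))
            }
        }
        reach <- min(reach,
                     if (geometry == "midline") 1.2 * max(abs(lim)) else reach)
        if (!is.finite(reach) || reach < minStreakFrames * px) next
        paths[[length(paths) + 1L]] <- rbind(p0, p0 + reach * dirv)
        vTracks <- c(vTracks, vTrack)
        keys <- c(keys, key)
    }
    speeds <- numeric()
    for (i in seq_along(paths)) {
        ky <- tryCatch(makeKymograph(movie, paths[[i]], width = width),
                       error = function(e) NULL)
        if (is.null(ky)) next
        sp <- estimateSpeeds(ky, minStreakFrames = minStreakFrames,
                             minR2 = minR2, kSD = kSD)
        if (!length(sp)) next
        ## one comet per kymograph: take the streak that matches the
        ## trajectory the line was drawn for
        j <- which.min(abs(sp - vTracks[i]))
        if (abs(sp[j] - vTracks[i]) <= 0.4 * max(vTracks[i], 0.1))
            speeds <- c(speeds, sp[j])
    }
    speeds
}

#' Per-embryo mean comet speed with exclusion rules
#'
#' An embryo's average speed is only meaningful when based on two or
#' more measured comets. For E16 embryos with fewer, the embryo is
#' flagged `"insufficient"` (re-measure or drop); two-cell embryos with
#' fewer are `"excluded"` from analysis.
#'
#' @param speeds numeric vector of comet speeds for one embryo.
#' @param context `"E16"` or `"two_cell"`.
#' @return A list with `mean` (NA unless status is `"ok"`), `status`
#'   (`"ok"`, `"insufficient"` or `"excluded"`) and `n`.
#' @export
embryoMeanSpeed <- function(speeds, context = c("E16", "two_cell")) {
    context <- match.arg(context)
    n <- length(speeds)
    if (n < 2L)
        return(list(mean = NA_real_,
                    status = if (context == "E16") "insufficient"
                             else "excluded",
                    n = n))
    list(mean = mean(speeds), status = "ok", n = n)
}

#' Summarize embryo means by genotype
#'
#' Per-genotype mean and SD of the per-embryo mean speeds and crossing
#' counts, with a warning when fewer than `totalCometsMin` comets were
#' measured in a genotype. A genotype with a single embryo reports SD 0
#' and is flagged.
#'
#' @param perEmbryo data.frame with columns `genotype`, `embryo`,
#'   `meanSpeed` (um/s), `nComets`, and optionally `crossings`.
#' @param totalCometsMin minimum comets per genotype before warning.
#' @return A data.frame with one row per genotype: `genotype`,
#'   `nEmbryos`, `totalComets`, `meanSpeed`, `sdSpeed`,
#'   `meanCrossings`, `sdCrossings`, `singleEmbryo`.
#' @export
genotypeSummary <- function(perEmbryo, totalCometsMin = 30L) {
    stopifnot(all(c("genotype", "embryo", "meanSpeed", "nComets") %in%
                  names(perEmbryo)))
    res <- lapply(split(perEmbryo, perEmbryo$genotype), function(g) {
        single <- nrow(g) == 1L
        data.frame(
            genotype = g$genotype[1L], nEmbryos = nrow(g),
            totalComets = sum(g$nComets),
            meanSpeed = mean(g$meanSpeed),
            sdSpeed = if (single) 0 else sd(g$meanSpeed),
            meanCrossings = if ("crossings" %in% names(g))
                mean(g$crossings) else NA_real_,
            sdCrossings = if ("crossings" %in% names(g)) {
                if (single) 0 else sd(g$crossings)
            } else NA_real_,
            singleEmbryo = single)
    })
    out <- do.call(rbind, res)
    rownames(out) <- NULL
    low <- out$totalComets < totalCometsMin
    if (any(low))
        warning("fewer than ", totalCometsMin, " comets analyzed for: ",
                paste(out$genotype[low], collapse = ", "))
    out
}
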