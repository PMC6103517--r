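## Frame-by-frame comet detection and nearest-neighbor trajectory
## linking; crossing counts at offset lines flanking the midline.

#' Detect comet spots in every frame of a movie
#'
#' Runs the smoothed-local-maxima detector of [countFoci()] on each
#' frame and links detections into trajectories by greedy
#' nearest-neighbor matching between consecutive frames, with a maximum
#' step of `3 vMax frameInterval` per elapsed frame. A track missing
#' from up to `maxGap` consecutive frames may be re-linked (gap
#' closing), so a single missed detection does not split a trajectory.
#'
#' @param movie a [TimeLapse-class] (bleach-correct it first).
#' @param sigma spot smoothing width (um).
#' @param kSD detection threshold multiplier.
#' @param vMax largest plausible comet speed (um/s), bounding the link
#'   step.
#' @param minSeparation minimum separation between detections in one
#'   frame (um).
#' @param maxGap frames a track may go undetected before it is closed.
#' @return A data.frame with columns `track`, `frame`, `time_s`, `x`,
#'   `y` (um), ordered by track then frame.
#' @export
detectTrajectories <- function(movie, sigma = 0.15, kSD = 5, vMax = 1.5,
                               minSeparation = 0.5, maxGap = 2L) {
    px <- pixelSize(movie)
    dt <- frameInterval(movie)
    dat <- imgData(movie)
    nF <- dim(dat)[1L]
    maxStep <- 3 * vMax * dt
    rows <- vector("list", nF)
    lastPos <- matrix(numeric(), 0L, 2L)  # positions of active tracks
    lastIds <- integer()
    lastAge <- integer()  # frames since the track was last seen
    nextId <- 1L
    for (k in seq_len(nF)) {
        det <- countFoci(dat[k, , ], pixelSize = px,
                         minSeparation = minSeparation, sigma = sigma,
                         kSD = kSD)$centers
        ids <- integer(nrow(det))
        matched <- logical(length(lastIds))
        if (nrow(det) && nrow(lastPos)) {
            dmat <- sqrt(outer(det[, 1L], lastPos[, 1L], "-")^2 +
                         outer(det[, 2L], lastPos[, 2L], "-")^2)
            lim <- matrix(maxStep * rep(lastAge, each = nrow(det)),
                          nrow(det))
            dmat[dmat > lim] <- Inf
            repeat {
                m <- which.min(dmat)
                if (!length(m) || !is.finite(dmat[m])) break
                i <- (m - 1L) %% nrow(dmat) + 1L
                j <- (m - 1L) %/% nrow(dmat) + 1L
                ids[i] <- lastIds[j]
                matched[j] <- TRUE
                dmat[i, ] <- Inf; dmat[, j] <- Inf
            }
        }
        new <- ids == 0L
        if (any(new)) {
            ids[new] <- seq.int(nextId, nextId + sum(new) - 1L)
            nextId <- nextId + sum(new)
        }
        if (nrow(det))
            rows[[k]] <- data.frame(track = ids, frame = k,
                                    time_s = (k - 1L) * dt,
                                    x = det[, 1L], y = det[, 2L])
        ## carry unmatched actives forward, aging them out after maxGap
        keepOld <- !matched & lastAge <= maxGap
        lastPos <- rbind(det, lastPos[keepOld, , drop = FALSE])
        lastIds <- c(ids, lastIds[keepOld])
        lastAge <- c(rep(1L, nrow(det)), lastAge[keepOld] + 1L)
    }
    out <- do.call(rbind, rows)
    if (is.null(out))
        out <- data.frame(track = integer(), frame = integer(),
                          time_s = numeric(), x = numeric(), y = numeric())
    out[order(out$track, out$frame), , drop = FALSE]
}

#' Count comets crossing offset lines flanking the midline
#'
#' Overlays a line of `lineLength` micrometers at `offset` micrometers
#' from the midline on either side and counts the comet trajectories
#' whose perpendicular distance from the midline passes from below
#' `offset` to at or beyond it while laterally within the line, within
#' the first `window` seconds. Each trajectory is counted at most once
#' per line.
#'
#' The comet's lateral position is taken as the median of the
#' trajectory's along-midline coordinate (it is constant for a comet
#' moving perpendicular to the midline, so the median is much less
#' noisy than any single sample). A trajectory may register more than
#' one crossing per line only after first retreating below
#' `offset - hysteresis` -- a genuine comet never retreats, so this
#' recovers crossings lost to trajectory identity switches without
#' double-counting detection jitter around the line.
#'
#' @param movie a [TimeLapse-class].
#' @param midline 2x2 endpoint matrix (um), e.g. from the annotation.
#' @param offset line offset from the midline (um).
#' @param lineLength line length (um).
#' @param window counting window (s); must not exceed the movie.
#' @param hysteresis retreat (um) required before a second crossing of
#'   the same line by one trajectory counts.
#' @param minSeparation in-frame detection separation (um).
#' @param ... further detection/linking parameters passed to
#'   [detectTrajectories()].
#' @return A list with `left`, `right`, `total` counts and the
#'   `trajectories` data.frame used.
#' @export
countCrossings <- function(movie, midline, offset = 3, lineLength = 5,
                           window = 10, hysteresis = 0.3,
                           minSeparation = 0.35, ...) {
    dt <- frameInterval(movie)
    duration <- (nFrames(movie) - 1L) * dt
    if (window > duration + 1e-9)
        stop("counting window (", window, " s) exceeds movie duration (",
             signif(duration, 4), " s)")
    trj <- detectTrajectories(movie, minSeparation = minSeparation, ...)
    trj <- trj[trj$time_s <= window + 1e-9, , drop = FALSE]
    counts <- c(left = 0L, right = 0L)
    if (nrow(trj)) {
        mc <- .midlineCoords(trj$x, trj$y, midline)
        trj$dist <- mc$dist
        trj$along <- mc$along
        for (id in unique(trj$track)) {
            tk <- trj[trj$track == id, , drop = FALSE]
            if (abs(median(tk$along)) > lineLength / 2) next
            for (s in c(-1, 1)) {
                sd <- s * tk$dist
                armed <- sd[1L] < offset  # must be seen below the line
                nm <- if (s < 0) "left" else "right"
                for (h in seq_along(sd)[-1L]) {
                    if (armed && sd[h] >= offset) {
                        counts[nm] <- counts[nm] + 1L
                        armed <- FALSE
                    } else if (!armed && sd[h] < offset - hysteresis) {
                        armed <- TRUE
                    }
                }
            }
        }
    }
    list(left = unname(counts["left"]), right = unname(counts["right"]),
         total = unname(counts["left"] + counts["right"]),
         trajectories = trj)
}
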