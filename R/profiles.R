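## Line-intensity profiles across the apical midline and their cohort
## summaries (peak / cytoplasmic regions).

#' Intensity profile across the apical midline
#'
#' Averages pixel intensities in bins of signed perpendicular distance
#' from the directed midline (left of the direction of travel is
#' negative), over a band of `width` micrometers along the midline
#' centered at its midpoint. Bins are one pixel wide; a pixel belongs to
#' the profile when its center lies inside the band and within `maxDist`
#' of the midline.
#'
#' @param img numeric matrix (typically a background-subtracted sum
#'   projection).
#' @param midline 2x2 matrix of segment endpoints (um).
#' @param pixelSize um per pixel.
#' @param width band width along the midline (um, default 1).
#' @param maxDist maximum |distance| from the midline (um, default 5).
#' @param embryo optional embryo identifier stored in the result.
#' @return A data.frame with columns `distance` (bin center, um),
#'   `intensity` (mean over the bin) and `npx` (pixels in the bin), with
#'   attributes `pixelSize` and `embryo`.
#' @examples
#' img <- matrix(7, 64, 64)
#' ml <- rbind(c(3.5, 1), c(3.5, 6))
#' pr <- lineProfile(img, ml, pixelSize = 0.11)
#' all(pr$intensity == 7)
#' @export
lineProfile <- function(img, midline, pixelSize, width = 1, maxDist = 5,
                        embryo = NA_character_) {
    mlLen <- sqrt(sum((midline[2L, ] - midline[1L, ])^2))
    if (mlLen < width)
        stop("midline segment (", signif(mlLen, 3),
             " um) is shorter than the band width (", width, " um)")
    d <- dim(img)
    mc <- .midlineCoordsImage(d, pixelSize, midline)
    ## reject bands that extend past the image: check the 4 band corners
    fr <- .pathFrame(midline)
    mid <- (midline[1L, ] + midline[2L, ]) / 2
    corners <- rbind(mid + fr$u * width / 2 + fr$n * maxDist,
                     mid + fr$u * width / 2 - fr$n * maxDist,
                     mid - fr$u * width / 2 + fr$n * maxDist,
                     mid - fr$u * width / 2 - fr$n * maxDist)
    lim <- c((d[2L] - 1) * pixelSize, (d[1L] - 1) * pixelSize)
    out <- corners[, 1L] < 0 | corners[, 1L] > lim[1L] |
        corners[, 2L] < 0 | corners[, 2L] > lim[2L]
    if (any(out))
        stop("profile band exits the image: corner(s) at ",
             paste(apply(corners[out, , drop = FALSE], 1L, function(p)
                 sprintf("(%.2f, %.2f)", p[1L], p[2L])), collapse = ", "),
             " um lie outside [0, ", signif(lim[1L], 4), "] x [0, ",
             signif(lim[2L], 4), "] um")
    sel <- abs(mc$dist) <= maxDist & abs(mc$along) <= width / 2
    if (!any(sel)) stop("no pixel centers inside the profile band")
    dd <- mc$dist[sel]
    vals <- img[sel]
    ## snap to 9 decimals before flooring so pixels that sit exactly on a
    ## slab edge bin deterministically (upward) instead of by FP wobble
    bin <- floor(round(dd / pixelSize, 9L))
    agg <- tapply(vals, bin, mean)
    cnt <- tapply(vals, bin, length)
    k <- as.integer(names(agg))
    o <- order(k)
    res <- data.frame(distance = (k[o] + 0.5) * pixelSize,
                      intensity = as.numeric(agg[o]),
                      npx = as.integer(cnt[o]))
    attr(res, "pixelSize") <- pixelSize
    attr(res, "embryo") <- embryo
    res
}

#' Summarize a cohort of midline profiles
#'
#' Computes the per-bin mean and SD across embryos, each embryo's mean
#' cytoplasmic (2.5-5 um from the midline) and peak-region intensity,
#' and the peak region itself. The peak region is found on the cohort
#' mean profile by the half-max rule: all bins whose intensity reaches
#' halfway between the mean cytoplasmic value and the profile maximum,
#' taking the connected run that contains the maximum (and restricted to
#' |distance| < 2.5 um). Optionally each profile is first normalized by
#' its own cytoplasmic mean (used for markers expressed from variable
#' arrays; endogenous markers are left unnormalized).
#'
#' @param profiles list of [lineProfile()] results on identical bin
#'   grids.
#' @param normalize logical; divide each profile by its cytoplasmic mean?
#' @param cytoRange distance range (um) defining the cytoplasmic region.
#' @return A list with `profile` (data.frame distance/mean/sd),
#'   `perEmbryo` (data.frame embryo/meanPeak/meanCyto), `peakRegion`
#'   (range of distances, um; `NULL` when the profile is flat and the
#'   half-max rule is undefined), `peakDefined` flag, and `normalize`.
#' @export
summarizeProfiles <- function(profiles, normalize = FALSE,
                              cytoRange = c(2.5, 5)) {
    stopifnot(length(profiles) >= 1L)
    dist0 <- profiles[[1L]]$distance
    for (p in profiles)
        if (length(p$distance) != length(dist0) ||
            max(abs(p$distance - dist0)) > 1e-9)
            stop("profiles are not on identical bin grids")
    cytoBins <- abs(dist0) >= cytoRange[1L] & abs(dist0) <= cytoRange[2L]
    if (!any(cytoBins)) stop("no bins in the cytoplasmic region")
    mat <- vapply(profiles, function(p) p$intensity, dist0)
    mat <- matrix(mat, nrow = length(dist0))
    if (normalize)
        mat <- sweep(mat, 2L, colMeans(mat[cytoBins, , drop = FALSE]), "/")
    mn <- rowMeans(mat)
    sdv <- apply(mat, 1L, sd)
    cytoMean <- mean(mn[cytoBins])
    pk <- which.max(mn)
    peakDefined <- mn[pk] > cytoMean + 1e-12
    peakRegion <- NULL
    peakBins <- logical(length(dist0))
    if (peakDefined) {
        thr <- cytoMean + 0.5 * (mn[pk] - cytoMean)
        above <- mn >= thr & abs(dist0) < cytoRange[1L]
        if (above[pk]) {
            lo <- pk; while (lo > 1L && above[lo - 1L]) lo <- lo - 1L
            hi <- pk; while (hi < length(above) && above[hi + 1L]) hi <- hi + 1L
            peakBins[lo:hi] <- TRUE
            peakRegion <- c(dist0[lo], dist0[hi])
        } else {
            peakDefined <- FALSE  # maximum sits outside +-2.5 um
        }
    }
    ids <- vapply(seq_along(profiles), function(i) {
        e <- attr(profiles[[i]], "embryo")
        if (is.null(e) || is.na(e)) paste0("embryo", i) else as.character(e)
    }, "")
    perEmbryo <- data.frame(
        embryo = ids,
        meanPeak = if (any(peakBins))
            colMeans(mat[peakBins, , drop = FALSE]) else NA_real_,
        meanCyto = colMeans(mat[cytoBins, , drop = FALSE]))
    list(profile = data.frame(distance = dist0, mean = mn, sd = sdv),
         perEmbryo = perEmbryo, peakRegion = peakRegion,
         peakDefined = peakDefined, normalize = normalize)
}
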