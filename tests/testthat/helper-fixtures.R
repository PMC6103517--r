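## Shared fixtures and independent brute-force oracles. The oracles are
## deliberately written as slow scalar loops over pixels, separate from
## any vectorized code path in the package.

## a small scene that keeps simulations fast
smallScene <- function(shape = 136L, L = 8, hw = 5, margin = 1,
                       frameInterval = 0.1)
    SceneParams(imageShape = c(shape, shape), primordiumLength = L,
                primordiumHalfWidth = hw, fieldMargin = margin,
                frameInterval = frameInterval)

## scene used for comet movies (matches the comet travel range)
cometScene <- function()
    SceneParams(imageShape = c(160L, 160L), primordiumLength = 10,
                primordiumHalfWidth = 5.5, fieldMargin = 2)

## noise-free ground truth
cleanTruth <- function(...)
    GroundTruth(readSD = 0, poissonGain = 1e9, bleachRate = 0,
                cometSpeedSD = 0, ...)

## ORACLE: mean over pixels whose centers fall in a rectangle, by loop
oracleRectMean <- function(img, px, rect) {
    acc <- 0; n <- 0L
    for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
        x <- (j - 1) * px; y <- (i - 1) * px
        if (x >= rect[1] && x <= rect[3] && y >= rect[2] && y <= rect[4]) {
            acc <- acc + img[i, j]; n <- n + 1L
        }
    }
    acc / n
}

## ORACLE: line profile by per-pixel point-to-line classification
oracleLineProfile <- function(img, midline, px, width = 1, maxDist = 5) {
    p0 <- midline[1, ]; p1 <- midline[2, ]
    v <- p1 - p0; len <- sqrt(sum(v^2)); u <- v / len
    mid <- len / 2
    sums <- list()
    for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
        x <- (j - 1) * px; y <- (i - 1) * px
        along <- (x - p0[1]) * u[1] + (y - p0[2]) * u[2] - mid
        dist <- (x - p0[1]) * u[2] - (y - p0[2]) * u[1]
        if (abs(along) <= width / 2 && abs(dist) <= maxDist) {
            k <- as.character(floor(round(dist / px, 9)))
            if (is.null(sums[[k]])) sums[[k]] <- c(0, 0)
            sums[[k]] <- sums[[k]] + c(img[i, j], 1)
        }
    }
    ks <- sort(as.integer(names(sums)))
    data.frame(distance = (ks + 0.5) * px,
               intensity = vapply(as.character(ks),
                                  function(k) sums[[k]][1] / sums[[k]][2],
                                  0))
}

## ORACLE: mean over pixels with centers within radius r px of a center
oracleCircleMean <- function(img, px, center, rUm) {
    acc <- 0; n <- 0L
    for (i in seq_len(nrow(img))) for (j in seq_len(ncol(img))) {
        x <- (j - 1) * px; y <- (i - 1) * px
        if ((x - center[1])^2 + (y - center[2])^2 <= rUm^2) {
            acc <- acc + img[i, j]; n <- n + 1L
        }
    }
    list(mean = acc / n, npx = n)
}

## ORACLE: Welch t statistic and df straight from the textbook formula
oracleWelch <- function(m1, s1, n1, m2, s2, n2) {
    se1 <- s1^2 / n1; se2 <- s2^2 / n2
    t <- (m1 - m2) / sqrt(se1 + se2)
    df <- (se1 + se2)^2 / (se1^2 / (n1 - 1) + se2^2 / (n2 - 1))
    list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

## ORACLE: crossings from the generator event log -- births that reach
## the offset line within the window while laterally inside it
oracleCrossings <- function(events, offset = 3, lineLength = 5,
                            window = 10) {
    ok <- abs(events$lateral_um) <= lineLength / 2 &
        events$speed_um_s > 0 &
        events$time_s + offset / events$speed_um_s <= window
    c(left = sum(ok & events$side < 0), right = sum(ok & events$side > 0),
      total = sum(ok))
}

## TRUE when no two same-side crossing comets in the log come closer
## laterally than `sep` while both in transit (such pairs are physically
## unresolvable and merge in any detector)
resolvableEvents <- function(events, sep = 0.6) {
    ev <- events[abs(events$lateral_um) <= 3.5, , drop = FALSE]
    if (nrow(ev) < 2) return(TRUE)
    for (a in seq_len(nrow(ev) - 1)) for (b in (a + 1):nrow(ev)) {
        if (ev$side[a] == ev$side[b] &&
            abs(ev$lateral_um[a] - ev$lateral_um[b]) < sep)
            return(FALSE)
    }
    TRUE
}

## hand-rendered single-comet movie: flat background plus one Gaussian
## spot moving along +x at speed v from (x0, y0)
handMovie <- function(v, x0 = 2, y0 = 7, bg = 100, amp = 60,
                      sigma = 0.15, px = 0.11, dt = 0.1, nF = 101L,
                      n = 128L, t0 = 0) {
    xs <- (seq_len(n) - 1) * px; ys <- xs
    mov <- array(bg, c(nF, n, n))
    for (k in seq_len(nF)) {
        t <- (k - 1) * dt
        if (t < t0) next
        cx <- x0 + v * (t - t0)
        if (cx > max(xs)) next
        mov[k, , ] <- bg + amp * outer(exp(-(ys - y0)^2 / (2 * sigma^2)),
                                       exp(-(xs - cx)^2 / (2 * sigma^2)))
    }
    TimeLapse(mov, px, dt, "EB1")
}

## the standard still-image measurement chain used in several tests
measureEnrichment <- function(sim) {
    ann <- sim$annotation
    px <- pixelSize(sim$marker)
    z <- selectFocusPlane(sim$tubulin, ann@gutBox)
    proj <- sumProject(sim$marker, z, 3L)
    bg <- estimateSlideBackground(proj, ann@bgRects, px)
    apicalEnrichment(proj, ann, px, slideBg = bg)
}
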