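## Box-ROI measurements: apical enrichment, percent depletion inputs and
## formula, and the circular centrosome ROI.

#' Apical enrichment from 2-um apical and cytoplasmic boxes
#'
#' Divides the background-subtracted mean intensity of the 2-um-wide
#' apical box (centered on the midline) by that of the 2-um-wide
#' cytoplasmic box for one image.
#'
#' @param img numeric matrix (sum projection).
#' @param annotation an [EmbryoAnnotation-class] providing the boxes.
#' @param pixelSize um per pixel.
#' @param slideBg scalar slide background to subtract (default 0, i.e.
#'   already subtracted).
#' @param embryo optional identifier.
#' @return One-row data.frame with `embryo`, `apicalMean`, `cytoMean`,
#'   `ratio`.
#' @export
apicalEnrichment <- function(img, annotation, pixelSize, slideBg = 0,
                             embryo = NA_character_) {
    A <- .rectMean(img, pixelSize, annotation@apicalBox) - slideBg
    C <- .rectMean(img, pixelSize, annotation@cytoBox) - slideBg
    if (C <= 0)
        stop("cytoplasmic mean <= 0 after background subtraction ",
             "(background over-subtraction?)")
    data.frame(embryo = embryo, apicalMean = A, cytoMean = C, ratio = A / C)
}

#' Gut and external box means for percent-depletion analysis
#'
#' Measures the mean intensity of the 10-um gut box (G) and the 2-um
#' external box (X) on a slide-background-subtracted image.
#'
#' @param img numeric matrix (sum projection).
#' @param annotation an [EmbryoAnnotation-class].
#' @param pixelSize um per pixel.
#' @param slideBg scalar slide background to subtract.
#' @param embryo optional identifier.
#' @return One-row data.frame with `embryo`, `G`, `X`.
#' @export
measureDepletionInputs <- function(img, annotation, pixelSize, slideBg = 0,
                                   embryo = NA_character_) {
    data.frame(embryo = embryo,
               G = .rectMean(img, pixelSize, annotation@gutBox) - slideBg,
               X = .rectMean(img, pixelSize, annotation@externalBox) - slideBg)
}

#' Percent depletion from sibling cohorts
#'
#' Each cohort's corrected signal is the mean over embryos of (G - X),
#' minus the autofluorescence estimate `auto` (the mean gut signal of
#' no-fluorophore control embryos). Percent depletion is
#' 100 (1 - signalMinus / signalPlus). Cohorts are siblings, not paired,
#' so the ratio of cohort means is used rather than a mean of per-pair
#' ratios.
#'
#' @param minus data.frame with columns `G`, `X` for the degraded cohort.
#' @param plus data.frame with columns `G`, `X` for the non-degraded
#'   cohort.
#' @param auto scalar autofluorescence estimate.
#' @return A list with `percent`, `signalMinus`, `signalPlus`, `auto`.
#' @export
percentDepletion <- function(minus, plus, auto = 0) {
    stopifnot(nrow(minus) >= 1L, nrow(plus) >= 1L)
    sMinus <- mean(minus$G - minus$X) - auto
    sPlus <- mean(plus$G - plus$X) - auto
    if (sPlus <= 0)
        stop("non-degraded cohort signal <= 0; cannot form a depletion ratio")
    if (sMinus < 0) {
        warning("degraded cohort signal below zero; clamping to 0 ",
                "(depletion capped at 100%)")
        sMinus <- 0
    }
    list(percent = 100 * (1 - sMinus / sPlus), signalMinus = sMinus,
         signalPlus = sPlus, auto = auto)
}

#' Mean intensity of a circular centrosome ROI
#'
#' Selects the z-plane maximizing the mean intensity inside a circular
#' ROI of `diameterPx` pixels, then returns the slide-background-
#' subtracted mean over pixels whose centers lie within the circle
#' radius of the ROI center (pixel-center-within-radius membership).
#'
#' @param stack an [ImageStack-class].
#' @param center ROI center `c(x, y)` in micrometers.
#' @param diameterPx ROI diameter in pixels (default 7).
#' @param slideBg scalar background to subtract.
#' @return A list with `mean` (background-subtracted ROI mean), `plane`
#'   (selected z index) and `npx` (pixels in the ROI).
#' @export
centrosomeIntensity <- function(stack, center, diameterPx = 7, slideBg = 0) {
    px <- pixelSize(stack)
    d <- dim(imgData(stack))
    r <- diameterPx / 2 * px
    lim <- c((d[3L] - 1) * px, (d[2L] - 1) * px)
    if (center[1L] - r < 0 || center[1L] + r > lim[1L] ||
        center[2L] - r < 0 || center[2L] + r > lim[2L])
        stop("circular ROI of radius ", signif(r, 3),
             " um at (", center[1L], ", ", center[2L],
             ") um is clipped by the image border")
    co <- .pixelXY(d[2:3], px)
    dx2 <- outer(rep(1, d[2L]), (co$x - center[1L])^2)
    dy2 <- outer((co$y - center[2L])^2, rep(1, d[3L]))
    mask <- dx2 + dy2 <= r^2
    means <- vapply(seq_len(d[1L]),
                    function(z) mean(imgData(stack)[z, , ][mask]), 0)
    z <- which.max(means)
    list(mean = means[z] - slideBg, plane = z, npx = sum(mask))
}
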