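test_that("apical enrichment has the scaling symmetries of a ratio", {
    sc <- smallScene()
    ## uniform gut: ratio 1
    sim <- simulatePrimordium(sc, cleanTruth(enrichmentRatio = 1,
                                             autofluoLevel = 0),
                              noise = FALSE)
    img <- sumProject(sim$marker, 4L, 3L)
    px <- pixelSize(sim$marker)
    bg <- estimateSlideBackground(img, sim$annotation@bgRects, px)
    e1 <- apicalEnrichment(img, sim$annotation, px, slideBg = bg)
    expect_equal(e1$ratio, 1, tolerance = 1e-9)
    ## enriched image: global multiplicative scaling leaves r unchanged;
    ## apical-only scaling multiplies it
    tr <- cleanTruth(enrichmentRatio = 3, hazeLevel = 0,
                     autofluoLevel = 0, slideBg = 0)
    sim3 <- simulatePrimordium(sc, tr, noise = FALSE)
    img3 <- sumProject(sim3$marker, 4L, 3L)
    ann <- sim3$annotation
    e3 <- apicalEnrichment(img3, ann, px)
    expect_equal(e3$ratio, 3, tolerance = 1e-6)
    eScaled <- apicalEnrichment(img3 * 2.5, ann, px)
    expect_equal(eScaled$ratio, e3$ratio, tolerance = 1e-12)
    apicalMask <- outer((seq_len(nrow(img3)) - 1) * px >= ann@apicalBox[2] &
                        (seq_len(nrow(img3)) - 1) * px <= ann@apicalBox[4],
                        (seq_len(ncol(img3)) - 1) * px >= ann@apicalBox[1] &
                        (seq_len(ncol(img3)) - 1) * px <= ann@apicalBox[3],
                        "&")
    imgA <- img3; imgA[apicalMask] <- imgA[apicalMask] * 2
    expect_equal(apicalEnrichment(imgA, ann, px)$ratio, 2 * e3$ratio,
                 tolerance = 1e-12)
    ## over-subtraction is an error, not a silent negative ratio
    expect_error(apicalEnrichment(img3, ann, px, slideBg = 1e6),
                 "over-subtraction")
})

test_that("percent depletion formula handles the edge cases", {
    mk <- function(G, X) data.frame(G = G, X = X)
    ## degraded signal zero: 100%
    expect_equal(percentDepletion(mk(0, 0), mk(10, 0))$percent, 100)
    ## identical cohorts: 0%
    expect_equal(percentDepletion(mk(c(5, 7), 0), mk(c(7, 5), 0))$percent, 0)
    ## negative degraded signal clamps to zero with a warning
    expect_warning(r <- percentDepletion(mk(1, 3), mk(10, 0)), "clamping")
    expect_equal(r$percent, 100)
    ## non-degraded signal <= 0 is an error
    expect_error(percentDepletion(mk(5, 0), mk(1, 2)), "cannot form")
})

test_that("noiseless percent depletion equals 100 delta and is monotone", {
    sc <- smallScene()
    got <- vapply(c(0, 0.25, 0.5, 0.931, 1), function(d) {
        co <- simulateDepletionCohort(sc, cleanTruth(depletionFraction = d),
                                      2, 2, 2, seed = 1, noise = FALSE)
        analyzeDepletionCohort(co)$percent
    }, 0)
    expect_equal(got, c(0, 25, 50, 93.1, 100), tolerance = 1e-9)
    expect_true(all(diff(got) > 0) || got[1] == 0)
})

test_that("noisy depletion recovery has small absolute error", {
    ## repeated noisy cohorts at delta = 0.9: mean absolute error below
    ## 2 percentage points
    sc <- smallScene()
    tr <- GroundTruth(depletionFraction = 0.9)
    err <- vapply(1:8, function(i) {
        co <- simulateDepletionCohort(sc, tr, 5, 5, 3, seed = 400 + i)
        abs(analyzeDepletionCohort(co)$percent - 90)
    }, 0)
    expect_lt(mean(err), 2)
})

test_that("centrosome ROI uses pixel-center circle membership", {
    ## uniform stack returns the value, with the documented 37-pixel ROI
    st <- ImageStack(array(8, c(3, 40, 40)), 0.11)
    ctr <- c(20 * 0.11, 20 * 0.11)  # centered on a pixel
    r <- centrosomeIntensity(st, ctr)
    expect_equal(r$mean, 8)
    expect_equal(r$npx, 37L)  # 7-px-diameter circle, center-in-radius rule
    ## planted Gaussian: equals the brute-force in-circle enumeration on
    ## the brightest plane
    arr <- array(10, c(3, 40, 40))
    xs <- (seq_len(40) - 1) * 0.11
    spot <- 50 * outer(exp(-(xs - ctr[2])^2 / (2 * 0.2^2)),
                       exp(-(xs - ctr[1])^2 / (2 * 0.2^2)))
    arr[2, , ] <- arr[2, , ] + spot
    stG <- ImageStack(arr, 0.11)
    rG <- centrosomeIntensity(stG, ctr, slideBg = 10)
    expect_equal(rG$plane, 2L)
    oc <- oracleCircleMean(arr[2, , ], 0.11, ctr, 3.5 * 0.11)
    expect_equal(rG$mean, oc$mean - 10, tolerance = 1e-12)
    expect_equal(rG$npx, oc$npx)
    ## border clipping is an error
    expect_error(centrosomeIntensity(st, c(0.1, 0.1)), "clipped")
})

test_that("foci counting is exact on planted spots", {
    sc <- SceneParams()
    ## blank image: zero
    blank <- simulateFociImage(sc, GroundTruth(fociCount = 0L), seed = 1)
    expect_equal(countFoci(blank$image)$count, 0L)
    ## planted spots with amplitude 10 background SDs, separation at
    ## least twice the merge radius: perfect sensitivity and specificity
    for (s in 1:4) {
        sim <- simulateFociImage(sc, GroundTruth(fociCount = 3L),
                                 seed = 60 + s, minSeparation = 2)
        cf <- countFoci(sim$image, minSeparation = 1)
        expect_equal(cf$count, 3L)
        ## every detection is within half a merge radius of a true center
        tru <- sim$annotation@fociCenters
        for (i in seq_len(nrow(cf$centers))) {
            dmin <- min(sqrt((tru[, 1] - cf$centers[i, 1])^2 +
                             (tru[, 2] - cf$centers[i, 2])^2))
            expect_lt(dmin, 0.5)
        }
    }
    ## two spots planted below the minimum separation merge into one
    ctr <- c(14.025, 14.025)
    pair <- simulateFociImage(sc, GroundTruth(fociCount = 2L), seed = 2,
                              centers = rbind(ctr, ctr + c(0.2, 0)))
    expect_equal(countFoci(pair$image)$count, 1L)
})

test_that("nucleus counting recovers planted tier counts", {
    sc <- SceneParams()
    ## blank
    blank <- simulateFociImage(sc, GroundTruth(nucleusCount = 0L),
                               seed = 1, what = "nuclei")
    expect_equal(countNuclei(blank$image)$count, 0L)
    ## 4 nuclei: the co-depletion arrest count; 16: the full E16 tier set
    for (k in c(4L, 16L)) {
        sim <- simulateFociImage(sc, GroundTruth(nucleusCount = k),
                                 seed = 70 + k, what = "nuclei",
                                 minSeparation = 2.5)
        expect_equal(countNuclei(sim$image)$count, k)
    }
})
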