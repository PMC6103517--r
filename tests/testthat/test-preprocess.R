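test_that("focus plane selection is an argmax with lower-index ties", {
    st <- ImageStack(array(rep(c(1, 5, 2), each = 16), c(3, 4, 4)), 0.11)
    expect_equal(selectFocusPlane(st), 2L)
    flat <- ImageStack(array(7, c(4, 4, 4)), 0.11)
    expect_equal(selectFocusPlane(flat), 1L)  # tie -> lower index
    ## invariant under positive global scaling
    st2 <- ImageStack(imgData(st) * 13.7, 0.11)
    expect_equal(selectFocusPlane(st2), selectFocusPlane(st))
    ## the generator builds the brightest plane at the stack center
    sim <- simulatePrimordium(smallScene(), cleanTruth(), noise = FALSE)
    expect_equal(selectFocusPlane(sim$tubulin, sim$annotation@gutBox), 4L)
    expect_error(selectFocusPlane(st, c(100, 100, 101, 101)), "empty ROI")
})

test_that("sum projection is exact and clips at boundaries", {
    st <- ImageStack(array(3, c(3, 5, 5)), 0.11)
    expect_equal(sumProject(st, 2L, 3L), matrix(9, 5, 5))
    ## boundary: center at z=1 sums only the 2 available slices
    expect_equal(sumProject(st, 1L, 3L), matrix(6, 5, 5))
    ## random stack equals the brute-force elementwise sum exactly
    set.seed(8)
    arr <- array(runif(5 * 6 * 7), c(5, 6, 7))
    stR <- ImageStack(arr, 0.11)
    expect_identical(sumProject(stR, 3L, 3L),
                     arr[2, , ] + arr[3, , ] + arr[4, , ])
    ## window total conservation
    expect_equal(sum(sumProject(stR, 3L, 3L)), sum(arr[2:4, , ]))
    expect_error(sumProject(st, 2L, 2L), "odd")
    expect_error(sumProject(st, 9L), "out of range")
})

test_that("slide background is the unweighted mean of rectangle means", {
    img <- matrix(0, 40, 40)
    r1 <- c(0, 0, 1, 1); r2 <- c(2, 0, 3, 1); r3 <- c(0, 2, 1, 3)
    px <- 0.11
    setRect <- function(img, rect, v) {
        xs <- (col(img) - 1) * px; ys <- (row(img) - 1) * px
        img[xs >= rect[1] & xs <= rect[3] & ys >= rect[2] & ys <= rect[4]] <- v
        img
    }
    img <- setRect(img, r1, 10); img <- setRect(img, r2, 20)
    img <- setRect(img, r3, 30)
    expect_equal(estimateSlideBackground(img, list(r1, r2, r3), px), 20)
    uni <- matrix(4.2, 30, 30)
    expect_equal(estimateSlideBackground(uni, list(r1, r2, r3), px), 4.2)
    expect_error(estimateSlideBackground(uni, list(r1, r2), px), "three")
    ## generated image: estimate recovers slide bg (+ uniform haze) near
    ## truth
    tr <- GroundTruth(slideBg = 50, hazeLevel = 0)
    sims <- lapply(1:6, function(i)
        simulatePrimordium(smallScene(), tr, seed = 50 + i))
    est <- vapply(sims, function(s) {
        proj <- sumProject(s$marker, 4L, 3L)
        ## 3 slide-bg planes summed in the projection
        estimateSlideBackground(proj, s$annotation@bgRects,
                                pixelSize(s$marker)) / 3
    }, 0)
    expect_lt(abs(mean(est) - 50), 3 * sd(est) / sqrt(length(est)) + 0.2)
})

test_that("scalar subtraction is linear and keeps negative values", {
    set.seed(3)
    img <- matrix(runif(64, 0, 10), 8, 8)
    expect_identical(subtractScalar(img, 0), img)
    expect_equal(mean(subtractScalar(img, 4)), mean(img) - 4)
    expect_true(any(subtractScalar(img, 20) < 0))  # not clipped
    ## measure-then-subtract equals subtract-then-measure for ROI means
    r <- c(0.2, 0.2, 0.6, 0.6)
    expect_equal(oracleRectMean(subtractScalar(img, 4), 0.11, r),
                 oracleRectMean(img, 0.11, r) - 4)
    expect_error(subtractScalar(img, NA_real_), "finite")
})

test_that("bleach correction flattens frame means", {
    const <- TimeLapse(array(5, c(6, 8, 8)), 0.11, 0.1)
    expect_equal(imgData(bleachCorrect(const)), imgData(const))
    expect_equal(imgData(bleachCorrect(const, "exponential_fit")),
                 imgData(const))
    ## exact exponential decay, B = 0
    nF <- 40L
    dec <- array(0, c(nF, 8, 8))
    for (k in seq_len(nF)) dec[k, , ] <- 100 * exp(-0.1 * (k - 1) * 0.1)
    mv <- TimeLapse(dec, 0.11, 0.1)
    corr <- bleachCorrect(mv, "exponential_fit")
    fm <- vapply(seq_len(nF), function(k) mean(imgData(corr)[k, , ]), 0)
    expect_lt(max(abs(fm / fm[1] - 1)), 1e-6)
    ## simple_ratio: exactly constant means, and idempotent
    corr2 <- bleachCorrect(mv)
    fm2 <- vapply(seq_len(nF), function(k) mean(imgData(corr2)[k, , ]), 0)
    expect_lt(max(abs(fm2 / fm2[1] - 1)), 1e-12)
    expect_equal(imgData(bleachCorrect(corr2)), imgData(corr2))
    bad <- TimeLapse(array(c(1, -2), c(2, 2, 2)), 0.11, 0.1)
    expect_error(bleachCorrect(bad), "nonpositive")
})

test_that("comet speed estimates are invariant to bleaching", {
    mv <- handMovie(v = 0.5)
    bleached <- mv
    dat <- imgData(bleached)
    for (k in seq_len(nFrames(mv)))
        dat[k, , ] <- dat[k, , ] * exp(-0.05 * (k - 1) * 0.1)
    bleached@data <- dat
    path <- rbind(c(2, 7), c(12, 7))
    s1 <- estimateSpeeds(makeKymograph(mv, path))
    s2 <- estimateSpeeds(makeKymograph(bleachCorrect(bleached), path))
    expect_equal(length(s1), 1L)
    expect_equal(s1, s2, tolerance = 0.01)
    ## and invariant under global intensity scaling
    scaled <- mv; scaled@data <- imgData(mv) * 3.3
    s3 <- estimateSpeeds(makeKymograph(scaled, path))
    expect_equal(s1, s3, tolerance = 1e-6)
})
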