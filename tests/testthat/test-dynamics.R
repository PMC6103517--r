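test_that("kymographs reproduce uniform and stationary structure", {
    uni <- TimeLapse(array(3, c(10, 40, 40)), 0.11, 0.1)
    ky <- makeKymograph(uni, rbind(c(1, 2), c(3, 2)))
    expect_lt(diff(range(imgData(ky))), 1e-12)
    expect_error(makeKymograph(uni, rbind(c(1, 2), c(10, 2))), "exits")
    expect_error(makeKymograph(uni, rbind(c(1, 2), c(3, 2)), width = 4),
                 "odd")
    ## stationary spot: vertical streak, estimated speed zero
    mv <- handMovie(v = 0, x0 = 4, y0 = 7)
    ky2 <- makeKymograph(mv, rbind(c(1, 7), c(12, 7)))
    sp <- estimateSpeeds(ky2)
    expect_equal(length(sp), 1L)
    expect_equal(sp[1], 0)
})

test_that("streak slopes recover speeds within 5% across the range", {
    for (v in c(0.2, 0.5, 0.8, 1.2)) {
        mv <- handMovie(v = v, x0 = 2, y0 = 7)
        ky <- makeKymograph(mv, rbind(c(2, 7), c(13, 7)))
        sp <- estimateSpeeds(ky)
        expect_equal(length(sp), 1L)
        expect_lt(abs(sp[1] - v) / v, 0.05)
    }
})

test_that("kymograph slope matches the generator event log", {
    sc <- cometScene()
    tr <- cleanTruth(cometSpeed = 0.558, cometRate = 1.5)
    sim <- simulateCometMovie(sc, tr, duration = 10, seed = 6,
                              noise = FALSE)
    sp <- measureCometSpeeds(sim$movie, sim$annotation)
    expect_gt(length(sp), 0L)
    ## every measured speed is within 5% of the logged constant speed
    expect_true(all(abs(sp - 0.558) / 0.558 < 0.05))
})

test_that("crossing counts equal the event-log oracle on clean movies", {
    sc <- cometScene()
    tr <- cleanTruth(cometSpeed = 0.558, cometRate = 1)
    tested <- 0L
    for (s in 1:14) {
        sim <- simulateCometMovie(sc, tr, duration = 10, seed = s,
                                  noise = FALSE)
        if (!resolvableEvents(sim$events)) next  # physically merged pair
        cr <- countCrossings(sim$movie, midline(sim$annotation))
        oc <- oracleCrossings(sim$events)
        expect_equal(cr$left, unname(oc["left"]))
        expect_equal(cr$right, unname(oc["right"]))
        tested <- tested + 1L
    }
    expect_gte(tested, 3L)
    ## an empty movie counts nothing
    sim0 <- simulateCometMovie(sc, cleanTruth(cometRate = 0),
                               duration = 10, seed = 1, noise = FALSE)
    cr0 <- countCrossings(sim0$movie, midline(sim0$annotation))
    expect_equal(cr0$total, 0L)
    ## a movie shorter than the window is rejected
    simS <- simulateCometMovie(sc, tr, duration = 2, seed = 1,
                               noise = FALSE)
    expect_error(countCrossings(simS$movie, midline(simS$annotation),
                                window = 10), "window")
})

test_that("crossing-count calibration matches the Poisson expectation", {
    ## the generator promises E[crossings per line] = cometRate; check
    ## the event-log totals over many movies against that expectation
    sc <- cometScene()
    lam <- 4
    tr <- cleanTruth(cometSpeed = 0.558, cometRate = lam)
    tot <- vapply(1:60, function(s) {
        sim <- simulateCometMovie(sc, tr, duration = 10, seed = 700 + s,
                                  noise = FALSE)
        unname(oracleCrossings(sim$events)["total"])
    }, 0)
    se <- sd(tot) / sqrt(length(tot))
    expect_lt(abs(mean(tot) - 2 * lam), 3 * se)
})

test_that("per-embryo averaging applies the exclusion rules", {
    expect_equal(embryoMeanSpeed(c(0.5, 0.7), "E16")$mean, 0.6)
    expect_equal(embryoMeanSpeed(c(0.9), "two_cell")$status, "excluded")
    expect_equal(embryoMeanSpeed(c(0.9), "E16")$status, "insufficient")
    expect_equal(embryoMeanSpeed(numeric(), "E16")$status, "insufficient")
})

test_that("genotype summaries flag sparse data and separate genotypes", {
    one <- data.frame(genotype = "G", embryo = "e1", meanSpeed = 0.7,
                      nComets = 3, crossings = 8)
    expect_warning(s1 <- genotypeSummary(one), "fewer than 30")
    expect_equal(s1$sdSpeed, 0)
    expect_true(s1$singleEmbryo)
    ## two genotypes at the observed speed gap: Welch on embryo means
    ## rejects at alpha = 0.01 for n >= 10 per group
    set.seed(5)
    reject <- vapply(1:30, function(i) {
        a <- rnorm(10, 0.56, 0.05)
        b <- rnorm(10, 0.72, 0.05)
        welchT(mean(a), sd(a), 10, mean(b), sd(b), 10)$p < 0.01
    }, TRUE)
    expect_gt(mean(reject), 0.95)
})
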