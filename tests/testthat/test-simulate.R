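test_that("generation is bit-identical under a fixed seed", {
    sc <- smallScene()
    tr <- GroundTruth()
    a <- simulatePrimordium(sc, tr, seed = 11)
    b <- simulatePrimordium(sc, tr, seed = 11)
    expect_identical(imgData(a$marker), imgData(b$marker))
    expect_identical(imgData(a$tubulin), imgData(b$tubulin))
    m1 <- simulateCometMovie(cometScene(), tr, duration = 3, seed = 4)
    m2 <- simulateCometMovie(cometScene(), tr, duration = 3, seed = 4)
    expect_identical(imgData(m1$movie), imgData(m2$movie))
    expect_identical(m1$events, m2$events)
    ## and the caller's RNG stream is left untouched
    set.seed(99); x1 <- runif(1)
    set.seed(99); invisible(simulatePrimordium(sc, tr, seed = 5))
    expect_identical(runif(1), x1)
})

test_that("unenriched noiseless marker is uniform inside the gut", {
    sim <- simulatePrimordium(smallScene(),
                              cleanTruth(enrichmentRatio = 1),
                              noise = FALSE)
    img <- imgData(sim$marker)[4, , ]  # central plane
    px <- pixelSize(sim$marker)
    inGut <- abs((col(img) - 1) * px - sim$annotation@midline[1, 1]) <= 4 &
        abs((row(img) - 1) * px - mean(sim$annotation@midline[, 2])) <= 2
    gut <- img[inGut]
    expect_lt(diff(range(gut)), 1e-9)
    expect_gt(mean(gut), GroundTruth()@slideBg)  # above background
})

test_that("noiseless box means match brute-force pixel enumeration", {
    sc <- smallScene()
    tr <- cleanTruth(enrichmentRatio = 3, cytoLevel = 100, hazeLevel = 0,
                     autofluoLevel = 0, slideBg = 0)
    sim <- simulatePrimordium(sc, tr, noise = FALSE)
    img <- imgData(sim$marker)[4, , ]  # central plane, weight 1
    px <- pixelSize(sim$marker)
    expect_equal(oracleRectMean(img, px, sim$annotation@apicalBox), 300,
                 tolerance = 1e-12)
    expect_equal(oracleRectMean(img, px, sim$annotation@cytoBox), 100,
                 tolerance = 1e-12)
})

test_that("background-subtracted gut intensity is linear in cytoLevel", {
    sc <- smallScene()
    base <- cleanTruth(enrichmentRatio = 2, cytoLevel = 50,
                       autofluoLevel = 0)
    gutMean <- function(tr) {
        sim <- simulatePrimordium(sc, tr, noise = FALSE)
        proj <- sumProject(sim$marker, 4L, 3L)
        bg <- estimateSlideBackground(proj, sim$annotation@bgRects,
                                      pixelSize(sim$marker))
        mean(subtractScalar(proj, bg)[
            .rectMaskTest(dim(proj), pixelSize(sim$marker),
                          sim$annotation@gutBox)])
    }
    .rectMaskTest <- function(dims, px, rect) {
        xs <- (seq_len(dims[2]) - 1) * px
        ys <- (seq_len(dims[1]) - 1) * px
        outer(ys >= rect[2] & ys <= rect[4], xs >= rect[1] & xs <= rect[3],
              "&")
    }
    g1 <- gutMean(base)
    g3 <- gutMean(cleanTruth(enrichmentRatio = 2, cytoLevel = 150,
                             autofluoLevel = 0))
    expect_equal(g3 / g1, 3, tolerance = 1e-9)
})

test_that("depletion cohorts implement the sibling design", {
    sc <- smallScene()
    expect_error(GroundTruth(depletionFraction = 2))
    ## delta = 1: degraded gut contains only haze + autofluo + slide bg
    tr <- cleanTruth(depletionFraction = 1, hazeLevel = 20,
                     autofluoLevel = 10, slideBg = 50)
    co <- simulateDepletionCohort(sc, tr, 1, 1, 1, seed = 1, noise = FALSE)
    img <- imgData(co$minus[[1]]$marker)[4, , ]
    px <- pixelSize(co$minus[[1]]$marker)
    gutM <- oracleRectMean(img, px, co$minus[[1]]$annotation@gutBox)
    expect_equal(gutM, 50 + 20 + 10, tolerance = 1e-9)
    ## no-fluorophore controls: autofluorescence only, no haze, no marker
    imgC <- imgData(co$controls[[1]]$marker)[4, , ]
    expect_equal(oracleRectMean(imgC, px, co$controls[[1]]$annotation@gutBox),
                 50 + 10, tolerance = 1e-9)
    ## delta = 0: the two cohorts are the same process; noiseless identical
    tr0 <- cleanTruth(depletionFraction = 0)
    co0 <- simulateDepletionCohort(sc, tr0, 1, 1, 1, seed = 2,
                                   noise = FALSE)
    expect_equal(imgData(co0$minus[[1]]$marker),
                 imgData(co0$plus[[1]]$marker))
})

test_that("comet movies honor the event model", {
    sc <- cometScene()
    expect_error(simulateCometMovie(sc, GroundTruth(), duration = -1),
                 "positive")
    ## no emission: background-only movie, empty event log
    sim0 <- simulateCometMovie(sc, cleanTruth(cometRate = 0),
                               duration = 3, seed = 1, noise = FALSE)
    expect_equal(nrow(sim0$events), 0L)
    expect_lt(diff(range(imgData(sim0$movie)[1, , ])), 1e-9)
    ## stationary spots are allowed
    simV0 <- simulateCometMovie(sc, cleanTruth(cometSpeed = 0,
                                               cometRate = 3),
                                duration = 3, seed = 2, noise = FALSE)
    expect_true(all(simV0$events$speed_um_s == 0))
    ## event log records time, side, lateral position, speed
    sim <- simulateCometMovie(sc, cleanTruth(cometRate = 4),
                              duration = 5, seed = 3)
    expect_true(all(c("time_s", "side", "lateral_um", "speed_um_s") %in%
                    names(sim$events)))
    expect_true(all(sim$events$side %in% c(-1, 1)))
    expect_true(all(abs(sim$events$lateral_um) <= 5))
})

test_that("planted foci are recorded and respect minimum separation", {
    sc <- SceneParams()
    tr <- GroundTruth(fociCount = 4L)
    sim <- simulateFociImage(sc, tr, seed = 7, minSeparation = 1.5)
    cen <- sim$annotation@fociCenters
    expect_equal(nrow(cen), 4L)
    d <- as.matrix(dist(cen))
    expect_gte(min(d[upper.tri(d)]), 1.5)
    ## explicit centers override random placement
    ctr <- rbind(c(14, 14), c(14.2, 14))
    sim2 <- simulateFociImage(sc, GroundTruth(fociCount = 2L), seed = 1,
                              centers = ctr)
    expect_equal(sim2$annotation@fociCenters, ctr)
})
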