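test_that("Welch t from moments matches the closed form and t.test", {
    ## identical groups: no signal
    r0 <- welchT(5, 1, 10, 5, 1, 10)
    expect_equal(r0$statistic, 0)
    expect_equal(r0$p, 1)
    ## swapping groups negates t, leaves p unchanged
    ra <- welchT(3.0, 1.0, 134, 1.8, 0.5, 64)
    rb <- welchT(1.8, 0.5, 64, 3.0, 1.0, 134)
    expect_equal(ra$statistic, -rb$statistic)
    expect_equal(ra$p, rb$p)
    ## closed-form oracle
    oc <- oracleWelch(3.0, 1.0, 134, 1.8, 0.5, 64)
    expect_equal(ra$statistic, oc$t, tolerance = 1e-12)
    expect_equal(ra$df, oc$df, tolerance = 1e-12)
    expect_equal(ra$p, oc$p, tolerance = 1e-12)
    ## agreement with stats::t.test on raw data with exactly those moments
    mkVec <- function(m, s, n) {
        x <- scale(rnorm(n))[, 1]  # mean 0, sd 1 exactly
        m + s * x
    }
    set.seed(12)
    a <- mkVec(3.0, 1.0, 134); b <- mkVec(1.8, 0.5, 64)
    tt <- t.test(a, b)
    rw <- welchT(mean(a), sd(a), 134, mean(b), sd(b), 64)
    expect_equal(rw$statistic, unname(tt$statistic), tolerance = 1e-10)
    expect_equal(rw$df, unname(tt$parameter), tolerance = 1e-10)
    expect_equal(rw$p, tt$p.value, tolerance = 1e-10)
    expect_error(welchT(1, 0, 5, 1, 0, 5), "degenerate")
})

test_that("Welch t holds its nominal type-I error", {
    set.seed(31)
    nSim <- 10000L; n <- 15L
    p <- vapply(seq_len(nSim), function(i) {
        a <- rnorm(n); b <- rnorm(n)
        welchT(mean(a), sd(a), n, mean(b), sd(b), n)$p
    }, 0)
    expect_gte(mean(p < 0.05), 0.04)
    expect_lte(mean(p < 0.05), 0.06)
})

test_that("paired t matches the one-sample formula on differences", {
    a <- c(1.2, 0.8, 1.5, 1.1, 0.9)
    b <- c(1.0, 0.7, 1.1, 1.2, 0.6)
    r <- pairedT(a, b)
    d <- a - b
    tOracle <- mean(d) / (sd(d) / sqrt(length(d)))
    expect_equal(r$statistic, tOracle, tolerance = 1e-12)
    expect_equal(r$df, length(d) - 1)
    expect_equal(r$p, 2 * pt(-abs(tOracle), length(d) - 1),
                 tolerance = 1e-12)
    ## identical vectors: t = 0, p = 1
    r0 <- pairedT(a, a)
    expect_equal(r0$statistic, 0)
    expect_equal(r0$p, 1)
    ## constant nonzero difference: degenerate
    expect_error(pairedT(a, a + 1), "degenerate")
    expect_error(pairedT(a, b[-1]), "length")
})

test_that("linear fit matches the normal equations", {
    ## perfect line
    x <- 1:10; y <- 2 * x + 3
    rf <- linearFit(x, y)
    expect_equal(rf$slope, 2, tolerance = 1e-12)
    expect_equal(rf$r.squared, 1, tolerance = 1e-12)
    ## independent y: R^2 near zero for large n
    set.seed(2)
    xn <- rnorm(500); yn <- rnorm(500)
    expect_lt(linearFit(xn, yn)$r.squared, 0.03)
    ## small fixture against the normal-equations oracle
    xs <- c(11.0, 14.5, 12.3, 13.8, 15.2, 10.9)
    ys <- c(3.1, 2.6, 2.9, 2.7, 2.5, 3.2)
    r <- linearFit(xs, ys)
    sxx <- sum((xs - mean(xs))^2)
    slope <- sum((xs - mean(xs)) * (ys - mean(ys))) / sxx
    intercept <- mean(ys) - slope * mean(xs)
    res <- ys - intercept - slope * xs
    r2 <- 1 - sum(res^2) / sum((ys - mean(ys))^2)
    expect_equal(r$slope, slope, tolerance = 1e-10)
    expect_equal(r$intercept, intercept, tolerance = 1e-10)
    expect_equal(r$r.squared, r2, tolerance = 1e-10)
    expect_error(linearFit(rep(1, 5), 1:5), "zero variance")
})

test_that("genotype pooling concatenates embryos and tests pools", {
    ## identical pools: p = 1
    v <- data.frame(genotype = rep(c("G", "C"), each = 4),
                    value = rep(c(1, 2, 3, 4), 2))
    r <- poolAndCompare(v, list(depleted = "G", wildtype = "C"))
    expect_equal(r$test$p, 1)
    ## one-genotype pools reduce to a plain Welch t
    w <- welchT(mean(v$value[1:4]), sd(v$value[1:4]), 4,
                mean(v$value[5:8]), sd(v$value[5:8]), 4)
    expect_equal(r$test$statistic, w$statistic)
    ## pools with exactly the published crossing-count moments (7.7 +- 3.3
    ## over 39 embryos vs 11.1 +- 4.1 over 33) reject at alpha = 0.001
    set.seed(9)
    mkVec <- function(m, s, n) m + s * scale(rnorm(n))[, 1]
    vals <- data.frame(
        genotype = c(rep(c("G", "GA", "GNP"), c(13, 13, 13)),
                     rep(c("C", "A", "M"), c(11, 11, 11))),
        value = c(mkVec(7.7, 3.3, 39), mkVec(11.1, 4.1, 33)))
    rp <- poolAndCompare(vals, list(dep = c("G", "GA", "GNP"),
                                    wt = c("C", "A", "M")))
    expect_lt(rp$test$p, 0.001)
    expect_equal(rp$poolMeans$mean, c(7.7, 11.1), tolerance = 1e-9)
    ## within-pool pairwise tests are reported
    vals <- data.frame(genotype = rep(c("G", "GA", "C", "A"), each = 5),
                       value = rnorm(20, 10, 2))
    rr <- poolAndCompare(vals, list(dep = c("G", "GA"), wt = c("C", "A")))
    expect_equal(nrow(rr$withinPool), 2L)
    ## unmapped genotype is an error
    expect_error(poolAndCompare(vals, list(dep = "G", wt = c("C", "A"))),
                 "not assigned")
})
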