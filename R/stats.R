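## The comparison statistics used throughout: Welch two-sample t on
## summary moments, paired t, ordinary least squares, genotype pooling.

#' Welch two-sample t test from summary statistics
#'
#' Computes t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2) with
#' Welch-Satterthwaite degrees of freedom and a two-tailed p-value.
#' Operating on moments (rather than raw vectors) lets published
#' summaries be compared directly; [poolAndCompare()] feeds it raw data.
#'
#' @param m1,s1,n1 mean, SD and size of group 1 (n1 >= 2).
#' @param m2,s2,n2 mean, SD and size of group 2.
#' @return A data.frame with `statistic`, `df`, `p`, group moments and
#'   `test`.
#' @examples
#' welchT(3.0, 1.0, 134, 1.8, 0.5, 64)
#' @export
welchT <- function(m1, s1, n1, m2, s2, n2) {
    stopifnot(n1 >= 2L, n2 >= 2L, s1 >= 0, s2 >= 0)
    if (s1 == 0 && s2 == 0)
        stop("both group SDs are zero; t statistic is degenerate")
    se2 <- s1^2 / n1 + s2^2 / n2
    t <- (m1 - m2) / sqrt(se2)
    df <- se2^2 / (s1^4 / (n1^2 * (n1 - 1)) + s2^4 / (n2^2 * (n2 - 1)))
    p <- 2 * pt(-abs(t), df)
    data.frame(statistic = t, df = df, p = p, mean1 = m1, sd1 = s1,
               n1 = n1, mean2 = m2, sd2 = s2, n2 = n2,
               test = "Welch two-sample t")
}

#' Paired t test
#'
#' Two-tailed one-sample t on the within-pair differences.
#'
#' @param a,b numeric vectors of equal length >= 2.
#' @return A data.frame with `statistic`, `df`, `p`, `meanDiff`,
#'   `sdDiff`, `n`, `test`.
#' @export
pairedT <- function(a, b) {
    if (length(a) != length(b)) stop("paired vectors differ in length")
    if (length(a) < 2L) stop("need at least 2 pairs")
    d <- a - b
    if (sd(d) <= 1e-12 * max(1, abs(mean(d)))) {
        if (all(d == 0))  # identical vectors: no evidence of a difference
            return(data.frame(statistic = 0, df = length(d) - 1, p = 1,
                              meanDiff = 0, sdDiff = 0, n = length(d),
                              test = "paired t"))
        stop("constant nonzero pairwise difference; ",
             "t statistic is degenerate (infinite)")
    }
    tt <- tryCatch(stats::t.test(a, b, paired = TRUE), error = function(e)
        stop("paired differences are degenerate: ", conditionMessage(e)))
    data.frame(statistic = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, meanDiff = mean(d), sdDiff = sd(d),
               n = length(d), test = "paired t")
}

#' Ordinary least-squares linear fit
#'
#' Slope, intercept, R-squared, and the two-tailed p-value of the slope
#' t statistic.
#'
#' @param x,y numeric vectors, length >= 3.
#' @return A data.frame with `slope`, `intercept`, `r.squared`, `p`,
#'   `n`.
#' @export
linearFit <- function(x, y) {
    stopifnot(length(x) == length(y), length(x) >= 3L)
    if (sd(x) == 0) stop("zero variance in x; slope is undefined")
    fit <- lm(y ~ x)
    n <- length(x)
    ssr <- sum(stats::resid(fit)^2)
    sst <- sum((y - mean(y))^2)
    r2 <- if (sst == 0) 1 else 1 - ssr / sst
    ## slope t test computed directly (avoids summary.lm's warning on a
    ## zero-residual fit)
    sxx <- sum((x - mean(x))^2)
    se <- sqrt(ssr / (n - 2) / sxx)
    p <- if (se == 0) 0 else 2 * pt(-abs(coef(fit)[2L] / se), n - 2)
    data.frame(slope = unname(coef(fit)[2L]),
               intercept = unname(coef(fit)[1L]),
               r.squared = r2, p = unname(p), n = n)
}

#' Pool genotypes and compare the pools
#'
#' Concatenates per-embryo values genotype-wise into two pools, runs a
#' Welch t test between the pools, and reports all pairwise
#' within-pool genotype tests (the check that no genotype within a pool
#' differs from its pool-mates).
#'
#' @param values data.frame with columns `genotype` and `value` (one row
#'   per embryo).
#' @param pools named list of two character vectors assigning every
#'   genotype to exactly one pool, e.g.
#'   `list(depleted = c("G","GA"), wildtype = c("C","A"))`.
#' @return A list with `test` (the pooled Welch data.frame), `poolMeans`
#'   (data.frame pool/mean/sd/n) and `withinPool` (data.frame of
#'   pairwise within-pool Welch tests).
#' @export
poolAndCompare <- function(values, pools) {
    stopifnot(is.data.frame(values),
              all(c("genotype", "value") %in% names(values)),
              length(pools) == 2L)
    gts <- unique(values$genotype)
    assign <- unlist(lapply(names(pools), function(p)
        stats::setNames(rep(p, length(pools[[p]])), pools[[p]])))
    if (any(duplicated(names(assign))))
        stop("a genotype is assigned to more than one pool")
    miss <- setdiff(gts, names(assign))
    if (length(miss))
        stop("genotypes not assigned to a pool: ",
             paste(miss, collapse = ", "))
    pooled <- split(values$value, assign[as.character(values$genotype)])
    if (any(lengths(pooled) == 0L)) stop("empty pool")
    p1 <- pooled[[names(pools)[1L]]]; p2 <- pooled[[names(pools)[2L]]]
    test <- welchT(mean(p1), sd(p1), length(p1),
                   mean(p2), sd(p2), length(p2))
    poolMeans <- data.frame(
        pool = names(pools),
        mean = c(mean(p1), mean(p2)), sd = c(sd(p1), sd(p2)),
        n = c(length(p1), length(p2)))
    within <- list()
    for (p in names(pools)) {
        g <- intersect(pools[[p]], gts)
        if (length(g) < 2L) next
        for (i in seq_len(length(g) - 1L)) for (j in (i + 1L):length(g)) {
            vi <- values$value[values$genotype == g[i]]
            vj <- values$value[values$genotype == g[j]]
            if (length(vi) < 2L || length(vj) < 2L) next
            w <- welchT(mean(vi), sd(vi), length(vi),
                        mean(vj), sd(vj), length(vj))
            within[[length(within) + 1L]] <-
                data.frame(pool = p, genotypeA = g[i], genotypeB = g[j],
                           statistic = w$statistic, df = w$df, p = w$p)
        }
    }
    list(test = test, poolMeans = poolMeans,
         withinPool = if (length(within)) do.call(rbind, within)
                      else data.frame())
}
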