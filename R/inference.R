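# closed-form OLS slope used inside the resampling loop
fastSlope <- function(x, y) {
    xm <- mean(x); ym <- mean(y)
    sxx <- sum((x - xm)^2)
    if (sxx == 0) return(NA_real_)
    sum((x - xm) * (y - ym)) / sxx
}

#' Ordinary least-squares slope with 95% confidence halfwidth
#'
#' Conventional regression of y on x with an intercept (set
#' \code{throughOrigin = TRUE} to force the line through zero). The
#' confidence halfwidth and slope p-value use the t reference with the
#' appropriate residual degrees of freedom.
#'
#' @param x,y equal-length numeric vectors, n >= 3, with var(x) > 0.
#' @param throughOrigin logical.
#' @return list of class \code{"slopeFit"}: \code{slope},
#'   \code{intercept}, \code{se}, \code{ci95Halfwidth}, \code{pSlope},
#'   \code{n}.
#' @examples
#' olsSlope(0:2, c(0, 2, 4))$slope  # 2
#' @export
olsSlope <- function(x, y, throughOrigin = FALSE) {
    if (length(x) != length(y)) stop("x and y lengths differ")
    n <- length(x)
    if (n < 3L) stop("need at least 3 points")
    if (stats::var(x) == 0) stop("x is degenerate (zero variance)")
    fit <- if (throughOrigin) stats::lm(y ~ x + 0) else stats::lm(y ~ x)
    co <- summary(fit)$coefficients
    srow <- if (throughOrigin) 1L else 2L
    df <- fit$df.residual
    out <- list(slope = unname(co[srow, 1L]),
                intercept = if (throughOrigin) 0 else unname(co[1L, 1L]),
                se = unname(co[srow, 2L]),
                ci95Halfwidth = stats::qt(0.975, df) * unname(co[srow, 2L]),
                pSlope = unname(co[srow, 4L]),
                n = n)
    class(out) <- "slopeFit"
    out
}

#' @export
print.slopeFit <- function(x, ...) {
    cat(sprintf("OLS slope %.4g +/- %.4g (95%% CI), intercept %.4g, p = %.4g, n = %d\n",
                x$slope, x$ci95Halfwidth, x$intercept, x$pSlope, x$n))
    invisible(x)
}

# draw resampled slope differences from the pooled rows; redraws resamples
# with a degenerate (zero-variance) x until valid, counting the redraws
resampleDiffs <- function(px, py, nA, nB, nRand, statFun) {
    nPool <- length(px)
    null <- numeric(nRand)
    redraws <- 0L
    for (b in seq_len(nRand)) {
        repeat {
            ia <- sample.int(nPool, nA, replace = TRUE)
            ib <- sample.int(nPool, nB, replace = TRUE)
            d <- statFun(px[ia], py[ia]) - statFun(px[ib], py[ib])
            if (is.finite(d)) break
            redraws <- redraws + 1L
            if (redraws > 1000L * nRand)
                stop("resampling keeps producing degenerate draws")
        }
        null[b] <- d
    }
    list(null = null, redraws = redraws)
}

finishRandomization <- function(observed, null, nRand, alternative) {
    exceed <- if (alternative == "two.sided") sum(abs(null) >= abs(observed))
              else sum(null >= observed)
    pMC <- (1 + exceed) / (nRand + 1)
    cmp <- if (alternative == "two.sided")
        sum(abs(observed) > abs(null)) else sum(observed > null)
    list(pMC = pMC, significant = cmp > 0.95 * nRand)
}

#' Pooled-resampling randomization test for a slope difference
#'
#' Tests whether the OLS slope of \code{yField} on \code{xField} differs
#' between two groups of pairwise-count rows. The rows of both groups are
#' pooled; group-sized sets are resampled from the pool with replacement;
#' both slopes are refit and their difference recorded, \code{nRand}
#' times. The difference is significant when the observed difference
#' exceeds 95% of the resampled differences (absolute values under the
#' default two-sided mode). The Monte-Carlo p uses the add-one estimator
#' \eqn{(1 + \#\{|null| \ge |obs|\})/(nRand + 1)}, so it can never be 0.
#' Resamples with a degenerate x are redrawn and counted.
#'
#' Rows are resampled as units; when rows are genotype pairs sharing
#' genotypes, that dependence is ignored by the procedure (a property of
#' the published design, documented in the vignette).
#'
#' @param pairsA,pairsB data.frames (e.g. from [pairwiseMatrix()]), one
#'   group each, with >= 3 rows.
#' @param xField,yField column names, e.g. \code{"dS"}, \code{"dN"},
#'   \code{"dnC"}.
#' @param nRand number of resampling replicates (1999 by convention).
#' @param seed optional integer for reproducibility.
#' @param alternative \code{"two.sided"} (default) or \code{"greater"}
#'   (slope A minus slope B).
#' @param throughOrigin force both regressions through the origin.
#' @return list of class \code{"slopeComparison"}: \code{fitA},
#'   \code{fitB}, \code{observedDiff}, \code{nullDiffs}, \code{pMC},
#'   \code{significant}, \code{nRand}, \code{nRedraws}.
#' @seealso [randomizationLocationTest()], [olsSlope()]
#' @export
randomizationSlopeTest <- function(pairsA, pairsB, xField, yField,
                                   nRand = 1999, seed = NULL,
                                   alternative = c("two.sided", "greater"),
                                   throughOrigin = FALSE) {
    alternative <- match.arg(alternative)
    xa <- pairsA[[xField]]; ya <- pairsA[[yField]]
    xb <- pairsB[[xField]]; yb <- pairsB[[yField]]
    if (length(xa) < 3L || length(xb) < 3L)
        stop("each group needs at least 3 rows")
    fitA <- olsSlope(xa, ya, throughOrigin)
    fitB <- olsSlope(xb, yb, throughOrigin)
    observed <- fitA$slope - fitB$slope
    statFun <- if (throughOrigin)
        function(x, y) if (sum(x^2) == 0) NA_real_ else sum(x * y) / sum(x^2)
    else fastSlope
    run <- function() {
        rs <- resampleDiffs(c(xa, xb), c(ya, yb), length(xa), length(xb),
                            nRand, statFun)
        fin <- finishRandomization(observed, rs$null, nRand, alternative)
        out <- list(fitA = fitA, fitB = fitB, observedDiff = observed,
                    nullDiffs = rs$null, pMC = fin$pMC,
                    significant = fin$significant, nRand = nRand,
                    nRedraws = rs$redraws, alternative = alternative,
                    statistic = "slope")
        class(out) <- "slopeComparison"
        out
    }
    if (is.null(seed)) run() else withSeed(seed, run())
}

#' Pooled-resampling randomization test for a location (mean) difference
#'
#' Same resampling scheme, p-value and significance rule as
#' [randomizationSlopeTest()], applied to the difference in group means.
#' Used for contrasts where the within-group regression is itself not
#' significant (e.g. homozygous nonsynonymous counts compared between
#' lineages irrespective of the heterozygous counts).
#'
#' @param a,b non-empty numeric vectors.
#' @inheritParams randomizationSlopeTest
#' @return list of class \code{"slopeComparison"} (statistic "mean"):
#'   \code{observedDiff} = mean(a) - mean(b), plus \code{nullDiffs},
#'   \code{pMC}, \code{significant}, \code{nRand}, \code{meanA},
#'   \code{meanB}.
#' @export
randomizationLocationTest <- function(a, b, nRand = 1999, seed = NULL,
                                      alternative = c("two.sided",
                                                      "greater")) {
    alternative <- match.arg(alternative)
    if (!length(a) || !length(b)) stop("groups must be non-empty")
    observed <- mean(a) - mean(b)
    pool <- c(a, b)
    run <- function() {
        null <- vapply(seq_len(nRand), function(i)
            mean(pool[sample.int(length(pool), length(a), replace = TRUE)]) -
            mean(pool[sample.int(length(pool), length(b), replace = TRUE)]),
            0)
        fin <- finishRandomization(observed, null, nRand, alternative)
        out <- list(meanA = mean(a), meanB = mean(b),
                    observedDiff = observed, nullDiffs = null,
                    pMC = fin$pMC, significant = fin$significant,
                    nRand = nRand, nRedraws = 0L,
                    alternative = alternative, statistic = "mean")
        class(out) <- "slopeComparison"
        out
    }
    if (is.null(seed)) run() else withSeed(seed, run())
}

#' @export
print.slopeComparison <- function(x, ...) {
    cat(sprintf("Randomization test on %s difference\n", x$statistic))
    if (x$statistic == "slope") {
        cat(sprintf("  group A: slope %.4g +/- %.4g\n", x$fitA$slope,
                    x$fitA$ci95Halfwidth))
        cat(sprintf("  group B: slope %.4g +/- %.4g\n", x$fitB$slope,
                    x$fitB$ci95Halfwidth))
    } else {
        cat(sprintf("  mean A %.4g, mean B %.4g\n", x$meanA, x$meanB))
    }
    cat(sprintf("  observed diff %.4g, p_MC = %.4g (%d resamples)%s\n",
                x$observedDiff, x$pMC, x$nRand,
                if (x$significant) " *" else ""))
    invisible(x)
}

#' Mann-Whitney U test with Bonferroni correction
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test: exact enumeration
#' when the smaller group has at most 8 observations and there are no
#' ties, normal approximation with tie correction otherwise. The
#' Bonferroni-corrected p multiplies by the size of the comparison family
#' (default 3: the S, N, N/S family).
#'
#' @param a,b non-empty numeric vectors.
#' @param nComparisons Bonferroni family size.
#' @return list: \code{U}, \code{pRaw}, \code{pBonferroni}.
#' @examples
#' mannWhitneyU(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mannWhitneyU <- function(a, b, nComparisons = 3) {
    ties <- anyDuplicated(c(a, b)) > 0L
    exact <- min(length(a), length(b)) <= 8L && !ties
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                              correct = !exact))
    p <- wt$p.value
    list(U = unname(wt$statistic), pRaw = p,
         pBonferroni = min(1, p * nComparisons))
}

#' Two-sample t-test with degenerate-variance guards
#'
#' Pooled-variance Student t by default; Welch behind the flag. When both
#' groups have zero variance the usual statistic is undefined: equal means
#' return t = 0, p = 1; different means return an infinite t with p = 0
#' and a warning.
#'
#' @param a,b numeric vectors with >= 2 observations each.
#' @param welch logical, use the Welch unequal-variance form.
#' @return list: \code{t}, \code{df}, \code{p}.
#' @export
twoSampleT <- function(a, b, welch = FALSE) {
    if (length(a) < 2L || length(b) < 2L)
        stop("each group needs at least 2 observations")
    if (stats::var(a) == 0 && stats::var(b) == 0) {
        df <- length(a) + length(b) - 2L
        if (mean(a) == mean(b)) return(list(t = 0, df = df, p = 1))
        warning("zero variance in both groups; returning infinite t")
        return(list(t = sign(mean(a) - mean(b)) * Inf, df = df, p = 0))
    }
    tt <- stats::t.test(a, b, var.equal = !welch)
    list(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value)
}
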