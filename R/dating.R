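roundHalfAway <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Lineage age from a within-lineage pairwise substitution rate
#'
#' Converts a mean pairwise substitution rate (substitutions per site
#' between genotypes of one lineage) into years since the lineage founder:
#' \deqn{age = rate / (\mu \times gensPerYear \times branchDivisor).}
#' Ages are returned unrounded and rounded to the nearest year (half away
#' from zero). Vectorized over \code{rate}.
#'
#' @param rate non-negative pairwise substitution rate(s) per site.
#' @param model an [AgeModel-class].
#' @return data.frame: \code{rate}, \code{years}, \code{years_rounded}.
#' @examples
#' lineageAgeYears(1.82e-5, AgeModel())             # ~508 years
#' lineageAgeYears(31.3e-5, mtAgeModel())           # ~1456 years
#' @export
lineageAgeYears <- function(rate, model = AgeModel()) {
    if (any(rate < 0)) stop("rate must be non-negative")
    years <- rate / (model@mu * model@gensPerYear * model@branchDivisor)
    data.frame(rate = rate, years = years,
               years_rounded = roundHalfAway(years))
}

#' Mean within-lineage pairwise substitution rate
#'
#' Each pair's total substitution count (non-coding + synonymous +
#' nonsynonymous) divided by its number of compared sites, averaged over
#' pairs, with the standard deviation.
#'
#' @param pairs data.frame from [pairwiseMatrix()] (columns \code{dnC},
#'   \code{dS}, \code{dN}, \code{sites_compared}).
#' @param sites optional override for the per-pair site count.
#' @return list: \code{mean}, \code{sd}, \code{n}, \code{perPair}.
#' @seealso [lineageAgeYears()]
#' @export
meanPairwiseRate <- function(pairs, sites = NULL) {
    if (!nrow(pairs)) stop("empty pairwise table")
    if (is.null(sites)) sites <- pairs$sites_compared
    r <- (pairs$dnC + pairs$dS + pairs$dN) / sites
    list(mean = mean(r), sd = if (length(r) > 1L) stats::sd(r) else 0,
         n = length(r), perPair = r)
}
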