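#' Study conditions for randomization-test calibration
#'
#' The fixed two-lineage scenario used to calibrate the slope
#' randomization test: a 40 kb genome with 40 genes (12 kb coding), two
#' lineages of 6 genotypes, 4000 mean generations at mu = 2e-6 (about 320
#' candidate mutations per genotype, ~96 of them in coding sequence, i.e.
#' comfortably above 50 expected coding mutations), genotype ages spread
#' +/- 50% around the lineage mean, and per-lineage nonsynonymous
#' retention probabilities \code{omega}. See the vignette for the
#' reasoning behind these sizes.
#'
#' @param seed integer master seed.
#' @param omega length-2 numeric, retention probability per lineage.
#' @return A [SimulationConfig-class].
#' @seealso [calibrateSlopeTest()]
#' @export
calibrationConfig <- function(seed, omega = c(0.5, 0.5)) {
    SimulationConfig(seed = seed, nContigs = 1L, contigLength = 40000L,
                     nGenes = 40L, geneLength = 300L,
                     genotypes = c(A = 6L, B = 6L), mu = 2e-6,
                     generations = c(A = 4000, B = 4000), tSpread = 0.5,
                     omega = c(A = omega[1L], B = omega[2L]), pHom = 0.1)
}

#' Replicate the slope randomization test over simulated studies
#'
#' Repeatedly simulates the two-lineage calibration scenario, runs the
#' pooled-resampling randomization test on the chosen pairwise contrast,
#' and records the outcome. With equal \code{omega} the rejection
#' fraction estimates the test's type-I error; with unequal \code{omega}
#' it estimates power (and \code{directionCorrect} tracks how often the
#' weaker-selection, higher-omega lineage shows the larger slope). The
#' reference genome is generated once and reused across replicates; each
#' replicate draws fresh lineages.
#'
#' @param nReps number of simulated studies.
#' @param omega length-2 numeric, per-lineage nonsynonymous retention.
#' @param nRand randomization replicates within each test.
#' @param seed integer master seed (replicate r uses seed + r).
#' @param xField,yField pairwise columns contrasted (default dN on dS).
#' @return data.frame with one row per replicate: \code{significant},
#'   \code{p_mc}, \code{observed_diff}, \code{slope_a}, \code{slope_b}.
#' @export
calibrateSlopeTest <- function(nReps = 500, omega = c(0.5, 0.5),
                               nRand = 499, seed = 1L, xField = "dS",
                               yField = "dN") {
    cfg0 <- calibrationConfig(seed, omega)
    genome <- generateReference(cfg0)
    rows <- vector("list", nReps)
    for (r in seq_len(nReps)) {
        cfg <- calibrationConfig(seed + r, omega)
        sims <- suppressMessages(simulateLineages(cfg, genome))
        pa <- pairwiseMatrix(genome, sims[grep("^A_", names(sims))])
        pb <- pairwiseMatrix(genome, sims[grep("^B_", names(sims))])
        rt <- randomizationSlopeTest(pa, pb, xField, yField, nRand = nRand,
                                     seed = seed + 500000L + r)
        rows[[r]] <- data.frame(significant = rt$significant, p_mc = rt$pMC,
                                observed_diff = rt$observedDiff,
                                slope_a = rt$fitA$slope,
                                slope_b = rt$fitB$slope)
    }
    do.call(rbind, rows)
}
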