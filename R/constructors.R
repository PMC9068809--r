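#' Construct a ReferenceGenome
#'
#' @param contigs named character vector or \code{DNAStringSet} of contig
#'   sequences (case-folded to upper).
#' @param genes \code{GRangesList} of CDS segments, one element per gene,
#'   named by gene id, segments in translation order; or \code{NULL} for a
#'   gene-free genome.
#' @return A [ReferenceGenome-class] object.
#' @examples
#' g <- ReferenceGenome(c(c1 = "ACGTACGTAC"))
#' genomeLength(g)
#' @export
ReferenceGenome <- function(contigs, genes = NULL) {
    if (!is(contigs, "DNAStringSet"))
        contigs <- DNAStringSet(toupper(contigs))
    if (is.null(genes))
        genes <- GRangesList()
    if (!is(genes, "GRangesList"))
        genes <- GRangesList(genes)
    new("ReferenceGenome", contigs = contigs, genes = genes,
        cache = new.env(parent = emptyenv()))
}

#' Construct a GenotypeCallSet
#'
#' @param genotypeId,lineageId identifiers.
#' @param calls \code{GRanges} with metadata columns \code{ref},
#'   \code{alt}, \code{zygosity}, \code{depth}, \code{qual}; or a
#'   data.frame with columns \code{contig}, \code{pos} (0-based),
#'   \code{ref}, \code{alt}, \code{zygosity}, and optionally
#'   \code{depth}, \code{qual}.
#' @param callableSites number of nucleotides examined.
#' @return A [GenotypeCallSet-class] object.
#' @examples
#' df <- data.frame(contig = "c1", pos = 3, ref = "A", alt = "G",
#'                  zygosity = "het")
#' cs <- GenotypeCallSet("g1", "L1", df, callableSites = 1000)
#' substitutionRate(cs)
#' @export
GenotypeCallSet <- function(genotypeId, lineageId = NA_character_,
                            calls = NULL, callableSites) {
    if (is.null(calls))
        calls <- data.frame(contig = character(), pos = integer(),
                            ref = character(), alt = character(),
                            zygosity = character())
    if (is.data.frame(calls)) {
        if (!"depth" %in% names(calls)) calls$depth <- rep(50L, nrow(calls))
        if (!"qual" %in% names(calls)) calls$qual <- rep(99, nrow(calls))
        calls <- GRanges(calls$contig,
                         IRanges(start = calls$pos + 1L, width = 1L),
                         ref = as.character(calls$ref),
                         alt = as.character(calls$alt),
                         zygosity = as.character(calls$zygosity),
                         depth = as.integer(calls$depth),
                         qual = as.numeric(calls$qual))
    }
    new("GenotypeCallSet", genotypeId = as.character(genotypeId),
        lineageId = as.character(lineageId), calls = calls,
        callableSites = as.numeric(callableSites))
}

#' Construct a SimulationConfig
#'
#' Defaults describe a two-lineage scaled-down study: a 2 x 50 kb genome
#' carrying 40 single-CDS genes, lineages "JPN1" (7 genotypes, 2540
#' generations, omega 0.2) and "JPN2" (5 genotypes, 1860 generations,
#' omega 0.5), mutation rate 2e-6 per site per generation, 10% of
#' retained mutations homozygous, genotype ages spread +/- 50% around the
#' lineage mean. See the package vignette for how these defaults were
#' chosen.
#'
#' @param seed integer master seed.
#' @param nContigs,contigLength,nGenes,geneLength genome geometry.
#' @param genotypes named integer vector, genotypes per lineage.
#' @param mu substitutions per site per generation.
#' @param generations named numeric vector, mean generations per lineage.
#' @param tSpread genotype-age heterogeneity fraction in [0, 1).
#' @param omega named numeric vector in (0,1], nonsynonymous retention
#'   probability per lineage.
#' @param pHom probability a retained mutation is homozygous.
#' @param kappa transition:transversion rate ratio (1 = no bias).
#' @param gcContent GC fraction of the simulated reference.
#' @return A [SimulationConfig-class] object.
#' @examples
#' cfg <- SimulationConfig(seed = 1, nGenes = 10L, contigLength = 10000L)
#' cfg
#' @export
SimulationConfig <- function(seed = 1L,
                             nContigs = 2L,
                             contigLength = 50000L,
                             nGenes = 40L,
                             geneLength = 300L,
                             genotypes = c(JPN1 = 7L, JPN2 = 5L),
                             mu = 2e-6,
                             generations = c(JPN1 = 2540, JPN2 = 1860),
                             tSpread = 0.5,
                             omega = c(JPN1 = 0.2, JPN2 = 0.5),
                             pHom = 0.1,
                             kappa = 1,
                             gcContent = 0.4) {
    gt <- as.integer(genotypes)
    names(gt) <- names(genotypes)
    new("SimulationConfig", seed = as.integer(seed),
        nContigs = as.integer(nContigs),
        contigLength = as.integer(contigLength),
        nGenes = as.integer(nGenes), geneLength = as.integer(geneLength),
        genotypes = gt, mu = mu,
        generations = generations[names(gt)], tSpread = tSpread,
        omega = omega[names(gt)], pHom = pHom, kappa = kappa,
        gcContent = gcContent)
}

#' Construct an AgeModel
#'
#' Defaults are the nuclear clock used for dating: mu = 7.17e-9
#' substitutions per site per generation (a long-term mutation-accumulation
#' estimate for \emph{Daphnia pulex}) and five generations per year.
#'
#' @param mu substitutions per site per generation.
#' @param gensPerYear generations per year.
#' @param branchDivisor 1 (published arithmetic) or 2 (split pairwise
#'   divergence over both branches).
#' @return An [AgeModel-class] object.
#' @examples
#' lineageAgeYears(1.82e-5, AgeModel())
#' @export
AgeModel <- function(mu = 7.17e-9, gensPerYear = 5, branchDivisor = 1) {
    new("AgeModel", mu = mu, gensPerYear = gensPerYear,
        branchDivisor = branchDivisor)
}

#' mtDNA clock preset
#'
#' Convenience preset using the asexual \emph{Daphnia pulex} mitochondrial
#' mutation-rate estimate, 4.3e-8 per site per generation.
#' @inheritParams AgeModel
#' @return An [AgeModel-class] object.
#' @export
mtAgeModel <- function(gensPerYear = 5, branchDivisor = 1)
    AgeModel(mu = 4.3e-8, gensPerYear = gensPerYear,
             branchDivisor = branchDivisor)
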