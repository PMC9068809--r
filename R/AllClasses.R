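#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame metadata metadata<-
#' @importFrom GenomicRanges GRanges GRangesList start end width strand seqnames
#' @importFrom IRanges IRanges
#' @importFrom GenomeInfoDb seqlevels seqlengths
#' @importFrom Biostrings DNAStringSet
#' @importFrom utils head
NULL

#' Reference genome with gene models
#'
#' Container for a haploid reference assembly together with its
#' protein-coding gene models. Contigs are held as a
#' \link[Biostrings]{DNAStringSet}; gene models as a
#' \link[GenomicRanges]{GRangesList} with one element per gene, each
#' element holding that gene's CDS segments *in translation order*
#' (ascending genomic start on the plus strand, descending on the minus
#' strand). All coordinates follow the usual Bioconductor 1-based
#' inclusive convention inside \code{GRanges}; user-facing site arguments
#' of functions in this package are 0-based, see the individual pages.
#'
#' Validity requires: contig alphabet restricted to A, C, G, T, N; every
#' CDS segment within its contig; segments of one gene non-overlapping,
#' on a single contig and strand; summed CDS length a positive multiple
#' of three.
#'
#' @slot contigs \code{DNAStringSet} of uppercase contig sequences.
#' @slot genes \code{GRangesList}, one element per gene, named by gene id.
#' @slot cache environment memoizing the position-level coding index.
#'
#' @seealso [ReferenceGenome()] constructor, [readFasta()], [readGff3Genes()]
#' @exportClass ReferenceGenome
setClass("ReferenceGenome",
    representation(contigs = "DNAStringSet", genes = "GRangesList",
                   cache = "environment"))

setValidity("ReferenceGenome", function(object) {
    msgs <- character()
    if (is.null(names(object@contigs)) || anyDuplicated(names(object@contigs)))
        msgs <- c(msgs, "contigs must have unique names")
    letters <- Biostrings::uniqueLetters(object@contigs)
    if (length(setdiff(letters, c("A", "C", "G", "T", "N"))))
        msgs <- c(msgs, "contig alphabet must be within {A,C,G,T,N}")
    gl <- object@genes
    if (length(gl)) {
        if (is.null(names(gl)) || anyDuplicated(names(gl)))
            msgs <- c(msgs, "genes must have unique names (gene ids)")
        clens <- stats::setNames(Biostrings::width(object@contigs),
                                 names(object@contigs))
        for (i in seq_along(gl)) {
            gr <- gl[[i]]
            id <- names(gl)[i]
            ctg <- as.character(seqnames(gr))
            if (length(unique(ctg)) != 1L ||
                length(unique(as.character(strand(gr)))) != 1L) {
                msgs <- c(msgs, paste0("gene ", id,
                    ": CDS segments must share one contig and strand"))
                next
            }
            if (!ctg[1L] %in% names(clens)) {
                msgs <- c(msgs, paste0("gene ", id, ": unknown contig ",
                                       ctg[1L]))
                next
            }
            if (any(start(gr) < 1L) || any(end(gr) > clens[[ctg[1L]]]))
                msgs <- c(msgs, paste0("gene ", id,
                    ": CDS segment outside contig bounds"))
            if (sum(width(gr)) %% 3L != 0L || sum(width(gr)) == 0L)
                msgs <- c(msgs, paste0("gene ", id,
                    ": CDS length must be a positive multiple of 3"))
            o <- order(start(gr))
            if (length(gr) > 1L &&
                any(start(gr)[o][-1L] <= end(gr)[o][-length(gr)]))
                msgs <- c(msgs, paste0("gene ", id,
                    ": CDS segments overlap"))
        }
    }
    if (length(msgs)) msgs else TRUE
})

#' One clonal genotype's filtered diploid variant calls
#'
#' Holds the biallelic single-nucleotide variant calls of one diploid
#' clonal genotype against a reference, after depth and quality
#' filtering, plus the number of callable sites (the denominator of the
#' per-genotype substitution rate). Calls are a \code{GRanges} (width-1
#' ranges) with metadata columns \code{ref}, \code{alt} (single bases),
#' \code{zygosity} (\code{"hom_alt"} or \code{"het"}), \code{depth} and
#' \code{qual}. At most one call per site.
#'
#' @slot genotypeId character scalar.
#' @slot lineageId character scalar.
#' @slot calls \code{GRanges} as described above.
#' @slot callableSites numeric scalar, number of nucleotides examined.
#'
#' @seealso [GenotypeCallSet()], [readVcfCalls()], [substitutionRate()]
#' @exportClass GenotypeCallSet
setClass("GenotypeCallSet",
    representation(genotypeId = "character", lineageId = "character",
                   calls = "GRanges", callableSites = "numeric"))

setValidity("GenotypeCallSet", function(object) {
    msgs <- character()
    if (length(object@genotypeId) != 1L || !nzchar(object@genotypeId))
        msgs <- c(msgs, "genotypeId must be a non-empty scalar")
    if (length(object@lineageId) != 1L)
        msgs <- c(msgs, "lineageId must be a scalar")
    cl <- object@calls
    need <- c("ref", "alt", "zygosity", "depth", "qual")
    if (!all(need %in% names(mcols(cl)))) {
        msgs <- c(msgs, paste0("calls must carry metadata columns: ",
                               paste(need, collapse = ", ")))
    } else if (length(cl)) {
        if (any(width(cl) != 1L))
            msgs <- c(msgs, "calls must be single-nucleotide (width 1)")
        if (any(as.character(mcols(cl)$ref) == as.character(mcols(cl)$alt)))
            msgs <- c(msgs, "ref and alt alleles must differ")
        if (!all(mcols(cl)$zygosity %in% c("hom_alt", "het")))
            msgs <- c(msgs, "zygosity must be 'hom_alt' or 'het'")
        if (any(mcols(cl)$depth < 0))
            msgs <- c(msgs, "depth must be non-negative")
        key <- paste(as.character(seqnames(cl)), start(cl))
        if (anyDuplicated(key))
            msgs <- c(msgs, "at most one call per site")
    }
    if (length(object@callableSites) != 1L || is.na(object@callableSites) ||
        object@callableSites < length(cl))
        msgs <- c(msgs, "callableSites must be >= number of calls")
    if (length(msgs)) msgs else TRUE
})

#' Simulation configuration for synthetic clonal lineages
#'
#' All knobs of the synthetic-data generator: genome geometry, the
#' per-site per-generation mutation rate, lineage sizes and ages, the
#' lineage-specific retention probability for nonsynonymous mutations
#' (the simulator's stand-in for purifying-selection strength, an
#' expected-dN/dS dial), the zygosity mixture and the master seed.
#'
#' @slot seed integer master seed.
#' @slot nContigs,contigLength,nGenes,geneLength genome geometry; gene
#'   length must be a multiple of 3 (start and stop codons included).
#' @slot genotypes named integer vector: genotypes per lineage.
#' @slot mu substitutions per site per generation.
#' @slot generations named numeric vector: mean generations since the
#'   lineage founder.
#' @slot tSpread genotype-age heterogeneity: each genotype's branch
#'   length is drawn uniformly on \code{[(1-tSpread)t, (1+tSpread)t]};
#'   0 gives the equal-branch star.
#' @slot omega named numeric vector in (0,1]: probability a
#'   nonsynonymous mutation is retained.
#' @slot pHom probability a retained mutation is homozygous.
#' @slot kappa transition:transversion rate ratio (1 = uniform spectrum).
#' @slot gcContent base composition of the simulated reference.
#'
#' @seealso [SimulationConfig()], [generateReference()], [simulateLineages()]
#' @exportClass SimulationConfig
setClass("SimulationConfig",
    representation(seed = "integer", nContigs = "integer",
                   contigLength = "integer", nGenes = "integer",
                   geneLength = "integer", genotypes = "integer",
                   mu = "numeric", generations = "numeric",
                   tSpread = "numeric", omega = "numeric", pHom = "numeric",
                   kappa = "numeric", gcContent = "numeric"))

setValidity("SimulationConfig", function(object) {
    msgs <- character()
    lin <- names(object@genotypes)
    if (is.null(lin) || anyDuplicated(lin) || any(!nzchar(lin)))
        msgs <- c(msgs, "genotypes must be named by unique lineage ids")
    for (sl in c("generations", "omega")) {
        v <- slot(object, sl)
        if (!setequal(names(v), lin))
            msgs <- c(msgs, paste0(sl, " must be named by the same lineages"))
    }
    if (any(object@genotypes < 1L))
        msgs <- c(msgs, "each lineage needs >= 1 genotype")
    if (object@mu <= 0 || object@mu >= 0.01)
        msgs <- c(msgs, "mu must satisfy 0 < mu << 1")
    if (any(object@omega <= 0) || any(object@omega > 1))
        msgs <- c(msgs, "omega must lie in (0, 1]")
    if (any(object@generations < 0))
        msgs <- c(msgs, "generations must be non-negative")
    if (object@pHom < 0 || object@pHom > 1)
        msgs <- c(msgs, "pHom must lie in [0, 1]")
    if (object@tSpread < 0 || object@tSpread >= 1)
        msgs <- c(msgs, "tSpread must lie in [0, 1)")
    if (object@kappa <= 0)
        msgs <- c(msgs, "kappa must be positive")
    if (object@gcContent <= 0 || object@gcContent >= 1)
        msgs <- c(msgs, "gcContent must lie in (0, 1)")
    if (object@geneLength %% 3L != 0L || object@geneLength < 9L)
        msgs <- c(msgs, "geneLength must be a multiple of 3 and >= 9")
    if (object@nGenes > 0L) {
        percontig <- ceiling(object@nGenes / object@nContigs)
        if ((object@geneLength + 1L) * percontig > object@contigLength)
            msgs <- c(msgs, "genes do not fit in contigs without overlap")
    }
    if (length(msgs)) msgs else TRUE
})

#' Molecular-clock model for lineage dating
#'
#' Parameters converting a within-lineage mean pairwise substitution rate
#' (substitutions per site) into a lineage age in years:
#' \deqn{age = rate / (\mu \times g \times d)}
#' with \eqn{\mu} the per-site per-generation mutation rate, \eqn{g} the
#' number of generations per year and \eqn{d} a branch divisor (1
#' reproduces the published arithmetic, where pairwise divergence is read
#' directly as age; 2 is the population-genetics convention that splits
#' divergence over the two branches).
#'
#' @slot mu substitutions per site per generation (> 0).
#' @slot gensPerYear generations per year (> 0).
#' @slot branchDivisor 1 or 2.
#'
#' @seealso [AgeModel()], [lineageAgeYears()]
#' @exportClass AgeModel
setClass("AgeModel",
    representation(mu = "numeric", gensPerYear = "numeric",
                   branchDivisor = "numeric"))

setValidity("AgeModel", function(object) {
    msgs <- character()
    if (object@mu <= 0) msgs <- c(msgs, "mu must be positive")
    if (object@gensPerYear <= 0)
        msgs <- c(msgs, "gensPerYear must be positive")
    if (!object@branchDivisor %in% c(1, 2))
        msgs <- c(msgs, "branchDivisor must be 1 or 2")
    if (length(msgs)) msgs else TRUE
})
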