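#' @rdname ReferenceGenome-class
setMethod("contigs", "ReferenceGenome", function(x) x@contigs)

#' @rdname ReferenceGenome-class
setMethod("geneModels", "ReferenceGenome", function(x) x@genes)

#' @rdname ReferenceGenome-class
setMethod("genomeLength", "ReferenceGenome",
          function(x) sum(as.numeric(Biostrings::width(x@contigs))))

setMethod("show", "ReferenceGenome", function(object) {
    cat("ReferenceGenome:", length(object@contigs), "contig(s),",
        format(genomeLength(object), big.mark = ","), "bp,",
        length(object@genes), "gene(s)\n")
    cds <- sum(as.numeric(sum(width(object@genes))))
    cat("  coding:", format(cds, big.mark = ","), "bp (",
        sprintf("%.1f%%", 100 * cds / max(1, genomeLength(object))), ")\n")
})

#' @rdname GenotypeCallSet-class
setMethod("genotypeId", "GenotypeCallSet", function(x) x@genotypeId)

#' @rdname GenotypeCallSet-class
setMethod("lineageId", "GenotypeCallSet", function(x) x@lineageId)

#' @rdname GenotypeCallSet-class
setMethod("variantCalls", "GenotypeCallSet", function(x) x@calls)

#' @rdname GenotypeCallSet-class
setMethod("callableSites", "GenotypeCallSet", function(x) x@callableSites)

setMethod("show", "GenotypeCallSet", function(object) {
    z <- table(factor(mcols(object@calls)$zygosity,
                      levels = c("hom_alt", "het")))
    cat("GenotypeCallSet", object@genotypeId,
        if (!is.na(object@lineageId)) paste0("(lineage ", object@lineageId, ")"),
        "\n  calls:", length(object@calls),
        sprintf("(%d hom_alt, %d het)", z[["hom_alt"]], z[["het"]]),
        "\n  callable sites:", format(object@callableSites, big.mark = ","),
        "\n  N_sub:", format(substitutionRate(object), digits = 4), "\n")
})

setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig (seed", object@seed, ")\n")
    cat("  genome:", object@nContigs, "x",
        format(object@contigLength, big.mark = ","), "bp,",
        object@nGenes, "genes of", object@geneLength, "bp\n")
    cat("  mu:", object@mu, "per site per generation; pHom:", object@pHom,
        "; kappa:", object@kappa, "; tSpread:", object@tSpread, "\n")
    for (l in names(object@genotypes))
        cat(sprintf("  lineage %s: %d genotypes, %g generations, omega %g\n",
                    l, object@genotypes[[l]], object@generations[[l]],
                    object@omega[[l]]))
})

setMethod("show", "AgeModel", function(object) {
    cat("AgeModel: mu =", object@mu, "per site per generation,",
        object@gensPerYear, "generations/year, branch divisor",
        object@branchDivisor, "\n")
})
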