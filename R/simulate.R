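# run expr under a given seed without disturbing the caller's RNG stream
withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    expr
}

SENSE_CODONS <- setdiff(names(Biostrings::GENETIC_CODE),
                        c("TAA", "TAG", "TGA"))
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Generate a synthetic reference genome with gene models
#'
#' Draws random contig sequences at the configured GC content and places
#' the configured number of non-overlapping single-CDS genes (random
#' strand), each starting with ATG, ending with a stop codon and free of
#' internal stops. Deterministic for a given config seed.
#'
#' @param config a [SimulationConfig-class].
#' @return A [ReferenceGenome-class].
#' @seealso [simulateLineages()], [writeSimulatedData()]
#' @export
generateReference <- function(config) {
    withSeed(config@seed, {
        gc <- config@gcContent
        baseProb <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2,
                      T = (1 - gc) / 2)
        glen <- config@geneLength
        nCodons <- glen %/% 3L
        perContig <- diff(round(seq(0, config@nGenes,
                                    length.out = config@nContigs + 1L)))
        seqs <- character(config@nContigs)
        geneRanges <- list()
        gid <- 0L
        for (ci in seq_len(config@nContigs)) {
            s <- sample(names(baseProb), config@contigLength, replace = TRUE,
                        prob = baseProb)
            k <- perContig[ci]
            if (k > 0L) {
                slack <- config@contigLength - k * (glen + 1L)
                if (slack < 0L) stop("genes cannot be placed in contig ", ci)
                gaps <- sort(sample.int(slack + 1L, k, replace = TRUE) - 1L)
                starts <- gaps + (seq_len(k) - 1L) * (glen + 1L)  # 0-based
                for (j in seq_len(k)) {
                    gid <- gid + 1L
                    body <- sample(SENSE_CODONS, nCodons - 2L, replace = TRUE)
                    geneSeq <- paste(c("ATG", body,
                                       sample(STOP_CODONS, 1L)),
                                     collapse = "")
                    minus <- runif(1) < 0.5
                    ins <- if (minus)
                        chartr("ACGT", "TGCA",
                               paste(rev(strsplit(geneSeq, "")[[1L]]),
                                     collapse = ""))
                    else geneSeq
                    s[(starts[j] + 1L):(starts[j] + glen)] <-
                        strsplit(ins, "")[[1L]]
                    geneRanges[[sprintf("gene%03d", gid)]] <- GRanges(
                        paste0("ctg", ci),
                        IRanges(starts[j] + 1L, starts[j] + glen),
                        strand = if (minus) "-" else "+")
                }
            }
            seqs[ci] <- paste(s, collapse = "")
        }
        names(seqs) <- paste0("ctg", seq_len(config@nContigs))
        ReferenceGenome(seqs, GRangesList(geneRanges))
    })
}

#' Simulate clonal diploid lineages accumulating substitutions
#'
#' Each lineage is a star topology: every genotype descends independently
#' from the lineage founder (identical to the reference). A genotype's
#' branch length is \code{generations} scaled by a uniform factor on
#' \code{[1 - tSpread, 1 + tSpread]} (genotype-age heterogeneity; set
#' \code{tSpread = 0} for equal branches). Candidate mutations are drawn
#' Poisson(mu x genome length x branch length), placed uniformly over
#' sites with the configured transition bias among the three alternate
#' bases. A candidate whose amino-acid effect is nonsynonymous is retained
#' with probability \code{omega[lineage]} (the purifying-selection
#' thinning); all other candidates are always retained. Retained mutations
#' are homozygous with probability \code{pHom}, else heterozygous; a later
#' mutation at an already-mutated site overwrites the earlier one (the
#' total overwritten is reported in a message). \code{callableSites} is
#' the genome length. Deterministic for a given config seed.
#'
#' @param config a [SimulationConfig-class].
#' @param genome the [ReferenceGenome-class] to mutate (normally from
#'   [generateReference()] with the same config).
#' @return named list of [GenotypeCallSet-class], one per genotype, with
#'   ids \code{<lineage>_g<i>}.
#' @export
simulateLineages <- function(config, genome) {
    idx <- codingIndex(genome)
    L <- genomeLength(genome)
    widths <- Biostrings::width(contigs(genome))
    ctgNames <- names(contigs(genome))
    cumw <- cumsum(as.numeric(widths))
    offsets <- c(0, head(cumw, -1L))
    transition <- c(A = "G", G = "A", C = "T", T = "C")
    tv1 <- c(A = "C", G = "C", C = "A", T = "A")
    tv2 <- c(A = "T", G = "T", C = "G", T = "G")
    pTs <- config@kappa / (config@kappa + 2)
    overwritten <- 0L
    out <- list()
    withSeed(config@seed + 1L, {
        for (lin in names(config@genotypes)) {
            omega <- config@omega[[lin]]
            tbar <- config@generations[[lin]]
            for (i in seq_len(config@genotypes[[lin]])) {
                tEff <- tbar * stats::runif(1, 1 - config@tSpread,
                                            1 + config@tSpread)
                nCand <- stats::rpois(1, config@mu * L * tEff)
                gidx <- sample.int(L, nCand, replace = TRUE)   # 1-based global
                ctgI <- findInterval(gidx - 1L, cumw) + 1L
                ctg <- ctgNames[ctgI]
                pos <- gidx - offsets[ctgI] - 1L               # 0-based
                refb <- substring(idx$contigChar[ctg], pos + 1L, pos + 1L)
                uTs <- stats::runif(nCand)
                uTv <- stats::runif(nCand)
                alt <- ifelse(uTs < pTs, transition[refb],
                              ifelse(uTv < 0.5, tv1[refb], tv2[refb]))
                alt <- unname(alt)
                uSel <- stats::runif(nCand)
                uZyg <- stats::runif(nCand)
                cls <- if (nCand)
                    classifyCore(idx, ctg, pos, alt, checkRef = FALSE)$class
                else character()
                keep <- !(cls %in% "nonsynonymous") | uSel < omega
                ctg <- ctg[keep]; pos <- pos[keep]; refb <- refb[keep]
                alt <- alt[keep]; uZyg <- uZyg[keep]
                # later mutations overwrite earlier ones at the same site
                key <- paste(ctg, pos)
                lastIdx <- rev(seq_along(key))[!duplicated(rev(key))]
                overwritten <- overwritten + length(key) - length(lastIdx)
                sel <- sort(lastIdx)
                df <- data.frame(
                    contig = ctg[sel], pos = pos[sel], ref = refb[sel],
                    alt = alt[sel],
                    zygosity = ifelse(uZyg[sel] < config@pHom, "hom_alt",
                                      "het"),
                    stringsAsFactors = FALSE)
                id <- sprintf("%s_g%d", lin, i)
                out[[id]] <- GenotypeCallSet(id, lin, df, callableSites = L)
            }
        }
    })
    if (overwritten > 0L)
        message(overwritten, " mutation(s) overwrote an earlier one at the",
                " same site")
    out
}

#' Write a full synthetic dataset to disk
#'
#' Generates the reference and lineages for \code{config} and writes the
#' file bundle consumed by the readers: \code{reference.fasta},
#' \code{genes.gff3}, one \code{<genotype>.vcf} per genotype and
#' \code{lineages.tsv} (columns \code{genotype_id}, \code{lineage_id},
#' \code{vcf_path}, \code{callable_sites}).
#'
#' @param config a [SimulationConfig-class].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with the generated \code{genome},
#'   \code{callsets} and all file \code{paths}.
#' @export
writeSimulatedData <- function(config, dir) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    genome <- generateReference(config)
    callsets <- simulateLineages(config, genome)
    fasta <- file.path(dir, "reference.fasta")
    gff <- file.path(dir, "genes.gff3")
    writeFasta(contigs(genome), fasta)
    writeGff3Genes(geneModels(genome), gff)
    vcfs <- vapply(callsets, function(cs) {
        p <- file.path(dir, paste0(genotypeId(cs), ".vcf"))
        writeVcfCalls(cs, p, contigs(genome))
        p
    }, "")
    tab <- data.frame(
        genotype_id = vapply(callsets, genotypeId, ""),
        lineage_id = vapply(callsets, lineageId, ""),
        vcf_path = basename(unname(vcfs)),    # relative to the TSV location
        callable_sites = vapply(callsets, callableSites, 0),
        stringsAsFactors = FALSE)
    lt <- file.path(dir, "lineages.tsv")
    writeLineageTable(tab, lt)
    invisible(list(genome = genome, callsets = callsets,
                   paths = list(fasta = fasta, gff3 = gff, vcfs = vcfs,
                                lineages = lt)))
}
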