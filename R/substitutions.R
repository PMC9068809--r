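#' Per-genotype substitution rate
#'
#' The proportion of substituted nucleotides in one diploid genotype,
#' weighting homozygous substitutions twice:
#' \deqn{N_{sub} = (2\,hom + het) / n_{examined}}
#' where \eqn{hom} and \eqn{het} are the numbers of sites at which both,
#' respectively one, of the two alleles differ from the reference, and the
#' denominator is the genotype's callable-site count.
#'
#' @param callset a [GenotypeCallSet-class].
#' @return numeric scalar.
#' @examples
#' df <- data.frame(contig = "c1", pos = c(1, 5, 9), ref = "A", alt = "G",
#'                  zygosity = c("hom_alt", "het", "het"))
#' substitutionRate(GenotypeCallSet("g", calls = df, callableSites = 1000))
#' @export
substitutionRate <- function(callset) {
    if (callableSites(callset) <= 0)
        stop("callableSites must be positive")
    z <- mcols(variantCalls(callset))$zygosity
    (2 * sum(z == "hom_alt") + sum(z == "het")) / callableSites(callset)
}

# classification annotation of one callset's alt alleles
annotateCalls <- function(idx, callset) {
    tab <- callsTable(callset)
    if (nrow(tab) == 0L) {
        tab$class <- character(0)
        tab$gene_id <- character(0)
        return(tab)
    }
    refb <- vapply(seq_len(nrow(tab)), function(i)
        substring(idx$contigChar[[tab$contig[i]]], tab$pos[i] + 1L,
                  tab$pos[i] + 1L), "")
    if (any(refb != tab$ref))
        stop("call ref allele disagrees with the reference genome at ",
             tab$contig[refb != tab$ref][1L], ":",
             tab$pos[refb != tab$ref][1L])
    ann <- classifyCore(idx, tab$contig, tab$pos, tab$alt)
    tab$class <- ann$class
    tab$gene_id <- ann$gene_id
    tab
}

#' Synonymous and nonsynonymous counts versus the reference
#'
#' Counts each coding variant site of a genotype once (irrespective of
#' zygosity, the published convention) into S or N according to
#' [classifyChange()]. With \code{alleleWeighted = TRUE} homozygous sites
#' count twice (a sensitivity-analysis mode).
#'
#' @param genome a [ReferenceGenome-class].
#' @param callsets a [GenotypeCallSet-class] or list of them.
#' @param alleleWeighted logical; weight homozygous sites by 2.
#' @return data.frame with one row per genotype: \code{genotype_id},
#'   \code{lineage_id}, \code{S}, \code{N}, \code{ratio} (N/S; \code{NA}
#'   when S = 0), \code{n_sub}.
#' @seealso [substitutionRate()], [pairwiseMatrix()]
#' @export
countSN <- function(genome, callsets, alleleWeighted = FALSE) {
    if (is(callsets, "GenotypeCallSet")) callsets <- list(callsets)
    idx <- codingIndex(genome)
    rows <- lapply(callsets, function(cs) {
        ann <- annotateCalls(idx, cs)
        w <- if (alleleWeighted) ifelse(ann$zygosity == "hom_alt", 2, 1)
             else rep(1, nrow(ann))
        S <- sum(w[ann$class %in% "synonymous"])
        N <- sum(w[ann$class %in% "nonsynonymous"])
        data.frame(genotype_id = genotypeId(cs), lineage_id = lineageId(cs),
                   S = S, N = N, ratio = if (S > 0) N / S else NA_real_,
                   n_sub = substitutionRate(cs), stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

# Pairwise comparison of two annotated call tables. A site contributes
# when the unordered diploid allele pair differs between the genotypes
# (no call = homozygous reference).
pairCore <- function(tabA, tabB, sites, alleleLevel = FALSE) {
    keyA <- paste(tabA$contig, tabA$pos)
    keyB <- paste(tabB$contig, tabB$pos)
    iB <- match(keyA, keyB)
    shared <- !is.na(iB)
    mismatch <- shared & tabA$ref != tabB$ref[iB]
    if (any(mismatch))
        stop("different reference alleles recorded at ",
             tabA$contig[mismatch][1L], ":", tabA$pos[mismatch][1L])

    # sites called in exactly one genotype always differ from hom-ref
    onlyA <- tabA[!shared, , drop = FALSE]
    onlyB <- tabB[is.na(match(keyB, keyA)), , drop = FALSE]
    one <- rbind(onlyA, onlyB)
    oneHom <- one$zygosity == "hom_alt"          # other genotype is hom ref
    oneW <- ifelse(one$zygosity == "hom_alt", 2L, 1L)
    oneClass <- one$class

    # sites called in both: differ unless same alt and same zygosity
    a <- tabA[shared, , drop = FALSE]
    b <- tabB[iB[shared], , drop = FALSE]
    diff2 <- !(a$alt == b$alt & a$zygosity == b$zygosity)
    a <- a[diff2, , drop = FALSE]
    b <- b[diff2, , drop = FALSE]
    bothHom <- a$zygosity == "hom_alt" & b$zygosity == "hom_alt"
    # allele weight: 2 minus the number of shared alleles in the two
    # unordered diploid genotypes
    sharedAlleles <- integer(nrow(a))
    ties <- 0L
    class2 <- character(nrow(a))
    for (i in seq_len(nrow(a))) {
        gA <- if (a$zygosity[i] == "hom_alt") c(a$alt[i], a$alt[i])
              else c(a$ref[i], a$alt[i])
        gB <- if (b$zygosity[i] == "hom_alt") c(b$alt[i], b$alt[i])
              else c(b$ref[i], b$alt[i])
        common <- sum(pmin(table(factor(gA, levels = unique(c(gA, gB)))),
                           table(factor(gB, levels = unique(c(gA, gB))))))
        sharedAlleles[i] <- common
        if (a$alt[i] == b$alt[i]) {
            class2[i] <- a$class[i]
        } else {
            cls <- unique(c(a$class[i], b$class[i]))
            if (length(cls) == 1L) {
                class2[i] <- cls
            } else {
                # discordant classification of the two non-shared alleles:
                # count the site as nonsynonymous (conservative) and log it
                class2[i] <- "nonsynonymous"
                ties <- ties + 1L
            }
        }
    }
    w2 <- 2L - sharedAlleles

    cls <- c(oneClass, class2)
    hom <- c(oneHom, bothHom)
    w <- if (alleleLevel) c(oneW, w2) else rep(1L, length(cls))

    tally <- function(sel) sum(w[sel])
    syn <- cls %in% "synonymous"
    non <- cls %in% "nonsynonymous"
    data.frame(dnC = tally(cls %in% "non_coding"),
               dS = tally(syn), dN = tally(non),
               dS_hom = tally(syn & hom), dS_het = tally(syn & !hom),
               dN_hom = tally(non & hom), dN_het = tally(non & !hom),
               sites_compared = sites, n_class_ties = ties)
}

#' Pairwise substitution counts between two genotypes of one lineage
#'
#' Counts sites at which the unordered diploid allele pairs of the two
#' genotypes differ (a genotype without a call is homozygous reference).
#' Differing non-coding sites increment \code{dnC}; differing coding
#' sites increment \code{dS} or \code{dN} by classifying the non-shared
#' alternate allele(s). Each coding count is additionally sorted by
#' zygosity, without regard to direction: \code{hom} when both genotypes
#' are homozygous at the site (homozygous reference included), \code{het}
#' when either genotype is heterozygous. With \code{alleleLevel = TRUE}
#' a site contributes the number of differing alleles (0--2) instead of 1.
#'
#' @param genome a [ReferenceGenome-class].
#' @param a,b [GenotypeCallSet-class] objects against the same reference.
#' @param alleleLevel logical, count differing alleles instead of sites.
#' @param sitesCompared number of sites compared; defaults to the full
#'   reference length (supply the callable-space intersection if known).
#' @return one-row data.frame: \code{genotype_a}, \code{genotype_b},
#'   \code{lineage_id}, \code{dnC}, \code{dS}, \code{dN}, \code{dS_hom},
#'   \code{dS_het}, \code{dN_hom}, \code{dN_het}, \code{sites_compared},
#'   \code{n_class_ties}.
#' @seealso [pairwiseMatrix()]
#' @export
pairwiseCounts <- function(genome, a, b, alleleLevel = FALSE,
                           sitesCompared = NULL) {
    idx <- codingIndex(genome)
    if (is.null(sitesCompared)) sitesCompared <- genomeLength(genome)
    res <- pairCore(annotateCalls(idx, a), annotateCalls(idx, b),
                    sitesCompared, alleleLevel)
    cbind(data.frame(genotype_a = genotypeId(a), genotype_b = genotypeId(b),
                     lineage_id = lineageId(a), stringsAsFactors = FALSE),
          res)
}

#' All within-lineage pairwise substitution counts
#'
#' Applies [pairwiseCounts()] to every unordered pair of the supplied
#' genotypes, yielding \eqn{n(n-1)/2} rows.
#'
#' @param genome a [ReferenceGenome-class].
#' @param callsets list of \eqn{n \ge 2} [GenotypeCallSet-class] objects
#'   (normally the genotypes of one lineage).
#' @inheritParams pairwiseCounts
#' @return data.frame as in [pairwiseCounts()], one row per pair.
#' @export
pairwiseMatrix <- function(genome, callsets, alleleLevel = FALSE,
                           sitesCompared = NULL) {
    if (length(callsets) < 2L)
        stop("need at least 2 genotypes for pairwise comparison")
    idx <- codingIndex(genome)
    if (is.null(sitesCompared)) sitesCompared <- genomeLength(genome)
    ann <- lapply(callsets, function(cs) annotateCalls(idx, cs))
    n <- length(callsets)
    rows <- vector("list", n * (n - 1L) / 2L)
    k <- 0L
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
        k <- k + 1L
        rows[[k]] <- cbind(
            data.frame(genotype_a = genotypeId(callsets[[i]]),
                       genotype_b = genotypeId(callsets[[j]]),
                       lineage_id = lineageId(callsets[[i]]),
                       stringsAsFactors = FALSE),
            pairCore(ann[[i]], ann[[j]], sitesCompared, alleleLevel))
    }
    do.call(rbind, rows)
}

#' Genes with genotype-specific (unique) nonsynonymous substitutions
#'
#' For each genotype, counts the genes containing at least one
#' nonsynonymous variant (site + alternate allele) present in that
#' genotype and in none of the other genotypes supplied. Pass the
#' genotypes of one lineage for the within-lineage tally (the published
#' convention); pass all genotypes for a cross-lineage tally.
#'
#' @param genome a [ReferenceGenome-class].
#' @param callsets list of \eqn{\ge 2} [GenotypeCallSet-class] objects.
#' @return data.frame: \code{genotype_id}, \code{lineage_id},
#'   \code{n_genes}.
#' @seealso [lineageMeanUnique()]
#' @export
uniqueNonsynGenes <- function(genome, callsets) {
    if (length(callsets) < 2L)
        stop("need at least 2 genotypes to assess uniqueness")
    idx <- codingIndex(genome)
    ann <- lapply(callsets, function(cs) {
        tab <- annotateCalls(idx, cs)
        tab[tab$class %in% "nonsynonymous", c("contig", "pos", "alt",
                                              "gene_id")]
    })
    keys <- lapply(ann, function(tab) paste(tab$contig, tab$pos, tab$alt))
    allKeys <- unlist(keys, use.names = FALSE)
    counts <- table(allKeys)
    rows <- lapply(seq_along(callsets), function(i) {
        private <- counts[keys[[i]]] == 1L
        data.frame(genotype_id = genotypeId(callsets[[i]]),
                   lineage_id = lineageId(callsets[[i]]),
                   n_genes = length(unique(ann[[i]]$gene_id[private])),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}

#' Lineage mean of unique-nonsynonymous-gene counts
#'
#' Arithmetic mean of per-genotype gene counts, conventionally reported
#' to one decimal place.
#'
#' @param counts numeric vector of per-genotype counts, or the data.frame
#'   returned by [uniqueNonsynGenes()].
#' @return numeric scalar (unrounded mean).
#' @examples
#' lineageMeanUnique(c(22, 37, 31, 25, 27, 31, 30))  # 29.0
#' @export
lineageMeanUnique <- function(counts) {
    if (is.data.frame(counts)) counts <- counts$n_genes
    if (!length(counts)) stop("empty counts")
    mean(counts)
}
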