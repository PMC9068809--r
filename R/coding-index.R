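# Position-level coding index: for every contig, which gene (if any) covers
# each base and where that base sits in the gene's spliced CDS. Built once
# per genome and cached in the object's environment slot; all codon-aware
# operations are vectorized lookups against it.

splicedCds <- function(contigs, gr) {
    ctg <- as.character(seqnames(gr))[1L]
    minus <- as.character(strand(gr))[1L] == "-"
    parts <- vapply(seq_along(gr), function(i) {
        s <- Biostrings::subseq(contigs[[ctg]], start(gr)[i], end(gr)[i])
        if (minus) s <- Biostrings::reverseComplement(s)
        as.character(s)
    }, "")
    paste(parts, collapse = "")
}

# ReferenceGenome objects are treated as immutable (the constructor gives
# each a private cache environment); the fingerprint only guards against
# a cache environment shared across structurally different objects.
genomeFingerprint <- function(genome) {
    list(contigs = names(genome@contigs),
         widths = Biostrings::width(genome@contigs),
         genes = names(genome@genes))
}

codingIndex <- function(genome) {
    cache <- genome@cache
    fp <- genomeFingerprint(genome)
    if (!is.null(cache$idx) && identical(cache$fp, fp))
        return(cache$idx)
    contigs <- genome@contigs
    gl <- genome@genes
    geneIdx <- lapply(Biostrings::width(contigs), integer)
    cdsPos <- lapply(Biostrings::width(contigs),
                     function(w) rep(NA_integer_, w))
    names(geneIdx) <- names(cdsPos) <- names(contigs)
    nGenes <- length(gl)
    cds <- character(nGenes)
    geneStrand <- character(nGenes)
    geneContig <- character(nGenes)
    for (i in seq_len(nGenes)) {
        gr <- gl[[i]]
        ctg <- as.character(seqnames(gr))[1L]
        minus <- as.character(strand(gr))[1L] == "-"
        geneContig[i] <- ctg
        geneStrand[i] <- if (minus) "-" else "+"
        cds[i] <- splicedCds(contigs, gr)
        cum <- 0L
        for (j in seq_along(gr)) {
            p <- start(gr)[j]:end(gr)[j]           # 1-based genomic
            w <- length(p)
            covered <- geneIdx[[ctg]][p] > 0L
            if (any(covered)) {
                warning("gene ", names(gl)[i], " overlaps another gene; ",
                        "first annotation kept at ", sum(covered), " site(s)")
                p <- p[!covered]
            }
            geneIdx[[ctg]][p] <- i
            cdsPos[[ctg]][p] <- if (minus) cum + (end(gr)[j] - p) else
                cum + (p - start(gr)[j])
            cum <- cum + w
        }
    }
    idx <- list(geneIdx = geneIdx, cdsPos = cdsPos, cds = cds,
                geneStrand = geneStrand, geneContig = geneContig,
                geneIds = names(gl),
                contigChar = stats::setNames(as.character(contigs),
                                             names(contigs)))
    cache$idx <- idx
    cache$fp <- fp
    idx
}

# Vectorized classification core. Returns data.frame(class, gene_id) with
# class in {synonymous, nonsynonymous, non_coding}; NA class where the
# codon contains an ambiguous base.
classifyCore <- function(idx, contig, pos, alt, checkRef = TRUE) {
    n <- max(length(contig), length(pos), length(alt))
    contig <- rep_len(as.character(contig), n)
    pos <- rep_len(as.integer(pos), n)
    alt <- rep_len(toupper(as.character(alt)), n)
    unknown <- !contig %in% names(idx$geneIdx)
    if (any(unknown)) stop("unknown contig: ", contig[unknown][1L])
    gi <- integer(n); cp <- integer(n); refb <- character(n)
    for (ctg in unique(contig)) {
        sel <- which(contig == ctg)
        p <- pos[sel]
        if (any(p < 0L | p >= length(idx$geneIdx[[ctg]])))
            stop("position outside contig ", ctg)
        gi[sel] <- idx$geneIdx[[ctg]][p + 1L]
        cp[sel] <- idx$cdsPos[[ctg]][p + 1L]
        refb[sel] <- substring(idx$contigChar[[ctg]], p + 1L, p + 1L)
    }
    if (checkRef && any(alt == refb))
        stop("alt allele equals the reference base at ",
             contig[alt == refb][1L], ":", pos[alt == refb][1L])
    cls <- rep("non_coding", n)
    gene <- rep(NA_character_, n)
    cod <- which(gi > 0L)
    if (length(cod)) {
        g <- gi[cod]
        gene[cod] <- idx$geneIds[g]
        codonStart <- (cp[cod] %/% 3L) * 3L + 1L
        codon <- substr(idx$cds[g], codonStart, codonStart + 2L)
        a <- alt[cod]
        minus <- idx$geneStrand[g] == "-"
        a[minus] <- chartr("ACGT", "TGCA", a[minus])
        mut <- codon
        off <- cp[cod] %% 3L
        substr(mut, off + 1L, off + 1L) <- a
        gc <- Biostrings::GENETIC_CODE
        aa0 <- unname(gc[codon])
        aa1 <- unname(gc[mut])
        cls[cod] <- ifelse(is.na(aa0) | is.na(aa1), NA_character_,
                           ifelse(aa0 == aa1, "synonymous", "nonsynonymous"))
        if (anyNA(cls[cod]))
            warning("ambiguous base in codon at ",
                    sum(is.na(cls[cod])), " site(s); class is NA")
    }
    data.frame(class = cls, gene_id = gene, stringsAsFactors = FALSE)
}

#' Classify a single-base change as synonymous, nonsynonymous or non-coding
#'
#' Coding sites are classified by substituting the alternate base into the
#' reference codon (strand-aware, spliced across CDS segments) and
#' comparing amino acids under the standard genetic code; stop-gain and
#' stop-loss changes count as nonsynonymous. Vectorized over sites.
#'
#' @param genome a [ReferenceGenome-class].
#' @param contig contig id(s).
#' @param pos 0-based position(s).
#' @param alt alternate base(s); must differ from the reference base.
#' @return character vector with values \code{"synonymous"},
#'   \code{"nonsynonymous"} or \code{"non_coding"}.
#' @examples
#' g <- ReferenceGenome(c(c1 = "ATGAAATAG"),
#'     GRangesList(g1 = GRanges("c1", IRanges(1, 9), strand = "+")))
#' classifyChange(g, "c1", c(5, 3), c("G", "G"))  # Lys->Lys, Lys->Glu
#' @export
classifyChange <- function(genome, contig, pos, alt) {
    classifyCore(codingIndex(genome), contig, pos, alt)$class
}

#' Mutational opportunity counts of a genome
#'
#' Enumerates all three possible single-base changes at every CDS position
#' and classifies each; the non-coding entry is the number of non-coding
#' sites. The synonymous:nonsynonymous opportunity ratio calibrates the
#' simulator and converts observed dN/dS into a retention-probability
#' estimate.
#'
#' @param genome a [ReferenceGenome-class].
#' @return named numeric vector: \code{synonymous} and
#'   \code{nonsynonymous} site-change counts and \code{non_coding} site
#'   count.
#' @export
siteOpportunities <- function(genome) {
    idx <- codingIndex(genome)
    syn <- 0; nonsyn <- 0; ncod <- 0
    bases <- c("A", "C", "G", "T")
    for (ctg in names(idx$geneIdx)) {
        covered <- which(idx$geneIdx[[ctg]] > 0L)
        ncod <- ncod + length(idx$geneIdx[[ctg]]) - length(covered)
        if (!length(covered)) next
        pos <- covered - 1L
        refb <- substring(idx$contigChar[[ctg]], covered, covered)
        p3 <- rep(pos, each = 3L)
        a3 <- unlist(lapply(refb, function(b) setdiff(bases, b)),
                     use.names = FALSE)
        cl <- classifyCore(idx, ctg, p3, a3)$class
        syn <- syn + sum(cl == "synonymous", na.rm = TRUE)
        nonsyn <- nonsyn + sum(cl == "nonsynonymous", na.rm = TRUE)
    }
    c(synonymous = syn, nonsynonymous = nonsyn, non_coding = ncod)
}
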