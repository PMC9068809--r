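#' Read contig sequences from FASTA
#'
#' Sequences are case-folded to upper case; duplicate contig ids and empty
#' files are errors. Alphabet is checked against A, C, G, T, N.
#'
#' @param path FASTA file.
#' @return A \link[Biostrings]{DNAStringSet} named by contig id.
#' @seealso [writeFasta()], [ReferenceGenome()]
#' @export
readFasta <- function(path) {
    seqs <- Biostrings::readDNAStringSet(path)
    if (length(seqs) == 0L)
        stop("no sequences in FASTA file: ", path)
    # readDNAStringSet keeps the full header line; contig id is first token
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    if (anyDuplicated(names(seqs)))
        stop("duplicate contig id in FASTA file: ",
             names(seqs)[duplicated(names(seqs))][1L])
    seqs <- DNAStringSet(toupper(as.character(seqs)))
    bad <- setdiff(Biostrings::uniqueLetters(seqs), c("A", "C", "G", "T", "N"))
    if (length(bad))
        stop("unexpected characters in FASTA: ", paste(bad, collapse = ","))
    seqs
}

#' Write contig sequences to FASTA
#'
#' @param contigs named character vector or \code{DNAStringSet}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(contigs, path) {
    if (!is(contigs, "DNAStringSet"))
        contigs <- DNAStringSet(toupper(contigs))
    Biostrings::writeXStringSet(contigs, path)
    invisible(path)
}

#' Read gene models (CDS features) from GFF3
#'
#' CDS features are grouped into genes by their \code{Parent} attribute
#' (falling back to \code{ID}), converted from GFF3's 1-based inclusive
#' coordinates into \code{GRanges}, and ordered in translation order
#' (ascending start on +, descending start on -). Genes whose summed CDS
#' length is not a positive multiple of 3 are skipped with a warning.
#' When \code{contigs} is supplied, genes whose spliced CDS contains an
#' internal stop codon trigger a warning (they are kept).
#'
#' @param path GFF3 file.
#' @param contigs optional \code{DNAStringSet} for internal-stop checking.
#' @return \code{GRangesList} named by gene id.
#' @seealso [writeGff3Genes()], [readFasta()]
#' @export
readGff3Genes <- function(path, contigs = NULL) {
    gr <- rtracklayer::import(path)
    gr <- gr[tolower(as.character(gr$type)) == "cds"]
    if (length(gr) == 0L)
        return(GRangesList())
    parent <- as.character(S4Vectors::unstrsplit(gr$Parent, ","))
    noparent <- !nzchar(parent) | is.na(parent)
    if (any(noparent)) {
        id <- if (!is.null(gr$ID)) as.character(gr$ID) else
            rep(NA_character_, length(gr))
        parent[noparent] <- id[noparent]
    }
    if (anyNA(parent) || any(!nzchar(parent)))
        stop("CDS feature without Parent or ID attribute in ", path)
    mcols(gr) <- NULL
    parts <- split(gr, parent)
    keep <- rep(TRUE, length(parts))
    out <- vector("list", length(parts))
    for (i in seq_along(parts)) {
        g <- parts[[i]]
        if (sum(width(g)) %% 3L != 0L) {
            warning("gene ", names(parts)[i], ": CDS length ",
                    sum(width(g)), " is not a multiple of 3; gene skipped")
            keep[i] <- FALSE
            next
        }
        minus <- as.character(strand(g))[1L] == "-"
        out[[i]] <- g[order(start(g), decreasing = minus)]
    }
    gl <- GRangesList(out[keep])
    names(gl) <- names(parts)[keep]
    if (!is.null(contigs) && length(gl)) {
        aa <- vapply(names(gl), function(id)
            as.character(Biostrings::translate(DNAStringSet(
                splicedCds(contigs, gl[[id]]))[[1L]],
                if.fuzzy.codon = "X", no.init.codon = TRUE)), "")
        internal <- grepl("\\*.", aa)
        if (any(internal))
            warning("internal stop codon in gene(s): ",
                    paste(names(gl)[internal], collapse = ", "))
    }
    gl
}

#' Write gene models as GFF3 CDS features
#'
#' @param genes \code{GRangesList} as in [ReferenceGenome-class].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeGff3Genes <- function(genes, path) {
    ids <- rep(names(genes), S4Vectors::elementNROWS(genes))
    gr <- unlist(genes, use.names = FALSE)
    # phase of each segment in translation order
    phase <- unlist(lapply(genes, function(g) {
        cum <- cumsum(c(0L, head(width(g), -1L)))
        as.integer((3L - cum %% 3L) %% 3L)
    }), use.names = FALSE)
    if (length(gr)) {
        mcols(gr) <- DataFrame(
            source = "ClonalSubs", type = "CDS", phase = phase,
            ID = paste0(ids, ".cds", unlist(lapply(
                S4Vectors::elementNROWS(genes), seq_len), use.names = FALSE)),
            Parent = ids)
    }
    rtracklayer::export(gr, path, format = "gff3")
    invisible(path)
}

#' Read one genotype's diploid variant calls from a single-sample VCF
#'
#' Applies the call-level filters used throughout the package: biallelic
#' single-nucleotide variants only, read depth \code{>= minDepth}
#' (default 5) and site quality strictly \code{> minQual} (default 20).
#' Genotypes 1/1 become \code{hom_alt}, 0/1 and 1/0 become \code{het};
#' 0/0 and missing genotypes are dropped. Indels and multiallelic records
#' are dropped with a message reporting the count. Multi-sample VCFs and
#' records without GT or DP are errors, as is any non-diploid genotype.
#'
#' @param path single-sample VCF (v4.x) file.
#' @param genotypeId,lineageId identifiers for the resulting call set
#'   (default: the VCF sample name, lineage \code{NA}).
#' @param callableSites number of nucleotides examined for this genotype
#'   (the denominator of [substitutionRate()]); it is an explicit input
#'   because it cannot be recovered from a VCF.
#' @param minDepth,minQual filter thresholds.
#' @return A [GenotypeCallSet-class].
#' @seealso [writeVcfCalls()], [readLineageTable()]
#' @export
readVcfCalls <- function(path, callableSites, genotypeId = NULL,
                         lineageId = NA_character_, minDepth = 5,
                         minQual = 20) {
    vcf <- VariantAnnotation::readVcf(path)
    if (ncol(vcf) != 1L)
        stop("expected a single-sample VCF, got ", ncol(vcf), " samples")
    gmat <- VariantAnnotation::geno(vcf)
    if (!"GT" %in% names(gmat)) stop("VCF lacks the GT genotype field")
    if (!"DP" %in% names(gmat)) stop("VCF lacks the DP depth field")
    if (is.null(genotypeId)) genotypeId <- colnames(vcf)[1L]

    rr <- SummarizedExperiment::rowRanges(vcf)
    ref <- as.character(VariantAnnotation::ref(vcf))
    altL <- VariantAnnotation::alt(vcf)
    nalt <- S4Vectors::elementNROWS(altL)
    alt1 <- rep(NA_character_, length(vcf))
    alt1[nalt == 1L] <- as.character(unlist(altL[nalt == 1L]))
    gt <- as.character(gmat$GT[, 1L])
    dp <- as.integer(gmat$DP[, 1L])
    qual <- as.numeric(VariantAnnotation::qual(vcf))

    ploidy <- lengths(strsplit(gsub("\\|", "/", gt), "/", fixed = TRUE))
    called <- !gt %in% c(".", "./.", ".|.")
    if (any(called & ploidy != 2L))
        stop("non-diploid genotype in VCF: ", gt[called & ploidy != 2L][1L])

    snv <- nchar(ref) == 1L & nalt == 1L & !is.na(alt1) & nchar(alt1) == 1L &
        alt1 %in% c("A", "C", "G", "T")
    nondropped <- sum(snv)
    if (length(vcf) > nondropped)
        message(length(vcf) - nondropped,
                " indel/multiallelic record(s) dropped")

    gtn <- gsub("\\|", "/", gt)
    zyg <- rep(NA_character_, length(vcf))
    zyg[gtn == "1/1"] <- "hom_alt"
    zyg[gtn %in% c("0/1", "1/0")] <- "het"
    keep <- snv & !is.na(zyg) & !is.na(dp) & dp >= minDepth &
        !is.na(qual) & qual > minQual
    ndropfilt <- sum(snv & !is.na(zyg)) - sum(keep)
    if (ndropfilt > 0)
        message(ndropfilt, " call(s) removed by depth/quality filters")

    calls <- GRanges(seqnames(rr)[keep],
                     IRanges(start(rr)[keep], width = 1L),
                     ref = ref[keep], alt = alt1[keep],
                     zygosity = zyg[keep], depth = dp[keep],
                     qual = qual[keep])
    GenotypeCallSet(genotypeId, lineageId, calls, callableSites)
}

#' Write a GenotypeCallSet as a single-sample VCF
#'
#' @param callset a [GenotypeCallSet-class].
#' @param path output file.
#' @param contigs optional \code{DNAStringSet}; contig header lines are
#'   written when supplied.
#' @return \code{path}, invisibly.
#' @export
writeVcfCalls <- function(callset, path, contigs = NULL) {
    cl <- variantCalls(callset)
    hdr <- c("##fileformat=VCFv4.2",
             "##source=ClonalSubs",
             if (!is.null(contigs))
                 sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                         Biostrings::width(contigs)),
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
             paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", genotypeId(callset), sep = "\t"))
    gt <- ifelse(mcols(cl)$zygosity == "hom_alt", "1/1", "0/1")
    body <- if (length(cl)) {
        o <- order(as.character(seqnames(cl)), start(cl))
        paste(as.character(seqnames(cl))[o], start(cl)[o], ".",
              mcols(cl)$ref[o], mcols(cl)$alt[o],
              format(mcols(cl)$qual[o], trim = TRUE), "PASS", ".", "GT:DP",
              paste0(gt[o], ":", mcols(cl)$depth[o]), sep = "\t")
    } else character()
    writeLines(c(hdr, body), path)
    invisible(path)
}

#' Read or write a lineage assignment table
#'
#' Tab-separated table with columns \code{genotype_id}, \code{lineage_id},
#' \code{vcf_path}, \code{callable_sites}. Duplicate genotype ids are an
#' error on read.
#'
#' @param path TSV file.
#' @return \code{readLineageTable}: a data.frame with those columns.
#' @export
readLineageTable <- function(path) {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             comment.char = "#")
    need <- c("genotype_id", "lineage_id", "vcf_path", "callable_sites")
    if (!all(need %in% names(tab)))
        stop("lineage table must have columns: ", paste(need, collapse = ", "))
    if (anyDuplicated(tab$genotype_id))
        stop("duplicate genotype_id in lineage table: ",
             tab$genotype_id[duplicated(tab$genotype_id)][1L])
    tab[need]
}

#' @rdname readLineageTable
#' @param tab data.frame as returned by \code{readLineageTable}.
#' @return \code{writeLineageTable}: \code{path}, invisibly.
#' @export
writeLineageTable <- function(tab, path) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Calls of a GenotypeCallSet as a plain data.frame
#'
#' @param callset a [GenotypeCallSet-class].
#' @return data.frame with columns \code{contig}, \code{pos} (0-based),
#'   \code{ref}, \code{alt}, \code{zygosity}, \code{depth}, \code{qual}.
#' @export
callsTable <- function(callset) {
    cl <- variantCalls(callset)
    data.frame(contig = as.character(seqnames(cl)), pos = start(cl) - 1L,
               ref = mcols(cl)$ref, alt = mcols(cl)$alt,
               zygosity = mcols(cl)$zygosity, depth = mcols(cl)$depth,
               qual = mcols(cl)$qual, stringsAsFactors = FALSE)
}

#' Classify a genomic site as coding or non-coding
#'
#' A site is coding iff it falls inside any gene's CDS segment.
#'
#' @param genome a [ReferenceGenome-class].
#' @param contig contig id(s).
#' @param pos 0-based site position(s).
#' @return character vector, \code{"coding"} or \code{"non_coding"}.
#' @examples
#' g <- ReferenceGenome(c(c1 = "ACGTACGTACGT"),
#'     GRangesList(g1 = GRanges("c1", IRanges(4, 9), strand = "+")))
#' siteRegion(g, "c1", c(2, 3, 8, 9))
#' @export
siteRegion <- function(genome, contig, pos) {
    idx <- codingIndex(genome)
    n <- max(length(contig), length(pos))
    contig <- rep_len(as.character(contig), n)
    pos <- rep_len(pos, n)
    unknown <- !contig %in% names(idx$geneIdx)
    if (any(unknown)) stop("unknown contig: ", contig[unknown][1L])
    out <- character(n)
    for (ctg in unique(contig)) {
        sel <- contig == ctg
        v <- idx$geneIdx[[ctg]]
        p <- pos[sel]
        if (any(p < 0 | p >= length(v)))
            stop("position outside contig ", ctg)
        out[sel] <- ifelse(v[p + 1L] > 0L, "coding", "non_coding")
    }
    out
}

#' Reference codon and within-codon offset at a coding position
#'
#' The codon is read in translation order: spliced over CDS segments and
#' reverse-complemented for minus-strand genes; the offset (0..2) counts
#' in the translation direction.
#'
#' @param genome a [ReferenceGenome-class].
#' @param geneId gene id.
#' @param pos 0-based genomic position on the gene's contig; must lie in
#'   the gene's CDS.
#' @return list with elements \code{codon} (3-letter string) and
#'   \code{offset} (0, 1 or 2).
#' @export
codonContext <- function(genome, geneId, pos) {
    idx <- codingIndex(genome)
    gi <- match(geneId, idx$geneIds)
    if (is.na(gi)) stop("unknown gene: ", geneId)
    ctg <- idx$geneContig[[gi]]
    v <- idx$geneIdx[[ctg]]
    if (pos < 0 || pos >= length(v) || v[pos + 1L] != gi)
        stop("position ", pos, " is not in the CDS of gene ", geneId)
    cp <- idx$cdsPos[[ctg]][pos + 1L]
    list(codon = substr(idx$cds[[gi]], (cp %/% 3L) * 3L + 1L,
                        (cp %/% 3L) * 3L + 3L),
         offset = cp %% 3L)
}
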