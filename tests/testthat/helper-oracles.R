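# Independent brute-force oracles. These deliberately avoid the package's
# coding index: genes are located by scanning segment lists, effects are
# judged by rebuilding and translating whole mutant CDS sequences, and
# pairwise counts come from reconstructed diploid sequences compared site
# by site. oraclePlain() extracts a plain-R view of a genome once so the
# per-site oracle loops stay affordable.

suppressPackageStartupMessages({
    library(GenomicRanges)
    library(IRanges)
    library(Biostrings)
})

makeGenome <- function(seqs, genes = list()) {
    gl <- GRangesList(lapply(genes, function(g) {
        gr <- GRanges(g$contig, IRanges(g$starts + 1L, g$ends), # 0-based in
                      strand = g$strand)
        gr[order(start(gr), decreasing = g$strand == "-")]
    }))
    names(gl) <- names(genes)
    ReferenceGenome(seqs, gl)
}

revcompChr <- function(s)
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1L]]), collapse = "")

oraclePlain <- function(genome) {
    gl <- geneModels(genome)
    list(cs = as.character(contigs(genome)),
         genes = lapply(stats::setNames(names(gl), names(gl)), function(id) {
             gr <- gl[[id]]
             list(contig = as.character(seqnames(gr))[1L],
                  strand = as.character(strand(gr))[1L],
                  starts = start(gr), ends = end(gr))  # translation order
         }))
}

# splice a gene's CDS out of contig strings (translation order)
oracleSplice <- function(cs, gene) {
    segs <- vapply(seq_along(gene$starts), function(i)
        substr(cs[[gene$contig]], gene$starts[i], gene$ends[i]), "")
    if (gene$strand == "-") segs <- vapply(segs, revcompChr, "")
    paste(segs, collapse = "")
}

# plain whole-string translation against the standard code table
oracleTranslate <- function(cds) {
    codons <- substring(cds, seq(1L, nchar(cds), 3L),
                        seq(3L, nchar(cds), 3L))
    aa <- Biostrings::GENETIC_CODE[codons]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
}

oracleTranslateGene <- function(genome, geneId, plain = oraclePlain(genome))
    oracleTranslate(oracleSplice(plain$cs, plain$genes[[geneId]]))

# classify one change by mutating the contig and re-translating the first
# gene that covers the position (first annotation wins, as in-package)
oracleClassify <- function(genome, contig, pos, alt,
                           plain = oraclePlain(genome)) {
    hit <- NULL
    for (id in names(plain$genes)) {
        g <- plain$genes[[id]]
        if (g$contig == contig &&
            any(pos + 1L >= g$starts & pos + 1L <= g$ends)) {
            hit <- g
            break
        }
    }
    if (is.null(hit)) return("non_coding")
    before <- oracleTranslate(oracleSplice(plain$cs, hit))
    mut <- plain$cs
    substr(mut[[contig]], pos + 1L, pos + 1L) <- alt
    after <- oracleTranslate(oracleSplice(mut, hit))
    if (before == after) "synonymous" else "nonsynonymous"
}

# rebuild each genotype's unordered diploid allele pair at every variant
# site and count differing sites the way the package contract states
oraclePairwise <- function(genome, csA, csB) {
    plain <- oraclePlain(genome)
    tabA <- callsTable(csA)
    tabB <- callsTable(csB)
    allele2 <- function(tab, key) {
        i <- match(key, paste(tab$contig, tab$pos))
        if (is.na(i)) return(NULL)
        if (tab$zygosity[i] == "hom_alt") c(tab$alt[i], tab$alt[i])
        else sort(c(tab$ref[i], tab$alt[i]))
    }
    keys <- union(paste(tabA$contig, tabA$pos), paste(tabB$contig, tabB$pos))
    res <- c(dnC = 0, dS = 0, dN = 0, dS_hom = 0, dS_het = 0, dN_hom = 0,
             dN_het = 0)
    for (key in keys) {
        parts <- strsplit(key, " ")[[1L]]
        ctg <- parts[1L]; pos <- as.integer(parts[2L])
        refb <- substr(plain$cs[[ctg]], pos + 1L, pos + 1L)
        gA <- allele2(tabA, key); if (is.null(gA)) gA <- c(refb, refb)
        gB <- allele2(tabB, key); if (is.null(gB)) gB <- c(refb, refb)
        if (identical(sort(gA), sort(gB))) next
        hom <- gA[1L] == gA[2L] && gB[1L] == gB[2L]
        vals <- unique(c(gA, gB))
        nonShared <- vals[vapply(vals, function(v)
            sum(gA == v) != sum(gB == v), TRUE)]
        alts <- setdiff(nonShared, refb)
        cls <- unique(vapply(alts, function(a)
            oracleClassify(genome, ctg, pos, a, plain), ""))
        cls <- if (length(cls) == 1L) cls else "nonsynonymous"
        if (cls == "non_coding") {
            res["dnC"] <- res["dnC"] + 1
        } else if (cls == "synonymous") {
            res["dS"] <- res["dS"] + 1
            res[if (hom) "dS_hom" else "dS_het"] <-
                res[if (hom) "dS_hom" else "dS_het"] + 1
        } else {
            res["dN"] <- res["dN"] + 1
            res[if (hom) "dN_hom" else "dN_het"] <-
                res[if (hom) "dN_hom" else "dN_het"] + 1
        }
    }
    res
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
oracleMWU <- function(a, b) {
    pooled <- c(a, b)
    n <- length(pooled)
    na <- length(a)
    uStat <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
    uObs <- uStat(a, b)
    m <- na * length(b) / 2
    sets <- utils::combn(n, na)
    us <- apply(sets, 2L, function(i) uStat(pooled[i], pooled[-i]))
    list(U = uObs, p = mean(abs(us - m) >= abs(uObs - m) - 1e-12))
}

# random genotype call set over a genome (valid ref alleles, no site reuse)
randomCallset <- function(genome, id, lineage, nCalls, pHom = 0.3) {
    cs <- as.character(contigs(genome))
    widths <- nchar(cs)
    L <- sum(widths)
    sites <- sample.int(L, min(nCalls, L))
    cum <- cumsum(widths)
    ci <- findInterval(sites - 1L, cum) + 1L
    pos <- sites - c(0L, head(cum, -1L))[ci] - 1L
    ctg <- names(cs)[ci]
    refb <- vapply(seq_along(sites), function(i)
        substr(cs[[ctg[i]]], pos[i] + 1L, pos[i] + 1L), "")
    alt <- vapply(refb, function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1L), "")
    GenotypeCallSet(id, lineage,
        data.frame(contig = ctg, pos = pos, ref = refb, alt = unname(alt),
                   zygosity = ifelse(runif(length(sites)) < pHom, "hom_alt",
                                     "het")),
        callableSites = L)
}

smallTestConfig <- function(seed = 1L, ...) {
    args <- list(seed = seed, nContigs = 1L, contigLength = 12000L,
                 nGenes = 12L, geneLength = 300L,
                 genotypes = c(L1 = 3L, L2 = 3L),
                 generations = c(L1 = 800, L2 = 800),
                 omega = c(L1 = 0.5, L2 = 0.5), mu = 5e-6, tSpread = 0)
    extra <- list(...)
    args[names(extra)] <- extra
    do.call(SimulationConfig, args)
}
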