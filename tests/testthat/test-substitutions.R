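test_that("the substitution rate weights homozygous sites twice", {
    df <- data.frame(contig = "c1", pos = c(1, 5, 9, 12, 20),
                     ref = "A", alt = "G",
                     zygosity = c("hom_alt", "hom_alt", "het", "het", "het"))
    cs <- GenotypeCallSet("g", calls = df, callableSites = 1000)
    expect_equal(substitutionRate(cs), (2 * 2 + 3) / 1000)

    empty <- GenotypeCallSet("g", callableSites = 500)
    expect_equal(substitutionRate(empty), 0)

    allHom <- GenotypeCallSet("g", calls = data.frame(
        contig = "c1", pos = c(0, 4, 8), ref = "A", alt = "C",
        zygosity = "hom_alt"), callableSites = 300)
    expect_equal(substitutionRate(allHom), 2 * 3 / 300)

    expect_error(substitutionRate(GenotypeCallSet("g", callableSites = 0)),
                 "positive")
})

test_that("the substitution rate matches hand arithmetic on random call sets", {
    set.seed(101)
    for (i in 1:25) {
        nHom <- sample(0:20, 1)
        nHet <- sample(0:20, 1)
        sites <- sample(100:10000, 1)
        n <- nHom + nHet
        if (n == 0) next
        df <- data.frame(contig = "c1", pos = sample.int(50000, n),
                         ref = "A", alt = "G",
                         zygosity = c(rep("hom_alt", nHom), rep("het", nHet)))
        cs <- GenotypeCallSet("g", calls = df, callableSites = sites)
        expect_identical(substitutionRate(cs), (2 * nHom + nHet) / sites)
    }
})

test_that("countSN counts coding sites once regardless of zygosity", {
    g <- makeGenome(c(c1 = "ATGAAATAGCCCCC"),
                    list(g1 = list(contig = "c1", starts = 0L, ends = 9L,
                                   strand = "+")))
    df <- data.frame(contig = "c1", pos = c(5L, 3L, 11L),
                     ref = c("A", "A", "C"), alt = c("G", "G", "T"),
                     zygosity = c("hom_alt", "het", "het"))
    cs <- GenotypeCallSet("g", "L", df, callableSites = 14)
    res <- countSN(g, cs)
    expect_equal(res$S, 1)
    expect_equal(res$N, 1)
    expect_equal(res$ratio, 1)
    # allele-weighted mode doubles homozygous sites
    resW <- countSN(g, cs, alleleWeighted = TRUE)
    expect_equal(resW$S, 2)
    expect_equal(resW$N, 1)

    noCoding <- GenotypeCallSet("g", "L", data.frame(
        contig = "c1", pos = 11L, ref = "C", alt = "A", zygosity = "het"),
        callableSites = 14)
    res0 <- countSN(g, noCoding)
    expect_equal(res0$S, 0)
    expect_equal(res0$N, 0)
    expect_true(is.na(res0$ratio))
})

test_that("pairwise counting handles one-sided, zygosity-differing and identical sites", {
    g <- makeGenome(c(c1 = "ATGAAATAGCCCCC"),
                    list(g1 = list(contig = "c1", starts = 0L, ends = 9L,
                                   strand = "+")))
    # a: hom_alt G at non-coding site, b: no call -> dnC = 1 (hom pair)
    a <- GenotypeCallSet("a", "L", data.frame(
        contig = "c1", pos = 11L, ref = "C", alt = "G",
        zygosity = "hom_alt"), callableSites = 14)
    b <- GenotypeCallSet("b", "L", NULL, callableSites = 14)
    pc <- pairwiseCounts(g, a, b)
    expect_equal(pc$dnC, 1)
    expect_equal(pc$dS + pc$dN, 0)

    # het vs hom_alt of the same synonymous alt: {R,X} vs {X,X} differ,
    # sorted het because one genotype is heterozygous
    a2 <- GenotypeCallSet("a", "L", data.frame(
        contig = "c1", pos = 5L, ref = "A", alt = "G", zygosity = "het"),
        callableSites = 14)
    b2 <- GenotypeCallSet("b", "L", data.frame(
        contig = "c1", pos = 5L, ref = "A", alt = "G", zygosity = "hom_alt"),
        callableSites = 14)
    pc2 <- pairwiseCounts(g, a2, b2)
    expect_equal(pc2$dS, 1)
    expect_equal(pc2$dS_het, 1)
    expect_equal(pc2$dS_hom, 0)

    # identical call sets differ nowhere
    pc3 <- pairwiseCounts(g, a2, a2)
    expect_equal(pc3$dnC + pc3$dS + pc3$dN, 0)

    # hom-ref vs hom-alt counts as a homozygous difference
    pc4 <- pairwiseCounts(g, b2, b)
    expect_equal(pc4$dS_hom, 1)
    expect_equal(pc4$dS_het, 0)
})

test_that("pairwise decomposition identities hold on simulated data", {
    cfg <- smallTestConfig(seed = 91L, pHom = 0.4)
    genome <- generateReference(cfg)
    sims <- suppressMessages(simulateLineages(cfg, genome))
    pm <- pairwiseMatrix(genome, sims)
    expect_true(all(pm$dS == pm$dS_hom + pm$dS_het))
    expect_true(all(pm$dN == pm$dN_hom + pm$dN_het))
    expect_true(all(pm[c("dnC", "dS", "dN")] >= 0))
})

test_that("pairwise totals equal the sum of private calls for disjoint genotypes", {
    g <- ReferenceGenome(c(c1 = paste(rep("ACGT", 100), collapse = "")))
    set.seed(7)
    a <- randomCallset(g, "a", "L", 15)
    bTab <- callsTable(randomCallset(g, "b", "L", 40))
    bTab <- bTab[!bTab$pos %in% callsTable(a)$pos, ][1:15, ]
    b <- GenotypeCallSet("b", "L", bTab, callableSites = 400)
    pc <- pairwiseCounts(g, a, b)
    expect_equal(pc$dnC + pc$dS + pc$dN, 30)
})

test_that("pairwise counts match the diploid-reconstruction oracle on random genomes", {
    set.seed(55)
    for (rep in 1:12) {
        cfg <- smallTestConfig(seed = 200L + rep,
                               nContigs = sample(1:2, 1),
                               contigLength = sample(800:1500, 1),
                               nGenes = sample(2:5, 1), geneLength = 60L)
        genome <- generateReference(cfg)
        a <- randomCallset(genome, "a", "L", sample(5:25, 1))
        b <- randomCallset(genome, "b", "L", sample(5:25, 1))
        got <- pairwiseCounts(genome, a, b)
        want <- oraclePairwise(genome, a, b)
        for (f in names(want))
            expect_equal(got[[f]], unname(want[[f]]),
                         label = sprintf("rep %d field %s", rep, f))
    }
})

test_that("pairwiseMatrix yields n(n-1)/2 symmetric records", {
    g <- ReferenceGenome(c(c1 = paste(rep("ACGT", 250), collapse = "")))
    set.seed(9)
    seven <- lapply(1:7, function(i) randomCallset(g, paste0("g", i), "L", 10))
    pm7 <- pairwiseMatrix(g, seven)
    expect_equal(nrow(pm7), 21L)
    five <- seven[1:5]
    pm5 <- pairwiseMatrix(g, five)
    expect_equal(nrow(pm5), 10L)
    expect_error(pairwiseMatrix(g, seven[1]), "at least 2")

    rev5 <- pairwiseMatrix(g, rev(five))
    key <- function(pm) {
        k <- apply(pm[, c("genotype_a", "genotype_b")], 1L, function(r)
            paste(sort(r), collapse = "-"))
        pm2 <- pm[order(k), c("dnC", "dS", "dN", "dS_hom", "dS_het",
                              "dN_hom", "dN_het")]
        rownames(pm2) <- sort(k)
        pm2
    }
    expect_equal(key(rev5), key(pm5))
})

test_that("pairwise comparison rejects conflicting reference alleles", {
    g <- ReferenceGenome(c(c1 = "ACGTACGTAC"))
    a <- GenotypeCallSet("a", "L", data.frame(
        contig = "c1", pos = 2L, ref = "G", alt = "T", zygosity = "het"),
        callableSites = 10)
    b <- GenotypeCallSet("b", "L", data.frame(
        contig = "c1", pos = 2L, ref = "A", alt = "T", zygosity = "het"),
        callableSites = 10)
    expect_error(pairwiseCounts(g, a, b), "ref allele|reference alleles")
})

test_that("unique nonsynonymous gene counts follow set algebra", {
    g <- makeGenome(c(c1 = "ATGAAATAGCCCATGTTTTAGCC"),
                    list(g1 = list(contig = "c1", starts = 0L, ends = 9L,
                                   strand = "+"),
                         g2 = list(contig = "c1", starts = 12L, ends = 21L,
                                   strand = "+")))
    # shared synonymous call (AAA -> AAG): never counted as unique nonsyn
    shared <- data.frame(contig = "c1", pos = 5L, ref = "A", alt = "G",
                         zygosity = "het")
    a <- GenotypeCallSet("a", "L", shared, callableSites = 23)
    b <- GenotypeCallSet("b", "L", shared, callableSites = 23)
    res <- uniqueNonsynGenes(g, list(a, b))
    expect_equal(res$n_genes, c(0L, 0L))

    # one private nonsynonymous call in g2 for genotype b
    b2 <- GenotypeCallSet("b", "L", rbind(shared, data.frame(
        contig = "c1", pos = 15L, ref = "T", alt = "G", zygosity = "het")),
        callableSites = 23)
    res2 <- uniqueNonsynGenes(g, list(a, b2))
    expect_equal(res2$n_genes, c(0L, 1L))

    # same site, different alt alleles: both private
    aAlt <- GenotypeCallSet("a", "L", data.frame(
        contig = "c1", pos = 15L, ref = "T", alt = "A", zygosity = "het"),
        callableSites = 23)
    res3 <- uniqueNonsynGenes(g, list(aAlt, b2))
    expect_equal(res3$n_genes, c(1L, 1L))
})

test_that("unique gene counts on simulated lineages match a brute-force oracle", {
    cfg <- smallTestConfig(seed = 300L, genotypes = c(L1 = 3L, L2 = 2L),
                           generations = c(L1 = 1200, L2 = 1200),
                           omega = c(L1 = 1, L2 = 1))
    genome <- generateReference(cfg)
    sims <- suppressMessages(simulateLineages(cfg, genome))
    lin1 <- sims[grep("^L1", names(sims))]
    got <- uniqueNonsynGenes(genome, lin1)

    plain <- oraclePlain(genome)
    keysOf <- function(cs) {
        tab <- callsTable(cs)
        cls <- vapply(seq_len(nrow(tab)), function(i)
            oracleClassify(genome, tab$contig[i], tab$pos[i], tab$alt[i],
                           plain), "")
        tab <- tab[cls == "nonsynonymous", ]
        paste(tab$contig, tab$pos, tab$alt)
    }
    keys <- lapply(lin1, keysOf)
    geneOf <- function(key) {
        parts <- strsplit(key, " ")
        vapply(parts, function(p) {
            gl <- geneModels(genome)
            pos <- as.integer(p[2L])
            for (id in names(gl)) {
                gr <- gl[[id]]
                if (as.character(seqnames(gr))[1L] == p[1L] &&
                    any(pos + 1L >= start(gr) & pos + 1L <= end(gr)))
                    return(id)
            }
            NA_character_
        }, "")
    }
    for (i in seq_along(lin1)) {
        private <- setdiff(keys[[i]], unlist(keys[-i]))
        expect_equal(got$n_genes[i], length(unique(geneOf(private))),
                     label = names(lin1)[i])
    }
})

test_that("lineage means of unique-gene counts reproduce the published table", {
    jpn1 <- c(22, 37, 31, 25, 27, 31, 30)
    jpn2 <- c(39, 37, 18, 22, 46)
    expect_equal(round(lineageMeanUnique(jpn1), 1), 29.0)
    expect_equal(round(lineageMeanUnique(jpn2), 1), 32.4)
    expect_equal(lineageMeanUnique(17), 17)
    expect_error(lineageMeanUnique(numeric()), "empty")
})
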