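test_that("generateReference is deterministic and honours geometry", {
    cfg <- smallTestConfig(seed = 5L)
    g1 <- generateReference(cfg)
    g2 <- generateReference(cfg)
    expect_identical(as.character(contigs(g1)), as.character(contigs(g2)))
    expect_identical(geneModels(g1), geneModels(g2))
    expect_equal(length(geneModels(g1)), 12L)
    expect_equal(genomeLength(g1), 12000)

    g3 <- generateReference(smallTestConfig(seed = 6L))
    expect_false(identical(as.character(contigs(g1)),
                           as.character(contigs(g3))))

    empty <- generateReference(smallTestConfig(seed = 5L, nGenes = 0L))
    expect_equal(length(geneModels(empty)), 0L)
})

test_that("every generated gene starts with ATG, ends with a stop, no internal stop", {
    cfg <- smallTestConfig(seed = 8L, nGenes = 30L, contigLength = 20000L,
                           nContigs = 3L)
    genome <- generateReference(cfg)
    plain <- oraclePlain(genome)
    for (id in names(geneModels(genome))) {
        prot <- oracleTranslateGene(genome, id, plain)
        expect_match(prot, "^M")
        expect_match(prot, "\\*$")
        expect_false(grepl("\\*.", prot))
    }
})

test_that("generated GC content tracks the configured fraction", {
    cfg <- smallTestConfig(seed = 9L, nGenes = 0L, contigLength = 50000L,
                           nContigs = 1L, gcContent = 0.6)
    genome <- generateReference(cfg)
    gc <- sum(Biostrings::letterFrequency(contigs(genome), c("G", "C"))) /
        genomeLength(genome)
    expect_lt(abs(gc - 0.6), 0.02)
})

test_that("zero generations yield zero calls", {
    cfg <- smallTestConfig(seed = 4L, generations = c(L1 = 0, L2 = 0))
    genome <- generateReference(cfg)
    sims <- simulateLineages(cfg, genome)
    expect_true(all(vapply(sims, function(cs)
        length(variantCalls(cs)) == 0L, TRUE)))
})

test_that("simulateLineages is deterministic under the config seed", {
    cfg <- smallTestConfig(seed = 15L)
    genome <- generateReference(cfg)
    s1 <- suppressMessages(simulateLineages(cfg, genome))
    s2 <- suppressMessages(simulateLineages(cfg, genome))
    expect_identical(lapply(s1, callsTable), lapply(s2, callsTable))
})

test_that("with omega=1 and pHom=0 all calls are het and totals match the Poisson mean", {
    cfg <- smallTestConfig(seed = 31L, omega = c(L1 = 1, L2 = 1), pHom = 0,
                           genotypes = c(L1 = 10L, L2 = 10L),
                           generations = c(L1 = 1000, L2 = 1000),
                           mu = 5e-6, tSpread = 0)
    genome <- generateReference(cfg)
    sims <- suppressMessages(simulateLineages(cfg, genome))
    lam <- 5e-6 * genomeLength(genome) * 1000       # expected candidates
    for (cs in sims) {
        tab <- callsTable(cs)
        expect_true(all(tab$zygosity == "het"))
        # overwrites at duplicate sites only ever reduce the count by a
        # handful; 3 Poisson standard deviations around the mean
        expect_lt(abs(nrow(tab) - lam), 3 * sqrt(lam) + 3)
        expect_equal(callableSites(cs), genomeLength(genome))
    }
})

test_that("omega=0-like selection removes nonsynonymous calls", {
    # omega must be > 0 by contract; 1e-12 is an effective zero
    cfg <- smallTestConfig(seed = 32L, omega = c(L1 = 1e-12, L2 = 1e-12))
    genome <- generateReference(cfg)
    sims <- suppressMessages(simulateLineages(cfg, genome))
    for (cs in sims) {
        tab <- callsTable(cs)
        if (!nrow(tab)) next
        cls <- classifyChange(genome, tab$contig, tab$pos, tab$alt)
        expect_false(any(cls == "nonsynonymous"))
    }
})

test_that("lowering omega thins nonsynonymous calls and leaves the rest untouched", {
    # identical seeds couple the candidate stream and the retention
    # uniforms, so the low-omega call set must be nested in the high-omega
    # one, with the synonymous and non-coding calls identical
    genome <- generateReference(smallTestConfig(seed = 41L))
    key <- function(tab) paste(tab$contig, tab$pos, tab$alt)
    tabs <- lapply(c(1, 0.5, 0.1), function(om) {
        cfg <- smallTestConfig(seed = 41L, omega = c(L1 = om, L2 = om))
        sims <- suppressMessages(simulateLineages(cfg, genome))
        lapply(sims, callsTable)
    })
    for (g in seq_along(tabs[[1L]])) {
        cls <- lapply(tabs, function(tt) {
            tab <- tt[[g]]
            cbind(tab, class = classifyChange(genome, tab$contig, tab$pos,
                                              tab$alt))
        })
        for (lo in 2:3) {
            expect_true(all(key(cls[[lo]]) %in% key(cls[[1L]])))
            nonNon <- function(tab) sort(key(tab[tab$class != "nonsynonymous", ]))
            expect_identical(nonNon(cls[[lo]]), nonNon(cls[[1L]]))
        }
        expect_lte(sum(cls[[3L]]$class == "nonsynonymous"),
                   sum(cls[[2L]]$class == "nonsynonymous"))
    }
})

test_that("with omega=1 the N:S call ratio matches the opportunity ratio", {
    cfg <- smallTestConfig(seed = 51L, omega = c(L1 = 1, L2 = 1),
                           genotypes = c(L1 = 12L, L2 = 12L),
                           generations = c(L1 = 2000, L2 = 2000),
                           mu = 5e-6, tSpread = 0)
    genome <- generateReference(cfg)
    opp <- siteOpportunities(genome)
    sims <- suppressMessages(simulateLineages(cfg, genome))
    counts <- countSN(genome, sims)
    N <- sum(counts$N); S <- sum(counts$S)
    ratioObs <- N / S
    ratioOpp <- opp[["nonsynonymous"]] / opp[["synonymous"]]
    # binomial Monte-Carlo tolerance on ~ (N+S) coding calls
    se <- ratioOpp * sqrt(1 / N + 1 / S)
    expect_lt(abs(ratioObs - ratioOpp), 4 * se)
})

test_that("mean pairwise divergence is ~ 2 mu_eff L t under the star topology", {
    cfg <- smallTestConfig(seed = 61L, omega = c(L1 = 1, L2 = 1),
                           genotypes = c(L1 = 8L, L2 = 8L),
                           generations = c(L1 = 1500, L2 = 1500),
                           mu = 4e-6, tSpread = 0)
    genome <- generateReference(cfg)
    sims <- suppressMessages(simulateLineages(cfg, genome))
    pm <- pairwiseMatrix(genome, sims[grep("^L1", names(sims))])
    tot <- pm$dnC + pm$dS + pm$dN
    expected <- 2 * 4e-6 * genomeLength(genome) * 1500
    # a shared site mutated in both genotypes can cancel; rare at this
    # divergence. 4 sd of the per-pair Poisson total around the mean.
    expect_lt(abs(mean(tot) - expected),
              4 * sqrt(2 * expected / nrow(pm)) + 0.01 * expected)
})

test_that("transition bias shifts the mutation spectrum", {
    cfg <- smallTestConfig(seed = 71L, kappa = 8, nGenes = 0L,
                           genotypes = c(L1 = 6L, L2 = 6L),
                           generations = c(L1 = 2000, L2 = 2000), mu = 5e-6)
    genome <- generateReference(cfg)
    sims <- suppressMessages(simulateLineages(cfg, genome))
    isTs <- function(r, a) paste0(r, a) %in% c("AG", "GA", "CT", "TC")
    tab <- do.call(rbind, lapply(sims, callsTable))
    fracTs <- mean(isTs(tab$ref, tab$alt))
    expect_gt(fracTs, 0.7)             # kappa 8 -> E[ts] = 0.8
    expect_lt(fracTs, 0.9)
})

test_that("simulated bundles round-trip through the file formats", {
    cfg <- smallTestConfig(seed = 81L)
    dir <- withr::local_tempdir()
    sim <- suppressMessages(writeSimulatedData(cfg, dir))
    seqs <- readFasta(sim$paths$fasta)
    expect_identical(as.character(seqs), as.character(contigs(sim$genome)))
    gl <- readGff3Genes(sim$paths$gff3, seqs)
    expect_setequal(names(gl), names(geneModels(sim$genome)))
    tab <- readLineageTable(sim$paths$lineages)
    expect_equal(nrow(tab), 6L)
    cs <- suppressMessages(readVcfCalls(file.path(dir, tab$vcf_path[1L]),
                                        tab$callable_sites[1L]))
    orig <- callsTable(sim$callsets[[tab$genotype_id[1L]]])
    orig <- orig[order(orig$contig, orig$pos), ]
    expect_equal(callsTable(cs)$pos, orig$pos)
})
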