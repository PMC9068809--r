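#' Read or write a simulation/pipeline config as YAML
#'
#' The YAML mirrors the [SimulationConfig()] arguments; named vectors
#' (\code{genotypes}, \code{generations}, \code{omega}) are YAML mappings
#' keyed by lineage id.
#'
#' @param path YAML file.
#' @return \code{readSimulationConfig}: a [SimulationConfig-class].
#' @export
readSimulationConfig <- function(path) {
    y <- yaml::read_yaml(path)
    args <- list()
    for (nm in c("seed", "nContigs", "contigLength", "nGenes", "geneLength",
                 "mu", "tSpread", "pHom", "kappa", "gcContent"))
        if (!is.null(y[[nm]])) args[[nm]] <- y[[nm]]
    for (nm in c("genotypes", "generations", "omega"))
        if (!is.null(y[[nm]])) args[[nm]] <- unlist(y[[nm]])
    do.call(SimulationConfig, args)
}

#' @rdname readSimulationConfig
#' @param config a [SimulationConfig-class].
#' @return \code{writeSimulationConfig}: \code{path}, invisibly.
#' @export
writeSimulationConfig <- function(config, path) {
    y <- list(seed = config@seed, nContigs = config@nContigs,
              contigLength = config@contigLength, nGenes = config@nGenes,
              geneLength = config@geneLength,
              genotypes = as.list(config@genotypes),
              mu = config@mu, generations = as.list(config@generations),
              tSpread = config@tSpread, omega = as.list(config@omega),
              pHom = config@pHom, kappa = config@kappa,
              gcContent = config@gcContent)
    yaml::write_yaml(y, path)
    invisible(path)
}

#' Validate a genome + variant-call input bundle
#'
#' Cross-checks a FASTA reference, GFF3 gene models and a lineage table
#' with its VCFs: contig names of GFF3 and VCF records must occur in the
#' FASTA, VCF files must exist, genotype ids must be unique. Problems are
#' collected, not thrown.
#'
#' @param fasta,gff3,lineageTable file paths (\code{gff3} may be
#'   \code{NULL}).
#' @return data.frame with columns \code{level} ("error") and
#'   \code{message}; zero rows when the bundle is clean.
#' @export
validateInputs <- function(fasta, gff3 = NULL, lineageTable = NULL) {
    probs <- character()
    ctgs <- NULL
    if (!file.exists(fasta)) {
        probs <- c(probs, paste0("FASTA not found: ", fasta))
    } else {
        ctgs <- tryCatch(names(readFasta(fasta)), error = function(e) {
            probs <<- c(probs, conditionMessage(e)); NULL })
    }
    if (!is.null(gff3)) {
        if (!file.exists(gff3)) {
            probs <- c(probs, paste0("GFF3 not found: ", gff3))
        } else if (!is.null(ctgs)) {
            gl <- tryCatch(suppressWarnings(readGff3Genes(gff3)),
                           error = function(e) {
                probs <<- c(probs, conditionMessage(e)); NULL })
            if (!is.null(gl) && length(gl)) {
                gffCtg <- unique(unlist(lapply(gl, function(g)
                    as.character(seqnames(g)))))
                miss <- setdiff(gffCtg, ctgs)
                if (length(miss))
                    probs <- c(probs, paste0("GFF3 contig absent from FASTA: ",
                                             paste(miss, collapse = ", ")))
            }
        }
    }
    if (!is.null(lineageTable)) {
        tab <- tryCatch(readLineageTable(lineageTable), error = function(e) {
            probs <<- c(probs, conditionMessage(e)); NULL })
        if (!is.null(tab)) {
            base <- dirname(lineageTable)
            for (i in seq_len(nrow(tab))) {
                vp <- tab$vcf_path[i]
                if (!file.exists(vp)) vp <- file.path(base, vp)
                if (!file.exists(vp)) {
                    probs <- c(probs, paste0("VCF not found: ",
                                             tab$vcf_path[i]))
                    next
                }
                vctg <- tryCatch({
                    cs <- suppressMessages(readVcfCalls(
                        vp, callableSites = tab$callable_sites[i]))
                    unique(as.character(seqnames(variantCalls(cs))))
                }, error = function(e) {
                    probs <<- c(probs, paste0(tab$vcf_path[i], ": ",
                                              conditionMessage(e)))
                    NULL })
                if (!is.null(vctg) && !is.null(ctgs)) {
                    miss <- setdiff(vctg, ctgs)
                    if (length(miss))
                        probs <- c(probs, paste0(
                            "VCF ", tab$genotype_id[i],
                            " contig absent from FASTA: ",
                            paste(miss, collapse = ", ")))
                }
            }
        }
    }
    data.frame(level = rep("error", length(probs)), message = probs,
               stringsAsFactors = FALSE)
}

writeTsv <- function(df, path, comment = NULL) {
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(comment)) writeLines(paste0("# ", comment), con)
    utils::write.table(format(df, trim = TRUE, digits = 10), con,
                       sep = "\t", quote = FALSE, row.names = FALSE)
    path
}

stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop("stage '", name, "' failed: ", conditionMessage(e),
             call. = FALSE))
}

#' Run the full analysis pipeline on a simulated dataset
#'
#' Orchestrates simulate, count, pairwise comparison, inference and dating
#' on the configured synthetic study, writing the complete output bundle
#' to \code{outDir}:
#' \itemize{
#'   \item the simulated inputs (FASTA, GFF3, VCFs, lineage TSV);
#'   \item \code{genotype_counts.tsv}: per-genotype S, N, N/S and N_sub,
#'     plus between-lineage Mann-Whitney (Bonferroni family of 3) and the
#'     t-test on N_sub in \code{group_tests.tsv};
#'   \item \code{pairwise.tsv}: within-lineage pairwise dnC/dS/dN with
#'     zygosity decompositions;
#'   \item \code{inference.tsv}: the slope contrasts (dS~dnC, dN~dnC,
#'     dN~dS, dS_hom~dS_het, dN_hom~dN_het) and the dN_hom location test
#'     between the first two lineages;
#'   \item \code{unique_genes.tsv}: per-genotype unique-nonsynonymous-gene
#'     counts and lineage means;
#'   \item \code{ages.tsv}: per-lineage mean pairwise rates and ages under
#'     \code{ageModel};
#'   \item \code{summary.txt} and a deterministic \code{manifest.json}
#'     (config, seed, version, file digests, row and filter-drop counts).
#' }
#' With fewer than two lineages the inference stage is skipped with a
#' logged reason. Any stage failure aborts with a stage-named error.
#'
#' @param config a [SimulationConfig-class].
#' @param outDir output directory.
#' @param nRand randomization replicates for the inference stage.
#' @param ageModel [AgeModel-class] used for dating the simulated
#'   lineages; the default uses the simulation's own mu and 5
#'   generations/year with the divisor 2 appropriate for pairwise
#'   divergence accruing on two branches.
#' @return invisibly, a list with all result tables and the manifest.
#' @export
runAll <- function(config, outDir, nRand = 1999, ageModel = NULL) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    if (is.null(ageModel))
        ageModel <- AgeModel(mu = config@mu, gensPerYear = 5,
                             branchDivisor = 2)

    sim <- stage("simulate",
                 suppressMessages(writeSimulatedData(config, outDir)))
    genome <- sim$genome

    # read the written VCFs back so the manifest records real filter drops
    tab <- stage("load", {
        lt <- readLineageTable(sim$paths$lineages)
        lt$n_input <- NA_integer_
        lt
    })
    callsets <- stage("load", lapply(seq_len(nrow(tab)), function(i) {
        vp <- tab$vcf_path[i]
        if (!file.exists(vp)) vp <- file.path(outDir, vp)
        suppressMessages(readVcfCalls(vp,
                                      callableSites = tab$callable_sites[i],
                                      genotypeId = tab$genotype_id[i],
                                      lineageId = tab$lineage_id[i]))
    }))
    names(callsets) <- tab$genotype_id
    nInput <- vapply(seq_len(nrow(tab)), function(i)
        length(variantCalls(sim$callsets[[tab$genotype_id[i]]])), 0L)
    nRetained <- vapply(callsets, function(cs) length(variantCalls(cs)), 0L)

    counts <- stage("count", countSN(genome, callsets))
    writeTsv(counts, file.path(outDir, "genotype_counts.tsv"),
             "per-genotype counts: S/N substitutions vs reference, N_sub per site")

    lineages <- unique(tab$lineage_id)
    pw <- stage("pairwise", do.call(rbind, lapply(lineages, function(l) {
        cs <- callsets[tab$genotype_id[tab$lineage_id == l]]
        if (length(cs) < 2L) return(NULL)
        pairwiseMatrix(genome, cs)
    })))
    if (is.null(pw)) stop("stage 'pairwise' failed: no lineage has >= 2 genotypes")
    writeTsv(pw, file.path(outDir, "pairwise.tsv"),
             "within-lineage pairwise substitution counts (sites)")

    groupTests <- NULL
    inference <- NULL
    skipReason <- NULL
    if (length(lineages) < 2L) {
        skipReason <- "inference skipped: fewer than 2 lineages"
        message(skipReason)
    } else {
        la <- lineages[1L]; lb <- lineages[2L]
        groupTests <- stage("infer", {
            rows <- lapply(c("S", "N", "ratio"), function(v) {
                mw <- mannWhitneyU(counts[[v]][counts$lineage_id == la],
                                   counts[[v]][counts$lineage_id == lb],
                                   nComparisons = 3)
                data.frame(test = "mann_whitney_u", variable = v,
                           statistic = mw$U, p_raw = mw$pRaw,
                           p_adjusted = mw$pBonferroni)
            })
            tt <- twoSampleT(counts$n_sub[counts$lineage_id == la],
                             counts$n_sub[counts$lineage_id == lb])
            rbind(do.call(rbind, rows),
                  data.frame(test = "t_test", variable = "n_sub",
                             statistic = tt$t, p_raw = tt$p,
                             p_adjusted = tt$p))
        })
        writeTsv(groupTests, file.path(outDir, "group_tests.tsv"),
                 paste0("between-lineage tests (", la, " vs ", lb, ")"))

        inference <- stage("infer", {
            pa <- pw[pw$lineage_id == la, ]
            pb <- pw[pw$lineage_id == lb, ]
            contrasts <- list(c("dnC", "dS"), c("dnC", "dN"), c("dS", "dN"),
                              c("dS_het", "dS_hom"), c("dN_het", "dN_hom"))
            rows <- lapply(seq_along(contrasts), function(i) {
                xf <- contrasts[[i]][1L]; yf <- contrasts[[i]][2L]
                rt <- randomizationSlopeTest(pa, pb, xf, yf, nRand = nRand,
                                             seed = config@seed + 1000L + i)
                data.frame(contrast = paste0(yf, "~", xf),
                           statistic = "slope",
                           slope_a = rt$fitA$slope,
                           ci95_a = rt$fitA$ci95Halfwidth,
                           p_slope_a = rt$fitA$pSlope,
                           slope_b = rt$fitB$slope,
                           ci95_b = rt$fitB$ci95Halfwidth,
                           p_slope_b = rt$fitB$pSlope,
                           observed_diff = rt$observedDiff, p_mc = rt$pMC,
                           significant = rt$significant)
            })
            # when neither lineage's dN_hom ~ dN_het regression is itself
            # significant, compare dN_hom locations ignoring dN_het
            last <- rows[[length(contrasts)]]
            loc <- randomizationLocationTest(
                pa$dN_hom, pb$dN_hom, nRand = nRand,
                seed = config@seed + 1999L)
            rows[[length(rows) + 1L]] <- data.frame(
                contrast = "dN_hom location", statistic = "mean",
                slope_a = loc$meanA, ci95_a = NA, p_slope_a = NA,
                slope_b = loc$meanB, ci95_b = NA, p_slope_b = NA,
                observed_diff = loc$observedDiff, p_mc = loc$pMC,
                significant = loc$significant)
            df <- do.call(rbind, rows)
            df$location_test_indicated <-
                c(rep(NA, length(contrasts)),
                  last$p_slope_a > 0.05 && last$p_slope_b > 0.05)
            df
        })
        writeTsv(inference, file.path(outDir, "inference.tsv"),
                 paste0("slope/location randomization tests, ", la, " vs ",
                        lb, ", nRand=", nRand))
    }

    uniq <- stage("unique_genes", do.call(rbind, lapply(lineages, function(l) {
        cs <- callsets[tab$genotype_id[tab$lineage_id == l]]
        if (length(cs) < 2L) return(NULL)
        uniqueNonsynGenes(genome, cs)
    })))
    means <- vapply(split(uniq$n_genes, uniq$lineage_id), mean, 0)
    uniq$lineage_mean <- means[uniq$lineage_id]
    writeTsv(uniq, file.path(outDir, "unique_genes.tsv"),
             "genes with genotype-specific nonsynonymous substitutions")

    ages <- stage("age", do.call(rbind, lapply(lineages, function(l) {
        p <- pw[pw$lineage_id == l, ]
        if (!nrow(p)) return(NULL)
        mr <- meanPairwiseRate(p)
        cbind(data.frame(lineage_id = l, mean_rate = mr$mean,
                         sd_rate = mr$sd, n_pairs = mr$n),
              lineageAgeYears(mr$mean, ageModel)[, c("years",
                                                     "years_rounded")])
    })))
    writeTsv(ages, file.path(outDir, "ages.tsv"),
             paste0("lineage ages; mu=", ageModel@mu, ", gens/year=",
                    ageModel@gensPerYear, ", branch divisor=",
                    ageModel@branchDivisor))

    summaryPath <- file.path(outDir, "summary.txt")
    stage("summary", {
        lines <- c("ClonalSubs pipeline summary",
                   sprintf("seed: %d; genotypes: %d; lineages: %s",
                           config@seed, nrow(tab),
                           paste(lineages, collapse = ", ")))
        if (!is.null(inference)) {
            lines <- c(lines, "", "slope contrasts (A vs B):")
            for (i in seq_len(nrow(inference)))
                lines <- c(lines, sprintf(
                    "  %-16s A=%.4g B=%.4g diff=%.4g p_mc=%.4g %s",
                    inference$contrast[i], inference$slope_a[i],
                    inference$slope_b[i], inference$observed_diff[i],
                    inference$p_mc[i],
                    ifelse(inference$significant[i], "SIGNIFICANT", "ns")))
        } else {
            lines <- c(lines, skipReason)
        }
        lines <- c(lines, "", "unique nonsynonymous genes (lineage means):",
                   sprintf("  %s: %.1f", names(means), means))
        writeLines(lines, summaryPath)
    })

    outputs <- c("genotype_counts.tsv", "pairwise.tsv", "unique_genes.tsv",
                 "ages.tsv", "summary.txt",
                 if (!is.null(inference)) c("inference.tsv",
                                            "group_tests.tsv"))
    manifest <- list(
        tool = "ClonalSubs",
        version = as.character(utils::packageVersion("ClonalSubs")),
        seed = config@seed,
        n_rand = nRand,
        config = yaml::yaml.load(yaml::as.yaml(list(
            seed = config@seed, nContigs = config@nContigs,
            contigLength = config@contigLength, nGenes = config@nGenes,
            geneLength = config@geneLength,
            genotypes = as.list(config@genotypes), mu = config@mu,
            generations = as.list(config@generations),
            tSpread = config@tSpread, omega = as.list(config@omega),
            pHom = config@pHom, kappa = config@kappa,
            gcContent = config@gcContent))),
        inputs = as.list(tools::md5sum(c(sim$paths$fasta, sim$paths$gff3,
                                         unname(sim$paths$vcfs)))),
        vcf_records = stats::setNames(as.list(as.integer(nInput)),
                                      tab$genotype_id),
        filter_drops = stats::setNames(as.list(as.integer(nInput -
                                                          nRetained)),
                                       tab$genotype_id),
        rows = stats::setNames(
            as.list(c(nrow(counts), nrow(pw), nrow(uniq), nrow(ages))),
            c("genotype_counts.tsv", "pairwise.tsv", "unique_genes.tsv",
              "ages.tsv")),
        outputs = outputs,
        skipped = if (is.null(skipReason)) list() else list(skipReason))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)

    invisible(list(genome = genome, callsets = callsets, counts = counts,
                   pairwise = pw, groupTests = groupTests,
                   inference = inference, uniqueGenes = uniq, ages = ages,
                   manifest = manifest))
}
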