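## End-to-end orchestration over plain-text artifacts. Each stage reads its
## inputs from files in `outdir` (written by upstream stages or supplied by
## the user), never mutates another stage's outputs, and the whole run is
## byte-deterministic for a fixed config + seed. A manifest records the
## seed, configuration digest, input hashes and package version.

pipelineStages <- c("simulate", "digest", "call", "annotate", "diff",
                    "enrich", "integrate", "cluster")

stageInputs <- list(
    simulate = character(),
    digest = "genome.fa",
    call = character(),          # checked dynamically: methylome TSVs
    annotate = c("islands.bed", "genes.refflat", "shared_sites.tsv"),
    diff = c("samples.tsv"),
    enrich = c("dmc_subtypeH.tsv", "dmc_subtypeL.tsv", "repeats.bed",
               "shared_sites.tsv"),
    integrate = c("dmc_subtypeH.tsv", "dmc_subtypeL.tsv",
                  "cpg_annotation.tsv", "islands.bed", "genes.refflat"),
    cluster = c("samples.tsv"))

writeTsv <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

readCohortTables <- function(outdir) {
    samp <- utils::read.table(file.path(outdir, "samples.tsv"), header = TRUE,
                              sep = "\t", stringsAsFactors = FALSE)
    tabs <- lapply(samp$sample, function(id)
        readMethylationCalls(file.path(outdir, paste0("meth_", id, ".tsv")),
                             "coverage", sampleId = id))
    names(tabs) <- samp$sample
    list(samples = samp, tables = tabs)
}

sharedFromFile <- function(outdir) {
    df <- utils::read.table(file.path(outdir, "shared_sites.tsv"),
                            header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$pos, width = 1L))
}

bundleFromFiles <- function(outdir, analysis) {
    islands <- readIntervals(file.path(outdir, "islands.bed"))
    genes <- readGeneModels(file.path(outdir, "genes.refflat"))
    repPath <- file.path(outdir, "repeats.bed")
    repeats <- if (file.exists(repPath)) readIntervals(repPath)
               else GenomicRanges::GRanges()
    if (length(repeats) && "name" %in%
            colnames(S4Vectors::mcols(repeats)))
        S4Vectors::mcols(repeats)$family <- S4Vectors::mcols(repeats)$name
    lenPath <- file.path(outdir, "chrom_lengths.tsv")
    if (file.exists(lenPath)) {
        ldf <- utils::read.table(lenPath, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
        lens <- stats::setNames(ldf$length, ldf$chrom)
    } else {
        hi <- max(BiocGenerics::end(islands))
        chroms <- unique(c(
            as.character(GenomeInfoDb::seqnames(islands)),
            as.character(GenomeInfoDb::seqnames(genes@transcripts))))
        lens <- stats::setNames(rep(hi + 10000000L, length(chroms)), chroms)
    }
    buildAnnotationBundle(islands, genes, repeats, lens,
                          promoterHalfwidth = analysis@promoterHalfwidth,
                          shoreWidth = analysis@shoreWidth)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order over plain-text
#' artifacts in `outdir`:
#' \describe{
#'   \item{simulate}{genome FASTA, island/repeat BED, refFlat gene models,
#'     chromosome lengths, planted truth, per-sample coverage-dialect
#'     methylomes, per-condition expression tables, a samples table.}
#'   \item{digest}{MspI fragment BED and the RRBS/ERRBS window coverage
#'     comparison.}
#'   \item{call}{coverage-filters every sample and writes the shared site
#'     universe.}
#'   \item{annotate}{per-CpG annotation of the shared sites.}
#'   \item{diff}{per-CpG tests for subtype H and subtype L against normals,
#'     DMC calls, per-chromosome summaries, and the overlap summary.}
#'   \item{enrich}{repeat enrichment per comparison.}
#'   \item{integrate}{high/low expression contrasts and DMC/fold-change
#'     correlations.}
#'   \item{cluster}{sample correlation matrix and Ward dendrogram (Newick).}
#' }
#' A stage whose required input files are absent fails with an error naming
#' them before any computation. Identical config and seed give byte-identical
#' outputs; `manifest.txt` records the run.
#'
#' @param outdir output directory (created if needed).
#' @param stages character subset of stages, or `"all"`.
#' @param simConfig a [SimulationConfig-class] (simulate stage).
#' @param analysis an [AnalysisConfig-class].
#' @param seed integer seed; overrides `simConfig@seed` when given.
#' @param plantArgs list of extra arguments for
#'   [plantDifferentialArchitecture()] (simulate stage), e.g. smaller planted
#'   architectures for reduced-scale runs.
#' @return invisibly, the manifest path.
#' @export
runPipeline <- function(outdir, stages = "all",
                        simConfig = simulationConfig(),
                        analysis = analysisConfig(), seed = NULL,
                        plantArgs = list()) {
    if (identical(stages, "all")) stages <- pipelineStages
    unknown <- setdiff(stages, pipelineStages)
    if (length(unknown))
        stop("unknown stage(s): ", paste(unknown, collapse = ", "),
             "; valid: ", paste(pipelineStages, collapse = ", "))
    stages <- pipelineStages[pipelineStages %in% stages]
    if (!is.null(seed)) simConfig@seed <- as.integer(seed)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    ## validate inputs for all requested stages before any computation
    for (st in stages) {
        need <- stageInputs[[st]]
        if (st != "simulate" && "simulate" %in% stages) next
        missing <- need[!file.exists(file.path(outdir, need))]
        if (length(missing))
            stop("stage '", st, "' requires missing input file(s): ",
                 paste(missing, collapse = ", "))
    }
    t0 <- Sys.time()
    logStage <- function(st) message(sprintf("[%s] stage %s (%.1fs elapsed)",
        format(Sys.time(), "%H:%M:%S"), st,
        as.numeric(difftime(Sys.time(), t0, units = "secs"))))

    for (st in stages) {
        logStage(st)
        switch(st,
        simulate = {
            sg <- generateGenome(simConfig)
            truth <- do.call(plantDifferentialArchitecture,
                             c(list(sg), plantArgs))
            Biostrings::writeXStringSet(sg@genome,
                file.path(outdir, "genome.fa"))
            writeIntervals(sg@islands, file.path(outdir, "islands.bed"))
            reps <- sg@repeats
            S4Vectors::mcols(reps)$name <- S4Vectors::mcols(reps)$family
            writeIntervals(reps, file.path(outdir, "repeats.bed"))
            writeGeneModels(sg@genes, file.path(outdir, "genes.refflat"))
            writeTsv(data.frame(chrom = names(sg@genome),
                                length = BiocGenerics::width(sg@genome)),
                     file.path(outdir, "chrom_lengths.tsv"))
            writeTsv(truth@planted, file.path(outdir, "truth_planted.tsv"))
            tabs <- simulateCohort(truth, simConfig)
            for (id in names(tabs))
                writeMethylationCalls(tabs[[id]],
                    file.path(outdir, paste0("meth_", id, ".tsv")))
            writeTsv(data.frame(sample = names(tabs),
                condition = sub("_[0-9]+$", "", names(tabs))),
                file.path(outdir, "samples.tsv"))
            for (cond in c("normal", "subtypeH", "subtypeL")) {
                ex <- simulateExpression(truth, cond, simConfig,
                    seed = simConfig@seed + match(cond,
                        c("normal", "subtypeH", "subtypeL")))
                writeExpression(ex,
                    file.path(outdir, paste0("expression_", cond, ".tsv")))
            }
        },
        digest = {
            genome <- Biostrings::readDNAStringSet(
                file.path(outdir, "genome.fa"))
            names(genome) <- sub(" .*", "", names(genome))
            frags <- digestGenome(genome)
            writeIntervals(frags, file.path(outdir, "fragments.bed"))
            if (file.exists(file.path(outdir, "islands.bed")) &&
                file.exists(file.path(outdir, "genes.refflat"))) {
                bundle <- bundleFromFiles(outdir, analysis)
                cmp <- compareCoverageWindows(frags, bundle, genome,
                    windows = list(rrbs = analysis@rrbsWindow,
                                   errbs = analysis@errbsWindow))
                rows <- do.call(rbind, lapply(names(cmp), function(w)
                    cbind(window = w, nCpG = cmp[[w]]$nCpG,
                          cmp[[w]]$features)))
                writeTsv(rows, file.path(outdir, "digest_coverage.tsv"))
            }
        },
        call = {
            co <- readCohortTables(outdir)
            univ <- sharedSites(co$tables, analysis@minCoverage)
            writeTsv(data.frame(
                chrom = as.character(GenomeInfoDb::seqnames(univ)),
                pos = BiocGenerics::start(univ)),
                file.path(outdir, "shared_sites.tsv"))
        },
        annotate = {
            bundle <- bundleFromFiles(outdir, analysis)
            univ <- sharedFromFile(outdir)
            writeTsv(annotateCpGs(univ, bundle),
                     file.path(outdir, "cpg_annotation.tsv"))
        },
        diff = {
            co <- readCohortTables(outdir)
            ctrl <- co$samples$sample[co$samples$condition == "NBM"]
            for (sub in c("subtypeH", "subtypeL")) {
                test <- co$samples$sample[co$samples$condition == sub]
                res <- diffMethTest(co$tables, sampleSet(test, ctrl),
                                    analysis@minCoverage)
                res <- callDmcs(res, analysis@qvalueCutoff,
                                analysis@diffCutoff)
                writeTsv(res, file.path(outdir,
                                        paste0("dmc_", sub, ".tsv")))
                writeTsv(dmcSummaryByChrom(res),
                    file.path(outdir, paste0("dmc_", sub, "_by_chrom.tsv")))
            }
            a <- utils::read.table(file.path(outdir, "dmc_subtypeH.tsv"),
                header = TRUE, sep = "\t", stringsAsFactors = FALSE)
            b <- utils::read.table(file.path(outdir, "dmc_subtypeL.tsv"),
                header = TRUE, sep = "\t", stringsAsFactors = FALSE)
            ov <- compareDmcSets(a, b, union(a$key, b$key))
            writeTsv(data.frame(metric = names(ov),
                                value = unlist(ov)),
                     file.path(outdir, "dmc_overlap.tsv"))
        },
        enrich = {
            bundle <- bundleFromFiles(outdir, analysis)
            univ <- sharedFromFile(outdir)
            out <- list()
            for (sub in c("subtypeH", "subtypeL")) {
                d <- utils::read.table(file.path(outdir,
                    paste0("dmc_", sub, ".tsv")), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
                re <- repeatEnrichment(d, univ, bundle@repeats)
                out[[sub]] <- cbind(comparison = sub, re)
            }
            writeTsv(do.call(rbind, out),
                     file.path(outdir, "repeat_enrichment.tsv"))
        },
        integrate = {
            bundle <- bundleFromFiles(outdir, analysis)
            ann <- utils::read.table(file.path(outdir, "cpg_annotation.tsv"),
                header = TRUE, sep = "\t", stringsAsFactors = FALSE)
            exN <- readExpression(file.path(outdir, "expression_normal.tsv"))
            rows <- list(); cors <- list()
            for (sub in c("subtypeH", "subtypeL")) {
                cond <- sub
                ex <- readExpression(file.path(outdir,
                    paste0("expression_", cond, ".tsv")))
                d <- utils::read.table(file.path(outdir,
                    paste0("dmc_", sub, ".tsv")), header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
                dm <- merge(d[d$status != "ns", ], ann, by = c("chrom", "pos"))
                fc <- expressionFoldChange(ex, exN)
                for (str in c("core_promoter", "upstream")) {
                    res <- tryCatch(
                        dmcFoldchangeCorrelation(dm, fc, str,
                            upstreamWindow = analysis@tssWindowExpr,
                            islandTssWindow = analysis@islandTssWindow),
                        error = function(e) NULL)
                    if (!is.null(res))
                        cors[[paste(sub, str)]] <- data.frame(
                            comparison = sub, stratum = str, r = res$r,
                            p = res$p, n = res$n)
                }
            }
            if (length(cors))
                writeTsv(do.call(rbind, cors),
                         file.path(outdir, "dmc_expression_correlation.tsv"))
            ## high-vs-low methylation contrast on the subtype H sample set
            co <- readCohortTables(outdir)
            tabH <- co$tables[[co$samples$sample[
                co$samples$condition == "subtypeH"][1L]]]
            tabH <- filterCoverage(tabH, analysis@minCoverage)
            exH <- readExpression(file.path(outdir, "expression_subtypeH.tsv"))
            grps <- expressionGroups(exH, analysis@exprPercentile)
            cats <- mapRegionsToTss(bundle@islands, bundle@genes,
                                    analysis@tssWindowExpr)
            vals <- regionMethylation(tabH, bundle@islands, "max",
                                      analysis@minCpgsPerRegion)
            ctr <- methylationExpressionContrast(vals, cats, grps)
            writeTsv(ctr, file.path(outdir, "expression_contrast.tsv"))
        },
        cluster = {
            co <- readCohortTables(outdir)
            univ <- sharedSites(co$tables, analysis@minCoverage)
            cl <- sampleClustering(pctMethMatrix(co$tables, univ))
            utils::write.table(round(cl$correlation, 6),
                file.path(outdir, "sample_correlation.tsv"), sep = "\t",
                quote = FALSE)
            writeLines(hclustToNewick(cl$hclust),
                       file.path(outdir, "dendrogram.nwk"))
        })
    }
    manifest <- c(
        paste0("package: errbs ", as.character(utils::packageVersion("errbs"))),
        paste0("seed: ", simConfig@seed),
        paste0("stages: ", paste(stages, collapse = ",")),
        paste0("config_digest: ", configDigest(simConfig, analysis)),
        "input_hashes:",
        {
            fs <- sort(setdiff(list.files(outdir), "manifest.txt"))
            paste0("  ", fs, ": ",
                   unname(tools::md5sum(file.path(outdir, fs))))
        })
    writeLines(manifest, file.path(outdir, "manifest.txt"))
    invisible(file.path(outdir, "manifest.txt"))
}

configDigest <- function(simConfig, analysis) {
    txt <- paste(c(vapply(slotNames(simConfig), function(s)
            paste(s, paste(methods::slot(simConfig, s), collapse = ","),
                  sep = "="), character(1)),
        vapply(slotNames(analysis), function(s)
            paste(s, paste(methods::slot(analysis, s), collapse = ","),
                  sep = "="), character(1))), collapse = ";")
    f <- tempfile(); on.exit(unlink(f))
    writeLines(txt, f)
    unname(tools::md5sum(f))
}

## Newick serialisation of an hclust dendrogram (branch lengths = merge
## heights), avoiding a tree-package dependency for one writer.
hclustToNewick <- function(hc) {
    lab <- hc$labels
    node <- function(i, parentH) {
        if (i < 0) return(sprintf("%s:%g", lab[-i], parentH))
        h <- hc$height[i]
        sprintf("(%s,%s):%g", node(hc$merge[i, 1L], h),
                node(hc$merge[i, 2L], h), parentH - h)
    }
    n <- nrow(hc$merge)
    h <- hc$height[n]
    paste0("(", node(hc$merge[n, 1L], h), ",", node(hc$merge[n, 2L], h), ");")
}
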