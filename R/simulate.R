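## Synthetic methylome generator. Emulates the study design the analysis
## assumes: a bimodal methylome (CpG islands low, background high),
## beta-binomial sampling noise at ~50x negative-binomial coverage, two tumor
## subtypes with opposed planted differential architectures (subtype H:
## promoter/island hypermethylation; subtype L: shore/intron/distal
## hypomethylation with distal-island hypermethylation), a shared
## mostly-hypermethylated core, and expression coupled to planted promoter
## methylation. Every generator is deterministic under a fixed seed.

## Sequence segments are assembled from tokens so CpG and MspI-site (CCGG)
## densities are controlled exactly: "CG" and "CCGG" tokens at the target
## rates, fillers chosen so no CG or CCGG can arise across token boundaries
## (fillers neither start with G nor end with C, and contain no CG).
.fillerTokens <- c("AA", "AG", "AT", "CA", "CT", "TA", "TG", "TT")

randSegment <- function(len, cpgDensity, mspDensity) {
    if (len <= 0) return("")
    m <- mspDensity
    q <- max(0, cpgDensity * (2 + 2 * m) - m)
    nTok <- ceiling(len / 2) + 8L
    tok <- sample(c("CG", "CCGG", .fillerTokens), nTok, replace = TRUE,
                  prob = c(q, m, rep((1 - q - m) / 8, 8)))
    substr(paste0(tok, collapse = ""), 1L, len)
}

#' Generate a synthetic genome with islands, genes and repeats
#'
#' Chromosomes are laid out as background sequence interrupted by CpG
#' islands (elevated CpG and MspI-site density) at evenly spaced slots with
#' random offsets. A fraction of genes have their TSS anchored at an island
#' midpoint (promoter CpG islands); the rest start at background positions.
#' Each transcript has three exons and two derived introns. Repeats are
#' interval annotations (Alu, L1, Simple, Low_complexity) covering about
#' `repeatFraction` of the genome.
#'
#' @param config a [SimulationConfig-class]; the seed is mandatory and the
#'   output is byte-deterministic given it.
#' @return A [SyntheticGenome-class].
#' @export
generateGenome <- function(config) {
    stopifnot(is(config, "SimulationConfig"))
    cfg <- config
    set.seed(cfg@seed)
    nIsl <- cfg@nIslandsPerChrom
    len <- cfg@chromLength
    chromNames <- paste0("chr", seq_len(cfg@nChroms))
    seqs <- character(cfg@nChroms)
    islands <- list()
    for (ci in seq_len(cfg@nChroms)) {
        if (nIsl == 0L) {
            seqs[ci] <- randSegment(len, cfg@backgroundCpGDensity,
                                    cfg@backgroundMspDensity)
            islands[[ci]] <- GenomicRanges::GRanges(
                seqnames = factor(character(), levels = chromNames),
                ranges = IRanges::IRanges())
            next
        }
        islLen <- pmax(300L, as.integer(round(stats::rnorm(nIsl,
            cfg@islandLengthMean, cfg@islandLengthMean / 5))))
        if (sum(islLen) >= len)
            stop("configured island total length exceeds chromosome length")
        slot <- len %/% nIsl
        margin <- 8000L
        if (any(islLen + 2L * margin > slot))
            stop("islands too long for the configured chromosome layout")
        off <- vapply(islLen, function(l)
            as.integer(floor(stats::runif(1, margin, slot - margin - l))),
            integer(1))
        islStart <- (seq_len(nIsl) - 1L) * slot + off + 1L
        parts <- character(2L * nIsl + 1L)
        cursor <- 1L
        for (i in seq_len(nIsl)) {
            parts[2L * i - 1L] <- randSegment(islStart[i] - cursor,
                cfg@backgroundCpGDensity, cfg@backgroundMspDensity)
            parts[2L * i] <- randSegment(islLen[i],
                cfg@islandCpGDensity, cfg@islandMspDensity)
            cursor <- islStart[i] + islLen[i]
        }
        parts[2L * nIsl + 1L] <- randSegment(len - cursor + 1L,
            cfg@backgroundCpGDensity, cfg@backgroundMspDensity)
        seqs[ci] <- paste0(parts, collapse = "")
        islands[[ci]] <- GenomicRanges::GRanges(
            factor(chromNames[ci], levels = chromNames),
            IRanges::IRanges(islStart, islStart + islLen - 1L))
    }
    genome <- Biostrings::DNAStringSet(stats::setNames(seqs, chromNames))
    islands <- do.call(c, islands)
    ## genes: a fraction anchored at island midpoints, the rest at background
    nGenes <- cfg@nGenes
    nAnchored <- round(cfg@promoterIslandFrac * nGenes)
    if (nAnchored > length(islands))
        stop("promoterIslandFrac requires ", nAnchored,
             " islands but only ", length(islands), " were generated")
    anchorIdx <- sort(sample(length(islands), nAnchored))
    anchorChr <- as.character(GenomeInfoDb::seqnames(islands))[anchorIdx]
    anchorTss <- as.integer((BiocGenerics::start(islands)[anchorIdx] +
                             BiocGenerics::end(islands)[anchorIdx]) %/% 2L)
    nFree <- nGenes - nAnchored
    freeChr <- sample(chromNames, nFree, replace = TRUE)
    freeTss <- as.integer(floor(stats::runif(nFree, 30000, len - 30000)))
    chr <- c(anchorChr, freeChr)
    tss <- c(anchorTss, freeTss)
    strand <- sample(c("+", "-"), nGenes, replace = TRUE)
    txLen <- as.integer(floor(stats::runif(nGenes, 6000, 20000)))
    txStart <- ifelse(strand == "+", tss, tss - txLen + 1L)
    txEnd <- ifelse(strand == "+", tss + txLen - 1L, tss)
    ord <- order(chr, txStart)
    txId <- sprintf("tx%04d", seq_len(nGenes))
    gene <- sprintf("gene%04d", seq_len(nGenes))
    mid <- (txStart + txEnd) %/% 2L
    exonStarts <- lapply(seq_len(nGenes), function(i)
        c(txStart[i], mid[i] - 100L, txEnd[i] - 499L))
    exonEnds <- lapply(seq_len(nGenes), function(i)
        c(txStart[i] + 299L, mid[i] + 99L, txEnd[i]))
    genes <- geneModelSet(txId[ord], gene[ord], chr[ord], strand[ord],
                          txStart[ord], txEnd[ord],
                          exonStarts[ord], exonEnds[ord])
    ## repeats: interval annotation tracks (sequence left untouched)
    reps <- list()
    for (ci in seq_len(cfg@nChroms)) {
        target <- cfg@repeatFraction * len
        repLen <- as.integer(100L + round(stats::rexp(
            ceiling(target / 300) + 50L, 1 / 250)))
        covBp <- cumsum(repLen)
        repLen <- repLen[covBp <= target]
        repStart <- as.integer(floor(stats::runif(length(repLen), 1,
                                                  len - max(repLen))))
        reps[[ci]] <- GenomicRanges::GRanges(
            factor(chromNames[ci], levels = chromNames),
            IRanges::IRanges(repStart, repStart + repLen - 1L),
            family = sample(c("Alu", "L1", "Simple", "Low_complexity"),
                            length(repLen), replace = TRUE,
                            prob = c(0.45, 0.2, 0.2, 0.15)))
    }
    repeats <- do.call(c, reps)
    repeats <- repeats[order(as.character(GenomeInfoDb::seqnames(repeats)),
                             BiocGenerics::start(repeats))]
    new("SyntheticGenome", genome = genome, islands = islands,
        repeats = repeats, genes = genes, cpgSites = cpgPositions(genome),
        config = cfg)
}

#' Plant the two opposed differential methylation architectures
#'
#' Subtype H receives `hyperFracH` of its sites as hypermethylation at
#' promoter-island CpGs (the remainder hypomethylated at background CpGs);
#' subtype L receives `hypoFracL` as hypomethylation at shore/intron/distal
#' background CpGs (the remainder hypermethylated at distal, non-promoter
#' island CpGs, where the low baseline leaves room for gain). A shared core
#' of `nCore` sites, `hyperFracCore` hypermethylated at promoter islands, is
#' planted in both subtypes. Per-site baselines (island low, background
#' high, with fixed beta-distributed spread) are drawn here so every sample
#' of every condition shares them. Direction fractions are exact by
#' construction.
#'
#' @param sg a [SyntheticGenome-class].
#' @param nH,hyperFracH,nL,hypoFracL,nCore,hyperFracCore architecture sizes
#'   and direction fractions.
#' @param effectSize planted shift in percentage points (applied on the
#'   pooled percent scale, symmetric across strands; clamped to `[0, 100]`).
#' @param overlapFraction fraction of subtype-L sites drawn from subtype-H's
#'   planted sites (default 0: disjoint beyond the shared core).
#' @return A [SyntheticTruth-class].
#' @export
plantDifferentialArchitecture <- function(sg, nH = 2000L, hyperFracH = 0.90,
        nL = 3000L, hypoFracL = 0.72, nCore = 500L, hyperFracCore = 0.79,
        effectSize = 40, overlapFraction = 0) {
    stopifnot(is(sg, "SyntheticGenome"))
    cfg <- sg@config
    set.seed(cfg@seed + 1L)
    bundle <- buildAnnotationBundle(sg@islands, sg@genes, sg@repeats,
        stats::setNames(BiocGenerics::width(sg@genome), names(sg@genome)))
    cpgs <- sg@cpgSites
    n <- length(cpgs)
    inIsland <- IRanges::overlapsAny(cpgs, bundle@islands, ignore.strand = TRUE)
    inProm <- IRanges::overlapsAny(cpgs, bundle@promoters, ignore.strand = TRUE)
    inShore <- IRanges::overlapsAny(cpgs, bundle@shores, ignore.strand = TRUE)
    inIntron <- IRanges::overlapsAny(cpgs, bundle@introns, ignore.strand = TRUE)
    regionClass <- ifelse(inIsland & inProm, "promoter-island",
        ifelse(!inIsland & inShore, "shore",
        ifelse(!inIsland & inIntron, "intron", "distal")))
    ## baselines: island low, background high, with fixed per-site spread
    mu0 <- ifelse(inIsland, cfg@islandBaseline, cfg@backgroundBaseline) / 100
    prec <- cfg@siteBaselinePrecision
    baseline <- 100 * stats::rbeta(n, mu0 * prec, (1 - mu0) * prec)
    promIslandPool <- which(inIsland & inProm)
    distalIslandPool <- which(inIsland & !inProm)
    bgPool <- which(!inIsland & !inProm)
    take <- function(pool, k, what) {
        if (length(pool) < k)
            stop("requested ", k, " planted ", what, " sites but only ",
                 length(pool), " eligible CpGs")
        sample(pool, k)
    }
    nHhyper <- round(nH * hyperFracH)
    nChyper <- round(nCore * hyperFracCore)
    hHyper <- take(promIslandPool, nHhyper, "promoter-island hyper")
    cHyper <- take(setdiff(promIslandPool, hHyper), nChyper, "core hyper")
    nLhypo <- round(nL * hypoFracL)
    hHypo <- take(bgPool, nH - nHhyper, "background hypo")
    lHypo <- take(setdiff(bgPool, hHypo), nLhypo, "background hypo")
    cHypo <- take(setdiff(bgPool, c(hHypo, lHypo)), nCore - nChyper,
                  "core hypo")
    lHyper <- take(distalIslandPool, nL - nLhypo, "distal-island hyper")
    if (overlapFraction > 0) {
        k <- round(overlapFraction * nL)
        swap <- sample(c(hHyper, hHypo), min(k, nH))
        lHyper <- c(lHyper, intersect(swap, hHyper))
        lHypo <- c(lHypo, intersect(swap, hHypo))
    }
    effectH <- effectL <- numeric(n)
    effectH[hHyper] <- effectSize; effectH[hHypo] <- -effectSize
    effectL[lHyper] <- effectSize; effectL[lHypo] <- -effectSize
    effectH[cHyper] <- effectL[cHyper] <- effectSize
    effectH[cHypo] <- effectL[cHypo] <- -effectSize
    S4Vectors::mcols(cpgs)$baseline <- baseline
    S4Vectors::mcols(cpgs)$effectH <- effectH
    S4Vectors::mcols(cpgs)$effectL <- effectL
    mkRows <- function(idx, subtype, direction) {
        if (!length(idx)) return(NULL)
        data.frame(chrom = as.character(GenomeInfoDb::seqnames(cpgs))[idx],
                   pos = BiocGenerics::start(cpgs)[idx], subtype = subtype,
                   direction = direction,
                   effect = ifelse(direction == "hyper", effectSize,
                                   -effectSize),
                   regionClass = regionClass[idx], stringsAsFactors = FALSE)
    }
    planted <- rbind(mkRows(hHyper, "H", "hyper"), mkRows(hHypo, "H", "hypo"),
                     mkRows(lHyper, "L", "hyper"), mkRows(lHypo, "L", "hypo"),
                     mkRows(cHyper, "core", "hyper"),
                     mkRows(cHypo, "core", "hypo"))
    if (is.null(planted))
        planted <- data.frame(chrom = character(), pos = integer(),
                              subtype = character(), direction = character(),
                              effect = numeric(), regionClass = character(),
                              stringsAsFactors = FALSE)
    new("SyntheticTruth", cpgs = cpgs, planted = planted, bundle = bundle)
}

betaBinomPct <- function(mu, prec) {
    ## mu in [0, 1]; degenerate shapes give deterministic 0/1
    a <- mu * prec; b <- (1 - mu) * prec
    p <- stats::rbeta(length(mu), pmax(a, 1e-9), pmax(b, 1e-9))
    p[a <= 0] <- 0
    p[b <= 0] <- 1
    p
}

#' Simulate one sample's methylome
#'
#' Per CpG, coverage is negative-binomial (mean `coverageMean`), split
#' evenly between strands; the per-sample methylation level is beta
#' distributed around the site mean (baseline, shifted by the planted effect
#' for tumor conditions and clamped to `[0, 100]`); bisulfite conversion
#' failure adds spurious methylation at rate `conversionFailure` percent.
#' Counts are binomial per strand and merged. Sites drawing zero coverage
#' are absent from the table; low-coverage sites are retained so the
#' coverage filter has work to do.
#'
#' @param truth a [SyntheticTruth-class].
#' @param condition `"normal"`, `"subtypeH"` or `"subtypeL"`.
#' @param sampleId sample name.
#' @param config the [SimulationConfig-class] used for the genome.
#' @param seed per-sample seed.
#' @param perStrand also return the stranded table (reverse-strand G rows at
#'   pos + 1) for QC.
#' @return A [MethylomeTable-class]; with `perStrand`, a list with `table`
#'   and `stranded`.
#' @export
simulateMethylome <- function(truth, condition = c("normal", "subtypeH",
        "subtypeL"), sampleId, config, seed, perStrand = FALSE) {
    condition <- match.arg(condition)
    set.seed(seed)
    cpgs <- truth@cpgs
    mc <- S4Vectors::mcols(cpgs)
    eff <- switch(condition, normal = 0, subtypeH = mc$effectH,
                  subtypeL = mc$effectL)
    mu <- pmin(100, pmax(0, mc$baseline + eff)) / 100
    n <- length(cpgs)
    cov <- stats::rnbinom(n, size = config@coverageSize, mu = config@coverageMean)
    covF <- stats::rbinom(n, cov, 0.5)
    covR <- cov - covF
    p <- betaBinomPct(mu, config@bbPrecision)
    pObs <- p + (1 - p) * config@conversionFailure / 100
    mF <- stats::rbinom(n, covF, pObs)
    mR <- stats::rbinom(n, covR, pObs)
    keep <- cov > 0L
    tab <- MethylomeTable(as.character(GenomeInfoDb::seqnames(cpgs))[keep],
                          BiocGenerics::start(cpgs)[keep],
                          (mF + mR)[keep], (cov - mF - mR)[keep], sampleId)
    if (!perStrand) return(tab)
    chrom <- as.character(GenomeInfoDb::seqnames(cpgs))
    pos <- BiocGenerics::start(cpgs)
    fwd <- data.frame(chrom = chrom[covF > 0], pos = pos[covF > 0],
        strand = "+", countM = mF[covF > 0],
        countU = (covF - mF)[covF > 0], context = "CpG",
        stringsAsFactors = FALSE)
    rev <- data.frame(chrom = chrom[covR > 0], pos = pos[covR > 0] + 1L,
        strand = "-", countM = mR[covR > 0],
        countU = (covR - mR)[covR > 0], context = "CpG",
        stringsAsFactors = FALSE)
    list(table = tab, stranded = rbind(fwd, rev))
}

#' Simulate non-CpG cytosine counts for conversion-rate QC
#'
#' Non-CpG cytosines are unmethylated; only conversion failure leaves them
#' read as C.
#'
#' @param nSites number of non-CpG cytosines.
#' @param config a [SimulationConfig-class].
#' @param seed seed.
#' @return named counts (`unconverted`, `converted`) as consumed by
#'   [estimateConversionRate()].
#' @export
simulateNonCpGCounts <- function(nSites, config, seed) {
    set.seed(seed)
    cov <- stats::rnbinom(nSites, size = config@coverageSize,
                          mu = config@coverageMean)
    m <- stats::rbinom(nSites, cov, config@conversionFailure / 100)
    c(unconverted = sum(m), converted = sum(cov - m))
}

#' Simulate a read stack over selected CpG sites
#'
#' One row per read base, with phred scores: a `lowQualFrac` fraction drawn
#' below 20, the rest at 20-40. Used to exercise the quality filter of the
#' calling stage.
#'
#' @param truth a [SyntheticTruth-class].
#' @param condition condition name as in [simulateMethylome()].
#' @param siteIdx indices into `truth@cpgs`.
#' @param config a [SimulationConfig-class].
#' @param seed seed.
#' @param lowQualFrac fraction of read bases with phred < 20.
#' @return data.frame `chrom, pos, strand, base, phred, context`.
#' @export
simulateReadStack <- function(truth, condition, siteIdx, config, seed,
                              lowQualFrac = 0.1) {
    set.seed(seed)
    cpgs <- truth@cpgs[siteIdx]
    mc <- S4Vectors::mcols(cpgs)
    eff <- switch(condition, normal = 0, subtypeH = mc$effectH,
                  subtypeL = mc$effectL)
    mu <- pmin(100, pmax(0, mc$baseline + eff)) / 100
    n <- length(cpgs)
    cov <- pmax(1L, stats::rnbinom(n, size = config@coverageSize,
                                   mu = config@coverageMean))
    p <- betaBinomPct(mu, config@bbPrecision)
    rows <- rep(seq_len(n), cov)
    total <- sum(cov)
    strand <- sample(c("+", "-"), total, replace = TRUE)
    base <- ifelse(stats::runif(total) < p[rows], "C", "T")
    phred <- ifelse(stats::runif(total) < lowQualFrac,
                    sample(2:19, total, replace = TRUE),
                    sample(20:40, total, replace = TRUE))
    data.frame(chrom = as.character(GenomeInfoDb::seqnames(cpgs))[rows],
               pos = BiocGenerics::start(cpgs)[rows] +
                     ifelse(strand == "-", 1L, 0L),
               strand = strand, base = base, phred = phred, context = "CpG",
               stringsAsFactors = FALSE)
}

#' Simulate a per-transcript expression table for one condition
#'
#' Each gene has a fixed log2 baseline shared across conditions (drawn from
#' the genome seed); genes whose promoter-island CpGs carry a planted
#' hypermethylation effect in the condition have their log2 mean lowered by
#' `couplingShift` (hypomethylated promoters stay high — promoter
#' methylation represses). Per-condition noise is drawn from `seed`.
#'
#' @param truth a [SyntheticTruth-class].
#' @param condition `"normal"`, `"subtypeH"` or `"subtypeL"`.
#' @param config a [SimulationConfig-class].
#' @param seed per-condition seed.
#' @param baselineLog2,sdLog2,noiseSd expression scale parameters.
#' @param couplingShift log2 downshift for promoter-hypermethylated genes
#'   (0 decouples expression from methylation).
#' @return data.frame `transcript`, `value` (linear array-scale units).
#' @export
simulateExpression <- function(truth, condition, config, seed,
        baselineLog2 = 8, sdLog2 = 1, noiseSd = 0.25, couplingShift = 2) {
    bundle <- truth@bundle
    tx <- bundle@genes@transcripts
    txId <- S4Vectors::mcols(tx)$txId
    if (any(is.na(S4Vectors::mcols(tx)$tss))) {
        warning("transcript(s) without TSS skipped")
        tx <- tx[!is.na(S4Vectors::mcols(tx)$tss)]
        txId <- S4Vectors::mcols(tx)$txId
    }
    set.seed(config@seed + 7L)
    geneBase <- stats::rnorm(length(tx), baselineLog2, sdLog2)
    eff <- switch(condition, normal = numeric(length(truth@cpgs)),
                  subtypeH = S4Vectors::mcols(truth@cpgs)$effectH,
                  subtypeL = S4Vectors::mcols(truth@cpgs)$effectL)
    hyperCpgs <- truth@cpgs[eff > 0]
    promIsl <- GenomicRanges::intersect(bundle@promoters, bundle@islands,
                                        ignore.strand = TRUE)
    hyperCpgs <- hyperCpgs[IRanges::overlapsAny(hyperCpgs, promIsl,
                                                ignore.strand = TRUE)]
    prom <- bundle@promoters[match(txId, S4Vectors::mcols(bundle@promoters)$txId)]
    affected <- IRanges::overlapsAny(prom, hyperCpgs, ignore.strand = TRUE)
    set.seed(seed)
    logv <- geneBase - couplingShift * affected +
        stats::rnorm(length(tx), 0, noiseSd)
    data.frame(transcript = txId, value = 2^logv, stringsAsFactors = FALSE)
}

#' Simulate a full cohort of methylomes
#'
#' `nPerGroup` replicates per condition (normal, subtype H, subtype L) with
#' per-sample seeds derived from `seedBase`.
#'
#' @param truth a [SyntheticTruth-class].
#' @param config a [SimulationConfig-class].
#' @param nPerGroup replicates per condition (default 2).
#' @param seedBase base seed for per-sample seed derivation.
#' @return named list of [MethylomeTable-class] objects
#'   (`NBM_i`, `subtypeH_i`, `subtypeL_i`).
#' @export
simulateCohort <- function(truth, config, nPerGroup = 2L,
                           seedBase = config@seed) {
    conds <- c(NBM = "normal", subtypeH = "subtypeH", subtypeL = "subtypeL")
    out <- list()
    k <- 0L
    for (g in names(conds)) for (i in seq_len(nPerGroup)) {
        k <- k + 1L
        id <- paste0(g, "_", i)
        out[[id]] <- simulateMethylome(truth, conds[[g]], id, config,
                                       seed = seedBase + 100L + k)
    }
    out
}
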