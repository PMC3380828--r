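#' @import methods
#' @importFrom stats setNames
NULL

## Central S4 containers. Interval-valued objects (islands, shores, peaks,
## repeats, fragments) are plain GRanges; the classes below add the semantics
## GRanges alone cannot carry (per-sample counts, group structure, analysis
## parameters, derived annotation layers, simulation ground truth).

#' MethylomeTable: per-sample CpG methylation calls
#'
#' One sample's strand-merged CpG methylation calls. Sites are width-1
#' [GenomicRanges::GRanges] anchored at the forward-strand C of each CpG
#' dinucleotide, carrying integer metadata columns `countM` (methylated reads)
#' and `countU` (unmethylated reads). Sites are unique and sorted by
#' chromosome then position.
#'
#' @slot sites GRanges with mcols `countM`, `countU`.
#' @slot sampleId single character sample identifier.
#' @export
setClass("MethylomeTable",
    representation(sites = "GRanges", sampleId = "character"))

setValidity("MethylomeTable", function(object) {
    s <- object@sites
    mc <- S4Vectors::mcols(s)
    if (!all(c("countM", "countU") %in% colnames(mc)))
        return("sites must carry mcols 'countM' and 'countU'")
    if (length(object@sampleId) != 1L || is.na(object@sampleId))
        return("sampleId must be a single non-NA string")
    if (length(s)) {
        if (any(mc$countM < 0) || any(mc$countU < 0))
            return("counts must be non-negative")
        if (any(BiocGenerics::width(s) != 1L))
            return("sites must be width-1 (the forward-strand C position)")
        if (is.unsorted(order(as.character(GenomeInfoDb::seqnames(s)),
                              BiocGenerics::start(s))) ||
            anyDuplicated(paste(GenomeInfoDb::seqnames(s),
                                BiocGenerics::start(s))))
            return("sites must be sorted and unique by (chrom, pos)")
    }
    TRUE
})

#' Construct a MethylomeTable
#'
#' @param chrom character chromosome names.
#' @param pos integer 1-based positions of the forward-strand C of each CpG.
#' @param countM,countU non-negative integer methylated / unmethylated read
#'   counts.
#' @param sampleId sample identifier.
#' @return A [MethylomeTable-class] object, sorted and de-duplicated
#'   (duplicate (chrom, pos) keys are an error).
#' @examples
#' mt <- MethylomeTable("chr1", c(101L, 250L), c(15L, 2L), c(5L, 18L), "s1")
#' pctMeth(mt)
#' @export
MethylomeTable <- function(chrom, pos, countM, countU, sampleId = "sample") {
    if (anyDuplicated(paste(chrom, pos)))
        stop("duplicate (chrom, pos) keys in methylation calls")
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos, width = 1L),
        countM = as.integer(countM), countU = as.integer(countU))
    gr <- gr[order(as.character(GenomeInfoDb::seqnames(gr)),
                   BiocGenerics::start(gr))]
    new("MethylomeTable", sites = gr, sampleId = as.character(sampleId))
}

#' SampleSet: test/control group assignment
#'
#' @slot test,control non-empty, disjoint character vectors of sample ids.
#' @export
setClass("SampleSet", representation(test = "character", control = "character"))

setValidity("SampleSet", function(object) {
    if (!length(object@test) || !length(object@control))
        return("each group needs at least one sample")
    if (length(intersect(object@test, object@control)))
        return("test and control groups must be disjoint")
    TRUE
})

#' @rdname SampleSet-class
#' @param test,control character vectors of sample ids.
#' @export
sampleSet <- function(test, control) new("SampleSet", test = test, control = control)

#' AnalysisConfig: analysis-wide thresholds
#'
#' Defaults follow the ERRBS study design: calls require 10x coverage and
#' phred >= 20 base quality; differential CpGs require q < 0.01 and a pooled
#' methylation difference of at least 25 percentage points (10 and 40 as
#' robustness cutoffs); shores are 2 kb island flanks; promoters are 2 kb
#' windows centered on the TSS; peaks are extended 500 bp per side;
#' expression integration uses 10 kb TSS windows (5 kb for island/shore
#' strata), a (-300, +300) bp core promoter, and top/bottom 15 percent
#' expression groups; region summaries require >= 3 covered CpGs; fragment
#' windows are 40-220 bp (RRBS) and 70-320 bp (ERRBS).
#'
#' @export
setClass("AnalysisConfig", representation(
    minCoverage = "integer", minBasequal = "integer",
    qvalueCutoff = "numeric", diffCutoff = "numeric",
    shoreWidth = "integer", promoterHalfwidth = "integer",
    peakFlank = "integer", tssWindowExpr = "integer",
    islandTssWindow = "integer", corePromoter = "integer",
    exprPercentile = "numeric", minCpgsPerRegion = "integer",
    rrbsWindow = "integer", errbsWindow = "integer",
    randomSeed = "integer"))

setValidity("AnalysisConfig", function(object) {
    pos <- c(object@minCoverage, object@minBasequal, object@shoreWidth,
             object@promoterHalfwidth, object@tssWindowExpr,
             object@islandTssWindow, object@minCpgsPerRegion)
    if (any(pos <= 0)) return("all thresholds must be strictly positive")
    if (object@diffCutoff <= 0 || object@diffCutoff > 100)
        return("diffCutoff must be in (0, 100]")
    if (object@qvalueCutoff <= 0 || object@qvalueCutoff > 1)
        return("qvalueCutoff must be in (0, 1]")
    TRUE
})

#' @rdname AnalysisConfig-class
#' @param minCoverage,minBasequal,qvalueCutoff,diffCutoff,shoreWidth
#'   analysis thresholds; see class description.
#' @param promoterHalfwidth,peakFlank,tssWindowExpr,islandTssWindow
#'   window sizes in bp.
#' @param corePromoter length-2 integer, bp around the TSS.
#' @param exprPercentile,minCpgsPerRegion,rrbsWindow,errbsWindow,randomSeed
#'   further thresholds; see class description.
#' @export
analysisConfig <- function(minCoverage = 10L, minBasequal = 20L,
        qvalueCutoff = 0.01, diffCutoff = 25, shoreWidth = 2000L,
        promoterHalfwidth = 1000L, peakFlank = 500L, tssWindowExpr = 10000L,
        islandTssWindow = 5000L, corePromoter = c(-300L, 300L),
        exprPercentile = 15, minCpgsPerRegion = 3L,
        rrbsWindow = c(40L, 220L), errbsWindow = c(70L, 320L),
        randomSeed = 1L) {
    new("AnalysisConfig", minCoverage = as.integer(minCoverage),
        minBasequal = as.integer(minBasequal), qvalueCutoff = qvalueCutoff,
        diffCutoff = diffCutoff, shoreWidth = as.integer(shoreWidth),
        promoterHalfwidth = as.integer(promoterHalfwidth),
        peakFlank = as.integer(peakFlank),
        tssWindowExpr = as.integer(tssWindowExpr),
        islandTssWindow = as.integer(islandTssWindow),
        corePromoter = as.integer(corePromoter),
        exprPercentile = exprPercentile,
        minCpgsPerRegion = as.integer(minCpgsPerRegion),
        rrbsWindow = as.integer(rrbsWindow),
        errbsWindow = as.integer(errbsWindow),
        randomSeed = as.integer(randomSeed))
}

#' GeneModelSet: transcript models with derived TSS and introns
#'
#' @slot transcripts width-spanning GRanges (one per transcript) with mcols
#'   `txId`, `gene`, `tss` (1-based TSS position: leftmost base for `+`
#'   transcripts, rightmost for `-`).
#' @slot exons,introns GRangesList keyed by transcript id; introns are the
#'   gaps between consecutive exons.
#' @export
setClass("GeneModelSet", representation(
    transcripts = "GRanges", exons = "GRangesList", introns = "GRangesList"))

setValidity("GeneModelSet", function(object) {
    mc <- S4Vectors::mcols(object@transcripts)
    if (!all(c("txId", "gene", "tss") %in% colnames(mc)))
        return("transcripts must carry mcols txId, gene, tss")
    if (anyDuplicated(mc$txId)) return("transcript ids must be unique")
    TRUE
})

#' AnnotationBundle: genome annotation layers for CpG classification
#'
#' Holds the islands supplied by the user together with every derived layer:
#' clipped/merged 2 kb shores, promoter windows, exon/intron unions, the
#' intergenic complement, repeats, and gene models. Built with
#' [buildAnnotationBundle()].
#'
#' @slot islands,shores,promoters,exons,introns,intergenic,repeats GRanges.
#' @slot genes GeneModelSet.
#' @slot seqlengths named integer chromosome lengths.
#' @export
setClass("AnnotationBundle", representation(
    islands = "GRanges", shores = "GRanges", promoters = "GRanges",
    exons = "GRanges", introns = "GRanges", intergenic = "GRanges",
    repeats = "GRanges", genes = "GeneModelSet", seqlengths = "integer"))

#' SimulationConfig: synthetic methylome generator parameters
#'
#' Defaults emulate the ERRBS study conditions: bimodal methylation with CpG
#' islands low (5 percent) and background high (85 percent); negative-binomial
#' coverage with mean 50 (the study averaged ~53x per base); beta-binomial
#' sampling with precision 300 plus per-site baseline spread (precision 15),
#' which together put replicate-replicate Pearson correlation of percent
#' methylation near 0.94, matching the 0.92-0.96 replicate correlations the
#' assay reports; 0.2 percent bisulfite conversion failure (conversion rate
#' 99.8 percent).
#'
#' @export
setClass("SimulationConfig", representation(
    nChroms = "integer", chromLength = "integer",
    nIslandsPerChrom = "integer", islandLengthMean = "integer",
    islandCpGDensity = "numeric", backgroundCpGDensity = "numeric",
    islandMspDensity = "numeric", backgroundMspDensity = "numeric",
    nGenes = "integer", promoterIslandFrac = "numeric",
    repeatFraction = "numeric",
    islandBaseline = "numeric", backgroundBaseline = "numeric",
    bbPrecision = "numeric", siteBaselinePrecision = "numeric",
    coverageMean = "numeric", coverageSize = "numeric",
    conversionFailure = "numeric", seed = "integer"))

setValidity("SimulationConfig", function(object) {
    d <- c(object@islandCpGDensity, object@backgroundCpGDensity)
    if (any(d <= 0) || any(d >= 1)) return("CpG densities must be in (0,1)")
    if (object@islandCpGDensity <= object@backgroundCpGDensity)
        return("island CpG density must exceed background density")
    if (length(object@seed) != 1L || is.na(object@seed))
        return("seed is mandatory")
    if (object@conversionFailure < 0 || object@conversionFailure > 5)
        return("conversion failure rate must be within [0, 5] percent")
    TRUE
})

#' @rdname SimulationConfig-class
#' @param nChroms,chromLength,nIslandsPerChrom,islandLengthMean genome layout.
#' @param islandCpGDensity,backgroundCpGDensity CpG dinucleotides per bp.
#' @param islandMspDensity,backgroundMspDensity CCGG sites per token pair
#'   (controls MspI fragment sizes; islands are MspI-dense).
#' @param nGenes,promoterIslandFrac,repeatFraction gene/repeat layout.
#' @param islandBaseline,backgroundBaseline percent methylation baselines.
#' @param bbPrecision,siteBaselinePrecision beta precisions for sampling noise
#'   and for fixed per-site baseline spread.
#' @param coverageMean,coverageSize negative-binomial coverage parameters.
#' @param conversionFailure percent of unmethylated C read as C.
#' @param seed mandatory integer seed.
#' @export
simulationConfig <- function(nChroms = 2L, chromLength = 2500000L,
        nIslandsPerChrom = 60L, islandLengthMean = 800L,
        islandCpGDensity = 0.08, backgroundCpGDensity = 0.010,
        islandMspDensity = 0.02, backgroundMspDensity = 0.001,
        nGenes = 80L, promoterIslandFrac = 0.7, repeatFraction = 0.12,
        islandBaseline = 5, backgroundBaseline = 85,
        bbPrecision = 300, siteBaselinePrecision = 15,
        coverageMean = 50, coverageSize = 8,
        conversionFailure = 0.2, seed = 1L) {
    new("SimulationConfig", nChroms = as.integer(nChroms),
        chromLength = as.integer(chromLength),
        nIslandsPerChrom = as.integer(nIslandsPerChrom),
        islandLengthMean = as.integer(islandLengthMean),
        islandCpGDensity = islandCpGDensity,
        backgroundCpGDensity = backgroundCpGDensity,
        islandMspDensity = islandMspDensity,
        backgroundMspDensity = backgroundMspDensity,
        nGenes = as.integer(nGenes), promoterIslandFrac = promoterIslandFrac,
        repeatFraction = repeatFraction, islandBaseline = islandBaseline,
        backgroundBaseline = backgroundBaseline, bbPrecision = bbPrecision,
        siteBaselinePrecision = siteBaselinePrecision,
        coverageMean = coverageMean, coverageSize = coverageSize,
        conversionFailure = conversionFailure, seed = as.integer(seed))
}

#' SyntheticGenome: generated genome plus annotation inputs
#'
#' @slot genome DNAStringSet.
#' @slot islands,repeats GRanges annotation tracks.
#' @slot genes GeneModelSet.
#' @slot cpgSites width-1 GRanges of every CG dinucleotide (C position).
#' @slot config the SimulationConfig used.
#' @export
setClass("SyntheticGenome", representation(
    genome = "DNAStringSet", islands = "GRanges", repeats = "GRanges",
    genes = "GeneModelSet", cpgSites = "GRanges", config = "SimulationConfig"))

#' SyntheticTruth: planted differential methylation architecture
#'
#' @slot cpgs width-1 GRanges over every genomic CpG with mcols `baseline`
#'   (fixed per-site percent methylation in the normal state), and per-subtype
#'   planted effect columns `effectH`, `effectL` (signed percentage points; 0
#'   when unplanted).
#' @slot planted data.frame of planted sites: chrom, pos, subtype (H, L,
#'   core), direction (hyper/hypo), effect (percentage points), regionClass
#'   (promoter-island / shore / intron / distal).
#' @slot bundle the AnnotationBundle the architecture was planted against.
#' @export
setClass("SyntheticTruth", representation(
    cpgs = "GRanges", planted = "data.frame", bundle = "AnnotationBundle"))

setMethod("show", "MethylomeTable", function(object) {
    cat("MethylomeTable '", object@sampleId, "': ", length(object@sites),
        " CpG sites on ",
        length(unique(GenomeInfoDb::seqnames(object@sites))),
        " chromosome(s)\n", sep = "")
})

setMethod("show", "SampleSet", function(object) {
    cat("SampleSet: test = {", paste(object@test, collapse = ", "),
        "}, control = {", paste(object@control, collapse = ", "), "}\n")
})

setMethod("show", "AnnotationBundle", function(object) {
    cat("AnnotationBundle:",
        length(object@islands), "islands,",
        length(object@shores), "shores,",
        length(object@promoters), "promoters,",
        length(object@genes@transcripts), "transcripts,",
        length(object@repeats), "repeats\n")
})

setMethod("show", "SyntheticTruth", function(object) {
    cat("SyntheticTruth:", length(object@cpgs), "CpGs,",
        nrow(object@planted), "planted sites",
        "(", sum(object@planted$subtype == "H"), "H /",
        sum(object@planted$subtype == "L"), "L /",
        sum(object@planted$subtype == "core"), "core )\n")
})

## ---- accessors ----

#' @rdname MethylomeTable-class
#' @param object,x a MethylomeTable.
#' @export
setGeneric("sites", function(object) standardGeneric("sites"))
#' @rdname MethylomeTable-class
#' @export
setMethod("sites", "MethylomeTable", function(object) object@sites)

#' @rdname MethylomeTable-class
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))
#' @rdname MethylomeTable-class
#' @export
setMethod("sampleId", "MethylomeTable", function(object) object@sampleId)

#' @rdname MethylomeTable-class
#' @export
setGeneric("methCounts", function(object) standardGeneric("methCounts"))
#' @rdname MethylomeTable-class
#' @export
setMethod("methCounts", "MethylomeTable",
    function(object) S4Vectors::mcols(object@sites)$countM)

#' @rdname MethylomeTable-class
#' @export
setGeneric("unmethCounts", function(object) standardGeneric("unmethCounts"))
#' @rdname MethylomeTable-class
#' @export
setMethod("unmethCounts", "MethylomeTable",
    function(object) S4Vectors::mcols(object@sites)$countU)

#' Per-site read coverage and percent methylation
#'
#' `siteCoverage()` is `countM + countU`; `pctMeth()` is
#' `100 * countM / coverage` (NA at zero coverage).
#'
#' @param object a MethylomeTable.
#' @export
setGeneric("siteCoverage", function(object) standardGeneric("siteCoverage"))
#' @rdname siteCoverage
#' @export
setMethod("siteCoverage", "MethylomeTable",
    function(object) methCounts(object) + unmethCounts(object))

#' @rdname siteCoverage
#' @export
setGeneric("pctMeth", function(object) standardGeneric("pctMeth"))
#' @rdname siteCoverage
#' @export
setMethod("pctMeth", "MethylomeTable", function(object) {
    cov <- siteCoverage(object)
    ifelse(cov > 0, 100 * methCounts(object) / cov, NA_real_)
})

#' Number of CpG sites in a table
#' @param x a MethylomeTable.
#' @export
setMethod("length", "MethylomeTable", function(x) length(x@sites))

#' Character site keys ("chrom:pos", 1-based)
#' @param object a MethylomeTable or GRanges.
#' @export
setGeneric("siteKeys", function(object) standardGeneric("siteKeys"))
#' @rdname siteKeys
#' @export
setMethod("siteKeys", "MethylomeTable", function(object) siteKeys(object@sites))
#' @rdname siteKeys
#' @export
setMethod("siteKeys", "GRanges", function(object) {
    if (!length(object)) return(character())
    paste0(GenomeInfoDb::seqnames(object), ":", BiocGenerics::start(object))
})
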