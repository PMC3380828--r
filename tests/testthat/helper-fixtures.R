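## Shared fixtures, built lazily and cached for the session. The mini
## fixtures keep unit tests fast; the full-scale cohort (default
## SimulationConfig) is reserved for the acceptance suite.

.fixtures <- new.env(parent = emptyenv())

miniSimConfig <- function(seed = 42L)
    simulationConfig(nChroms = 1L, chromLength = 500000L,
                     nIslandsPerChrom = 16L, nGenes = 16L, seed = seed)

miniGenome <- function() {
    if (is.null(.fixtures$sg)) .fixtures$sg <- generateGenome(miniSimConfig())
    .fixtures$sg
}

miniTruth <- function() {
    if (is.null(.fixtures$truth))
        .fixtures$truth <- plantDifferentialArchitecture(miniGenome(),
            nH = 150L, nL = 200L, nCore = 40L)
    .fixtures$truth
}

miniCohort <- function() {
    if (is.null(.fixtures$cohort))
        .fixtures$cohort <- simulateCohort(miniTruth(), miniSimConfig())
    .fixtures$cohort
}

## Default-seed full-scale cohort for the acceptance properties (study
## conditions: 2 normal, 2 subtype H, 2 subtype L; ~50k shared CpGs).
acceptanceFixture <- function() {
    if (is.null(.fixtures$acc)) {
        cfg <- simulationConfig()
        sg <- generateGenome(cfg)
        truth <- plantDifferentialArchitecture(sg)
        tabs <- simulateCohort(truth, cfg)
        ctrl <- c("NBM_1", "NBM_2")
        resH <- callDmcs(diffMethTest(tabs,
            sampleSet(c("subtypeH_1", "subtypeH_2"), ctrl)))
        resL <- callDmcs(diffMethTest(tabs,
            sampleSet(c("subtypeL_1", "subtypeL_2"), ctrl)))
        .fixtures$acc <- list(cfg = cfg, sg = sg, truth = truth, tabs = tabs,
                              resH = resH, resL = resL)
    }
    .fixtures$acc
}

randomMethylomeTable <- function(n = 50L, sampleId = "s", seed = 1L) {
    set.seed(seed)
    pos <- sort(sample(seq_len(100000L), n))
    MethylomeTable(rep("chr1", n), pos, rpois(n, 8), rpois(n, 8), sampleId)
}

grI <- function(starts, ends, chrom = "chr1")
    GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends))
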