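## Stranded base observations -> filtered, strand-merged CpG calls.
## On a bisulfite-converted read a C signals methylation, a T a converted
## (unmethylated) cytosine; the forward-strand C and the reverse-strand G of
## one CpG dinucleotide are merged into a single call at the C position.

#' Tally stranded base observations into per-cytosine counts
#'
#' Consumes a read-stack table (one row per aligned read base over a
#' cytosine) and produces per-position stranded counts. Observations with
#' phred quality below `minBasequal` are discarded (the threshold itself is
#' retained: "at least"). `C` is counted as methylated, `T` as unmethylated;
#' any other base symbol is skipped and counted in `nSkipped`. Cytosines in
#' non-CpG context (CHG/CHH) are tallied separately for conversion-rate
#' estimation.
#'
#' @param observations data.frame with columns `chrom`, `pos` (1-based),
#'   `strand` (`+`/`-`), `base` (`C`/`T`), `phred`; optional `context`
#'   (default `"CpG"`).
#' @param minBasequal minimum phred score, inclusive.
#' @return list with `stranded` (data.frame `chrom, pos, strand, countM,
#'   countU` for CpG context), `nonCpG` (named counts `unconverted`
#'   (C) and `converted` (T)), and `nSkipped`.
#' @export
callSitesFromStack <- function(observations, minBasequal = 20) {
    obs <- observations
    if (is.null(obs$context)) obs$context <- "CpG"
    obs <- obs[obs$phred >= minBasequal, , drop = FALSE]
    known <- obs$base %in% c("C", "T")
    nSkipped <- sum(!known)
    obs <- obs[known, , drop = FALSE]
    cpg <- obs[obs$context == "CpG", , drop = FALSE]
    non <- obs[obs$context != "CpG", , drop = FALSE]
    if (nrow(cpg)) {
        key <- paste(cpg$chrom, cpg$pos, cpg$strand, sep = "\r")
        cm <- tapply(cpg$base == "C", key, sum)
        cu <- tapply(cpg$base == "T", key, sum)
        parts <- do.call(rbind, strsplit(names(cm), "\r", fixed = TRUE))
        stranded <- data.frame(chrom = parts[, 1L],
                               pos = as.integer(parts[, 2L]),
                               strand = parts[, 3L],
                               countM = as.integer(cm),
                               countU = as.integer(cu),
                               stringsAsFactors = FALSE)
        stranded <- stranded[order(stranded$chrom, stranded$pos,
                                   stranded$strand), , drop = FALSE]
        rownames(stranded) <- NULL
    } else {
        stranded <- data.frame(chrom = character(), pos = integer(),
                               strand = character(), countM = integer(),
                               countU = integer(), stringsAsFactors = FALSE)
    }
    nonCpG <- c(unconverted = sum(non$base == "C"),
                converted = sum(non$base == "T"))
    list(stranded = stranded, nonCpG = nonCpG, nSkipped = nSkipped)
}

#' Merge forward and reverse strand counts of a CpG dinucleotide
#'
#' The forward-strand C at position `p` and the reverse-strand G at `p + 1`
#' observe the same CpG; their read coverage is merged before testing, with
#' the site reported at the forward C position. Merging conserves counts.
#'
#' @param stranded data.frame with columns `chrom`, `pos` (1-based),
#'   `strand`, `countM`, `countU` (e.g. from [callSitesFromStack()] or a
#'   cytosine report).
#' @param sampleId sample identifier for the returned table.
#' @return A [MethylomeTable-class].
#' @export
mergeCpGStrands <- function(stranded, sampleId = "sample") {
    if (!nrow(stranded))
        return(MethylomeTable(character(), integer(), integer(), integer(),
                              sampleId))
    cpos <- ifelse(stranded$strand == "-", stranded$pos - 1L, stranded$pos)
    key <- paste(stranded$chrom, cpos, sep = "\r")
    cm <- tapply(stranded$countM, key, sum)
    cu <- tapply(stranded$countU, key, sum)
    parts <- do.call(rbind, strsplit(names(cm), "\r", fixed = TRUE))
    MethylomeTable(parts[, 1L], as.integer(parts[, 2L]),
                   as.integer(cm), as.integer(cu), sampleId)
}

#' Coverage-filter a methylome table
#'
#' Retains sites with `coverage >= minCoverage` (inclusive). Monotone:
#' raising the threshold never adds sites.
#'
#' @param table a [MethylomeTable-class].
#' @param minCoverage minimum read coverage, inclusive (default 10x).
#' @return The filtered [MethylomeTable-class].
#' @export
filterCoverage <- function(table, minCoverage = 10L) {
    stopifnot(is(table, "MethylomeTable"))
    keep <- siteCoverage(table) >= minCoverage
    new("MethylomeTable", sites = table@sites[keep], sampleId = table@sampleId)
}

#' Estimate the bisulfite conversion rate
#'
#' Non-CpG cytosines (CHG/CHH) are essentially unmethylated in mammalian
#' genomes, so the fraction of them read as T estimates the conversion rate:
#' `100 * converted / (converted + unconverted)`.
#'
#' @param nonCpG either the named counts returned by [callSitesFromStack()],
#'   or a data.frame with `countM` (unconverted C) and `countU` (converted T)
#'   columns as stored by the cytosine-report reader.
#' @return Conversion rate as a percentage in `[0, 100]`.
#' @export
estimateConversionRate <- function(nonCpG) {
    if (is.data.frame(nonCpG)) {
        unconv <- sum(nonCpG$countM)
        conv <- sum(nonCpG$countU)
    } else {
        unconv <- nonCpG[["unconverted"]]
        conv <- nonCpG[["converted"]]
    }
    tot <- conv + unconv
    if (!isTRUE(tot > 0))
        stop("conversion rate undefined: no non-CpG cytosine observations")
    100 * conv / tot
}

#' Sites adequately covered in every sample
#'
#' Differential testing is performed only on CpG dinucleotides covered in all
#' test and control samples; this returns that shared site universe.
#'
#' @param tables list of [MethylomeTable-class] objects (at least 2).
#' @param minCoverage minimum coverage each sample must reach at a site.
#' @return A sorted width-1 [GenomicRanges::GRanges] of shared sites.
#' @export
sharedSites <- function(tables, minCoverage = 10L) {
    stopifnot(length(tables) >= 2L)
    keysets <- lapply(tables, function(t)
        siteKeys(filterCoverage(t, minCoverage)))
    shared <- Reduce(intersect, keysets)
    if (!length(shared)) return(GenomicRanges::GRanges())
    parts <- do.call(rbind, strsplit(shared, ":", fixed = TRUE))
    gr <- GenomicRanges::GRanges(parts[, 1L],
        IRanges::IRanges(as.integer(parts[, 2L]), width = 1L))
    gr[order(as.character(GenomeInfoDb::seqnames(gr)), BiocGenerics::start(gr))]
}
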