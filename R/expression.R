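## Coupling methylation to gene expression: percentile groups, island/shore
## TSS categories, per-region methylation summaries, high-vs-low contrasts,
## DMC / fold-change correlations.

#' Split transcripts into high / low / middle expression groups
#'
#' Percentiles come from the empirical CDF of the expression values. A
#' transcript is `high` when its right-continuous ECDF value `P(X <= x)`
#' strictly exceeds `1 - percentile/100`, and `low` when the left limit
#' `P(X < x)` falls strictly below `percentile/100`; the two-sided use of the
#' step function makes "top 15 percent" of 100 distinct values exactly 15
#' transcripts, symmetrically at both tails. With a single distinct value
#' both tails are degenerate: everything is `middle`, with a warning.
#'
#' @param expr data.frame with columns `transcript`, `value`.
#' @param percentile tail size in percent (default 15).
#' @return `expr` with added `percentile` (right-continuous ECDF) and
#'   `group` factor (high/low/middle).
#' @export
expressionGroups <- function(expr, percentile = 15) {
    stopifnot(nrow(expr) >= 1L, percentile > 0, percentile < 50)
    q <- percentile / 100
    n <- nrow(expr)
    fHi <- stats::ecdf(expr$value)(expr$value)        # P(X <= x)
    fLo <- vapply(expr$value, function(v) mean(expr$value < v), numeric(1))
    group <- rep("middle", n)
    if (length(unique(expr$value)) == 1L) {
        warning("all expression values identical: no high/low groups")
    } else {
        group[fHi > 1 - q] <- "high"
        group[fLo < q] <- "low"
    }
    expr$percentile <- fHi
    expr$group <- factor(group, levels = c("high", "low", "middle"))
    expr
}

#' Map islands/shores to TSSs within a window
#'
#' Pairs every region with every transcript whose TSS lies within `window`
#' bp, and classifies each pair as TSS-overlapping (the region spans the
#' TSS), upstream, or downstream, using the gene's orientation; overlap wins.
#'
#' @param regions GRanges (islands or shores).
#' @param genes a [GeneModelSet-class].
#' @param window bp around the TSS (default 10 kb).
#' @return data.frame with `region` (index into `regions`), `txId`,
#'   `category` factor.
#' @export
mapRegionsToTss <- function(regions, genes, window = 10000L) {
    tx <- genes@transcripts
    tssWin <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(tx),
        IRanges::IRanges(pmax(1L, S4Vectors::mcols(tx)$tss - window),
                         S4Vectors::mcols(tx)$tss + window))
    hits <- IRanges::findOverlaps(regions, tssWin, ignore.strand = TRUE)
    ri <- S4Vectors::queryHits(hits); ti <- S4Vectors::subjectHits(hits)
    tssPos <- S4Vectors::mcols(tx)$tss[ti]
    strand <- as.character(BiocGenerics::strand(tx))[ti]
    rs <- BiocGenerics::start(regions)[ri]
    re <- BiocGenerics::end(regions)[ri]
    cat <- ifelse(rs <= tssPos & tssPos <= re, "TSS-overlapping",
        ifelse(xor(re < tssPos, strand == "-"), "upstream", "downstream"))
    data.frame(region = ri, txId = S4Vectors::mcols(tx)$txId[ti],
               category = factor(cat, levels = c("TSS-overlapping",
                                                 "upstream", "downstream")),
               stringsAsFactors = FALSE)
}

#' Per-region methylation summary
#'
#' Maximum (or mean) percent methylation over the covered CpGs in each
#' region; regions with fewer than `minCpgs` covered CpGs are omitted.
#'
#' @param table a coverage-filtered [MethylomeTable-class].
#' @param regions GRanges.
#' @param statistic `"max"` or `"mean"`.
#' @param minCpgs minimum covered CpGs per region (default 3).
#' @return data.frame with `region` (index into `regions`), `nCpgs`, `value`.
#' @export
regionMethylation <- function(table, regions, statistic = c("max", "mean"),
                              minCpgs = 3L) {
    statistic <- match.arg(statistic)
    if (!length(regions))
        return(data.frame(region = integer(), nCpgs = integer(),
                          value = numeric()))
    pm <- pctMeth(table)
    hits <- IRanges::findOverlaps(table@sites, regions, ignore.strand = TRUE)
    ri <- S4Vectors::subjectHits(hits)
    vals <- pm[S4Vectors::queryHits(hits)]
    n <- tabulate(ri, nbins = length(regions))
    keep <- which(n >= minCpgs)
    fun <- if (statistic == "max") max else mean
    value <- vapply(keep, function(r) fun(vals[ri == r]), numeric(1))
    data.frame(region = keep, nCpgs = n[keep], value = value)
}

#' High- vs low-expression methylation contrast
#'
#' For each TSS category, compares the per-region methylation summaries of
#' regions whose transcripts are in the high expression group against those
#' in the low group, with a two-sided Wilcoxon rank-sum test
#' ([wilcoxonRankSum()]; exact for small samples). Each mapped region is an
#' independent observation. Categories with an empty group are skipped with
#' a warning.
#'
#' @param regionValues data.frame from [regionMethylation()].
#' @param regionCats data.frame from [mapRegionsToTss()].
#' @param exprGroups data.frame from [expressionGroups()].
#' @return data.frame per category: group sizes, medians, Wilcoxon p.
#' @export
methylationExpressionContrast <- function(regionValues, regionCats, exprGroups) {
    grp <- stats::setNames(as.character(exprGroups$group), exprGroups$transcript)
    df <- merge(regionCats, regionValues, by = "region")
    df$group <- grp[df$txId]
    out <- list()
    for (cat in levels(regionCats$category)) {
        hi <- df$value[df$category == cat & df$group == "high"]
        lo <- df$value[df$category == cat & df$group == "low"]
        if (!length(hi) || !length(lo)) {
            warning("category ", cat, " skipped: empty expression group")
            next
        }
        out[[cat]] <- data.frame(category = cat,
            nHigh = length(hi), nLow = length(lo),
            medianHigh = stats::median(hi), medianLow = stats::median(lo),
            p = wilcoxonRankSum(hi, lo), stringsAsFactors = FALSE)
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Expression fold-change between two conditions
#'
#' `log2(meanA / meanB)` per transcript (the symmetric, standard scale); set
#' `log2 = FALSE` for the raw ratio. When a condition table holds several
#' values per transcript they are averaged first.
#'
#' @param exprA,exprB data.frames with `transcript`, `value`.
#' @param log2 logical.
#' @return named numeric vector of fold-changes by transcript.
#' @export
expressionFoldChange <- function(exprA, exprB, log2 = TRUE) {
    mA <- tapply(exprA$value, exprA$transcript, mean)
    mB <- tapply(exprB$value, exprB$transcript, mean)
    common <- intersect(names(mA), names(mB))
    fc <- as.numeric(mA[common]) / as.numeric(mB[common])
    if (log2) fc <- base::log2(fc)
    stats::setNames(fc, common)
}

#' Correlate DMC methylation differences with expression fold-change
#'
#' Pairs each DMC in a regional stratum with the fold-change of its nearest
#' gene and runs a two-sided Pearson correlation test. Strata follow the
#' regional analysis design: the core promoter (-300 to +300 bp around the
#' TSS), upstream DMCs (up to 10 kb), upstream island/shore DMCs (up to 5 kb
#' from the TSS), and intronic DMCs (optionally restricted to islands or
#' shores).
#'
#' @param dmcAnnot annotated DMC data.frame: needs `diff`, `distTss`,
#'   `nearestTx`, `feature`, `islandContext` (see [annotateCpGs()] merged
#'   with [callDmcs()] output).
#' @param foldChange named vector from [expressionFoldChange()].
#' @param stratum one of `"core_promoter"`, `"upstream"`,
#'   `"upstream_island"`, `"upstream_shore"`, `"intronic"`,
#'   `"intronic_island"`, `"intronic_shore"`.
#' @param corePromoter,upstreamWindow,islandTssWindow stratum windows in bp.
#' @return list with `r`, `p`, `n`; fewer than 3 pairs or zero-variance
#'   fold-changes are errors.
#' @export
dmcFoldchangeCorrelation <- function(dmcAnnot, foldChange,
        stratum = c("core_promoter", "upstream", "upstream_island",
                    "upstream_shore", "intronic", "intronic_island",
                    "intronic_shore"),
        corePromoter = c(-300L, 300L), upstreamWindow = 10000L,
        islandTssWindow = 5000L) {
    stratum <- match.arg(stratum)
    d <- dmcAnnot
    sel <- switch(stratum,
        core_promoter = d$distTss >= corePromoter[1L] &
                        d$distTss <= corePromoter[2L],
        upstream = d$distTss < 0 & d$distTss >= -upstreamWindow,
        upstream_island = d$distTss < 0 & d$distTss >= -islandTssWindow &
                          d$islandContext == "island",
        upstream_shore = d$distTss < 0 & d$distTss >= -islandTssWindow &
                         d$islandContext == "shore",
        intronic = d$feature == "intron",
        intronic_island = d$feature == "intron" & d$islandContext == "island",
        intronic_shore = d$feature == "intron" & d$islandContext == "shore")
    d <- d[sel & d$nearestTx %in% names(foldChange), , drop = FALSE]
    if (nrow(d) < 3L)
        stop("fewer than 3 DMC-gene pairs in stratum ", stratum)
    fc <- foldChange[d$nearestTx]
    if (stats::sd(fc) == 0) stop("zero-variance fold-changes in stratum")
    ct <- stats::cor.test(d$diff, fc, method = "pearson",
                          alternative = "two.sided")
    list(r = unname(ct$estimate), p = ct$p.value, n = nrow(d))
}
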