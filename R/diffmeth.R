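## Per-CpG differential methylation: pooled percent differences, binomial
## logistic-regression likelihood-ratio tests, DMC calling, cross-comparison
## overlap bookkeeping, and sample clustering.

#' Pooled percent methylation difference between groups
#'
#' Group-level percent methylation is computed by summing methylated C counts
#' across the samples of a group and dividing by the group's total read
#' coverage; the difference is test minus control, in percentage points.
#'
#' @param countsM,countsU named numeric vectors (or single-row matrices) of
#'   methylated / unmethylated counts per sample at one site, or matrices
#'   (sites x samples) for vectorised use.
#' @param samples a [SampleSet-class]; names of `countsM` columns must cover
#'   both groups.
#' @return data.frame with `pctTest`, `pctControl`, `diff`.
#' @export
pooledPercentDifference <- function(countsM, countsU, samples) {
    if (is.null(dim(countsM))) countsM <- matrix(countsM, nrow = 1L,
        dimnames = list(NULL, names(countsM)))
    if (is.null(dim(countsU))) countsU <- matrix(countsU, nrow = 1L,
        dimnames = list(NULL, names(countsU)))
    stopifnot(all(c(samples@test, samples@control) %in% colnames(countsM)))
    mT <- rowSums(countsM[, samples@test, drop = FALSE])
    uT <- rowSums(countsU[, samples@test, drop = FALSE])
    mC <- rowSums(countsM[, samples@control, drop = FALSE])
    uC <- rowSums(countsU[, samples@control, drop = FALSE])
    if (any(mT + uT == 0) || any(mC + uC == 0))
        stop("zero pooled coverage in a group: site undefined")
    pt <- 100 * mT / (mT + uT)
    pc <- 100 * mC / (mC + uC)
    data.frame(pctTest = pt, pctControl = pc, diff = pt - pc)
}

#' Logistic-regression likelihood-ratio test per CpG
#'
#' Fits the binomial logistic model with group membership as the only
#' covariate against the intercept-only null and returns the likelihood-ratio
#' (deviance difference) statistic with a chi-square p-value on one degree of
#' freedom. With group as the sole covariate the maximum-likelihood fit is
#' available in closed form from the pooled per-group counts, and the
#' statistic equals the G-test on the pooled 2x2 table (with `0 * log 0 = 0`).
#'
#' @param methTest,unmethTest,methControl,unmethControl pooled counts per
#'   group (vectors for vectorised use over sites).
#' @return data.frame with `statistic` and `p`.
#' @export
logisticLrtTest <- function(methTest, unmethTest, methControl, unmethControl) {
    nT <- methTest + unmethTest
    nC <- methControl + unmethControl
    if (any(nT == 0 | nC == 0))
        stop("degenerate site: a group has zero pooled coverage")
    xlogy <- function(x, p) ifelse(x > 0, x * log(p), 0)
    ll <- function(m, u, p) xlogy(m, p) + xlogy(u, 1 - p)
    pT <- methTest / nT
    pC <- methControl / nC
    p0 <- (methTest + methControl) / (nT + nC)
    stat <- 2 * (ll(methTest, unmethTest, pT) + ll(methControl, unmethControl, pC)
                 - ll(methTest, unmethTest, p0) - ll(methControl, unmethControl, p0))
    stat <- pmax(stat, 0)
    data.frame(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Call differentially methylated cytosines
#'
#' A site is a hypermethylated DMC when `q < qvalueCutoff` and the pooled
#' difference is at least `+diffCutoff` percentage points; hypomethylated
#' symmetrically; all other sites are `ns`.
#'
#' @param results data.frame from [diffMethTest()] (needs columns `diff`,
#'   `q`).
#' @param qvalueCutoff FDR threshold (default 0.01).
#' @param diffCutoff minimum absolute pooled difference in percentage points
#'   (default 25; 10 and 40 as robustness cutoffs).
#' @return `results` with a `status` factor (hyper/hypo/ns) and the cutoffs
#'   recorded as attributes.
#' @export
callDmcs <- function(results, qvalueCutoff = 0.01, diffCutoff = 25) {
    status <- rep("ns", nrow(results))
    sig <- results$q < qvalueCutoff
    status[sig & results$diff >= diffCutoff] <- "hyper"
    status[sig & results$diff <= -diffCutoff] <- "hypo"
    results$status <- factor(status, levels = c("hyper", "hypo", "ns"))
    attr(results, "qvalueCutoff") <- qvalueCutoff
    attr(results, "diffCutoff") <- diffCutoff
    results
}

#' Per-chromosome DMC summary
#'
#' @param dmcs data.frame from [callDmcs()] with `chrom` and `status`.
#' @return data.frame of covered CpGs, hyper/hypo counts and percentages per
#'   chromosome.
#' @export
dmcSummaryByChrom <- function(dmcs) {
    tab <- table(dmcs$chrom, dmcs$status)
    covered <- rowSums(tab)
    data.frame(chrom = rownames(tab), covered = as.integer(covered),
               hyper = as.integer(tab[, "hyper"]),
               hypo = as.integer(tab[, "hypo"]),
               pctHyper = 100 * tab[, "hyper"] / covered,
               pctHypo = 100 * tab[, "hypo"] / covered,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Overlap bookkeeping between two DMC sets
#'
#' Set algebra over a shared site universe: sites unique to each comparison,
#' common sites, and among the common ones the concordant (same direction)
#' and discordant counts, with direction tallies.
#'
#' @param dmcsA,dmcsB data.frames with `key` (site key) and `status`
#'   restricted to called DMCs (status != "ns"), e.g. from [callDmcs()] rows.
#' @param universe character site keys both comparisons were tested on.
#' @return list with counts and percentages (one-decimal reporting is left to
#'   the caller).
#' @export
compareDmcSets <- function(dmcsA, dmcsB, universe) {
    a <- dmcsA[dmcsA$status != "ns", , drop = FALSE]
    b <- dmcsB[dmcsB$status != "ns", , drop = FALSE]
    if (!all(a$key %in% universe) || !all(b$key %in% universe))
        stop("DMC site absent from the shared universe")
    common <- intersect(a$key, b$key)
    uniqueA <- setdiff(a$key, b$key)
    uniqueB <- setdiff(b$key, a$key)
    unionN <- length(common) + length(uniqueA) + length(uniqueB)
    dirA <- stats::setNames(as.character(a$status), a$key)
    dirB <- stats::setNames(as.character(b$status), b$key)
    conc <- common[dirA[common] == dirB[common]]
    concHyper <- sum(dirA[conc] == "hyper")
    list(nA = nrow(a), nB = nrow(b),
         uniqueA = length(uniqueA), uniqueB = length(uniqueB),
         common = length(common), union = unionN,
         pctUnique = 100 * (length(uniqueA) + length(uniqueB)) / unionN,
         concordant = length(conc), discordant = length(common) - length(conc),
         pctConcordant = if (length(common)) 100 * length(conc) / length(common) else NA_real_,
         concordantHyper = concHyper,
         pctConcordantHyper = if (length(conc)) 100 * concHyper / length(conc) else NA_real_,
         hyperA = sum(dirA == "hyper"), hypoA = sum(dirA == "hypo"),
         hyperB = sum(dirB == "hyper"), hypoB = sum(dirB == "hypo"))
}

#' Percent methylation matrix over shared sites
#'
#' @param tables list of [MethylomeTable-class] objects.
#' @param universe GRanges of shared sites (see [sharedSites()]).
#' @return numeric matrix, sites x samples.
#' @export
pctMethMatrix <- function(tables, universe) {
    keys <- siteKeys(universe)
    m <- vapply(tables, function(t) {
        idx <- match(keys, siteKeys(t))
        pctMeth(t)[idx]
    }, numeric(length(keys)))
    rownames(m) <- keys
    colnames(m) <- vapply(tables, sampleId, character(1))
    m
}

#' Cluster samples on percent methylation
#'
#' Pairwise Pearson correlation of percent methylation over the shared
#' sites, hierarchical clustering on the 1 - Pearson distance with Ward's
#' agglomeration, and principal component coordinates. In region mode
#' (`regions` supplied), per-region mean methylation over regions with at
#' least `minCpgs` covered CpGs replaces per-site values before correlating.
#'
#' @param mat sites x samples percent methylation matrix (see
#'   [pctMethMatrix()]).
#' @param regions optional GRanges; triggers region-level mode.
#' @param minCpgs minimum covered CpGs per region in region mode (default 3).
#' @return list with `correlation` (matrix), `hclust`, `pca` (prcomp scores).
#' @export
sampleClustering <- function(mat, regions = NULL, minCpgs = 3L) {
    stopifnot(ncol(mat) >= 2L)
    if (!is.null(regions)) {
        keys <- do.call(rbind, strsplit(rownames(mat), ":", fixed = TRUE))
        gr <- GenomicRanges::GRanges(keys[, 1L],
            IRanges::IRanges(as.integer(keys[, 2L]), width = 1L))
        hits <- IRanges::findOverlaps(gr, regions, ignore.strand = TRUE)
        grp <- S4Vectors::subjectHits(hits)
        rows <- S4Vectors::queryHits(hits)
        counts <- tabulate(grp, nbins = length(regions))
        keep <- counts >= minCpgs
        mat <- do.call(rbind, lapply(which(keep), function(r)
            colMeans(mat[rows[grp == r], , drop = FALSE])))
        if (is.null(mat) || nrow(mat) < 2L)
            stop("fewer than two regions with >= ", minCpgs, " covered CpGs")
    }
    if (any(apply(mat, 2L, stats::sd) == 0))
        stop("zero-variance sample: correlation undefined")
    cc <- stats::cor(mat, method = "pearson")
    hc <- stats::hclust(stats::as.dist(1 - cc), method = "ward.D")
    pca <- stats::prcomp(t(mat), center = TRUE, scale. = FALSE)
    list(correlation = cc, hclust = hc, pca = pca$x)
}

#' Differential methylation test over a sample cohort
#'
#' End-to-end per-CpG testing: restricts to sites covered in every test and
#' control sample, pools counts per group, computes pooled percent
#' differences, the logistic LRT, and SLIM q-values.
#'
#' @param tables named list of [MethylomeTable-class] objects covering all
#'   samples in `samples`.
#' @param samples a [SampleSet-class].
#' @param minCoverage per-sample coverage filter (default 10).
#' @param qvalueMethod `"slim"` (default) or `"BH"`.
#' @return data.frame with one row per shared site: `chrom`, `pos`, `key`,
#'   pooled counts per group, percentages, `diff`, `statistic`, `p`, `q`.
#' @export
diffMethTest <- function(tables, samples, minCoverage = 10L,
                         qvalueMethod = c("slim", "BH")) {
    qvalueMethod <- match.arg(qvalueMethod)
    ids <- c(samples@test, samples@control)
    stopifnot(all(ids %in% names(tables)))
    tabs <- tables[ids]
    univ <- sharedSites(tabs, minCoverage)
    keys <- siteKeys(univ)
    getCol <- function(t, what) {
        idx <- match(keys, siteKeys(t))
        if (what == "M") methCounts(t)[idx] else unmethCounts(t)[idx]
    }
    cm <- vapply(tabs, getCol, numeric(length(keys)), what = "M")
    cu <- vapply(tabs, getCol, numeric(length(keys)), what = "U")
    colnames(cm) <- colnames(cu) <- ids
    pooled <- pooledPercentDifference(cm, cu, samples)
    mT <- rowSums(cm[, samples@test, drop = FALSE])
    uT <- rowSums(cu[, samples@test, drop = FALSE])
    mC <- rowSums(cm[, samples@control, drop = FALSE])
    uC <- rowSums(cu[, samples@control, drop = FALSE])
    lrt <- logisticLrtTest(mT, uT, mC, uC)
    q <- if (qvalueMethod == "slim") adjustPvaluesSlim(lrt$p)
         else stats::p.adjust(lrt$p, "BH")
    data.frame(chrom = as.character(GenomeInfoDb::seqnames(univ)),
               pos = BiocGenerics::start(univ), key = keys,
               methTest = mT, unmethTest = uT,
               methControl = mC, unmethControl = uC,
               pctTest = pooled$pctTest, pctControl = pooled$pctControl,
               diff = pooled$diff, statistic = lrt$statistic, p = lrt$p,
               q = q, stringsAsFactors = FALSE)
}
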