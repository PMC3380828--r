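## Exact and asymptotic enrichment statistics for peak / repeat overlap.

#' Two-sided Fisher exact test on a 2x2 table
#'
#' The two-sided p-value follows the minimum-likelihood convention: the sum
#' of all hypergeometric point probabilities (at the observed margins) not
#' exceeding the observed table's probability, with the customary 1 + 1e-7
#' relative tolerance. The odds ratio is the sample `ad / bc`; when any cell
#' is zero the Haldane correction (0.5 added to every cell) is applied and
#' flagged.
#'
#' @param tab 2x2 matrix (or length-4 vector, row-wise `a, b, c, d`) of
#'   non-negative counts with positive total.
#' @return list with `p`, `oddsRatio`, `haldane` (logical flag).
#' @examples
#' fisherExact2x2(matrix(c(11, 38, 1, 48), 2, byrow = TRUE))$p  # ~0.0037
#' @export
fisherExact2x2 <- function(tab) {
    if (!is.matrix(tab)) tab <- matrix(tab, 2L, 2L, byrow = TRUE)
    stopifnot(all(dim(tab) == 2L), all(tab >= 0))
    N <- sum(tab)
    if (N == 0) stop("all-zero contingency table")
    a <- tab[1L, 1L]
    r1 <- sum(tab[1L, ]); c1 <- sum(tab[, 1L])
    lo <- max(0L, r1 + c1 - N); hi <- min(r1, c1)
    support <- lo:hi
    dens <- stats::dhyper(support, c1, N - c1, r1)
    pObs <- stats::dhyper(a, c1, N - c1, r1)
    p <- min(1, sum(dens[dens <= pObs * (1 + 1e-7)]))
    haldane <- any(tab == 0)
    t2 <- if (haldane) tab + 0.5 else tab
    or <- (t2[1L, 1L] * t2[2L, 2L]) / (t2[1L, 2L] * t2[2L, 1L])
    list(p = p, oddsRatio = or, haldane = haldane)
}

#' Pearson chi-square test of independence
#'
#' Without continuity correction, df = (r-1)(c-1). A zero expected cell is an
#' error.
#'
#' @param tab contingency matrix of non-negative counts.
#' @return list with `statistic`, `df`, `p`.
#' @export
chiSquareIndependence <- function(tab) {
    stopifnot(is.matrix(tab), all(tab >= 0), sum(tab) > 0)
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected == 0)) stop("zero expected cell in chi-square test")
    res <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(statistic = unname(res$statistic), df = unname(res$parameter),
         p = res$p.value)
}

#' Operational enhancer set from H3K4me1/H3K4me3 peaks
#'
#' Within each cell line, H3K4me1 peaks overlapping (by >= 1 bp) any
#' H3K4me3 peak of the same line are dropped; the survivors from all lines
#' are union-merged so that peaks overlapping between lines are counted once.
#'
#' @param me1,me3 lists of GRanges, one element per cell line (parallel; a
#'   line's me3 element may be empty).
#' @return merged enhancer GRanges.
#' @export
defineEnhancers <- function(me1, me3) {
    stopifnot(length(me1) == length(me3))
    kept <- lapply(seq_along(me1), function(i) {
        g1 <- me1[[i]]
        g3 <- me3[[i]]
        if (!length(g3)) return(GenomicRanges::granges(g1))
        GenomicRanges::granges(
            g1[!IRanges::overlapsAny(g1, g3, ignore.strand = TRUE)])
    })
    kept <- kept[lengths(kept) > 0]
    if (!length(kept)) return(GenomicRanges::GRanges())
    GenomicRanges::reduce(do.call(c, kept), ignore.strand = TRUE)
}

#' Peak / DMC overlap row (Table-1 style)
#'
#' Peaks are extended by `flank` bp on each side. A peak counts as covered
#' when its extended interval contains at least one covered CpG; it counts in
#' the hypo (hyper) row when it contains a hypomethylated (hypermethylated)
#' DMC — a peak holding both directions increments both rows. The Fisher
#' test compares the hypo and hyper proportions among covered peaks:
#' `[[hypo, covered - hypo], [hyper, covered - hyper]]`.
#'
#' @param peaks GRanges of peak locations.
#' @param dmcs data.frame with `chrom`, `pos`, `status` (from [callDmcs()]).
#' @param covered GRanges of the covered-CpG universe (see [sharedSites()]).
#' @param flank bp added to each side of each peak (default 500; negative is
#'   an error).
#' @return list: `nPeaks`, `covered`, `hypo`, `hyper`, `anyDmc`,
#'   `anyDmcExclusive` (peaks counted once regardless of direction mix),
#'   `fisherP` (NA with a warning when no peaks are covered).
#' @export
peakDmcOverlap <- function(peaks, dmcs, covered, flank = 500L) {
    if (flank < 0) stop("flank must be non-negative")
    ext <- GenomicRanges::GRanges(GenomeInfoDb::seqnames(peaks),
        IRanges::IRanges(pmax(1L, BiocGenerics::start(peaks) - flank),
                         BiocGenerics::end(peaks) + flank))
    dmcGr <- function(status) {
        d <- dmcs[dmcs$status == status, , drop = FALSE]
        GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$pos, width = 1L))
    }
    covPeak <- IRanges::overlapsAny(ext, covered, ignore.strand = TRUE)
    hypoPeak <- IRanges::overlapsAny(ext, dmcGr("hypo"), ignore.strand = TRUE)
    hyperPeak <- IRanges::overlapsAny(ext, dmcGr("hyper"), ignore.strand = TRUE)
    nCov <- sum(covPeak); nHypo <- sum(hypoPeak); nHyper <- sum(hyperPeak)
    if (nCov == 0) {
        warning("no covered peaks: Fisher p undefined")
        p <- NA_real_
    } else {
        p <- fisherExact2x2(matrix(c(nHypo, nCov - nHypo,
                                     nHyper, nCov - nHyper),
                                   2L, byrow = TRUE))$p
    }
    list(nPeaks = length(peaks), covered = nCov, hypo = nHypo, hyper = nHyper,
         anyDmc = nHypo + nHyper, anyDmcExclusive = sum(hypoPeak | hyperPeak),
         fisherP = p)
}

#' Repeat-element enrichment of DMCs
#'
#' Fraction of DMCs of each direction overlapping any repeat, against the
#' fraction of all covered CpGs in repeats, with the odds ratio computed from
#' the two fractions (`(f/(1-f)) / (b/(1-b))`), a two-sided Fisher p on the
#' counts, and a per-family breakdown.
#'
#' @param dmcs data.frame with `chrom`, `pos`, `status`.
#' @param covered GRanges of covered CpGs (non-empty).
#' @param repeats GRanges with optional `name`/`family` mcol.
#' @return data.frame, one row per direction: n, fraction in repeats (pct),
#'   background pct, odds ratio, Fisher p; per-family percentages attached as
#'   `attr(x, "families")`.
#' @export
repeatEnrichment <- function(dmcs, covered, repeats) {
    if (!length(covered)) stop("zero covered sites")
    bgIn <- sum(IRanges::overlapsAny(covered, repeats, ignore.strand = TRUE))
    bgFrac <- bgIn / length(covered)
    mc <- S4Vectors::mcols(repeats)
    famCol <- intersect(c("family", "name"), colnames(mc))[1L]
    rows <- list(); fams <- list()
    for (status in c("hyper", "hypo")) {
        d <- dmcs[dmcs$status == status, , drop = FALSE]
        if (!nrow(d)) next
        gr <- GenomicRanges::GRanges(d$chrom, IRanges::IRanges(d$pos, width = 1L))
        hit <- IRanges::findOverlaps(gr, repeats, ignore.strand = TRUE,
                                     select = "first")
        f <- mean(!is.na(hit))
        or <- (f / (1 - f)) / (bgFrac / (1 - bgFrac))
        p <- fisherExact2x2(matrix(c(sum(!is.na(hit)), sum(is.na(hit)),
                                     bgIn, length(covered) - bgIn),
                                   2L, byrow = TRUE))$p
        rows[[status]] <- data.frame(status = status, n = nrow(d),
            pctInRepeat = 100 * f, pctBackground = 100 * bgFrac,
            oddsRatio = or, fisherP = p, stringsAsFactors = FALSE)
        if (!is.na(famCol)) {
            famHits <- mc[[famCol]][hit[!is.na(hit)]]
            tf <- table(famHits)
            fams[[status]] <- data.frame(status = status,
                family = names(tf), pctOfDmcs = 100 * as.integer(tf) / nrow(d),
                stringsAsFactors = FALSE)
        }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "families") <- if (length(fams)) do.call(rbind, fams) else NULL
    out
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact enumeration when the combined sample size is at most 20 and there
#' are no ties; the normal approximation with tie correction otherwise. Two
#' degenerate identical samples give p = 1 with a warning.
#'
#' @param x,y non-empty numeric samples.
#' @return two-sided p-value.
#' @export
wilcoxonRankSum <- function(x, y) {
    stopifnot(length(x) > 0, length(y) > 0)
    if (length(unique(c(x, y))) == 1L) {
        warning("all values identical in both samples: p = 1")
        return(1)
    }
    exact <- (length(x) + length(y)) <= 20L && !anyDuplicated(c(x, y))
    suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                        exact = exact))$p.value
}
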