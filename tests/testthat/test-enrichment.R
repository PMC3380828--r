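m2 <- function(a, b, c, d) matrix(c(a, b, c, d), 2L, byrow = TRUE)

test_that("two-sided Fisher p-values match the published peak-overlap table", {
    ## hypo/hyper proportions among covered peaks, per binding-site set
    expect_equal(round(fisherExact2x2(m2(5, 21, 1, 25))$p, 2), 0.19)
    expect_equal(round(fisherExact2x2(m2(9, 29, 1, 37))$p, 2), 0.01)
    expect_equal(round(fisherExact2x2(m2(3, 12, 1, 14))$p, 1), 0.6)
    expect_equal(round(fisherExact2x2(m2(11, 38, 1, 48))$p, 3), 0.004)
    expect_equal(round(fisherExact2x2(m2(36, 797, 19, 814))$p, 2), 0.03)
    ## symmetric table
    unit <- fisherExact2x2(m2(1, 1, 1, 1))
    expect_equal(unit$p, 1)
    expect_equal(unit$oddsRatio, 1)
    ## zero cells trigger the flagged Haldane correction
    hz <- fisherExact2x2(m2(0, 10, 5, 5))
    expect_true(hz$haldane)
    expect_equal(hz$oddsRatio, (0.5 * 5.5) / (10.5 * 5.5))
    expect_error(fisherExact2x2(m2(0, 0, 0, 0)))
})

test_that("Fisher implementation agrees with stats::fisher.test", {
    set.seed(13)
    for (i in 1:300) {
        tab <- matrix(rpois(4, sample(c(2, 8, 25), 1)), 2L)
        if (sum(tab) == 0) next
        mine <- fisherExact2x2(tab)
        ref <- stats::fisher.test(tab)
        expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
        ## transposing leaves p unchanged and inverts the OR
        tmine <- fisherExact2x2(t(tab))
        expect_equal(tmine$p, mine$p, tolerance = 1e-12)
        mirror <- fisherExact2x2(tab[, 2:1])
        expect_equal(mirror$oddsRatio, 1 / mine$oddsRatio, tolerance = 1e-9)
    }
})

test_that("chi-square independence is Pearson without continuity correction", {
    eq <- chiSquareIndependence(m2(10, 20, 10, 20))
    expect_equal(eq$statistic, 0)
    expect_equal(eq$p, 1)
    res <- chiSquareIndependence(m2(10, 90, 90, 10))
    expect_equal(res$statistic, 128)
    expect_equal(res$df, 1)
    ## doubling all cells doubles the statistic
    expect_equal(chiSquareIndependence(2 * m2(10, 90, 90, 10))$statistic, 256)
    expect_error(chiSquareIndependence(m2(0, 0, 5, 5)), "expected")
})

test_that("enhancers are me1-not-me3 per line, union-merged across lines", {
    ## me1 overlapping me3 in the same line is dropped
    e1 <- defineEnhancers(list(grI(100, 200)), list(grI(150, 250)))
    expect_equal(length(e1), 0L)
    ## survivors from different lines merge when they overlap
    e2 <- defineEnhancers(list(grI(100, 200), grI(150, 250)),
                          list(grI(900, 950), GenomicRanges::GRanges()))
    expect_equal(length(e2), 1L)
    expect_equal(BiocGenerics::start(e2), 100L)
    expect_equal(BiocGenerics::end(e2), 250L)
    ## empty me3 everywhere: plain union-merge of all me1
    e3 <- defineEnhancers(list(grI(1, 10), grI(5, 20)),
                          list(GenomicRanges::GRanges(),
                               GenomicRanges::GRanges()))
    expect_equal(length(e3), 1L)
})

test_that("peak/DMC overlap counts extended peaks by direction", {
    peaks <- grI(c(1000, 5000, 9000), c(1100, 5100, 9100))
    covered <- grI(1050, 1050)
    dmcs <- data.frame(chrom = "chr1", pos = 1450L, status = "hypo")
    ## the hypo DMC sits within the 500 bp flank of peak 1 only
    row <- peakDmcOverlap(peaks, dmcs, covered, flank = 500L)
    expect_equal(row$covered, 1L)
    expect_equal(row$hypo, 1L)
    expect_equal(row$hyper, 0L)
    ## flank monotonicity
    row0 <- peakDmcOverlap(peaks, dmcs, covered, flank = 0L)
    expect_lte(row0$hypo, row$hypo)
    expect_lte(row0$covered, row$covered)
    ## peak order invariance
    rowR <- peakDmcOverlap(rev(peaks), dmcs, covered, flank = 500L)
    expect_equal(rowR$hypo, row$hypo)
    expect_error(peakDmcOverlap(peaks, dmcs, covered, flank = -1L))
    expect_warning(p0 <- peakDmcOverlap(peaks, dmcs, grI(99000, 99000)),
                   "no covered peaks")
    expect_true(is.na(p0$fisherP))
})

test_that("the HOXA9/MEIS1 overlap row reconstructs from per-peak layout", {
    ## 60 peaks; 49 covered; 11 with a hypo DMC, 1 distinct peak with a hyper
    starts <- seq(1000, by = 10000, length.out = 60)
    peaks <- grI(starts, starts + 100)
    covered <- grI(starts[1:49] + 50, starts[1:49] + 50)
    dmcs <- rbind(
        data.frame(chrom = "chr1", pos = starts[1:11] + 60, status = "hypo"),
        data.frame(chrom = "chr1", pos = starts[12] + 60, status = "hyper"))
    row <- peakDmcOverlap(peaks, dmcs, covered, flank = 500L)
    expect_equal(row$covered, 49L)
    expect_equal(row$hypo, 11L)
    expect_equal(row$hyper, 1L)
    expect_equal(row$anyDmcExclusive, 12L)
    expect_equal(round(row$fisherP, 3), 0.004)
})

test_that("repeat enrichment odds ratios come from the overlap fractions", {
    ## covered universe: 1000 CpGs, 150 inside the repeat region (15%)
    covered <- grI(seq_len(1000) * 10, seq_len(1000) * 10)
    repeats <- grI(1, 1505)
    repeats$family <- "Alu"
    ## hypo DMCs: 100 sites, 24 in repeats -> OR (0.24/0.76)/(0.15/0.85) = 1.8
    hypo24 <- data.frame(chrom = "chr1",
        pos = c(seq_len(24) * 10, seq(200, by = 10, length.out = 76) * 10),
        status = "hypo")
    re <- repeatEnrichment(hypo24, covered, repeats)
    expect_equal(re$pctInRepeat[re$status == "hypo"], 24)
    expect_equal(re$pctBackground[1], 15)
    expect_equal(round(re$oddsRatio[re$status == "hypo"], 1), 1.8)
    expect_lt(re$fisherP[re$status == "hypo"], 0.05)
    fams <- attr(re, "families")
    expect_equal(fams$pctOfDmcs[fams$family == "Alu"], 24)
    ## 26% overlap -> OR 2.0
    hypo26 <- hypo24
    hypo26$pos[25:26] <- c(1250, 1260)
    re26 <- repeatEnrichment(hypo26, covered, repeats)
    expect_equal(round(re26$oddsRatio[re26$status == "hypo"], 1), 2)
    ## DMC fraction equal to background: OR = 1
    hypoBg <- data.frame(chrom = "chr1",
        pos = c(seq_len(15) * 10, seq(300, by = 10, length.out = 85) * 10),
        status = "hypo")
    reBg <- repeatEnrichment(hypoBg, covered, repeats)
    expect_equal(reBg$oddsRatio[reBg$status == "hypo"], 1)
    expect_error(repeatEnrichment(hypo24, GenomicRanges::GRanges(), repeats),
                 "zero covered")
})

test_that("Wilcoxon rank-sum switches between exact and approximate modes", {
    ## 2 of the 20 rank assignments are as extreme: exact p = 0.1
    expect_equal(wilcoxonRankSum(1:3, 4:6), 0.1)
    expect_equal(wilcoxonRankSum(4:6, 1:3), 0.1)
    expect_equal(suppressWarnings(wilcoxonRankSum(c(1, 2, 3), c(1, 2, 3))), 1)
    expect_warning(p <- wilcoxonRankSum(rep(2, 4), rep(2, 5)), "identical")
    expect_equal(p, 1)
    ## large samples: approximate mode, still symmetric
    set.seed(14)
    x <- stats::rnorm(50); y <- stats::rnorm(60, 1)
    expect_equal(wilcoxonRankSum(x, y), wilcoxonRankSum(y, x))
    expect_lt(wilcoxonRankSum(x, y), 0.05)
})
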