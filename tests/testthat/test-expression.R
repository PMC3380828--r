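test_that("expression groups take exactly the top/bottom 15% of distinct values", {
    eg <- expressionGroups(data.frame(transcript = paste0("t", 1:100),
                                      value = 1:100))
    expect_equal(sum(eg$group == "high"), 15L)
    expect_equal(sum(eg$group == "low"), 15L)
    expect_true(all(eg$value[eg$group == "high"] >= 86))
    expect_true(all(eg$value[eg$group == "low"] <= 15))
    ## two transcripts: the ECDF step function still splits them
    eg2 <- expressionGroups(data.frame(transcript = c("a", "b"),
                                       value = c(1, 2)))
    expect_equal(as.character(eg2$group), c("low", "high"))
    ## degenerate: all equal, flagged, no groups
    expect_warning(eg3 <- expressionGroups(
        data.frame(transcript = c("a", "b"), value = c(5, 5))), "identical")
    expect_true(all(eg3$group == "middle"))
})

test_that("island-to-TSS mapping categorises by overlap and orientation", {
    gm <- geneModelSet(c("txP", "txM"), c("g1", "g2"), c("chr1", "chr1"),
                       c("+", "-"), c(50001L, 150000L), c(60000L, 160000L),
                       list(50001L, 150000L), list(60000L, 160000L))
    ## island spanning the + strand TSS at 50001
    regions <- grI(c(49900, 46500, 30000, 162000),
                   c(50100, 47000, 30500, 163000))
    cats <- mapRegionsToTss(regions, gm, window = 10000L)
    byRegion <- split(as.character(cats$category), cats$region)
    expect_true("TSS-overlapping" %in% byRegion[["1"]])
    ## region 2 ends 3 kb 5' of the + TSS: upstream
    expect_equal(byRegion[["2"]][cats$txId[cats$region == 2] == "txP"],
                 "upstream")
    ## region 3 is 20 kb away: excluded entirely
    expect_false("3" %in% names(byRegion))
    ## region 4 is left of nothing but 2 kb beyond the - strand TSS at 160000:
    ## on a - gene, larger coordinates are upstream
    expect_equal(byRegion[["4"]], "upstream")
})

test_that("region methylation applies the >= 3 covered CpG rule", {
    tab <- MethylomeTable("chr1", c(10L, 20L, 30L, 100L, 110L),
                          c(2L, 8L, 4L, 5L, 5L),
                          c(8L, 2L, 6L, 5L, 5L), "s")
    regions <- grI(c(5, 95), c(40, 120))
    mx <- regionMethylation(tab, regions, "max")
    expect_equal(mx$region, 1L)      # the second region has only 2 CpGs
    expect_equal(mx$value, 80)
    mn <- regionMethylation(tab, regions, "mean")
    expect_equal(mn$value, mean(c(20, 80, 40)), tolerance = 1e-10)
    expect_true(all(regionMethylation(tab, regions, "max")$value >=
                    regionMethylation(tab, regions, "mean")$value))
    expect_equal(nrow(regionMethylation(tab, GenomicRanges::GRanges())), 0L)
})

test_that("high/low methylation contrast detects planted separation", {
    ## 12 regions mapped to 12 transcripts; high-expression genes carry low
    ## methylation at TSS-overlapping regions, low-expression genes high
    regionValues <- data.frame(region = 1:12, nCpgs = 5,
                               value = c(5, 8, 10, 7, 6, 9, 90, 85, 95, 88,
                                         92, 87))
    regionCats <- data.frame(region = 1:12, txId = paste0("t", 1:12),
        category = factor("TSS-overlapping",
            levels = c("TSS-overlapping", "upstream", "downstream")))
    eg <- data.frame(transcript = paste0("t", 1:12),
                     group = factor(rep(c("high", "low"), each = 6),
                                    levels = c("high", "low", "middle")))
    res <- suppressWarnings(   # upstream/downstream categories are empty
        methylationExpressionContrast(regionValues, regionCats, eg))
    expect_lt(res$p, 0.005)
    expect_lt(res$medianHigh, res$medianLow)
    ## identical distributions: p near 1
    regionValues$value <- rep(c(10, 20, 30, 40, 50, 60), 2)
    resSame <- suppressWarnings(
        methylationExpressionContrast(regionValues, regionCats, eg))
    expect_gt(resSame$p, 0.5)
    ## empty group: every category skipped with warnings
    eg$group[] <- "high"
    w <- capture_warnings(methylationExpressionContrast(regionValues,
                                                        regionCats, eg))
    expect_true(any(grepl("skipped", w)))
})

test_that("fold-change is the log2 ratio of per-transcript means", {
    a <- data.frame(transcript = c("t1", "t1", "t2"), value = c(4, 4, 2))
    b <- data.frame(transcript = c("t1", "t2"), value = c(1, 2))
    fc <- expressionFoldChange(a, b)
    expect_equal(unname(fc["t1"]), 2)
    expect_equal(unname(fc["t2"]), 0)
    expect_equal(unname(expressionFoldChange(a, b, log2 = FALSE)["t1"]), 4)
})

test_that("DMC/fold-change correlation recovers a planted inverse coupling", {
    set.seed(17)
    n <- 40
    diff <- stats::runif(n, -50, 50)
    fc <- stats::setNames(-0.04 * diff + stats::rnorm(n, 0, 0.3),
                          paste0("t", 1:n))
    ann <- data.frame(diff = diff, distTss = sample(-250:250, n),
                      nearestTx = paste0("t", 1:n),
                      feature = "promoter", islandContext = "island")
    res <- dmcFoldchangeCorrelation(ann, fc, "core_promoter")
    expect_lt(res$r, -0.5)
    expect_lt(res$p, 0.001)
    expect_equal(res$n, n)
    ## shuffled gene assignment destroys the correlation
    names(fc) <- sample(names(fc))
    resShuf <- dmcFoldchangeCorrelation(ann, fc, "core_promoter")
    expect_lt(abs(resShuf$r), 0.45)
    ## fewer than 3 pairs / degenerate fold-changes are errors
    expect_error(dmcFoldchangeCorrelation(ann[1:2, ], fc, "core_promoter"),
                 "fewer than 3")
    fcFlat <- stats::setNames(rep(1, n), paste0("t", 1:n))
    expect_error(dmcFoldchangeCorrelation(ann, fcFlat, "core_promoter"),
                 "zero-variance")
    ## stratum filters respect the window definitions
    annUp <- ann
    annUp$distTss <- -sample(400:4000, n)
    expect_error(dmcFoldchangeCorrelation(annUp, fc, "core_promoter"),
                 "fewer than 3")
    resUp <- dmcFoldchangeCorrelation(annUp, fc, "upstream_island")
    expect_equal(resUp$n, n)
})

test_that("simulated expression couples to planted promoter hypermethylation", {
    truth <- miniTruth()
    cfg <- miniSimConfig()
    exH <- simulateExpression(truth, "subtypeH", cfg, seed = 300L)
    exN <- simulateExpression(truth, "normal", cfg, seed = 301L)
    ## genes with planted promoter-island hypermethylation in subtype H
    bundle <- truth@bundle
    mcc <- S4Vectors::mcols(truth@cpgs)
    hyper <- truth@cpgs[mcc$effectH > 0]
    prom <- bundle@promoters
    affected <- S4Vectors::mcols(prom)$txId[
        IRanges::overlapsAny(prom, hyper, ignore.strand = TRUE)]
    affected <- intersect(affected, exH$transcript)
    expect_gt(length(affected), 3)
    lv <- log2(exH$value)
    isAff <- exH$transcript %in% affected
    expect_lt(mean(lv[isAff]), mean(lv[!isAff]))
    ## the same genes are unaffected in the normal condition
    lvN <- log2(exN$value)
    isAffN <- exN$transcript %in% affected
    expect_gt(stats::t.test(lvN[isAffN], lvN[!isAffN])$p.value, 0.01)
    ## zero coupling: no difference beyond sampling error
    ex0 <- simulateExpression(truth, "subtypeH", cfg, seed = 300L,
                              couplingShift = 0)
    lv0 <- log2(ex0$value)
    expect_gt(stats::t.test(lv0[isAff], lv0[!isAff])$p.value, 0.01)
})
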