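test_that("shore construction applies flank, clip and merge rules", {
    ## isolated island: two full-width shores
    s1 <- buildShores(grI(5001, 5800))
    expect_equal(BiocGenerics::start(s1), c(3001L, 5801L))
    expect_equal(BiocGenerics::end(s1), c(5000L, 7800L))
    ## downstream shore clipped at the next island
    s2 <- buildShores(grI(c(5001, 6501), c(5800, 6700)))
    expect_true(any(BiocGenerics::start(s2) == 5801 &
                    BiocGenerics::end(s2) == 6500))
    ## close islands: a single merged inter-island shore
    s3 <- buildShores(grI(c(1001, 1501), c(1200, 1700)))
    expect_true(any(BiocGenerics::start(s3) == 1201 &
                    BiocGenerics::end(s3) == 1500))
    ## chromosome-end clipping
    s4 <- buildShores(grI(501, 900), seqlengths = c(chr1 = 1500L))
    expect_equal(BiocGenerics::start(s4), c(1L, 901L))
    expect_equal(BiocGenerics::end(s4), c(500L, 1500L))
    expect_error(buildShores(grI(c(100, 150), c(200, 250))), "overlap")
})

test_that("shore invariants hold over random island configurations", {
    set.seed(11)
    for (i in 1:200) {
        n <- sample(2:25, 1)
        starts <- sort(sample(seq(1, 900000, by = 50), n))
        widths <- sample(200:3000, n, replace = TRUE)
        isl <- GenomicRanges::reduce(grI(starts, starts + widths - 1L))
        shores <- buildShores(isl, 2000L, c(chr1 = 1000000L))
        ## disjoint from islands and internally disjoint
        expect_equal(sum(BiocGenerics::width(
            GenomicRanges::intersect(shores, isl))), 0)
        expect_true(all(BiocGenerics::width(
            GenomicRanges::reduce(shores)) ==
            BiocGenerics::width(shores)))
        expect_true(all(BiocGenerics::width(shores) <= 4000L))
        ## shuffled input gives identical shores
        shuf <- isl[sample(length(isl))]
        expect_equal(BiocGenerics::start(buildShores(shuf, 2000L,
                                                     c(chr1 = 1000000L))),
                     BiocGenerics::start(shores))
    }
})

mkBundle <- function() {
    ## txA + strand TSS 10001; txB + strand with exon overlapping txA promoter
    gm <- geneModelSet(c("txA", "txB"), c("gA", "gB"), c("chr1", "chr1"),
                       c("+", "+"), c(10001L, 9500L), c(20000L, 9900L),
                       list(c(10001L, 15001L), 9500L),
                       list(c(10300L, 20000L), 9900L))
    buildAnnotationBundle(grI(30001, 30800), gm, seqlengths = c(chr1 = 50000L))
}

test_that("feature classification follows promoter > exon > intron > intergenic", {
    bundle <- mkBundle()
    pos <- grI(c(11000, 9800, 12000, 40000), c(11000, 9800, 12000, 40000))
    cls <- classifyFeature(pos, bundle)
    expect_equal(as.character(cls),
                 c("promoter", "promoter", "intron", "intergenic"))
    ## pos = TSS + 999 still inside the 2 kb promoter window
    expect_equal(as.character(classifyFeature(grI(11000, 11000), bundle)),
                 "promoter")
    ## just beyond the window, inside txA: exon/intron territory
    expect_equal(as.character(classifyFeature(grI(15100, 15100), bundle)),
                 "exon")
    expect_error(classifyFeature(grI(1, 1, "chrNA"), bundle), "chrNA")
})

test_that("island context is island > shore > beyond-shore", {
    isl <- grI(30001, 30800)
    shores <- buildShores(isl)
    ctx <- classifyIslandContext(
        grI(c(30400, 30900, 32801, 32800), c(30400, 30900, 32801, 32800)),
        isl, shores)
    expect_equal(as.character(ctx),
                 c("island", "shore", "beyond-shore", "shore"))
})

test_that("every position gets exactly one feature and one context label", {
    bundle <- mkBundle()
    set.seed(2)
    pos <- sort(sample(50000L, 300))
    gr <- grI(pos, pos)
    f <- classifyFeature(gr, bundle)
    c <- classifyIslandContext(gr, bundle@islands, bundle@shores)
    expect_false(any(is.na(f)))
    expect_false(any(is.na(c)))
})

test_that("TSS distance is signed by gene orientation with id tie-breaks", {
    gm <- geneModelSet(c("txP", "txM"), c("g1", "g2"), c("chr1", "chr1"),
                       c("+", "-"), c(10001L, 50001L), c(12000L, 52000L),
                       list(10001L, 50001L), list(12000L, 52000L))
    ## + strand TSS at 10001: upstream position gives negative distance
    d <- distanceToTss(grI(9001, 9001), gm)
    expect_equal(d$distance, -1000)
    expect_equal(d$txId, "txP")
    ## - strand TSS at 52000: smaller coordinate is downstream (positive)
    d2 <- distanceToTss(grI(51000, 51000), gm)
    expect_equal(d2$distance, 1000)
    expect_equal(d2$txId, "txM")
    ## equidistant to both TSSs: lexicographically smaller id wins
    mid <- (10001 + 52000) / 2  # 31000.5; use integer equidistant point
    gm2 <- geneModelSet(c("txB", "txA"), c("g", "g"), c("chr1", "chr1"),
                        c("+", "+"), c(1000L, 3000L), c(1500L, 3500L),
                        list(1000L, 3000L), list(1500L, 3500L))
    tie <- distanceToTss(grI(2000, 2000), gm2)
    expect_equal(tie$txId, "txA")
    expect_error(distanceToTss(grI(1, 1),
        geneModelSet(character(), character(), character(), character(),
                     integer(), integer(), list(), list())))
})

test_that("promoter CpG class follows the windowed obs/exp and GC thresholds", {
    ## GC 60%, obs/exp 0.80 in the single 500-bp window: HCP
    hcp <- paste0(strrep("CG", 36), strrep("G", 114), strrep("C", 114),
                  strrep("AT", 100))
    expect_equal(nchar(hcp), 500L)
    resH <- promoterCpGClass(hcp)
    expect_equal(resH$class, "HCP")
    expect_equal(resH$maxGC, 60)
    expect_equal(resH$maxObsExp, 0.8)
    ## all-AT: zero CpG everywhere, LCP
    expect_equal(promoterCpGClass(strrep("AT", 300))$class, "LCP")
    ## obs/exp ~0.61 at GC 50%: straddles the thresholds, ICP
    icp <- paste0(strrep("CG", 19), strrep("G", 106), strrep("C", 106),
                  strrep("AT", 125))
    expect_equal(nchar(icp), 500L)
    expect_equal(promoterCpGClass(icp)$class, "ICP")
    ## short sequences evaluated on one full-length window with a warning
    expect_warning(res <- promoterCpGClass(strrep("CG", 100)), "shorter")
    expect_equal(res$class, "HCP")
})

test_that("annotateCpGs combines all layers consistently", {
    bundle <- mkBundle()
    gr <- grI(c(30400, 11000), c(30400, 11000))
    ann <- annotateCpGs(gr, bundle)
    expect_equal(ann$islandContext, factor(c("island", "beyond-shore"),
        levels = c("island", "shore", "beyond-shore")))
    expect_equal(as.character(ann$feature[2]), "promoter")
    expect_equal(ann$distTss[2], 999)
})
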