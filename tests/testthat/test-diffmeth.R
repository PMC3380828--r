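test_that("pooled percent difference follows the summed-count formula", {
    ss <- sampleSet(c("t1", "t2"), c("c1", "c2"))
    cm <- c(t1 = 5, t2 = 10, c1 = 0, c2 = 5)
    cu <- c(t1 = 5, t2 = 0, c1 = 10, c2 = 5)
    res <- pooledPercentDifference(cm, cu, ss)
    expect_equal(res$pctTest, 75)
    expect_equal(res$pctControl, 25)
    expect_equal(res$diff, 50)
    ## identical groups: zero difference
    same <- pooledPercentDifference(c(t1 = 3, c1 = 3), c(t1 = 7, c1 = 7),
                                    sampleSet("t1", "c1"))
    expect_equal(same$diff, 0)
    ## extremes
    ext <- pooledPercentDifference(c(t1 = 10, c1 = 0), c(t1 = 0, c1 = 10),
                                   sampleSet("t1", "c1"))
    expect_equal(ext$diff, 100)
    expect_error(pooledPercentDifference(c(t1 = 0, c1 = 5),
                                         c(t1 = 0, c1 = 5),
                                         sampleSet("t1", "c1")),
                 "zero pooled coverage")
})

test_that("the logistic LRT equals the pooled G statistic on frozen cases", {
    ## equal proportions: the null is the MLE
    eq <- logisticLrtTest(8, 12, 8, 12)
    expect_equal(eq$statistic, 0)
    expect_equal(eq$p, 1)
    ## 80/20 vs 20/80: G = 2 * sum O ln(O/E) with E = 50 per cell
    res <- logisticLrtTest(80, 20, 20, 80)
    expect_equal(res$statistic, 77.0979, tolerance = 1e-5)
    expect_lt(res$p, 1e-17)
    ## label swap leaves the statistic unchanged
    swap <- logisticLrtTest(20, 80, 80, 20)
    expect_equal(swap$statistic, res$statistic)
    expect_error(logisticLrtTest(0, 0, 5, 5), "degenerate")
})

test_that("the closed-form LRT matches a glm binomial fit", {
    set.seed(21)
    for (i in 1:100) {
        m <- rpois(2, 20) + c(0, sample(0:30, 1))
        u <- rpois(2, 20) + 1
        fit1 <- stats::glm(cbind(m, u) ~ factor(c("t", "c")),
                           family = stats::binomial())
        fit0 <- stats::glm(cbind(m, u) ~ 1, family = stats::binomial())
        dev <- fit0$deviance - fit1$deviance
        mine <- logisticLrtTest(m[1], u[1], m[2], u[2])$statistic
        expect_equal(mine, dev, tolerance = 1e-8)
    }
})

test_that("DMC calling applies both thresholds and nests across cutoffs", {
    res <- data.frame(diff = c(30, 20, 30, -30), q = c(0.005, 0.005, 0.02, 0.001))
    dm <- callDmcs(res, 0.01, 25)
    expect_equal(as.character(dm$status), c("hyper", "ns", "ns", "hypo"))
    ## nesting: 40% subset of 25% subset of 10%
    set.seed(4)
    rr <- data.frame(diff = runif(500, -60, 60), q = runif(500))
    sig <- function(cut) which(callDmcs(rr, 0.05, cut)$status != "ns")
    expect_true(all(sig(40) %in% sig(25)))
    expect_true(all(sig(25) %in% sig(10)))
})

test_that("DMC set comparison reproduces inclusion-exclusion bookkeeping", {
    ## printed set sizes: |A| = 51,586, |B| = 54,592, common = 11,933
    universe <- sprintf("s%06d", seq_len(200000))
    common <- universe[1:11933]
    aOnly <- universe[11934:(11933 + 51586 - 11933)]
    bOnly <- universe[51587:(51586 + 54592 - 11933)]
    ## among common: 9,148 concordant of which 7,223 hyper
    dirA <- c(rep("hyper", 7223), rep("hypo", 1925), rep("hyper", 2785),
              rep("hyper", length(aOnly)))
    dirB <- c(rep("hyper", 7223), rep("hypo", 1925), rep("hypo", 2785),
              rep("hypo", length(bOnly)))
    A <- data.frame(key = c(common, aOnly), status = dirA)
    B <- data.frame(key = c(common, bOnly), status = dirB)
    ov <- compareDmcSets(A, B, universe)
    expect_equal(ov$union, 94245)
    expect_equal(ov$uniqueA + ov$uniqueB, 82312)
    expect_equal(round(ov$pctUnique, 1), 87.3)
    ## 9148/11933 = 76.66%, i.e. 76.6 at the table's printed precision
    expect_lt(abs(ov$pctConcordant - 76.6), 0.1)
    expect_equal(round(ov$pctConcordantHyper), 79)
    ## toy cases
    toy <- compareDmcSets(data.frame(key = "s1", status = "hyper"),
                          data.frame(key = "s2", status = "hyper"),
                          c("s1", "s2"))
    expect_equal(toy$common, 0L)
    expect_equal(toy$uniqueA + toy$uniqueB, 2L)
    same <- compareDmcSets(A, A, universe)
    expect_equal(same$pctUnique, 0)
    expect_equal(same$pctConcordant, 100)
    expect_error(compareDmcSets(A, B, universe[1:10]), "absent")
})

test_that("clustering distances behave at the correlation extremes", {
    m <- cbind(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1), c = c(1.1, 2, 3.2, 4))
    cl <- sampleClustering(m)
    expect_equal(cl$correlation["a", "a"], 1)
    expect_equal(1 - cl$correlation["a", "b"], 2)   # anti-correlated pair
    expect_equal(dim(cl$pca), c(3L, 3L))
    expect_error(sampleClustering(cbind(a = rep(1, 4), b = 1:4)),
                 "zero-variance")
})

test_that("region-level clustering averages only regions with enough CpGs", {
    m <- matrix(c(0, 10, 20, 90, 100, 95,
                  2, 12, 22, 88, 98, 93), ncol = 2,
                dimnames = list(paste0("chr1:", c(100, 110, 120, 5000, 5010,
                                                  9000)), c("s1", "s2")))
    regions <- grI(c(90, 4990, 8990), c(130, 5020, 9010))
    cl <- sampleClustering(m, regions = regions, minCpgs = 2L)
    expect_equal(cl$correlation["s1", "s2"], 1, tolerance = 1e-3)
    expect_error(sampleClustering(m, regions = regions, minCpgs = 5L),
                 "fewer than two regions")
})

test_that("diffMethTest pools counts over the shared universe", {
    t1 <- MethylomeTable("chr1", c(10L, 20L, 30L), c(10L, 0L, 10L),
                         c(0L, 10L, 10L), "t1")
    t2 <- MethylomeTable("chr1", c(10L, 20L), c(8L, 2L), c(2L, 8L), "t2")
    c1 <- MethylomeTable("chr1", c(10L, 20L, 40L), c(0L, 1L, 5L),
                         c(10L, 9L, 5L), "c1")
    c2 <- MethylomeTable("chr1", c(10L, 20L), c(1L, 0L), c(9L, 10L), "c2")
    res <- suppressMessages(diffMethTest(
        list(t1 = t1, t2 = t2, c1 = c1, c2 = c2),
        sampleSet(c("t1", "t2"), c("c1", "c2")), minCoverage = 10L))
    expect_equal(res$key, c("chr1:10", "chr1:20"))
    expect_equal(res$methTest, c(18, 2))
    expect_equal(res$pctTest, c(90, 10))
    expect_equal(res$pctControl, c(5, 5))
    expect_equal(res$diff, c(85, 5))
    ## q-values share the order of p-values
    expect_equal(order(res$q), order(res$p))
})
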