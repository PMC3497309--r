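test_that("rpkm matches its closed form and scale properties", {
    expect_equal(rpkm(0, 1e6, 1000), 0)
    expect_equal(rpkm(1000, 1e6, 1000), 1000)
    ## doubling count and library total together leaves RPKM unchanged
    expect_equal(rpkm(500, 5e5, 700), rpkm(1000, 1e6, 700))
    ## linearity in the count
    expect_equal(rpkm(37, 2e6, 1500), 37 * rpkm(1, 2e6, 1500))
    expect_error(rpkm(1, 0, 100), "positive")
    expect_error(rpkm(1, 1e6, 0), "positive")
})

test_that("log2 fold change applies the 0.001 zero substitution", {
    expect_equal(log2FoldChange(1, 1), 0)
    expect_equal(log2FoldChange(1.024, 0), 10)
    expect_equal(log2FoldChange(0, 1.024), -10)
    expect_equal(log2FoldChange(0, 0), 0)
    expect_error(log2FoldChange(-1, 1), "non-negative")
})

test_that("exact test handles the forced small cases", {
    ## x = y = 0, equal totals: P(0|0) = 1/2, doubled and capped to 1
    expect_equal(audicClaveriePValue(0, 0, 1e6, 1e6, tail = "lower"), 0.5)
    expect_equal(audicClaveriePValue(0, 0, 1e6, 1e6), 1)
    ## any tail-based p-value is a probability
    p <- audicClaveriePValue(c(0, 3, 50, 7), c(9, 3, 2, 700),
                             c(1e6, 1e6, 1e3, 2e6), c(1e6, 2e6, 1e6, 1e6))
    expect_true(all(p >= 0 & p <= 1))
})

test_that("exact test conditional mass normalizes to 1", {
    for (r in c(0.5, 1, 3)) {
        x <- 7; N1 <- 1e6; N2 <- r * 1e6
        s <- ploidyDGE:::.acLogPmf(0:4000, x, log(N2 / N1), log1p(N2 / N1))
        expect_equal(sum(exp(s)), 1, tolerance = 1e-12)
    }
})

test_that("exact test tails agree with the negative-binomial oracle", {
    ## spot grid here; the full [0,50]^2 sweep runs in the acceptance suite
    for (N in list(c(1e3, 1e6), c(1e6, 1e3), c(1e6, 1e6))) {
        for (x in c(0, 3, 17, 50)) for (y in c(0, 5, 23, 50)) {
            mine <- ploidyDGE:::.acTails(x, y, N[1], N[2])
            orc <- acOracleTails(x, y, N[1], N[2])
            for (side in c("lower", "upper")) {
                if (orc[[side]] > 1e-290) {
                    expect_lt(abs(mine[[side]] - orc[[side]]) / orc[[side]],
                              1e-10)
                } else {
                    expect_lt(mine[[side]], 1e-280)
                }
            }
        }
    }
})

test_that("exact test never overflows at deep counts", {
    p <- audicClaveriePValue(1e7, 1e7, 5e7, 5e7)
    expect_true(is.finite(p) && p > 0.9)
    p2 <- audicClaveriePValue(1e7, 1.01e7, 5e7, 5e7)
    expect_true(is.finite(p2) && p2 < 1e-100)
})

test_that("swapping libraries and counts together preserves significance order", {
    ## the doubled-tail construction is not exactly exchangeable (the mass
    ## conditions on x), but swapped p-values stay within a factor 2 and
    ## rank the same way
    set.seed(42)
    x <- rpois(50, 40); y <- rpois(50, 80)
    p1 <- audicClaveriePValue(x, y, 1e6, 2e6)
    p2 <- audicClaveriePValue(y, x, 2e6, 1e6)
    expect_true(all(pmax(p1, p2) / pmin(p1, p2) <= 2 + 1e-12))
    expect_gt(cor(rank(p1), rank(p2)), 0.95)
})

test_that("BH step-up matches hand computation and p.adjust", {
    expect_equal(bhFDR(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
    expect_equal(bhFDR(0.37), 0.37)
    expect_equal(bhFDR(rep(0.2, 5)), rep(0.2, 5))
    set.seed(7)
    p <- runif(200)^2
    expect_equal(bhFDR(p), p.adjust(p, method = "BH"))
    ## order preservation
    expect_true(all(diff(bhFDR(sort(p))) >= 0))
    expect_error(bhFDR(c(0.5, 1.2)), "0, 1")
})

test_that("DEU calling is null-safe and monotone in its thresholds", {
    tbl <- tinyCounts(x = c(100, 50, 0, 400), y = c(100, 50, 0, 400))
    de <- callDEUs(tbl)
    expect_equal(sum(de$is_deu), 0)
    expect_true(all(de$direction == "none"))
    ## unexpressed rows are excluded from the FDR family
    expect_true(is.na(de$fdr[3]))

    sim <- simulateCounts(simConfig(nUnigenes = 3000, deFraction = 0.1,
                                    effectLog2 = 3, seed = 5))
    loose <- callDEUs(sim$counts, fdrMax = 0.01)
    strict <- callDEUs(sim$counts, fdrMax = 0.0001)
    expect_lte(sum(strict$is_deu), sum(loose$is_deu))
    lfcStrict <- callDEUs(sim$counts, lfcMin = 2)
    expect_lte(sum(lfcStrict$is_deu), sum(callDEUs(sim$counts)$is_deu))
    ## up/down partition is exhaustive and disjoint
    de2 <- callDEUs(sim$counts)
    expect_equal(sum(de2$direction == "up") + sum(de2$direction == "down"),
                 sum(de2$is_deu))
    s <- deuSummary(de2)
    expect_equal(s$n_up + s$n_down, sum(de2$is_deu))
})

test_that("planted effects are recovered with controlled false discoveries", {
    sim <- simulateCounts(simConfig(nUnigenes = 5000, deFraction = 0.1,
                                    effectLog2 = 3, seed = 19))
    de <- callDEUs(sim$counts)
    truth <- sim$truth
    expect_gte(mean(de$is_deu[truth$is_de]), 0.9)
    expect_lte(mean(!truth$is_de[de$is_deu]), 0.01)
    ## called direction matches the planted sign
    called <- de$is_deu & truth$is_de
    expect_true(all(sign(de$log2fc[called]) ==
                        sign(truth$true_log2fc[called])))
})
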