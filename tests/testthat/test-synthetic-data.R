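test_that("simConfig validates its stated world", {
    expect_error(simConfig(libSize1 = 0), "positive")
    expect_error(simConfig(deFraction = 1.2), "\\[0, 1\\]")
    expect_error(simConfig(lengthRange = c(50, 200)), "100")
    expect_error(simConfig(dispersion = -1), "non-negative")
})

test_that("count simulation is deterministic and honors the null", {
    cfg <- simConfig(nUnigenes = 500, deFraction = 0, seed = 4)
    a <- simulateCounts(cfg)
    b <- simulateCounts(cfg)
    expect_identical(SummarizedExperiment::assay(a$counts, "counts"),
                     SummarizedExperiment::assay(b$counts, "counts"))
    expect_identical(a$truth, b$truth)
    expect_true(validObject(a$counts))
    ## no planted effects: truth is all-null
    expect_false(any(a$truth$is_de))
    expect_true(all(a$truth$true_log2fc == 0))
    ## equal libraries, no effect: aggregate count ratio near 1
    cnt <- SummarizedExperiment::assay(a$counts, "counts")
    expect_equal(sum(cnt[, 2]) / sum(cnt[, 1]), 1, tolerance = 0.01)
})

test_that("planted genes land on their stated log2 effect", {
    ## Monte-Carlo check: deep counts, 1000 planted genes at |lfc| = 2
    cfg <- simConfig(nUnigenes = 2000, deFraction = 0.5, effectLog2 = 2,
                     libSize1 = 2e7, libSize2 = 2e7, abundanceSdLog = 0.3,
                     seed = 6)
    sim <- simulateCounts(cfg)
    cnt <- SummarizedExperiment::assay(sim$counts, "counts")
    de <- sim$truth$is_de
    expect_equal(sum(de), 1000)
    obs <- log2(cnt[de, 2] / cnt[de, 1])
    expect_true(all(abs(obs - sim$truth$true_log2fc[de]) < 0.2))
    ## effects split half up / half down
    expect_equal(sum(sim$truth$true_log2fc > 0),
                 sum(sim$truth$true_log2fc < 0))
    ## truth invariant: |lfc| = effect exactly where flagged
    expect_true(all(abs(sim$truth$true_log2fc[de]) == 2))
})

test_that("dispersion switches the count law from Poisson to NB", {
    cfgP <- simConfig(nUnigenes = 4000, deFraction = 0, seed = 8,
                      abundanceSdLog = 0)
    cfgN <- simConfig(nUnigenes = 4000, deFraction = 0, seed = 8,
                      abundanceSdLog = 0, dispersion = 0.5)
    cntP <- SummarizedExperiment::assay(simulateCounts(cfgP)$counts, "counts")
    cntN <- SummarizedExperiment::assay(simulateCounts(cfgN)$counts, "counts")
    mu <- mean(cntP[, 1])
    ## Poisson: variance ~ mean; NB: variance ~ mu + 0.5 mu^2
    expect_equal(var(cntP[, 1]), mu, tolerance = 0.1)
    expect_equal(var(cntN[, 1]), mu + 0.5 * mu^2, tolerance = 0.15)
})

test_that("simulated FASTQ hits its N and low-quality rates", {
    reads <- simulateFastq(10000, readLen = 50, nRate = 0.02,
                           lowqRate = 0.1, seed = 13)
    total <- sum(Biostrings::width(reads))
    nFrac <- sum(Biostrings::letterFrequency(reads, "N")) / total
    ## binomial 3-SD bound around the configured rate
    expect_lt(abs(nFrac - 0.02), 3 * sqrt(0.02 * 0.98 / total))
    quals <- as(Biostrings::quality(reads), "IntegerList")
    lowFrac <- sum(sum(quals <= 10)) / total
    ## N bases are also low quality, so the floor is nRate + lowqRate terms
    expected <- 0.02 + 0.98 * 0.1
    expect_lt(abs(lowFrac - expected), 3 * sqrt(expected / total))
    ## determinism
    again <- simulateFastq(10000, readLen = 50, nRate = 0.02,
                           lowqRate = 0.1, seed = 13)
    expect_equal(as.character(reads), as.character(again))
    ## clean input survives the downstream filter entirely
    clean <- simulateFastq(200, nRate = 0, lowqRate = 0, seed = 1)
    expect_equal(filterReads(clean)$stats$removed, 0)
    ## saturated N input is removed entirely
    allN <- simulateFastq(50, nRate = 1, lowqRate = 0, seed = 1)
    expect_equal(filterReads(allN)$stats$kept, 0)
    expect_error(simulateFastq(10, readLen = 0), "positive")
})

test_that("annotation simulation plants enrichment at the stated odds", {
    truth <- data.frame(unigene_id = sprintf("U%04d", 1:2000),
                        is_de = rep(c(TRUE, FALSE), c(200, 1800)))
    ann <- simulateAnnotation(truth, nTerms = 30, enrichmentOdds = 20,
                              seed = 17)
    expect_length(ann$enrichedTerms, 3)
    ## planted terms contain DE unigenes far above the background rate
    for (tid in ann$enrichedTerms) {
        members <- ann$annotation$unigene_id[ann$annotation$term_id == tid]
        deRate <- mean(members %in% truth$unigene_id[truth$is_de])
        expect_gt(deRate, 0.3)   # background would be ~0.1
    }
    ## no enrichment without odds
    ann1 <- simulateAnnotation(truth, nTerms = 30, enrichmentOdds = 1,
                               seed = 17)
    expect_length(ann1$enrichedTerms, 0)
    expect_error(simulateAnnotation(truth, enrichmentOdds = 0), "positive")
    ## zero DE unigenes: every enrichment p is 1 (m = 0 everywhere)
    truth0 <- truth; truth0$is_de <- FALSE
    ann0 <- simulateAnnotation(truth0, nTerms = 10, seed = 2)
    res <- enrichTerms(character(0), ann0$annotation)
    expect_true(all(res$p_value == 1))
})

test_that("Ct simulation round-trips and validates", {
    ct <- simulateCt(c(g1 = 2, g2 = 1), ctNoiseSd = 0, seed = 21)
    ## two reference genes, both samples, all replicates
    expect_setequal(unique(ct$gene_id[ct$is_reference]),
                    c("18S_rRNA", "alpha_tubulin"))
    expect_equal(ddctFoldChange(ct)$fold, c(2, 1))
    expect_error(simulateCt(c(g = -1)), "positive")
    expect_error(simulateCt(c(g = 1), nReplicates = 0), "at least 1")
    ## determinism
    expect_identical(simulateCt(c(a = 3), ctNoiseSd = 0.2, seed = 5),
                     simulateCt(c(a = 3), ctNoiseSd = 0.2, seed = 5))
})

test_that("phenotype simulation converges on the configured means", {
    tp <- table1TraitParams()
    pheno <- simulatePhenotypes(tp, nPerGroup = 200, seed = 29)
    agg <- aggregate(value ~ family + ploidy + trait, pheno, mean)
    m <- merge(agg, tp, by = c("family", "ploidy", "trait"))
    ## sample means within 4 SEs of the configured means
    expect_true(all(abs(m$value - m$mean) <= 4 * m$sd / sqrt(200) + 1e-9))
    ## degenerate noise
    tp0 <- tp; tp0$sd <- 0
    p0 <- simulatePhenotypes(tp0, nPerGroup = 3, seed = 1)
    agg0 <- aggregate(value ~ family + ploidy + trait, p0,
                      function(v) diff(range(v)))
    expect_true(all(agg0$value == 0))
    expect_error(simulatePhenotypes(tp[, -4], nPerGroup = 3), "columns")
})
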