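#' Simulation configuration for two-library count tables
#'
#' Captures the stated world of a diploid/autotetraploid digital gene
#' expression experiment: number of unigenes, the fraction carrying a
#' planted expression effect, the planted |log2 fold change|, the two
#' library totals (total clean reads, the `N1`/`N2` the exact test
#' conditions on), the unigene length range, and the count dispersion.
#'
#' Counts are Poisson when `dispersion = 0` (the sampling model the exact
#' test assumes, and the default used for calibration) and negative
#' binomial with variance `mu + dispersion * mu^2` otherwise. Only a
#' fraction of clean reads maps to unigenes (`mappedFraction`), so mapped
#' column sums stay below the library totals. Relative unigene abundances
#' are log-normal with `abundanceSdLog` on the log scale.
#'
#' @param nUnigenes number of unigenes (default 10000).
#' @param deFraction fraction of unigenes with a planted effect, in
#'   \[0, 1\] (default 0.1).
#' @param effectLog2 planted |log2 fold change|, applied half up / half
#'   down (default 2).
#' @param libSize1,libSize2 total clean reads per library (default 5e6).
#' @param lengthRange integer pair, uniform unigene length range in nt
#'   (default c(200, 3000); minimum allowed 100).
#' @param dispersion negative-binomial dispersion; 0 = Poisson (default 0).
#' @param mappedFraction fraction of clean reads mapping to unigenes
#'   (default 0.7).
#' @param abundanceSdLog log-scale SD of relative abundances (default 1).
#' @param seed integer seed.
#' @return a validated `simConfig` list.
#' @export
simConfig <- function(nUnigenes = 10000L, deFraction = 0.1, effectLog2 = 2,
                      libSize1 = 5e6, libSize2 = 5e6,
                      lengthRange = c(200L, 3000L), dispersion = 0,
                      mappedFraction = 0.7, abundanceSdLog = 1, seed = 1L) {
    cfg <- list(nUnigenes = as.integer(nUnigenes), deFraction = deFraction,
                effectLog2 = effectLog2, libSize1 = libSize1,
                libSize2 = libSize2, lengthRange = as.integer(lengthRange),
                dispersion = dispersion, mappedFraction = mappedFraction,
                abundanceSdLog = abundanceSdLog, seed = as.integer(seed))
    if (cfg$nUnigenes < 1) stop("nUnigenes must be positive")
    if (cfg$deFraction < 0 || cfg$deFraction > 1)
        stop("deFraction must lie in [0, 1]")
    if (cfg$effectLog2 < 0) stop("effectLog2 must be non-negative")
    if (cfg$libSize1 <= 0 || cfg$libSize2 <= 0)
        stop("library sizes must be positive")
    if (length(cfg$lengthRange) != 2L || cfg$lengthRange[1] < 100L ||
        cfg$lengthRange[2] < cfg$lengthRange[1])
        stop("lengthRange must be an increasing pair with minimum >= 100")
    if (cfg$dispersion < 0) stop("dispersion must be non-negative")
    if (cfg$mappedFraction <= 0 || cfg$mappedFraction > 1)
        stop("mappedFraction must lie in (0, 1]")
    class(cfg) <- "simConfig"
    cfg
}

#' Simulate a two-library count table with known truth
#'
#' Draws unigene lengths uniformly over the configured range, log-normal
#' relative abundances, plants `round(deFraction * nUnigenes)` effects of
#' size `effectLog2` (alternating up/down), and samples counts so that a
#' null unigene's expected normalized ratio between libraries is exactly 1
#' and a planted unigene's is exactly `2^(+-effectLog2)`.
#'
#' @param config a [simConfig()].
#' @return list with `counts` (a [DGECounts]) and `truth` (a `data.frame`
#'   with `unigene_id`, `is_de`, `true_log2fc`).
#' @examples
#' sim <- simulateCounts(simConfig(nUnigenes = 100, seed = 7))
#' table(sim$truth$is_de)
#' @export
simulateCounts <- function(config = simConfig()) {
    stopifnot(inherits(config, "simConfig"))
    set.seed(config$seed)
    n <- config$nUnigenes
    len <- sample(seq(config$lengthRange[1], config$lengthRange[2]), n,
                  replace = TRUE)
    w <- stats::rlnorm(n, meanlog = 0, sdlog = config$abundanceSdLog)
    nDE <- round(config$deFraction * n)
    trueLfc <- numeric(n)
    if (nDE > 0) {
        deIdx <- sample.int(n, nDE)
        trueLfc[deIdx] <- rep_len(c(1, -1), nDE) * config$effectLog2
    }
    ## planted effects inflate library 2's expected mapped total by
    ## sum(w 2^lfc)/sum(w); rescale both libraries by a common factor when
    ## needed so mapped sums stay below the stated totals. A common factor
    ## cancels in every normalized ratio, so planted and null effects are
    ## untouched.
    inflate <- sum(w * 2^trueLfc) / sum(w)
    mEff <- min(config$mappedFraction, 0.92 / inflate)
    mu1 <- mEff * config$libSize1 * w / sum(w)
    mu2 <- mu1 * (config$libSize2 / config$libSize1) * 2^trueLfc
    if (config$dispersion == 0) {
        x <- stats::rpois(n, mu1)
        y <- stats::rpois(n, mu2)
    } else {
        size <- 1 / config$dispersion
        x <- stats::rnbinom(n, mu = mu1, size = size)
        y <- stats::rnbinom(n, mu = mu2, size = size)
    }
    ids <- sprintf("Unigene%05d", seq_len(n))
    counts <- DGECounts(cbind(diploid = x, tetraploid = y),
                        lengthNt = len,
                        libSizes = c(config$libSize1, config$libSize2),
                        unigeneIds = ids)
    truth <- data.frame(unigene_id = ids, is_de = trueLfc != 0,
                        true_log2fc = trueLfc, stringsAsFactors = FALSE)
    list(counts = counts, truth = truth)
}

## integer Phred vector -> quality string at a given offset
.qualString <- function(q, phredOffset) {
    rawToChar(as.raw(q + phredOffset))
}

#' Simulate FASTQ reads with controllable N content and quality
#'
#' Generates `nReads` reads of length `readLen`. Each base is replaced by
#' `N` independently with probability `nRate`; each base's quality is drawn
#' from the low range (2..10, i.e. Q <= 10) with probability `lowqRate` and
#' from the high range (30..40) otherwise. N bases always get quality 2.
#'
#' @param nReads,readLen positive integers.
#' @param nRate,lowqRate per-base probabilities in \[0, 1\].
#' @param seed integer seed.
#' @return a [Biostrings::QualityScaledDNAStringSet] (Phred qualities).
#' @export
simulateFastq <- function(nReads, readLen = 90L, nRate = 0, lowqRate = 0,
                          seed = 1L) {
    if (nReads < 1) stop("nReads must be positive")
    if (readLen < 1) stop("readLen must be positive")
    if (nRate < 0 || nRate > 1 || lowqRate < 0 || lowqRate > 1)
        stop("rates must lie in [0, 1]")
    set.seed(seed)
    total <- nReads * readLen
    bases <- sample(c("A", "C", "G", "T"), total, replace = TRUE)
    isN <- stats::runif(total) < nRate
    bases[isN] <- "N"
    quals <- ifelse(stats::runif(total) < lowqRate,
                    sample(2:10, total, replace = TRUE),
                    sample(30:40, total, replace = TRUE))
    quals[isN] <- 2L
    bmat <- matrix(bases, nrow = nReads, byrow = TRUE)
    qmat <- matrix(quals, nrow = nReads, byrow = TRUE)
    seqs <- apply(bmat, 1, paste0, collapse = "")
    qstr <- apply(qmat, 1, .qualString, phredOffset = 33L)
    dna <- Biostrings::DNAStringSet(seqs)
    names(dna) <- sprintf("read%06d", seq_len(nReads))
    Biostrings::QualityScaledDNAStringSet(dna, Biostrings::PhredQuality(qstr))
}

#' Simulate a unigene-to-term annotation map with planted enrichment
#'
#' Assigns terms to unigenes independently. Every term has a baseline
#' membership probability (drawn once per term); for the `nEnriched`
#' planted terms, membership odds for unigenes flagged as differentially
#' expressed in `truth` are multiplied by `enrichmentOdds`.
#'
#' @param truth the truth `data.frame` from [simulateCounts()] (columns
#'   `unigene_id`, `is_de`).
#' @param nTerms number of terms (default 50); must be at least
#'   `nEnriched`.
#' @param enrichmentOdds odds multiplier for DE membership in planted
#'   terms (default 1 = no enrichment).
#' @param nEnriched number of planted enriched terms (default 3; 0 if
#'   `enrichmentOdds == 1`).
#' @param termSizeRange expected term size range as a fraction of the
#'   universe (default c(0.01, 0.05)).
#' @param seed integer seed.
#' @return list with `annotation` (`data.frame` of `unigene_id`,
#'   `term_id`) and `enrichedTerms` (character vector of planted term
#'   ids, empty when `enrichmentOdds == 1`).
#' @export
simulateAnnotation <- function(truth, nTerms = 50L, enrichmentOdds = 1,
                               nEnriched = if (enrichmentOdds == 1) 0L else 3L,
                               termSizeRange = c(0.01, 0.05), seed = 1L) {
    if (enrichmentOdds <= 0) stop("enrichmentOdds must be positive")
    if (nTerms < nEnriched) stop("nTerms must be at least nEnriched")
    set.seed(seed)
    ids <- truth$unigene_id
    isDE <- truth$is_de
    n <- length(ids)
    termIds <- sprintf("TERM:%04d", seq_len(nTerms))
    enriched <- if (nEnriched > 0) termIds[seq_len(nEnriched)] else character(0)
    p0 <- stats::runif(nTerms, termSizeRange[1], termSizeRange[2])
    rows <- vector("list", nTerms)
    for (j in seq_len(nTerms)) {
        p <- rep(p0[j], n)
        if (termIds[j] %in% enriched) {
            odds <- enrichmentOdds * p0[j] / (1 - p0[j])
            p[isDE] <- odds / (1 + odds)
        }
        member <- stats::runif(n) < p
        if (any(member))
            rows[[j]] <- data.frame(unigene_id = ids[member],
                                    term_id = termIds[j],
                                    stringsAsFactors = FALSE)
    }
    list(annotation = do.call(rbind, rows), enrichedTerms = enriched)
}

#' Simulate a qPCR Ct table from true expression ratios
#'
#' Builds quantification-cycle values whose noiseless 2^-ddCt recovery
#' returns exactly the supplied tetraploid/diploid ratios. Two reference
#' genes (`18S_rRNA`, `alpha_tubulin`) with ratio 1 are always included.
#' Target baselines (diploid Ct) are drawn uniformly in 20..30; the
#' tetraploid Ct is lowered by log2(ratio); independent Gaussian noise of
#' SD `ctNoiseSd` is added to every well.
#'
#' @param trueRatios named positive numeric vector of tetraploid/diploid
#'   expression ratios, one per target gene.
#' @param nReplicates biological replicates per sample (default 3).
#' @param ctNoiseSd per-well Ct noise SD (default 0).
#' @param seed integer seed.
#' @return `data.frame` with `gene_id`, `sample` (`diploid`/`tetraploid`),
#'   `replicate`, `ct`, `is_reference`.
#' @export
simulateCt <- function(trueRatios, nReplicates = 3L, ctNoiseSd = 0,
                       seed = 1L) {
    if (any(trueRatios <= 0)) stop("trueRatios must be positive")
    if (nReplicates < 1) stop("nReplicates must be at least 1")
    if (ctNoiseSd < 0) stop("ctNoiseSd must be non-negative")
    set.seed(seed)
    genes <- names(trueRatios)
    if (is.null(genes)) genes <- sprintf("gene%02d", seq_along(trueRatios))
    refs <- c(`18S_rRNA` = 15, alpha_tubulin = 25)
    baseDip <- stats::runif(length(trueRatios), 20, 30)
    ctOf <- function(gene_id, base, shift, is_ref) {
        expand <- expand.grid(sample = c("diploid", "tetraploid"),
                              replicate = seq_len(nReplicates),
                              stringsAsFactors = FALSE)
        ct <- base + ifelse(expand$sample == "tetraploid", shift, 0)
        data.frame(gene_id = gene_id, sample = expand$sample,
                   replicate = expand$replicate, ct = ct,
                   is_reference = is_ref, stringsAsFactors = FALSE)
    }
    out <- c(
        lapply(seq_along(refs), function(i)
            ctOf(names(refs)[i], refs[i], 0, TRUE)),
        lapply(seq_along(trueRatios), function(i)
            ctOf(genes[i], baseDip[i], -log2(trueRatios[i]), FALSE)))
    tab <- do.call(rbind, out)
    if (ctNoiseSd > 0)
        tab$ct <- tab$ct + stats::rnorm(nrow(tab), 0, ctNoiseSd)
    rownames(tab) <- NULL
    tab
}

#' Simulate per-tree phenotype measurements
#'
#' Gaussian samples per family x ploidy x trait cell, using a parameter
#' table of group means and SDs (default: the packaged birch field-trial
#' fixture, [table1TraitParams()]). Draws are floored at a small positive
#' value since all traits are physical sizes.
#'
#' @param familyParams `data.frame` with columns `family`, `ploidy`,
#'   `trait`, `mean`, `sd`.
#' @param nPerGroup trees per family x ploidy cell (default 30, the
#'   per-family sampling depth of the field trial).
#' @param seed integer seed.
#' @return `data.frame` with `tree_id`, `family`, `ploidy`, `trait`,
#'   `value`.
#' @export
simulatePhenotypes <- function(familyParams = table1TraitParams(),
                               nPerGroup = 30L, seed = 1L) {
    req <- c("family", "ploidy", "trait", "mean", "sd")
    if (!all(req %in% names(familyParams)))
        stop("familyParams needs columns: ", paste(req, collapse = ", "))
    if (any(familyParams$sd < 0)) stop("SDs must be non-negative")
    if (nPerGroup < 1) stop("nPerGroup must be positive")
    set.seed(seed)
    out <- lapply(seq_len(nrow(familyParams)), function(i) {
        p <- familyParams[i, ]
        v <- stats::rnorm(nPerGroup, p$mean, p$sd)
        data.frame(
            tree_id = sprintf("%s_%s_%02d", p$family, substr(p$ploidy, 1, 3),
                              seq_len(nPerGroup)),
            family = p$family, ploidy = p$ploidy, trait = p$trait,
            value = pmax(v, 0.001), stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}
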