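#' Pipeline configuration
#'
#' Gathers every stage threshold (with the study's defaults), the stage
#' toggles, and the single global seed from which per-stage seeds are
#' derived (fixed additive derivation, so any stage can be rerun
#' independently yet reproducibly).
#'
#' @param seed global integer seed.
#' @param sim a [simConfig()] for the synthetic inputs (its own seed is
#'   overridden by the derived stage seed).
#' @param doQc,doDe,doEnrich,doQpcr,doPheno stage toggles.
#' @param maxNPct,lowqQ,maxLowqPct read-filter thresholds.
#' @param fdrMax,lfcMin differential-expression thresholds.
#' @param alphaEnrich enrichment threshold on the corrected p-value.
#' @param alphaPheno phenotype-test threshold.
#' @param enrichmentOdds,nTerms planted-annotation parameters.
#' @param nQpcrGenes number of DEUs carried into qPCR verification
#'   (default 17).
#' @param ctNoiseSd,nCtReplicates qPCR simulation parameters.
#' @param nTreesPerGroup phenotype simulation depth.
#' @return a `pipelineConfig` list.
#' @export
pipelineConfig <- function(seed = 1L, sim = simConfig(),
                           doQc = TRUE, doDe = TRUE, doEnrich = TRUE,
                           doQpcr = TRUE, doPheno = TRUE,
                           maxNPct = 5, lowqQ = 10L, maxLowqPct = 20,
                           fdrMax = 0.001, lfcMin = 1,
                           alphaEnrich = 0.05, alphaPheno = 0.01,
                           enrichmentOdds = 20, nTerms = 50L,
                           nQpcrGenes = 17L, ctNoiseSd = 0.1,
                           nCtReplicates = 3L, nTreesPerGroup = 30L) {
    cfg <- as.list(environment())
    stopifnot(inherits(sim, "simConfig"),
              fdrMax > 0, fdrMax <= 1, lfcMin >= 0,
              alphaEnrich > 0, alphaEnrich <= 1,
              alphaPheno > 0, alphaPheno <= 1)
    class(cfg) <- "pipelineConfig"
    cfg
}

## fixed fan-out of the global seed to per-stage seeds (kept below 2^31)
.stageSeed <- function(seed, stage) {
    offsets <- c(fastq = 1L, counts = 2L, annotation = 3L, ct = 4L,
                 phenotype = 5L)
    (abs(as.integer(seed)) + 7919L * offsets[[stage]]) %% 2147483587L
}

#' Run the full pipeline on synthetic inputs
#'
#' Generates every input with known ground truth, then runs read QC,
#' differential-expression calling, term enrichment, qPCR verification and
#' the phenotype comparison, writing one TSV per stage plus a JSON run
#' manifest recording thresholds, seeds and stage summary counts.
#'
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created if needed); `NULL` keeps
#'   everything in memory and writes nothing.
#' @param nReads reads in the synthetic FASTQ exercise (default 2000).
#' @return (invisibly) a list with the stage results and `manifest`.
#' @export
runPipeline <- function(config = pipelineConfig(), outDir = NULL,
                        nReads = 2000L) {
    stopifnot(inherits(config, "pipelineConfig"))
    res <- list()
    manifest <- list(
        package = "ploidyDGE",
        version = as.character(utils::packageVersion("ploidyDGE")),
        timestamp = format(Sys.time(), tz = "UTC"),
        seed = config$seed,
        thresholds = config[c("maxNPct", "lowqQ", "maxLowqPct", "fdrMax",
                              "lfcMin", "alphaEnrich", "alphaPheno")],
        stages = list())
    writeOut <- !is.null(outDir)
    if (writeOut) dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

    if (config$doQc) {
        reads <- simulateFastq(nReads, nRate = 0.02, lowqRate = 0.05,
                               seed = .stageSeed(config$seed, "fastq"))
        flt <- filterReads(reads, config$maxNPct, config$lowqQ,
                           config$maxLowqPct)
        res$qc <- list(summary = librarySummary(flt$kept),
                       filter = flt$stats)
        manifest$stages$qc <- flt$stats
        if (writeOut) {
            writeFastqFile(flt$kept, file.path(outDir, "clean_reads.fastq"))
            writeStageTable(res$qc$summary,
                            file.path(outDir, "library_summary.tsv"))
        }
    }

    simCfg <- config$sim
    simCfg$seed <- .stageSeed(config$seed, "counts")
    sim <- simulateCounts(simCfg)
    res$counts <- sim$counts
    res$truth <- sim$truth
    if (writeOut) {
        writeCountTable(sim$counts, file.path(outDir, "count_table.tsv"))
        writeStageTable(sim$truth, file.path(outDir, "truth.tsv"))
    }

    deus <- character(0)
    if (config$doDe) {
        res$de <- callDEUs(sim$counts, fdrMax = config$fdrMax,
                           lfcMin = config$lfcMin)
        s <- deuSummary(res$de)
        manifest$stages$de <- s[c("n", "n_up", "n_down")]
        deus <- res$de$unigene_id[res$de$is_deu]
        if (writeOut)
            writeStageTable(res$de, file.path(outDir, "de_results.tsv"))
    }

    if (config$doEnrich && config$doDe) {
        ann <- simulateAnnotation(sim$truth, nTerms = config$nTerms,
                                  enrichmentOdds = config$enrichmentOdds,
                                  seed = .stageSeed(config$seed, "annotation"))
        res$enrichment <- enrichTerms(deus, ann$annotation,
                                      alpha = config$alphaEnrich)
        res$enrichedTermsTruth <- ann$enrichedTerms
        manifest$stages$enrichment <- list(
            n_terms = nrow(res$enrichment),
            n_significant = sum(res$enrichment$significant))
        if (writeOut)
            writeStageTable(res$enrichment,
                            file.path(outDir, "enrichment.tsv"))
    }

    if (config$doQpcr && config$doDe) {
        deuTruth <- sim$truth[sim$truth$unigene_id %in% deus, ]
        k <- min(config$nQpcrGenes, nrow(deuTruth))
        if (k >= 3) {
            pick <- deuTruth[seq_len(k), ]
            ratios <- stats::setNames(2^pick$true_log2fc, pick$unigene_id)
            ct <- simulateCt(ratios, nReplicates = config$nCtReplicates,
                             ctNoiseSd = config$ctNoiseSd,
                             seed = .stageSeed(config$seed, "ct"))
            est <- ddctFoldChange(ct)
            rnaseq <- res$de$log2fc[match(est$gene_id, res$de$unigene_id)]
            res$qpcr <- list(estimates = est,
                             concordance = concordance(est$log2fc_qpcr,
                                                       rnaseq))
            manifest$stages$qpcr <- res$qpcr$concordance
            if (writeOut)
                writeStageTable(est, file.path(outDir, "qpcr_folds.tsv"))
        }
    }

    if (config$doPheno) {
        pheno <- simulatePhenotypes(nPerGroup = config$nTreesPerGroup,
                                    seed = .stageSeed(config$seed,
                                                      "phenotype"))
        res$phenoSummary <- summarizeGroups(pheno, alpha = config$alphaPheno)
        traits <- unique(res$phenoSummary$trait)
        res$percentDifferences <- stats::setNames(
            vapply(traits, function(tr)
                percentDifference(res$phenoSummary, tr), numeric(1)),
            traits)
        manifest$stages$phenotype <- list(
            n_traits = length(traits),
            n_significant = sum(res$phenoSummary$p_value <
                                    config$alphaPheno) / 2)
        if (writeOut) {
            writeStageTable(res$phenoSummary,
                            file.path(outDir, "phenotype_summary.tsv"))
            writeStageTable(
                data.frame(trait = traits,
                           percent_difference = res$percentDifferences),
                file.path(outDir, "percent_differences.tsv"))
        }
    }

    if (writeOut) {
        files <- list.files(outDir, pattern = "\\.tsv$", full.names = TRUE)
        manifest$inputs <- as.list(tools::md5sum(files))
        names(manifest$inputs) <- basename(files)
        jsonlite::write_json(manifest,
                             file.path(outDir, "manifest.json"),
                             auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
    res$manifest <- manifest
    invisible(res)
}
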