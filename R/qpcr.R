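#' Relative quantification by 2^-ddCt with reference-gene normalization
#'
#' For each target gene, each sample and each replicate, the target Ct is
#' normalized by the arithmetic mean Ct of the reference genes in the same
#' sample and replicate (dCt = Ct_gene - mean(Ct_refs); with two
#' references this equals normalizing expression by their geometric mean).
#' Replicates are then averaged per sample and
#' ddCt = mean dCt(treatment) - mean dCt(calibrator); the fold change is
#' `2^-ddCt`, assuming perfect doubling per cycle.
#'
#' @param ctTable `data.frame` with columns `gene_id`, `sample`,
#'   `replicate`, `ct`, `is_reference` (as produced by [simulateCt()]).
#' @param genes target genes to quantify (default: all non-reference
#'   genes present).
#' @param calibrator,treatment sample labels (defaults `"diploid"` and
#'   `"tetraploid"`).
#' @return `data.frame` with `gene_id`, `log2fc_qpcr` (= -ddCt) and
#'   `fold` (= 2^-ddCt).
#' @examples
#' ct <- simulateCt(c(gA = 2), ctNoiseSd = 0)
#' ddctFoldChange(ct)$fold  # 2
#' @export
ddctFoldChange <- function(ctTable, genes = NULL,
                           calibrator = "diploid", treatment = "tetraploid") {
    req <- c("gene_id", "sample", "replicate", "ct", "is_reference")
    if (!all(req %in% names(ctTable)))
        stop("ctTable needs columns: ", paste(req, collapse = ", "))
    for (s in c(calibrator, treatment))
        if (!any(ctTable$is_reference & ctTable$sample == s))
            stop("no reference gene measured in sample '", s, "'")
    refs <- ctTable[ctTable$is_reference, ]
    refMean <- stats::aggregate(ct ~ sample + replicate, data = refs,
                                FUN = mean)
    names(refMean)[names(refMean) == "ct"] <- "ref_ct"
    if (is.null(genes))
        genes <- unique(ctTable$gene_id[!ctTable$is_reference])
    out <- lapply(genes, function(g) {
        tg <- ctTable[ctTable$gene_id == g & !ctTable$is_reference, ]
        if (!all(c(calibrator, treatment) %in% tg$sample))
            stop("gene '", g, "' not measured in both samples")
        tg <- merge(tg, refMean, by = c("sample", "replicate"))
        tg$dct <- tg$ct - tg$ref_ct
        dctCal <- mean(tg$dct[tg$sample == calibrator])
        dctTrt <- mean(tg$dct[tg$sample == treatment])
        ddct <- dctTrt - dctCal
        data.frame(gene_id = g, log2fc_qpcr = -ddct, fold = 2^-ddct,
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Concordance between RNA-Seq and qPCR fold changes
#'
#' Pearson correlation between the two log2 fold-change vectors, with the
#' two-sided p-value from the t transform on n - 2 degrees of freedom.
#'
#' @param log2fcQpcr,log2fcRnaseq numeric vectors of matched log2 fold
#'   changes (at least 3 genes).
#' @return list with `r`, `p`, `n`.
#' @examples
#' concordance(c(1, 2, 3), c(2, 4, 5))$r  # 0.982
#' @export
concordance <- function(log2fcQpcr, log2fcRnaseq) {
    if (length(log2fcQpcr) != length(log2fcRnaseq))
        stop("fold-change vectors must have equal length")
    n <- length(log2fcQpcr)
    if (n < 3) stop("at least 3 genes are required")
    if (stats::sd(log2fcQpcr) == 0 || stats::sd(log2fcRnaseq) == 0)
        stop("correlation undefined: zero variance in a fold-change vector")
    ct <- stats::cor.test(log2fcQpcr, log2fcRnaseq, method = "pearson")
    list(r = unname(ct$estimate), p = ct$p.value, n = n)
}
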