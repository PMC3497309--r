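#' @importFrom Biostrings readQualityScaledDNAStringSet
#'   writeQualityScaledXStringSet quality letterFrequency width
#' @importFrom IRanges IntegerList
NULL

## per-read integer Phred qualities as an IntegerList
.readQuals <- function(reads) {
    methods::as(Biostrings::quality(reads), "IntegerList")
}

#' Read a FASTQ file into a quality-scaled string set
#'
#' Thin wrapper over [Biostrings::readQualityScaledDNAStringSet()] that
#' selects the quality encoding by Phred offset: 33 (Sanger/Illumina 1.8+)
#' or 64 (Illumina 1.3-1.7).
#'
#' @param path FASTQ file (plain or gzipped).
#' @param phredOffset 33 (default) or 64.
#' @return a [Biostrings::QualityScaledDNAStringSet].
#' @export
readFastqFile <- function(path, phredOffset = 33L) {
    scoring <- switch(as.character(phredOffset),
                      "33" = "phred", "64" = "illumina",
                      stop("phredOffset must be 33 or 64"))
    ## Biostrings warns about dropping its own internal metadata columns
    ## while re-wrapping the parsed set; nothing user-visible is lost
    withCallingHandlers(
        readQualityScaledDNAStringSet(path, quality.scoring = scoring),
        warning = function(w) {
            if (grepl("metadata columns", conditionMessage(w)))
                invokeRestart("muffleWarning")
        })
}

#' Write a quality-scaled string set as FASTQ
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeFastqFile <- function(reads, path) {
    writeQualityScaledXStringSet(reads, path)
    invisible(path)
}

#' Filter reads on N content and low-quality-base content
#'
#' A read is removed iff its N fraction exceeds `maxNPct` percent OR the
#' fraction of its bases with quality at or below `lowqQ` exceeds
#' `maxLowqPct` percent. Both thresholds are strict (a read exactly at the
#' boundary is kept). Input order is preserved.
#'
#' @param reads a [Biostrings::QualityScaledDNAStringSet].
#' @param maxNPct maximum tolerated percent of N bases (default 5).
#' @param lowqQ quality value at or below which a base counts as low
#'   quality (default 10).
#' @param maxLowqPct maximum tolerated percent of low-quality bases
#'   (default 20).
#' @return list with `kept` (the surviving reads, original order) and
#'   `stats` (counts: `input`, `kept`, `removed`, `removed_n`,
#'   `removed_lowq`; a read failing both rules is counted under both
#'   reasons).
#' @export
filterReads <- function(reads, maxNPct = 5, lowqQ = 10L, maxLowqPct = 20) {
    if (maxNPct < 0 || maxNPct > 100 || maxLowqPct < 0 || maxLowqPct > 100)
        stop("percent thresholds must lie in [0, 100]")
    w <- width(reads)
    nPct <- 100 * as.vector(letterFrequency(reads, "N")) / w
    lowqPct <- 100 * sum(.readQuals(reads) <= lowqQ) / w
    failN <- nPct > maxNPct
    failQ <- lowqPct > maxLowqPct
    keep <- !(failN | failQ)
    list(kept = reads[keep],
         stats = list(input = length(reads), kept = sum(keep),
                      removed = sum(!keep), removed_n = sum(failN),
                      removed_lowq = sum(failQ)))
}

#' Library-level sequencing summary
#'
#' The throughput/quality summary reported per sequencing library:
#' total reads, total nucleotides, Q20 percentage (bases with quality
#' strictly greater than 20), N percentage, and GC percentage computed
#' over non-N bases.
#'
#' @param reads a non-empty [Biostrings::QualityScaledDNAStringSet].
#' @return one-row `data.frame` with `total_reads`, `total_nt`,
#'   `q20_pct`, `n_pct`, `gc_pct`.
#' @export
librarySummary <- function(reads) {
    if (length(reads) == 0) stop("empty read set")
    w <- width(reads)
    totalNt <- sum(as.numeric(w))
    nN <- sum(as.numeric(letterFrequency(reads, "N")))
    nGC <- sum(as.numeric(letterFrequency(reads, "GC")))
    nQ20 <- sum(as.numeric(sum(.readQuals(reads) > 20L)))
    data.frame(total_reads = length(reads),
               total_nt = totalNt,
               q20_pct = 100 * nQ20 / totalNt,
               n_pct = 100 * nN / totalNt,
               gc_pct = if (totalNt > nN) 100 * nGC / (totalNt - nN) else NA_real_)
}

#' Assembly length summary with N50
#'
#' N50 is the smallest length L such that sequences of length at least L
#' together contain at least half of the total assembled bases.
#'
#' @param lengths positive integer vector of sequence lengths.
#' @return list with `count`, `total_nt`, `mean_nt`, `n50_nt`.
#' @examples
#' lengthSummary(c(5, 5, 3, 3, 2, 2, 2))$n50_nt  # 3
#' @export
lengthSummary <- function(lengths) {
    if (length(lengths) == 0) stop("empty length vector")
    if (any(lengths <= 0)) stop("lengths must be positive")
    s <- sort(lengths, decreasing = TRUE)
    cum <- cumsum(as.numeric(s))
    total <- cum[length(cum)]
    n50 <- s[which(cum >= total / 2)[1]]
    list(count = length(lengths), total_nt = total,
         mean_nt = total / length(lengths), n50_nt = n50)
}
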