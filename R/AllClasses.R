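#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom stats setNames
#' @importFrom utils read.delim write.table packageVersion
#' @importFrom tools md5sum
NULL

#' DGECounts: a two-library digital gene expression count table
#'
#' `DGECounts` extends [SummarizedExperiment::SummarizedExperiment] and holds
#' one count matrix (assay `"counts"`) with exactly two columns, one per
#' sequencing library (conventionally `diploid` and `tetraploid`).
#' `rowData` carries the unigene length in nucleotides (`length_nt`), needed
#' for RPKM; `colData` carries the total number of clean reads per library
#' (`libSize`, the totals conditioned on by the exact test). Library sizes
#' are the sequencing totals, not the column sums: mapped counts may (and
#' normally do) sum to less than the library size.
#'
#' @slot .. see [SummarizedExperiment::SummarizedExperiment]
#' @export
setClass("DGECounts", contains = "SummarizedExperiment")

setValidity("DGECounts", function(object) {
    msg <- character()
    if (!"counts" %in% SummarizedExperiment::assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    if (ncol(object) != 2L)
        msg <- c(msg, "exactly two libraries (columns) are required")
    if (!"length_nt" %in% colnames(rowData(object)))
        msg <- c(msg, "rowData must contain 'length_nt'")
    if (!"libSize" %in% colnames(colData(object)))
        msg <- c(msg, "colData must contain 'libSize'")
    if (length(msg)) return(msg)
    cnt <- assay(object, "counts")
    len <- rowData(object)$length_nt
    ls  <- colData(object)$libSize
    if (any(is.na(cnt)) || any(cnt < 0))
        msg <- c(msg, "counts must be non-negative")
    if (any(len <= 0))
        msg <- c(msg, "unigene lengths must be positive")
    if (any(ls <= 0))
        msg <- c(msg, "library sizes must be positive")
    if (!is.null(rownames(object)) && anyDuplicated(rownames(object)))
        msg <- c(msg, "unigene ids must be unique")
    if (nrow(cnt) > 0 && any(colSums(cnt) > ls))
        msg <- c(msg, "per-library count sums exceed the stated library sizes")
    if (length(msg)) msg else TRUE
})

#' Construct a DGECounts object
#'
#' @param counts integer matrix of mapped clean-read counts, one row per
#'   unigene, two columns (diploid then tetraploid library).
#' @param lengthNt positive integer vector of unigene lengths (nt).
#' @param libSizes numeric length-2 vector of total clean reads per library
#'   (the `N1`, `N2` of the exact test); must be at least the column sums.
#' @param unigeneIds optional character vector of unique row names.
#' @return a [DGECounts] object.
#' @examples
#' dge <- DGECounts(matrix(c(5L, 9L), 1), lengthNt = 500,
#'                  libSizes = c(1e6, 1e6), unigeneIds = "U1")
#' libSizes(dge)
#' @export
DGECounts <- function(counts, lengthNt, libSizes,
                      unigeneIds = rownames(counts)) {
    counts <- as.matrix(counts)
    if (is.null(colnames(counts)))
        colnames(counts) <- c("diploid", "tetraploid")
    if (is.null(unigeneIds))
        unigeneIds <- sprintf("Unigene%05d", seq_len(nrow(counts)))
    rownames(counts) <- unigeneIds
    se <- SummarizedExperiment(
        assays  = list(counts = counts),
        rowData = DataFrame(length_nt = as.integer(lengthNt)),
        colData = DataFrame(libSize = as.numeric(libSizes),
                            row.names = colnames(counts)))
    new("DGECounts", se)
}

#' Library sizes of a DGECounts object
#'
#' @param object a [DGECounts] object.
#' @return named numeric vector of total clean reads per library.
#' @export
setGeneric("libSizes", function(object) standardGeneric("libSizes"))

#' @rdname libSizes
#' @export
setMethod("libSizes", "DGECounts", function(object) {
    stats::setNames(colData(object)$libSize, colnames(object))
})

#' Unigene lengths of a DGECounts object
#'
#' @param object a [DGECounts] object.
#' @return named integer vector of lengths in nucleotides.
#' @export
setGeneric("unigeneLengths", function(object) standardGeneric("unigeneLengths"))

#' @rdname unigeneLengths
#' @export
setMethod("unigeneLengths", "DGECounts", function(object) {
    stats::setNames(rowData(object)$length_nt, rownames(object))
})

setMethod("show", "DGECounts", function(object) {
    cat("DGECounts with", nrow(object), "unigenes and 2 libraries\n")
    ls <- libSizes(object)
    cat(sprintf("  %s: libSize %s, mapped %s\n", colnames(object),
                format(ls, big.mark = ","),
                format(colSums(assay(object, "counts")), big.mark = ",")))
})
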