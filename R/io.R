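## TSV interchange between pipeline stages. Everything human-diffable:
## count tables carry their library sizes as '#key=value' header lines.

#' Write a DGECounts table to TSV
#'
#' Columns `unigene_id`, `length_nt`, `count_diploid`, `count_tetraploid`;
#' the library totals are stored in `#libSize_*` header lines so the file
#' round-trips through [readCountTable()].
#'
#' @param object a [DGECounts].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCountTable <- function(object, path) {
    stopifnot(is(object, "DGECounts"))
    ls <- libSizes(object)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("#libSize_%s=%.0f", names(ls), ls), con)
    df <- data.frame(unigene_id = rownames(object),
                     length_nt = rowData(object)$length_nt,
                     count_diploid = assay(object, "counts")[, 1L],
                     count_tetraploid = assay(object, "counts")[, 2L])
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a DGECounts table from TSV
#'
#' @param path a file written by [writeCountTable()].
#' @return a [DGECounts].
#' @export
readCountTable <- function(path) {
    hdr <- grep("^#libSize_", readLines(path, n = 10L), value = TRUE)
    if (length(hdr) != 2L)
        stop("count table must carry two #libSize_ header lines")
    kv <- sub("^#libSize_", "", hdr)
    libs <- stats::setNames(as.numeric(sub(".*=", "", kv)),
                            sub("=.*", "", kv))
    df <- utils::read.delim(path, comment.char = "#",
                            stringsAsFactors = FALSE)
    DGECounts(cbind(diploid = df$count_diploid,
                    tetraploid = df$count_tetraploid),
              lengthNt = df$length_nt,
              libSizes = libs[c("diploid", "tetraploid")],
              unigeneIds = df$unigene_id)
}

#' Write a pipeline stage table as TSV
#'
#' @param df a `data.frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeStageTable <- function(df, path) {
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read a pipeline stage table from TSV
#'
#' @param path a TSV written by [writeStageTable()] (or any plain TSV with
#'   a header; `#` lines are ignored).
#' @return a `data.frame`.
#' @export
readStageTable <- function(path) {
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
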