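#' Packaged phenotype parameter table for the birch field trial
#'
#' Group means and standard deviations for seven growth and morphology
#' traits, measured on diploid and autotetraploid birch (*Betula
#' platyphylla*) trees from four full-sib families (5x3, 5x9, 5x11, 6x5).
#' Units: height m, breast-height diameter mm, volume dm3, leaf area cm2,
#' fruit length mm, fruit diameter mm, stoma length um.
#'
#' @return `data.frame` with columns `family`, `ploidy`
#'   (`diploid`/`autotetraploid`), `trait`, `mean`, `sd`.
#' @export
table1TraitParams <- function() {
    path <- system.file("extdata", "birch_trait_params.tsv",
                        package = "ploidyDGE", mustWork = TRUE)
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Autotetraploid counts per full-sib family
#'
#' Number of colchicine-induced autotetraploid individuals recovered in
#' each of the four full-sib families.
#'
#' @return `data.frame` with columns `family`, `n_autotetraploid`.
#' @export
familyCounts <- function() {
    path <- system.file("extdata", "birch_family_counts.tsv",
                        package = "ploidyDGE", mustWork = TRUE)
    utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Per-family group summaries with significance letters
#'
#' Mean, SD and sample size per family x ploidy x trait cell, plus a
#' two-sample test (Welch by default) per family x trait comparing the two
#' ploidy groups. The group with the larger mean is labelled `A` and the
#' other `B` when the test rejects at `alpha`; both groups are labelled
#' `A` otherwise.
#'
#' @param traits `data.frame` with columns `family`, `ploidy`, `trait`,
#'   `value` (per-tree measurements, both ploidies in every family x
#'   trait).
#' @param alpha significance level (default 0.01).
#' @param method `"welch"` (default) or `"student"` (pooled variance).
#' @return `data.frame` with `family`, `ploidy`, `trait`, `mean`, `sd`,
#'   `n`, `p_value` (duplicated within a family x trait pair), `letter`.
#' @export
summarizeGroups <- function(traits, alpha = 0.01,
                            method = c("welch", "student")) {
    method <- match.arg(method)
    req <- c("family", "ploidy", "trait", "value")
    if (!all(req %in% names(traits)))
        stop("traits needs columns: ", paste(req, collapse = ", "))
    cells <- split(traits, list(traits$family, traits$trait), drop = TRUE)
    out <- lapply(cells, function(d) {
        ploidies <- sort(unique(d$ploidy))
        if (length(ploidies) != 2)
            stop("both ploidies required for family '", d$family[1],
                 "', trait '", d$trait[1], "'")
        vals <- split(d$value, d$ploidy)
        if (any(lengths(vals) < 2))
            stop("need at least 2 trees per cell (family '", d$family[1],
                 "', trait '", d$trait[1], "')")
        means <- vapply(vals, mean, numeric(1))
        if (identical(vals[[1]], vals[[2]])) {
            p <- 1
        } else {
            p <- tryCatch(
                stats::t.test(vals[[1]], vals[[2]],
                              var.equal = (method == "student"))$p.value,
                error = function(e) 1)
        }
        letter <- if (p < alpha) {
            ifelse(means == max(means), "A", "B")
        } else rep("A", 2)
        data.frame(family = d$family[1], ploidy = names(vals),
                   trait = d$trait[1], mean = unname(means),
                   sd = vapply(vals, stats::sd, numeric(1)),
                   n = lengths(vals), p_value = p, letter = letter,
                   stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

.traitMeans <- function(summaries, trait, ploidy) {
    sel <- summaries$trait == trait & summaries$ploidy == ploidy
    if (!any(sel)) stop("no rows for trait '", trait, "', ploidy '",
                        ploidy, "'")
    summaries$mean[sel]
}

#' Cross-family percent difference between ploidy groups
#'
#' `100 * (mean of autotetraploid family means - mean of diploid family
#' means) / (mean of diploid family means)`, unweighted across families.
#' Positive when the autotetraploids are larger.
#'
#' @param summaries `data.frame` with columns `family`, `ploidy`, `trait`,
#'   `mean` (group summaries or a parameter table such as
#'   [table1TraitParams()]).
#' @param trait trait name.
#' @param families the families that must all be present (default: the
#'   four full-sib families of the field trial).
#' @return percent difference (scalar).
#' @examples
#' percentDifference(table1TraitParams(), "stoma_length")  # 89.72
#' @export
percentDifference <- function(summaries, trait,
                              families = c("5x3", "5x9", "5x11", "6x5")) {
    sel <- summaries$trait == trait
    missing <- setdiff(families, summaries$family[sel])
    if (length(missing))
        stop("missing families for trait '", trait, "': ",
             paste(missing, collapse = ", "))
    dip <- mean(.traitMeans(summaries[sel, ], trait, "diploid"))
    tet <- mean(.traitMeans(summaries[sel, ], trait, "autotetraploid"))
    100 * (tet - dip) / dip
}

#' Cross-family mean of a trait for one ploidy
#'
#' Unweighted mean of the per-family group means.
#'
#' @inheritParams percentDifference
#' @param ploidy `"diploid"` or `"autotetraploid"`.
#' @param digits optional rounding for reporting (default `NULL`, no
#'   rounding).
#' @return mean in trait units.
#' @examples
#' crossFamilyMean(table1TraitParams(), "height", "autotetraploid",
#'                 digits = 2)  # 5.58
#' @export
crossFamilyMean <- function(summaries, trait, ploidy,
                            families = c("5x3", "5x9", "5x11", "6x5"),
                            digits = NULL) {
    sel <- summaries$trait == trait & summaries$ploidy == ploidy
    missing <- setdiff(families, summaries$family[sel])
    if (length(missing))
        stop("missing families: ", paste(missing, collapse = ", "))
    m <- mean(summaries$mean[sel])
    if (is.null(digits)) m else round(m, digits)
}
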