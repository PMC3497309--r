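#' Hypergeometric upper-tail enrichment p-value
#'
#' Probability of observing at least `m` differentially expressed members
#' in a term of size `M`, when `n` DEUs are drawn from an annotated
#' universe of `N` unigenes:
#' \deqn{P = 1 - \sum_{i=0}^{m-1}
#'   \binom{M}{i}\binom{N-M}{n-i} \big/ \binom{N}{n}}
#' The upper tail is summed directly through `lchoose` (never as
#' 1 minus the lower tail), so small p-values keep full relative accuracy.
#'
#' @param N annotated universe size.
#' @param n number of DEUs in the universe.
#' @param M term size (annotated unigenes carrying the term).
#' @param m DEUs carrying the term; must satisfy `m <= min(n, M)`.
#' @return upper-tail probability in \[0, 1\]; exactly 1 when `m = 0`.
#' @examples
#' hypergeomPValue(10, 3, 5, 2)  # 0.5
#' @export
hypergeomPValue <- function(N, n, M, m) {
    k <- max(length(N), length(n), length(M), length(m))
    N <- rep_len(N, k); n <- rep_len(n, k)
    M <- rep_len(M, k); m <- rep_len(m, k)
    if (any(M > N) || any(n > N)) stop("M and n must not exceed N")
    if (any(m > pmin(n, M))) stop("m must not exceed min(n, M)")
    if (any(c(N, n, M, m) < 0)) stop("counts must be non-negative")
    vapply(seq_len(k), function(j) {
        i <- seq(m[j], min(n[j], M[j]))
        min(1, sum(exp(lchoose(M[j], i) + lchoose(N[j] - M[j], n[j] - i) -
                           lchoose(N[j], n[j]))))
    }, numeric(1))
}

#' Bonferroni correction
#'
#' Each p-value multiplied by the number of tests, capped at 1.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return corrected p-values, same order.
#' @export
bonferroni <- function(p) {
    if (length(p) == 0) return(numeric(0))
    if (any(is.na(p)) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    pmin(1, p * length(p))
}

#' Term enrichment among differentially expressed unigenes
#'
#' Hypergeometric upper-tail test of every annotated term against the
#' annotated-transcriptome background, with Bonferroni correction. The
#' universe is the set of unigenes carrying at least one annotation in the
#' supplied table; DEUs outside the universe are dropped. The same
#' machinery serves GO terms and KEGG pathways.
#'
#' @param deus character vector of DEU unigene ids.
#' @param annotation `data.frame` with columns `unigene_id`, `term_id`.
#' @param alpha significance threshold on the corrected p-value
#'   (default 0.05; significant means strictly below).
#' @return `data.frame` sorted by corrected p-value: `term_id`, `N`, `n`,
#'   `M`, `m`, `p_value`, `p_corrected`, `significant`.
#' @export
enrichTerms <- function(deus, annotation, alpha = 0.05) {
    if (!all(c("unigene_id", "term_id") %in% names(annotation)))
        stop("annotation needs columns unigene_id and term_id")
    annotation <- unique(annotation[, c("unigene_id", "term_id")])
    universe <- unique(annotation$unigene_id)
    N <- length(universe)
    deus <- unique(intersect(deus, universe))
    n <- length(deus)
    terms <- split(annotation$unigene_id, annotation$term_id)
    empty <- lengths(terms) == 0
    if (any(empty)) {
        warning("skipping ", sum(empty), " term(s) with no members")
        terms <- terms[!empty]
    }
    M <- lengths(terms)
    m <- vapply(terms, function(g) length(intersect(g, deus)), integer(1))
    p <- hypergeomPValue(N, n, M, m)
    pc <- bonferroni(p)
    res <- data.frame(term_id = names(terms), N = N, n = n,
                      M = as.integer(M), m = as.integer(m),
                      p_value = p, p_corrected = pc,
                      significant = pc < alpha,
                      stringsAsFactors = FALSE)
    res <- res[order(res$p_corrected, res$p_value, res$term_id), ]
    rownames(res) <- NULL
    res
}
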