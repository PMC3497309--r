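#' RPKM normalization
#'
#' Reads per kilobase of transcript per million mapped reads:
#' `1e9 * count / (libTotal * lengthNt)`.
#'
#' @param count non-negative numeric vector of mapped read counts.
#' @param libTotal positive library total (recycled).
#' @param lengthNt positive transcript length in nucleotides (recycled).
#' @return numeric vector of RPKM values; zero exactly where `count` is zero.
#' @examples
#' rpkm(1000, 1e6, 1000)  # 1000
#' @export
rpkm <- function(count, libTotal, lengthNt) {
    if (any(libTotal <= 0)) stop("library total must be positive")
    if (any(lengthNt <= 0)) stop("transcript length must be positive")
    if (any(count < 0)) stop("counts must be non-negative")
    1e9 * count / (libTotal * lengthNt)
}

#' Log2 fold change with zero substitution
#'
#' log2(numerator/denominator) after replacing any zero operand by
#' `zeroSub` (default 0.001), the convention used for RPKM ratios where
#' one library has no mapped reads for a transcript. Both operands zero
#' yields 0 (the substitution cancels).
#'
#' @param numerator,denominator non-negative numeric vectors (RPKM values;
#'   numerator conventionally the tetraploid library).
#' @param zeroSub positive replacement for exact zeros.
#' @return numeric vector of log2 ratios.
#' @examples
#' log2FoldChange(1.024, 0)  # 10
#' @export
log2FoldChange <- function(numerator, denominator, zeroSub = 0.001) {
    if (any(numerator < 0) || any(denominator < 0))
        stop("RPKM values must be non-negative")
    if (zeroSub <= 0) stop("zeroSub must be positive")
    num <- ifelse(numerator == 0, zeroSub, numerator)
    den <- ifelse(denominator == 0, zeroSub, denominator)
    log2(num / den)
}

## Conditional mass of the second library's count given the first:
## P(y | x) = (N2/N1)^y * (x+y)! / (x! y!) / (1 + N2/N1)^(x+y+1),
## i.e. y | x ~ NegBinom(size = x + 1, prob = N1/(N1+N2)).
## All terms in log space via lgamma; tails summed in linear space anchored
## at the observed y, stepping away from the mode with early termination,
## so the smaller tail is always the directly-summed one (no cancellation).
.acLogPmf <- function(yv, x, logr, log1pr) {
    yv * logr + lgamma(x + yv + 1) - lgamma(x + 1) - lgamma(yv + 1) -
        (x + yv + 1) * log1pr
}

.acTails <- function(x, y, N1, N2) {
    logr <- log(N2) - log(N1)
    log1pr <- log1p(N2 / N1)
    logpmf_y <- .acLogPmf(y, x, logr, log1pr)
    pmf <- exp(logpmf_y)
    mu <- (x + 1) * (N2 / N1)            # conditional mean of y given x
    if (y <= mu) {
        ## lower tail directly: terms for y' = y, y-1, ..., 0 shrink
        if (y == 0) {
            lower <- pmf
        } else {
            ## step y' -> y'-1 multiplies the pmf by y'(1+r)/((x+y') r)
            ks <- y:1
            logterms <- logpmf_y +
                c(0, cumsum(log(ks) - log(x + ks) - logr + log1pr))
            lower <- sum(exp(rev(logterms)))
        }
        upper <- 1 - lower + pmf
    } else {
        ## upper tail directly: terms for y' = y, y+1, ... shrink (y > mode)
        upper <- 0
        loga <- logpmf_y
        y0 <- y
        chunk <- 512L
        repeat {
            ys <- y0 + seq_len(chunk) - 1L
            ## pmf ratio P(y'+1)/P(y') = r (x+y'+1) / ((y'+1)(1+r))
            steps <- logr + log(x + ys + 1) - log(ys + 1) - log1pr
            logterms <- loga + c(0, cumsum(steps[-chunk]))
            terms <- exp(logterms)
            upper <- upper + sum(rev(terms))
            last <- terms[chunk]
            if (last == 0 || last < upper * 1e-17) break
            loga <- logterms[chunk] + steps[chunk]
            y0 <- y0 + chunk
        }
        lower <- 1 - upper + pmf
    }
    c(lower = min(lower, 1), upper = min(upper, 1), pmf = pmf)
}

#' Audic-Claverie exact test for two sequencing libraries
#'
#' Probability of equal expression of a transcript between two libraries,
#' conditioned on the observed count `x` in library 1 and the library
#' totals `N1`, `N2`. The conditional mass of the count `y` in library 2 is
#' \deqn{P(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
#'   \frac{(x+y)!}{x!\,y!}\left(1+\frac{N_2}{N_1}\right)^{-(x+y+1)}}
#' The default two-sided p-value doubles the smaller of the two tail sums
#' \eqn{P(Y \le y \mid x)} and \eqn{P(Y \ge y \mid x)} and caps at 1.
#' Everything is computed through log-gamma, so counts up to 1e7 do not
#' overflow.
#'
#' @param x,y non-negative observed counts in library 1 and 2 (vectorized).
#' @param N1,N2 positive library totals (total clean reads).
#' @param tail `"two.sided"` (default), `"lower"` (\eqn{P(Y \le y)}) or
#'   `"upper"` (\eqn{P(Y \ge y)}).
#' @return numeric vector of p-values in \[0, 1\].
#' @examples
#' audicClaveriePValue(0, 0, 1e6, 1e6)   # 1
#' audicClaveriePValue(5, 15, 1e6, 1e6)
#' @export
audicClaveriePValue <- function(x, y, N1, N2,
                                tail = c("two.sided", "lower", "upper")) {
    tail <- match.arg(tail)
    if (any(N1 <= 0) || any(N2 <= 0)) stop("library totals must be positive")
    if (any(x < 0) || any(y < 0)) stop("counts must be non-negative")
    n <- max(length(x), length(y), length(N1), length(N2))
    x <- rep_len(x, n); y <- rep_len(y, n)
    N1 <- rep_len(N1, n); N2 <- rep_len(N2, n)
    vapply(seq_len(n), function(i) {
        t <- .acTails(x[i], y[i], N1[i], N2[i])
        switch(tail,
               two.sided = min(1, 2 * min(t[["lower"]], t[["upper"]])),
               lower = t[["lower"]],
               upper = t[["upper"]])
    }, numeric(1))
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' `q_(i) = min_(j >= i) p_(j) * k / j`, capped at 1; ties keep the stable
#' input order, and the adjustment preserves the ranking of the raw
#' p-values.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return numeric vector of FDR-adjusted values, same order as input.
#' @examples
#' bhFDR(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bhFDR <- function(p) {
    if (length(p) == 0) return(numeric(0))
    if (any(is.na(p)) || any(p < 0 | p > 1))
        stop("p-values must lie in [0, 1]")
    k <- length(p)
    o <- order(p)                       # stable for ties
    q <- rev(cummin(rev(p[o] * k / seq_len(k))))
    pmin(1, q)[order(o)]
}

#' Call differentially expressed unigenes (DEUs)
#'
#' Runs the full two-library differential-expression procedure on a
#' [DGECounts] table: RPKM per library, log2 fold change
#' (tetraploid/diploid) with the 0.001 zero substitution, the
#' Audic-Claverie exact p-value on raw counts, Benjamini-Hochberg FDR, and
#' the joint call `fdr <= fdrMax & |log2fc| >= lfcMin`.
#'
#' @param object a [DGECounts] object (column 1 diploid, column 2
#'   tetraploid).
#' @param fdrMax FDR threshold for significance (default 0.001).
#' @param lfcMin minimum absolute log2 fold change (default 1).
#' @param tail tail convention passed to [audicClaveriePValue()].
#' @param fdrScope `"expressed"` (default) adjusts only unigenes with at
#'   least one mapped read in either library (others get `fdr = NA`, never
#'   called); `"all"` adjusts every row.
#' @param zeroSub zero replacement for the fold change (default 0.001).
#' @return a `data.frame` with one row per unigene: counts, RPKMs,
#'   `log2fc`, `p_value`, `fdr`, `is_deu`, `direction` (`up`/`down`/`none`);
#'   up/down totals are attached as attribute `"summary"` (see
#'   [deuSummary()]).
#' @export
callDEUs <- function(object, fdrMax = 0.001, lfcMin = 1,
                     tail = "two.sided",
                     fdrScope = c("expressed", "all"),
                     zeroSub = 0.001) {
    stopifnot(is(object, "DGECounts"))
    fdrScope <- match.arg(fdrScope)
    validObject(object)
    cnt <- assay(object, "counts")
    len <- rowData(object)$length_nt
    ls <- libSizes(object)
    x <- cnt[, 1L]; y <- cnt[, 2L]
    rpkmD <- rpkm(x, ls[[1L]], len)
    rpkmT <- rpkm(y, ls[[2L]], len)
    lfc <- log2FoldChange(rpkmT, rpkmD, zeroSub = zeroSub)
    p <- audicClaveriePValue(x, y, ls[[1L]], ls[[2L]], tail = tail)
    fdr <- rep(NA_real_, length(p))
    in_scope <- if (fdrScope == "expressed") (x + y) > 0 else rep(TRUE, length(p))
    fdr[in_scope] <- bhFDR(p[in_scope])
    is_deu <- !is.na(fdr) & fdr <= fdrMax & abs(lfc) >= lfcMin
    direction <- ifelse(is_deu, ifelse(lfc > 0, "up", "down"), "none")
    res <- data.frame(
        unigene_id = rownames(object),
        length_nt = len,
        count_diploid = x,
        count_tetraploid = y,
        rpkm_diploid = rpkmD,
        rpkm_tetraploid = rpkmT,
        log2fc = lfc,
        p_value = p,
        fdr = fdr,
        is_deu = is_deu,
        direction = direction,
        row.names = NULL,
        stringsAsFactors = FALSE)
    attr(res, "summary") <- list(
        n = nrow(res),
        n_up = sum(direction == "up"),
        n_down = sum(direction == "down"),
        fdr_max = fdrMax, lfc_min = lfcMin,
        lib_sizes = as.list(ls))
    res
}

#' Up/down summary of a DEU call
#'
#' @param deuResult the `data.frame` returned by [callDEUs()].
#' @return list with `n`, `n_up`, `n_down` and the thresholds used.
#' @export
deuSummary <- function(deuResult) {
    s <- attr(deuResult, "summary")
    if (is.null(s))
        s <- list(n = nrow(deuResult),
                  n_up = sum(deuResult$direction == "up"),
                  n_down = sum(deuResult$direction == "down"))
    s
}
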