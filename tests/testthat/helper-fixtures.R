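## Small builders shared across test files.

## a QualityScaledDNAStringSet from parallel base/quality-integer vectors
makeReads <- function(seqs, quals, ids = sprintf("r%02d", seq_along(seqs))) {
    stopifnot(length(seqs) == length(quals))
    qstr <- vapply(quals, function(q) rawToChar(as.raw(q + 33L)),
                   character(1))
    dna <- Biostrings::DNAStringSet(seqs)
    names(dna) <- ids
    Biostrings::QualityScaledDNAStringSet(dna,
                                          Biostrings::PhredQuality(qstr))
}

## one read of given length with nN leading Ns and nLowq leading low-quality
## bases (Q = qLow), everything else Q = qHigh
boundaryRead <- function(len = 100L, nN = 0L, nLowq = 0L, qLow = 10L,
                         qHigh = 30L) {
    bases <- c(rep("N", nN), rep("A", len - nN))
    quals <- c(rep(qLow, nLowq), rep(qHigh, len - nLowq))
    makeReads(paste0(bases, collapse = ""), list(quals))
}

## tiny deterministic count table
tinyCounts <- function(x, y, len = 1000L, N1 = 1e6, N2 = 1e6) {
    DGECounts(cbind(diploid = x, tetraploid = y),
              lengthNt = rep_len(len, length(x)),
              libSizes = c(N1, N2),
              unigeneIds = sprintf("U%03d", seq_along(x)))
}

## independent tail oracle for the two-library exact test: the conditional
## law of y given x is negative binomial with size x+1, prob N1/(N1+N2)
acOracleTails <- function(x, y, N1, N2) {
    p <- N1 / (N1 + N2)
    c(lower = stats::pnbinom(y, size = x + 1, prob = p),
      upper = stats::pnbinom(y - 1, size = x + 1, prob = p,
                             lower.tail = FALSE))
}

## exhaustive hypergeometric oracle: enumerate every n-subset of a universe
## of N with M marked elements and count draws with >= m marked
hyperEnumOracle <- function(N, n, M, m) {
    marked <- seq_len(M)
    draws <- utils::combn(N, n)
    mean(colSums(matrix(draws %in% marked, nrow = n)) >= m)
}
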