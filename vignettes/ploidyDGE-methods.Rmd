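---
title: "Methods and design of ploidyDGE"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of ploidyDGE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ploidyDGE)
```

## The problem

Induced autotetraploidy in birch changes tree architecture — stouter
stems, bigger leaves, fruit and stomata, shorter stature — and the
transcriptome of the shoot apical meristem along with it. The classic
study design sequences one RNA-Seq library per ploidy (no biological
replicates), quantifies expression per assembled unigene, and asks which
unigenes changed. ploidyDGE implements the statistical chain of that
design end to end, together with generators that produce every input with
known ground truth.

## The exact two-library test

With a single library per condition, dispersion cannot be estimated;
the appropriate model is Poisson sampling of reads. Conditional on the
count $x$ observed in library 1 and the library totals $N_1, N_2$ (total
clean reads — these are *not* the column sums of mapped counts), the count
$y$ in library 2 under equal expression has mass

$$P(y \mid x) = \left(\frac{N_2}{N_1}\right)^{y}
  \frac{(x+y)!}{x!\,y!}\left(1+\frac{N_2}{N_1}\right)^{-(x+y+1)},$$

which is negative binomial with size $x+1$ and success probability
$N_1/(N_1+N_2)$ — the posterior predictive of a Poisson count under a flat
prior on the rate. The printed exponent $(x+y+1)$ belongs to the
denominator term $(1+N_2/N_1)$; that is the only reading under which the
mass normalizes to 1, and the package's tests verify the normalization.

Numerical choices:

* all factorials go through `lgamma`, so counts up to $10^7$ cannot
  overflow;
* tail sums are accumulated in linear space anchored at the observed $y$,
  stepping *away* from the conditional mode with successive pmf ratios, so
  the directly-summed tail is always the small one and never suffers
  cancellation; the complementary tail is $1 - \text{tail} + P(y|x)$;
* upper-tail summation extends in chunks until the last term falls below
  $10^{-17}$ of the running sum.

The two-sided p-value doubles the smaller of $P(Y \le y \mid x)$ and
$P(Y \ge y \mid x)$ and caps at 1. One-sided tails are available via the
`tail` argument, since the original description does not say which was
used. A caveat established during development: the statistic is *not*
exactly exchangeable under swapping $(x, N_1) \leftrightarrow (y, N_2)$ —
the mass conditions on $x$ — but swapped p-values agree within a factor of
2 and rank identically for practical purposes; the test suite asserts this
weaker, true property.

p-values are adjusted by the Benjamini–Hochberg step-up
($q_{(i)} = \min_{j \ge i} p_{(j)} k / j$, capped at 1), implemented
directly and cross-checked against `stats::p.adjust` in the tests. By
default the FDR family contains only unigenes with at least one mapped
read in either library (`fdrScope = "expressed"`); rows with zero counts
everywhere have $p = 1$ and carry no information. Calls require
FDR $\le 0.001$ **and** $|\log_2$ ratio$| \ge 1$, where the ratio is the
tetraploid/diploid RPKM ratio with 0.001 substituted for a zero RPKM (the
substitution applies to the fold change only; the test always uses raw
counts).

## Enrichment

Term enrichment among DEUs uses the hypergeometric upper tail

$$P = 1 - \sum_{i=0}^{m-1}
  \binom{M}{i}\binom{N-M}{n-i}\Big/\binom{N}{n}$$

with $N$ the unigenes carrying at least one annotation, $n$ the DEUs
inside that universe, $M$ the term size and $m$ the DEU overlap. The
implementation sums the upper tail directly through `lchoose` rather than
computing $1 - \text{lower}$, so small p-values retain full relative
accuracy; tests compare it against `phyper` and against exhaustive
enumeration of all $\binom{N}{n}$ draws for $N \le 12$. Correction is
Bonferroni across all terms tested in one call (one family per
namespace); significance means corrected $p < 0.05$ strictly. Term
membership is flat — no propagation up an ontology graph — matching
annotation tables produced by BLAST-based annotation; that is a documented
limitation, not an option.

## qPCR verification

Relative expression is $2^{-\Delta\Delta C_t}$: per replicate,
$\Delta C_t = C_t^{\text{gene}} - \text{mean}(C_t^{\text{refs}})$ using
the arithmetic mean of the two reference genes (equivalent to normalizing
expression by their geometric mean — the combination rule is not specified
in the original description, and this is the standard choice);
$\Delta\Delta C_t$ is the difference of per-sample replicate means
(replicates are biological and unpaired), and amplification efficiency is
fixed at 2 since no efficiency correction is described. Concordance with
RNA-Seq is the Pearson correlation of log2 fold changes with the
$t$-transform p-value on $n-2$ degrees of freedom (via
`stats::cor.test`); log2 scale is the default because correlating linear
folds lets a single large fold dominate.

## Phenotypes

Group summaries are per family × ploidy × trait; the two-sample test
behind the significance letters is Welch's $t$ by default (the original
table does not name its test; a pooled-variance Student test is available
via `method`). The headline percent differences are computed from
**unweighted** means of the four family means per ploidy — the only
aggregation scheme that reproduces all seven published percentages from
the packaged group-parameter table, verified to ±0.01 points in the
acceptance tests. `crossFamilyMean` does not round by default (one
published check value, 4.275, carries three decimals); pass `digits = 2`
for report-style values.

## The synthetic world

The generators' defaults are the stated conditions of the design, with
unstated quantities fixed once at field-plausible values:

* **Counts** (`simulateCounts`): $10^4$ unigenes, library totals
  $5\times10^6$ clean reads each, of which 70% map to unigenes; lengths
  uniform on 200–3000 nt (the length distribution is never stated; RPKM
  only needs positive lengths); relative abundances log-normal with
  $\sigma_{\log} = 1$ (realistic heterogeneity while keeping median
  planted genes detectable); a planted fraction (default 10%) of effects
  of exactly $\pm$`effectLog2`, half up and half down; Poisson counts at
  `dispersion = 0` (the test's own sampling model, used for calibration),
  negative binomial with variance $\mu + \phi\mu^2$ otherwise. Planted
  effects inflate the tetraploid library's expected mapped total; when
  that would push mapped sums above the stated totals, both libraries are
  rescaled by a common factor, which cancels in every normalized ratio and
  leaves both planted and null effects exact. Null unigenes therefore have
  expected normalized ratio exactly 1 regardless of what else is planted.
* **Reads** (`simulateFastq`): i.i.d. bases with per-base N probability
  and per-base low-quality probability (Q drawn from 2–10 versus 30–40; N
  bases get Q 2). No adapter or error-profile realism — read-level realism
  is out of scope; the generator exists to exercise the filter rules.
* **Annotation** (`simulateAnnotation`): terms assigned independently with
  per-term baseline probabilities (term sizes 1–5% of the universe);
  planted terms multiply the membership *odds* of DE unigenes by
  `enrichmentOdds` (default 20 in the pipeline).
* **Ct tables** (`simulateCt`): reference genes at fixed Ct (15 and 25),
  target diploid baselines uniform on 20–30, tetraploid Ct lowered by
  $\log_2$ ratio, i.i.d. Gaussian well noise. Noiseless recovery is exact
  to floating precision — the inversion is algebraic.
* **Phenotypes** (`simulatePhenotypes`): Gaussian per cell from the
  packaged parameter table, $n = 30$ trees per cell by default (thirty
  saplings per family were transplanted in the underlying trial; the
  per-cell measurement n is never printed). Draws are floored at 0.001
  since traits are physical sizes; with the packaged means/SDs the floor
  is touched only in the far tail of leaf area and biases nothing
  detectable.

What a green test does **not** establish: real libraries have correlated
expression, mapping ambiguity, composition effects and adapter
contamination that the generators deliberately omit; calibration results
transfer to real data only insofar as Poisson sampling holds between
technical libraries.

A consequence worth stating plainly: at $n = 30$ the weakest cell of the
phenotype table (fruit length in family 5×11, standardized difference
about 0.7) has only moderate power at $\alpha = 0.01$, so the simulation
does not reproduce "every cell significant" — the tests require all
large-effect traits significant in every family and near-complete
significance overall.

## Pipeline and reproducibility

`runPipeline` chains the stages with one global seed fanned out to fixed
per-stage seeds (additive offsets, kept below $2^{31}$), so any stage can
be rerun independently and reproduce bit-identical output; stages
exchange plain TSV (count tables carry their library totals as `#`
header lines) and the run manifest is JSON with thresholds, seeds, stage
summary counts and file digests. Reported timestamps are the only
non-deterministic manifest field.

## Known limitations

* No replicate-aware inference, dispersion estimation, or read mapping —
  the pipeline consumes count tables, as the design dictates.
* Flat annotation only; no ontology graph, no true-path propagation.
* No adapter trimming or quality trimming; filtering is whole-read.
* The exact test's two-sided construction is one of several in use
  (doubling versus summing both tails by mass); the doubled-tail choice is
  configurable only between tails, not constructions.
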