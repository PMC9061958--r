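---
title: "Chi-square homogeneity testing under indeterminacy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chi-square homogeneity testing under indeterminacy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neutroChisq)
```

## The model

The classical chi-square test of homogeneity asks whether $h$
independent multinomial samples share one category-probability vector.
With observed counts $Y_{ij}$ (group $j$, category $i$), group totals
$n_j$, and pooled estimates $\hat p_i = \sum_j Y_{ij} / \sum_j n_j$, the
statistic is

$$Q = \sum_{j=1}^{h} \sum_{i=1}^{k} \frac{(Y_{ij} - n_j \hat p_i)^2}{n_j \hat p_i},$$

referred to a chi-square distribution with $(h-1)(k-1)$ degrees of
freedom (or $h(k-1)$ when the probabilities are pre-specified rather
than estimated).

Neutrosophic statistics extends this to data that carry a *measure of
indeterminacy*: a dimensionless coefficient $I_N \in [I_L, I_U]$
quantifying the uncertain fraction of a quantity. A neutrosophic number
decomposes as $x_N = a + b\,I_N$ — determinate part $a$ plus
indeterminate coefficient $b$ scaled by the indeterminacy — giving the
interval $[a + b I_L,\; a + b I_U]$. For the test statistic the package
uses the multiplicative form $(1 + I_N)\,Q_L$, under which the interval
statistic is $Q_N \in [\,(1+I_L) Q_L,\; (1+I_U) Q_L\,]$. Setting
$I_L = I_U = 0$ collapses every interval to its determinate part and
the procedure is exactly the classical test; the test suite verifies
this reduction against an independently coded brute-force Pearson sum
and the $2\times2$ closed form
$N(ad-bc)^2 / ((a{+}b)(c{+}d)(a{+}c)(b{+}d))$.

Two statistic constructions are provided because they answer different
inputs:

* `neutrosophicStatistic()` — the multiplicative form above, for a
  single observed table whose counts are suspected to carry relative
  indeterminacy $I_N$. This is the form the DNA worked example and the
  sweep use.
* `generalIntervalStatistic()` — the additive two-sum form for
  genuinely interval-valued counts $[Y_{ijL}, Y_{ijU}]$: the
  determinate part is the Pearson sum of the lower table with the
  lower pooled estimates, the indeterminate coefficient the Pearson
  sum of the upper table with the upper estimates, and the endpoints
  follow $a + b I$. The two constructions coincide whenever the lower
  and upper tables are equal.

The pooled estimator also has interval endpoints (one per endpoint
table), but no additional indeterminacy of its own is propagated into
the statistic: the statistic's indeterminacy enters only through
$I_{Q_N}$. No principled combination rule for estimator-level and
statistic-level indeterminacy exists in this formulation, so the
package does not invent one.

## The decision rule

An interval statistic can straddle the critical value, so the decision
is trichotomous:

* **do not reject** when $Q_U \le$ critical value (the whole interval
  is compatible with $H_0$),
* **reject** when $Q_L >$ critical value (the whole interval exceeds
  it),
* **indeterminate** otherwise — the state the indeterminacy measure
  adds over the classical test, reported as a result, not an error.

This rule is conservative in both directions and agrees with the
single-value comparison whenever the interval lies entirely on one
side, which covers every case of the worked example. The command-line
front end exposes the trichotomy as exit codes (0 / 3 / 4) so
pipelines can branch on it.

## Parameters that matter

* `alpha` (default 0.05): significance level; the critical value is
  `qchisq(1 - alpha, df)`.
* `indeterminacy` (default `[0, 0]`): the indeterminacy interval,
  dimensionless. Upper bounds above 1 mean the indeterminate part
  exceeds the determinate one; the constructor refuses them unless
  `cap = FALSE`, and then warns.
* `critical`: an override for the critical value. The worked DNA
  example is reported against a tabulated value of 9.35, which is the
  0.975 chi-square quantile at 3 degrees of freedom, not the 0.95
  quantile (7.815) that $\alpha = 0.05$ implies. The package always
  computes the quantile from `alpha` and reproduces the 9.35 only
  through this override, so that non-reproduction analyses are not
  silently biased toward acceptance. With the worked example's
  statistic near 0.0066 the choice does not affect the decision.
* Minimum expected count: any expected cell below 5 raises a warning
  (the classical adequacy heuristic for the chi-square approximation);
  an expected cell of exactly 0 is an error because the statistic is
  undefined.
* Probability vectors must sum to 1 within an absolute tolerance of
  1e-9.

## The DNA front end

`countNucleotides()` turns a FASTA file into a count table with the
fixed category order A, C, G, T. Sequences are uppercased first (FASTA
case conveys masking, not identity); characters outside {A, C, G, T} —
ambiguity codes, gaps — are excluded rather than rejected, with the
per-group excluded count kept in the table metadata, because the test
concerns A/C/G/T composition only. Count tables read from CSV/TSV strip
thousands separators, so tables printed in the style `38,514` can be
used verbatim. The canonical 2 × 4 example — nucleotide counts for the
BRCA2 tumour-suppressor gene in two counting groups — ships both as
`brca2CountTable()` and as a CSV under `extdata/`.

## The worked example and the sweep

```{r example}
tab <- brca2CountTable()
res <- neutroChisqTest(tab, indeterminacy = indeterminacyInterval(0, 0.05),
                       critical = 9.35)
res
head(indeterminacySweep(tab, critical = 9.35), 4)
```

The sweep holds the data (hence $Q_L$) fixed and rescales the upper
endpoint as $(1 + I_U) Q_L$ over the 20-point grid 0, 0.01–0.09,
0.1–1.0: a purely deterministic sensitivity analysis showing at which
indeterminacy level, if any, the decision leaves the do-not-reject
state. A rounding-provenance note: published renderings of this table
are computed from the three-significant-digit value 0.00664 rather
than the full-precision statistic 0.0066405, so full-precision sweep
values agree with them to about 1e-6 absolute but can differ in the
sixth decimal place (0.0073045 vs 0.007304 at $I_U = 0.1$). The package
stores full precision and leaves rounding to display.

## Monte Carlo calibration

The indeterminacy sweep is not a sampling experiment, so the operating
characteristics of the interval test are measured, not assumed.
`generateNullTable()` draws each group from a multinomial with a shared
probability vector (the $H_0$ sampling model); `estimateTypeIError()`
and `estimatePower()` run the test over seeded replicates and report
rejection and indeterminate rates with the binomial standard error
$\sqrt{r(1-r)/R}$. There is no published distributional statement for
$Q_U = (1+I_U) Q_L$ under $H_0$ referred to the unchanged critical
value; empirically, widening $I_U$ can only move rejections into the
indeterminate state (the suite checks this on paired seeds), so the
rejection rate at $I = [0,0]$ is the classical type-I error and is
calibrated near $\alpha$.

Problem sizes are chosen to be statistically meaningful yet quick: the
calibration check uses $h = 2$ groups of $n = 500$, $k = 4$ uniform
categories and 2000 replicates, for which three binomial standard
errors around 0.05 is ±0.015; the power check uses a strong composition
contrast ((0.4, 0.1, 0.1, 0.4) vs uniform) at $n = 500$ where the
noncentral approximation puts power essentially at 1. Randomness
follows a substream protocol: a root seed spawns one sub-seed per
replicate (or FASTA record), so results are bit-reproducible and
independent of execution order.

`generateSyntheticFasta()` closes the loop end to end: it writes
records whose base composition is exactly multinomial(length, p), and
`countNucleotides()` on the written file recovers the generated counts
identically. What the generators deliberately do not emulate: real
sequences are not i.i.d. letters (GC skew, repeats, positional
structure), real counting pipelines produce correlated errors rather
than a clean relative indeterminacy, and the second counting group of
the shipped example has no documented generating procedure — the
generator documents its own and does not claim to replicate it.
Passing tests therefore certify the arithmetic and the operating
characteristics under the stated sampling model, not the realism of
that model for any particular laboratory pipeline.

## Degenerate inputs and numerical choices

Counts must be nonnegative integers with at least two categories;
tables with a zero grand total, probability vectors containing zeros,
and homogeneity tests with a single group (degrees of freedom would be
0) are errors. Ties at the decision boundary resolve conservatively:
$Q_U$ exactly equal to the critical value is do-not-reject, $Q_L$
exactly equal is not a rejection. The statistic is accumulated in
double precision with no rescaling — with at most a few thousand cells
the naive sum is well within tolerance, as the 1e-10 relative agreement
with the brute-force oracle confirms.

## Limitations

* The indeterminacy interval is supplied by the user; the package
  neither estimates it from data nor propagates estimator-level
  indeterminacy.
* No small-sample exact or permutation test, no continuity correction,
  no multiple-testing adjustment — this is a single-table tool.
* The interval decision rule is a design choice of this package;
  published treatments compare only a single computed value to the
  critical value and do not define behaviour for straddling intervals.
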