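---
title: "Testing association with multiple covariate sets: model, null distributions and design choices"
author: "multigt authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing association with multiple covariate sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(multigt)
```

## The model and its test

`multigt` addresses a recurring question in integrative genomics: is a
response variable — one gene's expression, say — associated with a
*set* of high-dimensional covariates, such as the copy-number probes in a
megabase window around the gene, the methylation probes near its
transcription start site, or both at once?  With tens of covariates and a
few dozen to a few hundred samples, fitting a regression of the response
on all probes is hopeless, and probe-by-probe testing throws away the
signal that many small, coherent effects carry jointly.

The set-based view treats the per-covariate coefficients as random
effects.  For one covariate set $X$ ($N \times J$),

$$ E(Y_n) = \alpha + \sum_{j=1}^{J} \beta_j X_{nj},
   \qquad \beta_j \sim \mathcal N(0, \tau), $$

and "no association" becomes the single hypothesis $H_0: \tau = 0$.  The
score test of this variance component never fits the high-dimensional
model.  With $r = Y - \mu$ the residuals from the null fit (intercept
plus any confounders, by ordinary least squares), the statistic is the
ratio of quadratic forms

$$ Q(X) = \frac{r^t X X^t r}{r^t r}, $$

optionally standardized as $T = (Q - E[Q]) / \sqrt{\mathrm{Var}[Q]}$.
Only the $J$-dimensional cross-product $X^t r$ is ever formed, so a
genome-wide scan over tens of thousands of responses is cheap.

With a second set $Z$ (say methylation) and its own variance component,
the score vector at the null has one centered $Q$ per set, and three ways
of combining them are exposed in `joint_statistic()`:

* `sum` (default): $Q(X, Z) = \sum_m w_m Q_m$ with unit weights.  For
  unit weights this is *identical* to the single-set statistic of the
  column-merged matrix $[X\,|\,Z]$ — the joint test is one global test on
  the pooled covariates.  This identity is exact and is enforced to
  $10^{-10}$ relative tolerance in the test suite.
* `centered_squared`: $\sum_m w_m (Q_m - E[Q_m])^2$, the squared norm of
  the centered score vector.
* `standardized_sum`: $\sum_m w_m T_m$, which rebalances sets whose
  sizes, scales or variances differ strongly.

The weight $w_m$ realizes a fixed a-priori ratio between the
random-effect variances of the sets; it is a design choice, not a fitted
quantity, and defaults to 1 for every set.  Per-column centering and
scaling of covariates is available (`standardize = TRUE`) but off by
default, since raw covariate variance is part of what the pooled
statistic should weight; both behaviours are legitimate and the choice is
left to the analyst.

Nothing is estimated under the alternative: $\beta$, $\gamma$, $\tau$ and
link functions other than the identity are out of scope by design.

## Null distributions

Two routes to a p-value are implemented.

**Permutation (default).**  `permutation_pvalue()` permutes the residual
vector and recomputes the statistic.  Without confounders this is exactly
permuting the response; with confounders it is the usual approximate
residual-permutation scheme.  The estimator is add-one,
$p = (1 + \#\{Q^{(b)} \ge Q\}) / (1 + B)$, so $p \in (0, 1]$, the
smallest attainable value is $1/(B+1)$, and ties count against rejection.
When $N! \le B$ and no confounders are present the full permutation group
is enumerated and the p-value is exact.  One permutation stream, fixed by
the seed, is shared by all responses of a run: results are then identical
under any execution order, and p-values are comparable across responses
because every response faces the same null draws.

**Weighted chi-square ratio.**  Under the gaussian linear model the exact
finite-sample null law of the sum-mode statistic is

$$ Q \;\sim\; \frac{\sum_i \lambda_i \chi^2_{1,i}}{\sum_{j=1}^{d} \chi^2_{1,j}}, $$

where $d$ is the residual degrees of freedom and $\lambda_i$ are the
eigenvalues of the merged, weighted covariate Gram matrix projected onto
the residual space (`spectral_null()`, computed in $J$-space).
`asymptotic_pvalue()` rewrites $P(Q \ge q)$ as
$P(\sum_i (\lambda_i - q)\,\chi^2_{1,i} \ge 0)$ — zero eigenvalues padded
up to $d$ — and evaluates it by numerical inversion of the
characteristic function (Imhof-type integrand under adaptive quadrature,
absolute accuracy about $10^{-6}$).  For a single covariate this law
reduces to a scaled Beta$(1/2, (N-2)/2)$, which the test suite uses as an
independent closed-form check; permutation and quadrature p-values agree
within Monte-Carlo error on gaussian data.

The moments used for standardization are those of the rotation-invariant
null (residual direction uniform on the unit sphere of the residual
space): $E[Q] = \mathrm{tr}(A)/d$ and
$\mathrm{Var}[Q] = 2\,(d\,\mathrm{tr}(A^2) - \mathrm{tr}(A)^2) /
(d^2(d+2))$ with $A$ the projected $X X^t$.  For intercept-only nulls the
permutation mean of $Q$ coincides with $\mathrm{tr}(A)/d$ exactly (the
residuals sum to zero, and exchangeability does the rest); permutation
*variances* differ slightly from the spherical ones, which is harmless
because permutation p-values, not moment approximations, carry the
inference.  For the `centered_squared` mode no single-matrix spectral
representation exists, so p-values for that mode are permutation-only;
this also sidesteps any one- versus two-sided ambiguity.

Numerical edges: eigenvalues below $10^{-10}$ of the largest are treated
as zero; a statistic above the largest eigenvalue has p-value 0 and one
below the smallest support point has p-value 1; covariate sets that are
constant on the residual space are flagged (`var_q` undefined) and a
degenerate response (residual variance numerically zero) is an error at
`fit_null()` time and a flagged row in the genome-wide runner.

## Cis windows

`build_sets()` maps each covariate platform to per-gene sets: a probe
belongs to a gene's set when it lies on the same chromosome within
`flank_bp` of the transcription start site *in either direction*.  The
interval is closed — a probe exactly at the boundary is in — and strand
never affects membership.  Defaults used throughout the examples are
1 Mb for copy number and 50 Kb for methylation, reflecting the typical
reach of cis-acting dosage and methylation effects.  Chromosome labels
are compared after stripping a leading `chr` and case-folding.  BED
inputs (0-based, half-open) are converted on read; interval probes are
represented by their midpoint, since platforms rarely warrant anything
finer.  Genes whose window contains no probe are flagged, never dropped:
the genome-wide runner still tests them on their nonempty sets.
Duplicate probes at one position are retained — deduplication is a
platform-curation decision that the package does not take silently.

## The simulation engine

`simulate_linked_sets()` reproduces a transparent linkage design: $X$
entries iid $\mathcal N(1,\, 2.25)$ and $Z = \pm X + W$ with
$W \sim \mathcal N(0, \mathrm{var}_w)$, so matched probe pairs have
correlation $\pm\sqrt{2.25/(2.25 + \mathrm{var}_w)}$ — 0.83 for
$\mathrm{var}_w = 1$, 0.56 for $\mathrm{var}_w = 5$ — and unmatched pairs
are independent.  `simulate_from_covariance()` instead draws both blocks
from an arbitrary (empirical) covariance matrix, for correlation
structure closer to real platforms.

`simulate_region()` overlays four association-region effect types on a
matrix of response probes, the first `n_associated` of which are truly
associated: `x_only` (only $X$ drives the response), `additive` (both
sets, linearly), `multiplicative` (both sets plus their product) and
`complementary` ("split samples": $X$ drives the first half of the
samples, $Z$ the rest — two mechanisms in different sample subsets, the
pattern a joint test is uniquely placed to find).  Each associated
response tracks the *mean of a small window* of covariates (half-width 2)
around its matched index, exercising the set-based power argument rather
than a single-probe effect.

Three generator constants are not dictated by the design and were fixed
once at values a simulation study in this field would call realistic:
effect size $b = 0.5$ (signal comparable to but not dominating unit
noise), noise SD 1, effect-window half-width 2.  All are exposed as
arguments.  The sample split in `complementary` is deterministic
(first $\lceil N/2 \rceil$ columns) so that runs are reproducible.
Because these constants are choices, the simulator's guarantees are
checked as *properties and rankings* — type-I error calibration at zero
effect, higher AUC under strong positive linkage than under weak linkage,
the joint test beating the weaker individual test in complementary
regions — not as curve-matching.

What the generator does not emulate: heteroscedastic and heavy-tailed
expression noise, probe-level measurement artefacts, spatial correlation
along the genome beyond the linkage/covariance structure, and count-type
responses.  Passing tests therefore demonstrate calibration and relative
power under clean gaussian conditions, not performance claims on any
particular real data set.

## Genome-wide runs and summaries

`run_genomewide()` ties the pieces together: align samples by identifier
(never by position), build the windows, and for every response fit the
null, compute the individual statistics (e.g. a CN test and an ME test)
and the joint statistic, and attach p-values.  Sizes used in the bundled
examples and tests (tens of samples, tens to hundreds of probes, a few
hundred permutations) were chosen so that the entire suite illustrates
every code path at desk scale; all of them scale up linearly.

`summarize_selection()` applies the raw-p threshold selection
(default $\alpha = 0.001$; FDR adjustment is available behind a flag but
raw p-values make comparisons between tests and data sets cleaner) and
computes, genome-wide and per chromosome arm:

* **overlap** — of the responses selected by the joint test, the fraction
  also selected by one individual test;
* **new discoveries** — its complement: associations only the pooled test
  finds, typically many-small-effects cases;
* **dilution** — of the responses selected by an individual test, the
  fraction the joint test misses: the price of pooling a strong
  single-set effect with an uninformative set.

Ratios with empty denominators are reported as missing, never as zero.
Selection is at the response-probe level; collapsing probes to genes is
deliberately left to the user.

## Worked example

```{r example}
dir <- tempfile("fixture")
paths <- make_fixtures(dir, seed = 11)
res <- run_genomewide_files(paths$config)
head(res[, c("response_id", "arm", "n_cn", "n_me", "q_joint",
             "p_cn", "p_me", "p_joint")])
summ <- summarize_selection(res, alpha = 0.05)
subset(summ$ratios, scope == "genomewide")
```

The fixture plants copy-number associations in the first ten genes
(copy number is generated segmentally: a per-sample arm-level offset
shared by all probes on the arm, plus probe noise) and methylation
associations in five more.  At this toy scale the joint test recovers
genes from both groups; the dilution column shows which individually
found associations the pooled test loses.

## Known limitations

* Identity link and gaussian residuals only; no count or survival
  responses.
* The residual-permutation scheme with confounders is approximate (exact
  schemes would refit per permutation).
* The spectral route requires `sum` mode; other modes are
  permutation-only.
* No liftover, transcript-model resolution or annotation retrieval; the
  gene and probe annotations are taken as given.
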