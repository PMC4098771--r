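---
title: "Data-adaptive flagging of low-expressed genes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Data-adaptive flagging of low-expressed genes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dafs)
```

## The problem

A single RNA-seq sample mixes two populations of genes: a high-expressed
(HE) class whose log2 expression is approximately normal, and a
low-expressed (LE) class of noisy, weakly measured genes piled up at the
left of the distribution. There is no consensus constant — "10 reads",
"100 counts per million" — that separates them, because the boundary
depends on sequencing depth, library preparation, normalization and
species. This package estimates the boundary *from the sample itself*,
without imposing a mixture model on the data.

## The pipeline

`estimateCutoff()` runs four steps on one sample.

**1. Prepare.** Zeros on the count/RPKM/FPKM scales encode absence of
signal; they are removed, and the rest is log2-transformed
(`prepareSample()`). Input already on the log2 scale passes through
unchanged — a 0 there is data.

**2. K-S profile.** For each trimming percentile $p$ on an arithmetic
grid, take the strict upper tail $Y_p = \{x_i : x_i > x_{(p)}\}$ above
the empirical $p$-quantile and measure its agreement with a normal
reference by the scaled Kolmogorov–Smirnov distance

$$D_p = \sqrt{n_p}\,\sup_y\,|F_p(y) - F(y)|,$$

where $n_p = |Y_p|$, $F_p$ is the empirical CDF of the tail and $F$ is
the reference CDF (`ksDistance()`, `computeProfile()`). The grid starts
at $p_0$, the fraction of values tied at the minimum observed level (for
log2-transformed counts, the fraction of counts of 1), and stops at 0.50
so that at least half the data always describes the putative normal HE
component. The spacing is 0.01 by default; 0.005 is used automatically
for samples of 50,000+ values, where the finer grid no longer produces
many-to-one percentile-to-distance mappings. The grid is built by integer
index arithmetic, so spacing is exact.

**Reference parameters.** The reference normal is centered at the tail
*median* with the tail *standard deviation* as scale. This pairing is the
crux of the method's adaptivity: while LE contamination remains in the
lower reaches of the tail, the median stays anchored on the normal HE
bulk but the SD is inflated by the contamination, so $D_p$ keeps falling
as contamination is trimmed and reaches its minimum where the tail first
consists of the HE component alone. If the location were the tail mean,
it would drift left with the contamination, the fitted normal would
partially absorb it, and the profile minimum would appear several
percentiles early, placing the expression cutoff inside the upper tail
of the LE class.
The $\sqrt{n_p}$ factor is kept as part of the statistic (no
renormalization across the grid), so $D$ trends with tail size by
construction.

**3. Piecewise-linear fit.** The profile $p \mapsto D_p$ is modeled by a
one-dimensional adaptive regression spline (`fitMars()`): an expansion
$\hat f(x) = \sum_m \alpha_m B_m(x)$ in an intercept, an optional linear
term and reflected hinge pairs $(x-t)_+$, $(t-x)_+$ at knots $t$ chosen
from observed grid values. A greedy forward pass adds the
RSS-minimizing hinge pair until `maxTerms` (default 21) or until the RSS
improvement is negligible; a backward pass deletes terms one at a time
and returns the visited sub-model minimizing the generalized
cross-validation score

$$\mathrm{GCV}(M) = \frac{\mathrm{RSS}/N}{(1 - C(M)/N)^2},
  \qquad C(M) = M + \mathrm{penalty}\times K,$$

with $M$ basis terms, $K$ distinct knots and `penalty = 3` by default.
The knots of the pruned model are the points where the fitted slope
changes — the structure the cutoff rule reads.

**4. Cutoff.** `slopeChangePoints()` classifies each knot by the sign of
the fitted slope on its two sides; the optimal quantile cutoff $q_c$ is
the *left-most* knot whose pattern is decreasing-to-increasing (a local
minimum of the fitted profile). The expression cutoff is the empirical
$q_c$-quantile of the prepared values; for raw counts it is also reported
as $\mathrm{round}(2^{\mathrm{cutoff}})$. Genes at or below the cutoff
(and zero-expression genes) are flagged LE (`flagGenes()`).

## Numerical choices in the spline engine

* Candidate knots keep at least `minSpan = 2` observations from each data
  boundary (an end-span), preventing boundary knots that the pruning
  cannot reliably reject on 40–100-point profiles. No spacing constraint
  is imposed *between* interior knots: the greedy search routinely needs
  to refine within one or two observations of an earlier, provisional
  placement (the scaffolding knot is then pruned away), and a between-knot
  span rule blocks exactly that refinement.
* Ties in RSS reduction (within $10^{-12}$ relative) go to the smaller
  knot; the fit is fully deterministic.
* Hinges enter as pairs but are pruned individually.
* A segment slope below $10^{-8}\,\Delta y/\Delta x$ in magnitude counts
  as zero when classifying knots, so a decreasing-to-flat pattern is a
  bend, not a minimum — flat shelves do not trigger cutoffs.
* If the pruned model has no decreasing-to-increasing knot (data
  compatible with a single normal component), the pipeline falls back to
  the interior grid point minimizing the *fitted* curve and flags the
  result `fallbackUsed`. This keeps the contract total: degenerate input
  yields a bounded, reported cutoff rather than an error.

## The mixture comparator

The classical alternative models the sample as a two-component Gaussian
mixture
$f(x) = \pi_1\,\phi(x;\mu_1,\sigma_1^2) + \pi_2\,\phi(x;\mu_2,\sigma_2^2)$
and cuts at the crossing of the two weighted component densities.
`fitTwoComponent()` fits both the equal-variance and the
unequal-variance structure by EM and keeps the one with higher BIC
($2\log L - k\log n$; $k = 4$ or $5$).

The defaults emulate the canonical univariate mixture-fitting procedure
this comparator stands for: EM starts from the deterministic quantile
classification of the data (for two components, a hard split at the
median, with pooled or per-half variances as the structure dictates) and
iterates to a relative log-likelihood tolerance of $10^{-5}$, with no
random restarts. On overlapping, near-unimodal data this matters: a more
aggressive search (exposed via `restarts` and `tol`) can reach a
higher-likelihood optimum with a markedly different boundary and can
flip the BIC structure choice. Both behaviors are legitimate fits; the
default reproduces what the standard tool does, which is what a
comparator should do. Internally seeded restarts recover from degenerate
runs (a variance collapsing onto a point mass; variances are floored at
$10^{-6}\,\mathrm{var}(x)$), so the fit is a pure function of its input
in every case.

`intersectionCutoff()` solves $\pi_1\phi_1(x) = \pi_2\phi_2(x)$ in
closed form. With a common variance $\sigma^2$,

$$x_{\mathrm{evar}} = \frac{2\sigma^2\ln(\pi_1/\pi_2) +
  (\mu_2-\mu_1)(\mu_1+\mu_2)}{2(\mu_2-\mu_1)};$$

with unequal variances the condition is quadratic in $x$ and the root
inside $(\mu_1, \mu_2)$ is returned (when neither root separates the
means — extreme weight imbalance — the root nearer the midpoint is
used). The quadratic is solved in the numerically stable two-root form,
agrees with bisection to $10^{-8}$ and reduces to $x_{\mathrm{evar}}$
continuously as $\sigma_2/\sigma_1 \to 1$.

## The simulation harness

`simScenario()` provides two labeled five-component Gaussian generators
whose parameters are the study conditions themselves:

```{r scenarios}
simScenario("log2_count")
simScenario("log2_rpkm")
```

The first emulates a clearly bimodal log2 raw-count sample (LE =
components 1–2, mass 0.36); the second a heavily overlapping log2 RPKM
sample (LE = component 1, mass 0.11). Each replicate draws 5,000 values;
the full study uses 500 replicates. Replicate $r$ of a study seeded $s$
uses seed $s + r$, so shorter runs are prefixes of longer ones and every
result is exactly reproducible.

`runStudy()` applies, per replicate, any of: the adaptive pipeline
(`dafs`), the mixture comparator (`mixture`), and sensitivity-forced
cutoffs `sen85`/`sen90`/`sen95` — the empirical $(1-s)$-quantile
(linear-interpolation convention; differences between quantile
conventions are $O(1/n_{HE})$, well inside Monte-Carlo noise) of the
true-HE values. `evaluateCutoff()` scores each cutoff against the truth
labels (positive class HE, predicted HE strictly above the cutoff) and
the study reports mean ± SE of sensitivity/specificity/PPV/NPV and the
mean/2.5%/median/97.5% cutoff summaries.

**What the generator does and does not emulate.** Draws are continuous
Gaussian mixtures on the log2 scale: they reproduce the density shapes,
class overlap and class imbalance that drive the method's behavior, but
not the discreteness of low counts, the point mass at zero (handled
upstream by `prepareSample()`), technical-replicate correlation, or
multi-modal FPKM profiles. Passing the simulation study therefore
demonstrates correct recovery of a known LE/HE boundary under realistic
density shapes — not performance on any particular real library, where
the per-dataset grid step choice and preprocessing still matter.

## Problem sizes and test design

The unit suite checks the engines against independent oracles:
brute-force K-S sup computation on inputs up to 2,000 points, exhaustive
least-squares enumeration over all knot subsets of size ≤ 2 for the
spline engine, bisection for the density intersection, and the analytic
HE-mixture quantile for the sensitivity-forced cutoffs. The end-to-end
checks run the study at 100 replicates (500 for the cheap
sensitivity-forced cutoffs), sizes at which the Monte-Carlo error is a
few times smaller than the tolerances asserted; `scripts/acceptance.R`
reruns both scenarios at the full 500 replicates.

## Known limitations

* The method assumes an approximately normal HE component on the log2
  scale. `ksDistance()` accepts any reference CDF, but the pipeline does
  not expose alternative references; strongly non-normal HE components
  shift the profile minimum.
* Samples below ~1,000 expressed genes produce thin tails and a warning;
  below 100 the pipeline refuses to run.
* Cutoffs are per-sample by design. Multi-sample tables are processed
  column by column; no consensus cutoff is computed.
* The mixture comparator is restricted to two components; selecting or
  merging a larger number of components is out of scope.
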