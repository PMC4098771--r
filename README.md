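# dafs — data-adaptive flagging of low-expressed genes in RNA-seq

RNA-seq measures many transcripts at abundances too low to be biologically
meaningful, and there is no consensus constant — "10 reads", "100 counts per
million", "40% of the lowest-ranked genes" — that separates real signal from
noise: the boundary depends on sequencing depth, normalization, library
preparation and species. `dafs` estimates that boundary *from the sample
itself*, flagging each gene as low-expressed (LE) or high-expressed (HE),
for anyone who filters or down-weights low counts before differential
expression analysis.

## The method

For one sample, after removing zeros and log2-transforming, the package
profiles the agreement of quantile-trimmed upper tails with a normal
reference across trimming percentiles *p* from *p₀* (the fraction of values
tied at the minimum) to 0.50:

> D(p) = √n_p · sup_y | F_p(y) − F(y) |

where Y_p = { xᵢ : xᵢ > x₍p₎ } is the strict upper tail, n_p = |Y_p|, F_p
its empirical CDF, and F a normal CDF centered at the tail median with the
tail SD as scale. While LE contamination remains in the tail, the median
stays anchored on the HE bulk but the SD is inflated, so D falls until the
contamination is fully trimmed. A one-dimensional adaptive regression
spline (reflected hinge pairs, forward selection, GCV pruning) is fit to
p ↦ D(p), and the optimal quantile cutoff q_c is the left-most knot where
the fitted slope turns from decreasing to increasing. The expression cutoff
is the empirical q_c-quantile; for counts it is also reported as
round(2^cutoff).

A two-component Gaussian-mixture comparator is included: EM under equal and
unequal variance structures, BIC selection, and the closed-form intersection
of the weighted component densities. A simulation harness reproduces the
method's evaluation on two labeled five-component mixture generators
(bimodal log2 counts; heavily overlapping log2 RPKM) with
sensitivity/specificity/PPV/NPV scoring.

## Worked example

```r
library(dafs)

# a simulated log2-count sample with known LE/HE labels
d <- sampleScenario(simScenario("log2_count"), seed = 42)
sample <- ExpressionSample(d$values, scale = "log2", name = "sim42")

res <- estimateCutoff(sample)
res
#> DafsResult for 'sim42'
#>   q_c = 0.3302  (p0 = 0.0002)
#>   cutoff (log2 scale) = 6.1427

evaluateCutoff(d$values, d$labels, cutoffLog2(res))[
  , c("sensitivity", "specificity", "ppv", "npv")]
#>   sensitivity specificity    ppv    npv
#> 1       0.967       0.849 0.9179 0.9364

intersectionCutoff(fitTwoComponent(d$values))
#> [1] 5.4318
```

The estimated q_c of 0.33 says the lowest third of expressed genes in this
sample is noise-dominated; everything above log2 expression 6.14 (a count
of ~71) is flagged HE, capturing 96.7% of the true HE genes. The mixture
comparator places its boundary at 5.43 for the same sample.

`flagGenes(sample, res)` returns the per-gene LE/HE table;
`plotProfile(res)` shows the K-S profile, the spline fit and the selected
cutoff.

## Command line

A thin wrapper over the same functions is installed with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("scripts", "dafs", package = "dafs"))') \
  cutoff counts.tsv --all --scale raw_count --out cutoffs.tsv
```

Subcommands: `cutoff`, `profile`, `mixture`, `simulate`; exit status 0 on
success, 2 on input error.

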