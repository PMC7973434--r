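---
title: "Methods: colony-fitness analysis of SGA screens"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colony-fitness analysis of SGA screens}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical model, the synthetic-data
generator, the numerical choices and the known limitations of
`sgascreen`. It is the package's methods reference; nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## The measurement and its artifacts

A synthetic genetic array (SGA) screen pins each double mutant as a 2x2
block of four technical-replicate colonies on a 1536-position plate
(32 x 48), and repeats the whole cross in independent batches — with three
batches, every (library gene, query) pair contributes 12 colonies. Raw
colony areas carry several layers of structure that are nuisance for
fitness inference:

* plate-to-plate and batch-to-batch scale differences;
* row and column effects from pinning geometry and plate edges;
* smooth spatial gradients (agar thickness, temperature, imaging);
* correlation among the four colonies of a quadruplicate, which share a
  pinning source and a local neighbourhood;
* a variance that grows as colonies get smaller;
* outright growth failures (colony size 0), which are censoring events,
  not small fitness values;
* spurious "interactions" of genes physically linked to a query locus,
  because the double mutant is rarely recovered through meiosis.

Every analysis stage below addresses one of these.

## Normalization

Per plate, library-position sizes are log2-transformed (zero sizes become
missing), centred on the plate median, and polished: plate, row and column
medians are subtracted in turn until all are zero. Plain alternating
subtraction converges only at a power-law rate when rows and columns have
even counts (the median is then the midpoint of an order-statistic pair),
so after a few sweeps the remaining offsets are removed exactly by a
Newton step: once the middle order statistics are stable, "all medians
zero" is a linear system in one global, 32 row and 48 column offsets.
The practical consequence is that complete plates leave normalization with
plate/row/column medians at machine precision rather than at ~1e-6.

A smooth spatial surface is then subtracted: a 9x9 moving median of the
residuals, evaluated for each colony with its own quadruplicate block
excluded from the window. The exclusion matters: a surface estimated from
a window containing the colony's own block partially absorbs that block's
shared effect and any true interaction sitting there, attenuating both the
estimated technical-replicate correlation and strong effect sizes. A final
short polish restores the zero-median invariants.

All medians are computed over library positions only — deliberately empty
quadrants (guide positions) would otherwise bias them. Because every step
is a subtraction of medians of log2 values, the output is exactly
invariant to a global rescaling of raw sizes; units (pixel area vs mm^2)
are irrelevant.

Two residual imperfections are documented rather than hidden. First,
median polish still sees each gene's two colonies per row (of 48) and per
column (of 32), so very strong effects are attenuated by a few percent —
measured as a bias of ~0.05–0.09 log2 units on planted unit effects at
default noise, within the package's accepted effect-error budget of 0.2.
Second, the iterated polish has multiple nearby fixed points; perturbing
inputs at machine precision (e.g. a text round trip) can select a
neighbouring one, changing values by ~1e-4. Within one run everything is
exactly deterministic.

## Filtering

*Failed mutants.* A library gene is dropped from a batch (for all queries)
when its median control colony size is below `min_fraction` (default 0.1)
of its plate's median library size, strictly. The threshold is a package
default: published screens describe excluding mutants that "failed to
grow" on control plates without quantifying the cutoff; 10% of the plate
median cleanly separates failed blocks from small-but-growing ones in the
simulator and is configurable.

*Linkage.* Genes whose interval midpoint lies within 500 kb (inclusive) of
a query-locus midpoint on the same chromosome are excluded for the screen.
The window boundary convention (midpoints, inclusive) is a package choice;
published descriptions give only "within 500 kb". `run_pipeline()`
excludes the union over all query loci, because every reported contrast
involves the control query, whose own locus neighbourhood is equally
contaminated.

## The differential-fitness model

Per gene, normalized values follow

    value ~ 0 + query + batch

fitted by generalized least squares. Two covariance features are
estimated screen-wide and shared across genes:

*Mean-variance trend.* A robust lowess of sqrt(residual SD) against the
mean fitted log2 size (one point per gene, from preliminary unweighted
fits), discretized to 30 knots with flat extrapolation. Observation
weights are the inverse predicted variance (fourth power of the predicted
sqrt-SD). The regressor is the *fitted* mean rather than the raw size: the
fitted value is the model's estimate of the expected size, which is what
the generator's variance trend is a function of.

*Consensus replicate correlation.* Each quadruplicate is a block of
technical replicates. Per gene, a one-way ANOVA moment estimator on the
residuals gives an intra-block correlation (between-block degrees of
freedom reduced by the design rank, since query and batch are constant
within blocks); estimates are clamped to (-1/(k-1)+0.01, 0.99) and pooled
as a 15%-trimmed mean on the atanh scale, back-transformed. One shared
value is used because individual estimates from 12 blocks of 4 are far too
noisy. This estimator has a known small negative bias (~0.03–0.05 at this
block structure, slightly larger after median-based normalization); the
package accepts it because the downstream effect is mild conservativeness
of a few percent on raw p-values while Benjamini–Hochberg behaviour on
null screens remains clean, and because a single-number consensus is
robust against the heavy per-gene noise.

GLS uses the analytic inverse square root of the exchangeable block
correlation matrix — scaling by sqrt(weight) preserves the correlation
structure, so whitening needs no per-gene factorization. Genes whose
design loses a query entirely (e.g. per-query linkage exclusion) keep
their remaining contrasts; genes rank-deficient beyond that are dropped
and logged.

*Moderation.* Prior df d0 and prior variance s0² are estimated by moment
matching on log s² using digamma/trigamma relations, inverting the
trigamma numerically (Newton). When the moment estimate of the
between-gene excess variance is non-positive, d0 = Inf and the prior is
the df-weighted pooled variance — pooled rather than the raw geometric
mean because the geometric mean of chi-squared variance estimates is
biased low by exp(digamma(d/2) − log(d/2)), which would inflate every
moderated statistic; the pooled variance is unbiased and coincides with
the common value when all per-gene variances are equal. The posterior is
the usual pooling formula, and moderated t-statistics use d0 + d_g degrees
of freedom.

*Contrasts and calling.* Each mutant vs control, and each mutant vs the
reference deletion. Two-sided p-values, BH-adjusted within each contrast
(each contrast is its own screen report). A gene is called at
`padj < alpha` (default 0.05) with its sign from the effect — no
effect-size floor. The +-0.5 log2 thresholds that appear in cluster
displays are reporting colors only, never calling rules.

## Trifecta classification

For an allele A, reference deletion B and control, with contrasts
A−control (A), B−control (B) and A−B (D), priority rules (first match
wins):

1. D significant, B not → `unique_gain_{sign}` (sign from A when A is
   significant, else from D): an interaction the allele has gained.
2. D and B significant, opposite signs → `residual_restored`: the allele
   reverts the deletion's interaction — retained function.
3. D and B significant, same sign → `increased_sensitivity`.
4. A and B significant, same sign, D not → `shared_{sign}`: function lost
   by both alleles alike.
5. otherwise `none`.

The priority order resolves genes that satisfy several quadrant
descriptions at once; unique gain is ranked first because it is the
category defined by the strictest explicit criterion (allele-vs-reference
difference with a silent reference). The "combined significance" score of
the 2D-volcano tables is the more significant (smaller) adjusted p-value
of the pair on a −log10 scale.

## Enrichment and disease mapping

One-sided hypergeometric over-representation per term, with term gene sets
intersected with the background first, BH across all terms of a
collection, and an FDR flag at 0.1. The background is the post-filter
screen universe (all genes that survived the failed-mutant and linkage
filters) — the statistically defensible choice, since only those genes
could have been called. Depletion is not tested. Disease mapping is a
plain per-disease intersection; a gene may contribute to several diseases.

## The synthetic-screen generator

The generator is first-class, tested code; its defaults are the study
conditions the package validates against:

| parameter | default | meaning |
|---|---|---|
| `n_genes` | 1000 | library size (desk-scale stand-in for ~3–5k) |
| `n_chromosomes`, `spacing` | 3, 25 kb | regular genome; 500-kb windows then cover a realistic few % of the library |
| queries | 3 mutants + control | mutants share one locus (alleles of one gene) |
| `n_batches`, `quad` | 3, 4 | 12 colonies per double mutant |
| `base_log2` | 10 | baseline colony size (~1024 area units) |
| `sigma0` | 0.3 | colony-level log2 SD |
| `trend_strength` | 0.3 | SD inflation per log2 of expected size deficit |
| `rho` | 0.4 | intra-quadruplicate correlation |
| `batch_sd`, `rowcol_sd`, `spatial_amplitude` | 0.2, 0.1, 0.2 | nuisance magnitudes (log2) |
| `dropout_p` | 0.02 | colony failure probability |
| `frac_pos`, `frac_neg` | 0.05, 0.05 | planted interaction fractions per mutant |
| effect magnitude | \|N(1, 0.3)\| | placeholder; raw effect-size distributions are not published |
| linkage artifact | −1.5·(1 − d/500 kb) | additive fitness dip inside the window |

Colony size is `2^(base + delta + linkage_penalty + batch + row + col +
spatial + block + eps)`: the block effect is shared by the four colonies
of a quadruplicate and carries fraction `rho` of the variance; `eps` has
the trend-inflated SD; dropouts and empty positions are emitted as size 0.
Linked genes get no special interaction effect — the linkage dip is an
additive artifact, precisely so the 500-kb filter can be tested against
it.

What the generator does **not** emulate: mating/sporulation efficiency,
pinning-source carryover between plates, image segmentation errors,
non-log-normal size distributions, and gene-gene epistasis beyond the
query contrasts. Passing tests therefore demonstrate correctness of the
statistical machinery under the stated generative model, not robustness to
every artifact of real plates.

Scale choices: validation runs use a 1000-gene library (null calibration,
recovery), 700 genes (trifecta) and 800 genes (linkage coverage) — large
enough for stable screen-wide estimates (the consensus correlation and
trend want several hundred genes) while keeping a full 20-screen
calibration affordable on one CPU.

## Numerical and degenerate-input conventions

* Grid indices are 1-based, top-left origin (common quantifier output).
* Gene position = interval midpoint; BED coordinates 0-based half-open.
* Zero/failed colonies are missing values downstream, except in the
  failed-mutant rule where they are evidence.
* PCA component signs are fixed by making each component's
  largest-magnitude loading positive; missing values are imputed by gene
  means for display analyses only.
* Clustering default is uncentered correlation distance with average
  linkage (the defaults of the classic colony-screen clustering tool);
  constant-zero profiles get the maximal distance 2 with a warning.
* Ties in clustering are broken by input order via the standard
  agglomeration implementation.
* `run_pipeline()` writes a manifest (package version, seed, config and
  input hashes) so identical inputs reproduce identical outputs.

## Known limitations

* The consensus-correlation estimator's small negative bias (above) makes
  raw p-values mildly anticonservative (a few percent at alpha = 0.05
  under a matched model with the estimated consensus); BH-level error
  control on null screens is unaffected in all simulations the suite runs.
* Median polish attenuates very strong effects by a few percent; effect
  estimates are best interpreted comparatively, as in the trifecta plots.
* The spatial estimator is a stand-in for whatever the original
  colony-processing protocol used; a 9x9 moving median was chosen for
  robustness to true interactions and has no tunable smoothness beyond
  the window size.
* Enrichment results depend entirely on the annotation collections and
  background supplied; the package ships none.
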