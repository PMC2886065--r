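---
title: "Liquid-association scouting: model, conventions, and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Liquid-association scouting: model, conventions, and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lascout)
```

## The statistic

Correlation finds gene pairs that move together; liquid association
(LA) finds the third gene that decides *when* they move together. For
three profiles $X, Y, Z$ observed over $n$ conditions and standardized
to a common Gaussian scale, the LA score is

$$\mathrm{LA}(X, Y \mid Z) \;=\; \frac{1}{n}\sum_{i=1}^{n} X_i Y_i Z_i .$$

For standard-normal triples this equals $E[Z \cdot \rho(X,Y \mid Z)]$
under mild regularity: it is the covariance between the mediator's
level and the conditional correlation of the pair. A positive score
means the pair co-expresses more strongly when $Z$ is high ("positive
LA-scouting gene"); a negative score the reverse. The statistic is
fully symmetric in its three arguments, which the search modes exploit.

`scout_z()` fixes a lead pair $(X, Y)$ and ranks every other gene as a
candidate $Z$; `search_pairs()` fixes one lead $X$ and ranks every
unordered pair $(Y, Z)$; `lead_set_report()` runs `scout_z()` over all
pairs from a lead gene set and emits the tabular schema
(X, Y, Z, LA score, high/low subgroup correlations, p-value, place).

## Gaussianization and batch handling

Expression compendia assembled from several experimental series mix
incompatible scales. The pipeline's only batch correction is a
rank-based **normal-score transform applied per gene within each
series**: the value with rank $r$ among $m$ observed values in a batch
becomes $\Phi^{-1}(r/(m+1))$ (van der Waerden scores, the convention of
the LA literature; Blom's $\Phi^{-1}((r - 3/8)/(m + 1/4))$ is available
as an option). Ties receive the average rank before mapping, which
keeps the transform deterministic and order-independent; a
`stable_order` policy is provided for sensitivity checks. The
transformed batches are concatenated back in the original sample order
and are *not* re-standardized globally: the LA score divides the raw
triple sum by the sample count, and a global re-centering option exists
only for sensitivity analysis.

Consequences worth knowing:

* The transform is invariant under any strictly increasing per-batch
  relabeling of the data, so it is insensitive to monotone scale
  differences between series.
* A batch's transformed profile is a permutation of a fixed quantile
  grid whose variance is $< 1$ (about 0.84 at $m = 20$). Products of
  three such profiles are therefore attenuated relative to the
  population value $E[Z c(Z)]$; at the 88-sample, three-batch scale the
  sample LA of a planted triple sits noticeably below its asymptotic
  target (the acceptance script reports this attenuation explicitly as
  `mean_la_bias_88`), while at $n = 5000$ in a single batch it matches
  the analytic value within Monte-Carlo error. Rankings are essentially
  unaffected because all candidates are attenuated alike.
* A gene with fewer than two observed values in a batch cannot be
  scored there; it is masked for that batch and flagged, never imputed.

## Missing data and the denominator

Spotted-array tables contain blanks, so every operation works on
complete $(x, y, z)$ triples. The default denominator is the number of
complete triples actually used, keeping the score a mean; a `total_n`
policy divides by the full profile length instead, which reproduces the
fixed-denominator convention on complete data and shrinks scores
proportionally under missingness. At least three complete triples are
required, otherwise the triple errors out (or is dropped from a scan).

## Ranking conventions

TOP and BOT lists are the two signed ends of the candidate ranking,
with 1-based places. Equal scores are ordered lexicographically by gene
id — an arbitrary but reproducible tie-break. Candidates exclude the
lead genes themselves (self-mediation is degenerate). `search_pairs()`
reports each unordered pair once, members labelled in gene-id order,
because the statistic is symmetric in $(Y, Z)$. The default list length
of 20 per end matches standard scouting practice.

## Significance

Printed p-values for LA scores have no single canonical recipe, so two
methods are implemented and the choice is explicit:

* **Permutation** (`permutation_pvalue()`): the mediator profile is
  shuffled $B$ times and $p = (1 + \#\text{extreme})/(B + 1)$. The
  default scope shuffles **within each batch**, respecting the
  per-series transform; a global scope is available. Default
  $B = 10{,}000$; the draw is seeded and leaves the caller's RNG state
  untouched. The sign-matched one-sided p (default) corresponds to the
  signed ranking ends; note that under the null it is uniform on
  $(0, \tfrac12]$ by construction, so null-calibration checks use the
  two-sided variant.
* **Asymptotic** (`asymptotic_pvalue()`): $\sqrt{n}\,\mathrm{LA}$ is
  approximately standard normal for independent normal-scored profiles
  (a mean of bounded, near-unit-variance products), giving a tail
  p-value without resampling. Because the quantile-grid variance is
  slightly below 1, this p is mildly conservative-to-anticonservative
  at small batch sizes; the two methods agree within Monte-Carlo error
  at $n = 88$ on Gaussian nulls (tested).

`lead_set_report()` uses the asymptotic method by default so that
multi-pair reports stay interactive; pass
`pvalue_cfg = list(method = "permutation", ...)` for the resampling
p-value. Reported p-values are descriptive; no multiplicity correction
is applied across a genome-wide ranking, and places — not p-values —
are the primary evidence ordering.

The **null-pool experiment** (`null_pool_experiment()`) asks how often
a target gene would emerge as the place-1 positive scout for random
lead pairs drawn from a pool of process-irrelevant genes. Pairs are
drawn uniformly without replacement among distinct unordered pairs
(seeded, with the full draw returned for audit), each pair is scouted
over *all* candidate genes, and the count divided by the number of
pairs estimates the chance detection rate. "Leading" means place 1 of
the positive end; a flag is not provided to widen this because the
positive end is what defines a scouting claim, but both ends are
available from the underlying `scout_z()` call. The pool is
user-supplied (typically "everything except the named pathway genes"),
since any fixed irrelevance list is a scientific judgement, not a
package default.

## LAP views

`lap_split()` sorts samples by the mediator and contrasts the Pearson
correlation of the lead pair within the high and low subgroups. The
default is a median split: all mediator-observed samples are
partitioned into halves differing by at most one sample, with no
excluded middle. Smaller fractions (e.g. 0.25) take the top and bottom
tails and exclude the middle, which sharpens the contrast at the cost
of sample size. Published analyses do not always state their split
convention, and different conventions give visibly different subgroup
correlations for the same triple — which is why the fraction and the
data space (transformed by default, raw optional) are explicit
arguments rather than hidden constants. Ties at a cut are resolved by
sample order; a constant mediator therefore yields a deterministic,
order-based split rather than an error. Subgroups need at least three
complete pairs; a constant lead profile within a subgroup yields a
flagged `NA` correlation rather than a crash.

## The synthetic generator

`generate_dataset()` draws background genes i.i.d. standard normal per
sample and plants triplets $(X, Y, Z)$ with $Z \sim N(0,1)$ and
$(X, Y) \mid Z$ bivariate normal with unit variances and correlation
$c(Z)$. The mediation families keep $|c| < 1$ everywhere:

* `tanh`: $c(z) = \rho_{\max}\tanh(\kappa z)$ — smooth, saturating;
  the default study condition is $\rho_{\max} = 0.9$, $\kappa = 1$,
  chosen as a strong-but-not-degenerate mediation whose population LA,
  $E[Z c(Z)] = 0.545$, sits in the range of scores a genome-wide scan
  flags as leading.
* `linear_clipped`: $c(z) = \rho_{\max}\,\mathrm{clip}(\kappa z, -1, 1)$.
* `constant`: no mediation; the analytic LA is exactly 0, making it the
  negative control.

The analytic expectation `expected_la()` uses 64-node Gauss–Hermite
quadrature for the smooth tanh family and closed-form normal moments
for the kinked clipped family (where polynomial quadrature converges
too slowly to honor the 1e-8 accuracy contract); the test suite
cross-checks both against adaptive quadrature.

Default batch sizes are 20, 60 and 8 samples — three series of the
size structure typical for a merged bacterial stress-response
compendium — so that synthetic runs exercise the per-batch transform
path, not just a single homogeneous panel. Missingness is
missing-completely-at-random only. The generator does **not** emulate
two-channel array noise physics (dye bias, spatial artifacts),
correlated background structure (operons, regulons), or informative
missingness; passing tests on synthetic data therefore demonstrate
algorithmic correctness and statistical calibration, not robustness to
every artifact of real microarray data.

## Problem sizes and numerical choices

The test suite and the acceptance script run at deliberately modest
scales chosen to make every stochastic check stable: exhaustive-oracle
comparisons at 50 genes × 40 samples (tolerance 1e-10 against naive
triple loops), recovery over 50 replicate genome scans of 200 genes ×
88 samples, consistency at $n = 5000$, null calibration from hundreds
of replicates at $B$ in the low thousands, and null-pool draws of a few
hundred pairs. The vectorized scan is a dense matrix product, so a full
genome (~5,000 genes × 88 samples) scout takes milliseconds and a full
single-lead pair search a few seconds. Seeds are explicit arguments
everywhere randomness enters; seeded helpers restore the caller's RNG
state.

## Known limitations

* The per-series normal score is the only batch handling; systematic
  effects that reorder samples within a series are not corrected.
* The asymptotic p-value ignores the finite-sample variance deficit of
  quantile scores (see attenuation above).
* Probe-to-gene collapsing (`collapse_probes()`) is off by default;
  running on probe-level rows and on collapsed rows gives different
  scores, and the choice is the user's.
* Reported subgroup correlations depend on the split convention; when
  comparing against published tables or plots, match the fraction and
  data space explicitly.
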