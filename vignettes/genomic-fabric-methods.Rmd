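---
title: "Methods: variability, adaptive cut-offs and expression coordination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variability, adaptive cut-offs and expression coordination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genofabric)
```

## The model

`genofabric` analyses two-color spotted-microarray experiments in which a
small number of biological replicas (typically 4 per condition) are
profiled on arrays that probe each gene with one or more redundant spots.
Two samples of the same experimental group are co-hybridized per array,
one per channel (Cy3/Cy5). The framework extracts three independent
characteristics per gene and condition:

1. **Level** — the normalized, redundancy-aggregated expression value per
   replica, and its mean.
2. **Variability (REV)** — a chi-squared interval-corrected pooled
   coefficient of variation across replicas and spots, in percent.
3. **Coordination** — the Pearson correlation of the gene's replicate
   levels with those of every other gene.

The premise is biological: genes whose products must appear in fixed
stoichiometry coordinate their transcription, and genes critical to the
tissue are held at low variability by homeostatic control. Changes in the
coordination structure of a pathway ("fabric remodeling") can therefore
reveal regulation that per-gene fold changes miss.

## Spot filtering and normalization

A spot is retained only if it is unflagged and its foreground is at least
twice its background **in every profiled sample**; one bad sample discards
the spot everywhere, keeping the spot universe identical across replicas.
The boundary case `fg == 2 * bg` is kept, reading the exclusion rule
("less than twice") literally.

Normalization alternates two median-scaling steps on the
background-subtracted valid spots — each array-channel sample to the
global median, then each array to the global median — and stops when the
maximum relative change of any value between successive iterations falls
below `tol` (default 0.05, i.e. the documented 5% stopping level; the
stopping functional is our concrete, testable realization of the original
method's "maximum error of estimate"). Median scaling removes exactly the
multiplicative per-(array, channel) effects the generator plants, is
idempotent, and is equivariant under global rescaling. Non-positive
background-subtracted signals are floored at `1e-3` times the smallest
positive net signal and counted; with the validity filter in place this
path is rarely taken.

Redundant spots are aggregated per gene and replica by a weighted mean.
The weights are inverse squared across-replica spot CVs (renormalized to
sum to 1), falling back to equal weights when any member spot has zero or
undefined CV; an `equal` scheme is available via the `weights` argument.
The weighted average always lies within the member-spot range.

## REV and GES

For gene $i$ with $R_i$ spots and $n$ replicas,

$$\mathrm{REV}_i = \underbrace{\tfrac12\left(\sqrt{r_i/\chi^2_{r_i;0.975}}
+ \sqrt{r_i/\chi^2_{r_i;0.025}}\right)}_{\text{correction}}
\; \underbrace{\sqrt{\tfrac1{R_i}\sum_k (s_{ik}/\mu_{ik})^2}}_{\text{pooled CV}}
\times 100\%, \qquad r_i = nR_i - 1.$$

The quantile convention is fixed so that the correction exceeds 1
(2.1475 at $r=3$, 1.3482 at $r=7$, $\to 1$ as $r \to \infty$): its role is
to widen a CV estimated from few measurements, and the interval midpoint
with the opposite tail assignment would shrink it instead. The correction
is strictly decreasing in $r$, so redundancy directly buys certainty.

GES converts REV ranks (decreasing, average ranks for ties) into midpoint
percentiles $100(\mathrm{rank}-0.5)/N$. The midpoint form keeps extremes
inside $(0, 100)$ and is deterministic; the most variable gene lands below
the 1st percentile for $N \ge 50$ and the most stable above the 99th.
Genes with any non-positive spot mean have no defined CV; they are
excluded from REV and from the GES ranking rather than being assigned a
value. Stable-gene counting (`count_stable`) uses a strict `REV < 10`
threshold; the GES-shift screen flags genes whose stability percentile
moves by more than 50 points between conditions, the scale of moves that
single out genes switching from tight to loose control.

## Regulation calls

The signed fold change is the means ratio oriented so that $|x| \ge 1$,
with equality of means falling in the positive branch. The per-gene
cut-off $\mathrm{CUT} = 1 + \sqrt{2(\mathrm{REV}_A^2 +
\mathrm{REV}_B^2)}/100$ rises with the gene's own noise, replacing a
uniform fold threshold; at REV 10%/10% it is 1.2, at 25%/25% it is 1.5.
The significance test is the heteroscedastic (Welch) t-test on the
gene-level replica values (4 vs 4), matching the redundancy-aggregated
representation the criterion operates on; spot-level testing is
deliberately not the default because spots of a gene share the same RNA
pool. No across-gene multiple-testing correction is applied: the
multiplicity control of the framework lives in the per-gene widening of
REV (and hence CUT) through $r_i = nR_i - 1$, which is how the composite
criterion suppresses false positives without an FDR stage. Both groups
constant makes the p-value undefined; such genes are excluded and
reported.

## Coordination and fabric remodeling

Correlations are computed on normalized **linear** levels, the scale the
REV/CUT machinery operates on (`log2 = TRUE` switches to log scale).
With 4 replicas the one-sided $p<0.05$ critical correlation, obtained by
inverting $t = \rho\sqrt{n-2}/\sqrt{1-\rho^2}$, is 0.8999 — hence the
class thresholds: synergistic $\rho > 0.90$, antagonistic $\rho < -0.90$,
independent $|\rho| < 0.05$, all strict, with boundary values left
unclassified. For other replica counts `critical_rho(n, alpha)` supplies
the matching threshold while the independence band stays at 0.05 unless
overridden.

Profile similarity admits two natural definitions — overlap of classified
partners, and goodness of a linear fit between the two profile vectors.
Both are computed; the $R^2 \ge 0.9$ rule (with the slope sign choosing
similar vs opposite) decides the class, and the shared
synergistic/antagonistic/independent partner counts are reported
alongside. Profiles overlapping in fewer than 10 genes are classed
neutral with a warning. For pathway summaries, the similar-profile
percentage is taken over **all evaluable within-set pairs** — the
denominator choice is documented here precisely because alternatives
(e.g. expression-filtered pairs) exist.

Whole-transcriptome class counting does not materialize the full
$n \times n$ matrix: `coordination_class_counts()` streams tiles of
standardized rows and is tested to agree exactly with the naive scan.

## Enrichment

Gene sets are ranked by the standardized hypergeometric deviation
$Z = (r - nR/N)/\sqrt{n\,\tfrac RN(1-\tfrac RN)(1-\tfrac{n-1}{N-1})}$
with a seeded permutation p-value (draws of $R$ positives among $N$,
smoothed by $+1/(n_{\mathrm{perm}}+1)$), flagged significant at $Z > 2$
and $p < 0.05$. The Z formula is verified in the test suite against
exact hypergeometric moments obtained by enumeration.

## The synthetic-data generator

The generator emulates the study design the pipeline targets: two
conditions × 4 replicas, two samples per array (one per channel),
redundant spots per gene, log-normal expression with per-gene CV,
multiplicative per-(array, channel) scaling, additive background, a
corrupted-spot fraction, planted DEGs and planted coordination modules.
Design choices worth making explicit:

* **Noise model.** Replicate signals are log-normal around the condition
  mean at the planted CV — the standard model for fluorescence
  intensities, and the one that keeps "CV" well defined at every level.
* **Spot redundancy.** Each (spot, replica) value is an independent
  draw at the planted CV. This matches the degrees-of-freedom
  bookkeeping $r = nR - 1$, which treats every spot as an independent
  measurement; it is the regime in which pooling $R$ spots genuinely
  sharpens the CV estimate. Genes inside planted modules instead share
  their replicate factor across spots, so that the gene-level
  correlation equals the module target after aggregation.
* **Modules.** `plant_correlation()` mixes a common standardized
  replicate factor into each member so the *expected* pairwise
  correlation equals the target, preserving marginal means and spreads.
  Its `exact = TRUE` mode rebuilds members from an orthonormal basis of
  the centered sample space (a Gram-matrix square root), making every
  pairwise *sample* correlation exactly the target; this requires module
  size $\le$ replicas $- 1$ and is what the remodeling tests use, since
  with 4 replicas a stochastic $\rho = 0.97$ spreads widely around its
  target (Fisher-z standard error 1) and exact pair counts could not
  otherwise be asserted. Negative targets flip the factor sign for half
  the members (an all-pairs-negative module is impossible below
  $-1/(k-1)$).
* **Corruption.** A corrupted spot is, with equal probability, flagged
  or given `fg < 2 * bg` in one random sample — exactly the signatures
  the validity filter is specified to catch, which couples the generator
  to the filter contract.
* **Planted folds** multiply (up) or divide (down) the second condition's
  mean, matching the sign convention of the fold-change branch.
* **Defaults.** 1,000 genes × 2 spots (the redundancy scale of 4x44k
  rat arrays carrying ~17,657 unigenes), log-normal baseline around
  1,000 a.u. (log-sd 1), CVs 5–35% (REV roughly 7–50% after correction),
  1.1% DEGs at 1.5–6×, 2% corrupted spots, array-scale log-sd 0.2,
  background 50 a.u. One seed fixes all randomness; identical
  configurations reproduce byte-identical tables.

What the generator does **not** emulate: spatial array artifacts,
scanner-level saturation, dye-specific (as opposed to channel-scale)
bias, probe-sequence effects, and correlated spot noise outside planted
modules. Passing the validation suite therefore demonstrates the
statistical machinery is implemented correctly and recovers planted
structure under the stated noise model — not that any particular
biological dataset satisfies that model.

## Numerical choices and edge cases

* Background-subtracted signals $\le 0$ are floored (smallest positive
  net × $10^{-3}$) and counted; normalization caps at `max_iter = 50`
  and reports its convergence trace.
* REV/GES tie-breaks use average ranks; the GES mean is exactly 50.
* All class boundaries (0.90, −0.90, 0.05; `REV < 10`) are strict, and
  the boundary values themselves are tested.
* Fold change requires strictly positive means; equality takes the
  positive branch, making `fold_change` antisymmetric off the diagonal.
* `sim_config` validates every field (fractions in $[0,1]$, folds
  $\ge 1$, $|\rho| \le 1$) and round-trips through YAML at 16-digit
  precision.

## Validation problem sizes

The package validates itself on synthetic data sized to run comfortably
on a laptop: parameter-recovery runs use 2,000 genes × 2 spots × 4
replicas per condition (median pooled CV within ±10% of a planted 0.15;
planted 4–6× DEGs recalled at ≥ 90% with ≤ 5% false positives);
correlation machinery is verified against brute-force oracles on ≤ 50
gene instances to $10^{-12}$; remodeling deltas are checked exactly on
constructed 3-gene modules. A run of the full pipeline on 2,000 genes
takes a few seconds.

## Known limitations

* With a single spot and 4 replicas ($r = 3$) the *median* of the
  pooled-CV estimator sits ≈ 11% below the true CV (the median of
  $\chi^2_3$ is 2.37, not 3); the chi-squared correction widens the
  estimate into an interval midpoint but is not a median-bias
  correction. Redundancy ($R \ge 2$) pulls the median within ±10%,
  which is why parameter-recovery checks run at the default $R = 2$.
* With 4 replicas, sample correlations are noisy (Fisher-z SE 1); class
  counts on real modules are estimates, and the 0.90 threshold controls
  the per-pair error rate only, not any across-pair multiplicity.
* The enrichment background and positive set are the caller's choice;
  results are database- and universe-dependent.
* The importer for externally normalized matrices assumes the package's
  own two-row-header TSV dialect, not vendor raw formats.
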