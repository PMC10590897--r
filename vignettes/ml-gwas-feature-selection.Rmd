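---
title: "VIP-guided SNP selection for classifying herbicide-damage tolerance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{VIP-guided SNP selection for classifying herbicide-damage tolerance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Off-target dicamba drift injures non-tolerant soybean, and the severity of
the symptoms depends on the genetic background of the line. Field programs
rate damage visually on a 1–4 scale (0.5 increments) across multi-environment
trials and want to know (i) which genomic regions drive the differential
response and (ii) whether a small SNP panel can classify new lines as
tolerant, moderate or susceptible before they are ever exposed.

With thousands of chip SNPs and only a few hundred lines, fitting a
classifier to all markers overfits badly. `mlgwas` implements a supervised
feature-selection pipeline that funnels the full SNP set down to a handful of
informative, mutually uncorrelated predictors:

1. **Phenotype adjustment.** Plot-level ratings are adjusted to per-genotype
   least-squares means under a REML linear mixed model and binned into
   tolerance classes.
2. **PLS/VIP scoring.** A partial-least-squares regression of adjusted scores
   on all dosages ranks SNPs by Variable Importance in Projection.
3. **Thresholding and pruning.** SNPs with VIP < 2.0 are discarded; among the
   survivors, any pair with |r| ≥ 0.7 loses its lower-VIP member.
4. **Forward stepwise classification.** Random-forest and radial-SVM models
   grow a SNP subset greedily under 5-fold cross-validation, recording the
   full metric trace and the overfitting curve.

A synthetic-data module simulates the whole setting — LD-blocked genotypes,
planted QTL, multi-environment ordinal ratings — so every stage is testable
without field data.

## The phenotype model

Each plot rating is modelled as

$$y_{ijr} = g_i + e_j + (ge)_{ij} + r_{jr} + \varepsilon_{ijr},$$

with genotype $g_i$ fixed and environment $e_j$, genotype-by-environment
$(ge)_{ij}$ and replicate-within-environment $r_{jr}$ random, fitted by REML
(`lme4`). Because genotype is the only fixed term, the fixed-effect estimates
are exactly the estimated marginal (ls-) means at equal environment weights:
random effects are integrated out at zero, and genotypes observed in
different environment subsets stay comparable through the shared environment
effects. The ordinal ratings are treated as numeric — a linear mixed model on
the scores, not an ordinal link — which mirrors standard practice for this
scale and keeps the adjusted means on the familiar 1–4 metric.

Classes follow the adjusted score: tolerant ≤ 2 < moderate ≤ 3 < susceptible.
Both boundary values are deliberately inclusive on the less-severe side
(a score of exactly 2 is tolerant, exactly 3 is moderate).

A closed-form fallback (`method = "balanced"`) returns plain genotype means
on complete balanced designs; the REML fit reduces to it there, which the
test suite checks to 1e-6.

## PLS, VIP and the funnel

PLS1 is fitted by NIPALS on column-standardized dosages and a standardized
response. Standardizing dosages (the common convention for chip data) makes
VIP comparable across minor-allele frequencies. The component count is chosen
by 10-fold cross-validation of RMSEP under the one-standard-error rule: the
smallest count whose mean CV error is within one SE of the minimum. This
operationalizes "few components with low validation error" reproducibly; a
fixed count can be forced via `n_components`.

For predictor $j$,

$$\mathrm{VIP}_j = \sqrt{\frac{p \sum_a SS_a\, (w_{ja}/\lVert w_a \rVert)^2}{\sum_a SS_a}},$$

where $w_a$ is the weight vector and $SS_a$ the response sum of squares
explained by component $a$. The squared VIPs average to exactly 1 over the
$p$ predictors — an analytic identity the acceptance suite verifies to 1e-6
on a simulated 300 × 1,000 panel — so thresholds above 1 select predictors
with an above-average share of the fitted response index. The default cutoff
of 2.0 follows the recommendation for settings with many more predictors
than observations and strong multicollinearity. The implementation is
cross-checked in the tests against both a directly coded evaluation of the
formula and `mixOmics::vip`.

Pruning is a greedy pass in descending VIP order: keep a SNP iff its absolute
Pearson correlation with every already-kept SNP is below 0.7. This is
deterministic, independent of input order (the order is re-derived from the
VIPs, ties broken by genome position), always discards the lower-VIP member
of a violating pair, and ends with max pairwise |r| < 0.7. An exhaustive
enumeration oracle in the tests confirms the greedy outcome is always
reachable under the pairwise drop rule.

## Stepwise classification

`evaluate_subset()` runs stratified 5-fold CV (stratification keeps all three
classes in every fold under the typical ~19/62/19 mix) and pools out-of-fold
predictions into one confusion matrix. Overall accuracy is
correct/total (Eq.-style percentage at the report surface, proportion in the
trace); per-class accuracy, precision and specificity use one-vs-rest
TP/TN/FP/FN counts, with precision reported as "–" when a class is never
predicted.

The random forest uses 500 trees (a conventional default; the count is not
critical) with ⌊√p⌋ features per split. The radial SVM tunes cost
{0.01, 0.1, 1, 10, 100, 1000} × gamma {0.0001, 0.001, 0.01, 0.5, 1} by an
inner stratified 3-fold grid search on the training folds only — outer test
folds never enter the tuning — with one-vs-one voting for the three classes.

`forward_select()` starts from the highest-VIP candidate and, at each
iteration, evaluates every remaining candidate as the next predictor,
keeping the best (ties: higher VIP, then genome order). Two semantics exist
because the procedure is describable either way: the default greedy
best-addition, and a `vip-order` mode that adds candidates in fixed VIP
order. The trace intentionally continues past the first non-improvement up
to `max_iters`, so the decline of accuracy with superfluous predictors — the
overfitting curve — is observable; the best subset is the argmax over the
whole trace, earliest iteration on ties. Note that greedy selection is only
stepwise-optimal: each addition maximizes accuracy given the already-chosen
prefix, which does not guarantee dominance over every fixed-order prefix of
the same length at every iteration.

Determinism: fold assignment and all model RNG derive from the spec seed, so
repeat evaluations are identical on a platform; cross-platform bit-identity
of random forests is not guaranteed.

## The synthetic-data generator

The generator emulates the study conditions rather than any particular
dataset: inbred lines (one haplotype doubled; a heterozygosity option
exists), SNPs laid out in blocks of 10 along 20 chromosomes, within-block
LD from a Gaussian copula with AR(1) correlation 0.9 between adjacent SNPs (dosage-scale correlations of roughly 0.4-0.8, so tag-SNP redundancy within blocks is real),
target MAFs uniform on [0.05, 0.5] with whole-block redraws until every
realized MAF clears the lower bound (the chip is assumed pre-filtered).
Liability is additive: planted QTL effects (large-effect loci drawn among
SNPs with MAF ≥ 0.2, mirroring the intermediate-frequency major locus this
trait shows in practice) plus polygenic, environment, G×E,
replicate-within-environment and residual Gaussian components with default
variances 0.10 / 0.25 / 0.10 / 0.05 / 0.50. Six breakpoints bin the
liability onto the 1–4 grid; by default they are placed so a Gaussian
liability yields roughly 19% tolerant / 62% moderate / 19% susceptible at
the plot-rating level, the class mix typical of advanced breeding panels
under prolonged exposure. Note the genotype-level mix after adjustment is
more concentrated than the plot-level mix — averaging over environments and
replicates shrinks the adjusted means toward the grand mean, and because
the grand mean sits nearer the moderate/susceptible boundary than the
tolerant one, the adjusted-score classes skew away from tolerant relative
to the plot-level target. This is a property of classifying smoothed means
against fixed rating thresholds, not a calibration error; pass explicit
`liability_breakpoints` to shift the mix.

Genotype and phenotype streams are seeded independently from the master
seed, so re-simulating phenotypes never perturbs the genotypes. With the
binning disabled (`return_liability = TRUE`) a method-of-moments
decomposition over a large balanced simulation recovers every variance
component within 10% relative error (tested at 5,000 lines × 1,000
environments × 2 replicates — the environment component needs many
environment draws to be estimable at that precision).

What the generator does **not** emulate: pedigree structure among lines
(the real panel derives from 232 biparental crosses), spatial field trends,
drift-dosage physics, and chip-specific missingness patterns. Passing tests
therefore demonstrate the pipeline's statistical behaviour under an
idealized additive-liability world, not performance on any real panel.

## Numerical choices and edge cases

* REML convergence is delegated to `lme4` (nloptwrap, absolute tolerances
  1e-8); variance components estimated at the zero boundary are flagged, not
  errors. Random terms with a single level (one environment) are dropped
  with a message.
* Missing dosages are excluded from MAF counting and mean-imputed per SNP
  before modelling — the simplest deterministic choice, always logged.
* Minor-allele orientation is recomputed from the data; a SNP at exactly the
  MAF threshold is kept (the filter drops strictly-below).
* Zero-variance SNP columns: undefined correlation → dropped from pruning
  with a log entry; skipped by the marker scan.
* PLS deflation that exhausts the response truncates the component count
  rather than producing degenerate weights; constant responses are an error.
* VIP ties at the threshold are broken by ascending (chromosome, position),
  making selections reproducible across runs.
* The comparator scan clamps p-values away from zero at the smallest
  representable double, keeping LOD finite.

## Problem sizes used in the checks

The test suite and acceptance checks run entirely on simulated data at desk
scale: 300 lines × 1,000 SNPs with one large planted QTL for the recovery
and overfitting checks (20 seeds), 150-line subsets and ≤ 5 candidates for
the brute-force stepwise equivalence, and 500 balanced lines for the
permutation null. The analysis scripts under `analysis/` run the same
pipeline at the study scale (551 lines × 4,970 SNPs, nine environments,
three replicates); their outputs land under `results/`.

## Known limitations

* The liability model is purely additive; no dominance or epistasis.
* No kinship or population-structure correction in either the PLS stage or
  the comparator scan — deliberate, as the selection pipeline itself applies
  none, but on structured panels VIP can pick up stratification.
* The comparator scan's LOD > 4.0 flag carries no multiple-testing
  guarantee; it is a plotting convention, not an inferential claim.
* Ordinal ratings are treated as numeric throughout; with few rating
  categories the adjusted means inherit some coarseness.
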