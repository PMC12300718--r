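---
title: "Methods: QSAR modelling of PFAS binding to human transthyretin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QSAR modelling of PFAS binding to human transthyretin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfasttr)
```

## The modelling problem

Human transthyretin (hTTR) distributes the thyroid hormone thyroxine (T4)
in serum and across the blood-brain and placental barriers. Per- and
polyfluoroalkyl substances (PFAS) can displace T4 from hTTR, a molecular
initiating event for thyroid-hormone system disruption. The measurable
quantities are (i) the median displacement activity of a compound in a
competitive fluorescence assay, dichotomized at 50% into active (A) versus
weak/not-active (I), and (ii) for compounds with a quantified half-maximal
effect concentration, the relative competitive potency
RP = EC50(T4) / EC50(compound), modelled on the log10 scale. A compound
with Log RP ≥ 0 binds hTTR at least as strongly as T4 itself; the
literature threshold Log RP ≥ −1.26 defines a *strong* binder.

`pfasttr` implements both models — a linear discriminant classifier for
the activity class and an OLS regression for Log RP — together with the
descriptor engines, the model-development workflow, the published
fixed-coefficient equations, and the applicability-domain (AD) and
uncertainty framework that accompanies every prediction. Replicate
endpoint values are handled as the assay data demand: replicate median
activities must agree on the class (values straddling 50% raise an error
rather than silently averaging), and replicate EC50s enter as the
arithmetic mean of their individual RP values before the log transform.

## Molecular graphs and curation

Structures enter as SMILES. Canonicalization is delegated to Open Babel
(via `ChemmineOB`), with stereo markers stripped by default: the models
use two-dimensional structure only, so stereoisomers are duplicates of
their non-chiral form. Curation excludes multi-component notations (salts
when a component is ionic or metal-bearing, mixtures otherwise), compounds
with elements outside {H, C, N, O, F, S, P, Cl, Br, I, Si, B}, charged
species, and duplicates; every exclusion is recorded with its reason, and
problems never abort a batch.

The molecular graph is hydrogen-explicit, with aromatic bonds at
conventional order 1.5 (taken from Open Babel's aromaticity perception via
MOL2 output — SDF output is Kekulé-assigned and would lose that
distinction). Atoms carry three pinned weighting properties: relative
atomic mass, Sanderson electronegativity, and static dipole polarizability
(Å³). Sanderson rather than Pauling electronegativity is used for the
`e`-weighted descriptors: it is the weighting convention of the
widely-used 2D descriptor software this package's descriptor names follow,
and it places AATSC0e for perfluorinated acids in the range (≈ 0.15–0.35)
that the published regression equation's coefficient scale implies.
GATS-type descriptors are variance-normalized and nearly insensitive to
this choice.

## The seven descriptors

* `ATSC_d(w)` — centered Broto-Moreau autocorrelation:
  Σ over unordered atom pairs at topological distance d of
  (w_i − w̄)(w_j − w̄); at lag 0, Σ(w_i − w̄)².
* `AATSC_d(w)` — the same, averaged over the number of contributing terms.
  `AATSC0e` is therefore the population variance of the atomic
  electronegativities.
* `GATS_d(w)` — Geary autocorrelation: mean squared weight difference over
  ordered pairs at distance d (halved), over the sample variance of the
  weights. A homoatomic graph has zero variance; the degenerate value is 0
  by default (configurable to NaN) — PFAS structures never trigger it.
* `MIC_k` — mass-weighted information content of the neighborhood-symmetry
  partition: atoms are grouped by iterated rooted signatures (element,
  heavy-atom degree, sorted incident bond orders, refined k times — a
  Weinberg/WL-style refinement that stabilizes early when it can), and
  −Σ_i (m_i/M) log2(n_class(i)/n) is returned. One equivalence class gives 0.
* `piPC_k` — natural log of 1 + the sum over all simple k-bond paths of the
  product of conventional bond orders along the path.
* `GGI_k` — Galvez topological charge index: with A the bond-order-weighted
  adjacency and D* the inverse-square distance matrix, the charge-transfer
  term CT_ij = (AD*)_ij − (AD*)_ji is summed as |CT| over unordered pairs
  at distance exactly k. Molecules whose skeleton diameter is below k score
  exactly 0 — for `GGI9` this cleanly separates long-chain from short-chain
  PFAS.

Hydrogen convention: the autocorrelations and MIC are computed on the
hydrogen-explicit graph; `piPC` and `GGI` on the hydrogen-suppressed
skeleton, the convention of the path-count and charge-index families.
All seven are graph invariants; the test suite checks each engine against
independent brute-force enumeration oracles on every connected graph of up
to 7 atoms and against closed forms on hand-evaluable cases.

Externally computed descriptor matrices can be ingested from CSV and are
filtered before modelling: near-constant columns (modal value covering
> 80% of compounds), one member of each pair with |r| > 0.95 (the
alphabetically later name is dropped, for determinism), and columns whose
span exceeds two orders of magnitude. The range rule is read as the plain
absolute span max − min > 10², configurable, since a ratio reading is
undefined for sign-crossing descriptors.

## Model development workflow

**Splitting "by structure".** Within each stratum (activity class for
classification; the whole set for regression) descriptors are autoscaled,
PC1 scores computed, compounds ranked, and every third rank (3, 6, 9, …)
assigned to the test set. This systematic 1-in-3 assignment keeps both
sets spread over the full structural range, which is the point of
structure-ranked splitting; the PC1 sign is canonicalized (dominant
loading positive) so the split never depends on an SVD sign convention.

**Fitting.** `qsar_lda()` is canonical two-class LDA with pooled
covariance; descriptors are autoscaled by default and the scaler travels
with the model. Exact score ties classify as the active class
(precautionary), implemented with a √ε relative tolerance since exact
floating-point ties essentially never occur. `qsar_mlr()` is OLS with
standard errors, the inverse design cross-product (needed for leverages
and prediction intervals) and the training response range stored on the
object. Both are implemented natively — they are the modelling algorithms
under study — and are cross-checked in the tests against `MASS::lda` and
`lm()` to 1e-8.

**Step-up selection.** Forward beam search: the best 25 subsets (by
training MR for LDA, R² for OLS) are retained at each size and each is
extended by every unused descriptor. With an infinite beam this reduces
exactly to exhaustive search, which the tests verify on all pairs.

**Overfitting control.** The leave-one-out bootstrap: models are refit on
n-with-replacement resamples and out-of-bag compounds predicted; each
compound's error is averaged over the resamples excluding it. B = 100
resamples per run, with the spread reported over 5 repeats of the whole
procedure. Resamples that lose a class are redrawn (logged, at most 100
tries). The advisory `overfit_knee()` reads the smallest model size after
which the bootstrap error stops improving by more than 0.005 — the
flattening/increase signature of selection overfitting.

**Chance-correlation checks.** The step-up procedure is rerun on
randomized descriptors (100 runs), drawn uniformly within each column's
range, or respecting each column's nature (binary → Bernoulli at observed
frequency, integer → uniform integers, continuous → uniform). Two numbers
are reported: the empirical fraction of runs reaching the real criterion,
and a tail probability from a normal fit to the run criteria. The normal
tail is the headline value because 100 runs cannot resolve probabilities
below 0.01 empirically, and published values of this statistic are of the
order 10⁻³. Y-scrambling (50 permutations of the response) reports the
mean scrambled R²; near the null expectation p/(n−1) when no chance
correlation is present.

**Metrics.** Classification: ACC, MR, SN, SP, P with class A as positive,
and AUC as the Mann-Whitney statistic (rank-based, tie-correct, equal to
the trapezoidal ROC area). Regression: R², MAE, Q²_LOO (true refit without
each compound), and external Q²_F3 = 1 − (PRESS_test/n_test)/(TSS_train/n_train).
Degenerate inputs (single-class truth, zero response variance, too few
compounds for a leave-one-out refit) degrade to NaN with a warning rather
than erroring.

## Applicability domains and uncertainty

Classification: a query is a structural outlier when the mean cosine
similarity to its 3 nearest training compounds (autoscaled model
descriptors) falls below the threshold that keeps 95% of training
compounds inside — the 5th percentile of the training k-NN similarity
distribution, matching a published threshold of this construction
(0.9661) with a flagged outlier far below it (0.7690). The endpoint check
deems posteriors in (0.25, 0.75) uncertain; the uncertainty check compares
the Shannon entropy of the posteriors (nats; base is cosmetic since the
rule is scale-invariant) with the maximum training entropy. For two
classes the band and entropy checks are mathematically equivalent at
matched thresholds; both are exposed because their reference values are
set independently.

Regression: leverage h = x₀'(X'X)⁻¹x₀ against the cutoff h* = 3(p+1)/n
(for the published model, h*(3, 43) = 0.2791); standardized residuals
flagged beyond ±2.5 SD; prediction intervals
ŷ ± t·s·√(1+h) compared with the maximum training interval width; and the
prediction checked against the training response range. The binary
structural verdict uses h ≤ h*, with the raw leverage always reported,
since reliability degrades continuously with leverage. Williams-plot
coordinates are exported as plain data.

An overall verdict is reliable only when every component check passes.

## The published fixed-coefficient models

`frozen_lda()` / `frozen_mlr()` carry the full-dataset equations exactly
as printed (coefficients rounded to two significant figures *are* the
published models; they are deliberately distinct from any refit). The
prior terms log(0.61)/log(0.39) use the natural log — the canonical LDA
posterior identity — with base 10 available for sensitivity analysis; the
choice shifts both scores by a near-common constant and essentially never
flips a classification. Posteriors are the softmax of the scores.
`sequential_screen()` chains the two: classify everything; compounds with
reliable active classifications get a Log RP prediction; reliable
predictions at or above −1.26 (inclusive) are strong binders. Tiers are
mutually exclusive: `weak/not active`, `active-moderate`, `active-strong`,
`unreliable`; per-compound failures are logged and never abort the batch.

## Synthetic data

The generators define the study conditions for all tests:

* `gen_classification_dataset()` — two identity-covariance Gaussian clouds
  separated by δ Mahalanobis units along the first axis; Bayes accuracy
  Φ(δ/2) in closed form. Defaults: 74 + 49 compounds, 4 descriptors,
  δ = 2.5 (Bayes accuracy ≈ 0.89, the accuracy regime of the activity
  model).
* `gen_regression_dataset()` — y = Xβ + ε with σ set from the target R²
  via R² = ‖β‖²/(‖β‖² + σ²). Defaults: n = 63, p = 3, target R² = 0.8, the
  geometry of the potency model.
* `gen_fluoroalkyl_smiles()` — valid, curation-clean SMILES of the
  modelled chemotypes (perfluoroalkyl carboxylic/sulfonic acids,
  fluorotelomer alcohols, methyl ethers, amides, perfluoroalkanes) with
  chain lengths spanning 3–11 perfluorinated carbons; distinct structures
  whenever the chain-length × head-group grid allows.

What the synthetic data do not emulate: assay noise structure, the
real descriptor correlation structure of PFAS, and class overlap driven by
structural similarity rather than Gaussian geometry. Passing tests
therefore demonstrate the correctness of the algorithms under known
conditions, not field performance on new chemistry.

## Numerical choices and limitations

* Problem sizes in the tests and the acceptance script (oracle sweeps over
  all ≤ 7-atom graphs, 50 reference-fit comparisons, 200 coverage
  replicates of 20 fresh points, 100 randomization runs, 40-compound
  screening batches) are chosen to make the checks statistically decisive
  while keeping a full run in tens of seconds.
* The published full-dataset performance line (ACC 0.87 on 121 compounds;
  R² 0.80 on 63) requires the original supplementary dataset, which is an
  external file; the refit machinery is validated against reference
  implementations and the published class priors (74/121 → 0.61) instead.
* Exact numeric parity with any particular external descriptor software is
  not guaranteed: MIC's class refinement and GGI's adjacency weighting
  follow documented conventions validated against brute-force oracles, and
  the descriptor scale was checked for consistency against the published
  coefficient magnitudes and descriptor ranges.
* The leave-one-out bootstrap is the plain out-of-bag estimator (not
  0.632); the empirical-vs-normal-tail duality of the randomization
  probability is reported rather than resolved, as 100 runs cannot decide
  between them.
* The models are PFAS-specific; applying them outside that class is
  outside their domain by construction, and the AD machinery will flag
  most such queries.
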