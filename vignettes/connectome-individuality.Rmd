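---
title: "Quantifying individual variability in functional connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying individual variability in functional connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcfingerprint)
```

## The scientific question

Resting-state functional connectivity — the matrix of correlations between
spontaneous fluctuation time series of brain parcels — carries a reproducible
individual signature in humans: a person's connectome from one half of their
data resembles their own other half more than anyone else's. `fcfingerprint`
implements the analysis chain used to ask the same question in awake mouse
fMRI cohorts: frame censoring, Fisher-z connectome construction, network
similarity and fingerprinting statistics, edgewise uniqueness/consistency
measures, and connectome-based predictive modelling (CPM) of a behavioural
phenotype (rotarod latency to fall). Because imaging data are large and
externally hosted, the package ships a synthetic-cohort generator that
reproduces the *structure* of such a study — 16 mice, six sessions of four
runs of 198 usable frames at TR 2.5 s, 86 cortical nodes in six modules — so
the entire pipeline is testable end to end.

## The generative model

All simulation happens on the Fisher-z edge scale. With `E = n(n-1)/2` edges,
the session connectome of mouse `m` in session `s` is

```
z[m, s, e] = g[e] + a[m, e] + eps[m, s, e]
```

* `g ~ N(0, sigma_group^2)` — structure shared by the whole cohort,
* `a[m] ~ N(0, sigma_individual^2)` — the stable, mouse-specific deviation,
* `eps[m, s] ~ N(0, sigma_session^2)` — fresh per-session noise,

all independent across edges. This is the additive decomposition that the
similarity/identification analyses implicitly assume, in its simplest form.
Optional per-module multipliers scale `sigma_individual` edge-wise (an edge
takes the geometric mean of its two endpoint modules' multipliers), which is
how differential-power positive controls with regionally concentrated
individuality are built.

### Calibrating the default scales

The study design this emulates reports cohort-mean similarities of roughly
`z(r) = 0.9` between animals and `z(r) = 1.08` within animals for
three-session half-connectomes. Under the model, with `a = sigma_group^2`,
`b = sigma_individual^2` and `c = sigma_session^2 / 3` (three sessions per
half), the expected between- and within-animal correlations over many edges
are

```
r_group      = a / (a + b + c)          -> tanh(0.90) = 0.716
r_individual = (a + b) / (a + b + c)    -> tanh(1.08) = 0.793
```

Fixing `sigma_group = 0.30` (a typical spread of z values in cortical
connectomes) and solving gives `sigma_individual ~ 0.10` and
`sigma_session ~ 0.28`. These are the package defaults. They are calibration
choices, not estimates — the real relative magnitude of individual versus
session variance in mouse fMRI is unknown — but they place the default
cohort in the same similarity regime as the real data.

### What the generator does not emulate

Edges are statistically independent in the generator, whereas real
connectomes have heavy spatial correlation (modules, hemispheric mirrors,
distance effects) and far fewer effective degrees of freedom than 3655.
Consequences to keep in mind when reading test results:

* With 3655 independent edges, the sampling error of a half-to-half
  similarity is tiny, so identification saturates near 100% at the default
  scales — much higher than the ~60–70% seen on real mouse data. Passing
  identification tests therefore demonstrates correctness of the statistics,
  not realism of the difficulty of the task.
* Session noise is homoscedastic; there is no motion-correlated artefact in
  the connectomes themselves (motion traces are generated separately and
  only drive censoring).
* No hemodynamics, no spatially correlated voxel noise, no image domain at
  all: parcel time series, when requested, are drawn directly as
  multivariate Gaussians with the target correlation structure.

### Behaviour and planted signal

Behaviour is a per-mouse scalar, `baseline + beta * mean(a[m, planted]) +
N(0, noise_sd)`, with a 2-day × 4-trial saturating learning curve emitted
around it (the curve is deterministic given the scalar, so the trial mean is
the scalar exactly; the 150 s baseline is an arbitrary scale choice). One
subtlety is worth spelling out: if the planted edges' individual deviations
are independent, a scalar coupled to their *mean* correlates only `~1/sqrt(k)`
with any single edge, so no single-edge selection procedure — CPM's included
— could recover a 20-edge planted set. That is a property of the generative
model, not a defect of CPM. The behaviour specification therefore has a
`shared_sd` parameter: a per-mouse latent factor added to every planted
edge's deviation, making the planted edges co-vary and each one carry the
behavioural signal. `shared_sd = 0` (the default) gives the plain
edge-independent model used for null calibration; recovery tests switch it
on (`shared_sd = 0.3`, `beta = 100`, `noise_sd = 1`, chosen by a power
calculation so single-edge Spearman correlations sit near 0.9).

## Frame censoring

Censoring follows three rules applied in sequence to each run's motion
trace:

1. a frame is flagged if framewise displacement exceeds **50 µm** or DVARS
   exceeds **Q75 + 1.5 × IQR** of the run's DVARS distribution;
2. the one frame immediately after each flagged frame is also removed (a
   flag on the final frame augments nothing);
3. any surviving contiguous segment shorter than **5 frames** is removed.

Runs keeping fewer than **50 frames** and sessions keeping fewer than
**192 frames** (8 min at TR 2.5 s) are excluded. All comparisons are strict
("less than"), so a run with exactly 50 frames survives. Numerical choices
made explicit here because they affect bit-reproducibility: quantiles use
linear interpolation between order statistics (R's type 7), and the DVARS
threshold is computed per run — the acquisition unit — rather than per
session (a `dvars_thresh` argument lets callers pool differently).

## Connectomes, halves, and similarity

Connectomes are Fisher z-transformed Pearson correlations over kept frames,
with `r` clipped into `[-1 + 1e-7, 1 - 1e-7]` before `atanh` so duplicated
signals produce a large finite value that preserves ordering. The canonical
edge order is the row-major upper triangle over the (hemisphere, module,
within-module) node order; every edge statistic and CPM selection uses this
one indexing. Kept frames of a session's surviving runs are concatenated
before correlating (correlate-per-run-then-average is available as a config
option; the acquisition protocol leaves either reading open).

For similarity analyses each mouse's six usable sessions are split into two
halves of three, minimising the difference in total included frames by
exhaustive search over the 10 unordered 3+3 partitions; ties pick the
lexicographically smallest set for the half containing the first session.
Mice with seven valid sessions first drop the highest-motion session
(operationalised as highest mean FD, which the protocol leaves undefined);
mice with fewer than six enter only the CPM analysis.

The similarity matrix entry `(i, j)` is the Fisher z of the correlation
between mouse `j`'s first-half and mouse `i`'s second-half edge vectors.
Individual similarity is the diagonal; group similarity averages the
`2(n-1)` off-diagonal entries of a mouse's row and column combined. The
normalized relative individual effect is `(individual - group)/individual`;
at the parcel level (where weak profiles can go negative), negative
similarities are rounded to 0.001 first and negative effects to 0.
Identification requires the diagonal to be the *strict* maximum of its row
(or column) — ties fail — and the two directions are reported separately.
Permutation nulls shuffle identities of one half and use the
`(1 + #{null >= obs}) / (N + 1)` convention by default; the rank convention
`#{null >= obs} / N` is a flag, since published analyses often report ranks.

## Edgewise statistics

After z-normalizing each half-connectome across its edges, the edgewise
product of a mouse's two halves measures agreement. Group consistency `Phi`
is the across-mice mean of that product; differential power `DP` is the
empirical probability, over all ordered mouse pairs and both cross
directions, that a mouse's within-animal product strictly exceeds a
cross-animal product. This package implements DP exactly as that
probability (the earlier human-fingerprinting literature aggregates
log-probabilities instead; the two orderings are close but not identical —
a deliberate divergence documented here). "Top 1%" displays select edges
strictly above the 99th interpolated percentile, excluding threshold ties,
and report per-module-pair selection fractions.

## Sessions-per-connectome analysis

For `k = 1, 2, 3` sessions per half, all combinations of two disjoint
k-subsets of the six sessions are enumerated. Unordered counting gives 15,
45 and 10 combinations; published counts for this design (15/45/20) match
unordered counting at k = 1, 2 but ordered counting at k = 3, and no single
convention reproduces all three. The package defaults to unordered
(10 at k = 3) and offers the ordered convention, which reproduces 15/45/20,
as a flag. Similarity values are averaged over combinations per mouse;
identification rates are kept per combination.

## CPM

Leave-one-out cross-validation over mice: per fold, Spearman-correlate every
edge of the session-averaged connectomes with behaviour across the training
mice (two-sided t-approximation p; an exact permutation p is available for
n ≤ 10), select `p < 0.05` (uncorrected) edges split by correlation sign,
sum each training mouse's z values over the positive and the negative set,
fit least squares `behaviour ~ intercept + pos_sum + neg_sum`, and predict
the held-out mouse. "Combined in a single regression model" admits two
readings; the two-predictor model is the default and a single
`pos_sum - neg_sum` composite is a flag. Folds that select nothing predict
the training mean (logged), keeping the cross-validated correlation
computable. Significance comes from rerunning the whole LOOCV on shuffled
behaviour (the shuffle loop reuses the fold-wise edge ranks, which do not
depend on behaviour — an algebraic speedup, verified in tests to agree with
a literal rerun). Consensus edges are those selected in every fold; their
distribution over association–association, association–sensory and
sensory–sensory edge categories (946/1848/861 of the 3655 in the default
parcellation) is compared with pooled two-proportion Z-tests under
Benjamini–Hochberg correction.

Paired contrasts elsewhere in the pipeline use the paired Student t-test
with `Cohen's d = t / sqrt(n)` — the convention consistent with the printed
effect sizes this design reports, e.g. `t = 7.32, n = 16 -> d = 1.83`.
Repeated-measures ANOVA with sphericity corrections is deliberately out of
scope; per-k paired contrasts are reported instead.

## Problem sizes used by the test-suite

Unit tests run on small parcellations (8–16 nodes) and cohorts of 5–18 mice
so the whole suite completes in a few minutes; oracle-equivalence checks use
100+ random instances of up to 300 frames / 16 mice; null-calibration checks
use 10,000 identity shuffles and 200 replicate null cohorts at 100 CPM
shuffles each; recovery checks use the full 86-node, 16–18-mouse default
design. These sizes are the package's own choices for statistically adequate
yet quick verification.

## Known limitations

* Identification difficulty on synthetic data is not representative of real
  data (see the independence caveat above).
* The generator plants behavioural signal only through the shared-latent
  mechanism; more realistic spatially structured brain-behaviour coupling is
  out of scope.
* Image-domain preprocessing (registration, nuisance regression, filtering)
  is entirely upstream of this package: motion traces and parcel time series
  (or precomputed connectomes) are its inputs.
* The sparsity-mask control and the hierarchy-score correlation accept user
  tables; the package ships no anatomical hierarchy values.
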