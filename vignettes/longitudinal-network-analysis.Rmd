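---
title: "Longitudinal functional brain network analysis: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal functional brain network analysis: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(longconn)
```

## The scientific problem

Neurodegenerative disease progression is increasingly described at the
level of functional brain networks: region-to-region statistical
couplings estimated from resting-state electrophysiology. In
Parkinson's disease, longitudinal designs track a patient cohort over
years of follow-up and ask three questions:

1. **Which subnetwork of connections weakens as the disease
   progresses?** (a mass-univariate contrast over ~22,000 edges,
   demanding family-wise error control)
2. **Does the loss of connectivity track clinical decline** — global
   cognition (MoCA) and motor severity (UPDRS-III)?
3. **Is the spatial pattern of loss related to the lateralization of
   motor symptoms?** Motor signs in Parkinson's disease typically start
   on one body side, reflecting contralateral nigrostriatal
   degeneration, so left-affected and right-affected patients are
   analyzed as separate subgroups.

`longconn` implements the full analysis chain for such a design —
source reconstruction, band-specific phase-locking connectivity, the
network-based statistic, a per-patient network index, clinical
correlations, and lateralized subgroup analyses — together with a
synthetic longitudinal cohort generator so that every stage can be
exercised and validated without access to any clinical recording.

## Pipeline overview

Sensor EEG (or, in practice here, simulated sensor data) flows through:

1. **wMNE inversion** (`compute_wmne_operator`, `apply_inverse`):
   depth-weighted minimum-norm mapping from channels to region time
   series through a leadfield.
2. **Band filtering** (`bandpass`): zero-phase FIR band-pass in the
   canonical rhythms θ (4–8 Hz), α1 (8–10), α2 (10–13), β (13–30).
3. **Phase extraction and PLV** (`instantaneous_phase`, `plv_dynamic`,
   `assemble_static`): phase-locking value per window, averaged over
   windows and epochs into one static matrix per band.
4. **NBS** (`nbs`): edgewise paired statistics with confound
   adjustment, supra-threshold component extraction, and sign-flip
   permutation control of the family-wise error over component extent.
5. **Network index** (`compute_ni`, `ni_trajectories`,
   `longitudinal_ni_test`, `correlate_ni_score`): per-subject mean
   weight over a significance-derived edge set, compared across visits
   and correlated with clinical scores.
6. **Lateralization** (`assign_dominant_side`, `subgroup_nbs`,
   `dominance_summary`): side assignment from UPDRS-III items 20–26,
   per-subgroup NBS, hemispheric/lobar dominance summaries.

The numbered scripts under `analysis/` run this chain end to end on the
synthetic cohort and write their tables under `results/`.

## Models and statistics

### Weighted minimum-norm estimate

Given a leadfield $G$ (channels × sources), the wMNE kernel is

$$K = (G^\top G + \lambda B^\top B)^{-1} G^\top,\qquad
  B = \mathrm{diag}(\lVert g_k \rVert^{w}),$$

with depth-weight exponent $w$ (default 1) built from the gain column
norms, so deep (weak-gain) sources are not penalized into silence. The
algebraically equivalent sensor-space form
$B^{-2} G^\top (G B^{-2} G^\top + \lambda I)^{-1}$ is kept as an
internal consistency check; the two agree to 1e−8 on well-conditioned
inputs. Because no regularization value is canonical, the default
$\lambda$ comes from an explicit SNR rule,
$\lambda = \mathrm{tr}(G B^{-2} G^\top) / (n_{ch}\,\mathrm{SNR}^2)$
with SNR 3, and the value used is logged with every run. Data are
assumed pre-whitened; a diagonal noise covariance can be supplied.

### Phase-locking value

For two narrowband signals with instantaneous phases
$\phi_i(t), \phi_j(t)$ (angle of the FFT-based analytic signal),

$$\mathrm{PLV}_{ij} = \left| \frac{1}{T} \sum_{t=1}^{T}
  e^{\sqrt{-1}\,(\phi_i(t) - \phi_j(t))} \right| \in [0, 1].$$

PLV is symmetric, invariant to a common phase offset, 1 for a constant
lag, and concentrates below $3/\sqrt{T}$ for independent phases
(Rayleigh null).

### Network-based statistic

For a paired contrast between visits $a$ and $b$, each subject
contributes a difference map $d = w(a) - w(b)$ per edge. The edge
statistic is the *intercept* t of the regression of $d$ on centered
confounds (age, sex, education, LEDD, dominant side; categorical
confounds dummy-coded) — i.e. the adjusted mean difference, df
$= n - 1 - |\text{confounds}|$. Edges with $t \geq$ a primary
threshold form a graph; connected components are the candidate
subnetworks, scored by extent (edge count). The null distribution of
the maximum extent is built by sign-flipping each subject's difference
map — exact under exchangeability of the two visit labels within
subject — and rerunning the full edgewise + component pipeline. The
corrected p for a component of extent $k$ is
$(1 + \#\{\text{perm max extent} \geq k\}) / (1 + B)$; with
`n_permutations = "exact"` all $2^n$ sign patterns are enumerated and
the p-value is the exact enumeration fraction.

### Network index

For a subnetwork with $N$ edges and a subject's connectivity weights
$W_i$ on those edges,

$$\mathrm{NI} = \frac{\sum_i^N W_i}{N},$$

computed per subject per visit from that subject's own matrix. The NI
of the full edge set is the global mean connectivity; the NI scales
linearly with the weights. Longitudinal change is tested with a paired
t-test per visit pair (a Wilcoxon option exists), Bonferroni-corrected
over the three pairs *within* one band/contrast — families are never
pooled across bands, matching the per-band presentation of such
analyses. The NI edge mask derived from one group is deliberately
applicable to any other group (controls, the opposite lateralized
subgroup): cross-application is how "does this network change in
controls too?" is asked.

## Key parameters

| Parameter | Default | Where | Meaning |
|---|---|---|---|
| `lambda` | SNR rule, SNR 3 | `compute_wmne_operator` | Tikhonov regularization (logged) |
| `weight_exponent` | 1 | `compute_wmne_operator` | depth weighting power |
| bands | θ 4–8, α1 8–10, α2 10–13, β 13–30 Hz | `eeg_bands` | analysis rhythms |
| `window_length_s` | epoch length | `plv_dynamic` | PLV averaging window |
| `edge_trim_s` | 1 s | `plv_dynamic` | transient trim per epoch edge |
| `primary_threshold` | user-set | `nbs` | supra-threshold edge cut |
| `n_permutations` | 1000 | `nbs` | sign-flip permutations (min 100) |
| `alpha` | 0.05 | `nbs` | component significance level |
| `edge_alpha` | 0.05 | `change_correlated_subnetwork` | per-edge screening level |

The **primary threshold is a required user choice**, reported with
every result: published analyses of this kind print the threshold
alongside each network, and there is no canonical rule for it. Raising
it shrinks components (monotonically — this is tested); a lenient
threshold on ~22k edges lets supra-threshold noise edges attach to a
true component and dilute its edge set, which matters when the
*identity* of the edges (not just detection) is the goal.

## The synthetic cohort generator

`simulate_longitudinal_cohort()` emulates the statistical structure of
a three-visit patient/control study:

* **Connectivity**: per subject, a trait matrix (group baseline +
  between-subject noise, SD 0.05) plus per-visit measurement noise
  (SD 0.02) on every edge. Patients additionally lose weight on a
  planted connected subnetwork — by default 125 edges over 72 regions,
  88.9% of them in one hemisphere, mirroring the shape of reported
  dysconnectivity networks — with mean decrements 0 / 0.05 / 0.10 at
  BL / 3YFU / 5YFU scaled by a per-subject progression multiplier
  (mean 1, SD 0.25). Out-of-range values are clipped to [0, 1] and the
  clip count is logged, never silent.
* **Clinical scores**: each patient's MoCA change equals
  `score_coupling` (default −20 points per unit connectivity loss)
  times their *realized* mean planted-edge loss, plus noise (SD 1.1);
  UPDRS-III couples positively (+30) to the same loss on top of a small
  progression drift. MoCA is truncated at [0, 30] and UPDRS-III at
  [0, 132] with a logged count.
* **Lateralization**: dominant side drawn L : R : symmetric at 23:10:2
  (the proportions of a typical lateralized PD cohort); UPDRS items
  20–26 left/right body sums are generated strictly consistent with the
  drawn side at every visit. Side-specific planted effects
  (`planted = list(L = ..., R = ...)`) let left-affected patients lose
  contralateral (right-hemisphere) connectivity and vice versa.
* **Determinism**: all randomness derives from the single `seed`; the
  same call is bit-identical.

Where the design needed values no published table provides — the
magnitude of edge decrements, noise SDs, score-coupling slopes — they
were chosen once for testability: effects large enough that recovery
studies have near-1 power at n = 35, noise calibrated so the
change–change correlation sits in the middle of the range such studies
report (~0.4 at the defaults). These are *not* estimates of any real
cohort.

What the generator does **not** emulate, and hence what green tests do
not establish about real data: volume-conduction leakage between
regions (no orthogonalization is implemented, deliberately), realistic
EEG artifacts, distance- or network-structured baseline connectivity,
cross-sectional coupling between score *levels* and NI *levels* (only
changes are coupled — so same-timepoint correlations are weak in the
synthetic cohort by construction), missing visits, and medication
effects.

### Coupled-source model

`simulate_coupled_sources()` produces narrowband signals with known
ground-truth phase coupling by shared-component mixing:
$x_i = \sqrt{a_i}\, s_{\text{common}} + \sqrt{1 - a_i}\,
s_{\text{private},i}$, all components band-filtered unit-variance
noise, so a coupled pair's linear correlation is
$\sqrt{a_i a_j} = c_{ij}$. The induced long-run PLV is a monotone
function of $c_{ij}$, obtained from the simulation oracle
`plv_oracle()` (a 10-minute record at the same mixing weight, cached
per band). Coupling matrices must decompose into blocks with rank-one
structure $c_{ij} = \sqrt{a_i a_j}$ — uniform blocks and disjoint
pairs always qualify; anything else is rejected rather than silently
approximated.

## Numerical choices

* **Filtering**: zero-phase FIR (Hamming-window `fir1` +
  forward-backward `filtfilt`). Cutoffs at `0.75·lo` and `1.5·hi` with
  the filter order sized so the transitions fit inside one octave:
  unit gain (±5%) across the band, ≥ 40 dB one octave outside. FIR was
  chosen over high-order Butterworth because narrow normalized bands
  (e.g. α1 at 250 Hz) make IIR transfer-function filtering numerically
  fragile.
* **Analytic signal**: FFT method (one-sided spectrum doubling),
  implemented in-package.
* **Transients**: 1 s discarded at each epoch edge before any phase
  statistic (logged, configurable).
* **PLV windows**: one window per epoch by default. Sub-second windows
  contain only ~2–3 effectively independent phase samples (the
  narrowband coherence time is ≈ 1/bandwidth), which biases PLV upward
  by >0.3 under weak coupling; epoch-length windows keep the static
  estimate within ±0.05 of the long-run value, which is the accuracy
  contract the test suite enforces. Shorter windows remain available
  for genuinely dynamic analyses.
* **Permutation p**: always uses the +1 correction (never exactly
  zero); exact enumeration is available for n ≤ 20.
* **Ties and ordering**: components are sorted by extent with ties
  broken by smallest canonical edge position; top-degree regions break
  ties by lower region index. All text output uses locale-independent
  formatting, so reruns are byte-identical.
* **Degenerate inputs**: empty subnetworks are an error for NI (the
  statistic is undefined); all-zero paired differences return t = 0,
  p = 1 explicitly; rank-deficient confound designs and constant
  confounds are rejected naming the offending column.

## Design choices on genuinely open points

* **Confound adjustment in the paired design**: difference maps
  regressed on an intercept plus centered confounds, testing the
  intercept. This is the standard covariate formulation for a paired
  NBS; a two-group label-permutation scheme is not provided — the
  package's contrasts are within-subject.
* **Edge screening for score-correlated subnetworks**
  (`change_correlated_subnetwork`): per-edge Pearson screening at an
  explicit, uncorrected `edge_alpha` (default 0.05). No published rule
  fixes this threshold; it is a parameter, never hard-coded, and the
  retained set is reported with per-edge r and p. A leave-k-out
  sensitivity mode (`drop_extreme`) re-estimates the NI–score
  correlation without the sharpest decliners.
* **Side assignment**: a side label requires strict dominance at
  *every* visit; equality at all visits is `symmetric`, anything mixed
  is `inconsistent`, and both are excluded from subgroup analyses. The
  data model stores only left-body and right-body item sums (axial
  items are not lateralizable).
* **"Within-hemisphere" shares** are computed as intra-hemisphere edges
  over all edges of the subnetwork, with interhemispheric edges a
  separate class; region shares are over distinct endpoint regions.
* **Atlas**: the packaged 210-region table follows the Brainnetome
  cortical nomenclature (105 homotopic pairs, even 0-based indices
  left) with a documented gyrus→lobe mapping of the package's own; the
  sensorimotor strip is a separate "central" lobe by default and can be
  folded into frontal/parietal (`default_atlas(central =
  "frontal-parietal")`). User atlases are validated row by row.

## Validation studies and problem sizes

The test suite and `scripts/acceptance.R` run these studies (all sizes
are the package's reference conditions):

* **Exactness**: on 6 subjects × 8 regions, the `"exact"` permutation
  p equals an independently coded full-enumeration oracle (all 64 sign
  patterns), exactly.
* **FWER calibration**: 200 global-null cohorts (20 subjects, 30
  regions, 500 permutations, threshold 2.0): the fraction with any
  component at corrected p < 0.05 must fall in the exact binomial 99%
  interval around 0.05. The calibration threshold is 2.0 because at
  high thresholds the max-extent null concentrates on {0, 1, 2} and
  tie-heavy discreteness makes the procedure conservative; a moderate
  threshold spreads the extent distribution so the realized error rate
  is informative about the permutation machinery itself.
* **Recovery**: 125-edge planted decrement at 3× the edge noise SD,
  n = 35, 20 replicates: the top significant component overlaps the
  planted set at Jaccard ≥ 0.8 in ≥ 90% of replicates (threshold 4 —
  see the primary-threshold discussion above).
* **NI power/FPR**: 100 progressive-decrement cohorts (corrected BL vs
  5YFU p < 0.05 in ≥ 95%) and 100 no-decrement cohorts (uncorrected
  false-positive rate within the binomial 99% band around 5%).
* **Correlation recovery**: score noise set for a target change–change
  correlation of 0.6; the sample r at n = 200 must land within ±0.1,
  and the UPDRS-III coupling must come out negative.
* **Lateralization**: antisymmetry of side assignment under left/right
  swap (exact), and ≥ 90% contralateral-dominance recovery over 10
  lateralized-planting cohorts.
* **Determinism**: the demo pipeline rerun with one seed is
  byte-identical.

## Known limitations

* No leakage correction: PLV between reconstructed sources inherits
  volume-conduction artifacts in real data; results on real recordings
  should be read with that in mind (orthogonalized or
  imaginary-coherence measures are out of scope here).
* The NBS implementation scores components by extent only; intensity
  (sum-of-t) scoring and threshold-free variants are not provided.
* The generator's effect sizes are set for testability, not estimated
  from any cohort; power numbers from the studies above do not
  transfer to real effect sizes.
* Mixed-effects longitudinal modelling is out of scope: the
  longitudinal tests are the paired tests the analysis design calls
  for, on completers only (listwise exclusion of missing visits).
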