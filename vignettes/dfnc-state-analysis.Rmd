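---
title: "Dynamic functional network connectivity states: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic functional network connectivity states: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dfncstates)
```

## The analysis in one paragraph

`dfncstates` implements a sliding-window dynamic functional network
connectivity (dFNC) analysis for resting-state fMRI component time courses,
of the kind used to study recurring "brain states" in ageing cohorts and
intervention trials. Seven ICA components covering the default-mode (DMN),
salience (SN) and executive-control (ECN) networks are observed for T = 200
volumes at TR = 2.4 s. After motion quality control and time-course
post-processing, connectivity between the 21 component pairs is estimated in
182 tapered sliding windows per session with an L1-penalized precision
(graphical lasso) estimator and Fisher z-transformed. Pooling all windows of
all subject-sessions, k-means finds k = 4 recurring connectivity states;
each window is assigned to its nearest state, and per-session temporal
metrics — fraction of time per state, mean dwell time, number of transitions
— feed random-intercept mixed models that contrast pre/post change across
the three arms of a randomized trial (meditation, active control, passive
control).

Because the motivating cohort data are not publicly distributable, the
package ships a synthetic cohort generator whose hidden-state structure is
known exactly, so every downstream stage is testable end to end.

## The synthetic cohort generator

The generator is a Markov-switching multivariate Gaussian model at window
resolution:

* **States.** Four C x C correlation archetypes built from a DMN/SN/ECN
  partition (defaults: components 1–3 DMN, 4–5 SN, 6–7 ECN): *weak* (all
  off-diagonals at `weak_level`), *sn_neg* (SN anti-correlated with DMN and
  ECN, everything else strong), *strong* (all off-diagonals at
  `strong_level`), *dmn_neg* (DMN anti-correlated with SN and ECN, SN–ECN
  strong, within-DMN weak). Default levels are `strong_level = 0.6`,
  `negative_level = -0.4`, `weak_level = 0.05`. These values are a design
  choice matching the qualitative block pattern of published state matrices,
  which print no numbers; they are not estimates. Each matrix is repaired to
  positive semi-definiteness by eigenvalue clipping at 1e-6 followed by
  diagonal re-normalization — deterministic and sign-preserving — and the
  constructor refuses parameter combinations the repair distorts by more
  than 0.15.

* **Hidden dynamics.** A k-state chain with kernel P(i→j) = c·π_j (j ≠ i),
  which has stationary distribution exactly π and expected switch count
  (n−1)·c·(1−Σπ²) over n steps. Defaults π = (0.45, 0.22, 0.16, 0.17) and
  c = 0.08 reproduce the canonical occupancies (45/22/16/17 %) and ≈10
  transitions per 182-window session. Sequences are drawn at *window*
  resolution (length T − W) after a 1000-step burn-in.

* **Signals.** Each TR draws a zero-mean Gaussian vector with the active
  state's correlation matrix, smoothed by an AR(1) recursion (default
  coefficient 0.3, innovations rescaled to keep unit marginal variance) to
  mimic hemodynamic smoothness. The window-level state sequence is expanded
  to TRs by *center alignment*: TR t takes the label of the window whose
  center is nearest, w = t − floor((W−1)/2), clamped to [1, Nw]. An
  alternative ("first window covering the TR") was considered and rejected:
  it places each window's tapered data about half a window *behind* its own
  truth label, which makes generator truth systematically incomparable to
  pipeline output — the very thing window-resolution truth is for.

* **Trial design.** Arms of 40/43/41 subjects, two visits each; age ~
  N(69.3, 3.9²) truncated at 65, education ~ N(13.2, 3.1²) (years), sex ~
  Bernoulli. Visit-2 sessions of an arm with an `intervention_effect` use a
  shifted chain: an additive occupancy shift (default meditation arm:
  −0.06 state 1, +0.06 state 3) and a switch-rate multiplier (default
  1.25), emulating the direction of published intervention findings. Every
  record derives its own seed from the master seed (seed + 1000·record), so
  subjects are individually reproducible.

What the generator does *not* emulate: voxel-level noise and preprocessing
residue, inter-subject variability of the state archetypes themselves,
scanner drift beyond a random-walk motion trace, and any relation between
covariates (age, sex, education) and the dynamics. Tests passing on this
cohort therefore validate the pipeline's estimation machinery, not its
behaviour under realistic physiological confounds.

## Preprocessing

The per-session chain is detrend (least-squares polynomial, default order
1) → despike → fifth-order Butterworth low-pass at 0.15 Hz → temporal
normalization (zero mean, unit SD per component). Motion regression (OLS
projection on the six realignment parameters plus intercept) is applied at
the connectivity-estimation boundary, on the full-length series.

* **Motion QC** excludes sessions exceeding 3 mm translation or 1.5°
  rotation, measured as excursion from the *first* time point — the
  realignment reference — rather than peak-to-peak; the thresholds are
  arguments.
* **Despiking** is a running-median/MAD scheme (half-width 5, threshold 4
  robust SDs), since the cited toolbox despiker's internal fit is not
  specified anywhere usable. When the local MAD is zero the global robust
  SD substitutes; if that is zero too, any nonzero deviation from the
  running median is a spike.
* **Low-pass filtering** is zero-phase (forward + reversed pass), with
  reflective edge padding of 3·order samples. The first sample is
  subtracted before each pass so the filter's zero initial state is exact
  for the constant component; start-up transients then involve only the
  fluctuating part, which the padding absorbs. DC gain is exactly 1.
* Re-running temporal normalization is exactly idempotent. Detrending
  again after the full chain removes a small amount of energy (order 1e-3
  relative at T = 200) because median replacement and IIR edge handling
  reintroduce a slight trend component; this is inherent to both
  operations, and the test suite bounds it rather than pretending it is
  zero.

## Windowed connectivity estimation

* **Windows.** Length W = 18 TR (43.2 s), step 1 TR. The window count
  convention is Nw = T − W (182 windows for 200 volumes): the taper's
  Gaussian tails extend one step past the rectangle, consuming the final
  start. This matches the canonical printed count exactly.
* **Taper.** The rectangle is convolved with a discrete Gaussian of σ = 2
  TR truncated at ±4σ, giving a support of W + 2·ceil(4σ) = 34 samples,
  normalized to sum 1. The σ = 2 TR reading follows the convolution
  parameter convention of the originating toolbox ("α = 2 TR"); the
  alternative FWHM = 4.8 s reading (σ ≈ 0.85 TR) is available by passing
  `sigma_tr` explicitly. Each window's taper is centered on its rectangle;
  weights falling outside the series are dropped and the rest re-normalized.
* **Covariance.** Weighted covariance with weighted mean and denominator
  1 − Σw² (the weighted analogue of the unbiased estimator).
* **Graphical lasso.** Block coordinate descent (compiled) maximizing
  log det Θ − tr(SΘ) − λΣ_{i≠j}|Θ_ij|, diagonal unpenalised. λ defaults to
  0.1; no principled value is derivable from the printed methods of the
  studies this follows, so the default is fixed for determinism and exposed
  as an argument. Along a session the solver warm-starts each window's
  regression coefficients from the previous window (consecutive windows
  share 17/18 of their data); only coefficients are warm-started — reusing
  the covariance estimate can make subproblems indefinite — and a cold
  restart is attempted before declaring non-convergence. Correlations are
  computed from the regularized covariance Σ̂ = Θ⁻¹, Fisher z-transformed
  (clipped at |r| ≤ 0.999999), and vectorized in row-major pair order
  (1-2, 1-3, …, 6-7).

## State clustering

Squared-Euclidean k-means with k-means++ seeding, best of 10 restarts by
within-cluster sum of squares (WCSS), over all windows of all sessions
pooled (both visits jointly). Assignment uses Euclidean distance with ties
to the lowest cluster index, and re-assigning the training windows
reproduces the fitted partition exactly. The elbow criterion is
operationalized as the maximum second difference of the WCSS curve over the
interior of the k grid (ties toward smaller k); the grid must bracket the
candidate strictly, so detecting k = 2 requires k = 1 in the grid. A
non-monotone WCSS curve (possible with finite restarts) is smoothed by a
running minimum with a warning. k defaults to 4 but is an argument, and
`elbow_select` reports the full WCSS/variance-explained table.

**Matching fitted states to archetypes.** The natural criterion — Pearson
correlation between centroid and archetype patterns — is undefined for the
*weak* and *strong* archetypes, whose off-diagonal patterns are constant
(they differ only in level, which correlation removes). The assignment
therefore minimizes total Euclidean distance between centroids and the
archetypes' Fisher-z off-diagonal vectors over all permutations
(exhaustive; k ≤ 8 in practice). Pearson correlation is still reported as
the diagnostic, and drives the `unmatched` rule for patterned archetypes
(r < 0.3); flat archetypes use an RMS z-distance rule (> 0.3) instead.

## Temporal metrics

Fraction of time is the window count per state divided by Nw (sums to 1 by
construction). Dwell times are maximal-run lengths; never-visited states
report NA, not zero, to avoid deflating group averages. The
windows-to-seconds conversion uses the span convention (n + W − 1)·TR — the
time from the first TR of the first window to the last TR of the last
window at step 1 — which reproduces the canonical printed conversions
(22 windows = 93.6 s, 12 = 69.6 s, 9 = 62.4 s) exactly. Transition counts
are adjacent label changes (= number of runs − 1).

## Group statistics

Per outcome (four state fractions, transitions):
`outcome ~ visit * arm + age_c + sex + edu_c + (1 | subject)`, REML, with
age and education mean-centered and sex a two-level factor.

* **Within-group change**: the V3 − V1 marginal-mean contrast per arm,
  standardized to Cohen's d by the model-based subject-level SD
  √(σ²_subject + σ²_residual). This standardizer is deterministic and
  model-consistent; a baseline-SD convention would be equally defensible
  but depends on the visit-1 sample. p-values are adjusted over the
  three-contrast family with the Sidak bound — the within-arm family is not
  a pairwise family, so the studentized-range (Tukey) adjustment does not
  apply to it.
* **Interaction**: joint F test of the two visit:arm terms with
  Satterthwaite denominator degrees of freedom (all sum-of-squares types
  coincide for the highest-order term). Interaction p-values are
  Benjamini–Hochberg adjusted across outcomes.
* **Pairwise differences in change**: the three arm-pair contrasts of the
  V3 − V1 change, a genuine pairwise family, Tukey-adjusted.
* **Experienced-state sensitivity**: refitting after keeping only subjects
  with positive time in a state. Positivity is required at *both* visits
  (both rows of a subject are kept or dropped together); an either-visit
  option exists because the convention is not fixed by any source we
  follow.

## Numerical and testing choices

* All stochastic operations take explicit seeds; clustering defaults to
  seed 20160625 (arbitrary, fixed for reproducibility of the shipped
  configuration).
* The graphical-lasso solver is verified against brute-force grid
  optimization of the bivariate penalized likelihood (tolerance 1e-4) and
  the unpenalised Θ = S⁻¹ limit; the chain constructor round-trips through
  an eigenvector-based stationary-distribution oracle at 1e-8.
* Statistical calibration runs at sizes chosen to characterize the
  estimator rather than the original trial: the interaction test's type-I
  error is estimated from 500 null replicates at 15 subjects per arm, and
  standardized-change recovery (d ∈ {0.3, 0.5}) from 200 replicates at 40
  per arm — the scale of published within-group effects. The end-to-end
  recovery check runs the full default cohort: 124 subjects × 2 visits ×
  182 windows.
* Simulation-backed summary targets (state occupancies in percent and the
  rounded mean transition count of the reference chain) are recomputed from
  scratch by `scripts/acceptance.R` from 2000 simulated sequences.

## Known limitations

* With truth drawn at window resolution and a 34-sample tapered data span,
  windows near a hidden-state switch observe a *mixture* of two states
  while their truth is the single center label. Under the default switching
  rate only about 40 % of windows are mixture-free. Mixture windows
  resemble intermediate patterns that fall disproportionately into the
  weakly connected state's neighbourhood, so window-level agreement with
  truth and the weak state's estimated occupancy carry an intrinsic ceiling
  that no classifier operating window-by-window can exceed; the test suite
  reports the measured values rather than hiding them. Per-state *relative*
  comparisons (arm contrasts on metrics) are much less affected because the
  blurring is common to all arms and visits.
* Explained variance of k-means on synthetic windowed features is far
  below values reported for real cohorts; no synthetic construction is
  claimed to reproduce real-data variance decompositions.
* The elbow criterion is a heuristic; with weak separation it defaults to
  the smallest interior candidate. Fixing k = 4 explicitly is the
  recommended analysis path, mirroring standard practice.
* The non-parametric re-analysis layer of the motivating literature is out
  of scope.
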