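---
title: "Phase-aligned dynamic connectotyping: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase-aligned dynamic connectotyping: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(connectodyn)
```

## The scientific problem

In a widely spaced event-related fMRI task, stimuli are separated by about
20 s, so the hemodynamic response to each trial evolves and returns to
baseline without interference from its neighbors. Every acquisition frame
can then be labeled by its *phase*: frame 1 is acquired concurrently with
the stimulus, frame 8 is 17.5 s later (TR 2.5 s). Frames that share a phase
across trials of the same stimulus class ("replica" frames) are draws from
the same point in the dynamic evolution of the task. Stacking them per
(frame, stimulus) condition and estimating a connectivity matrix per stack
yields a trajectory of 16 connectivity snapshots per participant (8 frames
x 2 stimulus classes), and a repeated-measures ANOVA on the frame-by-stimulus
interaction asks whether network-to-network communication *changes
differently over the trial* for the two stimulus classes -- a question about
dynamic connectivity, not activation.

`connectodyn` implements this pipeline end to end: atlas bookkeeping,
motion censoring and trial eligibility, replica-frame stacking, connectotype
estimation, per-network-pair statistics, and a seeded synthetic BOLD
generator used to validate every stage.

## The connectotype model

Each region's signal is modeled as a weighted sum of all other regions'
signals. For region $i$ with (normalized) stack signal $x_i \in
\mathbb{R}^n$ over the $n$ frames of a condition stack,

$$ \hat x_i = \sum_{j \ne i} \beta_{ij}\, x_j, \qquad
   \hat\beta_{i\cdot} = \arg\min_\beta \; \lVert x_i - X_{-i}\beta \rVert^2
   + \lambda \lVert \beta \rVert^2 . $$

The fitted $\beta$ matrix is the connectivity estimate: directed (rows are
the modeled *target* region, columns the predictor *source* region), dense,
with an exactly zero diagonal. In the standard regime the stack has 40
frames and 333 regions, so the problem is heavily underdetermined and the
ridge penalty is essential; $\lambda$ is selected by k-fold
cross-validation over frames (frames come from different trials and are
exchangeable within a stack, making CV over frames valid). One global
$\lambda$ per stack is the default: 40 frames carry too little information
for stable per-region selection, though a per-region mode exists.

Two implementation notes:

* **All rows from one inverse.** The ridge problem excluding the target
  column has the closed form $\hat\beta_{ij} = -\Theta_{ij}/\Theta_{ii}$
  with $\Theta = (X^\top X + \lambda I)^{-1}$, which follows from the block
  inversion of the full normal equations. One $p \times p$ inverse per
  $\lambda$ therefore yields all 333 target rows exactly; the unit tests
  verify equality with an independent per-row least-squares fit as
  $\lambda \to 0$.
* **No pre-whitening.** Autocorrelation is deliberately not removed: in
  task data the temporal evolution is signal. (Resting-state applications
  of the same model typically do remove it.)

Signals are z-scored within each stack before fitting. Within a stack all
frames share the same evoked mean, so demeaning removes evoked activation
exactly -- which is what makes the pipeline sensitive to *co-fluctuation*
(connectivity) rather than co-activation; variance normalization makes
betas comparable across conditions and participants, which the downstream
repeated-measures ANOVA requires.

The Pearson baseline (`pearson_matrix()`) computes the classical
correlation matrix on the *identical* frames, so any difference in
downstream results is attributable to the estimator alone.

## Alignment, censoring and inclusion

* **Frame displacement.** FD is the absolute sum of frame-to-frame changes
  in the six rigid-body parameters, rotations converted to arc length on a
  50 mm sphere (the common convention; configurable). FD of the first frame
  of each run is defined as 0. Precomputed FD traces are accepted.
* **Censoring.** A frame is kept iff FD is *strictly below* the threshold
  (default 0.3 mm). The boundary case is ambiguous in common usage;
  strict-keep-below is chosen, documented, and configurable via the
  threshold itself.
* **Trial eligibility.** A trial enters the analysis only if it spans the
  full 8 frames (20 s) before the next onset (or the run end) and its
  predecessor began at least 20 s earlier. Catch trials -- trials with a
  shortened 5/7.5/10 s inter-trial interval -- fail the first rule, and the
  trial immediately after a catch trial fails the second. Only the 8
  in-trial frames are required after the onset, not a full 20 s tail
  beyond the trial; the preceding-gap rule is what protects the stack from
  contamination by the previous response.
* **Fixed frame count.** Each condition stack is subsampled to exactly 40
  frames, *uniformly at random* (seeded), never lowest-FD-first, to avoid
  motion-correlated selection bias. Participants lacking 40 surviving
  frames in any of the 16 conditions are excluded, with the limiting
  condition reported.

Per-condition sampling seeds are derived from the master seed and the
(participant, condition) labels, so adding a participant never reshuffles
another's frames.

## Statistics

For each of the 36 ordered network pairs (6 analysis networks: CiP, Def,
DoA, FrP, Sal, VeA; the directed convention makes (A,B) and (B,A) distinct
families of beta weights):

1. **Box-Cox normalization** of the pooled pair values (one transform per
   pair, the default granularity; per-condition transforms would break
   cross-condition comparability). Beta weights can be negative, so a
   data-driven shift $\varepsilon - \min(v)$ with
   $\varepsilon = 10^{-3}\,\mathrm{range}(v)$ precedes the transform. The
   exponent $\lambda$ maximizes the profile log-likelihood via BFGS -- a
   gradient-based optimization of the transform parameter. (Optimizing the
   *base* of a logarithm cannot affect normality, since base changes are
   affine in log space; the exponent is the parameter that matters.)
2. **Two-stage repeated-measures ANOVA.** Stage 1 fits a fixed-effects
   linear model (participant + frame * stimulus) on connection-level
   transformed values and removes the participant effect; stage 2
   aggregates the adjusted values to a participant x 16-condition matrix
   and runs the classical two-way within-subject decomposition, reporting
   the frame-by-stimulus interaction F with nominal df (7, 7(n-1)). On
   complete balanced data this fit-then-aggregate route coincides exactly
   with aggregating cell means directly (the participant effect is constant
   within participant), and the test suite asserts that equivalence; the
   `stage1 = "means"` mode is retained for sensitivity analysis with
   incomplete tables.
3. **Sphericity.** Mauchly's test is computed on the orthonormalized
   interaction contrasts and reported, but it *gates nothing*: the
   Greenhouse-Geisser epsilon adjustment is always applied (adjust-only-
   when-significant is available behavior-wise by reading `mauchly_p`, but
   a discontinuous default pipeline is avoided). Epsilon is clamped to
   [1/7, 1]; with fewer than 8 participants the contrast covariance is
   singular and epsilon falls back to the lower bound with a warning rather
   than failing. Huynh-Feldt is available (`epsilon = "hf"`). Three
   p-values are reported per pair: `p_nominal` (no adjustment),
   `p_uncorrected` (epsilon-adjusted, family-uncorrected) and
   `p_corrected` (family-corrected).
4. **Family-wise correction** across the 36 pairs. Treating 36 independent
   interaction tests as a "Tukey-Kramer" family is nonstandard usage; the
   default here maps each two-sided p to a standard-normal quantile and
   refers it to the studentized-range distribution with 36 groups
   (df = Inf), which is slightly more conservative than Sidak; Holm,
   Bonferroni, Sidak and none are selectable.
5. **Post-hoc localization**: per-frame paired t-tests of word vs
   pseudoword participant-level means, and marginal-mean summaries with
   dispersion bars of 1.15 x SD (distribution plots) or 1.15 x SE
   (group-mean plots).

## The synthetic cohort generator

No public dataset accompanies the design this package targets, so the
generator is a first-class, tested component that emulates the study
conditions: a Gordon-style 333-ROI/12-network parcellation (network sizes
as published, 47 unassigned ROIs; within-network ROI identity is arbitrary
because only membership enters the pipeline), TR 2.5 s, 10 runs of 24
trials (18 pseudowords, 6 words), 2.5 s stimulus + 17.5 s fixation, and 3
catch trials per run drawing their shortened ITI from {5, 7.5, 10} s.
Catch trials are never placed last in a run, so every catch trial is
followed by an onset at a short gap and the gap-based eligibility rules
exclude exactly the trials they should.

Frames are drawn from the equilibrium linear system
$x = (I - B)^{-1}\eta$: each region's signal *is* a weighted sum of all
others plus innovation noise, so the connectotype model is correctly
specified and estimation can be validated against the generating coupling.
Design choices worth making explicit:

* **Symmetric ground-truth coupling.** Under the equilibrium model only
  the symmetrized coupling is identifiable by any regression of the
  stationary distribution, so $B_0$ is symmetric (co-fluctuation
  strengths); the estimator itself remains directed. $B_0$ has positive
  within-network blocks (networks co-fluctuate), weaker random
  between-network coupling, and is rescaled to spectral radius 0.45; every
  condition matrix is checked for spectral radius < 1 and the offending
  condition is named on failure.
* **Planted interaction.** The designated network-pair block (both
  directed sub-blocks, preserving symmetry) is scaled by $g(f, s)$: by
  default $g = 1$ everywhere except a word-specific bump peaking at frames
  3-4 -- the phase where the hemodynamic response peaks -- of height
  1 + amplitude. The null configuration ($g \equiv 1$) makes every
  condition identical by construction.
* **Evoked activity** enters as an innovation mean
  $\mathrm{hrf}(\text{offset}) \cdot a \cdot \text{gain}_s$ with a
  double-gamma HRF peaking at 5.7 s and back below 5% of peak by 20 s.
  Because the mean is constant within a condition stack, stimulus-specific
  gains create *pure activation differences with zero connectivity
  difference* -- the specificity control: an activation-only cohort must
  yield no connectivity detection, and the validation suite asserts it
  does not.
* **Frames are conditionally independent given their phase** by default:
  the analysis stacks same-phase frames from *different trials*, which are
  independent in reality, so this matches the estimand. An optional AR(1)
  coupling of innovations across the frames of one trial
  (`ground_truth(ar1 = ...)`) exists to stress-test against task
  autocorrelation.
* **Motion and artifact.** Motion is simulated directly as an FD-like
  positive trace (lognormal body, median 0.1 mm; occasional uniform spikes
  0.35-1.5 mm at rate 1.5%), because FD is the only quantity the pipeline
  consumes; a six-parameter random-walk mode exists to test the FD
  computation. Crucially, every frame receives a motion-locked common
  intensity artifact: `artifact_gain` (default 32) times the frame's FD,
  scaled by fixed per-region loadings. Sub-threshold frames therefore
  still carry shared artifact, as real censored BOLD data do. This term is
  what gives the Pearson baseline its realistic disadvantage: shared
  high-leverage components inflate and destabilize marginal correlations,
  while the connectotype regression absorbs them in the predictor span. In
  a purely iid Gaussian world the sample correlation is an efficient
  estimator and the contrast between estimators disappears -- passing the
  estimator-contrast suite on this generator therefore demonstrates
  robustness to shared artifact, not superiority on artifact-free data.
* **Between-subject variability**: each participant receives
  $B_0 + $ symmetric Gaussian perturbation (sd 0.02), plus an independent
  activation map; a shared global fluctuation (sd 0.8) models
  non-artifactual whole-brain covariation.
* With the default low-motion settings ~99% of frames survive the 0.3 mm
  threshold and a 15-participant cohort is typically fully included. The
  word conditions are the binding constraint: 6 words per run across 10
  runs, minus catch losses, leaves ~45 eligible word trials against the
  40-frame requirement. How often participants fail in the *real* study
  (15 of 24 survived) depends on motion distributions the generator does
  not attempt to calibrate.

## Validation-study problem sizes

The seeded simulation suites run on a reduced six-network schema (CiP = 3,
Def = 8, DoA = 6, FrP = 5, Sal = 3, VeA = 5 ROIs, 4 unassigned; 36 pairs)
with 12-participant cohorts, 10 runs and 40 frames per condition -- the
full temporal design at reduced spatial dimension, chosen so a 20-replicate
study of the complete pipeline runs in minutes. The canonical planted
effect for power studies is amplitude 1.75 (block coupling x 2.75 at the
response peak for words), selected by a pre-registered-style power sweep on
this schema: it sits where the connectotype pipeline detects reliably while
the Pearson baseline mostly does not, the regime the method is designed to
expose. Null calibration uses the same conditions with amplitude 0: the
nominal-df interaction test rejects at ~5% per pair and family-corrected
false positives are rare, as asserted by the validation suite.

## Known limitations

* The generator works at region level; voxel/surface synthesis, scanner
  physics, physiological noise and preprocessing (registration, nuisance
  regression, filtering) are out of scope -- inputs are assumed parcellated
  and preprocessed (an optional drop-first-k-frames flag covers steady-
  state discard for real inputs).
* The exact regularizer and CV scheme of the original connectotyping
  implementation are not recoverable from the published description
  ("regularization and cross-validation"); ridge with k-fold CV is this
  package's interpretation and is pluggable.
* The "Tukey-Kramer across 36 tests" correction is likewise an
  interpretation of a nonstandard description; alternatives are provided
  and the choice is a config flag.
* Passing the synthetic validation shows the pipeline detects what it is
  designed to detect under the stated generative assumptions (linear
  coupling, Gaussian innovations, FD-proportional artifact); it does not
  certify performance on real BOLD, whose noise is richer.
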