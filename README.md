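# connectodyn

Phase-aligned dynamic functional connectivity for task fMRI.

## What problem this solves

In a widely spaced event-related fMRI task (stimuli ~20 s apart, TR 2.5 s),
every acquired frame can be labeled by its position within a trial: frame 1
is concurrent with the stimulus, frame 8 is 17.5 s later. Frames sharing a
position across trials of the same stimulus class are "replica" frames —
snapshots of the same moment in the dynamic evolution of the task. Stacking
them per (frame, stimulus) condition gives 16 stacks per participant
(8 frames x 2 stimulus classes, e.g. words vs pseudowords in a lexical
decision task), and estimating connectivity per stack yields a *trajectory*
of connectivity over the trial.

Connectivity is estimated by **connectotyping**: each region's signal
`x_i` is modeled as a regularized weighted sum of all other regions,

    x_i  ≈  Σ_{j≠i} β_ij x_j     (ridge penalty λ, chosen by
                                  cross-validation over frames)

giving a directed, dense beta matrix with zero diagonal per condition. For
every ordered pair of functional networks (36 pairs over the six-network
analysis family CiP, Def, DoA, FrP, Sal, VeA of a Gordon-style 333-ROI
parcellation), the pair's beta weights are Box-Cox normalized and a
repeated-measures ANOVA tests the **frame x stimulus interaction** — does
this network pair's communication evolve differently over the trial for the
two stimulus classes? — with Mauchly/Greenhouse-Geisser sphericity
handling, family-wise correction across the 36 pairs, and per-frame paired
post-hoc tests. A Pearson-correlation baseline runs on the identical
frames. Motion handling (frame displacement censoring at 0.3 mm, trial
eligibility, random subsampling to 40 frames per condition, participant
inclusion) follows the widely spaced design's rules.

Because the target kind of dataset is not publicly deposited, the package
includes a first-class synthetic BOLD generator (`ground_truth()`,
`simulate_cohort()`) producing seeded cohorts with known condition-dependent
coupling, evoked activity, head motion and motion-locked artifacts — used
by the test suite to validate calibration, power, effect localization and
the connectotype-vs-Pearson contrast. See the methods vignette
(`vignettes/dynamic-connectotyping.Rmd`) for the models and every design
choice.

## Worked example

Simulate a 12-participant cohort on a reduced six-network schema with a
connectivity interaction planted between the Cingulo-Parietal (CiP) and
Fronto-Parietal (FrP) networks at frames 3–4 for words, then run the full
pipeline:

```r
library(connectodyn)

schema <- scaled_parcellation(
  c(CiP = 3, Def = 8, DoA = 6, FrP = 5, Sal = 3, VeA = 5), n_unassigned = 4)
planted <- enumerate_pairs(schema, c("CiP", "FrP"))[[2]]
gt <- ground_truth(schema, seed = 1, interaction_pair = planted,
                   interaction_amplitude = 1.75)
cfg <- pipeline_config(schema = schema, gt = gt, n_participants = 12,
                       master_seed = 1)
report <- run_pipeline(cfg)
report
#> <run_report> connectotype, 11 participants included, 36 pairs tested
#>   top pair: FrP and CiP (F = 8.275, p = 2.203e-05 adj, 0.01076 corrected)

head(report$results[order(report$results$p_corrected),
                    c("name", "F", "epsilon", "p_uncorrected", "p_corrected")], 4)
#> 1 FrP and CiP  8.28  0.647  0.0000220  0.0108
#> 2 CiP and FrP  7.98  0.668  0.0000241  0.0117
#> 3 CiP and DoA  2.07  0.512  0.111      1.000
#> 4 DoA and CiP  1.99  0.502  0.124      1.000

round(report$posthoc[["CiP and FrP"]], 5)
#> [1] 0.49394 0.03286 0.00009 0.00029 0.01795 0.01590 0.80511 0.72032
```

One participant was excluded (fewer than 40 surviving frames in a
condition; `report$inclusion` gives the reason). The planted pair is the
top hit in both directions with family-corrected p ≈ 0.011, and the
post-hoc per-frame tests localize the effect exactly where it was planted
(frames 3–4). `cfg$estimator <- "pearson"` reruns the identical frames
through the correlation baseline; `robustness_sweep(cfg)` repeats the
analysis at FD thresholds 0.25/0.3/0.5 mm on the same cohort.

Atlas bookkeeping for the full-size schema:

```r
connection_table(gordon_parcellation())   # 36 pairs, Σ = 16,512 = 129·128
```

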