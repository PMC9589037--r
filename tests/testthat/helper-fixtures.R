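# shared fixtures: small schemas and cohort runners used across test files

# 30-ROI, 6-network reduction of the analysis family (plus 4 unassigned),
# the simulation-study schema used by the stochastic suites
sim_schema <- function() {
  scaled_parcellation(
    c(CiP = 3, Def = 8, DoA = 6, FrP = 5, Sal = 3, VeA = 5),
    n_unassigned = 4
  )
}

sim_cip_frp <- function(schema = sim_schema()) {
  enumerate_pairs(schema, c("CiP", "FrP"))[[2]]  # target CiP, source FrP
}

# tiny 3-ROI toy schema from the worked extraction examples
toy_schema <- function() scaled_parcellation(c(a = 2, b = 1))

# one full simulation-study replicate: simulate a cohort with the given
# planted amplitude and run the pipeline; study conditions are the frozen
# synthetic design (12 participants, 10 runs, 40 frames/condition)
sim_replicate <- function(rep, amplitude = 0, estimator = "connectotype",
                          stim_gain = c(word = 1, pseudoword = 1),
                          n_participants = 12, seed_base = 42,
                          schema = sim_schema()) {
  gt <- ground_truth(schema, seed = derive_seed(seed_base, "gt", rep),
                     interaction_pair = sim_cip_frp(schema),
                     interaction_amplitude = amplitude,
                     stim_gain = stim_gain)
  cfg <- pipeline_config(schema = schema, gt = gt,
                         n_participants = n_participants,
                         estimator = estimator,
                         master_seed = derive_seed(seed_base, "rep", rep))
  run_pipeline(cfg)
}

# small, fast pipeline configuration for structural/end-to-end tests:
# 4 runs, 15 frames per condition, 4 participants on a 14-ROI schema
quick_config <- function(seed = 7, ...) {
  schema <- scaled_parcellation(c(CiP = 3, Def = 4, FrP = 4), n_unassigned = 3)
  gt <- ground_truth(schema, seed = seed)
  pipeline_config(
    schema = schema, gt = gt,
    design = task_design(n_runs = 4),
    n_participants = 4, frames_per_condition = 12,
    master_seed = seed, ...
  )
}

# session with no censored frames and no catch trials: every trial eligible
clean_session <- function(schema = toy_schema(), n_runs = 1, seed = 5) {
  design <- task_design(n_runs = n_runs, catch_per_run = 0)
  gt <- ground_truth(schema, seed = seed, global_signal_sd = 0)
  motion <- motion_config(spike_prob = 0, body_sdlog = 0.05,
                          artifact_gain = 0)
  simulate_session(design, gt, motion, seed = seed)
}
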