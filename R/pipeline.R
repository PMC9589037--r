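#' Configuration for an end-to-end analysis run
#'
#' Bundles every setting of the simulate - align - fit - test pipeline. If
#' `sessions` is `NULL`, a synthetic cohort is simulated from `design`,
#' `gt` and `motion`; otherwise the supplied `participant_session` objects
#' are analyzed as-is.
#'
#' @param schema parcellation schema; defaults to the packaged 333-ROI
#'   Gordon-style schema.
#' @param design a [task_design()].
#' @param gt a [ground_truth()]; defaults to a null configuration on
#'   `schema`.
#' @param motion a [motion_config()].
#' @param sessions optional list of pre-built `participant_session`s.
#' @param n_participants synthetic cohort size (ignored when `sessions`
#'   given).
#' @param fd_threshold motion-censoring threshold in mm.
#' @param frames_per_condition replica frames each connectotype is fitted
#'   from.
#' @param min_gap_seconds preceding-onset gap required for trial
#'   eligibility.
#' @param included_networks networks entering the pair family.
#' @param estimator `"connectotype"` or `"pearson"`.
#' @param penalty a [penalty_config()].
#' @param family_method family-wise correction (see [correct_family()]).
#' @param epsilon sphericity correction estimator (`"gg"` or `"hf"`).
#' @param stage1 stage-1 mode of [rm_anova_pair()].
#' @param master_seed master seed; all stage/participant/condition seeds are
#'   derived from it.
#' @return a `pipeline_config` object.
#' @export
pipeline_config <- function(schema = gordon_parcellation(),
                            design = task_design(), gt = NULL,
                            motion = motion_config(), sessions = NULL,
                            n_participants = 15, fd_threshold = 0.3,
                            frames_per_condition = 40, min_gap_seconds = 20,
                            included_networks = NULL,
                            estimator = c("connectotype", "pearson"),
                            penalty = penalty_config(),
                            family_method = "tukey",
                            epsilon = "gg", stage1 = "lmm",
                            master_seed = 1) {
  if (is.null(gt)) gt <- ground_truth(schema, seed = master_seed)
  if (is.null(included_networks)) {
    included_networks <- if (all(included_networks() %in% schema$network_names))
      included_networks() else schema$network_names
  }
  structure(
    list(schema = schema, design = design, gt = gt, motion = motion,
         sessions = sessions, n_participants = n_participants,
         fd_threshold = fd_threshold,
         frames_per_condition = frames_per_condition,
         min_gap_seconds = min_gap_seconds,
         included_networks = included_networks,
         estimator = match.arg(estimator), penalty = penalty,
         family_method = family_method, epsilon = epsilon, stage1 = stage1,
         master_seed = master_seed),
    class = "pipeline_config"
  )
}

#' Run the full phase-aligned connectivity analysis
#'
#' Executes all stages: cohort simulation (or ingestion), motion censoring
#' and replica-frame stacking, per-condition random subsampling to a fixed
#' frame count, participant inclusion, per-condition connectivity
#' estimation, and per-network-pair repeated-measures ANOVA with family-wise
#' correction. Fully deterministic under `config$master_seed`.
#'
#' @param config a [pipeline_config()].
#' @param verbose log stage boundaries and frame accounting.
#' @return a `run_report`: list with `results` (one row per network pair),
#'   `inclusion` (per-participant frame accounting and exclusion reasons),
#'   `marginal_means`, `posthoc`, `fits`, `stack_provenance`, `provenance`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (verbose) message(sprintf(...))

  sessions <- config$sessions
  if (is.null(sessions)) {
    say("simulating cohort of %d participants", config$n_participants)
    sessions <- simulate_cohort(config$n_participants, config$design,
                                config$gt, config$motion,
                                seed = derive_seed(config$master_seed, "cohort"))
  }

  trial_frames <- config$design$trial_frames
  inclusion <- list()
  fits <- list()
  prov <- list()
  for (i in seq_along(sessions)) {
    sess <- sessions[[i]]
    stacks <- session_stacks(sess, fd_threshold = config$fd_threshold,
                             trial_frames = trial_frames,
                             min_gap_seconds = config$min_gap_seconds)
    counts <- vapply(stacks, function(s) ncol(s$data), 1L)
    ok <- participant_passes(stacks, config$frames_per_condition,
                             n_conditions = 2 * trial_frames)
    inclusion[[i]] <- tibble::tibble(
      participant = sess$participant, included = ok,
      min_frames = min(counts),
      limiting_condition = names(counts)[which.min(counts)],
      reason = if (ok) NA_character_ else
        sprintf("only %d frames in %s (need %d)", min(counts),
                names(counts)[which.min(counts)],
                config$frames_per_condition)
    )
    if (!ok) {
      say("participant %s excluded: %s", format(sess$participant),
          inclusion[[i]]$reason)
      next
    }
    sampled <- lapply(names(stacks), function(key) {
      sample_frames(stacks[[key]], config$frames_per_condition,
                    seed = derive_seed(config$master_seed, "sample",
                                       sess$participant, key))
    })
    names(sampled) <- names(stacks)
    prov[[as.character(sess$participant)]] <-
      lapply(sampled, `[[`, "provenance")
    fits[[as.character(sess$participant)]] <- lapply(sampled, function(st) {
      if (config$estimator == "pearson") {
        pearson_matrix(st)
      } else {
        fit_connectotype(st, config$penalty)$beta
      }
    })
    say("participant %s: fitted %d conditions (min stack %d frames)",
        format(sess$participant), length(sampled), min(counts))
  }
  inclusion <- do.call(rbind, inclusion)
  if (is.null(fits) || length(fits) == 0) {
    stop("no participant survived inclusion:\n",
         paste(inclusion$reason[!inclusion$included], collapse = "\n"))
  }

  say("testing %d^2 network pairs on %d participants",
      length(config$included_networks), length(fits))
  pairs <- enumerate_pairs(config$schema, config$included_networks)
  tables <- lapply(pairs, function(p) pair_table(fits, p, trial_frames))
  tests <- lapply(tables, rm_anova_pair, epsilon = config$epsilon,
                  stage1 = config$stage1)
  p_unc <- vapply(tests, `[[`, 1, "p_uncorrected")
  p_corr <- correct_family(p_unc, config$family_method)
  for (i in seq_along(tests)) tests[[i]]$p_corrected <- p_corr[i]

  results <- tibble::tibble(
    name = vapply(pairs, function(p)
      paste(p$target_network, "and", p$source_network), ""),
    target = vapply(pairs, function(p) p$target_network, ""),
    source = vapply(pairs, function(p) p$source_network, ""),
    n_connections = vapply(tests, `[[`, 1L, "n_connections"),
    F = vapply(tests, `[[`, 1, "F"),
    df_num = vapply(tests, `[[`, 1, "df_num"),
    df_den = vapply(tests, `[[`, 1, "df_den"),
    epsilon = vapply(tests, `[[`, 1, "epsilon"),
    mauchly_p = vapply(tests, `[[`, 1, "mauchly_p"),
    p_nominal = vapply(tests, `[[`, 1, "p_nominal"),
    p_uncorrected = p_unc,
    p_corrected = p_corr,
    significant = p_corr < 0.05
  )
  structure(
    list(results = results, inclusion = inclusion,
         marginal_means = do.call(rbind, lapply(tables, marginal_means)),
         posthoc = setNames(lapply(tests, `[[`, "posthoc"), results$name),
         fits = fits, stack_provenance = prov,
         provenance = list(
           estimator = config$estimator,
           fd_threshold = config$fd_threshold,
           frames_per_condition = config$frames_per_condition,
           master_seed = config$master_seed,
           n_included = length(fits),
           config_hash = config_hash(config[setdiff(names(config),
                                                    c("sessions", "gt"))])
         )),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %s, %d participants included, %d pairs tested\n",
              x$provenance$estimator, x$provenance$n_included,
              nrow(x$results)))
  top <- x$results[order(x$results$p_corrected), ][1, ]
  cat(sprintf("  top pair: %s (F = %.3f, p = %.4g adj, %.4g corrected)\n",
              top$name, top$F, top$p_uncorrected, top$p_corrected))
  invisible(x)
}

#' Re-run the analysis across motion-censoring thresholds
#'
#' Simulates (or takes) one cohort and repeats the full analysis at each FD
#' threshold, so threshold-driven differences reflect censoring alone. The
#' summary tracks a target pair's marginal-mean trajectory across
#' thresholds.
#'
#' @param config a [pipeline_config()].
#' @param thresholds FD thresholds (mm) to sweep.
#' @param target_pair `c(target, source)` network names for the trajectory
#'   summary; defaults to the planted interaction pair if present, else the
#'   first pair.
#' @return a `sweep_report`: list with `reports` (one `run_report` per
#'   threshold), `summary` (tibble of the target pair's marginal means per
#'   threshold), `inclusion` (participants included per threshold).
#' @export
robustness_sweep <- function(config, thresholds = c(0.25, 0.3, 0.5),
                             target_pair = NULL) {
  stopifnot(all(thresholds > 0))
  if (is.null(config$sessions)) {
    config$sessions <- simulate_cohort(
      config$n_participants, config$design, config$gt, config$motion,
      seed = derive_seed(config$master_seed, "cohort"))
  }
  if (is.null(target_pair)) {
    target_pair <- if (!is.null(config$gt$interaction_pair)) {
      c(config$gt$interaction_pair$target_network,
        config$gt$interaction_pair$source_network)
    } else {
      rep(config$included_networks[1], 2)
    }
  }
  reports <- lapply(thresholds, function(th) {
    cfg <- config
    cfg$fd_threshold <- th
    run_pipeline(cfg)
  })
  names(reports) <- format(thresholds)
  summary <- do.call(rbind, lapply(seq_along(thresholds), function(i) {
    mm <- reports[[i]]$marginal_means
    mm <- mm[mm$target == target_pair[1] & mm$source == target_pair[2], ]
    mm$fd_threshold <- thresholds[i]
    mm
  }))
  structure(
    list(reports = reports, summary = summary,
         inclusion = tibble::tibble(
           fd_threshold = thresholds,
           n_included = vapply(reports, function(r)
             r$provenance$n_included, 1L, USE.NAMES = FALSE))),
    class = "sweep_report"
  )
}

#' @export
print.sweep_report <- function(x, ...) {
  cat("<sweep_report>\n")
  print(x$inclusion)
  invisible(x)
}

#' Write a run report's tables as TSV files
#'
#' @param report a `run_report`.
#' @param dir output directory.
#' @return invisible vector of files written.
#' @export
write_run_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(results = file.path(dir, "pair_tests.tsv"),
             means = file.path(dir, "marginal_means.tsv"),
             inclusion = file.path(dir, "inclusion.tsv"))
  write.table(report$results, paths["results"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(report$marginal_means, paths["means"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(report$inclusion, paths["inclusion"], sep = "\t",
              quote = FALSE, row.names = FALSE)
  jsonlite::write_json(report$provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(paths, file.path(dir, "provenance.json")))
}
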