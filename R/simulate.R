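#' Head-motion simulation settings
#'
#' Motion is simulated directly as a frame-displacement-like positive trace:
#' a lognormal body (typical sub-threshold wobble) plus occasional uniform
#' spikes that exceed the censoring threshold. Defaults describe a
#' low-motion cohort in which ~99% of frames survive a 0.3 mm threshold.
#'
#' @param body_meanlog,body_sdlog lognormal parameters of the baseline FD
#'   trace (mm).
#' @param spike_prob per-frame probability of a motion spike.
#' @param spike_range range (mm) spikes are drawn from uniformly.
#' @param artifact_gain amplitude (signal units per mm of FD) of the
#'   motion-locked common intensity artifact added to every region's signal.
#'   Head motion perturbs the measured BOLD signal roughly in proportion to
#'   the displacement, across the whole brain at once; frames below the
#'   censoring threshold therefore still carry shared artifact. Marginal
#'   correlations are inflated by such common components, whereas a model
#'   that regresses each region on all the others absorbs them.
#' @param mode `"fd"` simulates the FD trace directly; `"six-parameter"`
#'   simulates a rigid-body parameter random walk from which FD is computed
#'   via [compute_fd()].
#' @param step_sd random-walk step s.d. for six-parameter mode
#'   (mm for translations; radians for rotations).
#' @return a `motion_config` object.
#' @export
motion_config <- function(body_meanlog = log(0.1), body_sdlog = 0.35,
                          spike_prob = 0.015, spike_range = c(0.35, 1.5),
                          artifact_gain = 32,
                          mode = c("fd", "six-parameter"), step_sd = 0.02) {
  structure(
    list(body_meanlog = body_meanlog, body_sdlog = body_sdlog,
         spike_prob = spike_prob, spike_range = spike_range,
         artifact_gain = artifact_gain,
         mode = match.arg(mode), step_sd = step_sd),
    class = "motion_config"
  )
}

simulate_motion_run <- function(n_frames, config, seed) {
  with_seed(seed, {
    if (config$mode == "six-parameter") {
      steps <- matrix(rnorm(n_frames * 6, sd = config$step_sd), n_frames, 6)
      steps[1, ] <- 0
      params <- apply(steps, 2, cumsum)
      colnames(params) <- c("trans_x", "trans_y", "trans_z",
                            "rot_x", "rot_y", "rot_z")
      list(fd = compute_fd(params)$fd, params = params)
    } else {
      fd <- rlnorm(n_frames, config$body_meanlog, config$body_sdlog)
      spikes <- runif(n_frames) < config$spike_prob
      fd[spikes] <- runif(sum(spikes), config$spike_range[1],
                          config$spike_range[2])
      fd[1] <- 0
      list(fd = fd, params = NULL)
    }
  })
}

#' Draw equilibrium frames from the linear coupling model
#'
#' Each frame is an independent draw of `x = (I - B)^(-1) eta` with
#' `eta ~ N(mean, noise_sd^2)` plus an optional shared (global) innovation.
#' The stationary covariance is
#' `(I - B)^(-1) (I - B)^(-T) * noise_sd^2` (plus the rank-one global term),
#' which is what the connectotype estimator inverts.
#'
#' @param b square coupling matrix with zero diagonal and spectral
#'   radius < 1.
#' @param n number of frames.
#' @param noise_sd innovation s.d.
#' @param global_sd s.d. of the shared innovation added to all regions.
#' @param mean per-region innovation mean (recycled), default 0.
#' @param seed integer seed.
#' @return regions x frames numeric matrix.
#' @export
simulate_equilibrium_frames <- function(b, n, noise_sd = 1, global_sd = 0,
                                        mean = 0, seed = 1) {
  p <- nrow(b)
  r <- spectral_radius_of(b)
  if (r >= 1) stop(sprintf("spectral radius %.3f >= 1; system unsolvable", r))
  with_seed(seed, {
    eta <- matrix(rnorm(p * n, sd = noise_sd), p, n) + mean
    if (global_sd > 0) {
      eta <- eta + rep(rnorm(n, sd = global_sd), each = p)
    }
    solve(diag(p) - b, eta)
  })
}

#' Simulate one participant's task session
#'
#' Generates per-run parcellated timeseries, a BIDS-style event table and a
#' frame-displacement trace. Every acquired frame is assigned its phase
#' (frame index within the active trial) and stimulus; the frame is then an
#' independent draw from the equilibrium system under the condition's
#' ground-truth coupling `B(frame, stimulus)`, with innovation mean
#' `hrf(offset) * activation * stim_gain` so evoked activity rides on top of
#' the coupling structure. Catch trials occupy only their shortened window.
#' A motion-locked common artifact (`motion$artifact_gain` times the frame's
#' FD, scaled by fixed per-region loadings) is added to the measured signal,
#' so frames surviving the censoring threshold still carry shared
#' sub-threshold artifact, as real scrubbed BOLD data do.
#'
#' @param design a [task_design()].
#' @param gt a [ground_truth()].
#' @param motion a [motion_config()].
#' @param seed integer seed; the session is fully deterministic under
#'   (seed, design, gt, motion).
#' @param participant identifier stored with the session.
#' @return a `participant_session`: list with `timeseries` (list of
#'   regions x frames matrices, one per run), `events`, `motion` (list of
#'   per-run FD vectors), `design`, `participant`, `seed`.
#' @export
simulate_session <- function(design = task_design(), gt, motion = motion_config(),
                             seed = 1, participant = 1) {
  stopifnot(inherits(design, "task_design"), inherits(gt, "ground_truth"))
  events <- simulate_design(design, derive_seed(seed, "events"))
  p <- gt$schema$n_roi
  tr <- design$tr_seconds

  # pre-solve (I - B)^{-1} per condition
  solves <- list()
  for (s in c("word", "pseudoword")) {
    for (f in seq_len(design$trial_frames)) {
      solves[[cond_key(f, s)]] <-
        solve(diag(p) - ground_truth_matrix(gt, f, s))
    }
  }
  base_solve <- solve(diag(p) - gt$base_connectivity)

  artifact_load <- with_seed(derive_seed(seed, "artifact-loadings"),
                             runif(p, 0.5, 1.5))

  timeseries <- vector("list", design$n_runs)
  fd <- vector("list", design$n_runs)
  for (run in seq_len(design$n_runs)) {
    ev <- events[events$run == run, ]
    n_frames <- run_length_frames(ev, design)
    phase <- rep(NA_integer_, n_frames)
    stim <- rep(NA_character_, n_frames)
    onset_frame <- as.integer(round(ev$onset / tr))
    next_onset <- c(onset_frame[-1], n_frames)
    for (i in seq_len(nrow(ev))) {
      span <- min(design$trial_frames, next_onset[i] - onset_frame[i])
      idx <- onset_frame[i] + seq_len(span)
      phase[idx] <- seq_len(span)
      stim[idx] <- ev$trial_type[i]
    }
    x <- matrix(0, p, n_frames)
    with_seed(derive_seed(seed, "bold", run), {
      eta <- matrix(rnorm(p * n_frames, sd = gt$noise_sd), p, n_frames)
      if (gt$global_signal_sd > 0) {
        eta <- eta + rep(rnorm(n_frames, sd = gt$global_signal_sd), each = p)
      }
      if (!is.null(gt$ar1) && gt$ar1 != 0) {
        # couple innovations across the frames of each trial
        for (i in seq_len(nrow(ev))) {
          span <- min(design$trial_frames, next_onset[i] - onset_frame[i])
          idx <- onset_frame[i] + seq_len(span)
          for (k in idx[-1]) {
            eta[, k] <- gt$ar1 * eta[, k - 1] +
              sqrt(1 - gt$ar1^2) * eta[, k]
          }
        }
      }
      for (s in c("word", "pseudoword")) {
        gain <- gt$stim_gain[[s]]
        for (f in seq_len(design$trial_frames)) {
          idx <- which(phase == f & stim == s)
          if (!length(idx)) next
          mu <- gt$hrf_samples[f] * gt$activation * gain
          x[, idx] <- solves[[cond_key(f, s)]] %*% (eta[, idx, drop = FALSE] + mu)
        }
      }
      idx <- which(is.na(phase))
      if (length(idx)) {
        x[, idx] <- base_solve %*% eta[, idx, drop = FALSE]
      }
    })
    fd_run <- simulate_motion_run(n_frames, motion,
                                  derive_seed(seed, "motion", run))$fd
    if (motion$artifact_gain > 0) {
      x <- x + motion$artifact_gain * (artifact_load %o% fd_run)
    }
    timeseries[[run]] <- x
    fd[[run]] <- fd_run
  }
  structure(
    list(timeseries = timeseries, events = events, motion = fd,
         design = design, participant = participant, seed = seed),
    class = "participant_session"
  )
}

#' @export
print.participant_session <- function(x, ...) {
  cat(sprintf("<participant_session> %s: %d runs, %d regions, %d trials\n",
              format(x$participant), length(x$timeseries),
              nrow(x$timeseries[[1]]), nrow(x$events)))
  invisible(x)
}

cond_key <- function(frame, stimulus) sprintf("f%d_%s", frame, stimulus)

#' Simulate a cohort of participant sessions
#'
#' Each participant receives an individually perturbed copy of the base
#' coupling (`B0` plus symmetric Gaussian noise of s.d. `gt$subject_sd`,
#' zero diagonal preserved), creating the between-subject variability the
#' repeated-measures analysis operates on. The default cohort size mirrors
#' the 15 participants surviving motion filtering in the study design this
#' generator emulates.
#'
#' @param n_participants cohort size.
#' @param design,gt,motion see [simulate_session()].
#' @param seed master seed; each participant draws independent sub-seeds.
#' @return list of `participant_session` objects.
#' @export
simulate_cohort <- function(n_participants = 15, design = task_design(), gt,
                            motion = motion_config(), seed = 1) {
  lapply(seq_len(n_participants), function(i) {
    gti <- perturb_ground_truth(gt, derive_seed(seed, "participant-b0", i))
    simulate_session(design, gti, motion,
                     seed = derive_seed(seed, "participant", i),
                     participant = i)
  })
}

perturb_ground_truth <- function(gt, seed) {
  if (gt$subject_sd <= 0) return(gt)
  p <- gt$schema$n_roi
  b <- with_seed(seed, {
    e <- matrix(rnorm(p * p, sd = gt$subject_sd), p, p)
    gt$base_connectivity + (e + t(e)) / 2
  })
  diag(b) <- 0
  gt$base_connectivity <- b
  check_spectral_radii(gt)
  gt
}

#' Write a session to disk as plain-text fixtures
#'
#' Emits, per run, a headerless TSV timeseries matrix (regions as rows), a
#' BIDS-style `events.tsv` (onset, duration, trial_type, plus a
#' non-standard `is_catch` column) and a one-column FD trace, along with a
#' JSON manifest recording the seed and a config hash.
#'
#' @param session a `participant_session`.
#' @param out_dir output directory (created if missing).
#' @return invisible character vector of files written.
#' @export
write_session <- function(session, out_dir) {
  stopifnot(inherits(session, "participant_session"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  files <- character(0)
  for (run in seq_along(session$timeseries)) {
    ts_path <- file.path(out_dir, sprintf("run-%02d_bold.tsv", run))
    write.table(session$timeseries[[run]], ts_path, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    ev <- session$events[session$events$run == run,
                         c("onset", "duration", "trial_type", "is_catch")]
    ev_path <- file.path(out_dir, sprintf("run-%02d_events.tsv", run))
    write.table(ev, ev_path, sep = "\t", quote = FALSE, row.names = FALSE)
    fd_path <- file.path(out_dir, sprintf("run-%02d_fd.tsv", run))
    write.table(data.frame(fd = session$motion[[run]]), fd_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
    files <- c(files, ts_path, ev_path, fd_path)
  }
  manifest <- list(
    participant = session$participant, seed = session$seed,
    n_runs = length(session$timeseries),
    n_regions = nrow(session$timeseries[[1]]),
    config_hash = config_hash(session$design)
  )
  man_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, man_path, auto_unbox = TRUE, digits = NA)
  invisible(c(files, man_path))
}

#' Read a session previously written by [write_session()]
#'
#' @param dir directory holding the per-run TSVs and manifest.
#' @param design the [task_design()] the session was simulated under.
#' @param drop_first_k optionally discard the first k frames of every run
#'   (steady-state discard for real acquisitions; synthetic data needs none).
#' @return a `participant_session`.
#' @export
read_session <- function(dir, design = task_design(), drop_first_k = 0) {
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  runs <- seq_len(man$n_runs)
  timeseries <- list(); motion <- list(); events <- list()
  for (run in runs) {
    x <- as.matrix(read.delim(
      file.path(dir, sprintf("run-%02d_bold.tsv", run)), header = FALSE))
    dimnames(x) <- NULL
    ev <- read.delim(file.path(dir, sprintf("run-%02d_events.tsv", run)))
    fd <- read.delim(file.path(dir, sprintf("run-%02d_fd.tsv", run)))$fd
    if (drop_first_k > 0) {
      keep <- -(seq_len(drop_first_k))
      x <- x[, keep, drop = FALSE]
      fd <- fd[keep]
      ev$onset <- ev$onset - drop_first_k * design$tr_seconds
      ev <- ev[ev$onset >= 0, ]
      fd[1] <- 0
    }
    timeseries[[run]] <- x
    motion[[run]] <- fd
    events[[run]] <- tibble::tibble(run = run, trial = seq_len(nrow(ev)),
                                    onset = ev$onset, duration = ev$duration,
                                    trial_type = ev$trial_type,
                                    is_catch = ev$is_catch)
  }
  structure(
    list(timeseries = timeseries, events = do.call(rbind, events),
         motion = motion, design = design,
         participant = man$participant, seed = man$seed),
    class = "participant_session"
  )
}
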