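#' Frame displacement from six rigid-body parameters
#'
#' FD at frame t is the absolute sum of frame-to-frame changes in the six
#' rigid-body realignment parameters, with rotations converted to arc
#' displacement on a sphere of `head_radius_mm` (50 mm convention). The
#' first frame's FD is defined as zero.
#'
#' @param six_params matrix with 6 columns: translations (mm) in x, y, z
#'   then rotations (radians) about x, y, z; one row per frame.
#' @param head_radius_mm sphere radius used for rotation-to-mm conversion.
#' @return a `motion_trace`: list with `fd` (mm per frame) and `source`.
#' @export
compute_fd <- function(six_params, head_radius_mm = 50) {
  six_params <- as.matrix(six_params)
  if (ncol(six_params) != 6) {
    stop("six_params must have exactly 6 columns (3 translations, 3 rotations)")
  }
  scaled <- six_params
  scaled[, 4:6] <- scaled[, 4:6] * head_radius_mm
  d <- abs(apply(scaled, 2, function(col) c(0, diff(col))))
  d <- matrix(d, ncol = 6)
  motion_trace(rowSums(d), source = "six-parameter")
}

#' Construct a motion trace from precomputed FD values
#'
#' @param fd non-negative per-frame frame displacement (mm); the first
#'   frame is forced to zero.
#' @param source provenance label.
#' @return a `motion_trace`.
#' @export
motion_trace <- function(fd, source = "precomputed") {
  if (any(fd < 0)) stop("frame displacement must be non-negative")
  fd[1] <- 0
  structure(list(fd = fd, source = source), class = "motion_trace")
}

#' Motion-censoring keep-mask
#'
#' A frame is kept iff its FD is strictly below the threshold (frames at or
#' above the threshold are censored); the first frame of a run always
#' survives since its FD is zero by convention.
#'
#' @param trace a [motion_trace()] or numeric FD vector.
#' @param threshold_mm censoring threshold in mm (default 0.3).
#' @return logical keep-mask, one element per frame.
#' @export
censor_mask <- function(trace, threshold_mm = 0.3) {
  if (threshold_mm <= 0) stop("threshold_mm must be positive")
  fd <- if (inherits(trace, "motion_trace")) trace$fd else trace
  fd < threshold_mm
}

#' Trials eligible for phase-aligned stacking
#'
#' A trial is eligible when (a) it spans the full `trial_frames` frames
#' before the next onset (or the end of the run), and (b) the preceding
#' onset is at least `min_gap_seconds` earlier, so the previous trial's
#' hemodynamic response has returned to baseline. The first trial of a run
#' has no preceding-gap constraint. Catch trials (shortened inter-trial
#' interval) fail (a); the trial following a catch trial fails (b).
#'
#' @param events event table for ONE run (columns `onset`, `trial_type`,
#'   and optionally `trial`), sorted by onset.
#' @param run_frames total acquired frames in the run.
#' @param tr_seconds repetition time.
#' @param trial_frames required trial span in frames.
#' @param min_gap_seconds required gap since the preceding onset.
#' @return the eligible subset of `events`, with added columns
#'   `onset_frame` (0-based) and `eligible`.
#' @export
eligible_trials <- function(events, run_frames, tr_seconds = 2.5,
                            trial_frames = 8, min_gap_seconds = 20) {
  if (is.unsorted(events$onset, strictly = TRUE)) {
    stop("events must be sorted by onset")
  }
  onset <- events$onset
  n <- length(onset)
  gap_next <- c(onset[-1], run_frames * tr_seconds) - onset
  gap_prev <- c(Inf, diff(onset))
  ok <- gap_next >= trial_frames * tr_seconds & gap_prev >= min_gap_seconds
  out <- events
  out$onset_frame <- as.integer(round(onset / tr_seconds))
  out$eligible <- ok
  out[ok, , drop = FALSE]
}

#' Stack replica frames for one (frame, stimulus) condition
#'
#' Collects, across the given eligible trials of a run, the frame at phase
#' `frame_index` (1 = the acquisition concurrent with stimulus onset) of
#' every trial whose target frame survives the censoring mask. Columns carry
#' provenance (run, trial, global frame index).
#'
#' @param timeseries regions x frames matrix for the run.
#' @param trials eligible trials (output of [eligible_trials()]) for the run.
#' @param frame_index phase within the trial, 1-based.
#' @param keep_mask logical per-frame keep-mask for the run.
#' @param run run identifier recorded in the provenance.
#' @param condition optional (frame, stimulus) condition label.
#' @param trial_frames trial span; `frame_index` must not exceed it.
#' @return a `frame_stack`: list with `data` (regions x kept trials),
#'   `condition`, and `provenance` (data.frame run/trial/frame).
#' @export
stack_replicas <- function(timeseries, trials, frame_index, keep_mask,
                           run = 1, condition = NULL, trial_frames = 8) {
  if (frame_index < 1 || frame_index > trial_frames) {
    stop("frame_index out of range 1..", trial_frames)
  }
  frames <- trials$onset_frame + frame_index  # 1-based column index
  if (any(frames > ncol(timeseries))) {
    stop("frame_index exceeds the run's acquired frames for some trial")
  }
  keep <- keep_mask[frames]
  frames <- frames[keep]
  structure(
    list(
      data = timeseries[, frames, drop = FALSE],
      condition = condition,
      provenance = data.frame(
        run = rep(run, length(frames)),
        trial = trials$trial[keep],
        frame = frames
      )
    ),
    class = "frame_stack"
  )
}

#' @export
print.frame_stack <- function(x, ...) {
  lab <- if (is.null(x$condition)) "" else
    sprintf(" [%s]", cond_key(x$condition$frame, x$condition$stimulus))
  cat(sprintf("<frame_stack>%s %d regions x %d frames\n",
              lab, nrow(x$data), ncol(x$data)))
  invisible(x)
}

bind_stacks <- function(stacks) {
  structure(
    list(
      data = do.call(cbind, lapply(stacks, `[[`, "data")),
      condition = stacks[[1]]$condition,
      provenance = do.call(rbind, lapply(stacks, `[[`, "provenance"))
    ),
    class = "frame_stack"
  )
}

#' Randomly subsample a stack to a fixed number of frames
#'
#' Draws exactly `n` columns uniformly without replacement (random rather
#' than lowest-FD selection, to avoid motion-related batch effects);
#' deterministic under `seed`.
#'
#' @param stack a `frame_stack`.
#' @param n frames to retain (default 40).
#' @param seed integer seed.
#' @return a `frame_stack` with exactly `n` columns.
#' @export
sample_frames <- function(stack, n = 40, seed = 1) {
  if (ncol(stack$data) < n) {
    stop(sprintf(
      "condition has only %d surviving frames (< %d): participant/condition excluded",
      ncol(stack$data), n))
  }
  idx <- with_seed(seed, sample(ncol(stack$data), n))
  stack$data <- stack$data[, idx, drop = FALSE]
  stack$provenance <- stack$provenance[idx, , drop = FALSE]
  stack
}

#' Build all 16 condition stacks for one session
#'
#' Applies motion censoring and trial eligibility per run, then stacks
#' replica frames for every (frame 1..8) x (word, pseudoword) condition
#' across runs.
#'
#' @param session a `participant_session`.
#' @param fd_threshold censoring threshold in mm.
#' @param trial_frames,min_gap_seconds eligibility rules
#'   (see [eligible_trials()]).
#' @return named list of 16 `frame_stack`s, keys `f<frame>_<stimulus>`.
#' @export
session_stacks <- function(session, fd_threshold = 0.3, trial_frames = 8,
                           min_gap_seconds = 20) {
  design <- session$design
  tr <- design$tr_seconds
  conds <- expand.grid(frame = seq_len(trial_frames),
                       stimulus = c("word", "pseudoword"),
                       stringsAsFactors = FALSE)
  per_run <- lapply(seq_along(session$timeseries), function(run) {
    ev <- session$events[session$events$run == run, ]
    ts <- session$timeseries[[run]]
    keep <- censor_mask(motion_trace(session$motion[[run]]), fd_threshold)
    el <- eligible_trials(ev, run_frames = ncol(ts), tr_seconds = tr,
                          trial_frames = trial_frames,
                          min_gap_seconds = min_gap_seconds)
    lapply(seq_len(nrow(conds)), function(ci) {
      sel <- el[el$trial_type == conds$stimulus[ci], , drop = FALSE]
      stack_replicas(ts, sel, conds$frame[ci], keep, run = run,
                     condition = list(frame = conds$frame[ci],
                                      stimulus = conds$stimulus[ci]))
    })
  })
  stacks <- lapply(seq_len(nrow(conds)), function(ci) {
    bind_stacks(lapply(per_run, `[[`, ci))
  })
  names(stacks) <- cond_key(conds$frame, conds$stimulus)
  stacks
}

#' Participant inclusion rule
#'
#' A participant is included only when every one of the 16 condition stacks
#' holds at least `min_frames` surviving replica frames, so all
#' per-condition connectotypes can be fitted from the same frame count.
#'
#' @param stacks named list of the participant's condition stacks.
#' @param min_frames required frames per condition (default 40).
#' @param n_conditions expected number of conditions.
#' @return `TRUE` or `FALSE`.
#' @export
participant_passes <- function(stacks, min_frames = 40, n_conditions = 16) {
  if (length(stacks) != n_conditions) {
    stop(sprintf("expected %d condition stacks, got %d",
                 n_conditions, length(stacks)))
  }
  all(vapply(stacks, function(s) ncol(s$data), 1L) >= min_frames)
}
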