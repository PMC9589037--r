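#' Widely spaced lexical-decision task design
#'
#' Describes the acquisition grid and trial structure of a widely spaced
#' event-related design: one stimulus frame followed by fixation, with
#' stimuli separated by 20 s so single-trial hemodynamic responses do not
#' overlap. Defaults mirror a 10-run lexical decision study: TR 2.5 s,
#' 24 stimuli per run (18 pseudowords, 6 words), 2.5 s stimulus + 17.5 s
#' fixation (8 frames per trial), and 3 catch trials per run whose
#' inter-trial interval is shortened to 5, 7.5 or 10 s.
#'
#' @param tr_seconds repetition time in seconds.
#' @param n_runs number of functional runs.
#' @param trials_per_run stimuli per run.
#' @param words_per_run,pseudowords_per_run per-run counts by stimulus class;
#'   must sum to `trials_per_run`.
#' @param catch_per_run number of catch trials per run.
#' @param trial_frames frames per full-length trial (stimulus + fixation).
#' @param catch_iti_choices_seconds ITIs (s) a catch trial draws from.
#' @return a `task_design` object.
#' @export
task_design <- function(tr_seconds = 2.5, n_runs = 10, trials_per_run = 24,
                        words_per_run = 6, pseudowords_per_run = 18,
                        catch_per_run = 3, trial_frames = 8,
                        catch_iti_choices_seconds = c(5, 7.5, 10)) {
  if (words_per_run + pseudowords_per_run != trials_per_run) {
    stop("words_per_run + pseudowords_per_run must equal trials_per_run")
  }
  if (catch_per_run > trials_per_run) {
    stop("catch_per_run cannot exceed trials_per_run")
  }
  structure(
    list(tr_seconds = tr_seconds, n_runs = n_runs,
         trials_per_run = trials_per_run, words_per_run = words_per_run,
         pseudowords_per_run = pseudowords_per_run,
         catch_per_run = catch_per_run, trial_frames = trial_frames,
         catch_iti_choices_seconds = catch_iti_choices_seconds),
    class = "task_design"
  )
}

#' @export
print.task_design <- function(x, ...) {
  cat(sprintf(paste0("<task_design> TR %.2g s, %d runs x %d trials ",
                     "(%d words/%d pseudowords, %d catch), %d frames/trial\n"),
              x$tr_seconds, x$n_runs, x$trials_per_run, x$words_per_run,
              x$pseudowords_per_run, x$catch_per_run, x$trial_frames))
  invisible(x)
}

#' Simulate per-run event tables for a task design
#'
#' Word/pseudoword order is randomized per run; `catch_per_run` trials are
#' chosen at random (never the final trial, so every catch trial is followed
#' by an onset at a short gap) and draw their shortened ITI uniformly from
#' the design's choices. Non-catch trials are separated by exactly
#' `trial_frames * tr_seconds` (20 s at defaults). Deterministic under
#' `seed`.
#'
#' @param design a [task_design()].
#' @param seed integer seed.
#' @return a tibble with one row per trial: `run`, `trial`, `onset` (s),
#'   `duration` (s), `trial_type`, `is_catch`, `iti_seconds`.
#' @export
simulate_design <- function(design = task_design(), seed = 1) {
  stopifnot(inherits(design, "task_design"))
  d <- design
  runs <- lapply(seq_len(d$n_runs), function(run) {
    with_seed(derive_seed(seed, "design", run), {
      types <- sample(c(rep("word", d$words_per_run),
                        rep("pseudoword", d$pseudowords_per_run)))
      is_catch <- rep(FALSE, d$trials_per_run)
      if (d$catch_per_run > 0) {
        eligible_pos <- seq_len(max(d$trials_per_run - 1L, 1L))
        is_catch[sample(eligible_pos, d$catch_per_run)] <- TRUE
      }
      iti <- ifelse(
        is_catch,
        sample(d$catch_iti_choices_seconds, d$trials_per_run, replace = TRUE),
        (d$trial_frames - 1) * d$tr_seconds
      )
      # onset-to-onset gap: stimulus frame + ITI
      gap <- d$tr_seconds + iti
      onset <- cumsum(c(0, gap[-d$trials_per_run]))
      tibble::tibble(
        run = run, trial = seq_len(d$trials_per_run), onset = onset,
        duration = d$tr_seconds, trial_type = types,
        is_catch = is_catch, iti_seconds = iti
      )
    })
  })
  do.call(rbind, runs)
}

# total acquisition frames in one run of an event table
run_length_frames <- function(events_run, design) {
  last <- max(events_run$onset)
  as.integer(round(last / design$tr_seconds)) + design$trial_frames
}

#' Canonical double-gamma hemodynamic response function
#'
#' Difference of two gamma densities (response peak minus undershoot),
#' peaking near 6 s after stimulus onset and back to baseline by ~20 s.
#'
#' @param t time since stimulus onset in seconds (non-negative).
#' @param peak_shape,peak_rate gamma parameters of the positive lobe.
#' @param under_shape,under_rate gamma parameters of the undershoot.
#' @param under_ratio undershoot amplitude as a fraction of the main lobe.
#' @return HRF amplitude at `t` (arbitrary units, hrf(0) = 0).
#' @export
#' @examples
#' canonical_hrf(6)
canonical_hrf <- function(t, peak_shape = 7, peak_rate = 1.05,
                          under_shape = 15, under_rate = 1, under_ratio = 1 / 6) {
  if (any(t < 0)) stop("canonical_hrf is undefined for negative t")
  dgamma(t, shape = peak_shape, rate = peak_rate) -
    under_ratio * dgamma(t, shape = under_shape, rate = under_rate)
}
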