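#' Ground-truth generative model for synthetic task BOLD
#'
#' Defines the condition-dependent connectivity and evoked activation used by
#' [simulate_session()]. Frames are drawn from the equilibrium linear system
#' `x = (I - B)^(-1) eta`, so that each region's signal is exactly a weighted
#' sum of all the others plus innovation noise -- the estimand of the
#' connectotype model. The base coupling matrix `B0` is symmetric with
#' positive within-network blocks (networks co-fluctuate), weaker random
#' between-network coupling, and an optional positively coupled
#' `interaction_pair` block whose strength is scaled by `g(frame, stimulus)`
#' to plant a time-by-stimulus connectivity interaction.
#'
#' @param schema a [parcellation_schema][load_parcellation] describing the
#'   regions and networks.
#' @param seed seed for the random components of `B0` and the activation map.
#' @param interaction_pair optional `network_pair`: the block carrying the
#'   planted interaction (applied symmetrically to both directed blocks).
#' @param interaction_amplitude peak relative scaling of the interaction
#'   block; the default profile rises at frames 3-4 for words
#'   (`g = 1 + amplitude` there) and stays 1 for pseudowords. 0 plants
#'   nothing (null configuration, `g == 1`).
#' @param interaction_profile optional 8 x 2 matrix (frames x word/pseudoword)
#'   of block scalings `g(f, s)`, overriding the default profile.
#' @param spectral_radius spectral radius `B0` is rescaled to (< 1).
#' @param within_strength,between_strength,cross_strength relative magnitudes
#'   of within-network, between-network and interaction-block coupling before
#'   the global rescale.
#' @param activation_sd spread of per-region evoked amplitudes around 1.
#' @param activation optional explicit per-region amplitude vector,
#'   overriding the random map (e.g. `rep(0, n)` for no evoked activity).
#' @param ar1 optional AR(1) coefficient coupling innovations across the
#'   frames of one trial (0 = conditionally independent frames, the
#'   default; same-phase frames from different trials stay independent
#'   either way). Useful for stress-testing against task autocorrelation.
#' @param stim_gain named numeric, evoked-amplitude gain per stimulus class;
#'   unequal gains create pure activation differences with no connectivity
#'   difference (the co-activation control).
#' @param noise_sd innovation standard deviation.
#' @param global_signal_sd standard deviation of a shared innovation added to
#'   every region (a global BOLD fluctuation); inflates marginal
#'   correlations while leaving direct couplings untouched.
#' @param subject_sd standard deviation of the symmetric per-participant
#'   perturbation of `B0` used by [simulate_cohort()].
#' @param tr_seconds frame spacing used to evaluate the HRF at frame offsets.
#' @param trial_frames frames per trial (length of the HRF sampling grid).
#' @return a `ground_truth` object.
#' @export
ground_truth <- function(schema, seed = 1,
                         interaction_pair = NULL, interaction_amplitude = 0,
                         interaction_profile = NULL,
                         spectral_radius = 0.45, within_strength = 1,
                         between_strength = 0.2, cross_strength = 0.5,
                         activation_sd = 0.3, activation = NULL,
                         ar1 = 0,
                         stim_gain = c(word = 1, pseudoword = 1),
                         noise_sd = 1, global_signal_sd = 0.8,
                         subject_sd = 0.02, tr_seconds = 2.5,
                         trial_frames = 8) {
  stopifnot(inherits(schema, "parcellation_schema"))
  stopifnot(spectral_radius > 0, spectral_radius < 1)
  b0 <- base_connectivity(schema, seed = seed, radius = spectral_radius,
                          within = within_strength, between = between_strength,
                          cross = cross_strength, pair = interaction_pair)
  if (is.null(interaction_profile)) {
    bump <- c(0, 0.25, 1, 1, 0.4, 0.15, 0, 0)[seq_len(trial_frames)]
    interaction_profile <- cbind(
      word = 1 + interaction_amplitude * bump,
      pseudoword = rep(1, trial_frames)
    )
  } else {
    stopifnot(nrow(interaction_profile) == trial_frames,
              ncol(interaction_profile) == 2)
    colnames(interaction_profile) <- c("word", "pseudoword")
  }
  if (is.null(activation)) {
    activation <- with_seed(derive_seed(seed, "activation"),
                            1 + rnorm(schema$n_roi, sd = activation_sd))
  }
  stopifnot(length(activation) == schema$n_roi, abs(ar1) < 1)
  gt <- structure(
    list(schema = schema, base_connectivity = b0,
         interaction_pair = interaction_pair,
         interaction_profile = interaction_profile,
         activation = activation, ar1 = ar1, stim_gain = stim_gain,
         hrf_samples = canonical_hrf((seq_len(trial_frames) - 1) * tr_seconds),
         noise_sd = noise_sd, global_signal_sd = global_signal_sd,
         subject_sd = subject_sd, tr_seconds = tr_seconds,
         trial_frames = trial_frames, seed = seed),
    class = "ground_truth"
  )
  check_spectral_radii(gt)
  gt
}

#' @export
print.ground_truth <- function(x, ...) {
  planted <- if (is.null(x$interaction_pair)) "none" else {
    sprintf("%s and %s (peak g %.2f)", x$interaction_pair$target_network,
            x$interaction_pair$source_network, max(x$interaction_profile))
  }
  cat(sprintf("<ground_truth> %d regions, planted interaction: %s\n",
              x$schema$n_roi, planted))
  invisible(x)
}

# symmetric base coupling: positive within-network blocks, weak random
# between-network coupling, optional positive interaction block
base_connectivity <- function(schema, seed, radius, within, between,
                              cross, pair = NULL) {
  p <- schema$n_roi
  with_seed(derive_seed(seed, "base-connectivity"), {
    b <- matrix(rnorm(p * p, sd = between), p, p)
    b <- (b + t(b)) / 2
    for (net in schema$network_names) {
      idx <- roi_indices(schema, net) + 1L
      blk <- matrix(runif(length(idx)^2, 0.5, 1.5) * within,
                    length(idx), length(idx))
      b[idx, idx] <- (blk + t(blk)) / 2
    }
    if (!is.null(pair)) {
      ti <- roi_indices(schema, pair$target_network) + 1L
      si <- roi_indices(schema, pair$source_network) + 1L
      blk <- matrix(runif(length(ti) * length(si), 0.5, 1.5) * cross,
                    length(ti), length(si))
      b[ti, si] <- blk
      b[si, ti] <- t(blk)
    }
    diag(b) <- 0
    b * radius / max(abs(eigen(b, symmetric = TRUE, only.values = TRUE)$values))
  })
}

#' Condition-specific ground-truth connectivity matrix
#'
#' Returns `B0` with the interaction block (both directed sub-blocks, keeping
#' the matrix symmetric) scaled by `g(frame, stimulus)`; all other entries
#' and the zero diagonal are untouched.
#'
#' @param gt a [ground_truth()].
#' @param frame trial phase, 1-based.
#' @param stimulus `"word"` or `"pseudoword"`.
#' @return region-by-region numeric matrix.
#' @export
ground_truth_matrix <- function(gt, frame, stimulus) {
  stopifnot(inherits(gt, "ground_truth"))
  if (frame < 1 || frame > gt$trial_frames) {
    stop("frame must be in 1..", gt$trial_frames)
  }
  stimulus <- match.arg(stimulus, c("word", "pseudoword"))
  b <- gt$base_connectivity
  if (!is.null(gt$interaction_pair)) {
    g <- gt$interaction_profile[frame, stimulus]
    ti <- roi_indices(gt$schema, gt$interaction_pair$target_network) + 1L
    si <- roi_indices(gt$schema, gt$interaction_pair$source_network) + 1L
    b[ti, si] <- b[ti, si] * g
    if (!setequal(ti, si)) b[si, ti] <- b[si, ti] * g
  }
  b
}

spectral_radius_of <- function(b) {
  max(Mod(eigen(b, only.values = TRUE)$values))
}

check_spectral_radii <- function(gt, b0 = NULL) {
  for (s in c("word", "pseudoword")) {
    for (f in seq_len(gt$trial_frames)) {
      b <- if (is.null(b0)) ground_truth_matrix(gt, f, s) else {
        gt2 <- gt; gt2$base_connectivity <- b0; ground_truth_matrix(gt2, f, s)
      }
      r <- spectral_radius_of(b)
      if (r >= 1) {
        stop(sprintf(
          "ground-truth system unsolvable: spectral radius %.3f >= 1 at frame %d, %s",
          r, f, s))
      }
    }
  }
  invisible(TRUE)
}
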