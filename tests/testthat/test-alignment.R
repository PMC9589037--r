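test_that("frame displacement sums absolute parameter changes", {
  const <- matrix(1, 10, 6)
  expect_equal(compute_fd(const)$fd, rep(0, 10))

  step <- matrix(0, 5, 6)
  step[3:5, 1] <- 1  # 1 mm x-translation step at frame 3
  expect_equal(compute_fd(step)$fd, c(0, 0, 1, 0, 0))

  rot <- matrix(0, 4, 6)
  rot[2:4, 4] <- 0.01  # 0.01 rad pitch step -> 0.5 mm on a 50 mm sphere
  expect_equal(compute_fd(rot)$fd, c(0, 0.5, 0, 0))

  expect_error(compute_fd(matrix(0, 5, 5)), "6 columns")
  expect_error(motion_trace(c(0, -1)), "non-negative")
})

test_that("censoring keeps frames strictly below threshold, monotonically", {
  tr <- motion_trace(c(0, 0.29, 0.30, 0.31))
  expect_equal(censor_mask(tr, 0.3), c(TRUE, TRUE, FALSE, FALSE))
  expect_true(all(censor_mask(motion_trace(rep(0, 5)), 0.3)))
  fd <- motion_trace(c(0, runif(99, 0, 0.6)))
  expect_true(all(censor_mask(fd, 0.5) >= censor_mask(fd, 0.25)))
  expect_error(censor_mask(tr, 0), "positive")
})

test_that("trial eligibility enforces full length and the 20 s preceding gap", {
  ev <- simulate_design(task_design(n_runs = 1, catch_per_run = 0), seed = 2)
  run_frames <- 24 * 8
  el <- eligible_trials(ev, run_frames)
  expect_equal(nrow(el), 24)  # catch-free: all eligible incl. first and last

  evc <- simulate_design(task_design(n_runs = 1), seed = 2)
  catch_trials <- evc$trial[evc$is_catch]
  elc <- eligible_trials(evc, run_length_frames(evc, task_design()))
  # catch trials are short; the trial after a catch starts < 20 s later
  expect_true(all(!catch_trials %in% elc$trial))
  expect_true(all(!(catch_trials + 1) %in% elc$trial))
  others <- setdiff(evc$trial, c(catch_trials, catch_trials + 1))
  expect_true(all(others %in% elc$trial))

  # truncated run: last trial loses eligibility
  el_short <- eligible_trials(ev, run_frames - 1)
  expect_false(24 %in% el_short$trial)

  expect_error(eligible_trials(ev[c(2, 1, 3:24), ], run_frames), "sorted")
})

test_that("replica stacking collects one surviving column per eligible trial", {
  sess <- clean_session(n_runs = 1)
  ts <- sess$timeseries[[1]]
  ev <- sess$events[sess$events$run == 1, ]
  el <- eligible_trials(ev, ncol(ts))
  keep_all <- rep(TRUE, ncol(ts))
  pw <- el[el$trial_type == "pseudoword", ]
  for (f in c(1, 3, 8)) {
    st <- stack_replicas(ts, pw, f, keep_all)
    expect_equal(ncol(st$data), 18)
    # provenance points at the exact acquisition frame
    expect_equal(st$data[, 1], ts[, st$provenance$frame[1]])
    expect_equal(st$provenance$frame, pw$onset_frame + f)
  }
  empty <- stack_replicas(ts, pw, 3, rep(FALSE, ncol(ts)))
  expect_equal(ncol(empty$data), 0)
  expect_error(stack_replicas(ts, pw, 9, keep_all), "out of range")
  expect_error(stack_replicas(ts, pw, 0, keep_all), "out of range")
})

test_that("session stacks never cross trial or run boundaries", {
  sess <- clean_session(schema = sim_schema(), n_runs = 2)
  stacks <- session_stacks(sess)
  expect_length(stacks, 16)
  ev <- sess$events
  for (key in names(stacks)) {
    st <- stacks[[key]]
    f <- st$condition$frame
    for (k in seq_len(nrow(st$provenance))) {
      pr <- st$provenance[k, ]
      trial <- ev[ev$run == pr$run & ev$trial == pr$trial, ]
      onset_frame <- round(trial$onset / 2.5)
      expect_equal(pr$frame, onset_frame + f)
      expect_identical(trial$trial_type, st$condition$stimulus)
    }
  }
  # catch-free, zero-motion run: counts are exactly the eligible-trial counts
  n_by_stim <- table(ev$trial_type)
  for (key in names(stacks)) {
    stim <- sub("^f[0-9]+_", "", key)
    expect_equal(ncol(stacks[[key]]$data), n_by_stim[[stim]])
  }
})

test_that("lowering the FD threshold never grows any stack", {
  gt <- ground_truth(sim_schema(), seed = 12)
  sess <- simulate_session(task_design(), gt,
                           motion_config(spike_prob = 0.05), seed = 12)
  for (th in list(c(0.25, 0.3), c(0.3, 0.5))) {
    lo <- session_stacks(sess, fd_threshold = th[1])
    hi <- session_stacks(sess, fd_threshold = th[2])
    expect_true(all(
      vapply(names(lo), function(k) ncol(lo[[k]]$data), 1L) <=
        vapply(names(lo), function(k) ncol(hi[[k]]$data), 1L)
    ))
  }
})

test_that("frame subsampling is uniform, exact and seeded", {
  sess <- clean_session(schema = toy_schema(), n_runs = 3)
  st <- session_stacks(sess)[["f2_pseudoword"]]  # 54 columns
  s40 <- sample_frames(st, 40, seed = 3)
  expect_equal(ncol(s40$data), 40)
  expect_equal(nrow(unique(s40$provenance)), 40)
  expect_identical(sample_frames(st, 40, seed = 3), s40)
  expect_false(identical(sample_frames(st, 40, seed = 4)$provenance,
                         s40$provenance))
  # n equal to the stack size: same set, possibly permuted
  all54 <- sample_frames(st, ncol(st$data), seed = 1)
  expect_setequal(all54$provenance$frame, st$provenance$frame)
  expect_error(sample_frames(st, ncol(st$data) + 1, seed = 1), "excluded")
})

test_that("the participant rule requires 40 frames in all 16 conditions", {
  sess <- clean_session(schema = toy_schema(), n_runs = 10)
  stacks <- session_stacks(sess)
  expect_true(participant_passes(stacks))
  short <- stacks
  short[["f5_word"]]$data <- short[["f5_word"]]$data[, 1:39]
  expect_false(participant_passes(short))
  expect_true(participant_passes(short, min_frames = 0))
  expect_error(participant_passes(stacks[1:15]), "expected 16")
})
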