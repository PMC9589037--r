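test_that("an exactly linear region is recovered with vanishing penalty", {
  set.seed(21)
  n <- 500
  x1 <- rnorm(n); x2 <- rnorm(n)
  x <- rbind(0.5 * x1 + 0.5 * x2, x1, x2)
  ct <- fit_connectotype(x, penalty_config(grid = 1e-8, normalize = "demean"))
  expect_equal(ct$beta[1, ], c(0, 0.5, 0.5), tolerance = 1e-6)
  expect_equal(diag(ct$beta), rep(0, 3))
})

test_that("the ridge solution matches an independent per-row OLS oracle", {
  for (p in c(5, 8)) {
    set.seed(p)
    x <- matrix(rnorm(p * 600), p, 600)
    ct <- fit_connectotype(x, penalty_config(grid = 1e-8, normalize = "demean"))
    xs <- t(x - rowMeans(x))
    for (i in seq_len(p)) {
      ols <- coef(lm(xs[, i] ~ xs[, -i] - 1))
      expect_equal(unname(ct$beta[i, -i]), unname(ols), tolerance = 1e-6)
    }
  }
})

test_that("betas recover the generating coupling from equilibrium frames", {
  sch <- scaled_parcellation(c(A = 5, B = 5))
  gt <- ground_truth(sch, seed = 4, global_signal_sd = 0)
  b <- gt$base_connectivity
  x <- simulate_equilibrium_frames(b, 5000, seed = 5)
  ct <- fit_connectotype(x, penalty_config(grid = 0.01, normalize = "demean"))
  off <- row(b) != col(b)
  expect_gt(cor(ct$beta[off], b[off]), 0.95)
})

test_that("the underdetermined 40-frame regime yields finite regularized fits", {
  sch <- gordon_parcellation()
  keep <- sch$network %in% included_networks()
  gt <- ground_truth(scaled_parcellation(c(X = 129)), seed = 6)
  x <- simulate_equilibrium_frames(gt$base_connectivity, 40, seed = 7)
  ct <- fit_connectotype(x, penalty_config())
  expect_equal(dim(ct$beta), c(129, 129))
  expect_true(all(is.finite(ct$beta)))
  expect_gt(ct$penalty, 0)
  expect_false(isSymmetric(ct$beta))
  expect_true(sum(keep) == 129)
})

test_that("cross-validation picks heavy shrinkage for noise, light for signal", {
  set.seed(30)
  noise <- matrix(rnorm(30 * 40), 30, 40)
  sel <- select_penalty(noise, penalty_config())
  grid <- penalty_config()$grid
  expect_gte(sel$lambda, sort(grid, decreasing = TRUE)[2])
  expect_equal(nrow(sel$curve), length(grid))

  # noiseless exactly-linear system: small penalties predict better
  z <- matrix(rnorm(4 * 60), 4, 60)
  lin <- rbind(z, colSums(z), z[1, ] - z[3, ])
  sel2 <- select_penalty(lin, penalty_config())
  small <- sel2$curve$mse[which.min(sel2$curve$lambda)]
  large <- sel2$curve$mse[which.max(sel2$curve$lambda)]
  expect_lt(small, large)
})

test_that("fits are deterministic and flag degenerate stacks", {
  sess <- clean_session(schema = sim_schema(), n_runs = 3)
  st <- sample_frames(session_stacks(sess)[["f4_pseudoword"]], 40, seed = 2)
  f1 <- fit_connectotype(st, penalty_config())
  f2 <- fit_connectotype(st, penalty_config())
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$penalty, f2$penalty)

  bad <- st
  bad$data[5, ] <- 3  # constant region
  expect_error(fit_connectotype(bad, penalty_config()), "zero-variance.*5")
  tiny <- st
  tiny$data <- tiny$data[, 1:3]
  expect_error(fit_connectotype(tiny, penalty_config(folds = 5)), "folds")
})

test_that("z-scored fits are invariant to per-region rescaling of the input", {
  set.seed(40)
  x <- matrix(rnorm(12 * 80), 12, 80)
  scl <- runif(12, 0.2, 5)
  f1 <- fit_connectotype(x, penalty_config(grid = 1))
  f2 <- fit_connectotype(x * scl, penalty_config(grid = 1))
  expect_equal(f1$beta, f2$beta, tolerance = 1e-10)
})

test_that("per-region penalty sharing fits each target with its own penalty", {
  set.seed(41)
  z <- matrix(rnorm(5 * 60), 5, 60)
  x <- rbind(z, colSums(z) + rnorm(60, sd = 0.01))  # one highly predictable row
  cfg <- penalty_config(grid = c(0.01, 10, 1000), sharing = "per-region")
  ct <- fit_connectotype(x, cfg)
  expect_length(ct$penalty, 6)
  expect_lt(ct$penalty[6], max(cfg$grid))
})

test_that("the Pearson baseline behaves like a correlation matrix should", {
  set.seed(31)
  x <- matrix(rnorm(6 * 1000), 6, 1000)
  x[2, ] <- x[1, ]        # duplicate region
  x[3, ] <- -x[1, ]       # anti-correlated region
  r <- pearson_matrix(x)
  expect_true(isSymmetric(r))
  expect_equal(diag(r), rep(1, 6))
  expect_equal(r[1, 2], 1)
  expect_equal(r[1, 3], -1)
  ind <- pearson_matrix(matrix(rnorm(8 * 1000), 8, 1000))
  expect_lt(max(abs(ind[row(ind) != col(ind)])), 0.1)
  x[4, ] <- 2
  expect_error(pearson_matrix(x), "zero-variance")
  expect_error(pearson_matrix(x[, 1:2]), "3 frames")
})

test_that("residual variances diagnose fit quality sensibly", {
  set.seed(32)
  n <- 200
  x1 <- rnorm(n); x2 <- rnorm(n)
  x <- rbind(0.5 * x1 + 0.5 * x2, x1, x2)
  ct <- fit_connectotype(x, penalty_config(grid = 1e-8, normalize = "demean"))
  rv <- predict_residuals(ct, x, normalize = "demean")
  expect_lt(rv[1], 1e-12)

  # zero betas leave the raw (unit, z-scored) variance untouched
  ct0 <- ct
  ct0$beta[] <- 0
  y <- matrix(rnorm(3 * 100), 3, 100)
  rv0 <- predict_residuals(ct0, y, normalize = "zscore")
  expect_equal(unname(rv0), rep(1, 3), tolerance = 1e-12)

  # a CV-selected fit never inflates residual variance above raw variance
  sess <- clean_session(schema = sim_schema(), n_runs = 3)
  st <- sample_frames(session_stacks(sess)[["f1_word"]], 15, seed = 3)
  fit <- fit_connectotype(st, penalty_config())
  expect_true(all(predict_residuals(fit, st) <= 1 + 1e-12))
  expect_error(predict_residuals(fit, st$data[1:4, ]), "region count")
})
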