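make_fits <- function(n_part, schema, f = function(i, fr, s) NULL, seed = 1) {
  # nested participant -> condition list of region x region matrices
  p <- schema$n_roi
  with_seed(seed, lapply(seq_len(n_part), function(i) {
    conds <- list()
    for (s in c("word", "pseudoword")) {
      for (fr in 1:8) {
        m <- matrix(rnorm(p * p, sd = 0.1), p, p)
        extra <- f(i, fr, s)
        if (!is.null(extra)) m <- m + extra
        diag(m) <- 0
        conds[[cond_key(fr, s)]] <- m
      }
    }
    conds
  }))
}

test_that("Box-Cox recovers the theoretically correct exponent", {
  ln <- with_seed(50, rlnorm(10000))
  r1 <- boxcox_fit(ln)
  expect_lt(abs(r1$lambda), 0.15)
  expect_equal(r1$shift, 0)  # already positive: no shift

  nm <- with_seed(51, rnorm(10000, mean = 20, sd = 2))
  r2 <- boxcox_fit(nm)
  expect_lt(abs(r2$lambda - 1), 0.2)
})

test_that("Box-Cox shifting and edge cases behave as documented", {
  v <- c(-2, -1, 0, 3, 5)
  r <- boxcox_fit(v)
  expect_true(all(v + r$shift > 0))
  expect_equal(r$shift, 2 + 1e-3 * 7)
  expect_true(all(diff(r$transformed[order(v)]) > 0))  # monotone
  expect_error(boxcox_fit(rep(2, 10)), "all values equal")
  expect_error(boxcox_fit(c(1, NA, 3)), "finite")
  # lambda = 1 is an affine (shape-preserving) map
  expect_equal(boxcox_transform(v + 3, 1), (v + 3) - 1)
  # lambda -> 0 limit is the log
  expect_equal(boxcox_transform(c(1, 2, 4), 1e-9), log(c(1, 2, 4)),
               tolerance = 1e-6)
})

test_that("Box-Cox against the MASS profile-likelihood oracle", {
  v <- with_seed(52, rgamma(2000, shape = 3))
  r <- boxcox_fit(v)
  prof <- MASS::boxcox(v ~ 1, lambda = seq(-1, 2, 0.01), plotit = FALSE)
  expect_equal(r$lambda, prof$x[which.max(prof$y)], tolerance = 0.02)
})

test_that("pair tables index (participant, connection, frame, stimulus)", {
  sch <- toy_schema()
  pair <- enumerate_pairs(sch, c("a", "b"))[[2]]  # target a, source b
  fits <- make_fits(3, sch)
  tbl <- pair_table(fits, pair)
  expect_equal(dim(tbl$values), c(3, 2, 8, 2))
  expect_equal(tbl$values[2, , 5, 1],
               extract_pair_values(fits[[2]][[cond_key(5, "word")]], pair))
  expect_equal(tbl$values[1, , 8, 2],
               extract_pair_values(fits[[1]][[cond_key(8, "pseudoword")]], pair))
  # transform preserves order within the pooled values
  o <- order(as.vector(tbl$values))
  expect_true(all(diff(as.vector(tbl$transformed)[o]) >= 0))
  broken <- fits
  broken[[2]][[cond_key(3, "word")]] <- NULL
  expect_error(pair_table(broken, pair), "missing condition")
})

test_that("stage-2 interaction F matches the aov() oracle", {
  for (seed in c(60, 61)) {
    y <- with_seed(seed, array(rnorm(6 * 8 * 2), c(6, 8, 2)))
    an <- rm_anova_cells(y)
    long <- data.frame(
      value = as.vector(y),
      participant = factor(rep(1:6, 16)),
      frame = factor(rep(rep(1:8, each = 6), 2)),
      stimulus = factor(rep(c("w", "p"), each = 48))
    )
    fit <- aov(value ~ frame * stimulus +
                 Error(participant / (frame * stimulus)), data = long)
    ref <- summary(fit)[["Error: participant:frame:stimulus"]][[1]]
    expect_equal(an$F, ref["frame:stimulus", "F value"], tolerance = 1e-10)
    expect_equal(an$df_num, ref["frame:stimulus", "Df"])
    expect_equal(an$df_den, ref["Residuals", "Df"])
  }
})

test_that("sphericity handling matches the car::Anova oracle", {
  n <- 12
  y <- with_seed(62, matrix(rnorm(n * 16), n, 16) +
                   matrix(rnorm(n * 2, sd = 2), n, 2)[, rep(1:2, each = 8)])
  mlm <- lm(y ~ 1)
  idata <- data.frame(frame = factor(rep(1:8, 2)),
                      stimulus = factor(rep(c("word", "pw"), each = 8)))
  av <- summary(car::Anova(mlm, idata = idata, idesign = ~ frame * stimulus,
                           type = 3), multivariate = FALSE)
  cf <- orthonormal_contrasts(8)
  cs <- matrix(c(1, -1) / sqrt(2), 2, 1)
  ours <- mauchly_epsilon(y, kronecker(cs, cf))
  # reference implementations differ slightly in one term of the Box
  # series; agreement to ~1e-3 on the p-value is the expected match
  expect_equal(ours$mauchly_p,
               av$sphericity.tests["frame:stimulus", "p-value"],
               tolerance = 5e-3)
  expect_equal(ours$mauchly_w,
               unname(av$sphericity.tests["frame:stimulus", "Test statistic"]),
               tolerance = 1e-8)
  expect_equal(ours$epsilon,
               unname(av$pval.adjustments["frame:stimulus", "GG eps"]),
               tolerance = 1e-8)
})

test_that("epsilon hits its bounds in the designed covariance regimes", {
  cf <- orthonormal_contrasts(4)
  # compound symmetry (iid conditions): epsilon near 1 at large n
  y <- with_seed(63, matrix(rnorm(600 * 4), 600, 4))
  expect_gt(mauchly_epsilon(y, cf)$epsilon, 0.95)
  # rank-1 dominated covariance: epsilon near the lower bound 1/(k-1)
  z <- with_seed(64, rnorm(200))
  y1 <- z %o% c(2, -1, 0.5, 1) +
    with_seed(65, matrix(rnorm(200 * 4, sd = 0.01), 200, 4))
  expect_lt(mauchly_epsilon(y1, cf)$epsilon, 1 / 3 + 0.05)
  # too few subjects: graceful lower-bound fallback
  expect_warning(
    out <- mauchly_epsilon(matrix(rnorm(3 * 4), 3, 4), cf), "singular")
  expect_equal(out$epsilon, 1 / 3)
})

test_that("the pair ANOVA is invariant where it must be", {
  sch <- toy_schema()
  pair <- enumerate_pairs(sch, c("a", "b"))[[2]]
  fits <- make_fits(6, sch, seed = 66)
  tbl <- pair_table(fits, pair)
  res <- rm_anova_pair(tbl)
  expect_true(res$F > 0 && res$p_uncorrected <= 1)
  expect_gte(res$p_uncorrected, res$p_nominal)  # epsilon adjustment
  expect_true(res$epsilon > 1 / 7 - 1e-12 && res$epsilon <= 1)

  # location invariance: shifting all values leaves F identical when the
  # Box-Cox shift tracks the minimum (values stay non-positive-minimum)
  shifted <- lapply(fits, function(pp) lapply(pp, function(m) m - 5))
  res2 <- rm_anova_pair(pair_table(shifted, pair))
  expect_equal(res2$F, res$F, tolerance = 1e-9)

  # fit-then-aggregate equals direct cell means on complete balanced data
  res3 <- rm_anova_pair(tbl, stage1 = "means")
  expect_equal(res3$F, res$F, tolerance = 1e-9)

  one <- pair_table(fits[1], pair)
  expect_error(rm_anova_pair(one), "2 participants")
})

test_that("a strong planted frame-3/4 interaction is detected and localized", {
  sch <- toy_schema()
  pair <- enumerate_pairs(sch, c("a", "b"))[[2]]
  effect <- function(i, fr, s) {
    if (s == "word" && fr %in% 3:4) 0.4 else 0
  }
  fits <- make_fits(8, sch, f = effect, seed = 67)
  tbl <- pair_table(fits, pair)
  res <- rm_anova_pair(tbl)
  expect_lt(res$p_uncorrected, 0.001)
  expect_true(which.min(res$posthoc) %in% 3:4)
})

test_that("post-hoc paired tests respect symmetry and degeneracy", {
  sch <- toy_schema()
  pair <- enumerate_pairs(sch, c("a", "b"))[[2]]
  fits <- make_fits(5, sch, seed = 68)
  # identical word and pseudoword values -> all t = 0, p = 1
  same <- lapply(fits, function(pp) {
    for (fr in 1:8) pp[[cond_key(fr, "pseudoword")]] <- pp[[cond_key(fr, "word")]]
    pp
  })
  expect_equal(posthoc_frames(pair_table(same, pair)), rep(1, 8))
  # two-sided: swapping the stimulus labels changes nothing
  swapped <- lapply(fits, function(pp) {
    q <- pp
    for (fr in 1:8) {
      q[[cond_key(fr, "word")]] <- pp[[cond_key(fr, "pseudoword")]]
      q[[cond_key(fr, "pseudoword")]] <- pp[[cond_key(fr, "word")]]
    }
    q
  })
  expect_equal(posthoc_frames(pair_table(swapped, pair)),
               posthoc_frames(pair_table(fits, pair)), tolerance = 1e-9)
})

test_that("family-wise correction implements its documented contracts", {
  expect_equal(correct_family(rep(1, 36)), rep(1, 36))
  expect_equal(correct_family(0.01), 0.01)  # family of one
  expect_equal(correct_family(c(0.001, rep(0.5, 35)), "bonferroni")[1], 0.036)
  p <- c(0.001, 0.02, 0.5, 0.9)
  for (m in c("tukey", "holm", "bonferroni", "sidak")) {
    q <- correct_family(p, m)
    expect_true(all(q >= p - 1e-12) && all(q <= 1))
    expect_false(is.unsorted(q))  # monotone in p
  }
  # the studentized-range family is more conservative than Sidak
  expect_gt(correct_family(p, "tukey")[1], correct_family(p, "sidak")[1])
  expect_error(correct_family(c(0.5, 1.2)), "0, 1")
  expect_error(correct_family(0.5, "fancy"))
})

test_that("marginal means summarize each of the 16 cells with 1.15x bars", {
  sch <- toy_schema()
  pair <- enumerate_pairs(sch, c("a", "b"))[[2]]
  fits <- make_fits(4, sch, seed = 69)
  tbl <- pair_table(fits, pair)
  mm_sd <- marginal_means(tbl, "sd")
  mm_se <- marginal_means(tbl, "se")
  expect_equal(nrow(mm_sd), 16)
  n_cell <- 4 * 2  # participants x connections
  expect_equal(mm_se$dispersion, mm_sd$dispersion / sqrt(n_cell))
  i <- which(mm_sd$frame == 3 & mm_sd$stimulus == "word")
  v <- as.vector(tbl$values[, , 3, 1])
  expect_equal(mm_sd$mean[i], mean(v))
  expect_equal(mm_sd$dispersion[i], 1.15 * sd(v))
  # constant input: zero dispersion
  const <- lapply(fits, function(pp) lapply(pp, function(m) {
    m[] <- 2; diag(m) <- 0; m
  }))
  ctbl <- pair_table(const, pair, transform = FALSE)
  cm <- marginal_means(ctbl)
  expect_equal(cm$mean, rep(2, 16))
  expect_equal(cm$dispersion, rep(0, 16))
})
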