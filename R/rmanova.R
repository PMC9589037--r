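#' Assemble the per-pair condition table from fitted connectivity matrices
#'
#' Collects, for one network pair, every participant's connection values in
#' all 16 (frame, stimulus) conditions into a 4-dimensional array indexed
#' (participant, connection, frame, stimulus), and Box-Cox-transforms the
#' pooled values (one transform per pair).
#'
#' @param fits nested list: `fits[[participant]][[cond_key]]` is a
#'   region x region connectivity matrix, keys `f<frame>_<stimulus>`.
#' @param pair a `network_pair`.
#' @param trial_frames number of frame levels.
#' @param transform apply [boxcox_fit()] to the pooled values.
#' @return a `pair_table`: list with `pair`, `values`, `transformed`,
#'   `boxcox`, `participants`.
#' @export
pair_table <- function(fits, pair, trial_frames = 8, transform = TRUE) {
  n_part <- length(fits)
  n_conn <- count_connections(pair)
  stimuli <- c("word", "pseudoword")
  values <- array(
    NA_real_, dim = c(n_part, n_conn, trial_frames, 2),
    dimnames = list(NULL, NULL, paste0("f", seq_len(trial_frames)), stimuli)
  )
  for (i in seq_len(n_part)) {
    for (f in seq_len(trial_frames)) {
      for (s in seq_along(stimuli)) {
        m <- fits[[i]][[cond_key(f, stimuli[s])]]
        if (is.null(m)) stop("missing condition ", cond_key(f, stimuli[s]),
                             " for participant ", i)
        values[i, , f, s] <- extract_pair_values(m, pair)
      }
    }
  }
  bc <- NULL
  transformed <- values
  if (transform) {
    bc <- boxcox_fit(as.vector(values))
    transformed <- array(bc$transformed, dim = dim(values),
                         dimnames = dimnames(values))
  }
  structure(
    list(pair = pair, values = values, transformed = transformed,
         boxcox = bc, participants = names(fits) %||% seq_len(n_part)),
    class = "pair_table"
  )
}

#' @export
print.pair_table <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<pair_table> %s and %s: %d participants x %d connections x %d frames x 2\n",
              x$pair$target_network, x$pair$source_network, d[1], d[2], d[3]))
  invisible(x)
}

pair_table_long <- function(tbl, use_transformed = TRUE) {
  vals <- if (use_transformed) tbl$transformed else tbl$values
  d <- dim(vals)
  grid <- expand.grid(participant = seq_len(d[1]), connection = seq_len(d[2]),
                      frame = seq_len(d[3]), stimulus = c(1L, 2L))
  data.frame(
    value = as.vector(vals),
    participant = factor(grid$participant),
    connection = factor(grid$connection),
    frame = factor(grid$frame),
    stimulus = factor(c("word", "pseudoword")[grid$stimulus],
                      levels = c("word", "pseudoword"))
  )
}

# participant x frame x stimulus array of participant-level means
participant_cell_means <- function(tbl, use_transformed = TRUE,
                                   adjusted = NULL) {
  vals <- if (!is.null(adjusted)) adjusted else {
    if (use_transformed) tbl$transformed else tbl$values
  }
  apply(vals, c(1, 3, 4), mean)
}

#' Greenhouse-Geisser epsilon and Mauchly's sphericity test
#'
#' Operates on the orthonormalized within-subject contrasts of a
#' participant-by-condition matrix. Epsilon is the Greenhouse-Geisser
#' estimate clamped to `[1/q, 1]` where `q` is the contrast dimension;
#' Mauchly's W is converted to a chi-square p-value. When the contrast
#' covariance is singular (too few participants) epsilon falls back to its
#' lower bound with a warning rather than failing.
#'
#' @param y participant x condition numeric matrix.
#' @param contrasts condition x q orthonormal contrast matrix defining the
#'   within-subject effect (columns orthonormal, orthogonal to the
#'   intercept).
#' @return list with `mauchly_w`, `mauchly_p`, `epsilon`.
#' @export
mauchly_epsilon <- function(y, contrasts) {
  n <- nrow(y)
  q <- ncol(contrasts)
  z <- y %*% contrasts
  s <- stats::cov(z)
  tr <- sum(diag(s))
  eps_low <- 1 / q
  if (n - 1 < q || !all(is.finite(s)) || tr <= 0) {
    warning("singular contrast covariance: epsilon set to its lower bound")
    return(list(mauchly_w = NA_real_, mauchly_p = NA_real_,
                epsilon = eps_low))
  }
  epsilon <- tr^2 / (q * sum(s * s))
  epsilon <- min(1, max(eps_low, epsilon))
  detS <- det(s)
  if (detS <= 0) {
    warning("singular contrast covariance: Mauchly test unavailable")
    return(list(mauchly_w = NA_real_, mauchly_p = NA_real_,
                epsilon = epsilon))
  }
  w <- detS / (tr / q)^q
  # Box's two-term chi-square series for -d * rho * log W
  d <- n - 1
  rho <- 1 - (2 * q^2 + q + 2) / (6 * q * d)
  z <- -d * rho * log(w)
  df <- q * (q + 1) / 2 - 1
  w2 <- (q + 2) * (q - 1) * (q - 2) * (2 * q^3 + 6 * q^2 + 3 * q + 2) /
    (288 * (d * q * rho)^2)
  pr1 <- pchisq(z, df, lower.tail = FALSE)
  pr2 <- pchisq(z, df + 4, lower.tail = FALSE)
  list(mauchly_w = w, mauchly_p = pr1 + w2 * (pr2 - pr1),
       epsilon = epsilon)
}

# orthonormal polynomial-free contrasts: Helmert, orthonormalized
orthonormal_contrasts <- function(k) {
  c_raw <- stats::contr.helmert(k)
  qr.Q(qr(cbind(1, c_raw)))[, -1, drop = FALSE]
}

# classical two-way within-subject ANOVA from an n x f x s cell-mean array;
# returns the frame-by-stimulus interaction decomposition
rm_anova_cells <- function(y) {
  n <- dim(y)[1]; nf <- dim(y)[2]; ns <- dim(y)[3]
  grand <- mean(y)
  m_f <- apply(y, 2, mean)
  m_s <- apply(y, 3, mean)
  m_fs <- apply(y, c(2, 3), mean)
  m_if <- apply(y, c(1, 2), mean)
  m_is <- apply(y, c(1, 3), mean)
  m_i <- apply(y, 1, mean)
  inter <- sweep(sweep(m_fs, 1, m_f), 2, m_s) + grand
  ss_fs <- n * sum(inter^2)
  resid <- y
  for (i in seq_len(n)) {
    resid[i, , ] <- y[i, , ] - m_if[i, ] %o% rep(1, ns) -
      rep(1, nf) %o% m_is[i, ] - m_fs + m_i[i] + outer(m_f, rep(1, ns)) +
      outer(rep(1, nf), m_s) - grand
  }
  ss_err <- sum(resid^2)
  df_num <- (nf - 1) * (ns - 1)
  df_den <- df_num * (n - 1)
  f_stat <- (ss_fs / df_num) / (ss_err / df_den)
  list(F = f_stat, df_num = df_num, df_den = df_den,
       ss_interaction = ss_fs, ss_error = ss_err)
}

#' Repeated-measures ANOVA for one network pair
#'
#' Tests the frame-by-stimulus interaction of the pair's connectivity
#' values in two stages. Stage 1 fits a fixed-effects linear model
#' (participant + frame * stimulus) on the connection-level transformed
#' values and removes the participant effect; stage 2 aggregates the
#' adjusted values to a participant x 16-condition matrix and runs the
#' classical two-way within-subject ANOVA. Sphericity is assessed with
#' Mauchly's test on the interaction contrasts and the p-value is always
#' epsilon-adjusted (Greenhouse-Geisser by default).
#'
#' @param tbl a [pair_table()].
#' @param epsilon `"gg"` (Greenhouse-Geisser) or `"hf"` (Huynh-Feldt).
#' @param stage1 `"lmm"`: fit-then-aggregate as described above;
#'   `"means"`: aggregate participant cell means directly (sensitivity
#'   mode).
#' @param posthoc compute per-frame paired t-tests (word vs pseudoword on
#'   participant-level means).
#' @return an `rmanova_result`: list with `pair`, `F`, `df_num`, `df_den`,
#'   `epsilon`, `mauchly_p`, `p_nominal` (no sphericity adjustment),
#'   `p_uncorrected` (epsilon-adjusted, family-uncorrected), `p_corrected`
#'   (`NA` until [correct_family()]), `posthoc`, `cell_means`.
#' @export
rm_anova_pair <- function(tbl, epsilon = c("gg", "hf"),
                          stage1 = c("lmm", "means"), posthoc = TRUE) {
  stopifnot(inherits(tbl, "pair_table"))
  epsilon <- match.arg(epsilon)
  stage1 <- match.arg(stage1)
  n <- dim(tbl$values)[1]
  if (n < 2) stop("repeated-measures ANOVA needs at least 2 participants")
  nf <- dim(tbl$values)[3]

  adjusted <- NULL
  if (stage1 == "lmm") {
    long <- pair_table_long(tbl, use_transformed = TRUE)
    fit <- lm(value ~ participant + frame * stimulus, data = long,
              contrasts = list(participant = "contr.sum",
                               frame = "contr.sum", stimulus = "contr.sum"))
    if (any(is.na(coef(fit)))) stop("rank-deficient stage-1 design")
    mm <- model.matrix(fit)
    part_cols <- grep("^participant", colnames(mm))
    part_effect <- mm[, part_cols, drop = FALSE] %*%
      coef(fit)[part_cols]
    adj_long <- long$value - as.vector(part_effect)
    adjusted <- array(adj_long, dim = dim(tbl$transformed))
  }
  cells <- participant_cell_means(tbl, adjusted = adjusted)

  an <- rm_anova_cells(cells)
  ymat <- matrix(cells, nrow = n)  # conditions stimulus-major: f1..f8 word, f1..f8 pw
  cf <- orthonormal_contrasts(nf)
  cs <- matrix(c(1, -1) / sqrt(2), 2, 1)
  sph <- mauchly_epsilon(ymat, kronecker(cs, cf))
  eps <- sph$epsilon
  if (epsilon == "hf") {
    b <- an$df_num
    hf <- (n * b * eps - 2) / (b * (n - 1 - b * eps))
    eps <- min(1, max(sph$epsilon, hf))
  }
  res <- list(
    pair = tbl$pair,
    n_participants = n,
    n_connections = dim(tbl$values)[2],
    F = an$F, df_num = an$df_num, df_den = an$df_den,
    epsilon = eps, mauchly_p = sph$mauchly_p,
    p_nominal = pf(an$F, an$df_num, an$df_den, lower.tail = FALSE),
    p_uncorrected = pf(an$F, eps * an$df_num, eps * an$df_den,
                       lower.tail = FALSE),
    p_corrected = NA_real_,
    posthoc = if (posthoc) posthoc_frames(tbl) else NULL,
    cell_means = cells
  )
  class(res) <- "rmanova_result"
  res
}

#' @export
print.rmanova_result <- function(x, ...) {
  cat(sprintf(
    "<rmanova_result> %s and %s: F(%g, %g) = %.4f, eps = %.3f, p = %.4g (adj), %.4g (corr)\n",
    x$pair$target_network, x$pair$source_network, x$df_num, x$df_den,
    x$F, x$epsilon, x$p_uncorrected, x$p_corrected))
  invisible(x)
}

#' Family-wise correction across network-pair tests
#'
#' Default `"tukey"` treats the family of pair tests as a comparison family
#' under a studentized-range adjustment: each two-sided p-value is mapped to
#' its standard-normal quantile and referred to the studentized-range
#' distribution with `length(pvals)` groups (df = Inf). `"holm"`,
#' `"bonferroni"`, `"sidak"` and `"none"` are available alternatives.
#'
#' @param pvals vector of uncorrected p-values in [0, 1].
#' @param method correction method.
#' @return corrected p-values in [0, 1].
#' @export
correct_family <- function(pvals,
                           method = c("tukey", "holm", "bonferroni",
                                      "sidak", "none")) {
  method <- match.arg(method)
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(pvals)
  if (m <= 1 || method == "none") return(pvals)
  switch(method,
    tukey = {
      z <- qnorm(pmax(pvals, 1e-300) / 2, lower.tail = FALSE)
      ptukey(z * sqrt(2), nmeans = m, df = Inf, lower.tail = FALSE)
    },
    holm = p.adjust(pvals, "holm"),
    bonferroni = p.adjust(pvals, "bonferroni"),
    sidak = 1 - (1 - pvals)^m
  )
}

#' Per-frame post-hoc paired tests
#'
#' For each frame, a two-sided paired t-test of word versus pseudoword
#' participant-level mean connectivity (transformed scale).
#'
#' @param tbl a [pair_table()].
#' @return numeric vector of 8 p-values (one per frame).
#' @export
posthoc_frames <- function(tbl) {
  cells <- participant_cell_means(tbl)
  n <- dim(cells)[1]
  if (n < 2) stop("post-hoc tests need at least 2 participants")
  vapply(seq_len(dim(cells)[2]), function(f) {
    d <- cells[, f, 1] - cells[, f, 2]
    if (all(d == 0)) return(1)
    t.test(d)$p.value
  }, 1)
}

#' Marginal means and dispersion per condition
#'
#' Means over participants and connections for each (frame, stimulus) cell,
#' with dispersion bars of 1.15 times the chosen spread statistic
#' (standard deviation for distribution-style plots, standard error for
#' group-mean plots).
#'
#' @param tbl a [pair_table()].
#' @param dispersion `"sd"` or `"se"`.
#' @param use_transformed use transformed values (default: raw connectivity
#'   values, as plotted).
#' @param bar_factor multiplier on the spread statistic.
#' @return tibble: pair, frame, stimulus, mean, dispersion,
#'   dispersion_type, n.
#' @export
marginal_means <- function(tbl, dispersion = c("sd", "se"),
                           use_transformed = FALSE, bar_factor = 1.15) {
  dispersion <- match.arg(dispersion)
  vals <- if (use_transformed) tbl$transformed else tbl$values
  d <- dim(vals)
  out <- expand.grid(frame = seq_len(d[3]),
                     stimulus = c("word", "pseudoword"),
                     stringsAsFactors = FALSE)
  stat <- t(vapply(seq_len(nrow(out)), function(i) {
    v <- as.vector(vals[, , out$frame[i],
                        if (out$stimulus[i] == "word") 1 else 2])
    spread <- sd(v)
    if (dispersion == "se") spread <- spread / sqrt(length(v))
    c(mean(v), bar_factor * spread, length(v))
  }, c(0, 0, 0)))
  tibble::tibble(
    target = tbl$pair$target_network, source = tbl$pair$source_network,
    frame = out$frame, stimulus = out$stimulus,
    mean = stat[, 1], dispersion = stat[, 2],
    dispersion_type = dispersion, n = as.integer(stat[, 3])
  )
}
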