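#' Ridge penalty and cross-validation settings for connectotype fitting
#'
#' @param grid candidate ridge penalties (positive, typically log-spaced).
#'   A length-one grid skips cross-validation and uses that penalty.
#' @param folds cross-validation fold count (frames from different trials
#'   are exchangeable within a stack, so folding over frames is valid).
#' @param sharing `"global"`: one penalty for all regions, selected by the
#'   summed held-out error (the stable choice in the 40-frame regime);
#'   `"per-region"`: an individual penalty per modeled region.
#' @param normalize `"zscore"` (demean and variance-normalize each region
#'   across the stack's frames; makes betas comparable across conditions and
#'   participants) or `"demean"`.
#' @param seed seed used to shuffle frames before folding.
#' @return a `penalty_config` object.
#' @export
penalty_config <- function(grid = 10^seq(-2, 3, length.out = 8), folds = 5,
                           sharing = c("global", "per-region"),
                           normalize = c("zscore", "demean"), seed = 1) {
  if (!length(grid) || any(grid < 0)) stop("grid must be non-negative values")
  if (folds < 2) stop("folds must be >= 2")
  structure(
    list(grid = sort(grid), folds = folds, sharing = match.arg(sharing),
         normalize = match.arg(normalize), seed = seed),
    class = "penalty_config"
  )
}

normalize_stack <- function(data, normalize) {
  mu <- rowMeans(data)
  x <- data - mu
  if (normalize == "zscore") {
    s <- sqrt(rowSums(x^2) / (ncol(x) - 1))
    zero <- which(s == 0)
    if (length(zero)) {
      stop("zero-variance region(s): ", paste(zero, collapse = ", "))
    }
    x <- x / s
  } else {
    zero <- which(rowSums(x^2) == 0)
    if (length(zero)) {
      stop("zero-variance region(s): ", paste(zero, collapse = ", "))
    }
  }
  x
}

# All-rows ridge solution via the precision matrix.
# For target i, the coefficients regressing x_i on all other regions with an
# L2 penalty are beta_i = -Theta[-i, i] / Theta[i, i],
# Theta = (X'X + lambda I)^{-1}: the i-th normal equations of the full
# system restricted to the remaining columns. One p x p inverse therefore
# yields every target row at once, exactly.
ridge_beta <- function(xt, lambda) {
  p <- ncol(xt)
  a <- crossprod(xt)
  diag(a) <- diag(a) + lambda
  theta <- tryCatch(chol2inv(chol(a)), error = function(e) solve(a))
  beta <- -theta / diag(theta)   # beta[i, j]: target i, source j
  diag(beta) <- 0
  beta
}

#' Select the ridge penalty by k-fold cross-validation over frames
#'
#' Frames are shuffled with the config seed and split into folds; for each
#' candidate penalty the connectotype is fitted on the training frames and
#' the mean squared prediction error summed over regions is measured on the
#' held-out frames. The penalty minimizing the pooled held-out error wins;
#' ties break toward the larger (more regularized) penalty.
#'
#' @param stack a `frame_stack` (or regions x frames matrix).
#' @param config a [penalty_config()].
#' @return list with `lambda` (selected penalty) and `curve`
#'   (tibble: lambda, mse).
#' @export
select_penalty <- function(stack, config = penalty_config()) {
  data <- stack_data(stack)
  n <- ncol(data)
  if (n < config$folds) stop("fewer frames than CV folds")
  x <- t(normalize_stack(data, config$normalize))  # frames x regions
  fold_id <- with_seed(config$seed,
                       sample(rep(seq_len(config$folds), length.out = n)))
  sse <- numeric(length(config$grid))
  for (k in seq_len(config$folds)) {
    tr <- x[fold_id != k, , drop = FALSE]
    te <- x[fold_id == k, , drop = FALSE]
    if (!nrow(tr) || !nrow(te)) stop("degenerate CV fold (empty)")
    for (li in seq_along(config$grid)) {
      beta <- ridge_beta(tr, config$grid[li])
      resid <- te - te %*% t(beta)
      sse[li] <- sse[li] + sum(resid^2)
    }
  }
  mse <- sse / (n * ncol(x))
  best <- max(config$grid[mse <= min(mse) + 1e-12])
  list(lambda = best, curve = tibble::tibble(lambda = config$grid, mse = mse))
}

#' Fit a connectotype on a stack of replica frames
#'
#' Models each region's (normalized) signal as a weighted sum of all other
#' regions' signals under an L2 (ridge) penalty; the penalty is selected by
#' cross-validation over frames unless the grid has length one. The
#' resulting beta matrix is directed (rows = modeled/target region,
#' columns = source region) with an exactly zero diagonal. No
#' autocorrelation pre-whitening is applied: in task data the temporal
#' evolution is signal, not nuisance.
#'
#' @param stack a `frame_stack` (or regions x frames matrix).
#' @param config a [penalty_config()].
#' @return a `connectotype`: list with `beta`, `condition`, `penalty`,
#'   `cv_curve`, `fit_stats` (per-region residual variance on the stack).
#' @export
fit_connectotype <- function(stack, config = penalty_config()) {
  data <- stack_data(stack)
  if (ncol(data) < 2 || nrow(data) < 2) {
    stop("stack must have at least 2 regions and 2 frames")
  }
  x <- t(normalize_stack(data, config$normalize))
  if (length(config$grid) > 1) {
    sel <- select_penalty(stack, config)
    lambda <- sel$lambda
    curve <- sel$curve
  } else {
    lambda <- config$grid
    curve <- NULL
  }
  if (config$sharing == "per-region") {
    # per-region penalty: refit each target with its own CV-selected lambda
    lambda <- per_region_lambda(x, config)
    beta <- matrix(0, ncol(x), ncol(x))
    for (lam in unique(lambda)) {
      rows <- which(lambda == lam)
      beta[rows, ] <- ridge_beta(x, lam)[rows, , drop = FALSE]
    }
  } else {
    beta <- ridge_beta(x, lambda)
  }
  resid <- x - x %*% t(beta)
  structure(
    list(beta = beta,
         condition = if (inherits(stack, "frame_stack")) stack$condition,
         penalty = lambda, cv_curve = curve,
         fit_stats = colSums(resid^2) / (nrow(x) - 1)),
    class = "connectotype"
  )
}

per_region_lambda <- function(x, config) {
  n <- nrow(x)
  fold_id <- with_seed(config$seed,
                       sample(rep(seq_len(config$folds), length.out = n)))
  sse <- matrix(0, length(config$grid), ncol(x))
  for (k in seq_len(config$folds)) {
    tr <- x[fold_id != k, , drop = FALSE]
    te <- x[fold_id == k, , drop = FALSE]
    for (li in seq_along(config$grid)) {
      beta <- ridge_beta(tr, config$grid[li])
      sse[li, ] <- sse[li, ] + colSums((te - te %*% t(beta))^2)
    }
  }
  vapply(seq_len(ncol(x)), function(i) {
    max(config$grid[sse[, i] <= min(sse[, i]) + 1e-12])
  }, 1)
}

#' @export
print.connectotype <- function(x, ...) {
  lab <- if (is.null(x$condition)) "" else
    sprintf(" [%s]", cond_key(x$condition$frame, x$condition$stimulus))
  cat(sprintf("<connectotype>%s %d regions, penalty %s\n",
              lab, nrow(x$beta),
              paste(signif(unique(x$penalty), 3), collapse = "/")))
  invisible(x)
}

stack_data <- function(stack) {
  if (inherits(stack, "frame_stack")) stack$data else as.matrix(stack)
}

#' Pearson correlation baseline on the same frames
#'
#' The traditional connectivity estimate computed from the identical frame
#' stack: the symmetric matrix of pairwise Pearson correlations between
#' region timeseries (unit diagonal; the diagonal is excluded from any
#' downstream pair extraction).
#'
#' @param stack a `frame_stack` (or regions x frames matrix), >= 3 frames.
#' @return region x region correlation matrix.
#' @export
pearson_matrix <- function(stack) {
  data <- stack_data(stack)
  if (ncol(data) < 3) stop("need at least 3 frames for correlations")
  s <- apply(data, 1, sd)
  if (any(s == 0)) {
    stop("zero-variance region(s): ", paste(which(s == 0), collapse = ", "))
  }
  cor(t(data))
}

#' Per-region residual variance of a fitted connectotype on a stack
#'
#' Applies the fitted beta weights to a (normalized) stack and returns the
#' residual variance of each modeled region.
#'
#' @param connectotype a fitted `connectotype`.
#' @param stack a `frame_stack` (or matrix) with matching region count.
#' @param normalize normalization to apply before prediction; use the same
#'   setting the model was fitted with.
#' @return named numeric vector, one residual variance per region.
#' @export
predict_residuals <- function(connectotype, stack,
                              normalize = c("zscore", "demean")) {
  data <- stack_data(stack)
  if (nrow(data) != nrow(connectotype$beta)) {
    stop("region count of stack does not match the fitted connectotype")
  }
  x <- t(normalize_stack(data, match.arg(normalize)))
  resid <- x - x %*% t(connectotype$beta)
  setNames(colSums(resid^2) / (nrow(x) - 1),
           rownames(connectotype$beta) %||% seq_len(ncol(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export a connectotype as TSV with a JSON sidecar
#'
#' @param connectotype a fitted `connectotype`.
#' @param path output TSV path; the sidecar replaces the extension with
#'   `.json`.
#' @param roi_id ROI labels for the header row/column.
#' @return invisible vector of files written.
#' @export
write_connectotype <- function(connectotype, path,
                               roi_id = seq_len(nrow(connectotype$beta))) {
  beta <- connectotype$beta
  dimnames(beta) <- list(roi_id, roi_id)
  write.table(beta, path, sep = "\t", quote = FALSE,
              row.names = TRUE, col.names = NA)
  sidecar <- sub("\\.[^.]+$", ".json", path)
  jsonlite::write_json(
    list(condition = connectotype$condition,
         penalty = connectotype$penalty,
         config_hash = config_hash(connectotype[c("condition", "penalty")])),
    sidecar, auto_unbox = TRUE, digits = NA)
  invisible(c(path, sidecar))
}
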