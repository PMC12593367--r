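#' Energies relative to the training-pool minimum
#'
#' Shifts absolute energies so the minimum over the pool is zero; ordering
#' is preserved. When the training pool grows and a lower minimum enters,
#' all relative energies shift accordingly.
#'
#' @param energies Numeric absolute (or relative) energies of the pool.
#' @return Relative energies with minimum 0.
#' @export
relative_energies <- function(energies) {
  if (length(energies) == 0) stop("empty energy pool")
  energies - min(energies)
}

#' Fit a Gaussian process regression model on a precomputed kernel
#'
#' The precomputed structure kernel acts as the prior covariance; the dual
#' weights solve (K_train + alpha I) w = y by Cholesky factorization. The
#' prior mean is zero on the relative energies.
#'
#' @param K_train Normalized, PSD training kernel block (n x n).
#' @param y_rel Relative training energies (kJ/mol), see
#'   [relative_energies()].
#' @param alpha Observation-noise variance (kJ/mol)^2, default 1e-6.
#' @param train_labels Optional training structure labels.
#' @return Object of class `gpr_model` with `dual_weights`, `alpha`,
#'   `train_labels`, `y_reference`.
#' @export
gpr_fit <- function(K_train, y_rel, alpha = 1e-6, train_labels = NULL) {
  stopifnot(alpha > 0)
  Km <- unclass(K_train)
  n <- nrow(Km)
  if (length(y_rel) != n) stop("y_rel length must match kernel size")
  ch <- tryCatch(chol(Km + diag(alpha, n)), error = function(e) {
    ev <- eigen(Km, symmetric = TRUE, only.values = TRUE)$values
    stop("factorization failure (min kernel eigenvalue ", format(min(ev)),
         "); kernel must be PSD within tolerance")
  })
  w <- backsolve(ch, forwardsolve(t(ch), y_rel))
  if (is.null(train_labels)) train_labels <- rownames(Km)
  structure(list(dual_weights = as.numeric(w), alpha = alpha,
                 train_labels = train_labels,
                 y_reference = attr(y_rel, "reference")),
            class = "gpr_model")
}

#' Predict relative energies from a cross-kernel block
#'
#' @param model A [gpr_fit()] model.
#' @param K_cross test x train kernel block, columns aligned with the
#'   training structures.
#' @return Predicted relative energies.
#' @export
gpr_predict <- function(model, K_cross) {
  K_cross <- as.matrix(unclass(K_cross))
  if (ncol(K_cross) != length(model$dual_weights)) {
    stop("cross-kernel columns (", ncol(K_cross),
         ") must match the training size (", length(model$dual_weights), ")")
  }
  as.numeric(K_cross %*% model$dual_weights)
}

.error_report <- function(truth, pred, n_train) {
  res <- truth - pred
  list(rmse = sqrt(mean(res^2)), mae = mean(abs(res)),
       n_train = n_train, n_test = length(truth))
}

#' Block-wise GPR learning curve
#'
#' Reproduces the iterative training protocol: a fixed random test set is
#' held out, the remaining pool is split into random training blocks, and
#' for each cumulative number of blocks the model is refit with the target
#' energies set relative to the global minimum of the training pool so far,
#' then evaluated (RMSE, MAE) on the fixed test set.
#'
#' @param K Full normalized kernel over all structures.
#' @param energies Absolute energies (kJ/mol).
#' @param block_size Training block size (default 500).
#' @param n_test Test-set size drawn at random (ignored when `test_idx`
#'   given).
#' @param test_idx Optional explicit test-set indices.
#' @param alpha Observation-noise variance, see [gpr_fit()].
#' @param seed RNG seed for the test/block split.
#' @return Data frame with one row per cumulative train size: `n_train`,
#'   `rmse`, `mae`, `n_test`.
#' @export
learning_curve <- function(K, energies, block_size = 500L, n_test = 2000L,
                           test_idx = NULL, alpha = 1e-6, seed = 1L) {
  n <- nrow(K)
  set.seed(seed)
  if (is.null(test_idx)) {
    if (n_test >= n) stop("not enough structures for a training block plus the test set")
    test_idx <- sample(n, n_test)
  }
  if (is.character(test_idx)) test_idx <- match(test_idx, rownames(unclass(K)))
  pool <- setdiff(seq_len(n), test_idx)
  if (length(intersect(pool, test_idx)) > 0) stop("train/test overlap")
  pool <- sample(pool)
  n_blocks <- max(1L, length(pool) %/% block_size)
  out <- data.frame()
  for (b in seq_len(n_blocks)) {
    tr <- pool[seq_len(min(b * block_size, length(pool)))]
    y_rel <- relative_energies(energies[tr])
    model <- gpr_fit(unclass(K)[tr, tr], y_rel, alpha = alpha)
    pred <- gpr_predict(model, unclass(K)[test_idx, tr, drop = FALSE])
    truth <- energies[test_idx] - min(energies[tr])
    rep_ <- .error_report(truth, pred, length(tr))
    out <- rbind(out, as.data.frame(rep_))
  }
  out
}

#' k-fold cross-validated GPR errors
#'
#' Random fold assignment; each fold's model is trained on the remaining
#' folds with target energies set relative to the training fold's global
#' minimum, and evaluated on the held-out fold.
#'
#' @param K Full normalized kernel.
#' @param energies Absolute energies (kJ/mol).
#' @param folds Number of folds (default 5).
#' @param alpha Observation-noise variance.
#' @param seed RNG seed for the fold split.
#' @return List with `rmse_mean`, `rmse_sd`, `mae_mean`, `mae_sd`,
#'   `per_fold` (data frame).
#' @export
cross_validate <- function(K, energies, folds = 5L, alpha = 1e-6, seed = 1L) {
  n <- nrow(K)
  stopifnot(n >= folds)
  set.seed(seed)
  assign <- sample(rep_len(seq_len(folds), n))
  per <- data.frame()
  for (f in seq_len(folds)) {
    tr <- which(assign != f); te <- which(assign == f)
    y_rel <- relative_energies(energies[tr])
    model <- gpr_fit(unclass(K)[tr, tr], y_rel, alpha = alpha)
    pred <- gpr_predict(model, unclass(K)[te, tr, drop = FALSE])
    truth <- energies[te] - min(energies[tr])
    per <- rbind(per, as.data.frame(.error_report(truth, pred, length(tr))))
  }
  list(rmse_mean = mean(per$rmse), rmse_sd = stats::sd(per$rmse),
       mae_mean = mean(per$mae), mae_sd = stats::sd(per$mae),
       per_fold = per)
}

#' Subset structures within an energy window
#'
#' Structures whose energy lies within `window` kJ/mol of the global
#' minimum of the set (ties at the window edge included).
#'
#' @param energies Absolute energies.
#' @param window Window in kJ/mol above the global minimum.
#' @return Integer indices of the subset.
#' @export
energy_window_subset <- function(energies, window) {
  if (anyNA(energies)) stop("energies present required")
  idx <- which(energies - min(energies) <= window + 1e-12)
  if (length(idx) == 0) stop("empty subset: window excludes every structure")
  idx
}
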