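#' Elastic-net modeling of uORF activity
#'
#' Fits the regularized linear model minimizing
#' (1/2n) ||y - Xw||^2 + lambda1 ||w||_1 + lambda2 ||w||^2, with
#' lambda1 = alpha * l1_ratio and lambda2 = 0.5 * alpha * (1 - l1_ratio), by
#' cyclic coordinate descent with an unpenalized intercept. The trial protocol
#' repeats a random 80/20 train/test split, min-max scales features on the
#' training data, fits, and scores the held-out R^2; a single-feature ordinary
#' regression on Kozak score serves as the baseline in every trial.
#'
#' @name enr_model
NULL

#' Elastic-net configuration
#'
#' @param alpha Penalty magnitude (> 0 for regularization; 0 reduces to OLS).
#' @param l1_ratio Mix in [0, 1]: 1 = lasso, 0 = ridge (halved).
#' @param n_trials Number of random-split trials.
#' @param test_fraction Held-out fraction per trial.
#' @param seed Integer seed.
#' @return An `enr_config` list, including the implied lambda1/lambda2.
#' @export
enr_config <- function(alpha = 0.01, l1_ratio = 0.5, n_trials = 100,
                       test_fraction = 0.2, seed = 1L) {
  stopifnot(alpha >= 0, l1_ratio >= 0, l1_ratio <= 1,
            test_fraction > 0, test_fraction < 1)
  structure(list(alpha = alpha, l1_ratio = l1_ratio,
                 lambda1 = alpha * l1_ratio,
                 lambda2 = 0.5 * alpha * (1 - l1_ratio),
                 n_trials = as.integer(n_trials),
                 test_fraction = test_fraction, seed = as.integer(seed)),
            class = "enr_config")
}

#' Min-max scale a feature matrix
#'
#' Maps each column to [0, 1] on its own range. Constant columns are left at 0
#' with a warning. Returned parameters are applied to test data with
#' [apply_minmax()] (values outside the training range scale outside [0, 1];
#' no clipping).
#'
#' @param X Numeric matrix.
#' @return list(X, mins, ranges)
#' @export
minmax_scale <- function(X) {
  mins <- apply(X, 2, min)
  maxs <- apply(X, 2, max)
  ranges <- maxs - mins
  if (any(ranges == 0)) {
    warning("constant column(s) scaled to 0: ",
            paste(colnames(X)[ranges == 0], collapse = ", "))
  }
  list(X = apply_minmax(X, list(mins = mins, ranges = ranges)),
       mins = mins, ranges = ranges)
}

#' Apply stored min-max parameters to new data
#' @param X Numeric matrix.
#' @param params list(mins, ranges) from [minmax_scale()].
#' @return Scaled matrix (constant training columns map to 0).
#' @export
apply_minmax <- function(X, params) {
  r <- ifelse(params$ranges == 0, 1, params$ranges)
  out <- sweep(sweep(X, 2, params$mins, "-"), 2, r, "/")
  out[, params$ranges == 0] <- 0
  out
}

#' Elastic-net fit by cyclic coordinate descent
#'
#' Minimizes (1/2n)||y - b0 - Xw||^2 + lambda1||w||_1 + lambda2||w||^2 with an
#' unpenalized intercept b0. Iterates until the objective decrease falls below
#' `tol`.
#'
#' @param X Feature matrix (n x p), typically min-max scaled.
#' @param y Response.
#' @param lambda1 L1 penalty weight.
#' @param lambda2 L2 penalty weight (on the squared norm).
#' @param tol Convergence tolerance on the objective decrease.
#' @param max_iter Maximum coordinate-descent sweeps.
#' @return list(weights, intercept, objective, iterations, converged)
#' @export
elastic_net_fit <- function(X, y, lambda1, lambda2, tol = 1e-9,
                            max_iter = 10000L) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(n >= 2, length(y) == n)
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  yc <- y - ym
  z <- colSums(Xc^2) / n                  # (1/n) x_j' x_j
  w <- numeric(p)
  res <- yc                                # residual y - Xc w
  obj <- function() sum(res^2) / (2 * n) + lambda1 * sum(abs(w)) +
    lambda2 * sum(w^2)
  prev <- obj()
  converged <- FALSE
  it <- 0L
  soft <- function(a, l) sign(a) * max(abs(a) - l, 0)
  while (it < max_iter) {
    it <- it + 1L
    for (j in seq_len(p)) {
      if (z[j] == 0) next
      rho <- sum(Xc[, j] * res) / n + z[j] * w[j]
      wj <- soft(rho, lambda1) / (z[j] + 2 * lambda2)
      if (wj != w[j]) {
        res <- res + Xc[, j] * (w[j] - wj)
        w[j] <- wj
      }
    }
    cur <- obj()
    if (prev - cur < tol) { converged <- TRUE; break }
    prev <- cur
  }
  if (!converged) {
    stop(sprintf("coordinate descent did not converge in %d sweeps (objective %.6g)",
                 max_iter, prev))
  }
  intercept <- ym - sum(xm * w)
  list(weights = stats::setNames(w, colnames(X)), intercept = intercept,
       objective = obj(), iterations = it, converged = converged)
}

#' Coefficient of determination on held-out data
#' @param y Observed response.
#' @param yhat Predictions.
#' @return 1 - RSS/TSS with TSS around the test-set mean.
#' @export
r_squared <- function(y, yhat) {
  1 - sum((y - yhat)^2) / sum((y - mean(y))^2)
}

#' Repeated random-split elastic-net trials with a Kozak-only baseline
#'
#' Each trial draws a fresh 80/20 split, min-max scales on the training data,
#' fits the elastic net, and scores held-out R^2; an ordinary single-feature
#' regression on the Kozak score over the same split is fit as the baseline.
#'
#' @param X Feature matrix with named columns.
#' @param y Response (uORF effect_log2).
#' @param config [enr_config()].
#' @param kozak_col Column used for the baseline.
#' @return list(trials = data.frame(trial, r2_test, r2_kozak), weights =
#'   n_trials x p matrix, selected = logical matrix, config)
#' @export
run_trials <- function(X, y, config = enr_config(), kozak_col = "kozak_score") {
  X <- as.matrix(X)
  n <- nrow(X)
  stopifnot(length(y) == n, kozak_col %in% colnames(X))
  set.seed(config$seed)
  n_test <- max(1L, round(config$test_fraction * n))
  W <- matrix(NA_real_, config$n_trials, ncol(X),
              dimnames = list(NULL, colnames(X)))
  r2f <- r2k <- numeric(config$n_trials)
  for (t in seq_len(config$n_trials)) {
    test <- sample(n, n_test)
    train <- setdiff(seq_len(n), test)
    sc <- minmax_scale(X[train, , drop = FALSE])
    Xte <- apply_minmax(X[test, , drop = FALSE], sc)
    fit <- elastic_net_fit(sc$X, y[train], config$lambda1, config$lambda2)
    W[t, ] <- fit$weights
    pred <- as.vector(Xte %*% fit$weights) + fit$intercept
    r2f[t] <- r_squared(y[test], pred)
    kfit <- stats::lm.fit(cbind(1, sc$X[, kozak_col]), y[train])
    kpred <- kfit$coefficients[1] + kfit$coefficients[2] * Xte[, kozak_col]
    r2k[t] <- r_squared(y[test], kpred)
  }
  list(trials = data.frame(trial = seq_len(config$n_trials),
                           r2_test = r2f, r2_kozak = r2k),
       weights = W, selected = W != 0, config = config)
}

#' Full-model vs Kozak-only baseline comparison
#'
#' @param trials Result of [run_trials()].
#' @return list(r2_full_mean, r2_kozak_mean, n_full_better, wrt_p) — the
#'   Wilcoxon rank-sum p across the per-trial R^2 values.
#' @export
kozak_only_baseline <- function(trials) {
  tr <- trials$trials
  list(r2_full_mean = mean(tr$r2_test),
       r2_kozak_mean = mean(tr$r2_kozak),
       n_full_better = sum(tr$r2_test > tr$r2_kozak),
       wrt_p = wilcoxon_rank_sum(tr$r2_test, tr$r2_kozak))
}

#' Per-feature weight summary over trials
#'
#' Mean weight, selection frequency, and a one-sample Wilcoxon signed-rank
#' test of the per-trial weights against zero, BH-adjusted across features.
#' (The signed-rank-across-trials procedure is this package's construction,
#' not a published convention.)
#'
#' @param trials Result of [run_trials()] (>= 20 trials recommended).
#' @return data.frame(feature, mean_weight, selection_freq, p, fdr)
#' @export
feature_significance <- function(trials) {
  W <- trials$weights
  p <- apply(W, 2, function(w) {
    if (all(w == 0)) return(1)
    suppressWarnings(stats::wilcox.test(w, mu = 0)$p.value)
  })
  data.frame(feature = colnames(W),
             mean_weight = colMeans(W),
             selection_freq = colMeans(W != 0),
             p = p, fdr = bh_adjust(p),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Grid search over elastic-net hyperparameters
#'
#' Convenience helper: mean held-out R^2 and mean number of selected features
#' for each (alpha, l1_ratio) combination over a reduced number of trials.
#'
#' @param X,y Data.
#' @param alphas,l1_ratios Grids.
#' @param n_trials Trials per combination.
#' @param seed Integer seed.
#' @return data.frame(alpha, l1_ratio, mean_r2, mean_selected)
#' @export
enr_grid_search <- function(X, y, alphas = c(0.001, 0.01, 0.1),
                            l1_ratios = c(0.25, 0.5, 0.75), n_trials = 20,
                            seed = 1L) {
  grid <- expand.grid(alpha = alphas, l1_ratio = l1_ratios)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    tr <- run_trials(X, y, enr_config(grid$alpha[i], grid$l1_ratio[i],
                                      n_trials = n_trials, seed = seed))
    data.frame(alpha = grid$alpha[i], l1_ratio = grid$l1_ratio[i],
               mean_r2 = mean(tr$trials$r2_test),
               mean_selected = mean(rowSums(tr$selected)))
  })
  do.call(rbind, res)
}
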