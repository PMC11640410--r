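#' Log2-transform an expression study
#'
#' Applied to raw-scale matrices before any cross-study comparison; the
#' missingness mask is untouched.
#'
#' @param study An [expression_study()] with `log_scale = FALSE` and all
#'   observed values strictly positive.
#' @return The study with `values = log2(values)` and `log_scale = TRUE`.
#' @export
log2_transform <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  if (isTRUE(study$log_scale)) {
    stop("study is already on the log2 scale", call. = FALSE)
  }
  bad <- which(!study$missing_mask & study$values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf(
      "nonpositive observed value at feature '%s', sample '%s'",
      rownames(study$values)[bad[1, 1]], colnames(study$values)[bad[1, 2]]),
      call. = FALSE)
  }
  study$values <- log2(study$values)
  study$log_scale <- TRUE
  study
}

#' Impute missing expression values iteratively
#'
#' MissForest-style iterative imputation: after a column-mean (per-feature
#' mean) initialisation, features are visited in order of descending
#' missingness and each feature's missing entries are re-predicted from
#' all other features (samples as observations), repeating until the
#' normalized change in the imputed cells
#' \eqn{\gamma = \sum \Delta^2 / \sum x_{imp}^2} falls below `tol` or
#' `max_iter` is reached. Observed cells are never altered.
#'
#' @param study An [expression_study()] on the log2 scale.
#' @param method Per-feature regressor: `"rf"` (random forest, 100 trees,
#'   the default), `"ridge"` (closed-form ridge, much faster), or
#'   `"mean"` (feature-mean fill, no iteration).
#' @param max_iter Maximum number of sweeps (default 10).
#' @param tol Convergence threshold on the normalized change (default
#'   1e-4).
#' @param seed Seed for the forest's bootstrap resampling; the result is
#'   deterministic given `seed`.
#' @param num_trees Trees per forest when `method = "rf"`.
#' @return The study with no missing values; `missing_mask` still records
#'   which cells were imputed.
#' @export
impute_missing <- function(study, method = c("rf", "ridge", "mean"),
                           max_iter = 10, tol = 1e-4, seed = 1,
                           num_trees = 100) {
  stopifnot(inherits(study, "expression_study"))
  method <- match.arg(method)
  if (!isTRUE(study$log_scale)) {
    stop("impute on the log2 scale (run log2_transform first)",
         call. = FALSE)
  }
  mask <- study$missing_mask
  if (!any(mask)) return(study)
  if (any(rowSums(!mask) == 0)) {
    stop("feature(s) with no observed values cannot be imputed",
         call. = FALSE)
  }
  x <- study$values
  # initialise with per-feature means
  fmeans <- rowMeans(x, na.rm = TRUE)
  for (i in which(rowSums(mask) > 0)) x[i, mask[i, ]] <- fmeans[i]

  if (method == "mean") {
    study$values <- x
    return(study)
  }

  feats <- which(rowSums(mask) > 0)
  ord <- feats[order(-rowSums(mask)[feats], rownames(x)[feats])]
  n_samp <- ncol(x)
  converged <- FALSE
  with_seed(seed, {
    for (iter in seq_len(max_iter)) {
      prev <- x[mask]
      for (i in ord) {
        obs <- !mask[i, ]
        mis <- mask[i, ]
        # observations are samples; predictors are all other features
        pred <- t(x[-i, , drop = FALSE])
        y <- x[i, obs]
        if (method == "rf") {
          df <- data.frame(pred[obs, , drop = FALSE], check.names = TRUE)
          fit <- ranger::ranger(
            x = df, y = y, num.trees = num_trees,
            seed = substream_seed(seed, sprintf("f%d_i%d", i, iter)),
            num.threads = 1
          )
          newd <- data.frame(pred[mis, , drop = FALSE], check.names = TRUE)
          x[i, mis] <- stats::predict(fit, data = newd,
                                      num.threads = 1)$predictions
        } else {
          x[i, mis] <- ridge_predict(pred[obs, , drop = FALSE], y,
                                     pred[mis, , drop = FALSE])
        }
      }
      gamma <- sum((x[mask] - prev)^2) / max(sum(x[mask]^2), .Machine$double.eps)
      if (gamma < tol) {
        converged <- TRUE
        break
      }
    }
  })
  if (!converged) {
    warning("imputation did not converge within max_iter; returning last iterate",
            call. = FALSE)
  }
  stopifnot(identical(study$values[!mask], x[!mask]))
  study$values <- x
  study
}

#' Closed-form ridge regression prediction
#'
#' Standardized predictors, intercept unpenalized; lambda fixed at a
#' small multiple of the predictor count, adequate for the n << p
#' regimes these small studies sit in.
#' @noRd
ridge_predict <- function(x_obs, y, x_new, lambda = NULL) {
  mu <- colMeans(x_obs)
  sdv <- apply(x_obs, 2, stats::sd)
  keep <- sdv > 0
  if (!any(keep)) return(rep(mean(y), nrow(x_new)))
  xs <- scale(x_obs[, keep, drop = FALSE], mu[keep], sdv[keep])
  xn <- scale(x_new[, keep, drop = FALSE], mu[keep], sdv[keep])
  p <- ncol(xs)
  lambda <- lambda %||% max(1, p / max(1, nrow(xs)))
  beta <- solve(crossprod(xs) + diag(lambda, p), crossprod(xs, y - mean(y)))
  drop(mean(y) + xn %*% beta)
}
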