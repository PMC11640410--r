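#' Per-feature two-group fit
#'
#' Ordinary pooled-variance two-sample statistics per feature, with the
#' effect coded resistant minus control throughout the package.
#'
#' @param study An [expression_study()] on the log2 scale with no missing
#'   values.
#' @return A tibble with columns `feature_id`, `logFC`
#'   (mean(resistant) - mean(control)), `s2` (pooled within-group
#'   variance), `df_residual` (n1 + n2 - 2), `t_ordinary`, and the group
#'   sizes `n1`, `n2`.
#' @export
fit_two_group <- function(study) {
  stopifnot(inherits(study, "expression_study"))
  if (!isTRUE(study$log_scale)) {
    stop("fit requires log2-scale values", call. = FALSE)
  }
  if (anyNA(study$values)) {
    stop("missing values present; impute first", call. = FALSE)
  }
  res <- study$groups == "resistant"
  n1 <- sum(res)
  n2 <- sum(!res)
  if (n1 < 2 || n2 < 2) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  xr <- study$values[, res, drop = FALSE]
  xc <- study$values[, !res, drop = FALSE]
  m1 <- rowMeans(xr)
  m2 <- rowMeans(xc)
  ss1 <- rowSums((xr - m1)^2)
  ss2 <- rowSums((xc - m2)^2)
  df <- n1 + n2 - 2
  s2 <- (ss1 + ss2) / df
  logfc <- m1 - m2
  se <- sqrt(s2 * (1 / n1 + 1 / n2))
  t_ord <- ifelse(se > 0, logfc / se, ifelse(logfc == 0, 0, sign(logfc) * Inf))
  tibble::tibble(
    feature_id = rownames(study$values),
    logFC = unname(logfc),
    s2 = unname(s2),
    df_residual = df,
    t_ordinary = unname(t_ord),
    n1 = n1, n2 = n2
  )
}

#' Estimate the variance prior by the method of moments
#'
#' Fits a scaled inverse chi-square prior to the per-feature residual
#' variances using the moment equations on log s2 (closed forms on the
#' digamma/trigamma scale). `d0 = Inf` when the observed log-variance
#' spread is no larger than the sampling spread.
#'
#' @param s2 Per-feature residual variances.
#' @param df Residual degrees of freedom (scalar; all features share the
#'   design).
#' @return A list with `d0` (prior df, possibly `Inf`) and `s0_2` (prior
#'   variance).
#' @export
estimate_var_prior <- function(s2, df) {
  stopifnot(length(df) == 1, df >= 1)
  s2 <- pmax(s2, 1e-300)
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  ebar <- mean(e)
  n <- length(e)
  evar <- sum((e - ebar)^2) / (n - 1)
  excess <- evar - trigamma(df / 2)
  if (excess <= 0) {
    # no excess spread: common-variance limit, prior variance = pooled mean
    return(list(d0 = Inf, s0_2 = mean(s2)))
  }
  d0 <- 2 * trigamma_inverse(excess)
  s0_2 <- exp(ebar + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_2 = s0_2)
}

#' Newton inversion of the trigamma function
#' @noRd
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Empirical-Bayes moderation of two-group fits
#'
#' Shrinks per-feature variances toward the prior:
#' `s2_post = (d0 * s0_2 + df * s2) / (d0 + df)`, giving a moderated t on
#' `d0 + df` degrees of freedom (capped at the pooled residual df). With `d0 = 0` this is the ordinary t;
#' with `d0 = Inf` every feature uses the common prior variance.
#'
#' @param fits Output of [fit_two_group()].
#' @param params `"estimate"` (default; method-of-moments via
#'   [estimate_var_prior()]) or a list with `d0` and `s0_2`.
#' @return `fits` with columns `t_moderated`, `df_total`, `s2_post`, `p`
#'   (two-sided), plus attributes `d0` and `s0_2`.
#' @export
ebayes_moderate <- function(fits, params = "estimate") {
  df <- unique(fits$df_residual)
  if (length(df) != 1) {
    stop("all features must share the design (one df_residual)",
         call. = FALSE)
  }
  if (identical(params, "estimate")) {
    params <- estimate_var_prior(fits$s2, df)
  }
  d0 <- params$d0
  s0_2 <- params$s0_2
  if (is.null(d0) || is.null(s0_2) || d0 < 0 || (is.finite(d0) && s0_2 <= 0)) {
    stop("invalid prior: need d0 >= 0 and s0_2 > 0", call. = FALSE)
  }
  s2_post <- if (is.infinite(d0)) {
    rep(s0_2, nrow(fits))
  } else {
    (d0 * s0_2 + df * fits$s2) / (d0 + df)
  }
  se <- sqrt(s2_post * (1 / fits$n1 + 1 / fits$n2))
  t_mod <- ifelse(se > 0, fits$logFC / se,
                  ifelse(fits$logFC == 0, 0, sign(fits$logFC) * Inf))
  # cap total df at the pooled residual df across features (the prior
  # cannot carry more information than the data it was estimated from)
  df_total <- min(d0 + df, df * nrow(fits))
  p <- 2 * stats::pt(-abs(t_mod), df = df_total)
  # zero variance & zero logFC: degenerate but defined
  p[se == 0 & fits$logFC == 0] <- 1
  out <- fits |>
    dplyr::mutate(t_moderated = t_mod, df_total = df_total,
                  s2_post = s2_post, p = p)
  attr(out, "d0") <- d0
  attr(out, "s0_2") <- s0_2
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment (via [stats::p.adjust()]) with input
#' validation; order-preserving.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Call differential expression
#'
#' A feature is DE when `adj_p < alpha` and, if a fold-change cutoff is
#' given, `|logFC| > lfc_cut`. mRNA analyses use `lfc_cut = 1`; the
#' miRNA meta-analysis stage selects on adjusted p only.
#'
#' @param results A tibble with columns `p` and `logFC` (e.g. from
#'   [ebayes_moderate()] or [run_meta()] via `p`/`es_meta`).
#' @param alpha Adjusted-p threshold (default 0.05).
#' @param lfc_cut Absolute log2-fold-change cutoff, or `NULL` for none.
#' @return `results` with columns `adj_p` and `is_de` added.
#' @export
call_des <- function(results, alpha = 0.05, lfc_cut = NULL) {
  adj <- bh_adjust(results$p)
  is_de <- adj < alpha
  if (!is.null(lfc_cut)) is_de <- is_de & abs(results$logFC) > lfc_cut
  dplyr::mutate(results, adj_p = adj, is_de = is_de)
}

#' One-call differential expression for a study
#'
#' Convenience wrapper: [fit_two_group()], [ebayes_moderate()],
#' [call_des()].
#'
#' @inheritParams fit_two_group
#' @inheritParams call_des
#' @inheritParams ebayes_moderate
#' @return A DE-result tibble (one row per feature) with `feature_id`,
#'   `logFC`, `t_ordinary`, `t_moderated`, `p`, `adj_p`, `is_de`.
#' @export
de_analysis <- function(study, alpha = 0.05, lfc_cut = NULL,
                        params = "estimate") {
  fit_two_group(study) |>
    ebayes_moderate(params = params) |>
    call_des(alpha = alpha, lfc_cut = lfc_cut)
}
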