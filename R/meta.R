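#' Per-study effect sizes for meta-analysis
#'
#' The per-study effect is the log2 fold change, and its standard error is
#' recovered from the t statistic as `se = |logFC / t|` — the identity
#' linking an estimate, its standard error and its t value. Features with
#' `t = 0` (se undefined) are excluded for that study with a warning.
#'
#' A standardized-mean-difference alternative (`effect = "smd"`, Hedges-g
#' style with the small-sample correction) is available for sensitivity
#' analyses.
#'
#' @param de A DE tibble from [de_analysis()] / [ebayes_moderate()]
#'   (needs `feature_id`, `logFC`, `t_moderated` or `t_ordinary`, and for
#'   SMD `s2`, `n1`, `n2`).
#' @param study_id Label for the study.
#' @param statistic Which t to divide by: `"moderated"` (default) or
#'   `"ordinary"`.
#' @param effect `"logfc"` (default) or `"smd"`.
#' @return A tibble with columns `feature_id`, `study_id`, `es`, `se`,
#'   `weight` (1/se^2).
#' @export
study_effects <- function(de, study_id,
                          statistic = c("moderated", "ordinary"),
                          effect = c("logfc", "smd")) {
  statistic <- match.arg(statistic)
  effect <- match.arg(effect)
  tval <- if (statistic == "moderated" && "t_moderated" %in% names(de)) {
    de$t_moderated
  } else {
    de$t_ordinary
  }
  if (effect == "logfc") {
    se <- derive_se(de$logFC, tval)
    es <- de$logFC
  } else {
    sd_pool <- sqrt(de$s2)
    d <- de$logFC / sd_pool
    m <- de$n1 + de$n2 - 2
    j <- 1 - 3 / (4 * m - 1) # Hedges small-sample correction
    es <- j * d
    se <- sqrt((de$n1 + de$n2) / (de$n1 * de$n2) +
                 es^2 / (2 * (de$n1 + de$n2)))
  }
  keep <- is.finite(se) & se > 0
  if (any(!keep)) {
    warning(sprintf("%d feature(s) with undefined SE (t = 0) excluded for %s",
                    sum(!keep), study_id), call. = FALSE)
  }
  tibble::tibble(
    feature_id = de$feature_id[keep],
    study_id = study_id,
    es = es[keep],
    se = se[keep],
    weight = 1 / se[keep]^2
  )
}

#' Standard error from an estimate and its t statistic
#'
#' `se = |logFC / t|`, positive by convention. `t = 0` gives `NA` (the
#' caller flags and excludes such features).
#'
#' @param logfc Effect estimates.
#' @param t Corresponding t statistics.
#' @return Standard errors.
#' @export
derive_se <- function(logfc, t) {
  ifelse(t == 0 | !is.finite(t), NA_real_, abs(logfc / t))
}

#' Cochran's Q heterogeneity test
#'
#' `Q = sum w_i (es_i - es_fixed)^2` with inverse-variance weights
#' `w_i = 1/se_i^2`; under homogeneity Q is chi-square on k - 1 df.
#'
#' @param es,se Per-study effects and standard errors (length k >= 2).
#' @return A list with `Q`, `Q_p`, `df`, and the fixed-effect mean
#'   `es_fixed`.
#' @export
cochran_q <- function(es, se) {
  k <- length(es)
  if (k < 2) stop("Cochran's Q needs at least 2 studies", call. = FALSE)
  if (any(se <= 0)) stop("standard errors must be positive", call. = FALSE)
  w <- 1 / se^2
  es_fixed <- sum(w * es) / sum(w)
  q <- sum(w * (es - es_fixed)^2)
  list(Q = q, Q_p = stats::pchisq(q, df = k - 1, lower.tail = FALSE),
       df = k - 1L, es_fixed = es_fixed)
}

#' DerSimonian-Laird random-effects combination
#'
#' Moment estimator of the between-study variance
#' `tau2 = max(0, (Q - (k-1)) / (sum(w) - sum(w^2)/sum(w)))`, then
#' inverse-variance pooling with weights `1/(se^2 + tau2)`. The combined
#' z is treated as standard normal. With `model = "fixed"` the pooling
#' skips tau2 (plain inverse-variance).
#'
#' @param es,se Per-study effects and standard errors (length k >= 2).
#' @param model `"random"` (default) or `"fixed"`.
#' @return A one-row tibble: `k`, `es_meta`, `se_meta`, `z`, `p`, `Q`,
#'   `Q_p`, `tau2`, `model`.
#' @export
random_effects_combine <- function(es, se, model = c("random", "fixed")) {
  model <- match.arg(model)
  k <- length(es)
  het <- cochran_q(es, se)
  w <- 1 / se^2
  denom <- sum(w) - sum(w^2) / sum(w)
  if (model == "random") {
    if (denom <= 0) {
      stop("degenerate weight configuration (effective k = 1); cannot estimate tau2",
           call. = FALSE)
    }
    tau2 <- max(0, (het$Q - (k - 1)) / denom)
  } else {
    tau2 <- 0
  }
  w_star <- 1 / (se^2 + tau2)
  es_meta <- sum(w_star * es) / sum(w_star)
  se_meta <- 1 / sqrt(sum(w_star))
  z <- es_meta / se_meta
  tibble::tibble(
    k = k, es_meta = es_meta, se_meta = se_meta, z = z,
    p = 2 * stats::pnorm(-abs(z)),
    Q = het$Q, Q_p = het$Q_p, tau2 = tau2, model = model
  )
}

#' Random-effects meta-analysis across studies
#'
#' Harmonizes feature ids across the per-study effect tables (lower-cased,
#' trimmed exact match), combines every feature present in at least two
#' studies, BH-adjusts the combined p-values across the full feature set,
#' and labels direction by the sign of the combined effect.
#'
#' @param effects A tibble of per-study effects, e.g. rows of
#'   [study_effects()] bound together (`feature_id`, `study_id`, `es`,
#'   `se`).
#' @param model Meta-analytic model policy. The default `"q-gated"`
#'   follows the classical two-step procedure: Cochran's Q decides per
#'   feature, combining under the random-effects model when heterogeneity
#'   is significant at `q_alpha` and under the fixed-effect model
#'   otherwise. `"random"` forces the random-effects model everywhere
#'   (slightly conservative under exact homogeneity at small k, because
#'   the truncated tau2 estimate inflates the combined SE); `"fixed"`
#'   forces inverse-variance pooling.
#' @param q_alpha Q-test significance level for the q-gated policy.
#' @return A `mirmeta_meta` tibble, one row per feature: `feature_id`,
#'   `k`, `es_meta`, `se_meta`, `z`, `p`, `adj_p`, `Q`, `Q_p`, `tau2`,
#'   `model`, `direction` ("up"/"down"). Features seen in fewer than two
#'   studies are dropped (count in attribute `n_dropped`).
#' @export
run_meta <- function(effects, model = c("q-gated", "random", "fixed"),
                     q_alpha = 0.05) {
  model <- match.arg(model)
  effects <- dplyr::mutate(
    effects, feature_id = tolower(trimws(.data$feature_id)))
  counts <- dplyr::count(effects, .data$feature_id)
  keep_ids <- counts$feature_id[counts$n >= 2]
  if (length(keep_ids) == 0) {
    stop("no feature present in at least 2 studies", call. = FALSE)
  }
  n_dropped <- sum(counts$n < 2)
  if (n_dropped > 0) {
    message(n_dropped, " feature(s) present in <2 studies dropped from meta")
  }
  out <- effects |>
    dplyr::filter(.data$feature_id %in% keep_ids) |>
    dplyr::group_by(.data$feature_id) |>
    dplyr::group_modify(function(d, key) {
      if (model == "q-gated") {
        het <- cochran_q(d$es, d$se)
        m <- if (het$Q_p < q_alpha) "random" else "fixed"
      } else {
        m <- model
      }
      random_effects_combine(d$es, d$se, model = m)
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(
      adj_p = bh_adjust(.data$p),
      direction = ifelse(.data$es_meta >= 0, "up", "down")
    )
  attr(out, "n_dropped") <- n_dropped
  class(out) <- c("mirmeta_meta", class(out))
  out
}

#' @export
#' @rdname run_meta
#' @param x A `mirmeta_meta` result.
#' @param ... Unused.
glance.mirmeta_meta <- function(x, ...) {
  tibble::tibble(
    n_features = nrow(x),
    n_sig = sum(x$adj_p < 0.05),
    n_up = sum(x$adj_p < 0.05 & x$direction == "up"),
    n_down = sum(x$adj_p < 0.05 & x$direction == "down"),
    median_tau2 = stats::median(x$tau2),
    n_het = sum(x$Q_p < 0.05)
  )
}

#' Volcano plot of meta-analysis results
#'
#' Combined log2 effect against -log10 adjusted p; significant miRNAs
#' colored by direction.
#'
#' @param object A `mirmeta_meta` tibble from [run_meta()].
#' @param alpha Significance threshold for coloring.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mirmeta_meta <- function(object, alpha = 0.05, ...) {
  df <- dplyr::mutate(
    object,
    status = dplyr::case_when(
      .data$adj_p < alpha & .data$direction == "up" ~ "up",
      .data$adj_p < alpha & .data$direction == "down" ~ "down",
      TRUE ~ "ns"
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$es_meta, -log10(.data$adj_p),
                                   colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_colour_manual(
      values = c(up = "seagreen", down = "goldenrod2", ns = "grey70")) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::labs(x = "combined log2 effect (resistant - control)",
                  y = "-log10 adjusted p", colour = NULL) +
    ggplot2::theme_minimal()
}
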