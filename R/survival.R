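#' Dichotomize subjects by expression
#'
#' Median split by default: `high` is expression strictly above the
#' median. The `best_cutoff` rule scans every candidate cutpoint inside
#' the inner 80% of the expression distribution and picks the one
#' minimizing the log-rank p (the reported p is then an optimistic,
#' uncorrected minimum and is flagged as such).
#'
#' @param table A survival tibble with columns `time`, `event`,
#'   `expression` (one row per subject, times positive, event 0/1).
#' @param rule `"median"` (default) or `"best_cutoff"`.
#' @return A factor of `"high"`/`"low"` labels aligned to the rows, with
#'   attributes `cutoff` and (for best_cutoff) `cutoff_optimized = TRUE`.
#' @export
split_by_expression <- function(table, rule = c("median", "best_cutoff")) {
  rule <- match.arg(rule)
  check_survival_table(table)
  x <- table$expression
  if (length(unique(x)) < 2) {
    stop("all expression values identical; cannot split", call. = FALSE)
  }
  if (rule == "median") {
    cut <- stats::median(x)
  } else {
    qs <- stats::quantile(x, c(0.1, 0.9))
    cands <- sort(unique(x))
    cands <- cands[cands >= qs[1] & cands < qs[2]]
    if (length(cands) == 0) cands <- stats::median(x)
    ps <- vapply(cands, function(cc) {
      grp <- factor(ifelse(x > cc, "high", "low"), c("high", "low"))
      if (nlevels(droplevels(grp)) < 2) return(1)
      logrank_hr(table, grp)$p
    }, numeric(1))
    cut <- cands[which.min(ps)]
  }
  grp <- factor(ifelse(x > cut, "high", "low"), levels = c("high", "low"))
  if (any(table(grp) == 0)) {
    stop("split produced an empty group", call. = FALSE)
  }
  attr(grp, "cutoff") <- unname(cut)
  if (rule == "best_cutoff") attr(grp, "cutoff_optimized") <- TRUE
  grp
}

check_survival_table <- function(table) {
  req <- c("time", "event", "expression")
  if (!all(req %in% names(table))) {
    stop("survival table needs columns time, event, expression",
         call. = FALSE)
  }
  if (nrow(table) < 2) stop("need at least 2 subjects", call. = FALSE)
  if (any(table$time <= 0)) stop("times must be positive", call. = FALSE)
  if (!all(table$event %in% c(0, 1))) {
    stop("event must be 0 (censored) or 1 (death)", call. = FALSE)
  }
  invisible(table)
}

#' Kaplan-Meier product-limit estimate
#'
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` over distinct event times;
#' subjects censored at t remain at risk for events at t (standard tie
#' convention).
#'
#' @param times Positive follow-up times.
#' @param events Event indicators (1 death, 0 censored).
#' @param group Optional group labels; curves are estimated per group.
#' @return A tibble with columns `group`, `time`, `n_risk`, `n_event`,
#'   `surv`, one row per distinct event time, of class `mirmeta_km`.
#' @export
km_estimate <- function(times, events, group = NULL) {
  if (is.null(group)) group <- rep("all", length(times))
  stopifnot(length(times) == length(events),
            length(group) == length(times))
  out <- purrr::map_dfr(split(seq_along(times), group), function(idx) {
    tt <- times[idx]
    ee <- events[idx]
    ev_times <- sort(unique(tt[ee == 1]))
    if (length(ev_times) == 0) {
      return(tibble::tibble(group = group[idx][1], time = numeric(0),
                            n_risk = integer(0), n_event = integer(0),
                            surv = numeric(0)))
    }
    n_risk <- vapply(ev_times, function(t0) sum(tt >= t0), numeric(1))
    n_event <- vapply(ev_times, function(t0) sum(tt == t0 & ee == 1),
                      numeric(1))
    tibble::tibble(
      group = group[idx][1],
      time = ev_times,
      n_risk = as.integer(n_risk),
      n_event = as.integer(n_event),
      surv = cumprod(1 - n_event / n_risk)
    )
  })
  class(out) <- c("mirmeta_km", class(out))
  out
}

#' Two-group log-rank test with hazard-ratio reporting
#'
#' Standard observed/expected log-rank statistic over the pooled event
#' times: `chi2 = (O1 - E1)^2 / V`, p from chi-square on 1 df. The hazard
#' ratio (first level vs second) is the O/E ratio estimate
#' `HR = (O1/E1) / (O2/E2)` with
#' `95% CI = exp(log HR +/- 1.96 * sqrt(1/E1 + 1/E2))`, the reporting
#' convention of expression-dichotomized survival portals.
#'
#' @param table Survival tibble (`time`, `event`, ...).
#' @param groups Two-level factor/character vector aligned to rows; the
#'   first level (e.g. `"high"`) is the HR numerator.
#' @return A list of class `survival_result`: `km_curves` (a
#'   [km_estimate()] tibble), `chi2`, `p`, `hr`, `ci_low`, `ci_high`,
#'   `obs`/`exp` per group, `n` per group, `cutoff_optimized` flag.
#' @export
logrank_hr <- function(table, groups) {
  check_survival_table(table)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2) {
    stop("exactly two non-empty groups required", call. = FALSE)
  }
  groups <- droplevels(groups)
  g1 <- levels(groups)[1]
  tt <- table$time
  ee <- table$event
  in1 <- groups == g1
  ev_times <- sort(unique(tt[ee == 1]))
  o1 <- e1 <- v <- 0
  for (t0 in ev_times) {
    at_risk <- tt >= t0
    n <- sum(at_risk)
    n1 <- sum(at_risk & in1)
    d <- sum(tt == t0 & ee == 1)
    d1 <- sum(tt == t0 & ee == 1 & in1)
    o1 <- o1 + d1
    e1 <- e1 + d * n1 / n
    if (n > 1) {
      v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
    }
  }
  o2 <- sum(ee) - o1
  e2 <- sum(ee) - e1
  chi2 <- if (v > 0) (o1 - e1)^2 / v else 0
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  if (o1 == 0 || o2 == 0 || e1 == 0 || e2 == 0) {
    warning("a group has zero (expected) events; HR undefined",
            call. = FALSE)
    hr <- ci_low <- ci_high <- NA_real_
  } else {
    hr <- (o1 / e1) / (o2 / e2)
    half <- 1.96 * sqrt(1 / e1 + 1 / e2)
    ci_low <- exp(log(hr) - half)
    ci_high <- exp(log(hr) + half)
  }
  structure(
    list(
      km_curves = km_estimate(tt, ee, groups),
      chi2 = chi2, p = p, hr = hr, ci_low = ci_low, ci_high = ci_high,
      obs = stats::setNames(c(o1, o2), levels(groups)),
      exp = stats::setNames(c(e1, e2), levels(groups)),
      n = as.vector(table(groups)),
      cutoff_optimized = isTRUE(attr(groups, "cutoff_optimized"))
    ),
    class = "survival_result"
  )
}

#' @export
print.survival_result <- function(x, ...) {
  cat(sprintf(
    "<survival_result> log-rank chi2 = %.3f, p = %.4g | HR = %.3g (95%% CI %.3g-%.3g)\n",
    x$chi2, x$p, x$hr, x$ci_low, x$ci_high))
  if (x$cutoff_optimized) {
    cat("  note: cutoff optimized over candidates; p not corrected\n")
  }
  invisible(x)
}

#' @export
#' @rdname logrank_hr
#' @param x A `survival_result`.
#' @param ... Unused.
glance.survival_result <- function(x, ...) {
  tibble::tibble(chi2 = x$chi2, p = x$p, hr = x$hr,
                 ci_low = x$ci_low, ci_high = x$ci_high,
                 n_high = x$n[1], n_low = x$n[2],
                 events = sum(x$obs))
}

#' Survival analysis of one gene's expression
#'
#' Convenience wrapper: [split_by_expression()] then [logrank_hr()].
#'
#' @inheritParams split_by_expression
#' @return A `survival_result`.
#' @export
survival_analysis <- function(table, rule = c("median", "best_cutoff")) {
  grp <- split_by_expression(table, rule = rule)
  res <- logrank_hr(table, grp)
  res$cutoff <- attr(grp, "cutoff")
  res$cutoff_optimized <- isTRUE(attr(grp, "cutoff_optimized"))
  res
}

#' Kaplan-Meier plot
#'
#' Step curves per expression group.
#'
#' @param object A `survival_result` or `mirmeta_km` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.survival_result <- function(object, ...) {
  km <- object$km_curves |>
    dplyr::group_by(.data$group) |>
    dplyr::group_modify(~ dplyr::bind_rows(
      tibble::tibble(time = 0, n_risk = NA_integer_,
                     n_event = NA_integer_, surv = 1), .x)) |>
    dplyr::ungroup()
  ggplot2::ggplot(km, ggplot2::aes(.data$time, .data$surv,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "time (months)", y = "overall survival S(t)", colour = NULL,
      subtitle = sprintf("log-rank p = %.3g, HR = %.2f (%.2f-%.2f)",
                         object$p, object$hr, object$ci_low,
                         object$ci_high)) +
    ggplot2::theme_minimal()
}
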