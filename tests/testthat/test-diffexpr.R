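test_that("two-group fit matches the textbook pooled-variance t", {
  st <- random_study(10, 3, 3, seed = 42)
  fit <- fit_two_group(st)
  for (i in 1:10) {
    x1 <- st$values[i, 1:3]
    x2 <- st$values[i, 4:6]
    s2 <- (sum((x1 - mean(x1))^2) + sum((x2 - mean(x2))^2)) / 4
    t_hand <- (mean(x1) - mean(x2)) / sqrt(s2 * (1 / 3 + 1 / 3))
    expect_equal(fit$t_ordinary[i], t_hand, tolerance = 1e-10)
    expect_equal(fit$logFC[i], mean(x1) - mean(x2), tolerance = 1e-12)
  }
  # cross-check against t.test with pooled variance
  tt <- stats::t.test(st$values[1, 1:3], st$values[1, 4:6],
                      var.equal = TRUE)
  expect_equal(fit$t_ordinary[1], unname(tt$statistic), tolerance = 1e-10)
})

test_that("degenerate groups give zero effect and defined p", {
  st <- make_study(matrix(c(3, 3, 3 + 1e-9, 1, 1, 1 - 1e-9,
                            5, 5, 5, 5, 5, 5), 2, 6, byrow = TRUE),
                   n1 = 3, n2 = 3)
  fit <- fit_two_group(st)
  expect_equal(fit$logFC[1], 2, tolerance = 1e-6)
  expect_equal(fit$logFC[2], 0)
  expect_equal(fit$t_ordinary[2], 0)
  mod <- ebayes_moderate(fit, params = list(d0 = 0, s0_2 = 1))
  expect_equal(mod$p[2], 1) # zero variance, zero logFC
  expect_error(fit_two_group(make_study(matrix(rnorm(8), 2, 4),
                                        n1 = 1, n2 = 3)), "at least 2")
})

test_that("moderation limits: d0 = 0 is ordinary t, d0 = Inf is full shrinkage", {
  st <- random_study(50, 4, 4, seed = 7)
  fit <- fit_two_group(st)
  m0 <- ebayes_moderate(fit, params = list(d0 = 0, s0_2 = 1))
  expect_equal(m0$t_moderated, m0$t_ordinary, tolerance = 1e-12)
  mInf <- ebayes_moderate(fit, params = list(d0 = Inf, s0_2 = 0.7))
  expect_true(all(abs(mInf$s2_post - 0.7) < 1e-12))
})

test_that("moderated and ordinary t always share their sign", {
  st <- random_study(200, 3, 5, seed = 9)
  mod <- ebayes_moderate(fit_two_group(st))
  expect_true(all(sign(mod$t_moderated) == sign(mod$t_ordinary)))
})

test_that("prior estimation recovers a planted inverse-chi-square prior", {
  set.seed(123)
  n <- 20000
  d0 <- 4
  s0 <- 0.05
  df <- 6
  s2_true <- d0 * s0 / stats::rchisq(n, d0)
  s2_obs <- s2_true * stats::rchisq(n, df) / df
  est <- estimate_var_prior(s2_obs, df)
  expect_equal(est$d0, d0, tolerance = 0.15)
  expect_equal(est$s0_2, s0, tolerance = 0.05)
})

test_that("moderated statistics agree with the limma oracle", {
  skip_if_not_installed("limma")
  st <- random_study(500, 4, 4, seed = 15)
  mod <- ebayes_moderate(fit_two_group(st))
  design <- cbind(1, st$groups == "resistant")
  lf <- limma::eBayes(limma::lmFit(st$values, design))
  expect_equal(attr(mod, "d0"), lf$df.prior, tolerance = 1e-4)
  expect_equal(attr(mod, "s0_2"), lf$s2.prior, tolerance = 1e-6)
  expect_equal(mod$t_moderated, unname(lf$t[, 2]), tolerance = 1e-6)
  expect_equal(mod$p, unname(lf$p.value[, 2]), tolerance = 1e-6)
})

test_that("moderated p-values are uniform under the null", {
  set.seed(77)
  st <- random_study(3000, 4, 4, seed = 77)
  mod <- ebayes_moderate(fit_two_group(st))
  expect_gt(stats::ks.test(mod$p, "punif")$p.value, 0.01)
})

test_that("BH adjustment matches the hand step-up and is idempotent", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(4)
  p <- runif(100)^2
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  # order preserving map back to input order
  expect_equal(adj[order(p)], sort(adj))
  # independent step-up computation
  o <- order(p)
  m <- length(p)
  stepup <- rev(cummin(rev(pmin(1, m * p[o] / seq_len(m)))))
  expect_equal(adj[o], stepup)
})

test_that("DE calls combine the p and fold-change thresholds", {
  res <- tibble::tibble(
    feature_id = c("a", "b", "c"),
    logFC = c(1.5, 0.5, 0.2),
    p = c(0.01, 0.01, 0.049)
  )
  # BH over 3 p-values: adj = (0.015, 0.015, 0.049)
  out <- call_des(res, alpha = 0.05, lfc_cut = 1)
  expect_equal(out$is_de, c(TRUE, FALSE, FALSE))
  out2 <- call_des(res, alpha = 0.05, lfc_cut = NULL)
  expect_equal(out2$is_de, c(TRUE, TRUE, TRUE))
})

test_that("BH controls empirical FDR on a signal-plus-null mixture", {
  set.seed(2024)
  reps <- 20
  m <- 2000
  m1 <- 100
  fdp <- numeric(reps)
  for (r in seq_len(reps)) {
    z <- c(rnorm(m1, 4), rnorm(m - m1))
    p <- 2 * pnorm(-abs(z))
    sel <- bh_adjust(p) < 0.05
    fdp[r] <- if (any(sel)) sum(sel & seq_len(m) > m1) / sum(sel) else 0
  }
  mc_se <- sd(fdp) / sqrt(reps)
  expect_lte(mean(fdp), 0.05 + 2 * mc_se)
})
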