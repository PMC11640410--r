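test_that("standard errors derive from the logFC/t identity", {
  expect_equal(derive_se(1, 4), 0.25)
  expect_equal(derive_se(-2, -4), 0.5)
  expect_true(is.na(derive_se(1, 0)))
  de <- tibble::tibble(feature_id = c("a", "b"), logFC = c(1, 0),
                       t_moderated = c(2, 0), t_ordinary = c(2, 0))
  expect_warning(eff <- study_effects(de, "s1"), "excluded")
  expect_equal(eff$feature_id, "a")
  expect_equal(eff$se, 0.5)
  expect_equal(eff$weight, 4)
})

test_that("Cochran's Q matches hand computations", {
  hom <- cochran_q(c(0.8, 0.8, 0.8), c(0.2, 0.2, 0.2))
  expect_equal(hom$Q, 0)
  expect_equal(hom$Q_p, 1)
  opp <- cochran_q(c(1, -1), c(1, 1))
  expect_equal(opp$es_fixed, 0)
  expect_equal(opp$Q, 2)
  expect_equal(opp$df, 1L)
  expect_error(cochran_q(1, 1), "at least 2")
})

test_that("Q has the chi-square(k-1) moments under homogeneity", {
  set.seed(6)
  q <- replicate(5000, cochran_q(rnorm(3), rep(1, 3))$Q)
  expect_equal(mean(q), 2, tolerance = 3 * sd(q) / sqrt(5000))
  expect_equal(unname(quantile(q, 0.95)), qchisq(0.95, 2), tolerance = 0.25)
})

test_that("DerSimonian-Laird matches hand results and the fixed-effect limit", {
  r <- random_effects_combine(c(0.8, 0.8, 0.8), c(0.2, 0.2, 0.2))
  expect_equal(r$tau2, 0)
  expect_equal(r$es_meta, 0.8)
  expect_equal(r$se_meta, 0.2 / sqrt(3))
  r2 <- random_effects_combine(c(1, -1), c(1, 1))
  expect_equal(r2$tau2, 1)
  expect_equal(r2$es_meta, 0)
  expect_equal(r2$se_meta, 1) # w* = 0.5 each
  # tau2 = 0 => identical to inverse-variance fixed effect
  set.seed(10)
  es <- rnorm(4, 1, 0.01)
  se <- runif(4, 0.5, 2)
  rr <- random_effects_combine(es, se)
  if (rr$tau2 == 0) {
    rf <- random_effects_combine(es, se, model = "fixed")
    expect_equal(rr$es_meta, rf$es_meta)
    expect_equal(rr$se_meta, rf$se_meta)
  }
})

test_that("combined estimate is a convex combination of study effects", {
  set.seed(12)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    es <- rnorm(k, 0, 2)
    se <- runif(k, 0.1, 1.5)
    r <- random_effects_combine(es, se)
    expect_gte(r$es_meta, min(es) - 1e-12)
    expect_lte(r$es_meta, max(es) + 1e-12)
  }
})

test_that("DL agrees with the metafor oracle on random tables", {
  skip_if_not_installed("metafor")
  set.seed(99)
  for (i in 1:25) {
    k <- sample(2:8, 1)
    es <- rnorm(k, 0.3, 1)
    se <- runif(k, 0.1, 1)
    mine <- random_effects_combine(es, se)
    oracle <- metafor::rma(yi = es, sei = se, method = "DL")
    expect_equal(mine$es_meta, as.numeric(oracle$beta), tolerance = 1e-10)
    expect_equal(mine$tau2, oracle$tau2, tolerance = 1e-10)
    expect_equal(mine$Q, oracle$QE, tolerance = 1e-10)
  }
})

test_that("tau2 estimator recovers a planted between-study variance", {
  set.seed(55)
  k <- 20
  tau2 <- 0.5
  est <- replicate(200, {
    se <- runif(k, 0.1, 0.4)
    es <- rnorm(k, 0, sqrt(se^2 + tau2))
    random_effects_combine(es, se)$tau2
  })
  expect_lt(abs(median(est) - tau2), 0.15)
})

test_that("run_meta harmonizes ids, applies the k >= 2 rule and labels direction", {
  eff <- tibble::tibble(
    feature_id = c("hsa-miR-1-5p", "HSA-miR-1-5p ", "hsa-miR-2-5p",
                   "hsa-miR-2-5p", "hsa-miR-3-5p"),
    study_id = c("s1", "s2", "s1", "s2", "s1"),
    es = c(1, 1.2, -1, -0.8, 2),
    se = c(0.2, 0.2, 0.2, 0.2, 0.2)
  )
  expect_message(m <- run_meta(eff), "dropped")
  expect_setequal(m$feature_id, c("hsa-mir-1-5p", "hsa-mir-2-5p"))
  expect_equal(attr(m, "n_dropped"), 1)
  expect_equal(m$direction[m$feature_id == "hsa-mir-1-5p"], "up")
  expect_equal(m$direction[m$feature_id == "hsa-mir-2-5p"], "down")
  expect_true(all(m$adj_p >= m$p))
  expect_error(run_meta(eff[5, ]), "at least 2")
})

test_that("sign recovery: planted positive and negative effects split up/down", {
  set.seed(44)
  k <- 3
  eff <- purrr::map_dfr(1:10, function(i) {
    mu <- if (i <= 5) 2 else -2
    tibble::tibble(
      feature_id = sprintf("hsa-miR-%d-5p", i),
      study_id = sprintf("s%d", 1:k),
      es = rnorm(k, mu, 0.2),
      se = 0.2
    )
  })
  m <- run_meta(eff)
  g <- glance(m)
  expect_equal(g$n_up, 5)
  expect_equal(g$n_down, 5)
  expect_equal(g$n_sig, 10)
})

test_that("a strongly planted miRNA is recovered across seeded replicates", {
  hits <- 0
  reps <- 40
  for (r in seq_len(reps)) {
    cfg <- synth_config(n_features = 80, n_true_de = 1, missing_rate = 0,
                        samples_per_group = c(3, 6, 10), mu_effect = 2,
                        tau2 = 0.05, seed = 1000 + r)
    g <- synth_mirna_studies(cfg)
    de <- lapply(g$studies, de_analysis)
    eff <- purrr::imap_dfr(de, ~ study_effects(.x, paste0("s", .y)))
    m <- run_meta(eff)
    target <- tolower(g$truth$de_features$feature_id)
    if (m$adj_p[m$feature_id == target] < 0.05) hits <- hits + 1
  }
  expect_gte(hits / reps, 0.95)
})
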