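test_that("all generators are bit-identical under the same seed", {
  cfg <- synth_config(n_features = 60, n_true_de = 5, seed = 11,
                      samples_per_group = c(3, 4, 5))
  a <- synth_mirna_studies(cfg)
  b <- synth_mirna_studies(cfg)
  expect_identical(a, b)
  ma <- synth_mrna_studies(cfg, a$truth)
  mb <- synth_mrna_studies(cfg, b$truth)
  expect_identical(ma, mb)
  expect_identical(synth_interactions(a$truth, cfg),
                   synth_interactions(a$truth, cfg))
  expect_identical(synth_genesets(cfg, ma$truth),
                   synth_genesets(cfg, ma$truth))
  expect_identical(synth_edgelist(cfg, a$truth),
                   synth_edgelist(cfg, a$truth))
  expect_identical(synth_survival(cfg, n = 50), synth_survival(cfg, n = 50))
})

test_that("missingness mask obeys the configured rate and studies", {
  cfg0 <- synth_config(n_features = 50, n_true_de = 0, missing_rate = 0,
                       samples_per_group = c(3, 3, 3), seed = 2)
  g0 <- synth_mirna_studies(cfg0)
  expect_false(any(vapply(g0$studies, function(s) any(s$missing_mask),
                          logical(1))))
  cfg1 <- synth_config(n_features = 200, n_true_de = 0, missing_rate = 0.25,
                       missing_studies = 1, samples_per_group = c(5, 3, 3),
                       seed = 2)
  g1 <- synth_mirna_studies(cfg1)
  expect_gt(mean(g1$studies[[1]]$missing_mask), 0.18)
  expect_lt(mean(g1$studies[[1]]$missing_mask), 0.32)
  expect_false(any(g1$studies[[2]]$missing_mask))
  # invariant: no feature entirely missing
  expect_true(all(rowSums(!g1$studies[[1]]$missing_mask) > 0))
})

test_that("generator rejects invalid configurations", {
  expect_error(synth_config(samples_per_group = 1), "samples_per_group")
  expect_error(synth_config(n_true_de = 10, n_features = 5), "n_true_de")
  expect_error(synth_config(sigma2 = 0), "sigma2")
  expect_error(synth_config(tau2 = -1), "tau2")
  expect_error(synth_config(missing_rate = 1), "missing_rate")
})

test_that("per-study p-values are uniform on pure-null data", {
  cfg <- synth_config(n_features = 4000, n_true_de = 0, missing_rate = 0,
                      samples_per_group = c(5, 10, 25), seed = 31)
  g <- synth_mirna_studies(cfg)
  for (st in g$studies) {
    p <- de_analysis(st)$p
    expect_gt(stats::ks.test(p, "punif")$p.value, 0.01)
  }
})

test_that("null feature variance approaches sigma2 at large n", {
  cfg <- synth_config(n_features = 500, n_true_de = 0, missing_rate = 0,
                      k_studies = 1, samples_per_group = 200,
                      sigma2 = 0.25, seed = 5)
  st <- synth_mirna_studies(cfg)$studies[[1]]
  v <- apply(st$values[, st$groups == "control"], 1, var)
  expect_equal(mean(v), 0.25, tolerance = 0.02)
})

test_that("realized per-study effects have variance consistent with tau2", {
  cfg <- synth_config(n_features = 200, n_true_de = 150, k_studies = 3,
                      samples_per_group = c(3, 3, 3), tau2 = 0.3, seed = 8)
  tr <- synth_mirna_studies(cfg)$truth
  theta <- as.matrix(tr$de_features[, sprintf("study%d", 1:3)])
  dev <- theta - tr$de_features$true_effect
  n <- length(dev) # 450 realizations >= 300
  ss <- sum(dev^2)
  # chi-square interval for the variance at 99% confidence
  ci <- ss / stats::qchisq(c(0.995, 0.005), df = n)
  expect_gt(0.3, ci[1])
  expect_lt(0.3, ci[2])
})

test_that("planted miRNAs are human and every DEM has a planted target", {
  cfg <- synth_config(n_features = 100, n_true_de = 10, decoy_frac = 0.2,
                      seed = 13)
  g <- synth_mirna_studies(cfg)
  expect_true(all(startsWith(g$truth$de_features$feature_id, "hsa")))
  expect_true(all(g$truth$de_features$feature_id %in%
                    g$truth$target_map$mirna_id))
  ids <- rownames(g$studies[[1]]$values)
  expect_equal(sum(!startsWith(ids, "hsa")), 20)
})

test_that("mRNA target DE fraction drives the planted DEG sets", {
  cfg1 <- synth_config(n_features = 60, n_true_de = 8, n_genes = 400,
                       target_de_frac = 1, seed = 21)
  g <- synth_mirna_studies(cfg1)
  mr <- synth_mrna_studies(cfg1, g$truth)
  planted <- unique(g$truth$target_map$gene_symbol)
  expect_true(all(planted %in% unlist(mr$truth$de_genes)))

  cfg0 <- synth_config(n_features = 60, n_true_de = 8, n_genes = 400,
                       target_de_frac = 0, seed = 21)
  g0 <- synth_mirna_studies(cfg0)
  mr0 <- synth_mrna_studies(cfg0, g0$truth)
  expect_length(intersect(unique(g0$truth$target_map$gene_symbol),
                          unlist(mr0$truth$de_genes)), 0)
  bad_truth <- g0$truth
  bad_truth$target_map$gene_symbol[1] <- "NOSUCHGENE"
  expect_error(synth_mrna_studies(cfg0, bad_truth), "unknown gene")
})

test_that("interaction table contains planted pairs plus unique decoys", {
  cfg <- synth_config(n_features = 60, n_true_de = 8, n_decoy_pairs = 0,
                      seed = 3)
  g <- synth_mirna_studies(cfg)
  tab0 <- synth_interactions(g$truth, cfg)
  expect_setequal(paste(tab0$mirna_id, tab0$gene_symbol),
                  paste(g$truth$target_map$mirna_id,
                        g$truth$target_map$gene_symbol))
  expect_true(all(tab0$validated == 1))

  cfg2 <- synth_config(n_features = 60, n_true_de = 8, n_decoy_pairs = 100,
                       seed = 3)
  tab <- synth_interactions(g$truth, cfg2)
  decoys <- dplyr::anti_join(tab, g$truth$target_map,
                             by = c("mirna_id", "gene_symbol"))
  expect_equal(nrow(decoys) + nrow(g$truth$target_map), nrow(tab))
  expect_false(any(duplicated(tab[, c("mirna_id", "gene_symbol",
                                      "source_db")])))

  tf <- withr::local_tempfile(fileext = ".tsv")
  write_interactions(tab, tf)
  expect_equal(as.data.frame(read_interactions(tf)), as.data.frame(tab))
})

test_that("GMT round-trip preserves term membership", {
  cfg <- synth_config(n_features = 60, n_true_de = 8, n_genes = 300,
                      seed = 17)
  g <- synth_mirna_studies(cfg)
  mr <- synth_mrna_studies(cfg, g$truth)
  gs <- synth_genesets(cfg, mr$truth, n_terms = 12)
  tf <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gs, tf)
  gs2 <- read_gmt(tf, universe = gs$universe)
  expect_equal(gs2$terms$term_id, gs$terms$term_id)
  expect_equal(gs2$terms$genes, lapply(gs$terms$genes, sort))
})

test_that("planted hub has strictly maximal degree", {
  cfg <- synth_config(n_features = 60, n_true_de = 8, seed = 19)
  g <- synth_mirna_studies(cfg)
  el <- synth_edgelist(cfg, g$truth)
  net <- build_network(el$edges, min_score = 0)
  deg <- net$nodes$degree
  hub_deg <- net$nodes$degree[net$nodes$gene == el$hub]
  expect_gt(hub_deg, max(deg[net$nodes$gene != el$hub]))
})

test_that("survival generator is calibrated at beta = 0", {
  cfg <- synth_config(seed = 29)
  ps <- vapply(1:400, function(i) {
    tab <- synth_survival(cfg, n = 80, beta = 0, seed = 20000 + i)
    survival_analysis(tab)$p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
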