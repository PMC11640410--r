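#' Pipeline run configuration
#'
#' One object drives the whole run: the synthetic-data settings (or paths
#' to existing inputs) and the analysis thresholds. Thresholds default to
#' the conventional values for this analysis: adjusted p < 0.05
#' throughout, |log2FC| > 1 for mRNA DEG calls (miRNA meta selection uses
#' adjusted p only), kappa 0.96 for term grouping, interaction score 0.4
#' for the PPI network.
#'
#' @param synth A [synth_config()]; regenerated with `seed` if omitted.
#' @param alpha Adjusted-p significance threshold.
#' @param lfc_cut Absolute log2-fold-change cutoff for mRNA DEGs.
#' @param kappa Kappa-score threshold for enrichment term grouping.
#' @param min_score Minimum PPI edge confidence.
#' @param model Meta-analysis model policy (see [run_meta()]).
#' @param impute_method Imputation regressor (see [impute_missing()]).
#' @param go_method,pathway_method Multiplicity correction for the GO-like
#'   and pathway collections.
#' @param split_rule Expression dichotomization rule for survival.
#' @param seed Root seed; all stage substreams derive from it.
#' @return A list of class `run_config`.
#' @export
run_config <- function(synth = NULL, alpha = 0.05, lfc_cut = 1,
                       kappa = 0.96, min_score = 0.4,
                       model = "q-gated", impute_method = "rf",
                       go_method = "bonferroni", pathway_method = "bh",
                       split_rule = "median", seed = 1) {
  assert_prob(alpha, "alpha")
  if (!is.null(lfc_cut) && lfc_cut < 0) {
    stop("`lfc_cut` must be >= 0 or NULL", call. = FALSE)
  }
  assert_prob(min_score, "min_score")
  if (kappa < -1 || is.na(kappa)) stop("invalid `kappa`", call. = FALSE)
  structure(
    list(synth = synth %||% synth_config(seed = seed),
         alpha = alpha, lfc_cut = lfc_cut, kappa = kappa,
         min_score = min_score, model = model,
         impute_method = impute_method, go_method = go_method,
         pathway_method = pathway_method, split_rule = split_rule,
         seed = as.integer(seed)),
    class = "run_config"
  )
}

#' Read a pipeline configuration from a YAML file
#'
#' Top-level keys are [run_config()] arguments; a `synth:` block holds
#' [synth_config()] arguments.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  synth_args <- y$synth %||% list()
  if (is.null(synth_args$seed) && !is.null(y$seed)) {
    synth_args$seed <- y$seed
  }
  y$synth <- do.call(synth_config, synth_args)
  do.call(run_config, y)
}

#' Run the whole discovery pipeline
#'
#' Generates the synthetic inputs, preprocesses (imputation of the
#' studies carrying missing values), runs per-study differential
#' expression, combines miRNA effects with the random-effects
#' meta-analysis, filters to human miRNAs, maps them to validated
#' targets, intersects with the mRNA DEGs, and carries the overlap gene
#' set through enrichment, PPI hub ranking and survival analysis of the
#' top hub. Intermediates are written as TSVs when `outdir` is given,
#' together with a JSON + TSV summary; two runs with the same seed give
#' identical summaries.
#'
#' @param cfg A [run_config()].
#' @param outdir Optional output directory for intermediates and the
#'   summary.
#' @return A list of class `mirmeta_run` with elements `meta`, `dems`,
#'   `de_mrna` (list), `intersection`, `enrichment`, `hubs`, `survival`,
#'   `truth`, and `summary` (a one-row tibble).
#' @export
run_pipeline <- function(cfg = run_config(), outdir = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  scfg <- cfg$synth

  gen <- synth_mirna_studies(scfg)
  studies <- gen$studies
  truth <- gen$truth

  studies <- lapply(studies, function(st) {
    if (any(st$missing_mask)) {
      impute_missing(st, method = cfg$impute_method,
                     seed = substream_seed(cfg$seed, "impute"))
    } else {
      st
    }
  })

  de_mirna <- lapply(studies, de_analysis, alpha = cfg$alpha)
  effects <- purrr::imap_dfr(
    de_mirna, ~ study_effects(.x, study_id = sprintf("study%d", .y)))
  meta <- run_meta(effects, model = cfg$model)
  dems <- meta$feature_id[meta$adj_p < cfg$alpha]
  dems <- filter_human(dems)

  mr <- synth_mrna_studies(scfg, truth)
  truth <- mr$truth
  de_mrna <- lapply(mr$studies, de_analysis, alpha = cfg$alpha,
                    lfc_cut = cfg$lfc_cut)
  deg_lists <- lapply(de_mrna, function(d) d$feature_id[d$is_de])
  names(deg_lists) <- sprintf("mrna_study%d", seq_along(deg_lists))

  interactions <- synth_interactions(truth, scfg)
  target_map <- if (length(dems) > 0) {
    lookup_targets(dems, interactions, validated_only = TRUE)
  } else {
    list()
  }
  intersection <- intersect_targets_with_degs(target_map, deg_lists)
  overlap <- intersection$overlap

  enrichment <- hubs <- surv <- NULL
  if (length(overlap) > 0) {
    gs <- synth_genesets(scfg, truth)
    enrichment <- hypergeom_enrich(overlap, gs, method = cfg$go_method) |>
      kappa_group(gs, kappa_threshold = cfg$kappa)
    el <- synth_edgelist(scfg, truth)
    net <- build_network(el$edges, min_score = cfg$min_score,
                         keep_nodes = overlap)
    hubs <- rank_hubs(net, top_n = 10)
    surv_tab <- synth_survival(scfg)
    surv <- survival_analysis(surv_tab, rule = cfg$split_rule)
  } else {
    message("empty overlap gene set; downstream stages skipped")
  }

  summary <- tibble::tibble(
    seed = cfg$seed,
    n_dems = length(dems),
    n_dems_up = sum(meta$adj_p < cfg$alpha & meta$direction == "up" &
                      startsWith(meta$feature_id, "hsa")),
    n_dems_down = sum(meta$adj_p < cfg$alpha & meta$direction == "down" &
                        startsWith(meta$feature_id, "hsa")),
    n_degs_study1 = length(deg_lists[[1]]),
    n_degs_study2 = length(deg_lists[[2]]),
    n_degs_study3 = length(deg_lists[[3]]),
    n_overlap_genes = length(overlap),
    top_term = if (!is.null(enrichment)) enrichment$term_id[1] else NA_character_,
    top_term_adj_p = if (!is.null(enrichment)) enrichment$adj_p[1] else NA_real_,
    top_hub = if (!is.null(hubs)) hubs$gene[1] else NA_character_,
    top_hub_degree = if (!is.null(hubs)) hubs$degree[1] else NA_integer_,
    surv_hr = if (!is.null(surv)) surv$hr else NA_real_,
    surv_logrank_p = if (!is.null(surv)) surv$p else NA_real_
  )

  out <- structure(
    list(meta = meta, dems = dems, de_mirna = de_mirna, de_mrna = de_mrna,
         deg_lists = deg_lists, intersection = intersection,
         enrichment = enrichment, hubs = hubs, survival = surv,
         truth = truth, summary = summary, config = cfg),
    class = "mirmeta_run"
  )
  if (!is.null(outdir)) write_run(out, outdir)
  out
}

#' @export
print.mirmeta_run <- function(x, ...) {
  s <- x$summary
  cat("<mirmeta_run>\n")
  cat(sprintf("  DEMs: %d (%d up / %d down) | DEGs per study: %d / %d / %d\n",
              s$n_dems, s$n_dems_up, s$n_dems_down,
              s$n_degs_study1, s$n_degs_study2, s$n_degs_study3))
  cat(sprintf("  overlap genes: %d | top term: %s (adj p = %.3g)\n",
              s$n_overlap_genes, s$top_term, s$top_term_adj_p))
  cat(sprintf("  top hub: %s (degree %d) | survival HR = %.3g (log-rank p = %.3g)\n",
              s$top_hub, s$top_hub_degree, s$surv_hr, s$surv_logrank_p))
  invisible(x)
}

#' Persist a pipeline run's intermediates and summary
#'
#' @param run A `mirmeta_run`.
#' @param outdir Output directory (created if needed).
#' @return `run`, invisibly.
#' @export
write_run <- function(run, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  readr::write_tsv(run$meta, file.path(outdir, "meta.tsv"))
  for (i in seq_along(run$de_mirna)) {
    readr::write_tsv(run$de_mirna[[i]],
                     file.path(outdir, sprintf("de_mirna_study%d.tsv", i)))
  }
  for (i in seq_along(run$de_mrna)) {
    readr::write_tsv(run$de_mrna[[i]],
                     file.path(outdir, sprintf("de_mrna_study%d.tsv", i)))
  }
  readr::write_tsv(tidy(run$intersection) |>
                     dplyr::mutate(mirnas = purrr::map_chr(
                       .data$mirnas, ~ paste(.x %||% "", collapse = ";"))),
                   file.path(outdir, "overlap_genes.tsv"))
  if (!is.null(run$enrichment)) {
    readr::write_tsv(dplyr::select(run$enrichment, -"hits"),
                     file.path(outdir, "enrichment.tsv"))
  }
  if (!is.null(run$hubs)) {
    readr::write_tsv(run$hubs, file.path(outdir, "hubs.tsv"))
  }
  if (!is.null(run$survival)) {
    readr::write_tsv(run$survival$km_curves,
                     file.path(outdir, "km_curves.tsv"))
  }
  readr::write_tsv(run$summary, file.path(outdir, "summary.tsv"))
  jsonlite::write_json(as.list(run$summary),
                       file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(run)
}
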