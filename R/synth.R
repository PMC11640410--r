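#' Configuration for the synthetic-data generators
#'
#' The defaults define the standing study conditions used throughout the
#' package's tests: three small two-group miRNA studies on distinct
#' platforms (group sizes emulating 6-, 12- and ~100-sample GEO series),
#' shared planted effects with between-study heterogeneity, missing values
#' in the first (smallest) study only, a 10% admixture of non-human decoy
#' miRNA ids, and validated-style miRNA-to-gene interactions for the
#' planted signal.
#'
#' @param n_features Number of miRNA features per study.
#' @param n_true_de Number of features with a planted differential effect.
#' @param k_studies Number of miRNA studies.
#' @param samples_per_group Per-study two-group size; scalar or length
#'   `k_studies` vector.
#' @param mu_effect Mean magnitude of the planted log2 effect
#'   (resistant - control); each planted feature gets a random sign.
#' @param tau2 Between-study variance of the realized per-study effect
#'   (log2 units squared).
#' @param sigma2 Within-study noise variance (log2 units squared).
#' @param missing_rate Fraction of cells set missing, completely at
#'   random, in the studies listed in `missing_studies`.
#' @param missing_studies Indices of studies that receive missing values.
#' @param decoy_frac Fraction of features carrying a non-"hsa" species
#'   prefix (these are never planted as DE).
#' @param target_density Planted validated target genes per planted miRNA.
#' @param n_genes Gene universe size for the mRNA studies.
#' @param target_de_frac Fraction of planted target genes that are truly
#'   DE in at least one mRNA study.
#' @param n_extra_de Independently DE genes per mRNA study (not miRNA
#'   targets).
#' @param gene_effect Magnitude of the true mRNA log2 effect.
#' @param mrna_samples_per_group Per-study two-group size for the three
#'   mRNA studies.
#' @param n_decoy_pairs Random non-planted rows in the interaction table.
#' @param seed Root seed; every generator derives a named substream from
#'   it, so identical seeds give bit-identical outputs.
#'
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_features = 300,
                         n_true_de = 20,
                         k_studies = 3,
                         samples_per_group = c(3, 6, 50),
                         mu_effect = 2,
                         tau2 = 0.05,
                         sigma2 = 0.25,
                         missing_rate = 0.2,
                         missing_studies = 1,
                         decoy_frac = 0.1,
                         target_density = 5,
                         n_genes = 2000,
                         target_de_frac = 1.0,
                         n_extra_de = 100,
                         gene_effect = 2,
                         mrna_samples_per_group = c(7, 4, 10),
                         n_decoy_pairs = 300,
                         seed = 1) {
  n_features <- assert_count(n_features, "n_features", 1L)
  n_true_de <- assert_count(n_true_de, "n_true_de", 0L)
  k_studies <- assert_count(k_studies, "k_studies", 1L)
  if (n_true_de > n_features) {
    stop("`n_true_de` must not exceed `n_features`", call. = FALSE)
  }
  if (length(samples_per_group) == 1) {
    samples_per_group <- rep(samples_per_group, k_studies)
  }
  if (length(samples_per_group) != k_studies) {
    stop("`samples_per_group` must be scalar or length `k_studies`",
         call. = FALSE)
  }
  if (any(samples_per_group < 2)) {
    stop("`samples_per_group` must be >= 2 (within-group variance undefined)",
         call. = FALSE)
  }
  if (tau2 < 0) stop("`tau2` must be >= 0", call. = FALSE)
  if (sigma2 <= 0) stop("`sigma2` must be > 0", call. = FALSE)
  assert_prob(missing_rate, "missing_rate", 0, 1 - 1e-9)
  assert_prob(decoy_frac, "decoy_frac")
  assert_prob(target_de_frac, "target_de_frac")
  structure(
    list(n_features = n_features, n_true_de = n_true_de,
         k_studies = k_studies,
         samples_per_group = as.integer(samples_per_group),
         mu_effect = mu_effect, tau2 = tau2, sigma2 = sigma2,
         missing_rate = missing_rate,
         missing_studies = as.integer(missing_studies),
         decoy_frac = decoy_frac, target_density = target_density,
         n_genes = as.integer(n_genes), target_de_frac = target_de_frac,
         n_extra_de = as.integer(n_extra_de), gene_effect = gene_effect,
         mrna_samples_per_group = as.integer(mrna_samples_per_group),
         n_decoy_pairs = as.integer(n_decoy_pairs),
         seed = as.integer(seed)),
    class = "synth_config"
  )
}

mirna_feature_ids <- function(cfg) {
  n <- cfg$n_features
  n_decoy <- floor(n * cfg$decoy_frac)
  prefixes <- c("mmu", "rno", "gga")
  ids <- sprintf("hsa-miR-%d-5p", seq_len(n))
  if (n_decoy > 0) {
    idx <- seq.int(n - n_decoy + 1, n)
    ids[idx] <- sprintf("%s-miR-%d-5p",
                        prefixes[(seq_along(idx) - 1) %% 3 + 1], idx)
  }
  ids
}

#' Generate synthetic two-group miRNA studies with planted signal
#'
#' Null features are Normal(baseline, sigma2) in both groups; planted
#' features get a per-study group-mean difference drawn from
#' Normal(sign * mu_effect, tau2), the random-effects generative model.
#' Missingness is completely at random in the configured studies.
#' Planted features are always human ("hsa") ids; decoy species ids
#' exercise the downstream species filter.
#'
#' @param cfg A [synth_config()].
#' @return A list with `studies` (list of [expression_study()]) and
#'   `truth` (a `synth_truth` oracle: tibbles `de_features` with the true
#'   mean and per-study realized effects, `target_map` with planted
#'   miRNA-to-gene pairs, and the per-study `de_genes` sets filled in by
#'   [synth_mrna_studies()]).
#' @export
synth_mirna_studies <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  with_seed(substream_seed(cfg$seed, "mirna"), {
    ids <- mirna_feature_ids(cfg)
    hsa <- grepl("^hsa", ids)
    de_idx <- if (cfg$n_true_de > 0) {
      sample(which(hsa), cfg$n_true_de)
    } else {
      integer(0)
    }
    sign_i <- sample(c(-1, 1), cfg$n_true_de, replace = TRUE)
    mu_i <- sign_i * cfg$mu_effect
    baseline <- stats::runif(cfg$n_features, 4, 12)
    # realized per-study effect theta[i, s] ~ N(mu_i, tau2)
    theta <- matrix(0, cfg$n_true_de, cfg$k_studies)
    if (cfg$n_true_de > 0) {
      theta[] <- stats::rnorm(cfg$n_true_de * cfg$k_studies,
                              mean = mu_i, sd = sqrt(cfg$tau2))
    }
    studies <- vector("list", cfg$k_studies)
    for (s in seq_len(cfg$k_studies)) {
      n_g <- cfg$samples_per_group[s]
      n_s <- 2L * n_g
      m <- matrix(stats::rnorm(cfg$n_features * n_s, sd = sqrt(cfg$sigma2)),
                  cfg$n_features, n_s) + baseline
      # resistant samples first, shifted by the realized study effect
      if (cfg$n_true_de > 0) {
        m[de_idx, seq_len(n_g)] <- m[de_idx, seq_len(n_g)] + theta[, s]
      }
      rownames(m) <- ids
      colnames(m) <- sprintf("st%d_s%02d", s, seq_len(n_s))
      groups <- stats::setNames(
        rep(c("resistant", "control"), each = n_g), colnames(m))
      if (s %in% cfg$missing_studies && cfg$missing_rate > 0) {
        mask <- matrix(stats::runif(length(m)) < cfg$missing_rate,
                       nrow(m), ncol(m))
        # keep invariants: >=1 observed value per feature and per column
        full_rows <- rowSums(!mask) == 0
        mask[full_rows, 1] <- FALSE
        m[mask] <- NA_real_
      }
      studies[[s]] <- expression_study(
        m, groups, platform = sprintf("synthetic-platform-%d", s),
        log_scale = TRUE)
    }
    de_features <- tibble::tibble(
      feature_id = ids[de_idx],
      true_effect = mu_i
    )
    if (cfg$n_true_de > 0) {
      colnames(theta) <- sprintf("study%d", seq_len(cfg$k_studies))
      de_features <- dplyr::bind_cols(de_features,
                                      tibble::as_tibble(theta))
    }
    target_map <- synth_target_map(de_features$feature_id, cfg)
    truth <- structure(
      list(de_features = de_features, target_map = target_map,
           de_genes = NULL),
      class = "synth_truth"
    )
    list(studies = studies, truth = truth)
  })
}

synth_target_map <- function(dems, cfg) {
  if (length(dems) == 0) {
    return(tibble::tibble(mirna_id = character(), gene_symbol = character()))
  }
  genes <- sprintf("GENE%d", seq_len(cfg$n_genes))
  purrr::map_dfr(dems, function(mi) {
    tibble::tibble(
      mirna_id = mi,
      gene_symbol = sample(genes, max(1L, stats::rpois(1, cfg$target_density)))
    )
  }) |>
    dplyr::distinct()
}

#' Generate synthetic mRNA validation studies
#'
#' Gene-level two-group matrices in which a configurable fraction of the
#' planted miRNA target genes are truly DE (sign opposite their targeting
#' miRNA by default), alongside independently DE genes and nulls.
#'
#' @param cfg A [synth_config()].
#' @param truth The `synth_truth` from [synth_mirna_studies()]; its
#'   `de_genes` element is filled in on return.
#' @param opposite_sign Plant target-gene effects with the sign opposite
#'   the targeting miRNA's (canonical repression model).
#' @return A list with `studies` (3 gene-level [expression_study()]s) and
#'   the updated `truth`.
#' @export
synth_mrna_studies <- function(cfg, truth, opposite_sign = TRUE) {
  stopifnot(inherits(cfg, "synth_config"), inherits(truth, "synth_truth"))
  genes <- sprintf("GENE%d", seq_len(cfg$n_genes))
  unknown <- setdiff(truth$target_map$gene_symbol, genes)
  if (length(unknown) > 0) {
    stop("unknown gene ids in truth$target_map: ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  with_seed(substream_seed(cfg$seed, "mrna"), {
    k <- length(cfg$mrna_samples_per_group)
    planted <- unique(truth$target_map$gene_symbol)
    n_pick <- round(cfg$target_de_frac * length(planted))
    de_targets <- if (n_pick > 0) sample(planted, n_pick) else character(0)
    # effect sign: opposite of (one of) the targeting miRNA's true effect
    sign_lookup <- truth$target_map |>
      dplyr::left_join(truth$de_features[, c("feature_id", "true_effect")],
                       by = c("mirna_id" = "feature_id")) |>
      dplyr::group_by(.data$gene_symbol) |>
      dplyr::summarise(mirna_sign = sign(.data$true_effect[1]),
                       .groups = "drop")
    gene_sign <- stats::setNames(sign_lookup$mirna_sign,
                                 sign_lookup$gene_symbol)
    baseline <- stats::runif(cfg$n_genes, 4, 12)
    studies <- vector("list", k)
    de_genes <- vector("list", k)
    # every selected target gene is DE in >=1 study; membership per study
    # is random so the per-study DEG sets differ
    target_study <- if (length(de_targets) > 0) {
      lapply(seq_along(de_targets), function(i) {
        members <- which(stats::runif(k) < 0.7)
        if (length(members) == 0) members <- sample.int(k, 1)
        members
      })
    } else {
      list()
    }
    for (s in seq_len(k)) {
      n_g <- cfg$mrna_samples_per_group[s]
      n_s <- 2L * n_g
      m <- matrix(stats::rnorm(cfg$n_genes * n_s, sd = sqrt(cfg$sigma2)),
                  cfg$n_genes, n_s) + baseline
      rownames(m) <- genes
      colnames(m) <- sprintf("mst%d_s%02d", s, seq_len(n_s))
      in_study <- de_targets[vapply(seq_along(de_targets),
                                    function(i) s %in% target_study[[i]],
                                    logical(1))]
      extra_pool <- setdiff(genes, planted)
      extra <- sample(extra_pool, min(cfg$n_extra_de, length(extra_pool)))
      target_eff <- vapply(in_study, function(g) {
        s0 <- gene_sign[[g]]
        if (is.na(s0) || s0 == 0) s0 <- 1
        if (opposite_sign) -s0 * cfg$gene_effect else s0 * cfg$gene_effect
      }, numeric(1))
      eff <- c(
        stats::setNames(target_eff, in_study),
        stats::setNames(sample(c(-1, 1), length(extra), TRUE) *
                          cfg$gene_effect, extra)
      )
      if (length(eff) > 0) {
        m[names(eff), seq_len(n_g)] <- m[names(eff), seq_len(n_g)] + eff
      }
      groups <- stats::setNames(
        rep(c("resistant", "control"), each = n_g), colnames(m))
      studies[[s]] <- expression_study(
        m, groups, platform = sprintf("synthetic-rnaseq-%d", s),
        log_scale = TRUE)
      de_genes[[s]] <- sort(names(eff))
    }
    truth$de_genes <- de_genes
    list(studies = studies, truth = truth)
  })
}

#' Generate a validated-interaction table with decoys
#'
#' Contains every planted miRNA-to-gene pair (validated) plus random decoy
#' pairs that never duplicate a planted pair; `source_db` is drawn from a
#' fixed vocabulary mimicking validated-interaction databases.
#'
#' @param truth `synth_truth` from [synth_mirna_studies()].
#' @param cfg A [synth_config()].
#' @return A tibble with columns `mirna_id`, `gene_symbol`, `source_db`,
#'   `validated` (0/1); rows unique on (mirna, gene, source).
#' @export
synth_interactions <- function(truth, cfg) {
  stopifnot(inherits(truth, "synth_truth"), inherits(cfg, "synth_config"))
  sources <- c("mirtarbase", "tarbase", "mirecords")
  with_seed(substream_seed(cfg$seed, "interactions"), {
    planted <- truth$target_map |>
      dplyr::mutate(
        source_db = sample(sources, dplyr::n(), replace = TRUE),
        validated = 1L
      )
    n_decoy <- cfg$n_decoy_pairs
    if (n_decoy > 0) {
      mirnas <- mirna_feature_ids(cfg)
      genes <- sprintf("GENE%d", seq_len(cfg$n_genes))
      decoys <- tibble::tibble(
        mirna_id = sample(mirnas, 3 * n_decoy, replace = TRUE),
        gene_symbol = sample(genes, 3 * n_decoy, replace = TRUE)
      ) |>
        dplyr::distinct() |>
        dplyr::anti_join(truth$target_map,
                         by = c("mirna_id", "gene_symbol")) |>
        utils::head(n_decoy) |>
        dplyr::mutate(
          source_db = sample(sources, dplyr::n(), replace = TRUE),
          validated = sample(0:1, dplyr::n(), replace = TRUE)
        )
      planted <- dplyr::bind_rows(planted, decoys)
    }
    dplyr::distinct(planted, .data$mirna_id, .data$gene_symbol,
                    .data$source_db, .keep_all = TRUE)
  })
}

#' Generate a gene-set collection enriched for the planted signal
#'
#' One planted term concentrates the planted DE target genes (by default
#' 80% of its potential query hits are inside it); the remaining terms are
#' random draws from the universe across GO-style categories and a
#' pathway category.
#'
#' @param cfg A [synth_config()].
#' @param truth `synth_truth` with `de_genes` filled in.
#' @param n_terms Total number of terms.
#' @param planted_coverage Fraction of the planted target-DE genes placed
#'   inside the planted term.
#' @return A `geneset_collection` (see [geneset_collection()]), with the
#'   planted term named `"TERM_PLANTED"`.
#' @export
synth_genesets <- function(cfg, truth, n_terms = 50,
                           planted_coverage = 0.8) {
  stopifnot(inherits(cfg, "synth_config"), inherits(truth, "synth_truth"))
  genes <- sprintf("GENE%d", seq_len(cfg$n_genes))
  with_seed(substream_seed(cfg$seed, "genesets"), {
    categories <- c("BP", "MF", "CC", "pathway")
    planted_genes <- intersect(unique(truth$target_map$gene_symbol),
                               unique(unlist(truth$de_genes)))
    inside <- if (length(planted_genes) > 0) {
      sample(planted_genes,
             max(1L, round(planted_coverage * length(planted_genes))))
    } else {
      character(0)
    }
    planted_set <- unique(c(
      inside, sample(setdiff(genes, inside), 20)
    ))
    terms <- list(tibble::tibble(
      term_id = "TERM_PLANTED",
      name = "planted resistance module",
      category = "BP",
      genes = list(sort(planted_set))
    ))
    for (i in seq_len(n_terms - 1)) {
      sz <- sample(10:50, 1)
      terms[[i + 1]] <- tibble::tibble(
        term_id = sprintf("TERM%03d", i),
        name = sprintf("random term %d", i),
        category = sample(categories, 1),
        genes = list(sort(sample(genes, sz)))
      )
    }
    geneset_collection(dplyr::bind_rows(terms), universe = genes)
  })
}

#' Generate a protein-interaction edge list with a planted hub
#'
#' Random edges among the planted target genes plus background genes, with
#' one designated hub wired to enough neighbours that its degree is
#' strictly maximal by construction. Scores are uniform on [0.4, 1].
#'
#' @param cfg A [synth_config()].
#' @param truth `synth_truth`.
#' @param n_nodes Number of background nodes beyond the planted genes.
#' @param n_edges Number of random edges before hub wiring.
#' @return A list with `edges` (tibble `node_a`, `node_b`, `score`) and
#'   `hub` (the planted hub's gene symbol).
#' @export
synth_edgelist <- function(cfg, truth, n_nodes = 60, n_edges = 120) {
  stopifnot(inherits(cfg, "synth_config"), inherits(truth, "synth_truth"))
  with_seed(substream_seed(cfg$seed, "edgelist"), {
    planted <- unique(truth$target_map$gene_symbol)
    nodes <- unique(c(planted,
                      sprintf("GENE%d", sample(cfg$n_genes, n_nodes))))
    hub <- if (length(planted) > 0) planted[1] else nodes[1]
    others <- setdiff(nodes, hub)
    rnd <- tibble::tibble(
      node_a = sample(others, n_edges, replace = TRUE),
      node_b = sample(others, n_edges, replace = TRUE)
    ) |>
      dplyr::filter(.data$node_a != .data$node_b) |>
      dplyr::mutate(
        lo = ifelse(.data$node_a < .data$node_b, .data$node_a, .data$node_b),
        hi = ifelse(.data$node_a < .data$node_b, .data$node_b, .data$node_a)
      ) |>
      dplyr::distinct(.data$lo, .data$hi)
    # wire hub to more neighbours than any other node can reach
    max_other <- max(c(table(c(rnd$lo, rnd$hi)), 0))
    n_hub <- min(length(others), max_other + 5)
    hub_nb <- others[seq_len(n_hub)]
    hub_edges <- tibble::tibble(
      lo = ifelse(hub < hub_nb, hub, hub_nb),
      hi = ifelse(hub < hub_nb, hub_nb, hub)
    )
    edges <- dplyr::bind_rows(hub_edges, rnd) |>
      dplyr::distinct(.data$lo, .data$hi) |>
      dplyr::transmute(
        node_a = .data$lo, node_b = .data$hi,
        score = round(stats::runif(dplyr::n(), 0.4, 1), 3)
      )
    list(edges = edges, hub = hub)
  })
}

#' Generate a survival table for one gene
#'
#' Expression is standard normal; survival times are exponential with rate
#' `base_rate * exp(beta * high)` where `high` indicates above-median
#' expression, so `exp(beta)` is the true high-vs-low hazard ratio.
#' Censoring is independent exponential plus administrative cutoff.
#'
#' @param cfg A [synth_config()] (only the seed is used unless `seed`
#'   given).
#' @param n Number of subjects.
#' @param beta Log hazard ratio for the high-expression group.
#' @param base_rate Baseline event rate per month.
#' @param censor_rate Rate of the independent censoring process.
#' @param admin_time Administrative censoring time (months).
#' @param seed Optional seed overriding the config substream.
#' @return A tibble with columns `sample_id`, `time`, `event`,
#'   `expression`.
#' @export
synth_survival <- function(cfg, n = 200, beta = log(2), base_rate = 1 / 60,
                           censor_rate = 1 / 120, admin_time = 120,
                           seed = NULL) {
  seed <- seed %||% substream_seed(cfg$seed, "survival")
  with_seed(seed, {
    expr <- stats::rnorm(n)
    high <- expr > stats::median(expr)
    rate <- base_rate * exp(beta * high)
    t_event <- stats::rexp(n, rate)
    t_cens <- pmin(stats::rexp(n, censor_rate), admin_time)
    tibble::tibble(
      sample_id = sprintf("pat%03d", seq_len(n)),
      time = pmin(t_event, t_cens),
      event = as.integer(t_event <= t_cens),
      expression = expr
    )
  })
}

#' Write / read a gene-set collection in GMT format
#'
#' Standard GMT: one term per line, `name<TAB>description<TAB>gene1<TAB>...`.
#'
#' @param collection A [geneset_collection()].
#' @param path File path.
#' @param universe Universe for the re-read collection (defaults to the
#'   union of all term genes).
#' @return `read_gmt()` returns a [geneset_collection()].
#' @export
write_gmt <- function(collection, path) {
  lines <- purrr::pmap_chr(
    collection$terms[, c("term_id", "name", "genes")],
    function(term_id, name, genes) {
      paste(c(term_id, name, genes), collapse = "\t")
    }
  )
  writeLines(lines, path)
  invisible(collection)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  terms <- purrr::map_dfr(parts, function(p) {
    tibble::tibble(term_id = p[1], name = p[2], category = "pathway",
                   genes = list(sort(unique(p[-(1:2)]))))
  })
  geneset_collection(terms,
                     universe = universe %||% sort(unique(unlist(terms$genes))))
}
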