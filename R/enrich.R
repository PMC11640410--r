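#' Gene-set collection
#'
#' @param terms A tibble with columns `term_id`, `name`, `category` (one
#'   of BP, MF, CC, pathway) and `genes` (list-column of character
#'   vectors, non-empty).
#' @param universe Background gene vector; every term gene must belong to
#'   it.
#' @return An object of class `geneset_collection`.
#' @export
geneset_collection <- function(terms, universe) {
  stopifnot(is.data.frame(terms),
            all(c("term_id", "name", "category", "genes") %in% names(terms)))
  universe <- sort(unique(universe))
  if (any(lengths(terms$genes) == 0)) {
    stop("term gene sets must be non-empty", call. = FALSE)
  }
  outside <- setdiff(unique(unlist(terms$genes)), universe)
  if (length(outside) > 0) {
    stop("term genes outside the universe: ",
         paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
  }
  structure(list(terms = tibble::as_tibble(terms), universe = universe),
            class = "geneset_collection")
}

#' @export
print.geneset_collection <- function(x, ...) {
  cat(sprintf("<geneset_collection> %d terms over a universe of %d genes\n",
              nrow(x$terms), length(x$universe)))
  invisible(x)
}

#' Hypergeometric over-representation analysis
#'
#' For each term, the upper-tail hypergeometric probability of observing
#' at least the seen overlap: `p = P(X >= k)` with `X ~
#' Hypergeometric(N, K, n)` where N is the universe size, K the term
#' size and n the query size. Query genes outside the universe are
#' dropped with a message. Correction per `method`: Bonferroni is the
#' default for GO-style collections, BH for pathway collections, Holm
#' (Bonferroni step-down) also available.
#'
#' @param query Character vector of genes (e.g. the intersection report's
#'   overlap).
#' @param collection A [geneset_collection()].
#' @param method `"bonferroni"`, `"bh"` or `"holm"`.
#' @param alpha Significance threshold on the adjusted p.
#' @return A tibble sorted by p: `term_id`, `name`, `category`, `k`
#'   (overlap), `K` (term size), `n` (query size), `N` (universe size),
#'   `p`, `adj_p`, `significant`, `hits` (list-column).
#' @export
hypergeom_enrich <- function(query, collection,
                             method = c("bonferroni", "bh", "holm"),
                             alpha = 0.05) {
  method <- match.arg(method)
  stopifnot(inherits(collection, "geneset_collection"))
  query <- unique(query)
  inside <- intersect(query, collection$universe)
  n_dropped <- length(query) - length(inside)
  if (n_dropped > 0) {
    message(n_dropped, " query gene(s) outside the universe dropped")
  }
  if (length(inside) == 0) {
    stop("no query genes in the universe", call. = FALSE)
  }
  n <- length(inside)
  N <- length(collection$universe)
  res <- collection$terms |>
    dplyr::mutate(
      hits = purrr::map(.data$genes, ~ intersect(.x, inside)),
      k = lengths(.data$hits),
      K = lengths(.data$genes),
      n = n, N = N,
      p = stats::phyper(.data$k - 1, .data$K, N - .data$K, n,
                        lower.tail = FALSE)
    ) |>
    dplyr::select(-"genes")
  adj <- switch(method,
                bonferroni = stats::p.adjust(res$p, "bonferroni"),
                bh = bh_adjust(res$p),
                holm = stats::p.adjust(res$p, "holm"))
  res |>
    dplyr::mutate(adj_p = adj, method = method,
                  significant = .data$adj_p < alpha) |>
    dplyr::arrange(.data$p) |>
    dplyr::relocate("hits", .after = dplyr::last_col())
}

#' Cohen's kappa between two gene sets over a universe
#'
#' Chance-corrected agreement of the two membership indicator vectors;
#' 1 iff the sets are identical over the universe, 0 when agreement is at
#' chance level (the degenerate all-agree case is also 1).
#'
#' @param set_a,set_b Character vectors (subsets of `universe`).
#' @param universe Background genes.
#' @return Kappa in \[-1, 1\].
#' @export
kappa_score <- function(set_a, set_b, universe) {
  a <- universe %in% set_a
  b <- universe %in% set_b
  n <- length(universe)
  po <- mean(a == b)
  pe <- mean(a) * mean(b) + mean(!a) * mean(!b)
  if (abs(1 - pe) < 1e-12) return(if (po == 1) 1 else 0)
  (po - pe) / (1 - pe)
}

#' Group redundant enriched terms by kappa score
#'
#' Computes pairwise kappa between the significant terms' membership
#' vectors and single-links pairs with kappa at or above the threshold;
#' each resulting group is labelled by its most significant term.
#'
#' @param enrichment Result of [hypergeom_enrich()] (uses rows with
#'   `significant`, falling back to all rows if none are).
#' @param collection The [geneset_collection()] the terms came from.
#' @param kappa_threshold Grouping threshold (default 0.96); a threshold
#'   above 1 yields all-singleton groups.
#' @param use_all Group all terms rather than the significant subset.
#' @return `enrichment` with columns `group_id` (the representative
#'   term_id) and `kappa_group` (integer label); non-grouped rows get NA.
#' @export
kappa_group <- function(enrichment, collection, kappa_threshold = 0.96,
                        use_all = FALSE) {
  stopifnot(inherits(collection, "geneset_collection"))
  sel <- if (use_all || !any(enrichment$significant)) {
    enrichment
  } else {
    dplyr::filter(enrichment, .data$significant)
  }
  ids <- sel$term_id
  m <- length(ids)
  if (m == 0) stop("no terms to group", call. = FALSE)
  genes <- collection$terms$genes[match(ids, collection$terms$term_id)]
  adj <- diag(TRUE, m)
  if (m > 1) {
    for (i in seq_len(m - 1)) {
      for (j in seq.int(i + 1, m)) {
        kp <- kappa_score(genes[[i]], genes[[j]], collection$universe)
        adj[i, j] <- adj[j, i] <- kp >= kappa_threshold
      }
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  # label each group by its most significant member (input is p-sorted
  # only after hypergeom_enrich; order by p explicitly)
  reps <- vapply(split(seq_len(m), comp), function(idx) {
    ids[idx[which.min(sel$p[idx])]]
  }, character(1))
  grp <- tibble::tibble(term_id = ids,
                        kappa_group = as.integer(comp),
                        group_id = reps[as.character(comp)])
  dplyr::left_join(enrichment, grp, by = "term_id")
}
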