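#' Keep human miRNA identifiers
#'
#' Retains ids whose lower-cased form starts with the miRBase species tag
#' `"hsa"`; idempotent.
#'
#' @param mirna_ids Character vector of miRNA identifiers.
#' @return The human subset, original case preserved.
#' @export
filter_human <- function(mirna_ids) {
  mirna_ids[startsWith(tolower(mirna_ids), "hsa")]
}

#' Read / write a miRNA-gene interaction table
#'
#' TSV columns: `mirna_id`, `gene_symbol`, `source_db`, `validated` (0/1).
#'
#' @param path File path.
#' @param table The interaction tibble (for writing).
#' @return `read_interactions()` returns the tibble.
#' @export
read_interactions <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    mirna_id = readr::col_character(),
                    gene_symbol = readr::col_character(),
                    source_db = readr::col_character(),
                    validated = readr::col_integer()
                  ))
}

#' @rdname read_interactions
#' @export
write_interactions <- function(table, path) {
  readr::write_tsv(table, path)
  invisible(table)
}

#' Map significant miRNAs to target genes
#'
#' Looks up each miRNA's target-gene set in the interaction table
#' (case-insensitive on the miRNA id, set semantics across source
#' databases). miRNAs without any recorded target map to an empty set.
#'
#' @param dems Character vector of (human-filtered) miRNA ids.
#' @param interactions Interaction tibble with `mirna_id`, `gene_symbol`,
#'   `validated`.
#' @param validated_only Keep only experimentally validated rows (default
#'   `TRUE`).
#' @return A named list mapping each queried miRNA to a character vector
#'   of target genes; attribute `n_unmatched` counts miRNAs with no
#'   targets.
#' @export
lookup_targets <- function(dems, interactions, validated_only = TRUE) {
  if (nrow(interactions) == 0) {
    stop("interaction table is empty", call. = FALSE)
  }
  tab <- interactions
  if (validated_only) tab <- dplyr::filter(tab, .data$validated == 1)
  tab <- dplyr::mutate(tab, .mirna = tolower(trimws(.data$mirna_id)))
  out <- lapply(dems, function(mi) {
    sort(unique(tab$gene_symbol[tab$.mirna == tolower(trimws(mi))]))
  })
  names(out) <- dems
  n_unmatched <- sum(lengths(out) == 0)
  if (n_unmatched > 0) {
    message(n_unmatched, " miRNA(s) had no recorded targets")
  }
  attr(out, "n_unmatched") <- n_unmatched
  out
}

#' Intersect miRNA target genes with differentially expressed genes
#'
#' The candidate resistance genes are the targets of the significant
#' miRNAs that are also differentially expressed in the validation mRNA
#' studies. DEG lists are aggregated by union by default.
#'
#' @param target_map Named list from [lookup_targets()].
#' @param deg_lists List of per-study DEG character vectors (or a tibble
#'   list-column); names label the studies.
#' @param aggregate `"union"` (default), `"intersection"` or
#'   `"majority"` (gene DE in more than half of the studies).
#' @return A list of class `intersection_report`: `overlap` (sorted gene
#'   vector), `dem_targets`, `deg_union`, `venn` (counts of
#'   targets-only / overlap / degs-only), `per_study` tibble of per-study
#'   DEG counts and contributions, and `backmap`, a tibble mapping each
#'   overlap gene to its targeting miRNAs.
#' @export
intersect_targets_with_degs <- function(target_map, deg_lists,
                                        aggregate = c("union", "intersection",
                                                      "majority")) {
  aggregate <- match.arg(aggregate)
  if (is.null(names(deg_lists))) {
    names(deg_lists) <- sprintf("study%d", seq_along(deg_lists))
  }
  dem_targets <- sort(unique(unlist(target_map)))
  deg_union <- sort(unique(unlist(deg_lists)))
  deg_agg <- switch(
    aggregate,
    union = deg_union,
    intersection = sort(Reduce(intersect, deg_lists)),
    majority = {
      cnt <- table(unlist(lapply(deg_lists, unique)))
      sort(names(cnt)[cnt > length(deg_lists) / 2])
    }
  )
  overlap <- intersect(dem_targets, deg_agg)
  per_study <- purrr::imap_dfr(deg_lists, function(g, nm) {
    tibble::tibble(study_id = nm, n_degs = length(unique(g)),
                   n_in_overlap = length(intersect(unique(g), overlap)))
  })
  backmap <- purrr::imap_dfr(target_map, function(genes, mi) {
    tibble::tibble(gene_symbol = intersect(genes, overlap), mirna_id = mi)
  })
  if (nrow(backmap) == 0) {
    backmap <- tibble::tibble(gene_symbol = character(),
                              mirna_id = character())
  }
  backmap <- backmap |>
    dplyr::group_by(.data$gene_symbol) |>
    dplyr::summarise(mirnas = list(sort(unique(.data$mirna_id))),
                     .groups = "drop")
  structure(
    list(
      overlap = overlap,
      dem_targets = dem_targets,
      deg_union = deg_union,
      venn = c(targets_only = length(setdiff(dem_targets, deg_agg)),
               overlap = length(overlap),
               degs_only = length(setdiff(deg_agg, dem_targets))),
      per_study = per_study,
      backmap = backmap,
      aggregate = aggregate
    ),
    class = "intersection_report"
  )
}

#' @export
print.intersection_report <- function(x, ...) {
  cat(sprintf(
    "<intersection_report> %d DEM targets | %d DEGs (%s) | overlap: %d genes\n",
    length(x$dem_targets), length(x$deg_union), x$aggregate,
    length(x$overlap)))
  invisible(x)
}

#' @export
tidy.intersection_report <- function(x, ...) {
  dplyr::left_join(
    tibble::tibble(gene_symbol = x$overlap),
    x$backmap, by = "gene_symbol"
  )
}
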