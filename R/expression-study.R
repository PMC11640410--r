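#' Two-group expression study container
#'
#' Bundles a feature-by-sample expression matrix with its group labels
#' (`resistant` vs `control`), platform label, log-scale flag and a
#' missingness mask. This is the unit every per-study operation
#' ([log2_transform()], [impute_missing()], [fit_two_group()]) consumes.
#'
#' @param values Numeric matrix, features in rows, samples in columns.
#'   Missing entries are `NA`.
#' @param groups Either a named character vector (names = sample ids) or a
#'   data frame with columns `sample_id` and `group`; groups must be
#'   `"resistant"` or `"control"`.
#' @param platform Free-text platform label.
#' @param log_scale Logical; `TRUE` when `values` are already on the log2
#'   scale.
#'
#' @return An object of class `expression_study`: a list with elements
#'   `values` (matrix, `NA` where missing), `missing_mask` (logical matrix),
#'   `groups` (named character vector aligned to columns), `platform`,
#'   `log_scale`.
#'
#' @details Invariants enforced at construction: unique feature and sample
#'   ids, every sample labelled, at least two samples per group, no feature
#'   entirely missing.
#'
#' @examples
#' m <- matrix(rnorm(20), 5, 4,
#'             dimnames = list(paste0("hsa-miR-", 1:5, "-5p"),
#'                             paste0("s", 1:4)))
#' st <- expression_study(m, c(s1 = "resistant", s2 = "resistant",
#'                             s3 = "control", s4 = "control"))
#' st
#' @export
expression_study <- function(values, groups, platform = "synthetic",
                             log_scale = TRUE) {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have feature rownames and sample colnames",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicated feature ids", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicated sample ids", call. = FALSE)
  }
  if (is.data.frame(groups)) {
    if (!all(c("sample_id", "group") %in% names(groups))) {
      stop("`groups` data frame needs columns `sample_id` and `group`",
           call. = FALSE)
    }
    groups <- stats::setNames(as.character(groups$group),
                              as.character(groups$sample_id))
  }
  missing_samples <- setdiff(colnames(values), names(groups))
  if (length(missing_samples) > 0) {
    stop("samples without a group label: ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  }
  groups <- groups[colnames(values)]
  bad <- setdiff(unique(groups), c("resistant", "control"))
  if (length(bad) > 0) {
    stop("groups must be 'resistant' or 'control', got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(table(factor(groups, c("resistant", "control"))) < 2)) {
    stop("each group needs at least 2 samples", call. = FALSE)
  }
  mask <- is.na(values)
  if (any(rowSums(!mask) == 0)) {
    stop("feature(s) entirely missing: ",
         paste(utils::head(rownames(values)[rowSums(!mask) == 0], 5),
               collapse = ", "), call. = FALSE)
  }
  structure(
    list(values = values, missing_mask = mask, groups = groups,
         platform = platform, log_scale = isTRUE(log_scale)),
    class = "expression_study"
  )
}

#' @export
print.expression_study <- function(x, ...) {
  cat(sprintf(
    "<expression_study> %d features x %d samples (%d resistant / %d control)\n",
    nrow(x$values), ncol(x$values),
    sum(x$groups == "resistant"), sum(x$groups == "control")
  ))
  cat(sprintf("  platform: %s | log2 scale: %s | missing: %d cells (%.1f%%)\n",
              x$platform, x$log_scale, sum(x$missing_mask),
              100 * mean(x$missing_mask)))
  invisible(x)
}

#' Tidy an expression study into a long tibble
#'
#' @param x An [expression_study()].
#' @param ... Unused.
#' @return A tibble with columns `feature_id`, `sample_id`, `group`,
#'   `value`, `missing`.
#' @export
tidy.expression_study <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "feature_id") |>
    tidyr::pivot_longer(-"feature_id", names_to = "sample_id",
                        values_to = "value") |>
    dplyr::mutate(
      group = unname(x$groups[.data$sample_id]),
      missing = is.na(.data$value),
      .after = "sample_id"
    )
}

#' Read / write an expression study as TSV
#'
#' The matrix file has a `feature_id` first column and one column per
#' sample; the companion groups file has columns `sample_id` and `group`.
#' Missing cells are empty/NA fields.
#'
#' @param path,groups_path Paths for the matrix and group-label TSVs.
#' @param study An [expression_study()] (for writing).
#' @param platform,log_scale Metadata not stored in the TSVs.
#' @return `read_expression_study()` returns an [expression_study()];
#'   `write_expression_study()` returns `study` invisibly.
#' @export
read_expression_study <- function(path, groups_path, platform = "file",
                                  log_scale = TRUE) {
  mat_df <- readr::read_tsv(path, show_col_types = FALSE)
  grp_df <- readr::read_tsv(groups_path, show_col_types = FALSE)
  values <- as.matrix(mat_df[, -1, drop = FALSE])
  rownames(values) <- mat_df[[1]]
  expression_study(values, grp_df, platform = platform,
                   log_scale = log_scale)
}

#' @rdname read_expression_study
#' @export
write_expression_study <- function(study, path, groups_path) {
  tibble::as_tibble(study$values, rownames = "feature_id") |>
    readr::write_tsv(path)
  tibble::tibble(sample_id = names(study$groups),
                 group = unname(study$groups)) |>
    readr::write_tsv(groups_path)
  invisible(study)
}
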