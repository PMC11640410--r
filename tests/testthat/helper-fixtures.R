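# Small deterministic fixtures shared across tests.

make_study <- function(values, n1 = NULL, n2 = NULL, log_scale = TRUE,
                       feature_ids = NULL) {
  if (!is.matrix(values)) values <- matrix(values, nrow = 1)
  n <- ncol(values)
  n1 <- n1 %||% (n %/% 2)
  n2 <- n2 %||% (n - n1)
  rownames(values) <- feature_ids %||% sprintf("hsa-miR-%d-5p", seq_len(nrow(values)))
  colnames(values) <- sprintf("s%02d", seq_len(n))
  groups <- stats::setNames(rep(c("resistant", "control"), c(n1, n2)),
                            colnames(values))
  expression_study(values, groups, log_scale = log_scale)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

random_study <- function(n_feat, n1, n2, seed, effect = NULL, sd = 1) {
  set.seed(seed)
  m <- matrix(rnorm(n_feat * (n1 + n2), mean = 8, sd = sd), n_feat, n1 + n2)
  if (!is.null(effect)) m[seq_along(effect), seq_len(n1)] <-
      m[seq_along(effect), seq_len(n1)] + effect
  make_study(m, n1 = n1, n2 = n2)
}

# brute-force upper-tail hypergeometric by enumerating all n-subsets
enum_hyper_p <- function(N, K, n, k) {
  hits <- utils::combn(N, n, function(idx) sum(idx <= K) >= k)
  mean(hits)
}
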