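# Independent oracles and small fixture builders shared across test files.

# adjusted Rand index between two labelings
ari <- function(a, b) {
  igraph::compare(as.integer(factor(a)), as.integer(factor(b)),
                  method = "adjusted.rand")
}

# dense matrix -> named sparse "normalized" matrix; existing dimnames win
as_norm <- function(m, genes = NULL, cells = NULL) {
  genes <- genes %||% rownames(m) %||% sprintf("g%02d", seq_len(nrow(m)))
  cells <- cells %||% colnames(m) %||% sprintf("c%02d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, cells)
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# brute-force rank-AUC oracle: ranks by explicit pairwise comparison
# (ties contribute 0.5), truncated at rank_max, then the U-statistic.
brute_rank_auc <- function(x, sig_idx, rank_max) {
  n_genes <- length(x)
  ranks <- vapply(seq_len(n_genes), function(i) {
    1 + sum(x > x[i]) + 0.5 * (sum(x == x[i]) - 1)
  }, numeric(1))
  if (all(ranks[sig_idx] > rank_max)) return(0)
  ranks[ranks > rank_max] <- rank_max + 1
  n <- length(sig_idx)
  u <- sum(ranks[sig_idx]) - n * (n + 1) / 2
  max(0, 1 - u / (n * rank_max))
}

# all distinct assignments of a label multiset to positions
all_labelings <- function(labels) {
  uniq <- unique(labels)
  if (length(labels) == 1) return(list(labels))
  out <- list()
  for (u in uniq) {
    rest <- labels[-match(u, labels)]
    for (sub in all_labelings(rest)) out <- c(out, list(c(u, sub)))
  }
  unique(out)
}

# a small quantile oracle: type-7 linear interpolation, written out
q_type7 <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  x[lo] + (h - lo) * (x[min(lo + 1, length(x))] - x[lo])
}

# compact simulation used by several files (seconds, not minutes)
small_sim <- function(seed = 1, ...) {
  simulate_counts(design = sim_design(n_epithelial = 60, n_per_immune_leaf = 6),
                  seed = seed, ...)
}
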