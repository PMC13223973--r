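#' Per-cell quality-control metrics
#'
#' @param counts Genes x cells count matrix.
#' @param genes Gene table with `symbol` and `is_mito` columns, rows
#'   matching the matrix rows.
#' @return Tibble: `cell_id`, `total_counts`, `n_features`, `pct_mito`
#'   (fraction in `[0, 1]`, computed on raw counts).
#' @export
qc_metrics <- function(counts, genes) {
  stopifnot(nrow(counts) == nrow(genes))
  total <- Matrix::colSums(counts)
  mito_total <- Matrix::colSums(counts[genes$is_mito, , drop = FALSE])
  tibble(
    cell_id = colnames(counts),
    total_counts = as.numeric(total),
    n_features = as.integer(Matrix::colSums(counts > 0)),
    pct_mito = as.numeric(ifelse(total > 0, mito_total / total, 0))
  )
}

#' Filter cells on mitochondrial fraction and feature count
#'
#' Removes cells with *more than* `max_pct_mito` mitochondrial fraction
#' (dying cells) or *more than* `max_features` detected genes (doublets).
#' Both inequalities are strict: boundary cells are retained.
#'
#' @param counts Genes x cells count matrix.
#' @param genes Gene table (see [qc_metrics()]).
#' @param cells Optional per-cell metadata tibble with `cell_id` (and
#'   `sample_id` for the per-sample report); joined onto the QC columns.
#' @param max_pct_mito Mitochondrial-fraction cap (default 0.20).
#' @param max_features Detected-feature cap (default 5000).
#' @return List: `counts` (filtered), `cells` (metadata + QC columns +
#'   `qc_pass`/`qc_reason` for all input cells), `report` (removals per
#'   rule and per sample).
#' @export
qc_filter <- function(counts, genes, cells = NULL,
                      max_pct_mito = 0.20, max_features = 5000) {
  stopifnot(max_pct_mito > 0, max_pct_mito < 1, max_features > 0)
  qc <- qc_metrics(counts, genes)
  if (!is.null(cells)) qc <- left_join(qc, cells, by = "cell_id")
  if (!"sample_id" %in% names(qc)) qc$sample_id <- "sample_1"
  high_mito <- qc$pct_mito > max_pct_mito
  doublet <- qc$n_features > max_features
  qc$qc_pass <- !(high_mito | doublet)
  qc$qc_reason <- dplyr::case_when(
    high_mito & doublet ~ "high_mito+doublet",
    high_mito ~ "high_mito",
    doublet ~ "doublet",
    TRUE ~ "pass"
  )
  if (!any(qc$qc_pass)) abort("no cells survive QC filtering")
  report <- qc |>
    filter(!.data$qc_pass) |>
    count(.data$sample_id, .data$qc_reason, name = "n_removed")
  list(counts = counts[, qc$qc_pass, drop = FALSE], cells = qc, report = report)
}

#' Library-size log-normalization
#'
#' `value = ln(1 + scale * count / cell_total)`; all-zero cells map to
#' all-zero vectors. Sparsity is preserved (zero counts stay zero).
#'
#' @param counts Genes x cells count matrix.
#' @param scale Target library size (default 1e4).
#' @return Sparse normalized matrix of the same shape.
#' @export
lognormalize <- function(counts, scale = 1e4) {
  m <- methods::as(counts, "CsparseMatrix")
  totals <- Matrix::colSums(m)
  totals[totals == 0] <- 1  # all-zero cells have no non-zero entries to scale
  col_of <- rep.int(seq_len(ncol(m)), diff(m@p))
  m@x <- log1p(scale * m@x / totals[col_of])
  m
}

#' Graph-based clustering of normalized expression
#'
#' PCA (up to `n_pcs` components) on the cell x gene normalized matrix,
#' a k-nearest-neighbor graph on the PC scores, and Leiden community
#' detection. Deterministic given `seed`.
#'
#' @param norm Genes x cells normalized matrix.
#' @param n_neighbors Neighbors per cell (default 15).
#' @param resolution Leiden resolution (default 1).
#' @param n_pcs Maximum principal components (default 50).
#' @param seed Integer seed.
#' @return Integer cluster labels `0..K-1`, named by cell, relabeled by
#'   first occurrence.
#' @export
cluster_cells <- function(norm, n_neighbors = 15, resolution = 1,
                          n_pcs = 50, seed = 1) {
  n <- ncol(norm)
  if (n < 2) abort("clustering requires at least 2 cells")
  if (n_neighbors >= n) abort("n_neighbors must be smaller than the number of cells")
  x <- t(as.matrix(norm))
  keep <- apply(x, 2, var) > 0
  if (!any(keep)) {
    # identical cells: a single cluster
    return(setNames(rep(0L, n), colnames(norm)))
  }
  rank <- min(n_pcs, sum(keep), n - 1)
  pcs <- prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = FALSE,
                rank. = rank)$x
  d <- as.matrix(dist(pcs))
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    nn <- order(d[i, ])[2:(n_neighbors + 1)]
    cbind(i, nn)
  }))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  set.seed(seed)
  comm <- igraph::cluster_leiden(g, objective_function = "modularity",
                                 resolution = resolution, n_iterations = 5)
  memb <- igraph::membership(comm)
  labels <- as.integer(factor(memb, levels = unique(memb))) - 1L
  setNames(labels, colnames(norm))
}
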