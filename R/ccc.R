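#' Tukey's trimean
#'
#' `(Q1 + 2 * median + Q3) / 4` with type-7 (linear interpolation)
#' quartiles — the robust per-group expression summary used for
#' communication scoring.
#'
#' @param x Non-empty numeric vector.
#' @return Scalar trimean.
#' @export
trimean <- function(x) {
  if (!length(x) || all(is.na(x))) abort("trimean needs a non-empty vector")
  q <- quantile(x, c(0.25, 0.5, 0.75), type = 7, na.rm = TRUE)
  unname((q[1] + 2 * q[2] + q[3]) / 4)
}

geom_mean <- function(x) exp(mean(log(x)))

group_gene_trimeans <- function(norm, groups, genes_needed) {
  genes_needed <- intersect(genes_needed, rownames(norm))
  x <- as.matrix(norm[genes_needed, , drop = FALSE])
  vapply(groups, function(cells) {
    apply(x[, cells, drop = FALSE], 1, trimean)
  }, numeric(length(genes_needed))) |>
    matrix(nrow = length(genes_needed),
           dimnames = list(genes_needed, names(groups)))
}

ccc_prob_matrix <- function(tm, lr, group_names, kh) {
  # per LR pair, an ordered source x target probability matrix
  lapply(seq_len(nrow(lr)), function(i) {
    lig <- lr$ligand_subunits[[i]]; rec <- lr$receptor_subunits[[i]]
    l_vec <- apply(tm[lig, , drop = FALSE], 2, geom_mean)
    r_vec <- apply(tm[rec, , drop = FALSE], 2, geom_mean)
    lrprod <- outer(l_vec, r_vec)
    lrprod / (kh + lrprod)
  })
}

#' Ligand-receptor communication probability between cell groups
#'
#' For each ordered (source, target) group pair and each ligand-receptor
#' pair: L is the geometric mean of ligand-subunit trimeans in the source
#' group, R likewise for the receptor in the target group, and the
#' probability is the saturating `P = L*R / (Kh + L*R)`. Groups with fewer
#' than `min_cells` cells are excluded entirely; pairs with any subunit
#' absent from the matrix are skipped with a warning.
#'
#' @param norm Genes x cells normalized matrix.
#' @param labels Tibble with `cell_id`, `group`.
#' @param lr Ligand-receptor table from [lr_pairs()] / [read_lr_pairs()].
#' @param min_cells Minimum group size (default 10).
#' @param kh Saturation constant (default 0.5).
#' @return Tibble: `source`, `target`, `ligand`, `receptor`, `pathway`,
#'   `prob` in `[0, 1)`.
#' @export
communication_probability <- function(norm, labels, lr, min_cells = 10, kh = 0.5) {
  stopifnot(min_cells >= 1, kh > 0)
  groups <- split(labels$cell_id, labels$group)
  groups <- groups[lengths(groups) >= min_cells]
  if (!length(groups)) abort("no group reaches min_cells")
  present <- vapply(seq_len(nrow(lr)), function(i) {
    all(c(lr$ligand_subunits[[i]], lr$receptor_subunits[[i]]) %in% rownames(norm))
  }, logical(1))
  if (any(!present)) {
    warn(sprintf("%d LR pair(s) skipped: subunit(s) absent from matrix", sum(!present)))
  }
  lr <- lr[present, , drop = FALSE]
  if (!nrow(lr)) abort("no LR pair has all subunits in the matrix")
  all_genes <- unique(unlist(c(lr$ligand_subunits, lr$receptor_subunits)))
  tm <- group_gene_trimeans(norm, groups, all_genes)
  probs <- ccc_prob_matrix(tm, lr, names(groups), kh)
  grid <- tidyr::expand_grid(source = names(groups), target = names(groups))
  out <- purrr::map_dfr(seq_len(nrow(lr)), function(i) {
    mutate(grid, ligand = lr$ligand[i], receptor = lr$receptor[i],
           pathway = lr$pathway[i],
           prob = probs[[i]][cbind(.data$source, .data$target)])
  })
  out
}

#' Permutation significance of communication probabilities
#'
#' Group labels are permuted across cells `n_permutations` times (group
#' sizes preserved) and each observed probability is compared with its
#' permutation null: `p = (1 + #{perm >= obs}) / (1 + n_permutations)`.
#' An observed probability of 0 yields p = 1.
#'
#' @inheritParams communication_probability
#' @param n_permutations Number of label permutations (default 100).
#' @param seed Integer seed.
#' @return Tibble of class `ccc_result`: the
#'   [communication_probability()] columns plus `p_value`.
#' @export
permutation_significance <- function(norm, labels, lr, min_cells = 10,
                                     kh = 0.5, n_permutations = 100, seed = 1) {
  stopifnot(n_permutations >= 1)
  observed <- communication_probability(norm, labels, lr, min_cells, kh)
  set.seed(seed)
  exceed <- numeric(nrow(observed))
  for (b in seq_len(n_permutations)) {
    perm <- labels
    perm$group <- sample(perm$group)
    pb <- suppressWarnings(
      communication_probability(norm, perm, lr, min_cells, kh))
    # identical row order: same lr table, same group name set
    exceed <- exceed + (pb$prob >= observed$prob)
  }
  observed$p_value <- (1 + exceed) / (1 + n_permutations)
  observed$p_value[observed$prob == 0] <- 1
  class(observed) <- c("ccc_result", class(observed))
  observed
}

#' @export
glance.ccc_result <- function(x, ...) {
  tibble(n_pairs = dplyr::n_distinct(x$ligand, x$receptor),
         n_groups = dplyr::n_distinct(x$source),
         n_significant = sum(x$p_value <= 0.05 & x$prob > 0))
}

#' Aggregate communication probabilities per signaling pathway
#'
#' Sum of member-pair probabilities per (source, target, pathway), the
#' summary behind chord-diagram style displays.
#'
#' @param result Tibble from [communication_probability()] or
#'   [permutation_significance()].
#' @return Tibble: `source`, `target`, `pathway`, `prob`.
#' @export
pathway_probability <- function(result) {
  result |>
    group_by(.data$source, .data$target, .data$pathway) |>
    summarise(prob = sum(.data$prob), .groups = "drop")
}
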