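validate_gating_tree <- function(tree) {
  stopifnot(all(c("label", "parent", "signature") %in% names(tree)))
  if (anyDuplicated(tree$label)) abort("gating tree labels must be unique")
  bad_parent <- setdiff(tree$parent[!is.na(tree$parent)], tree$label)
  if (length(bad_parent)) abort(paste0("unknown parent label(s): ", paste(bad_parent, collapse = ", ")))
  # acyclicity: walking up from every node must terminate
  for (lab in tree$label) {
    seen <- character()
    cur <- lab
    while (!is.na(cur)) {
      if (cur %in% seen) abort("gating tree contains a cycle")
      seen <- c(seen, cur)
      cur <- tree$parent[match(cur, tree$label)]
    }
  }
  invisible(tree)
}

#' Progressive signature-based annotation
#'
#' Cells descend a gating tree level by level: at each node, a cell takes
#' the child label with the maximal signature score among children scoring
#' strictly above `threshold`; if no child scores above it the cell is
#' `"unclassified"` at that level and does not descend further. Ties are
#' broken by tree declaration order (deterministically, with a reported
#' tie count).
#'
#' @param scores Tibble with `cell_id` and one column per signature named
#'   in the tree.
#' @param tree Gating tree tibble (`label`, `parent`, `signature`); see
#'   [default_gating_tree()].
#' @param threshold Score a child must strictly exceed (default 0).
#' @return Tibble: `cell_id`, one `level<k>` column per tree depth, and
#'   `leaf` (deepest assigned label, `"unclassified"` if none).
#' @export
progressive_annotate <- function(scores, tree, threshold = 0) {
  validate_gating_tree(tree)
  missing <- setdiff(tree$signature, names(scores))
  if (length(missing)) {
    abort(paste0("missing score column(s): ", paste(missing, collapse = ", ")))
  }
  n <- nrow(scores)
  score_mat <- as.matrix(scores[, tree$signature, drop = FALSE])
  colnames(score_mat) <- tree$label

  out <- tibble(cell_id = scores$cell_id)
  current <- rep(NA_character_, n)  # NA = at root
  active <- rep(TRUE, n)
  level <- 0L
  n_ties <- 0L
  repeat {
    level <- level + 1L
    assigned <- rep(NA_character_, n)
    any_children <- FALSE
    for (parent in unique(current[active])) {
      children <- if (is.na(parent)) tree$label[is.na(tree$parent)] else tree$label[tree$parent %in% parent]
      if (!length(children)) next
      any_children <- TRUE
      rows <- which(active & (is.na(current) == is.na(parent)) &
                      (is.na(parent) | current == parent))
      s <- score_mat[rows, children, drop = FALSE]
      pos <- s > threshold
      best <- apply(s, 1, function(v) {
        ok <- which(v > threshold)
        if (!length(ok)) return(NA_integer_)
        ok[which.max(v[ok])]  # first max in declaration order
      })
      n_ties <- n_ties + sum(apply(s, 1, function(v) {
        ok <- v > threshold
        sum(ok & v == max(v[ok], -Inf)) > 1
      }), na.rm = TRUE)
      assigned[rows] <- ifelse(is.na(best), "unclassified", children[best])
    }
    if (!any_children) break
    out[[paste0("level", level)]] <- assigned
    stop_here <- !is.na(assigned) & assigned == "unclassified"
    active <- active & !is.na(assigned) & !stop_here
    current[active] <- assigned[active]
    # cells whose label has no children stop descending silently
    has_children <- vapply(current, function(l) !is.na(l) && any(tree$parent %in% l), logical(1))
    active <- active & has_children
    if (!any(active)) break
  }
  if (n_ties > 0) inform(sprintf("%d score tie(s) broken by tree declaration order", n_ties))
  level_cols <- grep("^level", names(out), value = TRUE)
  out$leaf <- apply(out[level_cols], 1, function(r) {
    r <- r[!is.na(r) & r != "unclassified"]
    if (length(r)) tail(r, 1) else "unclassified"
  })
  out
}

#' Activation-state call from two signatures
#'
#' A cell is activated when the larger of its two activation-signature
#' scores strictly exceeds `threshold` (default 0).
#'
#' @param scores Tibble with `cell_id` and the two score columns.
#' @param signature_1,signature_2 Score column names.
#' @param threshold Activation cutoff (default 0).
#' @param cell_ids Optional subset of cells to call.
#' @return Tibble: `cell_id`, `activated` (logical).
#' @export
activation_state <- function(scores, signature_1, signature_2,
                             threshold = 0, cell_ids = NULL) {
  missing <- setdiff(c(signature_1, signature_2), names(scores))
  if (length(missing)) abort(paste0("missing score column(s): ", paste(missing, collapse = ", ")))
  if (!is.null(cell_ids)) scores <- filter(scores, .data$cell_id %in% cell_ids)
  tibble(cell_id = scores$cell_id,
         activated = pmax(scores[[signature_1]], scores[[signature_2]]) > threshold)
}

#' Summarize activated fractions per subset and condition
#'
#' @param annotation Tibble with `cell_id` and grouping columns.
#' @param activation Tibble from [activation_state()].
#' @param ... Grouping columns (tidy-select), e.g. `leaf, condition`.
#' @return Tibble with group columns, `n`, `n_activated`, `frac_activated`.
#' @export
activation_summary <- function(annotation, activation, ...) {
  annotation |>
    inner_join(activation, by = "cell_id") |>
    group_by(...) |>
    summarise(n = dplyr::n(), n_activated = sum(.data$activated),
              frac_activated = mean(.data$activated), .groups = "drop")
}

#' Pearson chi-squared test of proportions
#'
#' Classic 2 x K (or R x K) chi-squared test without continuity
#' correction, used to compare cell-subset composition between conditions.
#'
#' @param tab Integer matrix or table with at least 2 rows and 2 columns.
#' @return One-row tibble: `statistic`, `df`, `p_value`.
#' @export
proportion_test <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2) abort("need at least a 2x2 table")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("table has a zero marginal row or column")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected <= 0)) abort("all expected counts must be positive")
  res <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble(statistic = unname(res$statistic), df = unname(res$parameter),
         p_value = res$p.value)
}
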