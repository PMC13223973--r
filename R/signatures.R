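match_signature_genes <- function(norm, signature_genes) {
  sig <- unique(trimws(signature_genes))
  found <- intersect(sig, rownames(norm))
  if (!length(found)) {
    abort(paste0("no signature gene found in matrix; missing: ",
                 paste(sig, collapse = ", ")))
  }
  n_missing <- length(sig) - length(found)
  if (n_missing > 0) {
    inform(sprintf("%d of %d signature gene(s) not in matrix; dropped", n_missing, length(sig)))
  }
  found
}

#' Sum-ratio signature score
#'
#' For each cell, 100 times the normalized expression summed over the
#' signature divided by the cell's total normalized expression. Cells with
#' zero total expression score 0. Invariant to rescaling a cell's vector.
#'
#' @param norm Genes x cells normalized matrix.
#' @param signature_genes Character vector of gene symbols (matched
#'   case-sensitively after whitespace stripping; unmatched genes dropped
#'   with a message).
#' @return Named numeric vector of per-cell scores in `[0, 100]`.
#' @export
score_sum_ratio <- function(norm, signature_genes) {
  found <- match_signature_genes(norm, signature_genes)
  total <- Matrix::colSums(norm)
  sig_sum <- Matrix::colSums(norm[found, , drop = FALSE])
  score <- ifelse(total > 0, 100 * sig_sum / total, 0)
  setNames(as.numeric(score), colnames(norm))
}

#' Rank-based AUC signature score
#'
#' Per cell, genes are ranked by decreasing expression (ties get average
#' rank) and ranks beyond `rank_max` are truncated to `rank_max + 1`. With
#' n signature genes, `U' = sum(ranks in signature) - n(n+1)/2` and the
#' score is `1 - U' / (n * rank_max)`, floored at 0 — a Mann-Whitney-style
#' statistic in `[0, 1]` that depends only on within-cell ranks. A cell
#' where every signature gene ranks beyond `rank_max` scores exactly 0
#' (the truncated formula alone would leave a residue of
#' `(n - 1) / (2 rank_max)`).
#'
#' @inheritParams score_sum_ratio
#' @param rank_max Rank truncation point (default 1500).
#' @return Named numeric vector of per-cell scores in `[0, 1]`.
#' @export
score_rank_auc <- function(norm, signature_genes, rank_max = 1500) {
  stopifnot(rank_max >= 1)
  found <- match_signature_genes(norm, signature_genes)
  x <- as.matrix(norm)
  sig_idx <- match(found, rownames(norm))
  n_sig <- length(sig_idx)
  scores <- vapply(seq_len(ncol(x)), function(c_i) {
    r <- rank(-x[, c_i], ties.method = "average")
    if (all(r[sig_idx] > rank_max)) return(0)  # no signature gene in range
    r[r > rank_max] <- rank_max + 1
    u <- sum(r[sig_idx]) - n_sig * (n_sig + 1) / 2
    max(0, 1 - u / (n_sig * rank_max))
  }, numeric(1))
  setNames(scores, colnames(x))
}

#' Score a list of signatures into a cell table
#'
#' @inheritParams score_sum_ratio
#' @param signatures Named list of gene vectors (e.g. from [read_gmt()]).
#' @param method `"sum_ratio"` or `"rank_auc"`.
#' @param rank_max Passed to [score_rank_auc()].
#' @return Tibble: `cell_id` plus one score column per signature.
#' @export
score_signatures <- function(norm, signatures, method = c("sum_ratio", "rank_auc"),
                             rank_max = 1500) {
  method <- match.arg(method)
  stopifnot(length(signatures) > 0, !is.null(names(signatures)))
  out <- tibble(cell_id = colnames(norm))
  for (nm in names(signatures)) {
    out[[nm]] <- switch(method,
      sum_ratio = score_sum_ratio(norm, signatures[[nm]]),
      rank_auc = score_rank_auc(norm, signatures[[nm]], rank_max = rank_max)
    )
  }
  out
}

#' Gene prevalence within a cell subset
#'
#' Fraction of subset cells in which a gene is detected (raw count > 0).
#'
#' @param counts Genes x cells count matrix.
#' @param cell_ids Non-empty character vector of subset cells.
#' @return Tibble: `gene`, `prevalence` in `[0, 1]`.
#' @export
gene_prevalence <- function(counts, cell_ids) {
  if (!length(cell_ids)) abort("cell subset is empty")
  missing <- setdiff(cell_ids, colnames(counts))
  if (length(missing)) abort(paste0("unknown cell id(s): ", paste(head(missing, 3), collapse = ", ")))
  sub <- counts[, cell_ids, drop = FALSE]
  tibble(gene = rownames(counts),
         prevalence = as.numeric(Matrix::rowSums(sub > 0)) / length(cell_ids))
}

#' Distill a reference signature by differential expression and prevalence
#'
#' Intersects a reference gene list with the significant, strongly
#' up-regulated genes of a DEG table and keeps those detected in at least
#' `min_prevalence` of the tumor cells — the procedure that reduces a
#' published bulk signature to a compact single-cell signature.
#'
#' @param reference_genes Character vector (the published signature).
#' @param deg_table Tibble from [differential_expression()].
#' @param prevalence Tibble from [gene_prevalence()] computed on malignant
#'   cells.
#' @param min_prevalence Inclusive prevalence cutoff (default 0.40).
#' @param log2fc_threshold DEG membership requires `log2fc >` this
#'   (default 1).
#' @param adj_p_threshold Optional adjusted-p cutoff; `NULL` (default)
#'   disables the p filter, matching a fold-change-only DEG definition.
#' @return Tibble: `gene`, `log2fc`, `prevalence` (possibly empty, with a
#'   warning).
#' @export
distill_signature <- function(reference_genes, deg_table, prevalence,
                              min_prevalence = 0.40, log2fc_threshold = 1,
                              adj_p_threshold = NULL) {
  stopifnot(min_prevalence > 0, min_prevalence <= 1)
  degs <- filter(deg_table, .data$log2fc > log2fc_threshold)
  if (!is.null(adj_p_threshold)) degs <- filter(degs, .data$adj_p < adj_p_threshold)
  out <- degs |>
    filter(.data$gene %in% reference_genes) |>
    inner_join(prevalence, by = "gene") |>
    filter(.data$prevalence >= min_prevalence) |>
    select("gene", "log2fc", "prevalence")
  if (!nrow(out)) warn("distilled signature is empty")
  out
}
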