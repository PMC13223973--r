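#' Wilcoxon differential expression between two cell groups
#'
#' Per gene: two-sided Wilcoxon rank-sum p on normalized values (normal
#' approximation), Benjamini-Hochberg adjusted p, and
#' `log2fc = log2((mean(expm1(x_A)) + 1) / (mean(expm1(x_B)) + 1))` —
#' fold change on de-logged means with pseudocount 1.
#'
#' @param norm Genes x cells normalized matrix.
#' @param cells_a,cells_b Disjoint cell-id vectors (each of length >= 3).
#' @return Tibble: `gene`, `log2fc`, `p`, `adj_p`, `pct_a`, `pct_b`
#'   (fraction of expressing cells per group).
#' @export
differential_expression <- function(norm, cells_a, cells_b) {
  if (length(intersect(cells_a, cells_b))) abort("cell groups overlap")
  if (length(cells_a) < 3 || length(cells_b) < 3) abort("each group needs >= 3 cells")
  a <- as.matrix(norm[, cells_a, drop = FALSE])
  b <- as.matrix(norm[, cells_b, drop = FALSE])
  n_genes <- nrow(norm)
  p <- vapply(seq_len(n_genes), function(g) {
    xa <- a[g, ]; xb <- b[g, ]
    if (max(xa, xb) == min(xa, xb)) return(1)  # constant gene: no evidence
    suppressWarnings(wilcox.test(xa, xb, exact = FALSE)$p.value)
  }, numeric(1))
  log2fc <- log2((rowMeans(expm1(a)) + 1) / (rowMeans(expm1(b)) + 1))
  tibble(
    gene = rownames(norm),
    log2fc = as.numeric(log2fc),
    p = p,
    adj_p = p.adjust(p, method = "BH"),
    pct_a = rowMeans(a > 0),
    pct_b = rowMeans(b > 0)
  )
}

#' Quartile-gated malignancy classifier
#'
#' The gate threshold is the third quartile (type-7 linear-interpolation
#' quantile) of the control-condition score distribution. Tumor-condition
#' cells are called malignant only if their score strictly exceeds the
#' threshold; tumor cells at or below it, and control cells above it, are
#' excluded from downstream analysis.
#'
#' @param scores Tibble with `cell_id`, `condition`, `score`.
#' @param tumor,control Condition labels (defaults `"AC"`, `"AV"`).
#' @param probs Quantile defining the gate (default 0.75).
#' @return An object of class `malignancy_gate`: the threshold and a
#'   per-cell call table (`call` in malignant / non_malignant / excluded,
#'   with `excluded_reason`).
#' @export
malignancy_gate <- function(scores, tumor = "AC", control = "AV", probs = 0.75) {
  stopifnot(all(c("cell_id", "condition", "score") %in% names(scores)))
  conds <- unique(scores$condition)
  if (!all(c(tumor, control) %in% conds)) abort("both conditions must be present")
  ctrl_scores <- scores$score[scores$condition == control]
  if (length(ctrl_scores) < 4) warn("fewer than 4 control cells: quantile is unstable")
  threshold <- unname(quantile(ctrl_scores, probs = probs, type = 7))
  calls <- scores |>
    mutate(
      call = dplyr::case_when(
        .data$condition == tumor & .data$score > threshold ~ "malignant",
        .data$condition == control & .data$score <= threshold ~ "non_malignant",
        TRUE ~ "excluded"
      ),
      excluded_reason = dplyr::case_when(
        .data$call != "excluded" ~ NA_character_,
        .data$condition == tumor ~ "tumor_below_gate",
        TRUE ~ "control_above_gate"
      )
    )
  structure(list(threshold = threshold, calls = calls,
                 tumor = tumor, control = control, probs = probs),
            class = "malignancy_gate")
}

#' @method print malignancy_gate
#' @export
print.malignancy_gate <- function(x, ...) {
  cat("Malignancy gate (Q", x$probs * 100, " of ", x$control, " scores)\n", sep = "")
  cat("  threshold:", format(x$threshold, digits = 6), "\n")
  print(count(x$calls, .data$call, .data$excluded_reason))
  invisible(x)
}

#' @export
tidy.malignancy_gate <- function(x, ...) x$calls

#' @export
glance.malignancy_gate <- function(x, ...) {
  tibble(
    threshold = x$threshold,
    n_malignant = sum(x$calls$call == "malignant"),
    n_non_malignant = sum(x$calls$call == "non_malignant"),
    n_excluded_tumor = sum(x$calls$excluded_reason %in% "tumor_below_gate"),
    n_excluded_control = sum(x$calls$excluded_reason %in% "control_above_gate")
  )
}

#' Reference-centered windowed copy-number inference
#'
#' Genes are ordered along the genome; each cell's normalized expression is
#' centered on the mean over reference (normal) cells, clipped to
#' `[-clip, clip]`, and smoothed by a centered moving average of
#' `window_size` genes within each chromosome. The per-cell burden is the
#' mean squared window score — elevated in cells carrying gains or losses.
#'
#' @param norm Genes x cells normalized matrix.
#' @param genes Gene table (`symbol`, `chromosome`, `start_position`)
#'   covering the matrix rows.
#' @param reference_cells At least 10 cell ids treated as copy-number
#'   normal.
#' @param window_size Genes per window (default 101).
#' @param clip Centering clip bound (default 3).
#' @return Object of class `cnv_profile`: `scores` (cells x windows),
#'   `windows` (map: chromosome, within-chromosome index range, flanking
#'   gene symbols), `burden` tibble, `reference_cells`.
#' @export
infer_cnv_windows <- function(norm, genes, reference_cells,
                              window_size = 101, clip = 3) {
  if (length(reference_cells) < 10) abort("need >= 10 reference cells")
  stopifnot(all(reference_cells %in% colnames(norm)))
  genes <- genes[match(rownames(norm), genes$symbol), ]
  if (anyNA(genes$symbol)) abort("gene table does not cover all matrix rows")
  if (any(is.na(genes$chromosome) | !nzchar(genes$chromosome))) {
    abort("all genes need a chromosome for CNV inference")
  }
  ord <- order(genes$chromosome, genes$start_position)
  x <- as.matrix(norm)[ord, , drop = FALSE]
  chrom <- genes$chromosome[ord]
  ref_mean <- rowMeans(x[, reference_cells, drop = FALSE])
  r <- pmin(pmax(x - ref_mean, -clip), clip)

  score_blocks <- list(); window_rows <- list()
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    m <- length(idx)
    if (m < window_size) {
      warn(sprintf("chromosome %s has %d genes (< window_size %d): skipped", ch, m, window_size))
      next
    }
    cs <- apply(r[idx, , drop = FALSE], 2, cumsum)
    padded <- rbind(0, cs)
    n_win <- m - window_size + 1
    w <- (padded[(window_size + 1):(m + 1), , drop = FALSE] -
            padded[1:n_win, , drop = FALSE]) / window_size
    score_blocks[[ch]] <- w
    window_rows[[ch]] <- tibble(
      chromosome = ch,
      start_index = seq_len(n_win),
      end_index = seq_len(n_win) + window_size - 1L,
      start_gene = rownames(r)[idx][seq_len(n_win)],
      end_gene = rownames(r)[idx][seq_len(n_win) + window_size - 1L]
    )
  }
  if (!length(score_blocks)) abort("no chromosome has enough genes for the window size")
  scores <- t(do.call(rbind, score_blocks))  # cells x windows
  windows <- bind_rows(window_rows)
  windows$window_id <- sprintf("%s_w%04d", windows$chromosome, windows$start_index)
  colnames(scores) <- windows$window_id
  burden <- tibble(cell_id = rownames(scores), burden = rowMeans(scores^2))
  structure(list(scores = scores, windows = windows, burden = burden,
                 reference_cells = reference_cells,
                 window_size = window_size, clip = clip),
            class = "cnv_profile")
}

#' @method print cnv_profile
#' @export
print.cnv_profile <- function(x, ...) {
  cat("CNV profile:", nrow(x$scores), "cells x", ncol(x$scores), "windows",
      "(window_size", x$window_size, ")\n")
  invisible(x)
}

#' @export
tidy.cnv_profile <- function(x, ...) x$burden

#' @export
glance.cnv_profile <- function(x, ...) {
  tibble(n_cells = nrow(x$scores), n_windows = ncol(x$scores),
         window_size = x$window_size, clip = x$clip,
         n_reference = length(x$reference_cells))
}

#' Concordance between the malignancy gate and CNV burden
#'
#' A cell is CNV-positive when its burden exceeds the `burden_quantile`
#' quantile of reference-cell burdens (so about `1 - burden_quantile` of
#' copy-number-normal cells are expected positive by construction).
#' Reports the gate-by-CNV confusion counts and the agreement fraction.
#'
#' @param gate A [malignancy_gate()] result.
#' @param profile A [infer_cnv_windows()] result covering the same cells.
#' @param burden_quantile Reference-burden quantile (default 0.95).
#' @return List of class `cnv_concordance`: `confusion` tibble, `agreement`
#'   over non-excluded cells, `burden_threshold`, `expected_reference_fpr`.
#' @export
cnv_concordance <- function(gate, profile, burden_quantile = 0.95) {
  ref_burden <- profile$burden$burden[profile$burden$cell_id %in% profile$reference_cells]
  burden_threshold <- unname(quantile(ref_burden, burden_quantile, type = 7))
  tab <- gate$calls |>
    inner_join(profile$burden, by = "cell_id") |>
    mutate(cnv_positive = .data$burden > burden_threshold)
  kept <- filter(tab, .data$call != "excluded")
  agreement <- if (nrow(kept)) {
    mean((kept$call == "malignant") == kept$cnv_positive)
  } else NA_real_
  confusion <- tab |>
    count(.data$call, .data$cnv_positive, name = "n") |>
    tidyr::complete(call = unique(tab$call), cnv_positive = c(TRUE, FALSE),
                    fill = list(n = 0L))
  structure(list(confusion = confusion, agreement = agreement,
                 burden_threshold = burden_threshold,
                 expected_reference_fpr = 1 - burden_quantile),
            class = "cnv_concordance")
}

#' @method print cnv_concordance
#' @export
print.cnv_concordance <- function(x, ...) {
  cat("Gate vs CNV-burden concordance\n")
  cat("  burden threshold:", format(x$burden_threshold, digits = 4),
      sprintf("(expected reference FPR %.0f%%)\n", 100 * x$expected_reference_fpr))
  cat("  agreement (non-excluded cells):", format(x$agreement, digits = 4), "\n")
  print(x$confusion)
  invisible(x)
}
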