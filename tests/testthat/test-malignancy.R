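test_that("differential expression handles degenerate and mirrored groups", {
  set.seed(2)
  m <- matrix(abs(rnorm(30 * 12)), 30, 12)
  m[5, ] <- 0                       # all-zero gene
  norm <- as_norm(m)
  a <- colnames(norm)[1:6]; b <- colnames(norm)[7:12]
  # identical groups: duplicate the same cells under new names
  dup <- cbind(m[, 1:6], m[, 1:6])
  norm_dup <- as_norm(dup, cells = sprintf("c%02d", 1:12))
  deg <- differential_expression(norm_dup, colnames(norm_dup)[1:6],
                                 colnames(norm_dup)[7:12])
  expect_true(all(deg$log2fc == 0))
  expect_true(all(deg$p == 1 | deg$p > 0.99))
  deg2 <- differential_expression(norm, a, b)
  expect_equal(deg2$log2fc[5], 0)
  expect_equal(deg2$p[5], 1)
  expect_true(all(deg2$adj_p >= deg2$p))
  expect_error(differential_expression(norm, a, c(a[1], b[1:2])), "overlap")
  expect_error(differential_expression(norm, a[1:2], b), ">= 3")
})

test_that("a planted 4-fold gene is recovered near log2FC = 2", {
  set.seed(31)
  n <- 500
  base_mu <- rep(5, 200)
  mk <- function(mu4) {
    sapply(seq_len(n), function(i) {
      mu <- base_mu; mu[7] <- mu4
      rnbinom(200, mu = mu, size = 2)
    })
  }
  counts <- cbind(mk(20), mk(5))
  counts <- as_norm(counts, genes = sprintf("g%03d", 1:200),
                    cells = sprintf("c%04d", 1:(2 * n)))
  norm <- lognormalize(counts)
  deg <- differential_expression(norm, colnames(norm)[1:n],
                                 colnames(norm)[(n + 1):(2 * n)])
  expect_lt(abs(deg$log2fc[7] - 2), 0.3)
  expect_lt(deg$adj_p[7], 0.05)
})

test_that("the malignancy gate applies the Q3 rule with strict boundaries", {
  # control scores whose Q3 is exactly the printed threshold 4.334
  scores <- tibble::tibble(
    cell_id = paste0("c", 1:8),
    condition = c(rep("AV", 5), rep("AC", 3)),
    score = c(0, 1, 2, 4.334, 5, 4.50, 4.334, 0.5)
  )
  gate <- malignancy_gate(scores)
  expect_equal(gate$threshold, 4.334)
  calls <- tidy(gate)
  expect_equal(calls$call[calls$cell_id == "c6"], "malignant")      # 4.50 > Q3
  expect_equal(calls$call[calls$cell_id == "c7"], "excluded")       # AC at Q3
  expect_equal(calls$call[calls$cell_id == "c4"], "non_malignant")  # AV at Q3
  expect_equal(calls$call[calls$cell_id == "c5"], "excluded")       # AV above
  # partition: every input cell gets exactly one call
  expect_equal(sum(table(calls$call)), nrow(scores))
})

test_that("the gate threshold matches a linear-interpolation quantile oracle", {
  scores <- tibble::tibble(
    cell_id = paste0("c", 1:5),
    condition = c("AV", "AV", "AV", "AV", "AC"),
    score = c(1, 2, 3, 4, 3.5)
  )
  expect_warning(gate <- malignancy_gate(scores), NA)
  expect_equal(gate$threshold, q_type7(c(1, 2, 3, 4), 0.75))  # 3.25
  expect_equal(gate$threshold, 3.25)
  expect_equal(tidy(gate)$call[5], "malignant")               # AC 3.5 > 3.25
  scores2 <- scores
  scores2$condition <- c("AC", "AC", "AV", "AV", "AV")
  expect_warning(malignancy_gate(scores2), "fewer than 4")
  expect_error(malignancy_gate(dplyr::filter(scores, condition == "AV")),
               "both conditions")
})

test_that("CNV windows reduce to clipped deviations at window_size 1 and
           match a brute-force moving average", {
  set.seed(6)
  genes <- tibble::tibble(symbol = sprintf("g%02d", 1:12),
                          chromosome = rep(c("chr1", "chr2"), each = 6),
                          start_position = rep(1:6, 2) * 100L)
  m <- matrix(abs(rnorm(12 * 25)), 12, 25)
  m[3, 1:5] <- m[3, 1:5] + 10      # one aberrant gene in query cells
  norm <- as_norm(m, genes = genes$symbol)
  ref <- colnames(norm)[11:25]
  prof1 <- infer_cnv_windows(norm, genes, ref, window_size = 1, clip = 3)
  ref_mean <- rowMeans(m[, 11:25])
  r_manual <- pmin(pmax(m - ref_mean, -3), 3)
  expect_equal(unname(prof1$scores[, "chr1_w0003"]), unname(r_manual[3, ]))

  prof3 <- infer_cnv_windows(norm, genes, ref, window_size = 3, clip = 3)
  # brute-force centered moving average over each chromosome block
  for (w in seq_len(nrow(prof3$windows))) {
    win <- prof3$windows[w, ]
    idx <- which(genes$chromosome == win$chromosome)[win$start_index:win$end_index]
    expect_equal(unname(prof3$scores[, win$window_id]),
                 unname(colMeans(r_manual[idx, , drop = FALSE])))
  }
  expect_equal(nrow(prof3$windows), 2 * (6 - 3 + 1))
})

test_that("CNV inference centers references, skips short chromosomes,
           and is invariant to gene-wise offsets", {
  set.seed(7)
  genes <- tibble::tibble(symbol = sprintf("g%02d", 1:20),
                          chromosome = c(rep("chr1", 17), rep("chr2", 3)),
                          start_position = c(1:17, 1:3) * 10L)
  m <- matrix(abs(rnorm(20 * 30)), 20, 30)
  norm <- as_norm(m, genes = genes$symbol)
  ref <- colnames(norm)[16:30]
  expect_warning(prof <- infer_cnv_windows(norm, genes, ref, window_size = 5),
                 "chr2")
  # query cells drawn from the reference distribution: scores near zero
  se <- 1 / sqrt(5 * 15)  # rough scale of a window mean
  expect_lt(mean(abs(prof$scores)), 3 * se + 0.2)
  # adding a gene-wise constant to every cell changes nothing
  shifted <- as_norm(m + rep(seq(0, 1.9, by = 0.1), 30), genes = genes$symbol)
  expect_warning(prof2 <- infer_cnv_windows(shifted, genes, ref, window_size = 5),
                 "chr2")
  expect_equal(prof$scores, prof2$scores)
  expect_error(infer_cnv_windows(norm, genes, ref[1:5]), ">= 10")
})

test_that("gate/CNV concordance reports the quantile rule honestly", {
  set.seed(8)
  burden <- tibble::tibble(cell_id = paste0("c", 1:40),
                           burden = c(runif(20, 0, 1), runif(20, 5, 6)))
  prof <- structure(list(burden = burden, reference_cells = paste0("c", 1:20)),
                    class = "cnv_profile")
  calls <- tibble::tibble(
    cell_id = paste0("c", 1:40),
    condition = c(rep("AV", 20), rep("AC", 20)),
    score = c(runif(20, 0, 1), runif(20, 2, 3)),
    call = c(rep("non_malignant", 20), rep("malignant", 20)),
    excluded_reason = NA_character_)
  gate <- structure(list(threshold = 1.5, calls = calls), class = "malignancy_gate")
  conc <- cnv_concordance(gate, prof)
  expect_equal(conc$expected_reference_fpr, 0.05)
  expect_gte(conc$agreement, 0.95)
  # reference-like cells: at most ~5% called CNV-positive by construction
  ref_pos <- dplyr::filter(conc$confusion, call == "non_malignant", cnv_positive)
  expect_lte(sum(ref_pos$n), 2)

  # empty malignant set: zero-count rows, no error
  calls0 <- dplyr::mutate(calls, call = "non_malignant")
  gate0 <- structure(list(threshold = 99, calls = calls0), class = "malignancy_gate")
  conc0 <- cnv_concordance(gate0, prof)
  expect_equal(sum(dplyr::filter(conc0$confusion, call == "malignant")$n), 0)
})
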