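lr1 <- function() lr_pairs(tibble::tibble(ligand = "L", receptor = "R",
                                          pathway = "toy"))

test_that("trimean matches its closed forms and the quantile oracle", {
  expect_equal(trimean(c(2, 2, 2, 2)), 2)
  expect_equal(trimean(5), 5)
  v <- c(0, 1, 2, 3, 4)
  oracle <- (q_type7(v, 0.25) + 2 * q_type7(v, 0.5) + q_type7(v, 0.75)) / 4
  expect_equal(trimean(v), oracle)
  expect_equal(trimean(v), 2)
  expect_error(trimean(numeric()), "non-empty")
})

test_that("communication probability follows the saturation law", {
  # constant expression: trimeans are exact, P = LR/(Kh + LR)
  n <- 24
  m <- rbind(L = c(rep(1, 12), rep(0, 12)), R = rep(0.5, n),
             X = rep(1, n))
  norm <- as_norm(m, genes = rownames(m))
  labels <- tibble::tibble(cell_id = colnames(norm),
                           group = rep(c("src", "tgt"), each = 12))
  res <- communication_probability(norm, labels, lr1(), min_cells = 5, kh = 0.5)
  # L = 1 in src, R = 0.5 in tgt: L*R = Kh, P = 0.5
  expect_equal(res$prob[res$source == "src" & res$target == "tgt"], 0.5)
  # ligand all-zero in the tgt-as-source direction: P = 0
  expect_equal(res$prob[res$source == "tgt" & res$target == "tgt"], 0)
  expect_true(all(res$prob >= 0 & res$prob < 1))
})

test_that("groups below min_cells vanish and multi-subunit pairs use a
           geometric mean", {
  m <- rbind(L1 = rep(2, 19), L2 = rep(8, 19), R = rep(1, 19))
  norm <- as_norm(m, genes = rownames(m))
  labels <- tibble::tibble(cell_id = colnames(norm),
                           group = c(rep("big", 10), rep("small", 9)))
  lr <- lr_pairs(tibble::tibble(ligand = "L1+L2", receptor = "R",
                                pathway = "toy"))
  res <- communication_probability(norm, labels, lr, min_cells = 10, kh = 0.5)
  expect_false(any(res$source == "small" | res$target == "small"))
  l_geo <- sqrt(2 * 8)  # geometric mean of subunit trimeans
  expect_equal(res$prob[1], l_geo * 1 / (0.5 + l_geo * 1))
})

test_that("probability is strictly increasing in ligand and receptor levels", {
  mk <- function(lv, rv) {
    m <- rbind(L = rep(lv, 20), R = rep(rv, 20))
    norm <- as_norm(m, genes = rownames(m))
    labels <- tibble::tibble(cell_id = colnames(norm),
                             group = rep(c("s", "t"), each = 10))
    communication_probability(norm, labels, lr1(), min_cells = 5)$prob[2]
  }
  expect_lt(mk(1, 1), mk(2, 1))
  expect_lt(mk(2, 1), mk(2, 3))
})

test_that("missing subunits are skipped with a warning", {
  m <- rbind(L = rep(1, 20), R = rep(1, 20))
  norm <- as_norm(m, genes = rownames(m))
  labels <- tibble::tibble(cell_id = colnames(norm),
                           group = rep(c("s", "t"), each = 10))
  lr <- lr_pairs(tibble::tibble(ligand = c("L", "GHOST"), receptor = c("R", "R"),
                                pathway = c("a", "b")))
  expect_warning(res <- communication_probability(norm, labels, lr, min_cells = 5),
                 "skipped")
  expect_setequal(unique(res$pathway), "a")
})

test_that("permutation p-values match exhaustive enumeration on a toy
           instance and are deterministic", {
  # 6 cells, 2 groups of 3; ligand high in the true source group
  m <- rbind(L = c(3, 2.5, 2, 0.1, 0.2, 0), R = c(1, 1, 1, 1, 1, 1))
  norm <- as_norm(m, genes = rownames(m))
  labels <- tibble::tibble(cell_id = colnames(norm),
                           group = c("s", "s", "s", "t", "t", "t"))
  obs <- communication_probability(norm, labels, lr1(), min_cells = 3)
  obs_p <- obs$prob[obs$source == "s" & obs$target == "t"]

  # exhaustive oracle over all distinct assignments of the label multiset
  perms <- all_labelings(labels$group)
  perm_probs <- vapply(perms, function(lab) {
    l <- trimean(m["L", lab == "s"])
    r <- trimean(m["R", lab == "t"])
    l * r / (0.5 + l * r)
  }, numeric(1))
  p_star <- mean(perm_probs >= obs_p)

  B <- 400
  res <- permutation_significance(norm, labels, lr1(), min_cells = 3,
                                  n_permutations = B, seed = 7)
  p_mc <- res$p_value[res$source == "s" & res$target == "t"]
  mc_se <- sqrt(p_star * (1 - p_star) / B)
  expect_lt(abs(p_mc - p_star), 3 * mc_se + 2 / (B + 1))

  res2 <- permutation_significance(norm, labels, lr1(), min_cells = 3,
                                   n_permutations = B, seed = 7)
  expect_identical(res$p_value, res2$p_value)
})

test_that("zero observed probability yields p = 1 and pathways aggregate
           by summation", {
  m <- rbind(L = rep(0, 12), R = rep(1, 12), L2 = rep(1, 12))
  norm <- as_norm(m, genes = rownames(m))
  labels <- tibble::tibble(cell_id = colnames(norm),
                           group = rep(c("s", "t"), each = 6))
  lr <- lr_pairs(tibble::tibble(ligand = c("L", "L2"), receptor = c("R", "R"),
                                pathway = c("p1", "p1")))
  res <- permutation_significance(norm, labels, lr, min_cells = 3,
                                  n_permutations = 20, seed = 1)
  expect_true(all(res$p_value[res$prob == 0] == 1))
  agg <- pathway_probability(res)
  one <- dplyr::filter(res, source == "s", target == "t")
  expect_equal(agg$prob[agg$source == "s" & agg$target == "t"],
               sum(one$prob))
})
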