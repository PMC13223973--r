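panel_cells <- function(rows) {
  # rows: list of named intensity overrides; all markers default to 1
  markers <- c("EPCAM", "PanCK", "CD3e", "CD8", "CD4", "CD14", "CD68", "CD20")
  tab <- purrr::map_dfr(rows, function(r) {
    v <- setNames(rep(1, length(markers)), markers)
    v[names(r)] <- r
    as.list(v)
  })
  dplyr::bind_cols(tibble::tibble(cell_id = paste0("c", seq_len(nrow(tab))),
                                  x_um = 0, y_um = 0), tab)
}

test_that("marker gates apply the boolean rules in priority order", {
  thr <- setNames(rep(10, 8), c("EPCAM", "PanCK", "CD3e", "CD8", "CD4",
                                "CD14", "CD68", "CD20"))
  cells <- panel_cells(list(
    list(CD3e = 50, CD8 = 50),                     # CD8 T
    list(CD68 = 50),                               # CD14- CD68+: macrophage
    list(CD14 = 50, CD68 = 50),                    # monocyte
    list(),                                        # all below: unassigned
    list(EPCAM = 50, PanCK = 50, CD3e = 50, CD8 = 50),  # multi+: tumor wins
    list(CD3e = 50, CD4 = 50),                     # CD4 T
    list(CD20 = 50)                                # B
  ))
  expect_message(gated <- gate_cell_types(cells, thresholds = thr),
                 "multi-positive")
  expect_equal(gated$type,
               c("CD8 T", "macrophage", "monocyte", "unassigned",
                 "tumor", "CD4 T", "B"))
  expect_error(gate_cell_types(dplyr::select(cells, -CD20), thresholds = thr),
               "CD20")
})

test_that("Otsu thresholds separate the simulated intensity mixture", {
  sp <- simulate_spatial(n_cells = 1200, seed = 13)
  gated <- gate_cell_types(sp$cells)
  expect_gt(mean(gated$type == sp$cells$true_type), 0.95)
})

test_that("the proximity graph is a thresholded distance graph", {
  cells <- tibble::tibble(cell_id = c("a", "b", "d"),
                          x_um = c(0, 90, 240), y_um = 0)
  g <- proximity_graph(cells, max_edge_distance = 100)
  edges <- igraph::as_data_frame(g)
  expect_equal(nrow(edges), 1)                     # 90 um: edge; 150 um: none
  expect_setequal(unlist(edges[1, c("from", "to")]), c("a", "b"))

  set.seed(5)
  pts <- tibble::tibble(cell_id = paste0("c", 1:200),
                        x_um = runif(200, 0, 300), y_um = runif(200, 0, 300))
  g2 <- proximity_graph(pts, max_edge_distance = 40)
  # brute-force oracle over all pairs
  want <- character()
  for (i in 1:199) for (j in (i + 1):200) {
    if (sqrt((pts$x_um[i] - pts$x_um[j])^2 + (pts$y_um[i] - pts$y_um[j])^2) <= 40)
      want <- c(want, paste(pts$cell_id[i], pts$cell_id[j]))
  }
  got <- igraph::as_data_frame(g2)
  got_keys <- paste(pmin(got$from, got$to), pmax(got$from, got$to))
  want_keys <- paste(pmin(sub(" .*", "", want), sub(".* ", "", want)),
                     pmax(sub(" .*", "", want), sub(".* ", "", want)))
  expect_setequal(got_keys, want_keys)

  # relabeling cell order leaves the edge set unchanged
  perm <- sample(200)
  g3 <- proximity_graph(pts[perm, ], max_edge_distance = 40)
  got3 <- igraph::as_data_frame(g3)
  expect_setequal(paste(pmin(got3$from, got3$to), pmax(got3$from, got3$to)),
                  got_keys)
})

test_that("niche clustering handles degenerate compositions and is
           permutation-equivariant", {
  # all cells identical composition: a single niche
  cells <- tibble::tibble(cell_id = paste0("c", 1:12),
                          x_um = rep(1:6, 2) * 10, y_um = rep(c(0, 10), each = 6))
  g <- proximity_graph(cells, max_edge_distance = 15)
  types <- setNames(rep("tumor", 12), cells$cell_id)
  nc <- niche_clusters(g, types, k_niches = 4, seed = 1)
  expect_equal(length(unique(nc$niche)), 1)

  sp <- simulate_spatial(n_cells = 600, seed = 17)
  g1 <- proximity_graph(sp$cells, 50)
  t1 <- setNames(sp$cells$true_type, sp$cells$cell_id)
  n1 <- niche_clusters(g1, t1, k_niches = 3, seed = 4)
  perm <- sample(nrow(sp$cells))
  g2 <- proximity_graph(sp$cells[perm, ], 50)
  n2 <- niche_clusters(g2, t1, k_niches = 3, seed = 4)
  expect_equal(n2$niche[match(n1$cell_id, n2$cell_id)], n1$niche)
})

test_that("neighborhood enrichment matches the exhaustive oracle on a
           line graph", {
  # increasing gaps make each cell's nearest neighbor unambiguous,
  # giving the 5-edge line graph 1-2-3-4-5-6
  cells <- tibble::tibble(x_um = c(0, 10, 21, 33, 46, 60), y_um = 0)
  types <- c("A", "A", "A", "B", "B", "B")
  B <- 4000
  enr <- neighborhood_enrichment(cells, types, k = 1, n_permutations = B,
                                 seed = 3)
  # oracle: all 20 distinct labelings of the line graph
  edges <- cbind(1:5, 2:6)
  count_ab <- function(lab) {
    m <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
    for (e in 1:5) {
      m[lab[edges[e, 1]], lab[edges[e, 2]]] <- m[lab[edges[e, 1]], lab[edges[e, 2]]] + 1
      m[lab[edges[e, 2]], lab[edges[e, 1]]] <- m[lab[edges[e, 2]], lab[edges[e, 1]]] + 1
    }
    m
  }
  perms <- all_labelings(types)
  counts <- lapply(perms, count_ab)
  exact_mean <- Reduce(`+`, counts) / length(counts)
  exact_sd <- sqrt(Reduce(`+`, lapply(counts, function(m) (m - exact_mean)^2)) /
                     length(counts))
  expect_equal(enr$observed, count_ab(types))
  for (i in 1:2) for (j in 1:2) {
    tol_mean <- 3 * exact_sd[i, j] / sqrt(B)
    expect_lt(abs(enr$perm_mean[i, j] - exact_mean[i, j]), tol_mean + 1e-9)
    tol_sd <- 3 * exact_sd[i, j] / sqrt(2 * B)
    expect_lt(abs(enr$perm_sd[i, j] - exact_sd[i, j]), tol_sd + 0.05)
  }

  enr2 <- neighborhood_enrichment(cells, types, k = 1, n_permutations = 50,
                                  seed = 3)
  enr3 <- neighborhood_enrichment(cells, types, k = 1, n_permutations = 50,
                                  seed = 3)
  expect_identical(enr2$z, enr3$z)
})

test_that("enrichment z-scores are invariant to rigid motions and handle a
           single type", {
  sp <- simulate_spatial(n_cells = 400, seed = 19)
  cells <- sp$cells
  e1 <- neighborhood_enrichment(cells, cells$true_type, k = 6,
                                n_permutations = 100, seed = 2)
  theta <- 0.7
  rotated <- dplyr::mutate(cells,
    x2 = cos(theta) * x_um - sin(theta) * y_um + 500,
    y2 = sin(theta) * x_um + cos(theta) * y_um - 200)
  rotated <- dplyr::mutate(rotated, x_um = x2, y_um = y2)
  e2 <- neighborhood_enrichment(rotated, cells$true_type, k = 6,
                                n_permutations = 100, seed = 2)
  expect_equal(e1$z, e2$z, tolerance = 1e-8)

  expect_warning(z1 <- neighborhood_enrichment(cells[1:20, ], rep("t", 20),
                                               k = 3, n_permutations = 10),
                 "single")
  expect_equal(dim(z1$z), c(1, 1))
  expect_equal(z1$z[1, 1], 0)
})

test_that("compartment assignment follows the tumor-density rule", {
  # ring of 10 tumor cells around an immune cell, all within 50 um
  ring <- tibble::tibble(cell_id = paste0("t", 1:10),
                         x_um = 30 * cos(2 * pi * (1:10) / 10),
                         y_um = 30 * sin(2 * pi * (1:10) / 10))
  cells <- dplyr::bind_rows(
    tibble::tibble(cell_id = "imm", x_um = 0, y_um = 0),
    ring,
    tibble::tibble(cell_id = "lonely", x_um = 500, y_um = 500))
  types <- c("CD8 T", rep("tumor", 10), "CD8 T")
  comp <- compartment_assign(cells, types)
  expect_equal(comp$compartment[comp$cell_id == "imm"], "epithelial")
  expect_equal(comp$compartment[comp$cell_id == "lonely"], "stromal")
  expect_equal(comp$n_tumor_neighbors[comp$cell_id == "imm"], 10)
})
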