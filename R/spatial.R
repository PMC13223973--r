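#' Otsu threshold of a marker intensity distribution
#'
#' Computed on `log1p` intensities over a 256-bin histogram, returned on
#' the raw intensity scale — a reproducible stand-in for manual gating.
#'
#' @param x Non-negative intensities.
#' @return Scalar threshold.
#' @export
otsu_threshold <- function(x) {
  lx <- log1p(x)
  breaks <- seq(min(lx), max(lx), length.out = 257)
  if (diff(range(lx)) == 0) return(expm1(lx[1]))
  h <- hist(lx, breaks = breaks, plot = FALSE)
  p <- h$counts / sum(h$counts)
  mids <- h$mids
  omega <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[length(mu)]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  expm1(mids[which.max(sigma_b)])
}

marker_gate_rules <- function() {
  # evaluated in priority order; first matching rule wins
  list(
    tumor = function(p) p[, "EPCAM"] & p[, "PanCK"],
    `CD8 T` = function(p) p[, "CD3e"] & p[, "CD8"],
    `CD4 T` = function(p) p[, "CD3e"] & p[, "CD4"],
    B = function(p) p[, "CD20"],
    monocyte = function(p) p[, "CD14"] & p[, "CD68"],
    macrophage = function(p) !p[, "CD14"] & p[, "CD68"]
  )
}

#' Threshold-gate multiplex-imaging cells into types
#'
#' Marker-positive means intensity strictly above the per-marker
#' threshold (Otsu on log intensities unless supplied). Boolean gates are
#' evaluated in a fixed priority order — tumor (EPCAM+PanCK+), CD8 T
#' (CD3e+CD8+), CD4 T (CD3e+CD4+), B (CD20+), monocyte (CD14+CD68+),
#' macrophage (CD14-CD68+) — and cells matching no rule are
#' `"unassigned"`.
#'
#' @param cells Tibble with one column per panel marker (EPCAM, PanCK,
#'   CD3e, CD8, CD4, CD14, CD68, CD20).
#' @param thresholds Optional named per-marker thresholds overriding Otsu.
#' @return Input tibble with a `type` column; thresholds and the
#'   multi-positive count attached as attributes `thresholds` and
#'   `n_multipositive`.
#' @export
gate_cell_types <- function(cells, thresholds = NULL) {
  rules <- marker_gate_rules()
  markers <- c("EPCAM", "PanCK", "CD3e", "CD8", "CD4", "CD14", "CD68", "CD20")
  missing <- setdiff(markers, names(cells))
  if (length(missing)) abort(paste0("missing marker column(s): ", paste(missing, collapse = ", ")))
  if (is.null(thresholds)) {
    thresholds <- vapply(markers, function(m) otsu_threshold(cells[[m]]), numeric(1))
  }
  pos <- vapply(markers, function(m) cells[[m]] > thresholds[[m]],
                logical(nrow(cells)))
  colnames(pos) <- markers
  match_mat <- vapply(rules, function(f) f(pos), logical(nrow(cells)))
  n_multi <- sum(rowSums(match_mat) > 1)
  if (n_multi > 0) inform(sprintf("%d multi-positive cell(s) resolved by gate priority", n_multi))
  first <- apply(match_mat, 1, function(r) {
    i <- which(r)[1]
    if (is.na(i)) "unassigned" else names(rules)[i]
  })
  out <- mutate(cells, type = first)
  attr(out, "thresholds") <- thresholds
  attr(out, "n_multipositive") <- n_multi
  out
}

#' Proximity graph on cell coordinates
#'
#' Undirected graph joining every pair of cells within
#' `max_edge_distance` (Euclidean), no self-loops.
#'
#' @param cells Tibble with `cell_id`, `x_um`, `y_um`.
#' @param max_edge_distance Edge cutoff in the coordinate unit
#'   (default 100 um).
#' @return An igraph object with vertex names `cell_id`.
#' @export
proximity_graph <- function(cells, max_edge_distance = 100) {
  stopifnot(max_edge_distance > 0)
  n <- nrow(cells)
  if (n < 2) abort("need at least 2 cells")
  d <- as.matrix(dist(cbind(cells$x_um, cells$y_um)))
  adj <- d <= max_edge_distance
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- cells$cell_id
  g
}

#' Niche clustering of neighborhood composition
#'
#' Each cell's neighborhood composition — counts of each cell type among
#' its proximity-graph neighbors, the cell itself included, row-normalized
#' — is clustered by seeded k-means into `k_niches` niches.
#'
#' @param graph Proximity graph from [proximity_graph()].
#' @param types Named character vector (names = cell ids) or tibble with
#'   `cell_id`, `type`.
#' @param k_niches Number of niches (default 6).
#' @param seed Integer seed.
#' @return Tibble: `cell_id`, `niche` (integer `1..k`), plus the
#'   composition columns.
#' @export
niche_clusters <- function(graph, types, k_niches = 6, seed = 1) {
  stopifnot(k_niches >= 2)
  if (is.data.frame(types)) types <- setNames(types$type, types$cell_id)
  ids <- igraph::V(graph)$name
  types <- types[ids]
  lvls <- sort(unique(types))
  adj <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
  diag(adj) <- 1  # self-inclusion guarantees a non-empty neighborhood
  onehot <- sapply(lvls, function(l) as.numeric(types == l))
  comp <- as.matrix(adj %*% onehot)
  comp <- comp / rowSums(comp)
  colnames(comp) <- lvls
  n_distinct_rows <- nrow(unique(comp))
  k <- min(k_niches, n_distinct_rows)
  if (k < 2) {
    labels <- rep(1L, length(ids))
  } else {
    # canonical row order makes labels equivariant under input permutation
    ord <- do.call(order, as.data.frame(comp))
    set.seed(seed)
    km <- kmeans(comp[ord, , drop = FALSE], centers = k, nstart = 10, iter.max = 100)
    sorted_labels <- as.integer(factor(km$cluster, levels = unique(km$cluster)))
    labels <- integer(length(ids))
    labels[ord] <- sorted_labels
  }
  bind_cols(tibble(cell_id = ids, niche = labels), as_tibble(comp))
}

knn_edges <- function(coords, k) {
  n <- nrow(coords)
  if (k >= n) abort("k must be smaller than the number of cells")
  d <- as.matrix(dist(coords))
  diag(d) <- Inf
  edges <- do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, order(d[i, ])[seq_len(k)])
  }))
  # symmetrize to an undirected edge set
  und <- unique(t(apply(edges, 1, sort)))
  und
}

#' Neighborhood enrichment z-scores
#'
#' Builds a k-nearest-neighbor spatial graph, counts edges joining each
#' ordered type pair, and standardizes the counts against a label
#' permutation null: `z = (obs - mean_perm) / sd_perm` (`z = 0` where the
#' permutation sd is 0). Positive z means the two types are spatial
#' neighbors more often than chance.
#'
#' @param cells Tibble with `x_um`, `y_um`.
#' @param types Character vector of cell types (same order as `cells`).
#' @param k Neighbors per cell (default 8).
#' @param n_permutations Label permutations (default 1000).
#' @param seed Integer seed.
#' @return Object of class `neighborhood_enrichment`: `z`, `observed`,
#'   `perm_mean`, `perm_sd` (types x types matrices).
#' @export
neighborhood_enrichment <- function(cells, types, k = 8,
                                    n_permutations = 1000, seed = 1) {
  stopifnot(nrow(cells) == length(types), n_permutations >= 1)
  lvls <- sort(unique(types))
  if (length(lvls) < 2) {
    warn("single cell type present: enrichment undefined, returning zero matrix")
    z <- matrix(0, 1, 1, dimnames = list(lvls, lvls))
    return(structure(list(z = z, observed = z, perm_mean = z, perm_sd = z,
                          k = k, n_permutations = n_permutations),
                     class = "neighborhood_enrichment"))
  }
  edges <- knn_edges(cbind(cells$x_um, cells$y_um), k)
  count_pairs <- function(lab) {
    f <- factor(lab, levels = lvls)
    a <- f[edges[, 1]]; b <- f[edges[, 2]]
    # each undirected edge contributes both ordered pairs
    m <- table(a, b) + t(table(a, b))
    matrix(as.numeric(m), length(lvls), length(lvls), dimnames = list(lvls, lvls))
  }
  obs <- count_pairs(types)
  set.seed(seed)
  sums <- matrix(0, length(lvls), length(lvls))
  sq_sums <- matrix(0, length(lvls), length(lvls))
  for (b in seq_len(n_permutations)) {
    cnt <- count_pairs(sample(types))
    sums <- sums + cnt
    sq_sums <- sq_sums + cnt^2
  }
  perm_mean <- sums / n_permutations
  perm_var <- pmax(sq_sums / n_permutations - perm_mean^2, 0)
  perm_sd <- sqrt(perm_var)
  z <- (obs - perm_mean) / perm_sd
  z[perm_sd == 0] <- 0
  dimnames(z) <- dimnames(perm_mean) <- dimnames(perm_sd) <- dimnames(obs)
  structure(list(z = z, observed = obs, perm_mean = perm_mean,
                 perm_sd = perm_sd, k = k, n_permutations = n_permutations),
            class = "neighborhood_enrichment")
}

#' @method print neighborhood_enrichment
#' @export
print.neighborhood_enrichment <- function(x, ...) {
  cat("Neighborhood enrichment (k =", x$k, ",", x$n_permutations, "permutations)\n")
  print(round(x$z, 2))
  invisible(x)
}

#' @export
tidy.neighborhood_enrichment <- function(x, ...) {
  as_tibble(as.table(x$z), .name_repair = "minimal") |>
    setNames(c("type_a", "type_b", "z"))
}

#' Assign epithelial vs stromal compartments by tumor-cell density
#'
#' A cell is in the epithelial (intra-tumoral) compartment when at least
#' `min_tumor_neighbors` tumor cells (other than itself) lie within
#' `radius`; otherwise stromal.
#'
#' @param cells Tibble with `cell_id`, `x_um`, `y_um`.
#' @param types Character vector of assigned types (same order).
#' @param tumor_type Label counting as tumor (default `"tumor"`).
#' @param radius Neighborhood radius in um (default 50).
#' @param min_tumor_neighbors Minimum tumor neighbors (default 3).
#' @return Tibble: `cell_id`, `n_tumor_neighbors`, `compartment`.
#' @export
compartment_assign <- function(cells, types, tumor_type = "tumor",
                               radius = 50, min_tumor_neighbors = 3) {
  stopifnot(nrow(cells) == length(types))
  d <- as.matrix(dist(cbind(cells$x_um, cells$y_um)))
  diag(d) <- Inf
  is_tumor <- types == tumor_type
  n_tumor <- as.integer((d <= radius) %*% is_tumor)
  tibble(cell_id = cells$cell_id,
         n_tumor_neighbors = n_tumor,
         compartment = ifelse(n_tumor >= min_tumor_neighbors, "epithelial", "stromal"))
}
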