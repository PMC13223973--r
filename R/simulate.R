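#' Default gene panel for simulation
#'
#' A desk-scale panel: `n_genes` genes laid out on `n_chromosomes`
#' pseudo-chromosomes with evenly spaced coordinates, the last `n_mito`
#' genes of the final chromosome flagged mitochondrial, and one gene named
#' `PTPRC` (CD45) used for the immune/epithelial split.
#'
#' @param n_genes Total genes (default 2000).
#' @param n_chromosomes Pseudo-chromosomes (default 4).
#' @param n_mito Mitochondrial genes (default 13, the human mtDNA
#'   protein-coding count).
#' @return Tibble: `gene_id`, `symbol`, `chromosome`, `start_position`,
#'   `is_mito`.
#' @export
sim_gene_panel <- function(n_genes = 2000, n_chromosomes = 4, n_mito = 13) {
  stopifnot(n_genes > n_mito, n_chromosomes >= 1)
  per_chrom <- rep(n_genes %/% n_chromosomes, n_chromosomes)
  per_chrom[n_chromosomes] <- per_chrom[n_chromosomes] + n_genes %% n_chromosomes
  chrom <- rep(paste0("chr", seq_len(n_chromosomes)), per_chrom)
  pos <- unlist(lapply(per_chrom, function(n) seq_len(n) * 10000L))
  symbol <- sprintf("G%04d", seq_len(n_genes))
  is_mito <- rep(FALSE, n_genes)
  mito_idx <- seq(n_genes - n_mito + 1L, n_genes)
  is_mito[mito_idx] <- TRUE
  symbol[mito_idx] <- sprintf("MT-%d", seq_len(n_mito))
  symbol[1L] <- "PTPRC"
  tibble(gene_id = symbol, symbol = symbol, chromosome = chrom,
         start_position = as.integer(pos), is_mito = is_mito)
}

#' Default immune gating tree
#'
#' The hierarchy used for progressive annotation: level 1 lineages
#' (T, B, NK, ILC, myeloid), then T-cell, CD4, B-cell, myeloid and ILC
#' subsets. Each node references a signature named `sig_<label>`.
#'
#' @return Tibble: `label`, `parent` (`NA` for level-1 nodes), `signature`.
#' @export
default_gating_tree <- function() {
  nodes <- list(
    c("T", NA), c("B", NA), c("NK", NA), c("ILC", NA), c("myeloid", NA),
    c("CD8", "T"), c("CD4", "T"), c("gdT", "T"),
    c("Th1", "CD4"), c("Th2", "CD4"), c("Th17", "CD4"),
    c("Treg", "CD4"), c("Tfh", "CD4"), c("Tn", "CD4"),
    c("plasma", "B"), c("B-Mmem", "B"), c("B-Cmem", "B"),
    c("Bn", "B"), c("Breg", "B"),
    c("monocyte-like", "myeloid"), c("Mac_Angio", "myeloid"),
    c("Mac_Prolif", "myeloid"), c("mast", "myeloid"),
    c("ILC1", "ILC"), c("ILC2", "ILC"), c("ILC3", "ILC")
  )
  tibble(
    label = map_chr(nodes, 1),
    parent = map_chr(nodes, 2),
    signature = paste0("sig_", map_chr(nodes, 1))
  )
}

#' Default cell-group design for simulation
#'
#' Two conditions — AC (ampullary carcinoma) and AV (normal ampulla of
#' Vater) — each with an epithelial compartment and an immune compartment
#' spanning every leaf of the gating tree. The AC epithelium is a mixture
#' of malignant cells and a normal-cell contamination fraction, which is
#' what makes the quartile gate's tumor-side exclusions meaningful.
#'
#' @param n_epithelial Epithelial cells per condition (default 500).
#' @param ac_normal_frac Fraction of AC epithelial cells that are
#'   copy-number-normal, non-malignant contamination (default 0.10).
#' @param n_per_immune_leaf Immune cells per leaf label per condition
#'   (default 30).
#' @param tree Gating tree tibble (see [default_gating_tree()]).
#' @return Tibble: `group`, `condition`, `compartment`, `malignant`,
#'   `subset_path`, `n_cells`.
#' @export
sim_design <- function(n_epithelial = 500, ac_normal_frac = 0.10,
                       n_per_immune_leaf = 30,
                       tree = default_gating_tree()) {
  stopifnot(ac_normal_frac >= 0, ac_normal_frac < 1)
  leaves <- setdiff(tree$label, tree$parent[!is.na(tree$parent)])
  paths <- vapply(leaves, function(lab) {
    path <- lab
    while (!is.na(tree$parent[match(path[1], tree$label)])) {
      path <- c(tree$parent[match(path[1], tree$label)], path)
    }
    paste(path, collapse = "/")
  }, character(1))
  n_ac_normal <- round(ac_normal_frac * n_epithelial)
  epi <- tibble(
    group = c("AC_malignant", "AC_epithelial_normal", "AV_epithelial"),
    condition = c("AC", "AC", "AV"),
    compartment = "epithelial",
    malignant = c(TRUE, FALSE, FALSE),
    subset_path = NA_character_,
    n_cells = c(n_epithelial - n_ac_normal, n_ac_normal, n_epithelial)
  )
  epi <- filter(epi, .data$n_cells > 0)
  imm <- tidyr::expand_grid(condition = c("AC", "AV"),
                            tibble(leaf = leaves, subset_path = unname(paths)))
  imm <- mutate(imm,
                group = paste(condition, leaf, sep = "_"),
                compartment = "immune", malignant = FALSE,
                n_cells = n_per_immune_leaf)
  bind_rows(epi, select(imm, "group", "condition", "compartment",
                        "malignant", "subset_path", "n_cells"))
}

#' Effect configuration for the count simulator
#'
#' Defines the planted structure: a tumor DEG program, genomic gain/loss
#' blocks, hierarchical immune marker programs, a ligand-receptor program
#' between the tumor group and angiogenic macrophages, an activated
#' sub-population, and a fraction of QC-violating cells.
#'
#' Counts follow a negative binomial: for gene g and cell c the mean is
#' `lib_c * base_g * 2^delta_gc` with gene-level dispersion `dispersion`
#' (NB size); library sizes are log-normal. DEG and ligand-receptor
#' effects are planted on well-expressed genes (baseline abundance above
#' the panel median) so a planted fold change survives the
#' pseudocount-one fold estimator. Marker and activation genes emulate
#' off/on genes: near-zero baseline (`marker_off_count` expected counts at
#' the median library) switched on by `2^marker_log2fc`, which is what
#' gives the zero-score gating rules their meaning.
#'
#' @param n_deg Planted DEGs in malignant cells (default 50; half up,
#'   half down at `deg_log2fc`).
#' @param deg_log2fc Absolute planted log2 fold change (default 2).
#' @param cnv_segments Tibble (`chromosome`, `start_index`, `length`,
#'   `fold`): contiguous within-chromosome blocks whose expression is
#'   multiplied by `fold` in malignant cells.
#' @param n_markers_per_node Marker-block size per gating-tree node (8).
#' @param marker_off_count Expected baseline count of a marker gene at the
#'   median library size (default 0.01 — essentially undetected).
#' @param marker_log2fc On-state fold for marker genes (default 7).
#' @param ptprc_log2fc On-state fold for PTPRC in immune cells (default 8).
#' @param lr_fold Fold enrichment of the planted ligand (tumor group) and
#'   receptor (Mac_Angio group) (default 8).
#' @param n_decoy_lr Unplanted ligand-receptor pairs in the shipped LR
#'   table (default 20).
#' @param activated_leaf,activated_frac,activation_log2fc Leaf carrying a
#'   planted activated sub-population, its exact activated fraction, and
#'   the on-fold of the two 6-gene activation signatures
#'   (defaults CD8, 0.70, 7).
#' @param n_compartment_markers,compartment_log2fc Size and fold of the
#'   broad expression programs separating the epithelial and immune
#'   compartments (defaults 40 genes, log2FC 2). Shared by both
#'   conditions, so they cancel in tumor-vs-control contrasts.
#' @param mito_frac Baseline mitochondrial fraction of the library (0.03).
#' @param high_mito_frac Mitochondrial fraction of planted QC-failing
#'   cells (0.30, above the 20% filter).
#' @param qc_violation_frac Fraction of cells planted to violate QC
#'   (half high-mito, half doublet-like; default 0.05).
#' @param doublet_lib_factor Library multiplier for doublet-like cells
#'   (default 10; with the default panel this pushes the detected-feature
#'   count well past the per-panel doublet cap).
#' @param lib_meanlog,lib_sdlog Log-normal library-size parameters
#'   (defaults log(5000), 0.25).
#' @param dispersion Negative-binomial size parameter (default 2).
#' @return A list of class `sim_effect_config`.
#' @export
sim_effect_config <- function(n_deg = 50, deg_log2fc = 2,
                              cnv_segments = tibble(
                                chromosome = c("chr1", "chr2", "chr3"),
                                start_index = c(50L, 100L, 150L),
                                length = c(150L, 150L, 150L),
                                fold = c(1.5, 0.5, 1.5)),
                              n_markers_per_node = 8,
                              marker_off_count = 0.01, marker_log2fc = 7,
                              ptprc_log2fc = 8,
                              lr_fold = 8, n_decoy_lr = 20,
                              activated_leaf = "CD8", activated_frac = 0.70,
                              activation_log2fc = 7,
                              n_compartment_markers = 40,
                              compartment_log2fc = 2,
                              mito_frac = 0.03, high_mito_frac = 0.30,
                              qc_violation_frac = 0.05,
                              doublet_lib_factor = 10,
                              lib_meanlog = log(5000), lib_sdlog = 0.25,
                              dispersion = 2) {
  stopifnot(n_deg >= 0, deg_log2fc >= 0, dispersion > 0,
            marker_off_count > 0, mito_frac > 0, mito_frac < 1,
            high_mito_frac > 0.2, qc_violation_frac >= 0,
            qc_violation_frac < 1,
            activated_frac >= 0, activated_frac <= 1)
  structure(as.list(environment()), class = "sim_effect_config")
}

# Place disjoint planted gene sets. Marker/activation genes may sit
# anywhere (their baseline is overridden); DEG and LR genes come from the
# well-expressed stratum (base above median) and avoid CNV segments so the
# DEG truth stays orthogonal to the CNV truth.
assign_planted_genes <- function(genes, base, config, tree) {
  n <- nrow(genes)
  ord <- order(genes$chromosome, genes$start_position)
  by_chrom <- split(seq_len(n)[ord], genes$chromosome[ord])
  cnv_idx <- integer()
  segs <- config$cnv_segments
  if (!is.null(segs) && nrow(segs)) {
    for (i in seq_len(nrow(segs))) {
      chr_genes <- by_chrom[[segs$chromosome[i]]]
      if (is.null(chr_genes)) abort(paste0("CNV segment on unknown chromosome: ", segs$chromosome[i]))
      idx <- segs$start_index[i] + seq_len(segs$length[i]) - 1L
      if (max(idx) > length(chr_genes)) abort("CNV segment exceeds chromosome length")
      cnv_idx <- c(cnv_idx, chr_genes[idx])
    }
  }
  reserved <- unique(c(which(genes$is_mito), which(genes$symbol == "PTPRC"), cnv_idx))
  pool <- setdiff(seq_len(n), reserved)
  expressed <- pool[base[pool] > median(base[pool])]

  take <- function(k, from) {
    if (k > length(from)) abort("gene panel too small for the planted configuration")
    picked <- sample(from, k)
    pool <<- setdiff(pool, picked)
    expressed <<- setdiff(expressed, picked)
    picked
  }
  deg_idx <- take(config$n_deg, expressed)
  lr_planted <- take(2, expressed)
  decoys <- matrix(take(2 * config$n_decoy_lr, expressed), ncol = 2)
  epi_prog <- take(config$n_compartment_markers, expressed)
  imm_prog <- take(config$n_compartment_markers, expressed)
  markers <- setNames(lapply(seq_len(nrow(tree)),
                             function(i) take(config$n_markers_per_node, pool)),
                      tree$label)
  act1 <- take(6, pool); act2 <- take(6, pool)
  list(deg = deg_idx, markers = markers, act1 = act1, act2 = act2,
       lr_ligand = lr_planted[1], lr_receptor = lr_planted[2],
       decoys = decoys, cnv = cnv_idx,
       epi_prog = epi_prog, imm_prog = imm_prog)
}

#' Simulate a count matrix with planted ground truth
#'
#' Draws a genes x cells UMI matrix from the negative-binomial model of
#' [sim_effect_config()], planting tumor DEGs, copy-number blocks,
#' hierarchical immune marker programs, a tumor-to-macrophage
#' ligand-receptor program, an activated sub-population, and QC-violating
#' cells, then returns the matrix together with full truth tables.
#'
#' @param design Group design tibble (see [sim_design()]).
#' @param genes Gene panel (see [sim_gene_panel()]).
#' @param config Effect configuration (see [sim_effect_config()]).
#' @param tree Gating tree (see [default_gating_tree()]).
#' @param seed Integer seed; the simulation is fully deterministic given it.
#' @return List: `counts` (dgCMatrix), `cells` (per-cell truth/metadata
#'   tibble), `genes`, `signatures` (named list: one marker signature per
#'   tree node plus `activation_1`/`activation_2`), `lr_pairs` (LR table
#'   with the planted pair first), and `truth` (planted DEG table, CNV
#'   segments with member genes, LR source/target groups, activation
#'   plant).
#' @export
simulate_counts <- function(design = sim_design(), genes = sim_gene_panel(),
                            config = sim_effect_config(),
                            tree = default_gating_tree(), seed = 1) {
  stopifnot(all(design$n_cells >= 1))
  set.seed(seed)
  n_genes <- nrow(genes)
  sym <- genes$symbol
  mito <- genes$is_mito

  # baseline relative abundances; mito genes pinned to mito_frac of the
  # library; marker-like genes pinned to a near-zero off state
  base <- rlnorm(n_genes, meanlog = 0, sdlog = 1)
  base[mito] <- 0
  base <- base / sum(base) * (1 - config$mito_frac)
  base[mito] <- config$mito_frac / sum(mito)

  planted <- assign_planted_genes(genes, base, config, tree)
  off_abundance <- config$marker_off_count / exp(config$lib_meanlog)
  marker_like <- c(unlist(planted$markers), planted$act1, planted$act2,
                   which(sym == "PTPRC"))
  base[marker_like] <- off_abundance
  nonspecial <- setdiff(which(!mito), marker_like)
  base[nonspecial] <- base[nonspecial] / sum(base[nonspecial]) *
    (1 - config$mito_frac - sum(base[marker_like]))

  deg_sign <- rep(c(1, -1), length.out = config$n_deg)
  cnv_log2 <- numeric(n_genes)
  segs <- config$cnv_segments
  if (length(planted$cnv)) {
    cnv_log2[planted$cnv] <- rep(log2(segs$fold), segs$length)
  }

  path_nodes <- function(p) if (is.na(p)) character() else strsplit(p, "/", fixed = TRUE)[[1]]

  cells <- tidyr::uncount(design, weights = .data$n_cells)
  n_cells <- nrow(cells)
  cells$cell_id <- sprintf("cell_%05d", seq_len(n_cells))
  cells$sample_id <- paste0(cells$condition, "_s", 1L + (seq_len(n_cells) %% 2L))
  cells$leaf <- vapply(cells$subset_path, function(p) {
    nodes <- path_nodes(p)
    if (length(nodes)) nodes[length(nodes)] else NA_character_
  }, character(1), USE.NAMES = FALSE)

  # planted activated sub-population: exact fraction of the target leaf
  cells$activated <- FALSE
  act_cells <- which(!is.na(cells$leaf) & cells$leaf == config$activated_leaf)
  if (length(act_cells)) {
    n_act <- round(config$activated_frac * length(act_cells))
    cells$activated[sample(act_cells, n_act)] <- TRUE
  }

  # planted QC violators
  cells$qc_violation <- "none"
  n_bad <- round(config$qc_violation_frac * n_cells)
  if (n_bad > 0) {
    bad <- sample(n_cells, n_bad)
    half <- length(bad) %/% 2
    cells$qc_violation[bad[seq_len(half)]] <- "high_mito"
    if (length(bad) > half) cells$qc_violation[bad[(half + 1):length(bad)]] <- "doublet"
  }

  lib <- rlnorm(n_cells, meanlog = config$lib_meanlog, sdlog = config$lib_sdlog)

  # per-group log2 effect vectors (cells of a group share one program)
  group_delta <- function(row) {
    d <- numeric(n_genes)
    if (row$compartment == "epithelial") {
      d[planted$epi_prog] <- config$compartment_log2fc
    }
    if (row$compartment == "immune") {
      d[planted$imm_prog] <- config$compartment_log2fc
      d[sym == "PTPRC"] <- config$ptprc_log2fc
      nodes <- path_nodes(row$subset_path)
      for (node in nodes) d[planted$markers[[node]]] <- config$marker_log2fc
      if (length(nodes) && nodes[length(nodes)] == "Mac_Angio") {
        d[planted$lr_receptor] <- log2(config$lr_fold)
      }
    }
    if (isTRUE(row$malignant)) {
      d[planted$deg] <- deg_sign * config$deg_log2fc
      d <- d + cnv_log2
      d[planted$lr_ligand] <- d[planted$lr_ligand] + log2(config$lr_fold)
    }
    d
  }
  deltas <- lapply(split(design, seq_len(nrow(design))), group_delta)
  names(deltas) <- design$group

  act_delta <- numeric(n_genes)
  act_delta[c(planted$act1, planted$act2)] <- config$activation_log2fc

  counts <- matrix(0L, nrow = n_genes, ncol = n_cells)
  for (c_i in seq_len(n_cells)) {
    d <- deltas[[cells$group[c_i]]]
    if (cells$activated[c_i]) d <- d + act_delta
    b <- base
    lib_c <- lib[c_i]
    if (cells$qc_violation[c_i] == "high_mito") {
      b[!mito] <- b[!mito] / sum(b[!mito]) * (1 - config$high_mito_frac)
      b[mito] <- config$high_mito_frac / sum(mito)
    } else if (cells$qc_violation[c_i] == "doublet") {
      # doublet-like: blend with another group's program, inflate library
      other <- deltas[[sample(setdiff(design$group, cells$group[c_i]), 1)]]
      d <- log2((2^d + 2^other) / 2)
      lib_c <- lib_c * config$doublet_lib_factor
    }
    mu <- lib_c * b * 2^d
    counts[, c_i] <- rnbinom(n_genes, mu = mu, size = config$dispersion)
  }
  counts <- methods::as(Matrix::Matrix(counts, sparse = TRUE), "CsparseMatrix")
  dimnames(counts) <- list(sym, cells$cell_id)

  signatures <- c(
    setNames(lapply(tree$label, function(l) sym[planted$markers[[l]]]),
             paste0("sig_", tree$label)),
    list(activation_1 = sym[planted$act1], activation_2 = sym[planted$act2])
  )

  lr <- tibble(
    ligand = c(sym[planted$lr_ligand], sym[planted$decoys[, 1]]),
    receptor = c(sym[planted$lr_receptor], sym[planted$decoys[, 2]]),
    pathway = c("planted", sprintf("decoy_%02d", seq_len(nrow(planted$decoys))))
  )

  truth <- list(
    deg = tibble(gene = sym[planted$deg], log2fc = deg_sign * config$deg_log2fc),
    cnv_segments = if (length(planted$cnv)) {
      mutate(segs, genes = split(sym[planted$cnv], rep(seq_len(nrow(segs)), segs$length)))
    } else segs,
    lr = tibble(ligand = sym[planted$lr_ligand], receptor = sym[planted$lr_receptor],
                source_group = "AC_malignant",
                target_group = grep("Mac_Angio", design$group, value = TRUE)),
    activated_leaf = config$activated_leaf,
    activated_frac = config$activated_frac
  )

  cells <- select(cells, "cell_id", "sample_id", "condition", "group",
                  "compartment", "malignant", "subset_path", "leaf",
                  "activated", "qc_violation")
  list(counts = counts, cells = cells, genes = genes,
       signatures = signatures, lr_pairs = lr_pairs(lr), truth = truth)
}

#' Simulate a segmented multiplex-imaging cell table
#'
#' Background cells follow a homogeneous spatial Poisson process on a
#' rectangular field; tertiary-lymphoid-structure-like (TLS) aggregates
#' are Gaussian clusters enriched in B and CD4 T cells; optional tumor
#' nests concentrate tumor cells. Marker intensities are log-normal with
#' type-specific means so threshold gating can recover the types.
#'
#' @param n_cells Background (non-aggregate) cell count.
#' @param type_proportions Named proportions over cell types; must sum
#'   to 1. Types must be among tumor, `CD8 T`, `CD4 T`, B, monocyte,
#'   macrophage.
#' @param tls_config List: `n_aggregates`, `radius_um`,
#'   `n_cells_per_aggregate`, `b_frac`, `cd4_frac`. `n_aggregates = 0`
#'   yields complete spatial randomness.
#' @param nest_config Optional list (`n_nests`, `radius_um`): when given,
#'   tumor cells are placed in Gaussian nests instead of uniformly.
#' @param field_um Field width/height in micrometers (length 2).
#' @param seed Integer seed.
#' @return List: `cells` (tibble: `cell_id`, `x_um`, `y_um`, marker
#'   intensity columns, `true_type`, `true_niche`) and `truth`
#'   (aggregate/nest centers and the config used).
#' @export
simulate_spatial <- function(n_cells = 2500,
                             type_proportions = c(tumor = 0.35, `CD8 T` = 0.15,
                                                  `CD4 T` = 0.15, B = 0.10,
                                                  monocyte = 0.10, macrophage = 0.15),
                             tls_config = list(n_aggregates = 3, radius_um = 50,
                                               n_cells_per_aggregate = 150,
                                               b_frac = 0.50, cd4_frac = 0.35),
                             nest_config = NULL,
                             field_um = c(1000, 1000), seed = 1) {
  if (any(field_um <= 0)) abort("field dimensions must be positive")
  if (abs(sum(type_proportions) - 1) > 1e-8) abort("type_proportions must sum to 1")
  set.seed(seed)

  types <- names(type_proportions)
  bg_type <- sample(types, n_cells, replace = TRUE, prob = type_proportions)
  x <- runif(n_cells, 0, field_um[1])
  y <- runif(n_cells, 0, field_um[2])
  niche <- rep("background", n_cells)

  nest_centers <- NULL
  if (!is.null(nest_config) && nest_config$n_nests > 0) {
    r <- nest_config$radius_um
    nest_centers <- tibble(nest = seq_len(nest_config$n_nests),
                           cx = runif(nest_config$n_nests, r, field_um[1] - r),
                           cy = runif(nest_config$n_nests, r, field_um[2] - r))
    tum <- which(bg_type == "tumor")
    nest_of <- sample(nest_config$n_nests, length(tum), replace = TRUE)
    x[tum] <- rnorm(length(tum), nest_centers$cx[nest_of], r / 3)
    y[tum] <- rnorm(length(tum), nest_centers$cy[nest_of], r / 3)
  }

  tls_centers <- NULL
  if (tls_config$n_aggregates > 0) {
    r <- tls_config$radius_um
    tls_centers <- tibble(aggregate = seq_len(tls_config$n_aggregates),
                          cx = runif(tls_config$n_aggregates, r, field_um[1] - r),
                          cy = runif(tls_config$n_aggregates, r, field_um[2] - r))
    other <- setdiff(types, c("B", "CD4 T"))
    other_p <- type_proportions[other] / sum(type_proportions[other]) *
      (1 - tls_config$b_frac - tls_config$cd4_frac)
    agg_p <- c(setNames(c(tls_config$b_frac, tls_config$cd4_frac), c("B", "CD4 T")), other_p)
    for (a in seq_len(tls_config$n_aggregates)) {
      n_a <- tls_config$n_cells_per_aggregate
      x <- c(x, rnorm(n_a, tls_centers$cx[a], r / 3))
      y <- c(y, rnorm(n_a, tls_centers$cy[a], r / 3))
      bg_type <- c(bg_type, sample(names(agg_p), n_a, replace = TRUE, prob = agg_p))
      niche <- c(niche, rep("tls", n_a))
    }
  }

  x <- pmin(pmax(x, 0), field_um[1])
  y <- pmin(pmax(y, 0), field_um[2])
  n <- length(x)

  # a niche is a region: truth is membership of the planted footprints,
  # whichever process a cell was drawn from
  niche <- rep("background", n)
  within_r <- function(centers, r) {
    if (is.null(centers)) return(rep(FALSE, n))
    Reduce(`|`, lapply(seq_len(nrow(centers)), function(i) {
      (x - centers$cx[i])^2 + (y - centers$cy[i])^2 <= r^2
    }))
  }
  if (!is.null(nest_centers)) niche[within_r(nest_centers, nest_config$radius_um)] <- "nest"
  if (!is.null(tls_centers)) niche[within_r(tls_centers, tls_config$radius_um)] <- "tls"

  # positive markers per type; intensities log-normal around high/low means
  panel <- c("EPCAM", "PanCK", "CD3e", "CD8", "CD4", "CD14", "CD68", "CD20")
  positive <- list(
    tumor = c("EPCAM", "PanCK"), `CD8 T` = c("CD3e", "CD8"),
    `CD4 T` = c("CD3e", "CD4"), B = "CD20",
    monocyte = c("CD14", "CD68"), macrophage = "CD68"
  )
  intensities <- sapply(panel, function(m) {
    hi <- vapply(bg_type, function(t) m %in% positive[[t]], logical(1))
    rlnorm(n, meanlog = ifelse(hi, log(50), log(5)), sdlog = 0.4)
  })
  colnames(intensities) <- panel

  cells <- bind_cols(
    tibble(cell_id = sprintf("sp_%05d", seq_len(n)), x_um = x, y_um = y),
    as_tibble(intensities),
    tibble(true_type = bg_type, true_niche = niche)
  )
  list(cells = cells,
       truth = list(tls_centers = tls_centers, nest_centers = nest_centers,
                    tls_config = tls_config, nest_config = nest_config,
                    type_proportions = type_proportions))
}
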