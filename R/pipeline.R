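#' Pipeline configuration
#'
#' Collects every stage parameter with its default in one validated list.
#' Defaults follow the analysis conventions of the workflow this package
#' reimplements: QC at 20% mitochondrial fraction and 5,000 features,
#' ln(1 + 1e4 c/total) normalization, a Q3 malignancy gate, 101-gene CNV
#' windows, trimean communication with Kh = 0.5 and min 10 cells per
#' group, and 8-neighbor enrichment with 1,000 permutations.
#'
#' @param seed Integer master seed; every stochastic stage derives from it.
#' @param max_pct_mito,max_features QC caps (strict inequalities).
#' @param normalize_scale Normalization target library size.
#' @param cluster_n_neighbors,cluster_resolution,n_pcs Clustering knobs.
#' @param scoring_method `"sum_ratio"` or `"rank_auc"`.
#' @param rank_max Rank truncation for `rank_auc`.
#' @param deg_log2fc_threshold DEG membership cutoff on log2FC.
#' @param adj_p_threshold Reporting threshold for signature-score DE
#'   (default 5.46e-6).
#' @param gate_quantile Control-score quantile for the malignancy gate.
#' @param cnv_window_size,cnv_clip,burden_quantile CNV stage knobs.
#' @param ccc_min_cells,ccc_kh,ccc_n_permutations Communication knobs.
#' @param run_ccc Whether the communication stage runs (needs an LR table).
#' @param activation_signatures Length-2 signature names for activation
#'   calls (`NULL` disables the activation sub-stage).
#' @param tumor_condition,control_condition Condition labels.
#' @param spatial_max_edge,spatial_k_niches,spatial_enrich_k,spatial_n_permutations
#'   Spatial stage knobs.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1,
                            max_pct_mito = 0.20, max_features = 5000,
                            normalize_scale = 1e4,
                            cluster_n_neighbors = 15, cluster_resolution = 1,
                            n_pcs = 50,
                            scoring_method = "sum_ratio", rank_max = 1500,
                            deg_log2fc_threshold = 1,
                            adj_p_threshold = 5.46e-6,
                            gate_quantile = 0.75,
                            cnv_window_size = 101, cnv_clip = 3,
                            burden_quantile = 0.95,
                            ccc_min_cells = 10, ccc_kh = 0.5,
                            ccc_n_permutations = 100, run_ccc = TRUE,
                            activation_signatures = c("activation_1", "activation_2"),
                            tumor_condition = "AC", control_condition = "AV",
                            spatial_max_edge = 100, spatial_k_niches = 6,
                            spatial_enrich_k = 8, spatial_n_permutations = 1000) {
  stopifnot(max_pct_mito > 0, max_pct_mito < 1, max_features > 0,
            gate_quantile > 0, gate_quantile < 1,
            cnv_window_size >= 1, ccc_min_cells >= 1, ccc_kh > 0,
            seed == as.integer(seed))
  structure(as.list(environment()), class = "pipeline_config")
}

#' Write a simulated bundle in the on-disk formats the pipeline reads
#'
#' @param sim Result of [simulate_counts()].
#' @param dir Output directory.
#' @return Invisibly, a named list of the paths written (`counts_dir`,
#'   `cells`, `genes`, `signatures`, `lr`, `gating_tree`, `truth_cells`).
#' @export
write_bundle <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  counts_dir <- file.path(dir, "counts")
  write_counts_mtx(sim$counts, counts_dir)
  paths <- list(
    counts_dir = counts_dir,
    cells = file.path(dir, "cells.csv"),
    genes = file.path(dir, "genes.csv"),
    signatures = file.path(dir, "signatures.gmt"),
    lr = file.path(dir, "lr_pairs.csv"),
    gating_tree = file.path(dir, "gating_tree.csv"),
    truth_cells = file.path(dir, "truth_cells.csv")
  )
  readr::write_csv(select(sim$cells, "cell_id", "sample_id", "condition"), paths$cells)
  readr::write_csv(sim$genes, paths$genes)
  write_gmt(sim$signatures, paths$signatures)
  readr::write_csv(select(as_tibble(sim$lr_pairs), "ligand", "receptor", "pathway"), paths$lr)
  readr::write_csv(default_gating_tree(), paths$gating_tree)
  readr::write_csv(sim$cells, paths$truth_cells)
  invisible(paths)
}

split_by_ptprc <- function(norm, clusters, seed) {
  if (!"PTPRC" %in% rownames(norm)) abort("PTPRC absent: cannot split immune vs epithelial")
  ptprc <- norm["PTPRC", ]
  cluster_mean <- tapply(ptprc, clusters[colnames(norm)], mean)
  set.seed(seed)
  km <- kmeans(as.numeric(cluster_mean), centers = 2, nstart = 5)
  immune_centers <- which.max(km$centers)
  immune_clusters <- as.integer(names(cluster_mean))[km$cluster == immune_centers]
  ifelse(clusters[colnames(norm)] %in% immune_clusters, "immune", "epithelial")
}

#' Run the full single-cell pipeline
#'
#' Executes QC, normalization, clustering, the CD45 (PTPRC)
#' immune/epithelial split, tumor-vs-control differential expression, the
#' quartile malignancy gate with CNV cross-validation, signature scoring,
#' progressive immune gating with activation and proportion tests, and
#' ligand-receptor communication — writing each stage's table as CSV plus
#' a JSON run log. Deterministic given (inputs, config).
#'
#' @param inputs Named list of paths: `counts_dir` (MTX triplet), `cells`
#'   (CSV: cell_id, sample_id, condition), `genes` (CSV gene table),
#'   `signatures` (GMT), `gating_tree` (CSV: label, parent, signature),
#'   and `lr` (CSV) when the communication stage is enabled. See
#'   [write_bundle()].
#' @param outdir Results directory (created).
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of the result paths.
#' @export
run_pipeline <- function(inputs, outdir, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  need <- c("counts_dir", "cells", "genes", "signatures", "gating_tree")
  missing <- setdiff(need, names(inputs))
  if (length(missing)) abort(paste0("missing input(s): ", paste(missing, collapse = ", ")))
  if (config$run_ccc && is.null(inputs$lr)) {
    abort("communication stage enabled but no LR table supplied")
  }
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  out <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  counts <- stage("read", read_counts_mtx(
    file.path(inputs$counts_dir, "matrix.mtx"),
    file.path(inputs$counts_dir, "features.tsv"),
    file.path(inputs$counts_dir, "barcodes.tsv")))
  cells_meta <- readr::read_csv(inputs$cells, col_types = readr::cols(), progress = FALSE)
  genes <- readr::read_csv(inputs$genes, col_types = readr::cols(), progress = FALSE)
  signatures <- read_gmt(inputs$signatures)
  tree <- readr::read_csv(inputs$gating_tree,
                          col_types = readr::cols(.default = "c"), progress = FALSE)

  # QC + normalization
  qc <- stage("qc", qc_filter(counts, genes, cells_meta,
                              max_pct_mito = config$max_pct_mito,
                              max_features = config$max_features))
  out$qc_cells <- file.path(outdir, "qc_cells.csv")
  readr::write_csv(qc$cells, out$qc_cells)
  out$qc_report <- file.path(outdir, "qc_report.csv")
  readr::write_csv(qc$report, out$qc_report)
  norm <- stage("normalize", lognormalize(qc$counts, scale = config$normalize_scale))
  kept <- filter(qc$cells, .data$qc_pass)

  # clustering + CD45 split
  clusters <- stage("cluster", cluster_cells(
    norm, n_neighbors = config$cluster_n_neighbors,
    resolution = config$cluster_resolution, n_pcs = config$n_pcs,
    seed = config$seed))
  compartment <- stage("cd45_split", split_by_ptprc(norm, clusters, config$seed + 1L))
  cell_table <- kept |>
    mutate(cluster = unname(clusters[.data$cell_id]),
           compartment = compartment[match(.data$cell_id, colnames(norm))])
  out$clusters <- file.path(outdir, "clusters.csv")
  readr::write_csv(select(cell_table, "cell_id", "sample_id", "condition",
                          "total_counts", "n_features", "pct_mito",
                          "cluster", "compartment"), out$clusters)

  # malignancy: DE, gate, CNV cross-validation
  epi <- filter(cell_table, .data$compartment == "epithelial")
  epi_tumor <- epi$cell_id[epi$condition == config$tumor_condition]
  epi_ctrl <- epi$cell_id[epi$condition == config$control_condition]
  deg <- stage("differential_expression",
               differential_expression(norm, epi_tumor, epi_ctrl))
  out$deg <- file.path(outdir, "deg.csv")
  readr::write_csv(deg, out$deg)
  deg_sig <- deg$gene[deg$log2fc > config$deg_log2fc_threshold]
  if (!length(deg_sig)) abort("pipeline stage 'malignancy' failed: no up-regulated DEGs")
  epi_norm <- norm[, epi$cell_id, drop = FALSE]
  mal_score <- stage("malignancy_score", switch(config$scoring_method,
    sum_ratio = score_sum_ratio(epi_norm, deg_sig),
    rank_auc = score_rank_auc(epi_norm, deg_sig, rank_max = config$rank_max)))
  gate <- stage("malignancy_gate", malignancy_gate(
    tibble(cell_id = epi$cell_id, condition = epi$condition,
           score = unname(mal_score)),
    tumor = config$tumor_condition, control = config$control_condition,
    probs = config$gate_quantile))
  out$gate <- file.path(outdir, "gate.csv")
  readr::write_csv(tidy(gate), out$gate)
  cnv <- stage("cnv", infer_cnv_windows(epi_norm, genes, epi_ctrl,
                                        window_size = config$cnv_window_size,
                                        clip = config$cnv_clip))
  out$cnv_burden <- file.path(outdir, "cnv_burden.csv")
  readr::write_csv(tidy(cnv), out$cnv_burden)
  conc <- cnv_concordance(gate, cnv, burden_quantile = config$burden_quantile)
  out$cnv_concordance <- file.path(outdir, "cnv_concordance.csv")
  readr::write_csv(mutate(conc$confusion, agreement = conc$agreement,
                          burden_threshold = conc$burden_threshold),
                   out$cnv_concordance)

  # signature scoring (all cells, all shipped signatures)
  scores <- stage("signatures", score_signatures(
    norm, signatures, method = config$scoring_method, rank_max = config$rank_max))
  out$scores <- file.path(outdir, "scores.csv")
  readr::write_csv(scores, out$scores)

  # progressive immune gating + activation + proportions
  imm_ids <- cell_table$cell_id[cell_table$compartment == "immune"]
  annotation <- stage("immune_gating", progressive_annotate(
    filter(scores, .data$cell_id %in% imm_ids), tree))
  annotation <- left_join(annotation,
                          select(cell_table, "cell_id", "condition"), by = "cell_id")
  if (!is.null(config$activation_signatures) &&
      all(config$activation_signatures %in% names(scores))) {
    act <- activation_state(scores, config$activation_signatures[1],
                            config$activation_signatures[2], cell_ids = imm_ids)
    annotation <- left_join(annotation, act, by = "cell_id")
  }
  out$annotation <- file.path(outdir, "annotation.csv")
  readr::write_csv(annotation, out$annotation)
  prop_tab <- table(annotation$condition, annotation$level1)
  prop <- if (all(dim(prop_tab) >= 2)) proportion_test(prop_tab) else
    tibble(statistic = NA_real_, df = NA_real_, p_value = NA_real_)
  prop_counts <- as_tibble(prop_tab, .name_repair = "minimal") |>
    setNames(c("condition", "label", "n"))
  out$proportions <- file.path(outdir, "proportions.csv")
  readr::write_csv(bind_cols(prop_counts,
                             prop[rep(1, nrow(prop_counts)), ]),
                   out$proportions)

  # ligand-receptor communication
  if (config$run_ccc) {
    lr <- read_lr_pairs(inputs$lr)
    malignant_ids <- gate$calls$cell_id[gate$calls$call == "malignant"]
    groups <- bind_rows(
      tibble(cell_id = malignant_ids, group = "tumor"),
      annotation |> filter(.data$leaf != "unclassified") |>
        select("cell_id", group = "leaf")
    )
    ccc <- stage("ccc", permutation_significance(
      norm[, groups$cell_id, drop = FALSE], groups, lr,
      min_cells = config$ccc_min_cells, kh = config$ccc_kh,
      n_permutations = config$ccc_n_permutations, seed = config$seed + 2L))
    out$ccc <- file.path(outdir, "ccc.csv")
    readr::write_csv(as_tibble(ccc), out$ccc)
    out$ccc_pathways <- file.path(outdir, "ccc_pathways.csv")
    readr::write_csv(pathway_probability(ccc), out$ccc_pathways)
  }

  log_path <- file.path(outdir, "run_log.json")
  jsonlite::write_json(list(
    package_version = as.character(utils::packageVersion("sctme")),
    seed = config$seed,
    config = unclass(config),
    inputs = inputs,
    stages = names(out),
    n_cells_in = ncol(counts), n_cells_after_qc = ncol(norm)
  ), log_path, auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  out$run_log <- log_path
  invisible(out)
}

#' Run the spatial analysis stage
#'
#' Gates marker intensities to cell types, builds the proximity graph,
#' clusters neighborhood compositions into niches, computes neighborhood
#' enrichment z-scores, and assigns epithelial/stromal compartments,
#' writing each result as CSV.
#'
#' @param spatial_csv CSV with `cell_id`, `x_um`, `y_um` and the marker
#'   panel columns.
#' @param outdir Results directory.
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list of result paths.
#' @export
run_spatial_pipeline <- function(spatial_csv, outdir, config = pipeline_config()) {
  cells <- readr::read_csv(spatial_csv, col_types = readr::cols(), progress = FALSE)
  if (!dir.exists(outdir)) dir.create(outdir, recursive = TRUE)
  out <- list()
  gated <- gate_cell_types(cells)
  out$types <- file.path(outdir, "spatial_types.csv")
  readr::write_csv(select(gated, "cell_id", "x_um", "y_um", "type"), out$types)
  g <- proximity_graph(gated, max_edge_distance = config$spatial_max_edge)
  out$edges <- file.path(outdir, "spatial_edges.csv")
  readr::write_csv(as_tibble(igraph::as_data_frame(g, what = "edges")), out$edges)
  niches <- niche_clusters(g, setNames(gated$type, gated$cell_id),
                           k_niches = config$spatial_k_niches, seed = config$seed)
  out$niches <- file.path(outdir, "spatial_niches.csv")
  readr::write_csv(niches, out$niches)
  enr <- neighborhood_enrichment(gated, gated$type, k = config$spatial_enrich_k,
                                 n_permutations = config$spatial_n_permutations,
                                 seed = config$seed + 1L)
  out$enrichment <- file.path(outdir, "spatial_enrichment.csv")
  readr::write_csv(tidy(enr), out$enrichment)
  comp <- compartment_assign(gated, gated$type)
  out$compartments <- file.path(outdir, "spatial_compartments.csv")
  readr::write_csv(comp, out$compartments)
  invisible(out)
}
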