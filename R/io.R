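#' Read a 10x-style Matrix Market count triplet
#'
#' Reads a sparse genes-by-cells count matrix from the conventional 10x
#' triplet: a Matrix Market `.mtx` file plus one TSV of gene records and one
#' TSV of cell barcodes. The MTX file is 1-based on disk (format standard);
#' the returned matrix indexes genes and cells by name.
#'
#' @param matrix_path Path to the Matrix Market file.
#' @param genes_path Path to the gene TSV (first column: gene id; an optional
#'   second column is taken as the symbol and used for row names).
#' @param barcodes_path Path to the barcode TSV (one barcode per line).
#' @return A `dgCMatrix` (genes x cells) with unique dimnames.
#' @export
read_counts_mtx <- function(matrix_path, genes_path, barcodes_path) {
  for (p in c(matrix_path, genes_path, barcodes_path)) {
    if (!file.exists(p)) abort(paste0("file not found: ", p))
  }
  m <- Matrix::readMM(matrix_path)
  if (methods::is(m, "nsparseMatrix") || methods::is(m, "lsparseMatrix")) {
    m <- m * 1  # pattern/logical MTX (e.g. an all-zero matrix) to numeric
  }
  genes <- readr::read_tsv(genes_path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
  barcodes <- readr::read_tsv(barcodes_path, col_names = FALSE, col_types = readr::cols(.default = "c"),
                              progress = FALSE)
  if (nrow(m) != nrow(genes)) {
    abort(sprintf("dimension mismatch: %s declares %d rows but %s has %d lines",
                  matrix_path, nrow(m), genes_path, nrow(genes)))
  }
  if (ncol(m) != nrow(barcodes)) {
    abort(sprintf("dimension mismatch: %s declares %d columns but %s has %d lines",
                  matrix_path, ncol(m), barcodes_path, nrow(barcodes)))
  }
  vals <- if (methods::is(m, "sparseMatrix")) m@x else as.vector(m)
  if (length(vals) && (any(vals < 0) || any(vals != round(vals)))) {
    abort("count matrix contains negative or non-integer entries")
  }
  gene_ids <- trimws(genes[[1]])
  cell_ids <- trimws(barcodes[[1]])
  if (anyDuplicated(gene_ids)) abort("duplicate gene identifiers in gene TSV")
  if (anyDuplicated(cell_ids)) abort("duplicate cell identifiers in barcode TSV")
  m <- methods::as(methods::as(m, "CsparseMatrix"), "dMatrix")
  dimnames(m) <- list(gene_ids, cell_ids)
  m
}

#' Write a count matrix as a 10x-style Matrix Market triplet
#'
#' @param counts Genes x cells sparse matrix with dimnames.
#' @param dir Output directory (created if absent). Files are written as
#'   `matrix.mtx`, `features.tsv`, `barcodes.tsv`.
#' @return Invisibly, the three paths written.
#' @export
write_counts_mtx <- function(counts, dir) {
  stopifnot(!is.null(rownames(counts)), !is.null(colnames(counts)))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("matrix.mtx", "features.tsv", "barcodes.tsv"))
  Matrix::writeMM(methods::as(counts, "CsparseMatrix"), paths[1])
  readr::write_tsv(tibble(id = rownames(counts), symbol = rownames(counts)),
                   paths[2], col_names = FALSE)
  readr::write_tsv(tibble(barcode = colnames(counts)), paths[3], col_names = FALSE)
  invisible(paths)
}

#' Read gene signatures from a GMT file
#'
#' One signature per tab-separated line: name, description, then gene
#' symbols. Duplicate symbols within a line are dropped with a warning.
#'
#' @param path GMT file path.
#' @return Named list of character vectors (one per signature, file order).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) return(setNames(list(), character()))
  sigs <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      abort(sprintf("GMT format error at line %d: fewer than 3 tab-separated fields", i))
    }
    genes <- trimws(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warn(sprintf("GMT line %d ('%s'): %d duplicate gene(s) removed",
                   i, fields[[1]], sum(duplicated(genes))))
      genes <- unique(genes)
    }
    if (!length(genes)) abort(sprintf("GMT line %d: empty gene set", i))
    nms[[i]] <- fields[[1]]
    sigs[[i]] <- genes
  }
  setNames(sigs, nms)
}

#' Write gene signatures to a GMT file
#'
#' @param signatures Named list of character vectors.
#' @param path Output path.
#' @param description Description field written per line (recycled).
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(signatures, path, description = "na") {
  stopifnot(length(signatures) == 0 || !is.null(names(signatures)))
  description <- rep_len(description, length(signatures))
  lines <- vapply(seq_along(signatures), function(i) {
    paste(c(names(signatures)[[i]], description[[i]], signatures[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a ligand-receptor pair table
#'
#' CSV with columns `ligand`, `receptor`, `pathway`; multi-subunit genes are
#' separated by `+` (e.g. `"IL12A+IL12B"`).
#'
#' @param path CSV path.
#' @return Tibble with list-columns `ligand_subunits`, `receptor_subunits`.
#' @export
read_lr_pairs <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  tab <- readr::read_csv(path, col_types = readr::cols(.default = "c"), progress = FALSE)
  need <- c("ligand", "receptor", "pathway")
  missing <- setdiff(need, names(tab))
  if (length(missing)) abort(paste0("LR table missing column(s): ", paste(missing, collapse = ", ")))
  lr_pairs(tab)
}

#' Build a validated ligand-receptor pair tibble
#'
#' @param tab Data frame with character columns `ligand`, `receptor`,
#'   `pathway` (subunits `+`-separated).
#' @return Tibble with added list-columns of subunit vectors.
#' @export
lr_pairs <- function(tab) {
  tab <- as_tibble(tab)
  split_subunits <- function(x) map(strsplit(x, "+", fixed = TRUE), trimws)
  tab$ligand_subunits <- split_subunits(tab$ligand)
  tab$receptor_subunits <- split_subunits(tab$receptor)
  bad <- map_int(tab$ligand_subunits, length) == 0 |
    map_int(tab$receptor_subunits, length) == 0
  if (any(bad)) abort("LR table has empty subunit list(s)")
  tab
}
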