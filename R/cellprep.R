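# Perturb-seq preprocessing: the cell dataset container, sgRNA assignment,
# QC filters, depth normalization, variable-feature selection and the
# knockout-efficiency check.

#' Construct a single-cell dataset
#'
#' Holds a genes x cells count matrix together with per-cell totals and
#' mitochondrial fractions (recomputed from the matrix), the cell x guide
#' capture-UMI table, and gene/guide metadata.
#'
#' @param counts Genes x cells matrix of non-negative integer counts with
#'   dimnames (base matrix or any Matrix class).
#' @param gene_meta data.frame with `gene_id` and logical `is_mito`
#'   (additional columns are kept).
#' @param guide_umis data.frame with `cell_id`, `guide_id`, `umis`.
#' @param guide_meta Optional guide annotation (e.g. a `guide_library`)
#'   mapping `guide_id` to `target_gene` and `category`.
#' @return An object of class `cell_dataset` with elements `counts`,
#'   `gene_meta`, `cell_meta` (`cell_id`, `total_counts`, `mito_fraction`),
#'   `guide_umis`, `guide_meta`.
#' @export
cell_dataset <- function(counts, gene_meta, guide_umis,
                         guide_meta = NULL) {
  if (is.null(rownames(counts)) ||
      (ncol(counts) > 0 && is.null(colnames(counts)))) {
    stop("counts must carry gene and cell dimnames")
  }
  if (ncol(counts) == 0 && is.null(colnames(counts))) {
    colnames(counts) <- character(0)
  }
  if (!all(c("gene_id", "is_mito") %in% names(gene_meta))) {
    stop("gene_meta needs gene_id and is_mito")
  }
  if (!identical(as.character(gene_meta$gene_id), rownames(counts))) {
    stop("gene_meta rows must match counts rownames in order")
  }
  if (nrow(guide_umis) > 0 &&
      !all(c("cell_id", "guide_id", "umis") %in% names(guide_umis))) {
    stop("guide_umis needs cell_id, guide_id, umis")
  }
  total <- Matrix::colSums(counts)
  mito <- if (any(gene_meta$is_mito)) {
    Matrix::colSums(counts[gene_meta$is_mito, , drop = FALSE])
  } else {
    numeric(ncol(counts))
  }
  cell_meta <- data.frame(
    cell_id = colnames(counts),
    total_counts = as.numeric(total),
    mito_fraction = ifelse(total > 0, mito / total, 0)
  )
  structure(list(counts = counts, gene_meta = as.data.frame(gene_meta),
                 cell_meta = cell_meta,
                 guide_umis = as.data.frame(guide_umis),
                 guide_meta = if (is.null(guide_meta)) NULL
                              else as.data.frame(guide_meta)),
            class = "cell_dataset")
}

#' @export
dim.cell_dataset <- function(x) dim(x$counts)

#' Write a cell dataset in MatrixMarket dialect
#'
#' Emits `matrix.mtx` (genes x cells), `features.tsv`, `barcodes.tsv` and
#' `guide_umis.tsv` under `dir`.
#'
#' @param dataset A `cell_dataset`.
#' @param dir Output directory (created if missing).
#' @export
write_cell_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "cell_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(methods::as(Matrix::Matrix(dataset$counts, sparse = TRUE),
                               "generalMatrix"), "CsparseMatrix")
  Matrix::writeMM(m, file.path(dir, "matrix.mtx"))
  utils::write.table(dataset$gene_meta, file.path(dir, "features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dataset$cell_meta["cell_id"],
                     file.path(dir, "barcodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(dataset$guide_umis, file.path(dir, "guide_umis.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(dataset$guide_meta)) {
    utils::write.table(dataset$guide_meta, file.path(dir, "guides.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a cell dataset written by [write_cell_dataset()]
#' @param dir Directory holding `matrix.mtx` plus sidecars.
#' @return A `cell_dataset`.
#' @export
read_cell_dataset <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  features <- utils::read.delim(file.path(dir, "features.tsv"))
  barcodes <- utils::read.delim(file.path(dir, "barcodes.tsv"),
                                header = FALSE)[[1]]
  dimnames(m) <- list(features$gene_id, barcodes)
  features$is_mito <- as.logical(features$is_mito)
  guide_umis <- utils::read.delim(file.path(dir, "guide_umis.tsv"))
  guide_path <- file.path(dir, "guides.tsv")
  guide_meta <- if (file.exists(guide_path)) {
    utils::read.delim(guide_path, colClasses = "character")
  }
  cell_dataset(m, features, guide_umis, guide_meta)
}

#' Assign sgRNA identities to cells
#'
#' A guide is "detected" in a cell when its capture UMIs reach `min_umis`;
#' a cell's status is `single`, `multiple` or `none` by the number of
#' detected guides. Only single-guide cells carry an unambiguous
#' perturbation and survive QC.
#'
#' @param dataset A `cell_dataset` (its `guide_meta` supplies the guide to
#'   target-gene map).
#' @param min_umis Detection threshold on capture UMIs.
#' @return data.frame with `cell_id`, `assigned_guides` (comma-joined),
#'   `status`, `target_gene` (single-status cells only; controls get `""`).
#' @export
assign_guides <- function(dataset, min_umis = 3) {
  stopifnot(inherits(dataset, "cell_dataset"))
  gu <- dataset$guide_umis
  det <- gu[gu$umis >= min_umis, , drop = FALSE]
  by_cell <- split(det$guide_id, factor(det$cell_id,
                                        levels = dataset$cell_meta$cell_id))
  n_det <- lengths(by_cell)
  status <- ifelse(n_det == 0, "none", ifelse(n_det == 1, "single", "multiple"))
  assigned <- vapply(by_cell, paste, character(1), collapse = ",")
  target <- rep("", length(by_cell))
  if (!is.null(dataset$guide_meta)) {
    map <- stats::setNames(dataset$guide_meta$target_gene,
                           dataset$guide_meta$guide_id)
    single <- status == "single"
    target[single] <- unname(map[assigned[single]])
    target[is.na(target)] <- ""
  }
  data.frame(cell_id = dataset$cell_meta$cell_id,
             assigned_guides = unname(assigned),
             status = unname(status),
             target_gene = unname(target))
}

#' QC-filter cells
#'
#' Keeps cells with a single detected sgRNA, strictly less than `max_mito`
#' mitochondrial read fraction, and at least `min_rnas` total UMIs
#' (boundary semantics: mito strict `<`, RNA `>=`).
#'
#' @param dataset A `cell_dataset`.
#' @param assignments Output of [assign_guides()].
#' @param max_mito Mitochondrial fraction cutoff (default 0.05).
#' @param min_rnas Minimum total UMIs per cell (default 200).
#' @return The filtered `cell_dataset`; attribute `qc_tallies` reports the
#'   number of cells failing each criterion and the number kept.
#' @export
qc_filter <- function(dataset, assignments, max_mito = 0.05, min_rnas = 200) {
  stopifnot(inherits(dataset, "cell_dataset"))
  a <- assignments[match(dataset$cell_meta$cell_id, assignments$cell_id), ]
  fail_guide <- a$status != "single"
  fail_mito <- !(dataset$cell_meta$mito_fraction < max_mito)
  fail_rna <- !(dataset$cell_meta$total_counts >= min_rnas)
  keep <- !(fail_guide | fail_mito | fail_rna)
  tallies <- c(not_single_guide = sum(fail_guide),
               high_mito = sum(fail_mito),
               low_rna = sum(fail_rna),
               kept = sum(keep))
  out <- cell_dataset(dataset$counts[, keep, drop = FALSE],
                      dataset$gene_meta,
                      dataset$guide_umis[
                        dataset$guide_umis$cell_id %in%
                          dataset$cell_meta$cell_id[keep], , drop = FALSE],
                      dataset$guide_meta)
  attr(out, "qc_tallies") <- tallies
  out
}

#' Depth-normalize expression
#'
#' `log1p` of counts scaled per cell to the median total count, a
#' deterministic monotone normalization; the downstream trajectory uses
#' correlation distances, which are insensitive to the particular monotone
#' choice.
#'
#' @param dataset A `cell_dataset` (typically QC-filtered).
#' @return Dense genes x cells matrix of normalized expression.
#' @export
normalize_expression <- function(dataset) {
  stopifnot(inherits(dataset, "cell_dataset"))
  m <- as.matrix(dataset$counts)
  total <- dataset$cell_meta$total_counts
  target <- stats::median(total)
  scale <- ifelse(total > 0, target / total, 0)
  log1p(sweep(m, 2, scale, "*"))
}

#' Select highly variable features
#'
#' Genes are ranked by standardized dispersion: variance/mean, z-scored
#' within `n_bins` mean-expression bins so that dispersion is compared
#' among genes of similar abundance. Ties break deterministically by gene
#' id. If fewer than `n` genes are present all are returned.
#'
#' @param normalized Genes x cells normalized matrix.
#' @param n Number of features to keep (default 2000).
#' @param n_bins Mean-expression bins for the z-score.
#' @return Character vector of selected gene ids.
#' @export
select_variable_features <- function(normalized, n = 2000, n_bins = 20) {
  g <- nrow(normalized)
  if (g <= n) return(rownames(normalized))
  mu <- rowMeans(normalized)
  v <- apply(normalized, 1, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  bins <- cut(rank(mu, ties.method = "first"),
              breaks = min(n_bins, g), labels = FALSE)
  z <- numeric(g)
  for (b in unique(bins)) {
    i <- bins == b
    s <- stats::sd(disp[i])
    z[i] <- if (is.na(s) || s == 0) 0 else (disp[i] - mean(disp[i])) / s
  }
  ord <- order(-z, rownames(normalized))
  rownames(normalized)[ord][seq_len(n)]
}

#' Knockout-efficiency check
#'
#' One-sided Mann-Whitney test that a targeted gene's normalized expression
#' is reduced in the cells carrying its guides relative to non-targeting
#' control cells.
#'
#' @param dataset A QC-filtered `cell_dataset`.
#' @param assignments Output of [assign_guides()] (single-guide cells are
#'   used).
#' @param gene Target gene id (must be in the expression panel).
#' @param normalized Optional precomputed [normalize_expression()] matrix.
#' @return A list with `p` (one-sided, target < control), `z`,
#'   `n_target`, `n_control`.
#' @export
knockout_efficiency <- function(dataset, assignments, gene,
                                normalized = NULL) {
  stopifnot(inherits(dataset, "cell_dataset"))
  if (!gene %in% rownames(dataset$counts)) {
    stop("gene ", gene, " is not in the expression panel")
  }
  if (is.null(normalized)) normalized <- normalize_expression(dataset)
  a <- assignments[assignments$cell_id %in% dataset$cell_meta$cell_id &
                     assignments$status == "single", ]
  target_cells <- a$cell_id[a$target_gene == gene]
  if (is.null(dataset$guide_meta)) stop("dataset lacks guide metadata")
  nt_guides <- dataset$guide_meta$guide_id[
    dataset$guide_meta$category == "non_targeting"]
  control_cells <- a$cell_id[a$assigned_guides %in% nt_guides]
  if (length(target_cells) == 0) stop("no cells carry guides for ", gene)
  if (length(control_cells) == 0) stop("no non-targeting control cells")
  mw <- mann_whitney(normalized[gene, target_cells],
                     normalized[gene, control_cells], "less")
  list(p = mw$p, z = mw$z, n_target = length(target_cells),
       n_control = length(control_cells))
}
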