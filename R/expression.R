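#' Expression matrix container
#'
#' A light container for a gene x unit (cell or sample) expression matrix
#' together with its transform state. Values are TPM (transcripts per
#' million) when `transform = "raw_tpm"`, or log2 units after one of the
#' two log transforms used throughout the package:
#' single-cell `log2(TPM/10 + 1)` and bulk `log2(TPM + 1)`.
#'
#' @param values numeric matrix, genes in rows, cells/samples in columns;
#'   rownames and colnames are required and must be unique.
#' @param modality `"single_cell"` or `"bulk"`.
#' @param transform `"raw_tpm"`, `"sc_log"` or `"bulk_log"`.
#' @return An object of class `ExpressionMatrix`.
#' @export
ExpressionMatrix <- function(values, modality = c("single_cell", "bulk"),
                             transform = c("raw_tpm", "sc_log", "bulk_log")) {
  modality <- match.arg(modality)
  transform <- match.arg(transform)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene rownames and unit colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene IDs: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate unit IDs: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]),
               collapse = ", "))
  if (any(values < 0, na.rm = TRUE)) stop("expression values must be >= 0")
  if (anyNA(values)) stop("expression values must not contain NA")
  structure(list(values = values, modality = modality, transform = transform),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d %s [%s, %s]\n",
              nrow(x$values), ncol(x$values),
              if (x$modality == "single_cell") "cells" else "samples",
              x$modality, x$transform))
  invisible(x)
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' Gene and unit identifiers
#'
#' @param x an `ExpressionMatrix`.
#' @return Character vector of IDs.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname gene_ids
#' @export
unit_ids <- function(x) colnames(x$values)

new_expression_like <- function(x, values) {
  ExpressionMatrix(values, modality = x$modality, transform = x$transform)
}

#' Read an expression matrix from disk
#'
#' Dense TSV/CSV: first column gene ID, header row of cell/sample IDs.
#' Matrix Market (`mtx`): coordinate file plus sidecar `<prefix>genes.tsv`
#' and `<prefix>barcodes.tsv` (one ID per line), genes in rows.
#'
#' @param path file path (for `mtx`, the `.mtx` file; sidecars are looked
#'   up next to it, or can be given explicitly).
#' @param format `"tsv"`, `"csv"` or `"mtx"`.
#' @param modality `"single_cell"` or `"bulk"`.
#' @param genes_path,units_path optional explicit sidecar paths for `mtx`.
#' @return An `ExpressionMatrix` with `transform = "raw_tpm"`.
#' @export
load_expression <- function(path, format = c("tsv", "csv", "mtx"),
                            modality = c("single_cell", "bulk"),
                            genes_path = NULL, units_path = NULL) {
  format <- match.arg(format)
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format %in% c("tsv", "csv")) {
    sep <- if (format == "tsv") "\t" else ","
    df <- tryCatch(
      utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                        stringsAsFactors = FALSE, comment.char = ""),
      error = function(e) stop("failed to parse ", path, ": ",
                               conditionMessage(e)))
    if (ncol(df) < 2) stop("expression table needs a gene column plus >= 1 unit")
    genes <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric expression values in ", path)
    rownames(m) <- genes
  } else {
    dir <- dirname(path)
    stem <- sub("\\.mtx$", "", basename(path))
    gp <- genes_path %||% .first_existing(
      file.path(dir, c(paste0(stem, "_genes.tsv"), "genes.tsv")))
    up <- units_path %||% .first_existing(
      file.path(dir, c(paste0(stem, "_barcodes.tsv"), "barcodes.tsv")))
    if (is.null(gp) || is.null(up))
      stop("mtx sidecar genes.tsv / barcodes.tsv not found next to ", path)
    mm <- as.matrix(Matrix::readMM(path))
    genes <- readLines(gp)
    units <- readLines(up)
    if (length(genes) != nrow(mm) || length(units) != ncol(mm))
      stop("mtx dimensions do not match sidecar files")
    rownames(mm) <- genes
    colnames(mm) <- units
    m <- mm
  }
  ExpressionMatrix(m, modality = modality, transform = "raw_tpm")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.first_existing <- function(paths) {
  hit <- paths[file.exists(paths)]
  if (length(hit)) hit[[1]] else NULL
}

#' Single-cell log transform
#'
#' Converts single-cell TPM to `log2(TPM/10 + 1)`. The division by 10
#' deflates library-complexity inflation of TPM in single cells, where a
#' library contains on the order of 100,000 transcripts so TPM counts each
#' transcript roughly ten times.
#'
#' @param m an `ExpressionMatrix` with `modality = "single_cell"` and
#'   `transform = "raw_tpm"`.
#' @return The transformed `ExpressionMatrix` (`transform = "sc_log"`).
#' @export
sc_log_transform <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$modality != "single_cell") stop("sc_log_transform requires single-cell data")
  if (m$transform != "raw_tpm") stop("matrix already transformed: ", m$transform)
  out <- m
  out$values <- log2(m$values / 10 + 1)
  out$transform <- "sc_log"
  out
}

#' Bulk log transform
#'
#' Converts bulk TPM to `log2(TPM + 1)`.
#'
#' @param m an `ExpressionMatrix` with `modality = "bulk"` and
#'   `transform = "raw_tpm"`.
#' @return The transformed `ExpressionMatrix` (`transform = "bulk_log"`).
#' @export
bulk_log_transform <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$modality != "bulk") stop("bulk_log_transform requires bulk data")
  if (m$transform != "raw_tpm") stop("matrix already transformed: ", m$transform)
  out <- m
  out$values <- log2(m$values + 1)
  out$transform <- "bulk_log"
  out
}

#' Invert a log transform back to TPM
#'
#' @param m a transformed `ExpressionMatrix`.
#' @return An `ExpressionMatrix` with `transform = "raw_tpm"`.
#' @export
invert_log_transform <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  out <- m
  out$values <- switch(m$transform,
    sc_log = (2^m$values - 1) * 10,
    bulk_log = 2^m$values - 1,
    stop("matrix is not log-transformed"))
  out$values[out$values < 0] <- 0  # guard tiny negative round-off
  out$transform <- "raw_tpm"
  out
}

#' Quality-control filter for cells
#'
#' Retains cells with at least `min_genes` expressed genes (expression
#' strictly above zero after the single-cell log transform) and a mean
#' log expression over the housekeeping panel of at least `min_hk`.
#' Housekeeping genes absent from the matrix are ignored; at least one
#' must be present.
#'
#' @param m an `ExpressionMatrix` with `transform = "sc_log"`.
#' @param housekeeping character vector of housekeeping gene IDs.
#' @param min_genes minimum number of expressed genes per cell (default 2000).
#' @param min_hk minimum mean housekeeping log expression (default 2.5).
#' @return The filtered `ExpressionMatrix`, with a per-cell QC report in
#'   attribute `"qc_report"` (data.frame: cell_id, n_expressed, hk_mean, kept).
#' @export
qc_filter_cells <- function(m, housekeeping, min_genes = 2000, min_hk = 2.5) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$transform != "sc_log") stop("qc_filter_cells expects sc_log expression")
  if (length(housekeeping) == 0) stop("housekeeping list is empty")
  hk <- intersect(housekeeping, gene_ids(m))
  if (length(hk) == 0) stop("no housekeeping gene found in the matrix")
  n_expr <- colSums(m$values > 0)
  hk_mean <- colMeans(m$values[hk, , drop = FALSE])
  keep <- n_expr >= min_genes & hk_mean >= min_hk
  report <- data.frame(cell_id = unit_ids(m), n_expressed = as.integer(n_expr),
                       hk_mean = as.numeric(hk_mean), kept = as.logical(keep),
                       row.names = NULL, stringsAsFactors = FALSE)
  if (!any(keep)) warning("all cells removed by QC")
  out <- m
  out$values <- m$values[, keep, drop = FALSE]
  attr(out, "qc_report") <- report
  out
}

#' Aggregate expression of each gene across cells
#'
#' `Ea(i) = log2(mean TPM across cells + 1)`, computed over the
#' QC-passing cells.
#'
#' @param m an `ExpressionMatrix` of raw single-cell TPM restricted to
#'   QC-passing cells.
#' @return Named numeric vector of aggregate expression per gene.
#' @export
aggregate_expression <- function(m) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$transform != "raw_tpm") stop("aggregate_expression expects raw TPM")
  if (ncol(m$values) == 0) stop("no cells to aggregate over")
  log2(rowMeans(m$values) + 1)
}

#' Gene filter for single-cell profiles
#'
#' Retains genes with aggregate expression strictly above `ea_min` and
#' detected (TPM > 0) in at least `min_detect_frac` of cells. Both
#' statistics are computed on the raw TPM restricted to QC-passing cells.
#'
#' @param m the `ExpressionMatrix` to subset (any transform; same genes as
#'   `tpm`).
#' @param tpm raw-TPM `ExpressionMatrix` over QC-passing cells.
#' @param ea_min aggregate-expression threshold (strict, default 2).
#' @param min_detect_frac minimum detection fraction (inclusive, default 0.2).
#' @return `m` restricted to the passing genes, input gene order preserved.
#' @export
filter_genes_sc <- function(m, tpm = m, ea_min = 2, min_detect_frac = 0.2) {
  stopifnot(inherits(m, "ExpressionMatrix"), inherits(tpm, "ExpressionMatrix"))
  if (tpm$transform != "raw_tpm") stop("`tpm` must be raw TPM")
  if (!identical(gene_ids(m), gene_ids(tpm)))
    stop("`m` and `tpm` must have identical gene sets in the same order")
  ea <- aggregate_expression(tpm)
  detect <- rowMeans(tpm$values > 0)
  keep <- ea > ea_min & detect >= min_detect_frac
  out <- m
  out$values <- m$values[keep, , drop = FALSE]
  out
}

#' Sample and gene filter for bulk profiles
#'
#' Discards samples with fewer than `min_genes` expressed genes
#' (log expression strictly above zero), then retains genes detected in at
#' least `min_detect_frac` of the remaining samples.
#'
#' @param m an `ExpressionMatrix` with `transform = "bulk_log"`.
#' @param min_genes minimum expressed genes per sample (default 2000).
#' @param min_detect_frac minimum detection fraction over kept samples
#'   (default 0.2).
#' @return The filtered `ExpressionMatrix`.
#' @export
filter_bulk <- function(m, min_genes = 2000, min_detect_frac = 0.2) {
  stopifnot(inherits(m, "ExpressionMatrix"))
  if (m$transform != "bulk_log") stop("filter_bulk expects bulk_log expression")
  keep_s <- colSums(m$values > 0) >= min_genes
  v <- m$values[, keep_s, drop = FALSE]
  if (ncol(v) == 0) {
    warning("all samples removed by bulk filter")
    out <- m; out$values <- v[0, , drop = FALSE]; return(out)
  }
  keep_g <- rowMeans(v > 0) >= min_detect_frac
  if (!any(keep_g)) warning("all genes removed by bulk filter")
  out <- m
  out$values <- v[keep_g, , drop = FALSE]
  out
}

#' Select tested genes
#'
#' Tested genes are those detected (post-filter) in both the single-cell
#' and the bulk profile and annotated with at least `min_terms` terms.
#'
#' @param sc filtered single-cell `ExpressionMatrix`.
#' @param bulk filtered bulk `ExpressionMatrix`, or `NULL` to skip the
#'   bulk requirement (synthetic single-profile runs).
#' @param ann an `AnnotationSet` (typically ancestor-propagated).
#' @param min_terms minimum number of annotated terms (default 2).
#' @return Character vector of gene IDs in lexicographic order.
#' @export
select_tested_genes <- function(sc, bulk, ann, min_terms = 2) {
  stopifnot(inherits(sc, "ExpressionMatrix"), inherits(ann, "AnnotationSet"))
  g <- gene_ids(sc)
  if (!is.null(bulk)) {
    stopifnot(inherits(bulk, "ExpressionMatrix"))
    g <- intersect(g, gene_ids(bulk))
  }
  counts <- table(ann$pairs$gene_id)
  annotated <- names(counts)[counts >= min_terms]
  out <- sort(intersect(g, annotated))
  if (length(out) == 0) stop("no tested genes: empty intersection")
  out
}

#' Read cell metadata
#'
#' @param path TSV with columns cell_id, sample_id, cell_type, platform.
#' @return data.frame with those columns.
#' @export
load_cell_metadata <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("cell_id", "sample_id", "cell_type", "platform")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("metadata missing columns: ", paste(miss, collapse = ", "))
  if (anyDuplicated(df$cell_id)) stop("duplicate cell_id in metadata")
  df[, need]
}
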