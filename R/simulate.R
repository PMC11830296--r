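#' Configuration for the synthetic single-cell generator
#'
#' Describes a zero-inflated single-cell TPM matrix with planted
#' co-expression modules. Each module is a set of genes sharing a latent
#' per-cell activity; module genes co-vary on the log scale with effect
#' size `module_activity`. Dropout is mean-dependent: the probability of
#' observing a transcript follows a logistic curve in the cell- and
#' gene-specific log2 abundance, centered at `dropout_midpoint` with
#' steepness `dropout_slope`. Housekeeping genes are high-mean and
#' low-variance, so they survive dropout almost everywhere. Each module
#' is tied to one synthetic ontology term; `module_restriction` limits a
#' module's activity to chosen strata (cell types or samples), which is
#' what creates stratum-specific recallable function.
#'
#' Defaults describe the reference benchmark condition used throughout
#' the package: 1000 cells, 10 modules of 30 genes, 600 background genes,
#' 50 housekeeping genes, and dropout tuned to roughly 60 % zeros.
#'
#' @param n_cells number of cells (default 1000).
#' @param n_modules number of planted modules (default 10).
#' @param genes_per_module genes per module (default 30).
#' @param n_background unannotated background genes (default 600).
#' @param n_housekeeping housekeeping genes (default 50).
#' @param module_activity log2-scale effect size of module activity
#'   (default 1.5).
#' @param noise_sd per-gene lognormal noise sd on the log2 scale
#'   (default 1).
#' @param baseline_range range of per-gene baseline log2 abundance
#'   (default c(4, 8)).
#' @param dropout_midpoint logistic dropout midpoint on the log2 abundance
#'   scale (default 6.8, giving ~60 % zeros under the other defaults).
#' @param dropout_slope logistic steepness (default 1).
#' @param n_samples number of donors/samples (default 4).
#' @param cell_types character vector of cell-type labels
#'   (default c("tumor", "immune")).
#' @param platform platform label recorded in the metadata
#'   (default "tenx").
#' @param module_restriction optional named list mapping `"M01"`-style
#'   module IDs to a list with elements `cell_type` and/or `sample` giving
#'   the strata in which the module is active; unrestricted modules are
#'   active everywhere.
#' @param annotation_noise fraction of spurious gene-term pairs added on
#'   top of the true ones (default 0.05).
#' @param seed integer seed.
#' @return A `SyntheticConfig` list.
#' @export
synthetic_config <- function(n_cells = 1000, n_modules = 10,
                             genes_per_module = 30, n_background = 600,
                             n_housekeeping = 50, module_activity = 1.5,
                             noise_sd = 1, baseline_range = c(4, 8),
                             dropout_midpoint = 6.8, dropout_slope = 1,
                             n_samples = 4,
                             cell_types = c("tumor", "immune"),
                             platform = "tenx",
                             module_restriction = NULL,
                             annotation_noise = 0.05, seed = 1) {
  cfg <- list(n_cells = n_cells, n_modules = n_modules,
              genes_per_module = genes_per_module,
              n_background = n_background,
              n_housekeeping = n_housekeeping,
              module_activity = module_activity, noise_sd = noise_sd,
              baseline_range = baseline_range,
              dropout_midpoint = dropout_midpoint,
              dropout_slope = dropout_slope, n_samples = n_samples,
              cell_types = cell_types, platform = platform,
              module_restriction = module_restriction,
              annotation_noise = annotation_noise, seed = seed)
  if (n_modules < 1 || genes_per_module < 1 || n_cells < 2)
    stop("infeasible synthetic configuration")
  if (module_activity <= 0) stop("module_activity must be > 0")
  if (annotation_noise < 0 || annotation_noise >= 1)
    stop("annotation_noise must lie in [0, 1)")
  structure(cfg, class = "SyntheticConfig")
}

module_id <- function(i) sprintf("M%02d", i)

#' Generate a synthetic single-cell dataset
#'
#' Draws cell strata, per-cell module activities (zeroed outside a
#' module's active strata), log-normal expression, mean-dependent logistic
#' dropout, and per-cell TPM rescaling to one million; emits matched
#' annotations (module genes to module terms, under a shallow is_a tree
#' root -> three mid-level terms -> module terms, plus a configurable
#' fraction of spurious pairs) and the ground truth.
#'
#' @param cfg a [synthetic_config()].
#' @return List with elements `expr` (raw-TPM `ExpressionMatrix`),
#'   `meta` (cell metadata data.frame), `ann` (`AnnotationSet`, leaf
#'   annotations only), `dag` (`OntologyDAG`), and `truth` (module gene
#'   sets, module terms, stratum activity map).
#' @export
generate_sc_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  withr_seed(cfg$seed, .generate_sc_dataset_impl(cfg))
}

.generate_sc_dataset_impl <- function(cfg) {
  n_mod_genes <- cfg$n_modules * cfg$genes_per_module
  mod_ids <- module_id(seq_len(cfg$n_modules))
  gene_names <- c(
    unlist(lapply(seq_len(cfg$n_modules), function(m)
      sprintf("%sG%03d", mod_ids[m], seq_len(cfg$genes_per_module)))),
    sprintf("BG%04d", seq_len(cfg$n_background)),
    sprintf("HK%03d", seq_len(cfg$n_housekeeping)))
  G <- length(gene_names)
  N <- cfg$n_cells
  is_hk <- startsWith(gene_names, "HK")
  module_of <- c(rep(seq_len(cfg$n_modules), each = cfg$genes_per_module),
                 rep(NA_integer_, cfg$n_background + cfg$n_housekeeping))

  # cell strata
  sample_id <- sprintf("S%02d", sample.int(cfg$n_samples, N, replace = TRUE))
  cell_type <- sample(cfg$cell_types, N, replace = TRUE)
  meta <- data.frame(cell_id = sprintf("C%05d", seq_len(N)),
                     sample_id = sample_id, cell_type = cell_type,
                     platform = cfg$platform, stringsAsFactors = FALSE)

  # per-gene baselines (log2 abundance); housekeeping high and tight
  baseline <- stats::runif(G, cfg$baseline_range[1], cfg$baseline_range[2])
  baseline[is_hk] <- stats::runif(sum(is_hk), 9, 10)

  # module activity per cell, zeroed outside the active strata
  active <- matrix(TRUE, cfg$n_modules, N)
  restr <- cfg$module_restriction
  if (!is.null(restr)) {
    for (mid in names(restr)) {
      m <- match(mid, mod_ids)
      if (is.na(m)) stop("unknown module in restriction: ", mid)
      on <- rep(TRUE, N)
      if (!is.null(restr[[mid]]$cell_type))
        on <- on & cell_type %in% restr[[mid]]$cell_type
      if (!is.null(restr[[mid]]$sample))
        on <- on & sample_id %in% restr[[mid]]$sample
      active[m, ] <- on
    }
  }
  activity <- matrix(stats::rnorm(cfg$n_modules * N), cfg$n_modules, N) * active

  # log2 expression: baseline + module loading + noise
  L <- matrix(baseline, G, N)
  has_mod <- !is.na(module_of)
  L[has_mod, ] <- L[has_mod, ] +
    cfg$module_activity * activity[module_of[has_mod], , drop = FALSE]
  noise <- matrix(stats::rnorm(G * N, sd = cfg$noise_sd), G, N)
  noise[is_hk, ] <- noise[is_hk, ] * 0.25
  L <- L + noise

  # mean-dependent dropout (housekeeping mostly survives via high mean)
  keep_p <- stats::plogis(cfg$dropout_slope * (L - cfg$dropout_midpoint))
  kept <- matrix(stats::runif(G * N) < keep_p, G, N)
  X <- 2^L * kept

  # per-cell TPM rescaling
  X <- sweep(X, 2, colSums(X), "/") * 1e6
  dimnames(X) <- list(gene_names, meta$cell_id)
  expr <- ExpressionMatrix(X, modality = "single_cell",
                           transform = "raw_tpm")

  # ontology: root -> 3 mid-level terms -> one leaf term per module
  leaf <- sprintf("SYN:%07d", 100 + seq_len(cfg$n_modules))
  mids <- sprintf("SYN:%07d", 10 + seq_len(3))
  root <- "SYN:0000001"
  parents <- c(stats::setNames(as.list(mids[(seq_len(cfg$n_modules) - 1) %% 3 + 1]),
                               leaf),
               stats::setNames(replicate(3, root, simplify = FALSE), mids),
               stats::setNames(list(character()), root))
  dag <- OntologyDAG(parents)

  module_genes <- split(gene_names[has_mod], module_of[has_mod])
  names(module_genes) <- mod_ids
  true_pairs <- data.frame(
    gene_id = unlist(module_genes, use.names = FALSE),
    term_id = rep(leaf, vapply(module_genes, length, 0L)),
    evidence = "IDA", stringsAsFactors = FALSE)
  n_noise <- round(cfg$annotation_noise * nrow(true_pairs))
  if (n_noise > 0) {
    noise_pairs <- data.frame(
      gene_id = sample(gene_names[!is_hk], n_noise, replace = TRUE),
      term_id = sample(leaf, n_noise, replace = TRUE),
      evidence = "IEP", stringsAsFactors = FALSE)
    true_pairs <- rbind(true_pairs, noise_pairs)
  }
  ann <- AnnotationSet(true_pairs)

  truth <- list(module_genes = module_genes,
                module_terms = stats::setNames(leaf, mod_ids),
                restriction = restr)
  list(expr = expr, meta = meta, ann = ann, dag = dag, truth = truth)
}

#' Pseudobulk profiles from single-cell TPM
#'
#' Each bulk sample is the mean TPM over a seeded bootstrap of cells
#' (optionally drawn within one `sample_id` stratum per bulk sample),
#' rescaled back to TPM. Averaging fills dropout zeros, so pseudobulk is
#' far less zero-inflated than its single-cell input.
#'
#' @param sc raw-TPM single-cell `ExpressionMatrix`.
#' @param meta cell metadata (used when `by_sample = TRUE`).
#' @param n_bulk_samples number of bulk profiles (>= 2).
#' @param seed integer seed.
#' @param by_sample draw each bulk profile from one donor's cells,
#'   cycling through donors?
#' @param cells_per_sample bootstrap draw size (default: all cells of the
#'   stratum, or all cells).
#' @return A raw-TPM bulk `ExpressionMatrix`.
#' @export
generate_pseudobulk <- function(sc, meta = NULL, n_bulk_samples = 10,
                                seed = 1, by_sample = FALSE,
                                cells_per_sample = NULL) {
  stopifnot(inherits(sc, "ExpressionMatrix"))
  if (sc$transform != "raw_tpm") stop("pseudobulk expects raw TPM input")
  if (n_bulk_samples < 2) stop("need at least 2 bulk samples")
  N <- ncol(sc$values)
  if (N < 2) stop("need at least 2 cells")
  withr_seed(seed, {
    cols <- lapply(seq_len(n_bulk_samples), function(b) {
      pool <- seq_len(N)
      if (by_sample) {
        if (is.null(meta)) stop("`meta` required when by_sample = TRUE")
        sids <- sort(unique(meta$sample_id))
        sid <- sids[(b - 1) %% length(sids) + 1]
        pool <- which(meta$sample_id[match(unit_ids(sc), meta$cell_id)] == sid)
      }
      k <- cells_per_sample %||% length(pool)
      idx <- sample(pool, k, replace = TRUE)
      v <- rowMeans(sc$values[, idx, drop = FALSE])
      v / sum(v) * 1e6
    })
    B <- do.call(cbind, cols)
    colnames(B) <- sprintf("BULK%03d", seq_len(n_bulk_samples))
    rownames(B) <- gene_ids(sc)
    ExpressionMatrix(B, modality = "bulk", transform = "raw_tpm")
  })
}

#' Write a synthetic dataset bundle to disk
#'
#' Emits the single-cell matrix as dense TSV and Matrix Market MTX (with
#' `genes.tsv` / `barcodes.tsv` sidecars), cell metadata TSV, annotations
#' as two-column+evidence TSV and GAF, the ontology as OBO, and the
#' ground truth as JSON. Everything round-trips through the package
#' loaders.
#'
#' @param data result of [generate_sc_dataset()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_fixture_bundle <- function(data, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- c(sc_tsv = file.path(dir, "sc_tpm.tsv"),
         sc_mtx = file.path(dir, "sc_tpm.mtx"),
         genes = file.path(dir, "genes.tsv"),
         barcodes = file.path(dir, "barcodes.tsv"),
         meta = file.path(dir, "cell_metadata.tsv"),
         ann_tsv = file.path(dir, "annotations.tsv"),
         ann_gaf = file.path(dir, "annotations.gaf"),
         obo = file.path(dir, "ontology.obo"),
         truth = file.path(dir, "ground_truth.json"))
  X <- data$expr$values
  utils::write.table(data.frame(gene_id = rownames(X), X,
                                check.names = FALSE),
                     p[["sc_tsv"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  Matrix::writeMM(Matrix::Matrix(X, sparse = TRUE), p[["sc_mtx"]])
  writeLines(rownames(X), p[["genes"]])
  writeLines(colnames(X), p[["barcodes"]])
  utils::write.table(data$meta, p[["meta"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data$ann$pairs, p[["ann_tsv"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_gaf(data$ann, p[["ann_gaf"]])
  write_obo(data$dag, p[["obo"]])
  jsonlite::write_json(data$truth, p[["truth"]], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(p)
}

#' Write an AnnotationSet as GAF 2.2
#'
#' @param ann an `AnnotationSet`.
#' @param path output path.
#' @export
write_gaf <- function(ann, path) {
  stopifnot(inherits(ann, "AnnotationSet"))
  p <- ann$pairs
  ev <- ifelse(is.na(p$evidence), "IDA", p$evidence)
  rows <- paste("SYNDB", p$gene_id, p$gene_id, "", p$term_id, "SYN:ref", ev,
                "", "P", "", "", "protein", "taxon:9606", "20260101",
                "SYNDB", "", "", sep = "\t")
  writeLines(c("!gaf-version: 2.2", rows), path)
}

#' Write an OntologyDAG as OBO 1.4
#'
#' @param dag an `OntologyDAG`.
#' @param path output path.
#' @export
write_obo <- function(dag, path) {
  stopifnot(inherits(dag, "OntologyDAG"))
  stanzas <- vapply(dag$terms, function(t) {
    is_a <- dag$parents[[t]] %||% character()
    paste(c("[Term]", paste0("id: ", t),
            if (length(is_a)) paste0("is_a: ", is_a), ""),
          collapse = "\n")
  }, "")
  writeLines(c("format-version: 1.4", "", stanzas), path)
}
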