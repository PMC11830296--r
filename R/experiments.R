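#' Derive a child seed from a base seed
#'
#' All experiment drivers route randomness through one base seed and
#' derive a distinct, reproducible child seed per stage/repeat.
#'
#' @param seed base integer seed.
#' @param ... integers identifying the stage (stream, repeat index, ...).
#' @return An integer below 2^31.
#' @export
derive_seed <- function(seed, ...) {
  ks <- c(seed, ...)
  s <- 0
  for (k in ks) s <- (s * 7919 + (as.numeric(k) %% 104729) + 1) %% 2147483629
  as.integer(s) + 1L
}

#' Run the full prediction-and-evaluation pipeline on one profile
#'
#' Composes the standard stages: single-cell log transform, cell QC,
#' gene filtering on QC-passing cells, co-expression network
#' construction, tested-gene selection, neighbor-voting relevance
#' scores over the evaluation terms, gene-centric evaluation (average PR
#' curve, Fmax, and IC-weighted RU-MI with Smin), predictions and
#' recalled sets at the Fmax threshold (or a fixed threshold), and
#' optionally term-centric cross-validated AUROC.
#'
#' @param tpm raw-TPM single-cell `ExpressionMatrix`.
#' @param ann an `AnnotationSet`; propagated with `dag` when given.
#' @param dag optional `OntologyDAG` for ancestor propagation.
#' @param housekeeping housekeeping gene IDs for cell QC.
#' @param variant a `NetworkVariantSpec` (default signed Spearman on all
#'   cells).
#' @param bulk optional filtered bulk `ExpressionMatrix`; when given,
#'   tested genes must also be detected there.
#' @param qc list of filter settings: `min_genes`, `min_hk`, `ea_min`,
#'   `min_detect_frac` (defaults 2000, 2.5, 2, 0.2).
#' @param term_bounds inclusive annotated-gene bounds for evaluation
#'   terms (default c(20, 1000)).
#' @param threshold `"fmax"` or a fixed numeric threshold in (0, 1].
#' @param restrict_tested optional gene IDs intersected with the tested
#'   set (used by the fixed-cell-count platform comparison).
#' @param term_centric run the cross-validated term-centric evaluation?
#' @param folds CV folds for the term-centric evaluation.
#' @param min_overlap minimum co-detected cells for "_dp" variants.
#' @param seed integer seed (CV fold splits).
#' @return A list with `eval` (`EvaluationResult`), `pred`
#'   (`PredictionResult` at the chosen threshold), `term_eval` (per-term
#'   CV AUROCs and their mean, or NULL), `scores`, `tested_genes`,
#'   `eval_terms`, `network_genes`, `n_cells`, and `threshold`.
#' @export
run_pipeline <- function(tpm, ann, dag = NULL, housekeeping,
                         variant = network_variant("spearman"),
                         bulk = NULL, qc = list(),
                         term_bounds = c(20, 1000), threshold = "fmax",
                         restrict_tested = NULL, term_centric = TRUE,
                         folds = 10, min_overlap = 10, seed = 1) {
  stopifnot(inherits(tpm, "ExpressionMatrix"), inherits(ann, "AnnotationSet"))
  qc <- utils::modifyList(list(min_genes = 2000, min_hk = 2.5, ea_min = 2,
                               min_detect_frac = 0.2), qc)
  if (!is.null(dag)) ann <- propagate_to_ancestors(ann, dag)

  lg <- sc_log_transform(tpm)
  lg <- qc_filter_cells(lg, housekeeping, min_genes = qc$min_genes,
                        min_hk = qc$min_hk)
  tpm_qc <- tpm
  tpm_qc$values <- tpm$values[, unit_ids(lg), drop = FALSE]
  lg <- filter_genes_sc(lg, tpm_qc, ea_min = qc$ea_min,
                        min_detect_frac = qc$min_detect_frac)
  # housekeeping genes carry no annotations and only serve QC
  keep <- !gene_ids(lg) %in% housekeeping
  lg$values <- lg$values[keep, , drop = FALSE]

  net <- build_network(lg, variant, min_overlap = min_overlap)
  tested <- select_tested_genes(lg, bulk, ann, min_terms = 2)
  if (!is.null(restrict_tested)) {
    tested <- intersect(tested, restrict_tested)
    if (length(tested) == 0) stop("restriction empties the tested-gene set")
  }
  ic <- information_content(ann)
  eval_terms <- select_evaluation_terms(ann, term_bounds[1], term_bounds[2])
  eval_terms <- eval_terms[
    eval_terms %in% ann$pairs$term_id[ann$pairs$gene_id %in% gene_ids(lg)]]
  if (length(eval_terms) == 0) stop("no evaluation term annotates a network gene")

  scores <- suppressWarnings(
    relevance_scores(net, ann, genes = tested, terms = eval_terms))
  ev <- suppressWarnings(evaluate_gene_centric(scores, ann, ic = ic))
  t_used <- if (identical(threshold, "fmax")) threshold_at_fmax(ev)
            else threshold
  pred <- predict_at_threshold(scores, ann, t_used)

  term_eval <- NULL
  if (term_centric) {
    counts <- table(ann$pairs$term_id[ann$pairs$gene_id %in% gene_ids(lg)])
    cv_terms <- eval_terms[counts[eval_terms] >= folds]
    if (length(cv_terms))
      term_eval <- suppressWarnings(
        evaluate_term_centric(net, ann, cv_terms, folds = folds, seed = seed))
  }
  list(eval = ev, pred = pred, term_eval = term_eval, scores = scores,
       tested_genes = tested, eval_terms = eval_terms,
       network_genes = gene_ids(lg), n_cells = ncol(lg$values),
       threshold = t_used)
}

#' Run the pipeline per stratum
#'
#' Splits the cells by cell type or by sample, and runs the full pipeline
#' within each stratum. Gene filters and networks are recomputed per
#' stratum, so a gene may be tested in one stratum and not another.
#' Strata with fewer than `min_cells` cells are skipped with a warning.
#'
#' @inheritParams run_pipeline
#' @param meta cell metadata data.frame (cell_id, sample_id, cell_type,
#'   platform).
#' @param by `"cell_type"` or `"sample"`.
#' @param min_cells minimum cells per stratum (default 50).
#' @param ... forwarded to [run_pipeline()].
#' @return Named list of pipeline results, one per retained stratum.
#' @export
run_stratified <- function(tpm, meta, ann, by = c("cell_type", "sample"),
                           min_cells = 50, ...) {
  by <- match.arg(by)
  col <- if (by == "sample") "sample_id" else "cell_type"
  strat <- meta[[col]][match(unit_ids(tpm), meta$cell_id)]
  if (anyNA(strat)) stop("cells missing from metadata")
  out <- list()
  for (s in sort(unique(strat))) {
    idx <- which(strat == s)
    if (length(idx) < min_cells) {
      warning("stratum ", s, " skipped (", length(idx), " cells < ",
              min_cells, ")")
      next
    }
    sub <- tpm
    sub$values <- tpm$values[, idx, drop = FALSE]
    out[[s]] <- run_pipeline(sub, ann, ...)
  }
  if (length(out) == 0) stop("no stratum passed the cell-count cutoff")
  out
}

#' Stratum-specific recalled terms and genes
#'
#' Given per-stratum predictions (each at its own Fmax threshold), a
#' recalled term is stratum-specific for a gene when it is recalled in at
#' least one but not all of the strata in which the gene was tested;
#' stratum-specific recalled genes of a term are defined symmetrically.
#' Only genes (terms) observable in at least two strata enter the
#' denominators.
#'
#' @param runs named list of pipeline results (or of `PredictionResult`
#'   objects) from >= 2 strata.
#' @return A `SpecificityReport` list: `gene_ratio` (fraction of genes
#'   with >= 1 stratum-specific recalled term), `term_ratio` (fraction of
#'   terms with >= 1 stratum-specific recalled gene), plus the per-gene
#'   and per-term specific sets.
#' @export
specificity_analysis <- function(runs) {
  if (length(runs) < 2) stop("need >= 2 strata")
  preds <- lapply(runs, function(r)
    if (inherits(r, "PredictionResult")) r else r$pred)
  strata <- names(preds)

  # genes: recalled terms per stratum where the gene was tested
  tested_in <- lapply(preds, function(p) names(p$recalled_terms))
  all_genes <- sort(unique(unlist(tested_in)))
  gene_specific <- list()
  gene_universe <- character()
  for (g in all_genes) {
    in_strata <- strata[vapply(tested_in, function(x) g %in% x, logical(1))]
    if (length(in_strata) < 2) next
    gene_universe <- c(gene_universe, g)
    sets <- lapply(preds[in_strata], function(p) p$recalled_terms[[g]])
    tab <- table(unlist(sets))
    spec <- names(tab)[tab < length(in_strata)]
    if (length(spec)) gene_specific[[g]] <- spec
  }

  # terms: recalled genes per stratum where the term was evaluated
  eval_in <- lapply(preds, function(p) names(p$recalled_genes))
  all_terms <- sort(unique(unlist(eval_in)))
  term_specific <- list()
  term_universe <- character()
  for (f in all_terms) {
    in_strata <- strata[vapply(eval_in, function(x) f %in% x, logical(1))]
    if (length(in_strata) < 2) next
    term_universe <- c(term_universe, f)
    sets <- lapply(preds[in_strata], function(p) p$recalled_genes[[f]])
    tab <- table(unlist(sets))
    spec <- names(tab)[tab < length(in_strata)]
    if (length(spec)) term_specific[[f]] <- spec
  }

  structure(list(
    gene_ratio = if (length(gene_universe))
      length(gene_specific) / length(gene_universe) else NA_real_,
    term_ratio = if (length(term_universe))
      length(term_specific) / length(term_universe) else NA_real_,
    gene_specific = gene_specific, term_specific = term_specific,
    n_genes = length(gene_universe), n_terms = length(term_universe),
    strata = strata), class = "SpecificityReport")
}

#' @export
print.SpecificityReport <- function(x, ...) {
  cat(sprintf(paste0(
    "SpecificityReport over %d strata: %.1f%% of %d genes with a\n",
    "stratum-specific recalled term; %.1f%% of %d terms with a\n",
    "stratum-specific recalled gene\n"),
    length(x$strata), 100 * x$gene_ratio, x$n_genes,
    100 * x$term_ratio, x$n_terms))
  invisible(x)
}

.metrics_row <- function(res) {
  data.frame(
    avg_auprc = res$eval$avg_auprc, fmax = res$eval$fmax,
    smin = res$eval$smin,
    avg_auroc = if (is.null(res$term_eval)) NA_real_
                else res$term_eval$avg_auroc,
    n_tested = length(res$tested_genes))
}

#' Performance as a function of cell number
#'
#' For each cell count `n` in the grid and each repeat, samples `n` cells
#' without replacement (seeded), reruns the full pipeline from scratch
#' (gene filters and network recomputed on the subsample), and records
#' the summary metrics.
#'
#' @inheritParams run_pipeline
#' @param grid strictly increasing cell counts, all <= the number of
#'   cells.
#' @param repeats repeats per grid point (default 10).
#' @param ... forwarded to [run_pipeline()].
#' @return Tidy data.frame: n, repeat index, seed used, avg_auprc, fmax,
#'   smin, avg_auroc, n_tested.
#' @export
subsample_performance <- function(tpm, ann, grid, repeats = 10, seed = 1,
                                  ...) {
  N <- ncol(tpm$values)
  if (any(grid > N)) stop("grid exceeds the ", N, " available cells")
  if (is.unsorted(grid, strictly = TRUE)) stop("grid must be strictly increasing")
  rows <- list()
  for (n in grid) {
    for (r in seq_len(repeats)) {
      s <- derive_seed(seed, n, r)
      idx <- withr_seed(s, sample.int(N, n))
      sub <- tpm
      sub$values <- tpm$values[, idx, drop = FALSE]
      res <- run_pipeline(sub, ann, seed = s, ...)
      rows[[length(rows) + 1]] <-
        cbind(data.frame(n = n, rep = r, seed = s), .metrics_row(res))
    }
  }
  do.call(rbind, rows)
}

#' Fixed-cell-count comparison across datasets
#'
#' Draws `n` cells from every dataset (each must have at least `n`),
#' restricts the tested genes to those detected in all datasets, and runs
#' the pipeline `repeats` times per dataset; used for comparing
#' platforms at matched sequencing depth in cells.
#'
#' @param datasets named list; each element a list with `expr` (raw-TPM
#'   `ExpressionMatrix`) and optionally `meta`.
#' @inheritParams run_pipeline
#' @param n cells drawn per dataset (default 550).
#' @param repeats repeats per dataset (default 10).
#' @param ... forwarded to [run_pipeline()].
#' @return Tidy data.frame: dataset, platform (from metadata when
#'   present), rep, seed, and the summary metrics.
#' @export
fixed_cell_compare <- function(datasets, ann, n = 550, repeats = 10,
                               seed = 1, ...) {
  if (length(datasets) < 2) stop("need >= 2 datasets")
  if (is.null(names(datasets))) stop("`datasets` must be named")
  for (nm in names(datasets)) {
    N <- ncol(datasets[[nm]]$expr$values)
    if (N < n) stop("dataset ", nm, " has ", N, " cells < n = ", n)
  }
  common <- Reduce(intersect, lapply(datasets, function(d)
    gene_ids(d$expr)[rowSums(d$expr$values > 0) > 0]))
  rows <- list()
  for (d in seq_along(datasets)) {
    nm <- names(datasets)[d]
    expr <- datasets[[nm]]$expr
    meta <- datasets[[nm]]$meta
    platform <- if (!is.null(meta)) meta$platform[1] else NA_character_
    for (r in seq_len(repeats)) {
      s <- derive_seed(seed, d, r)
      idx <- withr_seed(s, sample.int(ncol(expr$values), n))
      sub <- expr
      sub$values <- expr$values[, idx, drop = FALSE]
      res <- run_pipeline(sub, ann, restrict_tested = common, seed = s, ...)
      rows[[length(rows) + 1]] <-
        cbind(data.frame(dataset = nm, platform = platform, rep = r,
                         seed = s), .metrics_row(res))
    }
  }
  do.call(rbind, rows)
}

#' Shuffle gene-annotation links (negative control)
#'
#' Permutes the gene labels of the annotation pairs over a gene pool,
#' destroying any gene-term association while preserving per-term
#' annotation counts.
#'
#' @param ann an `AnnotationSet`.
#' @param genes gene pool to permute within (default: the annotation's
#'   gene universe).
#' @param seed integer seed.
#' @return A shuffled `AnnotationSet`.
#' @export
shuffle_annotations <- function(ann, genes = NULL, seed = 1) {
  stopifnot(inherits(ann, "AnnotationSet"))
  pool <- genes %||% ann$gene_universe
  withr_seed(seed, {
    p <- ann$pairs
    p$gene_id <- sample(pool, nrow(p), replace = TRUE)
    AnnotationSet(p)
  })
}
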