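# Shared fixture builders; everything is generated in code.

make_expr <- function(values, modality = "single_cell",
                      transform = "raw_tpm") {
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("g%02d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("c%02d", seq_len(ncol(values)))
  ExpressionMatrix(values, modality = modality, transform = transform)
}

# A symmetric random rank-normalized-looking network for voting tests.
random_network <- function(n_genes, seed) {
  W <- covote:::withr_seed(seed, {
    m <- matrix(stats::runif(n_genes^2), n_genes)
    m[lower.tri(m)] <- t(m)[lower.tri(m)]
    diag(m) <- 0
    m
  })
  dimnames(W) <- list(sprintf("g%02d", seq_len(n_genes)),
                      sprintf("g%02d", seq_len(n_genes)))
  structure(list(weights = W, variant = "random"),
            class = "CoexpressionNetwork")
}

random_annotation <- function(genes, terms, seed, p = 0.4) {
  covote:::withr_seed(seed, {
    hit <- matrix(stats::runif(length(genes) * length(terms)) < p,
                  length(genes))
    idx <- which(hit, arr.ind = TRUE)
    AnnotationSet(data.frame(gene_id = genes[idx[, 1]],
                             term_id = terms[idx[, 2]],
                             stringsAsFactors = FALSE))
  })
}

# Small-but-structured synthetic configuration for pipeline-level unit
# tests (fast: ~150 cells, 4 modules of 10 genes).
small_synth <- function(seed = 1, ...) {
  synthetic_config(n_cells = 150, n_modules = 4, genes_per_module = 10,
                   n_background = 40, n_housekeeping = 10,
                   n_samples = 2, seed = seed, ...)
}

small_pipeline_args <- function(data) {
  list(housekeeping = grep("^HK", gene_ids(data$expr), value = TRUE),
       dag = data$dag, qc = list(min_genes = 10),
       term_bounds = c(5, 500), folds = 5)
}

run_small_pipeline <- function(data, ...) {
  do.call(run_pipeline,
          c(list(tpm = data$expr, ann = data$ann), small_pipeline_args(data),
            list(...)))
}
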