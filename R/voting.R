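#' Neighbor-voting relevance scores
#'
#' The relevance of term f to gene i is the fraction of gene i's network
#' degree carried by neighbors annotated to f:
#' `Score(f, i) = sum_{k in f, k != i} W_ik / sum_{l != i} W_il`.
#' Self-exclusion is structural (the diagonal weight is zero), so each
#' gene is scored purely by its neighbors' labels — a built-in
#' leave-one-out for gene-centric evaluation.
#'
#' @param net a `CoexpressionNetwork`.
#' @param ann an `AnnotationSet` providing the votes.
#' @param genes genes to score (must be network genes); defaults to all
#'   network genes.
#' @param terms terms to score; defaults to all terms annotating at least
#'   one network gene.
#' @return A `RelevanceScores` object: numeric gene x term matrix in
#'   [0, 1]; rows for zero-degree genes are `NA` and flagged in the
#'   `zero_degree` attribute.
#' @export
relevance_scores <- function(net, ann, genes = NULL, terms = NULL) {
  stopifnot(inherits(net, "CoexpressionNetwork"),
            inherits(ann, "AnnotationSet"))
  net_genes <- rownames(net$weights)
  genes <- genes %||% net_genes
  if (!all(genes %in% net_genes))
    stop("genes not in network: ",
         paste(utils::head(setdiff(genes, net_genes), 5), collapse = ", "))
  if (is.null(terms)) {
    terms <- sort(unique(
      ann$pairs$term_id[ann$pairs$gene_id %in% net_genes]))
  }
  A <- annotation_matrix(ann, net_genes, terms)
  empty <- colSums(A) == 0
  if (any(empty))
    warning("terms with no annotated network gene score 0 everywhere: ",
            paste(utils::head(terms[empty], 5), collapse = ", "))
  deg <- node_degree(net)
  S <- (net$weights[genes, , drop = FALSE] %*% A) / deg[genes]
  zero <- deg[genes] == 0
  S[zero, ] <- NA_real_
  S <- pmin(pmax(S, 0), 1)  # guard round-off at the [0,1] boundary
  structure(list(scores = S, gene_ids = genes, term_ids = terms,
                 zero_degree = genes[zero]),
            class = "RelevanceScores")
}

#' @export
print.RelevanceScores <- function(x, ...) {
  cat(sprintf("RelevanceScores: %d genes x %d terms\n",
              length(x$gene_ids), length(x$term_ids)))
  invisible(x)
}

#' Threshold relevance scores into predictions and recalled sets
#'
#' A gene is predicted to relate to a term when its relevance score is
#' greater than or equal to the threshold. Recalled terms of a gene are
#' the intersection of its predicted and annotated terms (the true
#' positives); recalled genes of a term are defined symmetrically.
#'
#' @param s a `RelevanceScores` object.
#' @param ann the `AnnotationSet` defining the validated sets.
#' @param t threshold in (0, 1].
#' @return A `PredictionResult`: lists `predicted` and `recalled_terms`
#'   (per gene) and `recalled_genes` (per term), plus the threshold.
#' @export
predict_at_threshold <- function(s, ann, t) {
  stopifnot(inherits(s, "RelevanceScores"), inherits(ann, "AnnotationSet"))
  if (!is.numeric(t) || length(t) != 1 || t <= 0 || t > 1)
    stop("threshold must lie in (0, 1]")
  truth <- gene_term_sets(ann, s$gene_ids, s$term_ids)
  predicted <- apply(s$scores, 1, function(row)
    s$term_ids[!is.na(row) & row >= t], simplify = FALSE)
  recalled_terms <- Map(intersect, predicted, truth[s$gene_ids])
  recalled_genes <- lapply(stats::setNames(s$term_ids, s$term_ids),
    function(f) {
      hit <- vapply(recalled_terms, function(rt) f %in% rt, logical(1))
      names(recalled_terms)[hit]
    })
  structure(list(threshold = t, predicted = predicted,
                 recalled_terms = recalled_terms,
                 recalled_genes = recalled_genes),
            class = "PredictionResult")
}

#' @export
print.PredictionResult <- function(x, ...) {
  cat(sprintf("PredictionResult at t = %.2f: %d genes, %d terms\n",
              x$threshold, length(x$predicted), length(x$recalled_genes)))
  invisible(x)
}

#' Threshold achieving Fmax on the average PR curve
#'
#' @param eval an `EvaluationResult` from [average_pr_curve()] or
#'   [evaluate_gene_centric()].
#' @return The smallest threshold attaining the maximum F score.
#' @export
threshold_at_fmax <- function(eval) {
  curve <- eval$curve
  ok <- !is.na(curve$pr) & !is.na(curve$rc) & (curve$pr + curve$rc) > 0
  if (!any(ok)) stop("F undefined on the whole threshold grid")
  f <- with(curve[ok, ], 2 * pr * rc / (pr + rc))
  t_ok <- curve$threshold[ok]
  t_ok[which.max(f)]  # which.max returns the first (smallest t) on ties
}

#' Term-centric cross-validated AUROC
#'
#' For one term, the annotated network genes are split into seeded,
#' size-balanced folds. In each fold the held-out annotations are hidden,
#' relevance scores for the term are recomputed from the remaining
#' (training) positives, and the AUROC of held-out positives against
#' never-annotated genes is taken; training positives are excluded from
#' the ROC gene set. Returns the mean over folds.
#'
#' @param net a `CoexpressionNetwork`.
#' @param ann an `AnnotationSet`.
#' @param term term ID with at least `folds` annotated network genes.
#' @param folds number of folds (default 10).
#' @param seed integer seed for the fold split.
#' @return Average AUROC across folds.
#' @export
term_auroc_cv <- function(net, ann, term, folds = 10, seed = 1) {
  stopifnot(inherits(net, "CoexpressionNetwork"),
            inherits(ann, "AnnotationSet"))
  genes <- rownames(net$weights)
  deg <- node_degree(net)
  usable <- genes[deg > 0]
  if (length(usable) < length(genes))
    warning(length(genes) - length(usable), " zero-degree genes excluded")
  pos <- intersect(ann$pairs$gene_id[ann$pairs$term_id == term], usable)
  if (length(pos) < folds)
    stop("term ", term, " has ", length(pos), " annotated genes; needs >= ",
         folds, " (try fewer folds)")
  neg <- setdiff(usable, pos)
  if (length(neg) == 0) stop("no negative genes for term ", term)
  fold_of <- .assign_folds(length(pos), folds, seed)
  W <- net$weights
  aucs <- vapply(seq_len(folds), function(k) {
    test_pos <- pos[fold_of == k]
    train_pos <- pos[fold_of != k]
    a <- as.numeric(genes %in% train_pos)
    sc <- as.numeric(W %*% a) / deg
    names(sc) <- genes
    eval_genes <- c(test_pos, neg)
    roc_auc(sc[eval_genes], eval_genes %in% test_pos)
  }, numeric(1))
  mean(aucs)
}

.assign_folds <- function(n, folds, seed) {
  perm <- withr_seed(seed, sample.int(n))
  fold_of <- integer(n)
  fold_of[perm] <- rep_len(seq_len(folds), n)
  fold_of
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
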