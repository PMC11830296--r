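#' The standard decision-threshold grid
#'
#' @return `seq(0.01, 1, by = 0.01)` — 100 thresholds.
#' @export
threshold_grid <- function() seq(0.01, 1, by = 0.01)

#' Per-gene precision-recall curve and AUPRC
#'
#' At each threshold t, the predicted set `P(t)` holds the terms scored at
#' or above t. Precision is |P(t) ∩ T| / |P(t)| (undefined when P(t) is
#' empty; such thresholds are skipped for this gene's curve), recall is
#' |P(t) ∩ T| / |T|. AUPRC integrates precision over recall by the
#' trapezoid rule on the defined points sorted by recall ascending, with
#' no extrapolation; a curve that collapses to a single distinct recall
#' value contributes `pr * rc` (constant-precision extension).
#'
#' @param scores named numeric vector of relevance scores over the term
#'   universe for one gene.
#' @param truth character vector of the gene's annotated terms (non-empty).
#' @param grid threshold grid (default [threshold_grid()]).
#' @return List with `curve` (data.frame threshold/pr/rc over defined
#'   thresholds) and `auprc`.
#' @export
gene_pr_curve <- function(scores, truth, grid = threshold_grid()) {
  if (length(truth) == 0) stop("gene has no annotated terms")
  if (is.null(names(scores))) stop("`scores` must be named by term")
  scores <- scores[!is.na(scores)]
  terms <- names(scores)
  is_true <- terms %in% truth
  n_true <- length(truth)
  pr <- rc <- rep(NA_real_, length(grid))
  for (k in seq_along(grid)) {
    pred <- scores >= grid[k]
    np <- sum(pred)
    tp <- sum(pred & is_true)
    rc[k] <- tp / n_true
    if (np > 0) pr[k] <- tp / np
  }
  ok <- !is.na(pr)
  curve <- data.frame(threshold = grid[ok], pr = pr[ok], rc = rc[ok])
  list(curve = curve, auprc = .auprc_trapezoid(curve$pr, curve$rc))
}

# Trapezoid area of precision over recall; points sorted by recall
# ascending, duplicate recalls averaged, single-point curves extended at
# constant precision down to zero recall.
.auprc_trapezoid <- function(pr, rc) {
  if (length(pr) == 0) return(NA_real_)
  agg <- tapply(pr, rc, mean)
  r <- as.numeric(names(agg))
  p <- as.numeric(agg)
  o <- order(r)
  r <- r[o]; p <- p[o]
  if (length(r) == 1) return(p * r)
  sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
}

#' Average precision-recall curve, avgAUPRC and Fmax
#'
#' At each threshold, precision is averaged over the `m(t)` genes with at
#' least one prediction, and recall over all `M` tested genes. `Fmax` is
#' the maximum over thresholds of the harmonic mean of average precision
#' and recall; ties resolve to the smallest threshold.
#'
#' @param score_matrix gene x term relevance matrix (rows named by gene).
#' @param truth named list: per gene, its annotated terms (all non-empty).
#' @param grid threshold grid.
#' @return List with `curve` (threshold, pr, rc, m), `avg_auprc`, `fmax`,
#'   `fmax_threshold`, and `M`.
#' @export
average_pr_curve <- function(score_matrix, truth, grid = threshold_grid()) {
  genes <- rownames(score_matrix)
  if (is.null(genes) || !all(genes %in% names(truth)))
    stop("every score row needs a truth entry")
  M <- length(genes)
  if (M < 1) stop("need at least one tested gene")
  terms <- colnames(score_matrix)
  pr_mat <- rc_mat <- matrix(NA_real_, M, length(grid))
  for (g in seq_len(M)) {
    sc <- stats::setNames(as.vector(score_matrix[g, , drop = FALSE]), terms)
    sc <- sc[!is.na(sc)]
    is_true <- names(sc) %in% truth[[genes[g]]]
    n_true <- length(truth[[genes[g]]])
    for (k in seq_along(grid)) {
      pred <- sc >= grid[k]
      np <- sum(pred)
      rc_mat[g, k] <- sum(pred & is_true) / n_true
      if (np > 0) pr_mat[g, k] <- sum(pred & is_true) / np
    }
  }
  m_t <- colSums(!is.na(pr_mat))
  pr_t <- ifelse(m_t > 0, colMeans(pr_mat, na.rm = TRUE), NA_real_)
  rc_t <- colMeans(rc_mat)
  if (all(m_t == 0)) stop("no gene has a prediction at any threshold")
  curve <- data.frame(threshold = grid, pr = pr_t, rc = rc_t,
                      m = as.integer(m_t))
  def <- curve[!is.na(curve$pr), , drop = FALSE]
  f <- with(def, ifelse(pr + rc > 0, 2 * pr * rc / (pr + rc), 0))
  list(curve = curve,
       avg_auprc = .auprc_trapezoid(def$pr, def$rc),
       fmax = max(f),
       fmax_threshold = def$threshold[which.max(f)],
       M = M)
}

#' Information-content-weighted RU-MI curve and Smin
#'
#' Per gene and threshold, remaining uncertainty is the IC mass of the
#' false-negative terms and misinformation the IC mass of the
#' false-positive terms, each normalized by the IC mass of the union of
#' predicted and true terms; both are then averaged over all tested
#' genes. `Smin` is the minimum over thresholds of the Euclidean norm of
#' (ru, mi) and lies in [0, 1].
#'
#' @param score_matrix gene x term relevance matrix.
#' @param truth named list of per-gene annotated term sets.
#' @param ic named numeric vector of term information content covering
#'   every scored or annotated term.
#' @param grid threshold grid.
#' @return List with `curve` (threshold, ru, mi), `smin`,
#'   `smin_threshold`.
#' @export
ru_mi_curve <- function(score_matrix, truth, ic, grid = threshold_grid()) {
  genes <- rownames(score_matrix)
  terms <- colnames(score_matrix)
  need <- union(terms, unlist(truth[genes], use.names = FALSE))
  miss <- setdiff(need, names(ic))
  if (length(miss))
    stop("terms lacking an IC value: ",
         paste(utils::head(miss, 5), collapse = ", "))
  M <- length(genes)
  ru_mat <- mi_mat <- matrix(NA_real_, M, length(grid))
  for (g in seq_len(M)) {
    sc <- stats::setNames(as.vector(score_matrix[g, , drop = FALSE]), terms)
    sc <- sc[!is.na(sc)]
    t_set <- truth[[genes[g]]]
    if (length(t_set) == 0) stop("tested gene with empty truth: ", genes[g])
    ic_truth <- ic[t_set]
    for (k in seq_along(grid)) {
      p_set <- names(sc)[sc >= grid[k]]
      den <- sum(ic[union(p_set, t_set)])
      ru_mat[g, k] <- sum(ic_truth[!t_set %in% p_set]) / den
      mi_mat[g, k] <- sum(ic[setdiff(p_set, t_set)]) / den
    }
  }
  ru_t <- colMeans(ru_mat)
  mi_t <- colMeans(mi_mat)
  s <- sqrt(ru_t^2 + mi_t^2)
  list(curve = data.frame(threshold = grid, ru = ru_t, mi = mi_t),
       smin = min(s), smin_threshold = grid[which.min(s)])
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUROC: the probability that a random
#' positive outscores a random negative, ties counted half.
#'
#' @param scores numeric vector.
#' @param labels logical (or 0/1) vector, `TRUE` for positives.
#' @return AUROC in [0, 1].
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) stop("length mismatch")
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0)
    stop("AUROC needs at least one positive and one negative")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Mean of per-term AUROCs
#'
#' @param aurocs numeric vector of per-term (cross-validated) AUROCs.
#' @return Unweighted mean.
#' @export
avg_auroc <- function(aurocs) {
  if (length(aurocs) == 0) stop("no term AUROCs to average")
  mean(aurocs)
}

#' Gene-centric evaluation of a score matrix
#'
#' Bundles the per-gene PR curves, the average PR curve with avgAUPRC and
#' Fmax, and (when `ic` is given) the RU-MI curve with Smin.
#'
#' @param s a `RelevanceScores` object.
#' @param ann the `AnnotationSet` defining truth; genes without any
#'   annotated term in the score's term universe are dropped with a
#'   warning.
#' @param ic optional named IC vector enabling the RU-MI analysis.
#' @param grid threshold grid.
#' @return An `EvaluationResult` list: `curve`, `avg_auprc`, `fmax`,
#'   `fmax_threshold`, `per_gene_auprc`, `ru_mi` (or NULL), `smin`,
#'   `M`.
#' @export
evaluate_gene_centric <- function(s, ann, ic = NULL, grid = threshold_grid()) {
  stopifnot(inherits(s, "RelevanceScores"))
  truth <- gene_term_sets(ann, s$gene_ids, s$term_ids)
  keep <- lengths(truth) > 0 & !(s$gene_ids %in% s$zero_degree)
  if (!all(keep))
    warning(sum(!keep), " genes dropped (no truth terms or zero degree)")
  genes <- s$gene_ids[keep]
  if (length(genes) == 0) stop("no evaluable genes")
  S <- s$scores[genes, , drop = FALSE]
  avg <- average_pr_curve(S, truth, grid)
  per_gene <- vapply(genes, function(g)
    gene_pr_curve(stats::setNames(as.vector(S[g, , drop = FALSE]),
                                  colnames(S)),
                  truth[[g]], grid)$auprc, numeric(1))
  rumi <- NULL; smin <- NA_real_
  if (!is.null(ic)) {
    rumi <- ru_mi_curve(S, truth, ic, grid)
    smin <- rumi$smin
  }
  structure(list(curve = avg$curve, avg_auprc = avg$avg_auprc,
                 fmax = avg$fmax, fmax_threshold = avg$fmax_threshold,
                 per_gene_auprc = per_gene, ru_mi = rumi, smin = smin,
                 M = avg$M),
            class = "EvaluationResult")
}

#' @export
print.EvaluationResult <- function(x, ...) {
  cat(sprintf(
    "EvaluationResult: M = %d genes | avgAUPRC %.3f | Fmax %.3f (t = %.2f)%s\n",
    x$M, x$avg_auprc, x$fmax, x$fmax_threshold,
    if (!is.na(x$smin)) sprintf(" | Smin %.3f", x$smin) else ""))
  invisible(x)
}

#' Term-centric evaluation: cross-validated AUROC per term
#'
#' @param net a `CoexpressionNetwork`.
#' @param ann an `AnnotationSet`.
#' @param terms evaluation terms (typically [select_evaluation_terms()]).
#' @param folds CV folds (default 10).
#' @param seed seed for fold splits (one derived seed per term).
#' @return List with `per_term` (named AUROC vector) and `avg_auroc`.
#' @export
evaluate_term_centric <- function(net, ann, terms, folds = 10, seed = 1) {
  if (length(terms) == 0) stop("no evaluation terms")
  per_term <- vapply(seq_along(terms), function(i)
    term_auroc_cv(net, ann, terms[i], folds = folds,
                  seed = seed + i), numeric(1))
  names(per_term) <- terms
  list(per_term = per_term, avg_auroc = avg_auroc(per_term))
}
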