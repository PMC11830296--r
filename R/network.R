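#' Co-expression network variant specification
#'
#' The ten single-cell network variants cross three association metrics
#' (Pearson, Spearman, mutual information) with two treatments of dropout
#' zeros (kept, or excluded pairwise: the "_dp" variants) and, for the
#' correlation metrics only, signed versus absolute ranking (the "_abs"
#' variants). Mutual information is non-negative, so `absolute = TRUE`
#' is invalid for it.
#'
#' @param metric `"pearson"`, `"spearman"` or `"mi"`.
#' @param drop_zeros compute each pair only over cells where both genes are
#'   detected (TPM > 0)?
#' @param absolute rank edges by absolute association value?
#' @return An object of class `NetworkVariantSpec`.
#' @export
network_variant <- function(metric = c("pearson", "spearman", "mi"),
                            drop_zeros = FALSE, absolute = FALSE) {
  metric <- match.arg(metric)
  if (absolute && metric == "mi")
    stop("absolute ranking is invalid for mutual information (non-negative)")
  structure(list(metric = metric, drop_zeros = drop_zeros,
                 absolute = absolute),
            class = "NetworkVariantSpec")
}

#' Conventional name of a network variant
#'
#' @param spec a `NetworkVariantSpec`.
#' @return The "metric[_dp][_abs]" label, e.g. `"pearson_dp_abs"`.
#' @export
variant_name <- function(spec) {
  paste0(spec$metric,
         if (spec$drop_zeros) "_dp" else "",
         if (spec$absolute) "_abs" else "")
}

#' The ten standard network variants
#'
#' @return Named list of `NetworkVariantSpec` objects: mi, pearson,
#'   spearman, mi_dp, pearson_dp, spearman_dp, pearson_abs, spearman_abs,
#'   pearson_dp_abs, spearman_dp_abs.
#' @export
standard_variants <- function() {
  specs <- list(
    network_variant("mi"), network_variant("pearson"),
    network_variant("spearman"),
    network_variant("mi", drop_zeros = TRUE),
    network_variant("pearson", drop_zeros = TRUE),
    network_variant("spearman", drop_zeros = TRUE),
    network_variant("pearson", absolute = TRUE),
    network_variant("spearman", absolute = TRUE),
    network_variant("pearson", drop_zeros = TRUE, absolute = TRUE),
    network_variant("spearman", drop_zeros = TRUE, absolute = TRUE))
  names(specs) <- vapply(specs, variant_name, "")
  specs
}

#' Pairwise association matrix
#'
#' Raw gene-by-gene association under the chosen variant. With
#' `drop_zeros = TRUE` ("detected" meaning expression strictly above zero
#' on the log scale) each pair is computed over the cells where both genes
#' are detected; pairs co-detected in fewer than `min_overlap` cells are
#' `NA`. Constant vectors yield `NA` correlations. Mutual information uses
#' empirical (maximum-likelihood) estimation on equal-frequency bins,
#' `ceiling(sqrt(N))` bins per gene, recomputed on the co-detected subset
#' when zeros are dropped.
#'
#' @param m an `ExpressionMatrix` with `transform = "sc_log"`.
#' @param spec a `NetworkVariantSpec`.
#' @param min_overlap minimum co-detected cells for "_dp" pairs (default 10).
#' @return Symmetric numeric matrix with `NA` diagonal-free values; the
#'   diagonal is set to `NA` (it never enters ranking).
#' @export
pairwise_association <- function(m, spec, min_overlap = 10) {
  stopifnot(inherits(m, "ExpressionMatrix"),
            inherits(spec, "NetworkVariantSpec"))
  if (m$transform != "sc_log") stop("network construction expects sc_log values")
  X <- m$values
  G <- nrow(X); N <- ncol(X)
  if (G < 2) stop("need at least 2 genes")
  if (N < 2) stop("need at least 2 cells")
  if (!spec$drop_zeros) {
    R <- switch(spec$metric,
      pearson  = .safe_cor(t(X), method = "pearson"),
      spearman = .safe_cor(t(X), method = "spearman"),
      mi       = .mi_matrix(X))
  } else {
    R <- matrix(NA_real_, G, G, dimnames = list(rownames(X), rownames(X)))
    det <- X > 0
    for (i in seq_len(G - 1)) {
      xi <- X[i, ]; di <- det[i, ]
      for (j in (i + 1):G) {
        ok <- di & det[j, ]
        n <- sum(ok)
        if (n < min_overlap) next
        R[i, j] <- R[j, i] <- switch(spec$metric,
          pearson  = .safe_cor2(xi[ok], X[j, ok], "pearson"),
          spearman = .safe_cor2(xi[ok], X[j, ok], "spearman"),
          mi       = .mi_pair(xi[ok], X[j, ok]))
      }
    }
  }
  diag(R) <- NA_real_
  R
}

.safe_cor <- function(tx, method) {
  suppressWarnings(stats::cor(tx, method = method))  # constant cols -> NA
}

.safe_cor2 <- function(x, y, method) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = method)
}

.ef_bins <- function(x, nbins) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = nbins + 1),
                               names = FALSE, type = 7))
  if (length(br) < 2) return(rep(1L, length(x)))
  findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
}

.mi_pair <- function(x, y, bx = NULL, by = NULL) {
  n <- length(x)
  nb <- ceiling(sqrt(n))
  if (is.null(bx)) bx <- .ef_bins(x, nb)
  if (is.null(by)) by <- .ef_bins(y, nb)
  tab <- table(bx, by)
  p <- tab / n
  px <- rowSums(p); py <- colSums(p)
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / outer(px, py)[nz]))
}

.mi_matrix <- function(X) {
  G <- nrow(X); N <- ncol(X)
  nb <- ceiling(sqrt(N))
  B <- t(apply(X, 1, .ef_bins, nbins = nb))
  R <- matrix(NA_real_, G, G, dimnames = list(rownames(X), rownames(X)))
  for (i in seq_len(G - 1))
    for (j in (i + 1):G)
      R[i, j] <- R[j, i] <- .mi_pair(X[i, ], X[j, ], B[i, ], B[j, ])
  R
}

#' Rank-normalize an association matrix into network weights
#'
#' Upper-triangle association values (absolute values when
#' `absolute = TRUE`) are ranked ascending with ties receiving the average
#' rank, and divided by the number of non-missing pairs, so weights lie in
#' (0, 1] with the strongest edge at 1. Missing pairs receive the neutral
#' weight 0.5. Rank normalization makes downstream voting robust to the
#' shape of the raw association distribution.
#'
#' @param raw symmetric association matrix with `NA` diagonal.
#' @param absolute rank by absolute value?
#' @param variant variant label stored on the result.
#' @return A `CoexpressionNetwork`: symmetric weight matrix, zero diagonal.
#' @export
rank_normalize <- function(raw, absolute = FALSE, variant = "custom") {
  if (!is.matrix(raw) || nrow(raw) != ncol(raw))
    stop("`raw` must be a square matrix")
  G <- nrow(raw)
  ut <- upper.tri(raw)
  v <- raw[ut]
  if (absolute) v <- abs(v)
  ok <- !is.na(v)
  if (!any(ok)) stop("all pairwise associations are NA")
  w <- rep(0.5, length(v))
  w[ok] <- rank(v[ok], ties.method = "average") / sum(ok)
  W <- matrix(0, G, G, dimnames = dimnames(raw))
  W[ut] <- w
  W <- W + t(W)
  structure(list(weights = W, variant = variant),
            class = "CoexpressionNetwork")
}

#' @export
print.CoexpressionNetwork <- function(x, ...) {
  cat(sprintf("CoexpressionNetwork [%s]: %d genes\n",
              x$variant, nrow(x$weights)))
  invisible(x)
}

#' Node degree
#'
#' The degree of a gene is the total weight of all edges incident to it.
#'
#' @param net a `CoexpressionNetwork`.
#' @return Named numeric vector of degrees.
#' @export
node_degree <- function(net) {
  stopifnot(inherits(net, "CoexpressionNetwork"))
  rowSums(net$weights)
}

#' Build a co-expression network
#'
#' Composes [pairwise_association()] and [rank_normalize()] under one
#' variant specification.
#'
#' @inheritParams pairwise_association
#' @return A `CoexpressionNetwork`.
#' @export
build_network <- function(m, spec, min_overlap = 10) {
  raw <- pairwise_association(m, spec, min_overlap = min_overlap)
  rank_normalize(raw, absolute = spec$absolute, variant = variant_name(spec))
}

#' Integrate co-expression networks
#'
#' Averages the normalized edge weights of the member networks edgewise,
#' then re-ranks and normalizes the averages. The conventional members are
#' integrated_MI (both MI variants), integrated_pearson (4 Pearson
#' variants), integrated_spearman (4 Spearman variants) and
#' integrated_all (all 10).
#'
#' @param nets list of >= 2 `CoexpressionNetwork` objects on the same genes.
#' @param name variant label for the result; when `name = "integrated_all"`
#'   the member variants must be exactly the ten standard ones.
#' @return A `CoexpressionNetwork`.
#' @export
integrate_networks <- function(nets, name = "integrated") {
  if (length(nets) < 2) stop("need at least 2 networks to integrate")
  ids <- rownames(nets[[1]]$weights)
  for (n in nets) {
    stopifnot(inherits(n, "CoexpressionNetwork"))
    if (!identical(rownames(n$weights), ids))
      stop("networks must share an identical gene set and order")
  }
  if (name == "integrated_all") {
    have <- sort(vapply(nets, function(n) n$variant, ""))
    want <- sort(names(standard_variants()))
    if (!identical(have, want))
      stop("integrated_all requires exactly the 10 standard variants; got: ",
           paste(have, collapse = ", "))
  }
  avg <- Reduce(`+`, lapply(nets, `[[`, "weights")) / length(nets)
  diag(avg) <- NA_real_
  out <- rank_normalize(avg, absolute = FALSE, variant = name)
  out$variant <- paste0(name, ":",
                        paste(vapply(nets, `[[`, "", "variant"),
                              collapse = "+"))
  out
}

#' Write / read a network as a square-matrix TSV
#'
#' @param net a `CoexpressionNetwork`.
#' @param path output TSV path (gene IDs in first column and header).
#' @return `write_network` invisibly returns `path`; `read_network`
#'   returns a `CoexpressionNetwork`.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "CoexpressionNetwork"))
  df <- data.frame(gene_id = rownames(net$weights), net$weights,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  json <- file.path(dirname(path),
                    paste0(sub("\\.tsv$", "", basename(path)), ".variant.json"))
  jsonlite::write_json(list(variant = net$variant), json, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_network
#' @param path path written by `write_network`.
#' @export
read_network <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  W <- as.matrix(df[, -1, drop = FALSE])
  rownames(W) <- df[[1]]
  json <- file.path(dirname(path),
                    paste0(sub("\\.tsv$", "", basename(path)), ".variant.json"))
  variant <- if (file.exists(json))
    jsonlite::read_json(json)$variant else "unknown"
  structure(list(weights = W, variant = variant),
            class = "CoexpressionNetwork")
}
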