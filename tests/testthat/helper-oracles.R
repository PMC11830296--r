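# Independent brute-force oracles. These deliberately use plain loops and
# set arithmetic, not the package's vectorized code paths.

# Eq-style neighbor-voting score: explicit double loop over genes.
bf_relevance <- function(W, ann_pairs, genes, terms) {
  all_genes <- rownames(W)
  S <- matrix(NA_real_, length(genes), length(terms),
              dimnames = list(genes, terms))
  for (gi in genes) {
    deg <- 0
    for (l in all_genes) if (l != gi) deg <- deg + W[gi, l]
    for (f in terms) {
      members <- ann_pairs$gene_id[ann_pairs$term_id == f]
      num <- 0
      for (k in all_genes)
        if (k != gi && k %in% members) num <- num + W[gi, k]
      S[gi, f] <- if (deg > 0) num / deg else NA_real_
    }
  }
  S
}

# Pairwise-comparison AUROC, ties counted half.
bf_auroc <- function(scores, labels) {
  pos <- scores[as.logical(labels)]
  neg <- scores[!as.logical(labels)]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Per-gene PR points by direct set enumeration on the grid.
bf_gene_pr <- function(scores, truth, grid) {
  rows <- list()
  for (t in grid) {
    P <- names(scores)[scores >= t]
    tp <- length(intersect(P, truth))
    if (length(P) == 0) next
    rows[[length(rows) + 1]] <-
      data.frame(threshold = t, pr = tp / length(P),
                 rc = tp / length(truth))
  }
  do.call(rbind, rows)
}

# Trapezoid with average precision at duplicate recalls; single distinct
# recall extends at constant precision to zero recall.
bf_trapezoid <- function(pr, rc) {
  urc <- sort(unique(rc))
  up <- sapply(urc, function(r) mean(pr[rc == r]))
  if (length(urc) == 1) return(up * urc)
  a <- 0
  for (i in seq_len(length(urc) - 1))
    a <- a + (urc[i + 1] - urc[i]) * (up[i] + up[i + 1]) / 2
  a
}

# RU and MI components for one gene at one threshold by set arithmetic.
bf_ru_mi_gene <- function(P, T_set, ic) {
  den <- sum(ic[union(P, T_set)])
  c(ru = sum(ic[setdiff(T_set, P)]) / den,
    mi = sum(ic[setdiff(P, T_set)]) / den)
}

# Transitive ancestor closure by repeated expansion over an edge list.
bf_closure <- function(pairs, parent_edges) {
  repeat {
    extra <- merge(pairs, parent_edges, by.x = "term_id", by.y = "child")
    extra <- data.frame(gene_id = extra$gene_id, term_id = extra$parent,
                        stringsAsFactors = FALSE)
    new <- rbind(pairs[, c("gene_id", "term_id")], extra)
    new <- unique(new)
    if (nrow(new) == nrow(pairs)) return(new)
    pairs <- new
  }
}

# Two-pass textbook Pearson correlation.
bf_pearson <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
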