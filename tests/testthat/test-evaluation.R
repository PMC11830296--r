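test_that("per-gene PR points count predicted and true terms", {
  scores <- c(a = 0.9, b = 0.9, c = 0.1, d = 0.05)
  res <- gene_pr_curve(scores, truth = c("a", "c"))
  at <- res$curve[res$curve$threshold == 0.5, ]
  expect_equal(at$pr, 1 / 2)  # P = {a,b}, T = {a,c}
  expect_equal(at$rc, 1 / 2)
  # perfect separation: pr = rc = 1 wherever defined, AUPRC 1
  perfect <- gene_pr_curve(c(a = 1, b = 1, c = 0), truth = c("a", "b"))
  expect_true(all(perfect$curve$pr == 1))
  expect_true(all(perfect$curve$rc == 1))
  expect_equal(perfect$auprc, 1)
  expect_error(gene_pr_curve(scores, character()), "no annotated terms")
})

test_that("per-gene PR curves and AUPRC match enumeration oracles", {
  grid <- threshold_grid()
  for (s in 1:20) {
    n_terms <- sample(3:5, 1)
    terms <- paste0("t", seq_len(n_terms))
    scores <- covote:::withr_seed(300 + s,
      stats::setNames(round(stats::runif(n_terms), 2), terms))
    truth <- covote:::withr_seed(400 + s,
      sample(terms, sample(seq_len(n_terms - 1), 1)))
    got <- gene_pr_curve(scores, truth, grid)
    want <- bf_gene_pr(scores, truth, grid)
    expect_equal(got$curve$pr, want$pr, tolerance = 1e-12)
    expect_equal(got$curve$rc, want$rc, tolerance = 1e-12)
    expect_equal(got$auprc, bf_trapezoid(want$pr, want$rc),
                 tolerance = 1e-12)
  }
})

test_that("average PR separates the m(t) and M denominators", {
  # g1 predicted perfectly at 0.5; g2 has no prediction at 0.5
  S <- matrix(c(0.9, 0.1, 0.9, 0.1), 2,
              dimnames = list(c("g1", "g2"), c("a", "b")))
  truth <- list(g1 = c("a", "b"), g2 = c("a", "b"))
  avg <- average_pr_curve(S, truth)
  at <- avg$curve[50, ]  # t = 0.50
  expect_equal(at$m, 1L)
  expect_equal(at$pr, 1)            # mean over m(t) = 1 gene
  expect_equal(at$rc, (1 + 0) / 2)  # mean over all M = 2 genes
  # harmonic-mean arithmetic
  f <- 2 * 0.6 * 0.7 / (0.6 + 0.7)
  expect_equal(round(f, 4), 0.6462)
})

test_that("average PR, Fmax and avgAUPRC match a brute-force oracle", {
  grid <- threshold_grid()
  for (s in 1:10) {
    genes <- paste0("g", 1:4)
    terms <- paste0("t", 1:5)
    S <- covote:::withr_seed(500 + s,
      matrix(round(stats::runif(20), 2), 4,
             dimnames = list(genes, terms)))
    truth <- covote:::withr_seed(600 + s,
      lapply(stats::setNames(genes, genes),
             function(g) sample(terms, sample(1:4, 1))))
    got <- average_pr_curve(S, truth, grid)
    # oracle: direct set counting per gene and threshold
    pr_t <- rc_t <- m_t <- numeric(length(grid))
    for (k in seq_along(grid)) {
      prs <- c(); rcs <- c()
      for (g in genes) {
        P <- terms[S[g, ] >= grid[k]]
        tp <- length(intersect(P, truth[[g]]))
        rcs <- c(rcs, tp / length(truth[[g]]))
        if (length(P) > 0) prs <- c(prs, tp / length(P))
      }
      m_t[k] <- length(prs)
      pr_t[k] <- if (length(prs)) mean(prs) else NA
      rc_t[k] <- mean(rcs)
    }
    expect_equal(got$curve$pr, pr_t, tolerance = 1e-12)
    expect_equal(got$curve$rc, rc_t, tolerance = 1e-12)
    expect_equal(got$curve$m, as.integer(m_t))
    ok <- !is.na(pr_t)
    f <- 2 * pr_t[ok] * rc_t[ok] / (pr_t[ok] + rc_t[ok])
    f[is.nan(f)] <- 0
    expect_equal(got$fmax, max(f), tolerance = 1e-12)
    expect_equal(got$avg_auprc, bf_trapezoid(pr_t[ok], rc_t[ok]),
                 tolerance = 1e-12)
  }
})

test_that("RU-MI components follow the worked information-content case", {
  ic <- c(a = 3, b = 1, c = 2)
  # T = {a,b}, P = {b,c}: ru = IC(a)/IC(a,b,c), mi = IC(c)/IC(a,b,c)
  S <- matrix(c(0.1, 0.9, 0.9), 1, dimnames = list("g", c("a", "b", "c")))
  res <- ru_mi_curve(S, list(g = c("a", "b")), ic)
  at <- res$curve[50, ]  # t = 0.50
  expect_equal(at$ru, 3 / 6)
  expect_equal(at$mi, 2 / 6)
  want <- bf_ru_mi_gene(c("b", "c"), c("a", "b"), ic)
  expect_equal(c(at$ru, at$mi), unname(want), tolerance = 1e-12)
  # P = T at t: both zero; P empty: ru 1, mi 0
  expect_equal(res$curve$ru[95], 1)  # t = 0.95 > every score
  expect_equal(res$curve$mi[95], 0)
  S2 <- matrix(c(0.9, 0.9, 0.1), 1, dimnames = list("g", c("a", "b", "c")))
  res2 <- ru_mi_curve(S2, list(g = c("a", "b")), ic)
  expect_equal(res2$curve$ru[50], 0)
  expect_equal(res2$curve$mi[50], 0)
  expect_error(ru_mi_curve(S, list(g = c("a", "zz")), ic), "lacking an IC")
})

test_that("RU-MI means match per-gene set arithmetic on random instances", {
  grid <- threshold_grid()
  for (s in 1:10) {
    genes <- paste0("g", 1:3); terms <- paste0("t", 1:5)
    ic <- covote:::withr_seed(700 + s,
      stats::setNames(stats::runif(5, 0.5, 4), terms))
    S <- covote:::withr_seed(800 + s,
      matrix(round(stats::runif(15), 2), 3,
             dimnames = list(genes, terms)))
    truth <- covote:::withr_seed(900 + s,
      lapply(stats::setNames(genes, genes),
             function(g) sample(terms, sample(1:3, 1))))
    got <- ru_mi_curve(S, truth, ic, grid)
    for (k in c(1, 25, 50, 75, 100)) {
      comp <- sapply(genes, function(g)
        bf_ru_mi_gene(terms[S[g, ] >= grid[k]], truth[[g]], ic))
      expect_equal(got$curve$ru[k], mean(comp["ru", ]), tolerance = 1e-12)
      expect_equal(got$curve$mi[k], mean(comp["mi", ]), tolerance = 1e-12)
    }
    smin_oracle <- min(sqrt(got$curve$ru^2 + got$curve$mi^2))
    expect_equal(got$smin, smin_oracle, tolerance = 1e-12)
  }
})

test_that("AUROC equals the normalized Mann-Whitney statistic", {
  expect_equal(roc_auc(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(roc_auc(rep(1, 6), c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)),
               0.5)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "positive and")
  for (s in 1:20) {
    sc <- covote:::withr_seed(1100 + s,
      round(stats::rnorm(30), 1))  # rounding forces ties
    lab <- covote:::withr_seed(1200 + s, stats::runif(30) < 0.4)
    if (!any(lab) || all(lab)) next
    expect_equal(roc_auc(sc, lab), bf_auroc(sc, lab), tolerance = 1e-12)
  }
})

test_that("AUROC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  sc <- covote:::withr_seed(77, stats::rnorm(60))
  lab <- covote:::withr_seed(78, stats::runif(60) < 0.5)
  expect_equal(roc_auc(sc, lab),
               as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("AUROC is invariant under monotone score transforms", {
  sc <- covote:::withr_seed(79, stats::rexp(40))
  lab <- covote:::withr_seed(80, stats::runif(40) < 0.5)
  a <- roc_auc(sc, lab)
  expect_equal(roc_auc(log(sc + 1), lab), a, tolerance = 1e-12)
  expect_equal(roc_auc(rank(sc), lab), a, tolerance = 1e-12)
})

test_that("avgAUROC is the unweighted mean over terms", {
  expect_equal(avg_auroc(c(1, 0.5)), 0.75)
  expect_equal(avg_auroc(0.9), 0.9)
  expect_equal(avg_auroc(c(x = 0.6, y = 0.7, z = 0.8)),
               avg_auroc(c(z = 0.8, x = 0.6, y = 0.7)))
  expect_error(avg_auroc(numeric()), "no term")
})

test_that("gene-centric evaluation bundles curves, Fmax and Smin", {
  net <- random_network(12, seed = 21)
  genes <- rownames(net$weights)
  ann <- random_annotation(genes, paste0("t", 1:4), seed = 22, p = 0.5)
  s <- suppressWarnings(relevance_scores(net, ann))
  ic <- information_content(ann)
  ev <- suppressWarnings(evaluate_gene_centric(s, ann, ic = ic))
  expect_s3_class(ev, "EvaluationResult")
  expect_true(ev$fmax >= 0 && ev$fmax <= 1)
  expect_true(ev$smin >= 0 && ev$smin <= 1)
  expect_equal(nrow(ev$curve), 100)
  expect_length(ev$per_gene_auprc, ev$M)
})
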