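test_that("the variant grammar admits exactly the ten standard networks", {
  expect_error(network_variant("mi", absolute = TRUE), "invalid")
  v <- standard_variants()
  expect_length(v, 10)
  expect_setequal(names(v),
    c("mi", "pearson", "spearman", "mi_dp", "pearson_dp", "spearman_dp",
      "pearson_abs", "spearman_abs", "pearson_dp_abs", "spearman_dp_abs"))
})

test_that("pairwise associations honor metric, zeros and overlap rules", {
  x <- c(1, 2, 3, 4, 5, 6)
  m <- make_expr(rbind(dup1 = x, dup2 = x, neg = rev(x)),
                 transform = "raw_tpm")
  lg <- m; lg$transform <- "sc_log"  # values already on a log-like scale
  r <- pairwise_association(lg, network_variant("pearson"))
  expect_equal(r["dup1", "dup2"], 1)
  expect_equal(r["dup1", "neg"], -1)
  expect_true(all(is.na(diag(r))))

  # pairwise-complete computation under drop_zeros, NA below min_overlap
  z <- rbind(a = c(1, 2, 3, 0, 0, 0, 4, 7, 2, 8),
             b = c(2, 4, 6, 5, 1, 0, 8, 14, 4, 16),
             c = c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1))
  mz <- make_expr(z); mz$transform <- "sc_log"
  rz <- pairwise_association(mz, network_variant("pearson",
                                                 drop_zeros = TRUE),
                             min_overlap = 6)
  expect_equal(rz["a", "b"], 1)  # b = 2a on the 6 co-detected cells
  rz2 <- pairwise_association(mz, network_variant("pearson",
                                                  drop_zeros = TRUE),
                              min_overlap = 8)
  expect_true(is.na(rz2["a", "b"]))
  expect_true(is.na(rz["a", "c"]))  # constant vector

  # drop_zeros is a no-op without zeros
  nz <- make_expr(matrix(stats::runif(40) + 1, 4)); nz$transform <- "sc_log"
  expect_equal(
    pairwise_association(nz, network_variant("spearman", drop_zeros = TRUE),
                         min_overlap = 5),
    pairwise_association(nz, network_variant("spearman")))
})

test_that("Pearson associations match the textbook two-pass formula", {
  for (s in 1:20) {
    X <- covote:::withr_seed(s, matrix(stats::rnorm(8 * 30), 8))
    m <- make_expr(abs(X)); m$transform <- "sc_log"
    r <- pairwise_association(m, network_variant("pearson"))
    for (i in 1:7) for (j in (i + 1):8)
      expect_equal(r[i, j], bf_pearson(abs(X)[i, ], abs(X)[j, ]),
                   tolerance = 1e-12)
  }
})

test_that("mutual information is symmetric, non-negative and tracks dependence", {
  X <- covote:::withr_seed(3, {
    x <- stats::rnorm(400)
    rbind(a = x, b = x + stats::rnorm(400, sd = 0.1),
          c = stats::rnorm(400))
  })
  m <- make_expr(abs(X)); m$transform <- "sc_log"
  r <- pairwise_association(m, network_variant("mi"))
  expect_true(all(r[upper.tri(r)] >= 0))
  expect_equal(r["a", "b"], r["b", "a"])
  expect_gt(r["a", "b"], r["a", "c"])  # dependent pair carries more MI
})

test_that("rank normalization emits the stated weight conventions", {
  raw <- matrix(NA_real_, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  raw["a", "b"] <- raw["b", "a"] <- 0.9
  raw["a", "c"] <- raw["c", "a"] <- 0.5
  raw["b", "c"] <- raw["c", "b"] <- 0.1
  net <- rank_normalize(raw)
  expect_equal(net$weights["a", "b"], 1)
  expect_equal(net$weights["a", "c"], 2 / 3)
  expect_equal(net$weights["b", "c"], 1 / 3)
  expect_equal(diag(net$weights), c(a = 0, b = 0, c = 0))
  expect_equal(net$weights, t(net$weights))

  # absolute ranking puts -0.9 on top
  raw["a", "b"] <- raw["b", "a"] <- -0.9
  expect_equal(rank_normalize(raw, absolute = TRUE)$weights["a", "b"], 1)
  # all ties -> average rank 2 of 3
  raw[upper.tri(raw)] <- 0.4; raw[lower.tri(raw)] <- 0.4
  expect_equal(unique(rank_normalize(raw)$weights[upper.tri(raw)]), 2 / 3)
  # NA pairs take the neutral mid-weight, remaining ranks renormalize
  raw2 <- raw
  raw2["a", "b"] <- raw2["b", "a"] <- NA
  raw2["a", "c"] <- raw2["c", "a"] <- 0.8
  raw2["b", "c"] <- raw2["c", "b"] <- 0.2
  w <- rank_normalize(raw2)$weights
  expect_equal(w["a", "b"], 0.5)
  expect_equal(w["a", "c"], 1)
  expect_equal(w["b", "c"], 0.5)
  expect_error(rank_normalize(matrix(NA_real_, 2, 2)), "all")
})

test_that("weight multiset is {k/E} without ties and degrees sum to 2x weight", {
  raw <- random_network(7, seed = 11)$weights  # distinct uniforms
  diag(raw) <- NA
  net <- rank_normalize(raw)
  E <- choose(7, 2)
  expect_equal(sort(net$weights[upper.tri(net$weights)]),
               seq_len(E) / E)
  deg <- node_degree(net)
  expect_equal(sum(deg), 2 * sum(net$weights[upper.tri(net$weights)]))
  # worked 3-gene example
  W <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  W["a", "b"] <- W["b", "a"] <- 1
  W["a", "c"] <- W["c", "a"] <- 2 / 3
  W["b", "c"] <- W["c", "b"] <- 1 / 3
  net3 <- structure(list(weights = W, variant = "x"),
                    class = "CoexpressionNetwork")
  expect_equal(node_degree(net3), c(a = 5 / 3, b = 4 / 3, c = 1))
})

test_that("networks inherit metric invariances and are deterministic", {
  X <- covote:::withr_seed(5, matrix(stats::rexp(8 * 40), 8))
  m <- make_expr(X); m$transform <- "sc_log"
  spearman <- build_network(m, network_variant("spearman"))
  # strictly monotone per-gene transform leaves Spearman network unchanged
  m2 <- m; m2$values <- log1p(m$values)^3
  expect_equal(build_network(m2, network_variant("spearman"))$weights,
               spearman$weights)
  # positive affine transform leaves the Pearson network unchanged
  pearson <- build_network(m, network_variant("pearson"))
  m3 <- m; m3$values <- 2.5 * m$values + 1
  expect_equal(build_network(m3, network_variant("pearson"))$weights,
               pearson$weights)
  # gene permutation commutes with network construction
  perm <- c(3, 1, 2, 8, 5, 4, 7, 6)
  mp <- m; mp$values <- m$values[perm, ]
  expect_equal(build_network(mp, network_variant("pearson"))$weights,
               pearson$weights[perm, perm])
  expect_equal(build_network(m, network_variant("spearman"))$weights,
               spearman$weights)  # repeated call identical
})

test_that("integration averages weights then re-ranks", {
  net <- rank_normalize(random_network(5, 2)$weights)
  # identical members: re-ranking reproduces the input
  out <- integrate_networks(list(net, net), name = "integrated_pair")
  expect_equal(out$weights, net$weights)
  # members with reversed edge order and equal spacing -> all ties
  W1 <- matrix(0, 3, 3, dimnames = rep(list(c("a", "b", "c")), 2))
  W1["a", "b"] <- W1["b", "a"] <- 1 / 3
  W1["a", "c"] <- W1["c", "a"] <- 2 / 3
  W1["b", "c"] <- W1["c", "b"] <- 1
  W2 <- W1
  W2[W1 == 1 / 3] <- 1; W2[W1 == 1] <- 1 / 3
  n1 <- structure(list(weights = W1, variant = "v1"),
                  class = "CoexpressionNetwork")
  n2 <- structure(list(weights = W2, variant = "v2"),
                  class = "CoexpressionNetwork")
  both <- integrate_networks(list(n1, n2))
  expect_equal(unique(both$weights[upper.tri(both$weights)]), 2 / 3)
  # contracts
  n3 <- random_network(4, 9)
  expect_error(integrate_networks(list(n1, n3)), "identical gene set")
  expect_error(integrate_networks(list(n1, n2), name = "integrated_all"),
               "10 standard variants")
  expect_error(integrate_networks(list(n1)), "at least 2")
})

test_that("network TSV serialization round-trips with its variant sidecar", {
  net <- build_network({
    m <- make_expr(covote:::withr_seed(4, matrix(stats::rexp(60), 6)))
    m$transform <- "sc_log"; m
  }, network_variant("pearson"))
  path <- file.path(tempfile(), "net.tsv")
  dir.create(dirname(path))
  write_network(net, path)
  back <- read_network(path)
  expect_equal(back$weights, net$weights, tolerance = 1e-12)
  expect_identical(back$variant, "pearson")
})
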