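test_that("size factors recover exact scaling and match the brute-force oracle", {
  # sample B = 2 x sample A countwise -> factors (1/sqrt(2), sqrt(2))
  x <- toy_counts(c(10, 20, 40, 80, 6, 12), c("g1", "g2", "g3"), c("A", "B"))
  sf <- size_factors(x)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))

  # identical samples -> all ones
  y <- toy_counts(rep(c(5, 9, 30), each = 3), c("g1", "g2", "g3"),
                  c("A", "B", "C"))
  expect_equal(unname(size_factors(y)), c(1, 1, 1))

  # random NB matrix vs independent median-of-ratios implementation
  set.seed(42)
  m <- matrix(rnbinom(200 * 6, mu = 80, size = 10), 200, 6,
              dimnames = list(sprintf("g%03d", 1:200), sprintf("s%d", 1:6)))
  expect_equal(unname(size_factors(m)), oracle_size_factors(m), tolerance = 1e-12)
  expect_equal(exp(mean(log(size_factors(m)))), 1, tolerance = 1e-9)
})

test_that("size factors error without an all-positive feature unless the fallback is requested", {
  m <- matrix(c(0, 5, 7, 3, 0, 0), 3, 2,
              dimnames = list(c("g1", "g2", "g3"), c("A", "B")))
  expect_error(size_factors(m), "pseudo_reference = TRUE")
  sf <- size_factors(m, pseudo_reference = TRUE)
  expect_length(sf, 2L)
  expect_true(all(sf > 0))
})

test_that("BH adjustment equals the hand step-up and preserves order", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.037), 0.037)
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  set.seed(1)
  p <- runif(300)^2
  expect_equal(bh_adjust(p), oracle_bh(p), tolerance = 1e-15)
  shuf <- sample(300)
  expect_equal(bh_adjust(p)[shuf], bh_adjust(p[shuf]))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bh_adjust(c(0.5, NA)), "\\[0, 1\\]")
})

test_that("identical groups give zero fold changes and no calls", {
  base <- matrix(rnbinom(40, mu = 50, size = 20), 10, 4)
  x <- cbind(base[, 1:2], base[, 1:2])
  dimnames(x) <- list(sprintf("g%02d", 1:10), c("a1", "a2", "b1", "b2"))
  meta <- toy_meta(colnames(x), diet = c("SD", "SD", "HFD", "HFD"))
  de <- de_test(x, meta, "diet")
  expect_true(all(de$log2fc == 0))
  expect_true(all(de$call == "ns"))
  expect_true(all(de$p_raw == 1))
})

test_that("a strongly suppressed gene is called down in almost every replicate", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    n <- 8
    mu <- rep(300, 50)
    cnt <- cbind(
      matrix(rnbinom(50 * n, mu = mu, size = 20), 50, n),
      matrix(rnbinom(50 * n, mu = mu * c(2^-3, rep(1, 49)), size = 20), 50, n)
    )
    dimnames(cnt) <- list(sprintf("g%02d", 1:50), sprintf("s%02d", 1:(2 * n)))
    meta <- toy_meta(colnames(cnt), diet = rep(c("SD", "HFD"), each = n))
    de <- de_test(cnt, meta, "diet", alpha = 0.05, lfc_threshold = 1)
    if (de$call[de$feature_id == "g01"] == "down") hits <- hits + 1L
  }
  expect_gte(hits, 95L)
})

test_that("de_test is invariant to feature and sample order", {
  st <- simulate_study(signal_config(seed = 9, n_genes = 300, n_mirnas = 40))
  meta <- kidney_meta(st)
  x <- st$mrna$counts
  de1 <- de_test(x, meta, "diet")
  perm_f <- sample(nrow(x))
  perm_s <- sample(ncol(x))
  de2 <- de_test(x[perm_f, perm_s], meta, "diet")
  de2 <- de2[match(de1$feature_id, de2$feature_id), ]
  expect_equal(de1$log2fc, de2$log2fc, tolerance = 1e-12)
  expect_equal(de1$p_adj, de2$p_adj, tolerance = 1e-12)
  expect_identical(de1$call, de2$call)
})

test_that("scaling one sample's counts moves only its size factor, not fold changes", {
  set.seed(7)
  x <- matrix(rnbinom(100 * 6, mu = 200, size = 10) + 1, 100, 6,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("s%d", 1:6)))
  meta <- toy_meta(colnames(x), diet = rep(c("SD", "HFD"), each = 3))
  k <- 3
  x2 <- x
  x2[, 2] <- x[, 2] * k
  sf1 <- size_factors(x)
  sf2 <- size_factors(x2)
  # after rescaling to unit geometric mean the scaled sample's factor grows
  # by k (up to the global k^(1/n) renormalization)
  expect_equal(unname(sf2[2] / sf1[2]), unname(k * (sf2[1] / sf1[1])),
               tolerance = 1e-9)
  # with a pure ratio fold change (no pseudocount) the fold changes match
  de1 <- de_test(x, meta, "diet", pseudocount = 0)
  de2 <- de_test(x2, meta, "diet", pseudocount = 0)
  expect_equal(de1$log2fc, de2$log2fc, tolerance = 1e-6)
})

test_that("degenerate groupings and missing samples are rejected", {
  x <- toy_counts(c(5, 6, 7, 8), c("g1", "g2"), c("a", "b"))
  meta <- toy_meta(c("a", "b"), diet = c("SD", "SD"))
  expect_error(de_test(x, meta, "diet"), "degenerate")
  expect_error(de_test(x, toy_meta("a", "SD"), "diet"), "missing sample")
  meta4 <- toy_meta(c("a", "b"), diet = c("SD", "HFD"))
  expect_error(de_test(x, meta4, "diet"), ">= 2 samples per class")
})

test_that("all-zero features are excluded from testing and flagged not expressed", {
  x <- rbind(matrix(rnbinom(4 * 8, mu = 100, size = 20), 4, 8), 0)
  dimnames(x) <- list(c(sprintf("g%d", 1:4), "gZ"), sprintf("s%d", 1:8))
  meta <- toy_meta(colnames(x), diet = rep(c("SD", "HFD"), each = 4))
  de <- de_test(x, meta, "diet")
  expect_equal(de$call[de$feature_id == "gZ"], "not_expressed")
  expect_true(is.na(de$p_adj[de$feature_id == "gZ"]))
  expect_equal(sum(de$call != "not_expressed"), 4L)
})

test_that("complete-linkage clustering matches forced topologies and the naive oracle", {
  # three points where one pair is much closer: that pair merges first
  x <- matrix(c(0, 0, 1, 1, 3, 3), nrow = 3, byrow = TRUE,
              dimnames = list(c("p1", "p2", "p3"), c("d1", "d2")))
  cl <- cluster_features(x, normalize = FALSE, log_transform = FALSE)
  expect_equal(cl$height[1], 2)  # squared Euclidean (1^2 + 1^2)
  expect_equal(sort(cl$merge[1, ]), c(-2, -1))

  # duplicate feature rows merge first at height zero
  y <- rbind(a = c(5, 1, 9), b = c(5, 1, 9), c = c(50, 40, 2))
  colnames(y) <- c("s1", "s2", "s3")
  cl2 <- cluster_features(y, normalize = FALSE, log_transform = FALSE)
  expect_equal(cl2$height[1], 0)
  expect_equal(sort(cl2$merge[1, ]), c(-2, -1))

  set.seed(11)
  z <- matrix(rnorm(20 * 6), 20, 6,
              dimnames = list(sprintf("f%02d", 1:20), sprintf("s%d", 1:6)))
  cl3 <- cluster_features(z, normalize = FALSE, log_transform = FALSE)
  expect_equal(sort(cl3$height), oracle_complete_linkage_heights(z),
               tolerance = 1e-12)
  expect_error(cluster_features(z[1, , drop = FALSE], normalize = FALSE),
               "at least 2 features")
})
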