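test_that("pairwise distances match their defining formulas", {
  # 3-4-5 triangle
  d <- pairwise_distances(rbind(c(0, 0), c(3, 4)), "euclidean")
  expect_equal(d[1, 2], 5)

  # parallel and orthogonal vectors under cosine
  dc <- pairwise_distances(rbind(c(2, 2), c(1, 1), c(1, 0), c(0, 1)), "cosine")
  expect_equal(dc[1, 2], 0, tolerance = 1e-12)
  expect_equal(dc[3, 4], 1)

  # perfectly anti-correlated rows
  dr <- pairwise_distances(rbind(c(1, 2, 3), c(3, 2, 1)), "correlation")
  expect_equal(dr[1, 2], 2)

  expect_error(pairwise_distances(rbind(c(1, 1, 1), c(1, 2, 3)), "correlation"),
               "constant row")
  expect_error(pairwise_distances(rbind(c(0, 0), c(1, 2)), "cosine"), "zero row")
})

test_that("distance matrices are symmetric, nonnegative, zero-diagonal", {
  co <- standardize_features(impute_missing(generate_cohort(ibs_cohort_spec(seed = 8))))
  for (m in c("euclidean", "cosine", "correlation")) {
    d <- pairwise_distances(co, m)
    expect_equal(d, t(d), tolerance = 1e-12)
    expect_true(all(d >= 0))
    expect_equal(unname(diag(d)), rep(0, nrow(d)))
    if (m != "euclidean") expect_true(all(d <= 2 + 1e-12))
  }
})

test_that("kernel bandwidth is the mean over distinct pairs and is homogeneous", {
  d <- matrix(0, 3, 3)
  d[1, 2] <- d[2, 1] <- 1; d[1, 3] <- d[3, 1] <- 2; d[2, 3] <- d[3, 2] <- 3
  expect_equal(kernel_bandwidth(d), 2)
  expect_equal(kernel_bandwidth(3.7 * d), 3.7 * 2)
  expect_error(kernel_bandwidth(matrix(0, 3, 3)), "degenerate")
})

test_that("Gaussian kernel has the closed-form values and range (0, 1]", {
  d <- matrix(c(0, 1, 2, 1, 0, 1, 2, 1, 0), 3, 3)
  s <- gaussian_similarity(d, bandwidth = 1)
  expect_equal(unname(diag(s)), rep(1, 3))
  expect_equal(s[1, 2], exp(-0.5))
  expect_equal(s[1, 3], exp(-2))
  expect_true(all(s > 0 & s <= 1))
})

test_that("kNN-union sparsification matches the hand-enumerated example", {
  s <- diag(4)
  s[1, 2] <- 0.9; s[1, 3] <- 0.5; s[1, 4] <- 0.2
  s[2, 3] <- 0.4; s[2, 4] <- 0.1; s[3, 4] <- 0.8
  s[lower.tri(s)] <- t(s)[lower.tri(s)]
  rownames(s) <- colnames(s) <- as.character(1:4)

  g <- sparsify_knn_threshold(s, k = 1, threshold = 0.3)
  expect_equal(nrow(g$edges), 2)
  expect_setequal(paste(g$edges$from, g$edges$to), c("1 2", "3 4"))
  expect_equal(sort(g$edges$weight), c(0.8, 0.9))

  expect_warning(g2 <- sparsify_knn_threshold(s, k = 1, threshold = 0.95),
                 "empty edge set")
  expect_equal(nrow(g2$edges), 0)
  expect_equal(length(g2$nodes), 4)          # isolated nodes stay in the node set

  g3 <- sparsify_knn_threshold(s, k = 3, threshold = 0)
  expect_equal(nrow(g3$edges), 6)            # complete graph
})

test_that("sparsification is monotone in k and threshold", {
  co <- standardize_features(impute_missing(generate_cohort(ibs_cohort_spec(seed = 14))))
  s <- gaussian_similarity(pairwise_distances(co, "euclidean"))
  edge_key <- function(g) paste(g$edges$from, g$edges$to)
  for (k in c(3, 6, 10)) {
    lo <- suppressWarnings(sparsify_knn_threshold(s, k, 0.5))
    hi <- suppressWarnings(sparsify_knn_threshold(s, k, 0.2))
    expect_true(all(edge_key(lo) %in% edge_key(hi)))
  }
  for (thr in c(0.2, 0.4)) {
    small <- sparsify_knn_threshold(s, 4, thr)
    big <- sparsify_knn_threshold(s, 9, thr)
    expect_true(all(edge_key(small) %in% edge_key(big)))
  }
})

test_that("the graph is invariant to a global distance rescaling", {
  co <- standardize_features(impute_missing(generate_cohort(ibs_cohort_spec(seed = 15))))
  d <- pairwise_distances(co, "euclidean")
  g1 <- sparsify_knn_threshold(gaussian_similarity(d), 8, 0.3)
  d2 <- d * 4.2
  attr(d2, "metric") <- "euclidean"
  g2 <- sparsify_knn_threshold(gaussian_similarity(d2), 8, 0.3)
  expect_equal(g1$edges$from, g2$edges$from)
  expect_equal(g1$edges$to, g2$edges$to)
  expect_equal(g1$edges$weight, g2$edges$weight, tolerance = 1e-12)
})

test_that("graph summaries report degree, density and components", {
  tri <- graph_from_pairs(3, c(1, 2, 1), c(2, 3, 3))
  s <- graph_summary(tri)
  expect_equal(s$average_degree, 2)
  expect_equal(s$density, 1)
  expect_equal(s$n_components, 1)

  disj <- graph_from_pairs(4, c(1, 3), c(2, 4))
  expect_equal(graph_summary(disj)$n_components, 2)

  # mean normalized degree equals density exactly
  set.seed(31)
  for (i in 1:5) {
    g <- random_graph(12, 0.3)
    A <- psn_adjacency(g)
    expect_equal(mean(rowSums(A > 0) / (nrow(A) - 1)), graph_summary(g)$density)
  }
})

test_that("edge lists round-trip through TSV and GraphML export succeeds", {
  co <- generate_cohort(ibs_cohort_spec(seed = 16))
  g <- build_psn(co)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_psn_edges(g, tsv)
  back <- read_psn_edges(tsv, nodes = g$nodes)
  expect_equal(back$edges$from, g$edges$from)
  expect_equal(back$edges$to, g$edges$to)
  expect_equal(back$edges$weight, g$edges$weight, tolerance = 1e-12)

  gml <- withr::local_tempfile(fileext = ".graphml")
  write_psn_graphml(g, gml)
  expect_gt(file.size(gml), 0)
})
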