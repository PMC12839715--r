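test_that("centralities take their closed-form values on stars and cycles", {
  st <- star_graph(4)                        # center "1" + 4 leaves
  cent <- node_centralities(st)
  expect_equal(cent$degree[cent$participant_id == "1"], 1)
  expect_equal(cent$degree[cent$participant_id != "1"], rep(0.25, 4))
  expect_equal(cent$betweenness[cent$participant_id == "1"], 1)
  expect_equal(cent$betweenness[cent$participant_id != "1"], rep(0, 4))

  cy <- cycle_graph(5)
  cent5 <- node_centralities(cy)
  expect_equal(cent5$degree, rep(0.5, 5))
  expect_equal(length(unique(round(cent5$betweenness, 12))), 1)

  expect_error(node_centralities(graph_from_pairs(2, 1, 2)), "n < 3")
})

test_that("mean degree centrality equals density on any graph", {
  set.seed(91)
  for (i in 1:5) {
    g <- random_graph(15, 0.3)
    expect_equal(mean(node_centralities(g)$degree), graph_summary(g)$density)
  }
})

test_that("eigenvector centrality satisfies the eigen equation with unit L2 norm", {
  co <- generate_cohort(ibs_cohort_spec(seed = 26))
  g <- build_psn(co)
  cent <- node_centralities(g)
  x <- cent$eigenvector
  expect_equal(sum(x^2), 1, tolerance = 1e-8)
  expect_true(all(x >= 0))
  A <- psn_adjacency(g)
  Ax <- drop(A %*% x)
  lambda <- sum(x * Ax)
  expect_lt(max(abs(Ax - lambda * x)), 1e-6)
})

test_that("group comparisons report means, SDs and exact rank-sum p-values", {
  cent <- tibble::tibble(participant_id = as.character(1:4),
                         degree = c(1, 2, 3, 4),
                         betweenness = c(1, 2, 3, 4),
                         eigenvector = c(1, 2, 3, 4))
  out <- centrality_group_comparison(cent, c("IBS", "IBS", "HC", "HC"))
  deg <- out[out$measure == "degree", ]
  expect_equal(deg$mean[deg$group == "IBS"], 1.5)
  expect_equal(deg$mean[deg$group == "HC"], 3.5)
  expect_equal(unique(deg$p_value), 1 / 3)   # enumeration of all 6 assignments

  # identical groups: identical summaries
  cent2 <- cent
  cent2$degree <- c(1, 2, 1, 2)
  out2 <- centrality_group_comparison(cent2, c("IBS", "IBS", "HC", "HC"))
  deg2 <- out2[out2$measure == "degree", ]
  expect_equal(deg2$mean[1], deg2$mean[2])
  expect_equal(deg2$sd[1], deg2$sd[2])

  expect_error(centrality_group_comparison(cent, c("IBS", "HC", "HC", "HC")),
               "at least 2 members")
})

test_that("severity correlations recover monotone relationships", {
  co <- generate_cohort(ibs_cohort_spec(seed = 28))
  g <- build_psn(co)
  cent <- node_centralities(g)

  ibs_ids <- co$participant_id[co$diagnosis == "IBS"]
  sss_up <- setNames(rank(cent$degree[match(ibs_ids, cent$participant_id)]),
                     ibs_ids)
  up <- centrality_severity_correlation(cent, sss_up)
  expect_equal(up$rho[up$measure == "degree"], 1)
  dn <- centrality_severity_correlation(cent, 500 - sss_up)
  expect_equal(dn$rho[dn$measure == "degree"], -1)

  expect_error(centrality_severity_correlation(cent, setNames(rep(100, length(ibs_ids)), ibs_ids)),
               "constant")
})

test_that("centrality is uncorrelated with random severity scores", {
  co <- generate_cohort(ibs_cohort_spec(seed = 29))
  cent <- node_centralities(build_psn(co))
  ibs_ids <- co$participant_id[co$diagnosis == "IBS"]
  deg <- cent$degree[match(ibs_ids, cent$participant_id)]
  set.seed(30)
  small <- 0
  for (i in 1:100) {
    rho <- cor(deg, sample(500, length(ibs_ids), replace = TRUE), method = "spearman")
    if (abs(rho) < 0.4) small <- small + 1
  }
  expect_gte(small, 95)
})

test_that("Spearman rho equals the Pearson correlation of average ranks", {
  set.seed(44)
  for (i in 1:10) {
    x <- sample(1:6, 20, replace = TRUE)    # plenty of ties
    y <- rnorm(20)
    expect_equal(cor(x, y, method = "spearman"),
                 cor(rank(x), rank(y)), tolerance = 1e-12)
  }
})

test_that("feature importance ranks features and adjusts p-values upward", {
  co <- generate_cohort(ibs_cohort_spec(seed = 33))
  g <- build_psn(co)
  cent <- node_centralities(g)
  std <- standardize_features(impute_missing(co))

  # plant a feature identical to degree centrality
  std2 <- std
  std2$Left_Hippocampus <- cent$degree[match(std$participant_id,
                                             cent$participant_id)] + 1e-9
  fi <- feature_importance(std2, cent)
  expect_equal(fi$feature[1], "Left_Hippocampus")
  expect_equal(fi$rho[1], 1, tolerance = 1e-6)
  expect_true(all(fi$p_adjusted >= fi$p_value - 1e-15))
  expect_true(all(fi$p_adjusted <= 1))

  # BH adjusted p's are monotone in the raw-p ordering
  ord <- order(fi$p_value)
  expect_true(all(diff(fi$p_adjusted[ord]) >= -1e-15))
  expect_equal(nrow(fi), 42)
})

test_that("category comparison preserves the 36/6 split and detects separation", {
  co <- generate_cohort(ibs_cohort_spec(seed = 34))
  cent <- node_centralities(build_psn(co))
  fi <- feature_importance(standardize_features(impute_missing(co)), cent)
  cc <- category_comparison(fi)
  expect_setequal(cc$category, c("cognitive", "morphometric"))
  expect_equal(cc$n_features[cc$category == "morphometric"], 36L)
  expect_equal(cc$n_features[cc$category == "cognitive"], 6L)

  # all-equal |rho|: equal category means
  fi_eq <- fi
  fi_eq$rho <- 0.1
  cc_eq <- category_comparison(fi_eq)
  expect_equal(cc_eq$mean_abs_rho[1], cc_eq$mean_abs_rho[2])

  # one category strictly larger: exact rank-sum tail is tiny
  fi_sep <- fi
  fi_sep$rho <- ifelse(fi_sep$category == "cognitive",
                       0.8 + seq_len(nrow(fi_sep)) * 1e-3,
                       0.01 + seq_len(nrow(fi_sep)) * 1e-4)
  expect_lt(category_comparison(fi_sep)$p_value[1], 0.01)
})
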