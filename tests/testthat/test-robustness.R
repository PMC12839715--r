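test_that("metric comparison runs the pipeline once per distance measure", {
  co <- generate_cohort(ibs_cohort_spec(seed = 51))
  out <- compare_metrics(co)
  expect_equal(nrow(out), 3)
  expect_setequal(out$metric, c("euclidean", "cosine", "correlation"))
  expect_true(all(out$n_edges <= 78 * 77 / 2))
  expect_true(all(out$n_communities >= 1))
  # planted structure is metric-robust
  expect_lt(max(out$ari_vs_diagnosis) - min(out$ari_vs_diagnosis), 0.3)
})

test_that("metric agreement is stable across seeds", {
  diffs <- vapply(1:8, function(s) {
    out <- compare_metrics(generate_cohort(ibs_cohort_spec(seed = 60 + s)))
    abs(out$ari_vs_diagnosis[out$metric == "euclidean"] -
          out$ari_vs_diagnosis[out$metric == "cosine"])
  }, numeric(1))
  expect_gte(sum(diffs < 0.3), 7)
})

test_that("the k x threshold grid covers 16 conditions with monotone edge counts", {
  co <- generate_cohort(ibs_cohort_spec(seed = 52))
  out <- parameter_grid(co)
  expect_equal(nrow(out), 16)
  for (kk in unique(out$k)) {
    sub <- out[out$k == kk, ]
    sub <- sub[order(sub$threshold), ]
    expect_true(all(diff(sub$n_edges) <= 0))
  }
  for (tt in unique(out$threshold)) {
    sub <- out[out$threshold == tt, ]
    sub <- sub[order(sub$k), ]
    expect_true(all(diff(sub$n_edges) >= 0))
  }
})

test_that("grid rows satisfy the degree-density identity pipeline-wide", {
  co <- prepare <- generate_cohort(ibs_cohort_spec(seed = 53))
  out <- parameter_grid(co, ks = c(5, 10), thresholds = c(0.2, 0.4))
  std <- standardize_features(impute_missing(co))
  s <- gaussian_similarity(pairwise_distances(std, "euclidean"))
  for (i in seq_len(nrow(out))) {
    g <- sparsify_knn_threshold(s, out$k[i], out$threshold[i])
    expect_equal(mean(node_centralities(g)$degree), graph_summary(g)$density)
  }
})

test_that("removing zero edges is the identity and matches the unperturbed run", {
  co <- generate_cohort(ibs_cohort_spec(seed = 54))
  g <- build_psn(co)
  labels <- setNames(co$diagnosis, co$participant_id)
  out <- edge_removal_sweep(g, labels, fractions = 0, R = 2, seed = 1,
                            louvain_seed = 42)
  ref <- suppressWarnings(
    partition_agreement(louvain_communities(g, seed = 42), labels))
  expect_equal(out$n_edges, rep(nrow(g$edges), 2))
  expect_equal(out$ari_vs_diagnosis, rep(ref$ari, 2))
})

test_that("removing one edge from a tree splits it in two", {
  path5 <- graph_from_pairs(5, 1:4, 2:5)
  out <- edge_removal_sweep(path5, c("A", "A", "B", "B", "B"),
                            fractions = 0.25, R = 3, seed = 2)
  expect_equal(out$n_edges, rep(3L, 3))      # floor(0.25 * 4) = 1 removed
  expect_equal(out$n_components, rep(2, 3))
})

test_that("network topology is robust through heavy edge removal", {
  # strongly separated planted subgroups give one dense component per
  # subgroup; random removal of 45% of edges must not fragment them further
  stable <- vapply(1:10, function(s) {
    co <- generate_cohort(ibs_cohort_spec(effect_size = 4), seed = 70 + s)
    g <- build_psn(co)
    base <- graph_summary(g)$n_components
    out <- edge_removal_sweep(g, setNames(co$diagnosis, co$participant_id),
                              fractions = 0.45, R = 1, seed = s)
    out$n_components == base
  }, logical(1))
  expect_gte(sum(stable), 9)

  # a weak-structure cohort yields one connected component, maintained
  # through 45% removal (the regime the study's connected network sits in)
  connected <- vapply(1:10, function(s) {
    co <- generate_cohort(ibs_cohort_spec(effect_size = 0), seed = 70 + s)
    g <- build_psn(co)
    out <- edge_removal_sweep(g, setNames(co$diagnosis, co$participant_id),
                              fractions = 0.45, R = 1, seed = s)
    graph_summary(g)$n_components == 1 && out$n_components == 1
  }, logical(1))
  expect_gte(sum(connected), 9)
})

test_that("sweeps are exactly reproducible given the seed", {
  co <- generate_cohort(ibs_cohort_spec(seed = 55))
  g <- build_psn(co)
  labels <- setNames(co$diagnosis, co$participant_id)
  a <- edge_removal_sweep(g, labels, fractions = c(0.1, 0.3), R = 2, seed = 3)
  b <- edge_removal_sweep(g, labels, fractions = c(0.1, 0.3), R = 2, seed = 3)
  expect_identical(a, b)
})
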