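# Shared fixtures and independent oracles used across the suite.

# small cohort built by hand: 6 participants, 4 features
tiny_cohort <- function() {
  as_cohort(tibble::tibble(
    participant_id = paste0("P", 1:6),
    diagnosis = c("IBS", "IBS", "HC", "IBS", "HC", "HC"),
    age = c(40, 35, 28, 52, 31, 45),
    ibs_sss = c(210, 180, NA, 320, NA, NA),
    rbans_total = c(101, 95, 99, 84, 103, 97),
    Left_Hippocampus = c(3.1, 3.0, 2.8, 3.4, 2.9, 3.2),
    CC_Posterior = c(0.9, 1.1, 1.0, 0.8, 1.2, 1.0),
    RBANS_Language = c(98, 91, 104, 88, 110, 101),
    RBANS_Total_Scale = c(101, 95, 99, 84, 103, 97)
  ))
}

# graph from a compact edge specification, all nodes "1".."n"
graph_from_pairs <- function(n, from, to, weight = 1) {
  psn_graph(as.character(seq_len(n)),
            tibble::tibble(from = as.character(from), to = as.character(to),
                           weight = weight))
}

# two disjoint cliques of size k each
two_cliques <- function(k) {
  e1 <- t(combn(seq_len(k), 2))
  e2 <- t(combn(seq_len(k) + k, 2))
  graph_from_pairs(2 * k, c(e1[, 1], e2[, 1]), c(e1[, 2], e2[, 2]))
}

star_graph <- function(n_leaves) {
  graph_from_pairs(n_leaves + 1, rep(1, n_leaves), seq_len(n_leaves) + 1)
}

cycle_graph <- function(n) {
  graph_from_pairs(n, seq_len(n), c(seq_len(n)[-1], 1))
}

random_graph <- function(n, p = 0.4) {
  pairs <- t(combn(seq_len(n), 2))
  keep <- runif(nrow(pairs)) < p
  if (!any(keep)) keep[sample(nrow(pairs), 1)] <- TRUE
  graph_from_pairs(n, pairs[keep, 1], pairs[keep, 2])
}

# --- independent oracles -------------------------------------------------

# ARI by brute-force pair counting over all C(n,2) item pairs
ari_pair_oracle <- function(a, b) {
  n <- length(a)
  n11 <- na <- nb <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]
      sb <- b[i] == b[j]
      n11 <- n11 + (sa && sb)
      na <- na + sa
      nb <- nb + sb
    }
  }
  N <- n * (n - 1) / 2
  expected <- na * nb / N
  maximum <- (na + nb) / 2
  (n11 - expected) / (maximum - expected)
}

# modularity by direct double sum over the adjacency matrix
modularity_oracle <- function(graph, membership, weighted = TRUE) {
  A <- psn_adjacency(graph, weighted = weighted)
  k <- rowSums(A)
  m2 <- sum(A)
  q <- 0
  n <- nrow(A)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (membership[i] == membership[j]) {
        q <- q + A[i, j] - k[i] * k[j] / m2
      }
    }
  }
  unname(q / m2)
}

# Pearson chi-square by direct sum((O - E)^2 / E)
chisq_oracle <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# all set partitions of 1..n as membership vectors (restricted growth strings)
all_partitions <- function(n) {
  out <- list()
  grow <- function(prefix, k) {
    if (length(prefix) == n) {
      out[[length(out) + 1]] <<- prefix
      return(invisible())
    }
    for (c in seq_len(k + 1)) grow(c(prefix, c), max(k, c))
  }
  grow(integer(0), 0L)
  out
}

max_modularity_exhaustive <- function(graph) {
  parts <- all_partitions(length(graph$nodes))
  max(vapply(parts, function(p) modularity_oracle(graph, p), numeric(1)))
}
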