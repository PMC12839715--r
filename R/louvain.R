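# Modularity and Louvain community detection, implemented from scratch.
# Internal convention: B is a symmetric "doubled-diagonal" adjacency matrix
# (B[i,i] = 2 x self-loop weight, produced by aggregation), so that
# k = rowSums(B), 2m = sum(B), and
# Q = sum_c [ Sin_c / 2m - gamma (tot_c / 2m)^2 ].

#' Newman-Girvan modularity of a partition
#'
#' `Q = (1/2m) * sum_ij (A_ij - k_i k_j / 2m) * delta(c_i, c_j)`, with `A_ij`
#' the kernel similarity (weighted mode, default) or 1 (unweighted), `k_i`
#' the (weighted) degree and `m` the total (weighted) edge count.
#'
#' @param graph A `psn_graph` with at least one edge.
#' @param membership Community labels, named by node or in node order.
#' @param weighted Use edge weights (default `TRUE`).
#' @param resolution Resolution parameter gamma (1 = standard modularity).
#' @return Modularity Q, in \[-0.5, 1).
#' @export
modularity_q <- function(graph, membership, weighted = TRUE, resolution = 1) {
  if (nrow(graph$edges) == 0) stop("empty edge set: modularity undefined", call. = FALSE)
  B <- psn_adjacency(graph, weighted = weighted)
  membership <- align_membership(membership, graph$nodes)
  modularity_from_B(B, membership, resolution)
}

align_membership <- function(membership, nodes) {
  if (inherits(membership, "psn_partition")) membership <- membership$membership
  if (!is.null(names(membership))) {
    if (!all(nodes %in% names(membership))) {
      stop("membership does not cover all nodes", call. = FALSE)
    }
    membership <- membership[nodes]
  } else if (length(membership) != length(nodes)) {
    stop("membership length does not match node count", call. = FALSE)
  }
  as.integer(factor(membership))
}

modularity_from_B <- function(B, comm, gamma = 1) {
  m2 <- sum(B)
  k <- rowSums(B)
  sin_c <- vapply(split(seq_along(comm), comm),
                  function(ix) sum(B[ix, ix, drop = FALSE]), numeric(1))
  tot_c <- vapply(split(k, comm), sum, numeric(1))
  sum(sin_c / m2 - gamma * (tot_c / m2)^2)
}

# one local-moving phase; comm labels start as 1..n and end contiguous
louvain_one_level <- function(B, gamma, tol) {
  n <- nrow(B)
  k <- rowSums(B)
  m2 <- sum(B)
  comm <- seq_len(n)
  tot <- k
  improved <- FALSE
  repeat {
    n_moved <- 0L
    for (i in sample.int(n)) {
      ci <- comm[i]
      w <- B[i, ]
      w[i] <- 0
      nbr <- which(w > 0)
      cand <- unique(c(ci, comm[nbr]))
      wc <- vapply(cand, function(cc) sum(w[comm == cc]), numeric(1))
      tot_excl <- tot[cand]
      tot_excl[cand == ci] <- tot_excl[cand == ci] - k[i]
      score <- wc - gamma * k[i] * tot_excl / m2
      cur <- score[cand == ci]
      best <- max(score)
      if (2 * (best - cur) / m2 > tol) {      # actual modularity gain
        target <- min(cand[score >= best - 1e-12])   # ties -> lowest label
        if (target != ci) {
          tot[ci] <- tot[ci] - k[i]
          tot[target] <- tot[target] + k[i]
          comm[i] <- target
          n_moved <- n_moved + 1L
        }
      }
    }
    if (n_moved == 0L) break
    improved <- TRUE
  }
  list(membership = match(comm, unique(comm)), improved = improved)
}

#' Louvain community detection
#'
#' Greedy modularity optimization in two alternating phases: local node
#' moves (seeded-random sweep order, a move is accepted only if it improves
#' Q by more than `tol`, ties broken toward the lowest community label) and
#' aggregation of communities into a weighted supergraph, repeated until no
#' move improves Q. Deterministic given `seed`. Final labels are contiguous
#' integers sorted by decreasing community size.
#'
#' @param graph A `psn_graph` with at least one edge.
#' @param seed RNG seed for the sweep order. The greedy search is restarted
#'   `n_restarts` times from sub-seeds `seed, seed + 1, ...` and the
#'   highest-modularity partition is kept (ties go to the earliest restart),
#'   which markedly reduces the chance of a poor local optimum while
#'   remaining fully deterministic.
#' @param resolution Resolution parameter gamma.
#' @param weighted Optimize weighted (default) or binary modularity.
#' @param tol Minimum accepted modularity gain per move.
#' @param n_restarts Number of seeded restarts.
#' @return A `psn_partition`: list with `membership` (named integer vector),
#'   `modularity`, `n_communities`, `q_history` (Q after each pass of the
#'   winning restart), `sizes`, and the call parameters.
#' @export
louvain_communities <- function(graph, seed = 42, resolution = 1,
                                weighted = TRUE, tol = 1e-7, n_restarts = 4) {
  best <- NULL
  for (r in seq_len(n_restarts)) {
    cand <- louvain_single_run(graph, seed + r - 1L, resolution, weighted, tol)
    if (is.null(best) || cand$modularity > best$modularity + 1e-12) best <- cand
  }
  best$seed <- seed
  best$n_restarts <- n_restarts
  best
}

louvain_single_run <- function(graph, seed, resolution, weighted, tol) {
  if (nrow(graph$edges) == 0) stop("empty edge set: cannot detect communities", call. = FALSE)
  B0 <- psn_adjacency(graph, weighted = weighted)
  withr::with_seed(seed, {
    B <- B0
    flat <- seq_len(nrow(B0))
    q_history <- numeric(0)
    repeat {
      lev <- louvain_one_level(B, resolution, tol)
      if (!lev$improved) break
      flat <- lev$membership[flat]
      q_history <- c(q_history, modularity_from_B(B0, flat, resolution))
      B <- aggregate_B(B, lev$membership)
      if (nrow(B) == 1) break
    }
    if (!length(q_history)) {
      q_history <- modularity_from_B(B0, flat, resolution)
    }
    flat <- relabel_by_size(flat)
    structure(list(
      membership = setNames(flat, graph$nodes),
      modularity = modularity_from_B(B0, flat, resolution),
      n_communities = max(flat),
      sizes = as.integer(table(flat)),
      q_history = q_history,
      seed = seed, resolution = resolution, weighted = weighted
    ), class = "psn_partition")
  })
}

aggregate_B <- function(B, comm) {
  S <- matrix(0, nrow(B), max(comm))
  S[cbind(seq_along(comm), comm)] <- 1
  t(S) %*% B %*% S
}

# contiguous labels, largest community first (ties by first appearance)
relabel_by_size <- function(comm) {
  comm <- match(comm, unique(comm))
  sizes <- tabulate(comm)
  ord <- order(-sizes, seq_along(sizes))
  new_label <- integer(length(ord))
  new_label[ord] <- seq_along(ord)
  new_label[comm]
}

#' @export
print.psn_partition <- function(x, ...) {
  cat(sprintf("# PSN partition: %d communities (sizes %s), Q = %.4f, seed %d\n",
              x$n_communities, paste(x$sizes, collapse = "/"),
              x$modularity, x$seed))
  invisible(x)
}

#' @export
tidy.psn_partition <- function(x, ...) {
  tibble::tibble(participant_id = names(x$membership),
                 community = unname(x$membership))
}

#' @export
glance.psn_partition <- function(x, ...) {
  tibble::tibble(n_communities = x$n_communities,
                 modularity = x$modularity,
                 n_nodes = length(x$membership),
                 seed = x$seed, resolution = x$resolution,
                 weighted = x$weighted)
}

#' Export a partition as CSV
#'
#' @param partition A `psn_partition`.
#' @param path Output CSV (`participant_id`, `community`).
#' @return `path`, invisibly.
#' @export
write_partition <- function(partition, path) {
  readr::write_csv(tidy(partition), path)
  invisible(path)
}
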