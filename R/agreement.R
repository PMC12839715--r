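# Partition-agreement statistics: contingency tables, adjusted Rand index,
# normalized mutual information, and diagnostic-group assortativity.

#' Cross-tabulate two labelings
#'
#' @param a,b Label vectors over the same participants in the same order.
#' @return An integer contingency matrix (labels of `a` as rows).
#' @export
contingency_table <- function(a, b) {
  if (length(a) != length(b)) stop("labelings differ in length", call. = FALSE)
  as.matrix(unclass(table(a, b)))
}

as_counts <- function(x, y = NULL) {
  if (!is.null(y)) return(contingency_table(x, y))
  m <- as.matrix(unclass(x))
  if (any(m < 0) || any(m != round(m))) stop("counts must be nonnegative integers", call. = FALSE)
  m
}

#' Adjusted Rand Index
#'
#' Chance-corrected pair-counting agreement between two partitions:
#' `ARI = (sum_ij C(n_ij,2) - E) / (M - E)` with
#' `E = sum_i C(a_i,2) sum_j C(b_j,2) / C(n,2)` and
#' `M = (sum_i C(a_i,2) + sum_j C(b_j,2)) / 2`. 1 means identical
#' partitions, 0 chance-level agreement.
#'
#' @param x A contingency matrix (e.g. from [contingency_table()]) or a
#'   label vector.
#' @param y Second label vector when `x` is a labeling.
#' @return ARI in (-1, 1\]. When both partitions are trivial (`M = E`),
#'   0 is returned with a warning.
#' @export
adjusted_rand_index <- function(x, y = NULL) {
  N <- as_counts(x, y)
  n <- sum(N)
  if (n < 2) stop("need at least 2 co-labeled items", call. = FALSE)
  ch2 <- function(v) sum(v * (v - 1) / 2)
  sum_pairs <- ch2(N)
  a <- ch2(rowSums(N))
  b <- ch2(colSums(N))
  E <- a * b / ch2(n)
  M <- (a + b) / 2
  if (M == E) {
    warning("degenerate contingency table (M = E); ARI defined as 0")
    return(0)
  }
  (sum_pairs - E) / (M - E)
}

#' Normalized Mutual Information
#'
#' Plug-in mutual information of the two labelings divided by the
#' arithmetic mean of their entropies (natural log; the normalization makes
#' the result base-invariant). Ranges from 0 (independent) to 1 (identical
#' up to relabeling).
#'
#' @inheritParams adjusted_rand_index
#' @return NMI in \[0, 1\]. When both partitions are trivial (zero entropy),
#'   defined as 1.
#' @export
normalized_mutual_information <- function(x, y = NULL) {
  N <- as_counts(x, y)
  n <- sum(N)
  if (n < 1) stop("empty contingency table", call. = FALSE)
  P <- N / n
  pi <- rowSums(P)
  pj <- colSums(P)
  H <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  pos <- P > 0
  I <- sum(P[pos] * log(P[pos] / outer(pi, pj)[pos]))
  denom <- (H(pi) + H(pj)) / 2
  if (denom == 0) return(1)
  I / denom
}

#' Assortativity by a discrete node attribute
#'
#' Newman's discrete assortativity coefficient from the edge-level mixing
#' matrix (each edge counted in both directions, unweighted):
#' `r = (sum_i e_ii - sum_i a_i^2) / (1 - sum_i a_i^2)`. Positive values
#' mean nodes preferentially connect to same-label nodes.
#'
#' @param graph A `psn_graph` with at least one edge.
#' @param labels Node labels (e.g. diagnosis), named by node or in node order.
#' @return r in \[-1, 1\].
#' @export
group_assortativity <- function(graph, labels) {
  if (nrow(graph$edges) == 0) stop("empty edge set", call. = FALSE)
  if (!is.null(names(labels))) labels <- labels[graph$nodes]
  if (length(labels) != length(graph$nodes)) {
    stop("labels do not cover all nodes", call. = FALSE)
  }
  labels <- as.character(labels)
  lv <- sort(unique(labels))
  if (length(lv) < 2) stop("all nodes carry the same label: assortativity undefined", call. = FALSE)
  ti <- match(labels[match(graph$edges$from, graph$nodes)], lv)
  tj <- match(labels[match(graph$edges$to, graph$nodes)], lv)
  e <- matrix(0, length(lv), length(lv), dimnames = list(lv, lv))
  for (r in seq_along(ti)) {
    e[ti[r], tj[r]] <- e[ti[r], tj[r]] + 1
    e[tj[r], ti[r]] <- e[tj[r], ti[r]] + 1
  }
  e <- e / sum(e)
  a2 <- sum(rowSums(e)^2)
  if (1 - a2 == 0) stop("degenerate mixing matrix", call. = FALSE)
  (sum(diag(e)) - a2) / (1 - a2)
}

#' Agreement between a partition and diagnosis labels
#'
#' Convenience wrapper computing the contingency table, ARI and NMI between
#' a detected partition and a reference labeling.
#'
#' @param partition A `psn_partition` or label vector.
#' @param labels Reference labels over the same participants.
#' @return One-row tibble `ari`, `nmi`, plus the table as an attribute.
#' @export
partition_agreement <- function(partition, labels) {
  if (inherits(partition, "psn_partition")) {
    if (!is.null(names(labels))) labels <- labels[names(partition$membership)]
    partition <- partition$membership
  }
  tab <- contingency_table(partition, labels)
  out <- tibble::tibble(ari = adjusted_rand_index(tab),
                        nmi = normalized_mutual_information(tab))
  attr(out, "contingency") <- tab
  out
}
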