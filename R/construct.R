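# Patient similarity network construction: pairwise distances over the
# standardized feature matrix, Gaussian-kernel similarities with a
# data-adaptive bandwidth, and kNN-union-plus-threshold sparsification.

#' Pairwise participant distances
#'
#' Computes the full symmetric distance matrix between participant feature
#' vectors under one of three metrics:
#' \describe{
#'   \item{euclidean}{straight-line distance in feature space}
#'   \item{cosine}{`1 - cos(angle)` between feature vectors, in \[0, 2\]}
#'   \item{correlation}{`1 - Pearson rho` between feature vectors, in \[0, 2\]}
#' }
#'
#' @param x A standardized `psn_cohort` or a numeric matrix
#'   (participants x features) with no missing values.
#' @param metric One of `"euclidean"`, `"cosine"`, `"correlation"`.
#' @return A symmetric nonnegative matrix with zero diagonal and a
#'   `"metric"` attribute.
#' @export
pairwise_distances <- function(x, metric = c("euclidean", "cosine", "correlation")) {
  metric <- match.arg(metric)
  X <- if (inherits(x, "psn_cohort")) feature_matrix(x) else as.matrix(x)
  if (anyNA(X)) stop("missing values in feature matrix", call. = FALSE)
  d <- switch(metric,
    euclidean = as.matrix(dist(X)),
    cosine = {
      norms <- sqrt(rowSums(X^2))
      if (any(norms == 0)) stop("all-zero row: cosine distance undefined", call. = FALSE)
      1 - tcrossprod(X / norms)
    },
    correlation = {
      if (any(apply(X, 1, sd) == 0)) {
        stop("constant row: correlation distance undefined", call. = FALSE)
      }
      1 - cor(t(X))
    }
  )
  d <- (d + t(d)) / 2          # kill asymmetric rounding noise
  d[d < 0] <- 0
  diag(d) <- 0
  dimnames(d) <- list(rownames(X), rownames(X))
  attr(d, "metric") <- metric
  d
}

#' Data-adaptive Gaussian kernel bandwidth
#'
#' The bandwidth sigma is the mean distance over the `n(n-1)/2` unordered
#' distinct participant pairs (diagonal excluded), scaling the kernel to the
#' typical separation in feature space.
#'
#' @param d A distance matrix from [pairwise_distances()].
#' @return A positive scalar.
#' @export
kernel_bandwidth <- function(d) {
  d <- as.matrix(d)
  if (nrow(d) < 2) stop("need at least 2 participants", call. = FALSE)
  sigma <- mean(d[upper.tri(d)])
  if (sigma <= 0) stop("all pairwise distances are zero: degenerate cohort", call. = FALSE)
  sigma
}

#' Gaussian kernel similarity
#'
#' Maps distances to similarities `s = exp(-d^2 / (2 sigma^2))` in (0, 1],
#' with `s = 1` on the diagonal.
#'
#' @param d A distance matrix.
#' @param bandwidth Kernel scale sigma; defaults to [kernel_bandwidth()] of `d`.
#' @return A symmetric similarity matrix with unit diagonal and a
#'   `"bandwidth"` attribute.
#' @export
gaussian_similarity <- function(d, bandwidth = kernel_bandwidth(d)) {
  if (bandwidth <= 0) stop("bandwidth must be positive", call. = FALSE)
  s <- exp(-as.matrix(d)^2 / (2 * bandwidth^2))
  attr(s, "metric") <- attr(d, "metric")
  attr(s, "bandwidth") <- bandwidth
  s
}

#' Sparsify a similarity matrix into a kNN-union graph
#'
#' A candidate edge \{i, j\} exists iff j is among i's k most similar
#' neighbours or i is among j's (symmetric union); candidates with
#' similarity below `threshold` are then removed. Ties in the kNN ranking
#' are broken toward the lower participant index. Node degree may exceed k
#' under union semantics, and isolated nodes remain in the node set.
#'
#' @param s Similarity matrix from [gaussian_similarity()].
#' @param k Number of nearest neighbours, `1 <= k <= n - 1`.
#' @param threshold Minimum retained similarity, in \[0, 1).
#' @return A `psn_graph`: list with `nodes` (character), `edges` (tibble
#'   `from`, `to`, `weight`) and `params`.
#' @export
sparsify_knn_threshold <- function(s, k = 8, threshold = 0.3) {
  s <- as.matrix(s)
  n <- nrow(s)
  if (k < 1 || k > n - 1) stop("k must lie in [1, n - 1]", call. = FALSE)
  if (threshold < 0 || threshold >= 1) stop("threshold must lie in [0, 1)", call. = FALSE)
  ids <- rownames(s)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  keep <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    sim <- s[i, ]
    sim[i] <- -Inf
    nn <- order(-sim, seq_len(n))[seq_len(k)]   # ties -> lower index first
    keep[i, nn] <- TRUE
  }
  keep <- keep | t(keep)                        # kNN union symmetrization
  keep[lower.tri(keep, diag = TRUE)] <- FALSE
  keep[s < threshold] <- FALSE
  idx <- which(keep, arr.ind = TRUE)
  edges <- tibble::tibble(
    from = ids[idx[, 1]], to = ids[idx[, 2]],
    weight = s[idx]
  )
  edges <- dplyr::arrange(edges, match(.data$from, ids), match(.data$to, ids))
  if (nrow(edges) == 0) warning("sparsification produced an empty edge set")
  new_psn_graph(ids, edges, params = list(
    metric = attr(s, "metric"), k = k, threshold = threshold,
    bandwidth = attr(s, "bandwidth")
  ))
}

new_psn_graph <- function(nodes, edges, params = list()) {
  structure(list(nodes = nodes, edges = edges, params = params),
            class = "psn_graph")
}

#' Construct a PSN graph from an edge list
#'
#' @param nodes Character vector of node IDs (isolates allowed).
#' @param edges Data frame with columns `from`, `to` and optionally
#'   `weight` (defaults to 1).
#' @param params Optional construction parameter list.
#' @return A `psn_graph`.
#' @export
psn_graph <- function(nodes, edges, params = list()) {
  edges <- tibble::as_tibble(edges)
  if (!all(c("from", "to") %in% names(edges))) {
    stop("edges need `from` and `to` columns", call. = FALSE)
  }
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (!"weight" %in% names(edges)) edges$weight <- 1
  nodes <- as.character(nodes)
  if (!all(c(edges$from, edges$to) %in% nodes)) {
    stop("edge endpoints must be in the node set", call. = FALSE)
  }
  if (any(edges$from == edges$to)) stop("self-loops are not allowed", call. = FALSE)
  if (any(edges$weight <= 0) || any(edges$weight > 1)) {
    stop("edge weights must lie in (0, 1]", call. = FALSE)
  }
  new_psn_graph(nodes, edges[, c("from", "to", "weight")], params)
}

#' @export
print.psn_graph <- function(x, ...) {
  p <- x$params
  cat(sprintf("# PSN graph: %d nodes, %d edges", length(x$nodes), nrow(x$edges)))
  if (!is.null(p$metric)) {
    cat(sprintf(" (metric %s, k=%s, threshold=%s)", p$metric, p$k, p$threshold))
  }
  cat("\n")
  invisible(x)
}

#' Weighted adjacency matrix of a PSN graph
#'
#' @param graph A `psn_graph`.
#' @param weighted Use kernel similarities as weights (default) or binary 0/1.
#' @return Symmetric n x n matrix with node IDs as dimnames.
#' @export
psn_adjacency <- function(graph, weighted = TRUE) {
  n <- length(graph$nodes)
  A <- matrix(0, n, n, dimnames = list(graph$nodes, graph$nodes))
  if (nrow(graph$edges)) {
    i <- match(graph$edges$from, graph$nodes)
    j <- match(graph$edges$to, graph$nodes)
    w <- if (weighted) graph$edges$weight else 1
    A[cbind(i, j)] <- w
    A[cbind(j, i)] <- w
  }
  A
}

#' Convert a PSN graph to igraph
#'
#' @param graph A `psn_graph`.
#' @return An undirected weighted [igraph::igraph] object.
#' @export
as_igraph <- function(graph) {
  ig <- igraph::graph_from_data_frame(graph$edges, directed = FALSE,
                                      vertices = data.frame(name = graph$nodes))
  ig
}

#' Build a patient similarity network from a cohort
#'
#' Convenience wrapper running imputation (if needed), z-scoring (if needed),
#' pairwise distances, the Gaussian kernel with data-adaptive bandwidth, and
#' kNN-union-plus-threshold sparsification.
#'
#' @param cohort A `psn_cohort`.
#' @param metric Distance metric (see [pairwise_distances()]).
#' @param k,threshold Sparsification parameters.
#' @return A `psn_graph`.
#' @export
build_psn <- function(cohort, metric = "euclidean", k = 8, threshold = 0.3) {
  if (n_missing(cohort) > 0) cohort <- impute_missing(cohort)
  if (!isTRUE(attr(cohort, "standardized"))) cohort <- standardize_features(cohort)
  d <- pairwise_distances(cohort, metric)
  s <- gaussian_similarity(d)
  sparsify_knn_threshold(s, k = k, threshold = threshold)
}

#' Summarise a PSN graph
#'
#' @param graph A `psn_graph`.
#' @return One-row tibble: `n_nodes`, `n_edges`, `average_degree` (`2E/n`),
#'   `density` (`E / (n(n-1)/2)`), `n_components`.
#' @export
graph_summary <- function(graph) {
  n <- length(graph$nodes)
  E <- nrow(graph$edges)
  tibble::tibble(
    n_nodes = n,
    n_edges = E,
    average_degree = 2 * E / n,
    density = E / (n * (n - 1) / 2),
    n_components = igraph::count_components(as_igraph(graph))
  )
}

#' @export
glance.psn_graph <- function(x, ...) graph_summary(x)

#' @export
tidy.psn_graph <- function(x, ...) x$edges

#' Export / import a PSN edge list
#'
#' Writes a weighted edge list as TSV (`from`, `to`, `weight`); the importer
#' reconstructs the graph (isolated nodes are preserved through the `nodes`
#' argument). [write_psn_graphml()] exports GraphML via igraph.
#'
#' @param graph A `psn_graph`.
#' @param path Output file.
#' @return `path`, invisibly (writers); a `psn_graph` (reader).
#' @export
write_psn_edges <- function(graph, path) {
  readr::write_tsv(graph$edges, path)
  invisible(path)
}

#' @rdname write_psn_edges
#' @param nodes Node IDs including isolates; defaults to those in the file.
#' @export
read_psn_edges <- function(path, nodes = NULL) {
  edges <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (is.null(nodes)) nodes <- unique(c(edges$from, edges$to))
  new_psn_graph(nodes, edges)
}

#' @rdname write_psn_edges
#' @export
write_psn_graphml <- function(graph, path) {
  igraph::write_graph(as_igraph(graph), path, format = "graphml")
  invisible(path)
}

#' Plot a PSN graph
#'
#' Fruchterman-Reingold layout with nodes coloured by an optional grouping
#' (community or diagnosis) and edge alpha proportional to similarity.
#'
#' @param object A `psn_graph`.
#' @param colour_by Optional vector (named by node or in node order) used to
#'   colour nodes.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psn_graph <- function(object, colour_by = NULL, seed = 1, ...) {
  ig <- as_igraph(object)
  xy <- withr::with_seed(seed, igraph::layout_with_fr(ig))
  nodes <- tibble::tibble(participant_id = object$nodes,
                          x = xy[match(object$nodes, igraph::V(ig)$name), 1],
                          y = xy[match(object$nodes, igraph::V(ig)$name), 2])
  if (!is.null(colour_by)) {
    if (!is.null(names(colour_by))) colour_by <- colour_by[object$nodes]
    nodes$group <- factor(colour_by)
  }
  ed <- object$edges
  ed$x <- nodes$x[match(ed$from, nodes$participant_id)]
  ed$y <- nodes$y[match(ed$from, nodes$participant_id)]
  ed$xend <- nodes$x[match(ed$to, nodes$participant_id)]
  ed$yend <- nodes$y[match(ed$to, nodes$participant_id)]
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = ed,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend,
                   alpha = .data$weight),
      colour = "grey50", show.legend = FALSE
    )
  if (is.null(colour_by)) {
    p <- p + ggplot2::geom_point(data = nodes, ggplot2::aes(.data$x, .data$y), size = 2)
  } else {
    p <- p + ggplot2::geom_point(
      data = nodes, ggplot2::aes(.data$x, .data$y, colour = .data$group), size = 2
    ) + ggplot2::labs(colour = NULL)
  }
  p + ggplot2::theme_void()
}
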