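# Sensitivity analyses: similarity-metric comparison, k x threshold
# parameter grid, and random edge-removal robustness.

sweep_row <- function(graph, labels, louvain_seed, ...) {
  gs <- graph_summary(graph)
  if (gs$n_edges == 0) {
    return(tibble::tibble(..., n_edges = 0L, n_communities = NA_integer_,
                          modularity = NA_real_, ari_vs_diagnosis = NA_real_,
                          nmi_vs_diagnosis = NA_real_,
                          n_components = gs$n_components))
  }
  part <- louvain_communities(graph, seed = louvain_seed)
  agree <- suppressWarnings(partition_agreement(part, labels))
  tibble::tibble(..., n_edges = gs$n_edges,
                 n_communities = part$n_communities,
                 modularity = part$modularity,
                 ari_vs_diagnosis = agree$ari,
                 nmi_vs_diagnosis = agree$nmi,
                 n_components = gs$n_components)
}

as_sweep <- function(x) { class(x) <- c("psn_sweep", class(x)); x }

prepare_standardized <- function(cohort) {
  if (n_missing(cohort) > 0) cohort <- impute_missing(cohort)
  if (!isTRUE(attr(cohort, "standardized"))) cohort <- standardize_features(cohort)
  cohort
}

#' Compare similarity metrics
#'
#' Runs the full pipeline (distances, kernel with freshly recomputed
#' bandwidth, sparsification, Louvain) once per distance metric at fixed
#' `(k, threshold)` and reports edge counts, community structure and
#' agreement with diagnosis.
#'
#' @param cohort A `psn_cohort`.
#' @param k,threshold Sparsification parameters.
#' @param louvain_seed Seed for every Louvain run.
#' @return A `psn_sweep` tibble with one row per metric.
#' @export
compare_metrics <- function(cohort, k = 8, threshold = 0.3, louvain_seed = 42) {
  cohort <- prepare_standardized(cohort)
  labels <- setNames(cohort$diagnosis, cohort$participant_id)
  as_sweep(purrr::map_dfr(c("euclidean", "cosine", "correlation"), function(m) {
    s <- gaussian_similarity(pairwise_distances(cohort, m))
    g <- suppressWarnings(sparsify_knn_threshold(s, k = k, threshold = threshold))
    sweep_row(g, labels, louvain_seed, metric = m)
  }))
}

#' Sweep the k x threshold construction grid
#'
#' @param cohort A `psn_cohort`.
#' @param ks Neighbour counts to try.
#' @param thresholds Similarity thresholds to try.
#' @param metric Distance metric.
#' @param louvain_seed Seed for every Louvain run.
#' @return A `psn_sweep` tibble with one row per `(k, threshold)` condition.
#' @export
parameter_grid <- function(cohort, ks = c(5, 8, 10, 15),
                           thresholds = c(0.2, 0.3, 0.4, 0.5),
                           metric = "euclidean", louvain_seed = 42) {
  cohort <- prepare_standardized(cohort)
  labels <- setNames(cohort$diagnosis, cohort$participant_id)
  s <- gaussian_similarity(pairwise_distances(cohort, metric))
  grid <- expand.grid(k = ks, threshold = thresholds, KEEP.OUT.ATTRS = FALSE)
  as_sweep(purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    g <- suppressWarnings(sparsify_knn_threshold(s, k = grid$k[i],
                                                 threshold = grid$threshold[i]))
    sweep_row(g, labels, louvain_seed, k = grid$k[i], threshold = grid$threshold[i])
  }))
}

#' Robustness to random edge removal
#'
#' For each removal fraction f and repeat, removes `floor(f * E)` uniformly
#' chosen edges without replacement, reruns Louvain, and records agreement
#' with the reference labels and the component count.
#'
#' @param graph A `psn_graph`.
#' @param labels Reference labels (e.g. diagnosis), named by node or in
#'   node order.
#' @param fractions Removal fractions in \[0, 1).
#' @param R Repeats per fraction (distinct removal draws).
#' @param seed RNG seed for edge selection.
#' @param louvain_seed Seed for every Louvain run.
#' @return A `psn_sweep` tibble with one row per (fraction, repeat).
#' @export
edge_removal_sweep <- function(graph, labels,
                               fractions = seq(0, 0.45, by = 0.05),
                               R = 10, seed = 42, louvain_seed = 42) {
  stopifnot(all(fractions >= 0), all(fractions < 1), R >= 1)
  if (!is.null(names(labels))) labels <- labels[graph$nodes]
  E <- nrow(graph$edges)
  withr::with_seed(seed, {
    as_sweep(purrr::map_dfr(fractions, function(f) {
      purrr::map_dfr(seq_len(R), function(r) {
        n_drop <- floor(f * E)
        keep <- if (n_drop > 0) -sample.int(E, n_drop) else seq_len(E)
        g <- new_psn_graph(graph$nodes, graph$edges[keep, ], graph$params)
        sweep_row(g, labels, louvain_seed, fraction = f, rep = r)
      })
    }))
  })
}

#' Plot a sensitivity sweep
#'
#' For edge-removal sweeps, plots ARI (or component count) against the
#' removal fraction with per-fraction mean; for grid sweeps, a tile map of
#' edge counts over the k x threshold grid.
#'
#' @param object A `psn_sweep` tibble.
#' @param what `"ari"` or `"components"` (edge-removal sweeps only).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psn_sweep <- function(object, what = c("ari", "components"), ...) {
  what <- match.arg(what)
  if ("fraction" %in% names(object)) {
    yvar <- if (what == "ari") "ari_vs_diagnosis" else "n_components"
    ggplot2::ggplot(object, ggplot2::aes(.data$fraction, .data[[yvar]])) +
      ggplot2::geom_point(alpha = 0.4) +
      ggplot2::stat_summary(fun = mean, geom = "line", colour = "steelblue") +
      ggplot2::labs(x = "fraction of edges removed",
                    y = if (what == "ari") "ARI vs labels" else "connected components") +
      ggplot2::theme_minimal()
  } else if (all(c("k", "threshold") %in% names(object))) {
    ggplot2::ggplot(object, ggplot2::aes(factor(.data$k), factor(.data$threshold),
                                         fill = .data$n_edges)) +
      ggplot2::geom_tile() +
      ggplot2::labs(x = "k", y = "threshold", fill = "edges") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object, ggplot2::aes(.data$metric, .data$ari_vs_diagnosis)) +
      ggplot2::geom_col() +
      ggplot2::labs(x = NULL, y = "ARI vs diagnosis") +
      ggplot2::theme_minimal()
  }
}
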