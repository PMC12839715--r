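# Node centralities, group comparisons, centrality-severity correlations,
# and feature-importance analysis with Benjamini-Hochberg FDR control.

power_iteration <- function(A, tol = 1e-10, max_iter = 1000) {
  x <- rep(1 / sqrt(nrow(A)), nrow(A))
  for (it in seq_len(max_iter)) {
    y <- drop(A %*% x)
    nrm <- sqrt(sum(y^2))
    if (nrm == 0) return(x)            # no edges in component
    y <- y / nrm
    if (max(abs(y - x)) < tol) return(y)
    x <- y
  }
  x
}

#' Node centralities of a PSN graph
#'
#' Degree centrality is `degree / (n - 1)` (unweighted). Betweenness uses
#' unweighted (hop-count) shortest paths, normalized by `(n-1)(n-2)/2`.
#' Eigenvector centrality is the L2-normalized leading eigenvector of the
#' weighted adjacency matrix, computed by power iteration; on a
#' disconnected graph it is computed on the largest component with other
#' nodes set to 0 (with a warning).
#'
#' @param graph A `psn_graph` with at least 3 nodes.
#' @return Tibble `participant_id`, `degree`, `betweenness`, `eigenvector`.
#' @export
node_centralities <- function(graph) {
  n <- length(graph$nodes)
  if (n < 3) stop("betweenness undefined for n < 3", call. = FALSE)
  A <- psn_adjacency(graph, weighted = TRUE)
  degree <- rowSums(A > 0) / (n - 1)
  ig <- as_igraph(graph)
  btw <- igraph::betweenness(ig, weights = NA, normalized = TRUE)
  btw <- btw[match(graph$nodes, igraph::V(ig)$name)]
  comp <- igraph::components(ig)
  memb <- comp$membership[match(graph$nodes, igraph::V(ig)$name)]
  eig <- numeric(n)
  main <- which(memb == which.max(comp$csize))
  if (comp$no > 1) {
    warning("graph is disconnected; eigenvector centrality computed on the largest component")
  }
  v <- power_iteration(A[main, main, drop = FALSE])
  eig[main] <- abs(v)
  tibble::tibble(participant_id = graph$nodes,
                 degree = unname(degree),
                 betweenness = unname(btw),
                 eigenvector = eig)
}

centrality_measures <- c("degree", "betweenness", "eigenvector")

#' Compare centralities between diagnostic groups
#'
#' Group-wise mean and SD per centrality measure plus a two-sided
#' Wilcoxon rank-sum p-value (exact where sample sizes permit).
#'
#' @param centralities Output of [node_centralities()].
#' @param labels Two-level group labels, named by participant or in row order.
#' @return Tibble `measure`, `group`, `n`, `mean`, `sd`, `p_value` (the
#'   p-value repeated across the two group rows of a measure).
#' @export
centrality_group_comparison <- function(centralities, labels) {
  if (!is.null(names(labels))) labels <- labels[centralities$participant_id]
  labels <- as.character(labels)
  groups <- sort(unique(labels))
  if (length(groups) != 2) stop("exactly two groups required", call. = FALSE)
  if (any(table(labels) < 2)) stop("each group needs at least 2 members (SD undefined)", call. = FALSE)
  purrr::map_dfr(centrality_measures, function(m) {
    x <- centralities[[m]]
    p <- suppressWarnings(wilcox.test(x[labels == groups[1]],
                                      x[labels == groups[2]]))$p.value
    tibble::tibble(
      measure = m, group = groups,
      n = as.integer(table(labels)[groups]),
      mean = unname(vapply(groups, function(g) mean(x[labels == g]), numeric(1))),
      sd = unname(vapply(groups, function(g) sd(x[labels == g]), numeric(1))),
      p_value = p
    )
  })
}

spearman_test <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) stop("constant input: Spearman rho undefined", call. = FALSE)
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  c(rho = unname(ct$estimate), p = ct$p.value)
}

#' Correlate centralities with symptom severity
#'
#' Spearman correlations (average-rank tie handling, two-sided p from the
#' t-approximation) between each centrality measure and IBS-SSS, restricted
#' to IBS participants with a recorded score.
#'
#' @param centralities Output of [node_centralities()].
#' @param cohort A `psn_cohort` with `diagnosis` and `ibs_sss` columns, or a
#'   named numeric vector of patient-only scores.
#' @return Tibble `measure`, `n`, `rho`, `p_value`.
#' @export
centrality_severity_correlation <- function(centralities, cohort) {
  if (inherits(cohort, "data.frame")) {
    keep <- cohort$diagnosis == "IBS" & !is.na(cohort$ibs_sss)
    sss <- setNames(cohort$ibs_sss[keep], cohort$participant_id[keep])
  } else {
    sss <- cohort[!is.na(cohort)]
  }
  ids <- intersect(centralities$participant_id, names(sss))
  if (length(ids) < 3) stop("need at least 3 patients with severity scores", call. = FALSE)
  rows <- match(ids, centralities$participant_id)
  purrr::map_dfr(centrality_measures, function(m) {
    st <- spearman_test(centralities[[m]][rows], sss[ids])
    tibble::tibble(measure = m, n = length(ids), rho = st[["rho"]], p_value = st[["p"]])
  })
}

#' Feature importance via centrality correlation
#'
#' Spearman correlation of each standardized feature with degree centrality,
#' with two-sided p-values from the t-approximation and Benjamini-Hochberg
#' FDR adjustment across all features in the active run.
#'
#' @param cohort A `psn_cohort` (standardized; imputed/standardized on the
#'   fly otherwise).
#' @param centralities Output of [node_centralities()] on the same cohort.
#' @return A `psn_importance` tibble `feature`, `category`, `rho`,
#'   `p_value`, `p_adjusted`, sorted by decreasing absolute rho.
#' @export
feature_importance <- function(cohort, centralities) {
  if (!isTRUE(attr(cohort, "standardized"))) {
    cohort <- standardize_features(impute_missing(cohort))
  }
  rows <- match(centralities$participant_id, cohort$participant_id)
  if (anyNA(rows)) stop("centralities cover participants absent from the cohort", call. = FALSE)
  deg <- centralities$degree
  info <- feature_info(cohort)
  res <- purrr::map_dfr(info$feature, function(f) {
    st <- spearman_test(cohort[[f]][rows], deg)
    tibble::tibble(feature = f, rho = st[["rho"]], p_value = st[["p"]])
  })
  res$category <- info$category[match(res$feature, info$feature)]
  res$p_adjusted <- p.adjust(res$p_value, method = "BH")
  res <- res[order(-abs(res$rho)), c("feature", "category", "rho", "p_value", "p_adjusted")]
  class(res) <- c("psn_importance", class(res))
  res
}

#' Compare feature importance between categories
#'
#' Mean absolute Spearman rho within the morphometric and cognitive feature
#' categories, with a two-sided Wilcoxon rank-sum comparison of the
#' absolute-rho values.
#'
#' @param importance Output of [feature_importance()].
#' @return Tibble `category`, `n_features`, `mean_abs_rho`, `p_value`
#'   (repeated across rows).
#' @export
category_comparison <- function(importance) {
  cats <- sort(unique(importance$category))
  if (length(cats) != 2) stop("two feature categories required", call. = FALSE)
  ab <- abs(importance$rho)
  p <- suppressWarnings(wilcox.test(ab[importance$category == cats[1]],
                                    ab[importance$category == cats[2]]))$p.value
  tibble::tibble(
    category = cats,
    n_features = unname(vapply(cats, function(cc) sum(importance$category == cc), integer(1))),
    mean_abs_rho = unname(vapply(cats, function(cc) mean(ab[importance$category == cc]), numeric(1))),
    p_value = p
  )
}

#' Plot feature importance
#'
#' Bar chart of the top features ranked by absolute correlation with degree
#' centrality, coloured by category.
#'
#' @param object A `psn_importance` tibble.
#' @param n_top Number of features shown.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.psn_importance <- function(object, n_top = 15, ...) {
  d <- head(object[order(-abs(object$rho)), ], n_top)
  d$feature <- factor(d$feature, levels = rev(d$feature))
  ggplot2::ggplot(d, ggplot2::aes(x = abs(.data$rho), y = .data$feature,
                                  fill = .data$category)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "|Spearman rho| with degree centrality", y = NULL,
                  fill = NULL) +
    ggplot2::theme_minimal()
}
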