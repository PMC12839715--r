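# Uncertainty quantification for community-diagnosis agreement: bootstrap
# confidence intervals over full pipeline reruns, permutation tests with the
# network held fixed, and a modularity null model.

new_resampling <- function(type, observed, replicates, extra = list()) {
  structure(c(list(type = type, observed = observed, replicates = replicates),
              extra),
            class = "psn_resampling")
}

#' @export
print.psn_resampling <- function(x, ...) {
  cat(sprintf("# PSN resampling (%s): %d replicates, seed %s\n",
              x$type, nrow(x$replicates), x$seed))
  print(glance(x))
  invisible(x)
}

#' @export
tidy.psn_resampling <- function(x, ...) x$replicates

#' @export
glance.psn_resampling <- function(x, ...) {
  switch(x$type,
    bootstrap = dplyr::bind_cols(x$observed, x$ci_wide, tibble::tibble(
      n_replicates = nrow(x$replicates), n_skipped = x$n_skipped, seed = x$seed)),
    permutation = dplyr::bind_cols(x$observed, x$p_wide, tibble::tibble(
      n_replicates = nrow(x$replicates), seed = x$seed)),
    modularity_null = tibble::tibble(
      q_observed = x$observed$q, z_score = x$z_score, p_value = x$p_value,
      n_replicates = nrow(x$replicates), seed = x$seed)
  )
}

add_one_p <- function(replicates, observed) {
  (1 + sum(replicates >= observed)) / (length(replicates) + 1)
}

#' Bootstrap confidence intervals for community-diagnosis agreement
#'
#' Each replicate resamples participants with replacement and reruns the
#' full pipeline on the resampled table: z-scoring, pairwise distances, a
#' freshly recomputed kernel bandwidth, sparsification and Louvain community
#' detection; ARI and NMI are then computed against the resampled diagnosis
#' labels. Duplicated participants are retained as distinct nodes (distance
#' 0, similarity 1). Percentile 95% CIs use the 2.5th and 97.5th percentiles
#' of the replicate distributions.
#'
#' @param cohort A `psn_cohort` (raw scale; imputation and standardization
#'   are rerun inside every replicate).
#' @param metric,k,threshold Pipeline parameters (see [build_psn()]).
#' @param B Number of bootstrap resamples.
#' @param seed RNG seed for resampling.
#' @param louvain_seed Seed passed to [louvain_communities()] in every run.
#' @param max_skip_frac Error if more than this fraction of replicates is
#'   degenerate (empty graph or failed standardization).
#' @return A `psn_resampling` of type `"bootstrap"`.
#' @export
bootstrap_agreement_ci <- function(cohort, metric = "euclidean", k = 8,
                                   threshold = 0.3, B = 1000, seed = 42,
                                   louvain_seed = 42, max_skip_frac = 0.1) {
  if (B < 2) stop("B must be >= 2", call. = FALSE)
  cohort <- impute_missing(cohort)
  run_once <- function(tbl) {
    attr(tbl, "standardized") <- NULL        # replicate refits the scaling
    attr(tbl, "scaling") <- NULL
    g <- suppressWarnings(build_psn(tbl, metric = metric, k = k, threshold = threshold))
    if (nrow(g$edges) == 0) return(NULL)
    p <- louvain_communities(g, seed = louvain_seed)
    partition_agreement(p, setNames(tbl$diagnosis, tbl$participant_id))
  }
  observed <- run_once(cohort)
  if (is.null(observed)) stop("observed graph has no edges", call. = FALSE)
  n <- nrow(cohort)
  reps <- withr::with_seed(seed, {
    purrr::map(seq_len(B), function(b) {
      idx <- sample.int(n, replace = TRUE)
      tbl <- cohort[idx, ]
      tbl$participant_id <- make.unique(tbl$participant_id)
      tbl <- rebuild_cohort(tbl, cohort)
      tryCatch(run_once(tbl), error = function(e) NULL)
    })
  })
  ok <- !vapply(reps, is.null, logical(1))
  n_skipped <- sum(!ok)
  if (n_skipped > max_skip_frac * B) {
    stop(sprintf("%d/%d bootstrap replicates degenerate", n_skipped, B), call. = FALSE)
  }
  replicates <- dplyr::bind_rows(reps[ok])
  replicates$replicate <- which(ok)
  ci <- tibble::tibble(
    statistic = c("ari", "nmi"),
    ci_low = c(quantile(replicates$ari, 0.025, names = FALSE),
               quantile(replicates$nmi, 0.025, names = FALSE)),
    ci_high = c(quantile(replicates$ari, 0.975, names = FALSE),
                quantile(replicates$nmi, 0.975, names = FALSE))
  )
  ci_wide <- tibble::tibble(ari_low = ci$ci_low[1], ari_high = ci$ci_high[1],
                            nmi_low = ci$ci_low[2], nmi_high = ci$ci_high[2])
  new_resampling("bootstrap", observed, replicates,
                 list(ci = ci, ci_wide = ci_wide, n_skipped = n_skipped,
                      B = B, seed = seed))
}

#' Permutation test for community-diagnosis agreement
#'
#' Diagnosis labels are permuted uniformly while the detected partition (and
#' hence the network) is held fixed; ARI and NMI are recomputed per
#' replicate. The decision p-value uses the add-one convention
#' `p = (1 + #{replicate >= observed}) / (B + 1)`, which can never reach 0;
#' the plain exceedance proportion `#{>= obs} / B` is reported alongside.
#'
#' @param partition A `psn_partition` or label vector.
#' @param labels Diagnosis labels over the same participants.
#' @param B Number of permutations.
#' @param seed RNG seed.
#' @return A `psn_resampling` of type `"permutation"`.
#' @export
permutation_test_agreement <- function(partition, labels, B = 1000, seed = 42) {
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  if (inherits(partition, "psn_partition")) {
    if (!is.null(names(labels))) labels <- labels[names(partition$membership)]
    partition <- partition$membership
  }
  observed <- suppressWarnings(partition_agreement(partition, labels))
  replicates <- withr::with_seed(seed, {
    purrr::map_dfr(seq_len(B), function(b) {
      perm <- sample(labels)
      suppressWarnings(partition_agreement(partition, perm))
    })
  })
  replicates$replicate <- seq_len(B)
  p_wide <- tibble::tibble(
    ari_p = add_one_p(replicates$ari, observed$ari),
    nmi_p = add_one_p(replicates$nmi, observed$nmi),
    ari_p_plain = mean(replicates$ari >= observed$ari),
    nmi_p_plain = mean(replicates$nmi >= observed$nmi)
  )
  new_resampling("permutation", observed, replicates,
                 list(p_wide = p_wide, B = B, seed = seed))
}

#' Modularity null model test
#'
#' Community assignments are permuted over nodes (community sizes
#' preserved) and modularity recomputed, giving a null distribution for Q.
#' Reports the z-score `(Q_obs - mean) / sd` and the add-one empirical
#' p-value.
#'
#' @param graph A `psn_graph`.
#' @param partition A `psn_partition` or membership vector.
#' @param B Number of permutations.
#' @param seed RNG seed.
#' @param weighted Evaluate weighted (default) or binary modularity.
#' @return A `psn_resampling` of type `"modularity_null"`.
#' @export
modularity_null_test <- function(graph, partition, B = 100, seed = 42,
                                 weighted = TRUE) {
  if (B < 2) stop("B must be >= 2", call. = FALSE)
  membership <- align_membership(partition, graph$nodes)
  q_obs <- modularity_q(graph, membership, weighted = weighted)
  qs <- withr::with_seed(seed, {
    vapply(seq_len(B), function(b) {
      modularity_q(graph, sample(membership), weighted = weighted)
    }, numeric(1))
  })
  if (sd(qs) == 0) {
    rlang::abort("null modularity replicates have zero spread: z undefined",
                 class = "psn_degenerate_null", replicates = qs)
  }
  new_resampling(
    "modularity_null",
    tibble::tibble(q = q_obs),
    tibble::tibble(replicate = seq_len(B), q = qs),
    list(z_score = (q_obs - mean(qs)) / sd(qs),
         p_value = add_one_p(qs, q_obs),
         B = B, seed = seed)
  )
}
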