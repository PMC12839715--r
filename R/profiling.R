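# Community-level clinical/demographic profiles, omnibus and post hoc
# tests, and per-community distinguishing features by mean z-score.

community_groups <- function(cohort, partition) {
  m <- align_membership(partition, cohort$participant_id)
  factor(m, levels = sort(unique(m)))
}

#' Clinical and demographic profiles of communities
#'
#' Per community: size, IBS/HC counts, percent IBS, and mean +/- SD of age,
#' IBS-SSS (IBS members only, as controls carry no severity score) and the
#' RBANS Total Scale score, all on original measurement scales. The SD of a
#' size-1 community is reported as `NA`, not 0.
#'
#' @param cohort A `psn_cohort` on the original measurement scale.
#' @param partition A `psn_partition` or membership vector.
#' @return Tibble with one row per community.
#' @export
community_profiles <- function(cohort, partition) {
  g <- community_groups(cohort, partition)
  rb <- if ("rbans_total" %in% names(cohort)) cohort$rbans_total else rep(NA_real_, nrow(cohort))
  purrr::map_dfr(levels(g), function(cc) {
    ix <- which(g == cc)
    ibs <- ix[cohort$diagnosis[ix] == "IBS"]
    sss <- cohort$ibs_sss[ibs]
    sss <- sss[!is.na(sss)]
    tibble::tibble(
      community = as.integer(cc),
      n = length(ix),
      n_ibs = length(ibs),
      n_hc = length(ix) - length(ibs),
      pct_ibs = 100 * length(ibs) / length(ix),
      age_mean = mean(cohort$age[ix]), age_sd = sd(cohort$age[ix]),
      sss_mean = if (length(sss)) mean(sss) else NA_real_,
      sss_sd = if (length(sss)) sd(sss) else NA_real_,
      rbans_mean = mean(rb[ix]), rbans_sd = sd(rb[ix])
    )
  })
}

#' Community mean z-scores per feature
#'
#' @inheritParams community_profiles
#' @return Tibble `community`, `feature`, `category`, `mean_z`.
#' @export
community_feature_z <- function(cohort, partition) {
  if (!isTRUE(attr(cohort, "standardized"))) {
    cohort <- standardize_features(impute_missing(cohort))
  }
  g <- community_groups(cohort, partition)
  info <- feature_info(cohort)
  Z <- feature_matrix(cohort)
  purrr::map_dfr(levels(g), function(cc) {
    tibble::tibble(
      community = as.integer(cc),
      feature = info$feature,
      category = info$category,
      mean_z = colMeans(Z[g == cc, , drop = FALSE])
    )
  })
}

kw_eta_squared <- function(H, k, n) {
  eta <- (H - k + 1) / (n - k)
  if (eta < 0) {
    warning("negative Kruskal-Wallis eta-squared clamped to 0")
    eta <- 0
  }
  eta
}

#' Omnibus tests of clinical variables across communities
#'
#' Kruskal-Wallis tests (average-rank ties) for age, IBS-SSS (IBS members
#' only) and RBANS Total across communities, with effect size
#' `eta^2 = (H - k + 1) / (n - k)`, plus a Pearson chi-square test (no
#' continuity correction) of the community x diagnosis table. A variable
#' that is constant overall yields an `NA` row with a warning.
#'
#' @inheritParams community_profiles
#' @return Tibble `variable`, `test`, `statistic`, `df`, `p_value`, `eta_sq`.
#' @export
omnibus_tests <- function(cohort, partition) {
  g <- community_groups(cohort, partition)
  if (nlevels(g) < 2) stop("need at least 2 communities", call. = FALSE)
  vars <- list(
    age = list(x = cohort$age, g = g),
    ibs_sss = list(x = cohort$ibs_sss[cohort$diagnosis == "IBS"],
                   g = g[cohort$diagnosis == "IBS"]),
    rbans_total = if ("rbans_total" %in% names(cohort)) {
      list(x = cohort$rbans_total, g = g)
    }
  )
  vars <- vars[!vapply(vars, is.null, logical(1))]
  kw <- purrr::imap_dfr(vars, function(v, nm) {
    ok <- !is.na(v$x)
    x <- v$x[ok]; gg <- droplevels(v$g[ok])
    if (length(x) == 0 || sd(x) == 0 || nlevels(gg) < 2) {
      warning("variable ", nm, " constant or degenerate; omnibus test skipped")
      return(tibble::tibble(variable = nm, test = "kruskal_wallis",
                            statistic = NA_real_, df = NA_integer_,
                            p_value = NA_real_, eta_sq = NA_real_))
    }
    kt <- kruskal.test(x, gg)
    tibble::tibble(
      variable = nm, test = "kruskal_wallis",
      statistic = unname(kt$statistic), df = as.integer(kt$parameter),
      p_value = kt$p.value,
      eta_sq = kw_eta_squared(unname(kt$statistic), nlevels(gg), length(x))
    )
  })
  tab <- contingency_table(as.integer(g), cohort$diagnosis)
  cs <- suppressWarnings(chisq.test(tab, correct = FALSE))
  dplyr::bind_rows(kw, tibble::tibble(
    variable = "diagnosis", test = "chi_square",
    statistic = unname(cs$statistic), df = as.integer(cs$parameter),
    p_value = cs$p.value, eta_sq = NA_real_
  ))
}

#' Post hoc pairwise community comparisons
#'
#' Two-sided Mann-Whitney U tests for all `C(k, 2)` community pairs on one
#' clinical variable, with Bonferroni correction
#' `p_adj = min(1, raw * C(k, 2))`.
#'
#' @inheritParams community_profiles
#' @param variable One of `"age"`, `"ibs_sss"` (IBS members only),
#'   `"rbans_total"`.
#' @return Tibble `community_a`, `community_b`, `n_a`, `n_b`, `statistic_u`,
#'   `p_value`, `p_bonferroni`.
#' @export
posthoc_pairwise <- function(cohort, partition, variable = "age") {
  g <- community_groups(cohort, partition)
  if (nlevels(g) < 2) stop("need at least 2 communities", call. = FALSE)
  x <- cohort[[variable]]
  if (is.null(x)) stop("unknown variable: ", variable, call. = FALSE)
  if (variable == "ibs_sss") x[cohort$diagnosis != "IBS"] <- NA
  k <- nlevels(g)
  mult <- choose(k, 2)
  pairs <- combn(levels(g), 2)
  purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
    a <- x[g == pairs[1, j]]; a <- a[!is.na(a)]
    b <- x[g == pairs[2, j]]; b <- b[!is.na(b)]
    wt <- suppressWarnings(wilcox.test(a, b))
    tibble::tibble(
      community_a = as.integer(pairs[1, j]),
      community_b = as.integer(pairs[2, j]),
      n_a = length(a), n_b = length(b),
      statistic_u = unname(wt$statistic),
      p_value = wt$p.value,
      p_bonferroni = min(1, wt$p.value * mult)
    )
  })
}

#' Distinguishing features of each community
#'
#' Ranks all features by within-community mean z-score and reports the
#' `n_top` most elevated and `n_top` most reduced per community.
#'
#' @inheritParams community_profiles
#' @param n_top Number of features per direction.
#' @return Tibble `community`, `feature`, `category`, `mean_z`, `direction`
#'   (`"elevated"`/`"reduced"`), `rank` (1 = most extreme in its direction).
#' @export
distinguishing_features <- function(cohort, partition, n_top = 3) {
  mz <- community_feature_z(cohort, partition)
  n_feat <- length(unique(mz$feature))
  if (n_feat < 2 * n_top) {
    stop("need at least 2 * n_top features", call. = FALSE)
  }
  purrr::map_dfr(unique(mz$community), function(cc) {
    d <- mz[mz$community == cc, ]
    d <- d[order(-d$mean_z), ]
    up <- head(d, n_top)
    dn <- tail(d, n_top)
    dn <- dn[rev(seq_len(nrow(dn))), ]        # most reduced first
    dplyr::bind_rows(
      dplyr::mutate(up, direction = "elevated", rank = dplyr::row_number()),
      dplyr::mutate(dn, direction = "reduced", rank = dplyr::row_number())
    )
  })
}
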