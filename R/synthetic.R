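# Synthetic cohort generator: planted-subgroup feature tables emulating an
# IBS/HC brain-morphometry + cognition study, so the whole pipeline can be
# exercised and calibrated without the original data.

morphometric_feature_names <- function(n = 36) {
  base <- c(
    paste0(rep(c("Left_", "Right_"), each = 7),
           rep(c("Thalamus", "Caudate", "Putamen", "Pallidum",
                 "Hippocampus", "Amygdala", "Accumbens"), 2)),
    "Left_Cerebellum_White_Matter", "Right_Cerebellum_White_Matter",
    "Left_Cerebellum_Cortex", "Right_Cerebellum_Cortex",
    "CC_Posterior", "CC_Mid_Posterior", "CC_Central", "CC_Mid_Anterior",
    "CC_Anterior",
    "Left_Cerebral_White_Matter", "Right_Cerebral_White_Matter",
    "CerebralWhiteMatterVol", "Left_Cortex", "Right_Cortex", "CortexVol",
    "TotalGrayVol", "SubCortGrayVol", "eTIV", "CSF", "BrainSegVol",
    "BrainSegVolNotVent", "SupraTentorialVol"
  )
  if (n <= length(base)) head(base, n) else c(base, paste0("Morph_", seq_len(n - length(base))))
}

cognitive_feature_names <- function(n = 6) {
  base <- c("RBANS_Immediate_Memory", "RBANS_Visuospatial", "RBANS_Language",
            "RBANS_Attention", "RBANS_Delayed_Memory", "RBANS_Total_Scale")
  if (n <= length(base)) head(base, n) else c(base, paste0("RBANS_Extra_", seq_len(n - length(base))))
}

#' Specify a synthetic cohort
#'
#' Defines the generative model for [generate_cohort()]: planted subgroups of
#' given sizes, each with its own random +/-delta feature-mean shift pattern,
#' equicorrelated within-subgroup feature noise, a per-subgroup probability of
#' carrying the IBS label, and per-subgroup normal distributions for age,
#' IBS-SSS (truncated to \[0, 500\]) and the RBANS Total Scale score.
#'
#' @param n_per_group Integer vector of planted-subgroup sizes.
#' @param ibs_probability Per-subgroup probability that a member is labelled
#'   IBS (recycled if scalar).
#' @param effect_size delta, the magnitude of subgroup feature-mean shifts in
#'   within-subgroup SD units.
#' @param within_correlation Equicorrelation rho among features within a
#'   subgroup, in \[0, 1).
#' @param n_morphometric,n_cognitive Feature counts per category.
#' @param age_params,sss_params,rbans_params Per-subgroup `(mean, sd)` pairs,
#'   as a list of length-2 numeric vectors (recycled if a single pair).
#' @param missing_cells Number of feature cells to blank, each in a distinct
#'   participant row and a morphometric column.
#' @param seed Default RNG seed used by [generate_cohort()].
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_per_group,
                        ibs_probability = 0.5,
                        effect_size = 3,
                        within_correlation = 0.2,
                        n_morphometric = 36,
                        n_cognitive = 6,
                        age_params = list(c(35, 10)),
                        sss_params = list(c(200, 100)),
                        rbans_params = list(c(100, 15)),
                        missing_cells = 0,
                        seed = 42) {
  G <- length(n_per_group)
  stopifnot(G >= 1, all(n_per_group >= 1))
  if (length(ibs_probability) == 1) ibs_probability <- rep(ibs_probability, G)
  stopifnot(length(ibs_probability) == G,
            all(ibs_probability >= 0), all(ibs_probability <= 1))
  if (effect_size < 0) stop("effect_size must be >= 0", call. = FALSE)
  if (within_correlation < 0 || within_correlation >= 1) {
    stop("within_correlation must lie in [0, 1)", call. = FALSE)
  }
  recycle <- function(p) if (length(p) == 1) rep(p, G) else p
  age_params <- recycle(age_params)
  sss_params <- recycle(sss_params)
  rbans_params <- recycle(rbans_params)
  stopifnot(length(age_params) == G, length(sss_params) == G,
            length(rbans_params) == G)
  structure(list(
    n_per_group = as.integer(n_per_group),
    ibs_probability = ibs_probability,
    effect_size = effect_size,
    within_correlation = within_correlation,
    n_morphometric = as.integer(n_morphometric),
    n_cognitive = as.integer(n_cognitive),
    age_params = age_params,
    sss_params = sss_params,
    rbans_params = rbans_params,
    missing_cells = as.integer(missing_cells),
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("# cohort_spec: %d subgroups (sizes %s), delta=%g, rho_w=%g, %d+%d features, %d missing cells, seed %d\n",
              length(x$n_per_group), paste(x$n_per_group, collapse = "/"),
              x$effect_size, x$within_correlation, x$n_morphometric,
              x$n_cognitive, x$missing_cells, x$seed))
  invisible(x)
}

#' Study-shaped cohort specification
#'
#' Preset emulating a 78-participant IBS/HC cohort with four latent
#' subgroups of sizes 23/12/23/20, subgroup IBS probabilities 15/23, 9/12,
#' 10/23 and 15/20, subgroup age, IBS-SSS and RBANS Total distributions
#' matching the community profiles of the motivating study, and two missing
#' morphometric cells.
#'
#' @inheritParams cohort_spec
#' @return A `cohort_spec`.
#' @export
ibs_cohort_spec <- function(effect_size = 3, within_correlation = 0.2, seed = 42) {
  cohort_spec(
    n_per_group = c(23L, 12L, 23L, 20L),
    ibs_probability = c(15 / 23, 9 / 12, 10 / 23, 15 / 20),
    effect_size = effect_size,
    within_correlation = within_correlation,
    age_params = list(c(43.7, 10.1), c(27.7, 8.3), c(32.5, 11.9), c(33.8, 8.3)),
    sss_params = list(c(179.3, 128.4), c(240.6, 140.6), c(134.1, 135.1), c(208.8, 123.8)),
    rbans_params = list(c(101.8, 13.4), c(92.0, 15.8), c(99.5, 9.8), c(84.3, 10.9)),
    missing_cells = 2L,
    seed = seed
  )
}

rnorm_trunc <- function(n, mean, sd, lower, upper) {
  x <- rnorm(n, mean, sd)
  bad <- which(x < lower | x > upper)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] < lower | x[bad] > upper]
  }
  x
}

#' Generate a synthetic cohort with planted subgroups
#'
#' Features of subgroup g are drawn from a multivariate normal with mean
#' `delta * s_g` (`s_g` a subgroup-specific random sign vector) and
#' equicorrelated unit-variance covariance. Diagnosis labels are Bernoulli
#' with the subgroup's IBS probability; age and RBANS Total are normal;
#' IBS-SSS is normal truncated to \[0, 500\] by resampling and stored only
#' for participants labelled IBS. The planted assignment is returned in the
#' `subgroup` column.
#'
#' @param spec A [cohort_spec()].
#' @param seed RNG seed; defaults to `spec$seed`. The output is deterministic
#'   given `(spec, seed)`.
#' @return A `psn_cohort` with a `subgroup` metadata column.
#' @export
generate_cohort <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  withr::with_seed(seed, {
    G <- length(spec$n_per_group)
    n <- sum(spec$n_per_group)
    p <- spec$n_morphometric + spec$n_cognitive
    feats <- c(morphometric_feature_names(spec$n_morphometric),
               cognitive_feature_names(spec$n_cognitive))
    subgroup <- rep(seq_len(G), spec$n_per_group)
    rho <- spec$within_correlation

    X <- matrix(0, n, p, dimnames = list(NULL, feats))
    diagnosis <- character(n)
    age <- numeric(n)
    sss <- numeric(n)
    rbans <- numeric(n)
    for (g in seq_len(G)) {
      rows <- which(subgroup == g)
      ng <- length(rows)
      signs <- sample(c(-1, 1), p, replace = TRUE)
      shared <- rnorm(ng)
      noise <- matrix(rnorm(ng * p), ng, p)
      X[rows, ] <- rep(spec$effect_size * signs, each = ng) +
        sqrt(rho) * shared + sqrt(1 - rho) * noise
      diagnosis[rows] <- ifelse(runif(ng) < spec$ibs_probability[g], "IBS", "HC")
      age[rows] <- rnorm(ng, spec$age_params[[g]][1], spec$age_params[[g]][2])
      sss[rows] <- rnorm_trunc(ng, spec$sss_params[[g]][1], spec$sss_params[[g]][2], 0, 500)
      rbans[rows] <- rnorm(ng, spec$rbans_params[[g]][1], spec$rbans_params[[g]][2])
    }
    sss[diagnosis == "HC"] <- NA_real_

    data <- tibble::tibble(
      participant_id = sprintf("P%03d", seq_len(n)),
      diagnosis = diagnosis,
      age = age,
      ibs_sss = sss,
      rbans_total = rbans,
      subgroup = subgroup
    )
    data <- dplyr::bind_cols(data, tibble::as_tibble(X))
    cohort <- as_cohort(data, features = feats)
    if (spec$missing_cells > 0) {
      cohort <- inject_missingness(cohort, spec$missing_cells)
    }
    cohort
  })
}

#' Blank feature cells to emulate sparse missingness
#'
#' Blanks `n_cells` feature entries, each in a distinct participant row and a
#' morphometric column, mirroring cohorts where a handful of participants
#' lack a single volumetric measure.
#'
#' @param cohort A `psn_cohort`.
#' @param n_cells Number of cells to blank (at most one per participant).
#' @param seed Optional RNG seed; if `NULL` the current RNG stream is used.
#' @return The cohort with `n_cells` missing morphometric entries.
#' @export
inject_missingness <- function(cohort, n_cells, seed = NULL) {
  run <- function() {
    if (n_cells == 0) return(cohort)
    if (n_cells > nrow(cohort)) {
      stop("n_cells exceeds the number of participants", call. = FALSE)
    }
    info <- feature_info(cohort)
    morph <- info$feature[info$category == "morphometric"]
    if (!length(morph)) stop("no morphometric columns to blank", call. = FALSE)
    rows <- sample(nrow(cohort), n_cells)
    cols <- sample(morph, n_cells, replace = TRUE)
    for (i in seq_len(n_cells)) cohort[[cols[i]]][rows[i]] <- NA_real_
    cohort
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Planted partition of a synthetic cohort
#'
#' @param cohort A cohort generated by [generate_cohort()].
#' @return Integer vector of planted subgroup labels, named by participant.
#' @export
planted_partition <- function(cohort) {
  if (!"subgroup" %in% names(cohort)) {
    stop("cohort has no planted subgroup column", call. = FALSE)
  }
  setNames(as.integer(cohort$subgroup), cohort$participant_id)
}

#' Serialize a cohort specification to YAML
#'
#' @param spec A `cohort_spec`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_cohort_spec <- function(spec, path) {
  yaml::write_yaml(unclass(spec), path, precision = 15)
  invisible(path)
}

#' @rdname write_cohort_spec
#' @export
read_cohort_spec <- function(path) {
  do.call(cohort_spec, yaml::read_yaml(path))
}
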