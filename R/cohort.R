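# Cohort feature table: a classed tibble with one row per participant,
# reserved metadata columns, and a feature_info attribute mapping each
# feature column to a category (morphometric / cognitive).

.reserved_cols <- c("participant_id", "diagnosis", "age", "ibs_sss",
                    "rbans_total", "subgroup")

#' Create a cohort table
#'
#' A cohort table is a tibble with one row per participant, metadata columns
#' (`participant_id`, `diagnosis`, `age`, and optionally `ibs_sss`,
#' `rbans_total`, `subgroup`) and numeric feature columns. Feature categories
#' (`morphometric` or `cognitive`) are carried as an attribute and drive the
#' feature-importance category comparison.
#'
#' @param data A data frame with the columns described above.
#' @param features Character vector of feature column names. Defaults to all
#'   numeric columns that are not reserved metadata columns.
#' @param categories Named character vector mapping feature names to
#'   `"morphometric"` or `"cognitive"`. By default, columns whose names
#'   contain `"rbans"` (case-insensitive) are tagged cognitive, all others
#'   morphometric.
#' @return A `psn_cohort` tibble.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_per_group = c(10, 10), seed = 1))
#' cohort
as_cohort <- function(data, features = NULL, categories = NULL) {
  data <- tibble::as_tibble(data)
  if (!all(c("participant_id", "diagnosis") %in% names(data))) {
    stop("cohort requires `participant_id` and `diagnosis` columns", call. = FALSE)
  }
  data$participant_id <- as.character(data$participant_id)
  if (anyDuplicated(data$participant_id)) {
    dup <- unique(data$participant_id[duplicated(data$participant_id)])
    stop("duplicate participant IDs: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  bad <- setdiff(unique(data$diagnosis), c("IBS", "HC"))
  if (length(bad)) {
    stop("unknown diagnosis label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(features)) {
    candidates <- setdiff(names(data), .reserved_cols)
    features <- candidates[vapply(data[candidates], is.numeric, logical(1))]
  }
  if (!length(features)) stop("no feature columns found", call. = FALSE)
  missing_cols <- setdiff(features, names(data))
  if (length(missing_cols)) {
    stop("feature column(s) not in data: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(categories)) {
    categories <- ifelse(grepl("rbans", features, ignore.case = TRUE),
                         "cognitive", "morphometric")
    names(categories) <- features
  }
  categories <- categories[features]
  if (anyNA(categories) || !all(categories %in% c("morphometric", "cognitive"))) {
    stop("categories must cover all features with values morphometric/cognitive",
         call. = FALSE)
  }
  if ("ibs_sss" %in% names(data)) {
    sss <- data$ibs_sss[!is.na(data$ibs_sss)]
    if (length(sss) && (min(sss) < 0 || max(sss) > 500)) {
      stop("ibs_sss values must lie in [0, 500]", call. = FALSE)
    }
  }
  attr(data, "feature_info") <- tibble::tibble(
    feature = features, category = unname(categories)
  )
  class(data) <- c("psn_cohort", class(tibble::tibble()))
  data
}

#' @export
print.psn_cohort <- function(x, ...) {
  info <- feature_info(x)
  cat(sprintf("# PSN cohort: %d participants (%d IBS / %d HC), %d features (%d morphometric, %d cognitive)\n",
              nrow(x), sum(x$diagnosis == "IBS"), sum(x$diagnosis == "HC"),
              nrow(info), sum(info$category == "morphometric"),
              sum(info$category == "cognitive")))
  if (isTRUE(attr(x, "standardized"))) cat("# features standardized (z-scores)\n")
  NextMethod()
}

#' Feature metadata of a cohort
#'
#' @param cohort A `psn_cohort`.
#' @return `feature_info()`: a tibble with columns `feature` and `category`.
#' @export
feature_info <- function(cohort) {
  info <- attr(cohort, "feature_info")
  if (is.null(info)) stop("not a cohort table (no feature_info attribute)", call. = FALSE)
  info
}

#' @rdname feature_info
#' @return `feature_names()`: character vector of feature column names.
#' @export
feature_names <- function(cohort) feature_info(cohort)$feature

#' @rdname feature_info
#' @return `feature_matrix()`: numeric matrix (participants x features) with
#'   participant IDs as row names.
#' @export
feature_matrix <- function(cohort) {
  m <- as.matrix(cohort[, feature_names(cohort)])
  rownames(m) <- cohort$participant_id
  m
}

#' @rdname feature_info
#' @return `feature_scaling()`: the per-feature location/scale tibble recorded
#'   by [standardize_features()], or `NULL`.
#' @export
feature_scaling <- function(cohort) attr(cohort, "scaling")

# rebuild a cohort after row/column surgery, keeping metadata in sync
rebuild_cohort <- function(data, template, features = feature_names(template)) {
  info <- feature_info(template)
  info <- info[info$feature %in% features, ]
  out <- as_cohort(data, features = info$feature,
                   categories = setNames(info$category, info$feature))
  attr(out, "standardized") <- attr(template, "standardized")
  attr(out, "scaling") <- attr(template, "scaling")
  out
}

#' Drop the composite total-scale cognitive feature
#'
#' The RBANS Total Scale index is a composite of the five domain indices;
#' dropping it runs the 41-feature sensitivity variant of the analysis.
#'
#' @param cohort A `psn_cohort`.
#' @param feature Name of the composite column.
#' @return The cohort without that feature column.
#' @export
drop_total_scale <- function(cohort, feature = "RBANS_Total_Scale") {
  if (!feature %in% feature_names(cohort)) {
    stop("feature not present: ", feature, call. = FALSE)
  }
  keep <- setdiff(feature_names(cohort), feature)
  rebuild_cohort(cohort[, setdiff(names(cohort), feature)], cohort, features = keep)
}

#' Read / write a cohort CSV
#'
#' CSVs are UTF-8 with a header row; empty cells and `"NA"` are read as
#' missing. Column names are configurable through `schema`.
#'
#' @param path CSV file path.
#' @param schema Named list overriding the default metadata column names:
#'   `id`, `diagnosis`, `age`, `ibs_sss`, `rbans_total`; optionally
#'   `features` (character vector) and `n_features` (enforced feature count).
#' @param categories Passed to [as_cohort()].
#' @return A `psn_cohort`.
#' @export
read_cohort <- function(path, schema = list(), categories = NULL) {
  defaults <- list(id = "participant_id", diagnosis = "diagnosis", age = "age",
                   ibs_sss = "ibs_sss", rbans_total = "rbans_total",
                   features = NULL, n_features = NULL)
  schema <- utils::modifyList(defaults, schema)
  raw <- readr::read_csv(path, na = c("", "NA"), show_col_types = FALSE,
                         progress = FALSE)
  rename_map <- c(participant_id = schema$id, diagnosis = schema$diagnosis,
                  age = schema$age, ibs_sss = schema$ibs_sss,
                  rbans_total = schema$rbans_total)
  rename_map <- rename_map[rename_map %in% names(raw)]
  raw <- dplyr::rename(raw, !!!rename_map)
  features <- schema$features
  if (is.null(features)) {
    candidates <- setdiff(names(raw), .reserved_cols)
    features <- candidates[vapply(raw[candidates], is.numeric, logical(1))]
  }
  if (!is.null(schema$n_features) && length(features) != schema$n_features) {
    stop(sprintf("expected %d feature columns, found %d",
                 schema$n_features, length(features)), call. = FALSE)
  }
  as_cohort(raw, features = features, categories = categories)
}

#' @rdname read_cohort
#' @param cohort A `psn_cohort` to write.
#' @return `write_cohort()` returns `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort, path, na = "")
  invisible(path)
}

#' Mean-impute missing feature values
#'
#' Each missing feature cell is replaced by the mean of the observed values
#' in its column; observed entries are unchanged. Metadata columns (age,
#' IBS-SSS) are never imputed.
#'
#' @param cohort A `psn_cohort`.
#' @return The cohort with complete feature columns.
#' @export
impute_missing <- function(cohort) {
  feats <- feature_names(cohort)
  for (f in feats) {
    x <- cohort[[f]]
    if (all(is.na(x))) stop("feature fully missing: ", f, call. = FALSE)
    if (anyNA(x)) cohort[[f]][is.na(x)] <- mean(x, na.rm = TRUE)
  }
  cohort
}

#' Count missing feature cells
#'
#' @param cohort A `psn_cohort`.
#' @return Integer count of missing entries in the feature matrix.
#' @export
n_missing <- function(cohort) sum(is.na(feature_matrix(cohort)))

#' Z-score the feature columns
#'
#' Each feature is centred on its mean and scaled by its population standard
#' deviation (divide by n). The fitted location/scale pairs are attached as a
#' `"scaling"` attribute (see [feature_scaling()]) so the same transform can
#' be re-applied to new rows.
#'
#' @param cohort A `psn_cohort` with no missing feature values.
#' @param scaling Optional scaling tibble (columns `feature`, `mean`, `sd`)
#'   from a previous fit; if supplied it is applied instead of re-fitting.
#' @return The cohort with standardized feature columns.
#' @export
standardize_features <- function(cohort, scaling = NULL) {
  feats <- feature_names(cohort)
  X <- feature_matrix(cohort)
  if (anyNA(X)) stop("missing feature values; run impute_missing() first", call. = FALSE)
  if (is.null(scaling)) {
    mu <- colMeans(X)
    sigma <- sqrt(colMeans(sweep(X, 2, mu)^2))
    if (any(sigma <= 0)) {
      stop("constant feature: ", paste(feats[sigma <= 0], collapse = ", "),
           call. = FALSE)
    }
    scaling <- tibble::tibble(feature = feats, mean = unname(mu), sd = unname(sigma))
  } else {
    if (!all(feats %in% scaling$feature)) {
      stop("scaling does not cover all features", call. = FALSE)
    }
    scaling <- scaling[match(feats, scaling$feature), ]
  }
  Z <- sweep(sweep(X, 2, scaling$mean), 2, scaling$sd, "/")
  for (j in seq_along(feats)) cohort[[feats[j]]] <- unname(Z[, j])
  attr(cohort, "standardized") <- TRUE
  attr(cohort, "scaling") <- scaling
  cohort
}
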