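# Cohort container, CSV input, preprocessing and random splitting.
#
# A cohort is a patients x features table of tri-state binary values
# (0, 1, NA) plus a complete binary outcome vector. All downstream modules
# (feature selection, rule mining, model training) consume this container.

#' Construct a cohort table
#'
#' The central data container: a matrix of binary features (with `NA` for
#' missing cells), one binary outcome per patient, and patient identifiers.
#'
#' @param features Integer matrix (patients x features) with values in
#'   `{0, 1, NA}`; must have unique column names.
#' @param outcome Integer vector of 0/1 with no missing values, one entry
#'   per patient (1 = adverse event).
#' @param patient_ids Optional character vector of identifiers; defaults to
#'   row numbers.
#' @param outcome_name Name of the outcome column (kept for round-trips).
#' @return An object of class `cohort_table`.
#' @export
cohort_table <- function(features, outcome, patient_ids = NULL,
                         outcome_name = "events") {
  features <- as.matrix(features)
  storage.mode(features) <- "integer"
  outcome <- as.integer(outcome)
  if (nrow(features) < 1L) stop2("cohort must contain at least one patient")
  if (is.null(colnames(features)) || anyNA(colnames(features)) ||
      any(colnames(features) == "")) {
    stop2("all features must be named")
  }
  if (anyDuplicated(colnames(features))) {
    dups <- unique(colnames(features)[duplicated(colnames(features))])
    stop2("duplicate feature names: ", paste(dups, collapse = ", "))
  }
  if (length(outcome) != nrow(features)) {
    stop2("outcome length does not match the number of patients")
  }
  if (anyNA(outcome)) stop2("outcome must not contain missing values")
  bad <- !(features %in% c(0L, 1L) | is.na(features))
  if (any(bad)) stop2("feature values must be 0, 1, or missing")
  if (!all(outcome %in% c(0L, 1L))) stop2("outcome values must be 0 or 1")
  if (is.null(patient_ids)) patient_ids <- as.character(seq_len(nrow(features)))
  if (length(patient_ids) != nrow(features)) {
    stop2("patient_ids length does not match the number of patients")
  }
  structure(
    list(
      features = features,
      outcome = outcome,
      patient_ids = as.character(patient_ids),
      outcome_name = outcome_name
    ),
    class = "cohort_table"
  )
}

#' @export
print.cohort_table <- function(x, ...) {
  n <- nrow(x$features)
  p <- ncol(x$features)
  nmiss <- sum(is.na(x$features))
  cat(sprintf(
    "<cohort_table> %d patients x %d binary features (+ outcome '%s')\n",
    n, p, x$outcome_name
  ))
  cat(sprintf(
    "  events: %d (%.1f%%); missing cells: %d (%.2f%%)\n",
    sum(x$outcome), 100 * mean(x$outcome), nmiss,
    if (p > 0) 100 * nmiss / (n * p) else 0
  ))
  invisible(x)
}

#' @export
dim.cohort_table <- function(x) dim(x$features)

#' Feature names of a cohort
#' @param t A `cohort_table`.
#' @return Character vector of feature names.
#' @export
feature_names <- function(t) colnames(t$features)

# Subset rows of a cohort, keeping all features.
cohort_rows <- function(t, idx) {
  cohort_table(
    t$features[idx, , drop = FALSE], t$outcome[idx],
    t$patient_ids[idx], t$outcome_name
  )
}

#' Read a binary patient cohort from CSV
#'
#' Expects a header row; every column other than `outcome_column` is a
#' binary feature. Cells matching one of `missing_tokens` become missing;
#' all other cells must parse as 0 or 1. The outcome column must be
#' strictly binary and complete.
#'
#' @param path Path to a CSV file (RFC-4180, header row).
#' @param outcome_column Name of the outcome column. Default `"events"`.
#' @param missing_tokens Character vector of cell values treated as
#'   missing. Default `c("", "NA", "NaN")`.
#' @param id_column Optional name of a patient-identifier column.
#' @return A [cohort_table].
#' @export
read_cohort <- function(path, outcome_column = "events",
                        missing_tokens = c("", "NA", "NaN"),
                        id_column = NULL) {
  if (!file.exists(path)) stop2("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                         na.strings = NULL)
  if (!outcome_column %in% names(raw)) {
    stop2("outcome column '", outcome_column, "' not found")
  }
  ids <- NULL
  if (!is.null(id_column)) {
    if (!id_column %in% names(raw)) stop2("id column '", id_column, "' not found")
    ids <- raw[[id_column]]
    raw[[id_column]] <- NULL
  }
  parse_binary <- function(x, what, allow_missing) {
    x <- trimws(x)
    miss <- x %in% missing_tokens
    out <- rep(NA_integer_, length(x))
    ok <- !miss & x %in% c("0", "1")
    out[ok] <- as.integer(x[ok])
    bad <- !miss & !ok
    if (any(bad)) {
      stop2("non-binary value ", sQuote(x[which(bad)[1]]), " in column '",
            what, "'")
    }
    if (!allow_missing && any(miss)) {
      stop2("missing value in column '", what, "'")
    }
    out
  }
  outcome <- parse_binary(raw[[outcome_column]], outcome_column,
                          allow_missing = FALSE)
  feats <- setdiff(names(raw), outcome_column)
  if (anyDuplicated(feats)) {
    stop2("duplicate feature names: ",
          paste(unique(feats[duplicated(feats)]), collapse = ", "))
  }
  mat <- matrix(NA_integer_, nrow = nrow(raw), ncol = length(feats),
                dimnames = list(NULL, feats))
  for (f in feats) mat[, f] <- parse_binary(raw[[f]], f, allow_missing = TRUE)
  cohort_table(mat, outcome, patient_ids = ids, outcome_name = outcome_column)
}

#' Write a cohort to CSV
#'
#' Inverse of [read_cohort]: missing cells are written as empty strings.
#'
#' @param t A [cohort_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(t, path) {
  df <- as.data.frame(t$features, check.names = FALSE)
  df[[t$outcome_name]] <- t$outcome
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Remove constant features
#'
#' Drops every feature with fewer than two distinct observed non-missing
#' values. A feature constant among its non-missing cells counts as
#' constant even if it also has missing cells, since imputation would make
#' it fully constant.
#'
#' @param t A [cohort_table].
#' @return A list with `cohort` (the reduced table) and `removed` (dropped
#'   feature names, in original column order).
#' @export
drop_constant_features <- function(t) {
  n_distinct <- apply(t$features, 2, function(x) length(unique(x[!is.na(x)])))
  keep <- n_distinct >= 2
  if (!any(keep)) {
    stop2("all features are constant: ",
          paste(feature_names(t), collapse = ", "))
  }
  removed <- feature_names(t)[!keep]
  out <- cohort_table(
    t$features[, keep, drop = FALSE], t$outcome,
    t$patient_ids, t$outcome_name
  )
  list(cohort = out, removed = removed)
}

#' Fit per-feature modes for imputation
#'
#' Computes the most frequent non-missing value (0 or 1) of every feature.
#' Exact ties are broken toward 0 — the majority value in a sparse clinical
#' table — and flagged.
#'
#' @param t A [cohort_table]; every feature must have at least one
#'   non-missing value.
#' @return An object of class `mode_map`: list with integer vector `modes`
#'   and logical vector `ties`, both named by feature.
#' @export
fit_mode <- function(t) {
  ones <- colSums(t$features == 1L, na.rm = TRUE)
  zeros <- colSums(t$features == 0L, na.rm = TRUE)
  empty <- ones + zeros == 0
  if (any(empty)) {
    stop2("feature(s) entirely missing: ",
          paste(feature_names(t)[empty], collapse = ", "))
  }
  modes <- ifelse(ones > zeros, 1L, 0L)
  names(modes) <- feature_names(t)
  ties <- ones == zeros
  names(ties) <- feature_names(t)
  structure(list(modes = modes, ties = ties), class = "mode_map")
}

#' @export
print.mode_map <- function(x, ...) {
  cat(sprintf("<mode_map> %d features (%d ties broken toward 0)\n",
              length(x$modes), sum(x$ties)))
  invisible(x)
}

#' Impute missing cells with fitted modes
#'
#' Replaces every missing cell of each feature with that feature's mode
#' from `m`. Non-missing cells are untouched; fit the modes on training
#' data only when evaluating on held-out patients.
#'
#' @param t A [cohort_table].
#' @param m A `mode_map` from [fit_mode] covering all features of `t`.
#' @return A complete [cohort_table].
#' @export
impute <- function(t, m) {
  missing_feats <- setdiff(feature_names(t), names(m$modes))
  if (length(missing_feats) > 0) {
    stop2("mode map lacks feature(s): ", paste(missing_feats, collapse = ", "))
  }
  mat <- t$features
  for (f in feature_names(t)) {
    idx <- is.na(mat[, f])
    if (any(idx)) mat[idx, f] <- m$modes[[f]]
  }
  cohort_table(mat, t$outcome, t$patient_ids, t$outcome_name)
}

#' Randomly split a cohort into train and test parts
#'
#' Uniform random partition without replacement with
#' `|test| = floor(fraction_test * n)`, deterministic given `seed`. A draw
#' whose test part contains only one outcome class is redrawn with an
#' incremented sub-seed (rank-based metrics are undefined on one-class
#' test sets); redraws are reported via `message()`.
#'
#' @param t A [cohort_table] with at least 2 rows.
#' @param fraction_test Test proportion in (0, 1). Default 0.2.
#' @param seed Integer seed.
#' @param max_redraws Bound on redraw attempts. Default 100.
#' @return An object of class `split_pair`: list with `train`, `test`
#'   (cohort tables), `seed`, `fraction_test`, `redraws`, and the row
#'   indices `test_idx`.
#' @export
split_cohort <- function(t, fraction_test = 0.2, seed, max_redraws = 100L) {
  if (!(fraction_test > 0 && fraction_test < 1)) {
    stop2("fraction_test must lie strictly between 0 and 1")
  }
  n <- nrow(t$features)
  if (n < 2) stop2("need at least 2 patients to split")
  n_test <- floor(fraction_test * n)
  if (n_test < 1) stop2("fraction_test too small: empty test set")
  attempt <- 0L
  repeat {
    test_idx <- with_seed(seed + attempt, sort(sample.int(n, n_test)))
    y_test <- t$outcome[test_idx]
    if (length(unique(y_test)) == 2L || attempt >= max_redraws) break
    attempt <- attempt + 1L
    message(sprintf(
      "split seed %d drew a one-class test set; redrawing with sub-seed +%d",
      seed, attempt
    ))
  }
  if (length(unique(t$outcome[test_idx])) < 2L) {
    stop2("could not draw a two-class test set within ", max_redraws,
          " redraws (degenerate outcome distribution)")
  }
  structure(
    list(
      train = cohort_rows(t, setdiff(seq_len(n), test_idx)),
      test = cohort_rows(t, test_idx),
      seed = seed,
      fraction_test = fraction_test,
      redraws = attempt,
      test_idx = test_idx
    ),
    class = "split_pair"
  )
}

#' Summarise a cohort feature by feature
#'
#' Counts and percentages of positive values among non-missing cells for
#' every feature, plus an outcome row — the standard count (%) table for
#' categorical clinical variables.
#'
#' @param t A [cohort_table].
#' @return A data.frame with columns `variable`, `n_positive`,
#'   `n_observed`, `percent` (of non-missing), `n_missing`.
#' @export
describe_cohort <- function(t) {
  summarise_one <- function(x) {
    obs <- sum(!is.na(x))
    pos <- sum(x == 1L, na.rm = TRUE)
    c(pos, obs, if (obs > 0) 100 * pos / obs else 0, sum(is.na(x)))
  }
  cols <- c(as.list(as.data.frame(t$features)), list(t$outcome))
  rows <- vapply(cols, summarise_one, numeric(4))
  data.frame(
    variable = c(feature_names(t), t$outcome_name),
    n_positive = as.integer(rows[1, ]),
    n_observed = as.integer(rows[2, ]),
    percent = rows[3, ],
    n_missing = as.integer(rows[4, ]),
    row.names = NULL
  )
}
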