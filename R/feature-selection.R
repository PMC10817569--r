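# Chi-squared predictor ranking and nested best-k predictor sets.

#' Pearson chi-squared score of one binary feature against the outcome
#'
#' Computes the uncorrected Pearson chi-squared statistic on the 2x2
#' feature-by-outcome contingency table,
#' `n (ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))`. A table with any zero
#' marginal (feature or outcome constant) scores 0, so features that are
#' uninformative by construction rank last instead of erroring.
#'
#' @param feature Binary 0/1 vector without missing values.
#' @param outcome Binary 0/1 vector of the same length.
#' @param feature_name Optional label carried in the result.
#' @return An object of class `feature_score`: list with `feature_name`,
#'   `chi2`, and the 2x2 `contingency` matrix (feature 0/1 rows, outcome
#'   0/1 columns).
#' @export
chi2_score <- function(feature, outcome, feature_name = NULL) {
  if (length(feature) != length(outcome)) {
    stop2("feature and outcome lengths differ")
  }
  if (anyNA(feature) || anyNA(outcome)) {
    stop2("chi2_score requires complete vectors; impute first")
  }
  a <- as.numeric(sum(feature == 0 & outcome == 0))
  b <- as.numeric(sum(feature == 0 & outcome == 1))
  c_ <- as.numeric(sum(feature == 1 & outcome == 0))
  d <- as.numeric(sum(feature == 1 & outcome == 1))
  tab <- matrix(c(a, c_, b, d), 2, 2,
                dimnames = list(feature = c("0", "1"), outcome = c("0", "1")))
  n <- a + b + c_ + d
  denom <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  chi2 <- if (denom == 0) 0 else n * (a * d - b * c_)^2 / denom
  structure(
    list(feature_name = feature_name, chi2 = chi2, contingency = tab),
    class = "feature_score"
  )
}

#' Rank all features by chi-squared association with the outcome
#'
#' Scores every feature with [chi2_score] and orders them by descending
#' statistic; exact ties are broken by ascending feature name so the
#' ranking is deterministic.
#'
#' @param t A complete (imputed) [cohort_table].
#' @return A list of `feature_score` objects in rank order.
#' @export
rank_features <- function(t) {
  if (anyNA(t$features)) stop2("cohort has missing values; impute first")
  scores <- lapply(feature_names(t), function(f) {
    chi2_score(t$features[, f], t$outcome, feature_name = f)
  })
  chi2 <- vapply(scores, `[[`, numeric(1), "chi2")
  nm <- vapply(scores, `[[`, character(1), "feature_name")
  scores[order(-chi2, nm)]
}

#' Build nested top-k predictor sets for every k
#'
#' From the [rank_features] ordering, constructs the top-k feature set for
#' each k = 1..P. Sets are nested by construction: the k-th set is the
#' (k-1)-th plus the next-ranked feature.
#'
#' @param t A complete (imputed) [cohort_table].
#' @return An object of class `predictor_sweep`: list with `ranking`
#'   (ordered `feature_score` list) and `sets` (list of character vectors,
#'   `sets[[k]]` of length k).
#' @export
predictor_sweep <- function(t) {
  ranking <- rank_features(t)
  ordered <- vapply(ranking, `[[`, character(1), "feature_name")
  sets <- lapply(seq_along(ordered), function(k) ordered[seq_len(k)])
  structure(list(ranking = ranking, sets = sets), class = "predictor_sweep")
}

#' @export
print.predictor_sweep <- function(x, ...) {
  cat(sprintf("<predictor_sweep> %d nested predictor sets; top feature: %s\n",
              length(x$sets), x$sets[[1]]))
  invisible(x)
}

#' Merge knowledge-base predictors into every sweep set
#'
#' The hybrid model must see every feature its rules test, so each hybrid
#' predictor set is the union of the corresponding model set with all
#' features appearing in any rule of the knowledge base. Order: the model
#' set first, then KB-only features alphabetically.
#'
#' @param sweep A `predictor_sweep`.
#' @param kb A [rule_kb].
#' @param all_features Optional character vector of valid feature names;
#'   KB features outside it raise an error.
#' @return A `predictor_sweep` whose sets include the KB features.
#' @export
merge_with_kb_predictors <- function(sweep, kb, all_features = NULL) {
  kb_feats <- kb_features(kb)
  if (!is.null(all_features)) {
    unknown <- setdiff(kb_feats, all_features)
    if (length(unknown) > 0) {
      stop2("knowledge base references unknown feature(s): ",
            paste(unknown, collapse = ", "))
    }
  }
  kb_feats <- sort(kb_feats)
  sets <- lapply(sweep$sets, function(s) c(s, setdiff(kb_feats, s)))
  structure(list(ranking = sweep$ranking, sets = sets),
            class = "predictor_sweep")
}
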