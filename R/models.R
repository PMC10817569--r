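# Gradient-boosted base classifier and the hybrid (rule-adjusted) model.

#' Boosting configuration
#'
#' Defaults reflect a small, imbalanced binary cohort: the positive class
#' is upweighted (scale_pos_weight 5.2), the ensemble is kept very small
#' (7 trees) and shallow-ish (depth 6) to curb overfitting at n in the
#' low hundreds.
#'
#' @param positive_class_weight `scale_pos_weight` ratio. Default 5.2.
#' @param n_trees Number of boosting rounds. Default 7.
#' @param max_tree_depth Maximum tree depth. Default 6.
#' @param seed Training seed. Default 1.
#' @param threshold Probability cutoff for class predictions. Default 0.5.
#' @return An object of class `boost_config`.
#' @export
boost_config <- function(positive_class_weight = 5.2, n_trees = 7L,
                         max_tree_depth = 6L, seed = 1L, threshold = 0.5) {
  if (positive_class_weight <= 0 || n_trees <= 0 || max_tree_depth <= 0) {
    stop2("boost_config values must be positive")
  }
  if (!(threshold > 0 && threshold < 1)) {
    stop2("threshold must lie strictly between 0 and 1")
  }
  structure(
    list(positive_class_weight = positive_class_weight,
         n_trees = as.integer(n_trees),
         max_tree_depth = as.integer(max_tree_depth),
         seed = as.integer(seed), threshold = threshold),
    class = "boost_config"
  )
}

#' @export
print.boost_config <- function(x, ...) {
  cat(sprintf(
    "<boost_config> pos weight %.2f, %d trees, depth %d, seed %d, threshold %.2f\n",
    x$positive_class_weight, x$n_trees, x$max_tree_depth, x$seed, x$threshold
  ))
  invisible(x)
}

# Full resolved xgboost parameter list (remaining parameters at library
# defaults, recorded here so run manifests are self-describing).
resolve_params <- function(cfg) {
  list(
    objective = "binary:logistic",
    scale_pos_weight = cfg$positive_class_weight,
    max_depth = cfg$max_tree_depth,
    nthread = 1L,
    seed = cfg$seed
  )
}

#' Train the gradient-boosted base classifier
#'
#' Fits an xgboost binary classifier on the given predictor columns.
#' Training is single-threaded and seeded, so identical data, predictors
#' and config yield identical models.
#'
#' @param train A complete (imputed) [cohort_table] containing both
#'   outcome classes.
#' @param predictors Nonempty character vector of feature names to use.
#' @param cfg A [boost_config].
#' @return An object of class `fitted_model`: list with the xgboost
#'   `booster`, `predictors`, and `config`.
#' @export
train_base <- function(train, predictors, cfg = boost_config()) {
  if (length(predictors) == 0) stop2("empty predictor set")
  missing_f <- setdiff(predictors, feature_names(train))
  if (length(missing_f) > 0) {
    stop2("predictor(s) not in cohort: ", paste(missing_f, collapse = ", "))
  }
  if (anyNA(train$features[, predictors])) {
    stop2("training data has missing values; impute first")
  }
  if (length(unique(train$outcome)) < 2) {
    stop2("training set contains a single outcome class")
  }
  x <- train$features[, predictors, drop = FALSE]
  storage.mode(x) <- "double"
  dtrain <- xgboost::xgb.DMatrix(x, label = train$outcome, nthread = 1L)
  booster <- with_seed(cfg$seed, xgboost::xgb.train(
    params = resolve_params(cfg), data = dtrain,
    nrounds = cfg$n_trees, verbose = 0
  ))
  structure(
    list(booster = booster, predictors = predictors, config = cfg),
    class = "fitted_model"
  )
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf("<fitted_model> boosted classifier on %d predictor(s)\n",
              length(x$predictors)))
  print(x$config)
  invisible(x)
}

# Extract the predictor submatrix from a cohort or plain matrix.
predictor_matrix <- function(rows, predictors) {
  mat <- if (inherits(rows, "cohort_table")) rows$features else as.matrix(rows)
  missing_f <- setdiff(predictors, colnames(mat))
  if (length(missing_f) > 0) {
    stop2("rows lack predictor column(s): ", paste(missing_f, collapse = ", "))
  }
  out <- mat[, predictors, drop = FALSE]
  if (anyNA(out)) stop2("prediction rows have missing values; impute first")
  storage.mode(out) <- "double"
  out
}

#' Predict event probabilities with the base classifier
#'
#' @param m A `fitted_model`.
#' @param rows A [cohort_table] or 0/1 matrix providing every predictor
#'   column; may have zero rows.
#' @return Numeric vector of probabilities in `[0, 1]`.
#' @export
predict_base <- function(m, rows) {
  x <- predictor_matrix(rows, m$predictors)
  if (nrow(x) == 0) return(numeric(0))
  as.numeric(stats::predict(m$booster, xgboost::xgb.DMatrix(x, nthread = 1L)))
}

#' Combine a fitted base model with a knowledge base
#'
#' @param base A `fitted_model` whose predictor set covers every feature
#'   the KB references.
#' @param kb A [rule_kb].
#' @return An object of class `hybrid_model`.
#' @export
hybrid_model <- function(base, kb) {
  outside <- setdiff(kb_features(kb), base$predictors)
  if (length(outside) > 0) {
    stop2("knowledge-base feature(s) outside the model's predictor set: ",
          paste(outside, collapse = ", "))
  }
  structure(list(base = base, kb = kb), class = "hybrid_model")
}

#' @export
print.hybrid_model <- function(x, ...) {
  cat(sprintf("<hybrid_model> base classifier on %d predictor(s) + %d rule(s)\n",
              length(x$base$predictors), length(x$kb$rules)))
  invisible(x)
}

#' Predict rule-adjusted event probabilities
#'
#' Runs the base classifier, then moves each patient's probability by the
#' signed log-odds offsets of the rules that fire for that patient
#' (see [apply_rules]). With an empty knowledge base the output equals
#' [predict_base] exactly.
#'
#' @param h A `hybrid_model`.
#' @param rows A [cohort_table] or 0/1 matrix providing every predictor
#'   and knowledge-base feature.
#' @return Numeric vector of probabilities in `(0, 1)`.
#' @export
predict_hybrid <- function(h, rows) {
  p <- predict_base(h$base, rows)
  if (length(p) == 0) return(p)
  mat <- if (inherits(rows, "cohort_table")) rows$features else as.matrix(rows)
  adjust_probabilities(h$kb, mat, p)
}

#' Threshold probabilities into class predictions
#'
#' @param probabilities Numeric vector in `[0, 1]`.
#' @param threshold Cutoff in (0, 1); a probability equal to the
#'   threshold is classified positive. Default 0.5.
#' @return Integer vector of 0/1 predictions.
#' @export
classify <- function(probabilities, threshold = 0.5) {
  if (!(threshold > 0 && threshold < 1)) {
    stop2("threshold must lie strictly between 0 and 1")
  }
  as.integer(probabilities >= threshold)
}

#' Save a fitted model to a self-describing JSON file
#'
#' Stores the predictor list, the boosting configuration, and the
#' serialized ensemble (base64-encoded xgboost raw format) in one JSON
#' document.
#'
#' @param m A `fitted_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_model <- function(m, path) {
  obj <- list(
    predictors = m$predictors,
    config = unclass(m$config),
    booster_raw = jsonlite::base64_enc(xgboost::xgb.save.raw(m$booster))
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a fitted model written by [write_model]
#'
#' @param path JSON file path.
#' @return A `fitted_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path)
  cfg <- boost_config(
    positive_class_weight = obj$config$positive_class_weight,
    n_trees = obj$config$n_trees,
    max_tree_depth = obj$config$max_tree_depth,
    seed = obj$config$seed,
    threshold = obj$config$threshold
  )
  booster <- xgboost::xgb.load.raw(
    jsonlite::base64_dec(gsub("\\s", "", obj$booster_raw))
  )
  structure(
    list(booster = booster, predictors = unlist(obj$predictors), config = cfg),
    class = "fitted_model"
  )
}
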