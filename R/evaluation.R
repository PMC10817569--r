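# Repeated random-split evaluation harness, per-k sweep with MCC-argmax
# model selection, and paired model comparison.

metric_row <- function(probabilities, labels, threshold, ece_bins) {
  cc <- confusion_counts(labels, classify(probabilities, threshold))
  c(
    f1 = f1(cc), auc = auc(probabilities, labels), mcc = mcc(cc),
    ece = ece(probabilities, labels, n_bins = ece_bins)$ece
  )
}

#' Repeated random-split evaluation of base (and hybrid) models
#'
#' Runs `n_iter` iterations. Each iteration draws a random train/test
#' split (seeded by `derive_seed(base_seed, i)`), fits imputation modes
#' on the training part only, imputes both parts, trains the boosted
#' classifier on the given predictors, and evaluates F1, AUC, MCC and
#' ECE on the held-out rows (F1/MCC at the config threshold). When a
#' knowledge base is supplied, the rule-adjusted predictions are
#' evaluated on the same test rows in the same iteration, so base and
#' hybrid metrics are paired by construction.
#'
#' @param t A [cohort_table] (may contain missing values; each iteration
#'   imputes with train-fitted modes).
#' @param predictors Nonempty character vector of features to train on;
#'   must cover the KB features when `kb` is given.
#' @param kb Optional [rule_kb]; adds a `"hybrid"` model to the output.
#' @param cfg A [boost_config]. The per-iteration training seed is
#'   derived from the split seed, so the whole harness is reproducible
#'   from `base_seed` alone.
#' @param n_iter Number of random splits. Default 100.
#' @param base_seed Integer base seed. Default 1.
#' @param fraction_test Test proportion. Default 0.2.
#' @param ece_bins Calibration bins. Default 10.
#' @param selection `"fixed"` (default): train on `predictors` as given,
#'   the whole-dataset selection that mirrors the headline pipeline and
#'   carries its acknowledged selection leakage. `"per_split"`: a
#'   leakage-free alternative that re-ranks features by chi-squared on
#'   the imputed training part of every split and takes the top
#'   `length(predictors)` features (plus the KB features when a KB is
#'   given).
#' @return An object of class `metric_summary`: list with `iterations`
#'   (data.frame: iteration, seed, model, f1, auc, mcc, ece), `summary`
#'   (data.frame: model, metric, mean, sd), per-iteration `scores` and
#'   `labels` (per model, for ROC averaging), `split_keys` (hashable
#'   test-row index strings, for audit of pairing), and the settings.
#' @export
repeated_evaluation <- function(t, predictors, kb = NULL,
                                cfg = boost_config(), n_iter = 100L,
                                base_seed = 1L, fraction_test = 0.2,
                                ece_bins = 10L,
                                selection = c("fixed", "per_split")) {
  selection <- match.arg(selection)
  if (length(predictors) == 0) stop2("empty predictor set")
  models <- c("base", if (!is.null(kb)) "hybrid")
  rows <- vector("list", n_iter * length(models))
  scores <- stats::setNames(
    replicate(length(models), vector("list", n_iter), simplify = FALSE),
    models
  )
  labels <- vector("list", n_iter)
  split_keys <- character(n_iter)
  for (i in seq_len(n_iter)) {
    seed_i <- derive_seed(base_seed, i)
    sp <- split_cohort(t, fraction_test, seed = seed_i)
    modes <- fit_mode(sp$train)
    train_i <- impute(sp$train, modes)
    test_i <- impute(sp$test, modes)
    cfg_i <- cfg
    cfg_i$seed <- derive_seed(seed_i, 1L)
    predictors_i <- predictors
    if (selection == "per_split") {
      ranked <- vapply(rank_features(train_i), `[[`, character(1),
                       "feature_name")
      predictors_i <- ranked[seq_len(min(length(predictors), length(ranked)))]
      if (!is.null(kb)) {
        predictors_i <- c(predictors_i,
                          setdiff(sort(kb_features(kb)), predictors_i))
      }
    }
    model <- train_base(train_i, predictors_i, cfg_i)
    p_base <- predict_base(model, test_i)
    y <- test_i$outcome
    labels[[i]] <- y
    split_keys[i] <- paste(sp$test_idx, collapse = ",")
    scores$base[[i]] <- p_base
    rows[[i]] <- c(iteration = i, seed = seed_i,
                   metric_row(p_base, y, cfg$threshold, ece_bins))
    if (!is.null(kb)) {
      h <- hybrid_model(model, kb)
      p_hyb <- predict_hybrid(h, test_i)
      scores$hybrid[[i]] <- p_hyb
      rows[[n_iter + i]] <- c(iteration = i, seed = seed_i,
                              metric_row(p_hyb, y, cfg$threshold, ece_bins))
    }
  }
  iterations <- as.data.frame(do.call(rbind, rows))
  iterations$model <- rep(models, each = n_iter)
  iterations <- iterations[, c("iteration", "seed", "model",
                               "f1", "auc", "mcc", "ece")]
  summary_df <- do.call(rbind, lapply(models, function(mo) {
    sub <- iterations[iterations$model == mo, ]
    do.call(rbind, lapply(c("f1", "auc", "mcc", "ece"), function(me) {
      data.frame(model = mo, metric = me, mean = mean(sub[[me]]),
                 sd = stats::sd(sub[[me]]))
    }))
  }))
  rownames(summary_df) <- NULL
  structure(
    list(
      iterations = iterations, summary = summary_df,
      scores = scores, labels = labels, split_keys = split_keys,
      n_iterations = as.integer(n_iter), models = models,
      base_seed = as.integer(base_seed), fraction_test = fraction_test,
      ece_bins = as.integer(ece_bins), predictors = predictors
    ),
    class = "metric_summary"
  )
}

#' @export
print.metric_summary <- function(x, ...) {
  cat(sprintf("<metric_summary> %d iterations, model(s): %s\n",
              x$n_iterations, paste(x$models, collapse = ", ")))
  s <- x$summary
  for (mo in x$models) {
    sub <- s[s$model == mo, ]
    cat(sprintf("  %-7s %s\n", mo, paste(
      sprintf("%s %.3f±%.3f", sub$metric, sub$mean, sub$sd),
      collapse = "  "
    )))
  }
  invisible(x)
}

# Pull the mean of one metric for one model out of a metric_summary.
summary_mean <- function(ms, model, metric) {
  s <- ms$summary
  s$mean[s$model == model & s$metric == metric]
}

#' Evaluate every predictor-count k and select the best by mean MCC
#'
#' For each k, evaluates the base model on the top-k chi-squared set and
#' (when a KB is given) the hybrid model on the corresponding
#' KB-augmented set, using identical split seeds throughout so all
#' comparisons are paired. The operating k per model is the argmax of
#' mean MCC over the repeated splits; ties resolve toward the smallest k
#' (parsimony).
#'
#' @param t A [cohort_table].
#' @param sweep A `predictor_sweep` of base-model sets.
#' @param hybrid_sweep Optional `predictor_sweep` of KB-augmented sets
#'   (see [merge_with_kb_predictors]); required when `kb` is given.
#' @param kb Optional [rule_kb].
#' @param cfg A [boost_config].
#' @param n_iter Random splits per k. Default 100.
#' @param base_seed Base seed shared by every k and model. Default 1.
#' @param fraction_test Test proportion. Default 0.2.
#' @param ece_bins Calibration bins. Default 10.
#' @param k_values Optional integer subset of k to evaluate (defaults to
#'   every k the sweep provides).
#' @return An object of class `sweep_result`: list with `curve`
#'   (data.frame: k, model, mean and sd per metric), `k_star` (named
#'   integer: selected k per model), `summaries` (per-k list of
#'   `metric_summary` pairs), and the settings.
#' @export
sweep_predictor_counts <- function(t, sweep, hybrid_sweep = NULL, kb = NULL,
                                   cfg = boost_config(), n_iter = 100L,
                                   base_seed = 1L, fraction_test = 0.2,
                                   ece_bins = 10L, k_values = NULL) {
  if (!is.null(kb) && is.null(hybrid_sweep)) {
    stop2("hybrid evaluation needs hybrid_sweep (see merge_with_kb_predictors)")
  }
  ks <- k_values %||% seq_along(sweep$sets)
  curve_rows <- list()
  summaries <- list()
  for (k in ks) {
    base_ms <- repeated_evaluation(
      t, sweep$sets[[k]], kb = NULL, cfg = cfg, n_iter = n_iter,
      base_seed = base_seed, fraction_test = fraction_test,
      ece_bins = ece_bins
    )
    entry <- list(base = base_ms)
    sb <- base_ms$summary
    curve_rows[[length(curve_rows) + 1L]] <- data.frame(
      k = k, model = "base",
      mean_f1 = sb$mean[sb$metric == "f1"], sd_f1 = sb$sd[sb$metric == "f1"],
      mean_auc = sb$mean[sb$metric == "auc"], sd_auc = sb$sd[sb$metric == "auc"],
      mean_mcc = sb$mean[sb$metric == "mcc"], sd_mcc = sb$sd[sb$metric == "mcc"],
      mean_ece = sb$mean[sb$metric == "ece"], sd_ece = sb$sd[sb$metric == "ece"]
    )
    if (!is.null(kb)) {
      hyb_ms <- repeated_evaluation(
        t, hybrid_sweep$sets[[k]], kb = kb, cfg = cfg, n_iter = n_iter,
        base_seed = base_seed, fraction_test = fraction_test,
        ece_bins = ece_bins
      )
      entry$hybrid <- hyb_ms
      sh <- hyb_ms$summary
      sh <- sh[sh$model == "hybrid", ]
      curve_rows[[length(curve_rows) + 1L]] <- data.frame(
        k = k, model = "hybrid",
        mean_f1 = sh$mean[sh$metric == "f1"], sd_f1 = sh$sd[sh$metric == "f1"],
        mean_auc = sh$mean[sh$metric == "auc"], sd_auc = sh$sd[sh$metric == "auc"],
        mean_mcc = sh$mean[sh$metric == "mcc"], sd_mcc = sh$sd[sh$metric == "mcc"],
        mean_ece = sh$mean[sh$metric == "ece"], sd_ece = sh$sd[sh$metric == "ece"]
      )
    }
    summaries[[as.character(k)]] <- entry
  }
  curve <- do.call(rbind, curve_rows)
  rownames(curve) <- NULL
  models <- c("base", if (!is.null(kb)) "hybrid")
  k_star <- vapply(models, function(mo) {
    sub <- curve[curve$model == mo, ]
    sub$k[which.max(sub$mean_mcc)]  # first max -> smallest k on ties
  }, numeric(1))
  structure(
    list(
      curve = curve, k_star = k_star, summaries = summaries,
      k_values = ks, n_iterations = as.integer(n_iter),
      base_seed = as.integer(base_seed)
    ),
    class = "sweep_result"
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d predictor counts x %d iterations\n",
              length(x$k_values), x$n_iterations))
  for (mo in names(x$k_star)) {
    k <- x$k_star[[mo]]
    sub <- x$curve[x$curve$model == mo & x$curve$k == k, ]
    cat(sprintf("  %-7s k* = %d (mean MCC %.3f ± %.3f)\n",
                mo, k, sub$mean_mcc, sub$sd_mcc))
  }
  invisible(x)
}
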