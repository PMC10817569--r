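# End-to-end pipeline: load -> preprocess -> predictor sweep -> knowledge
# base -> paired repeated evaluation per k -> MCC-argmax selection ->
# summaries, curves and a reproducibility manifest.

#' Default pipeline configuration
#'
#' Returns the full configuration list with every tunable at its default:
#' 80/20 splits, 100 iterations, boosting at (5.2, 7, 6), mining at
#' support >= 10 and effect ratio >= 1.5 with arity <= 3, a 20-rule cap,
#' rank deltas (0.4, 0.8, 1.2), classification threshold 0.5, 10
#' calibration bins. Override any entry via the `config` argument of
#' [run_pipeline] or a YAML/JSON config file.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    cohort_path = NULL,
    kb_path = NULL,
    out_dir = "ruleboost_run",
    outcome_column = "events",
    missing_tokens = c("", "NA", "NaN"),
    fraction_test = 0.2,
    n_iterations = 100L,
    base_seed = 1L,
    boost = list(positive_class_weight = 5.2, n_trees = 7L,
                 max_tree_depth = 6L),
    threshold = 0.5,
    ece_bins = 10L,
    mining = list(min_support = 10L, min_effect_ratio = 1.5,
                  max_arity = 3L, polarities = "both"),
    max_rules = 20L,
    rank_deltas = c(low = 0.4, medium = 0.8, high = 1.2),
    k_values = NULL,
    roc_grid_points = 101L
  )
}

# Deep-merge user entries over the defaults (one level for sublists).
merge_config <- function(user) {
  cfg <- default_config()
  for (key in names(user)) {
    if (is.list(cfg[[key]]) && is.list(user[[key]])) {
      for (sub in names(user[[key]])) cfg[[key]][[sub]] <- user[[key]][[sub]]
    } else {
      cfg[[key]] <- user[[key]]
    }
  }
  if (!is.null(cfg$rank_deltas)) cfg$rank_deltas <- unlist(cfg$rank_deltas)
  cfg
}

#' Read a pipeline configuration file
#'
#' YAML (`.yml`/`.yaml`) or JSON (`.json`), merged over [default_config].
#'
#' @param path Config file path.
#' @return Full configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop2("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  user <- switch(ext,
    yml = ,
    yaml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop2("unsupported config format: .", ext)
  )
  merge_config(user)
}

stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[ruleboost] ", fmt), ...))
}

#' Run the full hybrid-model pipeline
#'
#' Executes, in order: cohort loading (or an already-built
#' [cohort_table] via `cohort`), constant-feature removal, full-data
#' mode imputation, the chi-squared predictor sweep, knowledge-base
#' construction (loaded from `kb_path`, or mined from the full imputed
#' data, auto-ranked and capped), KB-augmented hybrid predictor sets,
#' paired repeated evaluation of base and hybrid models for every k,
#' MCC-argmax selection of the operating k per model, paired t-tests of
#' the two selected models, and vertically averaged ROC curves. Writes
#' `sweep.csv`, `iteration_metrics.csv`, `summary.json`,
#' `roc_base.csv`, `roc_hybrid.csv`, `kb.json` and `manifest.json`
#' under `out_dir`. Reruns with the same config are bit-identical in
#' `summary.json`.
#'
#' @param config Partial configuration list (see [default_config]) or a
#'   path to a YAML/JSON config file.
#' @param cohort Optional [cohort_table], bypassing `cohort_path`.
#' @param verbose Log stage progress. Default TRUE.
#' @return List with `out_dir`, the `summary` list, the `sweep_result`,
#'   the final `kb`, and the selected per-model `metric_summary`
#'   objects; invisibly.
#' @export
run_pipeline <- function(config = list(), cohort = NULL, verbose = TRUE) {
  cfg <- if (is.character(config)) read_run_config(config)
         else merge_config(config)
  run <- function(stage_name, expr) {
    tryCatch(expr, error = function(e) {
      stop2("pipeline stage '", stage_name, "' failed: ", conditionMessage(e))
    })
  }

  # -- load ----------------------------------------------------------------
  t_raw <- run("load", {
    if (!is.null(cohort)) {
      cohort
    } else {
      if (is.null(cfg$cohort_path)) stop2("no cohort supplied")
      read_cohort(cfg$cohort_path, cfg$outcome_column, cfg$missing_tokens)
    }
  })
  stage(verbose, "loaded cohort: %d patients x %d features",
        nrow(t_raw$features), ncol(t_raw$features))

  # -- preprocess ----------------------------------------------------------
  dropped <- run("drop_constants", drop_constant_features(t_raw))
  t_raw <- dropped$cohort
  stage(verbose, "removed %d constant feature(s); %d candidate predictors",
        length(dropped$removed), ncol(t_raw$features))
  t_full <- run("full_imputation", impute(t_raw, fit_mode(t_raw)))

  # -- predictor sweep on the full imputed data ----------------------------
  sweep <- run("predictor_sweep", predictor_sweep(t_full))
  stage(verbose, "chi-squared sweep: %d nested predictor sets",
        length(sweep$sets))

  # -- knowledge base ------------------------------------------------------
  kb <- run("knowledge_base", {
    if (!is.null(cfg$kb_path)) {
      ext <- tolower(tools::file_ext(cfg$kb_path))
      if (ext == "json") read_kb_json(cfg$kb_path)
      else read_kb_csv(cfg$kb_path, rank_deltas = cfg$rank_deltas,
                       max_rules = cfg$max_rules)
    } else {
      cand <- mine_rules(
        t_full, min_support = cfg$mining$min_support,
        min_effect_ratio = cfg$mining$min_effect_ratio,
        max_arity = cfg$mining$max_arity,
        polarities = cfg$mining$polarities
      )
      if (length(cand) == 0) {
        rule_kb(list(), rank_deltas = cfg$rank_deltas,
                max_rules = cfg$max_rules)
      } else {
        select_kb(assign_ranks(cand), max_rules = cfg$max_rules,
                  rank_deltas = cfg$rank_deltas)
      }
    }
  })
  stage(verbose, "knowledge base: %d rule(s)", length(kb$rules))
  hybrid_sweep <- run("hybrid_sets",
                      merge_with_kb_predictors(sweep, kb,
                                               feature_names(t_full)))

  # -- paired sweep over k -------------------------------------------------
  boost <- boost_config(
    positive_class_weight = cfg$boost$positive_class_weight,
    n_trees = cfg$boost$n_trees, max_tree_depth = cfg$boost$max_tree_depth,
    threshold = cfg$threshold
  )
  stage(verbose, "evaluating %d predictor counts x %d iterations (paired)",
        length(cfg$k_values %||% sweep$sets), cfg$n_iterations)
  sw <- run("sweep_evaluation", sweep_predictor_counts(
    t_raw, sweep, hybrid_sweep = hybrid_sweep, kb = kb, cfg = boost,
    n_iter = cfg$n_iterations, base_seed = cfg$base_seed,
    fraction_test = cfg$fraction_test, ece_bins = cfg$ece_bins,
    k_values = cfg$k_values
  ))
  k_base <- sw$k_star[["base"]]
  k_hybrid <- sw$k_star[["hybrid"]]
  stage(verbose, "selected k: base %d, hybrid %d", k_base, k_hybrid)

  best_base <- sw$summaries[[as.character(k_base)]]$base
  best_hybrid <- sw$summaries[[as.character(k_hybrid)]]$hybrid

  # -- paired comparison at the selected k ---------------------------------
  comparison <- run("paired_comparison", {
    ib <- best_base$iterations
    ih <- best_hybrid$iterations[best_hybrid$iterations$model == "hybrid", ]
    lapply(stats::setNames(nm = c("f1", "auc", "mcc", "ece")), function(me) {
      paired_t_test(ih[[me]], ib[[me]])
    })
  })

  # -- ROC curves ----------------------------------------------------------
  roc_base <- run("roc", averaged_roc(best_base$scores$base,
                                      best_base$labels,
                                      cfg$roc_grid_points))
  roc_hybrid <- run("roc", averaged_roc(best_hybrid$scores$hybrid,
                                        best_hybrid$labels,
                                        cfg$roc_grid_points))

  # -- outputs -------------------------------------------------------------
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sw$curve, file.path(out_dir, "sweep.csv"),
                   row.names = FALSE)
  iter_out <- rbind(
    cbind(best_base$iterations[best_base$iterations$model == "base", ],
          k = k_base),
    cbind(best_hybrid$iterations[best_hybrid$iterations$model == "hybrid", ],
          k = k_hybrid)
  )
  utils::write.csv(iter_out, file.path(out_dir, "iteration_metrics.csv"),
                   row.names = FALSE)
  utils::write.csv(roc_base, file.path(out_dir, "roc_base.csv"),
                   row.names = FALSE)
  utils::write.csv(roc_hybrid, file.path(out_dir, "roc_hybrid.csv"),
                   row.names = FALSE)
  write_kb_json(kb, file.path(out_dir, "kb.json"))

  summarise_model <- function(ms, model, k) {
    s <- ms$summary[ms$summary$model == model, ]
    out <- list(k = k)
    for (i in seq_len(nrow(s))) {
      out[[paste0(s$metric[i], "_mean")]] <- s$mean[i]
      out[[paste0(s$metric[i], "_sd")]] <- s$sd[i]
    }
    out
  }
  summary <- list(
    n_patients = nrow(t_raw$features),
    n_candidate_predictors = ncol(t_raw$features),
    removed_constant_features = dropped$removed,
    event_count = sum(t_raw$outcome),
    event_rate_percent = 100 * mean(t_raw$outcome),
    n_rules = length(kb$rules),
    n_iterations = cfg$n_iterations,
    base = summarise_model(best_base, "base", k_base),
    hybrid = summarise_model(best_hybrid, "hybrid", k_hybrid),
    paired_tests = comparison
  )
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")

  manifest <- list(
    config = cfg,
    input_md5 = if (!is.null(cfg$cohort_path)) {
      unname(tools::md5sum(cfg$cohort_path))
    } else NULL,
    kb_md5 = if (!is.null(cfg$kb_path)) {
      unname(tools::md5sum(cfg$kb_path))
    } else NULL,
    split_seed_derivation =
      "seed_i = (base_seed * 48271 + i * 16807) mod (2^31 - 1) + 1",
    r_version = as.character(getRversion())
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  stage(verbose, "wrote outputs to %s", out_dir)

  invisible(list(
    out_dir = out_dir, summary = summary, sweep_result = sw, kb = kb,
    best_base = best_base, best_hybrid = best_hybrid,
    roc_base = roc_base, roc_hybrid = roc_hybrid
  ))
}
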