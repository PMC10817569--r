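# Synthetic binary cohort generator with planted conjunctive rule
# effects and ground truth for recovery testing.

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate a small, imbalanced emergency-department cohort of
#' binary clinical predictors: 266 patients, 35 informative-capable
#' sparse features plus 3 constant columns (38 features + outcome), a
#' target event prevalence of 17%, and about 1% missing cells.
#'
#' @param n_patients Number of rows. Default 266.
#' @param n_features Number of non-constant binary features. Default 35.
#' @param feature_sparsity Per-feature Bernoulli rates, recycled to
#'   `n_features`. Default: evenly spaced from 0.02 to 0.5, mirroring
#'   the spread of prevalences a clinical risk-factor table typically
#'   shows (rare ECG findings through common comorbidities).
#' @param baseline_event_rate Target outcome prevalence in (0, 1).
#'   Default 0.17.
#' @param planted_rules List of planted effects, each a list with
#'   `antecedent` (named 0/1 vector over feature names) and `effect`
#'   (log-odds shift when the antecedent holds). Default none.
#' @param missing_rate Probability that a feature cell is masked
#'   missing, completely at random. Default 0.01.
#' @param n_constant_features All-zero columns appended after the
#'   informative features. Default 3.
#' @param seed Mandatory integer seed.
#' @return An object of class `synth_config`.
#' @export
synth_config <- function(n_patients = 266L, n_features = 35L,
                         feature_sparsity = NULL,
                         baseline_event_rate = 0.17,
                         planted_rules = list(), missing_rate = 0.01,
                         n_constant_features = 3L, seed) {
  if (missing(seed)) stop2("synth_config requires an explicit seed")
  if (!(baseline_event_rate > 0 && baseline_event_rate < 1)) {
    stop2("baseline_event_rate must lie strictly between 0 and 1")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop2("missing_rate must lie in [0, 1)")
  }
  if (is.null(feature_sparsity)) {
    feature_sparsity <- seq(0.02, 0.5, length.out = n_features)
  }
  feature_sparsity <- rep_len(feature_sparsity, n_features)
  if (any(feature_sparsity < 0 | feature_sparsity > 1)) {
    stop2("feature_sparsity rates must lie in [0, 1]")
  }
  feats <- sprintf("f%02d", seq_len(n_features))
  for (pr in planted_rules) {
    if (is.null(pr$antecedent) || is.null(pr$effect)) {
      stop2("each planted rule needs an antecedent and an effect")
    }
    unknown <- setdiff(names(pr$antecedent), feats)
    if (length(unknown) > 0) {
      stop2("planted antecedent references unknown feature(s): ",
            paste(unknown, collapse = ", "))
    }
  }
  structure(
    list(
      n_patients = as.integer(n_patients),
      n_features = as.integer(n_features),
      feature_sparsity = feature_sparsity,
      baseline_event_rate = baseline_event_rate,
      planted_rules = planted_rules,
      missing_rate = missing_rate,
      n_constant_features = as.integer(n_constant_features),
      seed = as.integer(seed)
    ),
    class = "synth_config"
  )
}

# Calibrate the logistic intercept by bisection on the realized design so
# the expected prevalence (mean of per-patient event probabilities)
# matches the target.
calibrate_intercept <- function(eta, target, tol = 1e-6) {
  f <- function(b0) mean(stats::plogis(b0 + eta)) - target
  lo <- -30
  hi <- 30
  if (f(lo) > 0 || f(hi) < 0) stop2("infeasible target prevalence")
  for (iter in 1:100) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}

#' Generate a synthetic binary cohort with planted rule effects
#'
#' Features are drawn independently Bernoulli at the configured sparsity
#' rates. Each patient's event probability is
#' `plogis(intercept + sum of planted effects whose antecedents hold)`,
#' with the intercept calibrated by bisection on the realized feature
#' matrix so the expected prevalence matches `baseline_event_rate`.
#' Outcomes are then drawn Bernoulli, feature cells are masked missing
#' completely at random at `missing_rate`, and all-zero constant columns
#' are appended. Fully deterministic given the config seed.
#'
#' @param cfg A [synth_config].
#' @return List with `cohort` (a [cohort_table]) and `truth` (class
#'   `ground_truth`: planted rules, per-patient true probability, the
#'   calibrated intercept).
#' @export
generate_cohort <- function(cfg) {
  with_seed(cfg$seed, {
    n <- cfg$n_patients
    p <- cfg$n_features
    x <- vapply(seq_len(p), function(j) {
      stats::rbinom(n, 1L, cfg$feature_sparsity[j])
    }, integer(n))
    colnames(x) <- sprintf("f%02d", seq_len(p))
    eta <- rep(0, n)
    for (pr in cfg$planted_rules) {
      sat <- rep(TRUE, n)
      for (f in names(pr$antecedent)) {
        sat <- sat & (x[, f] == pr$antecedent[[f]])
      }
      eta <- eta + pr$effect * sat
    }
    intercept <- calibrate_intercept(eta, cfg$baseline_event_rate)
    prob <- stats::plogis(intercept + eta)
    outcome <- stats::rbinom(n, 1L, prob)
    if (cfg$missing_rate > 0) {
      mask <- matrix(stats::runif(n * p) < cfg$missing_rate, n, p)
      x[mask] <- NA_integer_
    }
    if (cfg$n_constant_features > 0) {
      consts <- matrix(0L, n, cfg$n_constant_features,
                       dimnames = list(NULL, sprintf(
                         "const_%d", seq_len(cfg$n_constant_features)
                       )))
      x <- cbind(x, consts)
    }
    truth <- structure(
      list(planted_rules = cfg$planted_rules, true_probability = prob,
           intercept = intercept),
      class = "ground_truth"
    )
    list(cohort = cohort_table(x, outcome), truth = truth)
  })
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf(
    "<ground_truth> %d planted rule(s); intercept %.3f; mean true prob %.3f\n",
    length(x$planted_rules), x$intercept, mean(x$true_probability)
  ))
  invisible(x)
}

#' Precision and recall of planted-rule recovery
#'
#' A planted rule counts as recovered when its exact literal set appears
#' among the mined rules with the direction implied by the sign of its
#' planted effect (positive log-odds shift = increase).
#'
#' @param mined List of mined [rule] objects.
#' @param truth A `ground_truth` from [generate_cohort].
#' @return List with `recall`, `precision` (`NA` with
#'   `precision_undefined = TRUE` when nothing was mined), and logical
#'   `recovered` per planted rule.
#' @export
recovery_report <- function(mined, truth) {
  canon <- function(ant) {
    ord <- order(names(ant))
    paste(sprintf("%s=%d", names(ant)[ord], as.integer(ant)[ord]),
          collapse = " & ")
  }
  mined_keys <- vapply(mined, function(r) canon(r$antecedent), character(1))
  mined_dirs <- vapply(mined, `[[`, character(1), "direction")
  recovered <- vapply(truth$planted_rules, function(pr) {
    want_dir <- if (pr$effect > 0) "increase" else "decrease"
    any(mined_keys == canon(pr$antecedent) & mined_dirs == want_dir)
  }, logical(1))
  planted_keys <- vapply(truth$planted_rules,
                         function(pr) canon(pr$antecedent), character(1))
  n_planted_mined <- sum(mined_keys %in% planted_keys)
  list(
    recall = if (length(recovered) > 0) mean(recovered) else NA_real_,
    precision = if (length(mined) > 0) n_planted_mined / length(mined)
                else NA_real_,
    precision_undefined = length(mined) == 0,
    recovered = recovered
  )
}
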