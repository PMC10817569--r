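# Fixture builders shared across test files. All cohorts are built in
# code; nothing is read from disk except via temp files written here.

# Cohort from a plain data.frame of 0/1/NA columns plus an outcome vector.
make_cohort <- function(df, outcome, outcome_name = "events") {
  cohort_table(as.matrix(df), outcome, outcome_name = outcome_name)
}

# A linearly separable toy cohort: one feature equal to the outcome plus
# independent noise features. Any sane classifier separates it perfectly.
separable_cohort <- function(n = 40, n_noise = 2, seed = 101) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  x <- cbind(signal = y)
  for (j in seq_len(n_noise)) {
    x <- cbind(x, stats::rbinom(n, 1L, 0.3))
  }
  colnames(x) <- c("signal", paste0("noise", seq_len(n_noise)))
  cohort_table(x, y)
}

# Write a small cohort CSV and return its path.
write_temp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# Independent brute-force metric oracles (deliberately naive; used to
# cross-check the package implementations).
oracle_mcc <- function(TP, FP, TN, FN) {
  num <- TP * TN - FP * FN
  den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  if (den == 0) 0 else num / den
}

oracle_f1 <- function(TP, FP, TN, FN) {
  if (TP == 0) return(0)
  prec <- TP / (TP + FP)
  rec <- TP / (TP + FN)
  2 * prec * rec / (prec + rec)
}

# Pairwise-comparison AUC: loop over every positive/negative pair.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Manual-binning ECE (event formulation, right-closed bins).
oracle_ece <- function(probs, labels, n_bins) {
  n <- length(probs)
  total <- 0
  for (b in seq_len(n_bins)) {
    lo <- (b - 1) / n_bins
    hi <- b / n_bins
    idx <- if (b == 1) probs >= 0 & probs <= hi else probs > lo & probs <= hi
    if (!any(idx)) next
    total <- total + sum(idx) / n * abs(mean(labels[idx]) - mean(probs[idx]))
  }
  total
}

# Uncorrected Pearson chi-squared via expected counts (independent of the
# closed-form route used by the package).
oracle_chi2 <- function(tab) {
  n <- sum(tab)
  if (n == 0) return(0)
  expected <- outer(rowSums(tab), colSums(tab)) / n
  if (any(expected == 0)) return(0)
  sum((tab - expected)^2 / expected)
}
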