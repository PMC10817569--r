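test_that("read_cohort parses binary CSVs and maps empty cells to missing", {
  path <- write_temp_csv(c("f1,f2,events", "1,0,1", "0,,0", "1,1,1", "0,0,0"))
  t <- read_cohort(path)
  expect_s3_class(t, "cohort_table")
  expect_equal(dim(t), c(4L, 2L))
  expect_equal(sum(is.na(t$features)), 1L)
  expect_true(is.na(t$features[2, "f2"]))
  expect_equal(t$outcome, c(1L, 0L, 1L, 0L))
})

test_that("read_cohort rejects contract violations", {
  bad_outcome <- write_temp_csv(c("f1,events", "1,2", "0,0"))
  expect_error(read_cohort(bad_outcome), "non-binary")
  no_outcome <- write_temp_csv(c("f1,f2", "1,0", "0,1"))
  expect_error(read_cohort(no_outcome), "outcome column")
  bad_cell <- write_temp_csv(c("f1,events", "7,1", "0,0"))
  expect_error(read_cohort(bad_cell), "non-binary")
  missing_outcome <- write_temp_csv(c("f1,events", "1,", "0,0"))
  expect_error(read_cohort(missing_outcome), "missing value")
})

test_that("missing-value tokens are configurable", {
  path <- write_temp_csv(c("f1,events", "1,1", "?,0", "0,1"))
  expect_error(read_cohort(path), "non-binary")
  t <- read_cohort(path, missing_tokens = c("", "?"))
  expect_true(is.na(t$features[2, 1]))
})

test_that("cohorts round-trip through CSV", {
  x <- matrix(c(1L, 0L, NA, 1L, 0L, 0L), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  t <- cohort_table(x, c(1L, 0L, 1L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cohort(t, path)
  t2 <- read_cohort(path)
  expect_identical(t2$features, t$features)
  expect_identical(t2$outcome, t$outcome)
})

test_that("drop_constant_features removes constants, including NA-padded ones", {
  t <- make_cohort(
    data.frame(allzero = c(0L, 0L, 0L), mixed = c(0L, 1L, 0L),
               napad = c(0L, NA, 0L)),
    outcome = c(0L, 1L, 0L)
  )
  res <- drop_constant_features(t)
  expect_equal(feature_names(res$cohort), "mixed")
  # removed order follows original column order
  expect_equal(res$removed, c("allzero", "napad"))
  # idempotent
  res2 <- drop_constant_features(res$cohort)
  expect_equal(res2$removed, character(0))
  expect_identical(res2$cohort$features, res$cohort$features)
})

test_that("drop_constant_features errors when every feature is constant", {
  t <- make_cohort(data.frame(a = c(0L, 0L), b = c(1L, 1L)), c(0L, 1L))
  expect_error(drop_constant_features(t), "a, b")
})

test_that("fit_mode computes per-feature modes with ties toward 0", {
  t <- make_cohort(
    data.frame(a = c(0L, 0L, 1L, NA), b = c(1L, 1L, 0L, 1L),
               tie = c(0L, 1L, NA, NA)),
    outcome = c(0L, 1L, 0L, 1L)
  )
  m <- fit_mode(t)
  expect_equal(unname(m$modes[c("a", "b", "tie")]), c(0L, 1L, 0L))
  expect_equal(unname(m$ties[c("a", "b", "tie")]), c(FALSE, FALSE, TRUE))
})

test_that("fit_mode errors on an entirely missing feature", {
  t <- make_cohort(data.frame(a = c(NA, NA), b = c(0L, 1L)), c(0L, 1L))
  expect_error(fit_mode(t), "entirely missing")
})

test_that("impute fills missing cells and leaves observed cells alone", {
  t <- make_cohort(data.frame(a = c(0L, 0L, 1L, NA)), c(0L, 1L, 0L, 1L))
  out <- impute(t, fit_mode(t))
  expect_equal(unname(out$features[, "a"]), c(0L, 0L, 1L, 0L))
  # identity on complete tables
  complete <- make_cohort(data.frame(a = c(0L, 1L, 1L)), c(0L, 1L, 1L))
  expect_identical(impute(complete, fit_mode(complete))$features,
                   complete$features)
})

test_that("imputing with train-fitted modes differs from self-fitted modes", {
  train <- make_cohort(data.frame(a = c(1L, 1L, 0L)), c(0L, 1L, 1L))
  test <- make_cohort(data.frame(a = c(0L, 0L, 1L, NA)), c(0L, 0L, 1L, 1L))
  via_train <- impute(test, fit_mode(train))
  via_self <- impute(test, fit_mode(test))
  expect_equal(via_train$features[4, "a"], c(a = 1L))
  expect_equal(via_self$features[4, "a"], c(a = 0L))
})

test_that("impute errors when the mode map misses a feature", {
  t <- make_cohort(data.frame(a = c(0L, 1L), b = c(NA, 1L)), c(0L, 1L))
  m <- fit_mode(make_cohort(data.frame(a = c(0L, 1L)), c(0L, 1L)))
  expect_error(impute(t, m), "lacks feature")
})

test_that("split_cohort sizes, determinism and partition invariant", {
  set.seed(1)
  t <- make_cohort(data.frame(a = rbinom(10, 1, 0.5)),
                   outcome = rep(c(0L, 1L), 5))
  sp <- split_cohort(t, 0.2, seed = 11)
  expect_equal(nrow(sp$test$features), 2L)
  expect_equal(nrow(sp$train$features), 8L)
  sp2 <- split_cohort(t, 0.2, seed = 11)
  expect_identical(sp$test_idx, sp2$test_idx)
  # partition over many seeds
  for (s in 1:20) {
    spx <- suppressMessages(split_cohort(t, 0.3, seed = s))
    got <- sort(c(spx$train$patient_ids, spx$test$patient_ids))
    expect_identical(got, sort(t$patient_ids))
  }
  # study-sized cohort: floor(0.2 * 266) = 53
  big <- make_cohort(data.frame(a = rbinom(266, 1, 0.5)),
                     outcome = rbinom(266, 1, 0.17))
  spb <- split_cohort(big, 0.2, seed = 3)
  expect_equal(nrow(spb$test$features), 53L)
  expect_equal(nrow(spb$train$features), 213L)
})

test_that("one-class test draws are redrawn, degenerate outcomes error", {
  # single positive among 10: most draws of size 3 miss it
  t <- make_cohort(data.frame(a = rep(c(0L, 1L), 5)),
                   outcome = c(1L, rep(0L, 9)))
  found_redraw <- FALSE
  for (s in 1:10) {
    sp <- withCallingHandlers(
      split_cohort(t, 0.3, seed = s),
      message = function(m) {
        found_redraw <<- TRUE
        invokeRestart("muffleMessage")
      }
    )
    expect_equal(length(unique(sp$test$outcome)), 2L)
  }
  expect_true(found_redraw)
  all_neg <- make_cohort(data.frame(a = rep(c(0L, 1L), 5)),
                         outcome = rep(0L, 10))
  expect_error(
    suppressMessages(split_cohort(all_neg, 0.3, seed = 1, max_redraws = 3)),
    "two-class"
  )
})

test_that("describe_cohort counts and percentages are consistent", {
  t <- make_cohort(
    data.frame(mostly = c(1L, 1L, 0L, NA), zero = c(0L, 0L, 0L, 0L)),
    outcome = c(1L, 0L, 0L, 0L)
  )
  d <- describe_cohort(t)
  mostly <- d[d$variable == "mostly", ]
  expect_equal(mostly$n_positive, 2L)
  expect_equal(mostly$percent, 100 * 2 / 3, tolerance = 1e-12)
  zero <- d[d$variable == "zero", ]
  expect_equal(zero$n_positive, 0L)
  expect_equal(zero$percent, 0)
  ev <- d[d$variable == "events", ]
  expect_equal(ev$n_positive, 1L)
  expect_equal(ev$percent, 25)
  expect_true(all(d$percent >= 0 & d$percent <= 100))
  expect_true(all(d$n_observed + d$n_missing == 4L))
})
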