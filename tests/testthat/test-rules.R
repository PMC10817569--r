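test_that("enumerate_antecedents counts match closed-form enumeration", {
  # 3 features, arity <= 3, both polarities: sum C(3,a) 2^a = 6 + 12 + 8
  both <- enumerate_antecedents(c("a", "b", "c"), 3, "both")
  expect_length(both, 26)
  keys <- vapply(both, ruleboost:::antecedent_key, character(1))
  expect_false(anyDuplicated(keys) > 0)
  # 35 features, positive only: 35 + C(35,2) + C(35,3)
  pos <- enumerate_antecedents(sprintf("f%02d", 1:35), 3, "positive_only")
  expect_length(pos, 35 + choose(35, 2) + choose(35, 3))
  expect_length(enumerate_antecedents("solo", 1, "positive_only"), 1)
  expect_error(enumerate_antecedents(c("a", "b"), 3), "exceeds")
})

test_that("score_antecedent computes support, rates and direction", {
  # 10 patients, 2 events both among the 5 carriers of f1
  t <- make_cohort(
    data.frame(f1 = c(rep(1L, 5), rep(0L, 5)), f2 = rep(0L, 10)),
    outcome = c(1L, 1L, 0L, 0L, 0L, rep(0L, 5))
  )
  r <- score_antecedent(c(f1 = 1), t)
  expect_equal(r$stats$support, 5)
  expect_equal(r$stats$subgroup_rate, 0.4)
  expect_equal(r$stats$baseline_rate, 0.2)
  expect_equal(r$stats$effect_ratio, 2)
  expect_equal(r$direction, "increase")
  expect_true(r$usable)
  # antecedent satisfied by everyone: subgroup equals baseline, tie flag
  all_sat <- score_antecedent(c(f2 = 0), t)
  expect_true(all_sat$tie)
  expect_equal(all_sat$stats$effect_ratio, 1)
  # zero support: unusable
  none <- score_antecedent(c(f2 = 1), t)
  expect_equal(none$stats$support, 0)
  expect_false(none$usable)
})

test_that("mine_rules equals a brute-force enumerate-and-filter oracle", {
  set.seed(31)
  n <- 120
  df <- as.data.frame(matrix(rbinom(n * 5, 1, 0.35), ncol = 5))
  names(df) <- paste0("f", 1:5)
  y <- rbinom(n, 1, 0.25)
  t <- make_cohort(df, y)
  min_support <- 8
  min_er <- 1.4
  mined <- mine_rules(t, min_support, min_er, max_arity = 3)
  # oracle: score every enumerated antecedent independently and re-filter
  oracle_keys <- character(0)
  for (ant in enumerate_antecedents(names(df), 3, "both")) {
    sat <- rep(TRUE, n)
    for (f in names(ant)) sat <- sat & (df[[f]] == ant[[f]])
    if (sum(sat) < min_support) next
    er <- mean(y[sat]) / mean(y)
    strength <- if (er == 0) Inf else max(er, 1 / er)
    if (strength >= min_er) {
      oracle_keys <- c(oracle_keys, ruleboost:::antecedent_key(ant))
    }
  }
  mined_keys <- vapply(mined, function(r) ruleboost:::antecedent_key(r$antecedent),
                       character(1))
  expect_setequal(mined_keys, oracle_keys)
  # stated sort order: effect strength desc, then support desc
  strengths <- vapply(mined, ruleboost:::rule_strength, numeric(1))
  expect_true(all(diff(strengths) <= 1e-12))
  # impossible support bound yields an empty list
  expect_length(mine_rules(t, min_support = n + 1), 0)
})

test_that("flipping all outcome labels flips every rule direction", {
  set.seed(77)
  n <- 150
  df <- as.data.frame(matrix(rbinom(n * 4, 1, 0.4), ncol = 4))
  names(df) <- paste0("f", 1:4)
  y <- rbinom(n, 1, 0.4)
  mined <- mine_rules(make_cohort(df, y), min_support = 10,
                      min_effect_ratio = 1.3, max_arity = 2)
  flipped <- mine_rules(make_cohort(df, 1L - y), min_support = 10,
                        min_effect_ratio = 1.0, max_arity = 2)
  flip_dir <- vapply(flipped, `[[`, character(1), "direction")
  names(flip_dir) <- vapply(flipped, function(r) {
    ruleboost:::antecedent_key(r$antecedent)
  }, character(1))
  for (r in mined) {
    if (r$tie) next
    key <- ruleboost:::antecedent_key(r$antecedent)
    expect_true(key %in% names(flip_dir))
    expect_false(flip_dir[[key]] == r$direction)
  }
})

test_that("assign_ranks splits strengths into tertiles and honors curation", {
  mk <- function(er, feat) {
    rule(setNames(1L, feat), if (er >= 1) "increase" else "decrease",
         stats = list(support = 20, subgroup_rate = 0.2 * er,
                      baseline_rate = 0.2, effect_ratio = er))
  }
  three <- list(mk(4, "a"), mk(2, "b"), mk(1.2, "c"))
  ranked <- assign_ranks(three)
  expect_equal(vapply(ranked, `[[`, character(1), "rank"),
               c("high", "medium", "low"))
  six <- list(mk(5, "a"), mk(4, "b"), mk(3, "c"),
              mk(2, "d"), mk(1.5, "e"), mk(1.2, "f"))
  ranks6 <- vapply(assign_ranks(six), `[[`, character(1), "rank")
  expect_equal(unname(table(ranks6)[c("low", "medium", "high")]),
               c(2L, 2L, 2L), ignore_attr = TRUE)
  expect_equal(ranks6, c("high", "high", "medium", "medium", "low", "low"))
  # curation override by antecedent key
  cur <- assign_ranks(three, curation = c("c=1" = "high"))
  expect_equal(cur[[3]]$rank, "high")
  expect_error(assign_ranks(three, curation = c("zz=1" = "low")), "unmined")
})

test_that("select_kb caps the knowledge base at max_rules", {
  mk <- function(i) {
    rule(setNames(1L, sprintf("f%02d", i)), "increase", "low",
         stats = list(support = 20, subgroup_rate = 0.4,
                      baseline_rate = 0.2, effect_ratio = 2))
  }
  fifty <- lapply(1:50, mk)
  expect_length(select_kb(fifty)$rules, 20)
  expect_length(select_kb(fifty[1:5])$rules, 5)
  empty <- select_kb(fifty, max_rules = 0)
  expect_length(empty$rules, 0)
})

test_that("apply_rules shifts probabilities additively in log-odds space", {
  deltas <- c(low = 0.4, medium = 0.8, high = 1.2)
  kb1 <- rule_kb(list(rule(c(a = 1), "increase", "high")),
                 rank_deltas = c(low = 0.5, medium = 0.75, high = 1.0))
  # no rule fires: identity
  expect_equal(apply_rules(kb1, c(a = 0, b = 1), 0.37), 0.37, tolerance = 1e-9)
  # logistic(logit(0.5) + 1.0) = 0.7311
  expect_equal(apply_rules(kb1, c(a = 1), 0.5), plogis(1), tolerance = 1e-6)
  # equal-rank opposite rules cancel exactly
  kb2 <- rule_kb(list(
    rule(c(a = 1), "increase", "medium"),
    rule(c(b = 0), "decrease", "medium")
  ), rank_deltas = deltas)
  expect_equal(apply_rules(kb2, c(a = 1, b = 0), 0.3), 0.3, tolerance = 1e-9)
  expect_error(apply_rules(kb1, c(b = 1), 0.5), "lacks")
})

test_that("apply_rules output stays in (0,1) and is monotone", {
  deltas <- c(low = 0.4, medium = 0.8, high = 1.2)
  kbs <- list(
    rule_kb(list(rule(c(a = 1), "increase", "high"),
                 rule(c(b = 1), "decrease", "low")), rank_deltas = deltas),
    rule_kb(list(), rank_deltas = deltas)
  )
  set.seed(13)
  for (kb in kbs) {
    for (i in 1:50) {
      row <- c(a = rbinom(1, 1, 0.5), b = rbinom(1, 1, 0.5))
      p <- runif(1)
      out <- apply_rules(kb, row, p)
      expect_true(out > 0 && out < 1)
    }
  }
  # monotone in p_base for a fixed fired set
  kb <- kbs[[1]]
  ps <- seq(0.05, 0.95, by = 0.1)
  outs <- vapply(ps, function(p) apply_rules(kb, c(a = 1, b = 0), p),
                 numeric(1))
  expect_true(all(diff(outs) > 0))
  # monotone in the number of fired increase rules
  kb_two <- rule_kb(list(
    rule(c(a = 1), "increase", "low"),
    rule(c(b = 1), "increase", "low")
  ), rank_deltas = deltas)
  p0 <- apply_rules(kb_two, c(a = 0, b = 0), 0.3)
  p1 <- apply_rules(kb_two, c(a = 1, b = 0), 0.3)
  p2 <- apply_rules(kb_two, c(a = 1, b = 1), 0.3)
  expect_true(p0 < p1 && p1 < p2)
})

test_that("knowledge bases round-trip through JSON and CSV", {
  t <- make_cohort(
    data.frame(f1 = c(rep(1L, 6), rep(0L, 14)), f2 = rbinom(20, 1, 0.5)),
    outcome = c(rep(1L, 4), rep(0L, 16))
  )
  cand <- mine_rules(t, min_support = 3, min_effect_ratio = 1.2,
                     max_arity = 2)
  expect_gt(length(cand), 0)
  kb <- select_kb(assign_ranks(cand), max_rules = 10,
                  rank_deltas = c(low = 0.3, medium = 0.7, high = 1.5))
  jpath <- withr::local_tempfile(fileext = ".json")
  write_kb_json(kb, jpath)
  kb_j <- read_kb_json(jpath)
  expect_equal(kb_j, kb)
  # JSON serialization is bit-exact on re-write
  jpath2 <- withr::local_tempfile(fileext = ".json")
  write_kb_json(kb_j, jpath2)
  expect_identical(readLines(jpath), readLines(jpath2))
  # CSV keeps literals, direction and rank (stats are not part of the dialect)
  cpath <- withr::local_tempfile(fileext = ".csv")
  write_kb_csv(kb, cpath)
  kb_c <- read_kb_csv(cpath, rank_deltas = kb$rank_deltas, max_rules = 10)
  expect_equal(
    lapply(kb_c$rules, function(r) r[c("antecedent", "direction", "rank")]),
    lapply(kb$rules, function(r) r[c("antecedent", "direction", "rank")])
  )
})

test_that("rule and rule_kb constructors enforce invariants", {
  expect_error(rule(c(a = 1, b = 0, c = 1, d = 1), "increase"), "between 1 and 3")
  expect_error(rule(c(a = 1, a = 0), "increase"), "distinct")
  expect_error(rule(c(a = 2), "increase"), "0 or 1")
  expect_error(rule(c(a = 1), "sideways"), "direction")
  expect_error(rule_kb(rank_deltas = c(low = 1, medium = 0.5, high = 2)),
               "increasing")
  r <- rule(c(a = 1), "increase", "low")
  expect_error(rule_kb(rep(list(r), 21)), "cap")
})
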