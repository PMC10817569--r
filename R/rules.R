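# Conjunctive rule mining, the curated knowledge base, and probability
# adjustment.
#
# A rule is "IF <conjunction of up to three literals> THEN raise (or
# lower) the predicted event probability", with a curator-assigned rank
# (low / medium / high) that maps to a log-odds offset. The knowledge base
# is the capped, ranked set of such rules applied on top of the boosted
# classifier's probability.

# An antecedent is a named integer vector: names are features, values the
# required 0/1. The canonical key string orders literals as given.
antecedent_key <- function(antecedent) {
  paste(sprintf("%s=%d", names(antecedent), as.integer(antecedent)),
        collapse = " & ")
}

parse_antecedent <- function(key) {
  parts <- strsplit(key, " & ", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^(.*)=([01])$", parts))
  if (any(vapply(m, length, integer(1)) != 3)) {
    stop2("malformed literal in antecedent: ", key)
  }
  vals <- vapply(m, function(x) as.integer(x[3]), integer(1))
  names(vals) <- vapply(m, `[[`, character(1), 2)
  vals
}

#' Construct a rule
#'
#' @param antecedent Named integer vector: names are distinct features,
#'   values the required 0/1 (a negative literal, value 0, encodes
#'   "absence of" a factor). Between 1 and 3 literals.
#' @param direction `"increase"` or `"decrease"` of the predicted event
#'   probability when the antecedent holds.
#' @param rank `"low"`, `"medium"`, `"high"`, or `NA` before curation.
#' @param stats Optional list with `support`, `subgroup_rate`,
#'   `baseline_rate`, `effect_ratio` recorded at mining time.
#' @param tie Logical: subgroup rate equalled the baseline at mining time.
#' @param usable Logical: FALSE when the antecedent had zero support.
#' @return An object of class `rule`.
#' @export
rule <- function(antecedent, direction, rank = NA_character_, stats = NULL,
                 tie = FALSE, usable = TRUE) {
  if (length(antecedent) < 1 || length(antecedent) > 3) {
    stop2("a rule must have between 1 and 3 literals")
  }
  if (anyDuplicated(names(antecedent))) {
    stop2("rule literals must use distinct features")
  }
  if (!all(antecedent %in% c(0L, 1L))) stop2("literal values must be 0 or 1")
  if (!direction %in% c("increase", "decrease")) {
    stop2("direction must be 'increase' or 'decrease'")
  }
  if (!is.na(rank) && !rank %in% c("low", "medium", "high")) {
    stop2("rank must be low, medium, or high")
  }
  antecedent <- stats::setNames(as.integer(antecedent), names(antecedent))
  structure(
    list(antecedent = antecedent, direction = direction, rank = rank,
         stats = stats, tie = tie, usable = usable),
    class = "rule"
  )
}

#' @export
print.rule <- function(x, ...) {
  arrow <- if (x$direction == "increase") "raise" else "lower"
  cat(sprintf("IF %s THEN %s probability [rank %s]\n",
              antecedent_key(x$antecedent), arrow,
              if (is.na(x$rank)) "?" else x$rank))
  if (!is.null(x$stats)) {
    cat(sprintf("  support %d, subgroup rate %.3f vs baseline %.3f (ratio %.2f)\n",
                x$stats$support, x$stats$subgroup_rate, x$stats$baseline_rate,
                x$stats$effect_ratio))
  }
  invisible(x)
}

#' Construct a rule knowledge base
#'
#' @param rules List of [rule] objects, all with assigned ranks.
#' @param rank_deltas Named numeric vector mapping low/medium/high to
#'   positive log-odds offsets, strictly increasing. Default
#'   `c(low = 0.4, medium = 0.8, high = 1.2)`.
#' @param max_rules Cap on the number of rules. Default 20.
#' @return An object of class `rule_kb`.
#' @export
rule_kb <- function(rules = list(),
                    rank_deltas = c(low = 0.4, medium = 0.8, high = 1.2),
                    max_rules = 20L) {
  if (!all(c("low", "medium", "high") %in% names(rank_deltas))) {
    stop2("rank_deltas must name low, medium, and high")
  }
  rank_deltas <- rank_deltas[c("low", "medium", "high")]
  if (any(rank_deltas <= 0) || any(diff(rank_deltas) <= 0)) {
    stop2("rank_deltas must be positive and strictly increasing")
  }
  if (length(rules) > max_rules) {
    stop2("knowledge base exceeds its cap of ", max_rules, " rules")
  }
  for (r in rules) {
    if (!inherits(r, "rule")) stop2("all elements of rules must be rule objects")
    if (is.na(r$rank)) stop2("all knowledge-base rules must have a rank")
  }
  structure(
    list(rules = rules, rank_deltas = rank_deltas,
         max_rules = as.integer(max_rules)),
    class = "rule_kb"
  )
}

#' @export
print.rule_kb <- function(x, ...) {
  cat(sprintf("<rule_kb> %d rule(s) (cap %d); deltas low=%.2f medium=%.2f high=%.2f\n",
              length(x$rules), x$max_rules,
              x$rank_deltas[["low"]], x$rank_deltas[["medium"]],
              x$rank_deltas[["high"]]))
  for (r in x$rules) print(r)
  invisible(x)
}

#' @export
length.rule_kb <- function(x) length(x$rules)

#' Features referenced by any rule in a knowledge base
#' @param kb A [rule_kb].
#' @return Character vector of distinct feature names.
#' @export
kb_features <- function(kb) {
  unique(unlist(lapply(kb$rules, function(r) names(r$antecedent))))
}

#' Enumerate all conjunctive antecedents up to a given arity
#'
#' Generates every subset of 1..`max_arity` distinct features; with
#' `polarities = "both"` each subset is crossed with all 0/1 value
#' assignments (the last literal cycles fastest, value 1 before 0).
#' Ordering is deterministic: arity ascending, subsets in `combn` order.
#'
#' @param features Character vector of feature names.
#' @param max_arity Maximum number of literals per antecedent (>= 1).
#' @param polarities `"both"` or `"positive_only"` (all literals require
#'   value 1).
#' @return List of named integer vectors (antecedents).
#' @export
enumerate_antecedents <- function(features, max_arity = 3L,
                                  polarities = c("both", "positive_only")) {
  polarities <- match.arg(polarities)
  if (max_arity < 1) stop2("max_arity must be at least 1")
  if (max_arity > length(features)) {
    stop2("max_arity exceeds the number of features")
  }
  out <- list()
  for (arity in seq_len(max_arity)) {
    combos <- utils::combn(features, arity, simplify = FALSE)
    if (polarities == "positive_only") {
      vals_grid <- list(rep(1L, arity))
    } else {
      vals_grid <- as.list(as.data.frame(t(as.matrix(
        expand.grid(rep(list(c(1L, 0L)), arity))[, rev(seq_len(arity)), drop = FALSE]
      ))))
    }
    for (combo in combos) {
      for (vals in vals_grid) {
        out[[length(out) + 1L]] <- stats::setNames(as.integer(vals), combo)
      }
    }
  }
  out
}

#' Score one antecedent against a cohort
#'
#' Computes the support (patients satisfying every literal), the subgroup
#' event rate among them, the overall baseline event rate, the provisional
#' direction (increase if the subgroup rate exceeds the baseline), and the
#' effect ratio subgroup/baseline.
#'
#' @param antecedent Named integer vector of literals.
#' @param t A complete (imputed) [cohort_table].
#' @return A [rule] with populated `stats`; `usable = FALSE` when support
#'   is zero or the cohort has no events, `tie = TRUE` when the subgroup
#'   rate equals the baseline.
#' @export
score_antecedent <- function(antecedent, t) {
  if (anyNA(t$features)) stop2("cohort has missing values; impute first")
  unknown <- setdiff(names(antecedent), feature_names(t))
  if (length(unknown) > 0) {
    stop2("antecedent references unknown feature(s): ",
          paste(unknown, collapse = ", "))
  }
  sat <- rep(TRUE, nrow(t$features))
  for (f in names(antecedent)) {
    sat <- sat & (t$features[, f] == antecedent[[f]])
  }
  support <- sum(sat)
  baseline <- mean(t$outcome)
  subgroup <- if (support > 0) mean(t$outcome[sat]) else NA_real_
  usable <- support > 0 && baseline > 0
  er <- if (usable) subgroup / baseline else NA_real_
  tie <- usable && subgroup == baseline
  direction <- if (usable && subgroup < baseline) "decrease" else "increase"
  rule(
    antecedent, direction,
    stats = list(support = support, subgroup_rate = subgroup,
                 baseline_rate = baseline, effect_ratio = er),
    tie = tie, usable = usable
  )
}

# effect strength used for sorting and ranking: fold change away from the
# baseline in whichever direction, i.e. max(ratio, 1/ratio)
rule_strength <- function(r) {
  er <- r$stats$effect_ratio
  if (is.na(er)) return(-Inf)
  if (er == 0) return(Inf)
  max(er, 1 / er)
}

#' Mine candidate conjunctive rules from a cohort
#'
#' Scores every antecedent up to `max_arity` and keeps those with support
#' at least `min_support` and fold change from the baseline event rate
#' (in either direction) at least `min_effect_ratio`. Survivors are
#' sorted by effect strength, then support, then antecedent key, so the
#' candidate order is deterministic. This quantitative screen is the
#' automated stand-in for expert clinical review; its survivors are meant
#' to be curated (see [assign_ranks]) before deployment.
#'
#' @param t A complete (imputed) [cohort_table].
#' @param min_support Minimum number of patients satisfying the
#'   antecedent. Default 10.
#' @param min_effect_ratio Minimum of `max(r, 1/r)` where `r` is the
#'   subgroup/baseline event-rate ratio. Default 1.5.
#' @param max_arity Maximum literals per antecedent. Default 3.
#' @param polarities Passed to [enumerate_antecedents]. Default `"both"`.
#' @return List of [rule] objects (possibly empty), unranked.
#' @export
mine_rules <- function(t, min_support = 10L, min_effect_ratio = 1.5,
                       max_arity = 3L,
                       polarities = c("both", "positive_only")) {
  polarities <- match.arg(polarities)
  if (anyNA(t$features)) stop2("cohort has missing values; impute first")
  feats <- feature_names(t)
  if (min_support > nrow(t$features)) return(list())
  n <- nrow(t$features)
  y <- t$outcome
  baseline <- mean(y)
  # literal satisfaction columns: for each feature, ==1 and ==0
  pos <- t$features == 1L
  neg <- !pos
  survivors <- list()
  strengths <- numeric(0)
  supports <- integer(0)
  keys <- character(0)
  antecedents <- enumerate_antecedents(feats, max_arity, polarities)
  for (ant in antecedents) {
    sat <- rep(TRUE, n)
    for (j in seq_along(ant)) {
      col <- if (ant[[j]] == 1L) pos[, names(ant)[j]] else neg[, names(ant)[j]]
      sat <- sat & col
    }
    support <- sum(sat)
    if (support < min_support || baseline == 0) next
    subgroup <- sum(y[sat]) / support
    er <- subgroup / baseline
    strength <- if (er == 0) Inf else max(er, 1 / er)
    if (strength < min_effect_ratio) next
    r <- rule(
      ant,
      direction = if (subgroup < baseline) "decrease" else "increase",
      stats = list(support = support, subgroup_rate = subgroup,
                   baseline_rate = baseline, effect_ratio = er),
      tie = subgroup == baseline, usable = TRUE
    )
    survivors[[length(survivors) + 1L]] <- r
    strengths <- c(strengths, strength)
    supports <- c(supports, support)
    keys <- c(keys, antecedent_key(ant))
  }
  survivors[order(-strengths, -supports, keys)]
}

#' Assign low/medium/high ranks to mined rules
#'
#' In automatic mode, rules are ranked by tertiles of the absolute log
#' effect ratio: the weakest third is `low`, the middle third `medium`,
#' the strongest third `high`; ties keep the incoming (mining) order.
#' A curation table — the editable stand-in for expert review — can
#' override individual ranks by antecedent key.
#'
#' @param rules Nonempty list of [rule] objects.
#' @param curation Optional overrides: a named character vector or a
#'   data.frame with columns `antecedent` and `rank`. Keys must match
#'   mined antecedents (syntax `"feature=1 & other=0"`); unknown keys
#'   raise an error.
#' @return The same rules with `rank` filled in, original order preserved.
#' @export
assign_ranks <- function(rules, curation = NULL) {
  if (length(rules) == 0) stop2("cannot rank an empty rule list")
  strength <- vapply(rules, function(r) abs(log(max(r$stats$effect_ratio,
                                                    .Machine$double.xmin))),
                     numeric(1))
  ord <- order(strength)  # stable: ties keep incoming order
  n <- length(rules)
  levels3 <- c("low", "medium", "high")
  grp <- ceiling(3 * seq_len(n) / n)
  for (i in seq_len(n)) {
    rules[[ord[i]]]$rank <- levels3[grp[i]]
  }
  if (!is.null(curation)) {
    if (is.data.frame(curation)) {
      overrides <- stats::setNames(as.character(curation$rank),
                                   curation$antecedent)
    } else {
      overrides <- curation
    }
    keys <- vapply(rules, function(r) antecedent_key(r$antecedent),
                   character(1))
    unknown <- setdiff(names(overrides), keys)
    if (length(unknown) > 0) {
      stop2("curation references unmined rule(s): ",
            paste(unknown, collapse = "; "))
    }
    for (key in names(overrides)) {
      rk <- overrides[[key]]
      if (!rk %in% levels3) stop2("invalid rank '", rk, "' for ", key)
      rules[[which(keys == key)]]$rank <- rk
    }
  }
  rules
}

#' Select the capped knowledge base from ranked candidates
#'
#' Keeps the first `max_rules` rules in the [mine_rules] candidate order
#' (strongest effects first) and packages them with the rank-to-offset
#' mapping.
#'
#' @param rules List of ranked [rule] objects.
#' @param max_rules Cap. Default 20.
#' @param rank_deltas Passed to [rule_kb].
#' @return A [rule_kb].
#' @export
select_kb <- function(rules, max_rules = 20L,
                      rank_deltas = c(low = 0.4, medium = 0.8, high = 1.2)) {
  kept <- rules[seq_len(min(length(rules), max_rules))]
  rule_kb(kept, rank_deltas = rank_deltas, max_rules = max_rules)
}

#' Adjust a predicted probability with the fired rules
#'
#' A rule fires for a patient when all of its literals are satisfied. The
#' base probability is moved in log-odds space:
#' `logit(p') = logit(p) + sum(s * delta_rank)` over fired rules, with
#' `s = +1` for increase rules and `-1` for decrease rules, then mapped
#' back through the logistic function. Additive log-odds offsets keep the
#' output strictly inside (0, 1) and compose symmetrically, so two fired
#' rules of equal rank and opposite direction cancel exactly. Base
#' probabilities are clipped to `[1e-6, 1 - 1e-6]` before the logit.
#'
#' @param kb A [rule_kb].
#' @param patient Named 0/1 vector (or single-row matrix) covering every
#'   feature the KB references.
#' @param p_base Base probability in (0, 1).
#' @return Adjusted probability.
#' @export
apply_rules <- function(kb, patient, p_base) {
  if (is.matrix(patient)) patient <- patient[1, ]
  needed <- kb_features(kb)
  missing_f <- setdiff(needed, names(patient))
  if (length(missing_f) > 0) {
    stop2("patient row lacks knowledge-base feature(s): ",
          paste(missing_f, collapse = ", "))
  }
  if (anyNA(patient[needed])) stop2("patient row has missing values")
  offset <- 0
  for (r in kb$rules) {
    fired <- all(patient[names(r$antecedent)] == r$antecedent)
    if (fired) {
      s <- if (r$direction == "increase") 1 else -1
      offset <- offset + s * kb$rank_deltas[[r$rank]]
    }
  }
  stats::plogis(clipped_logit(p_base) + offset)
}

# Vectorized probability adjustment over the rows of a feature matrix.
adjust_probabilities <- function(kb, rows, p_base) {
  if (length(kb$rules) == 0) return(p_base)
  needed <- kb_features(kb)
  missing_f <- setdiff(needed, colnames(rows))
  if (length(missing_f) > 0) {
    stop2("rows lack knowledge-base feature(s): ",
          paste(missing_f, collapse = ", "))
  }
  offset <- rep(0, nrow(rows))
  for (r in kb$rules) {
    fired <- rep(TRUE, nrow(rows))
    for (f in names(r$antecedent)) {
      fired <- fired & (rows[, f] == r$antecedent[[f]])
    }
    s <- if (r$direction == "increase") 1 else -1
    offset <- offset + fired * s * kb$rank_deltas[[r$rank]]
  }
  stats::plogis(clipped_logit(p_base) + offset)
}

# ---- Knowledge-base serialization ----------------------------------------

kb_to_df <- function(kb) {
  if (length(kb$rules) == 0) return(NULL)
  rows <- lapply(kb$rules, function(r) {
    lits <- sprintf("%s=%d", names(r$antecedent), r$antecedent)
    lits <- c(lits, rep("", 3 - length(lits)))
    data.frame(
      literal_1 = lits[1], literal_2 = lits[2], literal_3 = lits[3],
      direction = r$direction, rank = r$rank, stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write a knowledge base to CSV
#'
#' Columns `literal_1..literal_3` (syntax `feature=1` / `feature=0`,
#' blanks for unused slots), `direction`, `rank`. The CSV dialect carries
#' no rank deltas or provenance statistics; use [write_kb_json] for a
#' lossless round-trip.
#'
#' @param kb A [rule_kb].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kb_csv <- function(kb, path) {
  df <- kb_to_df(kb)
  if (is.null(df)) {
    df <- data.frame(literal_1 = character(0), literal_2 = character(0),
                     literal_3 = character(0), direction = character(0),
                     rank = character(0))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a knowledge base from CSV
#'
#' @param path CSV with columns `literal_1..literal_3`, `direction`,
#'   `rank` as written by [write_kb_csv].
#' @param rank_deltas,max_rules Passed to [rule_kb] (the CSV dialect does
#'   not store them).
#' @return A [rule_kb].
#' @export
read_kb_csv <- function(path,
                        rank_deltas = c(low = 0.4, medium = 0.8, high = 1.2),
                        max_rules = 20L) {
  df <- utils::read.csv(path, colClasses = "character")
  required <- c("literal_1", "direction", "rank")
  if (!all(required %in% names(df))) {
    stop2("knowledge-base CSV must have columns literal_1, direction, rank")
  }
  rules <- lapply(seq_len(nrow(df)), function(i) {
    lits <- unlist(df[i, intersect(c("literal_1", "literal_2", "literal_3"),
                                   names(df))])
    lits <- lits[!is.na(lits) & nzchar(lits)]
    rule(parse_antecedent(paste(lits, collapse = " & ")),
         direction = df$direction[i], rank = df$rank[i])
  })
  rule_kb(rules, rank_deltas = rank_deltas, max_rules = max_rules)
}

#' Write a knowledge base to JSON (lossless)
#'
#' Stores rules with literals, direction, rank, and mining statistics,
#' plus the rank-delta mapping and cap. [read_kb_json] round-trips this
#' file exactly.
#'
#' @param kb A [rule_kb].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kb_json <- function(kb, path) {
  obj <- list(
    rank_deltas = as.list(kb$rank_deltas),
    max_rules = kb$max_rules,
    rules = lapply(kb$rules, function(r) {
      list(
        antecedent = as.list(r$antecedent),
        direction = r$direction,
        rank = r$rank,
        stats = r$stats,
        tie = r$tie,
        usable = r$usable
      )
    })
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read a knowledge base from JSON
#'
#' @param path File written by [write_kb_json].
#' @return A [rule_kb].
#' @export
read_kb_json <- function(path) {
  obj <- jsonlite::read_json(path)
  rules <- lapply(obj$rules, function(r) {
    ant <- stats::setNames(as.integer(unlist(r$antecedent)),
                           names(r$antecedent))
    stats <- if (is.null(r$stats)) NULL else lapply(r$stats, function(v) {
      if (is.null(v)) NA_real_ else v
    })
    rule(ant, direction = r$direction, rank = r$rank, stats = stats,
         tie = isTRUE(r$tie), usable = !isFALSE(r$usable))
  })
  rule_kb(
    rules,
    rank_deltas = unlist(obj$rank_deltas)[c("low", "medium", "high")],
    max_rules = obj$max_rules
  )
}
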