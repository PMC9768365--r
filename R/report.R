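# Pipeline surface: evaluate one AUT, compare rules across a panel of
# AUTs, and run the stratified error analysis.  A thin command-line wrapper
# over these functions ships in inst/scripts/noduleval.R.

#' Read a directory of per-AUT prediction CSVs
#'
#' Multi-AUT layout: one prediction CSV per AUT in a directory, the file
#' name (without extension) being the AUT label.
#'
#' @param dir directory containing `*.csv` prediction files.
#' @return Named list (AUT label -> predictions as from
#'   [read_prediction_csv()]).
#' @export
read_predictions_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.csv$", full.names = TRUE))
  if (!length(files)) stop(sprintf("no prediction CSVs in %s", dir), call. = FALSE)
  out <- lapply(files, read_prediction_csv)
  names(out) <- sub("\\.csv$", "", basename(files))
  out
}

#' Evaluate one AUT's predictions under one rule
#'
#' Runs [match_case()] on every reference case, pools counts into a
#' [metric_set()], and produces a per-nodule audit table: every reference
#' nodule with its outcome (TP or FN), matched `pred_id` and tie-break
#' score, and every prediction with its outcome (TP or FP).  Predictions
#' for a case absent from the reference set are counted as false positives
#' within their own case universe, with a warning.
#'
#' @param cases named list of [case_record()] (the reference dataset).
#' @param predictions named list (case_id -> list of [predicted_nodule()]).
#' @param rule a [match_rule()] or rule-kind string.
#' @param match_order see [order_references()].
#' @param type_scope `"all"` or a vector of in-scope [nodule_types()]; see
#'   [apply_type_scope()].
#' @return Object of class `evaluation`: list with `rule`, `metrics`,
#'   `results` (per-case `match_result`s) and `audit` (data.frame).
#' @export
evaluate_aut <- function(cases, predictions, rule,
                         match_order = "size", type_scope = "all") {
  rule <- as_match_rule(rule)
  stray <- setdiff(names(predictions), names(cases))
  if (length(stray)) {
    warning(sprintf("predictions for case(s) absent from references (counted as FP): %s",
                    paste(stray, collapse = ", ")), call. = FALSE)
  }
  all_case_ids <- union(names(cases), stray)
  results <- lapply(all_case_ids, function(cid) {
    cs <- cases[[cid]]
    refs <- if (is.null(cs)) list() else cs$references
    spacing <- if (is.null(cs)) c(0.7, 0.7) else cs$pixel_spacing_mm
    preds <- predictions[[cid]] %||% list()
    scoped <- apply_type_scope(refs, preds, type_scope, rule, spacing,
                               match_order)
    match_case(scoped$refs, scoped$preds, rule, spacing, match_order)
  })
  names(results) <- all_case_ids
  audit <- build_audit(results)
  structure(list(rule = rule, metrics = compute_metrics(results),
                 results = results, audit = audit),
            class = "evaluation")
}

build_audit <- function(results) {
  rows <- lapply(results, function(r) {
    parts <- list()
    if (nrow(r$assignments)) {
      parts$tp_ref <- data.frame(case_id = r$case_id, kind = "reference",
                                 id = r$assignments$nodule_id, outcome = "TP",
                                 matched_id = r$assignments$pred_id,
                                 tiebreak_score = r$assignments$tiebreak_score,
                                 stringsAsFactors = FALSE)
      parts$tp_pred <- data.frame(case_id = r$case_id, kind = "prediction",
                                  id = r$assignments$pred_id, outcome = "TP",
                                  matched_id = r$assignments$nodule_id,
                                  tiebreak_score = r$assignments$tiebreak_score,
                                  stringsAsFactors = FALSE)
    }
    if (length(r$fn_ids)) {
      parts$fn <- data.frame(case_id = r$case_id, kind = "reference",
                             id = r$fn_ids, outcome = "FN",
                             matched_id = NA_character_,
                             tiebreak_score = NA_real_, stringsAsFactors = FALSE)
    }
    if (length(r$fp_ids)) {
      parts$fp <- data.frame(case_id = r$case_id, kind = "prediction",
                             id = r$fp_ids, outcome = "FP",
                             matched_id = NA_character_,
                             tiebreak_score = NA_real_, stringsAsFactors = FALSE)
    }
    if (!length(parts)) return(NULL)
    do.call(rbind, parts)
  })
  rows <- Filter(Negate(is.null), rows)
  audit <- if (length(rows)) do.call(rbind, rows) else
    data.frame(case_id = character(0), kind = character(0), id = character(0),
               outcome = character(0), matched_id = character(0),
               tiebreak_score = numeric(0), stringsAsFactors = FALSE)
  audit <- audit[order(audit$case_id, audit$kind, audit$id), , drop = FALSE]
  rownames(audit) <- NULL
  audit
}

#' @export
print.evaluation <- function(x, ...) {
  cat(sprintf("<evaluation under %s>\n", x$rule$kind))
  print(x$metrics)
  invisible(x)
}

#' Compare mark-labeling rules across a panel of AUTs
#'
#' Evaluates every AUT under every rule, then reports per-rule
#' mean +/- SD of recall / precision / F1 (percent), pairwise rule deltas
#' in percentage points, per-AUT relative TP differences against a baseline
#' rule, and the ANOVA + pairwise t-test comparison with significance
#' labels for each metric.
#'
#' @param cases named list of [case_record()].
#' @param predictions_by_aut named list (AUT label -> predictions as in
#'   [evaluate_aut()]).
#' @param rules list of [match_rule()]s or rule-kind strings (>= 2).
#' @param baseline rule kind used as the relative-difference baseline
#'   (default `"center_hit"`).
#' @param match_order,type_scope passed to [evaluate_aut()].
#' @param welch,paired passed to [compare_groups()].
#' @return Object of class `rule_comparison`: list with `per_aut`
#'   (data.frame aut x rule x metrics), `summary` (per-rule mean/sd in
#'   percent), `deltas` (pairwise mean differences, percentage points),
#'   `relative_differences` (per AUT vs baseline), and `tests` (per metric,
#'   a `group_comparison`).
#' @export
compare_rules <- function(cases, predictions_by_aut,
                          rules = list("center_hit", "center_distance",
                                       "area_overlap"),
                          baseline = "center_hit",
                          match_order = "size", type_scope = "all",
                          welch = FALSE, paired = FALSE) {
  stopifnot(length(rules) >= 2L, length(predictions_by_aut) >= 1L,
            !is.null(names(predictions_by_aut)))
  rules <- lapply(rules, as_match_rule)
  rule_kinds <- vapply(rules, function(r) r$kind, character(1))
  if (anyDuplicated(rule_kinds)) {
    stop("compare_rules: duplicate rules", call. = FALSE)
  }
  if (!baseline %in% rule_kinds) {
    stop(sprintf("compare_rules: baseline rule '%s' not among the rules", baseline),
         call. = FALSE)
  }
  auts <- names(predictions_by_aut)

  per_aut <- do.call(rbind, lapply(auts, function(aut) {
    do.call(rbind, lapply(rules, function(rl) {
      ev <- evaluate_aut(cases, predictions_by_aut[[aut]], rl,
                         match_order, type_scope)
      m <- ev$metrics
      data.frame(aut = aut, rule = rl$kind, tp = m$tp, fp = m$fp, fn = m$fn,
                 recall = m$recall, precision = m$precision, f1 = m$f1,
                 stringsAsFactors = FALSE)
    }))
  }))

  metrics <- c("recall", "precision", "f1")
  summary <- do.call(rbind, lapply(rule_kinds, function(rk) {
    sub <- per_aut[per_aut$rule == rk, , drop = FALSE]
    row <- data.frame(rule = rk, stringsAsFactors = FALSE)
    for (m in metrics) {
      if (nrow(sub) >= 2L) {
        ag <- aggregate_over_auts(100 * sub[[m]])
        row[[paste0(m, "_mean")]] <- ag$mean
        row[[paste0(m, "_sd")]] <- ag$sd
      } else {
        row[[paste0(m, "_mean")]] <- 100 * mean(sub[[m]])
        row[[paste0(m, "_sd")]] <- NA_real_
      }
    }
    row
  }))

  combs <- utils::combn(rule_kinds, 2L)
  deltas <- do.call(rbind, lapply(seq_len(ncol(combs)), function(i) {
    a <- combs[1L, i]; b <- combs[2L, i]
    ra <- summary[summary$rule == a, ]; rb <- summary[summary$rule == b, ]
    data.frame(rule_a = a, rule_b = b,
               recall = rule_delta(ra$recall_mean, rb$recall_mean),
               precision = rule_delta(ra$precision_mean, rb$precision_mean),
               f1 = rule_delta(ra$f1_mean, rb$f1_mean),
               stringsAsFactors = FALSE)
  }))

  base_tp <- per_aut$tp[per_aut$rule == baseline]
  names(base_tp) <- per_aut$aut[per_aut$rule == baseline]
  rd <- do.call(rbind, lapply(setdiff(rule_kinds, baseline), function(rk) {
    sub <- per_aut[per_aut$rule == rk, , drop = FALSE]
    data.frame(aut = sub$aut, compared_rule = rk, baseline_rule = baseline,
               rd = vapply(seq_len(nrow(sub)), function(i)
                 relative_difference(sub$tp[i], base_tp[[sub$aut[i]]]),
                 numeric(1)),
               stringsAsFactors = FALSE)
  }))

  tests <- if (length(auts) >= 2L) {
    stats::setNames(lapply(metrics, function(m) {
      groups <- lapply(rule_kinds, function(rk)
        per_aut[[m]][per_aut$rule == rk])
      names(groups) <- rule_kinds
      compare_groups(groups, welch = welch, paired = paired)
    }), metrics)
  } else NULL

  structure(list(per_aut = per_aut, summary = summary, deltas = deltas,
                 relative_differences = rd, tests = tests,
                 baseline = baseline),
            class = "rule_comparison")
}

#' @export
print.rule_comparison <- function(x, ...) {
  cat("<rule_comparison>\nPer-rule mean +/- SD (%):\n")
  print(x$summary, row.names = FALSE, digits = 4)
  cat("Pairwise mean differences (percentage points):\n")
  print(x$deltas, row.names = FALSE)
  if (!is.null(x$tests)) {
    for (m in names(x$tests)) {
      cat(sprintf("%s: ANOVA p = %.4g [%s]\n", m, x$tests[[m]]$anova$p,
                  x$tests[[m]]$anova$label))
    }
  }
  invisible(x)
}

#' Stratified false-negative error analysis
#'
#' Evaluates every AUT under one rule (center hit by default, the
#' convention for error analysis) and tabulates per-type miss rates, the
#' type x size-bin refinement, and the most-missed heatmap counts.
#'
#' @inheritParams compare_rules
#' @param rule single rule for the analysis.
#' @return List with `by_type`, `by_type_bin` ([miss_rate_by_type()]
#'   tables) and `heatmap` ([most_missed_per_bin()]).
#' @export
error_analysis <- function(cases, predictions_by_aut, rule = "center_hit",
                           match_order = "size", type_scope = "all") {
  rule <- as_match_rule(rule)
  results_by_aut <- lapply(predictions_by_aut, function(preds)
    evaluate_aut(cases, preds, rule, match_order, type_scope)$results)
  list(by_type = miss_rate_by_type(results_by_aut, cases, by = "type"),
       by_type_bin = miss_rate_by_type(results_by_aut, cases, by = "type_bin"),
       heatmap = most_missed_per_bin(results_by_aut, cases))
}

#' Write evaluation metrics to JSON
#'
#' @param x an `evaluation`, `rule_comparison`, or any list serialisable by
#'   jsonlite.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(x, path) {
  payload <- if (inherits(x, "evaluation")) {
    list(rule = x$rule$kind, metrics = unclass(x$metrics))
  } else if (inherits(x, "rule_comparison")) {
    list(summary = x$summary, deltas = x$deltas,
         relative_differences = x$relative_differences,
         baseline = x$baseline,
         tests = if (is.null(x$tests)) NULL else lapply(x$tests, function(tc)
           list(anova = tc$anova, pairs = tc$pairs)))
  } else x
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Write a miss-rate table or heatmap to CSV
#'
#' @param x a `miss_rate_table` or heatmap data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
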