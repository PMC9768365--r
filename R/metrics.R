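# Detection metrics, aggregation across AUTs, stratified miss rates, and
# the relative-difference statistic.
#
# Within one AUT, counts are pooled over cases before ratios are taken
# (micro-averaging); the mean +/- SD across AUTs is then computed over the
# per-AUT pooled metrics.  The SD uses the sample (n-1) denominator.

#' Compute recall / precision / F1 from match results
#'
#' Pools TP/FP/FN counts over the supplied per-case [match_case()] results
#' (micro-averaging), then applies
#' `recall = TP/(TP+FN)`, `precision = TP/(TP+FP)`,
#' `F1 = 2 * precision * recall / (precision + recall)`.
#' Zero denominators yield 0, so the metrics are total on degenerate input.
#'
#' @param results list of `match_result` objects covering disjoint cases for
#'   one AUT under one rule, or a single `match_result`.
#' @return Object of class `metric_set`: list with integer `tp`, `fp`, `fn`
#'   and numeric `recall`, `precision`, `f1`.
#' @export
#' @examples
#' metric_set(tp = 3, fp = 2, fn = 1)
compute_metrics <- function(results) {
  if (inherits(results, "match_result")) results <- list(results)
  stopifnot(length(results) >= 1L)
  case_ids <- vapply(results, function(r) r$case_id, character(1))
  if (anyDuplicated(case_ids[!is.na(case_ids)])) {
    stop("compute_metrics: results cover overlapping cases", call. = FALSE)
  }
  metric_set(tp = sum(vapply(results, function(r) r$tp, numeric(1))),
             fp = sum(vapply(results, function(r) r$fp, numeric(1))),
             fn = sum(vapply(results, function(r) r$fn, numeric(1))))
}

#' Build a metric set from raw counts
#'
#' @param tp,fp,fn non-negative integer counts.
#' @return Object of class `metric_set`.
#' @export
metric_set <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  recall <- if (tp + fn > 0) tp / (tp + fn) else 0
  precision <- if (tp + fp > 0) tp / (tp + fp) else 0
  f1 <- if (precision + recall > 0)
    2 * precision * recall / (precision + recall) else 0
  structure(list(tp = as.integer(tp), fp = as.integer(fp), fn = as.integer(fn),
                 recall = recall, precision = precision, f1 = f1),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat(sprintf("<metric_set TP %d FP %d FN %d | recall %.4f precision %.4f F1 %.4f>\n",
              x$tp, x$fp, x$fn, x$recall, x$precision, x$f1))
  invisible(x)
}

#' Mean and sample SD of per-AUT metric values
#'
#' The overall performance of a panel of AUTs is summarised as
#' mean +/- standard deviation of the per-AUT (pooled) metric values; the
#' SD uses the sample (n-1) denominator.
#'
#' @param values numeric vector, one value per AUT.
#' @return `list(mean = , sd = )`; with fewer than 2 values an error is
#'   raised (the SD of a single observation is undefined).
#' @export
aggregate_over_auts <- function(values) {
  stopifnot(is.numeric(values))
  if (length(values) < 2L) {
    stop("aggregate_over_auts: need >= 2 per-AUT values for a standard deviation",
         call. = FALSE)
  }
  list(mean = mean(values), sd = stats::sd(values))
}

#' Differences between two rules' mean metrics, in percentage points
#'
#' @param means_a,means_b numeric vectors of mean metric values on the
#'   percent scale (same metrics, same order, same AUT panel and dataset).
#' @return `means_a - means_b`, rounded to 2 decimals (percentage points).
#' @export
#' @examples
#' rule_delta(c(recall = 55.43), c(recall = 54.68))  # 0.75
rule_delta <- function(means_a, means_b) {
  stopifnot(length(means_a) == length(means_b))
  round(means_a - means_b, 2)
}

#' Relative difference in TP count between two rules
#'
#' For one AUT, the change in true-positive count under a compared rule
#' relative to a baseline rule:
#' `RD = (TP_compared - TP_baseline) / TP_baseline`.
#'
#' @param tp_compared,tp_baseline non-negative TP counts;
#'   `tp_baseline > 0` is required.
#' @return A number `>= -1`.
#' @export
relative_difference <- function(tp_compared, tp_baseline) {
  stopifnot(tp_compared >= 0)
  if (tp_baseline <= 0) {
    stop("relative_difference: undefined for a zero baseline TP count",
         call. = FALSE)
  }
  (tp_compared - tp_baseline) / tp_baseline
}

# FN nodule keys (case/nodule) of one AUT's results.
fn_keys_of_results <- function(results) {
  unlist(lapply(results, function(r) {
    if (length(r$fn_ids)) nodule_key(r$case_id, r$fn_ids) else character(0)
  }), use.names = FALSE)
}

# Per-reference bookkeeping table: key, type, bin.
reference_strata <- function(references) {
  refs <- flatten_references(references)
  data.frame(
    key = vapply(refs, function(r) nodule_key(r$case_id, r$nodule_id), character(1)),
    type = factor(vapply(refs, function(r) r$type, character(1)),
                  levels = nodule_types()),
    bin = size_bin_of(vapply(refs, function(r) r$average_diameter_mm, numeric(1))),
    stringsAsFactors = FALSE)
}

#' Per-type (optionally per-size-bin) miss rates across AUTs
#'
#' The miss rate of an AUT on a stratum is the number of its false-negative
#' reference nodules in the stratum divided by the number of reference
#' nodules in the stratum: `1 - recall` restricted to that stratum.  Strata
#' with no reference nodules are undefined (`NA`), never 0.
#'
#' @param results_by_aut named list (AUT label -> list of `match_result`
#'   over all cases, one rule).
#' @param references the reference dataset (list of [case_record()] or of
#'   [reference_nodule()]).
#' @param by `"type"` or `"type_bin"` for the type x size-bin refinement.
#' @return Object of class `miss_rate_table`: a data.frame with the stratum
#'   columns, `n_ref`, one miss-rate column per AUT, and `mean` / `sd`
#'   across AUTs (sample SD; `NA` when undefined).
#' @export
miss_rate_by_type <- function(results_by_aut, references,
                              by = c("type", "type_bin")) {
  by <- match.arg(by)
  stopifnot(is.list(results_by_aut), length(results_by_aut) >= 1L,
            !is.null(names(results_by_aut)))
  strata <- reference_strata(references)
  if (!nrow(strata)) stop("miss_rate_by_type: no reference nodules", call. = FALSE)
  grp <- if (by == "type") list(type = strata$type)
         else list(type = strata$type, bin = strata$bin)
  n_ref <- as.vector(table(interaction(grp, drop = FALSE, lex.order = TRUE)))

  levels_df <- if (by == "type") {
    data.frame(type = factor(nodule_types(), levels = nodule_types()))
  } else {
    expand.grid(bin = factor(size_bins(), levels = size_bins()),
                type = factor(nodule_types(), levels = nodule_types()))[, c("type", "bin")]
  }
  key_of <- function(df) if (by == "type") as.character(df$type)
                         else paste(df$type, df$bin, sep = "\r")
  strat_key <- key_of(strata)
  lvl_key <- key_of(levels_df)
  n_ref <- as.vector(table(factor(strat_key, levels = lvl_key)))

  out <- levels_df
  out$n_ref <- n_ref
  for (aut in names(results_by_aut)) {
    fn_keys <- fn_keys_of_results(results_by_aut[[aut]])
    unknown <- setdiff(fn_keys, strata$key)
    if (length(unknown)) {
      stop(sprintf("miss_rate_by_type: FN nodule(s) absent from references: %s",
                   paste(utils::head(unknown, 3), collapse = ", ")), call. = FALSE)
    }
    fn_n <- as.vector(table(factor(strat_key[match(fn_keys, strata$key)],
                                   levels = lvl_key)))
    out[[aut]] <- ifelse(n_ref > 0, fn_n / n_ref, NA_real_)
  }
  aut_cols <- names(results_by_aut)
  rates <- as.matrix(out[, aut_cols, drop = FALSE])
  out$mean <- rowMeans(rates)
  out$sd <- if (length(aut_cols) >= 2L) apply(rates, 1L, stats::sd) else NA_real_
  class(out) <- c("miss_rate_table", class(out))
  attr(out, "by") <- by
  out
}

#' Most-missed nodule type per size bin, counted over AUTs
#'
#' For each AUT and size bin, finds the nodule type with the highest miss
#' rate among types with defined rates in that bin; that type's cell gains
#' one count.  Exact ties credit every tied type (tied cells are flagged),
#' so column sums can exceed the AUT count only through ties.  Bins with no
#' reference nodules are excluded.
#'
#' @inheritParams miss_rate_by_type
#' @return data.frame, one row per size bin with references: `bin`, one
#'   integer count column per nodule type, and a `ties` column counting
#'   AUT-bin argmax ties.
#' @export
most_missed_per_bin <- function(results_by_aut, references) {
  tb <- miss_rate_by_type(results_by_aut, references, by = "type_bin")
  auts <- names(results_by_aut)
  bins <- size_bins()
  counts <- matrix(0L, nrow = length(bins), ncol = length(nodule_types()),
                   dimnames = list(bins, nodule_types()))
  ties <- integer(length(bins)); names(ties) <- bins
  keep <- logical(length(bins)); names(keep) <- bins
  for (b in bins) {
    sub <- tb[tb$bin == b, , drop = FALSE]
    if (!any(sub$n_ref > 0)) next
    keep[b] <- TRUE
    for (aut in auts) {
      rates <- sub[[aut]]
      if (all(is.na(rates))) next
      top <- max(rates, na.rm = TRUE)
      winners <- as.character(sub$type[!is.na(rates) & rates == top])
      counts[b, winners] <- counts[b, winners] + 1L
      if (length(winners) > 1L) ties[b] <- ties[b] + 1L
    }
  }
  out <- data.frame(bin = factor(bins[keep], levels = bins),
                    stringsAsFactors = FALSE)
  for (tp in nodule_types()) out[[tp]] <- counts[keep, tp]
  out$ties <- ties[keep]
  rownames(out) <- NULL
  out
}
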