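# Group comparison of mark-labeling rules: one-way ANOVA across rules,
# pairwise two-sample t-tests, and the ns / * / ** significance labels.
#
# Defaults mirror common practice in algorithm-comparison reports: a
# classical fixed-effects ANOVA, Student (pooled-variance) two-sided
# pairwise t-tests without multiplicity correction, treating per-AUT metric
# values under different rules as independent groups.  Welch and paired
# variants are available as switches.

#' One-way fixed-effects ANOVA
#'
#' Classical one-way ANOVA over k groups of per-AUT metric values; the
#' p-value comes from the F distribution with (k-1, N-k) degrees of
#' freedom.  Implemented via [stats::oneway.test()] with equal variances
#' assumed.
#'
#' @param groups list of >= 2 numeric vectors, each with >= 2 values.
#' @return `list(F = , p = , df = c(between, within))`.
#' @export
#' @examples
#' one_way_anova(list(c(1, 2), c(3, 4), c(5, 6)))  # F = 16 on (2, 3) df
one_way_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2L)
  sizes <- lengths(groups)
  if (any(sizes < 2L)) {
    stop("one_way_anova: every group needs >= 2 values", call. = FALSE)
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), sizes))
  if (stats::var(values) == 0) {
    # all observations identical: no variance to partition
    return(list(F = 0, p = 1,
                df = c(length(groups) - 1L, length(values) - length(groups))))
  }
  ht <- stats::oneway.test(values ~ g, var.equal = TRUE)
  list(F = unname(ht$statistic), p = unname(ht$p.value),
       df = unname(ht$parameter))
}

#' Two-sample t-test
#'
#' Two-sided t-test between two groups of per-AUT values.  The default is
#' Student's pooled-variance test; `welch = TRUE` drops the equal-variance
#' assumption and `paired = TRUE` pairs observations by position (the AUT
#' panel is identical across rule groups, so pairing is defensible, but the
#' unpaired test is the default reporting convention here).
#'
#' Degenerate input (zero variance in both groups) yields `t = 0, p = 1`
#' when the means agree; when they differ the result is flagged
#' `degenerate` with `p = 0`.
#'
#' @param a,b numeric vectors with >= 2 values each.
#' @param welch use the Welch unequal-variance test.
#' @param paired paired test (requires equal lengths).
#' @return `list(t = , p = , df = , degenerate = logical)`.
#' @export
two_sample_t <- function(a, b, welch = FALSE, paired = FALSE) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) >= 2L, length(b) >= 2L)
  if (paired && length(a) != length(b)) {
    stop("two_sample_t: paired test needs equal-length groups", call. = FALSE)
  }
  degenerate_var <- if (paired) stats::var(a - b) == 0 else
    (stats::var(a) == 0 && stats::var(b) == 0)
  if (degenerate_var) {
    if (isTRUE(all.equal(mean(a), mean(b)))) {
      return(list(t = 0, p = 1,
                  df = if (paired) length(a) - 1L else length(a) + length(b) - 2L,
                  degenerate = FALSE))
    }
    return(list(t = sign(mean(a) - mean(b)) * Inf, p = 0,
                df = if (paired) length(a) - 1L else length(a) + length(b) - 2L,
                degenerate = TRUE))
  }
  ht <- stats::t.test(a, b, var.equal = !welch, paired = paired)
  list(t = unname(ht$statistic), p = unname(ht$p.value),
       df = unname(ht$parameter), degenerate = FALSE)
}

#' Significance label for a p-value
#'
#' `**` when p <= 0.01, `*` when 0.01 < p <= 0.05, `ns` when p > 0.05
#' (boundaries inclusive on the significant side).
#'
#' @param p numeric p-value(s) in `[0, 1]`; vectorised.
#' @return Character vector of labels.
#' @export
#' @examples
#' significance_label(c(0.8503, 0.0120, 0.0075))  # "ns" "*" "**"
significance_label <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    stop("significance_label: p must lie in [0, 1]", call. = FALSE)
  }
  ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", "ns"))
}

#' Compare metric values across rule groups
#'
#' Runs the one-way ANOVA over all groups plus every pairwise t-test, with
#' significance labels attached.
#'
#' @param groups named list of numeric vectors (rule label -> per-AUT
#'   metric values); all groups must have the same length (same AUT panel).
#' @inheritParams two_sample_t
#' @return Object of class `group_comparison`: list with `anova`
#'   (`list(F, p, df, label)`) and `pairs` (data.frame `a`, `b`, `t`, `p`,
#'   `label`).
#' @export
compare_groups <- function(groups, welch = FALSE, paired = FALSE) {
  stopifnot(is.list(groups), length(groups) >= 2L, !is.null(names(groups)))
  if (length(unique(lengths(groups))) != 1L) {
    stop("compare_groups: all groups must cover the same AUT panel",
         call. = FALSE)
  }
  av <- one_way_anova(groups)
  av$label <- significance_label(av$p)
  combs <- utils::combn(names(groups), 2L)
  pairs <- do.call(rbind, lapply(seq_len(ncol(combs)), function(i) {
    a <- combs[1L, i]; b <- combs[2L, i]
    tt <- two_sample_t(groups[[a]], groups[[b]], welch = welch, paired = paired)
    data.frame(a = a, b = b, t = tt$t, p = tt$p,
               label = significance_label(tt$p),
               degenerate = tt$degenerate, stringsAsFactors = FALSE)
  }))
  structure(list(anova = av, pairs = pairs,
                 welch = welch, paired = paired),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison: ANOVA F = %.4g, p = %.4g [%s]>\n",
              x$anova$F, x$anova$p, x$anova$label))
  print(x$pairs, row.names = FALSE)
  invisible(x)
}
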