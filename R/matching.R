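# Mark-labeling rules and the greedy one-to-one matching procedure.
#
# A predicted nodule matches a reference nodule when at least one shared
# slice succeeds under the selected rule:
#   center_hit      - predicted box center lies inside the reference box
#                     (closed region: the boundary counts as inside)
#   center_distance - in-plane mm distance between box centers is strictly
#                     below the reference nodule's adaptive radius,
#                     max over slices of (long + short diameter) / 4
#   area_overlap    - |pred n ref| / |ref| strictly above the threshold
#                     (default 0.5)
# Ties at a threshold are failures (strict inequalities), documented as
# bit-exact behavior.

#' Define a mark-labeling rule
#'
#' @param kind one of `"center_hit"`, `"center_distance"`, `"area_overlap"`.
#' @param overlap_threshold overlap fraction threshold in (0, 1]; used only
#'   by the area-overlap rule.  Default 0.5.
#' @return Object of class `match_rule`.
#' @export
#' @examples
#' match_rule("area_overlap", overlap_threshold = 0.5)
match_rule <- function(kind = c("center_hit", "center_distance", "area_overlap"),
                       overlap_threshold = 0.5) {
  kind <- match.arg(kind)
  stopifnot(length(overlap_threshold) == 1L,
            overlap_threshold > 0, overlap_threshold <= 1)
  structure(list(kind = kind,
                 overlap_threshold = as.numeric(overlap_threshold)),
            class = "match_rule")
}

#' @export
print.match_rule <- function(x, ...) {
  extra <- if (x$kind == "area_overlap")
    sprintf(", threshold %g", x$overlap_threshold) else ""
  cat(sprintf("<match_rule %s%s>\n", x$kind, extra))
  invisible(x)
}

as_match_rule <- function(rule) {
  if (inherits(rule, "match_rule")) rule else match_rule(rule)
}

#' Adaptive matching radius of a reference nodule
#'
#' The center-distance rule compares the predicted-to-reference center
#' distance with a per-nodule threshold: the maximum over annotated slices
#' of one quarter of the sum of the long and short diameters (an average
#' radius), in mm.
#'
#' @param ref a [reference_nodule()].
#' @return Radius in mm.
#' @export
#' @examples
#' # slices with (long, short) = (8, 6) and (10, 6) mm -> max(3.5, 4) = 4 mm
matching_radius_mm <- function(ref) {
  max((ref$slices$long_diameter_mm + ref$slices$short_diameter_mm) / 4)
}

#' Largest annotated slice of a reference nodule
#'
#' @param ref a [reference_nodule()].
#' @return One-row data.frame: the slice with maximal box area (ties broken
#'   toward the lowest `slice_index`).
#' @export
largest_slice <- function(ref) {
  s <- ref$slices
  areas <- (s$x_max - s$x_min) * (s$y_max - s$y_min)
  s[which.max(areas), , drop = FALSE]  # which.max takes the first maximum
}

#' Per-slice match success under a rule
#'
#' Evaluates one (reference slice, predicted box) pair sharing a slice
#' index.  Also returns the rule's tie-break score: the in-plane center
#' distance in mm for the center rules (smaller is better), the overlap
#' fraction for the area rule (larger is better).
#'
#' @param rule a [match_rule()] or rule-kind string.
#' @param ref the [reference_nodule()] owning `ref_slice` (needed for the
#'   adaptive radius).
#' @param ref_slice one row of `ref$slices`.
#' @param pred_box a box (list/row with the box fields) on the same slice.
#' @param pixel_spacing_mm `c(row, col)` spacing in mm.
#' @return `list(success = logical, score = numeric)`.
#' @export
slice_success <- function(rule, ref, ref_slice, pred_box, pixel_spacing_mm) {
  rule <- as_match_rule(rule)
  if (ref_slice$slice_index != pred_box$slice_index) {
    stop("slice_success: reference slice and predicted box are on different slices",
         call. = FALSE)
  }
  switch(rule$kind,
    center_hit = {
      ctr <- box_center(pred_box)
      ok <- ctr[["x"]] >= ref_slice$x_min && ctr[["x"]] <= ref_slice$x_max &&
            ctr[["y"]] >= ref_slice$y_min && ctr[["y"]] <= ref_slice$y_max
      list(success = ok,
           score = center_distance_mm(pred_box, ref_slice, pixel_spacing_mm))
    },
    center_distance = {
      d <- center_distance_mm(pred_box, ref_slice, pixel_spacing_mm)
      list(success = d < matching_radius_mm(ref), score = d)
    },
    area_overlap = {
      f <- overlap_fraction(pred_box, ref_slice)
      list(success = f > rule$overlap_threshold, score = f)
    })
}

# Vectorised slice-pair evaluation over the shared slices of (ref, pred).
# Returns a data.frame(slice_index, success, score); zero rows when the two
# objects share no slice.
shared_slice_outcomes <- function(rule, ref, pred, pixel_spacing_mm) {
  shared <- intersect(ref$slices$slice_index, pred$boxes$slice_index)
  if (!length(shared)) {
    return(data.frame(slice_index = integer(0), success = logical(0),
                      score = numeric(0)))
  }
  rs <- ref$slices[match(shared, ref$slices$slice_index), , drop = FALSE]
  pb <- pred$boxes[match(shared, pred$boxes$slice_index), , drop = FALSE]
  sp_row <- pixel_spacing_mm[[1L]]; sp_col <- pixel_spacing_mm[[2L]]
  cx_p <- (pb$x_min + pb$x_max) / 2; cy_p <- (pb$y_min + pb$y_max) / 2
  cx_r <- (rs$x_min + rs$x_max) / 2; cy_r <- (rs$y_min + rs$y_max) / 2
  dist_mm <- sqrt(((cx_p - cx_r) * sp_col)^2 + ((cy_p - cy_r) * sp_row)^2)
  out <- switch(rule$kind,
    center_hit = {
      ok <- cx_p >= rs$x_min & cx_p <= rs$x_max &
            cy_p >= rs$y_min & cy_p <= rs$y_max
      data.frame(slice_index = shared, success = ok, score = dist_mm)
    },
    center_distance = {
      r_mm <- matching_radius_mm(ref)
      data.frame(slice_index = shared, success = dist_mm < r_mm,
                 score = dist_mm)
    },
    area_overlap = {
      inter <- intersect_area_vec(pb$x_min, pb$y_min, pb$x_max, pb$y_max,
                                  rs$x_min, rs$y_min, rs$x_max, rs$y_max)
      frac <- inter / ((rs$x_max - rs$x_min) * (rs$y_max - rs$y_min))
      data.frame(slice_index = shared, success = frac > rule$overlap_threshold,
                 score = frac)
    })
  out
}

#' Nodule-level match success
#'
#' A predicted nodule successfully detects a reference nodule when at least
#' one slice shared by the two box stacks succeeds under the rule.  The best
#' score over succeeding slice pairs is returned: minimum center distance
#' for the center rules, maximum overlap fraction for the area rule.  Zero
#' shared slices is a failure, never an error.
#'
#' @inheritParams slice_success
#' @param pred a [predicted_nodule()] from the same case.
#' @return `list(success = logical, score = numeric)`; `score` is `NA` on
#'   failure.
#' @export
nodule_success <- function(rule, ref, pred, pixel_spacing_mm) {
  rule <- as_match_rule(rule)
  if (!identical(ref$case_id, pred$case_id)) {
    stop("nodule_success: reference and prediction belong to different cases",
         call. = FALSE)
  }
  oc <- shared_slice_outcomes(rule, ref, pred, pixel_spacing_mm)
  ok <- oc$success
  if (!any(ok)) return(list(success = FALSE, score = NA_real_))
  score <- if (rule$kind == "area_overlap") max(oc$score[ok]) else min(oc$score[ok])
  list(success = TRUE, score = score)
}

# Center-hit tie-break: in-plane mm distance between the candidate
# prediction and the reference's largest slice.  The candidate's box at that
# slice index is used when present; otherwise its box on the slice nearest
# to it (ties toward the lower slice, since boxes are sorted ascending).
center_hit_tiebreak <- function(ref, pred, pixel_spacing_mm) {
  ls <- largest_slice(ref)
  i <- match(ls$slice_index, pred$boxes$slice_index)
  if (is.na(i)) i <- which.min(abs(pred$boxes$slice_index - ls$slice_index))
  center_distance_mm(pred$boxes[i, , drop = FALSE], ls, pixel_spacing_mm)
}

#' Order reference nodules for matching
#'
#' The greedy matching pass visits reference nodules in a deterministic
#' canonical order.  The default, `"size"`, sorts by descending
#' largest-slice box area with ties broken by ascending `nodule_id`, so a
#' large nodule cannot have its prediction consumed by a small neighbour
#' earlier in the queue.  `"id"` sorts by `nodule_id` alone; `"file"` keeps
#' the order given.
#'
#' @param refs list of [reference_nodule()].
#' @param match_order `"size"`, `"id"` or `"file"`.
#' @return The reordered list.
#' @export
order_references <- function(refs, match_order = c("size", "id", "file")) {
  match_order <- match.arg(match_order)
  if (match_order == "file" || length(refs) < 2L) return(refs)
  ids <- vapply(refs, function(r) r$nodule_id, character(1))
  if (match_order == "id") return(refs[order(ids)])
  areas <- vapply(refs, function(r) {
    s <- largest_slice(r)
    (s$x_max - s$x_min) * (s$y_max - s$y_min)
  }, numeric(1))
  refs[order(-areas, ids)]
}

#' Match one case's predictions against its reference nodules
#'
#' Implements the greedy, order-driven, one-to-one matching procedure.
#' Reference nodules are visited in the canonical matching order; for each,
#' the candidate set is every still-unmatched predicted nodule whose
#' [nodule_success()] holds.  No candidate makes the reference a false
#' negative.  Otherwise the candidate with the best tie-break score is
#' assigned as the true positive and leaves the pool, so the remaining
#' predictions go on to compete for later reference nodules.  After the
#' pass, every unassigned prediction is a false positive.
#'
#' Tie-break scores: under center hit, the in-plane center distance (mm) to
#' the reference's largest slice; under center distance, the smallest
#' succeeding center distance; under area overlap, the largest overlap
#' fraction.  Candidates with exactly equal scores fall back to the lowest
#' `pred_id`.
#'
#' @param refs list of [reference_nodule()] for one case.
#' @param preds list of [predicted_nodule()] for the same case.
#' @param rule a [match_rule()] or rule-kind string.
#' @param pixel_spacing_mm `c(row, col)` spacing in mm.
#' @param match_order see [order_references()].
#' @return Object of class `match_result`: list with `rule`, `case_id`,
#'   `assignments` (data.frame `nodule_id`, `pred_id`, `tiebreak_score`),
#'   `fn_ids`, `fp_ids`, and counts `tp`, `fn`, `fp`.
#' @export
#' @examples
#' ref <- reference_nodule("c1", "n1", "solid",
#'   data.frame(slice_index = 10, x_min = 100, y_min = 100,
#'              x_max = 110, y_max = 110,
#'              long_diameter_mm = 7, short_diameter_mm = 7), 7)
#' prd <- predicted_nodule("c1", "p1",
#'   data.frame(slice_index = 10, x_min = 101, y_min = 99,
#'              x_max = 111, y_max = 109))
#' match_case(list(ref), list(prd), "center_hit", c(0.7, 0.7))
match_case <- function(refs, preds, rule, pixel_spacing_mm = c(0.7, 0.7),
                       match_order = c("size", "id", "file")) {
  rule <- as_match_rule(rule)
  case_ids <- unique(c(vapply(refs, function(r) r$case_id, character(1)),
                       vapply(preds, function(p) p$case_id, character(1))))
  if (length(case_ids) > 1L) {
    stop("match_case: objects from multiple cases: ",
         paste(case_ids, collapse = ", "), call. = FALSE)
  }
  refs <- order_references(refs, match_order)
  pred_ids <- vapply(preds, function(p) p$pred_id, character(1))
  if (anyDuplicated(pred_ids)) {
    stop("match_case: duplicate pred_id within case", call. = FALSE)
  }
  unmatched <- rep(TRUE, length(preds))
  assignments <- vector("list", length(refs))
  fn_ids <- character(0)

  for (k in seq_along(refs)) {
    ref <- refs[[k]]
    cand_idx <- which(unmatched)
    if (!length(cand_idx)) {
      fn_ids <- c(fn_ids, ref$nodule_id)
      next
    }
    succ <- logical(length(cand_idx))
    score <- numeric(length(cand_idx))
    for (j in seq_along(cand_idx)) {
      ns <- nodule_success(rule, ref, preds[[cand_idx[j]]], pixel_spacing_mm)
      succ[j] <- ns$success
      score[j] <- if (!ns$success) NA_real_
        else if (rule$kind == "center_hit")
          center_hit_tiebreak(ref, preds[[cand_idx[j]]], pixel_spacing_mm)
        else ns$score
    }
    hit <- cand_idx[succ]
    if (!length(hit)) {
      fn_ids <- c(fn_ids, ref$nodule_id)
      next
    }
    sc <- score[succ]
    best <- if (rule$kind == "area_overlap") {
      # larger overlap wins; exact ties -> lowest pred_id
      tied <- hit[sc == max(sc)]
      tied[order(pred_ids[tied])][1L]
    } else {
      tied <- hit[sc == min(sc)]
      tied[order(pred_ids[tied])][1L]
    }
    assignments[[k]] <- data.frame(
      nodule_id = ref$nodule_id, pred_id = pred_ids[best],
      tiebreak_score = sc[match(best, hit)], stringsAsFactors = FALSE)
    unmatched[best] <- FALSE
  }

  assignments <- Filter(Negate(is.null), assignments)
  assignments <- if (length(assignments)) do.call(rbind, assignments) else
    data.frame(nodule_id = character(0), pred_id = character(0),
               tiebreak_score = numeric(0), stringsAsFactors = FALSE)
  rownames(assignments) <- NULL
  structure(list(rule = rule,
                 case_id = if (length(case_ids)) case_ids else NA_character_,
                 assignments = assignments,
                 fn_ids = fn_ids,
                 fp_ids = sort(pred_ids[unmatched]),
                 tp = nrow(assignments),
                 fn = length(fn_ids),
                 fp = sum(unmatched)),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result %s [%s]: TP %d, FN %d, FP %d>\n",
              x$case_id, x$rule$kind, x$tp, x$fn, x$fp))
  invisible(x)
}

#' Restrict a case to a detectable-type scope before matching
#'
#' Some AUTs only claim a subset of the six nodule types (e.g. the four
#' intrapulmonary types, excluding pleural findings).  Under a type scope,
#' out-of-scope reference nodules are excluded from TP/FN accounting, and
#' predictions that would have matched an excluded reference are dropped
#' rather than being counted as false positives: the AUT is neither credited
#' nor penalised for findings outside its claim.
#'
#' @param refs,preds one case's reference and predicted nodules.
#' @param type_scope `"all"` or a character vector of in-scope
#'   [nodule_types()].
#' @param rule,pixel_spacing_mm,match_order as in [match_case()]; the rule
#'   decides which predictions are absorbed by excluded references.
#' @return `list(refs = , preds = )`, both filtered.
#' @export
apply_type_scope <- function(refs, preds, type_scope, rule,
                             pixel_spacing_mm = c(0.7, 0.7),
                             match_order = "size") {
  if (identical(type_scope, "all") || is.null(type_scope)) {
    return(list(refs = refs, preds = preds))
  }
  assert_nodule_type(type_scope)
  in_scope <- vapply(refs, function(r) r$type %in% type_scope, logical(1))
  excluded <- refs[!in_scope]
  if (length(excluded) && length(preds)) {
    absorbed <- match_case(excluded, preds, rule, pixel_spacing_mm, match_order)
    drop_ids <- absorbed$assignments$pred_id
    preds <- Filter(function(p) !(p$pred_id %in% drop_ids), preds)
  }
  list(refs = refs[in_scope], preds = preds)
}
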