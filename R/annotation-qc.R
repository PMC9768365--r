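# Annotator qualification scoring and three-reader consensus merging for
# reference-standard construction.

#' Dice coefficient between two multi-slice regions
#'
#' Segmentation-agreement statistic `2 |A n B| / (|A| + |B|)`.  Regions are
#' per-slice pixel areas (bounding boxes here; polygon boundaries are an
#' annotation-side refinement this package does not require): the
#' intersection is summed over slices present in both regions, and each
#' region's total area over all of its own slices.
#'
#' @param region_a,region_b data.frames of per-slice boxes (`slice_index`,
#'   `x_min`, `y_min`, `x_max`, `y_max`), or [reference_nodule()] /
#'   [predicted_nodule()] objects.
#' @return A number in `[0, 1]`; errors when both regions are empty.
#' @export
dice_coefficient <- function(region_a, region_b) {
  a <- region_boxes(region_a)
  b <- region_boxes(region_b)
  area_a <- sum((a$x_max - a$x_min) * (a$y_max - a$y_min))
  area_b <- sum((b$x_max - b$x_min) * (b$y_max - b$y_min))
  if (area_a + area_b == 0) {
    stop("dice_coefficient: both regions are empty", call. = FALSE)
  }
  shared <- intersect(a$slice_index, b$slice_index)
  inter <- 0
  if (length(shared)) {
    ai <- a[match(shared, a$slice_index), , drop = FALSE]
    bi <- b[match(shared, b$slice_index), , drop = FALSE]
    inter <- sum(intersect_area_vec(ai$x_min, ai$y_min, ai$x_max, ai$y_max,
                                    bi$x_min, bi$y_min, bi$x_max, bi$y_max))
  }
  2 * inter / (area_a + area_b)
}

region_boxes <- function(x) {
  if (inherits(x, "reference_nodule")) return(x$slices)
  if (inherits(x, "predicted_nodule")) return(x$boxes)
  stopifnot(is.data.frame(x))
  x
}

# Reference-nodule list -> predicted-nodule list, so an annotation set can
# stand on the "prediction" side of match_case.
as_predictions <- function(refs) {
  lapply(refs, function(r) {
    predicted_nodule(r$case_id, r$nodule_id,
                     r$slices[, c("slice_index", "x_min", "y_min",
                                  "x_max", "y_max")])
  })
}

#' Score an annotation candidate against an expert panel
#'
#' Qualification exam scoring: the candidate's annotations are matched
#' against the expert panel's per case (candidate on the prediction side),
#' giving detection precision and recall; the Dice coefficient is averaged
#' over matched pairs.  The gate is strict: a candidate passes only with
#' precision > 0.8 AND recall > 0.8 AND Dice > 0.8 — exactly 0.8 on any
#' criterion fails.
#'
#' @param candidate,expert named lists (case_id -> list of
#'   [reference_nodule()]); `expert` must be non-empty.
#' @param rule mark-labeling rule used for detection matching (default
#'   center hit).
#' @param pixel_spacing_mm `c(row, col)` spacing in mm.
#' @param threshold passing threshold applied (strictly) to all three
#'   scores.
#' @return Object of class `qualification_result`: list with `precision`,
#'   `recall`, `dice`, `passed`, and the underlying counts.
#' @export
qualify_annotator <- function(candidate, expert, rule = "center_hit",
                              pixel_spacing_mm = c(0.7, 0.7),
                              threshold = 0.8) {
  rule <- as_match_rule(rule)
  if (!length(expert) || !length(flatten_references(expert))) {
    stop("qualify_annotator: expert annotation set is empty", call. = FALSE)
  }
  all_cases <- union(names(expert), names(candidate))
  tp <- fp <- fn <- 0L
  dice_values <- numeric(0)
  for (cid in all_cases) {
    exp_refs <- expert[[cid]] %||% list()
    cand_refs <- candidate[[cid]] %||% list()
    cand_preds <- as_predictions(cand_refs)
    res <- match_case(exp_refs, cand_preds, rule, pixel_spacing_mm)
    tp <- tp + res$tp; fp <- fp + res$fp; fn <- fn + res$fn
    if (res$tp > 0) {
      exp_ids <- vapply(exp_refs, function(r) r$nodule_id, character(1))
      cand_ids <- vapply(cand_refs, function(r) r$nodule_id, character(1))
      for (i in seq_len(nrow(res$assignments))) {
        e <- exp_refs[[match(res$assignments$nodule_id[i], exp_ids)]]
        cnd <- cand_refs[[match(res$assignments$pred_id[i], cand_ids)]]
        dice_values <- c(dice_values, dice_coefficient(cnd, e))
      }
    }
  }
  m <- metric_set(tp = tp, fp = fp, fn = fn)
  dice <- if (length(dice_values)) mean(dice_values) else 0
  structure(list(precision = m$precision, recall = m$recall, dice = dice,
                 passed = m$precision > threshold && m$recall > threshold &&
                          dice > threshold,
                 tp = tp, fp = fp, fn = fn, threshold = threshold),
            class = "qualification_result")
}

#' @export
print.qualification_result <- function(x, ...) {
  cat(sprintf("<qualification_result precision %.3f recall %.3f dice %.3f -> %s>\n",
              x$precision, x$recall, x$dice,
              if (x$passed) "PASSED" else "FAILED"))
  invisible(x)
}

#' Merge three readers' back-to-back annotations of one case
#'
#' Consistency check and union merge for the three-junior-reader annotation
#' step.  Nodules are "consistent" when all three readers detected the same
#' finding: detections are paired between every two readers by one-to-one
#' matching under the rule, pairs are grouped transitively, and a group
#' qualifies only if it holds exactly one nodule from each reader with all
#' three pairwise matches present.  Each consistent group is merged into a
#' single nodule whose per-slice geometry is the union (enclosing box) of
#' the readers' boxes.  Every slice of every detection outside a consistent
#' group is flagged for senior-expert review; arbitration itself is a
#' manual act downstream.
#'
#' @param readers list of exactly 3 annotation sets for the *same* case,
#'   each a list of [reference_nodule()].
#' @param rule mark-labeling rule for pairwise matching (default center
#'   hit).
#' @param pixel_spacing_mm `c(row, col)` spacing in mm.
#' @return Object of class `consensus_output`: list with `merged` (list of
#'   [reference_nodule()], ids `m1`, `m2`, ... in reader-1 nodule order)
#'   and `flags` (data.frame `case_id`, `slice_index`, `reason`).
#' @export
consensus_merge <- function(readers, rule = "center_hit",
                            pixel_spacing_mm = c(0.7, 0.7)) {
  if (length(readers) != 3L) {
    stop("consensus_merge: exactly 3 readers are required", call. = FALSE)
  }
  rule <- as_match_rule(rule)
  case_ids <- unique(unlist(lapply(readers, function(set)
    vapply(set, function(r) r$case_id, character(1)))))
  if (length(case_ids) > 1L) {
    stop("consensus_merge: readers annotate different cases", call. = FALSE)
  }

  # Node table: one row per (reader, nodule).
  nodes <- do.call(rbind, lapply(seq_len(3L), function(k) {
    set <- readers[[k]]
    if (!length(set)) return(NULL)
    data.frame(reader = k,
               idx = seq_along(set),
               nodule_id = vapply(set, function(r) r$nodule_id, character(1)),
               stringsAsFactors = FALSE)
  }))
  if (is.null(nodes) || !nrow(nodes)) {
    return(structure(list(merged = list(),
                          flags = data.frame(case_id = character(0),
                                             slice_index = integer(0),
                                             reason = character(0))),
                     class = "consensus_output"))
  }
  node_id <- function(reader, nid) paste(reader, nid, sep = "\r")
  nodes$key <- node_id(nodes$reader, nodes$nodule_id)

  # Pairwise one-to-one matching between reader pairs; collect edges.
  edges <- list()
  for (pair in list(c(1L, 2L), c(1L, 3L), c(2L, 3L))) {
    i <- pair[1L]; j <- pair[2L]
    res <- match_case(readers[[i]], as_predictions(readers[[j]]), rule,
                      pixel_spacing_mm)
    if (nrow(res$assignments)) {
      edges[[length(edges) + 1L]] <- data.frame(
        from = node_id(i, res$assignments$nodule_id),
        to = node_id(j, res$assignments$pred_id),
        stringsAsFactors = FALSE)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0))

  # Transitive grouping by union-find over match edges.
  parent <- stats::setNames(nodes$key, nodes$key)
  find_root <- function(x) {
    while (parent[[x]] != x) {
      parent[[x]] <<- parent[[parent[[x]]]]
      x <- parent[[x]]
    }
    x
  }
  for (i in seq_len(nrow(edges))) {
    ra <- find_root(edges$from[i]); rb <- find_root(edges$to[i])
    if (ra != rb) parent[[ra]] <- rb
  }
  nodes$group <- vapply(nodes$key, find_root, character(1))

  edge_key <- paste(edges$from, edges$to, sep = "\t")
  merged <- list()
  flagged_nodes <- character(0)
  for (g in unique(nodes$group)) {
    members <- nodes[nodes$group == g, , drop = FALSE]
    consistent <- nrow(members) == 3L &&
      setequal(members$reader, 1:3) && nrow(edges) >= 3L && {
        k <- function(i, j) paste(members$key[members$reader == i],
                                  members$key[members$reader == j], sep = "\t")
        all(c(k(1, 2), k(1, 3), k(2, 3)) %in% edge_key)
      }
    if (consistent) {
      parts <- lapply(1:3, function(r)
        readers[[r]][[members$idx[members$reader == r]]])
      merged[[length(merged) + 1L]] <- merge_nodule_union(parts, case_ids)
    } else {
      flagged_nodes <- c(flagged_nodes, members$key)
    }
  }
  # Stable merged ids, ordered by reader-1 member where present.
  if (length(merged)) {
    ord <- order(vapply(merged, function(m) m$nodule_id, character(1)))
    merged <- merged[ord]
    for (i in seq_along(merged)) merged[[i]]$nodule_id <- sprintf("m%d", i)
  }

  flags <- if (length(flagged_nodes)) {
    rows <- nodes[nodes$key %in% flagged_nodes, , drop = FALSE]
    fl <- do.call(rbind, lapply(seq_len(nrow(rows)), function(i) {
      nod <- readers[[rows$reader[i]]][[rows$idx[i]]]
      data.frame(case_id = nod$case_id,
                 slice_index = nod$slices$slice_index,
                 reason = sprintf("reader %d nodule %s not confirmed by all readers",
                                  rows$reader[i], rows$nodule_id[i]),
                 stringsAsFactors = FALSE)
    }))
    fl <- fl[order(fl$slice_index, fl$reason), , drop = FALSE]
    rownames(fl) <- NULL
    fl
  } else {
    data.frame(case_id = character(0), slice_index = integer(0),
               reason = character(0))
  }
  structure(list(merged = merged, flags = flags), class = "consensus_output")
}

# Union (enclosing box per slice) of the same finding annotated by the three
# readers; diameters take the per-slice maxima, type the readers' majority
# label (classification is re-done downstream, but the merge must carry a
# valid label).
merge_nodule_union <- function(parts, case_id) {
  first <- parts[[order(vapply(parts, function(p) p$nodule_id, character(1)))[1L]]]
  all_slices <- sort(unique(unlist(lapply(parts, function(p) p$slices$slice_index))))
  rows <- lapply(all_slices, function(si) {
    have <- Filter(function(p) si %in% p$slices$slice_index, parts)
    sl <- do.call(rbind, lapply(have, function(p)
      p$slices[p$slices$slice_index == si, , drop = FALSE]))
    data.frame(slice_index = si,
               x_min = min(sl$x_min), y_min = min(sl$y_min),
               x_max = max(sl$x_max), y_max = max(sl$y_max),
               long_diameter_mm = max(sl$long_diameter_mm),
               short_diameter_mm = max(sl$short_diameter_mm))
  })
  types <- vapply(parts, function(p) p$type, character(1))
  type <- names(sort(table(types), decreasing = TRUE))[1L]
  reference_nodule(parts[[1L]]$case_id, first$nodule_id, type,
                   do.call(rbind, rows),
                   mean(vapply(parts, function(p) p$average_diameter_mm,
                               numeric(1))))
}

#' Write consensus flags to CSV
#'
#' Schema: `case_id,slice_index,reason`.
#'
#' @param consensus a `consensus_output` from [consensus_merge()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_flags_csv <- function(consensus, path) {
  utils::write.csv(consensus$flags, path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
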