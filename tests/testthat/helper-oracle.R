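# Independent brute-force oracle for the matching procedure: an explicit,
# naive walk through the matching flowchart, written with scalar loops and
# its own geometry arithmetic.  Deliberately shares no code with the
# package internals.

oracle_center <- function(b) c((b$x_min + b$x_max) / 2, (b$y_min + b$y_max) / 2)

oracle_dist_mm <- function(a, b, spacing) {
  ca <- oracle_center(a); cb <- oracle_center(b)
  sqrt(((ca[1] - cb[1]) * spacing[2])^2 + ((ca[2] - cb[2]) * spacing[1])^2)
}

oracle_radius_mm <- function(ref) {
  best <- -Inf
  for (i in seq_len(nrow(ref$slices))) {
    v <- (ref$slices$long_diameter_mm[i] + ref$slices$short_diameter_mm[i]) / 4
    if (v > best) best <- v
  }
  best
}

oracle_pair_success <- function(kind, ref, pred, spacing, thr) {
  # Returns list(success, score): min distance / max fraction over
  # succeeding shared slices, NA when no shared slice succeeds.
  best <- NA_real_
  ok <- FALSE
  for (i in seq_len(nrow(ref$slices))) {
    si <- ref$slices$slice_index[i]
    j <- which(pred$boxes$slice_index == si)
    if (!length(j)) next
    rb <- ref$slices[i, ]; pb <- pred$boxes[j, ]
    if (kind == "center_hit") {
      ctr <- oracle_center(pb)
      hit <- ctr[1] >= rb$x_min && ctr[1] <= rb$x_max &&
             ctr[2] >= rb$y_min && ctr[2] <= rb$y_max
      if (hit) {
        d <- oracle_dist_mm(pb, rb, spacing)
        if (!ok || d < best) best <- d
        ok <- TRUE
      }
    } else if (kind == "center_distance") {
      d <- oracle_dist_mm(pb, rb, spacing)
      if (d < oracle_radius_mm(ref)) {
        if (!ok || d < best) best <- d
        ok <- TRUE
      }
    } else {
      ix <- min(pb$x_max, rb$x_max) - max(pb$x_min, rb$x_min)
      iy <- min(pb$y_max, rb$y_max) - max(pb$y_min, rb$y_min)
      inter <- max(0, ix) * max(0, iy)
      frac <- inter / ((rb$x_max - rb$x_min) * (rb$y_max - rb$y_min))
      if (frac > thr) {
        if (!ok || frac > best) best <- frac
        ok <- TRUE
      }
    }
  }
  list(success = ok, score = best)
}

oracle_largest_slice <- function(ref) {
  best_i <- 1L; best_area <- -Inf
  for (i in seq_len(nrow(ref$slices))) {
    a <- (ref$slices$x_max[i] - ref$slices$x_min[i]) *
         (ref$slices$y_max[i] - ref$slices$y_min[i])
    if (a > best_area) { best_area <- a; best_i <- i }
  }
  ref$slices[best_i, ]
}

oracle_hit_tiebreak <- function(ref, pred, spacing) {
  ls <- oracle_largest_slice(ref)
  j <- which(pred$boxes$slice_index == ls$slice_index)
  if (!length(j)) {
    gaps <- abs(pred$boxes$slice_index - ls$slice_index)
    j <- which(gaps == min(gaps))[1L]
  }
  oracle_dist_mm(pred$boxes[j, ], ls, spacing)
}

# Queue walk-through of the flowchart: references in canonical order
# (descending largest-slice area, ascending nodule_id), each taking the
# best still-free succeeding prediction.
oracle_match_case <- function(refs, preds, kind, spacing = c(0.7, 0.7),
                              thr = 0.5) {
  if (length(refs) > 1L) {
    areas <- sapply(refs, function(r) {
      ls <- oracle_largest_slice(r)
      (ls$x_max - ls$x_min) * (ls$y_max - ls$y_min)
    })
    ids <- sapply(refs, function(r) r$nodule_id)
    refs <- refs[order(-areas, ids)]
  }
  free <- rep(TRUE, length(preds))
  pred_ids <- if (length(preds)) sapply(preds, function(p) p$pred_id) else character(0)
  tp_pairs <- list(); fn <- character(0)
  for (ref in refs) {
    cand <- c(); score <- c()
    for (j in which(free)) {
      ps <- oracle_pair_success(kind, ref, preds[[j]], spacing, thr)
      if (ps$success) {
        cand <- c(cand, j)
        score <- c(score,
                   if (kind == "center_hit")
                     oracle_hit_tiebreak(ref, preds[[j]], spacing)
                   else ps$score)
      }
    }
    if (!length(cand)) { fn <- c(fn, ref$nodule_id); next }
    best_val <- if (kind == "area_overlap") max(score) else min(score)
    tied <- cand[score == best_val]
    pick <- tied[order(pred_ids[tied])][1L]
    tp_pairs[[length(tp_pairs) + 1L]] <- c(ref$nodule_id, pred_ids[pick])
    free[pick] <- FALSE
  }
  list(tp = length(tp_pairs),
       fn = length(fn),
       fp = sum(free),
       pairs = tp_pairs,
       fn_ids = sort(fn),
       fp_ids = sort(pred_ids[free]))
}
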