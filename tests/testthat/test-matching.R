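# Mark-labeling rules and greedy one-to-one matching.

sp <- c(0.7, 0.7)  # isotropic spacing for most cases below

test_that("box geometry: centers, areas, overlap fraction", {
  expect_equal(unname(box_center(box2d(0, 0, 0, 10, 10))), c(5, 5))
  expect_equal(unname(box_center(box2d(0, 2, 4, 6, 8))), c(4, 6))
  expect_equal(unname(box_center(box2d(0, 0, 0, 1, 3))), c(0.5, 1.5))
  ref <- box2d(3, 0, 0, 10, 10)
  expect_equal(overlap_fraction(ref, ref), 1)
  expect_equal(overlap_fraction(box2d(3, 20, 20, 30, 30), ref), 0)
  expect_equal(overlap_fraction(box2d(3, 5, 0, 15, 10), ref), 0.5)
  # asymmetric: prediction containing the reference scores 1
  expect_equal(overlap_fraction(box2d(3, -5, -5, 15, 15), ref), 1)
  expect_error(overlap_fraction(box2d(4, 0, 0, 1, 1), ref), "different slices")
})

test_that("adaptive matching radius is the max of (long+short)/4 over slices", {
  r <- reference_nodule("c", "n", "solid", data.frame(
    slice_index = 1:2, x_min = 0, y_min = 0, x_max = c(10, 11), y_max = 10,
    long_diameter_mm = c(8, 10), short_diameter_mm = c(6, 6)), 7)
  expect_equal(matching_radius_mm(r), 4)
  expect_equal(matching_radius_mm(make_ref(long_mm = 4, short_mm = 4)), 2)
  r2 <- reference_nodule("c", "n", "solid", data.frame(
    slice_index = 1:2, x_min = 0, y_min = 0, x_max = c(12, 6), y_max = c(8, 2),
    long_diameter_mm = c(12, 6), short_diameter_mm = c(8, 2)), 9)
  expect_equal(matching_radius_mm(r2), 5)
})

test_that("slice success: closed containment, strict distance, strict overlap", {
  ref <- make_ref(slice = 5, x = 0, y = 0, w = 10, h = 10,
                  long_mm = 8, short_mm = 8)  # radius 4 mm
  rs <- ref$slices[1, ]
  # center hit: interior point succeeds, boundary counts as inside
  inside <- slice_success("center_hit", ref, rs, box2d(5, 3, 3, 7, 7), sp)
  expect_true(inside$success)
  on_edge <- slice_success("center_hit", ref, rs, box2d(5, 5, 5, 15, 15), sp)
  expect_true(on_edge$success)  # center (10,10) on the closed boundary
  outside <- slice_success("center_hit", ref, rs, box2d(5, 10.1, 10.1, 20, 20), sp)
  expect_false(outside$success)

  # center distance: strictly below the adaptive radius
  just_in <- slice_success("center_distance", ref, rs,
                           box2d(5, 3.99 / 0.7, 0, 3.99 / 0.7 + 10, 10), sp)
  expect_true(just_in$success)
  expect_equal(just_in$score, 3.99, tolerance = 1e-9)
  at_thr <- slice_success("center_distance", ref, rs,
                          box2d(5, 4 / 0.7, 0, 4 / 0.7 + 10, 10), sp)
  expect_false(at_thr$success)  # distance exactly 4.0 mm fails

  # area overlap: strictly above the threshold; exactly 0.5 fails
  half <- slice_success("area_overlap", ref, rs, box2d(5, 5, 0, 15, 10), sp)
  expect_false(half$success)
  expect_equal(half$score, 0.5)
  more <- slice_success("area_overlap", ref, rs, box2d(5, 4, 0, 14, 10), sp)
  expect_true(more$success)
  expect_error(slice_success("center_hit", ref, rs, box2d(6, 0, 0, 1, 1), sp),
               "different slices")
})

test_that("anisotropic pixel spacing enters the mm distance per axis", {
  ref <- make_ref(slice = 1, x = 0, y = 0, w = 10, h = 10,
                  long_mm = 10, short_mm = 10)  # radius 5 mm
  rs <- ref$slices[1, ]
  # 8 px offset along x only: 8 * 0.5 = 4 mm < 5 succeeds
  res <- slice_success("center_distance", ref, rs,
                       box2d(1, 8, 0, 18, 10), c(0.9, 0.5))
  expect_true(res$success)
  expect_equal(res$score, 4)
  # same offset along y: 8 * 0.9 = 7.2 mm fails
  res <- slice_success("center_distance", ref, rs,
                       box2d(1, 0, 8, 10, 18), c(0.9, 0.5))
  expect_false(res$success)
  expect_equal(res$score, 7.2)
})

test_that("nodule success needs one shared succeeding slice; best score returned", {
  ref <- reference_nodule("c1", "n1", "solid", data.frame(
    slice_index = 10:12, x_min = 0, y_min = 0, x_max = 10, y_max = 10,
    long_diameter_mm = 8, short_diameter_mm = 8), 8)
  # prediction covers slices 9-10; only slice 10 is shared, and it succeeds
  pred <- make_pred("c1", "p1", slice = 9, x = 1, y = 1, w = 10, h = 10,
                    n_slices = 2L)
  expect_true(nodule_success("center_hit", ref, pred, sp)$success)
  # disjoint slice ranges: failure, not an error
  far <- make_pred("c1", "p2", slice = 1, x = 1, y = 1, w = 10, h = 10,
                   n_slices = 2L)
  res <- nodule_success("center_hit", ref, far, sp)
  expect_false(res$success)
  expect_true(is.na(res$score))
  # best score is the minimum distance over succeeding slice pairs
  pred2 <- predicted_nodule("c1", "p3", data.frame(
    slice_index = 10:11, x_min = c(2, 1), y_min = c(2, 1),
    x_max = c(12, 11), y_max = c(12, 11)))
  res <- nodule_success("center_distance", ref, pred2, sp)
  expect_true(res$success)
  expect_equal(res$score, sqrt(2) * 0.7, tolerance = 1e-12)
  expect_error(nodule_success("center_hit", ref,
                              make_pred("other_case"), sp), "different cases")
})

test_that("match_case: perfect detection, greedy order, best-candidate choice", {
  # 1 ref, 1 centered pred
  pc <- perfect_panel_case(k = 1L)
  res <- match_case(pc$refs, pc$preds, "center_hit", sp)
  expect_equal(c(res$tp, res$fp, res$fn), c(1L, 0L, 0L))

  # 2 refs, 1 pred satisfying both: first ref in matching order wins
  r1 <- make_ref("c1", "n1", x = 100, y = 100, w = 20, h = 20,
                 long_mm = 14, short_mm = 14)
  r2 <- make_ref("c1", "n2", x = 108, y = 108, w = 10, h = 10,
                 long_mm = 7, short_mm = 7)
  p <- make_pred("c1", "p1", x = 106, y = 106, w = 8, h = 8)
  res <- match_case(list(r1, r2), list(p), "center_hit", sp)
  expect_equal(res$assignments$nodule_id, "n1")  # larger nodule first
  expect_equal(res$fn_ids, "n2")
  # under match_order = "file" with r2 first, r2 takes the prediction
  res2 <- match_case(list(r2, r1), list(p), "center_hit", sp,
                     match_order = "file")
  expect_equal(res2$assignments$nodule_id, "n2")

  # 1 ref, 2 succeeding preds at distances 2 and 1 mm: nearer one is TP
  ref <- make_ref("c1", "n1", x = 100, y = 100, w = 10, h = 10,
                  long_mm = 10, short_mm = 10)
  near <- make_pred("c1", "pa", x = 100 + 1 / 0.7, y = 100, w = 10, h = 10)
  far  <- make_pred("c1", "pb", x = 100 + 2 / 0.7, y = 100, w = 10, h = 10)
  for (rule in c("center_hit", "center_distance")) {
    res <- match_case(list(ref), list(far, near), rule, sp)
    expect_equal(res$assignments$pred_id, "pa")
    expect_equal(res$fp_ids, "pb")
  }

  # exact tie-break score: lowest pred_id wins
  left  <- make_pred("c1", "pL", x = 100 - 2, y = 100, w = 10, h = 10)
  right <- make_pred("c1", "pZ", x = 100 + 2, y = 100, w = 10, h = 10)
  res <- match_case(list(ref), list(right, left), "center_distance", sp)
  expect_equal(res$assignments$pred_id, "pL")

  expect_error(match_case(list(ref), list(make_pred("c2")), "center_hit", sp),
               "multiple cases")
})

test_that("center-hit tie-break measures distance to the largest reference slice", {
  # largest slice is 20; pred A is nearer in-plane on slice 20, pred B is
  # nearer on slice 21 (a smaller slice).  A must win.
  ref <- reference_nodule("c1", "n1", "solid", data.frame(
    slice_index = 20:21, x_min = c(100, 104), y_min = c(100, 104),
    x_max = c(120, 116), y_max = c(120, 116),
    long_diameter_mm = 14, short_diameter_mm = 14), 14)
  a <- predicted_nodule("c1", "pa", data.frame(
    slice_index = 20, x_min = 101, y_min = 101, x_max = 121, y_max = 121))
  b <- predicted_nodule("c1", "pb", data.frame(
    slice_index = 21, x_min = 109, y_min = 109, x_max = 121, y_max = 121))
  res <- match_case(list(ref), list(b, a), "center_hit", sp)
  expect_equal(res$assignments$pred_id, "pa")
  # pred without a box on the largest slice falls back to its nearest slice
  expect_equal(res$fp_ids, "pb")
})

test_that("matching equals the brute-force flowchart walk on random small cases", {
  set.seed(20260925)
  n_cases <- 1200L
  for (i in seq_len(n_cases)) {
    cs <- random_small_case()
    kind <- sample(c("center_hit", "center_distance", "area_overlap"), 1L)
    got <- match_case(cs$refs, cs$preds, kind, sp)
    want <- oracle_match_case(cs$refs, cs$preds, kind, sp)
    expect_identical(got$tp, want$tp)
    expect_identical(got$fn, want$fn)
    expect_identical(as.integer(got$fp), as.integer(want$fp))
    expect_identical(sort(got$fn_ids), want$fn_ids)
    expect_identical(got$fp_ids, want$fp_ids)
    if (got$tp > 0) {
      got_pairs <- paste(got$assignments$nodule_id, got$assignments$pred_id)
      want_pairs <- vapply(want$pairs, paste, collapse = " ", character(1))
      expect_setequal(got_pairs, want_pairs)
    }
  }
})

test_that("conservation and one-to-one hold on randomized inputs", {
  set.seed(77)
  for (i in 1:1000) {
    cs <- random_small_case(max_refs = 5L, max_preds = 5L)
    kind <- sample(c("center_hit", "center_distance", "area_overlap"), 1L)
    res <- match_case(cs$refs, cs$preds, kind, sp)
    expect_equal(res$tp + res$fn, length(cs$refs))
    expect_equal(res$tp + res$fp, length(cs$preds))
    ref_ids <- c(res$assignments$nodule_id, res$fn_ids)
    pred_ids <- c(res$assignments$pred_id, res$fp_ids)
    expect_false(anyDuplicated(ref_ids) > 0)
    expect_false(anyDuplicated(pred_ids) > 0)
  }
})

test_that("adding predictions never lowers TP; removing references never raises FN", {
  set.seed(31)
  for (i in 1:200) {
    cs <- random_small_case(max_refs = 4L, max_preds = 4L)
    if (!length(cs$preds)) next
    kind <- sample(c("center_hit", "center_distance", "area_overlap"), 1L)
    full <- match_case(cs$refs, cs$preds, kind, sp)
    fewer_preds <- match_case(cs$refs, cs$preds[-1], kind, sp)
    expect_gte(full$tp, fewer_preds$tp)
    if (length(cs$refs)) {
      fewer_refs <- match_case(cs$refs[-1], cs$preds, kind, sp)
      expect_lte(fewer_refs$fn, full$fn)
    }
  }
})

test_that("exact predictions of disjoint references are perfect under all rules", {
  pc <- perfect_panel_case(k = 4L)
  for (rule in c("center_hit", "center_distance", "area_overlap")) {
    res <- match_case(pc$refs, pc$preds, rule, sp)
    expect_equal(res$tp, 4L)
    expect_equal(res$fp, 0L)
    expect_equal(res$fn, 0L)
  }
})

test_that("type scope excludes out-of-scope references and absorbs their predictions", {
  solid <- make_ref("c1", "n1", "solid", x = 50, y = 50)
  pleural <- make_ref("c1", "n2", "pleural", x = 200, y = 200)
  p_solid <- make_pred("c1", "p1", x = 50, y = 50)
  p_pleural <- make_pred("c1", "p2", x = 200, y = 200)
  scoped <- apply_type_scope(list(solid, pleural), list(p_solid, p_pleural),
                             c("solid", "part_solid", "pure_ground_glass",
                               "calcified"), match_rule("center_hit"), sp)
  expect_length(scoped$refs, 1L)
  expect_equal(scoped$refs[[1]]$type, "solid")
  # the pleural prediction is dropped, not left to become FP
  expect_length(scoped$preds, 1L)
  res <- match_case(scoped$refs, scoped$preds, "center_hit", sp)
  expect_equal(c(res$tp, res$fp, res$fn), c(1L, 0L, 0L))
  # default scope keeps everything
  all_scope <- apply_type_scope(list(solid, pleural), list(p_solid, p_pleural),
                                "all", match_rule("center_hit"), sp)
  expect_length(all_scope$refs, 2L)
})
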