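# Synthetic dataset generator and AUT simulator.

test_that("generation is reproducible: same seed, byte-identical CSV", {
  spec <- dataset_spec(n_cases = 5, seed = 99)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_reference_csv(generate_reference_dataset(spec), f1,
                      header_comment = "seed 99")
  write_reference_csv(generate_reference_dataset(spec), f2,
                      header_comment = "seed 99")
  expect_identical(readLines(f1), readLines(f2))
  # and a different seed changes the data
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_reference_csv(generate_reference_dataset(dataset_spec(n_cases = 5, seed = 100)),
                      f3, header_comment = "seed 100")
  expect_false(identical(readLines(f1)[-1], readLines(f3)[-1]))
})

test_that("degenerate type distribution produces only that type", {
  spec <- dataset_spec(n_cases = 4, type_proportions = c(solid = 1), seed = 3)
  cases <- generate_reference_dataset(spec)
  types <- vapply(flatten_references(cases), function(r) r$type, character(1))
  expect_true(all(types == "solid"))
})

test_that("generated nodules respect the schema invariants", {
  cases <- generate_reference_dataset(dataset_spec(n_cases = 8, seed = 17))
  refs <- flatten_references(cases)
  expect_gt(length(refs), 30)
  for (r in refs) {
    s <- r$slices
    expect_true(all(diff(s$slice_index) > 0))
    expect_true(all(s$x_max > s$x_min & s$y_max > s$y_min))
    expect_true(all(s$short_diameter_mm <= s$long_diameter_mm + 1e-9))
    # average diameter consistent with the largest slice's diameters
    ls <- largest_slice(r)
    expect_equal((ls$long_diameter_mm + ls$short_diameter_mm) / 2,
                 r$average_diameter_mm, tolerance = 1e-9)
    expect_lte(r$average_diameter_mm, 30)
  }
  # slice count tracks diameter / thickness
  for (cs in cases) {
    for (r in cs$references) {
      expect_equal(nrow(r$slices),
                   max(1L, round(r$average_diameter_mm / cs$slice_thickness_mm)))
    }
  }
  # within a case, 2-D footprints do not overlap (placement constraint)
  for (cs in cases) {
    n <- length(cs$references)
    if (n < 2) next
    fp <- t(vapply(cs$references, function(r)
      c(min(r$slices$x_min), min(r$slices$y_min),
        max(r$slices$x_max), max(r$slices$y_max)), numeric(4)))
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      disjoint <- fp[i, 3] <= fp[j, 1] || fp[j, 3] <= fp[i, 1] ||
                  fp[i, 4] <= fp[j, 2] || fp[j, 4] <= fp[i, 2]
      expect_true(disjoint)
    }
  }
})

test_that("nodule count concentrates around n_cases * mean", {
  spec <- dataset_spec(n_cases = 120, seed = 201)
  cases <- generate_reference_dataset(spec)
  n <- length(flatten_references(cases))
  lambda <- 120 * spec$nodules_per_case_mean
  # Poisson total +/- 3 SD, with slack for rare packing-failure skips
  expect_gt(n, lambda - 3.5 * sqrt(lambda))
  expect_lt(n, lambda + 3.5 * sqrt(lambda))
})

test_that("empirical type frequencies match the configured proportions", {
  spec <- dataset_spec(n_cases = 250, seed = 42)
  cases <- generate_reference_dataset(spec)
  types <- vapply(flatten_references(cases), function(r) r$type, character(1))
  obs <- table(factor(types, levels = nodule_types()))
  gof <- suppressWarnings(
    stats::chisq.test(obs, p = spec$type_proportions[nodule_types()]))
  expect_gt(gof$p.value, 0.001)
  # size-bin composition too
  bins <- size_bin_of(vapply(flatten_references(cases),
                             function(r) r$average_diameter_mm, numeric(1)))
  gof2 <- suppressWarnings(
    stats::chisq.test(table(bins), p = spec$size_bin_proportions))
  expect_gt(gof2$p.value, 0.001)
})

test_that("a perfect simulated AUT scores 1 under all three rules", {
  cases <- generate_reference_dataset(dataset_spec(n_cases = 6, seed = 7))
  perfect <- simulate_aut(cases, aut_profile(
    sensitivity = 1, center_jitter_sigma = 0, box_scale_sigma = 0,
    fp_per_case_mean = 0, slice_truncation_prob = 0, seed = 70))
  for (rule in c("center_hit", "center_distance", "area_overlap")) {
    m <- evaluate_aut(cases, perfect, rule)$metrics
    expect_equal(m$recall, 1)
    expect_equal(m$precision, 1)
  }
})

test_that("a blind simulated AUT yields tp = 0 and Poisson-scale FPs", {
  cases <- generate_reference_dataset(dataset_spec(n_cases = 10, seed = 7))
  blind <- simulate_aut(cases, aut_profile(
    sensitivity = 0, fp_per_case_mean = 3, seed = 71))
  m <- evaluate_aut(cases, blind, "center_distance")$metrics
  expect_equal(m$tp, 0L)
  expect_equal(m$fn, length(flatten_references(cases)))
  expect_gt(m$fp, 0L)
  # 10 cases at mean 3: stay within a loose 5-sigma band
  expect_lt(abs(m$fp - 30), 5 * sqrt(30))
})

test_that("simulated false positives never match a reference", {
  cases <- generate_reference_dataset(dataset_spec(n_cases = 10, seed = 7))
  fp_only <- simulate_aut(cases, aut_profile(
    sensitivity = 0, fp_per_case_mean = 4, seed = 72))
  for (rule in c("center_hit", "center_distance", "area_overlap")) {
    expect_equal(evaluate_aut(cases, fp_only, rule)$metrics$tp, 0L)
  }
})

test_that("per-type sensitivities are recovered from measured miss rates", {
  # moderately sized dataset; detection is Bernoulli per nodule, so the
  # measured per-type recall must sit within binomial noise of the
  # configured sensitivity under center-distance matching at mild jitter
  spec <- dataset_spec(n_cases = 60, seed = 505)
  cases <- generate_reference_dataset(spec)
  sens <- c(solid = 0.6, part_solid = 0.8, pure_ground_glass = 0.4,
            calcified = 0.7, pleural = 0.5, pleural_calcified = 0.75)
  preds <- simulate_aut(cases, aut_profile(
    sensitivity = sens, center_jitter_sigma = 0.1, box_scale_sigma = 0.05,
    fp_per_case_mean = 1, slice_truncation_prob = 0.1, seed = 506))
  results <- list(sim = evaluate_aut(cases, preds, "center_distance")$results)
  tab <- miss_rate_by_type(results, cases)
  for (i in seq_len(nrow(tab))) {
    ty <- as.character(tab$type[i])
    n <- tab$n_ref[i]
    if (n < 20) next  # too little data for a stable rate
    s <- sens[[ty]]
    expect_lt(abs((1 - tab$sim[i]) - s), 3 * sqrt(s * (1 - s) / n) + 1e-9)
  }
})

test_that("growing center jitter degrades area-overlap recall fastest", {
  spec <- dataset_spec(n_cases = 25, seed = 31)
  cases <- generate_reference_dataset(spec)
  recall_under <- function(jitter, rule) {
    preds <- simulate_aut(cases, aut_profile(
      sensitivity = 1, center_jitter_sigma = jitter, box_scale_sigma = 0.05,
      fp_per_case_mean = 0, slice_truncation_prob = 0, seed = 32))
    evaluate_aut(cases, preds, rule)$metrics$recall
  }
  jitters <- c(0.05, 0.15, 0.3)
  overlap <- vapply(jitters, recall_under, numeric(1), rule = "area_overlap")
  hit <- vapply(jitters, recall_under, numeric(1), rule = "center_hit")
  dist <- vapply(jitters, recall_under, numeric(1), rule = "center_distance")
  # overlap recall falls no slower than the center rules at every level
  expect_true(all(overlap <= hit + 1e-9))
  expect_true(all(overlap <= dist + 1e-9))
  # and the degradation over the jitter sweep is strictly worse
  expect_gt((overlap[1] - overlap[3]) + 1e-9, hit[1] - hit[3])
  # hit and distance stay close to each other
  expect_true(all(abs(hit - dist) < 0.1))
})
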