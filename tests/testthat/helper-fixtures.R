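# Fixture builders used across the suite.  Everything is generated in code;
# no data files.

# A single-slice (or multi-slice) reference nodule from compact arguments.
make_ref <- function(case_id = "c1", nodule_id = "n1", type = "solid",
                     slice = 10L, x = 100, y = 100, w = 10, h = 10,
                     long_mm = 7, short_mm = 7, avg_mm = (long_mm + short_mm) / 2,
                     n_slices = 1L) {
  rows <- lapply(seq_len(n_slices), function(k) {
    data.frame(slice_index = slice + k - 1L,
               x_min = x, y_min = y, x_max = x + w, y_max = y + h,
               long_diameter_mm = long_mm, short_diameter_mm = short_mm)
  })
  reference_nodule(case_id, nodule_id, type, do.call(rbind, rows), avg_mm)
}

make_pred <- function(case_id = "c1", pred_id = "p1",
                      slice = 10L, x = 100, y = 100, w = 10, h = 10,
                      n_slices = 1L) {
  rows <- lapply(seq_len(n_slices), function(k) {
    data.frame(slice_index = slice + k - 1L,
               x_min = x, y_min = y, x_max = x + w, y_max = y + h)
  })
  predicted_nodule(case_id, pred_id, do.call(rbind, rows))
}

# Random small case for oracle / property tests: up to max_refs reference
# nodules and max_preds predictions on a coarse integer grid, so boundary
# coincidences and score ties actually occur.  Relies on the caller's RNG
# state (wrap in set.seed / withr::with_seed).
random_small_case <- function(max_refs = 4L, max_preds = 4L,
                              case_id = "rc") {
  n_ref <- sample.int(max_refs + 1L, 1L) - 1L   # 0..max_refs
  n_pred <- sample.int(max_preds + 1L, 1L) - 1L
  refs <- lapply(seq_len(n_ref), function(i) {
    n_sl <- sample.int(3L, 1L)
    slice0 <- sample.int(6L, 1L)
    x <- sample.int(30L, 1L); y <- sample.int(30L, 1L)
    w <- sample.int(12L, 1L); h <- sample.int(12L, 1L)
    long_mm <- sample(2:12, 1L); short_mm <- sample.int(long_mm, 1L)
    rows <- do.call(rbind, lapply(seq_len(n_sl), function(k)
      data.frame(slice_index = slice0 + k - 1L,
                 x_min = x, y_min = y,
                 x_max = x + max(1L, w - (k - 1L) * sample.int(3L, 1L) + 1L),
                 y_max = y + max(1L, h - (k - 1L)),
                 long_diameter_mm = long_mm, short_diameter_mm = short_mm)))
    reference_nodule(case_id, sprintf("n%d", i), sample(nodule_types(), 1L),
                     rows, (long_mm + short_mm) / 2)
  })
  preds <- lapply(seq_len(n_pred), function(i) {
    n_sl <- sample.int(3L, 1L)
    slice0 <- sample.int(6L, 1L)
    x <- sample.int(36L, 1L); y <- sample.int(36L, 1L)
    w <- sample.int(12L, 1L); h <- sample.int(12L, 1L)
    rows <- do.call(rbind, lapply(seq_len(n_sl), function(k)
      data.frame(slice_index = slice0 + k - 1L,
                 x_min = x, y_min = y, x_max = x + w, y_max = y + h)))
    predicted_nodule(case_id, sprintf("p%d", i), rows)
  })
  list(refs = refs, preds = preds)
}

# Tiny deterministic dataset: k well-separated single-nodule findings per
# case, with predictions exactly equal to the references.
perfect_panel_case <- function(case_id = "c1", k = 3L) {
  refs <- lapply(seq_len(k), function(i)
    make_ref(case_id, sprintf("n%d", i), x = 40 * i, y = 40 * i,
             long_mm = 8, short_mm = 6))
  preds <- lapply(seq_len(k), function(i)
    make_pred(case_id, sprintf("p%d", i), x = 40 * i, y = 40 * i))
  list(refs = refs, preds = preds)
}
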