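# Synthetic dataset generator: reference cases with a realistic nodule
# type/size composition, and simulated AUT outputs with controllable error
# structure (per-stratum sensitivity, center jitter, box-size error, slice
# truncation, false positives).  Everything downstream of the generator is
# thereby testable without patient data.

#' Specification for a synthetic reference dataset
#'
#' Defaults reproduce the composition of a realistic multi-hospital chest-CT
#' test set: 6,109 nodules over 593 cases (10.3 per case, Poisson), six
#' nodule types at proportions 42.66 / 5.06 / 19.58 / 7.40 / 23.06 / 2.24 %
#' (solid, part-solid, pure ground-glass, calcified, pleural, pleural
#' calcified), and average-diameter size bins at 69.91 / 19.63 / 7.28 /
#' 3.18 % for `[0,4)`, `[4,6)`, `[6,10)`, `[10,Inf)` mm.  In-plane pixel
#' spacing is drawn uniformly from 0.5-0.9 mm; diameters are capped at
#' 30 mm (nodule definitions require a long diameter <= 3 cm).
#'
#' @param n_cases number of CT cases to generate.
#' @param nodules_per_case_mean Poisson mean nodule count per case.
#' @param type_proportions named numeric weights over [nodule_types()];
#'   normalised to sum to 1.
#' @param size_bin_proportions numeric weights over [size_bins()] (in bin
#'   order); normalised to sum to 1.
#' @param pixel_spacing_range_mm in-plane spacing range (row and col drawn
#'   independently), mm.
#' @param slice_thickness_range_mm slice thickness range, mm.
#' @param image_extent_px square image side, pixels.
#' @param min_diameter_mm smallest generated average diameter (annotation
#'   floor), mm.
#' @param max_diameter_mm largest generated average diameter, mm.
#' @param seed integer seed; the whole generation run is reproducible from
#'   it.
#' @return Object of class `dataset_spec`.
#' @export
dataset_spec <- function(n_cases = 50,
                         nodules_per_case_mean = 6109 / 593,
                         type_proportions = c(solid = 0.4266,
                                              part_solid = 0.0506,
                                              pure_ground_glass = 0.1958,
                                              calcified = 0.0740,
                                              pleural = 0.2306,
                                              pleural_calcified = 0.0224),
                         size_bin_proportions = c(0.6991, 0.1963, 0.0728, 0.0318),
                         pixel_spacing_range_mm = c(0.5, 0.9),
                         slice_thickness_range_mm = c(0.625, 2.5),
                         image_extent_px = 512,
                         min_diameter_mm = 2,
                         max_diameter_mm = 30,
                         seed = 1L) {
  stopifnot(n_cases >= 1, nodules_per_case_mean > 0,
            length(size_bin_proportions) == 4L,
            all(size_bin_proportions >= 0), all(type_proportions >= 0),
            sum(type_proportions) > 0, sum(size_bin_proportions) > 0,
            length(pixel_spacing_range_mm) == 2L,
            all(pixel_spacing_range_mm > 0), all(pixel_spacing_range_mm < 5),
            image_extent_px >= 64,
            min_diameter_mm > 0, max_diameter_mm > min_diameter_mm)
  missing_types <- setdiff(nodule_types(), names(type_proportions))
  if (length(missing_types)) {
    full <- stats::setNames(numeric(length(nodule_types())), nodule_types())
    full[names(type_proportions)] <- type_proportions
    type_proportions <- full
  }
  type_proportions <- type_proportions[nodule_types()]
  structure(list(
    n_cases = as.integer(n_cases),
    nodules_per_case_mean = nodules_per_case_mean,
    type_proportions = type_proportions / sum(type_proportions),
    size_bin_proportions = size_bin_proportions / sum(size_bin_proportions),
    pixel_spacing_range_mm = pixel_spacing_range_mm,
    slice_thickness_range_mm = slice_thickness_range_mm,
    image_extent_px = as.integer(image_extent_px),
    min_diameter_mm = min_diameter_mm,
    max_diameter_mm = max_diameter_mm,
    seed = as.integer(seed)), class = "dataset_spec")
}

#' Error profile of a simulated AUT
#'
#' @param sensitivity either a single detection probability, a named vector
#'   over [nodule_types()], or a matrix `[type x bin]` (rownames =
#'   [nodule_types()], colnames = [size_bins()]) of detection
#'   probabilities.
#' @param center_jitter_sigma SD of the Gaussian center perturbation, as a
#'   fraction of the nodule radius.
#' @param box_scale_sigma SD of the multiplicative log-normal box-size
#'   error.
#' @param fp_per_case_mean Poisson mean count of false-positive detections
#'   per case.
#' @param slice_truncation_prob probability of dropping each boundary slice
#'   of a detected stack (at least one slice is always kept).
#' @param seed integer seed for the simulation run.
#' @return Object of class `aut_profile`.
#' @export
aut_profile <- function(sensitivity = 0.6,
                        center_jitter_sigma = 0.1,
                        box_scale_sigma = 0.05,
                        fp_per_case_mean = 2,
                        slice_truncation_prob = 0.1,
                        seed = 1L) {
  stopifnot(center_jitter_sigma >= 0, box_scale_sigma >= 0,
            fp_per_case_mean >= 0,
            slice_truncation_prob >= 0, slice_truncation_prob <= 1)
  sens <- sensitivity_matrix(sensitivity)
  stopifnot(all(sens >= 0), all(sens <= 1))
  structure(list(sensitivity = sens,
                 center_jitter_sigma = center_jitter_sigma,
                 box_scale_sigma = box_scale_sigma,
                 fp_per_case_mean = fp_per_case_mean,
                 slice_truncation_prob = slice_truncation_prob,
                 seed = as.integer(seed)), class = "aut_profile")
}

sensitivity_matrix <- function(sensitivity) {
  types <- nodule_types(); bins <- size_bins()
  if (is.matrix(sensitivity)) {
    stopifnot(setequal(rownames(sensitivity), types),
              setequal(colnames(sensitivity), bins))
    return(sensitivity[types, bins])
  }
  if (length(sensitivity) == 1L && is.null(names(sensitivity))) {
    return(matrix(sensitivity, length(types), length(bins),
                  dimnames = list(types, bins)))
  }
  stopifnot(!is.null(names(sensitivity)))
  missing_types <- setdiff(types, names(sensitivity))
  if (length(missing_types)) {
    stop("sensitivity: missing type(s): ",
         paste(missing_types, collapse = ", "), call. = FALSE)
  }
  matrix(rep(sensitivity[types], times = length(bins)),
         nrow = length(types), dimnames = list(types, bins))
}

# Draw an average diameter: bin by the configured proportions, log-uniform
# within the bin ([10, Inf) truncated at max_diameter_mm).
draw_diameter <- function(n, spec) {
  lows <- c(spec$min_diameter_mm, 4, 6, 10)
  highs <- c(4, 6, 10, spec$max_diameter_mm)
  bin <- sample.int(4L, n, replace = TRUE, prob = spec$size_bin_proportions)
  exp(stats::runif(n, log(lows[bin]), log(highs[bin])))
}

#' Generate a synthetic reference dataset
#'
#' Builds `n_cases` cases.  Per nodule: a type drawn from the configured
#' type proportions and an average diameter drawn by size bin; the slice
#' count is `max(1, round(diameter / slice_thickness))`, and per-slice
#' boxes follow an elliptic taper (in-plane radius shrinking toward the end
#' slices of the stack).  Long and short diameters at each slice bracket
#' the tapered in-plane diameter symmetrically, so the nodule's average
#' diameter equals `(long + short) / 2` on its largest slice.  Nodules are
#' placed without overlap by rejection sampling (100 tries, then the
#' diameter is halved and placement retried).
#'
#' The run is fully reproducible from `spec$seed`.
#'
#' @param spec a [dataset_spec()].
#' @return Named list of [case_record()] keyed by case id
#'   (`case001`, ...).
#' @export
generate_reference_dataset <- function(spec) {
  stopifnot(inherits(spec, "dataset_spec"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)

  cases <- vector("list", spec$n_cases)
  case_ids <- sprintf("case%03d", seq_len(spec$n_cases))
  for (ci in seq_len(spec$n_cases)) {
    spacing <- stats::runif(2L, spec$pixel_spacing_range_mm[1],
                            spec$pixel_spacing_range_mm[2])
    thickness <- stats::runif(1L, spec$slice_thickness_range_mm[1],
                              spec$slice_thickness_range_mm[2])
    n_nod <- stats::rpois(1L, spec$nodules_per_case_mean)
    refs <- list()
    occupied <- data.frame(x_min = numeric(0), y_min = numeric(0),
                           x_max = numeric(0), y_max = numeric(0))
    for (ni in seq_len(n_nod)) {
      type <- sample(nodule_types(), 1L, prob = spec$type_proportions)
      diameter <- draw_diameter(1L, spec)
      nod <- place_nodule(case_ids[ci], sprintf("n%03d", ni), type, diameter,
                          spacing, thickness, spec$image_extent_px, occupied)
      if (is.null(nod)) next  # packing failure after shrink: skip nodule
      refs[[length(refs) + 1L]] <- nod$nodule
      occupied <- rbind(occupied, nod$footprint)
    }
    cases[[ci]] <- case_record(case_ids[ci], spacing, thickness,
                               references = refs)
  }
  names(cases) <- case_ids
  cases
}

# Place one nodule; returns NULL if the image cannot accommodate it even
# after shrinking.  `occupied` holds 2-D footprints (x/y extents over all
# slices) of already-placed nodules; footprints must stay disjoint so that
# configured sensitivities remain identifiable downstream.
place_nodule <- function(case_id, nodule_id, type, diameter_mm,
                         spacing, thickness, extent, occupied) {
  for (attempt in 1:2) {
    r_px_x <- diameter_mm / 2 / spacing[2L]
    r_px_y <- diameter_mm / 2 / spacing[1L]
    margin <- 4  # px gap between footprints
    lo_x <- ceiling(r_px_x) + 1; hi_x <- extent - ceiling(r_px_x) - 1
    lo_y <- ceiling(r_px_y) + 1; hi_y <- extent - ceiling(r_px_y) - 1
    if (lo_x >= hi_x || lo_y >= hi_y) { diameter_mm <- diameter_mm / 2; next }
    for (try in 1:100) {
      cx <- stats::runif(1L, lo_x, hi_x)
      cy <- stats::runif(1L, lo_y, hi_y)
      fp <- c(x_min = cx - r_px_x - margin, y_min = cy - r_px_y - margin,
              x_max = cx + r_px_x + margin, y_max = cy + r_px_y + margin)
      clash <- nrow(occupied) > 0 &&
        any(occupied$x_min < fp["x_max"] & occupied$x_max > fp["x_min"] &
            occupied$y_min < fp["y_max"] & occupied$y_max > fp["y_min"])
      if (!clash) {
        nodule <- build_nodule(case_id, nodule_id, type, diameter_mm,
                               cx, cy, spacing, thickness)
        return(list(nodule = nodule,
                    footprint = as.data.frame(as.list(fp))))
      }
    }
    diameter_mm <- diameter_mm / 2  # shrink once, then retry placement
  }
  NULL
}

# Multi-slice geometry: n_slices from diameter/thickness, elliptic taper of
# the in-plane radius, long/short diameters bracketing the tapered diameter
# so that (long + short)/2 = tapered diameter at every slice.
build_nodule <- function(case_id, nodule_id, type, diameter_mm,
                         cx, cy, spacing, thickness) {
  n_slices <- max(1L, as.integer(round(diameter_mm / thickness)))
  z0 <- stats::rpois(1L, 60)  # arbitrary stack position
  asym <- stats::runif(1L, 0, 0.15)  # long/short split around the mean
  k_mid <- ceiling(n_slices / 2)  # central slice carries the full diameter
  rows <- lapply(seq_len(n_slices), function(k) {
    # relative offset from the central slice in (-1, 1); taper > 0 everywhere
    rel <- (k - k_mid) / (n_slices / 2 + 0.5)
    taper <- sqrt(1 - rel^2)
    d_slice <- diameter_mm * taper
    long <- d_slice * (1 + asym)
    short <- d_slice * (1 - asym)
    half_x <- long / 2 / spacing[2L]
    half_y <- short / 2 / spacing[1L]
    data.frame(slice_index = z0 + k - 1L,
               x_min = cx - half_x, y_min = cy - half_y,
               x_max = cx + half_x, y_max = cy + half_y,
               long_diameter_mm = long, short_diameter_mm = short)
  })
  reference_nodule(case_id, nodule_id, type, do.call(rbind, rows), diameter_mm)
}

#' Simulate an AUT's predictions on a synthetic dataset
#'
#' Each reference nodule is detected independently with probability
#' `sensitivity[type, bin]`.  A detection copies the reference box stack,
#' then perturbs it: Gaussian center jitter with per-axis SD
#' `center_jitter_sigma * radius` (radius = the adaptive matching radius,
#' in mm, converted per axis to pixels), a multiplicative size error
#' `exp(N(0, box_scale_sigma))`, and each boundary slice independently
#' dropped with `slice_truncation_prob` (at least one slice always
#' remains).  False positives are drawn per case from
#' `Poisson(fp_per_case_mean)` and placed uniformly with their center
#' outside every reference box dilated by its radius, so they cannot be
#' matched and the configured sensitivity stays identifiable.
#'
#' The run is fully reproducible from `profile$seed`.
#'
#' @param cases named list of [case_record()] from
#'   [generate_reference_dataset()].
#' @param profile an [aut_profile()].
#' @return Named list (case_id -> list of [predicted_nodule()]).
#' @export
simulate_aut <- function(cases, profile) {
  stopifnot(inherits(profile, "aut_profile"))
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(profile$seed)

  out <- lapply(cases, function(cs) {
    spacing <- cs$pixel_spacing_mm
    preds <- list()
    k <- 0L
    for (ref in cs$references) {
      bin <- as.character(size_bin_of(ref$average_diameter_mm))
      p_detect <- profile$sensitivity[ref$type, bin]
      if (stats::runif(1L) > p_detect) next
      k <- k + 1L
      preds[[k]] <- perturb_reference(ref, sprintf("p%03d", k), profile, spacing)
    }
    n_fp <- stats::rpois(1L, profile$fp_per_case_mean)
    for (i in seq_len(n_fp)) {
      fp <- place_false_positive(cs, sprintf("p%03d", k + i), spacing)
      if (!is.null(fp)) preds[[length(preds) + 1L]] <- fp
    }
    preds
  })
  names(out) <- names(cases)
  out
}

perturb_reference <- function(ref, pred_id, profile, spacing) {
  radius_mm <- matching_radius_mm(ref)
  jitter_px <- c(stats::rnorm(1L, 0, profile$center_jitter_sigma * radius_mm / spacing[2L]),
                 stats::rnorm(1L, 0, profile$center_jitter_sigma * radius_mm / spacing[1L]))
  scale <- exp(stats::rnorm(1L, 0, profile$box_scale_sigma))
  s <- ref$slices
  keep <- rep(TRUE, nrow(s))
  if (nrow(s) > 1L && profile$slice_truncation_prob > 0) {
    if (stats::runif(1L) < profile$slice_truncation_prob) keep[1L] <- FALSE
    if (stats::runif(1L) < profile$slice_truncation_prob) keep[nrow(s)] <- FALSE
    if (!any(keep)) keep[ceiling(nrow(s) / 2)] <- TRUE
  }
  s <- s[keep, , drop = FALSE]
  cx <- (s$x_min + s$x_max) / 2 + jitter_px[1L]
  cy <- (s$y_min + s$y_max) / 2 + jitter_px[2L]
  hx <- (s$x_max - s$x_min) / 2 * scale
  hy <- (s$y_max - s$y_min) / 2 * scale
  predicted_nodule(ref$case_id, pred_id,
                   data.frame(slice_index = s$slice_index,
                              x_min = cx - hx, y_min = cy - hy,
                              x_max = cx + hx, y_max = cy + hy))
}

# A small spurious detection whose center stays clear of every reference
# box dilated by that reference's matching radius.
place_false_positive <- function(cs, pred_id, spacing) {
  extent <- 512
  pad <- 7  # largest FP half-width + 1, so small references cannot be covered
  dilated <- lapply(cs$references, function(ref) {
    r_px_x <- matching_radius_mm(ref) / spacing[2L] + pad
    r_px_y <- matching_radius_mm(ref) / spacing[1L] + pad
    s <- ref$slices
    data.frame(x_min = min(s$x_min) - r_px_x, y_min = min(s$y_min) - r_px_y,
               x_max = max(s$x_max) + r_px_x, y_max = max(s$y_max) + r_px_y)
  })
  for (try in 1:100) {
    cx <- stats::runif(1L, 12, extent - 12)
    cy <- stats::runif(1L, 12, extent - 12)
    inside <- any(vapply(dilated, function(d)
      cx >= d$x_min && cx <= d$x_max && cy >= d$y_min && cy <= d$y_max,
      logical(1)))
    if (!inside) {
      half <- stats::runif(1L, 2, 6)  # px
      si <- stats::rpois(1L, 60)
      return(predicted_nodule(cs$case_id, pred_id,
                              data.frame(slice_index = si,
                                         x_min = cx - half, y_min = cy - half,
                                         x_max = cx + half, y_max = cy + half)))
    }
  }
  NULL
}

#' Simulate a panel of AUTs
#'
#' Convenience wrapper: one [simulate_aut()] run per profile, with the
#' profile seeds offset so the panel members err independently.
#'
#' @param cases named list of [case_record()].
#' @param profiles named list of [aut_profile()] (names become AUT labels).
#' @return Named list (AUT label -> named list case_id -> predictions).
#' @export
simulate_aut_panel <- function(cases, profiles) {
  stopifnot(is.list(profiles), !is.null(names(profiles)))
  out <- lapply(profiles, function(p) simulate_aut(cases, p))
  names(out) <- names(profiles)
  out
}
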