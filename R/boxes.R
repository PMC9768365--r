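# Axis-aligned 2-D bounding boxes on CT slices.
#
# Coordinates are 0-based pixel indices with the half-open convention
# [x_min, x_max) x [y_min, y_max): area and intersection arithmetic are then
# unambiguous.  x runs along image columns, y along rows; pixel spacing is
# given as c(row, col) mm so that mm distances are
# sqrt((dx * spacing_col)^2 + (dy * spacing_row)^2).

#' Construct a 2-D bounding box on one CT slice
#'
#' Boxes use 0-based pixel coordinates with a half-open convention
#' `[x_min, x_max) x [y_min, y_max)`, so `x_max`/`y_max` are exclusive and
#' the pixel area is `(x_max - x_min) * (y_max - y_min)`.
#'
#' @param slice_index integer >= 0, 0-based slice position in the CT stack.
#' @param x_min,y_min,x_max,y_max box edges in pixels; `x_min < x_max` and
#'   `y_min < y_max` are required (degenerate boxes are rejected).
#' @return An object of class `box2d` (a named list).
#' @export
#' @examples
#' b <- box2d(10, 100, 120, 140, 160)
#' box_area(b)
#' box_center(b)
box2d <- function(slice_index, x_min, y_min, x_max, y_max) {
  stopifnot(length(slice_index) == 1L, is.finite(slice_index),
            slice_index >= 0, slice_index == as.integer(slice_index))
  for (v in list(x_min, y_min, x_max, y_max)) {
    if (length(v) != 1L || !is.finite(v)) {
      stop("box coordinates must be single finite numbers", call. = FALSE)
    }
  }
  if (x_min >= x_max || y_min >= y_max) {
    stop(sprintf(
      "degenerate box: need x_min < x_max and y_min < y_max (got [%g, %g) x [%g, %g))",
      x_min, x_max, y_min, y_max), call. = FALSE)
  }
  structure(list(slice_index = as.integer(slice_index),
                 x_min = as.numeric(x_min), y_min = as.numeric(y_min),
                 x_max = as.numeric(x_max), y_max = as.numeric(y_max)),
            class = "box2d")
}

#' Box center point
#'
#' @param box a `box2d` or any list/row with `x_min`, `y_min`, `x_max`,
#'   `y_max` fields.
#' @return Numeric vector `c(x, y)` in pixels: the midpoint of each axis.
#' @export
box_center <- function(box) {
  c(x = (box$x_min + box$x_max) / 2, y = (box$y_min + box$y_max) / 2)
}

#' Box pixel area
#'
#' @inheritParams box_center
#' @return `(x_max - x_min) * (y_max - y_min)` in square pixels.
#' @export
box_area <- function(box) {
  (box$x_max - box$x_min) * (box$y_max - box$y_min)
}

#' Fraction of a reference box covered by a predicted box
#'
#' The area-overlap mark-labeling rule scores a predicted box by the
#' proportion of the *reference* box area that the prediction covers:
#' `|pred intersect ref| / |ref|`.  Unlike IoU this is asymmetric: a
#' prediction that fully contains the reference scores 1 regardless of how
#' large the prediction is.
#'
#' @param pred,ref boxes (`box2d` or compatible lists) on the same slice.
#' @return A number in `[0, 1]`; 0 when disjoint, 1 when the reference is
#'   contained in the prediction.
#' @export
overlap_fraction <- function(pred, ref) {
  if (!is.null(pred$slice_index) && !is.null(ref$slice_index) &&
      pred$slice_index != ref$slice_index) {
    stop("overlap_fraction: boxes are on different slices", call. = FALSE)
  }
  ix <- max(0, min(pred$x_max, ref$x_max) - max(pred$x_min, ref$x_min))
  iy <- max(0, min(pred$y_max, ref$y_max) - max(pred$y_min, ref$y_min))
  (ix * iy) / box_area(ref)
}

# Vectorised intersection area over aligned coordinate vectors.
intersect_area_vec <- function(ax_min, ay_min, ax_max, ay_max,
                               bx_min, by_min, bx_max, by_max) {
  ix <- pmax(0, pmin(ax_max, bx_max) - pmax(ax_min, bx_min))
  iy <- pmax(0, pmin(ay_max, by_max) - pmax(ay_min, by_min))
  ix * iy
}

# In-plane center distance in mm between two boxes, given per-axis pixel
# spacing c(row, col).  x differences scale by the column spacing, y by the
# row spacing.
center_distance_mm <- function(a, b, pixel_spacing_mm) {
  dx <- ((a$x_min + a$x_max) - (b$x_min + b$x_max)) / 2
  dy <- ((a$y_min + a$y_max) - (b$y_min + b$y_max)) / 2
  sqrt((dx * pixel_spacing_mm[[2L]])^2 + (dy * pixel_spacing_mm[[1L]])^2)
}
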