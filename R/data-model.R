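# Domain types and CSV schemas for reference annotations, AUT predictions
# and case metadata.
#
# Reference CSV (exact header order):
#   case_id,nodule_id,type,slice_index,x_min,y_min,x_max,y_max,
#   long_diameter_mm,short_diameter_mm,avg_diameter_mm
# Prediction CSV:
#   case_id,pred_id,slice_index,x_min,y_min,x_max,y_max[,score]
# Case metadata CSV:
#   case_id,pixel_spacing_row_mm,pixel_spacing_col_mm,slice_thickness_mm

#' The six-type pulmonary nodule taxonomy
#'
#' Categorical labels for the reference-standard annotation vocabulary:
#' solid, part-solid, pure ground-glass, calcified, pleural, and pleural
#' calcified nodules.  Stored and serialized as stable lower-snake strings.
#'
#' @return Character vector of the six type labels, in canonical order.
#' @export
nodule_types <- function() {
  c("solid", "part_solid", "pure_ground_glass",
    "calcified", "pleural", "pleural_calcified")
}

assert_nodule_type <- function(type) {
  bad <- setdiff(unique(type), nodule_types())
  if (length(bad)) {
    stop(sprintf("unknown nodule type(s): %s (vocabulary: %s)",
                 paste(bad, collapse = ", "),
                 paste(nodule_types(), collapse = "|")), call. = FALSE)
  }
  invisible(type)
}

#' Size-bin labels over average diameter
#'
#' Four left-closed/right-open bins over average diameter in mm:
#' `[0,4)`, `[4,6)`, `[6,10)`, `[10,Inf)`.  They partition the positive
#' line, so every nodule falls in exactly one bin.
#'
#' @return Character vector of the four bin labels, ascending.
#' @export
size_bins <- function() {
  c("[0,4)", "[4,6)", "[6,10)", "[10,Inf)")
}

#' Map an average diameter to its size bin
#'
#' Binning is left-closed/right-open, so boundary diameters go to the upper
#' bin: 4.0 mm is in `[4,6)` and 10.0 mm in `[10,Inf)`.
#'
#' @param average_diameter_mm positive diameter(s) in mm; vectorised.
#' @return Factor with levels [size_bins()].
#' @export
#' @examples
#' size_bin_of(c(3.9, 4, 6, 10, 25))
size_bin_of <- function(average_diameter_mm) {
  if (any(!is.finite(average_diameter_mm)) || any(average_diameter_mm <= 0)) {
    stop("average_diameter_mm must be finite and > 0", call. = FALSE)
  }
  cut(average_diameter_mm, breaks = c(0, 4, 6, 10, Inf),
      labels = size_bins(), right = FALSE)
}

#' Construct a reference-standard nodule
#'
#' A reference nodule is a multi-slice annotated ground-truth finding: one
#' bounding box plus long/short diameters per annotated slice, a type label
#' from the six-type taxonomy, and an average diameter used for size
#' binning.  Slices must be strictly increasing in `slice_index`; gaps are
#' tolerated (annotation artifacts occur in real data).
#'
#' @param case_id,nodule_id identifier strings.
#' @param type one of [nodule_types()].
#' @param slices data.frame with columns `slice_index`, `x_min`, `y_min`,
#'   `x_max`, `y_max`, `long_diameter_mm`, `short_diameter_mm`; rows are
#'   sorted by `slice_index` on construction.
#' @param average_diameter_mm positive average diameter in mm.
#' @return Object of class `reference_nodule`.
#' @export
reference_nodule <- function(case_id, nodule_id, type, slices,
                             average_diameter_mm) {
  assert_nodule_type(type)
  stopifnot(is.data.frame(slices), nrow(slices) >= 1L,
            length(average_diameter_mm) == 1L, average_diameter_mm > 0)
  need <- c("slice_index", "x_min", "y_min", "x_max", "y_max",
            "long_diameter_mm", "short_diameter_mm")
  missing_cols <- setdiff(need, names(slices))
  if (length(missing_cols)) {
    stop("reference slices missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  slices <- slices[order(slices$slice_index), need, drop = FALSE]
  if (anyDuplicated(slices$slice_index)) {
    stop(sprintf("duplicate slice_index in nodule %s/%s", case_id, nodule_id),
         call. = FALSE)
  }
  if (any(slices$x_min >= slices$x_max) || any(slices$y_min >= slices$y_max)) {
    stop(sprintf("degenerate box in nodule %s/%s", case_id, nodule_id),
         call. = FALSE)
  }
  if (any(slices$long_diameter_mm <= 0) || any(slices$short_diameter_mm <= 0) ||
      any(slices$short_diameter_mm > slices$long_diameter_mm + 1e-9)) {
    stop(sprintf("invalid diameters in nodule %s/%s (need 0 < short <= long)",
                 case_id, nodule_id), call. = FALSE)
  }
  rownames(slices) <- NULL
  structure(list(case_id = as.character(case_id),
                 nodule_id = as.character(nodule_id),
                 type = as.character(type),
                 slices = slices,
                 average_diameter_mm = as.numeric(average_diameter_mm)),
            class = "reference_nodule")
}

#' Construct a predicted nodule (AUT output)
#'
#' A predicted nodule is a stack of per-slice bounding boxes emitted by an
#' algorithm under test, with an optional confidence score.
#'
#' @param case_id,pred_id identifier strings.
#' @param boxes data.frame with columns `slice_index`, `x_min`, `y_min`,
#'   `x_max`, `y_max`; sorted by `slice_index` on construction.
#' @param score optional numeric confidence.
#' @return Object of class `predicted_nodule`.
#' @export
predicted_nodule <- function(case_id, pred_id, boxes, score = NA_real_) {
  stopifnot(is.data.frame(boxes), nrow(boxes) >= 1L)
  need <- c("slice_index", "x_min", "y_min", "x_max", "y_max")
  missing_cols <- setdiff(need, names(boxes))
  if (length(missing_cols)) {
    stop("prediction boxes missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  boxes <- boxes[order(boxes$slice_index), need, drop = FALSE]
  if (anyDuplicated(boxes$slice_index)) {
    stop(sprintf("duplicate slice_index in prediction %s/%s", case_id, pred_id),
         call. = FALSE)
  }
  if (any(boxes$x_min >= boxes$x_max) || any(boxes$y_min >= boxes$y_max)) {
    stop(sprintf("degenerate box in prediction %s/%s", case_id, pred_id),
         call. = FALSE)
  }
  rownames(boxes) <- NULL
  structure(list(case_id = as.character(case_id),
                 pred_id = as.character(pred_id),
                 boxes = boxes,
                 score = as.numeric(score)),
            class = "predicted_nodule")
}

#' Construct a case record
#'
#' Bundles one CT case: its per-axis pixel spacing and slice thickness, the
#' reference nodules, and (optionally) predictions keyed by AUT label.
#'
#' @param case_id identifier string.
#' @param pixel_spacing_mm numeric `c(row, col)` spacing in mm, each in
#'   (0, 5).
#' @param slice_thickness_mm positive slice thickness in mm.
#' @param references list of [reference_nodule()] objects for this case.
#' @param predictions named list (AUT label -> list of
#'   [predicted_nodule()]); may be empty.
#' @return Object of class `case_record`.
#' @export
case_record <- function(case_id, pixel_spacing_mm = c(0.7, 0.7),
                        slice_thickness_mm = 1,
                        references = list(), predictions = list()) {
  stopifnot(length(pixel_spacing_mm) == 2L,
            all(pixel_spacing_mm > 0), all(pixel_spacing_mm < 5),
            slice_thickness_mm > 0)
  case_id <- as.character(case_id)
  for (r in references) {
    if (!identical(r$case_id, case_id)) {
      stop(sprintf("reference nodule %s carries case_id %s, expected %s",
                   r$nodule_id, r$case_id, case_id), call. = FALSE)
    }
  }
  structure(list(case_id = case_id,
                 pixel_spacing_mm = as.numeric(pixel_spacing_mm),
                 slice_thickness_mm = as.numeric(slice_thickness_mm),
                 references = references,
                 predictions = predictions),
            class = "case_record")
}

#' @export
print.case_record <- function(x, ...) {
  cat(sprintf("<case_record %s: %d reference nodule(s), %d AUT(s), spacing %.3g x %.3g mm>\n",
              x$case_id, length(x$references), length(x$predictions),
              x$pixel_spacing_mm[1], x$pixel_spacing_mm[2]))
  invisible(x)
}

#' @export
print.reference_nodule <- function(x, ...) {
  cat(sprintf("<reference_nodule %s/%s: %s, %.3g mm, %d slice(s)>\n",
              x$case_id, x$nodule_id, x$type, x$average_diameter_mm,
              nrow(x$slices)))
  invisible(x)
}

#' @export
print.predicted_nodule <- function(x, ...) {
  cat(sprintf("<predicted_nodule %s/%s: %d box(es)>\n",
              x$case_id, x$pred_id, nrow(x$boxes)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# CSV schemas

reference_csv_columns <- function() {
  c("case_id", "nodule_id", "type", "slice_index",
    "x_min", "y_min", "x_max", "y_max",
    "long_diameter_mm", "short_diameter_mm", "avg_diameter_mm")
}

prediction_csv_columns <- function() {
  c("case_id", "pred_id", "slice_index",
    "x_min", "y_min", "x_max", "y_max")
}

check_csv_header <- function(df, required, path) {
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("%s: missing required column(s): %s",
                 path, paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  invisible(df)
}

# Coerce columns to numeric with row-numbered parse errors.  Row numbers
# refer to file lines (header = line 1, first data row = line 2).
coerce_numeric_cols <- function(df, cols, path) {
  for (col in cols) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(parsed) & !is.na(v) & trimws(v) != "")
      if (length(bad) || anyNA(parsed)) {
        bad <- union(bad, which(is.na(parsed)))
        stop(sprintf("%s: non-numeric value in column '%s' at line(s) %s",
                     path, col, paste(bad + 1L, collapse = ", ")),
             call. = FALSE)
      }
      df[[col]] <- parsed
    } else if (anyNA(v)) {
      stop(sprintf("%s: missing value in column '%s' at line(s) %s",
                   path, col, paste(which(is.na(v)) + 1L, collapse = ", ")),
           call. = FALSE)
    }
  }
  df
}

validate_box_rows <- function(df, path) {
  bad <- which(df$x_min >= df$x_max | df$y_min >= df$y_max)
  if (length(bad)) {
    stop(sprintf("%s: degenerate box (x_min >= x_max or y_min >= y_max) at line(s) %s",
                 path, paste(bad + 1L, collapse = ", ")), call. = FALSE)
  }
  if (any(df$slice_index < 0) || any(df$slice_index != round(df$slice_index))) {
    stop(sprintf("%s: slice_index must be a non-negative integer", path),
         call. = FALSE)
  }
  invisible(df)
}

read_csv_table <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#",
                  colClasses = NA, check.names = TRUE)
}

#' Read a reference-standard annotation CSV
#'
#' Parses the reference schema
#' (`case_id,nodule_id,type,slice_index,x_min,y_min,x_max,y_max,long_diameter_mm,short_diameter_mm,avg_diameter_mm`),
#' groups rows by `(case_id, nodule_id)` into multi-slice
#' [reference_nodule()] objects, and assembles them into [case_record()]s.
#' Duplicate `(case_id, nodule_id, slice_index)` rows are rejected.
#'
#' @param path CSV file path.  Lines starting with `#` are ignored.
#' @param case_meta optional data.frame as returned by
#'   [read_case_metadata_csv()]; when given, per-case spacing and thickness
#'   are taken from it.
#' @param pixel_spacing_mm fallback `c(row, col)` spacing in mm for cases
#'   absent from `case_meta`.
#' @param slice_thickness_mm fallback slice thickness in mm.
#' @return Named list of [case_record()], keyed and sorted by `case_id`.
#' @export
read_reference_csv <- function(path, case_meta = NULL,
                               pixel_spacing_mm = c(0.7, 0.7),
                               slice_thickness_mm = 1) {
  df <- read_csv_table(path)
  check_csv_header(df, reference_csv_columns(), path)
  if (nrow(df) == 0L) return(structure(list(), names = character(0)))
  df <- coerce_numeric_cols(df, c("slice_index", "x_min", "y_min", "x_max",
                                  "y_max", "long_diameter_mm",
                                  "short_diameter_mm", "avg_diameter_mm"),
                            path)
  validate_box_rows(df, path)
  assert_nodule_type(df$type)
  key <- paste(df$case_id, df$nodule_id, df$slice_index, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(key %in% key[duplicated(key)])
    stop(sprintf("%s: duplicate (case_id, nodule_id, slice_index) at line(s) %s",
                 path, paste(dup + 1L, collapse = ", ")), call. = FALSE)
  }

  nodules <- lapply(split(df, paste(df$case_id, df$nodule_id, sep = "\r")),
                    function(g) {
    if (length(unique(g$type)) > 1L) {
      stop(sprintf("%s: nodule %s/%s has conflicting type labels",
                   path, g$case_id[1], g$nodule_id[1]), call. = FALSE)
    }
    reference_nodule(g$case_id[1], g$nodule_id[1], g$type[1],
                     g[, c("slice_index", "x_min", "y_min", "x_max", "y_max",
                           "long_diameter_mm", "short_diameter_mm")],
                     g$avg_diameter_mm[1])
  })

  case_ids <- sort(unique(df$case_id))
  cases <- lapply(case_ids, function(cid) {
    refs <- Filter(function(n) n$case_id == cid, nodules)
    refs <- refs[order(vapply(refs, function(n) n$nodule_id, character(1)))]
    names(refs) <- NULL
    sp <- pixel_spacing_mm; th <- slice_thickness_mm
    if (!is.null(case_meta)) {
      i <- match(cid, case_meta$case_id)
      if (!is.na(i)) {
        sp <- c(case_meta$pixel_spacing_row_mm[i],
                case_meta$pixel_spacing_col_mm[i])
        th <- case_meta$slice_thickness_mm[i]
      }
    }
    case_record(cid, sp, th, references = refs)
  })
  names(cases) <- case_ids
  cases
}

#' Read an AUT prediction CSV
#'
#' Parses the prediction schema
#' (`case_id,pred_id,slice_index,x_min,y_min,x_max,y_max[,score]`) and
#' groups rows into [predicted_nodule()] objects.  An empty data section is
#' valid: an AUT may output nothing.
#'
#' @param path CSV file path.  Lines starting with `#` are ignored.
#' @return Named list (by `case_id`, lexicographic) of lists of
#'   [predicted_nodule()], each case's predictions ordered by `pred_id`.
#' @export
read_prediction_csv <- function(path) {
  df <- read_csv_table(path)
  check_csv_header(df, prediction_csv_columns(), path)
  if (nrow(df) == 0L) return(structure(list(), names = character(0)))
  num_cols <- c("slice_index", "x_min", "y_min", "x_max", "y_max")
  df <- coerce_numeric_cols(df, num_cols, path)
  validate_box_rows(df, path)
  key <- paste(df$case_id, df$pred_id, df$slice_index, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- which(key %in% key[duplicated(key)])
    stop(sprintf("%s: duplicate (case_id, pred_id, slice_index) at line(s) %s",
                 path, paste(dup + 1L, collapse = ", ")), call. = FALSE)
  }
  has_score <- "score" %in% names(df)
  preds <- lapply(split(df, paste(df$case_id, df$pred_id, sep = "\r")),
                  function(g) {
    predicted_nodule(g$case_id[1], g$pred_id[1],
                     g[, c("slice_index", "x_min", "y_min", "x_max", "y_max")],
                     score = if (has_score) g$score[1] else NA_real_)
  })
  case_ids <- sort(unique(df$case_id))
  out <- lapply(case_ids, function(cid) {
    p <- Filter(function(x) x$case_id == cid, preds)
    p <- p[order(vapply(p, function(x) x$pred_id, character(1)))]
    names(p) <- NULL
    p
  })
  names(out) <- case_ids
  out
}

#' Read a case metadata CSV
#'
#' Schema: `case_id,pixel_spacing_row_mm,pixel_spacing_col_mm,slice_thickness_mm`.
#'
#' @param path CSV file path.
#' @return data.frame with those four columns.
#' @export
read_case_metadata_csv <- function(path) {
  df <- read_csv_table(path)
  check_csv_header(df, c("case_id", "pixel_spacing_row_mm",
                         "pixel_spacing_col_mm", "slice_thickness_mm"), path)
  df <- coerce_numeric_cols(df, c("pixel_spacing_row_mm", "pixel_spacing_col_mm",
                                  "slice_thickness_mm"), path)
  if (any(df$pixel_spacing_row_mm <= 0) || any(df$pixel_spacing_row_mm >= 5) ||
      any(df$pixel_spacing_col_mm <= 0) || any(df$pixel_spacing_col_mm >= 5)) {
    stop(sprintf("%s: pixel spacing must lie in (0, 5) mm", path), call. = FALSE)
  }
  df$case_id <- as.character(df$case_id)
  df
}

#' Write reference nodules to the annotation CSV schema
#'
#' @param cases named list of [case_record()] (or a flat list of
#'   [reference_nodule()]).
#' @param path output file path.
#' @param header_comment optional comment line (written prefixed with `#`).
#' @return `path`, invisibly.
#' @export
write_reference_csv <- function(cases, path, header_comment = NULL) {
  refs <- flatten_references(cases)
  rows <- lapply(refs, function(n) {
    s <- n$slices
    data.frame(case_id = n$case_id, nodule_id = n$nodule_id, type = n$type,
               slice_index = s$slice_index,
               x_min = s$x_min, y_min = s$y_min,
               x_max = s$x_max, y_max = s$y_max,
               long_diameter_mm = s$long_diameter_mm,
               short_diameter_mm = s$short_diameter_mm,
               avg_diameter_mm = n$average_diameter_mm,
               stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(stats::setNames(rep(list(character(0)), 11),
                                  reference_csv_columns()))
  write_csv_with_comment(df, path, header_comment)
}

#' Write predicted nodules to the prediction CSV schema
#'
#' @param predictions named list (case -> list of [predicted_nodule()]) or a
#'   flat list of [predicted_nodule()].
#' @param path output file path.
#' @param header_comment optional comment line (written prefixed with `#`).
#' @return `path`, invisibly.
#' @export
write_prediction_csv <- function(predictions, path, header_comment = NULL) {
  preds <- flatten_predictions(predictions)
  rows <- lapply(preds, function(p) {
    b <- p$boxes
    data.frame(case_id = p$case_id, pred_id = p$pred_id,
               slice_index = b$slice_index,
               x_min = b$x_min, y_min = b$y_min,
               x_max = b$x_max, y_max = b$y_max,
               score = p$score, stringsAsFactors = FALSE)
  })
  df <- if (length(rows)) do.call(rbind, rows) else
    as.data.frame(stats::setNames(rep(list(character(0)), 8),
                                  c(prediction_csv_columns(), "score")))
  if (nrow(df) && all(is.na(df$score))) df$score <- NULL
  write_csv_with_comment(df, path, header_comment)
}

write_csv_with_comment <- function(df, path, header_comment = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header_comment)) {
    writeLines(paste0("# ", header_comment), con)
  }
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Helpers used across modules

flatten_references <- function(x) {
  if (inherits(x, "reference_nodule")) return(list(x))
  if (inherits(x, "case_record")) return(x$references)
  out <- list()
  for (el in x) {
    if (inherits(el, "case_record")) out <- c(out, el$references)
    else if (inherits(el, "reference_nodule")) out <- c(out, list(el))
    else if (is.list(el)) out <- c(out, flatten_references(el))
    else stop("expected case_record or reference_nodule objects", call. = FALSE)
  }
  out
}

flatten_predictions <- function(x) {
  if (inherits(x, "predicted_nodule")) return(list(x))
  out <- list()
  for (el in x) {
    if (inherits(el, "predicted_nodule")) out <- c(out, list(el))
    else out <- c(out, flatten_predictions(el))
  }
  out
}

# Globally unique nodule key within one dataset.
nodule_key <- function(case_id, nodule_id) paste(case_id, nodule_id, sep = "/")
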