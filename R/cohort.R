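#' LAD mean dose difference between treatment positions
#'
#' The quantity that drives the position decision: the mean dose to the left
#' anterior descending coronary artery (LAD) planned in the supine position
#' minus the mean dose planned in the prone position, in Gy. A positive
#' difference means the prone position spares the LAD; a negative difference
#' means the supine position does.
#'
#' @param lad_supine Numeric vector of LAD mean doses in the supine position (Gy).
#' @param lad_prone Numeric vector of LAD mean doses in the prone position (Gy).
#' @return Numeric vector of dose differences (Gy), `lad_supine - lad_prone`.
#' @examples
#' compute_dose_difference(10, 3)   # +7 Gy: prone preferable
#' compute_dose_difference(1.2, 4)  # -2.8 Gy: supine preferable
#' @export
compute_dose_difference <- function(lad_supine, lad_prone) {
  if (length(lad_supine) != length(lad_prone)) {
    stop("lad_supine and lad_prone must have equal length")
  }
  bad <- !is.finite(lad_supine) | !is.finite(lad_prone)
  if (any(bad)) {
    stop("missing or non-finite LAD dose at position(s): ",
         paste(which(bad), collapse = ", "))
  }
  lad_supine - lad_prone
}

#' Gold-standard position label from the dose difference
#'
#' Encodes the reference ("gold standard") decision made from full treatment
#' plans in both positions: `0` when the prone position is preferred (positive
#' dose difference) and `1` when the supine position is preferred (negative
#' dose difference). An exact zero difference carries no dosimetric preference
#' and is deterministically labelled `0` (prone); with continuous doses ties
#' have probability zero and the rule only fixes reproducibility.
#'
#' @param dose_diff Numeric vector of LAD mean dose differences (supine -
#'   prone, Gy).
#' @return Integer vector of labels: `1` = supine preferred, `0` = prone
#'   preferred.
#' @examples
#' gold_standard_label(c(2, -1.5, 0))  # 0, 1, 0
#' @export
gold_standard_label <- function(dose_diff) {
  if (any(!is.finite(dose_diff))) {
    stop("dose_diff must be finite at position(s): ",
         paste(which(!is.finite(dose_diff)), collapse = ", "))
  }
  as.integer(dose_diff < 0)
}

# Required numeric columns and their lower bounds (closed when strict = FALSE).
.cohort_covariates <- c("bmi", "a_heart", "d_median", "ptv")
.cohort_bounds <- list(
  bmi      = list(min = 0, strict = TRUE),
  a_heart  = list(min = 0, strict = FALSE),
  d_median = list(min = 0, strict = FALSE),
  ptv      = list(min = 0, strict = TRUE),
  lad_supine = list(min = 0, strict = FALSE),
  lad_prone  = list(min = 0, strict = FALSE)
)

#' Construct and validate a labelled patient cohort
#'
#' Builds a `position_cohort` from a data frame with one row per patient.
#' Required columns are `patient_id`, the four covariates `bmi` (kg/m^2),
#' `a_heart` (in-field heart area on the mid-heart supine CT slice, cm^2),
#' `d_median` (median LAD-chest-wall distance, mm) and `ptv` (planning target
#' volume, cm^3), plus dose information: either both `lad_supine` and
#' `lad_prone` (Gy) or a precomputed `dose_diff` column. An optional
#' `heart_diff` column (mean heart-dose difference, Gy) is carried along, and
#' an optional `label` column overrides the label otherwise derived with
#' [gold_standard_label()].
#'
#' @param data A data frame of patient records.
#' @return A data frame of class `position_cohort` with columns `patient_id`,
#'   the covariates, dose columns when present, `dose_diff` and integer
#'   `label`.
#' @seealso [read_cohort_csv()], [generate_cohort()]
#' @export
as_cohort <- function(data) {
  data <- as.data.frame(data)
  if (nrow(data) == 0L) stop("cohort is empty")

  required <- c("patient_id", .cohort_covariates)
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols)) {
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  }
  has_doses <- all(c("lad_supine", "lad_prone") %in% names(data))
  if (!has_doses && !"dose_diff" %in% names(data)) {
    stop("need either both lad_supine and lad_prone, or a dose_diff column")
  }

  num_cols <- intersect(c(.cohort_covariates, "lad_supine", "lad_prone",
                          "dose_diff", "heart_diff", "label"), names(data))
  for (col in num_cols) {
    v <- data[[col]]
    if (!is.numeric(v)) {
      v <- suppressWarnings(as.numeric(as.character(v)))
      if (any(is.na(v) & !is.na(data[[col]]))) {
        stop("non-numeric value in column '", col, "' at row(s): ",
             paste(which(is.na(v) & !is.na(data[[col]])), collapse = ", "))
      }
      data[[col]] <- v
    }
    if (anyNA(data[[col]]) && col != "heart_diff") {
      stop("missing value in column '", col, "' at row(s): ",
           paste(which(is.na(data[[col]])), collapse = ", "))
    }
  }

  for (col in intersect(names(.cohort_bounds), names(data))) {
    b <- .cohort_bounds[[col]]
    bad <- if (b$strict) data[[col]] <= b$min else data[[col]] < b$min
    if (any(bad)) {
      stop("column '", col, "' violates ",
           if (b$strict) "> " else ">= ", b$min,
           " at row(s): ", paste(which(bad), collapse = ", "))
    }
  }

  if (has_doses) {
    dd <- compute_dose_difference(data$lad_supine, data$lad_prone)
    if ("dose_diff" %in% names(data) &&
        any(abs(data$dose_diff - dd) > 1e-8)) {
      stop("dose_diff column inconsistent with lad_supine - lad_prone at row(s): ",
           paste(which(abs(data$dose_diff - dd) > 1e-8), collapse = ", "))
    }
    data$dose_diff <- dd
  }

  if ("label" %in% names(data)) {
    if (!all(data$label %in% c(0, 1))) {
      stop("label column must be 0/1; offending row(s): ",
           paste(which(!data$label %in% c(0, 1)), collapse = ", "))
    }
    data$label <- as.integer(data$label)
  } else {
    data$label <- gold_standard_label(data$dose_diff)
  }

  data$patient_id <- as.character(data$patient_id)
  class(data) <- c("position_cohort", "data.frame")
  data
}

#' Read a patient cohort from CSV
#'
#' Reads an RFC-4180 CSV with a header row into a validated
#' [position_cohort][as_cohort]. Column names may be remapped with
#' `column_map`, a named character vector `c(canonical = "file_column")`,
#' e.g. `c(bmi = "BodyMassIndex")`. Labels are derived from the dose
#' difference with [gold_standard_label()] unless the file supplies a
#' `label` column.
#'
#' @param path Path to the CSV file.
#' @param column_map Optional named character vector mapping canonical column
#'   names to the names used in the file.
#' @return A `position_cohort` data frame.
#' @export
read_cohort_csv <- function(path, column_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(data) == 0L) stop("empty cohort file: ", path)
  if (!is.null(column_map)) {
    for (canonical in names(column_map)) {
      from <- column_map[[canonical]]
      if (!from %in% names(data)) {
        stop("column_map refers to absent column '", from, "'")
      }
      names(data)[names(data) == from] <- canonical
    }
  }
  as_cohort(data)
}

#' Write a patient cohort to CSV
#'
#' Inverse of [read_cohort_csv()]: writes all cohort columns with full
#' precision (15 significant digits) so that a write-then-read round trip
#' reproduces every numeric field.
#'
#' @param cohort A `position_cohort`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  stopifnot(inherits(cohort, "position_cohort"))
  out <- as.data.frame(cohort)
  for (col in names(out)) {
    if (is.numeric(out[[col]]) && !is.integer(out[[col]])) {
      out[[col]] <- formatC(out[[col]], digits = 15, format = "g")
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.position_cohort <- function(x, ...) {
  cat(sprintf("<position_cohort> %d patients, %d supine-preferred (label 1), %d prone-preferred (label 0)\n",
              nrow(x), sum(x$label == 1), sum(x$label == 0)))
  NextMethod()
}
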