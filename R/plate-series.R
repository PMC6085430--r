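#' One well's OD600 time series
#'
#' A `plate_series` holds the optical-density trace of a single well together
#' with its metadata. Times are stored in hours internally; readers convert
#' from minutes or seconds on ingest.
#'
#' @param well_id Plate coordinate, e.g. `"A1"`.
#' @param times Numeric vector of timestamps in hours, strictly increasing.
#' @param od Numeric vector of OD600 readings, same length as `times`.
#'   Blank-corrected values may be non-positive; they are masked downstream
#'   when the log transform is taken.
#' @param strain,condition Character labels for the strain and the growth
#'   condition (sugar mixture / supplement).
#' @param replicate Positive integer replicate index.
#' @param time_unit Unit of the supplied `times`; converted to hours.
#' @param blank_correction Character note recording any blank correction
#'   already applied (set by [blank_correct()]).
#'
#' @return An object of class `plate_series`.
#' @export
#' @examples
#' ps <- plate_series("A1", times = 0:5, od = 0.05 * 2^(0.5 * 0:5),
#'                    strain = "wt", condition = "glucose+lactose")
#' ps
plate_series <- function(well_id, times, od, strain = NA_character_,
                         condition = NA_character_, replicate = 1L,
                         time_unit = c("hours", "minutes", "seconds"),
                         blank_correction = "none") {
  time_unit <- match.arg(time_unit)
  times <- as.numeric(times) / switch(time_unit,
    hours = 1, minutes = 60, seconds = 3600)
  od <- as.numeric(od)
  if (length(times) != length(od)) {
    stop("`times` and `od` must have the same length", call. = FALSE)
  }
  if (length(times) < 4L) {
    stop("a plate series needs at least 4 timepoints", call. = FALSE)
  }
  if (anyNA(times) || any(!is.finite(times))) {
    stop("`times` must be finite", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (anyNA(od) || any(!is.finite(od))) {
    stop("`od` must be finite", call. = FALSE)
  }
  if (!is.na(replicate) && (replicate != as.integer(replicate) || replicate < 1)) {
    stop("`replicate` must be a positive integer", call. = FALSE)
  }
  structure(
    list(well_id = as.character(well_id), strain = as.character(strain),
         condition = as.character(condition), replicate = as.integer(replicate),
         times = times, od = od, blank_correction = blank_correction),
    class = "plate_series"
  )
}

#' @export
print.plate_series <- function(x, ...) {
  cat(sprintf("<plate_series> well %s  strain=%s  condition=%s  rep=%d\n",
              x$well_id, x$strain, x$condition, x$replicate))
  cat(sprintf("  %d timepoints, %.2f-%.2f h, OD %.4g-%.4g (blank: %s)\n",
              length(x$times), min(x$times), max(x$times),
              min(x$od), max(x$od), x$blank_correction))
  invisible(x)
}

#' @export
length.plate_series <- function(x) length(x$times)

#' Plate layout: mapping from wells to sample metadata
#'
#' @param wells data.frame with columns `well`, `strain`, `condition`,
#'   `replicate`, `is_blank`. Missing `replicate` defaults to 1, missing
#'   `is_blank` to `FALSE`.
#'
#' @return An object of class `plate_layout` (a validated data.frame).
#' @export
#' @examples
#' plate_layout(data.frame(well = c("A1", "H12"),
#'                         strain = c("wt", "blank"),
#'                         condition = "glc+lac",
#'                         replicate = 1,
#'                         is_blank = c(FALSE, TRUE)))
plate_layout <- function(wells) {
  wells <- as.data.frame(wells)
  required <- c("well", "strain", "condition")
  missing_cols <- setdiff(required, names(wells))
  if (length(missing_cols)) {
    stop("layout is missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(wells$replicate)) wells$replicate <- 1L
  if (is.null(wells$is_blank)) wells$is_blank <- FALSE
  wells$well <- as.character(wells$well)
  wells$is_blank <- as.logical(wells$is_blank)
  if (anyDuplicated(wells$well)) {
    stop("duplicate well id(s) in layout: ",
         paste(unique(wells$well[duplicated(wells$well)]), collapse = ", "),
         call. = FALSE)
  }
  if (!any(!wells$is_blank)) {
    stop("layout must contain at least one non-blank well", call. = FALSE)
  }
  class(wells) <- c("plate_layout", "data.frame")
  wells
}

#' Read a plate layout from CSV or YAML
#'
#' CSV layouts carry the columns `well`, `strain`, `condition`, `replicate`,
#' `is_blank`. YAML layouts map each well id to a mapping with those fields,
#' e.g. `A1: {strain: wt, condition: glc+lac, replicate: 1}`.
#'
#' @param path Path to a `.csv`/`.tsv` or `.yml`/`.yaml` file.
#' @return A [plate_layout()].
#' @export
read_plate_layout <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yml", "yaml")) {
    raw <- yaml::read_yaml(path)
    rows <- lapply(names(raw), function(w) {
      entry <- raw[[w]]
      data.frame(well = w,
                 strain = entry$strain %||% NA_character_,
                 condition = entry$condition %||% NA_character_,
                 replicate = entry$replicate %||% 1L,
                 is_blank = isTRUE(entry$is_blank))
    })
    plate_layout(do.call(rbind, rows))
  } else {
    sep <- if (ext == "tsv") "\t" else ","
    plate_layout(utils::read.table(path, header = TRUE, sep = sep,
                                   stringsAsFactors = FALSE))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
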