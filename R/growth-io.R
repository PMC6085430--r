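#' Read plate-reader OD600 time series
#'
#' Parses a long- or wide-format table of OD600 readings and attaches
#' metadata from a plate layout. Long tables carry the columns
#' `(time, well, od)`; wide tables have the time column first followed by one
#' column per well. Times are converted to hours on ingest.
#'
#' @param source A file path or a data.frame.
#' @param layout A [plate_layout()] covering every well in the table.
#' @param dialect `"long"` or `"wide"`.
#' @param time_unit Unit of the time column (`"hours"`, `"minutes"`,
#'   `"seconds"`); converted to hours.
#' @param sep Field separator when `source` is a path (default `","`).
#'
#' @return A list of class `plate_collection` with elements `series` (list of
#'   [plate_series()] for the non-blank wells) and `blanks` (list of
#'   [plate_series()] for the blank wells).
#' @export
#' @examples
#' lay <- plate_layout(data.frame(well = c("A1", "A2"), strain = c("wt", "s"),
#'                                condition = "glc+lac"))
#' tab <- data.frame(time = c(0, 10, 20), A1 = c(0.05, 0.06, 0.07),
#'                   A2 = c(0.05, 0.055, 0.06))
#' pc <- read_plate_table(tab, lay, dialect = "wide", time_unit = "minutes")
#' length(pc$series)
read_plate_table <- function(source, layout, dialect = c("long", "wide"),
                             time_unit = c("hours", "minutes", "seconds"),
                             sep = ",") {
  dialect <- match.arg(dialect)
  time_unit <- match.arg(time_unit)
  stopifnot(inherits(layout, "plate_layout"))
  tab <- if (is.character(source)) {
    utils::read.table(source, header = TRUE, sep = sep,
                      stringsAsFactors = FALSE, check.names = FALSE)
  } else {
    as.data.frame(source, check.names = FALSE)
  }

  if (dialect == "wide") {
    if (names(tab)[1] != "time") {
      stop("wide tables must have `time` as their first column, found `",
           names(tab)[1], "`", call. = FALSE)
    }
    wells <- names(tab)[-1]
    long <- data.frame(
      time = rep(tab$time, times = length(wells)),
      well = rep(wells, each = nrow(tab)),
      od   = unlist(tab[-1], use.names = FALSE)
    )
  } else {
    needed <- c("time", "well", "od")
    if (!all(needed %in% names(tab))) {
      stop("long tables need columns (time, well, od); found (",
           paste(names(tab), collapse = ", "), ")", call. = FALSE)
    }
    long <- tab[needed]
  }

  unknown <- setdiff(unique(long$well), layout$well)
  if (length(unknown)) {
    stop("well(s) not in layout: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  bad_od <- which(!is.finite(suppressWarnings(as.numeric(long$od))))
  if (length(bad_od)) {
    stop("non-numeric od value at row(s): ",
         paste(utils::head(bad_od, 5), collapse = ", "), call. = FALSE)
  }
  long$od <- as.numeric(long$od)
  if (anyDuplicated(long[c("time", "well")])) {
    dup <- long[duplicated(long[c("time", "well")]), , drop = FALSE][1, ]
    stop(sprintf("duplicate reading for well %s at time %s", dup$well, dup$time),
         call. = FALSE)
  }

  build_one <- function(w) {
    rows <- long[long$well == w, , drop = FALSE]
    rows <- rows[order(rows$time), , drop = FALSE]
    meta <- layout[layout$well == w, , drop = FALSE]
    plate_series(w, rows$time, rows$od, strain = meta$strain,
                 condition = meta$condition, replicate = meta$replicate,
                 time_unit = time_unit)
  }
  present <- layout$well[layout$well %in% long$well]
  is_blank <- layout$is_blank[match(present, layout$well)]
  out <- list(series = lapply(present[!is_blank], build_one),
              blanks = lapply(present[is_blank], build_one))
  names(out$series) <- present[!is_blank]
  names(out$blanks) <- present[is_blank]
  class(out) <- "plate_collection"
  out
}

#' @export
print.plate_collection <- function(x, ...) {
  cat(sprintf("<plate_collection> %d sample wells, %d blank wells\n",
              length(x$series), length(x$blanks)))
  invisible(x)
}

#' Subtract the blank signal from a well's OD trace
#'
#' `mean_per_timepoint` subtracts, at each timepoint, the mean reading of the
#' blank wells (which must share the series' time grid); `scalar` subtracts a
#' single constant.
#'
#' @param series A [plate_series()].
#' @param blanks List of blank [plate_series()] (for `mean_per_timepoint`),
#'   or ignored for `scalar`.
#' @param method `"mean_per_timepoint"` or `"scalar"`.
#' @param value Scalar blank when `method = "scalar"`.
#'
#' @return The corrected [plate_series()]; the correction applied is recorded
#'   in its `blank_correction` field. Corrected OD may be non-positive; such
#'   points are masked later by [log_transform()].
#' @export
blank_correct <- function(series, blanks = list(),
                          method = c("mean_per_timepoint", "scalar"),
                          value = NULL) {
  method <- match.arg(method)
  stopifnot(inherits(series, "plate_series"))
  if (method == "scalar") {
    if (is.null(value) || !is.finite(value)) {
      stop("`value` must be a finite scalar for scalar correction",
           call. = FALSE)
    }
    est <- rep(value, length(series$times))
    note <- sprintf("scalar %.6g", value)
  } else {
    if (!length(blanks)) {
      stop("mean_per_timepoint correction requires at least one blank well",
           call. = FALSE)
    }
    mats <- lapply(blanks, function(b) {
      if (length(b$times) != length(series$times) ||
          max(abs(b$times - series$times)) > 1e-9) {
        stop("blank well ", b$well_id, " is not on the series' time grid",
             call. = FALSE)
      }
      b$od
    })
    est <- rowMeans(do.call(cbind, mats))
    note <- sprintf("mean of %d blank well(s) per timepoint", length(blanks))
  }
  out <- series
  out$od <- series$od - est
  out$blank_correction <- if (identical(series$blank_correction, "none")) {
    note
  } else {
    paste(series$blank_correction, note, sep = " + ")
  }
  out
}

# Fixed column orders for the tabular result records.
.lag_cols <- c("well", "strain", "condition", "replicate", "Xi", "Xf",
               "lag_t", "gen_time", "ratio", "mu1", "mu2", "is_diauxic",
               "reason", "sse", "n_masked", "error")
.summary_cols <- c("group", "n", "q1", "median", "q3", "whisker_low",
                   "whisker_high", "n_outliers")

#' Write analysis records to CSV
#'
#' Serializes a homogeneous collection of diauxic-lag records or group
#' summaries with a fixed column order and 12 significant digits, so that a
#' write/read round trip reproduces numeric values within 1e-12 (relative).
#'
#' @param records A data.frame as returned by [analyze_plate()], a list of
#'   `diauxic_lag` objects, or a list of `group_summary` objects.
#' @param sink Output file path or connection.
#' @return Invisibly, the data.frame that was written.
#' @export
write_results <- function(records, sink) {
  df <- results_frame(records)
  out <- df
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) {
    ifelse(is.na(v), NA_character_, sprintf("%.12g", v))
  })
  utils::write.table(out, sink, sep = ",", row.names = FALSE, quote = TRUE,
                     na = "NA")
  invisible(df)
}

results_frame <- function(records) {
  if (is.data.frame(records)) return(records)
  if (!is.list(records)) stop("unsupported record collection", call. = FALSE)
  if (!length(records)) {
    return(stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = length(.lag_cols))), .lag_cols))
  }
  classes <- unique(vapply(records, function(r) class(r)[1], character(1)))
  if (length(classes) != 1L) {
    stop("mixed record types: ", paste(classes, collapse = ", "),
         call. = FALSE)
  }
  rows <- switch(classes,
    diauxic_lag = lapply(records, as.data.frame),
    group_summary = lapply(records, as.data.frame),
    stop("unsupported record type: ", classes, call. = FALSE))
  do.call(rbind, rows)
}

#' Read back a results CSV written by [write_results()]
#'
#' @param source File path or connection.
#' @return A data.frame.
#' @export
read_results <- function(source) {
  utils::read.table(source, header = TRUE, sep = ",",
                    stringsAsFactors = FALSE)
}
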