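#' Log-transform an OD600 trace
#'
#' Takes log2 of the OD values so that slopes read directly in doublings per
#' hour. Points at or below `floor` are masked (dropped and counted) rather
#' than clamped: the logarithm of near-blank readings would otherwise
#' dominate the least-squares fits.
#'
#' @param series A [plate_series()].
#' @param floor OD threshold below which points are masked (default 0.01).
#' @param ceiling Optional OD ceiling: points at or above it are masked too.
#'   Use on saturating plates to exclude the stationary tail, which would
#'   otherwise present a second plateau to the segment fitter; the lag
#'   statistic only needs the early second-phase slope.
#' @return An object of class `log_series` with fields `times`, `y`
#'   (log2 OD at the retained points), `floor`, `n_masked`, `interval`
#'   (median sampling interval, hours) and the well metadata.
#' @export
log_transform <- function(series, floor = 0.01, ceiling = NULL) {
  stopifnot(inherits(series, "plate_series"))
  if (!is.finite(floor) || floor <= 0) {
    stop("`floor` must be a positive OD value", call. = FALSE)
  }
  keep <- series$od > floor
  if (!is.null(ceiling)) {
    if (ceiling <= floor) stop("`ceiling` must exceed `floor`", call. = FALSE)
    keep <- keep & series$od < ceiling
  }
  n_masked <- sum(!keep)
  if (sum(keep) < 9L) {
    stop(sprintf(paste0("insufficient data in well %s: %d points retained ",
                        "above floor %.3g (%d masked); need at least 9"),
                 series$well_id, sum(keep), floor, n_masked),
         call. = FALSE)
  }
  structure(
    list(times = series$times[keep], y = log2(series$od[keep]),
         floor = floor, n_masked = n_masked,
         interval = stats::median(diff(series$times)),
         well_id = series$well_id, strain = series$strain,
         condition = series$condition, replicate = series$replicate),
    class = "log_series"
  )
}

# Closed-form OLS of y on x over index interval [i, j], vectorized over
# equal-length index vectors using prefix sums. Returns slope, intercept, sse.
.interval_ols <- function(px, py, pxx, pxy, pyy, i, j) {
  ns  <- j - i + 1
  sx  <- px[j + 1L] - px[i]
  sy  <- py[j + 1L] - py[i]
  sxx <- pxx[j + 1L] - pxx[i]
  sxy <- pxy[j + 1L] - pxy[i]
  syy <- pyy[j + 1L] - pyy[i]
  sxx_c <- sxx - sx * sx / ns
  sxy_c <- sxy - sx * sy / ns
  syy_c <- syy - sy * sy / ns
  slope <- sxy_c / sxx_c
  intercept <- (sy - slope * sx) / ns
  sse <- pmax(syy_c - slope * sxy_c, 0)
  list(slope = slope, intercept = intercept, sse = sse, n = ns)
}

# Simple scalar OLS used for single-segment fits.
.ols_line <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  sxy <- sum((x - mx) * (y - my))
  slope <- sxy / sxx
  intercept <- my - slope * mx
  sse <- sum((y - intercept - slope * x)^2)
  list(slope = slope, intercept = intercept, sse = sse, n = n)
}

#' Fit three line segments to a log-OD series
#'
#' Performs an exhaustive search over all breakpoint pairs `(b1, b2)` such
#' that each of the three segments holds at least `min_pts` points. Each
#' candidate segmentation fits its three segments independently by ordinary
#' least squares (discontinuities allowed at the breakpoints); the candidate
#' with the smallest total squared error wins, ties broken by the smaller
#' `b1`, then the smaller `b2`. The sampling grids involved are short (at
#' most a few dozen points at 10-minute intervals over 12 h), so exhaustive
#' enumeration is exact and cheap.
#'
#' @param ls A [log_transform()] result.
#' @param min_pts Minimum points per segment; default
#'   `max(3, floor(0.05 * n))` where `n` is the number of retained points.
#' @return An object of class `segment_fit` with breakpoint indices `b1`,
#'   `b2` (last retained-grid index of segments 1 and 2), per-segment
#'   `slopes` (log2-OD per hour, i.e. doublings/hour), `intercepts`, point
#'   counts `n_seg`, per-segment `sse_seg`, total `sse`, and the one-segment
#'   OLS `sse_one` used by [detect_diauxie()].
#' @export
fit_three_segments <- function(ls, min_pts = NULL) {
  stopifnot(inherits(ls, "log_series"))
  x <- ls$times; y <- ls$y; n <- length(x)
  if (is.null(min_pts)) min_pts <- max(3L, floor(0.05 * n))
  min_pts <- as.integer(min_pts)
  if (min_pts < 3L) stop("`min_pts` must be at least 3", call. = FALSE)
  if (n < 3L * min_pts) {
    stop(sprintf("need at least %d points for 3 segments of >= %d, have %d",
                 3L * min_pts, min_pts, n), call. = FALSE)
  }

  px  <- c(0, cumsum(x))
  py  <- c(0, cumsum(y))
  pxx <- c(0, cumsum(x * x))
  pxy <- c(0, cumsum(x * y))
  pyy <- c(0, cumsum(y * y))

  b1_range <- min_pts:(n - 2L * min_pts)
  # sse of segment 1 (1..b1) and segment 3 (b2+1..n) for every admissible cut
  sse1 <- .interval_ols(px, py, pxx, pxy, pyy,
                        rep(1L, length(b1_range)), b1_range)$sse
  b2_range <- (2L * min_pts):(n - min_pts)
  sse3 <- .interval_ols(px, py, pxx, pxy, pyy,
                        b2_range + 1L, rep(n, length(b2_range)))$sse

  # all candidate pairs, b1-major then b2 ascending so which.min's
  # first-minimum rule implements the tie-break
  reps <- (n - min_pts) - (b1_range + min_pts) + 1L
  b1v <- rep(b1_range, times = reps)
  b2v <- unlist(lapply(b1_range, function(b1) (b1 + min_pts):(n - min_pts)),
                use.names = FALSE)
  mid <- .interval_ols(px, py, pxx, pxy, pyy, b1v + 1L, b2v)$sse
  total <- sse1[match(b1v, b1_range)] + mid + sse3[match(b2v, b2_range)]
  best <- which.min(total)
  b1 <- b1v[best]; b2 <- b2v[best]

  seg_idx <- list(1:b1, (b1 + 1L):b2, (b2 + 1L):n)
  segs <- lapply(seg_idx, function(ix) .ols_line(x[ix], y[ix]))
  one <- .ols_line(x, y)

  structure(
    list(b1 = b1, b2 = b2,
         slopes = vapply(segs, `[[`, numeric(1), "slope"),
         intercepts = vapply(segs, `[[`, numeric(1), "intercept"),
         n_seg = lengths(seg_idx),
         sse_seg = vapply(segs, `[[`, numeric(1), "sse"),
         sse = sum(vapply(segs, `[[`, numeric(1), "sse")),
         sse_one = one$sse, slope_one = one$slope,
         min_pts = min_pts, n = n),
    class = "segment_fit"
  )
}

#' @export
print.segment_fit <- function(x, ...) {
  cat(sprintf("<segment_fit> breakpoints at indices (%d, %d) of %d points\n",
              x$b1, x$b2, x$n))
  cat(sprintf("  slopes (dbl/h): %.4g | %.4g | %.4g   total sse %.4g\n",
              x$slopes[1], x$slopes[2], x$slopes[3], x$sse))
  invisible(x)
}

#' Diauxic lag from a three-segment fit
#'
#' Extrapolates the three fitted lines and computes the intersection `Xi` of
#' segments 1 and 2 and `Xf` of segments 2 and 3. The diauxic lag is
#' `lag_t = Xf - Xi`; the first-sugar generation time is `g = 1/slope_1`
#' (hours per doubling, slopes being in log2 units); the normalized lag
#' ratio is `lag_t / g = lag_t * slope_1`. Because the intersections are
#' extrapolated from the straight portions, curved retardation/acceleration
#' points near the transitions do not bias the lag estimate.
#'
#' @param fit A [fit_three_segments()] result.
#' @return An object of class `diauxic_lag` with fields `Xi`, `Xf`, `lag_t`,
#'   `gen_time`, `ratio`, `mu1`, `mu2` (doublings/hour) and `sse`.
#' @export
lag_from_fit <- function(fit) {
  stopifnot(inherits(fit, "segment_fit"))
  s <- fit$slopes; a <- fit$intercepts
  tol <- 1e-12 * max(1, abs(s))
  if (s[1] <= 0) {
    stop("no growth: first-segment slope is not positive", call. = FALSE)
  }
  if (abs(s[1] - s[2]) <= tol || abs(s[2] - s[3]) <= tol) {
    stop("undefined intersection: adjacent segments are parallel",
         call. = FALSE)
  }
  Xi <- (a[2] - a[1]) / (s[1] - s[2])
  Xf <- (a[3] - a[2]) / (s[2] - s[3])
  lag_t <- Xf - Xi
  gen_time <- 1 / s[1]
  structure(
    list(Xi = Xi, Xf = Xf, lag_t = lag_t, gen_time = gen_time,
         ratio = lag_t * s[1], mu1 = s[1], mu2 = s[3], sse = fit$sse),
    class = "diauxic_lag"
  )
}

#' @export
print.diauxic_lag <- function(x, ...) {
  cat(sprintf("<diauxic_lag> Xi=%.3f h  Xf=%.3f h  lag=%.3f h  g=%.3f h  ratio=%.3f\n",
              x$Xi, x$Xf, x$lag_t, x$gen_time, x$ratio))
  invisible(x)
}

#' @export
as.data.frame.diauxic_lag <- function(x, ...) {
  data.frame(Xi = x$Xi, Xf = x$Xf, lag_t = x$lag_t, gen_time = x$gen_time,
             ratio = x$ratio, mu1 = x$mu1, mu2 = x$mu2, sse = x$sse)
}

#' Classify a growth curve as diauxic or monophasic
#'
#' A curve is called diauxic only if all three criteria hold:
#' (a) the one-segment OLS sse exceeds `r_min` times the three-segment sse
#' (a single line is a much worse description);
#' (b) the middle-segment slope is at most `slope_frac` of the first-segment
#' slope (growth genuinely arrests);
#' (c) the extrapolated lag is at least `min_lag` (default two sampling
#' intervals; shorter gaps are within grid resolution).
#' The first failing criterion is returned as the reason. Shifts between two
#' PTS sugars produce near-monophasic curves, which this test routes away
#' from the lag statistic while still reporting a growth rate.
#'
#' @param ls The [log_transform()] result the fit was computed on.
#' @param fit The [fit_three_segments()] result.
#' @param r_min Minimum sse ratio for criterion (a); default 5.
#' @param slope_frac Maximum middle/first slope fraction for (b); default 0.25.
#' @param min_lag Minimum lag in hours for (c); default twice the sampling
#'   interval.
#' @return List with `is_diauxic` (flag), `reason` (`NA` when diauxic, else
#'   the first failing criterion `"a"`, `"b"` or `"c"`), `sse_ratio` and
#'   `lag_t`.
#' @export
detect_diauxie <- function(ls, fit, r_min = 5, slope_frac = 0.25,
                           min_lag = NULL) {
  stopifnot(inherits(ls, "log_series"), inherits(fit, "segment_fit"))
  if (is.null(min_lag)) min_lag <- 2 * ls$interval
  abs_tol <- 1e-10
  sse_ratio <- fit$sse_one / max(fit$sse, abs_tol)
  if (fit$sse_one < abs_tol || sse_ratio < r_min) {
    return(list(is_diauxic = FALSE, reason = "a", sse_ratio = sse_ratio,
                lag_t = NA_real_))
  }
  s <- fit$slopes
  if (s[1] <= 0) {
    return(list(is_diauxic = FALSE, reason = "no_growth",
                sse_ratio = sse_ratio, lag_t = NA_real_))
  }
  if (s[2] > slope_frac * s[1]) {
    return(list(is_diauxic = FALSE, reason = "b", sse_ratio = sse_ratio,
                lag_t = NA_real_))
  }
  lag_t <- tryCatch(lag_from_fit(fit)$lag_t, error = function(e) NA_real_)
  if (!is.finite(lag_t) || lag_t < min_lag) {
    return(list(is_diauxic = FALSE, reason = "c", sse_ratio = sse_ratio,
                lag_t = lag_t))
  }
  list(is_diauxic = TRUE, reason = NA_character_, sse_ratio = sse_ratio,
       lag_t = lag_t)
}

#' Analyze a whole plate of growth curves
#'
#' Runs, per well, [log_transform()] then [fit_three_segments()],
#' [detect_diauxie()] and [lag_from_fit()]. Wells classified non-diauxic
#' report the single-segment growth rate and no ratio; wells that fail
#' outright (e.g. all readings below the OD floor) produce a per-well error
#' record without aborting the plate.
#'
#' @param series A `plate_collection`, a list of [plate_series()], or a
#'   single [plate_series()].
#' @param floor OD floor passed to [log_transform()].
#' @param ceiling Optional OD ceiling passed to [log_transform()] for
#'   saturating plates.
#' @param min_pts Minimum points per segment (see [fit_three_segments()]).
#' @param r_min,slope_frac,min_lag Classification thresholds
#'   (see [detect_diauxie()]).
#' @return A data.frame with one row per well: `well`, `strain`, `condition`,
#'   `replicate`, `Xi`, `Xf`, `lag_t`, `gen_time`, `ratio`, `mu1`, `mu2`,
#'   `is_diauxic`, `reason`, `sse`, `n_masked`, `error`.
#' @export
#' @examples
#' pre <- strain_presets()
#' plate <- simulate_plate(pre, replicates = 2, seed = 1)
#' res <- analyze_plate(plate$series)
#' res[, c("well", "strain", "lag_t", "ratio")]
analyze_plate <- function(series, floor = 0.01, ceiling = NULL,
                          min_pts = NULL, r_min = 5,
                          slope_frac = 0.25, min_lag = NULL) {
  if (inherits(series, "plate_collection")) series <- series$series
  if (inherits(series, "plate_series")) series <- list(series)
  if (!length(series)) stop("no series to analyze", call. = FALSE)

  na_row <- function(ps, msg = NA_character_) {
    data.frame(well = ps$well_id, strain = ps$strain, condition = ps$condition,
               replicate = ps$replicate, Xi = NA_real_, Xf = NA_real_,
               lag_t = NA_real_, gen_time = NA_real_, ratio = NA_real_,
               mu1 = NA_real_, mu2 = NA_real_, is_diauxic = NA,
               reason = NA_character_, sse = NA_real_, n_masked = NA_integer_,
               error = msg, stringsAsFactors = FALSE)
  }

  rows <- lapply(series, function(ps) {
    tryCatch({
      ls <- log_transform(ps, floor = floor, ceiling = ceiling)
      fit <- fit_three_segments(ls, min_pts = min_pts)
      det <- detect_diauxie(ls, fit, r_min = r_min, slope_frac = slope_frac,
                            min_lag = min_lag)
      row <- na_row(ps)
      row$is_diauxic <- det$is_diauxic
      row$reason <- det$reason
      row$n_masked <- ls$n_masked
      if (det$is_diauxic) {
        lag <- lag_from_fit(fit)
        row$Xi <- lag$Xi; row$Xf <- lag$Xf; row$lag_t <- lag$lag_t
        row$gen_time <- lag$gen_time; row$ratio <- lag$ratio
        row$mu1 <- lag$mu1; row$mu2 <- lag$mu2; row$sse <- lag$sse
      } else {
        # monophasic wells still carry a growth rate (single-line fit)
        row$mu1 <- fit$slope_one
        row$sse <- fit$sse
      }
      row
    }, error = function(e) na_row(ps, conditionMessage(e)))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
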