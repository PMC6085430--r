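# Independently written reference implementations used to cross-check the
# package's fitters. They share no code with the package internals: the
# segment oracle enumerates breakpoints with explicit loops and QR-based
# least squares (.lm.fit), the quantile oracle applies the interpolation
# formula for type-7 quantiles directly.

oracle_fit_three_segments <- function(x, y, min_pts = 3L) {
  n <- length(x)
  best_sse <- Inf
  best <- NULL
  for (b1 in min_pts:(n - 2L * min_pts)) {
    for (b2 in (b1 + min_pts):(n - min_pts)) {
      sse <- 0
      for (seg in list(1:b1, (b1 + 1L):b2, (b2 + 1L):n)) {
        f <- stats::.lm.fit(cbind(1, x[seg]), y[seg])
        sse <- sse + sum(f$residuals^2)
      }
      if (sse < best_sse) {  # strict < keeps the earliest (b1, b2) on ties
        best_sse <- sse
        best <- list(b1 = b1, b2 = b2, sse = sse)
      }
    }
  }
  best
}

oracle_lag_from_lines <- function(slopes, intercepts) {
  Xi <- (intercepts[2] - intercepts[1]) / (slopes[1] - slopes[2])
  Xf <- (intercepts[3] - intercepts[2]) / (slopes[2] - slopes[3])
  list(Xi = Xi, Xf = Xf, lag_t = Xf - Xi, gen_time = 1 / slopes[1],
       ratio = (Xf - Xi) * slopes[1])
}

oracle_quantile_type7 <- function(v, p) {
  v <- sort(v)
  n <- length(v)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  v[lo] + (h - lo) * (v[hi] - v[lo])
}

oracle_box <- function(v) {
  q1 <- oracle_quantile_type7(v, 0.25)
  q3 <- oracle_quantile_type7(v, 0.75)
  med <- oracle_quantile_type7(v, 0.5)
  iqr <- q3 - q1
  out <- v[v < q1 - 1.5 * iqr | v > q3 + 1.5 * iqr]
  inl <- v[!(v < q1 - 1.5 * iqr | v > q3 + 1.5 * iqr)]
  list(q1 = q1, median = med, q3 = q3,
       whisker_low = min(inl), whisker_high = max(inl),
       outliers = sort(out))
}

oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxx <- sum(x^2); sxy <- sum(x * y)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  list(slope = slope, intercept = intercept)
}

# convenience: a noiseless diauxic series with chosen parameters
make_curve <- function(..., schedule = default_schedule(), seed = NULL) {
  simulate_diauxic_curve(diauxic_params(...), schedule = schedule,
                         seed = seed)
}
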