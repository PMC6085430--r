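test_that("log transform is log2 with floor masking", {
  s <- plate_series("A1", seq(0, 2, by = 0.2), rep(0.05, 11))
  ls <- log_transform(s)
  expect_equal(ls$y, rep(log2(0.05), 11))

  doubling <- plate_series("A1", 0:10, 0.05 * 2^(0:10))
  expect_equal(diff(log_transform(doubling)$y), rep(1, 10))

  below <- plate_series("A1", seq_len(73) / 6,
                        c(rep(0.005, 70), rep(0.05, 3)))
  expect_error(log_transform(below), "insufficient data")
  expect_error(log_transform(doubling, floor = -1), "positive")
})

test_that("three-segment fit recovers exact piecewise input", {
  ps <- make_curve(od0 = 0.05, mu1 = 0.5, t1 = 4, t2 = 5, mu2 = 0.5)
  ls <- log_transform(ps)
  fit <- fit_three_segments(ls)
  expect_equal(fit$slopes, c(0.5, 0, 0.5), tolerance = 1e-9)
  # breakpoints at the grid points nearest the true phase boundaries
  expect_lt(abs(ls$times[fit$b1] - 4), 1 / 6 + 1e-9)
  expect_lt(abs(ls$times[fit$b2] - 5), 1 / 6 + 1e-9)
  expect_lt(fit$sse, 1e-18)
})

test_that("a straight line is fit equally well by one or three segments", {
  s <- plate_series("A1", default_schedule(),
                    0.05 * 2^(0.4 * default_schedule()))
  fit <- fit_three_segments(log_transform(s))
  expect_lt(fit$sse, 1e-18)
  expect_lt(fit$sse_one, 1e-18)
  expect_equal(fit$slopes, rep(0.4, 3), tolerance = 1e-9)
})

test_that("fit matches the brute-force breakpoint enumeration oracle", {
  for (seed in 1:10) {
    p <- diauxic_params(od0 = 0.05, mu1 = 0.5, t1 = 4, t2 = 5.5, mu2 = 0.45,
                        sigma = 0.02)
    ps <- simulate_diauxic_curve(p, seed = seed)
    ls <- log_transform(ps)
    fit <- fit_three_segments(ls, min_pts = 3)
    orc <- oracle_fit_three_segments(ls$times, ls$y, min_pts = 3)
    expect_identical(c(fit$b1, fit$b2), c(orc$b1, orc$b2))
    expect_equal(fit$sse, orc$sse, tolerance = 1e-9)
  }
})

test_that("lag geometry follows from the line intersections", {
  fit <- structure(list(slopes = c(0.5, 0, 0.5),
                        intercepts = c(log2(0.05), log2(0.2),
                                       log2(0.2) - 0.5 * 5),
                        sse = 0), class = "segment_fit")
  lag <- lag_from_fit(fit)
  expect_equal(lag$Xi, 4)
  expect_equal(lag$Xf, 5)
  expect_equal(lag$lag_t, 1)
  expect_equal(lag$gen_time, 2)
  expect_equal(lag$ratio, 0.5)

  par_fit <- fit; par_fit$slopes <- c(0.5, 0.5, 0.7)
  expect_error(lag_from_fit(par_fit), "parallel")
  ng_fit <- fit; ng_fit$slopes <- c(-0.1, 0, 0.5)
  expect_error(lag_from_fit(ng_fit), "no growth")
})

test_that("lag values agree with an independent intersection formula", {
  pre <- strain_presets()
  plate <- simulate_plate(pre, replicates = 6, seed = 7)
  for (ps in plate$series) {
    ls <- log_transform(ps)
    fit <- fit_three_segments(ls)
    lag <- lag_from_fit(fit)
    orc <- oracle_lag_from_lines(fit$slopes, fit$intercepts)
    expect_equal(lag$Xi, orc$Xi, tolerance = 1e-9)
    expect_equal(lag$Xf, orc$Xf, tolerance = 1e-9)
    expect_equal(lag$ratio, orc$ratio, tolerance = 1e-9)
  }
})

test_that("diauxie classification separates biphasic from monophasic", {
  mono <- plate_series("A1", default_schedule(),
                       0.05 * 2^(0.5 * default_schedule()))
  ls <- log_transform(mono)
  det <- detect_diauxie(ls, fit_three_segments(ls))
  expect_false(det$is_diauxic)
  expect_equal(det$reason, "a")

  dia <- make_curve(od0 = 0.05, mu1 = 0.5, t1 = 4, t2 = 5, mu2 = 0.5)
  ls2 <- log_transform(dia)
  det2 <- detect_diauxie(ls2, fit_three_segments(ls2))
  expect_true(det2$is_diauxic)
  expect_true(is.na(det2$reason))

  # a "plateau" still climbing at half the first-phase rate is not diauxie
  sched <- default_schedule()
  y <- ifelse(sched < 4, 0.5 * sched + log2(0.05),
       ifelse(sched < 6, 0.25 * (sched - 4) + log2(0.05) + 2,
              0.5 * (sched - 6) + log2(0.05) + 2.5))
  tilted <- plate_series("A1", sched, 2^y)
  ls3 <- log_transform(tilted)
  det3 <- detect_diauxie(ls3, fit_three_segments(ls3))
  expect_false(det3$is_diauxic)
  expect_equal(det3$reason, "b")
})

test_that("analyze_plate records per-well failures without aborting", {
  pre <- strain_presets(sigma = 0)
  plate <- simulate_plate(pre, replicates = 6, seed = 2)
  dead <- plate_series("D1", default_schedule(),
                       rep(0.005, 73), strain = "dead")
  res <- analyze_plate(c(plate$series, list(D1 = dead)))
  expect_equal(nrow(res), 19)
  expect_equal(sum(!is.na(res$error)), 1)
  expect_match(res$error[res$well == "D1"], "insufficient data")
  ok <- res[is.na(res$error), ]
  expect_equal(ok$ratio, plate$truth$ratio, tolerance = 1e-6)
})

test_that("ratio is invariant to OD rescaling", {
  p <- diauxic_params(od0 = 0.05, mu1 = 0.5, t1 = 4, t2 = 5.5, mu2 = 0.45,
                      sigma = 0.02)
  ps <- simulate_diauxic_curve(p, seed = 11)
  base <- lag_from_fit(fit_three_segments(log_transform(ps)))
  for (c_scale in c(0.1, 10)) {
    scaled <- ps
    scaled$od <- ps$od * c_scale
    # keep the floor proportional so the same points are retained
    fit <- fit_three_segments(log_transform(scaled, floor = 0.01 * c_scale))
    lag <- lag_from_fit(fit)
    expect_equal(lag$Xi, base$Xi, tolerance = 1e-9)
    expect_equal(lag$Xf, base$Xf, tolerance = 1e-9)
    expect_equal(lag$lag_t, base$lag_t, tolerance = 1e-9)
    expect_equal(lag$gen_time, base$gen_time, tolerance = 1e-9)
    expect_equal(lag$ratio, base$ratio, tolerance = 1e-9)
  }
})

test_that("ratio is invariant to the declared time unit", {
  p <- diauxic_params(od0 = 0.05, mu1 = 0.5, t1 = 4, t2 = 5.5, mu2 = 0.45,
                      sigma = 0.02)
  ps_h <- simulate_diauxic_curve(p, seed = 12)
  ps_m <- plate_series(ps_h$well_id, ps_h$times * 60, ps_h$od,
                       time_unit = "minutes")
  lag_h <- lag_from_fit(fit_three_segments(log_transform(ps_h)))
  lag_m <- lag_from_fit(fit_three_segments(log_transform(ps_m)))
  expect_equal(lag_m$ratio, lag_h$ratio, tolerance = 1e-9)
  expect_equal(lag_m$lag_t, lag_h$lag_t, tolerance = 1e-9)
})

test_that("ratio equals lag times first slope identically", {
  pre <- strain_presets()
  plate <- simulate_plate(pre, replicates = 3, seed = 5)
  res <- analyze_plate(plate$series)
  ok <- res[!is.na(res$ratio), ]
  expect_equal(ok$ratio, ok$lag_t * ok$mu1, tolerance = 1e-12)
  expect_equal(ok$ratio, ok$lag_t / ok$gen_time, tolerance = 1e-12)
})

test_that("estimated lag grows with the generated plateau duration", {
  lags <- vapply(seq(0.6, 3, by = 0.4), function(d) {
    ps <- make_curve(od0 = 0.05, mu1 = 0.5, t1 = 3, t2 = 3 + d, mu2 = 0.5)
    lag_from_fit(fit_three_segments(log_transform(ps)))$lag_t
  }, numeric(1))
  expect_true(all(diff(lags) >= -1e-9))
})

test_that("saturating plates are analyzable with an OD ceiling mask", {
  pre <- strain_presets(cap = 1.0)
  plate <- simulate_plate(pre, replicates = 3, seed = 6)
  res <- analyze_plate(plate$series, ceiling = 0.5)
  expect_true(all(res$is_diauxic))
  expect_equal(aggregate(ratio ~ strain, res, stats::median)$ratio,
               aggregate(ratio ~ strain, plate$truth, unique)$ratio,
               tolerance = 0.15)
})
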