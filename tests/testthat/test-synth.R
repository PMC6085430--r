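test_that("default schedule covers 12 h at 10-min intervals", {
  sched <- default_schedule()
  expect_length(sched, 73)
  expect_equal(diff(sched), rep(1 / 6, 72))
  ps <- simulate_diauxic_curve(diauxic_params(), seed = 1)
  expect_length(ps$times, 73)
})

test_that("noiseless curves follow the piecewise closed form", {
  p <- diauxic_params(od0 = 0.05, mu1 = 0.5, t1 = 4, t2 = 5, mu2 = 0.5,
                      sigma = 0, blank = 0)
  ps <- simulate_diauxic_curve(p)
  # 0.05 * 2^(0.5*4) = 0.2 at t1, flat through the plateau
  expect_equal(ps$od[ps$times == 4], 0.2)
  plateau <- ps$od[ps$times >= 4 & ps$times < 5]
  expect_equal(plateau, rep(0.2, length(plateau)))
  # closed form everywhere, to near machine precision
  expected <- ifelse(ps$times < 4, 0.05 * 2^(0.5 * ps$times),
              ifelse(ps$times < 5, 0.2, 0.2 * 2^(0.5 * (ps$times - 5))))
  expect_equal(ps$od, expected, tolerance = 1e-12)
})

test_that("parameter invariants are enforced", {
  expect_error(diauxic_params(od0 = -1), "od0")
  expect_error(diauxic_params(mu1 = 0), "rates")
  expect_error(diauxic_params(t1 = 5, t2 = 4), "t1 < t2")
  expect_error(diauxic_params(sigma = -0.1), "sigma")
  # cap below the plateau OD is impossible
  expect_error(diauxic_params(od0 = 0.05, mu1 = 1, t1 = 4, t2 = 5,
                              cap = 0.5), "cap")
  expect_error(simulate_diauxic_curve(diauxic_params(),
                                      schedule = c(0, 1, 1, 2)),
               "increasing")
})

test_that("noise is multiplicative lognormal with the stated sd", {
  p <- diauxic_params(od0 = 0.1, mu1 = 0.5, t1 = 4, t2 = 5, mu2 = 0.5,
                      sigma = 0.02)
  draws <- vapply(1:1000, function(s) {
    simulate_diauxic_curve(p, schedule = c(0, 1, 2, 3), seed = s)$od[2]
  }, numeric(1))
  mean_log2 <- log2(0.1 * 2^0.5)  # noiseless mean at t = 1
  se <- (0.02 / log(2)) / sqrt(1000)
  expect_lt(abs(mean(log2(draws)) - mean_log2), 3 * se)
  expect_equal(sd(log(draws)), 0.02, tolerance = 0.1)
})

test_that("simulate_plate is deterministic and emits analytic truth", {
  pre <- strain_presets()
  a <- simulate_plate(pre, replicates = 6, seed = 9)
  b <- simulate_plate(pre, replicates = 6, seed = 9)
  expect_identical(lapply(a$series, `[[`, "od"),
                   lapply(b$series, `[[`, "od"))
  expect_length(a$series, 18)
  expect_equal(nrow(a$truth), 18)
  expect_equal(sort(unique(a$truth$ratio)), c(0.5, 1.0, 2.0))
  # truth is analytic: ratio = lag * mu1 exactly
  expect_equal(a$truth$ratio, a$truth$lag_t * a$truth$mu1)
  # per-well streams are independent of each other but seed-reproducible
  c <- simulate_plate(pre, replicates = 6, seed = 10)
  expect_false(identical(a$series[["A1"]]$od, c$series[["A1"]]$od))

  dup <- c(pre, pre[1])
  expect_error(simulate_plate(dup, replicates = 2), "duplicate")
})

test_that("nucleotide timecourse templates hit their quoted fold changes", {
  # wild type: ~30% rise over basal, then plateau
  wt <- simulate_ppgpp_timecourse("wt_rise", basal = 0.10, sigma = 0)
  f <- fraction_of_total_g(wt, "ppGpp")
  expect_equal(max(f), 0.13, tolerance = 1e-12)
  expect_equal(f[1], 0.10, tolerance = 1e-12)

  # RelA-only: fivefold pppGpp spike at mid-lag
  sp <- simulate_ppgpp_timecourse("relA_spike", basal = 0.05, sigma = 0,
                                  schedule = seq(0, 3, by = 0.05))
  fq <- fraction_of_total_g(sp, "pppGpp")
  expect_equal(max(fq), 5 * 0.05, tolerance = 1e-12)

  # SpoT-only: precipitous drop to the floor
  dr <- simulate_ppgpp_timecourse("spoT_drop", basal = 0.10, floor_frac = 0,
                                  sigma = 0)
  expect_equal(min(fraction_of_total_g(dr, "ppGpp")), 0, tolerance = 1e-12)

  expect_error(simulate_ppgpp_timecourse("wt_rise", basal = 0.8),
               "overflow")
})

test_that("nucleotide generator fractions are proper at any noise level", {
  for (prof in c("wt_rise", "relA_spike", "spoT_drop")) {
    tc <- simulate_ppgpp_timecourse(prof, basal = 0.1, sigma = 0.1,
                                    seed = 4)
    fr <- sapply(c("ppGpp", "pppGpp", "GTP"),
                 function(s) fraction_of_total_g(tc, s))
    expect_true(all(fr >= 0 & fr <= 1))
    expect_equal(rowSums(fr), rep(1, nrow(fr)), tolerance = 1e-12)
  }
})

test_that("decay generator matches its exponential closed form", {
  tc <- simulate_decay(k = -log(2) / 0.5, n = 6, interval = 0.5, sigma = 0)
  f <- fraction_of_total_g(tc, "ppGpp")
  expect_equal(f[-1] / f[-6], rep(0.5, 5), tolerance = 1e-12)
  # semilog points exactly collinear
  resid <- stats::lm(log(f) ~ tc$times)$residuals
  expect_lt(max(abs(resid)), 1e-12)
  expect_error(simulate_decay(k = 0.1), "negative")
  expect_error(simulate_decay(k = -1, n = 2), "3 points")
})

test_that("qPCR generator encodes fold changes in Ct differences", {
  tab <- simulate_qpcr(c(ackA = 0.25, pta = 1.0), sigma = 0)
  # three technical replicates, identical without noise
  reps <- tab$ct[tab$sample == "treated" & tab$gene == "ackA"]
  expect_length(reps, 3)
  expect_equal(reps, rep(reps[1], 3))
  out <- ddct(tab, "ackA", "parC", "reference")
  expect_equal(out$ddct[out$sample == "treated"], 2)  # -log2(0.25)
  out2 <- ddct(tab, "pta", "parC", "reference")
  expect_equal(out2$fold[out2$sample == "treated"], 1)
  expect_error(simulate_qpcr(c(ackA = -1)), "> 0")
  expect_error(simulate_qpcr(c(parC = 2)), "control")
})
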