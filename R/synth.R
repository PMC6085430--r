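#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so seeded simulators never perturb the global random stream.
#' With `seed = NULL` the code runs on the ambient stream.
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

#' Default 12-hour plate-reader schedule
#'
#' Readings every 10 minutes over 12 hours including t = 0: 73 timepoints,
#' in hours.
#' @return Numeric vector of times in hours.
#' @export
default_schedule <- function() seq(0, 12, by = 1 / 6)

#' Parameters of a piecewise-exponential diauxic growth curve
#'
#' Encodes the three-phase structure of a diauxic shift: exponential growth
#' on the first sugar at `mu1` doublings/hour until `t1`, a flat plateau at
#' the phase-1 ceiling until `t2`, then exponential growth at `mu2`
#' doublings/hour, optionally capped at a carrying capacity.
#'
#' @param od0 Initial OD600 (> 0).
#' @param mu1,mu2 Phase 1 / phase 2 growth rates in doublings per hour (> 0).
#' @param t1 End of phase 1, hours (glucose exhaustion).
#' @param t2 End of the lag plateau, hours (`t2 > t1 > 0`).
#' @param cap Optional carrying-capacity OD; must exceed the plateau OD.
#'   `NULL` (default) means unbounded growth over the observation window.
#' @param sigma Standard deviation of the multiplicative log-noise (>= 0).
#' @param blank Additive baseline added to every reading.
#' @return An object of class `diauxic_params`.
#' @export
diauxic_params <- function(od0 = 0.05, mu1 = 0.46, t1 = 3, t2 = 4,
                           mu2 = 0.46, cap = NULL, sigma = 0, blank = 0) {
  if (!is.finite(od0) || od0 <= 0) stop("`od0` must be > 0", call. = FALSE)
  if (mu1 <= 0 || mu2 <= 0) stop("growth rates must be > 0", call. = FALSE)
  if (!(t1 > 0 && t2 > t1)) stop("need 0 < t1 < t2", call. = FALSE)
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  plateau <- od0 * 2^(mu1 * t1)
  if (!is.null(cap) && cap <= plateau) {
    stop(sprintf("`cap` (%.3g) must exceed the plateau OD (%.3g)",
                 cap, plateau), call. = FALSE)
  }
  structure(list(od0 = od0, mu1 = mu1, t1 = t1, t2 = t2, mu2 = mu2,
                 cap = cap, sigma = sigma, blank = blank),
            class = "diauxic_params")
}

# Noiseless mean OD of the piecewise-exponential model.
diauxic_mean <- function(params, t) {
  p <- params
  plateau <- p$od0 * 2^(p$mu1 * p$t1)
  od <- ifelse(t < p$t1, p$od0 * 2^(p$mu1 * t),
        ifelse(t < p$t2, plateau,
               plateau * 2^(p$mu2 * (t - p$t2))))
  if (!is.null(p$cap)) od <- pmin(od, p$cap)
  od
}

#' Simulate one diauxic growth curve
#'
#' Observed readings are `blank + mean(t) * exp(eps)` with independent
#' `eps ~ Normal(0, sigma^2)` per timepoint: multiplicative lognormal noise,
#' i.e. additive on the log-OD scale, which mirrors how plate-reader error
#' scales with signal and keeps OD positive.
#'
#' @param params A [diauxic_params()].
#' @param schedule Strictly increasing time grid in hours
#'   (default [default_schedule()]).
#' @param seed Integer seed; identical inputs give bit-identical output.
#' @param well_id,strain,condition,replicate Metadata for the returned
#'   series.
#' @return A [plate_series()].
#' @export
#' @examples
#' p <- diauxic_params(od0 = 0.05, mu1 = 0.5, t1 = 4, t2 = 5, mu2 = 0.5)
#' ps <- simulate_diauxic_curve(p, seed = 1)
#' length(ps$times)  # 73 readings over 12 h at 10-min intervals
simulate_diauxic_curve <- function(params, schedule = default_schedule(),
                                   seed = NULL, well_id = "sim",
                                   strain = NA_character_,
                                   condition = NA_character_,
                                   replicate = 1L) {
  stopifnot(inherits(params, "diauxic_params"))
  if (any(diff(schedule) <= 0)) {
    stop("`schedule` must be strictly increasing", call. = FALSE)
  }
  mean_od <- diauxic_mean(params, schedule)
  od <- if (params$sigma > 0) {
    eps <- with_seed(seed, stats::rnorm(length(schedule), 0, params$sigma))
    params$blank + mean_od * exp(eps)
  } else {
    params$blank + mean_od
  }
  plate_series(well_id, schedule, od, strain = strain, condition = condition,
               replicate = replicate)
}

#' Strain presets for a simulated diauxic plate
#'
#' Three presets labelled by their ppGpp synthetase content — `sR` (wild
#' type, both synthetases), `R` (RelA only) and `s` (SpoT only) — sharing
#' the measured glucose-phase growth rate and differing only in plateau
#' duration, chosen so the true normalized lag ratios order
#' `sR < R < s` (wild type quickest, SpoT-only slowest). Lag magnitudes per
#' strain are not published numerically, so the default ratios
#' `{0.5, 1, 2}` respect only the ordering.
#'
#' @param ratios Named true normalized lag ratios, one per strain label.
#' @param mu1,mu2 Growth rates in doublings/hour (default 0.46, the measured
#'   glucose-lactose rate).
#' @param od0 Inoculum OD600 (default 0.05).
#' @param t1 Glucose-exhaustion time in hours.
#' @param sigma Multiplicative log-noise sd (default 0.02).
#' @param cap Carrying-capacity OD. Default `NULL` (no saturation), which
#'   keeps the phase-2 slope well-defined over the full 12-h window; set
#'   `cap = 1.0` to emulate a realistic saturating plate, and then analyze
#'   with an OD `ceiling` (see [log_transform()]) so the stationary tail
#'   does not masquerade as the diauxic plateau.
#' @param blank Additive baseline.
#' @return A named list of `strain_preset` objects
#'   (`list(label, params, ratio)`).
#' @export
strain_presets <- function(ratios = c(sR = 0.5, R = 1.0, s = 2.0),
                           mu1 = 0.46, mu2 = 0.46, od0 = 0.05, t1 = 3,
                           sigma = 0.02, cap = NULL, blank = 0) {
  if (is.null(names(ratios)) || any(!nzchar(names(ratios)))) {
    stop("`ratios` must be a named vector", call. = FALSE)
  }
  if (anyDuplicated(names(ratios))) {
    stop("duplicate preset labels", call. = FALSE)
  }
  out <- lapply(names(ratios), function(lab) {
    lag <- ratios[[lab]] / mu1   # ratio = lag / g with g = 1/mu1
    structure(list(label = lab,
                   params = diauxic_params(od0 = od0, mu1 = mu1, t1 = t1,
                                           t2 = t1 + lag, mu2 = mu2,
                                           cap = cap, sigma = sigma,
                                           blank = blank),
                   ratio = ratios[[lab]]),
              class = "strain_preset")
  })
  names(out) <- names(ratios)
  out
}

#' Simulate a plate of diauxic curves with known ground truth
#'
#' Lays out `replicates` wells per preset (one plate row per preset), each
#' with an independent noise stream derived from `(seed, well index)`, and
#' emits a truth table of the analytic `Xi`, `Xf`, lag, generation time and
#' normalized ratio for every well.
#'
#' @param presets A list of presets from [strain_presets()].
#' @param replicates Wells per preset (>= 1); the experiments this emulates
#'   used three independent runs with duplicate wells, i.e. six values.
#' @param schedule Time grid in hours.
#' @param seed Integer seed.
#' @return List with `series` (list of [plate_series()]), `truth`
#'   (data.frame: well, strain, replicate, od0, mu1, t1, t2, mu2, Xi, Xf,
#'   lag_t, gen_time, ratio) and `layout` (a [plate_layout()]).
#' @export
simulate_plate <- function(presets, replicates = 6,
                           schedule = default_schedule(), seed = 1) {
  labels <- vapply(presets, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("duplicate preset labels", call. = FALSE)
  if (replicates < 1) stop("`replicates` must be >= 1", call. = FALSE)
  n_wells <- length(presets) * replicates
  well_seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n_wells))

  series <- vector("list", n_wells)
  truth <- vector("list", n_wells)
  idx <- 0L
  for (i in seq_along(presets)) {
    pre <- presets[[i]]
    p <- pre$params
    for (r in seq_len(replicates)) {
      idx <- idx + 1L
      well <- paste0(LETTERS[i], r)
      series[[idx]] <- simulate_diauxic_curve(
        p, schedule = schedule, seed = well_seeds[idx], well_id = well,
        strain = pre$label, condition = "simulated", replicate = r)
      truth[[idx]] <- data.frame(
        well = well, strain = pre$label, replicate = r,
        od0 = p$od0, mu1 = p$mu1, t1 = p$t1, t2 = p$t2, mu2 = p$mu2,
        Xi = p$t1, Xf = p$t2, lag_t = p$t2 - p$t1, gen_time = 1 / p$mu1,
        ratio = (p$t2 - p$t1) * p$mu1, stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, truth)
  names(series) <- truth$well
  layout <- plate_layout(data.frame(well = truth$well, strain = truth$strain,
                                    condition = "simulated",
                                    replicate = truth$replicate,
                                    is_blank = FALSE))
  list(series = series, truth = truth, layout = layout)
}

# piecewise-linear template evaluated on a time grid
.pw_linear <- function(t, knots_t, knots_f) {
  stats::approx(knots_t, knots_f, xout = t, rule = 2)$y
}

#' Simulate a ppGpp/pppGpp timecourse across a diauxic shift
#'
#' Generates intensities for the three guanine channels such that the focal
#' species' fraction of total G follows one of three qualitative templates
#' observed across the shift: `wt_rise` (ppGpp rises ~30% above basal and
#' plateaus through the lag, relaxing afterwards), `relA_spike` (pppGpp
#' spikes `fold`-times basal at mid-lag then falls), `spoT_drop` (ppGpp
#' falls precipitously to `floor_frac` early in the lag, then slowly
#' recovers). Templates are piecewise linear in time; only the qualitative
#' dynamics are constrained by observation, not a functional form.
#'
#' @param profile One of `"wt_rise"`, `"relA_spike"`, `"spoT_drop"`.
#' @param basal Pre-lag basal fraction of the focal species (0 < basal < 1).
#' @param schedule Time grid in hours.
#' @param lag_window Length-2 vector `(start, end)` of the lag in hours.
#' @param fold Fold change of the template (default 1.3 for `wt_rise`, 5 for
#'   `relA_spike`).
#' @param floor_frac Minimum fraction reached by `spoT_drop` (default 0).
#' @param other_basal Constant fraction assigned to the non-focal minor
#'   channel.
#' @param sigma Multiplicative log-noise sd applied per channel intensity.
#' @param seed Integer seed.
#' @param total Total G intensity (arbitrary units, constant over time).
#' @return A [nucleotide_timecourse()]; at `sigma = 0` its fractions
#'   reproduce the template exactly.
#' @export
simulate_ppgpp_timecourse <- function(profile = c("wt_rise", "relA_spike",
                                                  "spoT_drop"),
                                      basal = 0.1,
                                      schedule = seq(0, 3, by = 0.1),
                                      lag_window = c(1, 2), fold = NULL,
                                      floor_frac = 0, other_basal = 0.02,
                                      sigma = 0, seed = NULL, total = 1000) {
  profile <- match.arg(profile)
  if (!(basal > 0 && basal < 1)) stop("need 0 < basal < 1", call. = FALSE)
  w1 <- lag_window[1]; w2 <- lag_window[2]
  if (!(w2 > w1)) stop("`lag_window` must be increasing", call. = FALSE)
  span <- w2 - w1
  if (is.null(fold)) fold <- switch(profile, wt_rise = 1.3, relA_spike = 5,
                                    spoT_drop = NA_real_)

  f <- switch(profile,
    wt_rise = {
      peak <- fold * basal
      if (peak >= 1) {
        stop("fraction overflow: basal * fold must stay below 1",
             call. = FALSE)
      }
      .pw_linear(schedule,
                 c(w1, w1 + 0.1 * span, w2, w2 + 0.5 * span),
                 c(basal, peak, peak, basal))
    },
    relA_spike = {
      peak <- fold * basal
      if (peak >= 1) {
        stop("fraction overflow: basal * fold must stay below 1",
             call. = FALSE)
      }
      .pw_linear(schedule,
                 c(w1, (w1 + w2) / 2, w2),
                 c(basal, peak, basal))
    },
    spoT_drop = {
      if (floor_frac < 0 || floor_frac >= basal) {
        stop("`floor_frac` must lie in [0, basal)", call. = FALSE)
      }
      .pw_linear(schedule,
                 c(w1, w1 + 0.2 * span, w2, w2 + span),
                 c(basal, floor_frac, floor_frac, basal))
    })
  if (any(f + other_basal >= 1)) {
    stop("fraction overflow: focal + minor channel fractions reach 1",
         call. = FALSE)
  }

  focal <- f * total
  minor <- rep(other_basal * total, length(schedule))
  gtp <- total - focal - minor
  if (sigma > 0) {
    noise <- with_seed(seed,
      matrix(exp(stats::rnorm(3 * length(schedule), 0, sigma)), ncol = 3))
    focal <- focal * noise[, 1]
    minor <- minor * noise[, 2]
    gtp <- gtp * noise[, 3]
  }
  if (profile == "relA_spike") {
    # spike template describes the pentaphosphate channel
    nucleotide_timecourse(schedule, gtp = gtp, ppgpp = minor,
                          pppgpp = focal, time_unit = "hours")
  } else {
    nucleotide_timecourse(schedule, gtp = gtp, ppgpp = focal,
                          pppgpp = minor, time_unit = "hours")
  }
}

#' Simulate an exponential nucleotide decay series
#'
#' Fraction-of-total-G decays as `f0 * exp(k * t)` with multiplicative
#' lognormal noise; the default 0.5-minute interval matches 30-second
#' sampling after translation arrest.
#'
#' @param k Per-minute decay constant (must be negative).
#' @param n Number of points (>= 3).
#' @param interval Sampling interval in minutes (default 0.5).
#' @param sigma Multiplicative log-noise sd.
#' @param seed Integer seed.
#' @param f0 Initial fraction (default 0.5).
#' @param total Total G intensity per sample.
#' @return A [nucleotide_timecourse()] with times in minutes.
#' @export
#' @examples
#' tc <- simulate_decay(k = -log(2) / 0.5, n = 5)
#' fraction_of_total_g(tc, "ppGpp")  # halves every 30 s
simulate_decay <- function(k, n = 20, interval = 0.5, sigma = 0, seed = NULL,
                           f0 = 0.5, total = 1000) {
  if (!is.finite(k) || k >= 0) {
    stop("`k` must be a negative per-minute decay constant", call. = FALSE)
  }
  if (n < 3) stop("need at least 3 points", call. = FALSE)
  times <- (seq_len(n) - 1) * interval
  frac <- f0 * exp(k * times)
  if (sigma > 0) {
    frac <- frac * with_seed(seed, exp(stats::rnorm(n, 0, sigma)))
  }
  if (any(frac >= 1)) {
    stop("fraction overflow: decay fractions must stay below 1",
         call. = FALSE)
  }
  nucleotide_timecourse(times, gtp = (1 - frac) * total,
                        ppgpp = frac * total,
                        pppgpp = rep(0, n), time_unit = "minutes")
}

#' Simulate a comparative-Ct qPCR table
#'
#' Builds Ct values for a reference and a treated sample such that
#' `Ct(target, treated) = Ct(target, reference) - log2(fold) + noise`, with
#' the endogenous-control gene's Ct equal across samples up to noise.
#' Running [ddct()] on the noiseless output returns `true_folds` exactly.
#'
#' @param true_folds Named numeric vector of fold changes per target gene
#'   (> 0), treated relative to reference.
#' @param control_gene Endogenous control label (default `"parC"`).
#' @param ct_control_mean Control-gene Ct (default 18 cycles).
#' @param ct_target_mean Reference-sample Ct of each target (default 22).
#' @param sigma Per-replicate additive Ct noise sd.
#' @param n_replicates Technical replicates per (sample, gene) (default 3).
#' @param sample_names Length-2 labels `(reference, treated)`.
#' @param seed Integer seed.
#' @return A data.frame with columns `sample`, `gene`, `replicate`, `ct`.
#' @export
simulate_qpcr <- function(true_folds, control_gene = "parC",
                          ct_control_mean = 18, ct_target_mean = 22,
                          sigma = 0, n_replicates = 3,
                          sample_names = c("reference", "treated"),
                          seed = NULL) {
  if (is.null(names(true_folds)) || any(!nzchar(names(true_folds)))) {
    stop("`true_folds` must be named by gene", call. = FALSE)
  }
  if (any(true_folds <= 0)) stop("fold changes must be > 0", call. = FALSE)
  if (control_gene %in% names(true_folds)) {
    stop("the control gene cannot also be a target", call. = FALSE)
  }
  genes <- c(control_gene, names(true_folds))
  true_ct <- function(sample, gene) {
    if (gene == control_gene) return(ct_control_mean)
    if (sample == sample_names[1]) return(ct_target_mean)
    ct_target_mean - log2(true_folds[[gene]])
  }
  grid <- expand.grid(replicate = seq_len(n_replicates), gene = genes,
                      sample = sample_names, stringsAsFactors = FALSE)
  grid <- grid[, c("sample", "gene", "replicate")]
  grid$ct <- mapply(true_ct, grid$sample, grid$gene)
  if (sigma > 0) {
    grid$ct <- grid$ct +
      with_seed(seed, stats::rnorm(nrow(grid), 0, sigma))
  }
  rownames(grid) <- NULL
  grid
}
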