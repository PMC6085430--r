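#' Per-timepoint guanine nucleotide intensities
#'
#' Holds spot intensities for GTP, ppGpp and pppGpp measured in the same
#' sample at each timepoint. Fractions of total G
#' (`total G = GTP + ppGpp + pppGpp`) are derived on demand by
#' [fraction_of_total_g()].
#'
#' @param times Numeric timestamps, strictly increasing.
#' @param gtp,ppgpp,pppgpp Nonnegative intensities, same length as `times`;
#'   their sum must be positive at every timepoint.
#' @param time_unit `"minutes"` or `"hours"` (recorded, not converted:
#'   decay constants are reported in the unit supplied).
#' @return An object of class `nucleotide_timecourse`.
#' @export
nucleotide_timecourse <- function(times, gtp, ppgpp, pppgpp,
                                  time_unit = c("minutes", "hours")) {
  time_unit <- match.arg(time_unit)
  n <- length(times)
  if (length(gtp) != n || length(ppgpp) != n || length(pppgpp) != n) {
    stop("all channels must match the length of `times`", call. = FALSE)
  }
  if (any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing", call. = FALSE)
  }
  if (any(gtp < 0) || any(ppgpp < 0) || any(pppgpp < 0)) {
    stop("intensities must be nonnegative", call. = FALSE)
  }
  total <- gtp + ppgpp + pppgpp
  if (any(total <= 0)) {
    stop("zero total G at timepoint(s): ",
         paste(times[total <= 0], collapse = ", "), call. = FALSE)
  }
  structure(list(times = as.numeric(times), gtp = as.numeric(gtp),
                 ppgpp = as.numeric(ppgpp), pppgpp = as.numeric(pppgpp),
                 time_unit = time_unit),
            class = "nucleotide_timecourse")
}

#' @export
print.nucleotide_timecourse <- function(x, ...) {
  cat(sprintf("<nucleotide_timecourse> %d timepoints (%s), ppGpp fraction %.3g-%.3g\n",
              length(x$times), x$time_unit,
              min(fraction_of_total_g(x, "ppGpp")),
              max(fraction_of_total_g(x, "ppGpp"))))
  invisible(x)
}

#' Fraction of total G for one nucleotide species
#'
#' Normalizes a species' intensity to the summed GTP + ppGpp + pppGpp
#' intensities of the same sample ("total G").
#'
#' @param tc A [nucleotide_timecourse()].
#' @param species `"ppGpp"`, `"pppGpp"` or `"GTP"`.
#' @return Numeric vector of fractions in `[0, 1]`; at each timepoint the
#'   three species' fractions sum to 1.
#' @export
#' @examples
#' tc <- nucleotide_timecourse(0:2, gtp = c(2, 2, 2), ppgpp = c(1, 1, 1),
#'                             pppgpp = c(1, 1, 1))
#' fraction_of_total_g(tc, "ppGpp")  # 0.25 at every timepoint
fraction_of_total_g <- function(tc, species = c("ppGpp", "pppGpp", "GTP")) {
  stopifnot(inherits(tc, "nucleotide_timecourse"))
  species <- match.arg(species)
  total <- tc$gtp + tc$ppgpp + tc$pppgpp
  channel <- switch(species, ppGpp = tc$ppgpp, pppGpp = tc$pppgpp,
                    GTP = tc$gtp)
  channel / total
}

#' Semilog decay rate and half-life of a nucleotide fraction
#'
#' Fits ordinary least squares of `ln(fraction)` against time over the
#' points at or after `t_start` (typically the moment translation is
#' arrested). Nonpositive fractions in the window are masked with a warning.
#' The natural-log slope `k` gives `half_life = ln(2) / |k|`; a
#' log2-equivalent slope is also reported so decay can be read in the same
#' doublings-style units as growth rates.
#'
#' @param tc A [nucleotide_timecourse()].
#' @param species Species whose fraction decays (default `"ppGpp"`).
#' @param t_start Start of the decay window, in the timecourse's own time
#'   unit (default: first timepoint).
#' @return List with `k` (per time unit, natural log), `k_log2`
#'   (`k / ln 2`), `half_life` (`ln2 / |k|`; `NA` when non-decaying),
#'   `non_decaying` flag (`k >= 0`), `r2`, `n` and `time_unit`.
#' @export
#' @examples
#' tc <- simulate_decay(k = -1, n = 10, interval = 0.5)
#' decay_rate(tc)$half_life  # ln(2) minutes
decay_rate <- function(tc, species = c("ppGpp", "pppGpp", "GTP"),
                       t_start = NULL) {
  stopifnot(inherits(tc, "nucleotide_timecourse"))
  species <- match.arg(species)
  frac <- fraction_of_total_g(tc, species)
  if (is.null(t_start)) t_start <- tc$times[1]
  in_window <- tc$times >= t_start
  pos <- frac > 0
  if (any(in_window & !pos)) {
    warning(sum(in_window & !pos),
            " nonpositive fraction(s) masked from the decay window")
  }
  keep <- in_window & pos
  if (sum(keep) < 3L) {
    stop("fewer than 3 positive points at/after t_start", call. = FALSE)
  }
  x <- tc$times[keep]
  y <- log(frac[keep])
  fit <- .ols_line(x, y)
  syy <- sum((y - mean(y))^2)
  r2 <- if (syy > 0) 1 - fit$sse / syy else 1
  non_decaying <- fit$slope >= 0
  list(k = fit$slope, k_log2 = fit$slope / log(2),
       half_life = if (non_decaying) NA_real_ else log(2) / abs(fit$slope),
       non_decaying = non_decaying, r2 = r2, n = fit$n,
       time_unit = tc$time_unit)
}
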