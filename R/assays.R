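#' Fit a linear assay standard curve
#'
#' Ordinary least squares of instrument reading on known concentration,
#' e.g. acetate standards (1-10 nmole/well) or an ATP standard curve
#' (0.1-10 mM). The range of the standards is recorded so interpolation can
#' refuse out-of-range samples.
#'
#' @param conc Known standard concentrations (>= 2 distinct values).
#' @param reading Instrument readings, same length.
#' @param units Concentration unit label (recorded).
#' @return An object of class `standard_curve` with `slope`, `intercept`,
#'   `r2`, `valid_range` and `units`.
#' @export
#' @examples
#' sc <- fit_standard_curve(1:5, 2 * (1:5) + 1)
#' sc$slope; sc$intercept  # 2, 1
fit_standard_curve <- function(conc, reading, units = "mM") {
  if (length(conc) != length(reading)) {
    stop("`conc` and `reading` must have the same length", call. = FALSE)
  }
  if (length(unique(conc)) < 2L) {
    stop("need at least 2 distinct standard concentrations", call. = FALSE)
  }
  fit <- stats::lm(reading ~ conc)
  slope <- unname(stats::coef(fit)[2])
  if (slope == 0) stop("degenerate standard curve: zero slope", call. = FALSE)
  syy <- sum((reading - mean(reading))^2)
  r2 <- 1 - sum(stats::residuals(fit)^2) / syy
  structure(list(slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = r2, valid_range = range(conc), units = units),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("<standard_curve> reading = %.4g * conc + %.4g (r2 = %.4f), range [%g, %g] %s\n",
              x$slope, x$intercept, x$r2, x$valid_range[1], x$valid_range[2],
              x$units))
  invisible(x)
}

#' Interpolate a sample concentration from a standard curve
#'
#' Inverts the linear standard curve; if the pre-dilution concentration
#' falls outside the range spanned by the standards, an error instructs the
#' caller to dilute the sample into range, as assay practice demands.
#'
#' @param curve A [fit_standard_curve()] result.
#' @param reading Instrument reading(s) of the sample.
#' @param dilution_factor Fold dilution applied before reading (>= 1); the
#'   returned concentration is scaled back up by this factor.
#' @return Concentration(s) in the curve's units.
#' @export
interpolate_concentration <- function(curve, reading, dilution_factor = 1) {
  stopifnot(inherits(curve, "standard_curve"))
  if (any(dilution_factor < 1)) {
    stop("`dilution_factor` must be >= 1", call. = FALSE)
  }
  raw <- (reading - curve$intercept) / curve$slope
  out_of_range <- raw < curve$valid_range[1] | raw > curve$valid_range[2]
  if (any(out_of_range)) {
    stop(sprintf(paste0("reading maps to %.4g %s, outside the standard range ",
                        "[%g, %g]; dilute the sample into range"),
                 raw[out_of_range][1], curve$units,
                 curve$valid_range[1], curve$valid_range[2]), call. = FALSE)
  }
  dilution_factor * raw
}

#' Normalize a concentration to culture density or protein content
#'
#' @param conc Concentration value(s).
#' @param denom Normalizer: OD600 of the culture or mg protein (> 0).
#' @param units Unit label for the result (default `"mM per OD600"`).
#' @return Numeric vector `conc / denom` with a `units` attribute.
#' @export
#' @examples
#' normalize_per_od(0.25, 0.2)  # 1.25 mM/OD
normalize_per_od <- function(conc, denom, units = "mM per OD600") {
  if (any(denom <= 0)) stop("normalizer must be > 0", call. = FALSE)
  structure(conc / denom, units = units)
}

#' Express values relative to a reference sample
#'
#' Divides each value by the mean of the reference sample's values, e.g.
#' acetyl-phosphate per mg protein expressed as a fraction of the wild-type
#' level.
#'
#' @param values Numeric vector.
#' @param reference_values Values measured for the reference sample.
#' @return `values / mean(reference_values)`.
#' @export
relative_to_reference <- function(values, reference_values) {
  m <- mean(reference_values)
  if (!is.finite(m) || m == 0) {
    stop("reference mean must be finite and nonzero", call. = FALSE)
  }
  values / m
}

#' Comparative-Ct (2^-ddCt) relative expression
#'
#' Technical replicates are averaged on the Ct scale per (sample, gene);
#' `dCt = Ct(target) - Ct(control)` within each sample;
#' `ddCt = dCt(sample) - dCt(reference)`; the fold change is `2^-ddCt`, so
#' the reference sample's fold is exactly 1. Amplification efficiency is
#' fixed at 2, the comparative-Ct assumption.
#'
#' @param ct Data.frame with columns `sample`, `gene`, `ct` (and optionally
#'   `replicate`), e.g. from [simulate_qpcr()].
#' @param target_gene Gene whose expression is quantified.
#' @param control_gene Endogenous control present in every sample.
#' @param reference_sample Sample whose expression anchors the fold scale.
#' @return Data.frame with columns `sample`, `dct`, `ddct`, `fold`.
#' @export
#' @examples
#' tab <- simulate_qpcr(c(ackA = 0.25), sigma = 0)
#' ddct(tab, "ackA", "parC", "reference")
ddct <- function(ct, target_gene, control_gene, reference_sample) {
  needed <- c("sample", "gene", "ct")
  if (!all(needed %in% names(ct))) {
    stop("`ct` needs columns (sample, gene, ct)", call. = FALSE)
  }
  if (any(ct$ct <= 0)) stop("Ct values must be positive", call. = FALSE)
  samples <- unique(ct$sample)
  if (!reference_sample %in% samples) {
    stop("reference sample `", reference_sample, "` not present",
         call. = FALSE)
  }
  mean_ct <- function(s, g) {
    v <- ct$ct[ct$sample == s & ct$gene == g]
    if (!length(v)) {
      stop(sprintf("sample `%s` has no Ct for gene `%s`", s, g),
           call. = FALSE)
    }
    mean(v)
  }
  dct <- vapply(samples, function(s) {
    mean_ct(s, target_gene) - mean_ct(s, control_gene)
  }, numeric(1))
  ddct_v <- dct - dct[[reference_sample]]
  data.frame(sample = samples, dct = unname(dct), ddct = unname(ddct_v),
             fold = 2^(-unname(ddct_v)), stringsAsFactors = FALSE)
}
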