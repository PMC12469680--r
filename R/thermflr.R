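## Van't Hoff thermal denaturation and tryptophan-fluorescence analysis.
##
## Melting is modelled as a two-state N <-> U equilibrium followed by
## fluorescence: F(T) = [F_n(T) + F_u(T) K(T)] / [1 + K(T)] with
## K(T) = exp[-(dH/R)(1/T - 1/Tm)] and linear pre- and post-transition
## baselines (tryptophan emission drifts with temperature, so flat baselines
## are only the degenerate special case). Temperatures are converted to
## Kelvin for fitting and reported in Celsius.

#' Build a melt curve
#'
#' @param temp_C Temperatures in Celsius, strictly increasing; the standard
#'   scan covers 20-85 C at 2-5 degree steps.
#' @param fluorescence Fluorescence, arbitrary units.
#' @param protein_conc Protein concentration, M (metadata).
#' @return A `melt_curve` data.frame.
#' @export
melt_curve <- function(temp_C, fluorescence, protein_conc = NA_real_) {
  stopifnot(length(temp_C) == length(fluorescence))
  if (any(diff(temp_C) <= 0)) stop("temperatures must be strictly increasing",
                                   call. = FALSE)
  if (length(temp_C) < 8 || diff(range(temp_C)) < 30)
    warning("melt curve should span >= 30 C with >= 8 points")
  structure(data.frame(temp_C = temp_C, fluorescence = fluorescence),
            protein_conc = protein_conc,
            class = c("melt_curve", "data.frame"))
}

vant_hoff_model <- function(T_K, Tm_K, dH, bn0, bn1, bu0, bu1) {
  K <- exp(-(dH / R_GAS) * (1 / T_K - 1 / Tm_K))
  Fn <- bn0 + bn1 * T_K
  Fu <- bu0 + bu1 * T_K
  (Fn + Fu * K) / (1 + K)
}

#' Fit a two-state van't Hoff melting curve
#'
#' Six-parameter least-squares fit (Tm, van't Hoff enthalpy, two linear
#' baselines) of a fluorescence-monitored thermal denaturation. The initial
#' Tm is the temperature of maximal |dF/dT|; baselines are initialised from
#' the first and last quarter of the scan. At the fitted Tm the folded
#' fraction is exactly 0.5 by construction of the model.
#'
#' @param curve A `melt_curve` or data.frame with `temp_C`, `fluorescence`.
#' @param mask_above_C Optional post-transition cutoff; points above it are
#'   excluded (irreversible-aggregation artifacts are outside the model).
#' @return A `vant_hoff_fit`: `Tm` (Celsius), `dH_vH` (kcal/mol), baseline
#'   coefficients, `rss`, `boundary_warning`. Methods: `print`, `summary`,
#'   `coef`, `predict`, `residuals`, `plot`.
#' @export
fit_vant_hoff <- function(curve, mask_above_C = Inf) {
  d <- as.data.frame(curve)
  d <- d[d$temp_C <= mask_above_C, , drop = FALSE]
  T_K <- d$temp_C + 273.15
  Fl <- d$fluorescence

  ## transition presence: signal range must clear the local noise floor
  noise <- stats::median(abs(diff(Fl, differences = 2))) / 2
  if (diff(range(Fl)) <= 3 * max(noise, .Machine$double.eps) ||
      is_monotone_linear(T_K, Fl))
    stop("no transition detected in melt curve", call. = FALSE)

  dFdT <- diff(Fl) / diff(T_K)
  Tm0 <- T_K[which.max(abs(dFdT))]
  q <- max(3L, floor(length(T_K) / 4))
  lo <- seq_len(q); hi <- seq.int(length(T_K) - q + 1L, length(T_K))
  bn <- stats::coef(stats::lm(Fl[lo] ~ T_K[lo]))
  bu <- stats::coef(stats::lm(Fl[hi] ~ T_K[hi]))

  fit <- minpack.lm::nlsLM(
    fluorescence ~ vant_hoff_model(T_K, Tm_K, dH, bn0, bn1, bu0, bu1),
    data = data.frame(fluorescence = Fl, T_K = T_K),
    start = list(Tm_K = Tm0, dH = 100, bn0 = bn[[1]], bn1 = bn[[2]],
                 bu0 = bu[[1]], bu1 = bu[[2]]),
    lower = c(Tm_K = min(T_K), dH = 1, bn0 = -Inf, bn1 = -Inf,
              bu0 = -Inf, bu1 = -Inf),
    upper = c(Tm_K = max(T_K), dH = 5000, bn0 = Inf, bn1 = Inf,
              bu0 = Inf, bu1 = Inf),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  cf <- stats::coef(fit)
  Tm_C <- cf[["Tm_K"]] - 273.15
  boundary <- cf[["Tm_K"]] <= min(T_K) + 1e-6 || cf[["Tm_K"]] >= max(T_K) - 1e-6
  if (boundary) warning("fitted Tm at scan-range boundary")
  structure(list(Tm = Tm_C, dH_vH = cf[["dH"]],
                 native_baseline = c(intercept = cf[["bn0"]], slope = cf[["bn1"]]),
                 unfolded_baseline = c(intercept = cf[["bu0"]], slope = cf[["bu1"]]),
                 rss = sum(stats::residuals(fit)^2),
                 boundary_warning = boundary, data = d, nls = fit),
            class = "vant_hoff_fit")
}

## monotone series with no curvature beyond noise: a line explains it
is_monotone_linear <- function(x, y) {
  r <- stats::residuals(stats::lm(y ~ x))
  stats::sd(r) < 1e-3 * max(diff(range(y)), .Machine$double.eps) ||
    diff(range(r)) < 1e-9 * max(abs(y))
}

#' @export
print.vant_hoff_fit <- function(x, ...) {
  cat(sprintf("van't Hoff fit: Tm = %.2f C, dH_vH = %.1f kcal/mol, rss = %.3g%s\n",
              x$Tm, x$dH_vH, x$rss,
              if (x$boundary_warning) "  [Tm at boundary]" else ""))
  invisible(x)
}

#' @export
summary.vant_hoff_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  native baseline: %.4g + %.4g*T(K); unfolded: %.4g + %.4g*T(K)\n",
              object$native_baseline[["intercept"]], object$native_baseline[["slope"]],
              object$unfolded_baseline[["intercept"]], object$unfolded_baseline[["slope"]]))
  cat(sprintf("  n = %d points, %.0f-%.0f C\n", nrow(object$data),
              min(object$data$temp_C), max(object$data$temp_C)))
  invisible(object)
}

#' @export
coef.vant_hoff_fit <- function(object, ...) {
  c(Tm = object$Tm, dH_vH = object$dH_vH,
    bn0 = object$native_baseline[["intercept"]],
    bn1 = object$native_baseline[["slope"]],
    bu0 = object$unfolded_baseline[["intercept"]],
    bu1 = object$unfolded_baseline[["slope"]])
}

#' @export
predict.vant_hoff_fit <- function(object, newdata = NULL, ...) {
  tc <- if (is.null(newdata)) object$data$temp_C else newdata$temp_C
  cf <- coef(object)
  vant_hoff_model(tc + 273.15, cf[["Tm"]] + 273.15, cf[["dH_vH"]],
                  cf[["bn0"]], cf[["bn1"]], cf[["bu0"]], cf[["bu1"]])
}

#' @export
residuals.vant_hoff_fit <- function(object, ...)
  object$data$fluorescence - predict(object)

#' @export
plot.vant_hoff_fit <- function(x, ...) {
  graphics::plot(x$data$temp_C, x$data$fluorescence,
                 xlab = "temperature (C)", ylab = "fluorescence", ...)
  tt <- seq(min(x$data$temp_C), max(x$data$temp_C), length.out = 300)
  graphics::lines(tt, predict(x, data.frame(temp_C = tt)))
  graphics::abline(v = x$Tm, lty = 2)
  invisible(x)
}

#' Folded fraction of a fitted melt at given temperatures
#'
#' @param fit A `vant_hoff_fit`.
#' @param temp_C Temperatures, Celsius.
#' @return Fraction folded in `[0, 1]`; exactly 0.5 at the fitted Tm.
#' @export
folded_fraction <- function(fit, temp_C) {
  T_K <- temp_C + 273.15
  K <- exp(-(fit$dH_vH / R_GAS) * (1 / T_K - 1 / (fit$Tm + 273.15)))
  1 / (1 + K)
}

#' Melting-temperature shift between two fits
#'
#' Signed difference variant minus reference, Celsius; antisymmetric in its
#' arguments.
#'
#' @param fit_variant,fit_reference `vant_hoff_fit` objects.
#' @return Delta-Tm in Celsius.
#' @export
delta_tm <- function(fit_variant, fit_reference) {
  fit_variant$Tm - fit_reference$Tm
}

#' Buffer- and volume-corrected fluorescence
#'
#' F_corr = (F_raw - F_buffer) * (V_total / V_initial): buffer background is
#' subtracted and the dilution from titration additions undone.
#'
#' @param F_raw Raw fluorescence readings.
#' @param F_buffer Buffer blank (scalar or per-point).
#' @param V_total,V_initial Cuvette volumes after/before additions.
#' @return Corrected fluorescence.
#' @export
correct_fluorescence <- function(F_raw, F_buffer = 0, V_total = 1, V_initial = 1) {
  (F_raw - F_buffer) * (V_total / V_initial)
}

#' Baseline protein fluorescence from a concentration series
#'
#' Ordinary least-squares slope of (buffer/volume-corrected) fluorescence on
#' protein concentration; the slope is the baseline fluorescence of the
#' variant (units per M).
#'
#' @param conc_M Concentrations, M, with nonzero spread; >= 3 points.
#' @param fluorescence Corrected fluorescence, same length.
#' @return A `baseline_fit`: `slope`, `intercept`, `r_squared`.
#' @export
baseline_fluorescence <- function(conc_M, fluorescence) {
  stopifnot(length(conc_M) == length(fluorescence))
  if (length(conc_M) < 3) stop("need >= 3 points", call. = FALSE)
  if (diff(range(conc_M)) <= 0) stop("zero concentration spread", call. = FALSE)
  fit <- stats::lm(fluorescence ~ conc_M)
  structure(list(slope = stats::coef(fit)[[2]], intercept = stats::coef(fit)[[1]],
                 r_squared = suppressWarnings(summary(fit)$r.squared), lm = fit),
            class = "baseline_fit")
}

#' @export
print.baseline_fit <- function(x, ...) {
  cat(sprintf("baseline fluorescence: slope = %.4g units/M (R2 %.3f)\n",
              x$slope, x$r_squared))
  invisible(x)
}

#' @export
coef.baseline_fit <- function(object, ...)
  c(slope = object$slope, intercept = object$intercept)

#' Percent fluorescence gain on activation
#'
#' 100 * (F_sat - F_base) / F_base: the tryptophan fluorescence gain when a
#' saturating (conventionally 5x) concentration of heparin pentasaccharide
#' converts the protein to the activated form. Wild-type antithrombin gains
#' about 40%; conformationally perturbed mutants lose part or all of it.
#'
#' @param F_base Baseline fluorescence (> 0).
#' @param F_sat Fluorescence at saturating pentasaccharide.
#' @param excess_ratio Pentasaccharide excess over the saturating
#'   concentration (metadata, default 5).
#' @return A `gain_result`: `percent_gain`, `F_base`, `F_sat`,
#'   `excess_ratio`.
#' @export
fluorescence_gain <- function(F_base, F_sat, excess_ratio = 5) {
  if (!is.finite(F_base) || F_base <= 0)
    stop("baseline fluorescence must be positive", call. = FALSE)
  structure(list(percent_gain = 100 * (F_sat - F_base) / F_base,
                 F_base = F_base, F_sat = F_sat, excess_ratio = excess_ratio),
            class = "gain_result")
}

#' @export
print.gain_result <- function(x, ...) {
  cat(sprintf("fluorescence gain: %+.1f%% (%.4g -> %.4g)\n",
              x$percent_gain, x$F_base, x$F_sat))
  invisible(x)
}
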