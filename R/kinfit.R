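## Protease-inhibition kinetics: pseudo-first-order progress-curve fits,
## stoichiometry-of-inhibition titrations, second-order rate constants,
## activation metrics and the two-state R/A equilibrium partition.

#' Build a progress curve
#'
#' Residual protease activity versus time for an inhibition reaction run
#' under pseudo-first-order conditions (inhibitor in at least 10-fold molar
#' excess over protease). A warning flags curves that violate the 10-fold
#' excess rule.
#'
#' @param times Seconds, strictly increasing.
#' @param activity Residual activity (e.g. absorbance slope), non-negative.
#' @param inhibitor_conc Inhibitor (antithrombin) concentration, M.
#' @param protease_conc Protease concentration, M (optional).
#' @return A `progress_curve` data.frame with attributes.
#' @export
progress_curve <- function(times, activity, inhibitor_conc = NA_real_,
                           protease_conc = NA_real_) {
  stopifnot(length(times) == length(activity))
  if (any(diff(times) <= 0)) stop("times must be strictly increasing", call. = FALSE)
  if (any(activity < 0)) stop("negative activity", call. = FALSE)
  if (is.finite(inhibitor_conc) && is.finite(protease_conc) &&
      inhibitor_conc < 10 * protease_conc)
    warning("inhibitor < 10x protease: pseudo-first-order assumption doubtful")
  structure(data.frame(time_s = times, activity = activity),
            inhibitor_conc = inhibitor_conc, protease_conc = protease_conc,
            class = c("progress_curve", "data.frame"))
}

#' Fit a pseudo-first-order inhibition progress curve
#'
#' Least-squares fit of the single-exponential decay with a hard zero-activity
#' end point, A(t) = A0 * exp(-k_obs * t). Starting values come from a
#' log-linear regression on the positive activities; the nonlinear refinement
#' uses Levenberg-Marquardt. Unweighted by default; `weighting = "relative"`
#' weights by 1/A^2 (constant relative error).
#'
#' @param curve A `progress_curve`, or anything with `time_s`/`activity`
#'   columns.
#' @param weighting `"none"` (default) or `"relative"`.
#' @return A `pfo_fit` object: coefficients `k_obs` (1/s) and `A0`, with
#'   standard errors, residual sum of squares, and the data. Methods:
#'   `print`, `summary`, `coef`, `predict`, `residuals`, `plot`.
#' @export
fit_progress_curve <- function(curve, weighting = c("none", "relative")) {
  weighting <- match.arg(weighting)
  d <- as.data.frame(curve)
  if (nrow(d) < 4) stop("need at least 4 time points", call. = FALSE)
  A <- d$activity; t <- d$time_s
  pos <- A > 0
  if (sum(pos) < 3 || min(A) > 0.5 * max(A) ||
      stats::coef(stats::lm(log(A[pos]) ~ t[pos]))[[2]] >= 0)
    stop("no inhibition detected: activities do not decay", call. = FALSE)

  ll <- stats::lm(log(A[pos]) ~ t[pos])
  start <- list(A0 = exp(stats::coef(ll)[[1]]), k = max(-stats::coef(ll)[[2]], 1e-12))
  w <- if (weighting == "relative") 1 / pmax(A, max(A) * 1e-6)^2 else rep(1, length(A))
  fit <- minpack.lm::nlsLM(activity ~ A0 * exp(-k * time_s), data = d,
                           start = start, weights = w,
                           control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- stats::coef(fit)
  if (cf[["k"]] <= 0 || cf[["A0"]] <= 0)
    stop("progress-curve fit did not converge to positive parameters", call. = FALSE)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) c(A0 = NA, k = NA))
  structure(list(k_obs = cf[["k"]], A0 = cf[["A0"]],
                 se_k_obs = unname(se[["k"]]), se_A0 = unname(se[["A0"]]),
                 rss = sum(stats::residuals(fit)^2),
                 weighting = weighting, data = d, nls = fit),
            class = "pfo_fit")
}

#' @export
print.pfo_fit <- function(x, ...) {
  cat(sprintf("pseudo-first-order fit: k_obs = %.4g 1/s (se %.2g), A0 = %.4g, rss = %.3g\n",
              x$k_obs, x$se_k_obs, x$A0, x$rss))
  invisible(x)
}

#' @export
summary.pfo_fit <- function(object, ...) {
  cat("Single-exponential inhibition progress curve, zero-activity end point\n")
  print(object)
  cat(sprintf("  n = %d points over %.4g s; half-life %.4g s; weighting: %s\n",
              nrow(object$data), max(object$data$time_s),
              log(2) / object$k_obs, object$weighting))
  invisible(object)
}

#' @export
coef.pfo_fit <- function(object, ...) c(k_obs = object$k_obs, A0 = object$A0)

#' @export
predict.pfo_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time_s else newdata$time_s
  object$A0 * exp(-object$k_obs * t)
}

#' @export
residuals.pfo_fit <- function(object, ...) {
  object$data$activity - predict(object)
}

#' @export
plot.pfo_fit <- function(x, ...) {
  graphics::plot(x$data$time_s, x$data$activity, xlab = "time (s)",
                 ylab = "residual activity", ...)
  tt <- seq(0, max(x$data$time_s), length.out = 200)
  graphics::lines(tt, x$A0 * exp(-x$k_obs * tt))
  invisible(x)
}

#' Second-order association rate constant from a pseudo-first-order fit
#'
#' k2 = k_obs * SI / [inhibitor]: the observed rate is divided by the
#' effective inhibitor concentration [AT]/SI, because the substrate-pathway
#' turnover consumes SI moles of inhibitor per mole of protease inhibited.
#' With SI = 1 this is the plain k_obs / [AT].
#'
#' @param fit A `pfo_fit`, or a bare `k_obs` value in 1/s.
#' @param inhibitor_conc Inhibitor concentration, M (> 0).
#' @param SI Stoichiometry of inhibition (>= 1), default 1.
#' @return A `rate_constant`: list with `k2` (1/M/s), `SI`, `si_corrected`,
#'   `inhibitor_conc`, `k_obs`.
#' @export
second_order_rate <- function(fit, inhibitor_conc, SI = 1) {
  k_obs <- if (inherits(fit, "pfo_fit")) fit$k_obs else as.numeric(fit)
  if (!is.finite(inhibitor_conc) || inhibitor_conc <= 0)
    stop("inhibitor concentration must be positive", call. = FALSE)
  if (SI < 1) stop("SI must be >= 1", call. = FALSE)
  structure(list(k2 = k_obs * SI / inhibitor_conc, SI = SI,
                 si_corrected = SI != 1, inhibitor_conc = inhibitor_conc,
                 k_obs = k_obs),
            class = "rate_constant")
}

#' @export
print.rate_constant <- function(x, ...) {
  cat(sprintf("k2 = %.4g 1/(M s)  (k_obs %.4g 1/s, [I] %.3g M, SI %.3g%s)\n",
              x$k2, x$k_obs, x$inhibitor_conc, x$SI,
              if (x$si_corrected) ", SI-corrected" else ""))
  invisible(x)
}

#' Stoichiometry of inhibition from a titration
#'
#' Linear regression of residual protease activity on the inhibitor:protease
#' molar ratio; the stoichiometry of inhibition is the abscissa intercept
#' (-intercept/slope). Points below `floor_frac` of the uninhibited activity
#' lie past the linear decline and are excluded before fitting.
#'
#' @param ratio Inhibitor:protease molar ratios.
#' @param activity Residual activities (same units throughout).
#' @param floor_frac Exclusion floor as a fraction of the maximum activity
#'   (default 0.05).
#' @return A `stoich_fit`: `SI`, `slope`, `intercept`, `n_used`, `r_squared`,
#'   with `print`/`coef`/`predict` methods.
#' @export
fit_stoichiometry <- function(ratio, activity, floor_frac = 0.05) {
  stopifnot(length(ratio) == length(activity))
  keep <- activity >= floor_frac * max(activity)
  if (sum(keep) < 3) stop("fewer than 3 points in the linear decline", call. = FALSE)
  fit <- stats::lm(activity[keep] ~ ratio[keep])
  slope <- stats::coef(fit)[[2]]; intercept <- stats::coef(fit)[[1]]
  if (slope >= 0) stop("no titration: activity does not decline with ratio",
                       call. = FALSE)
  structure(list(SI = -intercept / slope, slope = slope, intercept = intercept,
                 n_used = sum(keep), floor_frac = floor_frac,
                 r_squared = suppressWarnings(summary(fit)$r.squared), lm = fit),
            class = "stoich_fit")
}

#' @export
print.stoich_fit <- function(x, ...) {
  cat(sprintf("stoichiometry fit: SI = %.3f (abscissa intercept; %d points, R2 %.3f)\n",
              x$SI, x$n_used, x$r_squared))
  invisible(x)
}

#' @export
coef.stoich_fit <- function(object, ...)
  c(SI = object$SI, slope = object$slope, intercept = object$intercept)

#' @export
predict.stoich_fit <- function(object, newdata = NULL, ...) {
  r <- if (is.null(newdata)) stop("supply newdata$ratio") else newdata$ratio
  object$intercept + object$slope * r
}

#' Fold-activation and percent of the allosteric activation window
#'
#' fold = k2_variant / k2 of the native wild type; the window is the native
#' to heparin-activated span of the wild type (e.g. 360-fold). Percent
#' activation is 100 * (fold - 1) / (window - 1), so the unactivated native
#' protein maps to 0% and the fully activated form to 100%.
#'
#' @param k2_variant,k2_native_wt,k2_activated_wt Second-order rate constants
#'   (1/M/s) or `rate_constant` objects; all positive.
#' @return An `activation_summary`: `fold`, `window_fold`,
#'   `percent_activation`.
#' @export
activation_metrics <- function(k2_variant, k2_native_wt, k2_activated_wt) {
  num <- function(x) if (inherits(x, "rate_constant")) x$k2 else as.numeric(x)
  kv <- num(k2_variant); kn <- num(k2_native_wt); ka <- num(k2_activated_wt)
  if (any(c(kv, kn, ka) <= 0)) stop("rates must be positive", call. = FALSE)
  window <- ka / kn
  if (window <= 1) stop("activation window <= 1: activated rate must exceed native",
                        call. = FALSE)
  fold <- kv / kn
  structure(list(fold = fold, window_fold = window,
                 percent_activation = 100 * (fold - 1) / (window - 1),
                 convention = "percent = 100*(fold-1)/(window-1)"),
            class = "activation_summary")
}

#' @export
print.activation_summary <- function(x, ...) {
  cat(sprintf("activation: %.3g-fold of a %.3g-fold window = %.1f%% activation\n",
              x$fold, x$window_fold, x$percent_activation))
  invisible(x)
}

#' Two-state R/A equilibrium partition from rate constants
#'
#' The native protein is a two-state equilibrium mixture R <-> A whose
#' observed association rate is the population-weighted average of the pure
#' R-state and pure A-state rates; the A-state fraction is therefore
#' f_A = (k_obs - k_R) / (k_A - k_R).
#'
#' @param k_obs_native Observed native-mixture rate constant, 1/M/s.
#' @param k_R Pure R-state rate constant (k_R < k_obs_native).
#' @param k_A Pure A-state rate constant (k_A > k_obs_native).
#' @return An `equilibrium_partition`: `f_R`, `f_A` (sum to 1), plus the
#'   input rates.
#' @export
equilibrium_partition <- function(k_obs_native, k_R, k_A) {
  if (!(k_R <= k_obs_native && k_obs_native <= k_A))
    stop("rate ordering violated: need k_R <= k_obs_native <= k_A", call. = FALSE)
  f_A <- (k_obs_native - k_R) / (k_A - k_R)
  structure(list(f_R = 1 - f_A, f_A = f_A, k_obs_native = k_obs_native,
                 k_R = k_R, k_A = k_A),
            class = "equilibrium_partition")
}

#' @export
print.equilibrium_partition <- function(x, ...) {
  cat(sprintf("two-state partition: %.2f%% R / %.2f%% A  (k_obs %.3g between k_R %.3g and k_A %.3g)\n",
              100 * x$f_R, 100 * x$f_A, x$k_obs_native, x$k_R, x$k_A))
  invisible(x)
}
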