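.fit_result <- function(params, se, residual_rms, converged, n_iter,
                        flags = list()) {
  structure(list(params = params, se = se, residual_rms = residual_rms,
                 converged = converged, n_iter = n_iter, flags = flags),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit_result:", if (x$converged) "converged" else "NOT converged",
      "in", x$n_iter, "iterations; residual RMS",
      signif(x$residual_rms, 4), "\n")
  for (nm in names(x$params))
    cat(sprintf("  %-10s %.6g (se %.3g)\n", nm, x$params[[nm]],
                if (nm %in% names(x$se)) x$se[[nm]] else NA))
  fl <- x$flags[vapply(x$flags, isTRUE, logical(1))]
  if (length(fl)) cat("  flags:", paste(names(fl), collapse = ", "), "\n")
  invisible(x)
}

#' Single-exponential association fit
#'
#' Least-squares fit of `signal = offset + amplitude * (1 - exp(-k_app * t))`.
#' Started from a semilog regression on the plateau-subtracted signal, then
#' refined by Levenberg-Marquardt. A flat trace (amplitude indistinguishable
#' from noise) is flagged `unidentifiable` with `k_app = NA`.
#'
#' @param trace data.frame with `time` (s) and `signal`; at least 8 points.
#' @return A `fit_result` with params `k_app` (s^-1), `amplitude`, `offset`.
#' @export
fit_exponential <- function(trace) {
  t <- trace$time; y <- trace$signal
  if (length(t) < 8) stop("need at least 8 time points")
  y_inf <- mean(y[t >= stats::quantile(t, 0.85)])
  a0 <- y_inf - y[1]
  spread <- max(abs(y - mean(y)))
  if (abs(a0) < 1e-12 || spread < 1e-12 ||
      abs(a0) < 1e-3 * stats::sd(y) * sqrt(2)) {
    return(.fit_result(list(k_app = NA_real_, amplitude = 0, offset = mean(y)),
                       list(), residual_rms = stats::sd(y), converged = FALSE,
                       n_iter = 0L, flags = list(unidentifiable = TRUE)))
  }
  z <- (y_inf - y) / a0
  keep <- z > 1e-8 & t < max(t)
  k0 <- tryCatch(-unname(stats::coef(stats::lm(log(z[keep]) ~ t[keep]))[2]),
                 error = function(e) NA_real_)
  if (!is.finite(k0) || k0 <= 0) k0 <- 2 / max(t)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ offset + amplitude * (1 - exp(-k_app * t)),
                      start = list(offset = y[1], amplitude = a0, k_app = k0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(.fit_result(list(k_app = k0, amplitude = a0, offset = y[1]),
                       list(), residual_rms = NA_real_, converged = FALSE,
                       n_iter = 200L, flags = list()))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(suppressWarnings(summary(fit)$coefficients[, "Std. Error"]),
                 error = function(e) rep(NA_real_, 3))
  span_ok <- cf[["k_app"]] * (max(t) - min(t)) >= 2
  .fit_result(list(k_app = cf[["k_app"]], amplitude = cf[["amplitude"]],
                   offset = cf[["offset"]]),
              list(k_app = unname(se["k_app"]), amplitude = unname(se["amplitude"]),
                   offset = unname(se["offset"])),
              residual_rms = sqrt(mean(stats::residuals(fit)^2)),
              converged = fit$convInfo$isConv,
              n_iter = fit$convInfo$finIter,
              flags = list(short_span = !span_ok))
}

#' Pseudo-first-order slope regression
#'
#' Weighted linear regression `k_app = k_on * conc + k_off`: the slope is the
#' observed on-rate, the intercept the off-rate. Weights are inverse squared
#' standard errors when provided. A fitted `k_off` more than 2 SE below zero
#' is flagged as a model violation.
#'
#' @param k_apps Apparent rates, s^-1 (>= 3 values).
#' @param concs Matching ligand concentrations, M.
#' @param se Optional standard errors of `k_apps`.
#' @return A `fit_result` with params `k_on` (M^-1 s^-1) and `k_off` (s^-1).
#' @export
fit_pseudo_first_order <- function(k_apps, concs, se = NULL) {
  if (length(k_apps) != length(concs)) stop("k_apps and concs differ in length")
  if (length(k_apps) < 3)
    stop("need at least 3 concentrations for slope and intercept with uncertainty")
  w <- if (!is.null(se)) 1 / se^2 else NULL
  fit <- stats::lm(k_apps ~ concs, weights = w)
  cf <- stats::coef(fit)
  # noise-free inputs trigger the "essentially perfect fit" note
  ses <- suppressWarnings(summary(fit)$coefficients[, "Std. Error"])
  k_off <- unname(cf[1]); k_off_se <- unname(ses[1])
  .fit_result(list(k_on = unname(cf[2]), k_off = k_off),
              list(k_on = unname(ses[2]), k_off = k_off_se),
              residual_rms = sqrt(mean(stats::residuals(fit)^2)),
              converged = TRUE, n_iter = 1L,
              flags = list(negative_k_off = k_off < -2 * k_off_se))
}

#' Fit a binding isotherm to a titration curve
#'
#' Fits `signal = background + amplitude * f(conc)` where `f` is the bound
#' fraction: the depletion-exact quadratic (default; correct when the probe
#' concentration is comparable to the Kd) or the hyperbolic
#' `conc / (kd + conc)`. Kd is initialised from a log-spaced grid search.
#'
#' @param curve A [simulate_titration()] result, or any data.frame with
#'   `conc` (M) and `signal` (>= 6 concentrations bracketing the Kd).
#' @param model `"quadratic"` or `"hyperbolic"`.
#' @param probe_tot Probe concentration, M (quadratic model; defaults to the
#'   curve's `meta`).
#' @return A `fit_result` with params `kd` (M), `amplitude`, `background`.
#'   Flags: `extrapolated` when the fitted Kd lies outside the concentration
#'   range by more than 100x; `unidentifiable` for a flat curve.
#' @export
fit_isotherm <- function(curve, model = c("quadratic", "hyperbolic"),
                         probe_tot = NULL) {
  model <- match.arg(model)
  conc <- curve$conc; y <- curve$signal
  if (length(conc) < 6) stop("need at least 6 concentrations")
  if (is.null(probe_tot)) probe_tot <- attr(curve, "meta")$probe_tot
  if (model == "quadratic" && is.null(probe_tot))
    stop("probe_tot is required for the quadratic model")
  if (max(y) - min(y) < 1e-12 * max(1, abs(mean(y))) ||
      stats::sd(y) < 1e-14) {
    return(.fit_result(list(kd = NA_real_, amplitude = 0, background = mean(y)),
                       list(), residual_rms = stats::sd(y), converged = FALSE,
                       n_iter = 0L, flags = list(unidentifiable = TRUE)))
  }
  frac <- function(kd, conc) {
    if (model == "quadratic")
      bound_fraction_quadratic(kd, h_tot = conc, p_tot = probe_tot)
    else conc / (kd + conc)
  }
  pos <- conc[conc > 0]
  kd_grid <- exp(seq(log(min(pos) / 100), log(max(pos) * 100), length.out = 40))
  sse <- vapply(kd_grid, function(kd) {
    f <- frac(kd, conc)
    cf <- stats::coef(stats::lm(y ~ f))
    sum((y - cf[1] - cf[2] * f)^2)
  }, numeric(1))
  kd0 <- kd_grid[which.min(sse)]
  f0 <- frac(kd0, conc)
  lin0 <- stats::coef(stats::lm(y ~ f0))
  # Levenberg-Marquardt on (background, amplitude, log kd): the log scale is
  # well-conditioned across orders of magnitude and keeps kd positive, and
  # nls.lm tolerates the weak kd identifiability of stoichiometric titrations
  resid_fn <- function(par) y - (par[1] + par[2] * frac(exp(par[3]), conc))
  fit <- minpack.lm::nls.lm(par = c(unname(lin0[1]), unname(lin0[2]),
                                    log(kd0)),
                            fn = resid_fn,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- fit$par
  se3 <- tryCatch(suppressWarnings(summary(fit)$coefficients[, "Std. Error"]),
                  error = function(e) rep(NA_real_, 3))
  kd <- exp(cf[3])
  extrap <- kd < min(pos) * 1e-2 || kd > max(pos) * 1e2
  if (extrap) warning("fitted Kd lies far outside the titrated range")
  .fit_result(list(kd = kd, amplitude = cf[2], background = cf[1]),
              list(kd = kd * se3[3], amplitude = se3[2], background = se3[1]),
              residual_rms = sqrt(mean(fit$fvec^2)),
              converged = fit$info %in% 1:4, n_iter = fit$niter,
              flags = list(extrapolated = extrap))
}
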