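#' FRET transfer efficiency
#'
#' `E = 1 / (1 + (r/r0)^6)`; `r0` is the distance of 50% transfer.
#'
#' @param r Inter-label distance, A (> 0).
#' @param r0 Forster radius, A (> 0).
#' @return Efficiency in (0, 1\].
#' @export
fret_efficiency <- function(r, r0) {
  stopifnot(all(r > 0), r0 > 0)
  1 / (1 + (r / r0)^6)
}

#' FRET parameter set
#'
#' @param r0 Forster radius, A (default 51, typical of long-range dye pairs).
#' @param d_state Named distances, A: entries `X` and `Y` (the bound complex
#'   YP reports the state-Y distance).
#' @param scale,background Signal scale and offset, arbitrary units.
#' @return List of class `fret_params`.
#' @export
fret_params <- function(r0 = 51, d_state = c(X = 60, Y = 40),
                        scale = 1, background = 0) {
  stopifnot(r0 > 0, all(c("X", "Y") %in% names(d_state)))
  structure(list(r0 = r0, d_state = d_state, scale = scale,
                 background = background), class = "fret_params")
}

#' Ensemble FRET signal from state populations
#'
#' `signal = background + scale * sum_s pop_s * E(d_s, r0)`; the bound complex
#' uses the state-Y label distance.
#'
#' @param populations Named non-negative fractions over `X`, `Y`, `YP`
#'   (must sum to 1).
#' @param params A [fret_params()].
#' @return Numeric signal.
#' @export
fret_signal <- function(populations, params) {
  stopifnot(all(c("X", "Y", "YP") %in% names(populations)))
  pop <- populations[c("X", "Y", "YP")]
  if (any(pop < -1e-12) || abs(sum(pop) - 1) > 1e-6)
    stop("populations must be non-negative and sum to 1")
  d <- c(params$d_state[["X"]], params$d_state[["Y"]], params$d_state[["Y"]])
  params$background + params$scale * sum(pop * fret_efficiency(d, params$r0))
}

#' Exact single-site bound fraction (tight-binding quadratic)
#'
#' Fraction of the limiting species bound, from the exact root of the
#' depletion-corrected single-site quadratic. The root is evaluated in the
#' cancellation-free form `2ab / (b + sqrt(b^2 - 4ab))`, stable when
#' `kd << totals`.
#'
#' @param kd_app Apparent dissociation constant, M.
#' @param h_tot,p_tot Totals of the two partners, M.
#' @return Bound fraction of `min(h_tot, p_tot)` in \[0, 1\].
#' @export
bound_fraction_quadratic <- function(kd_app, h_tot, p_tot) {
  stopifnot(kd_app >= 0, h_tot >= 0, p_tot >= 0)
  lim <- pmin(h_tot, p_tot)
  ifelse(lim == 0, 0, {
    b <- h_tot + p_tot + kd_app
    2 * h_tot * p_tot / (b + sqrt(b^2 - 4 * h_tot * p_tot)) / lim
  })
}

#' Simulate an equilibrium binding titration
#'
#' Maps [equilibrium_populations()] at each ligand concentration through an
#' observable. For `"fp"` the probe is the labeled peptide (held at
#' `probe_tot`) titrated with hinge; the signal is its bound fraction. For
#' `"fret"` the probe is the labeled hinge titrated with peptide; the signal is
#' the ensemble FRET signal. Additive i.i.d. Gaussian noise; bit-reproducible
#' for a fixed seed.
#'
#' @param rates A [rate_constants()].
#' @param probe_tot Probe concentration, M.
#' @param ligand_series Increasing ligand concentrations, M.
#' @param observable `"fp"` or `"fret"`.
#' @param params A [fret_params()] (FRET only).
#' @param noise_sd Gaussian noise SD, signal units.
#' @param seed Integer seed (required when `noise_sd > 0`).
#' @return data.frame of class `titration_curve`: `conc`, `signal`; attributes
#'   `meta` (probe, noise, seed, observable).
#' @export
simulate_titration <- function(rates, probe_tot, ligand_series,
                               observable = c("fp", "fret"),
                               params = fret_params(), noise_sd = 0,
                               seed = NULL) {
  observable <- match.arg(observable)
  if (is.unsorted(ligand_series, strictly = TRUE))
    stop("ligand_series must be strictly increasing")
  if (noise_sd > 0 && is.null(seed)) stop("a seed is required when noise_sd > 0")
  signal <- vapply(ligand_series, function(lig) {
    if (observable == "fp") {
      st <- equilibrium_populations(rates, h_tot = lig, p_tot = probe_tot)
      st$yp / probe_tot
    } else {
      st <- equilibrium_populations(rates, h_tot = probe_tot, p_tot = lig)
      fret_signal(c(X = st$x, Y = st$y, YP = st$yp) / probe_tot, params)
    }
  }, numeric(1))
  if (noise_sd > 0) {
    set.seed(seed)
    signal <- signal + stats::rnorm(length(signal), 0, noise_sd)
  }
  out <- data.frame(conc = ligand_series, signal = signal)
  class(out) <- c("titration_curve", "data.frame")
  attr(out, "meta") <- list(probe_tot = probe_tot, observable = observable,
                            noise_sd = noise_sd, seed = seed)
  out
}

#' Simulate association (mixing) time courses
#'
#' One trace per ligand concentration: the probe starts pre-equilibrated
#' between X and Y, the ligand is added at `t = 0`, and the three-state ODE is
#' integrated and mapped to the observable. For `"fret"` the probe is the
#' labeled hinge and the ligand the peptide; for `"fp"` the probe is the
#' labeled peptide and the ligand the hinge (signal = bound fraction). Warns
#' when the ligand is not in at least 10x excess (pseudo-first-order designs).
#'
#' @inheritParams simulate_titration
#' @param probe Probe concentration, M.
#' @param t_grid Increasing times, s, starting at 0.
#' @return List of `kinetic_trace` data.frames (`time`, `signal`), each with
#'   attribute `meta` (`conc`, `noise_sd`, `seed`).
#' @export
simulate_association <- function(rates, probe, ligand_series,
                                 observable = c("fp", "fret"), t_grid,
                                 params = fret_params(), noise_sd = 0,
                                 seed = NULL) {
  observable <- match.arg(observable)
  if (noise_sd > 0 && is.null(seed)) stop("a seed is required when noise_sd > 0")
  if (min(ligand_series) < 10 * probe)
    warning("ligand not in >= 10x excess over probe: ",
            "pseudo-first-order treatment may be invalid")
  f_y <- derive_equilibrium(rates)$f_y
  if (noise_sd > 0) set.seed(seed)
  lapply(seq_along(ligand_series), function(i) {
    lig <- ligand_series[i]
    if (observable == "fret") {
      init <- kinetic_state(x = (1 - f_y) * probe, y = f_y * probe, p = lig)
      tr <- simulate_kinetics(rates, init, t_grid)
      sig <- vapply(seq_len(nrow(tr)), function(k)
        fret_signal(c(X = tr$x[k], Y = tr$y[k], YP = tr$yp[k]) / probe, params),
        numeric(1))
    } else {
      init <- kinetic_state(x = (1 - f_y) * lig, y = f_y * lig, p = probe)
      tr <- simulate_kinetics(rates, init, t_grid)
      sig <- tr$yp / probe
    }
    if (noise_sd > 0) sig <- sig + stats::rnorm(length(sig), 0, noise_sd)
    out <- data.frame(time = tr$time, signal = sig)
    class(out) <- c("kinetic_trace", "data.frame")
    attr(out, "meta") <- list(conc = lig, noise_sd = noise_sd, seed = seed)
    out
  })
}

#' Gaussian-mixture surrogate distance distribution
#'
#' Normalised Gaussian mixture on a distance grid, standing in for spin-label
#' distance distributions; state means are typically the CB-CB distances of a
#' label-site pair ([site_pairs()]). If the grid truncates appreciable tail
#' mass the density is renormalised with a warning.
#'
#' @param weights Non-negative state weights summing to 1.
#' @param means Component means, A.
#' @param sigmas Component SDs, A (default 3.0, recycled).
#' @param grid Distance grid, A (default `seq(10, 80, 0.5)`).
#' @return data.frame of class `distance_distribution`: `r`, `density`
#'   (1/A, trapezoid-normalised to 1).
#' @export
deer_distribution <- function(weights, means, sigmas = 3.0,
                              grid = seq(10, 80, by = 0.5)) {
  stopifnot(all(weights >= 0), abs(sum(weights) - 1) < 1e-9,
            length(means) == length(weights), all(sigmas > 0))
  sigmas <- rep_len(sigmas, length(weights))
  dens <- rowSums(vapply(seq_along(weights), function(i)
    weights[i] * stats::dnorm(grid, means[i], sigmas[i]), numeric(length(grid))))
  mass <- pracma::trapz(grid, dens)
  if (mass < 1 - 1e-3)
    warning("grid truncates ", signif(1 - mass, 2),
            " of the distribution mass; density renormalised")
  out <- data.frame(r = grid, density = dens / mass)
  class(out) <- c("distance_distribution", "data.frame")
  out
}

#' Decompose an observed distance distribution into two state bases
#'
#' Non-negative least squares of the observed density on the state X and
#' state Y basis densities; weights are renormalised to sum to 1. Flags the
#' decomposition as unidentifiable when the bases are nearly collinear
#' (cosine similarity > 0.99).
#'
#' @param observed,basis_x,basis_y [deer_distribution()] objects on a common
#'   grid.
#' @return List: `w_x`, `w_y`, `residual_rms`, `unidentifiable`.
#' @export
decompose_deer <- function(observed, basis_x, basis_y) {
  if (!isTRUE(all.equal(observed$r, basis_x$r)) ||
      !isTRUE(all.equal(observed$r, basis_y$r)))
    stop("distributions must share a common grid")
  bx <- basis_x$density; by <- basis_y$density
  cosim <- sum(bx * by) / sqrt(sum(bx^2) * sum(by^2))
  fit <- pracma::lsqnonneg(cbind(bx, by), observed$density)
  w <- fit$x
  resid <- observed$density - as.numeric(cbind(bx, by) %*% w)
  tot <- sum(w)
  if (tot <= 0) w <- c(0.5, 0.5) else w <- w / tot
  list(w_x = w[1], w_y = w[2], residual_rms = sqrt(mean(resid^2)),
       unidentifiable = cosim > 0.99)
}

#' Infer the state-Y fraction from an on-rate ratio
#'
#' Under the fast pre-equilibrium with identical microscopic `k2`, observed
#' on-rates are proportional to the state-Y fraction, so
#' `F_Y = f_y_reference * k_on_variant / k_on_reference`. The reference is
#' typically a locked-Y variant taken to be 100% state Y.
#'
#' @param k_on_variant,k_on_reference Observed on-rates, M^-1 s^-1 (> 0).
#' @param f_y_reference State-Y fraction of the reference, in (0, 1\]
#'   (default 1).
#' @return List: `f_y`, `f_x = 1 - f_y`, `ratio`, `inconsistent` (TRUE when
#'   the implied fraction exceeds 1; the value is then clipped), and
#'   `assumes_identical_k2 = TRUE` (the stated modelling assumption).
#' @export
infer_fy_from_kon_ratio <- function(k_on_variant, k_on_reference,
                                    f_y_reference = 1) {
  stopifnot(k_on_variant > 0, k_on_reference > 0,
            f_y_reference > 0, f_y_reference <= 1)
  ratio <- k_on_variant / k_on_reference
  f_y <- f_y_reference * ratio
  inconsistent <- f_y > 1
  if (inconsistent) f_y <- 1
  list(f_y = f_y, f_x = 1 - f_y, ratio = ratio, inconsistent = inconsistent,
       assumes_identical_k2 = TRUE)
}
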