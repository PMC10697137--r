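# gas constant, kcal / (mol K)
.R_KCAL <- 1.98720425e-3

#' Microscopic rate constants of the three-state hinge model
#'
#' The model couples the hinge conformational pre-equilibrium to effector
#' binding: X <-> Y (rates `k1`, `k_m1`, s^-1) and Y + P <-> YP (`k2`,
#' M^-1 s^-1, and `k_m2`, s^-1). Only state Y binds the peptide.
#'
#' @param k1 X -> Y rate, s^-1.
#' @param k_m1 Y -> X rate, s^-1.
#' @param k2 Y + P association rate, M^-1 s^-1.
#' @param k_m2 YP dissociation rate, s^-1.
#' @return List of class `rate_constants`.
#' @export
rate_constants <- function(k1, k_m1, k2, k_m2) {
  v <- c(k1 = k1, k_m1 = k_m1, k2 = k2, k_m2 = k_m2)
  if (any(!is.finite(v)) || any(v < 0)) stop("rate constants must be finite and >= 0")
  if (k1 + k_m1 <= 0) stop("k1 + k_m1 must be positive")
  structure(as.list(v), class = "rate_constants")
}

#' @export
print.rate_constants <- function(x, ...) {
  eq <- derive_equilibrium(x)
  cat(sprintf("rate_constants: k1 %.3g, k-1 %.3g s-1; k2 %.3g M-1s-1, k-2 %.3g s-1\n",
              x$k1, x$k_m1, x$k2, x$k_m2))
  cat(sprintf("  F_Y %.4g, K_D,int %.3g M, K_D,app %.3g M\n",
              eq$f_y, eq$k_d_intrinsic, eq$k_d_app))
  invisible(x)
}

#' Equilibrium quantities derived from the rate constants
#'
#' @param rates A [rate_constants()].
#' @return List: `k_conf = k1/k_m1` (Inf when `k_m1 = 0`), `f_y = k1/(k1+k_m1)`
#'   (the fractional state-Y population of the unbound hinge),
#'   `k_d_intrinsic = k_m2/k2` (M; NA with `kd_defined = FALSE` when
#'   `k2 = 0`), and `k_d_app = k_d_intrinsic / f_y` (the apparent dissociation
#'   constant seen by a titration).
#' @export
derive_equilibrium <- function(rates) {
  k_conf <- if (rates$k_m1 == 0) Inf else rates$k1 / rates$k_m1
  f_y <- rates$k1 / (rates$k1 + rates$k_m1)
  kd_defined <- rates$k2 > 0
  k_d <- if (kd_defined) rates$k_m2 / rates$k2 else NA_real_
  list(k_conf = k_conf, f_y = f_y, k_d_intrinsic = k_d,
       k_d_app = if (kd_defined) {
         if (f_y > 0) k_d / f_y else Inf
       } else NA_real_,
       kd_defined = kd_defined)
}

#' Equilibrium populations under mass conservation
#'
#' Solves the coupled conformational and binding equilibria exactly: after
#' eliminating X through `K_conf`, the bound concentration solves the
#' single-site quadratic with the apparent dissociation constant
#' `K_D,app = K_D,intrinsic / F_Y`. A numerically stable root form avoids
#' cancellation when `K_D << totals`.
#'
#' @param rates A [rate_constants()].
#' @param h_tot Total hinge, M.
#' @param p_tot Total peptide, M.
#' @return List of class `kinetic_state`: concentrations `x`, `y`, `yp`, `p`
#'   (M) and `time = Inf`.
#' @export
equilibrium_populations <- function(rates, h_tot, p_tot) {
  stopifnot(h_tot >= 0, p_tot >= 0)
  eq <- derive_equilibrium(rates)
  f_y <- eq$f_y
  if (!eq$kd_defined || !is.finite(eq$k_d_app) || h_tot == 0 || p_tot == 0) {
    yp <- 0
  } else {
    b <- h_tot + p_tot + eq$k_d_app
    yp <- 2 * h_tot * p_tot / (b + sqrt(b^2 - 4 * h_tot * p_tot))
  }
  u <- h_tot - yp
  structure(list(x = (1 - f_y) * u, y = f_y * u, yp = yp, p = p_tot - yp,
                 time = Inf),
            class = "kinetic_state")
}

#' Initial state helper
#'
#' @param x,y,yp,p Concentrations, M (all >= 0).
#' @param time Time stamp, s.
#' @return List of class `kinetic_state`.
#' @export
kinetic_state <- function(x = 0, y = 0, yp = 0, p = 0, time = 0) {
  v <- c(x, y, yp, p)
  if (any(v < 0)) stop("concentrations must be non-negative")
  structure(list(x = x, y = y, yp = yp, p = p, time = time),
            class = "kinetic_state")
}

.rhs_three_state <- function(t, s, pars) {
  with(as.list(c(s, pars)), {
    conf <- k1 * x - k_m1 * y
    bind <- k2 * y * p - k_m2 * yp
    list(c(x = -conf, y = conf - bind, yp = bind, p = -bind))
  })
}

#' Simulate the three-state binding kinetics
#'
#' Integrates `dX/dt = -k1 X + k_m1 Y`, `dY/dt = k1 X - k_m1 Y - k2 Y P +
#' k_m2 YP`, `dYP/dt = k2 Y P - k_m2 YP`, `dP/dt = -k2 Y P + k_m2 YP` with
#' adaptive (lsoda) stepping, which switches to an implicit method in stiff
#' regimes. Mass conservation is enforced by projection to within 1e-9
#' relative.
#'
#' @param rates A [rate_constants()].
#' @param initial A [kinetic_state()] (non-negative concentrations).
#' @param t_grid Increasing times, s; `t_grid[1]` is the initial time.
#' @return data.frame of class `kinetic_trace`: `time`, `x`, `y`, `yp`, `p`.
#' @export
simulate_kinetics <- function(rates, initial, t_grid) {
  if (any(unlist(initial[c("x", "y", "yp", "p")]) < 0))
    stop("negative initial concentrations")
  if (is.unsorted(t_grid, strictly = TRUE) && length(t_grid) > 1)
    stop("t_grid must be strictly increasing")
  y0 <- c(x = initial$x, y = initial$y, yp = initial$yp, p = initial$p)
  if (length(t_grid) == 1) {
    out <- data.frame(time = t_grid, x = y0["x"], y = y0["y"],
                      yp = y0["yp"], p = y0["p"])
    rownames(out) <- NULL
    class(out) <- c("kinetic_trace", "data.frame")
    return(out)
  }
  h_tot <- initial$x + initial$y + initial$yp
  p_tot <- initial$p + initial$yp
  # per-species absolute tolerance so a trace-level probe in a large ligand
  # excess is still integrated to full relative accuracy
  atol <- 1e-12 * pmax(c(h_tot, h_tot, h_tot, p_tot), 1e-30)
  sol <- deSolve::lsoda(y0, t_grid, .rhs_three_state, unlist(rates),
                        rtol = 1e-10, atol = atol, maxsteps = 50000)
  out <- as.data.frame(sol)
  names(out)[1] <- "time"
  # project back onto the conservation manifold
  if (h_tot > 0) {
    f <- h_tot / (out$x + out$y + out$yp)
    out$x <- out$x * f; out$y <- out$y * f; out$yp <- out$yp * f
  }
  out$p <- p_tot - out$yp
  class(out) <- c("kinetic_trace", "data.frame")
  out
}

#' Exact linear solution at constant (excess) peptide
#'
#' With P clamped, the three hinge species obey a linear ODE solved here by
#' eigendecomposition (matrix exponential fallback when the rate matrix is
#' defective, flagged in the `defective` attribute). Serves as the analytic
#' oracle for [simulate_kinetics()] and covers stiff regimes exactly.
#'
#' @param rates A [rate_constants()].
#' @param p_const Clamped peptide concentration, M.
#' @param initial A [kinetic_state()] (its `p` is ignored).
#' @param t_grid Increasing times, s.
#' @return data.frame of class `kinetic_trace` with `p = p_const`; attribute
#'   `eigenvalues` holds the (sorted, ascending magnitude) relaxation rates.
#' @export
linear_solution_excess_p <- function(rates, p_const, initial, t_grid) {
  A <- rbind(c(-rates$k1, rates$k_m1, 0),
             c(rates$k1, -(rates$k_m1 + rates$k2 * p_const), rates$k_m2),
             c(0, rates$k2 * p_const, -rates$k_m2))
  y0 <- c(initial$x, initial$y, initial$yp)
  t0 <- t_grid[1]
  ev <- eigen(A)
  defective <- FALSE
  sc <- max(abs(ev$values), 1e-300)
  if (min(abs(diff(sort(Re(ev$values))))) > 1e-10 * sc &&
      rcond(ev$vectors) > 1e-12) {
    c0 <- solve(ev$vectors, y0)
    sol <- t(vapply(t_grid, function(t)
      Re(ev$vectors %*% (c0 * exp(ev$values * (t - t0)))), numeric(3)))
  } else {
    defective <- TRUE
    sol <- t(vapply(t_grid, function(t)
      as.numeric(pracma::expm(A * (t - t0)) %*% y0), numeric(3)))
  }
  out <- data.frame(time = t_grid, x = sol[, 1], y = sol[, 2], yp = sol[, 3],
                    p = p_const)
  class(out) <- c("kinetic_trace", "data.frame")
  attr(out, "eigenvalues") <- sort(abs(Re(ev$values)))
  attr(out, "defective") <- defective
  out
}

#' Observed on-rate under the fast pre-equilibrium
#'
#' When the conformational exchange is much faster than binding, the observed
#' association rate is the microscopic rate times the fraction of hinge poised
#' in the binding-competent state: `k_on = k2 * F_Y`.
#'
#' @param rates A [rate_constants()].
#' @param p_ref Optional reference peptide concentration, M, used for the
#'   validity flag: the pre-equilibrium treatment is valid when
#'   `(k1 + k_m1) >= 10 * (k2 * p_ref + k_m2)`.
#' @return List: `k_on` (M^-1 s^-1), `f_y`, `valid` (NA when `p_ref` absent).
#' @export
pre_equilibrium_kon <- function(rates, p_ref = NULL) {
  f_y <- derive_equilibrium(rates)$f_y
  valid <- if (is.null(p_ref)) NA else
    (rates$k1 + rates$k_m1) >= 10 * (rates$k2 * p_ref + rates$k_m2)
  list(k_on = rates$k2 * f_y, f_y = f_y, valid = valid)
}

#' Shift the conformational equilibrium by a stability change
#'
#' A mutation or staple that changes the X/Y stability by `ddg_conf`
#' (kcal/mol, positive favouring state Y) multiplies `K_conf` by
#' `exp(ddg_conf / RT)`. Because kinetic data constrain only the ratio, the
#' barrier position is a convention: `scale_km1` (default) divides `k_m1`,
#' `scale_k1` multiplies `k1`. The binding rates `k2`, `k_m2` are untouched
#' (non-interface substitutions).
#'
#' @param rates A [rate_constants()].
#' @param ddg_conf Stability shift, kcal/mol (positive favours Y).
#' @param temperature Kelvin (default 298.15).
#' @param convention `"scale_km1"` or `"scale_k1"`.
#' @return A [rate_constants()].
#' @export
apply_stability_shift <- function(rates, ddg_conf, temperature = 298.15,
                                  convention = c("scale_km1", "scale_k1")) {
  convention <- match.arg(convention)
  stopifnot(is.finite(ddg_conf), temperature > 0)
  f <- exp(ddg_conf / (.R_KCAL * temperature))
  if (convention == "scale_km1")
    rate_constants(rates$k1, rates$k_m1 / f, rates$k2, rates$k_m2)
  else
    rate_constants(rates$k1 * f, rates$k_m1, rates$k2, rates$k_m2)
}

#' Lock the hinge in one state
#'
#' Models an oxidised disulfide staple: locking X sets `k1 = 0` (the hinge can
#' never reach the binding-competent state), locking Y sets `k_m1 = 0`
#' (`F_Y = 1`).
#'
#' @param rates A [rate_constants()].
#' @param state `"X"` or `"Y"`.
#' @return A [rate_constants()].
#' @export
lock_state <- function(rates, state = c("X", "Y")) {
  state <- match.arg(state)
  if (state == "X") rate_constants(0, rates$k_m1, rates$k2, rates$k_m2)
  else rate_constants(rates$k1, 0, rates$k2, rates$k_m2)
}

#' Simulate a competition (chase) experiment
#'
#' Extends the three-state system with a second, unlabeled hinge (X2, Y2,
#' Y2P) sharing the free peptide pool. The labeled hinge starts
#' pre-equilibrated at `h_lab`; peptide (`p_tot`) is injected at
#' `schedule$t_peptide` and competitor hinge (`h_comp`, pre-equilibrated
#' between its X and Y states) at `schedule$t_competitor`.
#'
#' @param rates_labeled,rates_competitor [rate_constants()] for the two
#'   hinges.
#' @param h_lab Labeled hinge total, M.
#' @param p_tot Peptide injected, M.
#' @param h_comp Competitor hinge injected, M.
#' @param schedule List with `t_peptide` and `t_competitor` (s), both within
#'   the span of `t_grid`.
#' @param t_grid Increasing times, s.
#' @return data.frame of class `kinetic_trace`: `time`, `x`, `y`, `yp`
#'   (labeled hinge), `x2`, `y2`, `y2p` (competitor), `p`.
#' @export
simulate_competition <- function(rates_labeled, rates_competitor, h_lab,
                                 p_tot, h_comp, schedule, t_grid) {
  stopifnot(schedule$t_peptide >= t_grid[1],
            schedule$t_competitor >= t_grid[1],
            schedule$t_peptide <= t_grid[length(t_grid)],
            schedule$t_competitor <= t_grid[length(t_grid)])
  rl <- rates_labeled; rc <- rates_competitor
  rhs <- function(t, s, pars) {
    conf1 <- rl$k1 * s[1] - rl$k_m1 * s[2]
    bind1 <- rl$k2 * s[2] * s[7] - rl$k_m2 * s[3]
    conf2 <- rc$k1 * s[4] - rc$k_m1 * s[5]
    bind2 <- rc$k2 * s[5] * s[7] - rc$k_m2 * s[6]
    list(c(-conf1, conf1 - bind1, bind1, -conf2, conf2 - bind2, bind2,
           -bind1 - bind2))
  }
  f_lab <- derive_equilibrium(rl)$f_y
  f_cmp <- derive_equilibrium(rc)$f_y
  state <- c(x = (1 - f_lab) * h_lab, y = f_lab * h_lab, yp = 0,
             x2 = 0, y2 = 0, y2p = 0, p = 0)
  events <- unique(sort(c(schedule$t_peptide, schedule$t_competitor)))
  bounds <- unique(sort(c(t_grid[1], events, t_grid[length(t_grid)])))
  pieces <- list()
  scale <- max(h_lab, p_tot, h_comp, 1e-12)
  for (i in seq_len(length(bounds) - 1)) {
    t0 <- bounds[i]; t1 <- bounds[i + 1]
    if (t0 %in% events) {
      if (t0 == schedule$t_peptide) state["p"] <- state["p"] + p_tot
      if (t0 == schedule$t_competitor) {
        state["x2"] <- state["x2"] + (1 - f_cmp) * h_comp
        state["y2"] <- state["y2"] + f_cmp * h_comp
      }
    }
    tt <- unique(c(t0, t_grid[t_grid > t0 & t_grid < t1], t1))
    sol <- deSolve::lsoda(state, tt, rhs, NULL, rtol = 1e-10,
                          atol = 1e-14 * scale, maxsteps = 50000)
    keep <- sol[, 1] %in% t_grid & !(sol[, 1] == t1 & t1 %in% events)
    pieces[[i]] <- as.data.frame(sol)[keep, ]
    state <- sol[nrow(sol), -1]
  }
  # final point if the last bound is not an event start
  out <- do.call(rbind, pieces)
  if (!t_grid[length(t_grid)] %in% out$time)
    out <- rbind(out, stats::setNames(as.data.frame(t(c(bounds[length(bounds)], state))),
                                      names(out)))
  names(out)[1] <- "time"
  out <- out[!duplicated(out$time), ]
  rownames(out) <- NULL
  class(out) <- c("kinetic_trace", "data.frame")
  out
}
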