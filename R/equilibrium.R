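# Angular integrals are cached per (T*, k_s, theta_max): along an isotherm the
# orientational factor is pressure independent, so sweeps reuse it.
.ang_cache <- new.env(parent = emptyenv())

ang_key <- function(beta, params)
  sprintf("%.17g|%.17g|%.17g", beta, params$k_s, params$theta_max)

#' Normalized orientational factor of the hydrogen-bond well
#'
#' The hydrogen-bond statistical weight factors into the well-depth Boltzmann
#' factor times an orientational average of the harmonic strain,
#' `(1 / (2 theta_max)) * integral exp(-beta k_s theta^2) dtheta` over the
#' bonding window. Evaluated by adaptive quadrature; lies in (0, 1], equals 1
#' when `k_s = 0`, and collapses to 0 as `beta -> Inf`.
#'
#' @param state A [thermo_state()].
#' @param params An [mb_params()] object.
#' @return The dimensionless orientational factor.
#' @examples
#' hb_angular_integral(thermo_state(0.2, 0), mb_params())
#' hb_angular_integral(thermo_state(0.2, 0), mb_params(k_s = 0))  # 1
#' @export
hb_angular_integral <- function(state, params = mb_params()) {
  state <- as_state(state)
  ang_factors(state$beta, params)$integral
}

# orientational factor and mean harmonic strain <k_s theta^2>, cached
ang_factors <- function(beta, params) {
  key <- ang_key(beta, params)
  hit <- .ang_cache[[key]]
  if (!is.null(hit)) return(hit)
  tm <- params$theta_max
  ks <- params$k_s
  if (ks == 0) {
    out <- list(integral = 1, mean_spring = 0)
  } else {
    den <- stats::integrate(function(th) exp(-beta * ks * th^2),
                            -tm, tm, rel.tol = 1e-12, abs.tol = 0)$value
    num <- stats::integrate(function(th) ks * th^2 * exp(-beta * ks * th^2),
                            -tm, tm, rel.tol = 1e-12, abs.tol = 0)$value
    out <- list(integral = den / (2 * tm), mean_spring = num / den)
  }
  .ang_cache[[key]] <- out
  out
}

#' Isothermal-isobaric statistical weights of the four bond states
#'
#' Boltzmann weights including each state's pressure-volume cost:
#' \describe{
#'   \item{HB}{`exp(beta (eps_hb + eps_lj)) * I(beta) * exp(-beta p* v_hb)`,
#'     with `I` the orientational factor of [hb_angular_integral()].}
#'   \item{LJ}{`exp(beta eps_lj) * exp(-beta p* v_lj)`.}
#'   \item{0}{`exp(-beta p* v_0)`.}
#'   \item{c}{as HB but with the cage area `v_c` in place of `v_hb`.}
#' }
#' together with the cooperativity factor `delta = exp(beta eps_c)` that
#' applies only when six molecules close a full hexagonal cage (`eps_c` is
#' stored as the magnitude of the stabilizing cooperativity energy, so
#' `delta >= 1`: closing a cage lowers each member's energy by `eps_c`,
#' consistent with the cage mean bond energy `<E_c> = <E_HB> - eps_c`). All
#' arithmetic is done in log space; the log weights are kept alongside the
#' exponentiated values.
#'
#' @inheritParams hb_angular_integral
#' @return An object of class `state_weights`: a list with `delta_hb`,
#'   `delta_lj`, `delta_0`, `delta_c`, `delta_coop` and their logs
#'   (`log_delta_*`, `log_delta_coop`).
#' @examples
#' w <- state_weights(thermo_state(0.2, 0.19))
#' w$delta_coop  # exp(-0.03 / 0.2)
#' @export
state_weights <- function(state, params = mb_params()) {
  state <- as_state(state)
  b <- state$beta
  p <- state$p_star
  lI <- log(ang_factors(b, params)$integral)
  lw <- c(
    hb = b * (params$eps_hb + params$eps_lj) + lI - b * p * params$v_hb,
    lj = b * params$eps_lj - b * p * params$v_lj,
    o  = -b * p * params$v_0,
    c  = b * (params$eps_hb + params$eps_lj) + lI - b * p * params$v_c
  )
  lcoop <- b * params$eps_c
  if (any(!is.finite(lw)) || !is.finite(lcoop))
    stop("non-finite statistical weight: invalid state point", call. = FALSE)
  out <- list(
    delta_hb = exp(lw[["hb"]]), delta_lj = exp(lw[["lj"]]),
    delta_0 = exp(lw[["o"]]), delta_c = exp(lw[["c"]]),
    delta_coop = exp(lcoop),
    log_delta_hb = lw[["hb"]], log_delta_lj = lw[["lj"]],
    log_delta_0 = lw[["o"]], log_delta_c = lw[["c"]],
    log_delta_coop = lcoop
  )
  class(out) <- "state_weights"
  out
}

#' @export
print.state_weights <- function(x, ...) {
  cat("isothermal-isobaric state weights\n")
  cat(sprintf("  delta_hb = %g\n  delta_lj = %g\n  delta_0  = %g\n  delta_c  = %g\n  delta    = %g (cooperativity)\n",
              x$delta_hb, x$delta_lj, x$delta_0, x$delta_c, x$delta_coop))
  invisible(x)
}

# log-space core of the hexagon sum: returns the log weights relative to
# log S = log(delta_hb + delta_lj + delta_0), the relative amplitudes
# a = delta_hb/S, bb = delta_lj/S, cc = delta_0/S, q = delta*delta_c/S, and
# the bracket 1 - a^6 + q^6. Always safe: a < 1 strictly, so 1 - a^6 > 0 and
# the bracket is positive with no cancellation; q = a exp(beta (eps_c -
# p (v_c - v_hb))) stays O(1) at liquid state points.
hexagon_core <- function(w) {
  lw <- c(w$log_delta_hb, w$log_delta_lj, w$log_delta_0)
  m <- max(lw)
  lS <- m + log(sum(exp(lw - m)))
  a <- exp(w$log_delta_hb - lS)
  bb <- exp(w$log_delta_lj - lS)
  cc <- exp(w$log_delta_0 - lS)
  q <- exp(w$log_delta_coop + w$log_delta_c - lS)
  list(lS = lS, a = a, bb = bb, cc = cc, q = q, bracket = 1 - a^6 + q^6)
}

#' Log of the hexagon partition function
#'
#' The six bonds around a hexagon are independent except that the all-bonded
#' ring is promoted to the cooperative cage:
#' `Psi = (delta_hb + delta_lj + delta_0)^6 - delta_hb^6 + (delta delta_c)^6`.
#' Evaluated in log space (log-sum-exp), so it survives inverse temperatures
#' up to `beta ~ 50` and beyond; `Psi` is strictly positive because
#' `delta_hb` is strictly smaller than the three-state sum.
#'
#' @inheritParams hb_angular_integral
#' @return `log(Psi)` as a single number.
#' @examples
#' hexagon_partition(thermo_state(0.25, 0.1))
#' @export
hexagon_partition <- function(state, params = mb_params()) {
  w <- state_weights(state, params)
  h <- hexagon_core(w)
  6 * h$lS + log(h$bracket)
}

#' State populations from the hexagon partition function
#'
#' Populations are the logarithmic derivatives
#' `f_i = (1/6) d log(Psi) / d log(delta_i)` (with the cage weight carrying
#' the cooperativity factor), evaluated analytically:
#' `f_hb = (a - a^6) / B`, `f_lj = b / B`, `f_0 = c / B`,
#' `f_c = q^6 / B` with `a, b, c, q` the weights relative to their sum and
#' `B = 1 - a^6 + q^6`. They sum to one structurally (Euler homogeneity of
#' degree six of `Psi` in the weights).
#'
#' @inheritParams hb_angular_integral
#' @return Named numeric vector `c(f_hb, f_lj, f_0, f_c)`.
#' @examples
#' populations(thermo_state(0.2, 0.19))
#' sum(populations(thermo_state(0.2, 0.19)))  # 1
#' @export
populations <- function(state, params = mb_params()) {
  w <- state_weights(state, params)
  h <- hexagon_core(w)
  c(f_hb = (h$a - h$a^6) / h$bracket,
    f_lj = h$bb / h$bracket,
    f_0  = h$cc / h$bracket,
    f_c  = h$q^6 / h$bracket)
}

#' Gibbs energy per molecule
#'
#' From `Q = Psi^(N/6)` (the factor `N/6` counts hexagons, correcting the
#' three interaction sites per molecule for double counting) together with
#' the translational free-volume factor `(v_free_frac / (beta p*))` per
#' molecule:
#' `g = -(T*/6) log(Psi) + v_free_frac * T* * log(beta p*)`.
#' With `v_free_frac = 0` the bond term stands alone and `Psi = 1` gives
#' `g = 0`.
#'
#' @inheritParams hb_angular_integral
#' @return Gibbs energy per molecule in reduced units.
#' @examples
#' gibbs_per_molecule(thermo_state(0.2, 0.19))
#' @export
gibbs_per_molecule <- function(state, params = mb_params()) {
  state <- as_state(state)
  g <- -(state$t_star / 6) * hexagon_partition(state, params)
  if (params$v_free_frac > 0) {
    if (state$p_star <= 0)
      stop("free-volume term requires p* > 0 (the model evaporates at p* = 0)",
           call. = FALSE)
    g <- g + params$v_free_frac * state$t_star * log(state$beta * state$p_star)
  }
  g
}

#' Mean bond energies of the four states
#'
#' Boltzmann-averaged interaction energy of each bond state:
#' `<E_HB>` averages the harmonic well over the bonding window,
#' `<E_LJ> = -eps_lj`, `<E_0> = 0`, and `<E_c> = <E_HB> - eps_c`
#' (each cage molecule additionally carries the cooperativity bonus).
#'
#' @inheritParams hb_angular_integral
#' @return Named numeric vector `c(hb, lj, o, c)` of mean energies (<= 0).
#' @examples
#' mean_bond_energies(thermo_state(0.2, 0))
#' @export
mean_bond_energies <- function(state, params = mb_params()) {
  state <- as_state(state)
  af <- ang_factors(state$beta, params)
  e_hb <- -(params$eps_hb + params$eps_lj) + af$mean_spring
  c(hb = e_hb, lj = -params$eps_lj, o = 0, c = e_hb - params$eps_c)
}

state_volumes <- function(params)
  c(hb = params$v_hb, lj = params$v_lj, o = params$v_0, c = params$v_c)

# Analytic first derivatives of log Psi.
#   d logPsi / d p*   = -6 beta sum_i f_i v_i
#   d logPsi / d beta =  6 sum_i f_i u_i,  u_i = d log(weight_i)/d beta
# (the cage channel carries d log(delta)/d beta = -eps_c as well).
ln_psi_derivatives <- function(state, params = mb_params()) {
  state <- as_state(state)
  f <- populations(state, params)
  vol <- state_volumes(params)
  e <- mean_bond_energies(state, params)
  # d log I / d beta = -<k_s theta^2>, folded into e via e_hb definition
  u <- c(-(e[["hb"]] + state$p_star * vol[["hb"]]),
         -(e[["lj"]] + state$p_star * vol[["lj"]]),
         -(e[["o"]] + state$p_star * vol[["o"]]),
         -(e[["c"]] + state$p_star * vol[["c"]]))
  list(dp = -6 * state$beta * sum(f * vol),
       dbeta = 6 * sum(f * u))
}

#' Full equilibrium thermodynamics at one state point
#'
#' Populations plus every thermodynamic function obtained from the Gibbs
#' energy: molecular volume `v = dg/dp`, entropy `s = -dg/dT`, enthalpy
#' `h = g + T s`, number density `rho = 1/v`, isothermal compressibility
#' `kappa_t = -(1/v) dv/dp`, thermal expansivity `alpha_p = (1/v) dv/dT`,
#' and heat capacities `cp = dh/dT`, `cv = cp - T v alpha_p^2 / kappa_t`.
#'
#' First derivatives (`v`, `h`, `s`) are evaluated analytically through the
#' populations (the volume is the population-weighted state volume plus the
#' free-volume tail, the enthalpy the population-weighted mean bond enthalpy);
#' second derivatives differentiate those analytic functions with five-point
#' central stencils plus one level of Richardson extrapolation, with the
#' free-volume tail differentiated in closed form so small pressures stay
#' accurate.
#'
#' @inheritParams hb_angular_integral
#' @return An object of class `eq_props`: a list with `t_star`, `p_star`,
#'   `f_hb`, `f_lj`, `f_0`, `f_c`, `g`, `v`, `h`, `s`, `rho`, `kappa_t`,
#'   `alpha_p`, `cp`, `cv`.
#' @examples
#' eq <- equilibrium_properties(thermo_state(0.2, 0.19))
#' eq$cp - eq$cv  # always >= 0
#' @export
equilibrium_properties <- function(state, params = mb_params()) {
  state <- as_state(state)
  t <- state$t_star
  p <- state$p_star
  afr <- params$v_free_frac
  if (afr > 0 && p <= 0)
    stop("free-volume term requires p* > 0 (the model evaporates at p* = 0)",
         call. = FALSE)

  vol <- state_volumes(params)
  v_pop <- function(tt, pp) {
    sum(populations(thermo_state(tt, pp), params) * vol)
  }
  h_pop <- function(tt, pp) {
    st <- thermo_state(tt, pp)
    f <- populations(st, params)
    e <- mean_bond_energies(st, params)
    sum(f * (e + pp * vol))
  }

  f <- populations(state, params)
  g <- gibbs_per_molecule(state, params)
  v <- v_pop(t, p) + if (afr > 0) afr * t / p else 0
  h <- h_pop(t, p) + afr * t
  s <- (h - g) / t

  if (!is.finite(v) || v <= 0)
    stop("non-physical state: volume per molecule <= 0", call. = FALSE)

  hp <- fd_step(p)
  ht <- fd_step(t)
  dv_dp <- fd_first(function(pp) v_pop(t, pp), p, hp) -
    if (afr > 0) afr * t / p^2 else 0
  dv_dt <- fd_first(function(tt) v_pop(tt, p), t, ht) +
    if (afr > 0) afr / p else 0
  cp <- fd_first(function(tt) h_pop(tt, p), t, ht) + afr

  kappa_t <- -dv_dp / v
  alpha_p <- dv_dt / v
  if (!is.finite(kappa_t) || kappa_t <= 0)
    stop("non-physical state: isothermal compressibility <= 0", call. = FALSE)
  cv <- cp - t * v * alpha_p^2 / kappa_t

  out <- list(t_star = t, p_star = p,
              f_hb = f[["f_hb"]], f_lj = f[["f_lj"]],
              f_0 = f[["f_0"]], f_c = f[["f_c"]],
              g = g, v = v, h = h, s = s, rho = 1 / v,
              kappa_t = kappa_t, alpha_p = alpha_p, cp = cp, cv = cv)
  class(out) <- "eq_props"
  out
}

#' @export
print.eq_props <- function(x, ...) {
  cat(sprintf("equilibrium properties at T* = %g, p* = %g\n", x$t_star, x$p_star))
  cat(sprintf("  populations: HB %.4f  LJ %.4f  0 %.4f  cage %.4f\n",
              x$f_hb, x$f_lj, x$f_0, x$f_c))
  cat(sprintf("  g %.6g  v %.6g  h %.6g  s %.6g\n", x$g, x$v, x$h, x$s))
  cat(sprintf("  rho %.6g  kappa_t %.6g  alpha_p %.6g  cp %.6g  cv %.6g\n",
              x$rho, x$kappa_t, x$alpha_p, x$cp, x$cv))
  invisible(x)
}
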