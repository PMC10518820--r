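# Transport properties from the equilibrium solution: molecules perform a
# random walk whose step size and hop rate depend on the bond state they are
# in; the macroscopic coefficients are population-weighted averages.

canonical_label <- function(label) {
  lab <- tolower(as.character(label))
  lab[lab == "0"] <- "o"
  if (!all(lab %in% c("hb", "lj", "o", "c")))
    stop("unknown bond-state label; use one of \"hb\", \"lj\", \"0\", \"c\"",
         call. = FALSE)
  lab
}

#' Random-walk step size of each bond state
#'
#' HB and cage molecules step by the hydrogen-bond distance `r_hb`, LJ
#' molecules by the contact distance `sigma_lj`, and non-interacting molecules
#' by the mean intermolecular distance of the open state, `sqrt(v_0)`
#' (square root of the area per molecule in two dimensions).
#'
#' @param label Bond-state label(s): `"hb"`, `"lj"`, `"0"` or `"c"`.
#' @param state A [thermo_state()] (accepted for interface symmetry; the step
#'   sizes are state independent).
#' @param params An [mb_params()] object.
#' @return Step size(s) in reduced length units.
#' @examples
#' step_length("hb")  # 1
#' step_length("lj")  # 0.7
#' @export
step_length <- function(label, state = NULL, params = mb_params()) {
  lab <- canonical_label(label)
  lam <- c(hb = params$r_hb, lj = params$sigma_lj,
           o = sqrt(params$v_0), c = params$r_hb)
  unname(lam[lab])
}

#' Mean bond energy of one state
#'
#' Convenience wrapper around [mean_bond_energies()] for a single labelled
#' state: the Boltzmann-averaged interaction energy `<E_i>` (zero for the
#' open state, `-eps_lj` for LJ, the averaged harmonic well for HB, and the
#' HB value minus `eps_c` for the cage).
#'
#' @inheritParams step_length
#' @param state A [thermo_state()].
#' @return Mean bond energy (<= 0) in reduced units.
#' @examples
#' mean_bond_energy("lj", thermo_state(0.2, 0))  # -0.1
#' @export
mean_bond_energy <- function(label, state, params = mb_params()) {
  lab <- canonical_label(label)
  e <- mean_bond_energies(state, params)
  unname(e[lab])
}

#' Hop frequency of each bond state
#'
#' The step frequency is the Boltzmann factor of the state's mean bond
#' enthalpy, `nu_i = c_freq * exp(beta (<E_i> - p* v_i))` (default
#' `freq_form = "enthalpy"`): escaping a state means both breaking its bond
#' and doing pressure-volume work to open a void, so deeper wells and higher
#' pressures both slow the walk. With `freq_form = "energy"` only the bond
#' energy enters, `nu_i = c_freq * exp(beta <E_i>)`, and the rates are
#' pressure independent. At `p* = 0` the two forms coincide and the open
#' state hops at exactly `c_freq`; as `T* -> Inf` every rate tends to
#' `c_freq`.
#'
#' @inheritParams mean_bond_energy
#' @return Hop frequency (> 0) in reduced units.
#' @examples
#' step_frequency("0", thermo_state(0.2, 0))  # c_freq = 1
#' step_frequency("hb", thermo_state(0.2, 0.19))
#' @export
step_frequency <- function(label, state, params = mb_params()) {
  lab <- canonical_label(label)
  state <- as_state(state)
  e <- mean_bond_energies(state, params)[lab]
  arg <- if (params$freq_form == "enthalpy") {
    e - state$p_star * state_volumes(params)[lab]
  } else {
    e
  }
  unname(params$c_freq * exp(state$beta * arg))
}

resolve_populations <- function(eq, state, params) {
  if (is.null(eq)) return(populations(state, params))
  if (inherits(eq, "eq_props"))
    return(c(f_hb = eq$f_hb, f_lj = eq$f_lj, f_0 = eq$f_0, f_c = eq$f_c))
  if (is.numeric(eq) && length(eq) == 4) {
    f <- as.numeric(eq)
    names(f) <- c("f_hb", "f_lj", "f_0", "f_c")
    return(f)
  }
  stop("'eq' must be NULL, an eq_props object, or four populations",
       call. = FALSE)
}

#' Population-weighted diffusion coefficient
#'
#' Each state diffuses as a 2D random walk, `D_i = lambda_i^2 nu_i` (the
#' dimensional random-walk prefactor is absorbed into `c_freq`), and the
#' total coefficient is the population-weighted mixture
#' `D = sum_i f_i D_i`.
#'
#' @inheritParams hb_angular_integral
#' @param eq Optional equilibrium input: an [equilibrium_properties()] object,
#'   a numeric vector of four populations (HB, LJ, 0, c), or `NULL` to compute
#'   the populations from `state`.
#' @return A list with `d_total` and the named per-state vector `d_by_state`.
#' @examples
#' diffusion(thermo_state(0.2, 0.19))$d_total
#' @export
diffusion <- function(state, params = mb_params(), eq = NULL) {
  state <- as_state(state)
  f <- resolve_populations(eq, state, params)
  lab <- c("hb", "lj", "o", "c")
  lam <- step_length(lab, state, params)
  nu <- vapply(lab, function(l) step_frequency(l, state, params), numeric(1))
  d_i <- lam^2 * nu
  names(d_i) <- c("d_hb", "d_lj", "d_0", "d_c")
  list(d_total = sum(f * d_i), d_by_state = d_i)
}

#' Average molecular diameter
#'
#' Molecules in the HB, LJ and open states carry diameter `r_hb`; a molecule
#' bound in a hexagonal cage moves with the cage, of diameter `2 r_hb`. The
#' average is the population-weighted mixture
#' `d = (f_hb + f_lj + f_0) r_hb + 2 f_c r_hb`.
#'
#' @param eq An [equilibrium_properties()] object or a numeric vector of four
#'   populations (HB, LJ, 0, c).
#' @param params An [mb_params()] object.
#' @return The average diameter in reduced length units.
#' @examples
#' average_diameter(c(0.25, 0.25, 0.25, 0.25))  # 1.25
#' @export
average_diameter <- function(eq, params = mb_params()) {
  f <- resolve_populations(eq, NULL, params)
  (f[["f_hb"]] + f[["f_lj"]] + f[["f_0"]]) * params$r_hb +
    f[["f_c"]] * 2 * params$r_hb
}

#' Stokes-Einstein viscosity
#'
#' Inverts the Stokes-Einstein relation: `eta = T* / (c_se * D * d)` for
#' diffusion coefficient `D` and average diameter `d`, so that
#' `eta * D * d * c_se = T*` holds identically.
#'
#' @inheritParams hb_angular_integral
#' @param d_total Diffusion coefficient (> 0), e.g. from [diffusion()].
#' @param d_avg Average molecular diameter (> 0), from [average_diameter()].
#' @return Dynamic viscosity in reduced units.
#' @export
viscosity <- function(state, params = mb_params(), d_total, d_avg) {
  state <- as_state(state)
  if (!is.finite(d_total) || d_total <= 0)
    stop("singular viscosity: diffusion coefficient must be > 0", call. = FALSE)
  if (!is.finite(d_avg) || d_avg <= 0)
    stop("average diameter must be > 0", call. = FALSE)
  state$t_star / (params$c_se * d_total * d_avg)
}

#' Adiabatic speed of sound
#'
#' `c_s = sqrt(cp / (cv * rho * kappa_t))`: the isothermal compressibility is
#' corrected to adiabatic conditions by the heat-capacity ratio, with the
#' molecular mass equal to one in reduced units.
#'
#' @inheritParams hb_angular_integral
#' @param eq An [equilibrium_properties()] object.
#' @return Speed of sound in reduced units.
#' @export
speed_of_sound <- function(state, params = mb_params(), eq) {
  if (!inherits(eq, "eq_props"))
    stop("'eq' must be an equilibrium_properties() object", call. = FALSE)
  if (!is.finite(eq$kappa_t) || eq$kappa_t <= 0 ||
      !is.finite(eq$cv) || eq$cv <= 0)
    stop("non-physical equilibrium input: need kappa_t > 0 and cv > 0",
         call. = FALSE)
  sqrt(eq$cp / (eq$cv * eq$rho * eq$kappa_t))
}

#' Bridgman-style thermal conductivity
#'
#' Two-dimensional analogue of Bridgman's relation: heat hops molecule to
#' molecule at the speed of sound across a spacing `rho^(-1/2)`, giving
#' `kappa = bridgman_coef * rho^bridgman_exp * c_s` with defaults
#' `2 * rho^(1/2) * c_s` (`kB = 1`).
#'
#' @inheritParams speed_of_sound
#' @param c_s Speed of sound, from [speed_of_sound()].
#' @return Thermal conductivity in reduced units.
#' @export
thermal_conductivity <- function(state, params = mb_params(), eq, c_s) {
  if (!inherits(eq, "eq_props"))
    stop("'eq' must be an equilibrium_properties() object", call. = FALSE)
  params$bridgman_coef * eq$rho^params$bridgman_exp * c_s
}

#' Thermal diffusivity
#'
#' `a = kappa / (rho * cp)`: the rate at which temperature perturbations
#' spread (reduced length^2 x frequency).
#'
#' @param kappa_th Thermal conductivity, from [thermal_conductivity()].
#' @param eq An [equilibrium_properties()] object.
#' @return Thermal diffusivity in reduced units.
#' @export
thermal_diffusivity <- function(kappa_th, eq) {
  if (!inherits(eq, "eq_props"))
    stop("'eq' must be an equilibrium_properties() object", call. = FALSE)
  if (!is.finite(eq$cp) || eq$cp <= 0)
    stop("non-physical equilibrium input: need cp > 0", call. = FALSE)
  kappa_th / (eq$rho * eq$cp)
}

#' All transport properties at one state point
#'
#' Bundles the full dynamics map: per-state step sizes, hop rates, mean bond
#' energies and diffusivities, the total diffusion coefficient, the
#' Stokes-Einstein viscosity, average diameter, speed of sound, Bridgman
#' thermal conductivity and thermal diffusivity.
#'
#' @inheritParams hb_angular_integral
#' @param eq An [equilibrium_properties()] object, or `NULL` to compute it.
#' @return An object of class `dyn_props`: a list with `d_total`,
#'   `d_by_state`, `lambda_by_state`, `nu_by_state`, `e_mean_by_state`,
#'   `eta`, `d_avg`, `c_s`, `kappa_th`, `a_th`.
#' @examples
#' dyn <- dynamic_properties(thermo_state(0.2, 0.19))
#' dyn$eta * dyn$d_total * dyn$d_avg * mb_params()$c_se  # equals T* = 0.2
#' @export
dynamic_properties <- function(state, params = mb_params(), eq = NULL) {
  state <- as_state(state)
  if (is.null(eq)) eq <- equilibrium_properties(state, params)
  lab <- c("hb", "lj", "o", "c")
  dif <- diffusion(state, params, eq)
  d_avg <- average_diameter(eq, params)
  eta <- viscosity(state, params, dif$d_total, d_avg)
  c_s <- speed_of_sound(state, params, eq)
  kappa_th <- thermal_conductivity(state, params, eq, c_s)
  a_th <- thermal_diffusivity(kappa_th, eq)
  out <- list(
    t_star = state$t_star, p_star = state$p_star,
    d_total = dif$d_total, d_by_state = dif$d_by_state,
    lambda_by_state = stats::setNames(step_length(lab, state, params), lab),
    nu_by_state = stats::setNames(
      vapply(lab, function(l) step_frequency(l, state, params), numeric(1)), lab),
    e_mean_by_state = mean_bond_energies(state, params),
    eta = eta, d_avg = d_avg, c_s = c_s, kappa_th = kappa_th, a_th = a_th
  )
  class(out) <- "dyn_props"
  out
}

#' @export
print.dyn_props <- function(x, ...) {
  cat(sprintf("transport properties at T* = %g, p* = %g\n", x$t_star, x$p_star))
  cat(sprintf("  D %.6g  eta %.6g  d %.6g\n", x$d_total, x$eta, x$d_avg))
  cat(sprintf("  c_s %.6g  kappa_th %.6g  a_th %.6g\n", x$c_s, x$kappa_th, x$a_th))
  invisible(x)
}
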