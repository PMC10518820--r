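#' Model parameters for the 2D water model
#'
#' Collects every interaction constant, per-state molecular area, and
#' unit-fixing prefactor of the model, all in reduced units (energies in units
#' of the optimal hydrogen-bond strength, lengths in units of the
#' hydrogen-bond separation, Boltzmann constant equal to one). Energies are
#' stored as positive well depths; the energy functions apply the signs.
#'
#' The interaction constants default to the standard parameterisation of the
#' 2D model: `eps_hb = 1`, `r_hb = 1`, `eps_lj = 0.1`, `sigma_lj = 0.7`,
#' `k_s = 10`, `eps_c = 0.03`. The per-state areas are not fixed by those
#' constants and default to `v_hb = 1`, `v_lj = sigma_lj^2 = 0.49`,
#' `v_0 = 1`, `v_c = 1.2`: the LJ contact is the tight state, while the
#' ice-like cage is the open, low-density structure (`v_c > v_hb`), which is
#' what drives the volumetric anomalies.
#'
#' @param eps_hb Optimal hydrogen-bond depth (energy, >= 0).
#' @param r_hb Hydrogen-bond separation (length, > 0).
#' @param eps_lj Lennard-Jones contact depth (energy, >= 0).
#' @param sigma_lj Lennard-Jones contact distance (length, > 0).
#' @param k_s Angular spring constant weakening a hydrogen bond as the arm
#'   rotates away from its neighbour (energy / rad^2, >= 0).
#' @param eps_c Cooperativity bonus per molecule, granted only when six
#'   molecules close a full hexagonal cage (energy, >= 0).
#' @param v_hb,v_lj,v_0,v_c Area per molecule in the HB, LJ, non-interacting
#'   and cage states (all > 0, with `v_c >= v_hb`).
#' @param theta_max Half-width of the hydrogen-bonding orientation window
#'   (rad, in (0, pi/3]). An arm within `theta_max` of the neighbour direction
#'   can bond.
#' @param v_free_frac Fraction of the ideal translational free area
#'   `T*/p*` granted to every molecule on top of its state's core area
#'   (dimensionless, >= 0). This cell-model term leaves the state populations
#'   untouched (it is state independent) but gives the equation of state a
#'   finite compressibility floor; set to 0 for the bare lattice model.
#' @param c_freq Unit-fixing step-frequency prefactor of the random-walk
#'   dynamics (frequency, > 0).
#' @param c_se Dimensionless Stokes-Einstein constant; defaults to `3*pi`
#'   (stick boundary value; 2D hydrodynamics fixes no unique constant).
#' @param freq_form Form of the hop-rate Boltzmann factor: `"enthalpy"`
#'   (default) activates each hop with the mean bond enthalpy
#'   `<E_i> - p* v_i`, so compression slows every state; `"energy"` uses the
#'   mean bond energy `<E_i>` alone.
#' @param bridgman_coef,bridgman_exp Prefactor and density exponent of the 2D
#'   Bridgman conductivity relation `kappa = coef * rho^exp * c_s`; defaults
#'   2 and 1/2 (molecular spacing scales as `rho^(-1/2)` in two dimensions).
#'
#' @return An object of class `mb_params` (a validated named list).
#' @seealso [thermo_state()], [read_params_json()]
#' @examples
#' p <- mb_params()
#' p$eps_hb
#' mb_params(eps_c = 0)  # no cage cooperativity
#' @export
mb_params <- function(eps_hb = 1, r_hb = 1, eps_lj = 0.1, sigma_lj = 0.7,
                      k_s = 10, eps_c = 0.03,
                      v_hb = 1.0, v_lj = sigma_lj^2, v_0 = 1.0, v_c = 1.2,
                      theta_max = pi / 3, v_free_frac = 0.1,
                      c_freq = 1, c_se = 3 * pi,
                      freq_form = c("enthalpy", "energy"),
                      bridgman_coef = 2, bridgman_exp = 0.5) {
  p <- list(
    eps_hb = eps_hb, r_hb = r_hb, eps_lj = eps_lj, sigma_lj = sigma_lj,
    k_s = k_s, eps_c = eps_c,
    v_hb = v_hb, v_lj = v_lj, v_0 = v_0, v_c = v_c,
    theta_max = theta_max, v_free_frac = v_free_frac,
    c_freq = c_freq, c_se = c_se,
    freq_form = match.arg(freq_form),
    bridgman_coef = bridgman_coef, bridgman_exp = bridgman_exp
  )
  class(p) <- "mb_params"
  validate_params(p)
}

#' Validate model parameters
#'
#' Checks the invariants of an [mb_params()] object: energies non-negative,
#' lengths and areas positive, `v_c >= v_hb`, `theta_max` in (0, pi/3].
#'
#' @param params An `mb_params` object (or bare named list with its fields).
#' @return The validated object, invisibly classed as `mb_params`.
#' @export
validate_params <- function(params) {
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  for (f in c("eps_hb", "eps_lj", "k_s", "eps_c", "v_free_frac")) {
    if (!num1(params[[f]]) || params[[f]] < 0)
      stop(sprintf("'%s' must be a single finite number >= 0", f), call. = FALSE)
  }
  for (f in c("r_hb", "sigma_lj", "v_hb", "v_lj", "v_0", "v_c", "c_freq", "c_se")) {
    if (!num1(params[[f]]) || params[[f]] <= 0)
      stop(sprintf("'%s' must be a single finite number > 0", f), call. = FALSE)
  }
  if (params$v_c < params$v_hb)
    stop("'v_c' must be >= 'v_hb': the cage is the open, ice-like state", call. = FALSE)
  if (!num1(params$theta_max) || params$theta_max <= 0 || params$theta_max > pi / 3)
    stop("'theta_max' must lie in (0, pi/3]", call. = FALSE)
  if (!params$freq_form %in% c("enthalpy", "energy"))
    stop("'freq_form' must be \"enthalpy\" or \"energy\"", call. = FALSE)
  if (!num1(params$bridgman_coef) || params$bridgman_coef <= 0 ||
      !num1(params$bridgman_exp))
    stop("invalid Bridgman constants", call. = FALSE)
  class(params) <- "mb_params"
  invisible(params)
}

#' @export
print.mb_params <- function(x, ...) {
  cat("2D water model parameters (reduced units)\n")
  num <- vapply(x, is.numeric, logical(1))
  for (f in names(x)[num])
    cat(sprintf("  %-13s %g\n", f, x[[f]]))
  cat(sprintf("  %-13s %s\n", "freq_form", x$freq_form))
  invisible(x)
}

#' Read model parameters from a JSON configuration file
#'
#' The file is a flat JSON object whose keys are [mb_params()] argument
#' names; keys not present keep their defaults, unknown keys are an error.
#'
#' @param path Path to a JSON file.
#' @return A validated `mb_params` object.
#' @examples
#' cfg <- tempfile(fileext = ".json")
#' writeLines('{"eps_c": 0.05, "v_c": 1.3}', cfg)
#' read_params_json(cfg)$eps_c
#' @export
read_params_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(x)) x <- as.list(x)
  known <- names(formals(mb_params))
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop("unknown parameter key(s) in config: ", paste(bad, collapse = ", "),
         call. = FALSE)
  do.call(mb_params, x)
}

#' A thermodynamic state point in reduced units
#'
#' @param t_star Reduced temperature `T* = kB T / |eps_hb|` (> 0).
#' @param p_star Reduced pressure `p* = p r_hb^2 / |eps_hb|` (>= 0).
#' @return An object of class `thermo_state` with fields `t_star`, `p_star`
#'   and the inverse reduced temperature `beta = 1/T*`.
#' @examples
#' s <- thermo_state(0.2, 0.19)
#' s$beta * s$t_star  # exactly 1
#' @export
thermo_state <- function(t_star, p_star) {
  stopifnot(is.numeric(t_star), length(t_star) == 1L, is.finite(t_star),
            is.numeric(p_star), length(p_star) == 1L, is.finite(p_star))
  if (t_star <= 0) stop("'t_star' must be > 0", call. = FALSE)
  if (p_star < 0) stop("'p_star' must be >= 0", call. = FALSE)
  structure(list(t_star = t_star, p_star = p_star, beta = 1 / t_star),
            class = "thermo_state")
}

#' @export
print.thermo_state <- function(x, ...) {
  cat(sprintf("thermo_state: T* = %g, p* = %g (beta = %g)\n",
              x$t_star, x$p_star, x$beta))
  invisible(x)
}

as_state <- function(state) {
  if (inherits(state, "thermo_state")) return(state)
  if (is.numeric(state) && length(state) == 2L)
    return(thermo_state(state[[1]], state[[2]]))
  stop("'state' must be a thermo_state or a numeric (t_star, p_star) pair",
       call. = FALSE)
}
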