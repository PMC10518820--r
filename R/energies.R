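#' Hydrogen-bond pair energy
#'
#' Energy of a test molecule whose bonding arm points at angle `theta` to its
#' clockwise neighbour, within the bonding window: a harmonic angular well on
#' top of the Lennard-Jones contact,
#' `E_HB(theta) = -(eps_hb + eps_lj) + k_s * theta^2`.
#' The minimum sits at `theta = 0` with depth `-(eps_hb + eps_lj)`.
#'
#' @param theta Arm orientation angle(s) in radians; must satisfy
#'   `|theta| <= theta_max`.
#' @param params An [mb_params()] object.
#' @return Energy value(s) in reduced units.
#' @examples
#' energy_hb(0, mb_params())     # -1.1
#' energy_hb(0.3, mb_params())   # -1.1 + 10 * 0.09 = -0.2
#' @export
energy_hb <- function(theta, params = mb_params()) {
  if (any(abs(theta) > params$theta_max))
    stop("'theta' outside the hydrogen-bonding window [-theta_max, theta_max]",
         call. = FALSE)
  -(params$eps_hb + params$eps_lj) + params$k_s * theta^2
}

#' Lennard-Jones contact energy
#'
#' Orientation-independent van der Waals contact: a constant `-eps_lj`.
#'
#' @inheritParams energy_hb
#' @return The contact energy, `-eps_lj`.
#' @examples
#' energy_lj(mb_params())  # -0.1
#' @export
energy_lj <- function(params = mb_params()) {
  -params$eps_lj
}

#' Non-interacting state energy
#'
#' A molecule with no interaction with its clockwise neighbour: exactly zero,
#' independent of parameters and orientation.
#'
#' @return `0`.
#' @examples
#' energy_open()  # 0
#' @export
energy_open <- function() {
  0
}

#' Angle at which a strained hydrogen bond matches the LJ contact
#'
#' The harmonic well crosses the pure contact energy `-eps_lj` where
#' `k_s * theta^2 = eps_hb`, i.e. at `sqrt(eps_hb / k_s)`. Beyond that angle a
#' bonded orientation is energetically worse than an unbonded contact.
#'
#' @inheritParams energy_hb
#' @return The crossover angle in radians (`Inf` if `k_s = 0`).
#' @export
hb_crossover_angle <- function(params = mb_params()) {
  if (params$k_s == 0) return(Inf)
  sqrt(params$eps_hb / params$k_s)
}
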