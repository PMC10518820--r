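# Brute-force validators, independent of the analytic formulas: composite
# trapezoid quadrature for the angular integrals, and direct summation of
# Boltzmann weights over discretized hexagon configurations for the
# populations.

#' Composite trapezoid quadrature oracle
#'
#' Dense fixed-grid trapezoid rule used to validate the adaptive quadrature
#' of the angular integrals. Deliberately naive: no adaptivity, no
#' extrapolation.
#'
#' @param f Integrand, a vectorized function of one numeric argument.
#' @param a,b Integration limits.
#' @param n Number of nodes (>= 1000).
#' @return The composite trapezoid estimate of `integral(f, a, b)`.
#' @examples
#' quadrature_oracle(function(x) x^2, 0, 1, 1e5)  # ~1/3
#' @export
quadrature_oracle <- function(f, a, b, n = 1e5) {
  if (n < 1000) stop("'n' must be at least 1000", call. = FALSE)
  x <- seq(a, b, length.out = n)
  y <- f(x)
  h <- (b - a) / (n - 1)
  h * (sum(y) - (y[1] + y[n]) / 2)
}

hexagon_bond_weights <- function(state, params, n_theta) {
  state <- as_state(state)
  b <- state$beta
  p <- state$p_star
  tm <- params$theta_max
  theta <- seq(-tm, tm, length.out = n_theta)
  tw <- rep(1, n_theta); tw[c(1, n_theta)] <- 0.5
  tw <- tw * (2 * tm / (n_theta - 1)) / (2 * tm)  # normalized trapezoid weights
  # log weights per discretized bond state; scaled by their max for overflow
  # safety (a common per-bond factor cancels in the populations)
  lw_hb <- b * (params$eps_hb + params$eps_lj) - b * params$k_s * theta^2 -
    b * p * params$v_hb + log(tw)
  lw_c <- lw_hb + b * p * (params$v_hb - params$v_c)
  lw_lj <- b * params$eps_lj - b * p * params$v_lj
  lw_0 <- -b * p * params$v_0
  m <- max(lw_hb, lw_lj, lw_0)
  list(w_hb = exp(lw_hb - m), w_c = exp(lw_c - m),
       w_lj = exp(lw_lj - m), w_0 = exp(lw_0 - m),
       delta6 = exp(6 * b * params$eps_c))
}

#' Populations by enumeration of discretized hexagon configurations
#'
#' Discretizes the hydrogen-bond orientation onto `n_theta` trapezoid nodes
#' and sums Boltzmann weights over hexagon bond configurations directly,
#' with the all-bonded ring replaced by the cooperative cage channel
#' (cage volume and `delta^6`). Converges to the analytic [populations()] as
#' `n_theta` grows.
#'
#' Two routes are provided. The default factorizes the six independent bonds
#' into per-bond sums (exact for this partition function, fast). With
#' `full = TRUE` every one of the `(n_theta + 2)^6` configurations is visited
#' explicitly and its bond states are counted -- a slow cross-check that is
#' refused above `n_theta = 9`.
#'
#' @inheritParams hb_angular_integral
#' @param n_theta Number of angular nodes per hydrogen bond: odd (so that
#'   `theta = 0` is a node), between 3 and 21.
#' @param full If `TRUE`, enumerate all configurations explicitly.
#' @return Named numeric vector `c(f_hb, f_lj, f_0, f_c)` summing to one.
#' @examples
#' enumerate_populations(thermo_state(0.2, 0.19), n_theta = 9)
#' @export
enumerate_populations <- function(state, params = mb_params(), n_theta = 15,
                                  full = FALSE) {
  if (n_theta < 3 || n_theta > 21 || n_theta %% 2 == 0)
    stop("'n_theta' must be odd and between 3 and 21", call. = FALSE)
  bw <- hexagon_bond_weights(state, params, n_theta)

  if (!full) {
    q_hb <- sum(bw$w_hb)
    q_c <- sum(bw$w_c)
    z <- q_hb + bw$w_lj + bw$w_0
    psi <- z^6 - q_hb^6 + bw$delta6 * q_c^6
    return(c(f_hb = (q_hb * z^5 - q_hb^6) / psi,
             f_lj = bw$w_lj * z^5 / psi,
             f_0 = bw$w_0 * z^5 / psi,
             f_c = bw$delta6 * q_c^6 / psi))
  }

  if (n_theta > 9)
    stop("full enumeration is refused above n_theta = 9 ((n_theta + 2)^6 configurations)",
         call. = FALSE)
  m <- n_theta + 2L                       # labels: 1..n_theta HB, then LJ, 0
  w <- c(bw$w_hb, bw$w_lj, bw$w_0)
  cage_ratio <- bw$w_c / bw$w_hb          # constant exp(-beta p (v_c - v_hb))
  r6d6 <- cage_ratio[1]^6 * bw$delta6
  total <- 0
  count <- c(hb = 0, lj = 0, o = 0, c = 0)
  n_conf <- m^6
  chunk <- 2e5
  for (start in seq(0, n_conf - 1, by = chunk)) {
    idx <- start:min(start + chunk - 1, n_conf - 1)
    digit <- matrix(0L, length(idx), 6)
    rest <- idx
    for (k in 1:6) {
      digit[, k] <- rest %% m
      rest <- rest %/% m
    }
    wt <- w[digit[, 1] + 1L]
    for (k in 2:6) wt <- wt * w[digit[, k] + 1L]
    is_hb <- digit < n_theta
    n_hb <- rowSums(is_hb)
    n_lj <- rowSums(digit == n_theta)
    n_0 <- 6 - n_hb - n_lj
    allhb <- n_hb == 6L
    wt[allhb] <- wt[allhb] * r6d6         # promote all-bonded ring to cage
    total <- total + sum(wt)
    count["c"] <- count["c"] + 6 * sum(wt[allhb])
    count["hb"] <- count["hb"] + sum(wt[!allhb] * n_hb[!allhb])
    count["lj"] <- count["lj"] + sum(wt * n_lj)
    count["o"] <- count["o"] + sum(wt * n_0)
  }
  f <- count / (6 * total)
  c(f_hb = f[["hb"]], f_lj = f[["lj"]], f_0 = f[["o"]], f_c = f[["c"]])
}

#' Compare analytic populations against the enumeration oracle
#'
#' Evaluates [populations()] and [enumerate_populations()] at a set of state
#' points and tabulates the maximum absolute population error at each. State
#' points default to pseudo-random draws over the liquid window
#' `T* in [0.13, 0.40]`, `p* in [0.01, 1]` with a fixed documented seed
#' (1234) so that the table is reproducible.
#'
#' @param states Optional list of [thermo_state()] objects (or two-column
#'   matrix of `(t_star, p_star)` rows).
#' @param params An [mb_params()] object.
#' @param n_theta Angular resolution passed to [enumerate_populations()].
#' @param tol Pass threshold on the maximum absolute population error.
#' @param n_points Number of random state points when `states` is `NULL`.
#' @param seed Seed for the random state points.
#' @return A data frame with columns `t_star`, `p_star`, `max_abs_error`,
#'   `pass`.
#' @examples
#' validate_model(n_points = 3, n_theta = 9)
#' @export
validate_model <- function(states = NULL, params = mb_params(), n_theta = 15,
                           tol = 1e-3, n_points = 12, seed = 1234) {
  if (is.null(states)) {
    states <- withr_seed(seed, function() {
      t <- stats::runif(n_points, 0.13, 0.40)
      p <- stats::runif(n_points, 0.01, 1)
      lapply(seq_len(n_points), function(i) thermo_state(t[i], p[i]))
    })
  } else if (is.matrix(states)) {
    states <- lapply(seq_len(nrow(states)),
                     function(i) thermo_state(states[i, 1], states[i, 2]))
  }
  rows <- lapply(states, function(st) {
    st <- as_state(st)
    err <- max(abs(populations(st, params) -
                     enumerate_populations(st, params, n_theta)))
    data.frame(t_star = st$t_star, p_star = st$p_star,
               max_abs_error = err, pass = err < tol)
  })
  do.call(rbind, rows)
}

# run fn with a temporary RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  fn()
}
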