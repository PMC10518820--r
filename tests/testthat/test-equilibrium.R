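test_that("orientational factor matches brute-force quadrature and its limits", {
  st <- thermo_state(0.2, 0)
  got <- hb_angular_integral(st, defaults)
  tm <- defaults$theta_max
  oracle <- quadrature_oracle(function(th) exp(-st$beta * defaults$k_s * th^2),
                              -tm, tm, n = 1e5) / (2 * tm)
  expect_lt(abs(got - oracle), 1e-8)
  expect_gt(got, 0); expect_lt(got, 1)
  # k_s = 0: integrand is 1 everywhere
  expect_equal(hb_angular_integral(st, mb_params(k_s = 0)), 1)
  # Gaussian collapse at large beta: value tends to 0
  expect_lt(hb_angular_integral(thermo_state(0.005, 0), defaults), 0.02)
  expect_gt(hb_angular_integral(thermo_state(0.005, 0), defaults), 0)
})

test_that("statistical weights obey their structural identities", {
  w <- state_weights(ref_state, mb_params(eps_c = 0))
  expect_equal(w$delta_coop, 1)
  # v_c = v_hb makes the cage weight equal the HB weight bitwise in log space
  w2 <- state_weights(ref_state, mb_params(v_c = 1, v_hb = 1))
  expect_identical(w2$log_delta_c, w2$log_delta_hb)
  # every Boltzmann exponent zero: all four weights are 1
  w3 <- state_weights(thermo_state(0.3, 0), neutral_params)
  expect_equal(c(w3$delta_hb, w3$delta_lj, w3$delta_0, w3$delta_c),
               rep(1, 4))
  expect_true(all(c(w$delta_hb, w$delta_lj, w$delta_0, w$delta_c) > 0))
})

test_that("hexagon partition function reduces to (3 Delta)^6 for equal weights", {
  # all weights 1 and neutral cooperativity: Psi = 3^6 - 1 + 1 = 729
  ln_psi <- hexagon_partition(thermo_state(0.3, 0), neutral_params)
  expect_equal(ln_psi, log(729), tolerance = 1e-12)
})

test_that("log Psi rises with attraction and falls with pressure", {
  states <- random_states(10)
  for (st in states) {
    base <- hexagon_partition(st, defaults)
    expect_gt(hexagon_partition(st, mb_params(eps_hb = 1.01)), base)
    expect_gt(hexagon_partition(st, mb_params(eps_lj = 0.11)), base)
    expect_gt(hexagon_partition(st, mb_params(eps_c = 0.04)), base)
    expect_lt(hexagon_partition(thermo_state(st$t_star, st$p_star + 0.01),
                                defaults), base)
  }
})

test_that("populations sum to one and match the uniform closed form", {
  for (st in random_states(12)) {
    f <- populations(st, defaults)
    expect_true(all(f >= 0 & f <= 1))
    expect_lt(abs(sum(f) - 1), 1e-12)
  }
  # equal weights: (242, 243, 243, 1)/729 from the hexagon combinatorics
  f <- populations(thermo_state(0.3, 0), neutral_params)
  expect_equal(f, uniform_populations, tolerance = 1e-12)
  # infinite-temperature limit at p* = 0 approaches the same values
  f_hot <- populations(thermo_state(1e7, 0), defaults)
  expect_equal(f_hot, uniform_populations, tolerance = 1e-5)
})

test_that("population limits follow the hexagon structure", {
  # HB-dominant with the cage channel intact: the all-bonded ring is the cage
  p_cage <- mb_params(eps_hb = 5, eps_c = 0, v_c = 1, v_hb = 1)
  f <- populations(thermo_state(0.05, 0), p_cage)
  expect_gt(f[["f_c"]], 0.999)
  # HB-dominant with the cage channel crushed by its volume cost: hexagons
  # must contain a non-HB bond, so f_hb tends to 5/6
  p_nocage <- mb_params(eps_hb = 2, eps_c = 0, v_c = 60)
  f2 <- populations(thermo_state(0.1, 1), p_nocage)
  expect_equal(f2[["f_c"]], 0)
  expect_equal(f2[["f_hb"]], 5 / 6, tolerance = 1e-5)
})

test_that("Gibbs energy follows -(T/6) log Psi and deepens with attraction", {
  p0 <- mb_params(v_free_frac = 0)
  st <- thermo_state(0.22, 0.3)
  expect_equal(gibbs_per_molecule(st, p0),
               -(st$t_star / 6) * hexagon_partition(st, p0))
  g <- gibbs_per_molecule(st, defaults)
  expect_lt(gibbs_per_molecule(st, mb_params(eps_hb = 1.05)), g)
  expect_lt(gibbs_per_molecule(st, mb_params(eps_lj = 0.15)), g)
  expect_error(gibbs_per_molecule(thermo_state(0.2, 0), defaults), "p\\* > 0")
})

test_that("analytic first derivatives of log Psi match finite differences", {
  for (st in random_states(6, seed = 77)) {
    d <- mbwater:::ln_psi_derivatives(st, defaults)
    num_dp <- mbwater:::fd_first(
      function(p) hexagon_partition(thermo_state(st$t_star, p), defaults),
      st$p_star)
    num_db <- mbwater:::fd_first(
      function(b) hexagon_partition(thermo_state(1 / b, st$p_star), defaults),
      st$beta)
    expect_lt(abs(d$dp - num_dp) / abs(d$dp), 1e-6)
    expect_lt(abs(d$dbeta - num_db) / max(abs(d$dbeta), 1), 1e-6)
  }
})

test_that("equilibrium thermodynamics is internally consistent", {
  for (st in random_states(5, seed = 42)) {
    eq <- equilibrium_properties(st, defaults)
    # volume and entropy from numeric differentiation of the full Gibbs energy
    num_v <- mbwater:::fd_first(
      function(p) gibbs_per_molecule(thermo_state(st$t_star, p), defaults),
      st$p_star)
    num_s <- -mbwater:::fd_first(
      function(t) gibbs_per_molecule(thermo_state(t, st$p_star), defaults),
      st$t_star)
    expect_lt(abs(eq$v - num_v) / abs(eq$v), 1e-6)
    expect_lt(abs(eq$s - num_s) / max(abs(eq$s), 1), 1e-6)
    # identities
    expect_lt(abs(eq$g - (eq$h - st$t_star * eq$s)), 1e-8)
    expect_gte(eq$cp, eq$cv)
    expect_gt(eq$kappa_t, 0)
    expect_gt(eq$v, 0)
    expect_equal(eq$rho, 1 / eq$v)
    # cp - cv equals T v alpha^2 / kappa
    expect_equal(eq$cp - eq$cv,
                 st$t_star * eq$v * eq$alpha_p^2 / eq$kappa_t,
                 tolerance = 1e-10)
  }
})

test_that("heat capacity agrees with the curvature of the Gibbs energy", {
  st <- thermo_state(0.22, 0.3)
  eq <- equilibrium_properties(st, defaults)
  # cp = -T d2g/dT2, via second differences of g itself (independent route)
  h <- 1e-3 * st$t_star
  g <- function(t) gibbs_per_molecule(thermo_state(t, st$p_star), defaults)
  d2g <- (-g(st$t_star - 2 * h) + 16 * g(st$t_star - h) - 30 * g(st$t_star) +
            16 * g(st$t_star + h) - g(st$t_star + 2 * h)) / (12 * h^2)
  expect_equal(eq$cp, -st$t_star * d2g, tolerance = 1e-5)
})
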