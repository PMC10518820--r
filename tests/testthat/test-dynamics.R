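test_that("step sizes follow the bond geometry", {
  expect_equal(step_length("hb", params = defaults), 1)
  expect_equal(step_length("c", params = defaults), 1)
  expect_equal(step_length("lj", params = defaults), 0.7)
  expect_equal(step_length("0", params = defaults), sqrt(defaults$v_0))
  expect_equal(step_length(c("hb", "lj", "0", "c"), params = defaults),
               c(1, 0.7, 1, 1))
  expect_error(step_length("vdw"), "label")
})

test_that("mean bond energies match the quadrature oracle and their limits", {
  st <- thermo_state(0.2, 0)
  expect_equal(mean_bond_energy("lj", st, defaults), -0.1)
  expect_equal(mean_bond_energy("0", st, defaults), 0)
  e_hb <- mean_bond_energy("hb", st, defaults)
  tm <- defaults$theta_max
  num <- quadrature_oracle(function(th) energy_hb(th, defaults) *
                             exp(-st$beta * energy_hb(th, defaults)),
                           -tm, tm, n = 1e5)
  den <- quadrature_oracle(function(th) exp(-st$beta * energy_hb(th, defaults)),
                           -tm, tm, n = 1e5)
  expect_lt(abs(e_hb - num / den), 1e-8)
  # bounds: deeper than nothing, shallower than the window edge
  expect_gt(e_hb, -1.1)
  expect_lt(e_hb, -1.1 + defaults$k_s * tm^2)
  # T -> 0: the average collapses onto the well bottom
  expect_equal(mean_bond_energy("hb", thermo_state(0.002, 0), defaults), -1.1,
               tolerance = 1e-2)
  # cage state carries the cooperativity bonus
  expect_equal(mean_bond_energy("c", st, defaults), e_hb - defaults$eps_c)
  expect_true(all(mean_bond_energies(st, defaults) <= 0))
})

test_that("hop frequencies order by binding strength and hit their limits", {
  # open state hops at exactly c_freq when there is no pressure work
  expect_equal(step_frequency("0", thermo_state(0.2, 0), defaults), 1)
  st <- ref_state
  nu_hb <- step_frequency("hb", st, defaults)
  nu_lj <- step_frequency("lj", st, defaults)
  nu_0 <- step_frequency("0", st, defaults)
  expect_lt(nu_hb, nu_lj)
  expect_lt(nu_lj, nu_0)
  expect_true(all(c(nu_hb, nu_lj, nu_0) > 0))
  # infinite temperature: every rate tends to c_freq
  hot <- thermo_state(1e8, 0.19)
  for (lab in c("hb", "lj", "0", "c"))
    expect_equal(step_frequency(lab, hot, defaults), 1, tolerance = 1e-6)
  # compression slows the walk under the enthalpy form but not the energy form
  stp <- thermo_state(0.2, 0.8)
  expect_lt(step_frequency("0", stp, defaults),
            step_frequency("0", st, defaults))
  p_en <- mb_params(freq_form = "energy")
  expect_equal(step_frequency("0", stp, p_en), 1)
})

test_that("diffusion is the exact population-weighted mixture", {
  for (st in random_states(6, seed = 9)) {
    dif <- diffusion(st, defaults)
    f <- populations(st, defaults)
    expect_identical(dif$d_total, sum(f * dif$d_by_state))
    expect_true(all(dif$d_by_state > 0))
  }
  # frozen open-state system at p* = 0: D = v_0 * c_freq
  st0 <- thermo_state(0.2, 0)
  dif <- diffusion(st0, defaults, eq = c(0, 0, 1, 0))
  expect_equal(dif$d_total, defaults$v_0 * defaults$c_freq)
})

test_that("a frozen single-state walk is Arrhenius with the bond energy as slope", {
  # LJ state at p* = 0: ln D = const + <E_lj> * (1/T*), exactly
  betas <- seq(3, 8, length.out = 6)
  lnD <- sapply(betas, function(b) {
    log(diffusion(thermo_state(1 / b, 0), defaults, eq = c(0, 1, 0, 0))$d_total)
  })
  slope <- coef(lm(lnD ~ betas))[["betas"]]
  expect_equal(slope, -defaults$eps_lj, tolerance = 1e-10)
  # at pressure the slope becomes the activation enthalpy <E_lj> - p* v_lj
  lnDp <- sapply(betas, function(b) {
    log(diffusion(thermo_state(1 / b, 0.3), defaults, eq = c(0, 1, 0, 0))$d_total)
  })
  slope_p <- coef(lm(lnDp ~ betas))[["betas"]]
  expect_equal(slope_p, -defaults$eps_lj - 0.3 * defaults$v_lj,
               tolerance = 1e-10)
})

test_that("average diameter mixes molecule and cage sizes linearly", {
  expect_equal(average_diameter(c(0, 0, 0, 1), defaults), 2)
  expect_equal(average_diameter(c(0.5, 0.3, 0.2, 0), defaults), 1)
  expect_equal(average_diameter(c(0.25, 0.25, 0.25, 0.25), defaults), 1.25)
})

test_that("viscosity inverts the Stokes-Einstein relation", {
  for (st in random_states(6, seed = 5)) {
    dif <- diffusion(st, defaults)
    d_avg <- average_diameter(populations(st, defaults), defaults)
    eta <- viscosity(st, defaults, dif$d_total, d_avg)
    expect_lt(abs(eta * dif$d_total * d_avg * defaults$c_se - st$t_star), 1e-10)
  }
  # doubling c_freq doubles D and therefore halves eta
  p2 <- mb_params(c_freq = 2)
  d1 <- dynamic_properties(ref_state, defaults)
  d2 <- dynamic_properties(ref_state, p2)
  expect_equal(d2$eta, d1$eta / 2, tolerance = 1e-12)
  expect_error(viscosity(ref_state, defaults, 0, 1), "singular")
})

test_that("sound speed is an equilibrium quantity with the gamma = 1 limit", {
  eq <- equilibrium_properties(ref_state, defaults)
  cs <- speed_of_sound(ref_state, defaults, eq)
  expect_true(is.finite(cs) && cs > 0)
  # gamma = 1 limit: force cp = cv in a copy of the equilibrium solution
  eq1 <- eq
  eq1$cp <- eq1$cv
  expect_equal(speed_of_sound(ref_state, defaults, eq1),
               sqrt(1 / (eq$rho * eq$kappa_t)))
  # invariant under the kinetic prefactor (c_freq is dynamics only)
  eqf <- equilibrium_properties(ref_state, mb_params(c_freq = 7))
  expect_equal(speed_of_sound(ref_state, defaults, eqf), cs)
})

test_that("conductivity and thermal diffusivity follow the Bridgman chain", {
  eq <- equilibrium_properties(ref_state, defaults)
  cs <- speed_of_sound(ref_state, defaults, eq)
  k <- thermal_conductivity(ref_state, defaults, eq, cs)
  expect_equal(k, 2 * sqrt(eq$rho) * cs)
  expect_equal(thermal_conductivity(ref_state, defaults, eq, 2 * cs), 2 * k)
  expect_equal(thermal_diffusivity(0, eq), 0)
  expect_equal(thermal_diffusivity(k, eq), k / (eq$rho * eq$cp))
})

test_that("the bundled dynamics object is self-consistent", {
  dyn <- dynamic_properties(ref_state, defaults)
  f <- populations(ref_state, defaults)
  expect_equal(dyn$d_total, sum(f * dyn$d_by_state))
  expect_equal(unname(dyn$lambda_by_state), c(1, 0.7, 1, 1))
  expect_true(all(dyn$nu_by_state > 0))
  expect_true(all(dyn$e_mean_by_state <= 0))
  expect_lt(abs(dyn$eta * dyn$d_total * dyn$d_avg * defaults$c_se -
                  ref_state$t_star), 1e-10)
  expect_gt(dyn$a_th, 0)
})
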