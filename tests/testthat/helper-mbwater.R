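# shared fixtures: default parameterisation and a few reference state points
defaults <- mb_params()

ref_state <- thermo_state(0.2, 0.19)

# parameter set in which every Boltzmann exponent vanishes: all weights are 1
neutral_params <- mb_params(eps_hb = 0, eps_lj = 0, k_s = 0, eps_c = 0,
                            v_free_frac = 0)

# fixed pseudo-random liquid-window state points, shared across tests
random_states <- function(n, seed = 1234) {
  set.seed(seed)
  t <- runif(n, 0.13, 0.40)
  p <- runif(n, 0.01, 1)
  lapply(seq_len(n), function(i) thermo_state(t[i], p[i]))
}

# closed-form uniform-weight populations: (242, 243, 243, 1) / 729
uniform_populations <- c(f_hb = 242, f_lj = 243, f_0 = 243, f_c = 1) / 729
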