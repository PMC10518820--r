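# Finite-difference machinery for the thermodynamic derivatives.
# Five-point central first-derivative stencil (fourth order) plus one level
# of Richardson extrapolation; the Gibbs energy is smooth and cheap, so this
# keeps second-derivative quantities (cp, cv, kappa_t) well below 1e-5 noise.

# relative step 1e-4, shrunk near the domain boundary x = 0 so that x - 2h
# stays positive for strictly positive variables (T*, p*)
fd_step <- function(x, rel = 1e-4) {
  h <- rel * max(1, abs(x))
  if (x > 0) h <- min(h, x / 8)
  h
}

fd_stencil5 <- function(f, x, h) {
  (f(x - 2 * h) - 8 * f(x - h) + 8 * f(x + h) - f(x + 2 * h)) / (12 * h)
}

# Richardson-extrapolated first derivative: the five-point stencil is O(h^4),
# so (16 D(h/2) - D(h)) / 15 cancels the leading error term.
fd_first <- function(f, x, h = fd_step(x)) {
  d1 <- fd_stencil5(f, x, h)
  d2 <- fd_stencil5(f, x, h / 2)
  (16 * d2 - d1) / 15
}
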