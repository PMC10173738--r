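# Independent oracles used to freeze expected values.

# Gamma density via its unnormalized kernel and a numerical normalizing
# constant (independent of dgamma / lgamma).
oracle_gamma_pdf <- function(t, shape, scale) {
  kern <- function(u) u^(shape - 1) * exp(-u / scale)
  z <- integrate(kern, 0, 50 * shape * scale, rel.tol = 1e-10)$value
  kern(t) / z
}

# Survival / density ratio by quadrature of the kernel.
oracle_inverse_hazard <- function(age, shape, scale) {
  kern <- function(u) u^(shape - 1) * exp(-u / scale)
  surv <- integrate(kern, age, 50 * shape * scale, rel.tol = 1e-10)$value
  surv / kern(age)
}

# Minimal mirror-symmetric two-filament initial state: axial filaments
# anchored at psi = 0 (right) and psi = pi (left), nucleus at the center.
mirror_init <- function(config, length0 = 0, tau = 80) {
  mts <- data.frame(
    psi = c(0, pi), theta = c(0, 0), length = c(length0, length0),
    phase = c(0L, 0L), drawn_tau = c(tau, tau), cat_clock = c(0, 0),
    buckling_ref = c(NA_real_, NA_real_), side = c(1L, -1L),
    anchor = c(1L, 2L), pair = c(-1L, 0L))
  list(nucleus = nucleus_state(c(0, 0), 0), mts = mts)
}

wt_config <- function(...) sim_config(...)
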