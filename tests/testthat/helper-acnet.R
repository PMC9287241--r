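# Shared fixtures; heavier objects are built once per test run and cached.
.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, expr, envir = .cache)
  get(key, envir = .cache)
}

default_params <- function() cached("params", ac_params())
default_net <- function() cached("net", build_network(default_params()))

default_spectrum <- function() {
  cached("spectrum",
         spectral_decomposition(coefficient_matrix(default_net())))
}

jump_state <- function(params = default_params()) {
  u0 <- rep(0, 5)
  u0[1] <- params$a / params$tau_m
  u0
}

# adaptation run at a given SOI, converged to the adapted state
adapted_run <- function(soi, n = 111L, tol = 1e-6) {
  cached(paste0("adapt_", soi, "_", n, "_", tol),
         suppressWarnings(run_stimulus_train(
           default_net(), default_params(), stimulus_train(soi, n),
           tol = tol, keep_spectra = FALSE)))
}

# a single decoupled column with the default local weights: off-diagonal
# excitatory couplings removed
decoupled_net <- function() {
  net <- build_network(default_params())
  net$W_ee[upper.tri(net$W_ee) | lower.tri(net$W_ee)] <- 0
  net
}

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(max(abs(object - expected)) / max(abs(expected)), tol)
}
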