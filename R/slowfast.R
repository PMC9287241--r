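#' Fast transmitter-release drop-off over one inter-stimulus interval
#'
#' Closed-form component-wise update of the synaptic efficacy during the
#' stimulus-evoked activity: integrating the release term of the depression
#' equation with the normal-mode solution of `u(t)` gives
#'
#' \deqn{\mathcal F_s(q_s) = q_s \prod_{n=1}^{2N} \exp\!\Big(
#'   -\frac{\alpha\, c_{n,s}\,(e^{\lambda_{n,s}\Delta} - 1)}
#'        {\tau_o\, \lambda_{n,s}}\, x_{n,s}\Big)},
#'
#' with `Delta` the interval length and `x_n` the excitatory part of the
#' n-th right eigenvector.  The product over conjugate pairs is real up to a
#' numerical residual, which is checked and discarded.  For `|lambda|`
#' numerically zero the limit `(e^{lambda Delta} - 1)/lambda -> Delta` is
#' used.  A linear firing rate (`alpha x`) is assumed; the gain `alpha` is
#' carried explicitly in the exponent.
#'
#' @param q efficacy vector at the stimulus (length N).
#' @param dec `ac_spectrum` of the interval's coefficient matrix.
#' @param coeffs `ac_coefs` of the interval's initial (jump) state.
#' @param delta interval length `t_{s+1} - t_s` (s).
#' @param params an `ac_params`.
#' @return Efficacy vector after transmitter release (length N).
#' @export
fast_dropoff <- function(q, dec, coeffs, delta, params) {
  stopifnot(inherits(dec, "ac_spectrum"), delta >= 0)
  lam <- dec$values
  phi <- ifelse(abs(lam) * delta < 1e-12, delta, (exp(lam * delta) - 1) / lam)
  N <- dec$N
  X <- dec$right[seq_len(N), , drop = FALSE]       # u-parts of the modes
  integral <- as.vector(X %*% (as.vector(unclass(coeffs)) * phi))
  scale <- max(abs(integral), 1e-300)
  if (max(abs(Im(integral))) > 1e-9 * scale)
    warning("imaginary residual in release integral: ",
            format(max(abs(Im(integral))) / scale, digits = 3))
  q * exp(-params$alpha * Re(integral) / params$tau_o)
}

#' Slow vesicle replenishment between stimuli
#'
#' Exponential recovery of the efficacy towards 1 over the inter-stimulus
#' interval: `q_{s+1} = 1 - (1 - F) exp(-Delta / tau_rec)`.  Subcortical
#' (non-adapting) entries are forced back to 1.
#'
#' @param q_after_drop efficacy vector after [fast_dropoff()].
#' @param delta interval length (s), >= 0.
#' @param params an `ac_params`.
#' @param adapting logical mask of adapting areas; non-adapting entries are
#'   set to 1 (default: all adapt).
#' @return Recovered efficacy vector.
#' @export
slow_recovery <- function(q_after_drop, delta, params,
                          adapting = rep(TRUE, length(q_after_drop))) {
  if (delta < 0) stop("interval length must be non-negative", call. = FALSE)
  stopifnot(all(q_after_drop >= 0 & q_after_drop <= 1))
  q1 <- 1 - (1 - q_after_drop) * exp(-delta / params$tau_rec)
  q1[!adapting] <- 1
  q1
}

#' Drive the network through a periodic stimulus train (slow-fast scheme)
#'
#' Iterates the slow-fast approximation over the train: at each onset the
#' state is reset to the stimulus-induced jump (`a / tau_m` on the IC
#' excitatory variable; the state is assumed to have decayed to zero between
#' stimuli), the coefficient matrix `M_s = M(Q_s)` is re-assembled and
#' decomposed into normal modes, the mode coefficients are computed, and the
#' efficacy is updated by the fast drop-off followed by slow recovery.  The
#' sequence `q_s` is recorded together with the per-interval spectra and
#' coefficients.  Iteration stops early once `max |q_{s+1} - q_s| < tol`
#' (the adapted state has converged; later stimuli would repeat it).
#'
#' @param net an `ac_network`.
#' @param params an `ac_params`.
#' @param train an `ac_train`; SOIs below 0.5 s trigger a warning because the
#'   between-stimulus decay assumption degrades there.
#' @param tol early-stop tolerance on the efficacy update.
#' @param keep_spectra store every interval's spectrum/coefficients
#'   (default); if `FALSE` only the first and last are retained (elements for
#'   intermediate stimuli are `NULL`).
#' @return An `ac_adaptation`: list with `q` (matrix, row s+1 = efficacy at
#'   stimulus s, s = 0 ... S_used - 1), `spectra`, `coefs` (lists indexed the
#'   same way), `n_used`, `converged`, `u0`, `train`, `net`, `params`.
#' @export
run_stimulus_train <- function(net, params = net$params, train,
                               tol = 1e-6, keep_spectra = TRUE) {
  stopifnot(inherits(net, "ac_network"), inherits(train, "ac_train"))
  if (train$soi < 0.5)
    warning("SOI below 0.5 s: the assumption that u, v decay to zero ",
            "between stimuli becomes inaccurate", call. = FALSE)
  N <- net$N
  S <- train$n_stimuli
  u0 <- rep(0, N); u0[1L] <- params$a / params$tau_m
  q <- rep(1, N)
  qs <- matrix(NA_real_, S, N, dimnames = list(NULL, net$areas))
  spectra <- vector("list", S)
  coefs <- vector("list", S)
  converged <- FALSE
  n_used <- S
  for (s in seq_len(S)) {
    qs[s, ] <- q
    dec <- spectral_decomposition(coefficient_matrix(net, params, q))
    co <- mode_coefficients(dec, u0)
    if (keep_spectra || s == 1L || s == S) {
      spectra[[s]] <- dec
      coefs[[s]] <- co
    }
    if (s == S) break
    fdrop <- fast_dropoff(q, dec, co, train$soi, params)
    q_next <- slow_recovery(fdrop, train$soi, params, net$adapting)
    if (max(abs(q_next - q)) < tol) {
      converged <- TRUE
      n_used <- s
      qs <- qs[seq_len(s), , drop = FALSE]
      spectra <- spectra[seq_len(s)]
      coefs <- coefs[seq_len(s)]
      break
    }
    q <- q_next
  }
  if (!keep_spectra && n_used > 1L && is.null(spectra[[n_used]])) {
    dec <- spectral_decomposition(coefficient_matrix(net, params, qs[n_used, ]))
    spectra[[n_used]] <- dec
    coefs[[n_used]] <- mode_coefficients(dec, u0)
  }
  structure(list(q = qs, spectra = spectra, coefs = coefs,
                 n_used = n_used, converged = converged, u0 = u0,
                 train = train, net = net, params = params),
            class = "ac_adaptation")
}

#' @export
print.ac_adaptation <- function(x, ...) {
  cat("Slow-fast adaptation run: SOI =", x$train$soi, "s,",
      x$train$n_stimuli, "stimuli requested,", x$n_used, "computed",
      if (x$converged) "(converged early)" else "", "\n")
  cat("  adapted efficacy:",
      paste(sprintf("%s=%.4f", colnames(x$q), x$q[nrow(x$q), ]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Spectrum and coefficients at a given adaptation state
#'
#' @param adapt an `ac_adaptation`.
#' @param state `"initial"` (first stimulus, q = 1), `"adapted"` (last
#'   computed stimulus), or a 1-based stimulus index.
#' @return List with `dec`, `coeffs`, `q`, `index`.
#' @export
adaptation_state <- function(adapt, state = c("adapted", "initial")) {
  stopifnot(inherits(adapt, "ac_adaptation"))
  s <- if (is.numeric(state)) as.integer(state)
       else switch(match.arg(state), initial = 1L, adapted = adapt$n_used)
  if (s < 1L || s > adapt$n_used) stop("no such stimulus index", call. = FALSE)
  dec <- adapt$spectra[[s]]
  co <- adapt$coefs[[s]]
  if (is.null(dec)) {
    dec <- spectral_decomposition(
      coefficient_matrix(adapt$net, adapt$params, adapt$q[s, ]))
    co <- mode_coefficients(dec, adapt$u0)
  }
  list(dec = dec, coeffs = co, q = adapt$q[s, ], index = s)
}

#' Stitch the slow-fast solution into a continuous trajectory
#'
#' Reconstructs `u(t)`, `v(t)` over the whole train by evolving each
#' interval's normal-mode superposition from its jump state, and carries the
#' piecewise-constant efficacy alongside.  Useful for comparison with
#' [integrate_full()].
#'
#' @param adapt an `ac_adaptation` (run with `keep_spectra = TRUE`).
#' @param dt_out output sampling interval (s).
#' @return An `ac_trajectory` with `u`, `v`, `q`, `d`.
#' @export
slow_fast_trajectory <- function(adapt, dt_out = 1e-3) {
  stopifnot(inherits(adapt, "ac_adaptation"))
  soi <- adapt$train$soi
  S <- adapt$n_used
  pieces_u <- vector("list", S); pieces_v <- vector("list", S)
  times <- numeric(0); qrows <- vector("list", S)
  local_t <- seq(0, soi, by = dt_out)
  local_t <- local_t[local_t < soi - 1e-12]
  for (s in seq_len(S)) {
    st <- adaptation_state(adapt, s)
    tr <- evolve_modes(st$dec, st$coeffs, local_t)
    pieces_u[[s]] <- tr$u; pieces_v[[s]] <- tr$v
    times <- c(times, (s - 1L) * soi + local_t)
    qrows[[s]] <- matrix(st$q, length(local_t), adapt$net$N, byrow = TRUE)
  }
  u <- do.call(rbind, pieces_u); v <- do.call(rbind, pieces_v)
  q <- do.call(rbind, qrows)
  colnames(q) <- adapt$net$areas
  structure(list(time = times, u = u, v = v, q = q, d = 1 - q),
            class = "ac_trajectory")
}

#' Validate the slow-fast scheme against the full model
#'
#' Runs the slow-fast scheme and the full numerical integration (nonlinear
#' tanh and linearised firing rates) on the same train, and reports the
#' per-stimulus, per-area peak amplitudes of `u(t)` with their relative
#' differences.
#'
#' @inheritParams run_stimulus_train
#' @param dt_out sampling interval for peak extraction (s).
#' @return A data frame with columns `stimulus`, `area`, `peak_slowfast`,
#'   `peak_tanh`, `peak_linear`, `rel_diff_tanh`, `rel_diff_linear`.
#' @export
validate_against_full_model <- function(net, params = net$params, train,
                                        dt_out = 1e-3) {
  adapt <- run_stimulus_train(net, params, train, tol = 0)
  sf <- slow_fast_trajectory(adapt, dt_out)
  full_t <- integrate_full(net, params, train, "tanh", dt_out)
  full_l <- integrate_full(net, params, train, "linear", dt_out)
  S <- train$n_stimuli
  peak_in <- function(traj, s, area) {
    sel <- traj$time >= (s - 1L) * train$soi - 1e-12 &
           traj$time < s * train$soi - 1e-12
    max(abs(traj$u[sel, area]))
  }
  grid <- expand.grid(stimulus = seq_len(S), area = net$areas[net$adapting],
                      stringsAsFactors = FALSE)
  res <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
    s <- grid$stimulus[i]; ar <- grid$area[i]
    p_sf <- peak_in(sf, s, ar)
    p_t <- peak_in(full_t, s, ar)
    p_l <- peak_in(full_l, s, ar)
    data.frame(stimulus = s, area = ar, peak_slowfast = p_sf,
               peak_tanh = p_t, peak_linear = p_l,
               rel_diff_tanh = abs(p_sf - p_t) / p_t,
               rel_diff_linear = abs(p_sf - p_l) / p_l)
  }))
  res
}

#' Export the adaptation sequence as CSV
#'
#' Rows `(stimulus_index, area, q, d)`; stimulus indices are 0-based so the
#' initial state is index 0.
#' @param adapt an `ac_adaptation`.
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_adaptation <- function(adapt, path) {
  S <- nrow(adapt$q)
  df <- data.frame(stimulus_index = rep(0:(S - 1L), each = adapt$net$N),
                   area = rep(adapt$net$areas, S),
                   q = as.vector(t(adapt$q)))
  df$d <- 1 - df$q
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
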