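#' Periodic delta-stimulus train
#'
#' Describes stimulation by `n_stimuli` identical delta-like tone onsets with
#' a fixed stimulus onset interval (SOI): the s-th stimulus occurs at
#' `t_s = s * soi`, `s = 0, 1, ...`.  The afferent input enters only the
#' excitatory population of the inferior colliculus; inhibitory populations
#' receive no afferent input.
#'
#' @param soi stimulus onset interval (s), > 0.
#' @param n_stimuli number of stimuli, >= 1.
#' @return An `ac_train`: list with `soi`, `n_stimuli`, `onsets`.
#' @export
stimulus_train <- function(soi, n_stimuli = 111L) {
  if (!is.numeric(soi) || length(soi) != 1L || soi <= 0)
    stop("'soi' must be a positive scalar (seconds)", call. = FALSE)
  n_stimuli <- as.integer(n_stimuli)
  if (n_stimuli < 1L) stop("'n_stimuli' must be >= 1", call. = FALSE)
  structure(list(soi = soi, n_stimuli = n_stimuli,
                 onsets = (seq_len(n_stimuli) - 1L) * soi),
            class = "ac_train")
}

#' Numerically integrate the full nonlinear model
#'
#' Reference integrator for the complete system: membrane dynamics of `u` and
#' `v` with firing rate `g[x] = tanh(alpha x)` (or the linearised
#' `g[x] = alpha x`), and the short-term synaptic depression equation
#' `dq/dt = -q g[u] / tau_o + (1 - q) / tau_rec` for the cortical areas;
#' the subcortical efficacies (IC, thalamus) are held at 1.  Each delta
#' stimulus is realised as an instantaneous jump `u_IC <- u_IC + a / tau_m`
#' (the integral of the membrane equation across the impulse), and the smooth
#' system is integrated between onsets with an adaptive solver restarted at
#' every jump.
#'
#' @param net an `ac_network`.
#' @param params an `ac_params`.
#' @param train an `ac_train`.
#' @param firing_rate `"tanh"` (default) or `"linear"`.
#' @param dt_out output sampling interval (s), default 1 ms.
#' @param t_end end of integration; defaults to `n_stimuli * soi`.
#' @param fix_q optional efficacy vector: clamps `q` to this value everywhere
#'   (no depression dynamics), giving the plain linear/nonlinear network.
#' @param rtol,atol solver tolerances.
#' @return An `ac_trajectory` with `time`, `u`, `v`, `q` and `d = 1 - q`
#'   (matrices, time x area).
#' @export
integrate_full <- function(net, params = net$params, train,
                           firing_rate = c("tanh", "linear"),
                           dt_out = 1e-3, t_end = NULL, fix_q = NULL,
                           rtol = 1e-9, atol = 1e-12) {
  stopifnot(inherits(net, "ac_network"), inherits(train, "ac_train"))
  firing_rate <- match.arg(firing_rate)
  if (dt_out <= 0) stop("'dt_out' must be positive", call. = FALSE)
  N <- net$N
  if (is.null(t_end)) t_end <- train$n_stimuli * train$soi
  g <- if (firing_rate == "tanh") function(x) tanh(params$alpha * x)
       else function(x) params$alpha * x
  clamped <- !is.null(fix_q)
  if (clamped) stopifnot(length(fix_q) == N, all(fix_q > 0 & fix_q <= 1))
  adapting <- net$adapting

  deriv <- function(t, y, parms) {
    u <- y[seq_len(N)]; v <- y[N + seq_len(N)]
    q <- if (clamped) fix_q else y[2L * N + seq_len(N)]
    gu <- g(u); gv <- g(v)
    du <- (-u + (net$W_ee %*% (q * gu)) - net$W_ei %*% gv) / params$tau_m
    dv <- (-v + net$W_ie %*% gu - net$W_ii %*% gv) / params$tau_m
    dq <- -q * gu / params$tau_o + (1 - q) / params$tau_rec
    dq[!adapting] <- 0
    if (clamped) dq[] <- 0
    list(c(du, dv, dq))
  }

  jump <- params$a / params$tau_m
  y <- c(rep(0, 2L * N), if (clamped) fix_q else rep(1, N))
  times_out <- seq(0, t_end, by = dt_out)
  onsets <- train$onsets[train$onsets < t_end - 1e-12]
  bounds <- sort(unique(c(0, onsets, t_end)))
  rows <- vector("list", length(bounds) - 1L)
  for (k in seq_len(length(bounds) - 1L)) {
    t0 <- bounds[k]; t1 <- bounds[k + 1L]
    if (any(abs(onsets - t0) < 1e-12)) y[1L] <- y[1L] + jump
    grid <- times_out[times_out > t0 + 1e-12 & times_out < t1 - 1e-12]
    grid <- c(t0, grid, t1)
    sol <- deSolve::lsoda(y, grid, deriv, parms = NULL,
                          rtol = rtol, atol = atol)
    if (any(!is.finite(sol)))
      stop("state diverged (non-finite values) during interval [",
           format(t0), ", ", format(t1), "]", call. = FALSE)
    last <- k == length(bounds) - 1L
    keep <- rep(TRUE, nrow(sol))
    if (!last) keep[nrow(sol)] <- FALSE   # interval end belongs to next piece
    rows[[k]] <- sol[keep, , drop = FALSE]
    y <- sol[nrow(sol), -1L]
  }
  out <- do.call(rbind, rows)
  # keep only the requested output grid (interval endpoints coincide with it
  # up to rounding; match by distance, not identity)
  idx <- vapply(times_out, function(t) which.min(abs(out[, 1L] - t)), 0L)
  out <- out[idx, , drop = FALSE]
  out[, 1L] <- times_out
  u <- out[, 1L + seq_len(N), drop = FALSE]
  v <- out[, 1L + N + seq_len(N), drop = FALSE]
  q <- if (clamped) matrix(fix_q, nrow(out), N, byrow = TRUE)
       else out[, 1L + 2L * N + seq_len(N), drop = FALSE]
  colnames(u) <- net$areas; colnames(v) <- net$areas; colnames(q) <- net$areas
  structure(list(time = out[, 1L], u = u, v = v, q = q, d = 1 - q),
            class = "ac_trajectory")
}

#' @export
print.ac_trajectory <- function(x, ...) {
  cat("State trajectory:", length(x$time), "samples over [",
      format(min(x$time)), ",", format(max(x$time)), "] s;",
      ncol(x$u), "areas\n")
  invisible(x)
}

#' Export a trajectory as CSV
#'
#' Columns `time_s`, then `u_<area>`, `v_<area>` and, when present,
#' `q_<area>`, `d_<area>`.
#' @param traj an `ac_trajectory`.
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  df <- data.frame(time_s = traj$time)
  for (comp in c("u", "v", "q", "d")) {
    m <- traj[[comp]]
    if (is.null(m)) next
    colnames(m) <- paste0(comp, "_", colnames(m))
    df <- cbind(df, as.data.frame(m))
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Compare nonlinear and linearised firing rates
#'
#' Runs [integrate_full()] twice, with `tanh` and with linear firing rates,
#' and reports per-area discrepancies of `u(t)`: the maximum absolute
#' difference and the L2 difference, both relative to the corresponding norm
#' of the tanh solution.
#'
#' @inheritParams integrate_full
#' @return A data frame with columns `area`, `rel_linf`, `rel_l2`.
#' @export
compare_firing_rates <- function(net, params = net$params, train,
                                 dt_out = 1e-3, ...) {
  a <- integrate_full(net, params, train, firing_rate = "tanh",
                      dt_out = dt_out, ...)
  b <- integrate_full(net, params, train, firing_rate = "linear",
                      dt_out = dt_out, ...)
  rel <- function(x, y, p) {
    nx <- if (p == Inf) max(abs(x)) else sqrt(sum(x^2))
    nd <- if (p == Inf) max(abs(x - y)) else sqrt(sum((x - y)^2))
    if (nx == 0 && nd == 0) 0 else nd / max(nx, .Machine$double.xmin)
  }
  data.frame(area = colnames(a$u),
             rel_linf = vapply(seq_len(ncol(a$u)), function(i)
               rel(a$u[, i], b$u[, i], Inf), 0),
             rel_l2 = vapply(seq_len(ncol(a$u)), function(i)
               rel(a$u[, i], b$u[, i], 2), 0),
             row.names = NULL)
}
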