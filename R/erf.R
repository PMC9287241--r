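#' MEG weighting matrix of the network
#'
#' The simulated MEG signal is the sum over all synaptic inputs, each
#' weighted by its topology multiplier:
#' `R(t) = sum_j [ blockdiag(K1 o W_ee, K2 o W_ei) (u; v) ]_j`
#' (`o` = element-wise Hadamard product).  This returns the 2N x 2N block
#' matrix; `colSums` of it give the per-source weights actually applied to
#' the state vector.  Following the printed forward model, `W_ee` enters
#' without the efficacy modulation `Q`; set `weights = "depressed"` to apply
#' `Q` (column-wise) instead.
#'
#' @param net an `ac_network`.
#' @param weights `"static"` (default) or `"depressed"`.
#' @param q efficacy vector, only used for `weights = "depressed"`.
#' @return 2N x 2N numeric matrix.
#' @export
meg_weight_matrix <- function(net, weights = c("static", "depressed"),
                              q = rep(1, net$N)) {
  weights <- match.arg(weights)
  W <- net$K1 * net$W_ee
  if (weights == "depressed") W <- W %*% diag(q, net$N)
  N <- net$N
  B <- matrix(0, 2L * N, 2L * N)
  B[seq_len(N), seq_len(N)] <- W
  B[N + seq_len(N), N + seq_len(N)] <- net$K2 * net$W_ei
  lab <- c(paste0("u_", net$areas), paste0("v_", net$areas))
  dimnames(B) <- list(lab, lab)
  B
}

#' Simulated MEG signal from a state trajectory
#'
#' Applies the forward model to a trajectory of `(u, v)` and sums over all
#' cortical inputs.
#'
#' @param net an `ac_network`.
#' @param traj an `ac_trajectory`.
#' @param weights,q see [meg_weight_matrix()].
#' @return An `ac_erf`: list with `time`, `R`.
#' @export
meg_signal <- function(net, traj, weights = "static", q = rep(1, net$N)) {
  stopifnot(inherits(net, "ac_network"), inherits(traj, "ac_trajectory"))
  w <- colSums(meg_weight_matrix(net, weights, q))
  Z <- cbind(traj$u, traj$v)
  structure(list(time = traj$time, R = as.vector(Z %*% w)),
            class = "ac_erf")
}

#' @export
print.ac_erf <- function(x, ...) {
  cat("Simulated ERF:", length(x$time), "samples over [",
      format(min(x$time)), ",", format(max(x$time)), "] s")
  if (!is.null(attr(x, "state"))) cat(";", attr(x, "state"), "state")
  if (!is.null(attr(x, "soi"))) cat(", SOI", attr(x, "soi"), "s")
  cat("\n")
  invisible(x)
}

#' Single-stimulus ERF waveform from an adaptation run
#'
#' Synthesises the ERF for one stimulus of a slow-fast run as the normal-mode
#' sum `R(t) = sum_n c_n kappa_n exp(lambda_n t)`.  Model time starts at the
#' stimulus onset; `shift_ms` (a display allowance for subcortical conduction,
#' conventionally 30 ms) is stored as an attribute and applied only when
#' exporting, never in analysis.
#'
#' @param adapt an `ac_adaptation`.
#' @param state `"adapted"`, `"initial"`, or a stimulus index.
#' @param dt sampling interval (s).
#' @param t_max waveform length (s); default `min(soi, 0.6)`.
#' @param shift_ms display shift (ms), default 0.
#' @param weights forward-model flag, see [meg_weight_matrix()].
#' @return An `ac_erf` with attributes `state`, `soi`, `variant`,
#'   `stimulus_index`, `shift_ms`, `p1_polarity` (sign of the
#'   feedforward-dominated deflection, used to orient landmark extraction).
#' @export
erf_waveform <- function(adapt, state = "adapted", dt = 1e-3, t_max = NULL,
                         shift_ms = 0, weights = "static") {
  stopifnot(inherits(adapt, "ac_adaptation"))
  st <- adaptation_state(adapt, state)
  if (is.null(t_max)) t_max <- min(adapt$train$soi, 0.6)
  times <- seq(0, t_max, by = dt)
  w <- colSums(meg_weight_matrix(adapt$net, weights, st$q))
  kappa <- as.vector(w %*% st$dec$right)
  rn <- outer(unclass(st$coeffs) * kappa, rep(1, length(times))) *
    exp(outer(st$dec$values, times))
  R <- colSums(rn)
  if (max(abs(Im(R))) > 1e-9 * max(abs(R), 1e-300))
    warning("imaginary residual in ERF synthesis")
  ff <- .type_groups(adapt$net)$feedforward
  wf <- colSums(meg_weight_matrix(adapt$net, weights, st$q) * ff)
  ff_wave <- Re(as.vector((wf %*% st$dec$right) %*%
                            (unclass(st$coeffs) * exp(outer(st$dec$values, times)))))
  pol <- sign(ff_wave[which.max(abs(ff_wave))])
  structure(list(time = times, R = Re(R)),
            class = "ac_erf",
            state = if (is.character(state)) state else "indexed",
            stimulus_index = st$index, soi = adapt$train$soi,
            variant = adapt$net$variant, shift_ms = shift_ms,
            p1_polarity = if (is.na(pol) || pol == 0) 1 else pol,
            modes = list(lambda = st$dec$values,
                         weight = unclass(st$coeffs) * kappa))
}

#' Per-mode contributions to the MEG signal
#'
#' For each normal mode, its input efficiency `|c_n|` (initial amplitude),
#' its MEG efficiency `kappa_n = sum_j [blockdiag(K1 o W_ee, K2 o W_ei)
#' (x_n; y_n)]_j`, and the complex trajectory `r_n(t) = c_n kappa_n
#' exp(lambda_n t)`.  A conjugate pair contributes `2 Re(r_n(t))` to the real
#' signal, and `sum_n r_n(t) = R(t)`.
#'
#' Note: `|c_n|` and `kappa_n` individually depend on the eigenvector
#' normalisation convention (unit-norm right vectors here); their product
#' `|c_n| |kappa_n|`, the total mode contribution, does not.
#'
#' @param dec an `ac_spectrum`.
#' @param coeffs an `ac_coefs`.
#' @param net an `ac_network`.
#' @param times optional time grid for `r_n(t)` (default none).
#' @param weights,q see [meg_weight_matrix()].
#' @return List with `table` (data frame: `mode_id`, `nu_hz`, `gamma_per_s`,
#'   `abs_c`, `arg_c`, `kappa`, `total = abs_c * |kappa|`, `pair`) and, if
#'   `times` given, the complex matrix `r` (mode x time) plus `time`.
#' @export
mode_contributions <- function(dec, coeffs, net, times = NULL,
                               weights = "static", q = rep(1, net$N)) {
  stopifnot(inherits(dec, "ac_spectrum"))
  w <- colSums(meg_weight_matrix(net, weights, q))
  kappa <- as.vector(w %*% dec$right)
  cn <- unclass(coeffs)
  tab <- data.frame(mode_id = seq_along(cn),
                    nu_hz = dec$nu, gamma_per_s = dec$gamma,
                    abs_c = Mod(cn), arg_c = Arg(cn),
                    kappa_re = Re(kappa), kappa_im = Im(kappa),
                    total = Mod(cn) * Mod(kappa),
                    pair = dec$pair)
  out <- list(table = tab, kappa = kappa)
  if (!is.null(times)) {
    out$r <- (cn * kappa) * exp(outer(dec$values, times))
    out$time <- times
  }
  out
}

# connection-type masks over the 2N x 2N forward-model matrix
.type_groups <- function(net) {
  N <- net$N
  ee <- matrix(0, 2L * N, 2L * N)
  row_i <- row(diag(N)); col_j <- col(diag(N))
  masks <- list(
    feedforward = col_j < row_i,
    lateral = col_j == row_i,
    feedback = col_j > row_i)
  out <- lapply(masks, function(m) {
    g <- ee
    g[seq_len(N), seq_len(N)] <- m
    g
  })
  inh <- ee
  inh[N + seq_len(N), N + seq_len(N)] <- 1
  out$inhibitory <- inh
  out
}

#' Decompose the MEG signal by anatomical connection groups
#'
#' Partitions the summands of the forward model into groups and returns one
#' waveform per group; the groups always sum to the total signal exactly.
#' Schemes:
#' \describe{
#'   \item{`incoming`}{by receiving area (row of the weight matrices); the
#'     MEG analogue of source modelling.}
#'   \item{`outgoing`}{by sending area (column), i.e. the field driven by an
#'     area's excitatory and inhibitory output.}
#'   \item{`type`}{feedforward, feedback, lateral
#'     (excitatory-to-excitatory classes) and inhibitory
#'     (inhibitory-to-excitatory) connections.}
#' }
#'
#' @param net an `ac_network`.
#' @param traj an `ac_trajectory`.
#' @param scheme `"incoming"`, `"outgoing"` or `"type"`.
#' @param weights,q see [meg_weight_matrix()].
#' @return An `ac_erf_decomposition`: list with `time`, `groups` (matrix,
#'   time x group), `total` (= rowSums of `groups`), `scheme`.
#' @export
decompose_by_connection <- function(net, traj,
                                    scheme = c("incoming", "outgoing", "type"),
                                    weights = "static", q = rep(1, net$N)) {
  stopifnot(inherits(net, "ac_network"), inherits(traj, "ac_trajectory"))
  scheme <- match.arg(scheme)
  B <- meg_weight_matrix(net, weights, q)
  N <- net$N
  Z <- cbind(traj$u, traj$v)
  if (scheme == "type") {
    masks <- .type_groups(net)
    groups <- vapply(masks, function(m) as.vector(Z %*% colSums(B * m)),
                     numeric(nrow(Z)))
  } else {
    sel <- if (scheme == "incoming") function(i) {
      m <- matrix(0, 2L * N, 2L * N); m[c(i, N + i), ] <- 1; m
    } else function(i) {
      m <- matrix(0, 2L * N, 2L * N); m[, c(i, N + i)] <- 1; m
    }
    groups <- vapply(seq_len(N),
                     function(i) as.vector(Z %*% colSums(B * sel(i))),
                     numeric(nrow(Z)))
    colnames(groups) <- net$areas
  }
  structure(list(time = traj$time, groups = groups,
                 total = rowSums(groups), scheme = scheme),
            class = "ac_erf_decomposition")
}

#' @export
print.ac_erf_decomposition <- function(x, ...) {
  cat("ERF decomposition by", x$scheme, "connections:",
      paste(colnames(x$groups), collapse = ", "), "\n")
  invisible(x)
}

#' Export an ERF waveform as CSV
#'
#' Columns `time_ms` (with the display shift applied) and `R`.
#' @param erf an `ac_erf`.
#' @param path file path.
#' @return The path, invisibly.
#' @export
write_erf <- function(erf, path) {
  shift <- attr(erf, "shift_ms")
  if (is.null(shift)) shift <- 0
  utils::write.csv(data.frame(time_ms = erf$time * 1000 + shift, R = erf$R),
                   path, row.names = FALSE)
  invisible(path)
}
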