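#' Assemble the coefficient matrix of the linearised network
#'
#' For a linear firing rate `g[x] = alpha * x` and a fixed synaptic-efficacy
#' vector `q`, the excitatory/inhibitory state `(u, v)` obeys the homogeneous
#' linear system `d/dt (u, v) = M (u, v)` with the 2N x 2N block matrix
#'
#' \deqn{M = \frac{1}{\tau_m}\begin{pmatrix} \alpha W_{ee} Q - I & -\alpha
#'   W_{ei} \\ \alpha W_{ie} & -\alpha W_{ii} - I \end{pmatrix}, \quad
#'   Q = \mathrm{diag}(q).}
#'
#' `Q` multiplies `W_ee` from the right: the efficacy of a connection is that
#' of its presynaptic (sending) population.
#'
#' @param net an `ac_network`.
#' @param params an `ac_params`; defaults to the parameters stored in `net`.
#' @param q synaptic-efficacy vector in (0, 1], length `net$N` (default all 1).
#' @return A 2N x 2N numeric matrix (units 1/s) with `u`/`v` block labels.
#' @export
coefficient_matrix <- function(net, params = net$params, q = rep(1, net$N)) {
  stopifnot(inherits(net, "ac_network"), length(q) == net$N)
  if (any(q <= 0 | q > 1)) stop("efficacy 'q' must lie in (0, 1]", call. = FALSE)
  N <- net$N
  al <- params$alpha
  I <- diag(N)
  M <- rbind(cbind(al * net$W_ee %*% diag(q, N) - I, -al * net$W_ei),
             cbind(al * net$W_ie, -al * net$W_ii - I)) / params$tau_m
  lab <- c(paste0("u_", net$areas), paste0("v_", net$areas))
  dimnames(M) <- list(lab, lab)
  M
}

#' Normal-mode decomposition of the coefficient matrix
#'
#' Computes eigenvalues `lambda_n = gamma_n + i omega_n`, right eigenvectors
#' (the normal modes, unit Euclidean norm) and left eigenvectors rescaled to
#' biorthonormality, so that the bilinear product of left row `m` with right
#' column `n` is `delta_mn`.  Modes are sorted by `|omega|` ascending (ties:
#' `gamma` descending) with the positive-frequency member of each conjugate
#' pair first; `pair` maps each underdamped mode to its conjugate partner.
#'
#' @param M square numeric (or complex) matrix, typically from
#'   [coefficient_matrix()].
#' @param tol biorthonormality tolerance beyond which `M` is declared
#'   numerically defective (non-diagonalisable) and an error is raised.
#' @return An object of class `ac_spectrum`: list with `values` (complex
#'   eigenvalues), `gamma`, `omega`, `nu` (= omega / 2 pi, Hz), `right`
#'   (2N x 2N complex matrix, modes in columns), `left` (2N x 2N, rows),
#'   `pair` (integer partner index, `NA` for overdamped modes), `damping`
#'   (`"underdamped"`/`"overdamped"`), and `N`.
#' @export
spectral_decomposition <- function(M, tol = 1e-8) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M), all(is.finite(M)))
  e <- eigen(M)
  val <- e$values
  V <- e$vectors
  if (!is.complex(val)) { val <- as.complex(val); V <- V + 0i }

  ord <- order(abs(Im(val)), -Re(val), -Im(val))
  val <- val[ord]
  V <- V[, ord, drop = FALSE]

  L <- tryCatch(solve(V), error = function(e2)
    stop("coefficient matrix is numerically defective: ", conditionMessage(e2),
         call. = FALSE))
  resid <- max(abs(L %*% V - diag(nrow(M))))
  if (resid > tol)
    stop("coefficient matrix is numerically defective ",
         "(biorthonormality residual ", format(resid, digits = 3), ")",
         call. = FALSE)

  n <- length(val)
  underdamped <- abs(Im(val)) > 1e-8
  pair <- rep(NA_integer_, n)
  used <- rep(FALSE, n)
  for (i in seq_len(n)) {
    if (!underdamped[i] || used[i]) next
    j <- which(!used & seq_len(n) != i &
                 abs(val - Conj(val[i])) < 1e-6 * (1 + abs(val[i])))
    if (length(j)) {
      j <- j[1L]
      pair[i] <- j; pair[j] <- i
      used[i] <- TRUE; used[j] <- TRUE
    }
  }

  structure(list(values = val,
                 gamma = Re(val), omega = Im(val), nu = Im(val) / (2 * pi),
                 right = V, left = L, pair = pair,
                 damping = ifelse(underdamped, "underdamped", "overdamped"),
                 N = as.integer(nrow(M) / 2), M = M),
            class = "ac_spectrum")
}

#' @export
print.ac_spectrum <- function(x, ...) {
  cat("Normal-mode spectrum (", length(x$values), " modes)\n", sep = "")
  df <- data.frame(nu_hz = round(x$nu, 3), gamma_per_s = round(x$gamma, 3),
                   damping = x$damping)
  print(df)
  invisible(x)
}

#' Mode coefficients for an initial condition
#'
#' Projects an initial state `(u0, v0)` on the left eigenvectors:
#' `c_n = <(u0, v0), (xi_n, eta_n)>` (bilinear product with the
#' biorthonormalised left vectors), so that the superposition
#' `sum_n c_n (x_n, y_n)` reproduces the initial state exactly.  For a real
#' initial state, coefficients of conjugate mode pairs are conjugate; the
#' modulus `|c_n|` is the initial amplitude (input efficiency) of mode `n`
#' and `Arg(c_n)` its initial phase.
#'
#' @param dec an `ac_spectrum`.
#' @param u0,v0 initial excitatory and inhibitory state vectors (length N).
#' @return Complex vector of length 2N, class `ac_coefs`.
#' @export
mode_coefficients <- function(dec, u0, v0 = rep(0, dec$N)) {
  stopifnot(inherits(dec, "ac_spectrum"))
  z0 <- c(u0, v0)
  if (length(z0) != nrow(dec$right))
    stop("initial state has wrong dimension", call. = FALSE)
  structure(as.vector(dec$left %*% z0), class = "ac_coefs")
}

#' Analytic evolution of the normal-mode superposition
#'
#' Evaluates `(u(t), v(t)) = sum_n c_n exp(lambda_n t) (x_n, y_n)` on a time
#' grid.  The imaginary residual of the superposition (zero in exact
#' arithmetic for a real initial state) is checked against `imag_tol` and
#' discarded.
#'
#' @param dec an `ac_spectrum`.
#' @param coeffs coefficients from [mode_coefficients()].
#' @param times non-negative, increasing time grid (s).
#' @param imag_tol relative imaginary-residual tolerance.
#' @return An `ac_trajectory`: list with `time`, `u` and `v` (matrices,
#'   time x area).
#' @export
evolve_modes <- function(dec, coeffs, times, imag_tol = 1e-9) {
  stopifnot(inherits(dec, "ac_spectrum"), all(diff(times) > 0) || length(times) == 1L,
            all(times >= 0))
  E <- exp(outer(dec$values, times))        # 2N x T
  Z <- dec$right %*% (E * as.vector(unclass(coeffs)))
  scale <- max(abs(Z), 1e-300)
  if (max(abs(Im(Z))) > imag_tol * scale)
    warning("imaginary residual ", format(max(abs(Im(Z))) / scale, digits = 3),
            " exceeds tolerance; check conjugate pairing of coefficients")
  Z <- Re(Z)
  N <- dec$N
  areas <- sub("^u_", "", rownames(dec$M)[seq_len(N)])
  u <- t(Z[seq_len(N), , drop = FALSE])
  v <- t(Z[N + seq_len(N), , drop = FALSE])
  colnames(u) <- areas; colnames(v) <- areas
  structure(list(time = times, u = u, v = v), class = "ac_trajectory")
}

#' Export a normal-mode spectrum as a CSV table
#'
#' One row per mode: frequency, decay rate, coefficient modulus and argument,
#' damping class, and the real/imaginary eigenvector components per area.
#'
#' @param dec an `ac_spectrum`.
#' @param coeffs optional `ac_coefs` (moduli/arguments written if given).
#' @param path optional file path; if `NULL` the data frame is returned only.
#' @return The data frame, invisibly if written to `path`.
#' @export
spectrum_table <- function(dec, coeffs = NULL, path = NULL) {
  V <- dec$right
  comp <- cbind(Re(t(V)), Im(t(V)))
  colnames(comp) <- c(paste0("re_", rownames(dec$M)), paste0("im_", rownames(dec$M)))
  df <- data.frame(mode_id = seq_along(dec$values),
                   nu_hz = dec$nu, gamma_per_s = dec$gamma,
                   damping_class = dec$damping)
  if (!is.null(coeffs)) {
    df$abs_c <- Mod(unclass(coeffs))
    df$arg_c <- Arg(unclass(coeffs))
  }
  df <- cbind(df, as.data.frame(comp))
  if (!is.null(path)) {
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(df))
  }
  df
}
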