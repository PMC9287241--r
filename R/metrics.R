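#' Extract ERF landmarks (P1m, N1m, P2m)
#'
#' Locates the three canonical deflections inside configurable latency
#' windows, in model time (no display shift).  The P1m is the extremum of
#' the feedforward-dominated polarity within its window; the N1m is the
#' extremum of the opposite polarity; the P2m is the next extremum of P1m
#' polarity after the N1m.  Peak values are refined beyond the time grid:
#' waveforms synthesised by [erf_waveform()] carry their normal-mode sum, and
#' the extremum of the analytic signal is located by numerical optimisation
#' around the grid maximum; other waveforms use a three-point parabolic
#' interpolation.  Either way magnitudes vary smoothly with model parameters
#' rather than being quantised by the grid.  A window containing no extremum
#' of the required polarity yields an explicit `NA` row (flagged in
#' `found`), never a silent zero.
#'
#' @param erf an `ac_erf` (or any list with `time` and `R`).
#' @param windows named list of `c(start, end)` windows in seconds; defaults
#'   are standard auditory-ERF latency ranges expressed in model time, i.e.
#'   without the ~30 ms subcortical conduction delay that separates model
#'   time from sensor latency.
#' @param polarity sign of the P1m deflection; defaults to the
#'   `p1_polarity` attribute set by [erf_waveform()], else `+1`.
#' @return An `ac_peaks` data frame: `landmark`, `latency_s`, `amplitude`
#'   (signed), `magnitude`, `found`.
#' @export
extract_peaks <- function(erf,
                          windows = list(P1m = c(0, 0.04),
                                         N1m = c(0.04, 0.20),
                                         P2m = c(0.10, 0.35)),
                          polarity = NULL) {
  if (is.null(polarity)) polarity <- attr(erf, "p1_polarity")
  if (is.null(polarity)) polarity <- 1
  t <- erf$time; R <- erf$R
  modes <- attr(erf, "modes")
  signs <- c(P1m = polarity, N1m = -polarity, P2m = polarity)
  rows <- list()
  for (lm in c("P1m", "N1m", "P2m")) {
    win <- windows[[lm]]
    lo <- win[1]
    # the P2m is the next opposite deflection after the N1m
    if (lm == "P2m" && !is.null(rows$N1m) && isTRUE(rows$N1m$found))
      lo <- max(lo, rows$N1m$latency_s)
    sel <- which(t >= lo & t <= win[2])
    found <- FALSE; lat <- NA_real_; amp <- NA_real_
    if (length(sel) >= 3L) {
      y <- signs[[lm]] * R[sel]
      i <- which.max(y)
      if (y[i] > 0) {
        found <- TRUE
        gi <- sel[i]
        if (!is.null(modes) && gi > 1L && gi < length(t)) {
          # the waveform is an analytic mode sum: locate the true extremum
          s <- signs[[lm]]
          f <- function(tt) s * Re(sum(modes$weight * exp(modes$lambda * tt)))
          opt <- stats::optimize(f, lower = t[gi - 1L], upper = t[gi + 1L],
                                 maximum = TRUE, tol = 1e-12)
          lat <- opt$maximum
          amp <- s * opt$objective
        } else if (gi > 1L && gi < length(t)) {
          # parabola through the three samples around the extremum
          y3 <- signs[[lm]] * R[(gi - 1L):(gi + 1L)]
          denom <- y3[1] - 2 * y3[2] + y3[3]
          if (is.finite(denom) && denom < 0) {
            delta <- 0.5 * (y3[1] - y3[3]) / denom
            delta <- max(min(delta, 0.5), -0.5)
            dt <- t[gi + 1L] - t[gi]
            lat <- t[gi] + delta * dt
            amp <- signs[[lm]] *
              (y3[2] - 0.25 * (y3[1] - y3[3]) * delta)
          } else {
            lat <- t[gi]; amp <- R[gi]
          }
        } else {
          lat <- t[gi]; amp <- R[gi]
        }
      }
    }
    rows[[lm]] <- data.frame(landmark = lm, latency_s = lat,
                             amplitude = amp, magnitude = abs(amp),
                             found = found)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("ac_peaks", "data.frame")
  out
}

#' Peak amplitude of a state-variable waveform
#'
#' Parabolic-refined maximum of `|x(t)|`; used for the per-area `u(t)` peak
#' amplitudes entering the recovery fits.
#'
#' @param t time grid.
#' @param x signal.
#' @return List with `magnitude` and `latency_s`.
#' @export
peak_amplitude <- function(t, x) {
  i <- which.max(abs(x))
  if (i > 1L && i < length(x)) {
    s <- sign(x[i])
    y3 <- s * x[(i - 1L):(i + 1L)]
    denom <- y3[1] - 2 * y3[2] + y3[3]
    if (is.finite(denom) && denom < 0) {
      delta <- max(min(0.5 * (y3[1] - y3[3]) / denom, 0.5), -0.5)
      return(list(magnitude = y3[2] - 0.25 * (y3[1] - y3[3]) * delta,
                  latency_s = t[i] + delta * (t[i + 1L] - t[i])))
    }
  }
  list(magnitude = abs(x[i]), latency_s = t[i])
}

#' Fit the saturating-exponential recovery model
#'
#' Nonlinear least-squares fit of
#' `P(SOI) = A (1 - exp(-(SOI - t0) / tau_soi))`
#' to peak amplitudes measured at several SOIs, with all three parameters
#' free.  Starting values come from an integral linear-regression
#' linearisation (Jacquelin's method for `y = a + b exp(c x)`): the running
#' trapezoidal integral `S_k` of the data satisfies a linear relation whose
#' regression yields `c = -1/tau`, after which `a`, `b` follow from a second
#' linear regression.  The refinement uses Levenberg-Marquardt least squares
#' with a 1e-10 parameter tolerance; if it fails to converge, the
#' initialiser's estimate is returned with `converged = FALSE`.
#'
#' @param soi strictly increasing SOIs (s), at least 4.
#' @param peaks peak magnitudes (positive), same length.
#' @return An `ac_fit`: list with `A`, `t0`, `tau_soi`, `residual` (L2 norm),
#'   `converged`, `fitted`, `data`.
#' @export
fit_recovery <- function(soi, peaks) {
  stopifnot(length(soi) == length(peaks), length(soi) >= 4L,
            all(diff(soi) > 0), all(is.finite(peaks)))
  init <- .jacquelin_exp(soi, peaks)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A * (1 - exp(-(x - t0) / tau)),
      data = data.frame(x = soi, y = peaks),
      start = list(A = init$A, t0 = init$t0, tau = init$tau),
      control = minpack.lm::nls.lm.control(ptol = 1e-10, ftol = 1e-10,
                                           maxiter = 500)),
    error = function(e) NULL)
  if (is.null(fit)) {
    est <- c(A = init$A, t0 = init$t0, tau = init$tau)
    conv <- FALSE
  } else {
    est <- stats::coef(fit)
    names(est) <- c("A", "t0", "tau")
    conv <- TRUE
  }
  if (est[["tau"]] <= 0) {
    conv <- FALSE
    est[["tau"]] <- abs(est[["tau"]])
  }
  fitted <- est[["A"]] * (1 - exp(-(soi - est[["t0"]]) / est[["tau"]]))
  structure(list(A = est[["A"]], t0 = est[["t0"]], tau_soi = est[["tau"]],
                 residual = sqrt(sum((peaks - fitted)^2)),
                 converged = conv, fitted = fitted,
                 data = data.frame(soi = soi, peak = peaks)),
            class = "ac_fit")
}

# Integral-equation linearisation for y = a + b exp(c x)
# (here a = A, b = -A exp(t0 / tau), c = -1 / tau).
.jacquelin_exp <- function(x, y) {
  n <- length(x)
  S <- c(0, cumsum(0.5 * (y[-1] + y[-n]) * diff(x)))
  X1 <- x - x[1]; Y1 <- y - y[1]
  M <- cbind(X1, S)
  ab <- tryCatch(stats::lm.fit(M, Y1)$coefficients, error = function(e) c(NA, NA))
  c_est <- ab[2]
  if (!is.finite(c_est) || c_est >= 0) c_est <- -1 / (max(x) / 3)
  E <- exp(c_est * x)
  cf <- stats::lm.fit(cbind(1, E), y)$coefficients
  a_est <- cf[1]; b_est <- cf[2]
  tau <- -1 / c_est
  A <- a_est
  t0 <- if (is.finite(b_est) && A > 0 && -b_est / A > 0) tau * log(-b_est / A)
        else -tau
  list(A = unname(A), t0 = unname(t0), tau = unname(tau))
}

#' @export
print.ac_fit <- function(x, ...) {
  cat(sprintf(
    "Recovery fit: A = %.5g, t0 = %.4g s, tau_soi = %.4g s (residual %.3g%s)\n",
    x$A, x$t0, x$tau_soi, x$residual,
    if (x$converged) "" else "; NOT converged"))
  invisible(x)
}

#' Local saturation rate of a recovery curve
#'
#' Finite-difference diagnostic of whether peak amplitudes follow a single
#' saturating exponential: for consecutive SOI pairs,
#' `f_j = (F_j - F_{j+1}) / ((F_j - F_inf) (SOI_{j+1} - SOI_j))`,
#' where `F_inf` is the saturation amplitude (the initial-state peak, the
#' largest the response can be).  For data generated by the exponential
#' model, `f_j` is constant over an evenly spaced grid; deviations from
#' constancy expose model misfit.  Pairs with `F_j = F_inf` are dropped with
#' a warning (the rate is undefined there).
#'
#' @param soi strictly increasing SOIs (s), at least 2.
#' @param peaks peak amplitudes `F_j`.
#' @param F_inf saturation amplitude.
#' @return An `ac_saturation` data frame: `soi_lo`, `soi_hi`, `f` (1/s).
#' @export
local_saturation_rate <- function(soi, peaks, F_inf) {
  stopifnot(length(soi) == length(peaks), length(soi) >= 2L,
            all(diff(soi) > 0), is.finite(F_inf))
  j <- seq_len(length(soi) - 1L)
  denom <- (peaks[j] - F_inf) * (soi[j + 1L] - soi[j])
  f <- (peaks[j] - peaks[j + 1L]) / denom
  bad <- peaks[j] == F_inf
  if (any(bad)) {
    warning(sum(bad), " pair(s) dropped: peak equals the saturation ",
            "amplitude, local rate undefined")
    f <- f[!bad]; j <- j[!bad]
  }
  out <- data.frame(soi_lo = soi[j], soi_hi = soi[j + 1L], f = f)
  class(out) <- c("ac_saturation", "data.frame")
  out
}

#' Adapted-state response amplitudes across an SOI design
#'
#' Runs the slow-fast pipeline for each SOI and measures, in the adapted
#' state (and once in the initial state, which is SOI-independent):
#' \describe{
#'   \item{`ERF`}{the N1m peak magnitude of the simulated ERF;}
#'   \item{`core`/`belt`/`parabelt` (contribution)}{the peak magnitude of
#'     each cortical area's contribution to the ERF, i.e. the
#'     incoming-connection decomposition of the forward model — the model
#'     analogue of source modelling;}
#'   \item{`u_core`/`u_belt`/`u_parabelt` (state)}{the peak amplitude of the
#'     raw excitatory state variable `u(t)` of each area.}
#' }
#'
#' @param net an `ac_network`.
#' @param params an `ac_params`.
#' @param sois SOI design (s).
#' @param n_stimuli stimuli per condition (default 111).
#' @param signals `"all"` (ERF + both area measures) or `"erf"` (ERF only;
#'   faster for dense designs).
#' @param dt waveform sampling interval (s).
#' @param windows landmark windows for [extract_peaks()].
#' @param tol efficacy convergence tolerance passed to
#'   [run_stimulus_train()]; tighten for dense designs where consecutive
#'   conditions differ by less than the default tolerance.
#' @return List with `adapted` (data frame `soi`, `signal`, `magnitude`,
#'   `latency_s`) and `initial` (data frame `signal`, `magnitude`,
#'   `latency_s`).
#' @export
soi_response_curve <- function(net, params = net$params, sois,
                               n_stimuli = 111L, signals = c("all", "erf"),
                               dt = 1e-3, windows = NULL, tol = 1e-6) {
  signals <- match.arg(signals)
  area_sig <- c("core", "belt", "parabelt")
  measure <- function(adapt, state) {
    erf <- erf_waveform(adapt, state, dt = dt)
    pk <- if (is.null(windows)) extract_peaks(erf)
          else extract_peaks(erf, windows = windows)
    n1 <- pk[pk$landmark == "N1m", ]
    rows <- data.frame(signal = "ERF", magnitude = n1$magnitude,
                       latency_s = n1$latency_s)
    if (signals == "all") {
      st <- adaptation_state(adapt, state)
      tr <- evolve_modes(st$dec, st$coeffs, erf$time)
      dinc <- decompose_by_connection(adapt$net, tr, "incoming")
      for (ar in area_sig) {
        p <- peak_amplitude(tr$time, dinc$groups[, ar])
        rows <- rbind(rows, data.frame(signal = ar, magnitude = p$magnitude,
                                       latency_s = p$latency_s))
        p <- peak_amplitude(tr$time, tr$u[, ar])
        rows <- rbind(rows, data.frame(signal = paste0("u_", ar),
                                       magnitude = p$magnitude,
                                       latency_s = p$latency_s))
      }
    }
    rows
  }
  adapted <- vector("list", length(sois))
  initial <- NULL
  for (i in seq_along(sois)) {
    adapt <- run_stimulus_train(net, params,
                                stimulus_train(sois[i], n_stimuli),
                                tol = tol, keep_spectra = FALSE)
    m <- measure(adapt, "adapted")
    m <- cbind(soi = sois[i], m)
    adapted[[i]] <- m
    if (is.null(initial)) initial <- measure(adapt, "initial")
  }
  list(adapted = do.call(rbind, adapted), initial = initial)
}

#' Adaptation-lifetime report over network variants
#'
#' For each variant, runs the full slow-fast pipeline over the SOI design,
#' then fits the saturating-exponential recovery model to the adapted-state
#' N1m peak magnitudes (signal `"ERF"`) and to the per-area peak amplitudes
#' of core, belt and parabelt.  The per-area measure is either each area's
#' contribution to the ERF (`area_measure = "contribution"`, default — the
#' source-modelling analogue) or the raw state variable `u(t)`
#' (`area_measure = "state"`); see the methods vignette for why the
#' contribution measure is the primary one.
#'
#' @param variants character vector of variant names.
#' @param params an `ac_params`.
#' @param sois SOI design (s), default `c(0.5, 1, 2.5, 5, 10)`.
#' @param n_stimuli stimuli per condition (default 111).
#' @param area_measure `"contribution"` or `"state"`.
#' @param ... passed to [build_network()] (e.g. `directions`).
#' @return An `ac_lifetime_report` data frame: `variant`, `signal`, `A`,
#'   `t0_s`, `tau_soi_s`, `residual`, `converged`.  The per-condition peak
#'   amplitudes are attached as attribute `"curves"`.
#' @export
adaptation_lifetime_report <- function(variants = "DEF", params = ac_params(),
                                       sois = c(0.5, 1, 2.5, 5, 10),
                                       n_stimuli = 111L,
                                       area_measure = c("contribution",
                                                        "state"),
                                       ...) {
  area_measure <- match.arg(area_measure)
  keep <- c("ERF", if (area_measure == "contribution")
    c("core", "belt", "parabelt") else c("u_core", "u_belt", "u_parabelt"))
  rows <- list(); curves <- list()
  for (vr in variants) {
    net <- build_network(params, variant = vr, ...)
    curve <- soi_response_curve(net, params, sois, n_stimuli)
    curves[[vr]] <- curve
    for (sig in keep) {
      d <- curve$adapted[curve$adapted$signal == sig, ]
      fit <- fit_recovery(d$soi, d$magnitude)
      rows[[paste(vr, sig)]] <- data.frame(
        variant = vr, signal = sub("^u_", "", sig), A = fit$A, t0_s = fit$t0,
        tau_soi_s = fit$tau_soi, residual = fit$residual,
        converged = fit$converged)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "curves") <- curves
  attr(out, "area_measure") <- area_measure
  class(out) <- c("ac_lifetime_report", "data.frame")
  out
}
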