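#' Model parameters of the auditory-cortex network
#'
#' Collects the scalar parameters of the five-area neural-mass model: the
#' synaptic weights of the four connection classes, the membrane and synaptic
#' time constants, the afferent input strength, the firing-rate gain, and the
#' MEG topology multipliers.  Defaults are the standard parametrisation used
#' throughout the package, chosen to produce realistic-looking event-related
#' fields.
#'
#' @param w_ee_d lateral (within-area) excitatory-to-excitatory weight.
#' @param w_ee_ff feedforward excitatory-to-excitatory weight between
#'   neighbouring areas (away from the midbrain).
#' @param w_ee_fb feedback excitatory-to-excitatory weight between
#'   neighbouring areas (towards the midbrain).
#' @param w_ie_d local excitatory-to-inhibitory weight.
#' @param w_ei_d local inhibitory-to-excitatory weight.
#' @param w_ii_d local inhibitory-to-inhibitory weight.
#' @param tau_m membrane time constant (s).
#' @param tau_o neurotransmitter release time constant of short-term synaptic
#'   depression (s); must be much smaller than `tau_rec` for the slow-fast
#'   scheme to be valid.
#' @param tau_rec neurotransmitter replenishment time constant (s).
#' @param a afferent input strength delivered to the excitatory population of
#'   the inferior colliculus at each stimulus (dimensionless; a delta input of
#'   this weight produces a state jump `a / tau_m`).
#' @param alpha firing-rate gain: the firing rate is `tanh(alpha * x)` or, in
#'   the linearised system, `alpha * x`.
#' @param k1_d,k1_ff,k1_fb MEG topology multipliers for lateral, feedforward
#'   and feedback excitatory connections.  Feedforward and lateral input
#'   arrives near the soma and drives primary current away from the cortical
#'   surface (negative multipliers); feedback input arrives in superficial
#'   layers and drives current towards the surface (positive multiplier).
#' @param k2_d MEG topology multiplier for local inhibitory-to-excitatory
#'   connections.
#'
#' @return An object of class `ac_params`: a named list of validated scalars.
#' @examples
#' p <- ac_params()
#' p$tau_rec / p$tau_o   # time-scale separation of depression and recovery
#' @export
ac_params <- function(w_ee_d = 2, w_ee_ff = 0.5, w_ee_fb = 0.4,
                      w_ie_d = 3.5, w_ei_d = 2.2, w_ii_d = 2.5,
                      tau_m = 0.03, tau_o = 0.04, tau_rec = 5,
                      a = 0.02, alpha = 1,
                      k1_d = -1, k1_ff = -1, k1_fb = 15, k2_d = 2) {
  p <- list(w_ee_d = w_ee_d, w_ee_ff = w_ee_ff, w_ee_fb = w_ee_fb,
            w_ie_d = w_ie_d, w_ei_d = w_ei_d, w_ii_d = w_ii_d,
            tau_m = tau_m, tau_o = tau_o, tau_rec = tau_rec,
            a = a, alpha = alpha,
            k1_d = k1_d, k1_ff = k1_ff, k1_fb = k1_fb, k2_d = k2_d)
  for (key in names(p)) {
    val <- p[[key]]
    if (!is.numeric(val) || length(val) != 1L || !is.finite(val))
      stop("parameter '", key, "' must be a finite numeric scalar", call. = FALSE)
  }
  for (key in c("tau_m", "tau_o", "tau_rec")) {
    if (p[[key]] <= 0)
      stop("time constant '", key, "' must be positive", call. = FALSE)
  }
  if (p$tau_o >= p$tau_rec)
    stop("'tau_o' must be smaller than 'tau_rec' (slow-fast assumption)",
         call. = FALSE)
  structure(p, class = "ac_params")
}

#' @export
print.ac_params <- function(x, ...) {
  cat("Auditory-cortex model parameters\n")
  cat("  weights   : w_ee(d/ff/fb) =", x$w_ee_d, x$w_ee_ff, x$w_ee_fb,
      " w_ie =", x$w_ie_d, " w_ei =", x$w_ei_d, " w_ii =", x$w_ii_d, "\n")
  cat("  time (s)  : tau_m =", x$tau_m, " tau_o =", x$tau_o,
      " tau_rec =", x$tau_rec, "\n")
  cat("  input     : a =", x$a, " alpha =", x$alpha, "\n")
  cat("  MEG       : k1(d/ff/fb) =", x$k1_d, x$k1_ff, x$k1_fb,
      " k2 =", x$k2_d, "\n")
  invisible(x)
}
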