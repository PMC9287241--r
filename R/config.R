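.RUN_KEYS <- c("variant", "soi", "n_stimuli", "directions",
               "added_ff", "added_fb", "firing_rate", "dt_out", "meg_weights")

#' Load a model configuration file
#'
#' Reads a YAML (or JSON, a YAML subset) configuration whose keys are the
#' model parameter names (`tau_m`, `tau_o`, `tau_rec`, `a`, `alpha`,
#' `w_ee_d`, `w_ee_ff`, `w_ee_fb`, `w_ie_d`, `w_ei_d`, `w_ii_d`, `k1_d`,
#' `k1_ff`, `k1_fb`, `k2_d`) plus run settings (`variant`, `soi`,
#' `n_stimuli`, `directions`, `added_ff`, `added_fb`, `firing_rate`,
#' `dt_out`, `meg_weights`).  Missing parameters fall back to the defaults
#' of [ac_params()]; unknown keys are rejected with an error naming them;
#' invalid values are rejected with the offending key named.
#'
#' @param path config file path, or `NULL` for an all-defaults config.
#' @return An `ac_config`: list with `params` (an `ac_params`), `run` (named
#'   list of run settings) and `resolved` (the fully resolved key set, ready
#'   to echo into a run manifest).
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    out <- tryCatch(yaml::read_yaml(path), error = function(e)
      stop("config parse failure: ", conditionMessage(e), call. = FALSE))
    if (is.null(out)) list() else out
  }
  par_keys <- names(formals(ac_params))
  unknown <- setdiff(names(raw), c(par_keys, .RUN_KEYS))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  params <- tryCatch(do.call(ac_params, raw[intersect(names(raw), par_keys)]),
                     error = function(e)
                       stop("invalid parameter value: ", conditionMessage(e),
                            call. = FALSE))
  run <- list(variant = "DEF", soi = 0.5, n_stimuli = 111L,
              directions = "both", added_ff = params$w_ee_ff,
              added_fb = params$w_ee_fb, firing_rate = "tanh",
              dt_out = 1e-3, meg_weights = "static")
  for (k in intersect(names(raw), .RUN_KEYS)) run[[k]] <- raw[[k]]
  if (!run$variant %in% c("DEF", "CP", "TB", "CPN", "TBN"))
    stop("invalid value for key 'variant': ", run$variant, call. = FALSE)
  if (!is.numeric(run$soi) || run$soi <= 0)
    stop("invalid value for key 'soi'", call. = FALSE)
  run$n_stimuli <- as.integer(run$n_stimuli)
  structure(list(params = params, run = run,
                 resolved = c(unclass(params), run)),
            class = "ac_config")
}

#' Write a run manifest
#'
#' Records the fully resolved configuration, package version, optional seed
#' (only noise-bearing fixture generation is seeded; the simulation pipeline
#' is deterministic) and output paths, so that any export can be reproduced.
#'
#' @param config an `ac_config`.
#' @param outputs character vector of output paths.
#' @param seed optional integer seed.
#' @param path manifest file path (YAML).
#' @return The path, invisibly.
#' @export
write_manifest <- function(config, outputs = character(0), seed = NULL,
                           path) {
  stopifnot(inherits(config, "ac_config"))
  man <- list(tool = "acnet",
              version = as.character(utils::packageVersion("acnet")),
              config = config$resolved,
              outputs = as.list(outputs))
  if (!is.null(seed)) man$seed <- as.integer(seed)
  yaml::write_yaml(man, path)
  invisible(path)
}
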