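#' Area labels of the five-stage auditory pathway model
#'
#' Ordered from the midbrain upwards: inferior colliculus (IC), thalamus, and
#' the three cortical stages core, belt and parabelt.
#' @export
ac_areas <- c("IC", "thalamus", "core", "belt", "parabelt")

.CORTICAL <- 3:5
.N_AREAS <- 5L

#' Build the network topology of the auditory-cortex model
#'
#' Constructs the five-area network: the four weight matrices, the two MEG
#' topology matrices, and the mask of adapting (cortical) areas.  Convention:
#' row = receiving area, column = sending area, so `W_ee[i, j]` is the
#' connection from area `j` into area `i`; feedforward connections therefore
#' occupy the subdiagonal and feedback connections the superdiagonal.
#'
#' In the default serial network (`"DEF"`) only neighbouring areas are
#' connected, so `W_ee` is tridiagonal.  All inhibitory pathways are local,
#' making `W_ei`, `W_ie` and `W_ii` diagonal.  Structural variants add an
#' excitatory shortcut: `"CP"` between core and parabelt, `"TB"` between
#' thalamus and belt.  Their normalised counterparts `"CPN"` and `"TBN"`
#' rescale `W_ee` uniformly so that its element sum (the norm used for the
#' excitation-inhibition balance) equals that of the serial network.
#'
#' MEG weighting: only cortical rows of `K1`/`K2` are non-zero (subcortical
#' areas do not generate a measurable field), but the thalamus-to-core
#' feedforward connection does contribute because its synapses terminate in
#' cortex.  An added shortcut receives the generic multiplier of its class
#' (`k1_ff` feedforward, `k1_fb` feedback) when it lands on a cortical row,
#' and zero otherwise.
#'
#' @param params an [ac_params()] object.
#' @param variant one of `"DEF"`, `"CP"`, `"TB"`, `"CPN"`, `"TBN"`.
#' @param directions whether an added shortcut is feedforward-only
#'   (`"forward"`, default) or bidirectional (`"both"`).  The feedforward-only
#'   default reproduces the reported magnitude of the excitation effect on
#'   the adaptation lifetime (about half a second); see the methods vignette.
#' @param added_ff,added_fb weights of the added feedforward/feedback
#'   connection in the CP/TB families; default to the generic serial-network
#'   values `w_ee_ff` and `w_ee_fb`.
#' @return An object of class `ac_network` with elements `N`, `areas`,
#'   `W_ee`, `W_ei`, `W_ie`, `W_ii`, `K1`, `K2`, `adapting`, `variant`,
#'   `params`.
#' @examples
#' net <- build_network(ac_params())
#' sum(net$W_ee)               # 13.6 for the serial network
#' net$W_ee["belt", "core"]    # feedforward core -> belt
#' @export
build_network <- function(params = ac_params(),
                          variant = c("DEF", "CP", "TB", "CPN", "TBN"),
                          directions = c("forward", "both"),
                          added_ff = params$w_ee_ff,
                          added_fb = params$w_ee_fb) {
  stopifnot(inherits(params, "ac_params"))
  variant <- match.arg(variant)
  directions <- match.arg(directions)
  N <- .N_AREAS
  lab <- ac_areas

  W_ee <- matrix(0, N, N, dimnames = list(lab, lab))
  diag(W_ee) <- params$w_ee_d
  for (i in seq_len(N - 1L)) {
    W_ee[i + 1L, i] <- params$w_ee_ff   # feedforward i -> i+1
    W_ee[i, i + 1L] <- params$w_ee_fb   # feedback  i+1 -> i
  }
  def_sum <- sum(W_ee)

  dmat <- function(w) matrix(diag(w, N), N, N, dimnames = list(lab, lab))
  W_ei <- dmat(params$w_ei_d)
  W_ie <- dmat(params$w_ie_d)
  W_ii <- dmat(params$w_ii_d)

  K1 <- matrix(0, N, N, dimnames = list(lab, lab))
  for (i in .CORTICAL) {
    K1[i, i] <- params$k1_d
    K1[i, i - 1L] <- params$k1_ff            # includes thalamus -> core
    if (i + 1L <= N) K1[i, i + 1L] <- params$k1_fb
  }
  K2 <- matrix(0, N, N, dimnames = list(lab, lab))
  diag(K2)[.CORTICAL] <- params$k2_d

  add_shortcut <- function(W, K1, from, to) {
    # 'from' is the lower (earlier) area; from -> to is feedforward
    W[to, from] <- W[to, from] + added_ff
    if (to %in% .CORTICAL) K1[to, from] <- params$k1_ff
    if (directions == "both") {
      W[from, to] <- W[from, to] + added_fb
      if (from %in% .CORTICAL) K1[from, to] <- params$k1_fb
    }
    list(W = W, K1 = K1)
  }
  base <- substr(variant, 1L, 2L)
  if (base == "CP") {
    m <- add_shortcut(W_ee, K1, from = 3L, to = 5L)
    W_ee <- m$W; K1 <- m$K1
  } else if (base == "TB") {
    m <- add_shortcut(W_ee, K1, from = 2L, to = 4L)
    W_ee <- m$W; K1 <- m$K1
  }
  if (variant %in% c("CPN", "TBN"))
    W_ee <- W_ee * (def_sum / sum(W_ee))

  structure(list(N = N, areas = lab,
                 W_ee = W_ee, W_ei = W_ei, W_ie = W_ie, W_ii = W_ii,
                 K1 = K1, K2 = K2,
                 adapting = stats::setNames(seq_len(N) %in% .CORTICAL, lab),
                 variant = variant, params = params),
            class = "ac_network")
}

#' @rdname build_network
#' @export
build_default_network <- function(params = ac_params()) {
  build_network(params, variant = "DEF")
}

#' @export
print.ac_network <- function(x, ...) {
  cat("Auditory-cortex network (variant ", x$variant, ", ", x$N,
      " areas)\n", sep = "")
  cat("  areas:", paste(x$areas, collapse = ", "), "\n")
  cat("  sum(W_ee) =", format(sum(x$W_ee), digits = 10),
      "; adapting:", paste(x$areas[x$adapting], collapse = ", "), "\n")
  invisible(x)
}

#' Export the topology matrices as CSV files
#'
#' Writes one CSV per matrix (`W_ee`, `W_ei`, `W_ie`, `W_ii`, `K1`, `K2`),
#' with area labels as header row and first column.
#'
#' @param net an `ac_network`.
#' @param dir output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_topology <- function(net, dir) {
  stopifnot(inherits(net, "ac_network"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  mats <- c("W_ee", "W_ei", "W_ie", "W_ii", "K1", "K2")
  paths <- character(0)
  for (m in mats) {
    path <- file.path(dir, paste0(tolower(m), ".csv"))
    utils::write.csv(net[[m]], path, row.names = TRUE)
    paths <- c(paths, path)
  }
  invisible(paths)
}
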