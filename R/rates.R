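# Transition-rate law of the 24-state regulatory unit.
#
# Only single-component transitions are allowed: exactly one of (ca, sp, ip,
# tpm) may change, and tropomyosin may only step between adjacent positions
# (B<->C, C<->M; the direct B<->M jump is forbidden). Troponin coupling is
# thermodynamically closed: eta ties calcium binding to switch-peptide
# docking, mu ties the switch peptide to the inhibitory peptide, so every
# troponin 4-cycle satisfies detailed balance by construction.
#
# Tropomyosin mobility is gated by troponin: both forward shifts (B->C and
# C->M) run at full rate only while the unit is switched and released (sp
# docked on TnC, ip off actin) and are attenuated by lam otherwise.
# Nearest-neighbor (chain-stiffness) coupling enters three ways: the B<->C
# rates carry exp(-(gamma/RT)*Delta) with Delta the change in summed
# azimuthal distance to the neighbors (cooperative inhibition), each
# M-state neighbor adds f_XY to the C->M rate, and each M-state neighbor
# retards the M->C rate by exp(-gamma/RT) (an open stretch of tropomyosin
# holds itself open).

# Normalize a neighbor argument ("B"/"C"/"M", 0..2, NA or NULL) to integer/NA
nbr_to_x <- function(nbr) {
  if (is.null(nbr) || length(nbr) == 0L || is.na(nbr)) return(NA_integer_)
  if (is.character(nbr)) {
    x <- match(nbr, TPM_LEVELS) - 1L
    if (is.na(x)) stop("unknown neighbor tpm position '", nbr, "'")
    x
  } else {
    x <- as.integer(nbr)
    if (x < 0L || x > 2L) stop("neighbor tpm position index must be 0..2")
    x
  }
}

#' Transition rate between two regulatory-unit states
#'
#' Evaluates the model's rate law for a single regulatory unit embedded in a
#' filament, given the tropomyosin positions of its nearest neighbors and
#' the calcium concentration. Transitions that change more than one state
#' component, or jump tropomyosin directly between B and M, have rate 0.
#'
#' The law is: calcium binds at `kCa_plus * ca` and unbinds at `kCa_minus`
#' (divided by `eta` while the switch peptide is docked); the switch peptide
#' docks at `kSP_plus` (times `eta` with calcium bound, divided by `mu` with
#' the inhibitory peptide bound) and undocks at `kSP_minus`; the inhibitory
#' peptide binds at `kIP_plus` (divided by `mu` while the switch peptide is
#' docked) and unbinds at `kIP_minus`. Tropomyosin shifts B-to-C at
#' `kref_BC * K_BC^delta * exp(-(gamma/RT) * D)` and C-to-B at
#' `kref_BC * K_BC^(delta-1) * exp(-(gamma/RT) * D')`, where `D` (`D'`) is
#' the change in summed azimuthal distance between this tropomyosin's
#' position index (B=0, C=1, M=2) and its present neighbors' positions, so
#' the B/C ratio is `K_BC` exactly when the coupling terms cancel. Myosin
#' binds (C-to-M) at `kMD_plus + f_XY * nM` and detaches (M-to-C) at
#' `kMD_minus * exp(-(gamma/RT) * nM)`, with `nM` the number of present
#' M-state neighbors: through the end-to-end overlap an open tropomyosin
#' both promotes its neighbors' opening and is held open by them. Both
#' forward shifts (B-to-C and C-to-M) run at full rate only while troponin
#' is switched and released (`sp = 1`, `ip = 0`) and carry the factor
#' `lam` otherwise.
#'
#' @param from,to state indices in 1..24 (see [ru_states()], [ru_state()]).
#' @param params a [param_set()].
#' @param ca calcium concentration in micromolar (>= 0).
#' @param left,right tropomyosin position of the left/right neighbor
#'   (`"B"`, `"C"`, `"M"` or 0/1/2), or `NA`/`NULL` for a chain end.
#' @return The transition rate in 1/s (0 for forbidden transitions).
#' @examples
#' p <- thinfil_params("set1")
#' # switched-and-released unit, no neighbors: the bare B -> C rate
#' b <- ru_state(0, 1, 0, "B"); c0 <- ru_state(0, 1, 0, "C")
#' transition_rate(b, c0, p, ca = 0.1)   # 675 * 2.3^0.48
#' @export
transition_rate <- function(from, to, params, ca, left = NA, right = NA) {
  stopifnot(inherits(params, "tf_params"))
  if (!is.finite(ca) || ca < 0) stop("ca must be a finite value >= 0")
  f <- state_components(from)
  t <- state_components(to)
  if (from == to) stop("from and to must differ")
  ndiff <- (f$ca != t$ca) + (f$sp != t$sp) + (f$ip != t$ip) + (f$x != t$x)
  if (ndiff != 1L) return(0)

  p <- params
  if (f$ca != t$ca) {
    if (t$ca == 1L) return(p$kCa_plus * ca)
    r <- p$kCa_minus
    if (f$sp == 1L) r <- r / p$eta
    return(r)
  }
  if (f$sp != t$sp) {
    if (t$sp == 1L) {
      r <- p$kSP_plus
      if (f$ca == 1L) r <- r * p$eta
      if (f$ip == 1L) r <- r / p$mu
      return(r)
    }
    return(p$kSP_minus)
  }
  if (f$ip != t$ip) {
    if (t$ip == 1L) {
      r <- p$kIP_plus
      if (f$sp == 1L) r <- r / p$mu
      return(r)
    }
    return(p$kIP_minus)
  }
  # tropomyosin move
  if (abs(f$x - t$x) != 1L) return(0)  # direct B<->M forbidden
  nbr <- c(nbr_to_x(left), nbr_to_x(right))
  nbr <- nbr[!is.na(nbr)]
  n_m <- sum(nbr == 2L)
  g <- p$gamma / p$rt
  gate <- if (f$sp == 1L && f$ip == 0L) 1 else p$lam
  if (f$x == 0L && t$x == 1L) {        # B -> C
    d <- sum(abs(1 - nbr)) - sum(abs(0 - nbr))
    return(p$kref_BC * p$K_BC^p$delta * gate * exp(-g * d))
  }
  if (f$x == 1L && t$x == 0L) {        # C -> B
    d <- sum(abs(0 - nbr)) - sum(abs(1 - nbr))
    return(p$kref_BC * p$K_BC^(p$delta - 1) * exp(-g * d))
  }
  if (f$x == 1L && t$x == 2L)          # C -> M
    return((p$kMD_plus + p$f_XY * n_m) * gate)
  p$kMD_minus * exp(-g * n_m)          # M -> C
}

# All outgoing transitions from state `from` (index 1..24) as a data frame
# (to, rate). Shared by the master-equation oracle and transition tests.
unit_transitions <- function(from, params, ca, left = NA, right = NA) {
  f <- state_components(from)
  cand <- integer(0)
  flip <- function(ca_, sp_, ip_, x_) ca_ * 12L + sp_ * 6L + ip_ * 3L + x_ + 1L
  cand <- c(cand, flip(1L - f$ca, f$sp, f$ip, f$x),
            flip(f$ca, 1L - f$sp, f$ip, f$x),
            flip(f$ca, f$sp, 1L - f$ip, f$x))
  if (f$x > 0L) cand <- c(cand, flip(f$ca, f$sp, f$ip, f$x - 1L))
  if (f$x < 2L) cand <- c(cand, flip(f$ca, f$sp, f$ip, f$x + 1L))
  rate <- vapply(cand, function(tt)
    transition_rate(from, tt, params, ca, left, right), numeric(1))
  data.frame(to = cand, rate = rate)
}
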