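#' @useDynLib thinfil, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Tropomyosin azimuthal positions and their numeric coordinates used by the
# nearest-neighbor coupling rule: x(B)=0, x(C)=1, x(M)=2.
TPM_LEVELS <- c("B", "C", "M")

#' Enumerate the 24 regulatory-unit states
#'
#' Each regulatory unit of the thin filament is described by four components:
#' calcium bound to the troponin C regulatory site (`ca`), the troponin I
#' switch peptide docked on the TnC N-lobe (`sp`), the troponin I inhibitory
#' peptide bound to actin (`ip`), and the azimuthal position of tropomyosin
#' (`tpm`, one of blocked `B`, closed `C`, open/myosin-bound `M`). The
#' product space has 2 x 2 x 2 x 3 = 24 states.
#'
#' The ordering is lexicographic in (`ca`, `sp`, `ip`, `tpm`) with `ca` most
#' significant and `tpm` ordered B < C < M. This ordering is frozen: state
#' indices returned by [ru_state()] and used throughout the package refer to
#' rows of this table.
#'
#' @return A data frame with 24 rows and columns `ca`, `sp`, `ip` (0/1
#'   integers) and `tpm` (character, `"B"`, `"C"` or `"M"`), plus an `x`
#'   column giving the numeric tropomyosin position.
#' @examples
#' s <- ru_states()
#' nrow(s)                      # 24
#' sum(s$tpm == "M")            # 8
#' @export
ru_states <- function() {
  g <- expand.grid(tpm = TPM_LEVELS, ip = 0:1, sp = 0:1, ca = 0:1,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  s <- data.frame(ca = g$ca, sp = g$sp, ip = g$ip, tpm = g$tpm,
                  stringsAsFactors = FALSE)
  s$x <- match(s$tpm, TPM_LEVELS) - 1L
  s
}

#' Index of a regulatory-unit state
#'
#' Maps the four state components to the 1-based row index of [ru_states()].
#'
#' @param ca,sp,ip 0 or 1: calcium on TnC, TnI switch peptide on TnC, TnI
#'   inhibitory peptide on actin.
#' @param tpm tropomyosin position, `"B"`, `"C"` or `"M"` (or 0/1/2).
#' @return Integer index in 1..24 (vectorized over the arguments).
#' @examples
#' ru_state(ca = 0, sp = 0, ip = 1, tpm = "B")  # the resting/diastolic state
#' @export
ru_state <- function(ca, sp, ip, tpm) {
  if (is.character(tpm)) {
    xt <- match(tpm, TPM_LEVELS) - 1L
    if (anyNA(xt)) stop("unknown tpm position; must be one of B, C, M")
  } else {
    xt <- as.integer(tpm)
    if (any(xt < 0L | xt > 2L)) stop("tpm position index must be 0, 1 or 2")
  }
  ca <- as.integer(ca); sp <- as.integer(sp); ip <- as.integer(ip)
  if (any(c(ca, sp, ip) < 0L) || any(c(ca, sp, ip) > 1L))
    stop("ca, sp and ip must be 0 or 1")
  ca * 12L + sp * 6L + ip * 3L + xt + 1L
}

# Internal: integer (0..2) tpm position of state index (1..24)
state_tpm_x <- function(idx) (as.integer(idx) - 1L) %% 3L

# Internal: decompose a state index into its components
state_components <- function(idx) {
  i <- as.integer(idx) - 1L
  if (any(i < 0L | i > 23L)) stop("state index out of range 1..24")
  list(ca = i %/% 12L, sp = (i %/% 6L) %% 2L, ip = (i %/% 3L) %% 2L,
       x = i %% 3L)
}
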