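# Gas constant times temperature (~300 K), J/mol; converts the chain
# coupling energy gamma (J/mol) to the dimensionless exponent used by the
# neighbor-coupling factor.
RT_DEFAULT <- 2494

PARAM_RATE_FIELDS <- c("kCa_plus", "kCa_minus", "kSP_plus", "kSP_minus",
                       "kIP_plus", "kIP_minus", "kMD_plus", "kMD_minus",
                       "kref_BC", "f_XY")
PARAM_FIELDS <- c(PARAM_RATE_FIELDS,
                  c("K_BC", "delta", "lam", "eta", "mu", "gamma"))

#' Construct a thin-filament parameter set
#'
#' Bundles all rate constants and coupling coefficients of the 24-state
#' regulatory-unit model for one genotype condition. Rates are per second
#' (`kCa_plus` per micromolar per second); `K_BC` is the dimensionless
#' equilibrium constant of the tropomyosin B-to-C transition absent TnI
#' inhibition; `delta` positions the B/C energy barrier (the forward rate
#' carries `K_BC^delta`, the reverse `K_BC^(delta-1)`); `lam` attenuates both
#' forward tropomyosin shifts (B-to-C and C-to-M) except while troponin is
#' switched and released (switch peptide docked, inhibitory peptide off
#' actin); `eta` couples
#' calcium binding to switch-peptide docking and `mu` couples the switch and
#' inhibitory peptides (both >= 1 intensify the coupling); `gamma` is the
#' effective tropomyosin chain-stiffness energy in J/mol, converted to a
#' dimensionless exponent by dividing by `rt`.
#'
#' @param kCa_plus,kCa_minus calcium on/off rates for the TnC regulatory site.
#' @param kSP_plus,kSP_minus TnI switch peptide docking/undocking rates.
#' @param kIP_plus,kIP_minus TnI inhibitory peptide binding/unbinding rates.
#' @param kMD_plus,kMD_minus tropomyosin C-to-M (myosin binding) and M-to-C
#'   rates.
#' @param kref_BC reference tropomyosin B/C transition rate (1/s).
#' @param K_BC B-to-C equilibrium constant (dimensionless, > 0).
#' @param f_XY crossbridge-mediated cooperative attachment rate (1/s), added
#'   to the C-to-M rate once per neighbor already in the M state.
#' @param delta barrier position in `[0, 1]`.
#' @param lam attenuation in `(0, 1]` of the troponin-inhibited forward
#'   tropomyosin shifts.
#' @param eta,mu dimensionless troponin coupling factors (>= 1).
#' @param gamma nearest-neighbor tropomyosin coupling (chain-stiffness)
#'   energy, J/mol; scales the B/C neighbor-coupling exponent and the
#'   M-state holding factor `exp(-gamma/rt)` per myosin-bound neighbor.
#' @param n_units number of regulatory units in the simulated filament.
#' @param rt thermal energy scale RT in J/mol used to non-dimensionalize
#'   `gamma`.
#' @return An object of class `tf_params` (a named list).
#' @seealso [thinfil_params()] for the packaged parameter sets,
#'   [apply_mutation()] for mutation scalings.
#' @export
param_set <- function(kCa_plus, kCa_minus, kSP_plus, kSP_minus,
                      kIP_plus, kIP_minus, kMD_plus, kMD_minus,
                      kref_BC, K_BC, f_XY, delta, lam, eta, mu, gamma,
                      n_units = 26L, rt = RT_DEFAULT) {
  p <- list(kCa_plus = kCa_plus, kCa_minus = kCa_minus,
            kSP_plus = kSP_plus, kSP_minus = kSP_minus,
            kIP_plus = kIP_plus, kIP_minus = kIP_minus,
            kMD_plus = kMD_plus, kMD_minus = kMD_minus,
            kref_BC = kref_BC, K_BC = K_BC, f_XY = f_XY,
            delta = delta, lam = lam, eta = eta, mu = mu, gamma = gamma,
            n_units = as.integer(n_units), rt = rt)
  validate_params(p)
  class(p) <- "tf_params"
  p
}

validate_params <- function(p) {
  for (f in c(PARAM_FIELDS, "n_units", "rt")) {
    v <- p[[f]]
    if (is.null(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", f, "' must be a single finite number")
  }
  for (f in PARAM_RATE_FIELDS)
    if (p[[f]] < 0) stop("rate constant '", f, "' must be >= 0")
  if (p$K_BC <= 0) stop("K_BC must be > 0")
  if (p$delta < 0 || p$delta > 1) stop("delta must lie in [0, 1]")
  if (p$lam <= 0 || p$lam > 1) stop("lam must lie in (0, 1]")
  if (p$eta < 1 || p$mu < 1) stop("eta and mu must be >= 1")
  if (p$n_units < 1L) stop("n_units must be >= 1")
  if (p$rt <= 0) stop("rt must be > 0")
  invisible(p)
}

#' @export
print.tf_params <- function(x, ...) {
  cat("Thin-filament parameter set (", x$n_units, " regulatory units)\n",
      sep = "")
  vals <- unlist(x[PARAM_FIELDS])
  for (f in names(vals)) cat(sprintf("  %-10s %g\n", f, vals[[f]]))
  cat(sprintf("  gamma/RT   %.4g (RT = %g J/mol)\n", x$gamma / x$rt, x$rt))
  invisible(x)
}

#' Packaged parameter sets
#'
#' Loads one of the two packaged parameter fixtures: `"set1"`, calibrated for
#' steady-state force-pCa behavior, or `"set2"`, calibrated for twitch
#' kinetics of a representative human engineered heart tissue.
#'
#' @param which `"set1"` or `"set2"`.
#' @param n_units number of regulatory units (default 26).
#' @return A [param_set()] object.
#' @examples
#' p <- thinfil_params("set1")
#' p$K_BC   # 2.3
#' @export
thinfil_params <- function(which = c("set1", "set2"), n_units = 26L) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0(which, ".json"), package = "thinfil",
                      mustWork = TRUE)
  p <- read_param_set(path)
  p$n_units <- as.integer(n_units)
  p
}

#' Specify a tropomyosin mutation
#'
#' A mutation is represented as multiplicative scalings of the chain
#' stiffness `gamma` and the B/C equilibrium `K_BC`, applied in proportion to
#' the fraction of mutant tropomyosin incorporated (`expression`). The
#' default scalings are those fitted for the dilated-cardiomyopathy variant
#' TPM1 M8R: gamma halved and K_BC reduced by 26%.
#'
#' @param gamma_scale multiplicative factor on `gamma` at 100% expression.
#' @param kbc_scale multiplicative factor on `K_BC` at 100% expression.
#' @param expression fraction of mutant tropomyosin in `[0, 1]`.
#' @return An object of class `tf_mutation`.
#' @export
mutation_spec <- function(gamma_scale = 0.5, kbc_scale = 0.74,
                          expression = 1) {
  if (!is.finite(gamma_scale) || gamma_scale <= 0)
    stop("gamma_scale must be > 0")
  if (!is.finite(kbc_scale) || kbc_scale <= 0)
    stop("kbc_scale must be > 0")
  if (!is.finite(expression) || expression < 0 || expression > 1)
    stop("expression must lie in [0, 1]")
  structure(list(gamma_scale = gamma_scale, kbc_scale = kbc_scale,
                 expression = expression),
            class = "tf_mutation")
}

#' Apply a mutation to a wild-type parameter set
#'
#' Interpolates linearly between wild-type and fully mutant parameter values
#' in proportion to the mutant expression fraction: a scaled field `v`
#' becomes `v * (1 - e + e * scale)` at expression `e`. Only `gamma` and
#' `K_BC` are affected; all other fields are returned unchanged.
#'
#' @param wt wild-type [param_set()].
#' @param spec a [mutation_spec()].
#' @return A new `tf_params` object.
#' @examples
#' wt <- thinfil_params("set1")
#' m8r <- apply_mutation(wt, mutation_spec(0.5, 0.74, expression = 1))
#' m8r$K_BC  # ~1.70
#' @export
apply_mutation <- function(wt, spec) {
  stopifnot(inherits(wt, "tf_params"), inherits(spec, "tf_mutation"))
  e <- spec$expression
  out <- wt
  out$gamma <- wt$gamma * (1 - e + e * spec$gamma_scale)
  out$K_BC <- wt$K_BC * (1 - e + e * spec$kbc_scale)
  validate_params(out)
  out
}
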