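#' Gyromagnetic ratios used for coherence-transfer-pathway gradient ratios
#'
#' Values in rad s^-1 T^-1 for 1H, 13C and 15N.  The sign of the 15N ratio is
#' negative; CTP gradient amplitudes use the magnitude of the ratio.
#'
#' @return Named numeric vector with elements `H1`, `C13`, `N15`.
#' @export
#' @examples
#' r <- gyromagnetic_ratios()
#' abs(r[["N15"]] / r[["H1"]])   # ~0.1014
gyromagnetic_ratios <- function() {
  c(H1 = 26.7522128e7, C13 = 6.728284e7, N15 = -2.7126e7)
}

#' Scalar coupling constants used to derive transfer delays
#'
#' Container for the three coupling constants that parameterise the INEPT-type
#' and long-range transfer delays of the heteronuclear modules.  Defaults are
#' the conventional small-molecule values; all must be strictly positive (in
#' Hz).
#'
#' @param one_bond_JCH One-bond 1H-13C coupling in Hz (the `cnst2` role).
#' @param long_range_JCH Long-range (n-bond) 1H-13C coupling in Hz.
#' @param one_bond_JNH One-bond 1H-15N coupling in Hz.
#' @return An object of class `noah_couplings`.
#' @export
#' @examples
#' coupling_constants(one_bond_JCH = 146)
coupling_constants <- function(one_bond_JCH = 145,
                               long_range_JCH = 5,
                               one_bond_JNH = 90) {
  vals <- c(one_bond_JCH = one_bond_JCH,
            long_range_JCH = long_range_JCH,
            one_bond_JNH = one_bond_JNH)
  if (!is.numeric(vals) || anyNA(vals) || any(vals <= 0)) {
    noah_abort("all coupling constants must be strictly positive (Hz)",
               "noah_nonpositive_coupling")
  }
  structure(as.list(vals), class = "noah_couplings")
}

#' @export
print.noah_couplings <- function(x, ...) {
  cat(sprintf("<couplings> 1J(CH) = %g Hz, nJ(CH) = %g Hz, 1J(NH) = %g Hz\n",
              x$one_bond_JCH, x$long_range_JCH, x$one_bond_JNH))
  invisible(x)
}

#' Compute the standard transfer delays from coupling constants
#'
#' The one-bond 1H-13C transfer delay is Delta = 1/(4 * 1J(CH)), the
#' long-range HMBC evolution delay is Delta_LR = 1/(2 * nJ(CH)), and the
#' analogous 15N delay is Delta_N = 1/(4 * 1J(NH)).  All values are returned
#' in seconds.
#'
#' @param constants A [coupling_constants()] object.
#' @return Named list with elements `delta`, `delta_lr`, `delta_n` (seconds).
#' @export
#' @examples
#' compute_delays(coupling_constants(one_bond_JCH = 146))$delta * 1e3  # 1.7123 ms
compute_delays <- function(constants = coupling_constants()) {
  if (!inherits(constants, "noah_couplings")) {
    constants <- do.call(coupling_constants, as.list(constants))
  }
  list(delta    = 1 / (4 * constants$one_bond_JCH),
       delta_lr = 1 / (2 * constants$long_range_JCH),
       delta_n  = 1 / (4 * constants$one_bond_JNH))
}

#' Refocusing gradient amplitude for a CTP selection scheme
#'
#' For a heteronuclear module whose t1 period is bracketed by `n_gradients`
#' PFGs of amplitude `g1_amplitude`, the final refocusing gradient must have
#' amplitude `n * g1 * |gamma_X / gamma_H|`.  The per-gradient contribution is
#' rounded to one decimal place (the precision at which gradient amplitudes
#' are set) before multiplying by the number of gradients.
#'
#' @param g1_amplitude Encoding gradient amplitude, percent of maximum
#'   gradient strength; must be in (0, 100].
#' @param gamma_ratio Ratio of gyromagnetic ratios (heteronucleus over 1H);
#'   the magnitude is used.
#' @param n_gradients Number of PFGs bracketing the t1 period (>= 1).
#' @return Refocusing amplitude in percent.
#' @export
#' @examples
#' r <- gyromagnetic_ratios()
#' ctp_gradient_amplitude(80, r[["N15"]] / r[["H1"]], 1)  # 8.1
ctp_gradient_amplitude <- function(g1_amplitude, gamma_ratio, n_gradients) {
  noah_stopifnot(is.numeric(n_gradients) && length(n_gradients) == 1 &&
                   n_gradients >= 1 && n_gradients == as.integer(n_gradients),
                 "n_gradients must be an integer >= 1")
  noah_stopifnot(is.numeric(g1_amplitude) && length(g1_amplitude) == 1 &&
                   g1_amplitude > 0 && g1_amplitude <= 100,
                 "g1_amplitude must be in (0, 100] percent")
  n_gradients * round(g1_amplitude * abs(gamma_ratio), 1)
}
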