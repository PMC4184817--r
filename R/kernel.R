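#' Biphasic flavoprotein response kernel
#'
#' Closed-form temporal kernel of the flavoprotein transient: oxidation of
#' mitochondrial flavoproteins brightens the tissue immediately after
#' stimulation (light phase) and the subsequent reduction darkens it below
#' baseline (dark phase).  The kernel is
#'
#' \deqn{k(t) = a\left[(1 - e^{-t/\tau_1})e^{-t/\tau_2}
#'            - u(1 - e^{-t/\tau_2})e^{-t/\tau_3}\right]}
#'
#' with rise constant `tau1`, light-phase decay `tau2`, undershoot fraction
#' `u` and undershoot decay `tau3`.  `k(0) = 0`; for `u > 0` the curve has a
#' single positive peak followed by a single sub-baseline trough; for
#' `u = 0` it is non-negative everywhere (no dark phase).  `t < 0` maps
#' to 0.
#'
#' @param t seconds since stimulus onset (vectorized; negative values give 0).
#' @param a amplitude scale (fractional dF/F).
#' @param tau1 rise time constant, seconds (> 0).
#' @param tau2 light-phase decay constant, seconds (> 0).
#' @param tau3 undershoot decay constant, seconds (> 0).
#' @param u undershoot fraction in [0, 1).
#' @return numeric vector of fractional dF/F values.
#' @examples
#' curve(biphasicKernel(x, a = 0.005), 0, 40, xlab = "s", ylab = "dF/F")
#' @export
biphasicKernel <- function(t, a = 1, tau1 = 1, tau2 = 6, tau3 = 10, u = 0.6) {
  stopifnot(tau1 > 0, tau2 > 0, tau3 > 0, u >= 0, u < 1)
  tp <- pmax(t, 0)
  k <- a * ((1 - exp(-tp / tau1)) * exp(-tp / tau2) -
            u * (1 - exp(-tp / tau2)) * exp(-tp / tau3))
  k[t < 0] <- 0
  k
}
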