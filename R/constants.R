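#' Physical constants for phase-based MREPT
#'
#' Bundles the vacuum permeability and the Larmor angular frequency used in
#' the phase-based conductivity relation \eqn{\sigma \approx \nabla^2
#' \varphi_\pm / (2 \mu_0 \omega)}. The default Larmor frequency of
#' 127.76 MHz corresponds to proton imaging at 3 T.
#'
#' @param larmor_freq_hz Larmor frequency in Hz. Default `127.76e6` (3 T).
#' @return An object of class `ept_constants`: a list with elements `mu0`
#'   (H/m), `larmor_freq_hz` (Hz), `omega` (rad/s, always exactly
#'   `2 * pi * larmor_freq_hz`) and `two_mu0_omega` (the scale factor
#'   relating a phase Laplacian in rad/m^2 to conductivity in S/m; about
#'   2017.7 at 3 T).
#' @examples
#' k <- ept_constants()
#' k$two_mu0_omega   # ~2017.7: a Laplacian of 2017.7 rad/m^2 is 1 S/m
#' @export
ept_constants <- function(larmor_freq_hz = 127.76e6) {
  stopifnot(is.numeric(larmor_freq_hz), length(larmor_freq_hz) == 1L,
            is.finite(larmor_freq_hz), larmor_freq_hz > 0)
  mu0 <- 4e-7 * pi
  omega <- 2 * pi * larmor_freq_hz
  structure(
    list(mu0 = mu0, larmor_freq_hz = larmor_freq_hz, omega = omega,
         two_mu0_omega = 2 * mu0 * omega),
    class = "ept_constants"
  )
}

#' @export
print.ept_constants <- function(x, ...) {
  cat(sprintf("MREPT constants: f0 = %.4g MHz, omega = %.6g rad/s, 2*mu0*omega = %.6g\n",
              x$larmor_freq_hz / 1e6, x$omega, x$two_mu0_omega))
  invisible(x)
}
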