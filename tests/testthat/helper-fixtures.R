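# shared fixtures, all generated in code

# separable quadratic field a*(x^2+y^2+z^2) in rad with x,y,z in mm
quadratic_phase <- function(n = 16, a = 1.8e-4, spacing = c(1, 1, 1)) {
  co <- lapply(1:3, function(d) ((0:(n - 1)) * spacing[d])^2)
  v <- outer(outer(co[[1]], co[[2]], `+`), co[[3]], `+`) * a
  phase_volume(v, spacing)
}

uniform_labels <- function(n = 16) label_map(array(1L, c(n, n, n)))
uniform_magnitude <- function(n = 16) magnitude_volume(array(1, c(n, n, n)))

# analytic Laplacian of quadratic_phase in rad/m^2: 6a rad/mm^2 = 6a*1e6
quadratic_laplacian <- function(a = 1.8e-4) 6 * a * 1e6

# small saline phantom with forward phase attached
phantom_with_phase <- function(n = 48, snr = NULL, seed = 1L) {
  ds <- make_phantom(saline_phantom_spec(c(n, n, n)))
  ds$phase_true <- solve_forward_phase(ds$sigma_true)
  if (is.null(snr)) {
    ds$phase_wrapped <- wrap_phase(ds$phase_true)
  } else {
    ds <- add_complex_noise(ds, snr, seed = seed)
  }
  ds
}

# independent value of 2*mu0*omega at 3 T, written out from first principles
TWO_MU0_OMEGA <- 2 * (4 * pi * 1e-7) * (2 * pi * 127.76e6)

# circular difference in (-pi, pi]
circ_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}
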