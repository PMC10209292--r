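test_that("one-sided parabola fit is exact on polynomials in its model class", {
  h <- 1e-3
  t <- c(0, 1, 2, 3) * h
  f <- one_sided_parabola_fit(t, 5 * (t / h)^2)
  expect_equal(f$second_derivative, 10 / h^2, tolerance = 1e-9)
  expect_equal(f$correlation, 1)
  lin <- one_sided_parabola_fit(t, 7 * t)
  expect_equal(lin$second_derivative, 0, tolerance = 1e-6)
})

test_that("least-squares coefficients match an lm() oracle on a cubic", {
  t <- c(0, 1, 2, 3, 4)
  y <- t^3
  fit <- one_sided_parabola_fit(t, y)
  oracle <- lm(y ~ t + I(t^2))
  expect_equal(fit$second_derivative, 2 * unname(coef(oracle)[3]),
               tolerance = 1e-9)
  expect_equal(fit$fitted, unname(fitted(oracle)), tolerance = 1e-9)
  expect_equal(fit$correlation, unname(cor(fitted(oracle), y)),
               tolerance = 1e-9)
})

test_that("a separable quadratic yields its analytic Laplacian exactly", {
  n <- 16
  a <- 1.8e-4
  lap <- average_parabolic_laplacian(quadratic_phase(n, a),
                                     uniform_labels(n), uniform_magnitude(n))
  expect_true(all(lap$valid))
  expect_lt(max(abs(lap$values - quadratic_laplacian(a))), 1e-6)
  # and the C++ kernel agrees with the scalar R fit on one profile
  h <- 1e-3
  prof <- quadratic_phase(n, a)$values[8:12, 8, 8]
  f <- one_sided_parabola_fit((0:4) * h, prof)
  expect_equal(f$second_derivative, 2 * a * 1e6, tolerance = 1e-6)
})

test_that("kernels never cross a tissue-label boundary", {
  n <- 24
  ph <- quadratic_phase(n)
  labs <- array(0L, c(n, n, n))
  co <- 0:(n - 1)
  cyl <- outer((co - 11.5)^2, (co - 11.5)^2, `+`) <= 64
  labs[cyl] <- 1L
  labs <- label_map(array(labs, c(n, n, n)))
  mag <- uniform_magnitude(n)
  base <- average_parabolic_laplacian(ph, labs, mag)
  # arbitrary perturbation of the background phase leaves the compartment
  # untouched
  pert <- ph
  pert$values[labs$values == 0L] <- pert$values[labs$values == 0L] +
    10 * sin(seq_len(sum(labs$values == 0L)))
  after <- average_parabolic_laplacian(pert, labs, mag)
  sel <- labs$values == 1L
  expect_identical(base$values[sel], after$values[sel])
  expect_identical(base$valid[sel], after$valid[sel])
})

test_that("amplitude restriction excludes bright neighbours from the kernel", {
  n <- 12
  ph <- quadratic_phase(n)
  labs <- uniform_labels(n)
  mag <- array(1, c(n, n, n))
  mag[7:n, , ] <- 2                      # bright half
  base <- average_parabolic_laplacian(ph, labs, magnitude_volume(mag))
  pert <- ph
  pert$values[7:n, , ] <- -5             # corrupt the bright half
  after <- average_parabolic_laplacian(pert, labs, magnitude_volume(mag))
  sel <- array(FALSE, c(n, n, n))
  sel[1:2, 3:10, 3:10] <- TRUE           # kernels cannot reach the bright half
  expect_identical(base$values[sel], after$values[sel])
})

test_that("white-noise phase fails the correlation acceptance at most voxels", {
  set.seed(3)
  n <- 24
  ph <- phase_volume(array(rnorm(n^3), c(n, n, n)))
  lap <- average_parabolic_laplacian(ph, uniform_labels(n),
                                     uniform_magnitude(n))
  interior <- erode_mask(array(TRUE, c(n, n, n)), c(4, 4, 2))
  expect_gt(mean(!lap$valid[interior]), 0.5)
})

test_that("conductivity conversion applies sigma = lap / (2 mu0 omega)", {
  v <- array(c(TWO_MU0_OMEGA, 0, 1089.6, 2017.7), c(4, 1, 1))
  lap <- laplacian_map(v, array(TRUE, c(4, 1, 1)))
  sig <- conductivity_from_laplacian(lap)
  expect_equal(as.vector(sig$values)[1:2], c(1, 0))
  expect_equal(round(as.vector(sig$values)[3], 3), 0.540)
  expect_equal(round(as.vector(sig$values)[4], 3), 1.000)
})

test_that("parabolic and stencil Laplacians agree on smooth band-limited phase", {
  n <- 32
  co <- (0:(n - 1)) / n
  v <- 0.5 * sin(pi * outer(outer(co, co * 0, `+`), co * 0, `+`)) +
    0.3 * cos(pi * outer(outer(co * 0, co, `+`), co * 0.5, `+`))
  v <- array(v, c(n, n, n))
  ph <- phase_volume(v)
  lap <- average_parabolic_laplacian(ph, uniform_labels(n),
                                     uniform_magnitude(n))
  ref <- discrete_laplacian(v)
  interior <- erode_mask(array(TRUE, c(n, n, n)), c(4, 4, 2))
  rms <- function(x) sqrt(mean(x^2))
  expect_lt(rms(lap$values[interior] - ref[interior]) / rms(ref[interior]),
            0.05)
})

test_that("a global 2*pi phase offset does not change the conductivity map", {
  ds <- phantom_with_phase(32)
  base <- reconstruct_conductivity(ds, denoise = NULL)
  shifted <- ds
  shifted$phase_wrapped <- phase_volume(ds$phase_true$values + 2 * pi,
                                        ds$spacing_mm, wrapped = FALSE)
  ds$phase_wrapped <- phase_volume(ds$phase_true$values, ds$spacing_mm,
                                   wrapped = FALSE)
  again <- reconstruct_conductivity(shifted, denoise = NULL)
  plain <- reconstruct_conductivity(ds, denoise = NULL)
  expect_equal(again$values, plain$values, tolerance = 1e-9)
  expect_identical(again$valid, plain$valid)
  expect_equal(base$values[base$valid], plain$values[base$valid],
               tolerance = 1e-6)
})

test_that("noiseless phantom round trip recovers compartment conductivities within 1%", {
  ds <- phantom_with_phase(48)
  sig <- reconstruct_conductivity(ds, denoise = NULL)
  for (pair in list(c(1, 0.540), c(2, 1.069))) {
    sel <- erode_mask(ds$labels$values == pair[1], c(4, 4, 2)) & sig$valid
    expect_gt(sum(sel), 100)
    expect_lt(abs(mean(sig$values[sel]) / pair[2] - 1), 0.01)
  }
})

test_that("noisy reconstructions are repeatable across seeds", {
  means <- sapply(c(31L, 77L), function(seed) {
    ds <- phantom_with_phase(48, snr = 50, seed = seed)
    sig <- reconstruct_conductivity(ds, denoise = NULL)
    sel <- erode_mask(ds$labels$values == 2L, c(4, 4, 2)) & sig$valid
    c(mean(sig$values[sel]), sd(sig$values[sel]) / sqrt(sum(sel)))
  })
  pooled_se <- sqrt(sum(means[2, ]^2))
  expect_lt(abs(means[1, 1] - means[1, 2]), 3 * pooled_se)
})

test_that("all-background input yields an empty valid mask, not an error", {
  n <- 10
  lap <- average_parabolic_laplacian(quadratic_phase(n),
                                     label_map(array(0L, c(n, n, n))),
                                     uniform_magnitude(n))
  expect_false(any(lap$valid))
})
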