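test_that("phantom rasterization places compartments at their stated conductivities", {
  ds <- make_phantom(saline_phantom_spec(c(64, 64, 64)))
  labs <- ds$labels$values
  expect_setequal(unique(as.vector(labs)), c(0L, 1L, 2L))
  expect_equal(unique(ds$sigma_true$values[labs == 1L]), 0.540)
  expect_equal(unique(ds$sigma_true$values[labs == 2L]), 1.069)
  # the two cylinders are disjoint: no voxel carries both labels and the
  # connected components of the foreground are exactly two
  cc <- cc_label_3d(integer(length(labs)), as.vector(labs > 0L), dim(labs))
  expect_equal(max(cc), 2L)
})

test_that("empty compartment list yields a uniform background volume", {
  spec <- phantom_spec(c(8, 8, 8), background_conductivity = 0.3,
                       background_magnitude = 0.7)
  ds <- make_phantom(spec)
  expect_true(all(ds$labels$values == 0L))
  expect_true(all(ds$sigma_true$values == 0.3))
  expect_true(all(ds$magnitude$values == 0.7))
})

test_that("brain-like nested shells carry the literature tissue conductivities exactly", {
  ds <- make_phantom(brain_phantom_spec(c(40, 40, 32)))
  labs <- ds$labels$values
  expect_setequal(setdiff(unique(as.vector(labs)), 0L), 1:3)
  for (pair in list(c(1, 0.34), c(2, 0.59), c(3, 2.14)))
    expect_equal(mean(ds$sigma_true$values[labs == pair[1]]), pair[2])
})

test_that("overlapping compartments are rejected", {
  spec <- phantom_spec(c(24, 24, 24), compartments = list(
    cylinder_compartment(1L, 0.5, center = c(10, 10), radius = 6,
                         z_range = c(2, 20)),
    cylinder_compartment(2L, 1.0, center = c(12, 10), radius = 6,
                         z_range = c(2, 20))))
  expect_error(make_phantom(spec), "overlap")
})

test_that("forward phase solves the discrete Poisson problem exactly", {
  # uniform sigma = 1 S/m: the 7-point stencil Laplacian of the solution
  # must equal 2*mu0*omega everywhere interior
  sig <- conductivity_map(array(1, c(20, 20, 20)))
  ph <- solve_forward_phase(sig)
  lap <- discrete_laplacian(ph$values, ph$spacing_mm)
  interior <- !is.na(lap)
  expect_lt(max(abs(lap[interior] / TWO_MU0_OMEGA - 1)), 1e-9)
  expect_equal(TWO_MU0_OMEGA, ept_constants()$two_mu0_omega)
})

test_that("zero conductivity gives identically zero phase", {
  ph <- solve_forward_phase(conductivity_map(array(0, c(8, 8, 8))))
  expect_true(all(ph$values == 0))
})

test_that("forward/inverse consistency holds for structured phantoms", {
  for (n in c(32, 48)) {
    ds <- phantom_with_phase(n)
    lap <- discrete_laplacian(ds$phase_true$values, ds$spacing_mm)
    src <- TWO_MU0_OMEGA * ds$sigma_true$values
    interior <- !is.na(lap)
    expect_lt(max(abs(lap[interior] - src[interior])) / max(src), 1e-6)
  }
})

test_that("anisotropic spacing is honoured by the forward model", {
  sig <- conductivity_map(array(1, c(16, 16, 12)), spacing_mm = c(1, 1, 2))
  ph <- solve_forward_phase(sig)
  lap <- discrete_laplacian(ph$values, c(1, 1, 2))
  expect_lt(max(abs(lap[!is.na(lap)] / TWO_MU0_OMEGA - 1)), 1e-9)
})

test_that("wrap_phase folds values into [0, 2*pi) under the mod convention", {
  w <- wrap_phase(phase_volume(array(c(0.5, 2 * pi + 0.5, -0.25, 7 * pi),
                                     c(4, 1, 1))))
  expect_equal(as.vector(w$values),
               c(0.5, 0.5, 2 * pi - 0.25, pi), tolerance = 1e-12)
  expect_true(w$wrapped)
  expect_true(all(w$values >= 0 & w$values < 2 * pi))
})

test_that("complex noise is deterministic under a fixed seed and vanishes at huge SNR", {
  ds <- phantom_with_phase(24)
  a <- add_complex_noise(ds, 50, seed = 11L)
  b <- add_complex_noise(ds, 50, seed = 11L)
  expect_identical(a$phase_wrapped$values, b$phase_wrapped$values)
  expect_identical(a$magnitude$values, b$magnitude$values)
  c2 <- add_complex_noise(ds, 50, seed = 12L)
  expect_false(identical(a$phase_wrapped$values, c2$phase_wrapped$values))

  clean <- add_complex_noise(ds, 1e12, seed = 3L)
  expect_lt(max(abs(circ_diff(clean$phase_wrapped$values,
                              ds$phase_true$values))), 1e-9)
})

test_that("phase noise SD scales like 1/SNR", {
  ds <- phantom_with_phase(48)
  fg <- ds$labels$values > 0L
  expect_gt(sum(fg), 1e4)
  sd_at <- function(snr) {
    n <- add_complex_noise(ds, snr, seed = 21L)
    sd(circ_diff(n$phase_wrapped$values[fg], ds$phase_true$values[fg]))
  }
  ratio <- sd_at(25) / sd_at(50)
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)
})

test_that("noise rejects non-positive SNR and overlapping misuse is caught", {
  ds <- phantom_with_phase(16)
  expect_error(add_complex_noise(ds, 0), "positive")
  expect_error(add_complex_noise(ds, -3), "positive")
  expect_error(solve_forward_phase(
    conductivity_map(array(-1, c(8, 8, 8)))), "non-negative")
})
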