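## Synthetic forward simulator. Generates piecewise-constant conductivity
## phantoms (saline cylinders, brain-like nested shells), synthesizes the
## transceive phase that the phase-based MREPT relation implies for them by
## solving the DISCRETE Poisson problem L[phi] = 2*mu0*omega*sigma exactly,
## and degrades the resulting complex image with circular Gaussian noise and
## a compressed-sensing style undersampling + wavelet soft-thresholding
## reconstruction. Solving the discrete (not continuum) problem means the
## inverse pipeline can be tested to machine precision: the 7-point stencil
## applied to the generated phase reproduces the source exactly.

#' Describe a synthetic phantom
#'
#' @param grid_shape 3 positive integers, voxels per axis.
#' @param voxel_spacing_mm 3 positive reals, mm.
#' @param compartments List of compartment descriptors built with
#'   [cylinder_compartment()], [ellipsoid_compartment()] or
#'   [box_compartment()].
#' @param background_conductivity Background sigma in S/m (default 0).
#' @param background_magnitude Background image magnitude, a.u.
#' @param allow_nesting If `TRUE`, later compartments may carve into earlier
#'   ones (used for nested-shell phantoms); otherwise any overlap is an error.
#' @return An object of class `phantom_spec`.
#' @seealso [saline_phantom_spec()], [brain_phantom_spec()], [make_phantom()]
#' @export
phantom_spec <- function(grid_shape, voxel_spacing_mm = c(1, 1, 1),
                         compartments = list(),
                         background_conductivity = 0,
                         background_magnitude = 0.2,
                         allow_nesting = FALSE) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 3L))
  check_spacing(voxel_spacing_mm)
  stopifnot(is.numeric(background_conductivity),
            background_conductivity >= 0, background_magnitude >= 0)
  labs <- vapply(compartments, `[[`, integer(1), "label")
  if (anyDuplicated(labs)) stop("compartment labels must be unique", call. = FALSE)
  if (any(labs <= 0)) stop("compartment labels must be > 0", call. = FALSE)
  sig <- vapply(compartments, `[[`, numeric(1), "conductivity")
  if (any(sig < 0)) stop("conductivities must be >= 0", call. = FALSE)
  structure(list(grid_shape = grid_shape,
                 voxel_spacing_mm = as.numeric(voxel_spacing_mm),
                 compartments = compartments,
                 background_conductivity = background_conductivity,
                 background_magnitude = background_magnitude,
                 allow_nesting = isTRUE(allow_nesting)),
            class = "phantom_spec")
}

compartment <- function(type, label, conductivity, magnitude, geom) {
  stopifnot(conductivity >= 0, magnitude >= 0, label > 0)
  c(list(type = type, label = as.integer(label),
         conductivity = conductivity, magnitude = magnitude), geom)
}

#' Phantom compartment geometries
#'
#' Geometry descriptors for [phantom_spec()]. Coordinates are in mm, with
#' the origin at the centre of the first voxel. Cylinders run along the z
#' axis between `z_range[1]` and `z_range[2]`.
#'
#' @param label Positive integer compartment label.
#' @param conductivity Compartment conductivity, S/m.
#' @param magnitude Image magnitude inside the compartment, a.u.
#' @param center In-plane centre `c(x, y)` (cylinder) or 3D centre (others), mm.
#' @param radius Cylinder radius, mm.
#' @param z_range Axial extent `c(z0, z1)`, mm.
#' @param semiaxes Ellipsoid semi-axes, mm.
#' @param lower,upper Box corners, mm.
#' @return A compartment descriptor (a named list).
#' @export
cylinder_compartment <- function(label, conductivity, center, radius, z_range,
                                 magnitude = 1) {
  compartment("cylinder", label, conductivity, magnitude,
              list(center = center, radius = radius, z_range = z_range))
}

#' @rdname cylinder_compartment
#' @export
ellipsoid_compartment <- function(label, conductivity, center, semiaxes,
                                  magnitude = 1) {
  compartment("ellipsoid", label, conductivity, magnitude,
              list(center = center, semiaxes = semiaxes))
}

#' @rdname cylinder_compartment
#' @export
box_compartment <- function(label, conductivity, lower, upper, magnitude = 1) {
  compartment("box", label, conductivity, magnitude,
              list(lower = lower, upper = upper))
}

compartment_mask <- function(comp, shape, spacing) {
  ax <- lapply(1:3, function(d) (seq_len(shape[d]) - 1) * spacing[d])
  switch(comp$type,
    cylinder = {
      dx <- outer(ax[[1]] - comp$center[1], rep(1, shape[2]))
      dy <- outer(rep(1, shape[1]), ax[[2]] - comp$center[2])
      inplane <- dx^2 + dy^2 <= comp$radius^2
      zin <- ax[[3]] >= comp$z_range[1] & ax[[3]] <= comp$z_range[2]
      outer(inplane, zin) > 0
    },
    ellipsoid = {
      q1 <- ((ax[[1]] - comp$center[1]) / comp$semiaxes[1])^2
      q2 <- ((ax[[2]] - comp$center[2]) / comp$semiaxes[2])^2
      q3 <- ((ax[[3]] - comp$center[3]) / comp$semiaxes[3])^2
      outer(outer(q1, q2, `+`), q3, `+`) <= 1
    },
    box = {
      inax <- lapply(1:3, function(d)
        ax[[d]] >= comp$lower[d] & ax[[d]] <= comp$upper[d])
      outer(outer(inax[[1]], inax[[2]], `&`), inax[[3]], `&`) > 0
    },
    stop("unknown compartment type: ", comp$type, call. = FALSE)
  )
}

#' Two-cylinder saline phantom
#'
#' Convenience spec emulating a repeatability phantom with two independent
#' cylindrical saline compartments at conductivities of 0.540 S/m (3.3 g/L
#' NaCl) and 1.069 S/m (6.6 g/L NaCl).
#'
#' @param grid_shape Voxels per axis (default `c(96, 96, 96)`).
#' @param voxel_spacing_mm Voxel spacing, mm.
#' @return A `phantom_spec`.
#' @export
saline_phantom_spec <- function(grid_shape = c(96, 96, 96),
                                voxel_spacing_mm = c(1, 1, 1)) {
  ext <- (grid_shape - 1) * voxel_spacing_mm
  r <- 0.17 * min(ext[1:2])
  zr <- c(0.12, 0.88) * ext[3]
  phantom_spec(
    grid_shape, voxel_spacing_mm,
    compartments = list(
      cylinder_compartment(1L, 0.540,
                           center = c(0.28 * ext[1], 0.5 * ext[2]),
                           radius = r, z_range = zr, magnitude = 1),
      cylinder_compartment(2L, 1.069,
                           center = c(0.72 * ext[1], 0.5 * ext[2]),
                           radius = r, z_range = zr, magnitude = 0.95)
    )
  )
}

#' Brain-like three-tissue phantom
#'
#' Nested ellipsoidal shells emulating CSF (outer), grey matter (middle) and
#' white matter (inner) at the literature reference conductivities of 2.14,
#' 0.59 and 0.34 S/m for the 3 T Larmor frequency.
#'
#' @inheritParams saline_phantom_spec
#' @return A `phantom_spec` with labels 1 = WM, 2 = GM, 3 = CSF.
#' @export
brain_phantom_spec <- function(grid_shape = c(64, 64, 48),
                               voxel_spacing_mm = c(1, 1, 1)) {
  ext <- (grid_shape - 1) * voxel_spacing_mm
  ctr <- ext / 2
  # outer-to-inner nesting: later compartments may not overlap earlier ones,
  # so carve the shells by declaring the inner ellipsoids last
  phantom_spec(
    grid_shape, voxel_spacing_mm,
    compartments = list(
      ellipsoid_compartment(3L, 2.14, ctr, 0.44 * ext, magnitude = 1.4),
      ellipsoid_compartment(2L, 0.59, ctr, 0.36 * ext, magnitude = 1.0),
      ellipsoid_compartment(1L, 0.34, ctr, 0.24 * ext, magnitude = 0.8)
    ),
    allow_nesting = TRUE
  )
}

#' Realize a phantom spec as labelled volumes
#'
#' Rasterizes the compartments of a [phantom_spec()] onto the grid, giving
#' the true conductivity map, the tissue label map and a piecewise-constant
#' magnitude image. Phase fields are left empty; see [solve_forward_phase()].
#'
#' @param spec A `phantom_spec`.
#' @return A `synthetic_dataset` with elements `labels`, `sigma_true`,
#'   `magnitude` (and `NULL` phase fields).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  shape <- spec$grid_shape
  sp <- spec$voxel_spacing_mm
  labels <- array(0L, shape)
  sigma <- array(spec$background_conductivity, shape)
  mag <- array(spec$background_magnitude, shape)
  nesting <- isTRUE(spec$allow_nesting)
  for (comp in spec$compartments) {
    m <- compartment_mask(comp, shape, sp)
    if (!any(m))
      stop("compartment with label ", comp$label, " does not intersect the grid",
           call. = FALSE)
    if (!nesting && any(labels[m] != 0L))
      stop("compartments overlap (label ", comp$label,
           "); refusing ill-posed phantom spec", call. = FALSE)
    labels[m] <- comp$label
    sigma[m] <- comp$conductivity
    mag[m] <- comp$magnitude
  }
  synthetic_dataset(
    labels = label_map(labels, sp),
    sigma_true = conductivity_map(sigma, spacing_mm = sp),
    magnitude = magnitude_volume(mag, sp)
  )
}

synthetic_dataset <- function(labels, sigma_true, magnitude,
                              phase_true = NULL, phase_wrapped = NULL) {
  structure(list(labels = labels, sigma_true = sigma_true,
                 magnitude = magnitude, phase_true = phase_true,
                 phase_wrapped = phase_wrapped,
                 spacing_mm = labels$spacing_mm),
            class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  d <- dim(x$labels$values)
  cat(sprintf("<synthetic_dataset> %dx%dx%d; phase: %s%s\n", d[1], d[2], d[3],
              if (is.null(x$phase_true)) "none" else "true",
              if (is.null(x$phase_wrapped)) "" else " + wrapped"))
  invisible(x)
}

## --- discrete Poisson forward model -------------------------------------

# multiply matrix M along dimension d of 3D array A
apply_dim3 <- function(A, M, d) {
  dm <- dim(A)
  perm <- c(d, setdiff(1:3, d))
  B <- aperm(A, perm)
  B <- M %*% matrix(B, nrow = dm[d])
  dim(B) <- dm[perm]
  aperm(B, order(perm))
}

#' Synthesize the transceive phase of a conductivity map
#'
#' Solves the discrete Poisson problem `L[phi] = 2*mu0*omega*sigma`, where
#' `L` is the 7-point finite-difference Laplacian (spacing in meters), with
#' zero-Dirichlet values on the one-voxel grid boundary. The solve
#' diagonalizes the stencil with a type-I sine transform per axis, so it is
#' exact: applying [discrete_laplacian()] to the result recovers the source
#' at every interior voxel to machine precision. This is the generator used
#' for round-trip testing of the reconstruction pipeline; it is a discrete
#' construction, not an electromagnetic field simulation.
#'
#' @param sigma_true A `conductivity_map` (finite, non-negative values).
#' @param constants An [ept_constants()] object.
#' @return A `phase_volume` (unwrapped) over the full grid, zero on the
#'   boundary layer.
#' @export
solve_forward_phase <- function(sigma_true, constants = ept_constants()) {
  stopifnot(inherits(sigma_true, "conductivity_map"),
            inherits(constants, "ept_constants"))
  v <- sigma_true$values
  if (any(!is.finite(v))) stop("sigma must be finite", call. = FALSE)
  if (any(v < 0)) stop("sigma must be non-negative", call. = FALSE)
  d <- dim(v)
  n <- d - 2L
  stopifnot(all(n >= 1L))
  h <- sigma_true$spacing_mm * 1e-3
  src <- 2 * constants$mu0 * constants$omega *
    v[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1), drop = FALSE]
  dim(src) <- n
  S <- lapply(1:3, function(k) {
    j <- seq_len(n[k])
    outer(j, j, function(a, b) sin(pi * a * b / (n[k] + 1)))
  })
  lam <- lapply(1:3, function(k)
    -4 / h[k]^2 * sin(pi * seq_len(n[k]) / (2 * (n[k] + 1)))^2)
  shat <- src
  for (k in 1:3) shat <- apply_dim3(shat, S[[k]], k)
  denom <- outer(outer(lam[[1]], lam[[2]], `+`), lam[[3]], `+`)
  phihat <- shat / denom
  phi_int <- phihat
  for (k in 1:3) phi_int <- apply_dim3(phi_int, S[[k]], k)
  phi_int <- phi_int / prod((n + 1) / 2)
  phi <- array(0, d)
  phi[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)] <- phi_int
  phase_volume(phi, sigma_true$spacing_mm, wrapped = FALSE)
}

#' 7-point finite-difference Laplacian
#'
#' The reference second-difference stencil (spacing in meters), used both as
#' the forward model's defining operator and as an independent check on the
#' parabolic-fit estimator. Boundary voxels get `NA`.
#'
#' @param values 3D numeric array.
#' @param spacing_mm Voxel spacing, mm.
#' @return 3D array of the same shape, rad/m^2 if `values` is in radians.
#' @export
discrete_laplacian <- function(values, spacing_mm = c(1, 1, 1)) {
  check_vol3d(values)
  h <- check_spacing(spacing_mm) * 1e-3
  d <- dim(values)
  out <- array(NA_real_, d)
  i <- 2:(d[1] - 1); j <- 2:(d[2] - 1); k <- 2:(d[3] - 1)
  out[i, j, k] <-
    (values[i + 1, j, k] - 2 * values[i, j, k] + values[i - 1, j, k]) / h[1]^2 +
    (values[i, j + 1, k] - 2 * values[i, j, k] + values[i, j - 1, k]) / h[2]^2 +
    (values[i, j, k + 1] - 2 * values[i, j, k] + values[i, j, k - 1]) / h[3]^2
  out
}

## run code with a private, restored RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Add circular complex Gaussian noise to a synthetic dataset
#'
#' Forms the complex image `M * exp(i*phi)` from the dataset's magnitude and
#' true phase, adds i.i.d. circular Gaussian noise with per-channel SD equal
#' to `mean(M over foreground) / snr`, and stores the noisy magnitude and
#' the noisy (wrapped) phase. Deterministic given `seed`; the caller's RNG
#' state is untouched.
#'
#' @param dataset A `synthetic_dataset` with `phase_true` present.
#' @param snr Positive real signal-to-noise ratio. For large `snr` the phase
#'   noise SD is approximately `1/snr` in foreground voxels.
#' @param seed Integer seed.
#' @return The dataset with noisy `magnitude` and `phase_wrapped` (the clean
#'   `phase_true` is kept as ground truth).
#' @export
add_complex_noise <- function(dataset, snr, seed = 1L) {
  stopifnot(inherits(dataset, "synthetic_dataset"),
            !is.null(dataset$phase_true))
  if (!is.numeric(snr) || length(snr) != 1L || !is.finite(snr) || snr <= 0)
    stop("snr must be a positive real", call. = FALSE)
  M <- dataset$magnitude$values
  phi <- dataset$phase_true$values
  fg <- dataset$labels$values > 0L
  if (!any(fg)) fg <- M > 0
  sd_n <- mean(M[fg]) / snr
  z <- complex(modulus = M, argument = phi)
  n <- length(z)
  noise <- with_seed(seed,
    complex(real = stats::rnorm(n, sd = sd_n),
            imaginary = stats::rnorm(n, sd = sd_n)))
  zn <- z + noise
  magn <- array(Mod(zn), dim(M))
  phin <- array(Arg(zn) %% (2 * pi), dim(M))
  phin[phin >= 2 * pi] <- 0          # guard against floating-point 2*pi
  dataset$magnitude <- magnitude_volume(magn, dataset$spacing_mm)
  dataset$phase_wrapped <- phase_volume(phin, dataset$spacing_mm,
                                        wrapped = TRUE,
                                        mask = dataset$phase_true$mask)
  dataset
}

#' Wrap a phase volume into [0, 2*pi)
#'
#' @param phase A `phase_volume`.
#' @return A wrapped `phase_volume` with `values = phi mod 2*pi`.
#' @export
wrap_phase <- function(phase) {
  stopifnot(inherits(phase, "phase_volume"))
  v <- phase$values %% (2 * pi)
  v[v >= 2 * pi] <- 0
  phase_volume(v, phase$spacing_mm, wrapped = TRUE, mask = phase$mask)
}
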