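## Voxel-wise conductivity reconstruction. The phase Laplacian is estimated
## by one-sided least-squares parabola fits along each axis: for a target
## voxel, up to half-extent neighbours per side are collected (stopping at
## mask, tissue-label or image-amplitude boundaries), a quadratic is fitted
## through the target and each side, and the axis second derivative is the
## mean of the two side curvatures. Summing over axes gives the Laplacian;
## dividing by 2*mu0*omega gives conductivity. A voxel is accepted only if
## the aggregate Pearson correlation between fitted and measured phase
## reaches the acceptance threshold.

#' Reconstruction kernel settings
#'
#' @param max_extent Maximum kernel size per axis in voxels, default
#'   `c(9, 9, 6)`. The one-sided fit depth is `floor((extent - 1) / 2)`
#'   (4, 4 and 2 here): an even extent cannot be centred, so it is read as
#'   its largest centred-kernel reach.
#' @param correlation_threshold Minimum aggregate fit correlation for a
#'   voxel to be accepted, default 0.70.
#' @param amplitude_tolerance Fractional image-amplitude tolerance for a
#'   neighbour to join the kernel, default 0.10.
#' @param min_points_per_side Minimum neighbours per side for a fit
#'   (default 2, i.e. 3 samples with the target: the smallest determined
#'   parabola).
#' @param cor_aggregate How per-fit correlations combine into the per-voxel
#'   acceptance statistic: `"mean"` (default) averages over fits with
#'   residual degrees of freedom (a 3-sample fit interpolates exactly and
#'   carries no fit-quality information, so it is excluded; if every fit is
#'   saturated the statistic is 1), `"min"` takes the worst fit.
#' @return A list of class `kernel_config`.
#' @export
kernel_config <- function(max_extent = c(9, 9, 6),
                          correlation_threshold = 0.70,
                          amplitude_tolerance = 0.10,
                          min_points_per_side = 2L,
                          cor_aggregate = c("mean", "min")) {
  stopifnot(length(max_extent) == 3L, all(max_extent >= 3),
            correlation_threshold >= 0, correlation_threshold <= 1,
            amplitude_tolerance >= 0, min_points_per_side >= 2)
  structure(list(max_extent = as.integer(max_extent),
                 half_extent = as.integer(floor((max_extent - 1) / 2)),
                 correlation_threshold = correlation_threshold,
                 amplitude_tolerance = amplitude_tolerance,
                 min_points_per_side = as.integer(min_points_per_side),
                 cor_aggregate = match.arg(cor_aggregate)),
            class = "kernel_config")
}

#' One-sided least-squares parabola fit
#'
#' Fits `y ~ a + b*t + c*t^2` through ordered samples that include the
#' target at position 0, returning the second derivative `2c`. Positions
#' are in meters so the curvature is in rad/m^2 when `y` is in radians.
#' This is the scalar building block of [average_parabolic_laplacian()];
#' exposed mainly for testing and diagnostics.
#'
#' @param positions Numeric sample positions in meters (target at 0).
#' @param values Phase samples, radians.
#' @return List with `second_derivative` (2c), `fitted` values and
#'   `correlation` (Pearson r between fitted and measured; 1 for flat or
#'   exactly interpolated data).
#' @export
one_sided_parabola_fit <- function(positions, values) {
  stopifnot(length(positions) == length(values), length(positions) >= 3L)
  scale <- max(abs(positions))
  if (scale == 0) stop("positions are degenerate", call. = FALSE)
  t <- positions / scale
  X <- cbind(1, t, t^2)
  cf <- solve(crossprod(X), crossprod(X, values))
  fitted <- as.vector(X %*% cf)
  vy <- stats::var(values)
  vf <- stats::var(fitted)
  r <- if (vy <= 1e-18 * mean(values^2 + 1e-30)) 1
       else if (vf <= 0) 0
       else min(1, max(-1, stats::cor(values, fitted)))
  list(second_derivative = 2 * cf[3] / scale^2, fitted = fitted,
       correlation = r)
}

#' Average parabolic-fit Laplacian of a phase volume
#'
#' Estimates the per-voxel phase Laplacian with tissue- and
#' amplitude-restricted one-sided parabola fits (see the file-level
#' description). Kernels never cross a tissue-label boundary and only admit
#' neighbours whose image amplitude is within `amplitude_tolerance` of the
#' target, which keeps boundary artifacts out of the estimate. A voxel is
#' valid when every axis produced at least one side fit and the aggregate
#' fit correlation reaches `correlation_threshold`; invalid voxels carry
#' `NA` and are excluded from all downstream ROI statistics.
#'
#' @param phase An unwrapped (and typically denoised) `phase_volume`.
#' @param labels A `label_map`; fitting is restricted to voxels with
#'   label > 0 sharing the target's label.
#' @param magnitude A co-registered `magnitude_volume`.
#' @param cfg A [kernel_config()].
#' @param mask Optional logical array restricting the voxels processed
#'   (default: `labels > 0`).
#' @return A `laplacian_map` (values in rad/m^2).
#' @export
average_parabolic_laplacian <- function(phase, labels, magnitude,
                                        cfg = kernel_config(),
                                        mask = NULL) {
  stopifnot(inherits(phase, "phase_volume"), inherits(labels, "label_map"),
            inherits(magnitude, "magnitude_volume"),
            inherits(cfg, "kernel_config"))
  if (phase$wrapped) stop("phase must be unwrapped", call. = FALSE)
  dims <- dim(phase$values)
  stopifnot(identical(dims, dim(labels$values)),
            identical(dims, dim(magnitude$values)))
  if (is.null(mask)) mask <- labels$values > 0L
  res <- parabolic_laplacian_cpp(
    as.vector(phase$values), as.vector(labels$values),
    as.vector(magnitude$values), as.vector(mask & phase$mask), dims,
    cfg$half_extent, phase$spacing_mm * 1e-3,
    cfg$amplitude_tolerance, cfg$min_points_per_side,
    cfg$correlation_threshold,
    if (cfg$cor_aggregate == "min") 1L else 0L)
  laplacian_map(res$values, res$valid, phase$spacing_mm,
                fit_cor = res$fit_cor)
}

#' Convert a phase Laplacian to conductivity
#'
#' Applies the phase-based MREPT relation `sigma = lap / (2*mu0*omega)`
#' voxel-wise, propagating the validity mask.
#'
#' @param lap A `laplacian_map` in rad/m^2.
#' @param constants An [ept_constants()] object.
#' @return A `conductivity_map` in S/m.
#' @export
conductivity_from_laplacian <- function(lap, constants = ept_constants()) {
  stopifnot(inherits(lap, "laplacian_map"),
            inherits(constants, "ept_constants"))
  conductivity_map(lap$values / constants$two_mu0_omega, lap$valid,
                   lap$spacing_mm,
                   provenance = list(larmor_freq_hz = constants$larmor_freq_hz))
}

#' End-to-end conductivity reconstruction
#'
#' Runs the full inverse pipeline on a dataset with wrapped phase: unwrap,
#' optional adaptive diffusion denoising, average parabolic-fit Laplacian,
#' and conversion to conductivity. A global 2*pi offset in the unwrapped
#' phase is irrelevant, since the Laplacian of a constant is zero.
#'
#' @param dataset A `synthetic_dataset` (or any list with `phase_wrapped`,
#'   `magnitude`, `labels`).
#' @param kernel A [kernel_config()].
#' @param denoise A [diffusion_config()], or `NULL` to skip denoising.
#' @param constants An [ept_constants()] object.
#' @return A `conductivity_map` with provenance describing the stages run.
#' @export
reconstruct_conductivity <- function(dataset, kernel = kernel_config(),
                                     denoise = diffusion_config(),
                                     constants = ept_constants()) {
  phase <- dataset$phase_wrapped
  if (is.null(phase)) stop("dataset has no wrapped phase", call. = FALSE)
  stopifnot(inherits(phase, "phase_volume"))
  phi <- if (phase$wrapped) unwrap_phase(phase) else phase
  if (!is.null(denoise))
    phi <- adaptive_diffusion_filter(phi, dataset$magnitude, denoise)
  lap <- average_parabolic_laplacian(phi, dataset$labels, dataset$magnitude,
                                     kernel)
  sig <- conductivity_from_laplacian(lap, constants)
  sig$provenance <- list(larmor_freq_hz = constants$larmor_freq_hz,
                         kernel = unclass(kernel),
                         denoise = if (is.null(denoise)) NULL
                                   else unclass(denoise))
  sig
}

#' Erode a logical mask by a box structuring element
#'
#' Utility for excluding voxels whose reconstruction kernel could touch a
#' compartment boundary: a voxel survives only if the full
#' `(2*rx+1) x (2*ry+1) x (2*rz+1)` box around it lies inside the mask.
#'
#' @param mask Logical 3D array.
#' @param radius 3 non-negative integers, voxels per axis.
#' @return The eroded logical array.
#' @export
erode_mask <- function(mask, radius) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L, length(radius) == 3L)
  out <- mask
  for (ax in 1:3) {
    r <- as.integer(radius[ax])
    if (r < 1) next
    acc <- out
    for (by in seq_len(r)) {
      acc <- acc & shift_pad_false(out, ax, by) & shift_pad_false(out, ax, -by)
    }
    out <- acc
  }
  out
}

shift_pad_false <- function(A, ax, by) {
  d <- dim(A)
  out <- array(FALSE, d)
  n <- d[ax]
  src <- dst <- list(1:d[1], 1:d[2], 1:d[3])
  if (by > 0) { dst[[ax]] <- 1:(n - by); src[[ax]] <- (1 + by):n }
  else { dst[[ax]] <- (1 - by):n; src[[ax]] <- 1:(n + by) }
  out[dst[[1]], dst[[2]], dst[[3]]] <- A[src[[1]], src[[2]], src[[3]]]
  out
}
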