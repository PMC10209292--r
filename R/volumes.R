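## Lightweight S3 containers for co-registered 3D volumes. All volumes carry
## voxel spacing in mm (converted to meters only inside Laplacian math) and a
## logical foreground mask. Axis order is (x, y, z) and indices are R's
## 1-based array indices.

check_vol3d <- function(values, what = "values") {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop(what, " must be a 3D array", call. = FALSE)
  invisible(values)
}

check_spacing <- function(spacing_mm) {
  if (!is.numeric(spacing_mm) || length(spacing_mm) != 3L ||
      any(!is.finite(spacing_mm)) || any(spacing_mm <= 0))
    stop("voxel spacing must be 3 positive reals (mm)", call. = FALSE)
  as.numeric(spacing_mm)
}

default_mask <- function(values, mask) {
  if (is.null(mask)) return(array(TRUE, dim(values)))
  if (!identical(dim(mask), dim(values)))
    stop("mask dimensions must match values", call. = FALSE)
  mask <- array(as.logical(mask), dim(values))
  if (anyNA(mask)) stop("mask must not contain NA", call. = FALSE)
  mask
}

#' Transceive phase volume
#'
#' A 3D phase volume in radians, either wrapped into `[0, 2*pi)` or
#' continuous (unwrapped). The transceive phase is the quantity whose
#' Laplacian the phase-based MREPT relation converts to conductivity.
#'
#' @param values 3D numeric array, radians.
#' @param spacing_mm Voxel spacing, 3 positive reals in mm.
#' @param wrapped Logical; `TRUE` if values lie in `[0, 2*pi)`.
#' @param mask Logical 3D array marking foreground voxels (default: all).
#' @return An object of class `phase_volume`.
#' @export
phase_volume <- function(values, spacing_mm = c(1, 1, 1), wrapped = FALSE,
                         mask = NULL) {
  check_vol3d(values, "phase values")
  mask <- default_mask(values, mask)
  if (anyNA(values[mask])) stop("phase contains NA inside the mask", call. = FALSE)
  if (isTRUE(wrapped)) {
    v <- values[mask]
    if (length(v) && (min(v) < 0 || max(v) >= 2 * pi))
      stop("wrapped phase must lie in [0, 2*pi)", call. = FALSE)
  }
  structure(list(values = values, spacing_mm = check_spacing(spacing_mm),
                 wrapped = isTRUE(wrapped), mask = mask),
            class = "phase_volume")
}

#' Magnitude volume
#'
#' Non-negative image magnitude in arbitrary units; used by the
#' reconstruction kernel to restrict fits to voxels of similar signal.
#'
#' @inheritParams phase_volume
#' @return An object of class `magnitude_volume`.
#' @export
magnitude_volume <- function(values, spacing_mm = c(1, 1, 1), mask = NULL) {
  check_vol3d(values, "magnitude values")
  mask <- default_mask(values, mask)
  if (anyNA(values[mask]) || (sum(mask) && min(values[mask]) < 0))
    stop("magnitude must be finite and non-negative inside the mask", call. = FALSE)
  structure(list(values = values, spacing_mm = check_spacing(spacing_mm),
                 mask = mask),
            class = "magnitude_volume")
}

#' Tissue / compartment label map
#'
#' Integer labels (0 = background) identifying tissue classes or phantom
#' compartments. Reconstruction kernels never cross a label boundary.
#'
#' @param values 3D array of non-negative integers.
#' @inheritParams phase_volume
#' @return An object of class `label_map`.
#' @export
label_map <- function(values, spacing_mm = c(1, 1, 1)) {
  check_vol3d(values, "labels")
  if (anyNA(values) || any(values < 0) || any(values != round(values)))
    stop("labels must be non-negative integers", call. = FALSE)
  storage.mode(values) <- "integer"
  structure(list(values = values, spacing_mm = check_spacing(spacing_mm)),
            class = "label_map")
}

#' Phase-Laplacian map
#'
#' Per-voxel estimate of the phase Laplacian in rad/m^2, with a validity
#' mask from the parabolic-fit acceptance test and the per-voxel aggregate
#' fit correlation.
#'
#' @param values 3D numeric array, rad/m^2 (NA where no fit was possible).
#' @param valid Logical 3D array: fit accepted at this voxel.
#' @param fit_cor 3D numeric array of aggregate fit correlations (optional).
#' @inheritParams phase_volume
#' @return An object of class `laplacian_map`.
#' @export
laplacian_map <- function(values, valid, spacing_mm = c(1, 1, 1),
                          fit_cor = NULL) {
  check_vol3d(values, "laplacian values")
  valid <- default_mask(values, valid)
  if (any(valid & !is.finite(values)))
    stop("valid voxels must carry finite Laplacian values", call. = FALSE)
  structure(list(values = values, valid = valid,
                 spacing_mm = check_spacing(spacing_mm), fit_cor = fit_cor),
            class = "laplacian_map")
}

#' Conductivity map
#'
#' The pipeline's product: conductivity in S/m with the validity mask
#' inherited from the Laplacian fit and a provenance record (constants and
#' configuration used).
#'
#' @param values 3D numeric array, S/m.
#' @param valid Logical 3D array of accepted voxels.
#' @param provenance Optional named list recorded alongside the map.
#' @inheritParams phase_volume
#' @return An object of class `conductivity_map`.
#' @export
conductivity_map <- function(values, valid = NULL, spacing_mm = c(1, 1, 1),
                             provenance = NULL) {
  check_vol3d(values, "conductivity values")
  valid <- default_mask(values, valid)
  if (any(valid & !is.finite(values)))
    stop("valid voxels must carry finite conductivity", call. = FALSE)
  structure(list(values = values, valid = valid,
                 spacing_mm = check_spacing(spacing_mm),
                 provenance = provenance),
            class = "conductivity_map")
}

vol_summary_line <- function(x, unit) {
  d <- dim(x$values)
  sprintf("%dx%dx%d voxels, spacing %s mm%s", d[1], d[2], d[3],
          paste(format(x$spacing_mm, trim = TRUE), collapse = "x"), unit)
}

#' @export
print.phase_volume <- function(x, ...) {
  v <- x$values[x$mask]
  cat(sprintf("<phase_volume> %s; %s; range [%.3f, %.3f] rad\n",
              vol_summary_line(x, ""),
              if (x$wrapped) "wrapped" else "unwrapped",
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' @export
print.magnitude_volume <- function(x, ...) {
  cat(sprintf("<magnitude_volume> %s\n", vol_summary_line(x, "")))
  invisible(x)
}

#' @export
print.label_map <- function(x, ...) {
  labs <- sort(unique(as.vector(x$values)))
  cat(sprintf("<label_map> %s; labels: %s\n", vol_summary_line(x, ""),
              paste(labs, collapse = ", ")))
  invisible(x)
}

#' @export
print.laplacian_map <- function(x, ...) {
  cat(sprintf("<laplacian_map> %s; %d/%d voxels valid\n",
              vol_summary_line(x, ""), sum(x$valid), length(x$valid)))
  invisible(x)
}

#' @export
print.conductivity_map <- function(x, ...) {
  v <- x$values[x$valid]
  cat(sprintf("<conductivity_map> %s; %d valid voxels; median %.3f S/m\n",
              vol_summary_line(x, ""), sum(x$valid),
              if (length(v)) stats::median(v) else NA))
  invisible(x)
}

#' @export
summary.conductivity_map <- function(object, labels = NULL, ...) {
  if (is.null(labels)) {
    v <- object$values[object$valid]
    return(summary(v))
  }
  ids <- setdiff(sort(unique(as.vector(labels$values))), 0L)
  do.call(rbind, lapply(ids, function(id) {
    as.data.frame(unclass(roi_summary(object, labels, id))[
      c("roi", "n_voxels", "mean", "sd", "cov_percent")])
  }))
}
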