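## NIfTI I/O and pipeline orchestration. NIfTI is the only on-disk volume
## format; DICOM conversion is upstream of this package. Every pipeline
## output directory carries a provenance JSON naming the configuration
## hash, the seed and the package version.

#' Read a 3D volume from a NIfTI file
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param type One of `"phase"`, `"magnitude"`, `"labels"` or `"array"`
#'   (raw array plus spacing attribute).
#' @param wrapped For `type = "phase"`: whether the stored phase is wrapped.
#' @return The corresponding volume object, with spacing taken from the
#'   NIfTI header.
#' @export
read_volume <- function(path, type = c("array", "phase", "magnitude",
                                       "labels"),
                        wrapped = FALSE) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop("cannot read NIfTI file ", path, ": ",
                         conditionMessage(e), call. = FALSE))
  a <- as.array(img)
  a <- array(as.vector(a), dim(a))   # drop niftiImage attributes
  if (length(dim(a)) == 4L && dim(a)[4] == 1L) {
    dims <- dim(a)[1:3]
    a <- array(a, dims)
  }
  if (length(dim(a)) != 3L)
    stop(path, ": expected a 3D volume, got ",
         length(dim(a)), "D", call. = FALSE)
  sp <- RNifti::pixdim(img)[1:3]
  switch(type,
         array = structure(a, spacing_mm = sp),
         phase = phase_volume(a, sp, wrapped = wrapped),
         magnitude = magnitude_volume(a, sp),
         labels = label_map(round(a), sp))
}

#' Write a volume to a NIfTI file
#'
#' Spacing is stored in the header; values round-trip at float precision
#' (float64 is written, so numerically exactly).
#'
#' @param volume A volume object (anything with `values` and `spacing_mm`),
#'   or a raw 3D array (spacing taken from its `spacing_mm` attribute or
#'   1 mm).
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path) {
  if (is.list(volume)) {
    a <- volume$values
    sp <- volume$spacing_mm
  } else {
    a <- volume
    sp <- attr(volume, "spacing_mm")
    if (is.null(sp)) sp <- c(1, 1, 1)
  }
  check_vol3d(a)
  storage.mode(a) <- "double"
  img <- RNifti::asNifti(a)
  RNifti::pixdim(img) <- sp
  RNifti::writeNifti(img, path)
  invisible(path)
}

config_hash <- function(config) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                              force = TRUE), f)
  unname(tools::md5sum(f))
}

#' Default pipeline configuration
#'
#' A serializable description of a full synthetic run: phantom, noise, CS
#' degradation, reconstruction and statistics settings. Any element can be
#' overridden; the whole list can be written to / read from YAML.
#'
#' @param phantom `"saline"` or `"brain"` (which builtin phantom spec to
#'   simulate), or a ready `phantom_spec` object.
#' @param grid_shape Voxels per axis for the builtin phantoms.
#' @param snr Signal-to-noise ratio for [add_complex_noise()], or `NULL`
#'   for noiseless.
#' @param cs_factor Compressed-sensing acceleration factor (1 = none).
#' @param seed Integer seed for all stochastic stages.
#' @param larmor_freq_hz Larmor frequency, Hz.
#' @param kernel A [kernel_config()].
#' @param denoise A [diffusion_config()] or `NULL` to skip denoising.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(phantom = "saline", grid_shape = c(48, 48, 48),
                            snr = 50, cs_factor = 1, seed = 1L,
                            larmor_freq_hz = 127.76e6,
                            kernel = kernel_config(),
                            denoise = NULL) {
  structure(list(phantom = phantom, grid_shape = grid_shape, snr = snr,
                 cs_factor = cs_factor, seed = as.integer(seed),
                 larmor_freq_hz = larmor_freq_hz, kernel = kernel,
                 denoise = denoise),
            class = "pipeline_config")
}

#' Read / write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param config A [pipeline_config()].
#' @return `read_pipeline_config` returns a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- pipeline_config()
  for (k in intersect(names(y), c("phantom", "grid_shape", "snr",
                                  "cs_factor", "seed", "larmor_freq_hz")))
    cfg[[k]] <- y[[k]]
  cfg$grid_shape <- as.integer(cfg$grid_shape)
  cfg$seed <- as.integer(cfg$seed)
  if (!is.null(y$kernel)) cfg$kernel <- do.call(kernel_config, y$kernel)
  if (!is.null(y$denoise)) cfg$denoise <- do.call(diffusion_config, y$denoise)
  cfg
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  y <- lapply(unclass(config), function(x)
    if (inherits(x, "kernel_config")) unclass(x)[
      setdiff(names(x), "half_extent")]
    else if (inherits(x, "diffusion_config")) unclass(x)
    else x)
  yaml::write_yaml(y[!vapply(y, is.null, logical(1))], path)
  invisible(path)
}

#' Run the full synthetic pipeline
#'
#' Simulate (phantom, forward phase, optional noise and CS degradation),
#' reconstruct conductivity, summarize ROIs, and write all volumes plus a
#' provenance JSON to `outdir`. Fully deterministic under a fixed seed.
#'
#' @param config A [pipeline_config()] (or path to a YAML file).
#' @param outdir Output directory (created if missing), or `NULL` to skip
#'   writing files.
#' @return Invisibly, a list with `dataset`, `sigma` (the reconstructed
#'   `conductivity_map`), `rois` (data frame of per-ROI statistics) and
#'   `provenance`.
#' @export
run_pipeline <- function(config = pipeline_config(), outdir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "pipeline_config"))
  constants <- ept_constants(config$larmor_freq_hz)

  spec <- config$phantom
  if (is.character(spec))
    spec <- switch(spec,
                   saline = saline_phantom_spec(config$grid_shape),
                   brain = brain_phantom_spec(config$grid_shape),
                   stop("unknown phantom: ", spec, call. = FALSE))
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    message(sprintf("[%s] %.2fs", name, proc.time()[["elapsed"]] - t0))
    out
  }

  ds <- stage("simulate", {
    d <- make_phantom(spec)
    d$phase_true <- solve_forward_phase(d$sigma_true, constants)
    d$phase_wrapped <- wrap_phase(d$phase_true)
    d
  })
  if (!is.null(config$snr))
    ds <- stage("noise", add_complex_noise(ds, config$snr, config$seed))
  if (!is.null(config$cs_factor) && config$cs_factor > 1)
    ds <- stage("cs", emulate_cs_degradation(ds, config$cs_factor,
                                             config$seed + 1L))
  sigma <- stage("reconstruct",
                 reconstruct_conductivity(ds, config$kernel, config$denoise,
                                          constants))
  rois <- stage("stats", summary(sigma, labels = ds$labels))

  provenance <- list(
    package = "mrept",
    version = as.character(utils::packageVersion("mrept")),
    config_hash = config_hash(config),
    seed = config$seed,
    larmor_freq_hz = config$larmor_freq_hz)
  sigma$provenance <- c(sigma$provenance, list(config_hash = provenance$config_hash))

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_volume(sigma, file.path(outdir, "conductivity.nii.gz"))
    write_volume(list(values = array(as.numeric(sigma$valid), dim(sigma$valid)),
                      spacing_mm = sigma$spacing_mm),
                 file.path(outdir, "validity.nii.gz"))
    write_volume(ds$phase_wrapped, file.path(outdir, "phase_wrapped.nii.gz"))
    write_volume(ds$magnitude, file.path(outdir, "magnitude.nii.gz"))
    write_volume(list(values = array(as.numeric(ds$labels$values),
                                     dim(ds$labels$values)),
                      spacing_mm = ds$spacing_mm),
                 file.path(outdir, "labels.nii.gz"))
    utils::write.csv(rois, file.path(outdir, "roi_summary.csv"),
                     row.names = FALSE)
    writeLines(jsonlite::toJSON(provenance, auto_unbox = TRUE, digits = NA),
               file.path(outdir, "provenance.json"))
  }
  invisible(list(dataset = ds, sigma = sigma, rois = rois,
                 provenance = provenance))
}
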