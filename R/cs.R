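## Compressed-sensing style degradation. Emulates accelerated acquisition:
## pseudorandom variable-density undersampling of k-space (densely sampled
## center) followed by a sparsity-regularized reconstruction by iterative
## soft-thresholding (ISTA) in a separable multilevel Haar wavelet basis.
## Only the qualitative behaviour matters here: reconstruction quality
## degrades as the acceleration factor grows. Masks generated from the same
## seed are nested across factors (a single uniform priority field is
## thresholded at different densities), so degradation comparisons across
## factors are not confounded by mask resampling.

#' Compressed-sensing emulation settings
#'
#' @param center_frac Fully-sampled k-space centre radius as a fraction of
#'   the Nyquist radius (default 0.08).
#' @param density_width Width of the Gaussian sampling-density profile in
#'   normalized k-space radius units (default 0.25).
#' @param iterations ISTA iterations (default 30).
#' @param threshold_frac Initial soft threshold as a fraction of the largest
#'   wavelet coefficient of the zero-filled reconstruction (default 0.05).
#' @param threshold_decay Geometric decay of the threshold per iteration
#'   (default 0.7).
#' @param levels Haar decomposition levels (default 3, reduced if the grid
#'   is not divisible often enough by 2).
#' @return A list of class `cs_config`.
#' @export
cs_config <- function(center_frac = 0.08, density_width = 0.25,
                      iterations = 30L, threshold_frac = 0.05,
                      threshold_decay = 0.7, levels = 3L) {
  stopifnot(center_frac >= 0, density_width > 0, iterations >= 1,
            threshold_frac >= 0, threshold_decay > 0, threshold_decay <= 1,
            levels >= 0)
  structure(list(center_frac = center_frac, density_width = density_width,
                 iterations = as.integer(iterations),
                 threshold_frac = threshold_frac,
                 threshold_decay = threshold_decay,
                 levels = as.integer(levels)),
            class = "cs_config")
}

# normalized k-space radius (0 at DC, 1 at the Nyquist corner of each axis)
kspace_radius <- function(dims) {
  f <- lapply(dims, function(n) {
    i <- 0:(n - 1)
    ifelse(i <= n / 2, i, i - n) / (n / 2)
  })
  sqrt(outer(outer(f[[1]]^2, f[[2]]^2, `+`), f[[3]]^2, `+`))
}

#' Variable-density pseudorandom k-space sampling mask
#'
#' Gaussian sampling density over normalized k-space radius, fully sampled
#' inside `center_frac`, calibrated so the expected retained fraction equals
#' `1/cs_factor`. For a fixed seed the masks are nested in `cs_factor`.
#'
#' @param dims 3 integers, grid shape.
#' @param cs_factor Acceleration factor, `>= 1`.
#' @param seed Integer seed.
#' @param config A [cs_config()].
#' @return Logical 3D array in FFT index order (DC at `[1,1,1]`).
#' @export
cs_sampling_mask <- function(dims, cs_factor, seed = 1L,
                             config = cs_config()) {
  stopifnot(cs_factor >= 1)
  dims <- as.integer(dims)
  r <- kspace_radius(dims)
  center <- r <= config$center_frac
  w <- exp(-(r / config$density_width)^2)
  target <- 1 / cs_factor
  if (target >= 1) return(array(TRUE, dims))
  # calibrate scale c so mean(pmin(1, c*w) | center) = target
  frac <- function(cc) mean(pmax(center, pmin(1, cc * w)))
  if (frac(1e-12) >= target) {
    p <- array(0, dims)
  } else {
    cc <- stats::uniroot(function(cc) frac(cc) - target,
                         lower = 1e-12, upper = 1e12, tol = 1e-10)$root
    p <- pmin(1, cc * w)
  }
  u <- with_seed(seed, array(stats::runif(prod(dims)), dims))
  mask <- (u < p) | center
  dim(mask) <- dims
  mask
}

## orthogonal multilevel 1D Haar analysis matrix
haar_matrix <- function(n, levels) {
  W <- diag(n)
  m <- n
  lev <- 0
  while (lev < levels && m %% 2 == 0 && m >= 2) {
    B <- diag(n)
    half <- m / 2
    Bm <- matrix(0, m, m)
    for (i in seq_len(half)) {
      Bm[i, 2 * i - 1] <- Bm[i, 2 * i] <- 1 / sqrt(2)
      Bm[half + i, 2 * i - 1] <- 1 / sqrt(2)
      Bm[half + i, 2 * i] <- -1 / sqrt(2)
    }
    B[1:m, 1:m] <- Bm
    W <- B %*% W
    m <- half
    lev <- lev + 1
  }
  W
}

haar3_fwd <- function(A, Ws) {
  for (k in 1:3) A <- apply_dim3(A, Ws[[k]], k)
  A
}

haar3_inv <- function(A, Ws) {
  for (k in 1:3) A <- apply_dim3(A, t(Ws[[k]]), k)
  A
}

soft_threshold <- function(z, lambda) {
  m <- Mod(z)
  shrink <- pmax(0, m - lambda) / pmax(m, .Machine$double.eps)
  z * shrink
}

#' Emulate compressed-sensing acceleration artifacts
#'
#' Takes the dataset's complex image (noisy magnitude and phase if present,
#' otherwise the clean forward phase), discards k-space samples according to
#' a variable-density pseudorandom mask retaining about `1/cs_factor` of the
#' samples, reconstructs by iterative soft-thresholding in a Haar wavelet
#' basis with a final sampled-data consistency projection, and stores the
#' degraded magnitude and wrapped phase. `cs_factor = 1` keeps every sample,
#' so the reconstruction is the identity up to numerical tolerance.
#'
#' @param dataset A `synthetic_dataset` with phase present.
#' @param cs_factor Acceleration factor, `>= 1`.
#' @param seed Integer seed for the sampling mask.
#' @param config A [cs_config()].
#' @return The dataset with degraded `magnitude` and `phase_wrapped`.
#' @export
emulate_cs_degradation <- function(dataset, cs_factor, seed = 1L,
                                   config = cs_config()) {
  stopifnot(inherits(dataset, "synthetic_dataset"))
  if (!is.numeric(cs_factor) || cs_factor < 1)
    stop("cs_factor must be >= 1", call. = FALSE)
  phi <- if (!is.null(dataset$phase_wrapped)) dataset$phase_wrapped$values
         else if (!is.null(dataset$phase_true)) dataset$phase_true$values
         else stop("dataset has no phase; run solve_forward_phase() first",
                   call. = FALSE)
  M <- dataset$magnitude$values
  dims <- dim(M)
  img <- array(complex(modulus = M, argument = phi), dims)

  mask <- cs_sampling_mask(dims, cs_factor, seed, config)
  y <- stats::fft(img) * mask
  zf <- stats::fft(y, inverse = TRUE) / prod(dims)   # zero-filled recon

  Ws <- lapply(dims, haar_matrix, levels = config$levels)
  lambda <- config$threshold_frac * max(Mod(haar3_fwd(zf, Ws)))
  x <- zf
  for (it in seq_len(config$iterations)) {
    # gradient step on ||P x - y||^2 (P is an orthogonal projection)
    r <- stats::fft(stats::fft(x) * mask, inverse = TRUE) / prod(dims)
    x <- x - (r - zf)
    x <- haar3_inv(soft_threshold(haar3_fwd(x, Ws), lambda), Ws)
    lambda <- lambda * config$threshold_decay
  }
  # enforce measured k-space samples exactly
  kx <- stats::fft(x)
  kx[mask] <- stats::fft(img)[mask]
  x <- stats::fft(kx, inverse = TRUE) / prod(dims)

  magd <- array(Mod(x), dims)
  phid <- array(Arg(x) %% (2 * pi), dims)
  phid[phid >= 2 * pi] <- 0
  dataset$magnitude <- magnitude_volume(magd, dataset$spacing_mm)
  dataset$phase_wrapped <- phase_volume(phid, dataset$spacing_mm,
                                        wrapped = TRUE)
  dataset
}
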