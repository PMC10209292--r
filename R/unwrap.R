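## Region-growing 3D phase unwrapping. The wrapped interval [0, 2*pi) is
## split into six equal sub-intervals; 6-connected components of voxels
## sharing a sub-interval form regions over which no wrap can occur. The
## largest region seeds the unwrapped set, which then grows by repeatedly
## absorbing the neighbouring region with the largest shared border; the
## absorbed region's 2*pi offset is the integer that minimizes the mean
## absolute phase jump across that border. All tie-breaks are fixed
## (lowest region label), so the result is deterministic, and every voxel's
## correction is an exact integer multiple of 2*pi.

#' Partition a wrapped phase volume into single-interval regions
#'
#' Assigns every masked voxel the interval index `floor(6 * phi / (2*pi))`
#' (0-5) and labels 6-connected components within a single interval.
#'
#' @param phase A wrapped `phase_volume` with a non-empty mask.
#' @return An object of class `region_partition`: list with `region_labels`
#'   (3D integer array, 0 outside the mask), `interval_index` (per-region,
#'   0-based), `sizes` (voxels per region).
#' @export
partition_phase_intervals <- function(phase) {
  stopifnot(inherits(phase, "phase_volume"))
  if (!phase$wrapped) stop("phase must be wrapped", call. = FALSE)
  if (!any(phase$mask)) stop("mask is empty", call. = FALSE)
  dims <- dim(phase$values)
  k <- pmin(floor(phase$values * 3 / pi), 5L)
  storage.mode(k) <- "integer"
  lab <- cc_label_3d(as.vector(k), as.vector(phase$mask), dims)
  dim(lab) <- dims
  nreg <- max(lab)
  first <- match(seq_len(nreg), as.vector(lab))
  structure(list(region_labels = lab,
                 interval_index = as.vector(k)[first],
                 sizes = tabulate(lab, nreg)),
            class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf("<region_partition> %d regions over %d voxels\n",
              length(x$sizes), sum(x$sizes)))
  invisible(x)
}

# oriented border faces between distinct regions: data.frame(ra, rb, d)
# with d = phi_a - phi_b for 6-neighbour pairs a, b
region_border_pairs <- function(lab, values) {
  d <- dim(lab)
  out <- vector("list", 3L)
  for (ax in 1:3) {
    n <- d[ax]
    if (n < 2) next
    idx_a <- list(1:d[1], 1:d[2], 1:d[3])
    idx_b <- idx_a
    idx_a[[ax]] <- 1:(n - 1)
    idx_b[[ax]] <- 2:n
    la <- lab[idx_a[[1]], idx_a[[2]], idx_a[[3]], drop = FALSE]
    lb <- lab[idx_b[[1]], idx_b[[2]], idx_b[[3]], drop = FALSE]
    keep <- la > 0L & lb > 0L & la != lb
    if (!any(keep)) next
    va <- values[idx_a[[1]], idx_a[[2]], idx_a[[3]], drop = FALSE]
    vb <- values[idx_b[[1]], idx_b[[2]], idx_b[[3]], drop = FALSE]
    out[[ax]] <- data.frame(ra = la[keep], rb = lb[keep],
                            d = va[keep] - vb[keep])
  }
  pairs <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(pairs))
    pairs <- data.frame(ra = integer(), rb = integer(), d = numeric())
  # duplicate with both orientations so "ra in set, rb outside" covers all
  rbind(pairs, data.frame(ra = pairs$rb, rb = pairs$ra, d = -pairs$d))
}

best_offset <- function(D) {
  # integer k minimizing mean |D - 2*pi*k|; ties -> smallest k
  ks <- seq(floor(min(D) / (2 * pi)) - 1, ceiling(max(D) / (2 * pi)) + 1)
  cost <- vapply(ks, function(k) mean(abs(D - 2 * pi * k)), numeric(1))
  ks[which.min(cost)]
}

#' Unwrap a wrapped 3D phase volume
#'
#' Region-growing spatial unwrapping (see the module description). The
#' output is congruent with the input modulo 2*pi at every voxel, and is
#' defined up to a single global 2*pi multiple per connected mask component
#' (the largest region of each component keeps its wrapped values).
#'
#' @param phase A wrapped `phase_volume`.
#' @return An unwrapped `phase_volume`.
#' @export
unwrap_phase <- function(phase) {
  part <- partition_phase_intervals(phase)
  lab <- part$region_labels
  nreg <- length(part$sizes)
  dims <- dim(lab)

  offsets <- integer(nreg)
  if (nreg > 1L) {
    pairs <- region_border_pairs(lab, phase$values)
    # row indices grouped by each region, in both face orientations
    fa <- factor(pairs$ra, levels = seq_len(nreg))
    rows_by_ra <- split(seq_len(nrow(pairs)), fa)
    rows_by_rb <- split(seq_len(nrow(pairs)),
                        factor(pairs$rb, levels = seq_len(nreg)))
    # connected mask components (regions never straddle two components)
    comp <- cc_label_3d(integer(length(lab)), as.vector(phase$mask), dims)
    first <- match(seq_len(nreg), as.vector(lab))
    region_comp <- comp[first]

    inset <- rep(FALSE, nreg)
    # border face count between each outside region and the unwrapped set;
    # -Inf marks regions already absorbed
    bcount <- rep(0, nreg)
    absorb <- function(s, bcount) {
      rows <- rows_by_ra[[s]]
      bcount[s] <- -Inf
      if (length(rows))
        bcount <- bcount + tabulate(pairs$rb[rows], nreg) *
          is.finite(bcount)
      bcount
    }
    # the largest region of every mask component seeds with offset zero
    for (cid in unique(region_comp)) {
      regs <- which(region_comp == cid)
      start <- regs[which.max(part$sizes[regs])]  # ties -> lowest label
      inset[start] <- TRUE
      bcount <- absorb(start, bcount)
    }
    while (any(is.finite(bcount) & bcount > 0)) {
      r <- which.max(bcount)            # ties -> lowest label
      rows <- rows_by_rb[[r]]
      rows <- rows[inset[pairs$ra[rows]]]
      D <- pairs$d[rows] + 2 * pi * offsets[pairs$ra[rows]]
      offsets[r] <- best_offset(D)
      inset[r] <- TRUE
      bcount <- absorb(r, bcount)
    }
  }

  out <- phase$values
  sel <- lab > 0L
  out[sel] <- out[sel] + 2 * pi * offsets[lab[sel]]
  phase_volume(out, phase$spacing_mm, wrapped = FALSE, mask = phase$mask)
}
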