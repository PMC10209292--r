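## Repeatability and comparison statistics for ROI conductivity measures:
## per-ROI summaries with coefficient of variation, l2 relative error
## between images, Bland-Altman bias and limits of agreement, paired TOST
## equivalence testing with Monte-Carlo power, and repeated-measures ANOVA
## across sessions/methods.

#' Summarize a conductivity ROI
#'
#' Mean, sample SD and coefficient of variation (100*sd/mean) over the
#' valid voxels of one labelled region.
#'
#' @param sigma A `conductivity_map`.
#' @param labels A `label_map` sharing the grid.
#' @param roi Integer label of the region.
#' @return An object of class `roi_summary`: list with `roi`, `n_voxels`,
#'   `mean`, `sd`, `cov_percent`.
#' @export
roi_summary <- function(sigma, labels, roi) {
  stopifnot(inherits(sigma, "conductivity_map"), inherits(labels, "label_map"),
            identical(dim(sigma$values), dim(labels$values)))
  sel <- labels$values == roi & sigma$valid
  n <- sum(sel)
  if (n < 2L)
    stop("no valid voxels (need >= 2) in ROI ", roi, call. = FALSE)
  v <- sigma$values[sel]
  m <- mean(v)
  s <- stats::sd(v)
  structure(list(roi = roi, n_voxels = n, mean = m, sd = s,
                 cov_percent = cov_percent(m, s)),
            class = "roi_summary")
}

#' Coefficient of variation in percent
#'
#' @param mean,sd ROI mean and standard deviation (same units).
#' @return `100 * sd / mean`.
#' @export
cov_percent <- function(mean, sd) {
  stopifnot(sd >= 0)
  100 * sd / mean
}

#' @export
print.roi_summary <- function(x, ...) {
  cat(sprintf("ROI %d: n = %d, mean = %.3f, sd = %.3f S/m (CoV %.2f%%)\n",
              x$roi, x$n_voxels, x$mean, x$sd, x$cov_percent))
  invisible(x)
}

#' l2 relative error between two images
#'
#' `||I1 - I2|| / ||I1||` over the (optional) shared valid mask; the
#' standard image-difference metric, invariant to a common rescaling.
#'
#' @param I1,I2 Numeric arrays of identical shape (or volume objects with a
#'   `values` element).
#' @param mask Optional logical array selecting the voxels compared.
#' @return A single non-negative number.
#' @export
relative_error <- function(I1, I2, mask = NULL) {
  if (is.list(I1)) I1 <- I1$values
  if (is.list(I2)) I2 <- I2$values
  stopifnot(identical(dim(I1), dim(I2)))
  if (!is.null(mask)) { I1 <- I1[mask]; I2 <- I2[mask] }
  denom <- sqrt(sum(I1^2))
  if (denom == 0) stop("reference image has zero norm", call. = FALSE)
  sqrt(sum((I1 - I2)^2)) / denom
}

#' Bland-Altman agreement analysis
#'
#' Bias (mean of paired differences) and 95% limits of agreement
#' `bias +/- 1.96 * SD` of the differences.
#'
#' @param x1,x2 Paired measurements (equal length, `>= 2`), or `x1` a
#'   two-column matrix/data.frame.
#' @return An object of class `bland_altman`: list with `bias`, `loa_low`,
#'   `loa_high`, `sd_diff`, `differences`, `means`.
#' @export
bland_altman <- function(x1, x2 = NULL) {
  if (is.null(x2)) {
    x1 <- as.matrix(x1)
    stopifnot(ncol(x1) == 2L)
    x2 <- x1[, 2]; x1 <- x1[, 1]
  }
  stopifnot(length(x1) == length(x2))
  if (length(x1) < 2L) stop("need at least 2 pairs", call. = FALSE)
  d <- x1 - x2
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, loa_low = bias - 1.96 * s,
                 loa_high = bias + 1.96 * s, sd_diff = s,
                 differences = d, means = (x1 + x2) / 2),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias = %.4g, LoA = [%.4g, %.4g] (n = %d)\n",
              x$bias, x$loa_low, x$loa_high, length(x$differences)))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, margin = NULL, ...) {
  plot(x$means, x$differences, xlab = "mean of pair",
       ylab = "difference", ...)
  graphics::abline(h = c(x$bias, x$loa_low, x$loa_high),
                   lty = c(1, 2, 2), col = c("black", "grey40", "grey40"))
  if (!is.null(margin))
    graphics::abline(h = c(-margin, margin), lty = 3, col = "red")
  invisible(x)
}

#' Paired TOST equivalence test
#'
#' Two one-sided paired t-tests of the null `|mean difference| >= margin`.
#' Equivalence is declared when the larger of the two one-sided p-values is
#' at most `alpha`, equivalently when the `(1 - 2*alpha)` confidence
#' interval of the mean difference lies inside `(-margin, margin)`.
#'
#' @param x1,x2 Paired samples of equal length `n >= 2`.
#' @param margin Equivalence margin (same units as the data), `> 0`.
#' @param alpha Significance level (default 0.05; the CI level is
#'   `1 - 2*alpha`, i.e. 90%).
#' @return An object of class `equivalence_result`: list with `p_value`,
#'   `ci` (the `(1-2*alpha)` CI of the mean difference), `ci_bound` (its
#'   absolutely larger endpoint), `equivalent`, `mean_diff`, `sd_diff`,
#'   `n`, `margin`, `alpha`.
#' @export
tost_equivalence <- function(x1, x2, margin, alpha = 0.05) {
  if (length(x1) != length(x2)) stop("samples must be paired", call. = FALSE)
  n <- length(x1)
  stopifnot(n >= 2L, margin > 0, alpha > 0, alpha < 0.5)
  d <- x1 - x2
  m <- mean(d)
  s <- stats::sd(d)
  df <- n - 1
  if (s == 0) {
    # degenerate limit: the t statistics diverge
    p <- if (abs(m) < margin) 0 else if (abs(m) == margin) 0.5 else 1
    ci <- c(m, m)
  } else {
    se <- s / sqrt(n)
    p_lower <- stats::pt((m + margin) / se, df, lower.tail = FALSE)
    p_upper <- stats::pt((m - margin) / se, df)
    p <- max(p_lower, p_upper)
    ci <- m + c(-1, 1) * stats::qt(1 - alpha, df) * s / sqrt(n)
  }
  structure(list(p_value = p, ci = ci,
                 ci_bound = ci[which.max(abs(ci))],
                 equivalent = p <= alpha, mean_diff = m, sd_diff = s,
                 n = n, margin = margin, alpha = alpha),
            class = "equivalence_result")
}

#' @export
print.equivalence_result <- function(x, ...) {
  cat(sprintf(paste0("Paired TOST (margin %.3g, alpha %.2g): p = %.4g, ",
                     "%d%% CI [%.4g, %.4g] -> %sequivalent\n"),
              x$margin, x$alpha, x$p_value, round(100 * (1 - 2 * x$alpha)),
              x$ci[1], x$ci[2], if (x$equivalent) "" else "NOT "))
  invisible(x)
}

#' Power of the paired TOST procedure
#'
#' Statistical power of [tost_equivalence()] for paired normal data where
#' each arm has standard deviation `per_arm_sd` and the arms correlate with
#' coefficient `correlation`, so the paired difference has SD
#' `per_arm_sd * sqrt(2 * (1 - correlation))`. The primary method is seeded
#' Monte-Carlo; `method = "integration"` evaluates the exact finite-n power
#' by integrating the acceptance probability over the sampling distribution
#' of the difference SD (a cross-check, no randomness).
#'
#' @param n Pairs per replicate, `>= 2`.
#' @param per_arm_sd Per-arm SD, `> 0`.
#' @param correlation Correlation between arms, in `[0, 1)`.
#' @param margin Equivalence margin, `> 0`.
#' @param alpha Significance level (default 0.05).
#' @param true_diff True mean difference (default 0).
#' @param method `"montecarlo"` (default) or `"integration"`.
#' @param reps Monte-Carlo replicates (default 1e5).
#' @param seed Integer seed for the Monte-Carlo draw (default 1).
#' @return Estimated power in `[0, 1]`.
#' @export
tost_power <- function(n, per_arm_sd, correlation, margin, alpha = 0.05,
                       true_diff = 0, method = c("montecarlo", "integration"),
                       reps = 1e5, seed = 1L) {
  method <- match.arg(method)
  stopifnot(n >= 2, per_arm_sd > 0, margin > 0)
  if (!is.numeric(correlation) || correlation < 0 || correlation >= 1)
    stop("correlation must be in [0, 1)", call. = FALSE)
  sd_diff <- per_arm_sd * sqrt(2 * (1 - correlation))
  df <- n - 1
  tc <- stats::qt(1 - alpha, df)
  if (method == "montecarlo") {
    stopifnot(reps >= 1)
    d <- with_seed(seed,
      matrix(stats::rnorm(reps * n, mean = true_diff, sd = sd_diff),
             nrow = reps))
    m <- rowMeans(d)
    s2 <- (rowSums(d^2) - n * m^2) / (n - 1)
    se <- sqrt(pmax(s2, 0) / n)
    mean((m + margin) / se >= tc & (m - margin) / se <= -tc)
  } else {
    # declare equivalence iff |m| < margin - tc * s / sqrt(n); integrate
    # the normal probability of that interval over the density of s
    sd_m <- sd_diff / sqrt(n)
    f <- function(s) {
      half <- margin - tc * s / sqrt(n)
      p <- ifelse(half > 0,
                  stats::pnorm((half - true_diff) / sd_m) -
                    stats::pnorm((-half - true_diff) / sd_m), 0)
      # density of the sample SD: s^2 * df / sd^2 ~ chi^2_df
      p * 2 * s * df / sd_diff^2 *
        stats::dchisq(s^2 * df / sd_diff^2, df)
    }
    smax <- margin * sqrt(n) / tc
    stats::integrate(f, 0, smax, rel.tol = 1e-9)$value
  }
}

#' Repeated-measures ANOVA across sessions or methods
#'
#' One-way repeated-measures ANOVA per requested comparison: measurement
#' units (subject, or subject x ROI when an `roi` column is present) are
#' the blocks, the two (or more) sessions/methods are the within-unit
#' condition. P-values are Bonferroni-adjusted across comparisons.
#'
#' @param measurements Data frame with columns `subject`, `condition`,
#'   `value` and optionally `roi`.
#' @param comparisons List of character vectors of condition levels to
#'   compare (default: one comparison with all conditions).
#' @return Data frame with one row per comparison: `comparison`,
#'   `F`, `df1`, `df2`, `p_value`, `p_adjusted` (Bonferroni).
#' @export
session_anova <- function(measurements, comparisons = NULL) {
  stopifnot(is.data.frame(measurements),
            all(c("subject", "condition", "value") %in% names(measurements)))
  measurements$unit <- if ("roi" %in% names(measurements))
    interaction(measurements$subject, measurements$roi, drop = TRUE)
  else factor(measurements$subject)
  conds <- unique(as.character(measurements$condition))
  if (is.null(comparisons)) comparisons <- list(conds)
  rows <- lapply(comparisons, function(cmp) {
    d <- measurements[measurements$condition %in% cmp, ]
    d$condition <- factor(as.character(d$condition), levels = cmp)
    tab <- table(d$unit, d$condition)
    if (any(tab != 1L))
      stop("unbalanced table for comparison ", paste(cmp, collapse = " vs "),
           ": every unit needs exactly one value per condition",
           call. = FALSE)
    res <- rm_anova_oneway(d$value, d$condition, d$unit)
    data.frame(comparison = paste(cmp, collapse = " vs "),
               F = res$F, df1 = res$df1, df2 = res$df2, p_value = res$p)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "bonferroni")
  out
}

rm_anova_oneway <- function(value, condition, unit) {
  # classical within-subject decomposition
  k <- nlevels(condition)
  s <- nlevels(unit)
  grand <- mean(value)
  cond_means <- tapply(value, condition, mean)
  unit_means <- tapply(value, unit, mean)
  ss_cond <- s * sum((cond_means - grand)^2)
  ss_unit <- k * sum((unit_means - grand)^2)
  ss_tot <- sum((value - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_unit
  df1 <- k - 1
  df2 <- (k - 1) * (s - 1)
  ms_cond <- ss_cond / df1
  ms_err <- ss_err / df2
  tol <- 1e-12 * (ss_tot + 1e-30)
  if (ms_err <= tol) {
    # degenerate: no residual variation; F -> 0/0. Identical conditions
    # give no evidence of a difference.
    if (ss_cond <= tol) return(list(F = 0, df1 = df1, df2 = df2, p = 1))
    return(list(F = Inf, df1 = df1, df2 = df2, p = 0))
  }
  Fstat <- ms_cond / ms_err
  list(F = Fstat, df1 = df1, df2 = df2,
       p = stats::pf(Fstat, df1, df2, lower.tail = FALSE))
}
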