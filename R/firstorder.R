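## Gray-level discretization and first-order (intensity) features.

#' Fixed-bin-width gray-level discretization
#'
#' `level(v) = floor((v - min(masked)) / bin_width) + 1`, giving contiguous
#' integer levels starting at 1. Every texture family operates on this
#' discretized volume; each transform image (original or wavelet sub-band)
#' is discretized independently.
#'
#' @param volume numeric 3D array.
#' @param mask logical array; voxels outside it become NA.
#' @param bin_width positive bin width in intensity units.
#' @return list with `levels` (integer array, NA outside mask) and
#'   `n_levels`.
#' @export
discretize <- function(volume, mask, bin_width = 25) {
  if (bin_width <= 0) stop("bin_width must be positive")
  m <- if (inherits(mask, "tumor_mask")) mask$mask else mask
  stopifnot(identical(dim(m), dim(volume)))
  if (!any(m)) stop("empty mask")
  lv <- array(NA_integer_, dim(volume))
  vals <- volume[m]
  lv[m] <- as.integer(floor((vals - min(vals)) / bin_width)) + 1L
  list(levels = lv, n_levels = max(lv[m]))
}

#' First-order intensity features (18)
#'
#' Mean, median, minimum, maximum, range, variance (population), skewness,
#' kurtosis (non-excess; both defined as 0 for constant regions), energy,
#' total energy (energy times voxel volume), entropy and uniformity (from
#' the fixed-bin-width histogram), root mean square, mean absolute
#' deviation, robust MAD (restricted to values within the 10th-90th
#' percentile band), 10th and 90th percentiles, interquartile range.
#'
#' @param volume numeric 3D array.
#' @param mask logical array (or `tumor_mask`).
#' @param voxel_size_mm voxel edge length (for total energy).
#' @param bin_width histogram bin width for entropy/uniformity.
#' @return named numeric vector of 18 features.
#' @export
firstorder_features <- function(volume, mask, voxel_size_mm = 1,
                                bin_width = 25) {
  m <- if (inherits(mask, "tumor_mask")) mask$mask else mask
  stopifnot(identical(dim(m), dim(volume)))
  v <- volume[m]
  if (length(v) == 0) stop("empty mask")
  n <- length(v)
  mu <- mean(v)
  m2 <- mean((v - mu)^2)
  qs <- stats::quantile(v, c(0.10, 0.25, 0.50, 0.75, 0.90), names = FALSE)
  inb <- v >= qs[1L] & v <= qs[5L]
  lv <- floor((v - min(v)) / bin_width) + 1
  p <- tabulate(lv) / n
  p <- p[p > 0]
  c(
    Mean = mu,
    Median = qs[3L],
    Minimum = min(v),
    Maximum = max(v),
    Range = max(v) - min(v),
    Variance = m2,
    Skewness = if (m2 > 0) mean((v - mu)^3) / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) mean((v - mu)^4) / m2^2 else 0,
    Energy = sum(v^2),
    TotalEnergy = voxel_size_mm^3 * sum(v^2),
    Entropy = -sum(p * log2(p)),
    Uniformity = sum(p^2),
    RootMeanSquared = sqrt(mean(v^2)),
    MeanAbsoluteDeviation = mean(abs(v - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(v[inb] - mean(v[inb]))),
    `10Percentile` = qs[1L],
    `90Percentile` = qs[5L],
    InterquartileRange = qs[4L] - qs[2L]
  )
}
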