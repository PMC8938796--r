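## One-level separable 3D discrete wavelet transform (Coiflet-1,
## periodized). The periodized transform with an orthogonal filter is an
## orthogonal map, so coefficient energy equals input energy exactly and
## single-sub-band reconstructions sum back to the input. Each of the 8
## sub-bands (all low/high-pass combinations per axis, LLL..HHH) can be
## reconstructed to the original grid for masked feature extraction.

## Coiflet-1 decomposition low-pass filter (orthonormal, sums to sqrt(2))
coif1_filters <- function() {
  h <- c(-0.015655728135465443, -0.07273261951285419, 0.3848648468642029,
         0.8525720202122554, 0.3378976624578092, -0.07273261951285419)
  g <- rev(h) * (-1)^(seq_along(h) - 1L) # quadrature mirror
  list(lo = h, hi = g)
}

## (n/2) x n periodized analysis matrices for one axis
dwt_axis_matrices <- function(n) {
  if (n %% 2L != 0L) stop("wavelet transform requires even dimensions, got ", n)
  f <- coif1_filters()
  L <- length(f$lo)
  if (n < L) stop("volume too small for the wavelet filter (need >= ", L, ")")
  lo <- matrix(0, n / 2L, n)
  hi <- matrix(0, n / 2L, n)
  for (k in seq_len(n / 2L)) {
    idx <- ((2L * (k - 1L) + seq_len(L) - 1L) %% n) + 1L
    for (m in seq_len(L)) {
      lo[k, idx[m]] <- lo[k, idx[m]] + f$lo[m]
      hi[k, idx[m]] <- hi[k, idx[m]] + f$hi[m]
    }
  }
  list(lo = lo, hi = hi)
}

#' One-level 3D discrete wavelet transform
#'
#' @param volume numeric 3D array with even dimensions, each at least the
#'   filter length (6).
#' @return named list of 8 coefficient arrays of half size per axis;
#'   letter i of the name gives the filter applied along axis i
#'   (L = low pass, H = high pass).
#' @export
dwt3 <- function(volume) {
  d <- dim(volume)
  stopifnot(length(d) == 3L)
  mats <- lapply(d, dwt_axis_matrices)
  out <- list()
  for (f1 in c("L", "H")) for (f2 in c("L", "H")) for (f3 in c("L", "H")) {
    v <- axis_matmul(volume, if (f1 == "L") mats[[1L]]$lo else mats[[1L]]$hi, 1L)
    v <- axis_matmul(v, if (f2 == "L") mats[[2L]]$lo else mats[[2L]]$hi, 2L)
    v <- axis_matmul(v, if (f3 == "L") mats[[3L]]$lo else mats[[3L]]$hi, 3L)
    out[[paste0(f1, f2, f3)]] <- v
  }
  out
}

#' Wavelet sub-band images at the original grid size
#'
#' Decomposes the volume one level and reconstructs each sub-band
#' individually (all other coefficients zeroed) back to the original grid,
#' via the transposed analysis matrices (the transform is orthogonal).
#' The 8 reconstructions sum to the input volume.
#'
#' @param volume numeric 3D array with even dimensions >= 6 each.
#' @return named list of 8 full-size arrays, `wavelet-LLL` .. `wavelet-HHH`.
#' @export
wavelet_subbands <- function(volume) {
  d <- dim(volume)
  stopifnot(length(d) == 3L)
  mats <- lapply(d, dwt_axis_matrices)
  coefs <- dwt3(volume)
  out <- list()
  for (nm in names(coefs)) {
    fl <- strsplit(nm, "")[[1L]]
    v <- coefs[[nm]]
    v <- axis_matmul(v, t(if (fl[1L] == "L") mats[[1L]]$lo else mats[[1L]]$hi), 1L)
    v <- axis_matmul(v, t(if (fl[2L] == "L") mats[[2L]]$lo else mats[[2L]]$hi), 2L)
    v <- axis_matmul(v, t(if (fl[3L] == "L") mats[[3L]]$lo else mats[[3L]]$hi), 3L)
    out[[paste0("wavelet-", nm)]] <- v
  }
  out
}
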