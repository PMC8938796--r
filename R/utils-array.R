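## Internal 3D array helpers shared by the simulator, the wavelet transform
## and the texture-matrix builders. All volumes are plain numeric 3D arrays;
## voxel spacing travels separately (isotropic, mm).

#' Apply a matrix transform along one axis of a 3D array
#'
#' Computes, for every line of the array running along `axis`, the product
#' `M %*% line`. Used for separable filters (Gaussian smoothing, wavelet
#' analysis/synthesis steps).
#'
#' @param vol numeric 3D array.
#' @param M matrix with `ncol(M) == dim(vol)[axis]`.
#' @param axis axis index (1, 2 or 3).
#' @return 3D array with `dim[axis] == nrow(M)`.
#' @keywords internal
axis_matmul <- function(vol, M, axis) {
  stopifnot(length(dim(vol)) == 3L, axis %in% 1:3)
  perm <- switch(axis, c(1L, 2L, 3L), c(2L, 1L, 3L), c(3L, 1L, 2L))
  v <- aperm(vol, perm)
  dv <- dim(v)
  stopifnot(ncol(M) == dv[1L])
  r <- M %*% matrix(v, nrow = dv[1L])
  r <- array(r, c(nrow(M), dv[2L], dv[3L]))
  aperm(r, order(perm))
}

#' Dense 1D Gaussian filter matrix with reflected boundary
#' @keywords internal
gaussian_filter_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-half:half)^2) / (2 * sigma^2))
  k <- k / sum(k)
  M <- matrix(0, n, n)
  reflect <- function(j) {
    if (n == 1L) return(rep(1L, length(j)))
    # whole-sample symmetric reflection with period 2(n - 1)
    m <- (j - 1L) %% (2L * (n - 1L))
    ifelse(m >= n, 2L * (n - 1L) - m, m) + 1L
  }
  for (off in -half:half) {
    j <- reflect(seq_len(n) + off)
    M[cbind(seq_len(n), j)] <- M[cbind(seq_len(n), j)] + k[off + half + 1L]
  }
  M
}

#' Separable 3D Gaussian smoothing
#' @keywords internal
gaussian_smooth3 <- function(vol, sigma) {
  if (sigma <= 0) return(vol)
  d <- dim(vol)
  for (ax in 1:3) vol <- axis_matmul(vol, gaussian_filter_matrix(d[ax], sigma), ax)
  vol
}

#' Stationary Gaussian random field with tunable correlation length
#'
#' White noise smoothed with a Gaussian kernel of width `corr_length`
#' (voxels), then rescaled to unit standard deviation. Draws from the
#' current RNG stream.
#' @keywords internal
gaussian_random_field <- function(grid_shape, corr_length) {
  w <- array(stats::rnorm(prod(grid_shape)), grid_shape)
  f <- gaussian_smooth3(w, corr_length)
  s <- stats::sd(f)
  if (s > 0) f <- f / s
  f
}

#' Binary ellipsoid mask on a voxel grid
#'
#' @param grid_shape integer vector of 3 extents.
#' @param center ellipsoid center in voxel coordinates.
#' @param semi_axes semi-axis lengths in voxels.
#' @return logical 3D array.
#' @keywords internal
ellipsoid_mask <- function(grid_shape, center, semi_axes) {
  stopifnot(length(grid_shape) == 3L, all(grid_shape > 0),
            all(semi_axes > 0))
  i <- (seq_len(grid_shape[1L]) - center[1L]) / semi_axes[1L]
  j <- (seq_len(grid_shape[2L]) - center[2L]) / semi_axes[2L]
  k <- (seq_len(grid_shape[3L]) - center[3L]) / semi_axes[3L]
  outer(outer(i^2, j^2, `+`), k^2, `+`) <= 1
}

## 26-neighbourhood offsets and the 13 unique 3D directions (half-space)
neighbor_offsets_26 <- function() {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  as.matrix(g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ])
}

unique_directions_13 <- function() {
  off <- neighbor_offsets_26()
  keep <- off[, 3L] > 0 | (off[, 3L] == 0 & off[, 2L] > 0) |
    (off[, 3L] == 0 & off[, 2L] == 0 & off[, 1L] > 0)
  off[keep, , drop = FALSE]
}

#' Paired voxel values along an integer offset
#'
#' Returns the two aligned sub-arrays of `vol` displaced by `offset`,
#' as a list of equal-length vectors (row-major over the overlap region).
#' @keywords internal
shift_pairs <- function(vol, offset) {
  d <- dim(vol)
  if (any(d - abs(offset) <= 0)) {
    return(list(a = vol[integer(0)], b = vol[integer(0)]))
  }
  i1 <- max(1L, 1L - offset[1L]):min(d[1L], d[1L] - offset[1L])
  j1 <- max(1L, 1L - offset[2L]):min(d[2L], d[2L] - offset[2L])
  k1 <- max(1L, 1L - offset[3L]):min(d[3L], d[3L] - offset[3L])
  list(a = vol[i1, j1, k1, drop = FALSE],
       b = vol[i1 + offset[1L], j1 + offset[2L], k1 + offset[3L], drop = FALSE])
}

## derive a stream of child seeds (< 2^31) from a parent seed
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}
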