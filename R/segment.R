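## Seed-based region-growing tumor segmentation, performed on the lowest
## energy photon-counting bin (best iodine contrast) and propagated
## unchanged to every co-registered channel of the same subject.

#' Seeded region growing
#'
#' Grows, from a seed voxel, the connected set of voxels whose intensity
#' lies within `[mu_seed - tolerance, mu_seed + tolerance]`, where
#' `mu_seed` is the mean intensity over the 3x3x3 neighborhood of the seed
#' (clipped at the volume boundary). Deterministic for fixed inputs. The
#' seed voxel itself always belongs to the output.
#'
#' @param volume numeric 3D array.
#' @param seed_point integer voxel index (length 3).
#' @param tolerance absolute intensity half-band around the seed mean.
#' @param connectivity 6 or 26 (default) neighborhood.
#' @param max_fraction warn (leak detection) if the grown region exceeds
#'   this fraction of the volume.
#' @return object of class `tumor_mask`: logical `mask`, `seed_point`,
#'   `parameters`.
#' @export
region_grow <- function(volume, seed_point, tolerance,
                        connectivity = 26, max_fraction = 0.5) {
  d <- dim(volume)
  stopifnot(length(d) == 3L, length(seed_point) == 3L)
  seed_point <- as.integer(round(seed_point))
  if (any(seed_point < 1L) || any(seed_point > d)) stop("seed out of bounds")
  stopifnot(tolerance >= 0, connectivity %in% c(6, 26))

  nb <- lapply(1:3, function(ax) {
    max(1L, seed_point[ax] - 1L):min(d[ax], seed_point[ax] + 1L)
  })
  mu <- mean(volume[nb[[1L]], nb[[2L]], nb[[3L]]])
  candidate <- abs(volume - mu) <= tolerance

  offsets <- if (connectivity == 26) neighbor_offsets_26() else
    matrix(c(1, 0, 0, -1, 0, 0, 0, 1, 0, 0, -1, 0, 0, 0, 1, 0, 0, -1),
           ncol = 3, byrow = TRUE)

  region <- array(FALSE, d)
  region[seed_point[1L], seed_point[2L], seed_point[3L]] <- TRUE
  frontier <- region
  while (any(frontier)) {
    dil <- array(FALSE, d)
    for (r in seq_len(nrow(offsets))) {
      o <- offsets[r, ]
      if (any(d - abs(o) <= 0)) next
      i <- max(1L, 1L + o[1L]):min(d[1L], d[1L] + o[1L])
      j <- max(1L, 1L + o[2L]):min(d[2L], d[2L] + o[2L])
      k <- max(1L, 1L + o[3L]):min(d[3L], d[3L] + o[3L])
      dil[i, j, k] <- dil[i, j, k] |
        frontier[i - o[1L], j - o[2L], k - o[3L]]
    }
    frontier <- dil & candidate & !region
    region <- region | frontier
  }
  if (sum(region) > max_fraction * prod(d)) {
    warning("region grew beyond ", round(100 * max_fraction),
            "% of the volume - possible leak")
  }
  structure(list(mask = region, seed_point = seed_point,
                 parameters = list(tolerance = tolerance,
                                   connectivity = connectivity,
                                   seed_mean = mu)),
            class = "tumor_mask")
}

#' Propagate one mask onto co-registered channels
#'
#' Applies the identical voxel index set to every target volume (all CT
#' sets of one subject share a single segmentation).
#'
#' @param mask a `tumor_mask` (or logical array).
#' @param targets list of numeric arrays on the same grid.
#' @return named list, one element per target, each with `values` (masked
#'   voxel intensities in a fixed common order) and `n`.
#' @export
propagate_mask <- function(mask, targets) {
  m <- if (inherits(mask, "tumor_mask")) mask$mask else mask
  lapply(targets, function(v) {
    if (!identical(dim(v), dim(m))) stop("target grid does not match mask grid")
    list(values = v[m], n = sum(m))
  })
}
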