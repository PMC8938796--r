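## Mesh-based 3D shape (morphology) features. The binary mask is lightly
## smoothed with a 3x3x3 box filter and the 0.5 iso-surface is extracted
## by marching tetrahedra (6-tetrahedron cube decomposition, linear
## interpolation along cut edges). The smoothing makes the interpolated
## vertices track the underlying smooth boundary rather than the voxel
## staircase, so surface area and sphericity of quasi-spherical regions
## are close to their analytic values.

.tet_list <- list(c(0L, 1L, 3L, 7L), c(0L, 3L, 2L, 7L), c(0L, 2L, 6L, 7L),
                  c(0L, 6L, 4L, 7L), c(0L, 4L, 5L, 7L), c(0L, 5L, 1L, 7L))
.tet_edge_ends <- rbind(c(1L, 2L), c(1L, 3L), c(1L, 4L),
                        c(2L, 3L), c(2L, 4L), c(3L, 4L))
## triangles (triples of local edge ids) per inside-pattern case 1..14
.tet_tri_table <- list(
  list(c(1, 2, 3)),                 # {a}
  list(c(1, 4, 5)),                 # {b}
  list(c(2, 3, 5), c(2, 5, 4)),     # {a,b}
  list(c(2, 4, 6)),                 # {c}
  list(c(1, 3, 6), c(1, 6, 4)),     # {a,c}
  list(c(1, 2, 6), c(1, 6, 5)),     # {b,c}
  list(c(3, 5, 6)),                 # {a,b,c}
  list(c(3, 5, 6)),                 # {d}
  list(c(1, 2, 6), c(1, 6, 5)),     # {a,d}
  list(c(1, 3, 6), c(1, 6, 4)),     # {b,d}
  list(c(2, 4, 6)),                 # {a,b,d}
  list(c(2, 3, 5), c(2, 5, 4)),     # {c,d}
  list(c(1, 4, 5)),                 # {a,c,d}
  list(c(1, 2, 3))                  # {b,c,d}
)

## exact squared Euclidean distance transform (separable; per axis the
## parabola lower envelope is evaluated by shifted pmin passes)
edt_sq <- function(feature) {
  d <- dim(feature)
  D <- array(ifelse(feature, 0, Inf), d)
  for (ax in 1:3) {
    n <- d[ax]
    Dn <- D
    # distances are only needed near the zero level of the signed field
    # (the marching cells); offsets beyond 4 voxels cannot affect it
    for (off in seq_len(min(n - 1L, 4L))) {
      idx <- function(r) {
        i <- list(seq_len(d[1L]), seq_len(d[2L]), seq_len(d[3L]))
        i[[ax]] <- r
        i
      }
      # shift +off and -off along the axis, add off^2
      hi <- idx(seq_len(n - off))
      lo <- idx(seq_len(n - off) + off)
      Dn[lo[[1L]], lo[[2L]], lo[[3L]]] <-
        pmin(Dn[lo[[1L]], lo[[2L]], lo[[3L]]],
             D[hi[[1L]], hi[[2L]], hi[[3L]]] + off^2)
      Dn[hi[[1L]], hi[[2L]], hi[[3L]]] <-
        pmin(Dn[hi[[1L]], hi[[2L]], hi[[3L]]],
             D[lo[[1L]], lo[[2L]], lo[[3L]]] + off^2)
    }
    D <- Dn
  }
  D
}

## iso-surface triangles of a binary mask; returns list(A, B, C) of n x 3
## vertex coordinate matrices (voxel units of the *unpadded* grid),
## consistently oriented outward. The surface is the zero level of the
## signed Euclidean distance field (positive inside), extracted by
## marching tetrahedra with linear interpolation: flat boundary planes sit
## exactly half a voxel beyond the outermost voxel centers, and curved
## boundaries are tracked without staircase artifacts.
mask_signed_distance <- function(mask, pad = 3L) {
  d <- dim(mask)
  mk <- array(FALSE, d + 2L * pad)
  mk[pad + seq_len(d[1L]), pad + seq_len(d[2L]), pad + seq_len(d[3L])] <- mask
  f <- sqrt(edt_sq(!mk)) - sqrt(edt_sq(mk))  # signed distance, > 0 inside
  pmin(pmax(f, -4), 4)
}

field_isosurface <- function(f, iso, pad = 3L) {
  # EDT values are lattice distances, so the field can hit the iso level
  # exactly; nudge exact hits to the inside to keep the cases consistent
  f[f == iso] <- iso + 1e-9
  dp <- dim(f)
  corner <- function(cx, cy, cz) {
    f[(1L + cx):(dp[1L] - 1L + cx),
      (1L + cy):(dp[2L] - 1L + cy),
      (1L + cz):(dp[3L] - 1L + cz)]
  }
  bits <- cbind(cx = bitwAnd(0:7, 1L),
                cy = bitwAnd(bitwShiftR(0:7, 1L), 1L),
                cz = bitwAnd(bitwShiftR(0:7, 2L), 1L))
  cv <- lapply(1:8, function(c) corner(bits[c, 1L], bits[c, 2L], bits[c, 3L]))
  cmin <- Reduce(pmin, cv)
  cmax <- Reduce(pmax, cv)
  act <- which(cmin < iso & cmax > iso)
  if (length(act) == 0L) return(list(A = matrix(0, 0, 3), B = matrix(0, 0, 3), C = matrix(0, 0, 3)))
  org <- arrayInd(act, dp - 1L)          # cell origin (padded coords)
  V <- lapply(cv, function(a) a[act])    # corner values per active cell

  TA <- TB <- TC <- list()
  for (tet in .tet_list) {
    vids <- tet + 1L
    vals <- cbind(V[[vids[1L]]], V[[vids[2L]]], V[[vids[3L]]], V[[vids[4L]]])
    inside <- vals > iso
    case <- inside[, 1L] + 2L * inside[, 2L] + 4L * inside[, 3L] + 8L * inside[, 4L]
    # vertex coordinates (padded voxel units): origin + corner bits
    pcoord <- lapply(1:4, function(j) {
      sweep(org, 2L, -as.numeric(bits[vids[j], ]))  # org + bits
    })
    for (cs in 1:14) {
      sel <- which(case == cs)
      if (length(sel) == 0L) next
      vv <- vals[sel, , drop = FALSE]
      pp <- lapply(pcoord, function(p) p[sel, , drop = FALSE])
      ins <- matrix(c(bitwAnd(cs, 1L), bitwAnd(bitwShiftR(cs, 1L), 1L),
                      bitwAnd(bitwShiftR(cs, 2L), 1L), bitwAnd(bitwShiftR(cs, 3L), 1L)) > 0,
                    nrow = 1L)
      # reference inside point: mean of inside-vertex coords
      ref <- Reduce(`+`, lapply(which(ins), function(j) pp[[j]])) / sum(ins)
      edge_pt <- function(e) {
        u <- .tet_edge_ends[e, 1L]; w <- .tet_edge_ends[e, 2L]
        t <- (iso - vv[, u]) / (vv[, w] - vv[, u])
        pp[[u]] + t * (pp[[w]] - pp[[u]])
      }
      for (tri in .tet_tri_table[[cs]]) {
        Pa <- edge_pt(tri[1L]); Pb <- edge_pt(tri[2L]); Pc <- edge_pt(tri[3L])
        nrm <- cross3(Pb - Pa, Pc - Pa)
        flip <- rowSums(nrm * ((Pa + Pb + Pc) / 3 - ref)) < 0
        tmp <- Pb[flip, , drop = FALSE]
        Pb[flip, ] <- Pc[flip, , drop = FALSE]
        Pc[flip, ] <- tmp
        TA[[length(TA) + 1L]] <- Pa
        TB[[length(TB) + 1L]] <- Pb
        TC[[length(TC) + 1L]] <- Pc
      }
    }
  }
  list(A = do.call(rbind, TA) - pad,
       B = do.call(rbind, TB) - pad,
       C = do.call(rbind, TC) - pad)
}

## Deduplicate triangle-soup vertices and apply Taubin smoothing
## (alternating positive/negative Laplacian steps, which smooths the
## voxel staircase without the shrinkage of plain Laplacian smoothing).
## Vertices of the 0-level mesh lie on half-integer lattice positions, so
## exact keying is safe.
taubin_smooth <- function(tri, lambda = 0.5, mu = -0.53, iters = 60L) {
  n_tri <- nrow(tri$A)
  if (n_tri == 0L) return(tri)
  P <- rbind(tri$A, tri$B, tri$C)
  key <- paste(round(P[, 1L] * 4), round(P[, 2L] * 4), round(P[, 3L] * 4))
  uid <- match(key, unique(key))
  V <- P[!duplicated(key), , drop = FALSE]
  ia <- uid[seq_len(n_tri)]
  ib <- uid[n_tri + seq_len(n_tri)]
  ic <- uid[2L * n_tri + seq_len(n_tri)]
  ei <- c(ia, ib, ic, ib, ic, ia)
  ej <- c(ib, ic, ia, ia, ib, ic)
  n_v <- nrow(V)
  A <- Matrix::sparseMatrix(i = ei, j = ej, x = 1, dims = c(n_v, n_v),
                            use.last.ij = FALSE)
  A <- A != 0
  deg <- Matrix::rowSums(A)
  deg[deg == 0] <- 1
  for (it in seq_len(iters)) {
    V <- V + lambda * (as.matrix(A %*% V) / deg - V)
    V <- V + mu * (as.matrix(A %*% V) / deg - V)
  }
  list(A = V[ia, , drop = FALSE], B = V[ib, , drop = FALSE],
       C = V[ic, , drop = FALSE])
}

## iso-surface of a binary mask: marching tetrahedra on the signed
## Euclidean distance field at level `iso` (0 = the mask boundary,
## half a voxel outside the outermost voxel centers on flat faces)
mask_isosurface <- function(mask, iso = 0) {
  field_isosurface(mask_signed_distance(mask), iso)
}

mesh_area_volume <- function(tri) {
  if (nrow(tri$A) == 0L) return(c(area = 0, volume = 0))
  cr <- cross3(tri$B - tri$A, tri$C - tri$A)
  area <- sum(sqrt(rowSums(cr^2))) / 2
  vol <- abs(sum(tri$A[, 1L] * (tri$B[, 2L] * tri$C[, 3L] - tri$B[, 3L] * tri$C[, 2L]) +
               tri$A[, 2L] * (tri$B[, 3L] * tri$C[, 1L] - tri$B[, 1L] * tri$C[, 3L]) +
               tri$A[, 3L] * (tri$B[, 1L] * tri$C[, 2L] - tri$B[, 2L] * tri$C[, 1L])) / 6)
  c(area = area, volume = vol)
}

cross3 <- function(u, v) {
  cbind(u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L],
        u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L],
        u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L])
}

## exact maximum pairwise distance, chunked to bound memory
max_pairwise_dist <- function(P) {
  n <- nrow(P)
  if (n < 2L) return(0)
  best <- 0
  step <- 512L
  for (s in seq(1L, n, by = step)) {
    idx <- s:min(n, s + step - 1L)
    d2 <- outer(rowSums(P[idx, , drop = FALSE]^2), rowSums(P^2), `+`) -
      2 * P[idx, , drop = FALSE] %*% t(P)
    best <- max(best, max(d2))
  }
  sqrt(max(best, 0))
}

#' Mesh-based shape features (14)
#'
#' Mesh volume and surface area from the marching-tetrahedra iso-surface;
#' voxel-count volume; surface-to-volume ratio; sphericity; maximum 3D
#' diameter and maximum in-plane 2D diameters (slice/column/row planes)
#' over boundary voxel centers; principal axis lengths (4*sqrt of the
#' coordinate covariance eigenvalues), elongation and flatness.
#'
#' Degenerate (e.g. single-voxel) masks return defined values with the
#' attribute `degenerate = TRUE`.
#'
#' @param mask logical 3D array (or `tumor_mask`).
#' @param voxel_size_mm isotropic voxel edge length (mm).
#' @return named numeric vector of 14 features (lengths mm, areas mm^2,
#'   volumes mm^3).
#' @export
shape_features <- function(mask, voxel_size_mm = 1) {
  m <- if (inherits(mask, "tumor_mask")) mask$mask else mask
  n <- sum(m)
  if (n == 0) stop("empty mask")
  v <- voxel_size_mm

  tri <- taubin_smooth(mask_isosurface(m))
  av <- mesh_area_volume(tri)
  mesh_vol <- unname(av["volume"]) * v^3
  area <- unname(av["area"]) * v^2

  coords <- which(m, arr.ind = TRUE) * v
  ev <- if (n > 1L) {
    sort(pmax(eigen(stats::cov(coords), symmetric = TRUE, only.values = TRUE)$values, 0),
         decreasing = TRUE)
  } else c(0, 0, 0)

  # boundary voxels: in-mask with an exposed face (6-connectivity)
  d <- dim(m)
  interior <- array(TRUE, d)
  for (ax in 1:3) {
    lo <- hi <- m
    idx <- function(shift) {
      i <- list(seq_len(d[1L]), seq_len(d[2L]), seq_len(d[3L]))
      i[[ax]] <- pmin(pmax(i[[ax]] + shift, 1L), d[ax])
      i
    }
    il <- idx(-1L); ih <- idx(1L)
    interior <- interior & m[il[[1L]], il[[2L]], il[[3L]]] & m[ih[[1L]], ih[[2L]], ih[[3L]]]
    # voxels on the array border are boundary by construction
  }
  for (ax in 1:3) {
    brd <- list(seq_len(d[1L]), seq_len(d[2L]), seq_len(d[3L]))
    brd[[ax]] <- c(1L, d[ax])
    interior[brd[[1L]], brd[[2L]], brd[[3L]]] <- FALSE
  }
  bnd <- which(m & !interior, arr.ind = TRUE) * v
  if (nrow(bnd) == 0L) bnd <- coords

  max2d <- function(drop_axis, slice_axis) {
    sl <- bnd[, slice_axis]
    best <- 0
    for (z in unique(sl)) {
      P <- bnd[sl == z, -slice_axis, drop = FALSE]
      if (nrow(P) >= 2L) best <- max(best, max_pairwise_dist(P))
    }
    best
  }

  degenerate <- n < 2L || mesh_vol == 0 || area == 0
  sph <- if (area > 0) (36 * pi * mesh_vol^2)^(1 / 3) / area else 0
  out <- c(
    MeshVolume = mesh_vol,
    VoxelVolume = n * v^3,
    SurfaceArea = area,
    SurfaceVolumeRatio = if (mesh_vol > 0) area / mesh_vol else 0,
    Sphericity = sph,
    Maximum3DDiameter = max_pairwise_dist(bnd),
    Maximum2DDiameterSlice = max2d(3L, 3L),   # in-plane x-y, per z slice
    Maximum2DDiameterColumn = max2d(2L, 2L),  # x-z plane
    Maximum2DDiameterRow = max2d(1L, 1L),     # y-z plane
    MajorAxisLength = 4 * sqrt(ev[1L]),
    MinorAxisLength = 4 * sqrt(ev[2L]),
    LeastAxisLength = 4 * sqrt(ev[3L]),
    Elongation = if (ev[1L] > 0) sqrt(ev[2L] / ev[1L]) else 0,
    Flatness = if (ev[1L] > 0) sqrt(ev[3L] / ev[1L]) else 0
  )
  attr(out, "degenerate") <- degenerate
  out
}
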