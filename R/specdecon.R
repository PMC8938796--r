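## Spectral (basis-material) decomposition: sensitivity-matrix estimation from
## calibration vials and per-voxel linear decomposition of photon-counting CT
## energy-bin volumes into iodine / photoelectric / Compton-scatter maps.

#' Construct a sensitivity matrix object
#'
#' The sensitivity matrix maps basis-material concentrations to measured
#' energy-bin intensities: one row per energy bin, one column per basis
#' material (iodine in 1/(mg/mL), photoelectric and Compton in basis units).
#'
#' @param entries numeric matrix, rows = energy bins, columns = materials.
#' @param energies_keV numeric vector of bin threshold energies (row labels).
#' @param materials character vector of column labels.
#' @return object of class `sensitivity_matrix` with a cached condition
#'   number diagnostic.
#' @export
sensitivity_matrix <- function(entries, energies_keV,
                               materials = c("I", "PE", "CS")) {
  entries <- as.matrix(entries)
  stopifnot(nrow(entries) == length(energies_keV),
            ncol(entries) == length(materials))
  if (nrow(entries) < ncol(entries)) {
    stop("rank deficiency: fewer energy bins (", nrow(entries),
         ") than basis materials (", ncol(entries), ")")
  }
  if (qr(entries)$rank < ncol(entries)) {
    stop("sensitivity matrix is not of full column rank")
  }
  dimnames(entries) <- list(paste0("E", energies_keV), materials)
  structure(
    list(entries = entries,
         energies_keV = as.numeric(energies_keV),
         materials = materials,
         condition_number = kappa(entries, exact = TRUE)),
    class = "sensitivity_matrix"
  )
}

#' @export
print.sensitivity_matrix <- function(x, ...) {
  cat("Sensitivity matrix (", nrow(x$entries), " bins x ",
      ncol(x$entries), " materials), condition number ",
      signif(x$condition_number, 4), "\n", sep = "")
  print(x$entries)
  invisible(x)
}

#' Construct a spectral (multi-bin) volume
#'
#' @param bins named list of co-registered numeric 3D arrays, one per
#'   energy bin.
#' @param voxel_size_mm isotropic voxel spacing in mm.
#' @param energies_keV bin threshold energies.
#' @return object of class `spectral_volume`.
#' @export
spectral_volume <- function(bins, voxel_size_mm, energies_keV) {
  stopifnot(length(bins) == length(energies_keV), length(bins) >= 1L)
  d <- dim(bins[[1L]])
  for (b in bins) stopifnot(identical(dim(b), d))
  names(bins) <- paste0("E", energies_keV)
  structure(list(bins = bins, voxel_size_mm = voxel_size_mm,
                 energies_keV = as.numeric(energies_keV)),
            class = "spectral_volume")
}

#' Estimate the sensitivity matrix from calibration vials
#'
#' Per energy bin, ordinary least squares of the measured mean vial
#' intensities against the known vial concentrations. With noiseless basis
#' vials this recovers the true matrix exactly.
#'
#' @param vials a `vial_measurements` object (see
#'   [simulate_calibration_vials()]) or a list with elements
#'   `concentrations` (n x 3 matrix) and `intensities` (n x 4 matrix).
#' @return a [sensitivity_matrix()] object.
#' @export
estimate_sensitivity <- function(vials) {
  C <- as.matrix(vials$concentrations)
  B <- as.matrix(vials$intensities)
  stopifnot(nrow(C) == nrow(B))
  if (nrow(C) < ncol(C)) {
    stop("underdetermined calibration: ", nrow(C), " vial(s) for ",
         ncol(C), " basis materials")
  }
  q <- qr(C)
  if (q$rank < ncol(C)) {
    dep <- q$pivot[seq.int(q$rank + 1L, ncol(C))]
    lbl <- if (!is.null(colnames(C))) colnames(C)[dep] else dep
    stop("rank-deficient (collinear) vial design: rank ", q$rank, " < ",
         ncol(C), "; unresolved basis direction(s): ",
         paste(lbl, collapse = ", "),
         " - add vials spanning all three materials")
  }
  tA <- qr.coef(q, B)            # 3 x 4: concentrations -> intensities
  ener <- vials$energies_keV %||% seq_len(ncol(B))
  mats <- colnames(C) %||% c("I", "PE", "CS")
  sensitivity_matrix(t(tA), energies_keV = ener, materials = mats)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Decompose a spectral volume into material maps
#'
#' Solves, at every voxel, the linear system `A x = b` relating the vector
#' of energy-bin intensities `b` to the basis-material concentrations `x`.
#' With 4 bins and 3 materials the system is overdetermined and the
#' least-squares (pseudo-inverse) solution is used. Negative concentrations
#' are retained; masking and thresholding happen downstream.
#'
#' @param volume a [spectral_volume()].
#' @param A a [sensitivity_matrix()].
#' @param condition_limit warn (and record in provenance) if the matrix
#'   condition number exceeds this.
#' @return object of class `material_maps` with components `iodine`
#'   (mg/mL), `pe`, `cs` (basis units), `voxel_size_mm` and `provenance`.
#' @export
decompose <- function(volume, A, condition_limit = 1e6) {
  stopifnot(inherits(volume, "spectral_volume"), inherits(A, "sensitivity_matrix"))
  if (length(volume$bins) != nrow(A$entries)) {
    stop("bin count (", length(volume$bins), ") does not match sensitivity matrix rows (",
         nrow(A$entries), ")")
  }
  d <- dim(volume$bins[[1L]])
  B <- do.call(rbind, lapply(volume$bins, as.vector)) # nbins x nvox
  X <- qr.coef(qr(A$entries), B)                      # nmat x nvox
  ill <- is.finite(A$condition_number) && A$condition_number > condition_limit
  if (ill) warning("sensitivity matrix is ill-conditioned (condition number ",
                   signif(A$condition_number, 3), ")")
  maps <- lapply(seq_len(nrow(X)), function(m) array(X[m, ], d))
  names(maps) <- tolower(A$materials)
  structure(list(iodine = maps[["i"]], pe = maps[["pe"]], cs = maps[["cs"]],
                 voxel_size_mm = volume$voxel_size_mm,
                 provenance = list(condition_number = A$condition_number,
                                   ill_conditioned = ill)),
            class = "material_maps")
}

#' Select enhancing tumor voxels on the iodine map
#'
#' Iodine concentrations below `min_mgml` inside the tumor mask are
#' discarded as unreliable (noise dominates near the detection limit);
#' voxels at or above the threshold are kept.
#'
#' @param maps a `material_maps` object (or any list with an `iodine` array).
#' @param mask logical tumor mask array, or a `tumor_mask` object.
#' @param min_mgml concentration threshold in mg/mL (default 1.0).
#' @return list with `selection` (logical array: tumor voxels at/above the
#'   threshold), `values` (their iodine concentrations) and `n_tumor`.
#' @export
threshold_iodine <- function(maps, mask, min_mgml = 1.0) {
  m <- if (inherits(mask, "tumor_mask")) mask$mask else mask
  stopifnot(identical(dim(m), dim(maps$iodine)))
  if (!any(m)) stop("empty tumor mask")
  sel <- m & maps$iodine >= min_mgml
  list(selection = sel, values = maps$iodine[sel], n_tumor = sum(m))
}

#' Hounsfield-unit normalization
#'
#' Linear rescaling sending the water reference intensity to 0 HU and the
#' air reference to -1000 HU.
#'
#' @param volume numeric array (or vector).
#' @param water_ref,air_ref reference intensities; must differ.
#' @return array of HU values.
#' @export
hu_normalize <- function(volume, water_ref, air_ref) {
  if (water_ref == air_ref) stop("water and air references must differ")
  1000 * (volume - water_ref) / (water_ref - air_ref)
}
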