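## Conventional ("semantic") tumor metrics from the iodine map: quantities
## a radiologist reads directly, serving as the baseline against the
## agnostic radiomic feature bank.

#' Semantic iodine metrics of a segmented tumor
#'
#' Computes the five conventional metrics: tumor volume, iodine-enhanced
#' tumor volume, enhanced tumor percentage, accumulated iodine mass and
#' mean iodine concentration. Voxels below `min_mgml` are discarded as
#' unreliable before the iodine-weighted metrics are formed (they still
#' count toward tumor volume).
#'
#' Unit bookkeeping for the mass: concentration in mg/mL is numerically
#' identical to ug/mm^3, so `sum(c_i) * v` with the voxel volume `v` in
#' mm^3 yields micrograms; the reported `iodine_mass_mg` divides by 1000.
#'
#' @param iodine_map numeric 3D array of iodine concentrations (mg/mL).
#' @param mask logical tumor mask (or `tumor_mask` object).
#' @param voxel_size_mm isotropic voxel edge length (mm).
#' @param min_mgml enhancement threshold; default 1.0 mg/mL, voxels at or
#'   above it are kept.
#' @param mean_over `"enhanced"` (default) averages iodine over enhancing
#'   voxels only; `"tumor"` averages over the whole tumor (sensitivity
#'   analysis option).
#' @return object of class `semantic_features`: `tumor_volume_mm3`,
#'   `enhanced_volume_mm3`, `enhanced_percent`, `iodine_mass_mg`,
#'   `mean_iodine_mgml`, plus `no_enhancement` flag (TRUE when no voxel
#'   reaches the threshold; mass and mean are then reported as 0).
#' @export
compute_semantic <- function(iodine_map, mask, voxel_size_mm,
                             min_mgml = 1.0,
                             mean_over = c("enhanced", "tumor")) {
  mean_over <- match.arg(mean_over)
  m <- if (inherits(mask, "tumor_mask")) mask$mask else mask
  stopifnot(identical(dim(m), dim(iodine_map)), voxel_size_mm > 0)
  n_tumor <- sum(m)
  if (n_tumor == 0) stop("empty tumor mask")

  v <- voxel_size_mm^3                      # mm^3 per voxel
  vals <- iodine_map[m]
  enh <- vals >= min_mgml
  n_enh <- sum(enh)

  mass_ug <- sum(vals[enh]) * v             # mg/mL == ug/mm^3
  mean_iod <- if (mean_over == "tumor") {
    mean(vals)
  } else if (n_enh > 0) {
    mean(vals[enh])
  } else 0

  structure(list(
    tumor_volume_mm3 = n_tumor * v,
    enhanced_volume_mm3 = n_enh * v,
    enhanced_percent = 100 * n_enh / n_tumor,
    iodine_mass_mg = mass_ug / 1000,
    mean_iodine_mgml = mean_iod,
    no_enhancement = n_enh == 0,
    min_mgml = min_mgml
  ), class = "semantic_features")
}

#' Semantic metrics for every subject of a cohort
#'
#' @param iodine_maps list of iodine arrays (one per subject).
#' @param masks list of masks, parallel to `iodine_maps`.
#' @param voxel_size_mm voxel edge length (mm).
#' @param ids,labels optional subject ids and class labels.
#' @inheritParams compute_semantic
#' @return data.frame, one row per subject, with the five metrics.
#' @export
semantic_table <- function(iodine_maps, masks, voxel_size_mm,
                           ids = NULL, labels = NULL, min_mgml = 1.0) {
  stopifnot(length(iodine_maps) == length(masks))
  rows <- lapply(seq_along(iodine_maps), function(i) {
    s <- compute_semantic(iodine_maps[[i]], masks[[i]], voxel_size_mm, min_mgml)
    data.frame(tumor_volume_mm3 = s$tumor_volume_mm3,
               enhanced_volume_mm3 = s$enhanced_volume_mm3,
               enhanced_percent = s$enhanced_percent,
               iodine_mass_mg = s$iodine_mass_mg,
               mean_iodine_mgml = s$mean_iodine_mgml)
  })
  out <- do.call(rbind, rows)
  if (!is.null(ids)) out <- cbind(subject_id = ids, out)
  if (!is.null(labels)) out$class_label <- labels
  out
}
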