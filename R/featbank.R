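## The agnostic radiomic feature bank. Per volume: 14 shape features on
## the original mask, and 93 intensity/texture features (18 first order +
## 24 GLCM + 16 GLRLM + 16 GLSZM + 5 NGTDM + 14 GLDM) on the original
## image and each of the 8 one-level wavelet sub-bands, for
## 14 + 9 x 93 = 851 features in total. Names follow
## transform_family_feature_source, e.g. "original_shape_Sphericity_EID"
## or "wavelet-LLH_glcm_Contrast_PCD-E1".

intensity_families <- function() c("firstorder", "glcm", "glrlm", "glszm",
                                   "ngtdm", "gldm")

## crop volume+mask to the mask bounding box (padded), keeping each
## cropped dimension even and >= 12 so the wavelet transform applies;
## texture and intensity features depend only on masked voxels, so the
## crop changes nothing but the run time
crop_to_mask <- function(volume, mask, pad = 2L, min_size = 12L) {
  d <- dim(mask)
  rng <- lapply(1:3, function(ax) {
    pr <- range(which(apply(mask, ax, any)))
    lo <- max(1L, pr[1L] - pad); hi <- min(d[ax], pr[2L] + pad)
    n <- hi - lo + 1L
    want <- max(min_size, n + n %% 2L) # even, at least min_size
    want <- min(want, d[ax] - d[ax] %% 2L)
    # widen symmetrically to the wanted size within bounds
    while (hi - lo + 1L < want) {
      if (lo > 1L) lo <- lo - 1L
      if (hi - lo + 1L < want && hi < d[ax]) hi <- hi + 1L
      if (lo == 1L && hi == d[ax]) break
    }
    lo:hi
  })
  list(volume = volume[rng[[1L]], rng[[2L]], rng[[3L]], drop = FALSE],
       mask = mask[rng[[1L]], rng[[2L]], rng[[3L]], drop = FALSE])
}

#' Extract the full 851-feature agnostic radiomic bank from one volume
#'
#' @param volume numeric 3D array (one image channel).
#' @param mask logical tumor mask (or `tumor_mask`).
#' @param source_tag channel label appended to every feature name
#'   (`"EID"`, `"PCD-E1"` .. `"PCD-E4"`, `"I"`, `"PE"`, `"CS"`).
#' @param voxel_size_mm isotropic voxel spacing.
#' @param bin_width gray-level discretization width for this channel
#'   (applied independently to the original image and to each wavelet
#'   sub-band).
#' @param shape optional precomputed [shape_features()] vector for this
#'   mask (they depend on the mask only, so cohort extraction computes
#'   them once per subject).
#' @return named numeric vector of exactly 851 features.
#' @export
extract_all <- function(volume, mask, source_tag, voxel_size_mm = 1,
                        bin_width = 25, shape = NULL) {
  m <- if (inherits(mask, "tumor_mask")) mask$mask else mask
  stopifnot(identical(dim(m), dim(volume)))
  if (is.null(shape)) shape <- shape_features(m, voxel_size_mm)
  out <- stats::setNames(as.numeric(shape),
                         paste0("original_shape_", names(shape), "_", source_tag))

  cr <- crop_to_mask(volume, m)
  volume <- cr$volume; m <- cr$mask
  images <- c(list(original = volume), wavelet_subbands(volume))
  for (tr in names(images)) {
    img <- images[[tr]]
    dz <- discretize(img, m, bin_width)
    fo <- firstorder_features(img, m, voxel_size_mm, bin_width)
    fam <- list(
      firstorder = fo,
      glcm = glcm_features(dz$levels, dz$n_levels),
      glrlm = glrlm_features(dz$levels, dz$n_levels),
      glszm = glszm_features(dz$levels, dz$n_levels),
      ngtdm = ngtdm_features(dz$levels, dz$n_levels),
      gldm = gldm_features(dz$levels, dz$n_levels))
    for (fm in names(fam)) {
      out <- c(out, stats::setNames(
        as.numeric(fam[[fm]]),
        paste0(tr, "_", fm, "_", names(fam[[fm]]), "_", source_tag)))
    }
  }
  bad <- names(out)[!is.finite(out)]
  if (length(bad)) stop("non-finite feature value(s): ", paste(bad, collapse = ", "))
  if (length(out) != 851L) stop("feature census mismatch: ", length(out))
  out
}

#' Default per-channel discretization widths
#'
#' CT-like channels (EID, PCD bins) are HU-normalized upstream and use a
#' 25 HU bin width. Material maps live on concentration scales sized to
#' the decomposition noise: iodine in mg/mL uses 0.5, the photoelectric
#' basis map 0.1 and the Compton map 0.25 basis units, which keeps the
#' discretized level counts in the usual 20-60 range.
#' @export
default_bin_widths <- function() {
  list(EID = 25, `PCD-E1` = 25, `PCD-E2` = 25, `PCD-E3` = 25, `PCD-E4` = 25,
       I = 0.5, PE = 0.1, CS = 0.25)
}

#' Extract grouped feature tables for a whole cohort
#'
#' For every subject the eight channels (EID, the four PCD energy bins,
#' and the three material maps) are extracted with [extract_all()] and
#' grouped into the three feature spaces: EID (851 columns), PCD
#' (4 x 851 = 3404) and MaterialMaps (3 x 851 = 2553). CT channels are
#' HU-normalized with the supplied references before extraction.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param masks list of masks (one per subject); defaults to the
#'   ground-truth tumor masks.
#' @param material_maps list of `material_maps` per subject; defaults to
#'   decomposing each subject's spectral volume with the cohort's
#'   sensitivity matrix.
#' @param bin_widths named list of per-channel discretization widths,
#'   see [default_bin_widths()].
#' @param hu_refs optional list with `water` (named per-channel water
#'   reference intensity) and `air`; when supplied, EID/PCD channels are
#'   HU-normalized before extraction.
#' @return list of three data.frames (`EID`, `PCD`, `MaterialMaps`) with
#'   attributes `class_labels` and `subject_ids`.
#' @export
extract_cohort <- function(cohort, masks = NULL, material_maps = NULL,
                           bin_widths = default_bin_widths(),
                           hu_refs = NULL) {
  subs <- cohort$subjects
  n <- length(subs)
  if (is.null(masks)) masks <- lapply(subs, function(s) s$truth$tumor_mask)
  if (is.null(material_maps)) {
    material_maps <- lapply(subs, function(s) decompose(s$spectral, cohort$A))
  }
  vsz <- subs[[1L]]$spec$voxel_size_mm

  rows_eid <- vector("list", n)
  rows_pcd <- vector("list", n)
  rows_mat <- vector("list", n)
  for (i in seq_len(n)) {
    s <- subs[[i]]
    mk <- masks[[i]]
    mm <- material_maps[[i]]
    channels <- c(
      list(EID = s$eid),
      stats::setNames(s$spectral$bins, paste0("PCD-E", seq_along(s$spectral$bins))),
      list(I = mm$iodine, PE = mm$pe, CS = mm$cs))
    if (!is.null(hu_refs)) {
      for (ch in names(channels)) {
        if (ch %in% names(hu_refs$water)) {
          channels[[ch]] <- hu_normalize(channels[[ch]], hu_refs$water[[ch]],
                                         hu_refs$air %||% 0)
        }
      }
    }
    miss <- names(channels)[vapply(channels, is.null, logical(1L))]
    if (length(miss)) stop("subject ", s$id, " is missing channel(s): ",
                           paste(miss, collapse = ", "))
    shp <- shape_features(if (inherits(mk, "tumor_mask")) mk$mask else mk, vsz)
    feats <- lapply(names(channels), function(ch) {
      extract_all(channels[[ch]], mk, ch, vsz,
                  bin_width = bin_widths[[ch]] %||% 25, shape = shp)
    })
    names(feats) <- names(channels)
    rows_eid[[i]] <- feats$EID
    rows_pcd[[i]] <- do.call(c, unname(feats[paste0("PCD-E", 1:4)]))
    rows_mat[[i]] <- do.call(c, unname(feats[c("I", "PE", "CS")]))
  }
  as_table <- function(rows, group) {
    tb <- as.data.frame(do.call(rbind, rows), check.names = FALSE)
    attr(tb, "group") <- group
    attr(tb, "subject_ids") <- vapply(subs, `[[`, "", "id")
    attr(tb, "class_labels") <- vapply(subs, `[[`, "", "class_label")
    tb
  }
  list(EID = as_table(rows_eid, "EID"),
       PCD = as_table(rows_pcd, "PCD"),
       MaterialMaps = as_table(rows_mat, "MaterialMaps"))
}
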