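## I/O and the end-to-end pipeline: simulation -> calibration ->
## decomposition -> segmentation -> semantic metrics -> feature bank ->
## univariate screen -> dimensionality/MRMR -> repeated cross-validation
## -> pairwise model comparison, all driven by one seeded configuration.

#' Read / write NIfTI volumes
#'
#' Thin wrappers around RNifti preserving voxel spacing. The pipeline
#' assumes isotropic voxels and warns otherwise.
#'
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `read_volume`: numeric array with attribute `voxel_size_mm`.
#' @export
read_volume <- function(path) {
  if (!grepl("\\.nii(\\.gz)?$", path)) stop("not a NIfTI file path: ", path)
  img <- RNifti::readNifti(path)
  sp <- RNifti::pixdim(img)
  if (length(sp) >= 3L && max(abs(sp[1:3] - sp[1L])) > 1e-6 * sp[1L]) {
    warning("anisotropic voxel spacing ", paste(signif(sp[1:3], 4), collapse = "x"),
            " mm; the pipeline assumes isotropic voxels")
  }
  out <- array(as.numeric(img), dim(img))
  attr(out, "voxel_size_mm") <- sp[1L]
  out
}

#' @rdname read_volume
#' @param volume numeric array; attribute `voxel_size_mm` or argument.
#' @param voxel_size_mm voxel spacing written to the header.
#' @export
write_volume <- function(volume, path, voxel_size_mm = attr(volume, "voxel_size_mm")) {
  if (!grepl("\\.nii(\\.gz)?$", path)) stop("not a NIfTI file path: ", path)
  if (is.null(voxel_size_mm)) voxel_size_mm <- 1
  img <- RNifti::asNifti(array(as.numeric(volume), dim(volume)))
  RNifti::pixdim(img) <- rep(voxel_size_mm, 3L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a cohort to disk as NIfTI volumes plus a CSV manifest
#'
#' @param cohort a [simulate_cohort()] result.
#' @param out_dir output directory (created if needed).
#' @return path of the manifest CSV (columns: subject_id, class plus one
#'   file-path column per channel).
#' @export
write_cohort <- function(cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(cohort$subjects, function(s) {
    base <- file.path(out_dir, s$id)
    paths <- c(
      stats::setNames(paste0(base, "_pcd_e", seq_along(s$spectral$bins), ".nii.gz"),
                      paste0("pcd_e", seq_along(s$spectral$bins))),
      eid = paste0(base, "_eid.nii.gz"),
      iodine = paste0(base, "_iodine.nii.gz"),
      pe = paste0(base, "_pe.nii.gz"),
      cs = paste0(base, "_cs.nii.gz"),
      mask = paste0(base, "_mask.nii.gz"))
    vs <- s$spec$voxel_size_mm
    for (b in seq_along(s$spectral$bins)) {
      write_volume(s$spectral$bins[[b]], paths[[b]], vs)
    }
    write_volume(s$eid, paths[["eid"]], vs)
    write_volume(s$truth$iodine, paths[["iodine"]], vs)
    write_volume(s$truth$pe, paths[["pe"]], vs)
    write_volume(s$truth$cs, paths[["cs"]], vs)
    write_volume(s$truth$tumor_mask + 0, paths[["mask"]], vs)
    cbind(data.frame(subject_id = s$id, class = s$class_label),
          as.data.frame(as.list(paths)))
  })
  manifest <- do.call(rbind, rows)
  mf <- file.path(out_dir, "manifest.csv")
  utils::write.csv(manifest, mf, row.names = FALSE)
  mf
}

#' End-to-end pipeline configuration
#'
#' All stochastic stages derive their seeds deterministically from the
#' global seed, so a rerun with the same configuration reproduces every
#' numeric output.
#'
#' @param n_pos,n_neg subjects per class.
#' @param grid_shape,voxel_size_mm phantom grid geometry.
#' @param effect a [cohort_effect()].
#' @param seed global seed.
#' @param segment_tolerance region-growing tolerance in HU after
#'   normalization of the lowest-energy bin (NULL = use ground-truth masks).
#' @param cv overrides for [cv_config()] fields (list).
#' @param k_features MRMR/classifier feature count.
#' @param out_dir optional directory for CSV/JSON outputs.
#' @export
pipeline_config <- function(n_pos = 10L, n_neg = 10L,
                            grid_shape = c(48L, 48L, 48L),
                            voxel_size_mm = 0.125,
                            effect = cohort_effect(),
                            seed = 1L,
                            segment_tolerance = NULL,
                            cv = list(),
                            k_features = 11L,
                            out_dir = NULL) {
  list(n_pos = n_pos, n_neg = n_neg, grid_shape = grid_shape,
       voxel_size_mm = voxel_size_mm, effect = effect, seed = seed,
       segment_tolerance = segment_tolerance, cv = cv,
       k_features = k_features, out_dir = out_dir)
}

#' Run the full analysis pipeline
#'
#' Stages: (1) simulate the cohort; (2) simulate calibration vials and
#' estimate the sensitivity matrix; (3) decompose every subject's
#' spectral volume into material maps; (4) segment the tumor on the
#' lowest-energy PCD bin (or take the ground-truth masks); (5) semantic
#' iodine metrics; (6) the three grouped feature tables; (7) univariate
#' Wilcoxon/BH screen per group; (8) PCA dimensionality and repeated
#' cross-validation per group; (9) pairwise signed-rank AUC comparisons.
#'
#' @param config a [pipeline_config()].
#' @return list with `cohort_summary`, `sensitivity` (estimated matrix),
#'   `semantic` (per-subject table), `semantic_tests`, `tables` (three
#'   feature tables), `univariate`, `pca_dims`, `reports` (three
#'   `model_report`s), `comparisons` (pairwise signed-rank p-values),
#'   `config`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  seeds <- derive_seeds(config$seed, 4L)
  A_true <- make_sensitivity_model()

  ## 1: cohort
  cohort <- simulate_cohort(config$n_pos, config$n_neg, config$effect,
                            seed = seeds[1L], grid_shape = config$grid_shape,
                            voxel_size_mm = config$voxel_size_mm, A = A_true)

  ## 2: calibration (vials spanning the basis, mild noise)
  set.seed(seeds[2L])
  conc <- rbind(c(10, 0, 0), c(5, 0, 0), c(0, 1, 0), c(0, 0.5, 0),
                c(0, 0, 1), c(0, 0, 0.5), c(2, 1, 1))
  vials <- simulate_calibration_vials(A_true, conc,
                                      noise_sd = config$effect$noise_sd / 10)
  A_est <- estimate_sensitivity(vials)

  ## 3: material decomposition with the estimated matrix
  maps <- lapply(cohort$subjects, function(s) decompose(s$spectral, A_est))

  ## 4: segmentation
  if (is.null(config$segment_tolerance)) {
    masks <- lapply(cohort$subjects, function(s) s$truth$tumor_mask)
  } else {
    masks <- lapply(cohort$subjects, function(s) {
      ctr <- round(s$spec$tumor_center)
      region_grow(s$spectral$bins[[1L]], ctr, config$segment_tolerance)$mask
    })
  }

  ## 5: semantic metrics + group tests
  sem <- semantic_table(lapply(maps, `[[`, "iodine"), masks,
                        config$voxel_size_mm,
                        ids = vapply(cohort$subjects, `[[`, "", "id"),
                        labels = vapply(cohort$subjects, `[[`, "", "class_label"))
  labels <- sem$class_label
  sem_tests <- lapply(c("tumor_volume_mm3", "enhanced_volume_mm3",
                        "enhanced_percent", "iodine_mass_mg",
                        "mean_iodine_mgml"), function(v) {
    w <- wilcoxon_mw(sem[[v]][labels == "positive"],
                     sem[[v]][labels == "negative"])
    data.frame(metric = v, U = w$U, p_value = w$p_value)
  })
  sem_tests <- do.call(rbind, sem_tests)

  ## 6: feature bank; CT channels HU-normalized against the known
  ## soft-tissue background intensity (material vector (I, PE, CS) =
  ## (0, 1, 1)) of each channel
  water <- c(EID = sum(cohort$eid_row * c(0, 1, 1)),
             stats::setNames(as.numeric(A_true$entries %*% c(0, 1, 1)),
                             paste0("PCD-E", 1:4)))
  tables <- extract_cohort(cohort, masks = masks, material_maps = maps,
                           hu_refs = list(water = as.list(water), air = 0))

  ## 7: univariate screen per group
  univ <- lapply(tables, univariate_screen, labels = labels)

  ## 8: dimensionality + CV per group
  pca_dims <- vapply(tables, function(tb) pca_dim(tb), 0L)
  cv_args <- utils::modifyList(
    list(k_features = config$k_features, seed = seeds[3L]), config$cv)
  cvc <- do.call(cv_config, cv_args)
  folds <- stratified_mc_folds(labels, cvc)
  reports <- lapply(tables, run_cv, labels = labels, config = cvc,
                    folds = folds)

  ## 9: pairwise model comparison
  pairs <- utils::combn(names(reports), 2L, simplify = FALSE)
  comparisons <- do.call(rbind, lapply(pairs, function(pr) {
    cm <- compare_models(reports[[pr[1L]]]$auc_per_repeat,
                         reports[[pr[2L]]]$auc_per_repeat)
    data.frame(model_a = pr[1L], model_b = pr[2L],
               mean_auc_a = mean(reports[[pr[1L]]]$auc_per_repeat),
               mean_auc_b = mean(reports[[pr[2L]]]$auc_per_repeat),
               p_value = cm$p_value)
  }))

  out <- list(
    cohort_summary = list(n_pos = config$n_pos, n_neg = config$n_neg,
                          grid_shape = config$grid_shape,
                          class_counts = cohort$class_counts),
    sensitivity = A_est, semantic = sem, semantic_tests = sem_tests,
    tables = tables, univariate = univ, pca_dims = pca_dims,
    reports = reports, comparisons = comparisons, config = config)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(sem, file.path(config$out_dir, "semantic_features.csv"),
                     row.names = FALSE)
    utils::write.csv(sem_tests, file.path(config$out_dir, "semantic_tests.csv"),
                     row.names = FALSE)
    for (g in names(tables)) {
      utils::write.csv(cbind(subject_id = attr(tables[[g]], "subject_ids"),
                             class = attr(tables[[g]], "class_labels"),
                             tables[[g]]),
                       file.path(config$out_dir, paste0("features_", tolower(g), ".csv")),
                       row.names = FALSE)
      utils::write.csv(univ[[g]],
                       file.path(config$out_dir, paste0("univariate_", tolower(g), ".csv")),
                       row.names = FALSE)
    }
    utils::write.csv(comparisons, file.path(config$out_dir, "model_comparisons.csv"),
                     row.names = FALSE)
    summary_js <- list(
      pca_dims = as.list(pca_dims),
      metrics = lapply(reports, function(r) {
        list(mean = as.list(r$metrics["mean", ]), sd = as.list(r$metrics["sd", ]),
             pooled_auc = r$pooled_roc$auc)
      }),
      sensitivity = list(entries = A_est$entries,
                         condition_number = A_est$condition_number),
      seed = config$seed)
    jsonlite::write_json(summary_js, file.path(config$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
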