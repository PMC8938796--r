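#!/usr/bin/env Rscript

# Stage 6: multivariate analysis per feature space. The PCA 90% rule
# estimates the subset dimension; stratified Monte Carlo repeated
# cross-validation (50 repeats x 5 folds, >= 2 subjects of each class per
# validation fold) with in-fold MRMR selection and ridge-logistic
# classification yields per-repeat AUC/accuracy/precision/recall at the
# precision = recall threshold; pairwise Wilcoxon signed-rank tests
# compare the three models; the selection-frequency audit and the
# exhaustive k-sweep are written alongside.

library(pcdradiomics)

seed <- 2028L
raw <- lapply(c(EID = "eid", PCD = "pcd", MaterialMaps = "materialmaps"),
              function(g) utils::read.csv(file.path("results/tables",
                                                    paste0("features_", g, ".csv")),
                                          check.names = FALSE))
labels <- raw[[1]]$class
tables <- lapply(raw, function(tb)
  tb[, setdiff(names(tb), c("subject_id", "class")), drop = FALSE])

dims <- vapply(tables, function(tb) suppressWarnings(pca_dim(tb)), 0L)
cat("PCA 90% dimensions:", paste(names(dims), dims, collapse = ", "), "\n")
k <- max(dims)

cfg <- cv_config(n_repeats = 50, n_folds = 5, k_features = k, seed = seed)
folds <- stratified_mc_folds(labels, cfg)
reports <- lapply(tables, run_cv, labels = labels, config = cfg, folds = folds)

perf <- do.call(rbind, lapply(names(reports), function(g) {
  m <- reports[[g]]$metrics
  data.frame(model = g, k = k,
             accuracy = m["mean", "accuracy"], accuracy_sd = m["sd", "accuracy"],
             precision = m["mean", "precision"], recall = m["mean", "recall"],
             auc = m["mean", "auc"], auc_sd = m["sd", "auc"],
             pooled_auc = reports[[g]]$pooled_roc$auc)
}))
utils::write.csv(perf, "results/tables/classification_performance.csv",
                 row.names = FALSE)
print(perf)

pairs <- utils::combn(names(reports), 2, simplify = FALSE)
cmp <- do.call(rbind, lapply(pairs, function(pr) {
  data.frame(model_a = pr[1], model_b = pr[2],
             p_value = compare_models(reports[[pr[1]]]$auc_per_repeat,
                                      reports[[pr[2]]]$auc_per_repeat)$p_value)
}))
utils::write.csv(cmp, "results/tables/model_comparisons.csv", row.names = FALSE)
print(cmp)

for (g in names(reports)) {
  utils::write.csv(utils::head(reports[[g]]$selection_frequency, 25),
                   file.path("results/tables",
                             paste0("selection_frequency_", tolower(g), ".csv")),
                   row.names = FALSE)
}

# exhaustive sweep over the number of selected features (1..k) on the
# spectral (PCD) space, shared folds across ks
sw <- sweep_k(tables$PCD, labels, cfg, k_range = seq_len(k))
utils::write.csv(sw, "results/tables/k_sweep_pcd.csv", row.names = FALSE)
cat("Wrote k-sweep (1..", k, ") for the PCD space\n", sep = "")
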