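#!/usr/bin/env Rscript

# Stage 5: univariate association of every radiomic feature with the
# class label (two-sided Wilcoxon-Mann-Whitney), with Benjamini-Hochberg
# control at 0.05 applied within each feature group.

library(pcdradiomics)

for (g in c("eid", "pcd", "materialmaps")) {
  tb <- utils::read.csv(file.path("results/tables",
                                  paste0("features_", g, ".csv")),
                        check.names = FALSE)
  labels <- tb$class
  X <- tb[, setdiff(names(tb), c("subject_id", "class")), drop = FALSE]
  res <- univariate_screen(X, labels)
  utils::write.csv(res, file.path("results/tables",
                                  paste0("univariate_", g, ".csv")),
                   row.names = FALSE)
  cat(g, ":", sum(res$significant), "of", nrow(res),
      "features significant after BH\n")
}
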