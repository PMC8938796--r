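## Univariate association of features with the class label:
## Wilcoxon-Mann-Whitney rank-sum tests per feature with Benjamini-Hochberg
## false-discovery control, applied within each feature group.

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sided, unpaired. Exact p-value when the combined sample size is at
#' most 20 and no ties are present; otherwise the normal approximation
#' with tie correction. When every value in both groups is identical the
#' test is undefined and p = 1 is returned with a flag.
#'
#' @param x,y numeric vectors (both non-empty).
#' @return list with `U` (rank-sum statistic of `x`), `p_value`, and
#'   `degenerate` flag.
#' @export
wilcoxon_mw <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  if (length(unique(c(x, y))) == 1L) {
    return(list(U = length(x) * length(y) / 2, p_value = 1, degenerate = TRUE))
  }
  has_ties <- anyDuplicated(c(x, y)) > 0
  use_exact <- (length(x) + length(y)) <= 20 && !has_ties
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                       correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value, degenerate = FALSE)
}

#' Benjamini-Hochberg step-up correction
#'
#' @param p_values numeric vector of raw p-values in `[0, 1]`.
#' @param alpha significance level for the flags (default 0.05).
#' @return list with `adjusted` p-values and logical `significant` flags
#'   (adjusted <= alpha); empty input gives empty output.
#' @export
bh_correct <- function(p_values, alpha = 0.05) {
  if (length(p_values) == 0L) {
    return(list(adjusted = numeric(0), significant = logical(0)))
  }
  stopifnot(all(p_values >= 0 & p_values <= 1))
  adj <- stats::p.adjust(p_values, method = "BH")
  list(adjusted = adj, significant = adj <= alpha)
}

#' Univariate screen of a feature table
#'
#' Runs [wilcoxon_mw()] on every column against the two-level class label
#' and applies [bh_correct()] across the table's features (one feature
#' group; run once per group to control the FDR within groups).
#'
#' @param table data.frame or matrix, subjects x features.
#' @param labels class labels (two levels); factor or character.
#' @param alpha BH significance level.
#' @return data.frame with columns `feature`, `U`, `p_value`,
#'   `bh_adjusted_p`, `significant`, `degenerate`.
#' @export
univariate_screen <- function(table, labels, alpha = 0.05) {
  labels <- as.factor(labels)
  stopifnot(nlevels(labels) == 2L, min(table(labels)) >= 2L,
            nrow(table) == length(labels))
  lv <- levels(labels)
  res <- lapply(seq_len(ncol(table)), function(j) {
    col <- table[[j]]
    wilcoxon_mw(col[labels == lv[1L]], col[labels == lv[2L]])
  })
  p <- vapply(res, `[[`, 0, "p_value")
  bh <- bh_correct(p, alpha)
  data.frame(feature = colnames(table),
             U = vapply(res, `[[`, 0, "U"),
             p_value = p,
             bh_adjusted_p = bh$adjusted,
             significant = bh$significant,
             degenerate = vapply(res, `[[`, TRUE, "degenerate"),
             row.names = NULL)
}
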