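## Dimensionality estimation (PCA 90% variability rule) and minimum
## redundancy - maximum relevance (MRMR) feature ranking. MRMR uses the
## difference criterion (MID): greedy forward selection maximizing
## I(feature; class) - mean I(feature; selected), with mutual information
## estimated on equal-frequency 3-bin discretized features.

#' Number of components capturing a variance fraction
#'
#' Columns are standardized (zero mean, unit variance) before the
#' decomposition; zero-variance columns are dropped with a warning.
#'
#' @param table subjects x features data.frame or matrix (>= 2 rows).
#' @param var_frac target cumulative explained-variance fraction.
#' @return smallest k whose leading singular vectors capture at least
#'   `var_frac` of the variance; never exceeds `min(rows - 1, cols)`.
#' @export
pca_dim <- function(table, var_frac = 0.90) {
  X <- as.matrix(table)
  stopifnot(nrow(X) >= 2L, var_frac > 0, var_frac <= 1)
  sds <- apply(X, 2L, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance column(s) dropped")
    X <- X[, sds > 0, drop = FALSE]
  }
  pr <- stats::prcomp(X, center = TRUE, scale. = TRUE)
  ev <- pr$sdev^2
  frac <- cumsum(ev) / sum(ev)
  unname(which(frac >= var_frac - 1e-12)[1L])
}

## equal-frequency discretization into n_bins levels (quantile cut with
## mid-rank tie handling, so monotone transforms leave levels unchanged)
equal_freq_bins <- function(x, n_bins = 3L) {
  r <- rank(x, ties.method = "average")
  lv <- as.integer(ceiling(r / length(x) * n_bins))
  pmin(pmax(lv, 1L), n_bins)
}

## mutual information (nats) between two integer-level vectors
mi_discrete <- function(a, b, n_a = max(a), n_b = max(b)) {
  n <- length(a)
  joint <- tabulate(a + (b - 1L) * n_a, nbins = n_a * n_b) / n
  pa <- tabulate(a, nbins = n_a) / n
  pb <- tabulate(b, nbins = n_b) / n
  pij <- joint[joint > 0]
  idx <- which(joint > 0) - 1L
  ai <- idx %% n_a + 1L
  bi <- idx %/% n_a + 1L
  sum(pij * log(pij / (pa[ai] * pb[bi])))
}

## vectorized MI between every column of an n x p level matrix and one
## level vector; used for both relevance and redundancy updates
mi_columns <- function(Z, y, n_z = 3L, n_y = max(y)) {
  n <- nrow(Z)
  py <- tabulate(y, nbins = n_y) / n
  out <- numeric(ncol(Z))
  for (a in seq_len(n_z)) {
    Za <- Z == a
    pa <- colMeans(Za)
    for (b in seq_len(n_y)) {
      pab <- colMeans(Za & (y == b))
      pos <- pab > 0
      out[pos] <- out[pos] + pab[pos] * log(pab[pos] / (pa[pos] * py[b]))
    }
  }
  out
}

#' MRMR feature ranking
#'
#' Greedy forward selection: the first feature maximizes the mutual
#' information with the class label; each subsequent feature maximizes
#' relevance minus the mean redundancy (pairwise MI) with the already
#' selected features. Ties break to the earlier column, making the
#' ranking deterministic.
#'
#' @param table subjects x features data.frame or matrix.
#' @param labels class labels.
#' @param k number of features to rank (<= number of columns).
#' @param n_bins equal-frequency bins for MI estimation (default 3).
#' @param criterion `"mid"` (default; relevance minus mean redundancy) or
#'   `"miq"` (relevance divided by mean redundancy).
#' @return object of class `ranked_features`: `features` (ordered names),
#'   `relevance`, `redundancy` and `score` per selection step.
#' @export
mrmr_rank <- function(table, labels, k, n_bins = 3L,
                      criterion = c("mid", "miq")) {
  criterion <- match.arg(criterion)
  X <- as.matrix(table)
  p <- ncol(X)
  if (k > p) stop("k (", k, ") exceeds the number of features (", p, ")")
  y <- as.integer(as.factor(labels))
  stopifnot(length(unique(y)) >= 2L, nrow(X) == length(y))

  Z <- apply(X, 2L, equal_freq_bins, n_bins = n_bins)
  rel <- mi_columns(Z, y, n_z = n_bins, n_y = max(y))
  # constant features discretize to a single level; their MI is 0 already

  selected <- integer(0)
  red_sum <- numeric(p)
  rel_out <- red_out <- score_out <- numeric(k)
  for (step in seq_len(k)) {
    score <- if (step == 1L) {
      rel
    } else if (criterion == "mid") {
      rel - red_sum / length(selected)
    } else {
      rel / (red_sum / length(selected) + 1e-12)
    }
    score[selected] <- -Inf
    best <- which.max(score) # ties: first column in table order
    selected <- c(selected, best)
    rel_out[step] <- rel[best]
    red_out[step] <- if (step == 1L) 0 else red_sum[best] / (step - 1L)
    score_out[step] <- score[best]
    if (step < k) {
      red_sum <- red_sum + mi_columns(Z, Z[, best], n_z = n_bins, n_y = n_bins)
    }
  }
  structure(list(features = colnames(X)[selected],
                 indices = selected,
                 relevance = rel_out, redundancy = red_out,
                 score = score_out),
            class = "ranked_features")
}
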