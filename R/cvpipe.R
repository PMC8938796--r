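## Stratified Monte Carlo repeated cross-validation with in-fold MRMR
## feature selection and ridge-logistic classification. Per fold: rank
## features on the training subjects only, standardize with training
## statistics, fit, and predict the validation subjects. Per repeat the
## validation predictions are pooled into an ROC; the report aggregates
## mean +/- sd over repeats, with the per-repeat AUC vector kept for
## paired signed-rank model comparisons.

#' Cross-validation configuration
#'
#' @param n_repeats Monte Carlo repeats (default 50).
#' @param n_folds validation folds per repeat (default 5).
#' @param min_per_class_per_fold stratification constraint (default 2).
#' @param k_features MRMR features selected within each fold (default 11).
#' @param seed RNG seed for the fold draws.
#' @param lambda L2 (ridge) penalty of the logistic classifier. Unpenalized
#'   fits diverge on small separable training splits, so a light penalty
#'   is kept on by default.
#' @param positive_class label treated as positive for precision/recall.
#' @param n_bins equal-frequency bins for the MRMR MI estimates.
#' @export
cv_config <- function(n_repeats = 50L, n_folds = 5L,
                      min_per_class_per_fold = 2L, k_features = 11L,
                      seed = 1L, lambda = 0.05,
                      positive_class = "positive", n_bins = 3L) {
  stopifnot(n_folds >= 2L, n_repeats >= 1L, k_features >= 1L, lambda >= 0)
  list(n_repeats = as.integer(n_repeats), n_folds = as.integer(n_folds),
       min_per_class_per_fold = as.integer(min_per_class_per_fold),
       k_features = as.integer(k_features), seed = as.integer(seed),
       lambda = lambda, positive_class = positive_class,
       n_bins = as.integer(n_bins))
}

#' Stratified Monte Carlo fold assignments
#'
#' Per repeat, an independent random partition of the subjects into
#' `n_folds` validation folds such that every fold holds at least
#' `min_per_class_per_fold` subjects of each class. Class counts per fold
#' differ by at most one.
#'
#' @param labels class labels.
#' @param config a [cv_config()].
#' @return list of length `n_repeats`; each element is an integer vector
#'   assigning every subject to a validation fold 1..n_folds.
#' @export
stratified_mc_folds <- function(labels, config) {
  labels <- as.factor(labels)
  cls <- levels(labels)
  nf <- config$n_folds
  for (cl in cls) {
    n_c <- sum(labels == cl)
    if (floor(n_c / nf) < config$min_per_class_per_fold) {
      stop("infeasible stratification: class '", cl, "' has ", n_c,
           " subjects but needs at least ",
           nf * config$min_per_class_per_fold,
           " (", config$min_per_class_per_fold, " per validation fold)")
    }
  }
  set.seed(config$seed)
  lapply(seq_len(config$n_repeats), function(r) {
    fold <- integer(length(labels))
    for (cl in cls) {
      idx <- sample(which(labels == cl))
      n_c <- length(idx)
      base <- rep(seq_len(nf), floor(n_c / nf))
      extra <- sample(nf, n_c - length(base))
      fold[idx] <- c(base, extra)
    }
    fold
  })
}

## ridge-penalized logistic regression by Newton iteration (penalty on
## the slopes, not the intercept); sized for the tiny per-fold problems
ridge_logistic_fit <- function(X, y, lambda, max_iter = 50L, tol = 1e-8) {
  X1 <- cbind(1, X)
  p <- ncol(X1)
  beta <- numeric(p)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  for (it in seq_len(max_iter)) {
    eta <- as.vector(X1 %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- pmax(mu * (1 - mu), 1e-10)
    g <- crossprod(X1, y - mu) - pen %*% beta
    H <- crossprod(X1 * w, X1) + pen
    step <- solve(H, g)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  beta
}

ridge_logistic_predict <- function(beta, X) {
  1 / (1 + exp(-as.vector(cbind(1, X) %*% beta)))
}

#' ROC curve and AUC
#'
#' AUC via the rank (Mann-Whitney) statistic: the probability that a
#' random positive outranks a random negative, ties counted half.
#'
#' @param predictions numeric scores.
#' @param labels class labels (two present).
#' @param positive_class label counted as positive.
#' @return list with `auc`, and the monotone `curve` (data.frame fpr/tpr
#'   from (0,0) to (1,1)).
#' @export
roc_and_auc <- function(predictions, labels, positive_class = "positive") {
  pos <- labels == positive_class
  n_p <- sum(pos); n_n <- sum(!pos)
  if (n_p == 0L || n_n == 0L) stop("both classes must be present")
  r <- rank(predictions, ties.method = "average")
  auc <- (sum(r[pos]) - n_p * (n_p + 1) / 2) / (n_p * n_n)
  ord <- order(predictions, decreasing = TRUE)
  tpr <- c(0, cumsum(pos[ord]) / n_p)
  fpr <- c(0, cumsum(!pos[ord]) / n_n)
  # merge tied thresholds so the curve is a function of the threshold
  thr <- c(Inf, predictions[ord])
  keep <- !duplicated(thr, fromLast = TRUE)
  list(auc = auc, curve = data.frame(fpr = fpr[keep], tpr = tpr[keep],
                                     threshold = thr[keep]))
}

#' Precision = recall decision threshold
#'
#' Sweeps the unique scores as thresholds (score >= t positive); the
#' crossing of precision and recall is located by linear interpolation
#' between adjacent candidate thresholds. Without a crossing inside the
#' score range the fallback 0.5 is returned with a flag.
#'
#' @inheritParams roc_and_auc
#' @return list with `threshold` and `fallback` flag.
#' @export
decision_threshold <- function(predictions, labels, positive_class = "positive") {
  pos <- labels == positive_class
  if (!any(pos) || all(pos)) stop("both classes must be present")
  ts <- sort(unique(predictions))
  pr <- vapply(ts, function(t) {
    pred_pos <- predictions >= t
    tp <- sum(pred_pos & pos)
    c(if (any(pred_pos)) tp / sum(pred_pos) else 1, tp / sum(pos))
  }, numeric(2L))
  diffs <- pr[1L, ] - pr[2L, ] # precision - recall, increasing in t
  if (all(diffs < 0) || all(diffs > 0)) {
    return(list(threshold = 0.5, fallback = TRUE))
  }
  i <- which(diffs >= 0)[1L]
  if (i == 1L || diffs[i] == 0) {
    return(list(threshold = ts[i], fallback = FALSE))
  }
  # linear interpolation of the sign change between ts[i-1] and ts[i]
  d0 <- diffs[i - 1L]; d1 <- diffs[i]
  w <- -d0 / (d1 - d0)
  list(threshold = ts[i - 1L] + w * (ts[i] - ts[i - 1L]), fallback = FALSE)
}

classification_metrics <- function(predictions, labels, threshold,
                                   positive_class = "positive") {
  pos <- labels == positive_class
  pred_pos <- predictions >= threshold
  tp <- sum(pred_pos & pos)
  c(accuracy = mean(pred_pos == pos),
    precision = if (any(pred_pos)) tp / sum(pred_pos) else 0,
    recall = tp / sum(pos))
}

#' Run the repeated cross-validation pipeline on one feature table
#'
#' Within every fold: MRMR on the training subjects only selects
#' `k_features` columns, features are standardized with training mean/sd,
#' a ridge-logistic model is fit and validation probabilities predicted.
#' Per repeat the pooled validation predictions give the ROC/AUC and the
#' precision = recall threshold at which accuracy, precision and recall
#' are measured. The report aggregates mean and sd over repeats.
#'
#' @param table subjects x features data.frame or matrix (no missing
#'   values).
#' @param labels class labels, length nrow(table).
#' @param config a [cv_config()].
#' @param folds optional precomputed fold assignments (as produced by
#'   [stratified_mc_folds()]); defaults to drawing them from the config.
#' @return object of class `model_report`: `metrics` (mean/sd of
#'   accuracy, precision, recall, auc), `auc_per_repeat`, `pooled_roc`,
#'   `selection_frequency`, `fold_results`, `threshold` (mean over
#'   repeats), `config`.
#' @export
run_cv <- function(table, labels, config = cv_config(), folds = NULL) {
  X <- as.matrix(table)
  stopifnot(!anyNA(X), ncol(X) >= config$k_features)
  labels <- as.character(labels)
  if (is.null(folds)) folds <- stratified_mc_folds(labels, config)
  pc <- config$positive_class
  y_all <- as.integer(labels == pc)

  n_rep <- length(folds)
  auc_rep <- acc_rep <- prec_rep <- rec_rep <- thr_rep <- numeric(n_rep)
  pooled_scores <- pooled_labels <- list()
  fold_results <- list()
  for (r in seq_len(n_rep)) {
    fr <- folds[[r]]
    scores <- numeric(length(labels))
    for (f in sort(unique(fr))) {
      val <- fr == f
      tr <- !val
      if (length(unique(labels[tr])) < 2L) {
        stop("degenerate training split (one class absent); check stratification")
      }
      rk <- mrmr_rank(X[tr, , drop = FALSE], labels[tr], config$k_features,
                      n_bins = config$n_bins)
      sel <- rk$indices
      mu <- colMeans(X[tr, sel, drop = FALSE])
      sdv <- apply(X[tr, sel, drop = FALSE], 2L, stats::sd)
      sdv[sdv == 0] <- 1
      Xtr <- sweep(sweep(X[tr, sel, drop = FALSE], 2L, mu), 2L, sdv, "/")
      Xva <- sweep(sweep(X[val, sel, drop = FALSE], 2L, mu), 2L, sdv, "/")
      beta <- ridge_logistic_fit(Xtr, y_all[tr], config$lambda)
      scores[val] <- ridge_logistic_predict(beta, Xva)
      fold_results[[length(fold_results) + 1L]] <-
        list(repeat_id = r, fold_id = f,
             selected = colnames(X)[sel],
             predictions = scores[val], labels = labels[val])
    }
    roc <- roc_and_auc(scores, labels, pc)
    auc_rep[r] <- roc$auc
    th <- decision_threshold(scores, labels, pc)
    thr_rep[r] <- th$threshold
    met <- classification_metrics(scores, labels, th$threshold, pc)
    acc_rep[r] <- met["accuracy"]; prec_rep[r] <- met["precision"]
    rec_rep[r] <- met["recall"]
    pooled_scores[[r]] <- scores
    pooled_labels[[r]] <- labels
  }
  sel_freq <- selection_histogram(fold_results)
  pooled <- roc_and_auc(unlist(pooled_scores), unlist(pooled_labels), pc)
  metrics <- rbind(
    mean = c(accuracy = mean(acc_rep), precision = mean(prec_rep),
             recall = mean(rec_rep), auc = mean(auc_rep)),
    sd = c(accuracy = stats::sd(acc_rep), precision = stats::sd(prec_rep),
           recall = stats::sd(rec_rep), auc = stats::sd(auc_rep)))
  structure(list(metrics = metrics,
                 auc_per_repeat = auc_rep,
                 accuracy_per_repeat = acc_rep,
                 pooled_roc = pooled,
                 selection_frequency = sel_freq,
                 fold_results = fold_results,
                 threshold = mean(thr_rep),
                 config = config),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat("Repeated CV report (", x$config$n_repeats, " x ",
      x$config$n_folds, " folds, k = ", x$config$k_features, ")\n", sep = "")
  m <- x$metrics
  for (nm in colnames(m)) {
    cat(sprintf("  %-9s %.3f +/- %.3f\n", nm, m["mean", nm], m["sd", nm]))
  }
  cat("  pooled AUC", sprintf("%.3f", x$pooled_roc$auc), "\n")
  invisible(x)
}

#' Feature selection frequency over all folds
#'
#' @param fold_results list of per-fold results (from [run_cv()], or the
#'   `fold_results` component of a report).
#' @return data.frame `feature`, `frequency` sorted decreasing; a feature
#'   selected in every fold of a 50 x 5 run has frequency 250.
#' @export
selection_histogram <- function(fold_results) {
  if (inherits(fold_results, "model_report")) fold_results <- fold_results$fold_results
  tab <- table(unlist(lapply(fold_results, `[[`, "selected")))
  out <- data.frame(feature = names(tab), frequency = as.integer(tab),
                    row.names = NULL)
  out[order(-out$frequency, out$feature), , drop = FALSE]
}

#' Classifier performance as a function of the number of features
#'
#' Reruns the full cross-validation for every k in `k_range`, sharing the
#' fold assignments across ks so the comparison is paired.
#'
#' @inheritParams run_cv
#' @param k_range feature counts to evaluate (default 1..k_features).
#' @return data.frame with one row per k: mean and sd of accuracy,
#'   precision, recall and AUC.
#' @export
sweep_k <- function(table, labels, config = cv_config(),
                    k_range = seq_len(config$k_features)) {
  stopifnot(max(k_range) <= ncol(table))
  folds <- stratified_mc_folds(labels, config)
  rows <- lapply(k_range, function(k) {
    cfg <- config; cfg$k_features <- as.integer(k)
    rep <- run_cv(table, labels, cfg, folds = folds)
    data.frame(k = k,
               accuracy = rep$metrics["mean", "accuracy"],
               accuracy_sd = rep$metrics["sd", "accuracy"],
               precision = rep$metrics["mean", "precision"],
               recall = rep$metrics["mean", "recall"],
               auc = rep$metrics["mean", "auc"],
               auc_sd = rep$metrics["sd", "auc"])
  })
  do.call(rbind, rows)
}

#' Paired signed-rank comparison of two models' AUC samples
#'
#' Two-sided Wilcoxon signed-rank test on the per-repeat AUC vectors,
#' paired by repeat. Zero differences are dropped (their count is
#' reported); the exact distribution is used for n <= 25 pairs without
#' ties in the absolute differences.
#'
#' @param auc_a,auc_b equal-length per-repeat AUC vectors.
#' @return list with `p_value`, `n_nonzero`, `degenerate` flag (all
#'   differences zero gives p = 1).
#' @export
compare_models <- function(auc_a, auc_b) {
  stopifnot(length(auc_a) == length(auc_b))
  d <- auc_a - auc_b
  dn <- d[d != 0]
  nz <- length(dn)
  if (nz == 0L) return(list(p_value = 1, n_nonzero = 0L, degenerate = TRUE))
  if (nz <= 14L) {
    # exact sign-flip enumeration (valid with tied |d|, using mid-ranks)
    r <- rank(abs(dn))
    w_obs <- sum(r[dn > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), nz)))
    w_all <- as.vector(signs %*% r)
    p <- 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs))
    return(list(p_value = min(1, p), n_nonzero = nz, degenerate = FALSE))
  }
  use_exact <- nz <= 25 && !anyDuplicated(abs(dn))
  wt <- suppressWarnings(
    stats::wilcox.test(auc_a, auc_b, paired = TRUE, exact = use_exact,
                       alternative = "two.sided"))
  list(p_value = wt$p.value, n_nonzero = nz, degenerate = FALSE)
}
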