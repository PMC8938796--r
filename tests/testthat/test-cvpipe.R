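test_that("stratified folds satisfy the class minimum and partition", {
  labels <- rep(c("positive", "negative"), c(13, 12))
  cfg <- cv_config(n_repeats = 10, n_folds = 5, min_per_class_per_fold = 2,
                   seed = 11)
  folds <- stratified_mc_folds(labels, cfg)
  expect_length(folds, 10L)
  for (fr in folds) {
    expect_setequal(unique(fr), 1:5)          # every subject in one fold
    expect_length(fr, 25L)
    for (f in 1:5) {
      expect_gte(sum(fr == f & labels == "positive"), 2L)
      expect_gte(sum(fr == f & labels == "negative"), 2L)
    }
  }
  # total validation folds over the run
  expect_equal(sum(vapply(folds, function(fr) length(unique(fr)), 0L)), 50L)

  expect_error(stratified_mc_folds(rep(c("a", "b"), c(5, 20)), cfg),
               "infeasible")
})

test_that("AUC equals the rank-sum statistic, ties counted half", {
  r <- roc_and_auc(c(0.1, 0.2, 0.8, 0.9), c("negative", "negative", "positive", "positive"))
  expect_equal(r$auc, 1.0)
  expect_equal(r$curve$fpr[1], 0)
  expect_equal(utils::tail(r$curve$tpr, 1), 1)

  # all tied scores: half credit
  expect_equal(roc_and_auc(rep(0.5, 6), rep(c("positive", "negative"), 3))$auc, 0.5)

  # random scores vs the direct pairwise oracle
  set.seed(112)
  s <- round(runif(40), 2) # ties included
  l <- sample(c("positive", "negative"), 40, replace = TRUE, prob = c(0.4, 0.6))
  pos <- s[l == "positive"]; neg <- s[l == "negative"]
  oracle <- mean(outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b)))
  expect_equal(roc_and_auc(s, l)$auc, oracle, tolerance = 1e-12)
  # independent cross-check against pROC
  expect_equal(roc_and_auc(s, l)$auc,
               as.numeric(pROC::auc(pROC::roc(l, s, levels = c("negative", "positive"),
                                              direction = "<", quiet = TRUE))),
               tolerance = 1e-12)
  expect_true(all(diff(roc_and_auc(s, l)$curve$tpr) >= 0))
  expect_error(roc_and_auc(s, rep("positive", 40)), "both classes")
})

test_that("the precision = recall threshold matches a sweep oracle", {
  # perfectly separated: any threshold in the gap gives precision=recall=1
  th <- decision_threshold(c(0.1, 0.2, 0.8, 0.9),
                           c("negative", "negative", "positive", "positive"))
  expect_false(th$fallback)
  expect_gte(th$threshold, 0.2); expect_lte(th$threshold, 0.8)

  # symmetric balanced scores around 0.5
  th2 <- decision_threshold(c(0.3, 0.45, 0.55, 0.7),
                            c("negative", "negative", "positive", "positive"))
  expect_gte(th2$threshold, 0.45); expect_lte(th2$threshold, 0.55)

  # brute-force sweep: the returned threshold equalizes precision and
  # recall at least as well as any candidate cut
  set.seed(113)
  s <- runif(60)
  l <- ifelse(runif(60) < plogis(6 * (s - 0.5)), "positive", "negative")
  if (length(unique(l)) == 2) {
    th3 <- decision_threshold(s, l)
    gap <- function(t) {
      pp <- s >= t
      tp <- sum(pp & l == "positive")
      abs((if (any(pp)) tp / sum(pp) else 1) - tp / sum(l == "positive"))
    }
    best_cand <- min(vapply(sort(unique(s)), gap, 0))
    expect_lte(gap(th3$threshold), max(best_cand, 0.08) + 1e-9)
  }
})

test_that("separable and permuted tables give extreme and chance AUC", {
  set.seed(114)
  n <- 30
  y <- rep(c("positive", "negative"), each = n / 2)
  X <- data.frame(sep = ifelse(y == "positive", 1, 0) + rnorm(n, sd = 1e-3),
                  noise = rnorm(n))
  cfg <- cv_config(n_repeats = 5, n_folds = 5, k_features = 1, seed = 3)
  rep_sep <- run_cv(X, y, cfg)
  expect_equal(rep_sep$pooled_roc$auc, 1.0)
  expect_equal(unname(rep_sep$metrics["mean", "accuracy"]), 1.0)

  yp <- sample(y)
  rep_null <- run_cv(data.frame(f = rnorm(n)), yp,
                     cv_config(n_repeats = 20, n_folds = 5, k_features = 1, seed = 4))
  expect_gt(rep_null$pooled_roc$auc, 0.25)
  expect_lt(rep_null$pooled_roc$auc, 0.75)
})

test_that("no training information leaks into validation folds", {
  set.seed(115)
  n <- 24
  y <- rep(c("positive", "negative"), each = n / 2)
  cfg <- cv_config(n_repeats = 4, n_folds = 4, min_per_class_per_fold = 2,
                   k_features = 1, seed = 5)
  folds <- stratified_mc_folds(y, cfg)

  # canary A: a feature equal to the label everywhere drives AUC to 1
  X_full <- data.frame(leak = as.numeric(y == "positive") + rnorm(n, sd = 1e-3),
                       noise = rnorm(n))
  expect_gt(run_cv(X_full, y, cfg, folds = folds)$pooled_roc$auc, 0.99)

  # canary B: a feature that equals the label ONLY in the validation rows
  # of one fold (pure noise in training). With training-only selection and
  # standardization the validation AUC of that fold stays at chance on
  # average: the fitted sign of a noise feature is symmetric
  auc_b <- vapply(1:12, function(r) {
    fr <- stratified_mc_folds(y, cv_config(n_repeats = 1, n_folds = 4,
                                           min_per_class_per_fold = 2,
                                           seed = 50 + r))[[1]]
    val <- fr == 1L
    X <- data.frame(leak = rnorm(n), noise = rnorm(n))
    X$leak[val] <- as.numeric(y[val] == "positive")
    rep_b <- run_cv(X, y, cv_config(n_repeats = 1, n_folds = 4,
                                    min_per_class_per_fold = 2,
                                    k_features = 1, seed = 50 + r),
                    folds = list(fr))
    fold1 <- Filter(function(fl) fl$fold_id == 1L, rep_b$fold_results)[[1]]
    roc_and_auc(fold1$predictions, fold1$labels)$auc
  }, 0)
  expect_lt(mean(auc_b), 0.8)
  expect_gt(mean(auc_b), 0.2)
})

test_that("selection frequencies count folds and sum to k x folds", {
  set.seed(116)
  n <- 20
  y <- rep(c("positive", "negative"), each = 10)
  X <- as.data.frame(matrix(rnorm(n * 12), n))
  X$V1 <- X$V1 + (y == "positive") * 10 # always selected
  cfg <- cv_config(n_repeats = 6, n_folds = 5, k_features = 3, seed = 7)
  rep <- run_cv(X, y, cfg)
  sf <- rep$selection_frequency
  expect_equal(sf$frequency[sf$feature == "V1"], 30L) # every one of 6 x 5 folds
  expect_equal(sum(sf$frequency), 3L * 30L)           # k x total folds
  expect_true(all(sf$frequency <= 30L))
})

test_that("repeated CV is deterministic and the k-sweep shares folds", {
  set.seed(117)
  n <- 20
  y <- rep(c("positive", "negative"), each = 10)
  X <- as.data.frame(matrix(rnorm(n * 8), n))
  X$V1 <- X$V1 + (y == "positive") * 1.2
  cfg <- cv_config(n_repeats = 4, n_folds = 5, k_features = 3, seed = 9)
  r1 <- run_cv(X, y, cfg)
  r2 <- run_cv(X, y, cfg)
  expect_identical(r1$metrics, r2$metrics)
  expect_identical(r1$auc_per_repeat, r2$auc_per_repeat)

  sw <- sweep_k(X, y, cfg, k_range = 1:3)
  expect_equal(nrow(sw), 3L)
  cfg1 <- cfg; cfg1$k_features <- 1L
  folds <- stratified_mc_folds(y, cfg)
  expect_equal(sw$auc[1], run_cv(X, y, cfg1, folds = folds)$metrics["mean", "auc"],
               tolerance = 1e-12)
})

test_that("paired signed-rank comparison matches enumeration", {
  expect_equal(compare_models(c(1, 2, 3), c(1, 2, 3))$p_value, 1)
  expect_true(compare_models(c(1, 2, 3), c(1, 2, 3))$degenerate)

  # constant positive offset over 6 pairs: p = 2/64
  expect_equal(compare_models(1:6 + 0.1, 1:6 * 1.0)$p_value, 2 / 64)

  # random pairs vs independent enumeration for n <= 10
  set.seed(118)
  for (rep_i in 1:5) {
    a <- rnorm(8); b <- a + rnorm(8, 0.3)
    d <- a - b; d <- d[d != 0]
    r <- rank(abs(d))
    w_obs <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), length(d))))
    w_all <- as.vector(signs %*% r)
    p_or <- min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
    expect_equal(compare_models(a, b)$p_value, p_or, tolerance = 1e-12)
  }
})

test_that("pooled CV AUC approaches the binormal closed form", {
  # single Gaussian feature, class shift 1.5, unit variance:
  # theoretical AUC = Phi(1.5 / sqrt(2)) ~ 0.856
  set.seed(119)
  n <- 200
  y <- rep(c("positive", "negative"), each = n / 2)
  X <- data.frame(f = (y == "positive") * 1.5 + rnorm(n))
  cfg <- cv_config(n_repeats = 10, n_folds = 5, k_features = 1, seed = 13)
  rep <- run_cv(X, y, cfg)
  expect_lt(abs(rep$pooled_roc$auc - pnorm(1.5 / sqrt(2))), 0.05)
})
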