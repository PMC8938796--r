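# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite stays fast.

# ellipsoid test mask inside a given grid
make_ball <- function(grid = c(32, 32, 32), r = 10) {
  pcdradiomics:::ellipsoid_mask(grid, (grid + 1) / 2, rep(r, 3))
}

# small noiseless subject with uniform tumor iodine
make_uniform_subject <- function(grid = c(32, 32, 32), iodine = 5,
                                 noise_sd = 0, seed = 11) {
  spec <- phantom_spec(grid_shape = grid, noise_sd = noise_sd, seed = seed,
                       iodine_mean_mgml = iodine,
                       iodine_texture = list(corr_length = 2, amplitude = 0))
  simulate_subject(spec)
}

# independent mutual information (nats) by direct table enumeration,
# used as the MRMR oracle
mi_oracle <- function(a, b) {
  ta <- table(a, b)
  p <- ta / sum(ta)
  pa <- rowSums(p); pb <- colSums(p)
  s <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (p[i, j] > 0) s <- s + p[i, j] * log(p[i, j] / (pa[i] * pb[j]))
  }
  s
}

# brute-force greedy MRMR (MID criterion) recomputing every MI naively
mrmr_oracle <- function(X, y, k, n_bins = 3L) {
  bins <- function(x) {
    r <- rank(x, ties.method = "average")
    pmin(pmax(as.integer(ceiling(r / length(x) * n_bins)), 1L), n_bins)
  }
  Z <- apply(as.matrix(X), 2, bins)
  yf <- as.integer(as.factor(y))
  p <- ncol(Z)
  rel <- vapply(seq_len(p), function(j) mi_oracle(Z[, j], yf), 0)
  sel <- integer(0)
  for (step in seq_len(k)) {
    score <- vapply(seq_len(p), function(j) {
      if (j %in% sel) return(-Inf)
      if (length(sel) == 0) return(rel[j])
      rel[j] - mean(vapply(sel, function(s) mi_oracle(Z[, j], Z[, s]), 0))
    }, 0)
    sel <- c(sel, which.max(score))
  }
  colnames(X)[sel]
}

# exhaustive two-sided rank-sum p-value by enumerating all group
# assignments (oracle for small samples)
wmw_exact_oracle <- function(x, y) {
  all_v <- c(x, y)
  n1 <- length(x)
  u_stat <- function(xi) {
    sum(rank(all_v)[xi]) - n1 * (n1 + 1) / 2
  }
  obs <- u_stat(seq_len(n1))
  combos <- utils::combn(length(all_v), n1)
  us <- apply(combos, 2, u_stat)
  mu <- n1 * length(y) / 2
  mean(abs(us - mu) >= abs(obs - mu) - 1e-12)
}
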