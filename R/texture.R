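## Gray-level texture matrices and their derived statistics, computed in
## 3D on the discretized (fixed-bin-width) masked volume. Directional
## matrices (co-occurrence, run length) are built over the 13 unique 3D
## voxel directions and their features averaged across directions; zone,
## neighborhood-difference and dependence matrices use the full
## 26-neighborhood. Feature definitions follow the IBSI-aligned standard
## set; degenerate inputs (a single gray level) take their limit values.

.eps <- 2^-52

## per-family feature censuses (pinned; the group totals depend on them)
texture_census <- function() {
  list(glcm = 24L, glrlm = 16L, glszm = 16L, ngtdm = 5L, gldm = 14L)
}

## ---------------------------------------------------------------- GLCM --

glcm_matrix <- function(levels, n_levels, offset) {
  p <- shift_pairs(levels, offset)
  ok <- !is.na(p$a) & !is.na(p$b)
  a <- p$a[ok]; b <- p$b[ok]
  if (length(a) == 0L) return(matrix(0, n_levels, n_levels))
  cnt <- tabulate(a + (b - 1L) * n_levels, nbins = n_levels^2)
  M <- matrix(cnt, n_levels, n_levels)
  M + t(M) # symmetric co-occurrence
}

glcm_features_single <- function(P) {
  ng <- nrow(P)
  s <- sum(P)
  if (s == 0) return(NULL)
  P <- P / s
  i <- seq_len(ng)
  px <- rowSums(P); py <- colSums(P)
  mux <- sum(i * px); muy <- sum(i * py)
  sx <- sqrt(sum((i - mux)^2 * px)); sy <- sqrt(sum((i - muy)^2 * py))
  I <- matrix(i, ng, ng); J <- t(I)
  # diagonal (difference) and cross-diagonal (sum) marginals
  k_d <- 0:(ng - 1L)
  p_d <- as.vector(rowsum(as.vector(P), as.vector(abs(I - J))))
  if (length(p_d) < ng) p_d <- c(p_d, numeric(ng - length(p_d)))
  k_s <- 2:(2 * ng)
  p_s0 <- as.vector(rowsum(as.vector(P), as.vector(I + J)))
  p_s <- numeric(2L * ng - 1L)
  p_s[sort(unique(as.vector(I + J))) - 1L] <- p_s0
  hx <- -sum(px * log2(px + .eps))
  hy <- -sum(py * log2(py + .eps))
  hxy <- -sum(P * log2(P + .eps))
  pxy <- outer(px, py)
  hxy1 <- -sum(P * log2(pxy + .eps))
  hxy2 <- -sum(pxy * log2(pxy + .eps))
  da <- sum(k_d * p_d)
  autoc <- sum(I * J * P)

  # MCC: second largest eigenvalue of the transition-like matrix Q
  mcc <- {
    keep <- px > 0
    if (sum(keep) < 2L) 1 else {
      Pk <- P[keep, keep, drop = FALSE]
      Q <- (Pk / px[keep]) %*% t(Pk / matrix(py[keep], sum(keep), sum(keep), byrow = TRUE))
      ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
      sqrt(max(0, min(1, ev[2L])))
    }
  }

  c(Autocorrelation = autoc,
    ClusterProminence = sum((I + J - mux - muy)^4 * P),
    ClusterShade = sum((I + J - mux - muy)^3 * P),
    ClusterTendency = sum((I + J - mux - muy)^2 * P),
    Contrast = sum((I - J)^2 * P),
    Correlation = if (sx > 0 && sy > 0) (autoc - mux * muy) / (sx * sy) else 1,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(p_d * log2(p_d + .eps)),
    DifferenceVariance = sum((k_d - da)^2 * p_d),
    Id = sum(P / (1 + abs(I - J))),
    Idm = sum(P / (1 + (I - J)^2)),
    Idmn = sum(P / (1 + ((I - J) / ng)^2)),
    Idn = sum(P / (1 + abs(I - J) / ng)),
    Imc1 = if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0,
    Imc2 = sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy)))),
    InverseVariance = sum(P[I != J] / (I - J)[I != J]^2),
    JointAverage = mux,
    JointEnergy = sum(P^2),
    JointEntropy = hxy,
    MCC = mcc,
    MaximumProbability = max(P),
    SumAverage = sum(k_s * p_s),
    SumEntropy = -sum(p_s * log2(p_s + .eps)),
    SumSquares = sum((I - mux)^2 * P))
}

#' Gray level co-occurrence features (24), averaged over 13 directions
#' @param levels integer level array (NA outside mask), see [discretize()].
#' @param n_levels number of gray levels.
#' @return named numeric vector of 24 features.
#' @export
glcm_features <- function(levels, n_levels) {
  dirs <- unique_directions_13()
  acc <- NULL; nd <- 0L
  for (r in seq_len(nrow(dirs))) {
    f <- glcm_features_single(glcm_matrix(levels, n_levels, dirs[r, ]))
    if (is.null(f)) next
    acc <- if (is.null(acc)) f else acc + f
    nd <- nd + 1L
  }
  if (nd == 0L) stop("mask has no voxel pairs for co-occurrence")
  acc / nd
}

## --------------------------------------------------------------- GLRLM --

## run-length matrix for one direction: order voxels along the direction's
## lines and split runs where the line, the position or the level changes
glrlm_matrix <- function(levels, n_levels, offset) {
  d <- dim(levels)
  idx <- which(!is.na(levels))
  if (length(idx) == 0L) return(matrix(0, n_levels, 1L))
  co <- arrayInd(idx, d)
  lv <- levels[idx]
  # parameterize each line by the coordinate along the direction's first
  # nonzero axis (steps of the direction change it by exactly 1)
  ax <- which(offset != 0)[1L]
  t_par <- co[, ax] * offset[ax]
  line1 <- co[, 1L] - t_par * offset[1L]
  line2 <- co[, 2L] - t_par * offset[2L]
  line3 <- co[, 3L] - t_par * offset[3L]
  o <- order(line1, line2, line3, t_par)
  lv <- lv[o]; t_par <- t_par[o]
  l1 <- line1[o]; l2 <- line2[o]; l3 <- line3[o]
  n <- length(lv)
  newrun <- c(TRUE, l1[-1L] != l1[-n] | l2[-1L] != l2[-n] | l3[-1L] != l3[-n] |
                t_par[-1L] != t_par[-n] + 1L | lv[-1L] != lv[-n])
  run_id <- cumsum(newrun)
  run_len <- tabulate(run_id)
  run_lv <- lv[newrun]
  max_len <- max(run_len)
  M <- matrix(0, n_levels, max_len)
  cnt <- tabulate(run_lv + (run_len - 1L) * n_levels, nbins = n_levels * max_len)
  M[] <- cnt
  M
}

## shared statistics for (gray level x size) matrices: run length, zone
## size and dependence matrices all use the same functional forms
size_matrix_features <- function(M, n_voxels) {
  i <- seq_len(nrow(M))
  l <- seq_len(ncol(M))
  Ns <- sum(M)
  if (Ns == 0) stop("degenerate size matrix")
  P <- M / Ns
  mi <- rowSums(M); ml <- colSums(M)
  mu_i <- sum(i * rowSums(P)); mu_l <- sum(l * colSums(P))
  L2 <- matrix(l^2, nrow(M), ncol(M), byrow = TRUE)
  I2 <- matrix(i^2, nrow(M), ncol(M))
  out <- c(
    sum(M / L2) / Ns,                       # small emphasis
    sum(M * L2) / Ns,                       # large emphasis
    sum(mi^2) / Ns,                         # gray level non-uniformity
    sum(mi^2) / Ns^2,                       # ... normalized
    sum(ml^2) / Ns,                         # size non-uniformity
    sum(ml^2) / Ns^2,                       # ... normalized
    Ns / n_voxels,                          # percentage
    sum((matrix(i, nrow(M), ncol(M)) - mu_i)^2 * P),   # gray level variance
    sum((matrix(l, nrow(M), ncol(M), byrow = TRUE) - mu_l)^2 * P), # size variance
    -sum(P * log2(P + .eps)),               # entropy
    sum(M / I2) / Ns,                       # low gray level emphasis
    sum(M * I2) / Ns,                       # high gray level emphasis
    sum(M / (I2 * L2)) / Ns,
    sum(M * I2 / L2) / Ns,
    sum(M * L2 / I2) / Ns,
    sum(M * I2 * L2) / Ns
  )
  out
}

#' Gray level run length features (16), averaged over 13 directions
#' @inheritParams glcm_features
#' @export
glrlm_features <- function(levels, n_levels) {
  dirs <- unique_directions_13()
  n_vox <- sum(!is.na(levels))
  nms <- c("ShortRunEmphasis", "LongRunEmphasis", "GrayLevelNonUniformity",
           "GrayLevelNonUniformityNormalized", "RunLengthNonUniformity",
           "RunLengthNonUniformityNormalized", "RunPercentage",
           "GrayLevelVariance", "RunVariance", "RunEntropy",
           "LowGrayLevelRunEmphasis", "HighGrayLevelRunEmphasis",
           "ShortRunLowGrayLevelEmphasis", "ShortRunHighGrayLevelEmphasis",
           "LongRunLowGrayLevelEmphasis", "LongRunHighGrayLevelEmphasis")
  acc <- 0
  for (r in seq_len(nrow(dirs))) {
    M <- glrlm_matrix(levels, n_levels, dirs[r, ])
    acc <- acc + size_matrix_features(M, n_vox)
  }
  stats::setNames(acc / nrow(dirs), nms)
}

## --------------------------------------------------------------- GLSZM --

## connected zones (26-connectivity) of equal gray level, via the
## components of the same-level adjacency graph
glszm_matrix <- function(levels, n_levels) {
  d <- dim(levels)
  idx <- which(!is.na(levels))
  vox_id <- array(NA_integer_, d)
  vox_id[idx] <- seq_along(idx)
  dirs <- unique_directions_13()
  ei <- integer(0); ej <- integer(0)
  for (r in seq_len(nrow(dirs))) {
    pi_ <- shift_pairs(vox_id, dirs[r, ])
    pl <- shift_pairs(levels, dirs[r, ])
    ok <- !is.na(pl$a) & !is.na(pl$b) & pl$a == pl$b
    ei <- c(ei, pi_$a[ok]); ej <- c(ej, pi_$b[ok])
  }
  g <- igraph::graph_from_edgelist(cbind(ei, ej), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(idx) - igraph::vcount(g)))
  comp <- igraph::components(g)
  zone_size <- comp$csize
  # gray level of each zone: level of any member voxel
  memb <- comp$membership[seq_along(idx)]
  zone_lv <- integer(comp$no)
  zone_lv[memb] <- levels[idx]
  max_s <- max(zone_size)
  M <- matrix(0, n_levels, max_s)
  cnt <- tabulate(zone_lv + (zone_size - 1L) * n_levels, nbins = n_levels * max_s)
  M[] <- cnt
  M
}

#' Gray level size zone features (16)
#' @inheritParams glcm_features
#' @export
glszm_features <- function(levels, n_levels) {
  n_vox <- sum(!is.na(levels))
  M <- glszm_matrix(levels, n_levels)
  nms <- c("SmallAreaEmphasis", "LargeAreaEmphasis", "GrayLevelNonUniformity",
           "GrayLevelNonUniformityNormalized", "SizeZoneNonUniformity",
           "SizeZoneNonUniformityNormalized", "ZonePercentage",
           "GrayLevelVariance", "ZoneVariance", "ZoneEntropy",
           "LowGrayLevelZoneEmphasis", "HighGrayLevelZoneEmphasis",
           "SmallAreaLowGrayLevelEmphasis", "SmallAreaHighGrayLevelEmphasis",
           "LargeAreaLowGrayLevelEmphasis", "LargeAreaHighGrayLevelEmphasis")
  stats::setNames(size_matrix_features(M, n_vox), nms)
}

## --------------------------------------------------------------- NGTDM --

#' Neighboring gray tone difference features (5)
#'
#' For every masked voxel the mean gray level of its in-mask 26-neighbors
#' is formed; `s_i` accumulates the absolute differences per level.
#' Voxels with no valid neighbor are excluded.
#' @inheritParams glcm_features
#' @export
ngtdm_features <- function(levels, n_levels) {
  d <- dim(levels)
  val <- ifelse(is.na(levels), 0, as.numeric(levels))
  inm <- !is.na(levels)
  nb_sum <- array(0, d); nb_cnt <- array(0, d)
  offs26 <- neighbor_offsets_26()
  for (r in seq_len(nrow(offs26))) {
    o <- offs26[r, ]
    if (any(d - abs(o) <= 0)) next
    i <- max(1L, 1L + o[1L]):min(d[1L], d[1L] + o[1L])
    j <- max(1L, 1L + o[2L]):min(d[2L], d[2L] + o[2L])
    k <- max(1L, 1L + o[3L]):min(d[3L], d[3L] + o[3L])
    nb_sum[i, j, k] <- nb_sum[i, j, k] + val[i - o[1L], j - o[2L], k - o[3L]]
    nb_cnt[i, j, k] <- nb_cnt[i, j, k] + inm[i - o[1L], j - o[2L], k - o[3L]]
  }
  use <- inm & nb_cnt > 0
  lv <- levels[use]
  abar <- nb_sum[use] / nb_cnt[use]
  nvp <- sum(use)
  if (nvp == 0L) stop("no voxel has valid neighbors")
  n_i <- tabulate(lv, nbins = n_levels)
  s_i <- as.numeric(rowsum(abs(lv - abar), lv, reorder = TRUE))
  s_full <- numeric(n_levels)
  s_full[sort(unique(lv))] <- s_i
  p_i <- n_i / nvp
  i <- seq_len(n_levels)
  present <- p_i > 0
  ngp <- sum(present)

  coarse <- if (sum(p_i * s_full) > 0) 1 / sum(p_i * s_full) else 1e6
  contrast <- if (ngp > 1) {
    sum(outer(p_i[present], p_i[present]) *
          outer(i[present], i[present], `-`)^2) / (ngp * (ngp - 1)) *
      sum(s_full) / nvp
  } else 0
  busy_den <- sum(abs(outer(i[present] * p_i[present],
                            i[present] * p_i[present], `-`)))
  busy <- if (busy_den > 0) sum(p_i * s_full) / busy_den else 0
  cplx <- if (nvp > 0 && ngp > 1) {
    ip <- i[present]; pp <- p_i[present]; sp <- s_full[present]
    sum(outer(ip, ip, function(a, b) abs(a - b)) *
          (outer(pp * sp, rep(1, ngp)) + outer(rep(1, ngp), pp * sp)) /
          (outer(pp, rep(1, ngp)) + outer(rep(1, ngp), pp))) / nvp
  } else 0
  strength <- if (sum(s_full) > 0 && ngp > 1) {
    ip <- i[present]; pp <- p_i[present]
    sum((outer(pp, rep(1, ngp)) + outer(rep(1, ngp), pp)) *
          outer(ip, ip, `-`)^2) / sum(s_full)
  } else 0
  c(Coarseness = coarse, Contrast = contrast, Busyness = busy,
    Complexity = cplx, Strength = strength)
}

## ---------------------------------------------------------------- GLDM --

#' Gray level dependence features (14)
#'
#' The dependence of a voxel is 1 plus the number of its in-mask
#' 26-neighbors whose gray level differs by at most `alpha`.
#' @inheritParams glcm_features
#' @param alpha dependence tolerance in gray levels (default 0).
#' @export
gldm_features <- function(levels, n_levels, alpha = 0) {
  d <- dim(levels)
  dep <- array(0L, d)
  offs <- neighbor_offsets_26()
  for (r in seq_len(nrow(offs))) {
    o <- offs[r, ]
    if (any(d - abs(o) <= 0)) next
    i <- max(1L, 1L + o[1L]):min(d[1L], d[1L] + o[1L])
    j <- max(1L, 1L + o[2L]):min(d[2L], d[2L] + o[2L])
    k <- max(1L, 1L + o[3L]):min(d[3L], d[3L] + o[3L])
    a <- levels[i, j, k]
    b <- levels[i - o[1L], j - o[2L], k - o[3L]]
    ok <- !is.na(a) & !is.na(b) & abs(a - b) <= alpha
    dd <- dep[i, j, k]
    dd[ok] <- dd[ok] + 1L
    dep[i, j, k] <- dd
  }
  inm <- !is.na(levels)
  lv <- levels[inm]
  dp <- dep[inm] + 1L # include the center voxel
  max_d <- max(dp)
  M <- matrix(0, n_levels, max_d)
  cnt <- tabulate(lv + (dp - 1L) * n_levels, nbins = n_levels * max_d)
  M[] <- cnt
  nms <- c("SmallDependenceEmphasis", "LargeDependenceEmphasis",
           "GrayLevelNonUniformity", "GLNN_drop", "DependenceNonUniformity",
           "DependenceNonUniformityNormalized", "DependencePercentage_drop",
           "GrayLevelVariance", "DependenceVariance", "DependenceEntropy",
           "LowGrayLevelEmphasis", "HighGrayLevelEmphasis",
           "SmallDependenceLowGrayLevelEmphasis", "SmallDependenceHighGrayLevelEmphasis",
           "LargeDependenceLowGrayLevelEmphasis", "LargeDependenceHighGrayLevelEmphasis")
  raw <- stats::setNames(size_matrix_features(M, sum(inm)), nms)
  # the dependence family census (14) drops the normalized gray level
  # non-uniformity and the percentage (identically 1: every masked voxel
  # has a dependence)
  raw[!names(raw) %in% c("GLNN_drop", "DependencePercentage_drop")]
}

## ------------------------------------------------------------ dispatch --

#' Texture features of one family
#'
#' @param volume numeric volume.
#' @param mask logical mask (or `tumor_mask`).
#' @param family one of `"glcm"`, `"glrlm"`, `"glszm"`, `"ngtdm"`, `"gldm"`.
#' @param bin_width discretization bin width.
#' @return named numeric feature vector (24/16/16/5/14 values).
#' @export
texture_features <- function(volume, mask,
                             family = c("glcm", "glrlm", "glszm", "ngtdm", "gldm"),
                             bin_width = 25) {
  family <- match.arg(family)
  dz <- discretize(volume, mask, bin_width)
  fun <- switch(family, glcm = glcm_features, glrlm = glrlm_features,
                glszm = glszm_features, ngtdm = ngtdm_features,
                gldm = gldm_features)
  fun(dz$levels, dz$n_levels)
}
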