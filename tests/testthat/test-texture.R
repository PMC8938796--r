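# Brute-force oracles for the texture matrices: explicit voxel loops,
# independent of the vectorized builders in the package.

oracle_glcm <- function(lv, offset, n_levels) {
  d <- dim(lv)
  M <- matrix(0, n_levels, n_levels)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    i2 <- i + offset[1]; j2 <- j + offset[2]; k2 <- k + offset[3]
    if (i2 < 1 || i2 > d[1] || j2 < 1 || j2 > d[2] || k2 < 1 || k2 > d[3]) next
    a <- lv[i, j, k]; b <- lv[i2, j2, k2]
    if (is.na(a) || is.na(b)) next
    M[a, b] <- M[a, b] + 1
    M[b, a] <- M[b, a] + 1
  }
  M
}

oracle_runs <- function(lv, offset) {
  # walk every line in the direction explicitly, collect (level, length)
  d <- dim(lv)
  starts <- which(array(TRUE, d), arr.ind = TRUE)
  is_start <- apply(starts, 1, function(p) {
    q <- p - offset
    any(q < 1) || any(q > d)
  })
  runs <- list()
  for (r in which(is_start)) {
    p <- starts[r, ]
    cur_lv <- NA; cur_len <- 0
    while (all(p >= 1) && all(p <= d)) {
      v <- lv[p[1], p[2], p[3]]
      if (!is.na(v) && !is.na(cur_lv) && v == cur_lv) {
        cur_len <- cur_len + 1
      } else {
        if (!is.na(cur_lv)) runs[[length(runs) + 1]] <- c(cur_lv, cur_len)
        cur_lv <- v; cur_len <- 1
      }
      p <- p + offset
    }
    if (!is.na(cur_lv)) runs[[length(runs) + 1]] <- c(cur_lv, cur_len)
  }
  do.call(rbind, runs)
}

test_that("co-occurrence entropy matches pair enumeration on a toy image", {
  lv <- array(c(1, 2, 5, 2,
                3, 2, 1, 3,
                1, 3, 5, 5,
                3, 1, 2, 1), c(4, 4, 1))
  ng <- 5L
  dirs <- pcdradiomics:::unique_directions_13()
  ent <- c(); nd <- 0
  for (r in seq_len(nrow(dirs))) {
    M <- oracle_glcm(lv, dirs[r, ], ng)
    if (sum(M) == 0) next
    P <- M / sum(M)
    ent <- c(ent, -sum(P[P > 0] * log2(P[P > 0])))
    nd <- nd + 1
  }
  f <- glcm_features(lv, ng)
  expect_equal(unname(f["JointEntropy"]), mean(ent), tolerance = 1e-12)
  # and the package matrix itself equals the enumerated one per direction
  for (r in c(1, 4, 9)) {
    expect_equal(pcdradiomics:::glcm_matrix(lv, ng, dirs[r, ]),
                 oracle_glcm(lv, dirs[r, ], ng))
  }
})

test_that("constant images give degenerate texture limits", {
  d <- c(6, 6, 6)
  m <- array(TRUE, d)
  dz <- discretize(array(42, d), m, 25)
  g <- glcm_features(dz$levels, dz$n_levels)
  expect_equal(unname(g["Contrast"]), 0)
  expect_equal(unname(g["Correlation"]), 1)
  expect_equal(unname(g["JointEnergy"]), 1, tolerance = 1e-10)
  n <- ngtdm_features(dz$levels, dz$n_levels)
  expect_equal(unname(n["Coarseness"]), 1e6) # defined degenerate value
  expect_equal(unname(n["Contrast"]), 0)
  r <- glrlm_features(dz$levels, dz$n_levels)
  expect_true(all(is.finite(r)))
  z <- glszm_features(dz$levels, dz$n_levels)
  expect_equal(unname(z["ZonePercentage"]), 1 / prod(d) * 1) # one zone
})

test_that("run-length matrices match explicit line walking", {
  set.seed(81)
  d <- c(5, 6, 4)
  lv <- array(sample(1:3, prod(d), replace = TRUE), d)
  lv[sample(prod(d), 20)] <- NA # holes in the mask break runs
  ng <- 3L
  dirs <- pcdradiomics:::unique_directions_13()
  for (r in seq_len(nrow(dirs))) {
    runs <- oracle_runs(lv, dirs[r, ])
    M_or <- matrix(0, ng, max(runs[, 2]))
    for (q in seq_len(nrow(runs))) {
      M_or[runs[q, 1], runs[q, 2]] <- M_or[runs[q, 1], runs[q, 2]] + 1
    }
    M <- pcdradiomics:::glrlm_matrix(lv, ng, dirs[r, ])
    expect_equal(M[, seq_len(ncol(M_or)), drop = FALSE], M_or)
    if (ncol(M) > ncol(M_or)) expect_true(all(M[, -seq_len(ncol(M_or))] == 0))
  }
})

test_that("alternating patterns emphasize short runs, blocks long runs", {
  d <- c(6, 6, 6)
  m <- array(TRUE, d)
  alt <- array(rep(c(100, 0), length.out = prod(d)), d) # alternates along axis 1
  blk <- array(0, d); blk[4:6, , ] <- 100                # two large blocks
  f_alt <- texture_features(alt, m, "glrlm", bin_width = 50)
  f_blk <- texture_features(blk, m, "glrlm", bin_width = 50)
  expect_gt(unname(f_alt["ShortRunEmphasis"]), unname(f_blk["ShortRunEmphasis"]))
  expect_lt(unname(f_alt["LongRunEmphasis"]), unname(f_blk["LongRunEmphasis"]))
  # short-run emphasis never exceeds 1; long-run emphasis never below 1
  expect_lte(unname(f_alt["ShortRunEmphasis"]), 1)
  expect_gte(unname(f_alt["LongRunEmphasis"]), 1)
})

test_that("size zones match flood-fill enumeration", {
  # independent flood-fill zone oracle (26-connectivity, equal level)
  oracle_zones <- function(lv) {
    d <- dim(lv)
    seen <- array(FALSE, d)
    offs <- pcdradiomics:::neighbor_offsets_26()
    zones <- list()
    for (v in which(!is.na(lv))) {
      if (seen[v]) next
      p0 <- arrayInd(v, d)
      queue <- list(as.integer(p0)); seen[v] <- TRUE; size <- 0L
      lev <- lv[v]
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]; size <- size + 1L
        for (r in seq_len(nrow(offs))) {
          q <- p + offs[r, ]
          if (any(q < 1) || any(q > d)) next
          qi <- q[1] + (q[2] - 1) * d[1] + (q[3] - 1) * d[1] * d[2]
          if (!seen[qi] && !is.na(lv[qi]) && lv[qi] == lev) {
            seen[qi] <- TRUE
            queue[[length(queue) + 1]] <- q
          }
        }
      }
      zones[[length(zones) + 1]] <- c(lev, size)
    }
    do.call(rbind, zones)
  }

  # separated plateaus of one level: two zones of size 6
  lv2 <- array(NA_integer_, c(7, 3, 1))
  lv2[1:2, , 1] <- 1L
  lv2[6:7, , 1] <- 1L
  M2 <- pcdradiomics:::glszm_matrix(lv2, 1L)
  expect_equal(unname(M2[1, 6]), 2)

  # random small image vs the oracle
  set.seed(83)
  lv <- array(sample(1:3, 4 * 4 * 3, replace = TRUE), c(4, 4, 3))
  lv[sample(length(lv), 6)] <- NA
  zo <- oracle_zones(lv)
  M <- pcdradiomics:::glszm_matrix(lv, 3L)
  M_or <- matrix(0, 3, max(zo[, 2]))
  for (q in seq_len(nrow(zo))) M_or[zo[q, 1], zo[q, 2]] <- M_or[zo[q, 1], zo[q, 2]] + 1
  expect_equal(M[, seq_len(ncol(M_or)), drop = FALSE], M_or)
})

test_that("dependence and neighborhood-difference features match voxel loops", {
  set.seed(82)
  d <- c(4, 5, 3)
  lv <- array(sample(1:3, prod(d), replace = TRUE), d)
  ng <- 3L
  offs <- pcdradiomics:::neighbor_offsets_26()

  # GLDM oracle: count dependent neighbors per voxel
  dep_or <- array(0L, d)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    cnt <- 0L
    for (r in seq_len(nrow(offs))) {
      p <- c(i, j, k) + offs[r, ]
      if (any(p < 1) || any(p > d)) next
      if (lv[p[1], p[2], p[3]] == lv[i, j, k]) cnt <- cnt + 1L
    }
    dep_or[i, j, k] <- cnt + 1L
  }
  M_or <- matrix(0, ng, max(dep_or))
  for (v in seq_len(prod(d))) {
    M_or[lv[v], dep_or[v]] <- M_or[lv[v], dep_or[v]] + 1
  }
  f <- gldm_features(lv, ng)
  Nz <- sum(M_or)
  L2 <- matrix(seq_len(ncol(M_or))^2, ng, ncol(M_or), byrow = TRUE)
  expect_equal(unname(f["SmallDependenceEmphasis"]), sum(M_or / L2) / Nz)
  expect_equal(unname(f["LargeDependenceEmphasis"]), sum(M_or * L2) / Nz)
  expect_length(f, 14L)

  # NGTDM oracle: neighbor-average differences
  nvp <- 0; s_i <- numeric(ng); n_i <- numeric(ng)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    nb <- c()
    for (r in seq_len(nrow(offs))) {
      p <- c(i, j, k) + offs[r, ]
      if (any(p < 1) || any(p > d)) next
      nb <- c(nb, lv[p[1], p[2], p[3]])
    }
    nvp <- nvp + 1
    l0 <- lv[i, j, k]
    n_i[l0] <- n_i[l0] + 1
    s_i[l0] <- s_i[l0] + abs(l0 - mean(nb))
  }
  p_i <- n_i / nvp
  coarse_or <- 1 / sum(p_i * s_i)
  fn <- ngtdm_features(lv, ng)
  expect_equal(unname(fn["Coarseness"]), coarse_or, tolerance = 1e-12)
  expect_length(fn, 5L)
})
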