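full <- function(q) matrix(TRUE, nrow(q), ncol(q))

test_that("hand-enumerated co-occurrences match on a 2x2 image", {
  q <- rbind(c(0L, 1L), c(0L, 1L))
  g <- glcm_matrix(q, full(q), 1, 0, symmetric = TRUE, n_levels = 2)
  expect_equal(g$pair_count, 4)
  expect_equal(g$p["0", "1"], 0.5)
  expect_equal(g$p["1", "0"], 0.5)
  expect_equal(g$p["0", "0"], 0)
  expect_equal(glcm_entropy(g), log(2))
  expect_equal(glcm_contrast(g), 1)
  expect_equal(glcm_variance(g), 0.25)  # mu = 0.5
})

test_that("constant images give a single-cell matrix and zero features", {
  q <- matrix(3L, 4, 5)
  for (o in c(0, 45, 90, 135)) {
    g <- glcm_matrix(q, full(q), 1, o, n_levels = 8)
    expect_equal(sum(g$p > 0), 1)
    expect_equal(g$p["3", "3"], 1)
    expect_equal(glcm_entropy(g), 0)
    expect_equal(glcm_contrast(g), 0)
    expect_equal(glcm_variance(g), 0)
  }
})

test_that("checkerboard contrast equals the squared level difference", {
  k <- 5L
  q <- outer(1:6, 1:6, function(r, cc) ifelse((r + cc) %% 2 == 0, 0L, k))
  g0 <- glcm_matrix(q, full(q), 1, 0, n_levels = k + 1)
  g90 <- glcm_matrix(q, full(q), 1, 90, n_levels = k + 1)
  g45 <- glcm_matrix(q, full(q), 1, 45, n_levels = k + 1)
  expect_equal(glcm_contrast(g0), k^2)
  expect_equal(glcm_contrast(g90), k^2)
  expect_equal(glcm_contrast(g45), 0)  # diagonal neighbours match
})

test_that("uniform co-occurrences attain maximal entropy", {
  # 1xN strip of distinct levels: symmetric GLCM is uniform over 2(N-1) cells
  q <- matrix(0:5, nrow = 1)
  g <- glcm_matrix(q, full(q), 1, 0, n_levels = 6)
  expect_equal(glcm_entropy(g), log(10), tolerance = 1e-12)
  expect_equal(glcm_entropy(g), log(sum(g$p > 0)))
})

test_that("matrices and features match the brute-force oracle on random masked images", {
  set.seed(55)
  for (rep in 1:100) {
    nr <- sample(4:8, 1)
    nc <- sample(4:8, 1)
    nlev <- sample(3:6, 1)
    q <- matrix(sample(0:(nlev - 1), nr * nc, TRUE), nr, nc)
    mask <- matrix(runif(nr * nc) < 0.75, nr, nc)
    o <- sample(c(0, 45, 90, 135), 1)
    sym <- sample(c(TRUE, FALSE), 1)
    g <- glcm_matrix(q, mask, 1, o, symmetric = sym, n_levels = nlev)
    orc <- glcm_oracle(q, mask, 1, o, sym, nlev)
    expect_equal(unname(unclass(g$p)), orc$p)
    expect_equal(g$pair_count, orc$pair_count)
    if (g$pair_count > 0) {
      expect_equal(glcm_entropy(g), oracle_entropy(orc$p))
      expect_equal(glcm_contrast(g), oracle_contrast(orc$p))
      if (sym) expect_equal(glcm_variance(g), oracle_variance(orc$p))
      expect_equal(sum(g$p), 1, tolerance = 1e-12)
    }
  }
})

test_that("GLCM variance equals the pair-membership variance of grey levels", {
  set.seed(7)
  q <- matrix(sample(0:4, 49, TRUE), 7, 7)
  mask <- matrix(runif(49) < 0.8, 7, 7)
  g <- glcm_matrix(q, mask, 1, 0, symmetric = TRUE, n_levels = 5)
  # direct pixel-pair statistic: collect both members of every ordered pair
  vals <- c()
  for (r in 1:7) for (cc in 1:6) {
    if (mask[r, cc] && mask[r, cc + 1]) vals <- c(vals, q[r, cc], q[r, cc + 1])
  }
  expect_equal(glcm_variance(g), mean((vals - mean(vals))^2), tolerance = 1e-12)
})

test_that("quantization rounds, clamps, and drops invalid pixels", {
  t2 <- matrix(c(39.6, 40.4, 250, NA), 2, 2)
  valid <- matrix(c(TRUE, TRUE, FALSE, FALSE), 2, 2)
  qr <- quantize_map(t2, valid, texture_config())
  expect_equal(qr$q[1, 1], 40L)
  expect_equal(qr$q[2, 1], 40L)
  expect_true(is.na(qr$q[1, 2]))       # invalid excluded
  expect_equal(sum(qr$mask), 2)
  # fixed-bin arithmetic: 40 in [0,80] over 16 bins -> level 8
  qb <- quantize_map(matrix(40), matrix(TRUE),
                     texture_config(quantization = "fixed_bins",
                                    n_levels = 16, bin_range = c(0, 80)))
  expect_equal(qb$q[1, 1], 8L)
  expect_error(quantize_map(t2, valid & FALSE, texture_config()),
               class = "cartex_empty_roi")
})

test_that("features are invariant to a constant grey-level shift", {
  set.seed(12)
  t2 <- matrix(runif(64, 30, 50), 8, 8)
  labels <- array(1L, dim = c(8, 8, 1))
  m1 <- fake_t2_map(array(t2, dim = c(8, 8, 1)), labels)
  m2 <- fake_t2_map(array(t2 + 20, dim = c(8, 8, 1)), labels)
  f1 <- compartment_texture(m1)
  f2 <- compartment_texture(m2)
  expect_equal(f1$contrast[1], f2$contrast[1], tolerance = 1e-9)
  expect_equal(f1$variance[1], f2$variance[1], tolerance = 1e-9)
  expect_equal(f1$entropy[1], f2$entropy[1], tolerance = 1e-9)
  expect_equal(f2$mean_t2[1] - f1$mean_t2[1], 20, tolerance = 1e-9)
})

test_that("single-slice constant compartment yields zero texture and exact mean", {
  labels <- array(0L, dim = c(6, 10, 1))
  labels[2:4, 2:9, 1] <- 1L
  t2 <- array(0, dim = dim(labels))
  t2[labels == 1] <- 37
  f <- compartment_texture(fake_t2_map(t2, labels))
  pat <- f[f$compartment == "pat", ]
  expect_equal(pat$mean_t2, 37)
  expect_equal(pat$contrast, 0)
  expect_equal(pat$entropy, 0)
  expect_equal(pat$variance, 0)
  # absent compartments are NA and excluded from the all-compartment average
  expect_true(is.na(f$contrast[f$compartment == "mf"]))
  expect_equal(f$mean_t2[f$compartment == "all"], 37)
})

test_that("equal-pair-count slices aggregate to the plain feature average", {
  labels <- array(0L, dim = c(6, 10, 2))
  labels[2:4, 2:9, ] <- 1L
  t2 <- array(0, dim = dim(labels))
  t2[, , 1][labels[, , 1] == 1] <- 30                      # constant slice
  set.seed(9)
  v <- sample(c(35L, 45L), sum(labels[, , 2] == 1), TRUE)  # textured slice
  t2[, , 2][labels[, , 2] == 1] <- v
  f <- compartment_texture(fake_t2_map(t2, labels))
  pat <- f[f$compartment == "pat", ]
  # slice features individually
  f1 <- compartment_texture(fake_t2_map(t2[, , 1, drop = FALSE],
                                        labels[, , 1, drop = FALSE]))
  f2 <- compartment_texture(fake_t2_map(t2[, , 2, drop = FALSE],
                                        labels[, , 2, drop = FALSE]))
  expect_equal(pat$contrast,
               (f1$contrast[1] + f2$contrast[1]) / 2, tolerance = 1e-9)
  expect_equal(pat$entropy,
               (f1$entropy[1] + f2$entropy[1]) / 2, tolerance = 1e-9)
})

test_that("mask covering the whole image reproduces whole-image features", {
  set.seed(31)
  q <- matrix(sample(0:5, 60, TRUE), 6, 10)
  g_masked <- glcm_matrix(q, full(q), 1, 45, n_levels = 6)
  orc <- glcm_oracle(q, full(q), 1, 45, TRUE, 6)
  expect_equal(unname(unclass(g_masked$p)), orc$p)
})

test_that("expected contrast and variance increase with heterogeneity", {
  cfg_lo <- sim_config(heterogeneity_sd = c(incidence = 3, control = 3),
                       n_slices = 1, seed = 61)
  cfg_hi <- sim_config(heterogeneity_sd = c(incidence = 6, control = 6),
                       n_slices = 1, seed = 61)
  s <- sample_subjects(cfg_lo, seed = 61)
  p <- draw_t2_parameters(s, cfg_lo, seed = 62)
  sp <- p[p$subject_id == s$subject_id[1], ]
  set.seed(63)
  seeds <- sample.int(1e6, 60)
  feat_mean <- function(cfg) {
    v <- sapply(seeds, function(sd_) {
      f <- build_t2_field(sp, cfg, seed = sd_)
      tx <- compartment_texture(fake_t2_map(f$t2, f$labels))
      c(tx$contrast[tx$compartment == "all"],
        tx$variance[tx$compartment == "all"])
    })
    rowMeans(v)
  }
  lo <- feat_mean(cfg_lo)
  hi <- feat_mean(cfg_hi)
  expect_gt(hi[1], lo[1])
  expect_gt(hi[2], lo[2])
})
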