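test_that("spatial PCA recovers planted rank structure", {
  set.seed(71)
  # rank-1: mean-zero unit vector v -> PC1 proportional to v, full variance
  v <- rnorm(30); v <- v - mean(v); v <- v / sqrt(sum(v^2))
  pc <- spatial_pca(3 * v %*% t(v))
  expect_equal(pc$variance_explained[1], 1, tolerance = 1e-9)
  expect_equal(abs(sum(pc$components[, 1] * v)), 1, tolerance = 1e-9)

  # zero matrix -> all eigenvalues zero
  expect_equal(spatial_pca(matrix(0, 10, 10))$eigenvalues, rep(0, 10))

  # planted variance fractions 0.52 / 0.18 on orthogonal mean-zero maps
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(40 * 6), 40))))[, -1]   # orthonormal, mean-zero
  wts <- c(0.52, 0.18, 0.12, 0.10, 0.05, 0.03)
  M <- Q %*% diag(wts) %*% t(Q)
  pc2 <- spatial_pca(M)
  expect_equal(pc2$variance_explained[1:2], c(0.52, 0.18), tolerance = 1e-6)
  expect_error(spatial_pca(matrix(rnorm(25), 5)), "symmetric")
})

test_that("eigenvalue sum equals the trace of the centred matrix", {
  set.seed(72)
  z <- matrix(rnorm(20 * 20), 20); z <- (z + t(z)) / 2; diag(z) <- NA
  cm <- structure(list(z = z, index = data.frame(unit = paste0("u", 1:20)),
                       kind = "roi"), class = "corr_matrix")
  pc <- spatial_pca(cm)
  z0 <- z; diag(z0) <- 0
  zc <- sweep(z0, 2, colMeans(z0))
  expect_equal(sum(pc$eigenvalues), sum(diag((zc + t(zc)) / 2)),
               tolerance = 1e-9)
})

test_that("permutation eigenvalue test is deterministic and detects real effects", {
  set.seed(73)
  p <- 12
  mk <- function(shift = 0) {
    z <- matrix(rnorm(p * p, sd = 0.3), p); z <- (z + t(z)) / 2
    z[1:4, 1:4] <- z[1:4, 1:4] + shift
    diag(z) <- NA; z
  }
  labs <- rep(c("A", "B"), each = 6)
  mats <- c(replicate(6, mk(1), simplify = FALSE),
            replicate(6, mk(0), simplify = FALSE))
  r1 <- permutation_eigen_test(mats, labs, n = 300, seed = 5)
  r2 <- permutation_eigen_test(mats, labs, n = 300, seed = 5)
  expect_identical(r1$null_eigenvalues, r2$null_eigenvalues)
  expect_true(r1$significant[1])      # planted block difference is detected
  expect_equal(dim(r1$null_eigenvalues), c(300, 2))
  expect_warning(permutation_eigen_test(mats[1:6], rep(c("A", "B"), each = 3),
                                        n = 300, seed = 1),
                 "with replacement")
})

test_that("ROI derivation is symmetric, thresholded and hemisphere-split", {
  atl <- make_atlas(64, 64, 0.156)
  # 3 planted bilateral positive blobs + 1 bilateral negative pair
  m <- matrix(0, 64, 64)
  for (rc in list(c(18, 18), c(32, 22), c(46, 16)))
    m <- m + 2 * gaussian_footprint(atl, rc, 2)
  m <- m - 1.5 * gaussian_footprint(atl, c(25, 12), 2)
  rs <- derive_rois(m, atl, smooth_sigma = 1.5)
  expect_equal(rs$n_left, 4)
  expect_equal(rs$n_right, 4)
  # mirrored input gives identical ROI sets (mirror-invariance)
  rs2 <- derive_rois(mirror_lr(m), atl, smooth_sigma = 1.5)
  expect_equal(sort(sapply(rs$rois, sum)), sort(sapply(rs2$rois, sum)))
  # each ROI lives in one hemisphere
  lh <- left_hemisphere(atl)
  hems <- vapply(rs$rois, attr, "", which = "hemisphere")
  for (nm in names(rs$rois)) {
    inL <- sum(rs$rois[[nm]] & lh); inR <- sum(rs$rois[[nm]] & !lh)
    if (hems[nm] == "L") expect_equal(inR, 0) else expect_equal(inL, 0)
  }
  # uniform positive map: one component per hemisphere
  u <- derive_rois(matrix(1, 64, 64), atl, smooth_sigma = 0)
  expect_equal(length(u$rois), 2)
  expect_warning(z <- derive_rois(matrix(0, 64, 64), atl), "survive")
  expect_equal(length(z$rois), 0)
})

test_that("recovery matrices measure planted connectivity change", {
  set.seed(74)
  mk_cm <- function(z12) {
    z <- matrix(0.2, 4, 4); z[1, 2] <- z[2, 1] <- z12; diag(z) <- NA
    structure(list(z = z, index = data.frame(unit = paste0("r", 1:4)),
                   kind = "roi"), class = "corr_matrix")
  }
  w1 <- replicate(5, mk_cm(0.3 + rnorm(1, 0, 0.02)), simplify = FALSE)
  w4 <- replicate(5, mk_cm(0.6 + rnorm(1, 0, 0.02)), simplify = FALSE)
  rm <- recovery_matrix(w4, w1)
  expect_equal(rm$values[1, 2], 0.3, tolerance = 0.05)
  expect_equal(rm$values[3, 4], 0, tolerance = 1e-12)
  # identical sessions -> zeros; week swap flips sign
  rm0 <- recovery_matrix(w1, w1)
  expect_true(all(rm0$values == 0, na.rm = TRUE))
  expect_equal(recovery_matrix(w1, w4)$values, -rm$values)
})

test_that("recovery differences flag only truly changed edges", {
  set.seed(75)
  mk_cm <- function(z12) {
    z <- matrix(0.2, 4, 4); z[1, 2] <- z[2, 1] <- z12; diag(z) <- NA
    structure(list(z = z, index = data.frame(unit = paste0("r", 1:4)),
                   kind = "roi"), class = "corr_matrix")
  }
  mk_group <- function(delta) {
    w1 <- replicate(6, mk_cm(0.3 + rnorm(1, 0, 0.02)), simplify = FALSE)
    w4 <- replicate(6, mk_cm(0.3 + delta + rnorm(1, 0, 0.02)), simplify = FALSE)
    recovery_matrix(w4, w1)
  }
  A <- mk_group(0.4); B <- mk_group(0)
  rd <- recovery_difference(A, B, q = 0.05)
  expect_equal(nrow(rd$edges), 1)
  expect_equal(rd$edges$roi_a, "r1")
  expect_equal(rd$edges$roi_b, "r2")
  expect_equal(rd$edges$delta_z, rd$values[1, 2])
  expect_gt(rd$edges$delta_z, 0)
  # identical groups -> empty edge list
  rd0 <- recovery_difference(A, A)
  expect_equal(nrow(rd0$edges), 0)
  expect_true(all(rd0$values == 0, na.rm = TRUE))
})
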