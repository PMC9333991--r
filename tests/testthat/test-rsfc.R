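test_that("ROI time courses are unweighted pixel means", {
  set.seed(61)
  x <- matrix(rnorm(9 * 20), 9)
  mv <- toy_movie(x, h = 3, w = 3)
  roi1 <- matrix(FALSE, 3, 3); roi1[2, 2] <- TRUE
  expect_equal(roi_timecourse(mv, roi1), x[5, ])

  mv2 <- toy_movie(rbind(x[1, ], -x[1, ]), h = 2, w = 1)
  expect_equal(roi_timecourse(mv2, matrix(TRUE, 2, 1)), rep(0, 20))

  roi <- matrix(runif(9) > 0.5, 3, 3); roi[1, 1] <- TRUE
  manual <- colMeans(x[as.vector(roi), , drop = FALSE])
  expect_equal(roi_timecourse(mv, roi), manual)
  expect_error(roi_timecourse(mv, matrix(FALSE, 3, 3)), "intersect")
})

test_that("Fisher z is atanh with clipping", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.4), 0.4236489, tolerance = 1e-6)
  r <- c(-0.9, -0.3, 0.2, 0.8)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_warning(z1 <- fisher_z(1), "clipped")
  expect_equal(z1, atanh(1 - 1e-7))
})

test_that("seed maps recover planted homotopic correlation and reject noise", {
  atl <- tiny_atlas()
  net <- two_node_network(atl, r = 0.7, noise_sd = 0.02e-6, duration = 300)
  sim <- simulate_resting(atl, net, seed = 62)
  roi <- disc_mask(atl, c(net$nodes$row[1], net$nodes$col[1]), 2)
  sm <- seed_map(sim$movie, roi)
  partner <- sm[net$nodes$row[2], net$nodes$col[2]]
  expect_lt(abs(partner - atanh(0.7)), 2 / sqrt(300 - 3))
  # an unrelated far-away pixel behaves like a null correlation
  far <- sm[5, 16]
  expect_lt(abs(far), 0.35)
  # seed region itself correlates near-perfectly
  expect_gt(sm[net$nodes$row[1], net$nodes$col[1]], atanh(0.9))
})

test_that("correlation matrices match a brute-force loop and Pearson invariance", {
  set.seed(63)
  x <- matrix(rnorm(5 * 40), 5)
  mv <- toy_movie(x, h = 5, w = 1)
  cm <- corr_matrix(mv, spatial_step = 1)
  for (i in 1:5) for (j in 1:5) {
    if (i == j) expect_true(is.na(cm$z[i, j]))
    else expect_equal(cm$z[i, j], atanh(cor(x[i, ], x[j, ])), tolerance = 1e-12)
  }
  # invariance to affine rescaling of one unit
  x2 <- x; x2[3, ] <- 5 - 2.5 * x2[3, ]
  cm2 <- corr_matrix(toy_movie(x2, h = 5, w = 1), spatial_step = 1)
  z_mag <- abs(cm$z); z2_mag <- abs(cm2$z)
  expect_equal(z2_mag[upper.tri(z2_mag)], z_mag[upper.tri(z_mag)],
               tolerance = 1e-12)
  # identical traces clip to the maximal z
  x3 <- rbind(x[1, ], x[1, ])
  cm3 <- corr_matrix(toy_movie(x3, h = 2, w = 1), spatial_step = 1)
  expect_equal(cm3$z[1, 2], atanh(1 - 1e-7))
})

test_that("node degree equals the brute-force pairwise count and is monotone", {
  mk_cm <- function(z) {
    diag(z) <- NA
    structure(list(z = z, index = data.frame(unit = paste0("u", seq_len(nrow(z)))),
                   kind = "roi"), class = "corr_matrix")
  }
  allhi <- mk_cm(matrix(1, 4, 4))
  expect_equal(unname(node_degree(allhi)$degree), rep(3L, 4))
  alllo <- mk_cm(matrix(0.1, 4, 4))
  expect_equal(unname(node_degree(alllo)$degree), rep(0L, 4))

  set.seed(64)
  for (trial in 1:20) {
    z <- matrix(rnorm(20 * 20, sd = 0.5), 20); z <- (z + t(z)) / 2
    cm <- mk_cm(z)
    deg <- node_degree(cm, 0.4)$degree
    brute <- sapply(1:20, function(i)
      sum(sapply(setdiff(1:20, i), function(j) z[i, j] >= 0.4)))
    expect_identical(unname(deg), as.integer(brute))
    # monotone non-increasing in the threshold
    degs <- sapply(c(0.2, 0.4, 0.6), function(th)
      sum(node_degree(cm, th)$degree))
    expect_true(all(diff(degs) <= 0))
  }
})

test_that("a planted hub has higher degree than non-hubs", {
  atl <- tiny_atlas()
  nodes <- data.frame(name = c("hub", "a", "b", "c", "d"),
                      row = c(16, 8, 8, 24, 24), col = c(16, 8, 24, 8, 24),
                      sigma = 2, hemisphere = c("L", "L", "R", "L", "R"))
  edges <- data.frame(from = "hub", to = c("a", "b", "c", "d"), r = 0.5)
  net <- network_spec(nodes, edges, noise_sd = 0.02e-6, duration = 400)
  sim <- simulate_resting(atl, net, seed = 65)
  rois <- lapply(seq_len(5), function(k)
    disc_mask(atl, c(nodes$row[k], nodes$col[k]), 2))
  names(rois) <- nodes$name
  cm <- corr_matrix(sim$movie, rois = rois)
  deg <- node_degree(cm, 0.4)$degree
  expect_gt(deg["hub"], median(deg[-1]))
})

test_that("difference matrices subtract group means and flip sign on swap", {
  set.seed(66)
  mk <- function() {
    z <- matrix(rnorm(16), 4); z <- (z + t(z)) / 2; diag(z) <- NA
    structure(list(z = z, index = data.frame(unit = paste0("u", 1:4)),
                   kind = "roi"), class = "corr_matrix")
  }
  A <- list(mk(), mk()); B <- list(mk(), mk())
  d <- difference_matrix(A, B)
  expect_equal(d$z, (A[[1]]$z + A[[2]]$z) / 2 - (B[[1]]$z + B[[2]]$z) / 2)
  dswap <- difference_matrix(B, A)
  expect_equal(dswap$z, -d$z)
  expect_true(all(abs(difference_matrix(A, A)$z) < 1e-15, na.rm = TRUE))
})

test_that("single-pixel seed maps agree with pixelwise matrix rows", {
  set.seed(67)
  x <- matrix(rnorm(16 * 50), 16)
  mv <- toy_movie(x, h = 4, w = 4)
  cm <- corr_matrix(mv, spatial_step = 1)
  roi <- matrix(FALSE, 4, 4); roi[2, 3] <- TRUE
  sm <- seed_map(mv, roi)
  unit <- which(cm$index$row == 2 & cm$index$col == 3)
  for (k in seq_len(nrow(cm$index))) {
    if (k == unit) next
    expect_equal(sm[cm$index$row[k], cm$index$col[k]], cm$z[unit, k],
                 tolerance = 1e-9)
  }
})
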