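test_that("block extraction slices the expected number of complete blocks", {
  par <- stim_paradigm("electrical")        # 18 blocks of 50 s
  mv <- toy_movie(matrix(0, 4, 900), h = 2, w = 2, frame_rate = 1)
  st <- extract_blocks(mv, par)
  expect_equal(dim(st$blocks), c(18, 4, 50))
  expect_equal(st$onsets_s, 5 + 0:17 * 50)

  short <- toy_movie(matrix(0, 4, 140), h = 2, w = 2, frame_rate = 1)
  expect_warning(st2 <- extract_blocks(short, par), "truncated")
  expect_equal(dim(st2$blocks)[1], 2)
})

test_that("block averaging is baseline-subtracted", {
  par <- stim_paradigm("electrical", n_blocks = 2)
  const <- toy_movie(matrix(3.5, 4, 100), h = 2, w = 2, frame_rate = 1)
  avg <- block_average(extract_blocks(const, par))
  expect_equal(avg$avg, matrix(0, 4, 50))

  # single block equals that block minus its baseline mean
  x <- matrix(seq_len(50), 1, 50, byrow = TRUE)
  one <- toy_movie(x, h = 1, w = 1, frame_rate = 1)
  par1 <- stim_paradigm("electrical", n_blocks = 1)
  avg1 <- block_average(extract_blocks(one, par1))
  bl <- mean(x[1, 1:4])   # frames at t = 0..3 s, window [onset-5, onset-1)
  expect_equal(as.vector(avg1$avg), as.vector(x) - bl)
})

test_that("peak map equals the brute-force mean over the offset window", {
  par <- stim_paradigm("electrical", n_blocks = 1)
  set.seed(51)
  x <- matrix(rnorm(4 * 50), 4)
  mv <- toy_movie(x, h = 2, w = 2, frame_rate = 1)
  st <- extract_blocks(mv, par)
  avg <- block_average(st)
  pm <- peak_map(avg)
  # offset at 15 s; window [13, 17) -> frames with t = 13..16 -> idx 14..17
  expect_equal(as.vector(pm), rowMeans(avg$avg[, 14:17]))
  expect_error(peak_map(avg, window = c(2, 60)), "window|empty")
})

test_that("group threshold is 75% of the group-mean maximum, order-invariant", {
  m1 <- matrix(c(1, 2, 3, 4), 2); m2 <- matrix(c(5, 6, 7, 12), 2)
  expect_equal(group_threshold(list(m1, m2)), 0.75 * 8)
  expect_equal(group_threshold(list(m2, m1)), 0.75 * 8)
  expect_equal(group_threshold(list(m2)), 9)
  expect_error(group_threshold(list()), "no baseline")
})

test_that("response metrics follow the thresholding rules", {
  pk <- matrix(c(5, 7, 9), 1, 3)
  em <- response_metrics(pk, threshold = 6)
  expect_equal(em$area, 2)
  expect_equal(em$magnitude, 9)

  below <- response_metrics(matrix(c(1, 2), 1, 2), threshold = 6)
  expect_equal(below$area, 0)
  expect_true(is.na(below$magnitude))

  at <- response_metrics(matrix(6, 2, 2), threshold = 6)
  expect_equal(at$area, 4)             # ties at threshold count

  # monotonicity: area and magnitude non-decreasing as threshold decreases
  set.seed(52)
  pk2 <- matrix(runif(64, 0, 10), 8)
  ths <- c(8, 6, 4, 2)
  mets <- lapply(ths, function(th) response_metrics(pk2, th))
  areas <- sapply(mets, `[[`, "area")
  mags <- sapply(mets, function(m) ifelse(is.na(m$magnitude), -Inf, m$magnitude))
  expect_true(all(diff(areas) >= 0))
  expect_true(all(diff(mags) >= 0))

  # fallback region quantifies sub-threshold responses
  fb <- response_metrics(matrix(c(1, 2), 1, 2), threshold = 6,
                         fallback_region = matrix(c(TRUE, TRUE), 1, 2))
  expect_equal(fb$magnitude, 2)
  expect_equal(fb$area, 0)
})

test_that("incidence maps count responding mice per pixel", {
  blob <- matrix(c(10, 10, 0, 0), 2)
  inc <- incidence_map(list(blob, blob, blob), threshold = 5)
  expect_equal(inc, matrix(c(1, 1, 0, 0), 2))
  half <- incidence_map(list(blob, matrix(0, 2, 2)), threshold = 5)
  expect_equal(half, matrix(c(0.5, 0.5, 0, 0), 2))
  expect_true(all(inc * 3 == round(inc * 3)))
})

test_that("T-maps match the one-sample t formula and flag degenerate pixels", {
  par <- stim_paradigm("electrical", n_blocks = 3)
  # craft blocks whose peak-minus-baseline values are 2, 4, 6 at pixel 1
  x <- matrix(0, 2, 150)
  for (b in 1:3) x[1, (b - 1) * 50 + 14:17] <- c(2, 4, 6)[b]
  mv <- toy_movie(x, h = 2, w = 1, frame_rate = 1)
  tm <- t_map(extract_blocks(mv, par))
  expect_equal(tm$dof, 2L)
  expect_equal(tm$t[1, 1], 4 / (2 / sqrt(3)), tolerance = 1e-9)  # 3.4641
  expect_true(is.na(tm$t[2, 1]))        # zero variance across blocks

  allzero <- toy_movie(matrix(0, 2, 150), h = 2, w = 1, frame_rate = 1)
  tz <- t_map(extract_blocks(allzero, par))
  expect_true(all(is.na(tz$t)))
})

test_that("Cohen's D maps match the brute-force pooled formula", {
  set.seed(53)
  mk_t <- function(vals) structure(list(t = matrix(vals, 2, 2), dof = 9L),
                                   class = "t_map")
  A <- replicate(5, mk_t(rnorm(4, mean = 5)), simplify = FALSE)
  B <- replicate(5, mk_t(rnorm(4, mean = 3)), simplify = FALSE)
  dm <- cohens_d_map(A, B)
  for (px in 1:4) {
    a <- sapply(A, function(x) x$t[px]); b <- sapply(B, function(x) x$t[px])
    expect_equal(as.vector(dm$d)[px], cohens_d(a, b), tolerance = 1e-12)
  }
  # identical groups give d = 0 wherever included
  dm0 <- cohens_d_map(A, A)
  expect_true(all(dm0$d[dm0$inclusion_mask] == 0))
  # sub-threshold pixels are excluded
  lowA <- replicate(3, mk_t(rnorm(4, mean = 0, sd = 0.1)), simplify = FALSE)
  dml <- cohens_d_map(lowA, lowA)
  expect_true(all(is.na(dml$d)))
})
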