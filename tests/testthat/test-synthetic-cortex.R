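test_that("atlas mask is symmetric, landmarked, and about 1 cm^2 at default size", {
  atl <- make_atlas(128, 128, 0.078)
  expect_identical(atl$brain_mask, mirror_lr(atl$brain_mask))
  area_cm2 <- sum(atl$brain_mask) * atl$pixel_size^2 / 100
  expect_gt(area_cm2, 0.5)
  expect_lt(area_cm2, 1.5)

  small <- make_atlas(32, 32, 0.3)
  for (lm in small$landmarks) {
    expect_true(lm["row"] >= 1 && lm["row"] <= 32)
    expect_true(lm["col"] >= 1 && lm["col"] <= 32)
    expect_true(small$brain_mask[lm["row"], lm["col"]])
  }
  expect_error(make_atlas(16, 16, 0.3), "at least 32")
})

test_that("independent nodes decorrelate and a planted correlation is recovered", {
  atl <- tiny_atlas()
  net0 <- two_node_network(atl, r = 0, noise_sd = 0)
  sim <- simulate_resting(atl, net0, seed = 11)
  tc <- sim$truth$node_timecourses
  expect_lt(abs(cor(tc[1, ], tc[2, ])), 0.1)

  net <- two_node_network(atl, r = 0.7, noise_sd = 0)
  sim <- simulate_resting(atl, net, seed = 12)
  r_emp <- cor(sim$truth$node_timecourses[1, ], sim$truth$node_timecourses[2, ])
  expect_lt(abs(r_emp - 0.7), 0.1)
})

test_that("resting simulation is a pure function of the seed", {
  atl <- tiny_atlas()
  net <- two_node_network(atl, r = 0.5, noise_sd = 0.1e-6, duration = 30)
  a <- simulate_resting(atl, net, seed = 99)
  b <- simulate_resting(atl, net, seed = 99)
  expect_identical(a$movie$hbo, b$movie$hbo)
  c <- simulate_resting(atl, net, seed = 100)
  expect_false(identical(a$movie$hbo, c$movie$hbo))
})

test_that("non-PSD target matrices are rejected", {
  atl <- tiny_atlas()
  nodes <- data.frame(name = c("a", "b", "c"),
                      row = c(10, 16, 22), col = c(8, 16, 24),
                      sigma = 2, hemisphere = c("L", "L", "R"))
  edges <- data.frame(from = c("a", "a", "b"), to = c("b", "c", "c"),
                      r = c(0.9, 0.9, -0.9))
  expect_error(network_spec(nodes, edges), "positive semidefinite")
})

test_that("evoked block average recovers the planted amplitude at the node centre", {
  atl <- tiny_atlas()
  net <- two_node_network(atl, r = 0, noise_sd = 1e-14, signal_sd = 1e-14,
                          sampling_rate = 2)
  par <- stim_paradigm("electrical", n_blocks = 3)
  sim <- simulate_evoked(atl, net, par, "a_L", amplitude = 5e-6, seed = 4)
  expect_equal(sim$truth$block_onsets_s, 5 + 0:2 * 50)
  avg <- block_average(extract_blocks(sim$movie, par))
  ctr <- (net$nodes$col[1] - 1) * atl$height + net$nodes$row[1]
  expect_equal(max(avg$avg[ctr, ]), 5e-6, tolerance = 0.02)
  expect_error(simulate_evoked(atl, net, par, "nope", 1e-6, seed = 1),
               "unknown target node")
})

test_that("a fully attenuating lesion silences the evoked response", {
  atl <- tiny_atlas()
  net <- two_node_network(atl, r = 0, noise_sd = 0.05e-6, signal_sd = 0.1e-6,
                          sampling_rate = 2)
  par <- stim_paradigm("electrical", n_blocks = 6)
  les <- lesion_spec(center = c(net$nodes$row[1], net$nodes$col[1]),
                     radius = 3, attenuation = 1)
  sim <- simulate_evoked(atl, net, par, "a_L", amplitude = 5e-6, seed = 5,
                         lesion = les, session = "week1")
  avg <- block_average(extract_blocks(sim$movie, par))
  ctr <- (net$nodes$col[1] - 1) * atl$height + net$nodes$row[1]
  # peak-window response at the lesioned centre sits below 3x the SD of the
  # peak-window mean under the residual (resting + noise) fluctuations
  pk <- peak_map(avg)[net$nodes$row[1], net$nodes$col[1]]
  n_win <- length(13:16) * 2                 # 4 s window at 2 Hz
  floor3 <- 3 * sd(avg$avg[ctr, ]) / sqrt(n_win)
  expect_lt(abs(pk), floor3)

  # lesion monotonicity: response amplitude non-increasing in attenuation
  peaks <- sapply(c(0, 0.4, 0.8, 1), function(att) {
    l <- lesion_spec(center = c(net$nodes$row[1], net$nodes$col[1]),
                     radius = 3, attenuation = att)
    s <- simulate_evoked(atl, net, par, "a_L", 5e-6, seed = 5, lesion = l)
    max(block_average(extract_blocks(s$movie, par))$avg[ctr, ])
  })
  expect_true(all(diff(peaks) <= 1e-12))
})

test_that("zero-amplitude stimulation reduces to resting dynamics", {
  atl <- tiny_atlas()
  net <- two_node_network(atl, r = 0.3, noise_sd = 0.1e-6, sampling_rate = 1)
  par <- stim_paradigm("electrical", n_blocks = 2)
  ev <- simulate_evoked(atl, net, par, "a_L", amplitude = 0, seed = 7)
  net2 <- net; net2$duration <- par$n_blocks * par$block_s
  rest <- simulate_resting(atl, net2, seed = 7)
  expect_equal(ev$movie$hbo, rest$movie$hbo)
})

test_that("behavior generator plants asymmetry means and is seed-deterministic", {
  ge <- data.frame(group = c("ctl", "stroke"), session = "week1",
                   mean = c(0, 0.4), sd = c(0.05, 0.05))
  tb <- simulate_behavior(ge, n_mice = 40, seed = 3)
  sc <- asymmetry_score(tb)
  expect_equal(mean(sc[tb$group == "ctl"]), 0, tolerance = 0.03)
  expect_equal(mean(sc[tb$group == "stroke"]), 0.4, tolerance = 0.03)
  expect_identical(tb, simulate_behavior(ge, n_mice = 40, seed = 3))
  expect_true(all(tb$t_left >= 0 & tb$t_right >= 0))
})

test_that("expression generator plants fold changes recoverable by comparative Ct", {
  eff <- cbind(ctl = c(0, 0), treat = c(log2(3), 0))
  tab <- simulate_expression(2, eff, sd = 0.05, seed = 8, n_per_group = 20)
  rel <- comparative_ct(tab, control_group = "ctl")
  treat <- tab$meta$group == "treat"
  gm_fold <- 2^mean(log2(rel$levels["gene01", treat]))
  expect_equal(gm_fold, 3, tolerance = 0.1)
  gm_null <- 2^mean(log2(rel$levels["gene02", treat]))
  expect_equal(gm_null, 1, tolerance = 0.1)
  expect_identical(tab$ct, simulate_expression(2, eff, sd = 0.05, seed = 8,
                                               n_per_group = 20)$ct)
})
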