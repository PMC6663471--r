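test_that("Hanning modulation has unit peak, zero ends, closed-form
           quarter point", {
  tl <- timeline(data.frame(network_id = 1, onset_s = 10, offset_s = 20),
                 duration_s = 30)
  expect_equal(modulation_series(tl, 1, 15), 1)            # midpoint
  expect_equal(modulation_series(tl, 1, c(10, 20)), c(0, 0))
  expect_equal(modulation_series(tl, 1, 12.5), 0.5)        # sin^2(pi/4)
  expect_equal(modulation_series(tl, 1, c(5, 25)), c(0, 0))  # outside
  expect_equal(modulation_series(tl, 2, 15), 0)            # other network
})

test_that("timeline validation rejects overlap and out-of-range epochs", {
  expect_error(timeline(data.frame(network_id = 1, onset_s = -1,
                                   offset_s = 5), 60), "onset")
  expect_error(timeline(data.frame(network_id = c(1, 2),
                                   onset_s = c(0, 4),
                                   offset_s = c(5, 8)), 60), "overlap")
})

test_that("reference networks realize their layouts", {
  nets <- make_reference_networks(8, list(c(4, 4)))
  expect_equal(nets[[1]]$adjacency[1:4, 1:4] + diag(4),
               matrix(1, 4, 4))
  expect_equal(nets[[1]]$adjacency[1:4, 5:8], matrix(0, 4, 4))
  expect_equal(nets[[1]]$partition, rep(1:2, each = 4))

  expect_error(make_reference_networks(8, list(c(5, 5))), "exceeds")
  expect_error(make_reference_networks(8, list(c(4, 4)), within_weight = 0),
               "positive")

  # shuffled assignment is deterministic in the seed and module sizes hold
  n1 <- make_reference_networks(50, list(list(sizes = c(20, 20),
                                              assign = "shuffled")),
                                seed = 7)
  n2 <- make_reference_networks(50, list(list(sizes = c(20, 20),
                                              assign = "shuffled")),
                                seed = 7)
  expect_identical(n1[[1]]$partition, n2[[1]]$partition)
  expect_equal(sort(tabulate(n1[[1]]$partition)), c(rep(1, 10), 20, 20))
})

test_that("the default reference partitions are mutually dissimilar", {
  nets <- make_reference_networks(221, default_layouts(), seed = 100)
  for (i in 1:3)
    for (j in (i + 1):4)
      expect_lt(normalized_similarity(nets[[i]]$partition,
                                      nets[[j]]$partition), 0.3)
})

test_that("generated tensor has the documented geometry and determinism", {
  sim <- simulate_dfc(sim_config(seed = 3))
  expect_equal(sim$tensor$n_windows, 200)   # 60 s at 10/3 Hz
  expect_equal(sim$tensor$n_nodes, 221)
  expect_equal(length(sim$truth$window_labels), 200)
  sim2 <- simulate_dfc(sim_config(seed = 3))
  expect_identical(sim$tensor$weights, sim2$tensor$weights)
  sim3 <- simulate_dfc(sim_config(seed = 4))
  expect_false(identical(sim$tensor$weights, sim3$tensor$weights))
})

test_that("noise-free tensor slices are exactly proportional to the
           active reference network", {
  nets <- make_reference_networks(12, list(c(6, 6)))
  tl <- timeline(data.frame(network_id = 1, onset_s = 0, offset_s = 6), 6)
  cfg <- sim_config(n_nodes = 12, duration_s = 6, b_noise = 0,
                    tensor_noise_std = 0, seed = 1)
  out <- generate_tensor(cfg, nets, tl)
  # any in-epoch window: slice = a_signal * f1(t) * P exactly
  k <- which.min(abs(out$truth$window_centers_s - 3))
  f1 <- modulation_series(tl, 1, out$truth$window_centers_s[k])
  expect_equal(out$tensor$weights[, , k],
               0.45 * f1 * nets[[1]]$adjacency, tolerance = 1e-12)
  expect_gt(f1, 0.99)
})

test_that("edge-noise SD matches the configured level at full size", {
  cfg <- sim_config(seed = 9, a_signal = 0, b_noise = 0,
                    tensor_noise_std = 0.3)
  sim <- simulate_dfc(cfg)
  ut <- upper.tri(sim$tensor$weights[, , 1])
  vals <- apply(sim$tensor$weights, 3, function(s) s[ut])
  expect_lt(abs(sd(vals) - 0.3) / 0.3, 0.02)
})

test_that("ground-truth labels cover all windows and epochs", {
  sim <- simulate_dfc(sim_config(seed = 2))
  expect_equal(length(sim$truth$window_labels), 200)
  expect_setequal(unique(sim$truth$window_labels), c(0, 1, 2, 3, 4))
  ts_net <- truth_states(sim$truth, "network")
  expect_equal(length(ts_net), 4)
  ts_ep <- truth_states(sim$truth, "epoch")
  expect_equal(length(ts_ep), 5)
  # epoch windows are exactly the labelled windows, partitioned
  expect_setequal(unlist(lapply(ts_ep, `[[`, "windows")),
                  which(sim$truth$window_labels > 0))
})
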