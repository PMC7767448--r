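test_that("the default reservoir has 1471 neurons and 62 distinct inputs", {
  res <- build_reservoir(swc = swc_config(seed = 2))
  expect_equal(nrow(res$coords), 1471)
  expect_length(res$input_map, 62)
  expect_false(anyDuplicated(res$input_map) > 0)
  expect_setequal(names(res$input_map), montage_channels())
  expect_false(any(res$edges$pre == res$edges$post))
  expect_false(anyDuplicated(paste(res$edges$pre, res$edges$post)) > 0)
  # every edge respects the hard radius
  d <- sqrt(rowSums((res$coords[res$edges$pre, ] -
                       res$coords[res$edges$post, ])^2))
  expect_true(all(d <= res$radius_mm + 1e-9))
})

test_that("a vanishing radius produces no connections", {
  res <- build_reservoir(subsample_grid(80), swc = swc_config(radius_mm = 0))
  expect_equal(nrow(res$edges), 0)
})

test_that("three collinear neurons with certain wiring give the full digraph", {
  grid <- cbind(x = c(0, 1, 2), y = 0, z = 0)
  montage <- data.frame(channel = "A", x = 0, y = 0, z = 0)
  res <- build_reservoir(grid, montage,
                         swc_config(radius_mm = 1e6, base_prob = 1,
                                    inhibitory_fraction = 0, seed = 1))
  expect_equal(nrow(res$edges), 6)
  expect_setequal(paste(res$edges$pre, res$edges$post),
                  c("1 2", "1 3", "2 1", "2 3", "3 1", "3 2"))
  expect_true(all(res$edges$weight > 0 & res$edges$weight <= 1))
})

test_that("empirical connection probability decreases with distance", {
  res <- build_reservoir(swc = swc_config(seed = 4))
  g <- res$coords
  d2 <- as.matrix(stats::dist(g))^2
  cand <- which(d2 <= res$radius_mm^2 & d2 > 0, arr.ind = TRUE)
  shell <- round(sqrt(d2[cand]), 1)
  linked <- paste(res$edges$pre, res$edges$post)
  hit <- paste(cand[, 1], cand[, 2]) %in% linked
  p_hat <- tapply(hit, shell, mean)
  expect_true(all(diff(p_hat[order(as.numeric(names(p_hat)))]) < 0))
})

test_that("grid smaller than the montage is rejected", {
  expect_error(build_reservoir(load_fixture("grid1471")[1:10, ]),
               class = "snnerp_config_error")
})

test_that("all-zero input leaves weights unchanged and the log empty", {
  res <- toy_reservoir(cbind(0:1, 0, 0), c(A = 1L),
                       data.frame(pre = 1L, post = 2L, weight = 1))
  out <- run_stdp(res, toy_spikes(matrix(0L, 1, 30,
                                         dimnames = list("A", NULL))))
  expect_identical(out$reservoir$edges$weight, 1)
  expect_equal(nrow(out$firing_log), 0)
})

test_that("a causal two-neuron chain potentiates by a_plus*exp(-1/tau)", {
  res <- toy_reservoir(cbind(0:1, 0, 0), c(A = 1L),
                       data.frame(pre = 1L, post = 2L, weight = 1))
  spk <- matrix(0L, 1, 12, dimnames = list("A", NULL))
  spk[1, 6] <- 1L                      # one +1 input event at t = 5
  stdp <- stdp_config(a_plus = 0.01, a_minus = 0.004, tau_ms = 10)
  out <- run_stdp(res, toy_spikes(spk), lif_config(fire_threshold = 0.5),
                  stdp)
  expect_equal(out$firing_log$neuron, c(1L, 2L))
  expect_equal(out$firing_log$t, c(5L, 6L))      # post fires one step later
  expect_equal(out$reservoir$edges$weight, 1 + 0.01 * exp(-1 / 10),
               tolerance = 1e-12)
})

test_that("a post-then-pre ordering depresses by a_minus*exp(-dt/tau)", {
  # two input channels; the edge is too weak to drive LIF firing
  res <- toy_reservoir(cbind(0:1, 0, 0), c(A = 1L, B = 2L),
                       data.frame(pre = 1L, post = 2L, weight = 0.3))
  spk <- matrix(0L, 2, 12, dimnames = list(c("A", "B"), NULL))
  spk["B", 4] <- 1L                    # post (neuron 2) emits at t = 3
  spk["A", 6] <- 1L                    # pre  (neuron 1) emits at t = 5
  stdp <- stdp_config(a_plus = 0.01, a_minus = 0.004, tau_ms = 10)
  out <- run_stdp(res, toy_spikes(spk), lif_config(), stdp)
  expect_equal(out$reservoir$edges$weight, 0.3 - 0.004 * exp(-2 / 10),
               tolerance = 1e-12)
})

test_that("zero plasticity amplitudes preserve all weights", {
  set.seed(10)
  for (seed in 1:5) {
    toy <- random_toy(seed)
    res <- toy_reservoir(cbind(seq_len(toy$n), 0, 0), toy$input_map,
                         toy$edges, toy$inhib)
    out <- run_stdp(res, toy_spikes(toy$spikes), toy$lif,
                    stdp_config(0, 0, 10, 2))
    expect_identical(out$reservoir$edges$weight, toy$edges$weight)
  }
})

test_that("compiled dynamics match the straight-line re-simulation exactly", {
  for (seed in 1:20) {
    toy <- random_toy(seed)
    res <- toy_reservoir(cbind(seq_len(toy$n), 0, 0), toy$input_map,
                         toy$edges, toy$inhib)
    got <- run_stdp(res, toy_spikes(toy$spikes), toy$lif, toy$stdp,
                    passes = toy$passes)
    want <- ref_sim(toy$edges, toy$inhib, toy$spikes, toy$input_map,
                    toy$n, toy$lif, toy$stdp, toy$passes)
    expect_equal(got$reservoir$edges$weight, want$w, tolerance = 1e-12,
                 info = paste("seed", seed))
    expect_equal(got$firing_log$neuron, want$log$neuron,
                 info = paste("seed", seed))
    expect_equal(got$firing_log$t, want$log$t, info = paste("seed", seed))
    expect_equal(got$firing_log$polarity, want$log$polarity,
                 info = paste("seed", seed))
  }
})

test_that("training is deterministic given seeds and inputs", {
  g <- subsample_grid(100)
  coh <- generate_cohort(cohort_spec(n_per_group = 1, epoch_len = 300,
                                     time_points = "T1", stimuli = "target",
                                     seed = 6))
  st <- encode_sample(coh$samples[[1]])
  r1 <- run_stdp(build_reservoir(g, swc = swc_config(seed = 5)), st)
  r2 <- run_stdp(build_reservoir(g, swc = swc_config(seed = 5)), st)
  expect_identical(r1$reservoir$edges$weight, r2$reservoir$edges$weight)
  expect_identical(r1$firing_log, r2$firing_log)
})

test_that("unmapped channels are reported", {
  res <- toy_reservoir(cbind(0:1, 0, 0), c(A = 1L),
                       data.frame(pre = 1L, post = 2L, weight = 1))
  spk <- matrix(0L, 2, 5, dimnames = list(c("A", "ZZ"), NULL))
  expect_error(run_stdp(res, toy_spikes(spk)), class = "snnerp_input_error")
})

test_that("activity snapshots count firings per neuron and polarity", {
  empty <- data.frame(neuron = integer(0), t = integer(0),
                      polarity = integer(0))
  expect_equal(sum(snapshot_activity(empty, 100, 20, 5, 1300)), 0)
  log <- data.frame(neuron = c(7L, 7L, 3L), t = c(253L, 400L, 250L),
                    polarity = c(1L, 1L, -1L))
  snap <- snapshot_activity(log, 253, 10, 10, 1300)
  expect_equal(unname(snap[7, "positive"]), 1L)
  expect_equal(unname(snap[3, "negative"]), 1L)
  expect_equal(sum(snap), 2)
  # additivity over disjoint windows
  a <- snapshot_activity(log, 250, 20, 10, 1300)
  b <- snapshot_activity(log, 400, 20, 10, 1300)
  both <- snapshot_activity(log, 325, 170, 10, 1300)
  expect_equal(a + b, both)
  expect_error(snapshot_activity(log, 5, 20, 10, 1300),
               class = "snnerp_range_error")
})
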