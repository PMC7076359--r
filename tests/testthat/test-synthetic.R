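test_that("network generation is seed-deterministic and conserves length", {
  cfg <- test_config(108)
  n1 <- simulate_network(cfg)
  n2 <- simulate_network(cfg)
  expect_identical(as.data.frame(n1), as.data.frame(n2))
  bo <- attr(n1, "total_length_by_order")
  expect_equal(sum(bo), sum(n1$length_mm))
  expect_equal(unname(bo[1:3]),
               vapply(1:3, function(o) sum(n1$length_mm[n1$order == o]),
                      numeric(1)))
  # analytic lengths match the vertex geometry exactly
  expect_equal(n1$length_mm,
               sqrt((n1$x1 - n1$x0)^2 + (n1$y1 - n1$y0)^2))
})

test_that("disabling order 4 removes minor veins", {
  n <- simulate_network(test_config(109, include_order4 = FALSE))
  expect_identical(unname(attr(n, "total_length_by_order")["order4"]), 0)
  expect_true(all(n$order <= 3))
})

test_that("network density lands in the plausible VLA window", {
  for (seed in 110:112) {
    n <- simulate_network(test_config(seed))
    vla <- sum(n$length_mm) / attr(n, "lamina_area_mm2")
    expect_gt(vla, 0.1); expect_lt(vla, 5)
  }
})

test_that("rendering is bit-identical under the same seed", {
  cfg <- test_config(113, n_frames = 6L)
  s1 <- simulate_leaf(cfg)
  s2 <- simulate_leaf(cfg)
  expect_identical(s1$stack$frames, s2$stack$frames)
  expect_identical(s1$truth$trigger_psi, s2$truth$trigger_psi)
})

test_that("a single-segment network changes exactly one frame pair, on that segment", {
  cfg <- test_config(114, noise_sigma = 0, drift_per_frame = 0,
                     include_order4 = FALSE, n_secondaries = 0L,
                     image_size = c(120L, 160L))
  net <- simulate_network(cfg)
  expect_identical(nrow(net), 1L)   # just the midrib
  sim <- render_stack(net, simulate_schedule(net, cfg), cfg)
  changed <- which(vapply(seq_len(length(sim$stack) - 1L), function(i)
    any(sim$stack$frames[[i + 1L]] != sim$stack$frames[[i]]), logical(1)))
  expect_length(changed, 1L)
  d <- abs(sim$stack$frames[[changed + 1L]] - sim$stack$frames[[changed]])
  expect_identical(px_key(which(d > 0, arr.ind = TRUE)),
                   px_key(sim$truth$pixels[[1]]))
})

test_that("the dehydration trajectory declines and triggers map to their frames", {
  cfg <- test_config(115)
  sim <- simulate_leaf(cfg)
  expect_true(all(diff(sim$psi_by_frame) < 0))
  tr <- sim$truth[!is.na(sim$truth$trigger_frame), ]
  for (i in seq_len(nrow(tr))) {
    f <- tr$trigger_frame[i]
    expect_true(sim$psi_by_frame[f] <= tr$trigger_psi[i])
    if (f > 1) expect_true(sim$psi_by_frame[f - 1] > tr$trigger_psi[i])
  }
})

test_that("the major-vein weighted median trigger equals the configured psi50", {
  cfg <- test_config(116)
  net <- simulate_network(cfg)
  sch <- simulate_schedule(net, cfg)
  maj <- sch$order <= 3
  expect_equal(ovpipe:::weighted_median(sch$trigger_psi[maj],
                                        sch$length_mm[maj]),
               cfg$true_psi50)
})

test_that("midrib-first ordering holds on average", {
  cfg <- test_config(117)
  sch <- simulate_schedule(simulate_network(cfg), cfg)
  m1 <- mean(sch$trigger_psi[sch$order == 1])
  m3 <- mean(sch$trigger_psi[sch$order == 3])
  expect_gt(m1, m3)   # midrib triggers at less negative psi
})

test_that("simulated curve points fall on the generating sigmoid when noiseless", {
  cfg <- test_config(118)
  cv <- simulate_curve_points(24, cfg, noise_sd = 0)
  expect_identical(nrow(cv), 24L)
  tp <- attr(cv, "true_params")
  resp <- tp$v_max / (1 + exp(tp$slope * (cv$psi - tp$psi50)))
  expect_equal(cv$response, resp, tolerance = 1e-12)
  cv2 <- simulate_curve_points(24, test_config(119), noise_sd = 0)
  expect_false(identical(cv$psi, cv2$psi))
  expect_error(simulate_curve_points(4, cfg), ">= 5")
})

test_that("an amplitude at the noise floor is flagged", {
  cfg <- test_config(120, event_amplitude = 0.015, noise_sigma = 0.01,
                     n_frames = 4L)
  net <- simulate_network(cfg)
  expect_warning(render_stack(net, simulate_schedule(net, cfg), cfg),
                 "noise floor")
})

test_that("fixture sets round trip through the stack reader", {
  td <- withr::local_tempdir()
  sim <- simulate_leaf(test_config(121, n_frames = 5L))
  write_simulation(sim, td)
  expect_true(all(file.exists(file.path(td,
    c("stack.tif", "sidecar.yml", "truth_segments.csv",
      "network_segments.csv", "sim_config.yml")))))
  st <- read_stack(file.path(td, "stack.tif"), file.path(td, "sidecar.yml"))
  expect_identical(length(st), 5L)
  truth <- read.csv(file.path(td, "truth_segments.csv"))
  expect_equal(truth$length_mm, sim$truth$length_mm)
})
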