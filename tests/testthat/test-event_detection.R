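test_that("config validation rejects out-of-range settings", {
  expect_error(detection_config(threshold_value = 1.5), "\\[0, 1\\]")
  expect_error(detection_config(threshold_mode = "percentile",
                                threshold_value = 120), "\\(0, 100\\)")
  expect_error(detection_config(min_event_px = 0), ">= 1")
  expect_error(detection_config(smooth_sigma = -1), ">= 0")
})

test_that("identical frames give an all-zero difference and no events", {
  st <- hand_stack(events = list(), n_frames = 3L)
  d <- subtract_frames(st, detection_config(smooth_sigma = 0))
  expect_length(d$diffs, 2L)
  expect_true(all(vapply(d$diffs, max, numeric(1)) == 0))
  ev <- threshold_events(d)
  expect_identical(nrow(ev), 0L)
  cc <- cumulative_counts(ev)
  expect_true(all(cc$cum_pixels == 0))
})

test_that("a localized intensity step is recovered pixel-exactly without smoothing", {
  st <- hand_stack(events = list(list(frame = 2L, rows = 20L, cols = 30:34)),
                   amplitude = 0.3)
  d <- subtract_frames(st, detection_config(smooth_sigma = 0))
  nz <- which(d$diffs[[1]] != 0, arr.ind = TRUE)
  expect_identical(px_key(nz), px_key(cbind(20L, 30:34)))
  expect_equal(unique(d$diffs[[1]][nz]), 0.3)
  expect_error(subtract_frames(image_stack(list(matrix(0.5, 5, 5)), 0, 0.1)),
               "two frames")
})

test_that("component size filtering keeps real events and drops specks", {
  st <- hand_stack(events = list(
    list(frame = 2L, rows = 20:21, cols = 30:39),   # 20 px component
    list(frame = 2L, rows = 40L, cols = 10:11),     # 2 px speck
    list(frame = 2L, rows = 45L, cols = 50:51),     # 2 px speck
    list(frame = 2L, rows = 50L, cols = 60:61)),    # 2 px speck
    amplitude = 0.3)
  ev <- threshold_events(subtract_frames(
    st, detection_config(threshold_value = 0.1, min_event_px = 5,
                         smooth_sigma = 0)))
  expect_identical(nrow(ev), 1L)
  expect_identical(ev$pixel_count, 20L)
  expect_identical(ev$frame_index, 2L)
})

test_that("detection is invariant to a constant intensity offset", {
  sim <- simulate_leaf(test_config(104, noise_sigma = 0, drift_per_frame = 0,
                                   include_order4 = FALSE))
  cfg <- detection_config(smooth_sigma = 0, min_event_px = 1)
  ev1 <- threshold_events(subtract_frames(sim$stack, cfg))
  st2 <- sim$stack
  st2$frames <- lapply(st2$frames, function(f) f + 0.07)
  ev2 <- threshold_events(subtract_frames(st2, cfg,
                                          lamina = lamina_mask(sim$stack)))
  expect_identical(ev1$frame_index, ev2$frame_index)
  expect_identical(lapply(ev1$pixels, px_key), lapply(ev2$pixels, px_key))
})

test_that("with dedup on, event masks are pairwise disjoint", {
  sim <- simulate_leaf(test_config(105))
  ev <- threshold_events(subtract_frames(sim$stack, detection_config()))
  keys <- unlist(lapply(ev$pixels, function(p) paste(p[, 1], p[, 2])))
  expect_identical(anyDuplicated(keys), 0L)
})

test_that("dedup off keeps re-flagged pixels but the cumulative union is idempotent", {
  st <- hand_stack(events = list(
    list(frame = 2L, rows = 20:21, cols = 30:34),
    list(frame = 3L, rows = 20:21, cols = 30:34)),
    amplitude = 0.3, n_frames = 4L)
  # the same 10 px brighten at frame 2; frame 3 re-brightens them again
  st$frames[[3]][20:21, 30:34] <- st$frames[[3]][20:21, 30:34] + 0.3
  st$frames[[4]] <- st$frames[[3]]
  ev <- threshold_events(subtract_frames(
    st, detection_config(smooth_sigma = 0, min_event_px = 1, dedup = FALSE)))
  expect_identical(sort(unique(ev$frame_index)), c(2L, 3L))
  cc <- cumulative_counts(ev)
  expect_equal(cc$cum_pixels, c(0, 10, 10, 10))
})

test_that("cumulative union arithmetic matches disjoint event bookkeeping", {
  st <- hand_stack(events = list(
    list(frame = 2L, rows = 20L, cols = 30:39),
    list(frame = 4L, rows = 40L, cols = 10:19)),
    amplitude = 0.3, n_frames = 6L)
  ev <- threshold_events(subtract_frames(
    st, detection_config(smooth_sigma = 0, min_event_px = 1)))
  cc <- cumulative_counts(ev)
  expect_equal(cc$cum_pixels, c(0, 10, 10, 20, 20, 20))
  masks <- accumulate_events(ev)
  expect_identical(sum(masks[[6]]), 20L)
})
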