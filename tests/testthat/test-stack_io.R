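test_that("constructor enforces the stack contract", {
  fr <- replicate(3, matrix(runif(20), 4, 5), simplify = FALSE)
  st <- image_stack(fr, times = c(0, 5, 10), px_size = 0.05)
  expect_s3_class(st, "ov_stack")
  expect_length(st, 3L)

  expect_error(image_stack(fr, times = c(0, 5), px_size = 0.05),
               "does not match")
  expect_error(image_stack(fr, times = c(0, 10, 5), px_size = 0.05),
               "increasing")
  expect_error(image_stack(fr, times = c(0, 5, 10), px_size = 0),
               "positive")
  fr2 <- fr; fr2[[2]] <- matrix(0.1, 5, 5)
  expect_error(image_stack(fr2, times = c(0, 5, 10), px_size = 0.05),
               "identical")
  expect_error(image_stack(fr, c(0, 5, 10), 0.05, psi_final = 1),
               "<= 0")
})

test_that("grayscale conversion is the identity on gray input and uses fixed luminance on RGB", {
  g <- matrix(runif(30), 5, 6)
  expect_identical(ovpipe:::as_gray(g), g)
  rgb <- array(runif(90), dim = c(5, 6, 3))
  lum <- rgb[, , 1] * 0.2126 + rgb[, , 2] * 0.7152 + rgb[, , 3] * 0.0722
  expect_equal(ovpipe:::as_gray(rgb), lum)
})

test_that("TIFF round trip preserves intensities to 16-bit depth and sidecar times", {
  sim <- simulate_leaf(test_config(101, n_frames = 6L))
  td <- withr::local_tempdir()
  write_stack(sim$stack, file.path(td, "s.tif"),
              sidecar = file.path(td, "s.yml"))
  st <- read_stack(file.path(td, "s.tif"), file.path(td, "s.yml"))
  expect_identical(length(st), length(sim$stack))
  expect_identical(st$times, sim$stack$times)
  expect_equal(st$px_size, sim$stack$px_size)
  expect_lt(max(abs(st$frames[[3]] - sim$stack$frames[[3]])), 2^-15)
  expect_equal(st$meta$psi_final, sim$stack$meta$psi_final)
})

test_that("a frame directory is read in lexicographic order with interval-derived times", {
  td <- withr::local_tempdir()
  fr <- matrix(runif(600), 20, 30)
  for (i in 1:3) png::writePNG(fr, file.path(td, sprintf("frame_%02d.png", i)))
  yaml::write_yaml(list(px_size_mm = 0.05, interval_min = 5),
                   file.path(td, "meta.yml"))
  st <- read_stack(td, file.path(td, "meta.yml"))
  expect_length(st, 3L)
  expect_equal(st$times, c(0, 5, 10))
  # identical files stay identical after normalization
  expect_identical(st$frames[[1]], st$frames[[3]])
})

test_that("sidecar contract violations are hard errors", {
  td <- withr::local_tempdir()
  sim <- simulate_leaf(test_config(102, n_frames = 5L))
  write_stack(sim$stack, file.path(td, "s.tif"))
  yaml::write_yaml(list(px_size_mm = 0.1, times_min = c(0, 5, 10, 15)),
                   file.path(td, "bad_count.yml"))
  expect_error(read_stack(file.path(td, "s.tif"),
                          file.path(td, "bad_count.yml")),
               "4 times.*5 frames")
  yaml::write_yaml(list(interval_min = 5), file.path(td, "no_px.yml"))
  expect_error(read_stack(file.path(td, "s.tif"),
                          file.path(td, "no_px.yml")),
               "px_size_mm")
  expect_error(read_stack(file.path(td, "missing.tif"),
                          file.path(td, "no_px.yml")),
               "not found")
})

test_that("lamina mask recovers the simulated lamina area within 2% and metadata overrides it", {
  sim <- simulate_leaf(test_config(103, n_frames = 4L))
  truth <- attr(sim$network, "lamina_area_mm2")
  lam <- lamina_mask(sim$stack)
  expect_lt(abs(lam$area_mm2 - truth) / truth, 0.02)
  expect_identical(lam$area_source, "mask")
  st2 <- sim$stack
  st2$meta$leaf_area_mm2 <- 123.4
  lam2 <- lamina_mask(st2)
  expect_equal(lam2$area_mm2, 123.4)
  expect_identical(lam2$area_source, "metadata")
})

test_that("lamina area matches the constructed object and is translation invariant", {
  mk <- function(r0, c0) {
    f <- matrix(0.05, 260, 260)
    f[r0:(r0 + 199), c0:(c0 + 199)] <- 0.8
    image_stack(list(f), times = 0, px_size = 0.1)
  }
  a1 <- lamina_mask(mk(10, 10))
  expect_equal(a1$area_mm2, 200 * 200 * 0.01)
  a2 <- lamina_mask(mk(40, 55))
  expect_equal(a2$area_mm2, a1$area_mm2)
})

test_that("a uniform frame cannot be segmented and asks for a manual area", {
  st <- image_stack(list(matrix(0.5, 30, 30)), times = 0, px_size = 0.1)
  expect_error(lamina_mask(st), "leaf_area_mm2")
})
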