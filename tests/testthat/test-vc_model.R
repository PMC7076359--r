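logistic_points <- function(n = 25, v_max = 0.35, slope = 3, psi50 = -2.1,
                            from = -4, to = -0.4) {
  psi <- seq(from, to, length.out = n)
  vulnerability_curve(psi, v_max / (1 + exp(slope * (psi - psi50))))
}

test_that("curve construction sorts, keeps duplicates, and enforces minimum n", {
  lr <- tibble::tibble(psi_final = c(-1, -3, -2, -2, -4),
                       vla_embolized = c(0.01, 0.3, 0.1, 0.12, 0.35),
                       area_fraction_embolized = c(0.001, 0.03, 0.01,
                                                   0.012, 0.035))
  cv <- build_curve(lr)
  expect_s3_class(cv, "ov_curve")
  expect_identical(nrow(cv), 5L)
  expect_true(all(diff(cv$psi) <= 0))
  expect_identical(sum(cv$psi == -2), 2L)   # no implicit averaging
  expect_error(build_curve(lr[1:3, ]), "at least 5")
  expect_error(build_curve(dplyr::mutate(lr, psi_final = NA_real_)),
               "psi_final")
})

test_that("19 leaves give a 19-point endpoint curve", {
  lr <- tibble::tibble(psi_final = seq(-0.5, -4, length.out = 19),
                       vla_embolized = seq(0, 0.4, length.out = 19))
  expect_identical(nrow(build_curve(lr)), 19L)
})

test_that("per-event psi attribution interpolates linearly and is labelled", {
  st <- hand_stack(events = list(list(frame = 2L, rows = 20L, cols = 30:40),
                                 list(frame = 3L, rows = 40L, cols = 10:20),
                                 list(frame = 4L, rows = 50L, cols = 50:60)),
                   n_frames = 4L, amplitude = 0.3)
  ev <- threshold_events(subtract_frames(
    st, detection_config(smooth_sigma = 0, min_event_px = 1)))
  out <- assign_psi_continuous(ev, psi_initial = -0.5, psi_final = -2.5)
  # frames at t = 0, 5, 10, 15 min; events at frames 2..4
  expect_equal(out$psi_assigned,
               -0.5 + c(1, 2, 3) / 3 * (-2))
  expect_identical(attr(out, "psi_mode"), "interpolated")
  same <- assign_psi_continuous(ev, -1.5, -1.5)
  expect_true(all(same$psi_assigned == -1.5))
  expect_error(assign_psi_continuous(ev, NA, -2.5), "endpoint mode")
  expect_error(assign_psi_continuous(ev, -0.5, -2.5, times = c(0, 5)),
               "outside")
})

test_that("noiseless logistic data are recovered exactly; weibull agrees at the midpoint", {
  cv <- logistic_points()
  f <- fit_sigmoid(cv, family = "logistic", n_boot = 0)
  expect_equal(f$psi50, -2.1, tolerance = 1e-6)
  expect_equal(f$v_max, 0.35, tolerance = 1e-4)
  expect_lt(f$rss, 1e-10)
  fw <- fit_sigmoid(cv, family = "weibull", n_boot = 0)
  expect_lt(abs(fw$psi50 - (-2.1)), 0.05)
})

test_that("fitted curves are monotone and psi12 > psi50 > psi88", {
  cv <- logistic_points()
  for (fam in c("logistic", "weibull")) {
    f <- fit_sigmoid(cv, family = fam, n_boot = 0)
    grid <- seq(-6, -0.05, length.out = 300)
    expect_true(all(diff(predict(f, grid)) <= 1e-10))
    expect_gt(f$psi12, f$psi50)
    expect_gt(f$psi50, f$psi88)
    # extreme fractions stay finite and ordered
    expect_lt(psi_at_fraction(f, 0.999999), f$psi88)
    expect_true(is.finite(psi_at_fraction(f, 0.999999)))
  }
})

test_that("psi_at_fraction inverts the fitted sigmoid in closed form", {
  cv <- logistic_points()
  f <- fit_sigmoid(cv, family = "logistic", n_boot = 0)
  expect_identical(psi_at_fraction(f, 0.5), f$psi50)
  fw <- fit_sigmoid(cv, family = "weibull", n_boot = 0)
  expect_identical(psi_at_fraction(fw, 0.5), fw$psi50)
  # closed form vs numeric root of V(psi) = f * v_max
  for (frac in c(0.12, 0.5, 0.88)) {
    root <- uniroot(function(p) predict(fw, p) - frac * fw$v_max,
                    c(-20, -1e-9), tol = 1e-12)$root
    expect_equal(psi_at_fraction(fw, frac), root, tolerance = 1e-6)
  }
  expect_error(psi_at_fraction(f, 0), "between 0 and 1")
  expect_error(psi_at_fraction(f, 1.2), "between 0 and 1")
})

test_that("psi50 is invariant to scaling the response by a positive constant", {
  cv <- simulate_curve_points(20, sim_config(seed = 77), noise_sd = 0.02)
  for (fam in c("logistic", "weibull")) {
    f1 <- fit_sigmoid(cv, family = fam, n_boot = 0)
    cv2 <- vulnerability_curve(cv$psi, cv$response * 11.3)
    f2 <- fit_sigmoid(cv2, family = fam, n_boot = 0)
    expect_equal(f1$psi50, f2$psi50, tolerance = 1e-4)
  }
})

test_that("fit refuses degenerate inputs", {
  cv <- logistic_points(n = 4)
  expect_error(fit_sigmoid(cv), ">= 5")
  narrow <- vulnerability_curve(seq(-2.4, -2.0, length.out = 8),
                                rep(0.2, 8))
  expect_error(fit_sigmoid(narrow), "span")
  zeros <- vulnerability_curve(seq(-4, -1, length.out = 8), rep(0, 8))
  expect_error(fit_sigmoid(zeros), "zero")
})

test_that("bootstrap with a fixed seed is bit-reproducible and covers the estimate", {
  cv <- simulate_curve_points(20, sim_config(seed = 42), noise_sd = 0.02)
  f1 <- fit_sigmoid(cv, family = "logistic", n_boot = 200, seed = 9)
  f2 <- fit_sigmoid(cv, family = "logistic", n_boot = 200, seed = 9)
  expect_identical(f1$boot_psi50, f2$boot_psi50)
  expect_identical(f1$ci50, f2$ci50)
  expect_true(f1$ci50[1] <= f1$psi50 && f1$psi50 <= f1$ci50[2])
  # the bootstrap must not disturb the caller's RNG stream
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(fit_sigmoid(cv, n_boot = 50, seed = 1))
  expect_identical(runif(1), before)
})

test_that("continuous-mode curve from one analysis reproduces the trajectory", {
  an <- analyze_stack(simulate_leaf(test_config(107))$stack)
  cv <- continuous_curve(an)
  expect_identical(attr(cv, "psi_mode"), "interpolated")
  expect_identical(nrow(cv), nrow(an$cumulative))
  expect_true(all(diff(cv$psi) <= 0))
  # responses sorted by declining psi must be non-decreasing (monotone accumulation)
  expect_true(all(diff(cv$response) >= 0))
})

test_that("tidy, glance, and the curve CSV round trip behave", {
  cv <- logistic_points()
  f <- fit_sigmoid(cv, family = "weibull", n_boot = 50, seed = 2)
  td <- tidy(f)
  expect_true(all(c("psi50", "v_max", "b", "c") %in% td$term))
  g <- glance(f)
  expect_identical(g$nobs, 25L)
  expect_identical(g$family, "weibull")
  path <- withr::local_tempfile(fileext = ".csv")
  write_curve(cv, path)
  cv2 <- read_curve(path)
  expect_equal(cv2$psi, cv$psi)
  expect_equal(cv2$response, cv$response)
})
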