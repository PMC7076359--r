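#' Build a vulnerability curve from per-leaf results
#'
#' Pairs each leaf's final cumulative embolism response with its final water
#' potential — the endpoint design in which every leaf is dehydrated for a
#' different interval and contributes exactly one (psi, response) couple.
#' Duplicate psi values are kept as-is; no implicit averaging is performed.
#'
#' @param leaf_results Tibble with one row per leaf, as produced by
#'   [analyze_stack()] (`$leaf`) and stacked with `dplyr::bind_rows()`; must
#'   contain `psi_final` plus `vla_embolized` and/or
#'   `area_fraction_embolized`.
#' @param metric `"vla"` (embolized vein length per area, mm mm^-2) or
#'   `"area_fraction"`.
#' @param species_label Optional label carried into outputs.
#' @param min_leaves Minimum number of leaves required (default 5).
#' @return An `ov_curve` tibble with columns `psi` (MPa, sorted from 0
#'   toward more negative) and `response`, plus `metric`, `species_label`
#'   and `psi_mode = "endpoint"` attributes.
#' @export
build_curve <- function(leaf_results, metric = c("vla", "area_fraction"),
                        species_label = NULL, min_leaves = 5L) {
  metric <- match.arg(metric)
  col <- if (metric == "vla") "vla_embolized" else "area_fraction_embolized"
  if (!col %in% names(leaf_results))
    abort(sprintf("`leaf_results` lacks the `%s` column.", col))
  if (!"psi_final" %in% names(leaf_results))
    abort("`leaf_results` lacks `psi_final`.")
  if (any(!is.finite(leaf_results$psi_final)))
    abort("Every leaf needs a finite `psi_final` for the endpoint curve.")
  n <- nrow(leaf_results)
  if (n < min_leaves)
    abort(sprintf("Vulnerability curve needs at least %d leaves; got %d.",
                  min_leaves, n))
  vulnerability_curve(leaf_results$psi_final, leaf_results[[col]],
                      metric = metric, species_label = species_label,
                      psi_mode = "endpoint")
}

#' Construct a vulnerability curve from raw couples
#'
#' @param psi Leaf water potentials in MPa (all `<= 0`).
#' @param response Embolism responses (VLA in mm mm^-2 or area fraction).
#' @param metric `"vla"` or `"area_fraction"`.
#' @param species_label Optional label.
#' @param psi_mode `"endpoint"` (one couple per leaf) or `"interpolated"`
#'   (per-event psi attribution).
#' @return An `ov_curve` tibble sorted by `psi` descending.
#' @export
vulnerability_curve <- function(psi, response,
                                metric = c("vla", "area_fraction"),
                                species_label = NULL,
                                psi_mode = "endpoint") {
  metric <- match.arg(metric)
  if (any(psi > 0)) abort("Water potentials must be <= 0 MPa.")
  if (any(response < 0)) abort("Responses must be >= 0.")
  ord <- order(psi, decreasing = TRUE)
  out <- tibble(psi = as.numeric(psi)[ord],
                response = as.numeric(response)[ord])
  structure(out, class = c("ov_curve", class(out)),
            metric = metric, species_label = species_label,
            psi_mode = psi_mode)
}

#' Read / write vulnerability-curve couples as CSV
#'
#' The CSV has columns `psi_mpa`, `response`, and optionally `metric`.
#'
#' @param path CSV path.
#' @return An `ov_curve` (for `read_curve`); `path` invisibly (for
#'   `write_curve`).
#' @export
read_curve <- function(path) {
  if (!file.exists(path)) abort(sprintf("Curve CSV not found: %s", path))
  tab <- read.csv(path)
  if (!all(c("psi_mpa", "response") %in% names(tab)))
    abort("Curve CSV needs `psi_mpa` and `response` columns.")
  metric <- if ("metric" %in% names(tab)) as.character(tab$metric[1]) else "vla"
  vulnerability_curve(tab$psi_mpa, tab$response, metric = metric)
}

#' @rdname read_curve
#' @param curve An `ov_curve`.
#' @export
write_curve <- function(curve, path) {
  write.csv(data.frame(psi_mpa = curve$psi, response = curve$response,
                       metric = attr(curve, "metric")),
            path, row.names = FALSE)
  invisible(path)
}

#' Attribute a water potential to every event by linear interpolation
#'
#' The endpoint design measures only the final psi of each leaf. When both
#' an initial and a final psi are available, a per-event psi can be
#' attributed by interpolating linearly in time between them. This is an
#' extension of the endpoint workflow and all outputs are explicitly
#' labelled `"interpolated"`.
#'
#' @param events An `ov_events` tibble.
#' @param psi_initial Water potential at the first frame (MPa).
#' @param psi_final Water potential at the last frame (MPa);
#'   `psi_initial >= psi_final`.
#' @param times Capture times; defaults to those recorded in `events`.
#' @return `events` with a `psi_assigned` column and a
#'   `psi_mode = "interpolated"` attribute.
#' @export
assign_psi_continuous <- function(events, psi_initial, psi_final,
                                  times = NULL) {
  times <- times %||% attr(events, "times")
  if (is.null(times)) abort("No capture times available.")
  if (!isTRUE(is.finite(psi_initial)))
    abort(paste("`psi_initial` is missing: per-event psi attribution needs",
                "both endpoints. Use the endpoint mode (build_curve) with",
                "psi_final only."))
  if (!isTRUE(is.finite(psi_final)) || psi_initial < psi_final)
    abort("`psi_initial` must be >= `psi_final` (less negative).")
  if (nrow(events) &&
      (any(events$frame_index < 1L) || any(events$frame_index > length(times))))
    abort("Event frame index outside the supplied times.")
  t0 <- times[1]; t1 <- times[length(times)]
  frac <- if (t1 > t0) (times[events$frame_index] - t0) / (t1 - t0) else
    rep(0, nrow(events))
  out <- dplyr::mutate(events,
                       psi_assigned = psi_initial +
                         frac * (psi_final - psi_initial))
  for (a in c("dim_px", "lamina", "px_size", "times", "leaf_id", "meta",
              "threshold", "config"))
    attr(out, a) <- attr(events, a)
  class(out) <- class(events)
  attr(out, "psi_mode") <- "interpolated"
  out
}

#' Per-stack vulnerability curve from the cumulative embolism trajectory
#'
#' The continuous counterpart of [build_curve()]: instead of one endpoint
#' couple per leaf, the whole cumulative trajectory of a single analyzed
#' stack is paired with per-frame water potentials interpolated linearly in
#' time between `psi_initial` and `psi_final`. One fully dehydrated leaf
#' then yields an entire curve (and its own psi50). Like
#' [assign_psi_continuous()], this is an explicitly labelled extension of
#' the endpoint workflow.
#'
#' @param analysis An `ov_analysis` from [analyze_stack()].
#' @param psi_initial,psi_final Endpoint water potentials (MPa); default to
#'   the values recorded in the stack metadata.
#' @param metric `"vla"` or `"area_fraction"`.
#' @return An `ov_curve` with `psi_mode = "interpolated"`.
#' @export
continuous_curve <- function(analysis, psi_initial = NULL, psi_final = NULL,
                             metric = c("vla", "area_fraction")) {
  stopifnot(inherits(analysis, "ov_analysis"))
  metric <- match.arg(metric)
  meta <- attr(analysis$events, "meta")
  psi_initial <- psi_initial %||% meta$psi_initial
  psi_final <- psi_final %||% meta$psi_final
  if (!isTRUE(is.finite(psi_initial)))
    abort(paste("`psi_initial` is missing: the continuous mode needs both",
                "endpoint potentials. Use build_curve() otherwise."))
  if (!isTRUE(is.finite(psi_final)) || psi_initial < psi_final)
    abort("`psi_initial` must be >= `psi_final`.")
  tr <- analysis$cumulative
  t0 <- tr$time_min[1]; t1 <- tr$time_min[nrow(tr)]
  frac <- if (t1 > t0) (tr$time_min - t0) / (t1 - t0) else rep(0, nrow(tr))
  psi <- psi_initial + frac * (psi_final - psi_initial)
  resp <- if (metric == "vla") tr$vla_embolized else tr$area_fraction
  vulnerability_curve(psi, resp, metric = metric,
                      species_label = analysis$leaf$leaf_id,
                      psi_mode = "interpolated")
}

# ---- sigmoid model families -------------------------------------------------

sigmoid_value <- function(family, params, psi) {
  switch(family,
    logistic = params[["v_max"]] /
      (1 + exp(params[["slope"]] * (psi - params[["psi50"]]))),
    weibull = params[["v_max"]] *
      (1 - exp(-(abs(psi) / params[["b"]])^params[["c"]])),
    abort(sprintf("Unknown family '%s'.", family)))
}

sigmoid_psi_at <- function(family, params, fraction) {
  switch(family,
    logistic = params[["psi50"]] +
      log(1 / fraction - 1) / params[["slope"]],
    weibull = -params[["b"]] * (-log(1 - fraction))^(1 / params[["c"]]))
}

#' Fit a sigmoidal vulnerability curve and estimate psi50
#'
#' Least-squares fit of the embolism response against leaf water potential
#' with a free asymptote, using either a logistic model
#' \deqn{V(\Psi) = V_{max} / (1 + e^{s(\Psi - \Psi_{50})}), \quad s > 0}
#' or a Weibull model
#' \deqn{V(\Psi) = V_{max}\,(1 - e^{-(|\Psi|/b)^c}).}
#' The asymptote is left free because observed plateaus sit near, but not
#' exactly at, the major-vein density; fixing it would bias psi50. Fits use
#' multi-start Levenberg-Marquardt (starting points derived from the data
#' quantiles) because sparse noisy curves make the least-squares surface
#' multimodal. psi12, psi50 and psi88 are the closed-form potentials at 12%,
#' 50% and 88% of the asymptote. Uncertainty comes from a nonparametric
#' bootstrap: points are resampled with replacement `n_boot` times, each
#' replicate refit, and the 95% percentile interval of psi50 reported. The
#' seed is fixed and recorded, making the bootstrap bit-reproducible.
#'
#' @param curve An `ov_curve` with at least 5 points spanning >= 1 MPa.
#' @param family `"weibull"` (default, for comparability with common
#'   vulnerability-curve fitting conventions) or `"logistic"`.
#' @param n_boot Bootstrap replicates (0 disables the interval).
#' @param seed Integer RNG seed for the bootstrap.
#' @return An `ov_fit` object; see [tidy.ov_fit()], [glance.ov_fit()],
#'   [autoplot.ov_fit()], [psi_at_fraction()].
#' @export
fit_sigmoid <- function(curve, family = c("weibull", "logistic"),
                        n_boot = 500L, seed = 1L) {
  family <- match.arg(family)
  if (!all(c("psi", "response") %in% names(curve)))
    abort("`curve` needs `psi` and `response` columns.")
  n <- nrow(curve)
  if (n < 5L)
    abort(sprintf("Fitting requires >= 5 points; got %d.", n))
  if (diff(range(curve$psi)) < 1)
    abort("psi values must span at least 1 MPa for a meaningful fit.")
  if (all(curve$response == 0))
    abort("All responses are zero; nothing to fit.")
  fit <- fit_sigmoid_once(curve$psi, curve$response, family)
  if (is.null(fit))
    abort(paste("Sigmoid fit failed to converge from any start.",
                sprintf("family=%s, n=%d, psi span %.2f MPa.", family, n,
                        diff(range(curve$psi)))))
  params <- fit$params
  psi50 <- sigmoid_psi_at(family, params, 0.5)
  boot_psi50 <- numeric(0)
  ci50 <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    boot_psi50 <- with_preserved_rng(seed, {
      vapply(seq_len(n_boot), function(i) {
        idx <- sample.int(n, n, replace = TRUE)
        bf <- fit_sigmoid_once(curve$psi[idx], curve$response[idx], family,
                               start = params)
        if (is.null(bf)) NA_real_ else sigmoid_psi_at(family, bf$params, 0.5)
      }, numeric(1))
    })
    ok <- boot_psi50[is.finite(boot_psi50)]
    if (length(ok) >= max(20, n_boot / 2))
      ci50 <- unname(quantile(ok, c(0.025, 0.975)))
  }
  structure(
    list(family = family, params = params,
         v_max = params[["v_max"]],
         psi50 = psi50,
         psi12 = sigmoid_psi_at(family, params, 0.12),
         psi88 = sigmoid_psi_at(family, params, 0.88),
         ci50 = ci50, rss = fit$rss,
         n = n, n_boot = as.integer(n_boot), seed = as.integer(seed),
         boot_psi50 = boot_psi50,
         metric = attr(curve, "metric") %||% "vla",
         species_label = attr(curve, "species_label"),
         data = as_tibble(curve)),
    class = "ov_fit")
}

# one multi-start (or warm-start) nonlinear least-squares attempt
fit_sigmoid_once <- function(psi, response, family, start = NULL) {
  dat <- data.frame(psi = psi, response = response)
  v0 <- max(response) * 1.05 + 1e-9
  near_half <- psi[which.min(abs(response - v0 / 2))]
  p50_cands <- unique(c(near_half, quantile(psi, c(0.35, 0.5, 0.65),
                                            names = FALSE)))
  starts <- if (!is.null(start)) list(as.list(start)) else {
    if (family == "logistic")
      unlist(lapply(p50_cands, function(p)
        lapply(c(1, 2.5, 6), function(s)
          list(v_max = v0, slope = s, psi50 = p))), recursive = FALSE)
    else
      unlist(lapply(p50_cands, function(p)
        lapply(c(1.5, 3, 6), function(cc)
          list(v_max = v0, b = max(abs(p), 0.1), c = cc))),
        recursive = FALSE)
  }
  formula <- if (family == "logistic")
    response ~ v_max / (1 + exp(slope * (psi - psi50)))
  else
    response ~ v_max * (1 - exp(-(abs(psi) / b)^c))
  lower <- if (family == "logistic") c(v_max = 1e-9, slope = 1e-3,
                                       psi50 = min(psi) - 10)
           else c(v_max = 1e-9, b = 1e-3, c = 0.05)
  upper <- if (family == "logistic") c(v_max = Inf, slope = 200,
                                       psi50 = 0)
           else c(v_max = Inf, b = 100, c = 100)
  best <- NULL
  for (st in starts) {
    f <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        formula, data = dat, start = st, lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(f)) next
    rss <- sum(stats::residuals(f)^2)
    if (is.null(best) || rss < best$rss)
      best <- list(params = coef(f), rss = rss)
  }
  best
}

# run `expr` under a fixed seed without disturbing the caller's RNG stream
with_preserved_rng <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Water potential at a given fraction of the fitted asymptote
#'
#' Closed-form inversion of the fitted sigmoid; `fraction = 0.5` reproduces
#' the fitted psi50 exactly.
#'
#' @param fit An `ov_fit`.
#' @param fraction Fraction of `v_max` in (0, 1).
#' @return Water potential in MPa.
#' @export
psi_at_fraction <- function(fit, fraction) {
  stopifnot(inherits(fit, "ov_fit"))
  if (!isTRUE(fraction > 0 && fraction < 1))
    abort("`fraction` must lie strictly between 0 and 1.")
  sigmoid_psi_at(fit$family, fit$params, fraction)
}

#' Predicted response at given water potentials
#'
#' @param object An `ov_fit`.
#' @param psi Water potentials (MPa).
#' @param ... Unused.
#' @export
predict.ov_fit <- function(object, psi, ...) {
  sigmoid_value(object$family, object$params, psi)
}

#' @export
print.ov_fit <- function(x, ...) {
  cat(sprintf("<ov_fit> %s vulnerability curve (%s metric), n = %d\n",
              x$family, x$metric, x$n))
  cat(sprintf("  V_max  = %.4g\n", x$v_max))
  cat(sprintf("  psi12  = %.3f MPa\n", x$psi12))
  cat(sprintf("  psi50  = %.3f MPa", x$psi50))
  if (all(is.finite(x$ci50)))
    cat(sprintf("  [95%% CI %.3f, %.3f]", x$ci50[1], x$ci50[2]))
  cat(sprintf("\n  psi88  = %.3f MPa\n", x$psi88))
  cat(sprintf("  RSS %.4g; bootstrap n = %d, seed = %d\n",
              x$rss, x$n_boot, x$seed))
  invisible(x)
}

#' Tidy the parameters of a fitted vulnerability curve
#'
#' @param x An `ov_fit`.
#' @param ... Unused.
#' @return A tibble with one row per quantity (`term`, `estimate`,
#'   `conf.low`, `conf.high`), bootstrap bounds given for psi50.
#' @method tidy ov_fit
#' @export
tidy.ov_fit <- function(x, ...) {
  terms <- c(names(x$params), "psi12", "psi50", "psi88")
  est <- c(unname(x$params), x$psi12, x$psi50, x$psi88)
  lo <- hi <- rep(NA_real_, length(terms))
  i <- match("psi50", terms)
  lo[i] <- x$ci50[1]; hi[i] <- x$ci50[2]
  tibble(term = terms, estimate = est, conf.low = lo, conf.high = hi)
}

#' One-row summary of a fitted vulnerability curve
#'
#' @param x An `ov_fit`.
#' @param ... Unused.
#' @method glance ov_fit
#' @export
glance.ov_fit <- function(x, ...) {
  tibble(family = x$family, metric = x$metric, nobs = x$n,
         v_max = x$v_max, psi50 = x$psi50,
         ci50_low = x$ci50[1], ci50_high = x$ci50[2],
         rss = x$rss, n_boot = x$n_boot, seed = x$seed)
}

#' Plot a vulnerability curve with its fit and psi50 marker
#'
#' Points are the per-leaf couples; the line is the fitted sigmoid; the
#' dashed vertical line marks psi50, following the usual presentation of
#' optical vulnerability curves.
#'
#' @param object An `ov_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ov_fit
#' @export
autoplot.ov_fit <- function(object, ...) {
  grid <- tibble(psi = seq(min(object$data$psi) - 0.25,
                           max(object$data$psi) + 0.25, length.out = 200))
  grid$response <- predict(object, grid$psi)
  ylab <- if (object$metric == "vla")
    expression("VLA"[embolized] * " (mm mm"^-2 * ")")
  else "embolized area fraction"
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$psi, y = .data$response)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$psi50, linetype = "dashed") +
    ggplot2::annotate("text", x = object$psi50, y = max(object$data$response),
                      label = sprintf("psi50 = %.2f MPa", object$psi50),
                      hjust = -0.05, vjust = 1, size = 3) +
    ggplot2::labs(x = expression(Psi[leaf] * " (MPa)"), y = ylab,
                  title = object$species_label) +
    ggplot2::theme_minimal()
}

#' Write a structured fit report
#'
#' @param fit An `ov_fit`.
#' @param path Output path (YAML).
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  yaml::write_yaml(list(
    family = fit$family, metric = fit$metric,
    params = as.list(fit$params),
    psi12_mpa = fit$psi12, psi50_mpa = fit$psi50, psi88_mpa = fit$psi88,
    ci50_mpa = as.numeric(fit$ci50), rss = fit$rss,
    n_points = fit$n, n_boot = fit$n_boot, seed = fit$seed), path)
  invisible(path)
}
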