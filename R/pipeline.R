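#' Full per-leaf analysis: detect, accumulate, quantify
#'
#' Runs the optical-method processing chain on one stack: lamina
#' segmentation, sequential image subtraction, event thresholding, skeleton
#' length measurement, and the per-leaf summary pairing the final cumulative
#' embolized vein length per unit area (and the area-fraction alternative)
#' with the final leaf water potential.
#'
#' @param stack An `ov_stack`.
#' @param config A [detection_config()].
#' @param lamina Optional precomputed [lamina_mask()] result.
#' @return An `ov_analysis` object: list with
#'   * `leaf`: one-row tibble (`leaf_id`, `psi_final`, `n_events`,
#'     `total_length_mm`, `leaf_area_mm2`, `vla_embolized`,
#'     `area_fraction_embolized`),
#'   * `events`: measured `ov_events` tibble,
#'   * `cumulative`: per-frame tibble (`frame`, `time_min`, `cum_pixels`,
#'     `cum_length_mm`, `vla_embolized`, `area_fraction`),
#'   * `lamina`: the lamina mask result.
#' @export
analyze_stack <- function(stack, config = detection_config(), lamina = NULL) {
  stopifnot(inherits(stack, "ov_stack"))
  if (is.null(lamina)) lamina <- lamina_mask(stack)
  diffs <- subtract_frames(stack, config, lamina)
  events <- measure_events(threshold_events(diffs))
  n_frames <- length(stack$times)
  cum_len <- numeric(n_frames)
  if (nrow(events)) {
    per_frame <- tapply(events$skeleton_length_mm, events$frame_index, sum)
    cum_len[as.integer(names(per_frame))] <- per_frame
  }
  cum_len <- cumsum(cum_len)
  cc <- cumulative_counts(events)
  lam_px <- sum(lamina$mask)
  cumulative <- dplyr::mutate(cc,
    cum_length_mm = cum_len,
    vla_embolized = compute_vla(cum_len, lamina$area_mm2),
    area_fraction = .data$cum_pixels / lam_px)
  total_len <- if (nrow(events)) sum(events$skeleton_length_mm) else 0
  masks <- accumulate_events(events, n_frames)
  af <- area_fraction(masks[[n_frames]], lamina$mask)
  leaf <- tibble(
    leaf_id = stack$leaf_id,
    psi_final = stack$meta$psi_final,
    n_events = nrow(events),
    total_length_mm = total_len,
    leaf_area_mm2 = lamina$area_mm2,
    vla_embolized = compute_vla(total_len, lamina$area_mm2),
    area_fraction_embolized = af)
  structure(list(leaf = leaf, events = events, cumulative = cumulative,
                 lamina = lamina),
            class = "ov_analysis")
}

#' @export
print.ov_analysis <- function(x, ...) {
  cat(sprintf("<ov_analysis> leaf '%s': %d events, VLA_embolized %.3f mm/mm^2 (area fraction %.3f)\n",
              x$leaf$leaf_id, x$leaf$n_events, x$leaf$vla_embolized,
              x$leaf$area_fraction_embolized))
  invisible(x)
}

#' Plot the cumulative embolism trajectory of one analyzed stack
#'
#' @param object An `ov_analysis`.
#' @param metric `"vla"` or `"area_fraction"`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ov_analysis
#' @export
autoplot.ov_analysis <- function(object, metric = c("vla", "area_fraction"),
                                 ...) {
  metric <- match.arg(metric)
  ycol <- if (metric == "vla") "vla_embolized" else "area_fraction"
  ylab <- if (metric == "vla")
    expression("cumulative VLA"[embolized] * " (mm mm"^-2 * ")")
  else "cumulative embolized area fraction"
  ggplot2::ggplot(object$cumulative,
                  ggplot2::aes(x = .data$time_min, y = .data[[ycol]])) +
    ggplot2::geom_step() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "time (min)", y = ylab,
                  title = object$leaf$leaf_id) +
    ggplot2::theme_minimal()
}

#' Export detected events to CSV (and optionally masks to TIFF)
#'
#' @param events A measured `ov_events` tibble.
#' @param csv Path for the per-component CSV
#'   (`frame_index, component_id, pixel_count, centroid_row, centroid_col,
#'   skeleton_length_mm`).
#' @param masks_tiff Optional path for a multi-page binary TIFF of the
#'   cumulative masks.
#' @return `csv`, invisibly.
#' @export
export_events <- function(events, csv, masks_tiff = NULL) {
  tab <- dplyr::select(as_tibble(events), -dplyr::any_of("pixels"))
  write.csv(tab, csv, row.names = FALSE)
  if (!is.null(masks_tiff)) {
    masks <- accumulate_events(events, length(attr(events, "times")))
    tiff::writeTIFF(lapply(masks, function(m) m * 1.0), masks_tiff,
                    bits.per.sample = 8L, compression = "none")
  }
  invisible(csv)
}
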