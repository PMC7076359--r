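#' Detection settings for embolism events
#'
#' Embolism shows up as an abrupt local change in transmitted light between
#' consecutive frames. These settings control how the difference images are
#' formed and thresholded.
#'
#' Defaults suit 0-1 normalized stacks from consumer phone cameras: a fixed
#' cutoff of 0.05 on the absolute per-pixel change, light Gaussian smoothing
#' (sigma 1 px) to suppress sensor speckle, removal of connected components
#' below 10 px, and deduplication so that a vein segment flickering across
#' several frames is counted once. All are overridable per stack, in the
#' spirit of per-stack manual thresholds in optical-method practice.
#'
#' @param threshold_mode `"fixed"` (cutoff on the change magnitude),
#'   `"otsu_global"` (Otsu over all difference values), or `"percentile"`
#'   (cutoff at the given percentile of positive changes).
#' @param threshold_value Cutoff in `[0, 1]` for `"fixed"`; percentile in
#'   (0, 100) for `"percentile"`; ignored for `"otsu_global"`.
#' @param min_event_px Minimum connected-component size kept (>= 1).
#' @param max_event_area_px Optional cap on single-event area, to suppress
#'   slow large-area shrinkage artifacts near the lamina edge (`Inf` = off).
#' @param smooth_sigma Gaussian pre-smoothing sigma in pixels (0 = none).
#' @param dedup Exclude pixels already embolized in earlier frames so each
#'   vein segment is counted once.
#' @param hysteresis_frac Hysteresis segmentation: pixels above
#'   `hysteresis_frac * threshold` are kept when they belong to a connected
#'   component that contains at least one pixel above the full threshold
#'   (1 disables). Smoothing attenuates the rim and the ends of a thin
#'   event below a single cutoff; the dual threshold recovers those pixels
#'   without admitting isolated noise.
#' @return An object of class `ov_detection_config`.
#' @export
detection_config <- function(threshold_mode = c("fixed", "otsu_global",
                                                "percentile"),
                             threshold_value = 0.05,
                             min_event_px = 10L,
                             max_event_area_px = Inf,
                             smooth_sigma = 1.0,
                             dedup = TRUE,
                             hysteresis_frac = 0.5) {
  threshold_mode <- match.arg(threshold_mode)
  if (threshold_mode == "fixed" &&
      (threshold_value < 0 || threshold_value > 1))
    abort("Fixed `threshold_value` must lie in [0, 1].")
  if (threshold_mode == "percentile" &&
      (threshold_value <= 0 || threshold_value >= 100))
    abort("Percentile `threshold_value` must lie in (0, 100).")
  if (min_event_px < 1) abort("`min_event_px` must be >= 1.")
  if (smooth_sigma < 0) abort("`smooth_sigma` must be >= 0.")
  if (hysteresis_frac <= 0 || hysteresis_frac > 1)
    abort("`hysteresis_frac` must lie in (0, 1].")
  structure(list(threshold_mode = threshold_mode,
                 threshold_value = threshold_value,
                 min_event_px = as.integer(min_event_px),
                 max_event_area_px = max_event_area_px,
                 smooth_sigma = smooth_sigma,
                 dedup = isTRUE(dedup),
                 hysteresis_frac = hysteresis_frac),
            class = "ov_detection_config")
}

#' @export
print.ov_detection_config <- function(x, ...) {
  cat("<ov_detection_config>\n")
  for (k in names(x)) cat(sprintf("  %-18s %s\n", k, format(x[[k]])))
  invisible(x)
}

smooth_frame <- function(f, sigma) {
  if (sigma <= 0) return(f)
  as.matrix(EBImage::imageData(EBImage::gblur(EBImage::Image(f),
                                              sigma = sigma)))
}

#' Sequential image subtraction
#'
#' Forms the absolute difference between each pair of consecutive
#' (optionally smoothed) frames, restricted to the lamina. Consecutive-frame
#' differencing, rather than differencing against a fixed baseline, isolates
#' the rapid transmission changes characteristic of embolism while cancelling
#' slow illumination drift and any constant offset.
#'
#' @param stack An `ov_stack` with at least two frames.
#' @param config An [detection_config()] object.
#' @param lamina Optional result of [lamina_mask()]; computed if missing.
#' @return An `ov_diff_stack`: list with `diffs` (list of non-negative
#'   matrices, one per consecutive frame pair), `lamina`, `times`, `px_size`,
#'   `leaf_id`, `config`.
#' @export
subtract_frames <- function(stack, config = detection_config(),
                            lamina = NULL) {
  stopifnot(inherits(stack, "ov_stack"))
  if (length(stack$frames) < 2L)
    abort("Image subtraction needs at least two frames.")
  if (is.null(lamina)) lamina <- lamina_mask(stack)
  sm <- lapply(stack$frames, smooth_frame, sigma = config$smooth_sigma)
  diffs <- vector("list", length(sm) - 1L)
  for (i in seq_along(diffs)) {
    d <- abs(sm[[i + 1L]] - sm[[i]])
    d[!lamina$mask] <- 0
    diffs[[i]] <- pmin(d, 1)
  }
  structure(list(diffs = diffs, lamina = lamina, times = stack$times,
                 px_size = stack$px_size, leaf_id = stack$leaf_id,
                 meta = stack$meta, config = config),
            class = "ov_diff_stack")
}

resolve_threshold <- function(diffs, config) {
  switch(config$threshold_mode,
    fixed = config$threshold_value,
    otsu_global = {
      v <- unlist(lapply(diffs, function(d) d[d > 0]), use.names = FALSE)
      if (length(v) < 2L) return(Inf)
      EBImage::otsu(EBImage::Image(matrix(v, nrow = 1)), range = range(v))
    },
    percentile = {
      v <- unlist(lapply(diffs, function(d) d[d > 0]), use.names = FALSE)
      if (length(v) == 0L) return(Inf)
      quantile(v, config$threshold_value / 100, names = FALSE)
    })
}

#' Threshold difference images into embolism events
#'
#' Pixels whose change exceeds the configured cutoff form candidate event
#' masks; connected components (8-connectivity) smaller than `min_event_px`
#' are discarded as speckle, components larger than `max_event_area_px` as
#' shrinkage artifacts. With `dedup = TRUE` pixels already flagged in an
#' earlier frame are excluded, so a vein segment is counted only once.
#'
#' @param diffs An `ov_diff_stack` from [subtract_frames()].
#' @param config Optional [detection_config()]; defaults to the one stored
#'   in `diffs`.
#' @return An `ov_events` tibble with one row per connected component:
#'   `frame_index` (index of the later frame of the pair, 1-based),
#'   `component_id`, `pixel_count`, `centroid_row`, `centroid_col`, and a
#'   `pixels` list-column of n x 2 integer matrices (row, col). Attributes
#'   `dim`, `lamina`, `px_size`, `times`, `threshold` carry the context.
#' @export
threshold_events <- function(diffs, config = NULL) {
  stopifnot(inherits(diffs, "ov_diff_stack"))
  config <- config %||% diffs$config
  thr <- resolve_threshold(diffs$diffs, config)
  dm <- dim(diffs$diffs[[1]])
  seen <- matrix(FALSE, dm[1], dm[2])
  rows <- list()
  hfrac <- config$hysteresis_frac %||% 1
  for (i in seq_along(diffs$diffs)) {
    high <- diffs$diffs[[i]] > thr
    if (config$dedup) high <- high & !seen
    if (!any(high)) next
    bin <- diffs$diffs[[i]] > thr * hfrac
    if (config$dedup) bin <- bin & !seen
    lab <- as.matrix(EBImage::imageData(EBImage::bwlabel(EBImage::Image(bin))))
    counts <- tabulate(lab[lab > 0L])
    strong <- unique(lab[high])
    keep <- intersect(which(counts >= config$min_event_px &
                              counts <= config$max_event_area_px),
                      strong[strong > 0L])
    if (length(keep) == 0L) next
    cid <- 0L
    for (k in keep) {
      px <- which(lab == k, arr.ind = TRUE)
      dimnames(px) <- NULL
      cid <- cid + 1L
      rows[[length(rows) + 1L]] <- tibble(
        frame_index = i + 1L, component_id = cid,
        pixel_count = nrow(px),
        centroid_row = mean(px[, 1]), centroid_col = mean(px[, 2]),
        pixels = list(px))
      if (config$dedup) seen[px] <- TRUE
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble(frame_index = integer(), component_id = integer(),
           pixel_count = integer(), centroid_row = numeric(),
           centroid_col = numeric(), pixels = list())
  structure(out, class = c("ov_events", class(out)),
            dim_px = dm, lamina = diffs$lamina, px_size = diffs$px_size,
            times = diffs$times, leaf_id = diffs$leaf_id, meta = diffs$meta,
            threshold = thr, config = config)
}

#' Accumulate event masks over frames
#'
#' Builds, for every frame, the union of all event pixels detected at or
#' before that frame. Because it is a set union, the cumulative embolized
#' pixel count is non-decreasing regardless of overlaps between events —
#' mirroring the physically irreversible accumulation of embolism as the
#' leaf dehydrates.
#'
#' @param events An `ov_events` tibble from [threshold_events()].
#' @param n_frames Total number of frames; defaults to the stack length
#'   recorded in `events`.
#' @return A list of logical matrices, one per frame.
#' @export
accumulate_events <- function(events, n_frames = NULL) {
  dm <- attr(events, "dim_px")
  if (is.null(dm)) abort("`events` lacks stack dimensions; use threshold_events().")
  n_frames <- n_frames %||% (length(attr(events, "times")))
  cum <- matrix(FALSE, dm[1], dm[2])
  out <- vector("list", n_frames)
  by_frame <- split(events$pixels, events$frame_index)
  for (f in seq_len(n_frames)) {
    key <- as.character(f)
    if (!is.null(by_frame[[key]]))
      for (px in by_frame[[key]]) cum[px] <- TRUE
    out[[f]] <- cum
  }
  out
}

#' Per-frame cumulative embolism counts
#'
#' @param events An `ov_events` tibble.
#' @return A tibble with `frame`, `time_min`, `cum_pixels`.
#' @export
cumulative_counts <- function(events) {
  times <- attr(events, "times")
  masks <- accumulate_events(events, length(times))
  tibble(frame = seq_along(times), time_min = times,
         cum_pixels = vapply(masks, sum, numeric(1)))
}
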