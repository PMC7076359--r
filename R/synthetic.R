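#' Configuration for the synthetic leaf simulator
#'
#' The simulator fabricates a hierarchical vein network (orders 1-4) inside
#' an elliptical lamina, assigns each segment an embolism-trigger water
#' potential, and renders a transmitted-light time-lapse stack with sensor
#' noise and slow illumination drift, of the kind a consumer phone camera
#' produces. Every stage carries exact ground truth (analytic segment
#' lengths, trigger potentials, rasterized pixel sets), so the detection,
#' quantification and curve-fitting stages can each be validated against
#' known answers.
#'
#' Defaults emulate the study conditions the method was developed under:
#' ~0.1 mm/px effective resolution, 5-min capture cadence, dehydration from
#' near full hydration (-0.4 MPa) to -4 MPa, first embolism in the midrib
#' around -1 to -1.5 MPa, a network-level psi50 of -2.5 MPa (the scale of
#' published leaf values for temperate trees), endpoint major-vein density
#' around 0.3-0.5 mm mm^-2, and an abrupt transmission change of 0.2 on the
#' 0-1 intensity scale against pixel noise of sigma 0.01. Minor (order-4)
#' veins receive a strongly attenuated optical signal
#' (`amp_scale_by_order[4]`), reflecting the observation that phone cameras
#' resolve embolism only in veins up to the third order.
#'
#' @param seed Integer seed; all stochastic draws in the simulator flow from
#'   it and it is echoed into every output.
#' @param image_size `c(rows, cols)` in pixels.
#' @param px_size mm per pixel.
#' @param n_frames Number of frames (>= 2).
#' @param interval_min Capture interval in minutes.
#' @param psi_start,psi_end Water potential at the first/last frame (MPa);
#'   the dehydration trajectory is linear in time between them.
#' @param true_psi50 Configured network psi50 (MPa): the trigger schedule is
#'   calibrated so the major-vein length-weighted median trigger equals it.
#' @param trigger_sd SD (MPa) of per-segment trigger potentials.
#' @param order_shift Mean trigger offset (MPa) per vein order, least
#'   negative first: the midrib embolizes earliest.
#' @param noise_sigma Gaussian pixel noise SD per frame.
#' @param event_amplitude Abrupt intensity increase on an embolizing vein.
#' @param amp_scale_by_order Per-order multiplier on `event_amplitude`.
#' @param drift_per_frame Linear illumination drift added per frame.
#' @param include_order4 Generate order-4 (minor) veins.
#' @param n_secondaries Number of order-2 branches off the midrib.
#' @param min_seg_len_mm Segments shorter than this are not generated.
#' @param width_px Rasterized vein width per order, in pixels.
#' @param bg_level,lamina_level,vein_level Base transmittance of the
#'   background, lamina and water-filled veins.
#' @param ensure_complete Clamp triggers into the dehydration range so every
#'   segment embolizes before the last frame (for saturation fixtures).
#' @return An object of class `ov_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       image_size = c(220L, 300L),
                       px_size = 0.1,
                       n_frames = 30L,
                       interval_min = 5,
                       psi_start = -0.4,
                       psi_end = -4,
                       true_psi50 = -2.5,
                       trigger_sd = 0.25,
                       order_shift = c(0.5, 0.15, -0.1, -0.35),
                       noise_sigma = 0.01,
                       event_amplitude = 0.2,
                       amp_scale_by_order = c(1, 1, 1, 0.15),
                       drift_per_frame = 0.001,
                       include_order4 = TRUE,
                       n_secondaries = 10L,
                       min_seg_len_mm = 2,
                       width_px = c(5, 4, 3, 2),
                       bg_level = 0.08,
                       lamina_level = 0.5,
                       vein_level = 0.35,
                       ensure_complete = FALSE) {
  if (n_frames < 2L) abort("`n_frames` must be >= 2.")
  if (psi_start > 0 || psi_end > 0 || psi_end >= psi_start)
    abort("Need psi_end < psi_start <= 0 (dehydration decreases psi).")
  if (px_size <= 0) abort("`px_size` must be positive.")
  structure(as.list(environment()), class = "ov_sim_config")
}

#' @export
print.ov_sim_config <- function(x, ...) {
  cat("<ov_sim_config>\n")
  for (k in names(x)) cat(sprintf("  %-20s %s\n", k,
                                  paste(format(x[[k]]), collapse = " ")))
  invisible(x)
}

sim_times <- function(config)
  seq(0, by = config$interval_min, length.out = config$n_frames)

# linear dehydration trajectory
psi_of_time <- function(config) {
  times <- sim_times(config)
  function(t) approx(c(times[1], times[length(times)]),
                     c(config$psi_start, config$psi_end),
                     xout = t, rule = 2)$y
}

shoelace_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

#' Generate a hierarchical synthetic vein network
#'
#' Recursive branching inside an elliptical lamina: one midrib (order 1),
#' `n_secondaries` order-2 branches leaving it at alternating sides and
#' randomized angles, order-3 sub-branches, and optionally short order-4
#' stubs, with decreasing width. All geometry is in mm; analytic segment
#' lengths are stored, so the network's total vein length per order is known
#' exactly. Deterministic given the seed.
#'
#' @param config An [sim_config()].
#' @return An `ov_network`: tibble of segments (`segment_id`, `order`,
#'   `x0, y0, x1, y1` in mm, `width_mm`, `length_mm`) with attributes
#'   `lamina` (polygon, mm), `lamina_area_mm2`, `ellipse` (centre and
#'   semi-axes), `total_length_by_order`, and `config`.
#' @export
simulate_network <- function(config = sim_config()) {
  stopifnot(inherits(config, "ov_sim_config"))
  W <- config$image_size[2] * config$px_size
  H <- config$image_size[1] * config$px_size
  cx <- W / 2; cy <- H / 2
  a <- 0.45 * W; b <- 0.40 * H
  if (a < 4 || b < 2.5)
    abort("Lamina too small for the requested vein hierarchy; enlarge the image.")
  inside <- function(x, y, scale = 1)
    ((x - cx) / (a * scale))^2 + ((y - cy) / (b * scale))^2 <= 1
  # longest step from (x,y) along unit (dx,dy) staying inside scaled ellipse
  reach <- function(x, y, dx, dy, scale) {
    lo <- 0; hi <- 2 * (a + b)
    if (!inside(x + hi * dx, y + hi * dy, scale)) {
      for (i in 1:40) {
        mid <- (lo + hi) / 2
        if (inside(x + mid * dx, y + mid * dy, scale)) lo <- mid else hi <- mid
      }
    } else lo <- hi
    lo
  }
  segs <- with_preserved_rng(config$seed, {
    rows <- list()
    occupied <- matrix(numeric(0), 0, 2)  # sampled course of accepted veins
    sample_seg <- function(x0, y0, x1, y1, by = 0.25) {
      len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
      t <- seq(0, 1, length.out = max(2L, ceiling(len / by)))
      cbind(x0 + t * (x1 - x0), y0 + t * (y1 - y0))
    }
    # veins must not cross: reject a branch whose course (beyond its own
    # junction zone) comes close to any accepted vein. A major-order branch
    # that lies wholly inside the junction zone cannot be verified and is
    # not generated; minor (order-4) stubs are exempt since their optical
    # signal is below detectability anyway.
    clear_of_net <- function(x0, y0, x1, y1, strict, clearance = 0.9) {
      if (nrow(occupied) == 0L) return(TRUE)
      pts <- sample_seg(x0, y0, x1, y1)
      d0 <- sqrt((pts[, 1] - x0)^2 + (pts[, 2] - y0)^2)
      pts <- pts[d0 > 2.2, , drop = FALSE]
      if (nrow(pts) == 0L) return(!strict)
      dmin <- min(sqrt(outer(pts[, 1], occupied[, 1], "-")^2 +
                       outer(pts[, 2], occupied[, 2], "-")^2))
      dmin >= clearance
    }
    add <- function(order, x0, y0, x1, y1) {
      len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
      if (len < config$min_seg_len_mm * c(1, 1, 0.6, 0.3)[order]) return(NULL)
      if (order > 1L && !clear_of_net(x0, y0, x1, y1, strict = order <= 3L))
        return(NULL)
      occupied <<- rbind(occupied, sample_seg(x0, y0, x1, y1))
      rows[[length(rows) + 1L]] <<- tibble(
        order = order, x0 = x0, y0 = y0, x1 = x1, y1 = y1,
        width_mm = config$width_px[order] * config$px_size,
        length_mm = len)
      length(rows)
    }
    # order 1: midrib along the major axis
    x_base <- cx - 0.96 * a; x_tip <- cx + 0.96 * a
    add(1L, x_base, cy, x_tip, cy)
    # order 2: branches at alternating sides, tilted toward the tip
    frac <- seq(0.06, 0.92, length.out = config$n_secondaries)
    for (i in seq_along(frac)) {
      bx <- x_base + frac[i] * (x_tip - x_base); by <- cy
      side <- if (i %% 2 == 0) 1 else -1
      ang <- runif(1, 40, 65) * pi / 180
      dx <- cos(ang); dy <- side * sin(ang)
      len2 <- 0.9 * reach(bx, by, dx, dy, 0.93)
      id2 <- add(2L, bx, by, bx + len2 * dx, by + len2 * dy)
      if (is.null(id2)) next
      # order 3: sub-branches off this secondary
      for (fr in runif(sample(2:3, 1), 0.25, 0.8)) {
        px <- bx + fr * len2 * dx; py <- by + fr * len2 * dy
        rot <- sample(c(-1, 1), 1) * runif(1, 30, 55) * pi / 180
        d3x <- cos(ang + side * rot) ; d3y <- side * sin(ang + side * rot)
        nr3 <- sqrt(d3x^2 + d3y^2); d3x <- d3x / nr3; d3y <- d3y / nr3
        len3 <- min(0.55 * len2, 0.9 * reach(px, py, d3x, d3y, 0.96))
        id3 <- add(3L, px, py, px + len3 * d3x, py + len3 * d3y)
        if (is.null(id3) || !config$include_order4) next
        # order 4: short stubs off the tertiary
        for (f4 in runif(2, 0.3, 0.8)) {
          qx <- px + f4 * len3 * d3x; qy <- py + f4 * len3 * d3y
          a4 <- runif(1, 0, 2 * pi)
          len4 <- min(1.6, 0.9 * reach(qx, qy, cos(a4), sin(a4), 0.97))
          add(4L, qx, qy, qx + len4 * cos(a4), qy + len4 * sin(a4))
        }
      }
    }
    dplyr::bind_rows(rows)
  })
  segs <- dplyr::mutate(segs, segment_id = dplyr::row_number(),
                        .before = 1)
  theta <- seq(0, 2 * pi, length.out = 145)[-145]
  poly <- cbind(cx + a * cos(theta), cy + b * sin(theta))
  area <- shoelace_area(poly)
  by_order <- vapply(1:4, function(o)
    sum(segs$length_mm[segs$order == o]), numeric(1))
  names(by_order) <- paste0("order", 1:4)
  vla <- sum(by_order) / area
  if (vla < 0.1 || vla > 5)
    abort(sprintf("Simulated network VLA %.3f mm/mm^2 outside plausible 0.1-5 range.",
                  vla))
  structure(segs, class = c("ov_network", class(segs)),
            lamina = poly, lamina_area_mm2 = area,
            ellipse = c(cx = cx, cy = cy, a = a, b = b),
            total_length_by_order = by_order, config = config)
}

#' Major-vein (orders 1-3) length and VLA of a network
#'
#' @param network An `ov_network`.
#' @return A list with `major_length_mm`, `total_length_mm`,
#'   `lamina_area_mm2`, `vla_major`, `vla_total`.
#' @export
network_truth <- function(network) {
  bo <- attr(network, "total_length_by_order")
  area <- attr(network, "lamina_area_mm2")
  list(major_length_mm = sum(bo[1:3]), total_length_mm = sum(bo),
       lamina_area_mm2 = area,
       vla_major = sum(bo[1:3]) / area, vla_total = sum(bo) / area)
}

#' Draw the per-segment embolism schedule
#'
#' Trigger potentials are normal around the configured psi50 with an
#' order-dependent mean shift (lower orders embolize at less negative
#' potentials, reproducing the midrib-first pattern). After drawing, all
#' triggers are shifted rigidly so that the major-vein (orders 1-3)
#' length-weighted median trigger equals `true_psi50` exactly: the
#' configured psi50 is then the ground truth of the half-embolism point of
#' the major network, not merely its expectation.
#'
#' @param network An `ov_network`.
#' @param config The [sim_config()]; defaults to the one in `network`.
#' @return An `ov_schedule` tibble: `segment_id`, `order`, `length_mm`,
#'   `trigger_psi`.
#' @export
simulate_schedule <- function(network, config = attr(network, "config")) {
  n <- nrow(network)
  trig <- with_preserved_rng(config$seed + 1L,
    config$true_psi50 + config$order_shift[network$order] +
      rnorm(n, 0, config$trigger_sd))
  maj <- network$order <= 3L
  med <- weighted_median(trig[maj], network$length_mm[maj])
  trig <- trig + (config$true_psi50 - med)
  if (isTRUE(config$ensure_complete))
    trig <- pmin(pmax(trig, config$psi_end + 0.12), config$psi_start - 0.12)
  trig <- pmin(trig, -0.01)
  structure(tibble(segment_id = network$segment_id, order = network$order,
                   length_mm = network$length_mm, trigger_psi = trig),
            class = c("ov_schedule", class(tibble())))
}

weighted_median <- function(x, w) {
  ord <- order(x, decreasing = TRUE)   # psi declines over dehydration
  cw <- cumsum(w[ord])
  x[ord][which(cw >= sum(w) / 2)[1]]
}

disk_offsets <- function(width_px) {
  r <- max(width_px / 2, 0.5)
  ri <- floor(r)
  g <- expand.grid(dr = -ri:ri, dc = -ri:ri)
  g[g$dr^2 + g$dc^2 <= r^2, , drop = FALSE]
}

#' Rasterize a polyline at a given stroke width
#'
#' Stamps a pixel disk of diameter `width_px` along the polyline, sampled
#' densely enough that no gaps appear. The stroke ends with butt caps: the
#' stamped course is trimmed by the stroke radius at the two free ends, so
#' the rasterized stroke spans exactly the analytic polyline (a round cap
#' would protrude half a width beyond each endpoint and bias short-segment
#' lengths upward). Used by the renderer and directly useful for validating
#' skeleton-length estimation against analytic polyline lengths.
#'
#' @param verts n x 2 matrix of polyline vertices in mm `(x, y)`.
#' @param width_px Stroke width in pixels.
#' @param px_size mm per pixel.
#' @param dim `c(rows, cols)` of the target raster.
#' @return Integer matrix of unique `(row, col)` pixels.
#' @export
rasterize_polyline <- function(verts, width_px, px_size, dim) {
  offs <- disk_offsets(width_px)
  pts <- list()
  arc0 <- 0
  for (i in seq_len(nrow(verts) - 1L)) {
    x0 <- verts[i, 1]; y0 <- verts[i, 2]
    x1 <- verts[i + 1L, 1]; y1 <- verts[i + 1L, 2]
    len <- sqrt((x1 - x0)^2 + (y1 - y0)^2)
    nstep <- max(2L, ceiling(len / (px_size / 3)))
    t <- seq(0, 1, length.out = nstep)
    pts[[i]] <- cbind(y0 + t * (y1 - y0), x0 + t * (x1 - x0),  # (y, x) mm
                      arc0 + t * len)
    arc0 <- arc0 + len
  }
  pts <- do.call(rbind, pts)
  r_mm <- max(width_px / 2, 0.5) * px_size
  if (arc0 > 2 * r_mm)
    pts <- pts[pts[, 3] >= r_mm & pts[, 3] <= arc0 - r_mm, , drop = FALSE]
  else
    pts <- pts[abs(pts[, 3] - arc0 / 2) < px_size / 2, , drop = FALSE]
  ctr <- cbind(floor(pts[, 1] / px_size) + 1L, floor(pts[, 2] / px_size) + 1L)
  ctr <- unique(ctr)
  px <- cbind(rep(ctr[, 1], each = nrow(offs)) + offs$dr,
              rep(ctr[, 2], each = nrow(offs)) + offs$dc)
  px <- px[px[, 1] >= 1L & px[, 1] <= dim[1] &
           px[, 2] >= 1L & px[, 2] <= dim[2], , drop = FALSE]
  unique(px)
}

#' Generate a random self-avoiding polyline of known analytic length
#'
#' A random walk of straight steps with bounded turning angle, confined to a
#' box and kept clear of its own earlier course (a rasterized
#' self-overlapping path would shorten its own skeleton, which is a property
#' of the path, not of the length estimator). The exact length (sum of step
#' lengths) is returned alongside the vertices, providing an independent
#' oracle for length-measurement tests. A polyline may end early if no
#' self-avoiding continuation is found; its analytic length always matches
#' the returned vertices.
#'
#' @param n_steps Number of straight steps attempted.
#' @param step_mm Range of step lengths (mm).
#' @param box_mm `c(width, height)` of the containing box (mm).
#' @param margin_mm Margin kept from the box edge.
#' @param clearance_mm Minimum distance kept from the earlier course.
#' @return List with `verts` (matrix, mm) and `length_mm`.
#' @export
random_polyline <- function(n_steps = 6, step_mm = c(2, 5),
                            box_mm = c(25, 18), margin_mm = 2,
                            clearance_mm = 1.2) {
  lo <- margin_mm
  hix <- box_mm[1] - margin_mm; hiy <- box_mm[2] - margin_mm
  v <- matrix(NA_real_, n_steps + 1L, 2)
  v[1, ] <- c(runif(1, lo + 5, hix - 5), runif(1, lo + 5, hiy - 5))
  trail <- v[1, , drop = FALSE]
  ang <- runif(1, 0, 2 * pi)
  sample_step <- function(from, to) {
    len <- sqrt(sum((to - from)^2))
    t <- seq(0, 1, length.out = max(2L, ceiling(len / 0.3)))
    cbind(from[1] + t * (to[1] - from[1]), from[2] + t * (to[2] - from[2]))
  }
  n_done <- 0L
  for (i in seq_len(n_steps)) {
    placed <- FALSE
    for (try in 1:80) {
      turn <- if (i == 1L && try == 1L) 0 else runif(1, -5 * pi / 12,
                                                     5 * pi / 12)
      cand_ang <- ang + turn
      step <- runif(1, step_mm[1], step_mm[2])
      cand <- v[i, ] + step * c(cos(cand_ang), sin(cand_ang))
      ok <- cand[1] > lo && cand[1] < hix && cand[2] > lo && cand[2] < hiy
      if (ok && nrow(trail) > 1L) {
        # the clearance test ignores the trail near the shared joint; the
        # bounded turn prevents an immediate fold-back onto the last step
        dj <- sqrt((trail[, 1] - v[i, 1])^2 + (trail[, 2] - v[i, 2])^2)
        far <- trail[dj > 2 * clearance_mm, , drop = FALSE]
        if (nrow(far) > 0L) {
          pts <- sample_step(v[i, ], cand)
          dmin <- min(sqrt(outer(pts[, 1], far[, 1], "-")^2 +
                           outer(pts[, 2], far[, 2], "-")^2))
          ok <- dmin >= clearance_mm
        }
      }
      if (ok) { placed <- TRUE; ang <- cand_ang; break }
    }
    if (!placed) break
    trail <- rbind(trail, sample_step(v[i, ], cand))
    v[i + 1L, ] <- cand
    n_done <- i
  }
  v <- v[seq_len(n_done + 1L), , drop = FALSE]
  steps <- diff(v)
  list(verts = v, length_mm = sum(sqrt(rowSums(steps^2))))
}

#' Render a synthetic dehydration image stack with full ground truth
#'
#' The base frame is a bright lamina with darker water-filled veins on a
#' dark background. When a segment's trigger potential is reached along the
#' linear dehydration trajectory, its pixels brighten abruptly by the event
#' amplitude (scaled per order) and stay bright; Gaussian sensor noise and a
#' linear illumination drift are added per frame. Pixels shared with
#' already-embolized segments do not change again, so the per-segment
#' "novel" pixel sets — what image subtraction can actually see — are
#' disjoint and are recorded as ground truth.
#'
#' @param network An `ov_network`.
#' @param schedule An `ov_schedule` from [simulate_schedule()].
#' @param config The [sim_config()]; defaults to the one in `network`.
#' @return An `ov_sim` list: `stack` (an [image_stack()]), `truth` (tibble:
#'   `segment_id`, `order`, `length_mm`, `width_mm`, `trigger_psi`,
#'   `trigger_frame`, `n_pixels`, `n_novel_pixels`, plus `pixels` and
#'   `novel_pixels` list-columns), `lamina_mask`, `psi_by_frame`, `network`,
#'   `schedule`, `config`.
#' @export
render_stack <- function(network, schedule,
                         config = attr(network, "config")) {
  dm <- config$image_size
  if (config$event_amplitude <= 2 * config$noise_sigma)
    warn("event_amplitude is at or below the noise floor; events may be undetectable.")
  times <- sim_times(config)
  psi_fun <- psi_of_time(config)
  psi_frames <- psi_fun(times)
  trigger_frame <- vapply(schedule$trigger_psi, function(tp) {
    f <- which(psi_frames <= tp)
    if (length(f)) f[1] else NA_integer_
  }, integer(1))
  # lamina raster from the analytic ellipse
  el <- attr(network, "ellipse")
  rr <- (seq_len(dm[1]) - 0.5) * config$px_size
  cc <- (seq_len(dm[2]) - 0.5) * config$px_size
  lam <- outer(rr, cc, function(y, x)
    ((x - el["cx"]) / el["a"])^2 + ((y - el["cy"]) / el["b"])^2 <= 1)
  # rasterize segments
  pix <- vector("list", nrow(network))
  for (i in seq_len(nrow(network))) {
    v <- matrix(c(network$x0[i], network$y0[i],
                  network$x1[i], network$y1[i]), 2, 2, byrow = TRUE)
    p <- rasterize_polyline(v, config$width_px[network$order[i]],
                            config$px_size, dm)
    inlam <- lam[p]
    pix[[i]] <- p[inlam, , drop = FALSE]
  }
  # novel pixels in trigger order (ties resolved by segment id)
  emb <- matrix(FALSE, dm[1], dm[2])
  novel <- vector("list", nrow(network))
  ord <- order(trigger_frame, schedule$segment_id, na.last = TRUE)
  for (i in ord) {
    if (is.na(trigger_frame[i])) { novel[[i]] <- pix[[i]][0, , drop = FALSE]; next }
    p <- pix[[i]]
    fresh <- !emb[p]
    novel[[i]] <- p[fresh, , drop = FALSE]
    emb[p] <- TRUE
  }
  # base transmittance map
  base <- matrix(config$bg_level, dm[1], dm[2])
  base[lam] <- config$lamina_level
  for (i in seq_len(nrow(network))) base[pix[[i]]] <- config$vein_level
  amp <- config$event_amplitude * config$amp_scale_by_order
  frames <- with_preserved_rng(config$seed + 2L, {
    amp_map <- matrix(0, dm[1], dm[2])
    out <- vector("list", config$n_frames)
    pend <- split(seq_len(nrow(network)), trigger_frame)
    for (f in seq_len(config$n_frames)) {
      key <- as.character(f)
      if (!is.null(pend[[key]]))
        for (i in pend[[key]])
          amp_map[novel[[i]]] <- amp[network$order[i]]
      fr <- base + amp_map + config$drift_per_frame * (f - 1)
      if (config$noise_sigma > 0)
        fr <- fr + matrix(rnorm(prod(dm), 0, config$noise_sigma),
                          dm[1], dm[2])
      out[[f]] <- pmin(pmax(fr, 0), 1)
    }
    out
  })
  stack <- image_stack(frames, times, config$px_size,
                       leaf_id = sprintf("sim_seed%d", config$seed),
                       psi_final = config$psi_end,
                       psi_initial = config$psi_start,
                       notes = sprintf("synthetic; seed=%d", config$seed))
  truth <- tibble(
    segment_id = network$segment_id, order = network$order,
    length_mm = network$length_mm, width_mm = network$width_mm,
    trigger_psi = schedule$trigger_psi, trigger_frame = trigger_frame,
    n_pixels = vapply(pix, nrow, integer(1)),
    n_novel_pixels = vapply(novel, nrow, integer(1)),
    pixels = pix, novel_pixels = novel)
  structure(list(stack = stack, truth = truth, lamina_mask = lam,
                 psi_by_frame = psi_frames, network = network,
                 schedule = schedule, config = config),
            class = "ov_sim")
}

#' Simulate one full leaf: network, schedule, rendered stack
#'
#' @param config An [sim_config()].
#' @return An `ov_sim`; see [render_stack()].
#' @export
simulate_leaf <- function(config = sim_config()) {
  net <- simulate_network(config)
  render_stack(net, simulate_schedule(net, config), config)
}

#' Simulate vulnerability-curve couples directly
#'
#' Bypasses imaging entirely to exercise the curve-fitting stage alone: each
#' pseudo-leaf's final water potential is drawn uniformly over the
#' dehydration range and its response is the generating sigmoid plus
#' Gaussian noise.
#'
#' @param n_leaves Number of pseudo-leaves (>= 5).
#' @param config An [sim_config()] supplying the psi range, the true psi50
#'   and the seed.
#' @param noise_sd Response noise SD (same units as the response).
#' @param family Generating family, `"logistic"` or `"weibull"`.
#' @param v_max Generating asymptote (endpoint VLA scale, mm mm^-2).
#' @param slope Generating steepness: the logistic slope `s` (default 3) or
#'   the Weibull shape `c` (default 4). The defaults put 12-88% of the
#'   response between roughly -1.6 and -3.3 MPa around a -2.5 MPa midpoint,
#'   the transition width typical of leaf vulnerability curves.
#' @return An `ov_curve` with attribute `true_params` (list with `family`,
#'   `v_max`, `psi50`, ...).
#' @export
simulate_curve_points <- function(n_leaves = 20L, config = sim_config(),
                                  noise_sd = 0.02,
                                  family = c("logistic", "weibull"),
                                  v_max = 0.35, slope = NULL) {
  family <- match.arg(family)
  slope <- slope %||% if (family == "logistic") 3 else 4
  if (n_leaves < 5L) abort("`n_leaves` must be >= 5.")
  params <- if (family == "logistic")
    c(v_max = v_max, slope = slope, psi50 = config$true_psi50)
  else c(v_max = v_max, b = abs(config$true_psi50) / log(2)^(1 / slope),
         c = slope)
  pts <- with_preserved_rng(config$seed + 3L, {
    psi <- runif(n_leaves, config$psi_end, config$psi_start)
    resp <- sigmoid_value(family, params, psi) + rnorm(n_leaves, 0, noise_sd)
    list(psi = psi, resp = pmax(resp, 0))
  })
  cv <- vulnerability_curve(pts$psi, pts$resp, metric = "vla",
                            species_label = sprintf("sim_seed%d", config$seed))
  attr(cv, "true_params") <- c(list(family = family), as.list(params))
  cv
}

#' Write a simulated leaf as a reusable fixture set
#'
#' Writes the stack as multi-page TIFF + YAML sidecar (the same format
#' [read_stack()] ingests), the ground-truth segment table and the network
#' geometry as CSV, and the full configuration (seed included) as YAML.
#'
#' @param sim An `ov_sim` from [simulate_leaf()] / [render_stack()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "ov_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_stack(sim$stack, file.path(dir, "stack.tif"),
              sidecar = file.path(dir, "sidecar.yml"))
  truth <- dplyr::select(sim$truth, -dplyr::any_of(c("pixels",
                                                     "novel_pixels")))
  write.csv(truth, file.path(dir, "truth_segments.csv"), row.names = FALSE)
  write.csv(as.data.frame(sim$network),
            file.path(dir, "network_segments.csv"), row.names = FALSE)
  cfg <- sim$config
  cfg$image_size <- as.integer(cfg$image_size)
  yaml::write_yaml(unclass(cfg), file.path(dir, "sim_config.yml"))
  invisible(dir)
}
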