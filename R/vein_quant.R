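#' Skeletonize a binary vein mask
#'
#' Thins the mask to a one-pixel-wide, 8-connected medial line (Guo-Hall
#' thinning) and then reconstructs the blunt stroke ends that iterative
#' thinning erodes: each skeleton endpoint is extended along its outgoing
#' direction while the next pixel lies inside the mask and is supported by a
#' blunt mask face perpendicular to the march direction. The support test
#' stops the extension at the true end of a stroke centreline instead of
#' running into the rounded or cornered rim of the mask, so a 3 x 11 px bar
#' yields exactly its 11-pixel centreline while a 45-degree ribbon is not
#' overshot into its corner pixel.
#'
#' @param mask Logical matrix (non-empty).
#' @return Logical matrix of skeleton pixels.
#' @export
skeletonize_mask <- function(mask) {
  if (!is.matrix(mask)) abort("`mask` must be a matrix.")
  mask <- mask > 0
  if (!any(mask)) abort("Cannot skeletonize an empty mask.")
  sk <- .guo_hall_thin(mask)
  dist <- as.matrix(EBImage::imageData(EBImage::distmap(EBImage::Image(mask))))
  sk <- medialize_endpoints(sk, mask, dist)
  extend_endpoints(sk, mask, dist)
}

# King-move ring used to rotate a step direction by 45 degrees.
king_ring <- matrix(c(-1, -1, -1, 0, -1, 1, 0, 1, 1, 1, 1, 0, 1, -1, 0, -1),
                    ncol = 2, byrow = TRUE)

# Parallel thinning can leave a 1-px sideways hook where a diagonal stroke
# ends. Slide each endpoint among the three forward neighbours of its
# anchor to the most medial one (largest distance to background), which
# straightens the hook without changing topology.
medialize_endpoints <- function(sk, mask, dist) {
  nb <- neighbor_count(sk)
  ends <- which(sk & nb == 1L, arr.ind = TRUE)
  nr <- nrow(sk); nc <- ncol(sk)
  for (k in seq_len(nrow(ends))) {
    e <- ends[k, ]
    anchor <- NULL
    for (j in seq_len(nrow(king_ring))) {
      rr <- e[1] + king_ring[j, 1]; cc <- e[2] + king_ring[j, 2]
      if (rr >= 1L && rr <= nr && cc >= 1L && cc <= nc && sk[rr, cc]) {
        anchor <- c(rr, cc); break
      }
    }
    if (is.null(anchor)) next
    d <- e - anchor
    i0 <- which(king_ring[, 1] == d[1] & king_ring[, 2] == d[2])
    cand_dirs <- king_ring[(c(i0 - 1L, i0, i0 + 1L) - 1L) %% 8L + 1L, ,
                           drop = FALSE]
    best <- e; best_d <- dist[e[1], e[2]]
    for (j in seq_len(nrow(cand_dirs))) {
      rr <- anchor[1] + cand_dirs[j, 1]; cc <- anchor[2] + cand_dirs[j, 2]
      if (rr < 1L || rr > nr || cc < 1L || cc > nc) next
      if (!mask[rr, cc] || sk[rr, cc]) next
      if (dist[rr, cc] > best_d) { best <- c(rr, cc); best_d <- dist[rr, cc] }
    }
    if (best[1] != e[1] || best[2] != e[2]) {
      sk[e[1], e[2]] <- FALSE
      sk[best[1], best[2]] <- TRUE
    }
  }
  sk
}

# count of 8-neighbours for every pixel of `bin`
neighbor_count <- function(bin) {
  b <- matrix(0L, nrow(bin) + 2L, ncol(bin) + 2L)
  b[2:(nrow(bin) + 1L), 2:(ncol(bin) + 1L)] <- bin * 1L
  n <- matrix(0L, nrow(bin), ncol(bin))
  ri <- 2:(nrow(bin) + 1L); ci <- 2:(ncol(bin) + 1L)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    n <- n + b[ri + dr, ci + dc]
  }
  n
}

extend_endpoints <- function(sk, mask, dist) {
  nr <- nrow(sk); nc <- ncol(sk)
  nb <- neighbor_count(sk)
  ends <- which(sk & nb == 1L, arr.ind = TRUE)
  if (nrow(ends) == 0L) return(sk)
  inb <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  for (k in seq_len(nrow(ends))) {
    r <- ends[k, 1]; c <- ends[k, 2]
    # the single skeleton neighbour defines the outgoing direction
    hit <- NULL
    for (j in seq_len(nrow(offs))) {
      rr <- r + offs$dr[j]; cc <- c + offs$dc[j]
      if (inb(rr, cc) && sk[rr, cc]) { hit <- c(offs$dr[j], offs$dc[j]); break }
    }
    if (is.null(hit)) next
    dr <- -hit[1]; dc <- -hit[2]
    # perpendicular offsets used for the blunt-face support test
    if (dr == 0L || dc == 0L) { p1 <- c(dc, dr); p2 <- -c(dc, dr) }
    else { p1 <- c(dr, -dc); p2 <- c(-dr, dc) }
    pr <- r; pc <- c
    # thinning erodes a blunt end by about the stroke radius; never extend
    # further than that, or a rounded cap would be overshot
    steps_left <- max(1L, ceiling(dist[r, c]))
    while (steps_left > 0L) {
      steps_left <- steps_left - 1L
      qr <- pr + dr; qc <- pc + dc
      if (!inb(qr, qc) || !mask[qr, qc] || sk[qr, qc]) break
      s1r <- qr + p1[1]; s1c <- qc + p1[2]
      s2r <- qr + p2[1]; s2c <- qc + p2[2]
      sup <- (inb(s1r, s1c) && mask[s1r, s1c]) ||
             (inb(s2r, s2c) && mask[s2r, s2c])
      if (!sup) break
      # stop if q touches skeleton other than the pixel we came from:
      # the stroke end has been reached or another branch rejoined
      touch <- FALSE
      for (j in seq_len(nrow(king_ring))) {
        tr <- qr + king_ring[j, 1]; tc <- qc + king_ring[j, 2]
        if (tr == pr && tc == pc) next
        if (inb(tr, tc) && sk[tr, tc]) { touch <- TRUE; break }
      }
      if (touch) break
      sk[qr, qc] <- TRUE
      pr <- qr; pc <- qc
    }
  }
  sk
}

# Polygonal skeleton length: decompose the skeleton into paths between
# nodes (endpoints and junctions), simplify each path with Douglas-Peucker
# at `eps` px, and sum the Euclidean lengths of the simplified polylines.
# Unlike the raw chamfer step-sum (orthogonal = 1, diagonal = sqrt(2)),
# which overestimates strokes at intermediate angles by up to ~8% through
# staircase quantization, the polygonal reconstruction is unbiased to ~1-2%
# at any angle, while returning the identical value on axis-aligned and
# 45-degree strokes (where the staircase is degenerate).
skeleton_path_length_px <- function(sk, eps = 1.0) {
  idx <- which(sk)
  n <- length(idx)
  if (n < 2L) return(0)
  nr <- nrow(sk); nc <- ncol(sk)
  id <- matrix(0L, nr + 2L, nc + 2L)
  rr0 <- (idx - 1L) %% nr + 1L
  cc0 <- (idx - 1L) %/% nr + 1L
  id[cbind(rr0 + 1L, cc0 + 1L)] <- seq_len(n)
  # neighbour ids per pixel for the 8 king moves (padded lookup)
  nbr <- matrix(0L, n, 8L)
  for (j in 1:8)
    nbr[, j] <- id[cbind(rr0 + 1L + king_ring[j, 1],
                         cc0 + 1L + king_ring[j, 2])]
  # drop diagonal adjacencies shortcut by an orthogonal bridge
  orth_of <- function(dr, dc) c(which(king_ring[, 1] == dr &
                                        king_ring[, 2] == 0),
                                which(king_ring[, 1] == 0 &
                                        king_ring[, 2] == dc))
  for (j in which(king_ring[, 1] != 0 & king_ring[, 2] != 0)) {
    br <- orth_of(king_ring[j, 1], king_ring[j, 2])
    bridged <- nbr[, br[1]] > 0L | nbr[, br[2]] > 0L
    nbr[bridged, j] <- 0L
  }
  nbrs <- lapply(seq_len(n), function(i) nbr[i, nbr[i, ] > 0L])
  deg <- lengths(nbrs)
  coords <- cbind(rr0, cc0)
  visited <- new.env(hash = TRUE, parent = emptyenv())
  ekey <- function(a, b) paste0(min(a, b), "_", max(a, b))
  total <- 0
  walk <- function(a, b) {
    # follow the path a -> b ... until a node (deg != 2) is reached
    path <- c(a, b)
    assign(ekey(a, b), TRUE, envir = visited)
    prev <- a; cur <- b
    while (deg[cur] == 2L) {
      nxt <- nbrs[[cur]][nbrs[[cur]] != prev]
      if (length(nxt) == 0L) break
      if (exists(ekey(cur, nxt), envir = visited)) break
      assign(ekey(cur, nxt), TRUE, envir = visited)
      path <- c(path, nxt)
      prev <- cur; cur <- nxt
    }
    path
  }
  nodes <- which(deg != 2L)
  for (a in nodes)
    for (b in nbrs[[a]])
      if (!exists(ekey(a, b), envir = visited))
        total <- total + dp_path_length(coords[walk(a, b), , drop = FALSE],
                                        eps)
  # remaining unvisited edges belong to pure cycles
  for (a in which(deg == 2L))
    for (b in nbrs[[a]])
      if (!exists(ekey(a, b), envir = visited))
        total <- total + dp_path_length(coords[walk(a, b), , drop = FALSE],
                                        eps)
  total
}

dp_path_length <- function(pts, eps) {
  m <- nrow(pts)
  if (m < 2L) return(0)
  keep <- logical(m); keep[c(1L, m)] <- TRUE
  stack <- list(c(1L, m))
  while (length(stack)) {
    seg <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    i <- seg[1]; j <- seg[2]
    if (j - i < 2L) next
    a <- pts[i, ]; b <- pts[j, ]
    ab <- b - a; l2 <- sum(ab^2)
    mid <- (i + 1L):(j - 1L)
    if (l2 == 0) {
      d2 <- (pts[mid, 1] - a[1])^2 + (pts[mid, 2] - a[2])^2
    } else {
      t <- ((pts[mid, 1] - a[1]) * ab[1] + (pts[mid, 2] - a[2]) * ab[2]) / l2
      d2 <- (pts[mid, 1] - a[1] - t * ab[1])^2 +
            (pts[mid, 2] - a[2] - t * ab[2])^2
    }
    k <- which.max(d2)
    if (d2[k] > eps^2) {
      keep[mid[k]] <- TRUE
      stack <- c(stack, list(c(i, mid[k]), c(mid[k], j)))
    }
  }
  kp <- pts[keep, , drop = FALSE]
  sum(sqrt(rowSums(diff(kp)^2)))
}

# Chamfer edge-sum: orthogonal steps count 1, diagonal steps sqrt(2).
# Each adjacency is counted once (E, S, SE, SW from every pixel); a diagonal
# is skipped when either orthogonal "bridge" pixel of its 2x2 cell is set,
# because the path is then already represented by the two orthogonal edges.
skeleton_edge_length_px <- function(sk) {
  nr <- nrow(sk); nc <- ncol(sk)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- sk
  ri <- 2:(nr + 1L); ci <- 2:(nc + 1L)
  s <- pad[ri, ci]
  e  <- pad[ri, ci + 1L]
  so <- pad[ri + 1L, ci]
  se <- pad[ri + 1L, ci + 1L]
  sw <- pad[ri + 1L, ci - 1L]
  w  <- pad[ri, ci - 1L]
  n_orth <- sum(s & e) + sum(s & so)
  n_diag <- sum(s & se & !(e | so)) + sum(s & sw & !(w | so))
  n_orth + sqrt(2) * n_diag
}

#' Calibrated skeleton length of a binary component
#'
#' Computes the medial-axis skeleton of the mask and measures its length by
#' polygonal path reconstruction: the skeleton is decomposed into paths
#' between endpoints and junctions, each path is simplified to a polyline
#' (Douglas-Peucker, 1 px tolerance) and the Euclidean lengths are summed
#' and calibrated by `px_size`. On axis-aligned and 45-degree strokes this
#' equals the classical step-sum (orthogonal step = 1 px, diagonal =
#' sqrt(2) px, each skeleton edge counted once); at intermediate angles it
#' avoids both the up-to-41% overestimate of a plain pixel count and the
#' up-to-8% staircase bias of the step-sum. Components thinner than 2
#' skeleton pixels have zero length.
#'
#' @param mask Logical (or 0/1) matrix of one component; must be non-empty.
#' @param px_size mm per pixel (> 0).
#' @return Length in mm.
#' @export
skeleton_length <- function(mask, px_size) {
  if (!isTRUE(px_size > 0)) abort("`px_size` must be positive.")
  sk <- skeletonize_mask(mask)
  skeleton_path_length_px(sk) * px_size
}

#' Vein length per unit area
#'
#' The defining ratio of the VLA metric: cumulative embolized (or total)
#' vein length divided by the reference area, in mm per mm^2.
#'
#' @param total_length_mm Vein length in mm (>= 0).
#' @param leaf_area_mm2 Reference area in mm^2 (> 0).
#' @return VLA in mm mm^-2 (exact quotient).
#' @export
compute_vla <- function(total_length_mm, leaf_area_mm2) {
  if (!isTRUE(all(leaf_area_mm2 > 0)))
    abort("`leaf_area_mm2` must be positive.")
  if (any(total_length_mm < 0)) abort("`total_length_mm` must be >= 0.")
  total_length_mm / leaf_area_mm2
}

#' Embolized area fraction
#'
#' The conventional area-based embolism metric: the fraction of the lamina
#' showing embolized pixels, provided alongside the VLA-based metric for
#' comparability with other optical-method studies.
#'
#' @param cumulative_mask Logical matrix of cumulative embolized pixels;
#'   must be a subset of `lamina`.
#' @param lamina Logical lamina mask (non-empty).
#' @return Fraction in `[0, 1]`.
#' @export
area_fraction <- function(cumulative_mask, lamina) {
  cumulative_mask <- cumulative_mask > 0
  lamina <- lamina > 0
  if (!any(lamina)) abort("Lamina mask is empty.")
  if (any(cumulative_mask & !lamina))
    abort("Cumulative mask has pixels outside the lamina.")
  sum(cumulative_mask) / sum(lamina)
}

#' Measure skeleton length of every detected event
#'
#' @param events An `ov_events` tibble from [threshold_events()].
#' @return The same tibble with a `skeleton_length_mm` column appended.
#' @export
measure_events <- function(events) {
  px_size <- attr(events, "px_size")
  if (is.null(px_size)) abort("`events` carries no px_size attribute.")
  lens <- vapply(events$pixels, component_length_mm, numeric(1),
                 px_size = px_size)
  out <- dplyr::mutate(events, skeleton_length_mm = lens)
  attributes(out)[c("dim_px", "lamina", "px_size", "times", "leaf_id",
                    "meta", "threshold", "config")] <-
    attributes(events)[c("dim_px", "lamina", "px_size", "times", "leaf_id",
                         "meta", "threshold", "config")]
  class(out) <- class(events)
  out
}

component_length_mm <- function(px, px_size) {
  if (nrow(px) == 0L) return(0)
  r0 <- min(px[, 1]); c0 <- min(px[, 2])
  m <- matrix(FALSE, max(px[, 1]) - r0 + 3L, max(px[, 2]) - c0 + 3L)
  m[cbind(px[, 1] - r0 + 2L, px[, 2] - c0 + 2L)] <- TRUE
  skeleton_length(m, px_size)
}

#' Major and minor vein density from a cleared-leaf image
#'
#' Re-implements the vein-density measurement usually delegated to dedicated
#' phenotyping software: the stained vein network is segmented by a local
#' adaptive threshold, skeletonized, and split into major and minor veins by
#' the local vein width at each skeleton pixel (twice the Euclidean distance
#' to the background, the standard distance-transform width proxy). Widths
#' at or above `width_cutoff_px` count as major — the operable stand-in for
#' "veins up to the third order", since topological ordering from images is
#' unreliable. Lengths follow the same calibrated edge-sum as
#' [skeleton_length()]; `vla_total = vla_major + vla_minor` holds exactly
#' because the minor length is the total minus the major subset.
#'
#' @param image 2-D grayscale matrix in `[0, 1]` with veins darker or
#'   brighter than the background.
#' @param px_size mm per pixel.
#' @param width_cutoff_px Local vein width (px) separating major from minor.
#' @param vein_phase `"dark"` (stained veins darker than background,
#'   default), `"bright"`, or `"auto"` (side with less total area).
#' @param window Half-width (px) of the adaptive-threshold window.
#' @param offset Adaptive-threshold offset on the 0-1 intensity scale.
#' @param min_component_px Specks below this size are discarded.
#' @param region_mask Optional logical mask limiting the measured region;
#'   the region area is then its pixel area, matching the practice of
#'   measuring ~5 mm^2 cleared-leaf crops.
#' @return A one-row tibble: `vla_total`, `vla_major`, `vla_minor`
#'   (mm mm^-2), `region_area_mm2`, `total_length_mm`, `major_length_mm`,
#'   `minor_length_mm`.
#' @export
vein_density <- function(image, px_size, width_cutoff_px = 5,
                         vein_phase = c("dark", "bright", "auto"),
                         window = 15L, offset = 0.02,
                         min_component_px = 20L, region_mask = NULL) {
  vein_phase <- match.arg(vein_phase)
  if (!isTRUE(px_size > 0)) abort("`px_size` must be positive.")
  if (diff(range(image)) < 1e-6)
    abort("Image is uniform; vein segmentation found an empty skeleton.")
  segment <- function(img) {
    b <- EBImage::thresh(EBImage::Image(img), w = window, h = window,
                         offset = offset)
    as.matrix(EBImage::imageData(b)) > 0
  }
  mask <- switch(vein_phase,
    dark = segment(1 - image),
    bright = segment(image),
    auto = {
      md <- segment(1 - image); mb <- segment(image)
      if (sum(md) <= sum(mb)) md else mb
    })
  if (!is.null(region_mask)) mask <- mask & region_mask
  mask <- drop_small_components(mask, min_component_px)
  if (!any(mask))
    abort("Vein segmentation produced an empty skeleton; check `vein_phase`.")
  sk <- skeletonize_mask(mask)
  dist <- as.matrix(EBImage::imageData(EBImage::distmap(EBImage::Image(mask))))
  width_px <- 2 * dist
  major_sk <- sk & (width_px >= width_cutoff_px)
  total_mm <- skeleton_path_length_px(sk) * px_size
  major_mm <- skeleton_path_length_px(major_sk) * px_size
  minor_mm <- total_mm - major_mm
  area <- if (is.null(region_mask)) prod(dim(image)) * px_size^2 else
    sum(region_mask) * px_size^2
  tibble(vla_total = total_mm / area,
         vla_major = major_mm / area,
         vla_minor = minor_mm / area,
         region_area_mm2 = area,
         total_length_mm = total_mm,
         major_length_mm = major_mm,
         minor_length_mm = minor_mm)
}

drop_small_components <- function(mask, min_px) {
  if (!any(mask) || min_px <= 1) return(mask)
  lab <- as.matrix(EBImage::imageData(EBImage::bwlabel(EBImage::Image(mask))))
  counts <- tabulate(lab[lab > 0L])
  keep <- which(counts >= min_px)
  mask & matrix(lab %in% keep, nrow(mask), ncol(mask))
}
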