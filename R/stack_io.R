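#' Construct a calibrated time-lapse image stack
#'
#' An `ov_stack` holds the time-ordered grayscale frames captured from one
#' dehydrating leaf under transmitted light, together with the capture times
#' and the spatial calibration that makes vein lengths physically meaningful.
#'
#' @param frames List of 2-D numeric matrices with values in `[0, 1]`, all of
#'   identical dimensions. RGB arrays are converted to grayscale with fixed
#'   Rec. 709 luminance weights.
#' @param times Numeric vector of capture times in minutes from the first
#'   frame; must be strictly increasing and match `length(frames)`.
#' @param px_size Spatial calibration in mm per pixel (> 0). Mandatory: vein
#'   lengths are meaningless uncalibrated, and phone EXIF data cannot supply
#'   it for a transmitted-light rig.
#' @param leaf_id Label for the leaf (free text).
#' @param psi_final Leaf water potential at the end of dehydration (MPa,
#'   must be `<= 0`), measured with a pressure chamber on the scanned leaf.
#' @param psi_initial Optional water potential at the start of dehydration
#'   (MPa); must be `>= psi_final` when given.
#' @param leaf_area_mm2 Optional projected lamina area in mm^2; when supplied
#'   it overrides the area computed from [lamina_mask()].
#' @param notes Free-text notes carried through to outputs.
#'
#' @return An object of class `ov_stack`.
#' @seealso [read_stack()], [lamina_mask()], [analyze_stack()]
#' @export
image_stack <- function(frames, times, px_size, leaf_id = "leaf",
                        psi_final = NA_real_, psi_initial = NA_real_,
                        leaf_area_mm2 = NA_real_, notes = "") {
  if (!is.list(frames) || length(frames) == 0L)
    abort("`frames` must be a non-empty list of matrices.")
  frames <- lapply(frames, as_gray)
  dims <- vapply(frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    abort("All frames must share identical height x width.")
  times <- as.numeric(times)
  if (length(times) != length(frames))
    abort(sprintf("Frame count (%d) does not match number of times (%d).",
                  length(frames), length(times)))
  if (any(diff(times) <= 0))
    abort("`times` must be strictly increasing.")
  px_size <- as.numeric(px_size)
  if (!isTRUE(is.finite(px_size)) || px_size <= 0)
    abort("`px_size` (mm/pixel) must be a single positive number.")
  if (is.finite(psi_final) && psi_final > 0)
    abort("`psi_final` must be <= 0 MPa.")
  if (is.finite(psi_initial) && is.finite(psi_final) && psi_initial < psi_final)
    abort("`psi_initial` must be >= `psi_final` (less negative).")
  if (is.finite(leaf_area_mm2) && leaf_area_mm2 <= 0)
    abort("`leaf_area_mm2` must be positive when supplied.")
  structure(
    list(frames = frames, times = times, px_size = px_size,
         leaf_id = as.character(leaf_id)[1],
         meta = list(psi_final = psi_final, psi_initial = psi_initial,
                     leaf_area_mm2 = leaf_area_mm2, notes = notes)),
    class = "ov_stack")
}

#' @export
print.ov_stack <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<ov_stack> leaf '%s': %d frames of %d x %d px, %.4g mm/px\n",
              x$leaf_id, length(x$frames), d[1], d[2], x$px_size))
  cat(sprintf("  time span %.1f-%.1f min; psi_final %s MPa\n",
              min(x$times), max(x$times),
              ifelse(is.finite(x$meta$psi_final),
                     format(x$meta$psi_final), "NA")))
  invisible(x)
}

#' @export
length.ov_stack <- function(x) length(x$frames)

# Rec. 709 luminance; identity on an already-gray matrix.
as_gray <- function(frame) {
  if (is.matrix(frame)) return(frame)
  if (is.array(frame) && length(dim(frame)) == 3L) {
    nch <- dim(frame)[3]
    if (nch == 1L) return(frame[, , 1])
    w <- c(0.2126, 0.7152, 0.0722)
    return(frame[, , 1] * w[1] + frame[, , 2] * w[2] + frame[, , 3] * w[3])
  }
  abort("Frames must be 2-D matrices or 3-D (RGB/RGBA) arrays.")
}

#' Read an image stack and its metadata sidecar
#'
#' Reads either a multi-page TIFF or a directory of single-frame images
#' (PNG/TIFF/JPEG, taken in lexicographic filename order) together with a
#' YAML sidecar that supplies the capture times, the mm/pixel calibration,
#' and the measured leaf water potential(s).
#'
#' The sidecar is a human-editable key-value file. Recognised keys:
#' `px_size_mm` (required), `times_min` (per-frame times) or `interval_min`
#' (constant capture interval), `leaf_id`, `psi_final_mpa`,
#' `psi_initial_mpa`, `leaf_area_mm2`, `notes`.
#'
#' @param path Multi-page TIFF file or directory of frames.
#' @param sidecar Path to the YAML sidecar.
#' @return An [image_stack()] object.
#' @export
read_stack <- function(path, sidecar) {
  if (!file.exists(path)) abort(sprintf("Stack path not found: %s", path))
  if (!file.exists(sidecar)) abort(sprintf("Sidecar not found: %s", sidecar))
  sc <- yaml::read_yaml(sidecar)
  if (is.null(sc$px_size_mm))
    abort(sprintf("Sidecar %s lacks `px_size_mm`; calibration is mandatory.",
                  sidecar))
  frames <- read_frames(path)
  n <- length(frames)
  times <- if (!is.null(sc$times_min)) {
    tm <- as.numeric(sc$times_min)
    if (length(tm) != n)
      abort(sprintf(
        "Sidecar lists %d times but the stack has %d frames.", length(tm), n))
    tm
  } else if (!is.null(sc$interval_min)) {
    seq(0, by = as.numeric(sc$interval_min), length.out = n)
  } else {
    abort("Sidecar must provide `times_min` or `interval_min`.")
  }
  image_stack(frames, times, sc$px_size_mm,
              leaf_id = sc$leaf_id %||% basename(path),
              psi_final = as.numeric(sc$psi_final_mpa %||% NA_real_),
              psi_initial = as.numeric(sc$psi_initial_mpa %||% NA_real_),
              leaf_area_mm2 = as.numeric(sc$leaf_area_mm2 %||% NA_real_),
              notes = sc$notes %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_frames <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, full.names = TRUE,
                             pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                             ignore.case = TRUE))
    if (length(files) == 0L)
      abort(sprintf("No PNG/TIFF/JPEG frames found in directory %s", path))
    lapply(files, read_one_frame)
  } else {
    pages <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    lapply(pages, as_gray)
  }
}

read_one_frame <- function(f) {
  ext <- tolower(tools::file_ext(f))
  img <- switch(ext,
    png  = png::readPNG(f),
    tif  = ,
    tiff = tiff::readTIFF(f),
    jpg  = ,
    jpeg = {
      # EBImage bundles a JPEG reader; its Image is column-major x,y[,c]
      im <- EBImage::readImage(f)
      a <- EBImage::imageData(im)
      if (length(dim(a)) == 3L) aperm(a, c(2, 1, 3)) else t(a)
    },
    abort(sprintf("Unsupported frame format: %s", f)))
  as_gray(img)
}

#' Write an image stack to a multi-page TIFF (plus optional sidecar)
#'
#' Frames are stored as 16-bit grayscale, which is lossless for data
#' quantized at that depth.
#'
#' @param stack An `ov_stack`.
#' @param path Output TIFF path.
#' @param sidecar Optional path for a YAML sidecar mirroring the metadata.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, sidecar = NULL) {
  stopifnot(inherits(stack, "ov_stack"))
  frames <- lapply(stack$frames, function(f) pmin(pmax(f, 0), 1))
  tiff::writeTIFF(frames, path, bits.per.sample = 16L, compression = "none")
  if (!is.null(sidecar)) {
    meta <- list(leaf_id = stack$leaf_id,
                 px_size_mm = stack$px_size,
                 times_min = as.numeric(stack$times))
    if (is.finite(stack$meta$psi_final))
      meta$psi_final_mpa <- stack$meta$psi_final
    if (is.finite(stack$meta$psi_initial))
      meta$psi_initial_mpa <- stack$meta$psi_initial
    if (is.finite(stack$meta$leaf_area_mm2))
      meta$leaf_area_mm2 <- stack$meta$leaf_area_mm2
    if (nzchar(stack$meta$notes %||% "")) meta$notes <- stack$meta$notes
    yaml::write_yaml(meta, sidecar)
  }
  invisible(path)
}

#' Segment the leaf lamina and compute its area
#'
#' The lamina is taken as the largest connected region of the first frame
#' whose transmitted intensity differs from the background at a global Otsu
#' threshold, with interior holes (dark veins) filled. Whether the leaf is
#' the brighter or the darker phase depends on the rig, so by default the
#' side is chosen automatically: the candidate whose largest component
#' touches the image border least is taken to be the leaf.
#'
#' If the stack metadata carries a measured `leaf_area_mm2` (e.g. from a
#' leaf-area scanner), that value overrides the mask-derived area; the mask
#' itself is still returned for restricting event detection.
#'
#' @param stack An `ov_stack`.
#' @param foreground `"auto"`, `"bright"` or `"dark"`: which intensity phase
#'   is the leaf.
#' @return A list with `mask` (logical matrix), `area_mm2`, `area_source`
#'   (`"mask"` or `"metadata"`), and `threshold`.
#' @export
lamina_mask <- function(stack, foreground = c("auto", "bright", "dark")) {
  stopifnot(inherits(stack, "ov_stack"))
  foreground <- match.arg(foreground)
  f1 <- stack$frames[[1]]
  rng <- range(f1)
  if (diff(rng) < 1e-6)
    abort(paste("First frame is uniform; no lamina can be segmented.",
                "Supply `leaf_area_mm2` in the metadata instead."))
  thr <- EBImage::otsu(EBImage::Image(f1), range = rng)
  cand <- list(bright = f1 > thr, dark = f1 < thr)
  pick <- switch(foreground,
    bright = "bright", dark = "dark",
    auto = names(which.min(vapply(cand, border_contact, numeric(1)))))
  mask <- largest_component(cand[[pick]])
  if (!any(mask))
    abort(paste("Lamina segmentation found no foreground.",
                "Supply `leaf_area_mm2` in the metadata instead."))
  mask <- EBImage::fillHull(EBImage::Image(mask)) > 0
  area_mask <- sum(mask) * stack$px_size^2
  meta_area <- stack$meta$leaf_area_mm2
  if (isTRUE(is.finite(meta_area))) {
    list(mask = mask, area_mm2 = meta_area, area_source = "metadata",
         threshold = thr)
  } else {
    list(mask = mask, area_mm2 = area_mask, area_source = "mask",
         threshold = thr)
  }
}

# fraction of the phase's largest component lying on the image border
border_contact <- function(bin) {
  comp <- largest_component(bin)
  n <- sum(comp)
  if (n == 0L) return(Inf)
  nr <- nrow(comp); nc <- ncol(comp)
  border <- sum(comp[1, ]) + sum(comp[nr, ]) + sum(comp[, 1]) + sum(comp[, nc])
  border / n
}

largest_component <- function(bin) {
  lab <- EBImage::bwlabel(EBImage::Image(bin))
  lab <- as.matrix(EBImage::imageData(lab))
  if (max(lab) == 0L) return(bin & FALSE)
  counts <- tabulate(lab[lab > 0L])
  lab == which.max(counts)
}
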