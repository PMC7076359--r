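# Shared fixture builders. Everything is generated in code; no binary data.

# canonical pixel-set key for exact set comparisons
px_key <- function(m) {
  if (is.null(m) || nrow(m) == 0L) return(character(0))
  sort(paste(m[, 1], m[, 2]))
}

# horizontal bar mask: `len` px long, `wid` px wide
bar_mask <- function(len = 11L, wid = 3L, pad = 3L) {
  m <- matrix(FALSE, wid + 2L * pad, len + 2L * pad)
  m[pad + seq_len(wid), pad + seq_len(len)] <- TRUE
  m
}

# 45-degree ribbon: `n` 3x3 stamps along the diagonal
diag_mask <- function(n = 11L, pad = 2L) {
  side <- n + 2L * pad
  m <- matrix(FALSE, side, side)
  for (i in seq_len(n) - 1L)
    m[(pad + i):(pad + i + 2L), (pad + i):(pad + i + 2L)] <- TRUE
  m
}

# smaller, faster simulator settings for unit tests
test_config <- function(seed, ...) {
  args <- list(seed = seed, image_size = c(180L, 260L), n_frames = 16L)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

# a tiny synthetic stack built by hand: constant background with one
# rectangular brightening event per listed frame
hand_stack <- function(events = list(), n_frames = 4L, dim = c(60L, 80L),
                       base = 0.5, bg = 0.05, amplitude = 0.3,
                       px_size = 0.1) {
  lam_r <- 6:(dim[1] - 5); lam_c <- 6:(dim[2] - 5)
  base_frame <- matrix(bg, dim[1], dim[2])
  base_frame[lam_r, lam_c] <- base
  bump <- matrix(0, dim[1], dim[2])
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    for (ev in events)
      if (ev$frame == f) bump[ev$rows, ev$cols] <- amplitude
    frames[[f]] <- base_frame + bump
  }
  image_stack(frames, times = seq(0, by = 5, length.out = n_frames),
              px_size = px_size, leaf_id = "hand", psi_final = -2)
}
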