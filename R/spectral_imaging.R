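#' Raster configuration for the image-sequence representation
#'
#' Each mgf file is rendered as a sequence of RT-by-m/z intensity rasters,
#' one per consecutive retention-time window of 96.7 s, at 512 x 512
#' pixels; after image augmentation the frames are reduced to 256 x 256 and
#' stacked into a 256 x 256 x 98 volume for the 3D classifier. A full
#' 0-9476.6 s chromatographic run yields exactly 98 windows.
#'
#' @param window_seconds Window duration in seconds (default 96.7).
#' @param raster_size Rendered frame side in pixels (default 512).
#' @param volume_size Down-sampled frame side in pixels (default 256).
#' @param frames_per_file Fixed volume depth; shorter runs are padded with
#'   blank frames, longer runs truncated (default 98).
#' @param mz_range Named list of (low, high) m/z axis limits per layer, in
#'   Thomson.
#' @param intensity_encoding `"log1p_gray"` (default) or `"linear_gray"`.
#' @param aggregate `"max"` (default) or `"sum"`: how multiple peaks landing
#'   on one pixel combine.
#' @return A list of class `raster_config`.
#' @export
raster_config <- function(window_seconds = 96.7, raster_size = 512L,
                          volume_size = 256L, frames_per_file = 98L,
                          mz_range = list(proteomic = c(100, 2000),
                                          metabolomic = c(50, 1000)),
                          intensity_encoding = c("log1p_gray", "linear_gray"),
                          aggregate = c("max", "sum")) {
  stopifnot(window_seconds > 0, raster_size >= volume_size,
            frames_per_file >= 1)
  structure(list(window_seconds = window_seconds,
                 raster_size = as.integer(raster_size),
                 volume_size = as.integer(volume_size),
                 frames_per_file = as.integer(frames_per_file),
                 mz_range = mz_range,
                 intensity_encoding = match.arg(intensity_encoding),
                 aggregate = match.arg(aggregate)),
            class = "raster_config")
}

blank_frame <- function(size) matrix(0, size, size)

#' Map a peak to its raster pixel
#'
#' Column index encodes retention time within the window, row index encodes
#' m/z within the layer's axis range, both linear; row 1 is the low-m/z
#' edge and column 1 the window start.
#' @keywords internal
peak_pixel <- function(rt_in_window, mz, window_seconds, mz_lo, mz_hi, size) {
  col <- pmin(floor(rt_in_window / window_seconds * size) + 1L, size)
  row <- pmin(floor((mz - mz_lo) / (mz_hi - mz_lo) * size) + 1L, size)
  list(row = as.integer(row), col = as.integer(col))
}

#' Render a spectra file into its RT-window image sequence
#'
#' The RT axis is partitioned into consecutive `window_seconds` windows
#' starting at 0. Within each window every fragment peak lights the pixel
#' at (m/z, RT-within-window); multiple peaks on a pixel aggregate by max
#' (or sum). Intensities are encoded to [0, 1] grayscale (log1p then
#' min-max over the file by default). The natural frame count
#' `ceil(max RT / window)` is then padded with blank frames or truncated to
#' `frames_per_file`, so every file yields a fixed-shape sequence.
#'
#' @param sf A [spectra_file()] (intensities ideally already scaled).
#' @param cfg A [raster_config()].
#' @return A list of `spectrum_image` objects (matrix `pixels`,
#'   `frame_index`, `rt_window`), of length `cfg$frames_per_file`.
#' @export
render_windows <- function(sf, cfg = raster_config()) {
  stopifnot(inherits(sf, "spectra_file"))
  size <- cfg$raster_size
  mzr <- cfg$mz_range[[sf$omics_layer]]
  if (is.null(mzr)) stop("no m/z range configured for layer ", sf$omics_layer)
  if (length(sf$spectra) == 0) {
    warning("empty spectra file; rendering blank frames")
    n_frames <- 0L
  } else {
    rts <- rt_values(sf)
    n_frames <- max(1L, as.integer(ceiling(max(rts) / cfg$window_seconds)))
  }
  frames <- vector("list", n_frames)
  if (n_frames > 0) {
    stream <- extract_features(sf, preprocess_config(rt_step = 1e-9))
    # keep raw RT resolution here; drop peaks outside the m/z axis
    keep <- stream$mz >= mzr[1] & stream$mz <= mzr[2]
    stream <- stream[keep, , drop = FALSE]
    frame_of <- pmin(floor(stream$rt / cfg$window_seconds) + 1L, n_frames)
    enc <- encode_intensity(stream$intensity, cfg$intensity_encoding)
    for (f in seq_len(n_frames)) {
      px <- blank_frame(size)
      sel <- which(frame_of == f)
      if (length(sel) > 0) {
        start <- (f - 1L) * cfg$window_seconds
        pix <- peak_pixel(stream$rt[sel] - start, stream$mz[sel],
                          cfg$window_seconds, mzr[1], mzr[2], size)
        idx <- cbind(pix$row, pix$col)
        vals <- enc[sel]
        if (cfg$aggregate == "max") {
          o <- order(vals)
          px[idx[o, , drop = FALSE]] <- vals[o]
        } else {
          agg <- rowsum(vals, group = (pix$col - 1L) * size + pix$row)
          lin <- as.integer(rownames(agg))
          px[lin] <- pmin(agg[, 1], 1)
        }
      }
      frames[[f]] <- px
    }
  }
  # pad with blank frames or truncate to the fixed depth
  target <- cfg$frames_per_file
  if (n_frames < target)
    frames <- c(frames, replicate(target - n_frames, blank_frame(size),
                                  simplify = FALSE))
  else if (n_frames > target)
    frames <- frames[seq_len(target)]
  lapply(seq_len(target), function(f) {
    structure(list(frame_index = f, pixels = frames[[f]],
                   rt_window = c((f - 1) * cfg$window_seconds,
                                 f * cfg$window_seconds)),
              class = "spectrum_image")
  })
}

encode_intensity <- function(intensity, encoding) {
  if (length(intensity) == 0) return(numeric(0))
  v <- if (encoding == "log1p_gray") log1p(intensity) else intensity
  top <- max(v)
  if (top <= 0) return(rep(0, length(v)))
  pmin(pmax(v / top, 0), 1)
}

#' Image-level augmentation of a frame sequence
#'
#' A `round(transform_fraction * n)` subset of frames, chosen uniformly, is
#' modified; each chosen frame receives exactly one transform drawn
#' uniformly from \{random shift (vertical and horizontal), random zeroing
#' of a rectangle, random crop-and-rescale\}. Untouched frames are
#' bit-identical to their input, and the whole operation is deterministic
#' given the seed.
#'
#' @param seq List of `spectrum_image`s.
#' @param transform_fraction Fraction of frames to transform (default 0.3).
#' @param seed Integer seed.
#' @param max_shift_frac Maximum shift per axis as a fraction of the side
#'   (default 0.1).
#' @param max_zero_frac Maximum zeroed-rectangle area fraction (default 0.1).
#' @param crop_frac Retained side fraction for the crop transform
#'   (default 0.9).
#' @return The augmented list of `spectrum_image`s.
#' @export
augment_images <- function(seq, transform_fraction = 0.3, seed = 1L,
                           max_shift_frac = 0.1, max_zero_frac = 0.1,
                           crop_frac = 0.9) {
  stopifnot(transform_fraction >= 0, transform_fraction <= 1)
  n <- length(seq)
  k <- round(transform_fraction * n)
  if (k == 0) return(seq)
  set.seed(as.integer(seed))
  chosen <- sample.int(n, k)
  kinds <- sample(c("shift", "zero", "crop"), k, replace = TRUE)
  for (j in seq_len(k)) {
    i <- chosen[j]
    seq[[i]]$pixels <- apply_image_transform(seq[[i]]$pixels, kinds[j],
                                             max_shift_frac, max_zero_frac,
                                             crop_frac)
  }
  seq
}

apply_image_transform <- function(px, kind, max_shift_frac, max_zero_frac,
                                  crop_frac) {
  s <- nrow(px)
  switch(kind,
    shift = {
      maxs <- max(1L, floor(max_shift_frac * s))
      dr <- sample(c(-(maxs:1), 1:maxs), 1)
      dc <- sample(c(-(maxs:1), 1:maxs), 1)
      shift_matrix(px, dr, dc)
    },
    zero = {
      side <- max(1L, floor(sqrt(max_zero_frac) * s))
      h <- sample.int(side, 1); w <- sample.int(side, 1)
      r0 <- sample.int(s - h + 1L, 1); c0 <- sample.int(s - w + 1L, 1)
      px[r0:(r0 + h - 1L), c0:(c0 + w - 1L)] <- 0
      px
    },
    crop = {
      side <- max(2L, floor(crop_frac * s))
      r0 <- sample.int(s - side + 1L, 1); c0 <- sample.int(s - side + 1L, 1)
      resize_bilinear(px[r0:(r0 + side - 1L), c0:(c0 + side - 1L)], s)
    })
}

shift_matrix <- function(px, dr, dc) {
  s <- nrow(px)
  out <- matrix(0, s, s)
  src_r <- seq_len(s) - dr
  src_c <- seq_len(s) - dc
  ok_r <- src_r >= 1 & src_r <= s
  ok_c <- src_c >= 1 & src_c <= s
  out[which(ok_r), which(ok_c)] <- px[src_r[ok_r], src_c[ok_c]]
  out
}

#' Bilinear resize of a square image
#' @keywords internal
resize_bilinear <- function(px, out_size) {
  s <- nrow(px)
  if (s == out_size) return(px)
  # sample centers mapped into source coordinates
  pos <- (seq_len(out_size) - 0.5) * s / out_size + 0.5
  lo <- pmax(pmin(floor(pos), s), 1)
  hi <- pmin(lo + 1, s)
  w <- pmin(pmax(pos - lo, 0), 1)
  a <- px[lo, lo, drop = FALSE]; b <- px[lo, hi, drop = FALSE]
  c_ <- px[hi, lo, drop = FALSE]; d <- px[hi, hi, drop = FALSE]
  wr <- matrix(w, out_size, out_size)
  wc <- t(wr)
  a * (1 - wr) * (1 - wc) + b * (1 - wr) * wc +
    c_ * wr * (1 - wc) + d * wr * wc
}

#' Down-sample a frame sequence and stack it into the model volume
#'
#' Each frame is reduced from `raster_size` to `volume_size` by area
#' averaging (block mean when the sizes divide evenly, bilinear otherwise)
#' and the frames are stacked in RT order into a
#' `volume_size x volume_size x frames_per_file` array in [0, 1].
#'
#' @param seq List of exactly `cfg$frames_per_file` `spectrum_image`s.
#' @param cfg A [raster_config()].
#' @return A `volume_tensor`: 3D array with attributes `layer` and
#'   `file_id` when supplied.
#' @export
resize_and_stack <- function(seq, cfg = raster_config()) {
  if (length(seq) != cfg$frames_per_file)
    stop(sprintf("expected %d frames, got %d (padding happens in render_windows)",
                 cfg$frames_per_file, length(seq)))
  out <- array(0, dim = c(cfg$volume_size, cfg$volume_size,
                          cfg$frames_per_file))
  for (f in seq_along(seq)) {
    px <- seq[[f]]$pixels
    out[, , f] <- if (nrow(px) %% cfg$volume_size == 0) {
      block_mean(px, cfg$volume_size)
    } else resize_bilinear(px, cfg$volume_size)
  }
  structure(out, class = c("volume_tensor", class(out)))
}

block_mean <- function(px, out_size) {
  k <- nrow(px) %/% out_size
  if (k == 1) return(px)
  # average k x k blocks via row then column aggregation
  g <- rep(seq_len(out_size), each = k)
  rowagg <- rowsum(px, g) / k
  t(rowsum(t(rowagg), g) / k)
}

#' Full image pathway for one file: render, augment, stack
#'
#' @param sf A [spectra_file()].
#' @param cfg A [raster_config()].
#' @param transform_fraction Fraction of frames transformed (0 disables
#'   augmentation; default 0.3 for training data).
#' @param seed Integer seed for the augmentation draw.
#' @return A `volume_tensor` for the 3D classifier.
#' @export
file_to_volume <- function(sf, cfg = raster_config(),
                           transform_fraction = 0, seed = 1L) {
  frames <- render_windows(sf, cfg)
  if (transform_fraction > 0)
    frames <- augment_images(frames, transform_fraction, seed)
  vol <- resize_and_stack(frames, cfg)
  attr(vol, "layer") <- sf$omics_layer
  attr(vol, "file_id") <- sf$file_id
  vol
}
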