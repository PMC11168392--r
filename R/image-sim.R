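# Synthetic fluorescence frames with known speck positions, used to benchmark
# the detector end to end.

#' Simulate a fluorescence frame containing Gaussian specks
#'
#' Places `n_specks` isotropic Gaussian spots at random positions with a
#' guaranteed centre-to-centre separation of at least `4 * spot_sigma_px`
#' (so spots never merge under thresholding) and at least `3 * spot_sigma_px`
#' from the frame edge, on a constant background with additive Gaussian noise.
#' Intensities are clamped to the bit-depth range.
#'
#' @param n_specks Number of spots (>= 0).
#' @param frame_shape Integer `c(rows, cols)` of the frame.
#' @param spot_sigma_px Gaussian sigma of each spot in pixels (> 0).
#' @param spot_peak Peak intensity added by a spot at its centre (> 0).
#' @param background Constant background intensity.
#' @param noise_sd Standard deviation of the additive Gaussian noise
#'   (0 = noiseless).
#' @param bit_depth 8 or 16; intensity range is `[0, 2^bit_depth - 1]`.
#' @param seed Integer seed; identical seeds give bit-identical frames.
#' @return A list with `frame` (numeric matrix) and `truth` (tibble of
#'   0-based centroid coordinates `row`, `col` and `sigma_px`).
#' @examples
#' sim <- simulate_speck_image(n_specks = 5, frame_shape = c(64, 64),
#'                             spot_sigma_px = 1.5, spot_peak = 3000,
#'                             background = 500, noise_sd = 100, seed = 1)
#' dim(sim$frame)
#' @export
simulate_speck_image <- function(n_specks,
                                 frame_shape = c(96L, 96L),
                                 spot_sigma_px = 1.5,
                                 spot_peak = 3000,
                                 background = 500,
                                 noise_sd = 100,
                                 bit_depth = 16,
                                 seed = 1L) {
  stopifnot(length(frame_shape) == 2, all(frame_shape >= 8),
            n_specks >= 0, spot_sigma_px > 0, spot_peak > 0,
            bit_depth %in% c(8, 16), noise_sd >= 0)
  nr <- as.integer(frame_shape[1]); nc <- as.integer(frame_shape[2])
  margin <- 3 * spot_sigma_px
  min_sep <- 4 * spot_sigma_px
  if (nr - 2 * margin < 1 || nc - 2 * margin < 1) {
    stop("frame too small for the edge margin", call. = FALSE)
  }
  # Crude capacity bound: disks of radius min_sep/2 must fit in the frame.
  capacity <- floor((nr - 2 * margin) * (nc - 2 * margin) / (min_sep / 2)^2 / pi)
  if (n_specks > 0 && n_specks > capacity) {
    stop("`n_specks` too large for the non-overlap separation constraint",
         call. = FALSE)
  }

  with_substream(seed, {
    rows <- cols <- numeric(0)
    tries <- 0L
    while (length(rows) < n_specks) {
      if (tries > 10000L * max(n_specks, 1L)) {
        stop("could not place `n_specks` spots with the required separation",
             call. = FALSE)
      }
      tries <- tries + 1L
      r <- stats::runif(1, margin, nr - 1 - margin)
      c <- stats::runif(1, margin, nc - 1 - margin)
      if (length(rows) == 0 ||
          all((rows - r)^2 + (cols - c)^2 >= min_sep^2)) {
        rows <- c(rows, r); cols <- c(cols, c)
      }
    }

    frame <- matrix(as.numeric(background), nr, nc)
    half <- ceiling(4 * spot_sigma_px)
    for (i in seq_along(rows)) {
      r0 <- rows[i]; c0 <- cols[i]
      ri <- max(0, floor(r0 - half)):min(nr - 1, ceiling(r0 + half))
      ci <- max(0, floor(c0 - half)):min(nc - 1, ceiling(c0 + half))
      patch <- outer(ri, ci, function(rr, cc) {
        spot_peak * exp(-((rr - r0)^2 + (cc - c0)^2) / (2 * spot_sigma_px^2))
      })
      frame[ri + 1, ci + 1] <- frame[ri + 1, ci + 1] + patch
    }
    if (noise_sd > 0) {
      frame <- frame + matrix(stats::rnorm(nr * nc, 0, noise_sd), nr, nc)
    }
    frame <- pmin(pmax(frame, 0), 2^bit_depth - 1)
    list(
      frame = frame,
      truth = tibble::tibble(row = rows, col = cols, sigma_px = spot_sigma_px)
    )
  })
}

#' Write / read a grayscale frame
#'
#' Thin wrappers around the TIFF and PNG readers: frames are stored as 16-bit
#' grayscale images; in memory they are plain numeric matrices on the
#' original intensity scale.
#'
#' @param frame Numeric matrix of intensities.
#' @param path File path ending in `.tif`, `.tiff` or `.png`.
#' @param bit_depth 8 or 16.
#' @return `read_frame()` returns a numeric matrix; `write_frame()` returns
#'   `path` invisibly.
#' @export
write_frame <- function(frame, path, bit_depth = 16) {
  stopifnot(is.matrix(frame), bit_depth %in% c(8, 16))
  scaled <- pmin(pmax(frame / (2^bit_depth - 1), 0), 1)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(scaled, path, bits.per.sample = bit_depth)
  } else if (ext == "png") {
    png::writePNG(scaled, path)
  } else {
    stop("unsupported image extension: ", ext, call. = FALSE)
  }
  invisible(path)
}

#' @rdname write_frame
#' @export
read_frame <- function(path, bit_depth = 16) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else if (ext == "png") {
    png::readPNG(path)
  } else {
    stop("unsupported image extension: ", ext, call. = FALSE)
  }
  if (length(dim(img)) == 3) img <- img[, , 1]
  img * (2^bit_depth - 1)
}
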