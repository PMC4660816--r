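#' Synthetic medical phantom generator
#'
#' Produces grayscale images that emulate the gross statistics of medical
#' imagery for testing the watermarking pipeline: a smooth anatomy-like
#' background (sum of seeded elliptical Gaussian bumps over a mid-gray
#' base), windowed sinusoidal texture patches (oscillating detail the
#' texture component should capture), and optional additive Gaussian noise.
#' Pixel values stay inside [0, 255]; the construction targets the 30--220
#' range so that watermark-scale perturbations do not saturate at export.
#' Deterministic per seed; the caller's RNG state is untouched.
#'
#' Defaults: a 256x256 phantom with 6 blobs, texture amplitude 12 at
#' spatial frequency 0.1 cycles/pixel (period 10 px, coarse enough that
#' 4x4-cell block means retain part of the oscillation, as real coherent
#' texture does), and noise sigma 2 (below the decomposition's default
#' soft threshold).
#'
#' @param height,width dimensions, divisible by 4.
#' @param n_blobs number of smooth elliptical structures.
#' @param texture_amplitude peak amplitude of the sinusoidal texture.
#' @param texture_frequency texture frequency in cycles per pixel.
#' @param noise_sigma standard deviation of additive Gaussian noise.
#' @param n_texture_patches number of rectangular texture windows.
#' @param seed integer seed.
#' @return a [gray_image()] matrix.
#' @export
make_phantom <- function(height = 256L, width = 256L, n_blobs = 6L,
                         texture_amplitude = 12, texture_frequency = 0.1,
                         noise_sigma = 2, n_texture_patches = 3L, seed = 1L) {
  if (height %% 4L != 0L || width %% 4L != 0L) {
    stop("make_phantom: dimensions must be divisible by 4", call. = FALSE)
  }
  if (noise_sigma < 0 || texture_amplitude < 0) {
    stop("make_phantom: amplitudes must be nonnegative", call. = FALSE)
  }
  with_seed(seed, {
    y <- matrix(seq_len(height), height, width)
    x <- matrix(seq_len(width), height, width, byrow = TRUE)

    img <- matrix(90, height, width)
    for (b in seq_len(n_blobs)) {
      cy <- stats::runif(1, 0.15, 0.85) * height
      cx <- stats::runif(1, 0.15, 0.85) * width
      sy <- stats::runif(1, 0.06, 0.25) * height
      sx <- stats::runif(1, 0.06, 0.25) * width
      amp <- stats::runif(1, -45, 60)
      th <- stats::runif(1, 0, pi)
      xr <- (x - cx) * cos(th) + (y - cy) * sin(th)
      yr <- -(x - cx) * sin(th) + (y - cy) * cos(th)
      img <- img + amp * exp(-(xr^2 / (2 * sx^2) + yr^2 / (2 * sy^2)))
    }
    # keep the smooth background comfortably inside the 8-bit range
    img <- 30 + (img - min(img)) / max(max(img) - min(img), 1e-12) * 180

    if (texture_amplitude > 0 && n_texture_patches > 0L) {
      for (p in seq_len(n_texture_patches)) {
        ph <- max(8L, round(stats::runif(1, 0.15, 0.35) * height))
        pw <- max(8L, round(stats::runif(1, 0.15, 0.35) * width))
        r0 <- sample.int(height - ph, 1L)
        c0 <- sample.int(width - pw, 1L)
        th <- stats::runif(1, 0, pi)
        phase <- stats::runif(1, 0, 2 * pi)
        rows <- r0 + seq_len(ph)
        cols <- c0 + seq_len(pw)
        # raised-cosine window avoids sharp patch borders leaking into u
        wr <- 0.5 - 0.5 * cos(2 * pi * (seq_len(ph) - 0.5) / ph)
        wc <- 0.5 - 0.5 * cos(2 * pi * (seq_len(pw) - 0.5) / pw)
        carrier <- sin(2 * pi * texture_frequency *
          (x[rows, cols] * cos(th) + y[rows, cols] * sin(th)) + phase)
        img[rows, cols] <- img[rows, cols] +
          texture_amplitude * outer(wr, wc) * carrier
      }
    }
    if (noise_sigma > 0) {
      img <- img + stats::rnorm(length(img), sd = noise_sigma)
    }
    gray_image(pmin(pmax(img, 0), 255))
  })
}

#' Generate a binary authentication logo
#'
#' A deterministic 64x64-style two-level glyph (border, coarse checkerboard
#' quadrant, block letters "PM") standing in for an institutional logo.
#'
#' @param rows,cols logo dimensions.
#' @return 0/1 integer matrix.
#' @export
make_logo <- function(rows = 64L, cols = 64L) {
  m <- matrix(0L, rows, cols)
  m[c(1:2, rows - 1, rows), ] <- 1L
  m[, c(1:2, cols - 1, cols)] <- 1L
  # checkerboard in the lower-right quadrant
  rr <- seq(ceiling(rows / 2), rows)
  cc <- seq(ceiling(cols / 2), cols)
  blk <- max(2L, rows %/% 16L)
  m[rr, cc] <- (outer(rr %/% blk, cc %/% blk, "+") %% 2L)
  # block letters P M in the upper half (clipped to the logo for small sizes)
  put <- function(m, r, c, h, w) {
    if (r > nrow(m) || c > ncol(m)) {
      return(m)
    }
    m[r:min(r + h - 1L, nrow(m)), c:min(c + w - 1L, ncol(m))] <- 1L
    m
  }
  h <- max(4L, rows %/% 3L)
  w <- max(2L, cols %/% 20L)
  r0 <- max(4L, rows %/% 8L)
  c0 <- max(4L, cols %/% 10L)
  # P
  m <- put(m, r0, c0, h, w)
  m <- put(m, r0, c0, w, 3L * w)
  m <- put(m, r0 + h %/% 2L, c0, w, 3L * w)
  m <- put(m, r0, c0 + 2L * w, h %/% 2L, w)
  # M
  c1 <- c0 + 5L * w
  m <- put(m, r0, c1, h, w)
  m <- put(m, r0, c1 + 3L * w, h, w)
  m <- put(m, r0, c1 + w, h %/% 3L, w)
  m <- put(m, r0, c1 + 2L * w, h %/% 3L, w)
  m
}
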