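# Shared fixtures and memoized heavy computations.

# A small deterministic test image with smooth + oscillatory + noise content.
tiny_image <- function(n = 32L, seed = 7L) {
  set.seed(seed)
  x <- matrix(seq_len(n), n, n, byrow = TRUE)
  y <- matrix(seq_len(n), n, n)
  img <- 100 + 40 * exp(-((x - n / 2)^2 + (y - n / 2)^2) / (2 * (n / 4)^2)) +
    6 * sin(2 * pi * 0.12 * x) + matrix(rnorm(n * n, sd = 1.5), n, n)
  gray_image(pmin(pmax(img, 0), 255))
}

# Memoized attack-free suite over ten 256x256 phantoms at default parameters
# (used by several acceptance checks; computed once per test run).
.suite_cache <- new.env(parent = emptyenv())

attack_free_suite <- function() {
  if (is.null(.suite_cache$res)) {
    logo <- make_logo(64L, 64L)
    lb <- as_watermark_bits(logo)
    rows <- lapply(1:10, function(seed) {
      ph <- make_phantom(seed = seed)
      emb <- embed(ph, logo)
      det <- detect(emb$watermarked, emb$sidecar)
      vi <- verify_integrity(
        det$payload, det$v_star, det$payload_values, det$texture_levels
      )
      data.frame(
        seed = seed, nc = nc(lb, det$logo), psnr = psnr(ph, emb$watermarked),
        intact = vi$intact, n_flagged = vi$map$n_flagged
      )
    })
    .suite_cache$res <- do.call(rbind, rows)
  }
  .suite_cache$res
}

smooth_suite <- function() {
  if (is.null(.suite_cache$smooth)) {
    logo <- make_logo(64L, 64L)
    .suite_cache$smooth <- vapply(1:3, function(seed) {
      ph <- make_phantom(texture_amplitude = 0, noise_sigma = 0, seed = seed)
      psnr(ph, embed(ph, logo)$watermarked)
    }, numeric(1))
  }
  .suite_cache$smooth
}
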