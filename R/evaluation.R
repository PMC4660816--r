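#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 log10(255^2 / MSE)` with `MSE` the mean squared pixel
#' difference. Identical images have zero MSE and are reported as `Inf`.
#'
#' @param orig,test numeric matrices of equal size (8-bit scale).
#' @return PSNR in dB (possibly `Inf`).
#' @export
psnr <- function(orig, test) {
  if (!all(dim(orig) == dim(test))) {
    stop("psnr: image shapes differ", call. = FALSE)
  }
  mse <- mean((orig - test)^2)
  if (mse == 0) {
    return(Inf)
  }
  10 * log10(255^2 / mse)
}

#' Normalized correlation of binary watermarks
#'
#' `NC = sum(W * W') / (sqrt(sum(W^2)) * sqrt(sum(W'^2)))`; in `[0, 1]` for
#' binary inputs and 1 for perfect recovery. An all-zero reference watermark
#' leaves the ratio undefined and is rejected; an all-zero extraction is
#' reported as 0.
#'
#' @param W,W_star [watermark_bits()] objects (or 0/1 vectors/matrices) of
#'   equal shape.
#' @return normalized correlation.
#' @export
nc <- function(W, W_star) {
  wb <- function(x) {
    if (inherits(x, "watermark_bits")) x$bits else as.integer(x)
  }
  a <- wb(W)
  b <- wb(W_star)
  if (length(a) != length(b)) {
    stop("nc: watermark shapes differ", call. = FALSE)
  }
  if (all(a == 0L)) {
    stop("nc: reference watermark is all-zero (NC undefined)", call. = FALSE)
  }
  if (all(b == 0L)) {
    return(0)
  }
  sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
}

#' Attack specification
#'
#' @param kind `"salt_pepper"` or `"gaussian"`.
#' @param density fraction of pixels hit (salt & pepper), in (0, 1).
#' @param variance noise variance on the 8-bit intensity scale (Gaussian).
#' @param seed integer RNG seed making the attack reproducible.
#' @return object of class `attack_spec`.
#' @export
attack_spec <- function(kind = c("salt_pepper", "gaussian"),
                        density = NULL, variance = NULL, seed = 1L) {
  kind <- match.arg(kind)
  if (kind == "salt_pepper") {
    if (is.null(density) || !is.numeric(density) || density <= 0 || density >= 1) {
      stop("attack_spec: salt_pepper needs density in (0, 1)", call. = FALSE)
    }
    if (!is.null(variance)) {
      stop("attack_spec: `variance` is not a salt_pepper parameter", call. = FALSE)
    }
  } else {
    if (is.null(variance) || !is.numeric(variance) || variance <= 0) {
      stop("attack_spec: gaussian needs a positive variance", call. = FALSE)
    }
    if (!is.null(density)) {
      stop("attack_spec: `density` is not a gaussian parameter", call. = FALSE)
    }
  }
  structure(
    list(kind = kind, density = density, variance = variance, seed = as.integer(seed)),
    class = "attack_spec"
  )
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  code
}

#' Apply a seeded noise attack to an image
#'
#' Salt & pepper sets a `density` fraction of pixels to 0 or 255 with equal
#' probability; Gaussian adds zero-mean noise of the given variance. The
#' result is re-exported to 8 bits (attacks happen in the image channel).
#' Identical seeds give identical outputs; the caller's RNG state is left
#' untouched.
#'
#' @param img 8-bit image matrix.
#' @param spec an [attack_spec()].
#' @return attacked 8-bit image matrix.
#' @export
attack <- function(img, spec) {
  stopifnot(inherits(spec, "attack_spec"))
  n <- length(img)
  out <- with_seed(spec$seed, {
    if (spec$kind == "salt_pepper") {
      hit <- which(stats::runif(n) < spec$density)
      x <- img
      x[hit] <- ifelse(stats::runif(length(hit)) < 0.5, 0, 255)
      x
    } else {
      img + stats::rnorm(n, sd = sqrt(spec$variance))
    }
  })
  export_u8(out)
}

#' Run the robustness suite over an attack grid
#'
#' Embeds once, then for each attack spec: attack the watermarked image,
#' blindly detect, and record the authentication NC and the attacked-image
#' PSNR. An empty grid yields an empty table.
#'
#' @param host host image.
#' @param logo logo matrix or [watermark_bits()].
#' @param params [decomposition_params()].
#' @param attacks list of [attack_spec()] objects (possibly empty). A `NULL`
#'   element denotes the attack-free row.
#' @param plans plan pair, see [default_plans()].
#' @return data.frame with columns `kind`, `parameter`, `seed`, `nc`,
#'   `psnr_attacked`, plus attribute `psnr_watermarked`.
#' @export
run_robustness_suite <- function(host, logo, params = decomposition_params(),
                                 attacks = list(), plans = default_plans()) {
  logo <- as_watermark_bits(logo)
  emb <- embed(host, logo, params, plans)
  base_psnr <- psnr(host, emb$watermarked)
  rows <- lapply(attacks, function(spec) {
    if (is.null(spec)) {
      img <- emb$watermarked
      kind <- "none"
      par <- NA_real_
      seed <- NA_integer_
    } else {
      img <- attack(emb$watermarked, spec)
      kind <- spec$kind
      par <- if (kind == "salt_pepper") spec$density else spec$variance
      seed <- spec$seed
    }
    det <- detect(img, emb$sidecar)
    data.frame(
      kind = kind, parameter = par, seed = seed,
      nc = nc(logo, det$logo),
      psnr_attacked = psnr(emb$watermarked, img)
    )
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(
      kind = character(0), parameter = numeric(0), seed = integer(0),
      nc = numeric(0), psnr_attacked = numeric(0)
    )
  }
  attr(out, "psnr_watermarked") <- base_psnr
  out
}
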