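#' 1-level orthonormal Haar DWT
#'
#' Splits an even-dimension image into four half-size subbands LL, HL, LH,
#' HH. Orthonormal scaling: a constant image of value `c` yields `LL = 2c`
#' and zero detail bands, and the total energy (sum of squares) is preserved
#' exactly, so the inverse is the transpose and reconstruction is perfect.
#'
#' Convention for a 2x2 pixel block `[[a, b], [c, d]]` (rows = image rows):
#' `LL = (a+b+c+d)/2`, `HL = (a+b-c-d)/2` (vertical frequency),
#' `LH = (a-b+c-d)/2` (horizontal frequency), `HH = (a-b-c+d)/2`.
#'
#' @param img numeric matrix with even height and width.
#' @return object of class `subband_set`: list of matrices `LL`, `HL`, `LH`,
#'   `HH`, each `nrow(img)/2 x ncol(img)/2`.
#' @export
dwt1 <- function(img) {
  h <- nrow(img)
  w <- ncol(img)
  if (h %% 2L != 0L || w %% 2L != 0L) {
    stop("dwt1: image dimensions must be even", call. = FALSE)
  }
  ro <- seq(1L, h, 2L)
  re <- seq(2L, h, 2L)
  co <- seq(1L, w, 2L)
  ce <- seq(2L, w, 2L)
  a <- img[ro, co, drop = FALSE]
  b <- img[ro, ce, drop = FALSE]
  cc <- img[re, co, drop = FALSE]
  d <- img[re, ce, drop = FALSE]
  structure(
    list(
      LL = (a + b + cc + d) / 2,
      HL = (a + b - cc - d) / 2,
      LH = (a - b + cc - d) / 2,
      HH = (a - b - cc + d) / 2
    ),
    class = "subband_set"
  )
}

#' Inverse 1-level Haar DWT
#'
#' Exact inverse of [dwt1()].
#'
#' @param s a `subband_set` (list with equal-size matrices LL, HL, LH, HH).
#' @return reconstructed image matrix, twice the subband size.
#' @export
idwt1 <- function(s) {
  dims <- vapply(s[c("LL", "HL", "LH", "HH")], dim, integer(2))
  if (any(dims != dims[, 1])) {
    stop("idwt1: subband shapes differ", call. = FALSE)
  }
  hh <- nrow(s$LL)
  ww <- ncol(s$LL)
  a <- (s$LL + s$HL + s$LH + s$HH) / 2
  b <- (s$LL + s$HL - s$LH - s$HH) / 2
  cc <- (s$LL - s$HL + s$LH - s$HH) / 2
  d <- (s$LL - s$HL - s$LH + s$HH) / 2
  out <- matrix(0, 2L * hh, 2L * ww)
  ro <- seq(1L, 2L * hh, 2L)
  re <- seq(2L, 2L * hh, 2L)
  co <- seq(1L, 2L * ww, 2L)
  ce <- seq(2L, 2L * ww, 2L)
  out[ro, co] <- a
  out[ro, ce] <- b
  out[re, co] <- cc
  out[re, ce] <- d
  out
}

#' 2x2 discrete Fourier transform (real, degenerate case)
#'
#' For M = N = 2 the complex exponentials reduce to +-1, so all four
#' frequency coefficients of a real block are real. With the 1/(MN)
#' normalization on the forward transform and input `[[a, b], [c, d]]`
#' (first index = row = x):
#' `F(0,0) = (a+b+c+d)/4`, `F(0,1) = (a-b+c-d)/4`,
#' `F(1,0) = (a+b-c-d)/4`, `F(1,1) = (a-b-c+d)/4`.
#'
#' @param b 2x2 numeric matrix (spatial block).
#' @return 2x2 numeric matrix of frequency coefficients; entry `[u+1, v+1]`
#'   is `F(u, v)`.
#' @export
dft2x2 <- function(b) {
  stopifnot(is.matrix(b), all(dim(b) == c(2L, 2L)))
  matrix(
    c(
      (b[1, 1] + b[1, 2] + b[2, 1] + b[2, 2]) / 4,
      (b[1, 1] + b[1, 2] - b[2, 1] - b[2, 2]) / 4,
      (b[1, 1] - b[1, 2] + b[2, 1] - b[2, 2]) / 4,
      (b[1, 1] - b[1, 2] - b[2, 1] + b[2, 2]) / 4
    ),
    nrow = 2L
  )
}

#' Inverse 2x2 DFT
#'
#' Conjugate kernel without prefactor, making [dft2x2()] / `idft2x2()` an
#' exactly inverse pair: `f(x, y) = sum_uv F(u, v) * (-1)^(ux + vy)`.
#'
#' @param F 2x2 numeric matrix of (real) frequency coefficients.
#' @return 2x2 spatial block.
#' @export
idft2x2 <- function(F) {
  stopifnot(is.matrix(F), all(dim(F) == c(2L, 2L)))
  matrix(
    c(
      F[1, 1] + F[1, 2] + F[2, 1] + F[2, 2],
      F[1, 1] + F[1, 2] - F[2, 1] - F[2, 2],
      F[1, 1] - F[1, 2] + F[2, 1] - F[2, 2],
      F[1, 1] - F[1, 2] - F[2, 1] + F[2, 2]
    ),
    nrow = 2L
  )
}

# Gridwise 2x2-block DFT over a whole subband: returns the four coefficient
# planes, one value per block, blocks addressed by (block_row, block_col).
# This is dft2x2() applied to every tile at once.
blockdft_forward <- function(s) {
  h <- nrow(s)
  w <- ncol(s)
  if (h %% 2L != 0L || w %% 2L != 0L) {
    stop("blockdft: subband dimensions must be even", call. = FALSE)
  }
  ro <- seq(1L, h, 2L)
  re <- seq(2L, h, 2L)
  co <- seq(1L, w, 2L)
  ce <- seq(2L, w, 2L)
  a <- s[ro, co, drop = FALSE]
  b <- s[ro, ce, drop = FALSE]
  cc <- s[re, co, drop = FALSE]
  d <- s[re, ce, drop = FALSE]
  list(
    `00` = (a + b + cc + d) / 4,
    `01` = (a - b + cc - d) / 4,
    `10` = (a + b - cc - d) / 4,
    `11` = (a - b - cc + d) / 4
  )
}

blockdft_inverse <- function(Fp) {
  hh <- nrow(Fp$`00`)
  ww <- ncol(Fp$`00`)
  a <- Fp$`00` + Fp$`01` + Fp$`10` + Fp$`11`
  b <- Fp$`00` - Fp$`01` + Fp$`10` - Fp$`11`
  cc <- Fp$`00` + Fp$`01` - Fp$`10` - Fp$`11`
  d <- Fp$`00` - Fp$`01` - Fp$`10` + Fp$`11`
  out <- matrix(0, 2L * hh, 2L * ww)
  ro <- seq(1L, 2L * hh, 2L)
  re <- seq(2L, 2L * hh, 2L)
  co <- seq(1L, 2L * ww, 2L)
  ce <- seq(2L, 2L * ww, 2L)
  out[ro, co] <- a
  out[ro, ce] <- b
  out[re, co] <- cc
  out[re, ce] <- d
  out
}
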