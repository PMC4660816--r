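#' Grayscale image container
#'
#' A `gray_image` is a numeric matrix of intensities on the 8-bit scale
#' (nominally 0--255) with both dimensions divisible by 4. The divisibility
#' constraint is what the downstream pipeline needs: a 1-level DWT halves
#' each dimension and the embedding then tiles the subband into 2x2 blocks.
#' Intensities are kept as unclamped reals everywhere inside the solvers;
#' clamping/rounding to 8 bits happens only in [export_u8()] (and hence in
#' the file writers).
#'
#' @param x numeric matrix of pixel intensities.
#' @param check_dims if `TRUE` (default), require dimensions divisible by 4.
#' @return `x` as a plain numeric matrix, validated.
#' @examples
#' img <- gray_image(matrix(128, 8, 8))
#' @export
gray_image <- function(x, check_dims = TRUE) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop("gray_image: `x` must be a numeric matrix", call. = FALSE)
  }
  if (any(!is.finite(x))) {
    stop("gray_image: pixel intensities must all be finite", call. = FALSE)
  }
  if (check_dims && (nrow(x) %% 4L != 0L || ncol(x) %% 4L != 0L)) {
    stop(sprintf(
      "gray_image: dimensions %dx%d are not divisible by 4",
      nrow(x), ncol(x)
    ), call. = FALSE)
  }
  storage.mode(x) <- "double"
  x
}

#' Round and clamp an intensity field to the 8-bit range
#'
#' This is the only place intensities are quantized: the realistic channel
#' a watermarked image travels through. Detection always operates on the
#' exported 8-bit image.
#'
#' @param x numeric matrix.
#' @return integer-valued double matrix in `[0, 255]`.
#' @export
export_u8 <- function(x) {
  pmin(pmax(round(x), 0), 255)
}

#' Read an 8-bit grayscale image (PGM or PNG)
#'
#' Supports PGM dialects P2 (ASCII) and P5 (binary) with maxval <= 255, and
#' 8-bit single-channel PNG. Color or 16-bit inputs are rejected with an
#' explicit message rather than silently converted.
#'
#' @param path file path; format chosen by extension (`.pgm`, `.png`).
#' @return a [gray_image()] matrix (dimension check deferred to the callers
#'   that need it; the reader itself accepts any size).
#' @export
read_image <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("read_image: file not found: %s", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    pgm = read_pgm(path),
    png = read_png_gray(path),
    stop(sprintf("read_image: unsupported format '.%s' (PGM/PNG only)", ext),
      call. = FALSE
    )
  )
  gray_image(img, check_dims = FALSE)
}

#' Write an image as 8-bit PGM or PNG
#'
#' Intensities are exported through [export_u8()] first, so the written file
#' round-trips exactly for data already on the integer 0--255 grid.
#'
#' @param img numeric matrix.
#' @param path output path; format chosen by extension.
#' @param pgm_format `"P5"` (binary, default) or `"P2"` (ASCII) for PGM.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, pgm_format = c("P5", "P2")) {
  pgm_format <- match.arg(pgm_format)
  u8 <- export_u8(img)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    pgm = write_pgm(u8, path, format = pgm_format),
    png = png::writePNG(u8 / 255, target = path),
    stop(sprintf("write_image: unsupported format '.%s' (PGM/PNG only)", ext),
      call. = FALSE
    )
  )
  invisible(path)
}

read_png_gray <- function(path) {
  a <- png::readPNG(path, info = TRUE)
  info <- attr(a, "info")
  if (!is.null(info$bit.depth) && info$bit.depth > 8) {
    stop(sprintf(
      "read_image: %d-bit PNG not supported (8-bit grayscale only)",
      info$bit.depth
    ), call. = FALSE)
  }
  if (length(dim(a)) == 3L) {
    nch <- dim(a)[3]
    if (nch == 2L) {
      # gray + alpha: accept the gray channel, require opaque alpha
      if (any(a[, , 2] < 1)) {
        stop("read_image: PNG has non-trivial alpha channel", call. = FALSE)
      }
      a <- a[, , 1]
    } else {
      stop("read_image: color PNG not supported (grayscale only)",
        call. = FALSE
      )
    }
  }
  out <- round(a * 255)
  attributes(out) <- list(dim = dim(out))
  out
}

# -- PGM (P2/P5), maxval <= 255 ----------------------------------------------
# Tiny hand-rolled parser: handles '#' comments in the header and both the
# ASCII and binary raster dialects.

read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))

  # tokenize the header: magic, width, height, maxval (comments skipped)
  tokens <- character(0)
  buf <- ""
  in_comment <- FALSE
  while (length(tokens) < 4L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L) stop("read_pgm: truncated header", call. = FALSE)
    if (in_comment) {
      if (ch %in% c("\n", "\r")) in_comment <- FALSE
      next
    }
    if (ch == "#") {
      in_comment <- TRUE
      next
    }
    if (grepl("[[:space:]]", ch)) {
      if (nzchar(buf)) {
        tokens <- c(tokens, buf)
        buf <- ""
      }
    } else {
      buf <- paste0(buf, ch)
    }
  }
  magic <- tokens[1]
  w <- as.integer(tokens[2])
  h <- as.integer(tokens[3])
  maxval <- as.integer(tokens[4])
  if (!magic %in% c("P2", "P5")) {
    stop(sprintf("read_pgm: unsupported magic '%s'", magic), call. = FALSE)
  }
  if (is.na(w) || is.na(h) || w < 1L || h < 1L) {
    stop("read_pgm: invalid dimensions", call. = FALSE)
  }
  if (is.na(maxval) || maxval < 1L || maxval > 255L) {
    stop(sprintf("read_pgm: maxval %s unsupported (8-bit only)", tokens[4]),
      call. = FALSE
    )
  }
  n <- w * h
  if (magic == "P5") {
    raw <- readBin(con, "integer", n = n, size = 1L, signed = FALSE)
    if (length(raw) < n) stop("read_pgm: truncated raster", call. = FALSE)
    vals <- raw
  } else {
    txt <- readChar(con, file.size(path), useBytes = TRUE)
    txt <- gsub("#[^\n]*", " ", txt)
    vals <- suppressWarnings(as.numeric(strsplit(trimws(txt), "[[:space:]]+")[[1]]))
    if (length(vals) < n || anyNA(vals[seq_len(n)])) {
      stop("read_pgm: truncated or malformed ASCII raster", call. = FALSE)
    }
    vals <- vals[seq_len(n)]
  }
  # PGM raster is row-major, top row first
  matrix(as.double(vals), nrow = h, ncol = w, byrow = TRUE)
}

write_pgm <- function(u8, path, format = "P5") {
  h <- nrow(u8)
  w <- ncol(u8)
  vals <- as.integer(t(u8)) # row-major
  if (format == "P5") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeChar(sprintf("P5\n%d %d\n255\n", w, h), con, eos = NULL)
    writeBin(as.raw(vals), con)
  } else {
    lines <- apply(u8, 1L, paste, collapse = " ")
    writeLines(c("P2", sprintf("%d %d", w, h), "255", lines), path)
  }
  invisible(path)
}
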