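#' Ordered binary watermark sequence
#'
#' @param bits integer vector of 0/1 (row-major scan of the logo).
#' @param shape integer `c(rows, cols)` of the source logo; defaults to a
#'   single row.
#' @return object of class `watermark_bits`.
#' @export
watermark_bits <- function(bits, shape = c(1L, length(bits))) {
  bits <- as.integer(bits)
  if (length(bits) == 0L || !all(bits %in% c(0L, 1L))) {
    stop("watermark_bits: bits must be a non-empty 0/1 sequence", call. = FALSE)
  }
  shape <- as.integer(shape)
  if (length(shape) != 2L || prod(shape) != length(bits)) {
    stop("watermark_bits: shape does not match bit count", call. = FALSE)
  }
  structure(list(bits = bits, shape = shape), class = "watermark_bits")
}

#' Convert a two-level image to watermark bits
#'
#' Binarizes at 128 (values on the 0--255 scale) or 0.5 (values in `[0,1]`),
#' scanning row-major.
#'
#' @param m numeric matrix (a logo image).
#' @return a [watermark_bits()] object with the matrix's shape.
#' @export
as_watermark_bits <- function(m) {
  if (inherits(m, "watermark_bits")) {
    return(m)
  }
  stopifnot(is.matrix(m))
  thr <- if (max(m) > 1) 128 else 0.5
  watermark_bits(as.integer(t(m) >= thr), dim(m))
}

#' Reshape watermark bits to their logo matrix
#'
#' @param wb a [watermark_bits()] object.
#' @return 0/1 integer matrix of the declared shape.
#' @export
bits_matrix <- function(wb) {
  matrix(wb$bits, nrow = wb$shape[1], ncol = wb$shape[2], byrow = TRUE)
}

#' Embedding plan: where bits go inside the 2x2 DFT blocks
#'
#' The scheme consumes 2x2 blocks of one DWT subband in row-major order,
#' writing `strength * bit` into two fixed DFT coefficient positions per
#' block (both positions are filled before advancing to the next block).
#' Default positions follow the component assignment of the method:
#' `(0,0)` and `(1,0)` for the noise component, `(0,0)` and `(1,1)` for the
#' texture component. Default subbands separate the two channels (noise ->
#' HL, texture -> LH): both plans use coefficient position `(0,0)`, and two
#' watermarks writing the same (subband, position) slot of two components
#' that are summed into one image would collide irrecoverably.
#'
#' The two channels use different signaling. The robust logo channel is
#' unipolar (`0` / `strength`), the literal coefficient-substitution rule.
#' The fragile integrity channel is bipolar (`-strength` / `+strength`) by
#' default: both levels then have the same magnitude, and any modification
#' that wipes or replaces local content parks the coefficient near 0 --
#' maximally far from *both* levels -- so the coefficient-validity check in
#' [verify_integrity()] sees it. (With unipolar signaling a wiped
#' coefficient is indistinguishable from an honest 0 bit.)
#'
#' @param component `"noise"` or `"texture"`.
#' @param subband `"HL"` or `"LH"`; default depends on `component` (noise
#'   HL, texture LH).
#' @param positions list of two distinct `c(row, col)` pairs with entries in
#'   `{0, 1}`; defaults depend on `component`.
#' @param strength positive scale applied to bit values; extraction
#'   thresholds midway between the two levels.
#' @param bipolar if `TRUE`, bits map to `{-strength, +strength}` instead of
#'   `{0, strength}`; default `TRUE` for the texture (integrity) channel.
#' @return object of class `embedding_plan`.
#' @export
embedding_plan <- function(component = c("noise", "texture"),
                           subband = NULL,
                           positions = NULL, strength = 2.0,
                           bipolar = NULL) {
  component <- match.arg(component)
  if (is.null(subband)) subband <- if (component == "noise") "HL" else "LH"
  subband <- match.arg(subband, c("HL", "LH"))
  if (is.null(bipolar)) bipolar <- component == "texture"
  if (is.null(positions)) {
    positions <- if (component == "noise") {
      list(c(0L, 0L), c(1L, 0L))
    } else {
      list(c(0L, 0L), c(1L, 1L))
    }
  }
  if (length(positions) != 2L ||
    !all(vapply(positions, function(p) {
      length(p) == 2L && all(p %in% c(0L, 1L))
    }, logical(1))) ||
    identical(positions[[1]], positions[[2]])) {
    stop("embedding_plan: positions must be two distinct (row, col) pairs in {0,1}^2",
      call. = FALSE
    )
  }
  if (!is.numeric(strength) || length(strength) != 1L || strength <= 0) {
    stop("embedding_plan: strength must be a positive scalar", call. = FALSE)
  }
  structure(
    list(
      component = component, subband = subband,
      positions = lapply(positions, as.integer),
      strength = as.double(strength), bipolar = isTRUE(bipolar)
    ),
    class = "embedding_plan"
  )
}

# the two coefficient levels carrying bit 0 / bit 1
plan_levels <- function(plan) {
  if (plan$bipolar) c(-plan$strength, plan$strength) else c(0, plan$strength)
}

pos_key <- function(p) sprintf("%d%d", p[1], p[2])

# row-major block rank -> column-major matrix index, for an nbr x nbc grid
rank_to_index <- function(k, nbr, nbc) {
  i <- (k - 1L) %/% nbc + 1L
  j <- (k - 1L) %% nbc + 1L
  (j - 1L) * nbr + i
}

subband_capacity <- function(s) {
  2L * (nrow(s) %/% 2L) * (ncol(s) %/% 2L)
}

#' Embed bits into the 2x2-block DFT coefficients of a subband
#'
#' Blocks are consumed in row-major order; within each block the first
#' planned coefficient receives the next bit and the second planned
#' coefficient the bit after, each written as the plan's level for that bit
#' (see [embedding_plan()] on signaling). Unconsumed blocks are untouched (to machine precision, since only touched blocks are
#' transformed and re-synthesized).
#'
#' @param s subband coefficient matrix (even dimensions).
#' @param bits a [watermark_bits()] object or 0/1 vector.
#' @param plan an [embedding_plan()].
#' @return the watermarked subband matrix.
#' @export
embed_bits <- function(s, bits, plan) {
  if (inherits(bits, "watermark_bits")) bits <- bits$bits
  bits <- as.integer(bits)
  nbr <- nrow(s) %/% 2L
  nbc <- ncol(s) %/% 2L
  cap <- 2L * nbr * nbc
  n <- length(bits)
  if (n > cap) {
    stop(sprintf(
      "embed_bits: %d bits required but subband capacity is %d bits (%d blocks x 2)",
      n, cap, nbr * nbc
    ), call. = FALSE)
  }
  Fp <- blockdft_forward(s)
  lv <- plan_levels(plan)
  n1 <- ceiling(n / 2)
  n2 <- floor(n / 2)
  k1 <- pos_key(plan$positions[[1]])
  k2 <- pos_key(plan$positions[[2]])
  if (n1 > 0L) {
    idx <- rank_to_index(seq_len(n1), nbr, nbc)
    Fp[[k1]][idx] <- lv[1] + (lv[2] - lv[1]) * bits[seq(1L, by = 2L, length.out = n1)]
  }
  if (n2 > 0L) {
    idx <- rank_to_index(seq_len(n2), nbr, nbc)
    Fp[[k2]][idx] <- lv[1] + (lv[2] - lv[1]) * bits[seq(2L, by = 2L, length.out = n2)]
  }
  blockdft_inverse(Fp)
}

#' Extract bits from a subband's 2x2-block DFT coefficients
#'
#' Reads the planned coefficient positions in the same row-major traversal
#' as [embed_bits()] and rounds each value to the nearest of the plan's two
#' levels (threshold midway between them).
#'
#' @param s subband coefficient matrix.
#' @param plan the [embedding_plan()] used at embedding.
#' @param n number of bits to read.
#' @param shape optional logo shape for the returned [watermark_bits()].
#' @return a [watermark_bits()] object.
#' @export
extract_bits <- function(s, plan, n, shape = c(1L, n)) {
  vals <- extract_values(s, plan, n)
  watermark_bits(as.integer(vals >= mean(plan_levels(plan))), shape)
}

#' Read raw planned coefficient values from a subband
#'
#' Same traversal as [extract_bits()], but returns the real coefficient
#' values instead of thresholded bits. Attack-free these cluster tightly
#' around `0` and `strength`; their distance from those two levels is the
#' coefficient-validity signal the integrity check uses.
#'
#' @inheritParams extract_bits
#' @return numeric vector of length `n`.
#' @export
extract_values <- function(s, plan, n) {
  nbr <- nrow(s) %/% 2L
  nbc <- ncol(s) %/% 2L
  cap <- 2L * nbr * nbc
  if (n > cap) {
    stop(sprintf(
      "extract_values: %d values requested but subband capacity is %d",
      n, cap
    ), call. = FALSE)
  }
  Fp <- blockdft_forward(s)
  n1 <- ceiling(n / 2)
  n2 <- floor(n / 2)
  vals <- numeric(n)
  if (n1 > 0L) {
    idx <- rank_to_index(seq_len(n1), nbr, nbc)
    vals[seq(1L, by = 2L, length.out = n1)] <- Fp[[pos_key(plan$positions[[1]])]][idx]
  }
  if (n2 > 0L) {
    idx <- rank_to_index(seq_len(n2), nbr, nbc)
    vals[seq(2L, by = 2L, length.out = n2)] <- Fp[[pos_key(plan$positions[[2]])]][idx]
  }
  vals
}

# -- integrity payload (compressed texture) ----------------------------------

block_mean <- function(x, rows, cols) {
  fr <- nrow(x) %/% rows
  fc <- ncol(x) %/% cols
  stopifnot(fr * rows == nrow(x), fc * cols == ncol(x))
  t1 <- rowsum(x, rep(seq_len(rows), each = fr))
  t(rowsum(t(t1), rep(seq_len(cols), each = fc))) / (fr * fc)
}

# storage permutation: the code of cell (i,j) is stored at the block whose
# grid position is the toroidal half-shift of (i,j). Returns, for each
# storage slot (row-major block rank), the row-major rank of the cell whose
# code lives there.
cell_storage_order <- function(rows, cols, shift) {
  ij <- expand.grid(j = seq_len(cols), i = seq_len(rows)) # row-major cell order
  cell_rank <- (ij$i - 1L) * cols + ij$j
  si <- (ij$i - 1L + shift[1]) %% rows + 1L
  sj <- (ij$j - 1L + shift[2]) %% cols + 1L
  slot <- (si - 1L) * cols + sj
  ord <- integer(rows * cols)
  ord[slot] <- cell_rank
  ord
}

#' Compress the texture component into an embeddable integrity payload
#'
#' Block-mean downsampling to a `thumb_rows x thumb_cols` thumbnail followed
#' by uniform quantization to `bit_depth` bits over the thumbnail's min/max
#' range. Codes are serialized MSB-first; the code of each cell is assigned
#' to the subband block displaced by `shift` cells (toroidally), so that
#' local tampering does not destroy the very data needed to repair it.
#'
#' @param v texture component matrix.
#' @param thumb_rows,thumb_cols thumbnail dimensions; must divide `dim(v)`.
#'   Defaults (`dim(v)/4`) give one cell per 4x4-pixel tamper-map cell and,
#'   with `bit_depth = 2`, exactly fill one subband's embedding capacity.
#' @param bit_depth bits per thumbnail value (default 2).
#' @param shift integer cell displacement of the storage block; default a
#'   third of the grid in each direction (deliberately not half: the storage
#'   map must not be an involution, or tampered cells would host each
#'   other's codes and mask each other during mismatch attribution).
#' @return object of class `integrity_payload`: serialized `bits` (storage
#'   order) plus the layout (`thumb_rows`, `thumb_cols`, `bit_depth`,
#'   `vmin`, `vmax`, `shift`) needed to decode.
#' @export
compress_texture <- function(v, thumb_rows = nrow(v) %/% 4L,
                             thumb_cols = ncol(v) %/% 4L,
                             bit_depth = 2L,
                             shift = c(thumb_rows %/% 3L, thumb_cols %/% 3L)) {
  bit_depth <- as.integer(bit_depth)
  stopifnot(bit_depth >= 1L, bit_depth <= 8L)
  thumb <- block_mean(v, thumb_rows, thumb_cols)
  vmin <- min(thumb)
  vmax <- max(thumb)
  nlev <- 2L^bit_depth - 1L
  q <- if (vmax > vmin) {
    round((thumb - vmin) / (vmax - vmin) * nlev)
  } else {
    matrix(0L, thumb_rows, thumb_cols)
  }
  ord <- cell_storage_order(thumb_rows, thumb_cols, shift)
  codes_storage <- as.vector(t(q))[ord] # row-major cells, permuted to slots
  planes <- vapply(
    seq(bit_depth - 1L, 0L),
    function(p) (codes_storage %/% 2L^p) %% 2L,
    numeric(length(codes_storage))
  )
  structure(
    list(
      bits = as.integer(t(planes)),
      thumb_rows = as.integer(thumb_rows), thumb_cols = as.integer(thumb_cols),
      bit_depth = bit_depth, vmin = vmin, vmax = vmax,
      shift = as.integer(shift)
    ),
    class = "integrity_payload"
  )
}

payload_from_bits <- function(bits, layout) {
  structure(
    list(
      bits = as.integer(bits),
      thumb_rows = as.integer(layout$thumb_rows),
      thumb_cols = as.integer(layout$thumb_cols),
      bit_depth = as.integer(layout$bit_depth),
      vmin = as.double(layout$vmin), vmax = as.double(layout$vmax),
      shift = as.integer(layout$shift)
    ),
    class = "integrity_payload"
  )
}

payload_layout <- function(p) {
  p[c("thumb_rows", "thumb_cols", "bit_depth", "vmin", "vmax", "shift")]
}

#' Decode an integrity payload to its texture thumbnail
#'
#' Inverts the serialization and the storage displacement of
#' [compress_texture()], returning the quantized thumbnail in natural cell
#' order. Per-pixel decode error is bounded by half a quantization step plus
#' the block-mean downsampling error.
#'
#' @param p an `integrity_payload`.
#' @return numeric `thumb_rows x thumb_cols` matrix.
#' @export
decode_payload <- function(p) {
  rows <- p$thumb_rows
  cols <- p$thumb_cols
  b <- p$bit_depth
  ncells <- rows * cols
  if (length(p$bits) != ncells * b || !all(p$bits %in% c(0L, 1L))) {
    stop("decode_payload: payload bits do not match the declared layout",
      call. = FALSE
    )
  }
  bm <- matrix(p$bits, nrow = b) # column = one cell's code, MSB first
  codes_storage <- as.vector(2L^seq(b - 1L, 0L) %*% bm)
  ord <- cell_storage_order(rows, cols, p$shift)
  codes_rm <- numeric(ncells)
  codes_rm[ord] <- codes_storage # back to row-major cell order
  q <- matrix(codes_rm, nrow = rows, ncol = cols, byrow = TRUE)
  if (p$vmax > p$vmin) {
    p$vmin + q * (p$vmax - p$vmin) / (2L^b - 1L)
  } else {
    matrix(p$vmin, rows, cols)
  }
}

quant_step <- function(p) {
  if (p$vmax > p$vmin) (p$vmax - p$vmin) / (2L^p$bit_depth - 1L) else 0
}

# -- end-to-end embedding / detection ----------------------------------------

#' Default plan pair for the dual watermark
#'
#' Authentication logo in the HL subband of the noise component; integrity
#' payload in the LH subband of the texture component. The channels must not
#' share (subband, position) slots: the components are summed into one
#' image, so co-located writes would superpose irrecoverably.
#'
#' @param strength coefficient scale shared by both plans (default 2: the
#'   extraction margin `strength/2` then sits far above the coefficient
#'   drift the re-decomposition of an exported 8-bit image exhibits).
#' @return list with elements `noise` and `texture`.
#' @export
default_plans <- function(strength = 2.0) {
  list(
    noise = embedding_plan("noise", "HL", strength = strength),
    texture = embedding_plan("texture", "LH", strength = strength)
  )
}

plans_collide <- function(plans) {
  if (!identical(plans$noise$subband, plans$texture$subband)) {
    return(FALSE)
  }
  any(vapply(
    plans$noise$positions,
    function(p) any(vapply(plans$texture$positions, identical, logical(1), y = p)),
    logical(1)
  ))
}

#' Embed the dual watermark into a host image
#'
#' Pipeline: decompose the host into structure `u`, texture `v`, noise `w`;
#' embed the authentication logo into the noise plan's DWT subband of `w`
#' (blockwise 2x2 DFT coefficient substitution); compress `v` into the
#' integrity payload and embed it the same way into the texture plan's
#' subband of `v`; re-assemble `u + v' + w' + residual` and export to
#' 8 bits. Each channel owns its (subband, position) coefficient slots
#' exclusively across *both* oscillatory components: the corresponding
#' slots of the partner component are zeroed, so the watermarked image
#' carries exactly `strength * bit` in each slot regardless of how a later
#' decomposition splits the oscillatory content between v and w. The
#' sidecar records the protocol (parameters, plans, logo shape, payload
#' layout) needed for verification; detection is blind with respect to the
#' host image and the watermark content.
#'
#' @param host a [gray_image()] (dimensions divisible by 4).
#' @param logo a [watermark_bits()] object or 0/1 (or 0/255) logo matrix.
#' @param params [decomposition_params()].
#' @param plans plan pair from [default_plans()] (or a compatible list).
#' @param bit_depth integrity-payload bits per thumbnail cell (default 2,
#'   which exactly fills the texture subband's capacity).
#' @return list with `watermarked` (8-bit matrix), `sidecar` (protocol
#'   record), `decomposition`, and `payload`.
#' @export
embed <- function(host, logo, params = decomposition_params(),
                  plans = default_plans(), bit_depth = 2L) {
  host <- gray_image(host)
  logo <- as_watermark_bits(logo)
  if (plans_collide(plans)) {
    stop("embed: noise and texture plans share a (subband, position) slot",
      call. = FALSE
    )
  }
  dec <- decompose(host, params)

  sw <- dwt1(dec$w)
  sv <- dwt1(dec$v)
  nsb <- plans$noise$subband
  tsb <- plans$texture$subband

  cap_w <- subband_capacity(sw[[nsb]])
  if (length(logo$bits) > cap_w) {
    stop(sprintf(
      "embed: logo needs %d bits but the %s subband offers %d",
      length(logo$bits), nsb, cap_w
    ), call. = FALSE)
  }
  # the partner component's slots are zeroed outright (levels {0,0} would be
  # wrong for bipolar plans, so use a unipolar copy with 0 bits)
  zero_plan <- function(plan) {
    plan$bipolar <- FALSE
    plan
  }
  zeros_logo <- integer(length(logo$bits))
  sw[[nsb]] <- embed_bits(sw[[nsb]], logo, plans$noise)
  sv[[nsb]] <- embed_bits(sv[[nsb]], zeros_logo, zero_plan(plans$noise))

  payload <- compress_texture(dec$v, bit_depth = bit_depth)
  cap_v <- subband_capacity(sv[[tsb]])
  if (length(payload$bits) > cap_v) {
    stop(sprintf(
      "embed: integrity payload needs %d bits but the %s subband offers %d",
      length(payload$bits), tsb, cap_v
    ), call. = FALSE)
  }
  zeros_pay <- integer(length(payload$bits))
  sv[[tsb]] <- embed_bits(sv[[tsb]], payload$bits, plans$texture)
  sw[[tsb]] <- embed_bits(sw[[tsb]], zeros_pay, zero_plan(plans$texture))

  watermarked <- export_u8(dec$u + idwt1(sv) + idwt1(sw) + dec$residual)
  sidecar <- list(
    format = "pdemark-sidecar", version = 1L,
    params = unclass(params),
    noise_plan = unclass(plans$noise),
    texture_plan = unclass(plans$texture),
    logo_shape = logo$shape,
    payload_layout = payload_layout(payload)
  )
  list(
    watermarked = watermarked, sidecar = sidecar,
    decomposition = dec, payload = payload
  )
}

#' Blind detection of both watermarks
#'
#' Re-runs the decomposition on the (possibly attacked) watermarked image
#' with the embedding parameters, then reads the logo bits and the
#' integrity payload from the subbands of the re-assembled oscillatory
#' carrier `v* + w*`. The structure `u*` and the model residual reproduce
#' almost exactly under re-decomposition, so the carrier recovers the
#' embedded coefficient slots with small drift; how the solver splits the
#' small-amplitude embedded signal *between* v* and w* is unstable, which
#' is why the two channels are separated by subband rather than by
#' component at read-out. Requires only the protocol sidecar, not the host.
#'
#' @param watermarked 8-bit image matrix.
#' @param sidecar the sidecar record produced by [embed()] (or read back via
#'   [sidecar_read()]).
#' @return list with `logo` ([watermark_bits()]), `payload`
#'   (`integrity_payload`), `payload_values` (raw coefficient values for
#'   the integrity channel, used by the coefficient-validity check),
#'   `u_star`, `v_star`, `w_star`, `decomposition`.
#' @export
detect <- function(watermarked, sidecar) {
  watermarked <- gray_image(watermarked)
  params <- do.call(decomposition_params, sidecar$params)
  plan_fields <- c("component", "subband", "positions", "strength", "bipolar")
  noise_plan <- do.call(embedding_plan, sidecar$noise_plan[plan_fields])
  texture_plan <- do.call(embedding_plan, sidecar$texture_plan[plan_fields])
  lay <- sidecar$payload_layout
  shape <- as.integer(sidecar$logo_shape)
  dec <- decompose(watermarked, params)
  carrier <- dwt1(dec$v + dec$w)
  logo_star <- extract_bits(
    carrier[[noise_plan$subband]], noise_plan, prod(shape), shape
  )
  n_payload <- as.integer(lay$thumb_rows) * as.integer(lay$thumb_cols) *
    as.integer(lay$bit_depth)
  pay_vals <- extract_values(carrier[[texture_plan$subband]], texture_plan, n_payload)
  lv <- plan_levels(texture_plan)
  pay_bits <- as.integer(pay_vals >= mean(lv))
  list(
    logo = logo_star,
    payload = payload_from_bits(pay_bits, lay),
    payload_values = pay_vals,
    texture_levels = lv,
    u_star = dec$u, v_star = dec$v, w_star = dec$w,
    decomposition = dec
  )
}

#' Verify authenticity by normalized correlation
#'
#' @param logo,logo_star original and extracted [watermark_bits()] (equal
#'   shapes).
#' @param nc_threshold acceptance threshold (inclusive), default 0.95.
#' @return list with `authentic` (logical) and `nc`.
#' @export
verify_authenticity <- function(logo, logo_star, nc_threshold = 0.95) {
  logo <- as_watermark_bits(logo)
  logo_star <- as_watermark_bits(logo_star)
  if (!identical(logo$shape, logo_star$shape)) {
    stop("verify_authenticity: watermark shapes differ", call. = FALSE)
  }
  val <- nc(logo, logo_star)
  list(authentic = val >= nc_threshold, nc = val)
}

#' Blockwise tamper map
#'
#' @param flags logical matrix, one cell per 2x2 subband block (4x4 image
#'   pixels).
#' @return object of class `tamper_map` with `flags` and `n_flagged`.
#' @export
tamper_map <- function(flags) {
  stopifnot(is.matrix(flags), is.logical(flags))
  structure(list(flags = flags, n_flagged = sum(flags)), class = "tamper_map")
}

#' Verify integrity and localize tampering
#'
#' Two complementary checks at tamper-map granularity (one cell per 2x2
#' subband block, i.e. 4x4 image pixels):
#'
#' * **Coefficient validity** (when `coef_values` is supplied, as
#'   [detect()] does): attack-free, every integrity-channel coefficient
#'   sits within a small drift of one of the two embedding levels; a block
#'   whose coefficients stray further than `coef_tol` (default 0.3 of the
#'   gap between the levels: above the drift the 8-bit export channel
#'   produces, below the mid-gap bit-decision radius) has been modified and
#'   is flagged directly. With the default bipolar integrity signaling both
#'   levels have magnitude `strength`, so content wipes (coefficients near
#'   0) are always invalid. This localizes any pixel-level modification, including in
#'   smooth regions where the texture content itself carries no contrast.
#' * **Content comparison**: the extracted payload decodes to the embedded
#'   texture thumbnail, which is compared cell by cell against the
#'   thumbnail recomputed from `v*`. A cell mismatches when the absolute
#'   difference exceeds `tol` (default: one quantization step, floored at
#'   1 intensity unit). Because each cell's code is stored in a displaced
#'   block, a mismatch may mean either "this cell's content changed" or
#'   "the block storing this cell's code was modified"; the second cause is
#'   recognized (and the false flag suppressed) when the hosting block
#'   fails the validity check.
#'
#' @param payload_star extracted `integrity_payload`.
#' @param v_star detected texture component.
#' @param coef_values raw integrity-channel coefficient values
#'   (`detect()$payload_values`); `NULL` disables the validity check.
#' @param levels the two integrity-channel coefficient levels
#'   (`detect()$texture_levels`); required with `coef_values`.
#' @param tol content mismatch tolerance in intensity units; `NULL` for the
#'   default.
#' @param coef_tol coefficient validity tolerance; `NULL` for
#'   `0.3 * (levels[2] - levels[1])`.
#' @return list with `intact` (no flags) and `map` (a [tamper_map()]).
#'   An undecodable payload yields a fully flagged map.
#' @export
verify_integrity <- function(payload_star, v_star, coef_values = NULL,
                             levels = NULL, tol = NULL, coef_tol = NULL) {
  rows <- payload_star$thumb_rows
  cols <- payload_star$thumb_cols
  dec <- tryCatch(decode_payload(payload_star), error = function(e) NULL)
  if (is.null(dec)) {
    map <- tamper_map(matrix(TRUE, rows, cols))
    return(list(intact = FALSE, map = map))
  }

  validity <- matrix(FALSE, rows, cols) # TRUE = block coefficients corrupted
  if (!is.null(coef_values)) {
    if (is.null(levels) || length(levels) != 2L) {
      stop("verify_integrity: `levels` (length 2) is required with `coef_values`",
        call. = FALSE
      )
    }
    if (is.null(coef_tol)) coef_tol <- 0.3 * (levels[2] - levels[1])
    d <- pmin(abs(coef_values - levels[1]), abs(coef_values - levels[2]))
    bad_slot <- d > coef_tol
    # slots 2k-1, 2k belong to block rank k (row-major)
    n1 <- seq(1L, length(bad_slot), 2L)
    bad_block <- bad_slot[n1]
    if (length(bad_slot) >= 2L) {
      n2 <- seq(2L, length(bad_slot), 2L)
      bad_block[seq_along(n2)] <- bad_block[seq_along(n2)] | bad_slot[n2]
    }
    validity <- matrix(bad_block, nrow = rows, ncol = cols, byrow = TRUE)
  }

  thumb_star <- block_mean(v_star, rows, cols)
  if (is.null(tol)) tol <- max(quant_step(payload_star), 1)
  mismatch <- abs(dec - thumb_star) > tol
  shift <- payload_star$shift
  if (all(shift %% c(rows, cols) == 0L)) {
    content_flags <- mismatch
  } else {
    # corruption status of the block hosting each cell's stored code
    host_bad <- validity[
      (seq_len(rows) - 1L + shift[1]) %% rows + 1L,
      (seq_len(cols) - 1L + shift[2]) %% cols + 1L,
      drop = FALSE
    ]
    content_flags <- mismatch & !host_bad
  }
  map <- tamper_map(validity | content_flags)
  list(intact = map$n_flagged == 0L, map = map)
}

#' Recover tampered regions from the embedded texture thumbnail
#'
#' In flagged cells the pixel content is rebuilt as detected structure `u*`
#' plus the decoded thumbnail's value for that cell (nearest upsampling);
#' unflagged cells are returned untouched. Structure lost to tampering is
#' not recoverable (only the texture thumbnail is embedded); the contract is
#' that the repair strictly reduces the tampered-region error against the
#' pre-tamper watermarked image for texture-destroying tampering.
#'
#' @param tampered 8-bit watermarked-then-tampered image.
#' @param payload_star extracted `integrity_payload` (from [detect()]).
#' @param map [tamper_map()] from [verify_integrity()].
#' @param detection optional [detect()] result for `tampered` (reused to
#'   avoid a second decomposition); otherwise `params` is used to decompose.
#' @param params [decomposition_params()] used when `detection` is absent.
#' @return recovered 8-bit image matrix.
#' @export
recover <- function(tampered, payload_star, map, detection = NULL,
                    params = decomposition_params()) {
  tampered <- gray_image(tampered)
  if (map$n_flagged == 0L) {
    return(tampered)
  }
  u_star <- if (!is.null(detection)) {
    detection$u_star
  } else {
    decompose(tampered, params)$u
  }
  dec <- decode_payload(payload_star)
  fr <- nrow(tampered) %/% nrow(dec)
  fc <- ncol(tampered) %/% ncol(dec)
  dec_up <- dec[rep(seq_len(nrow(dec)), each = fr), rep(seq_len(ncol(dec)), each = fc)]
  maskpx <- map$flags[rep(seq_len(nrow(map$flags)), each = fr),
    rep(seq_len(ncol(map$flags)), each = fc),
    drop = FALSE
  ]
  out <- tampered
  repaired <- u_star + dec_up
  out[maskpx] <- repaired[maskpx]
  export_u8(out)
}

#' Write / read a protocol sidecar as JSON
#'
#' @param sidecar sidecar list from [embed()].
#' @param path JSON file path.
#' @return `path` (write) or the sidecar list (read).
#' @export
sidecar_write <- function(sidecar, path) {
  jsonlite::write_json(sidecar, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname sidecar_write
#' @export
sidecar_read <- function(path) {
  sc <- jsonlite::read_json(path, simplifyVector = TRUE)
  # positions come back as a 2x2 matrix or list; normalize to list of pairs
  for (pl in c("noise_plan", "texture_plan")) {
    pos <- sc[[pl]]$positions
    if (is.matrix(pos)) pos <- lapply(seq_len(nrow(pos)), function(i) pos[i, ])
    sc[[pl]]$positions <- lapply(pos, as.integer)
  }
  sc$logo_shape <- as.integer(sc$logo_shape)
  sc
}
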