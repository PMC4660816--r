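test_that("watermark bit containers validate and reshape consistently", {
  wb <- watermark_bits(c(1L, 0L, 1L, 1L), c(2L, 2L))
  expect_equal(bits_matrix(wb), matrix(c(1L, 0L, 1L, 1L), 2, 2, byrow = TRUE))
  expect_error(watermark_bits(c(0L, 2L)), "0/1")
  expect_error(watermark_bits(c(0L, 1L), c(3L, 1L)), "shape")
  logo <- make_logo(16L, 16L)
  expect_identical(bits_matrix(as_watermark_bits(logo)), logo)
  expect_identical(bits_matrix(as_watermark_bits(logo * 255)), logo)
})

test_that("embedding plans enforce distinct in-range positions and a positive strength", {
  p <- embedding_plan("noise")
  expect_identical(p$subband, "HL")
  expect_identical(p$positions, list(c(0L, 0L), c(1L, 0L)))
  p2 <- embedding_plan("texture")
  expect_identical(p2$subband, "LH")
  expect_identical(p2$positions, list(c(0L, 0L), c(1L, 1L)))
  expect_error(embedding_plan("noise", positions = list(c(0, 0), c(0, 0))), "distinct")
  expect_error(embedding_plan("noise", positions = list(c(0, 2), c(1, 1))), "distinct|\\{0,1\\}")
  expect_error(embedding_plan("noise", strength = 0), "positive")
})

test_that("capacity arithmetic is exact and violations name required vs available bits", {
  s <- matrix(0, 128, 128) # 64x64 blocks -> 8192 bit slots
  plan <- embedding_plan("noise")
  expect_error(
    embed_bits(s, rep(1L, 8193), plan),
    "8193 bits required but subband capacity is 8192"
  )
  expect_error(extract_bits(s, plan, 8193L), "capacity")
  expect_silent(embed_bits(s, rep(0L, 8192), plan))
})

test_that("bit-level embed/extract round trip is exact on random subbands", {
  set.seed(21)
  for (i in 1:10) {
    s <- matrix(rnorm(32 * 32, sd = 5), 32, 32)
    n <- sample(1:512, 1)
    bits <- sample(0:1, n, replace = TRUE)
    plan <- embedding_plan(sample(c("noise", "texture"), 1),
      strength = runif(1, 0.5, 4)
    )
    s2 <- embed_bits(s, bits, plan)
    expect_identical(extract_bits(s2, plan, n)$bits, as.integer(bits))
  }
})

test_that("extraction tolerates coefficient noise below half the strength", {
  set.seed(22)
  s <- matrix(rnorm(64 * 64, sd = 3), 64, 64)
  bits <- sample(0:1, 2048, replace = TRUE)
  plan <- embedding_plan("noise", strength = 2)
  s2 <- embed_bits(s, bits, plan)
  noisy <- s2 + matrix(runif(64 * 64, -0.95, 0.95), 64, 64) # < strength/2 in any mean
  expect_identical(extract_bits(noisy, plan, 2048)$bits, as.integer(bits))
  # all-zero subband reads as all-zero bits
  expect_true(all(extract_bits(matrix(0, 8, 8), plan, 32)$bits == 0L))
})

test_that("unconsumed blocks are untouched by embedding", {
  set.seed(23)
  s <- matrix(rnorm(16 * 16), 16, 16)
  plan <- embedding_plan("noise")
  s2 <- embed_bits(s, c(1L, 0L, 1L), plan) # 2 blocks consumed of 64
  changed <- which(abs(s2 - s) > 1e-12, arr.ind = TRUE)
  expect_true(all(changed[, "row"] <= 2)) # first block row only
  expect_true(all(changed[, "col"] <= 4)) # first two blocks, row-major
})

test_that("texture compression quantizes within its error bound and round trips", {
  set.seed(24)
  v <- matrix(rnorm(64 * 64, sd = 5), 64, 64)
  pay <- compress_texture(v, 16L, 16L, bit_depth = 4L)
  dec <- decode_payload(pay)
  thumb <- pdemark:::block_mean(v, 16L, 16L)
  rng <- max(thumb) - min(thumb)
  expect_lte(max(abs(dec - thumb)), rng / 2^4 + 1e-12)
  # 8-bit full-size thumbnail: error bounded by range/256
  pay8 <- compress_texture(v, 64L, 64L, bit_depth = 8L)
  expect_lte(max(abs(decode_payload(pay8) - v)), (max(v) - min(v)) / 256)
  # constant texture decodes to a constant thumbnail
  payc <- compress_texture(matrix(3.5, 16, 16), 4L, 4L)
  expect_equal(decode_payload(payc), matrix(3.5, 4, 4))
  expect_error(decode_payload(payload_from_bits(c(0L, 1L), pay)), "layout")
})

test_that("payload storage displacement is a permutation that decode inverts", {
  ord <- pdemark:::cell_storage_order(9L, 12L, c(3L, 4L))
  expect_true(all(sort(ord) == seq_len(9L * 12L)))
  set.seed(25)
  v <- matrix(rnorm(48 * 48, sd = 4), 48, 48)
  pay <- compress_texture(v) # 12x12 cells, shift (4,4)
  pay_noshift <- compress_texture(v, shift = c(0L, 0L))
  expect_false(identical(pay$bits, pay_noshift$bits))
  expect_equal(decode_payload(pay), decode_payload(pay_noshift))
})

test_that("end-to-end embedding is deterministic and capacity-checked", {
  ph <- make_phantom(64L, 64L, seed = 31L)
  logo <- make_logo(16L, 16L)
  e1 <- embed(ph, logo)
  e2 <- embed(ph, logo)
  expect_identical(e1$watermarked, e2$watermarked)
  expect_error(embed(ph, make_logo(64L, 64L)), "4096 bits but")
  collide <- list(
    noise = embedding_plan("noise", "HL"),
    texture = embedding_plan("texture", "HL")
  )
  expect_error(embed(ph, logo, plans = collide), "share")
})

test_that("blind detection recovers the logo and the payload attack-free", {
  ph <- make_phantom(128L, 128L, seed = 32L)
  logo <- make_logo(32L, 32L)
  emb <- embed(ph, logo)
  det <- detect(emb$watermarked, emb$sidecar)
  expect_identical(dim(bits_matrix(det$logo)), c(32L, 32L))
  expect_gte(nc(as_watermark_bits(logo), det$logo), 0.998)
  va <- verify_authenticity(logo, det$logo)
  expect_true(va$authentic)
  vi <- verify_integrity(det$payload, det$v_star, det$payload_values, det$texture_levels)
  expect_true(vi$intact)
  expect_identical(vi$map$n_flagged, 0L)
  # determinism of the full detection path
  det2 <- detect(emb$watermarked, emb$sidecar)
  expect_identical(det$logo$bits, det2$logo$bits)
})

test_that("detection of an unwatermarked image is rejected by verification", {
  ph <- make_phantom(128L, 128L, seed = 33L)
  logo <- make_logo(32L, 32L)
  emb <- embed(ph, logo) # defines the protocol/sidecar
  det0 <- detect(export_u8(ph), emb$sidecar)
  va <- verify_authenticity(logo, det0$logo)
  expect_false(va$authentic)
  expect_lt(va$nc, 0.7)
})

test_that("authenticity verdict follows the NC threshold contract", {
  w <- watermark_bits(rep(c(1L, 0L), 50), c(10L, 10L))
  expect_true(verify_authenticity(w, w)$authentic)
  expect_equal(verify_authenticity(w, w)$nc, 1)
  wc <- watermark_bits(1L - w$bits, w$shape)
  vc <- verify_authenticity(w, wc)
  expect_false(vc$authentic)
  expect_equal(vc$nc, 0)
  # inclusive threshold: NC exactly at the threshold accepts
  half <- watermark_bits(c(w$bits[1:50], 1L - w$bits[51:100]), w$shape)
  v <- verify_authenticity(w, half, nc_threshold = nc(w, half))
  expect_true(v$authentic)
  expect_error(
    verify_authenticity(w, watermark_bits(c(0L, 1L), c(1L, 2L))),
    "shapes"
  )
})

test_that("a flipped payload bit in transit breaks integrity", {
  ph <- make_phantom(64L, 64L, seed = 34L)
  emb <- embed(ph, make_logo(16L, 16L))
  det <- detect(emb$watermarked, emb$sidecar)
  bits <- det$payload$bits
  bits[1] <- 1L - bits[1] # MSB of one cell's code
  tampered_payload <- pdemark:::payload_from_bits(bits, det$payload)
  vi <- verify_integrity(tampered_payload, det$v_star)
  expect_false(vi$intact)
  expect_gte(vi$map$n_flagged, 1L)
})

test_that("tamper flags localize an injected patch and recovery repairs it", {
  ph <- make_phantom(256L, 256L, seed = 35L)
  logo <- make_logo(64L, 64L)
  emb <- embed(ph, logo)
  # tamper inside the strongest texture region: wipe a 16x16 patch to its mean
  en <- pdemark:::block_mean(emb$decomposition$v^2, 64L, 64L)
  ci <- which(en == max(en), arr.ind = TRUE)[1, ]
  r0 <- min((ci[1] - 1L) * 4L + 1L, 241L)
  c0 <- min((ci[2] - 1L) * 4L + 1L, 241L)
  tam <- emb$watermarked
  tam[r0:(r0 + 15L), c0:(c0 + 15L)] <-
    round(mean(tam[r0:(r0 + 15L), c0:(c0 + 15L)]))
  det <- detect(tam, emb$sidecar)
  vi <- verify_integrity(det$payload, det$v_star, det$payload_values, det$texture_levels)
  expect_false(vi$intact)
  truth <- matrix(FALSE, 64L, 64L)
  truth[
    ((r0 - 1L) %/% 4L + 1L):((r0 + 14L) %/% 4L + 1L),
    ((c0 - 1L) %/% 4L + 1L):((c0 + 14L) %/% 4L + 1L)
  ] <- TRUE
  jaccard <- sum(vi$map$flags & truth) / sum(vi$map$flags | truth)
  expect_gte(jaccard, 0.5)
  rec <- recover(tam, det$payload, vi$map, detection = det)
  maskpx <- truth[rep(1:64, each = 4L), rep(1:64, each = 4L)]
  mse_tam <- mean((tam[maskpx] - emb$watermarked[maskpx])^2)
  mse_rec <- mean((rec[maskpx] - emb$watermarked[maskpx])^2)
  expect_lt(mse_rec, mse_tam)
  # recovery never alters unflagged cells
  unflagged_px <- !vi$map$flags[rep(1:64, each = 4L), rep(1:64, each = 4L)]
  expect_identical(rec[unflagged_px], tam[unflagged_px])
})

test_that("recovery with an empty tamper map is the identity", {
  ph <- make_phantom(64L, 64L, seed = 36L)
  emb <- embed(ph, make_logo(16L, 16L))
  det <- detect(emb$watermarked, emb$sidecar)
  empty <- tamper_map(matrix(FALSE, 16L, 16L))
  expect_identical(recover(emb$watermarked, det$payload, empty), emb$watermarked)
})

test_that("sidecars survive a JSON round trip", {
  ph <- make_phantom(64L, 64L, seed = 37L)
  emb <- embed(ph, make_logo(16L, 16L))
  path <- tempfile(fileext = ".json")
  sidecar_write(emb$sidecar, path)
  sc <- sidecar_read(path)
  det1 <- detect(emb$watermarked, emb$sidecar)
  det2 <- detect(emb$watermarked, sc)
  expect_identical(det1$logo$bits, det2$logo$bits)
  expect_identical(det1$payload$bits, det2$payload$bits)
})
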