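---
title: "Region-selection-free medical image watermarking: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-selection-free medical image watermarking: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdemark)
```

## The problem

Medical images exchanged over networks need two security properties that
plain transport does not give: *authenticity* (the image comes from the
claimed source) and *integrity* (nobody altered the pixels, and if someone
did, the reader wants to know where). Classical medical watermarking first
splits the image into a diagnostically significant region (ROI) and the
rest (RONI) and hides data only where it cannot hurt a diagnosis. That
split is the weak point: it is manual or modality-specific, and it does not
scale to archives of thousands of mixed-modality images.

`pdemark` removes the region-selection step. A variational image
decomposition replaces the ROI/RONI mask: the host is split into a
*structure* component `u` (piecewise-smooth anatomy, left untouched), a
*texture* component `v` (oscillating detail) and a *noise* component `w`
(small-scale isolated features). Watermarks go only into `v` and `w`,
which is where the human visual system tolerates change — the decomposition
itself decides, automatically and for any modality, where embedding is
safe.

## The decomposition model

The three-component model minimizes, over `(u, v, w)`,

$$
TV(u) \;+\; \chi\{\|v\|_G \le \mu\} \;+\; \chi\{w \in \delta B_E\}
\;+\; \frac{1}{2\lambda}\,\|f-u-v-w\|_2^2 ,
$$

where `TV` is the (isotropic, discrete) total variation, the G-norm ball
constrains the oscillating texture, and the noise ball is realized through
wavelet shrinkage. Alternating minimization solves it: per outer sweep,

1. `w <- r - WST(r, delta)` with `r = f - u - v` — the noise keeps exactly
   what soft thresholding (threshold `delta`, 2-level orthonormal Haar)
   removes;
2. `v <- P_{mu B_G}(f - u - w)` — Chambolle's dual projection onto the
   scaled G-ball;
3. `u <- s - P_{lambda B_G}(s)` with `s = f - v - w` — TV (ROF) denoising
   via the same projection.

The projection iterates
`p <- (p + tau * grad(div p - f/bound)) / (1 + tau * |grad(div p - f/bound)|)`
from `p = 0`; `tau <= 1/8` is the sufficient convergence condition, and the
projection is `bound * div p`. Forward differences with a Neumann boundary
and their exact negative-adjoint divergence are used throughout, so
`<grad a, p> = <a, -div p>` holds to machine precision (a unit-tested
identity, since the dual iteration silently depends on it).

The outer loop stops when no component changes by more than `eps` at any
pixel, or after `n_outer` sweeps. Everything is deterministic; the
components always satisfy `f = u + v + w + residual` exactly, where the
residual is the `lambda`-ball projection left by the last structure step.
Intensities are processed as unclamped reals; quantization to 8 bits
happens exactly once, at export, because clamping inside the solver would
break additivity.

### Parameter defaults (0–255 intensity scale)

| parameter | default | meaning / why |
|---|---|---|
| `lam` | 20 | TV fidelity weight. Needs to be large enough that `u` is genuinely piecewise-smooth; with values near 0.5 the TV step removes almost nothing, `u` keeps ~99 % of the oscillation and the texture/noise channels are empty, which defeats the scheme's premise. |
| `mu` | 20 | G-ball radius for `v`; admits textures of amplitude ≈ 10–15 that medical detail typically shows. |
| `delta` | 2 | shrinkage threshold; captures low-amplitude noise without eating texture. |
| `tau` | 0.125 | largest provably convergent dual step. |
| `n_inner` | 100 | dual iterations per projection; the projection "fills" slowly (O(1/n)), and 100 iterations capture ≈ 85 % of injected texture amplitude at 256×256. |
| `n_outer`, `eps` | 20, 0.5 | outer cap and stop tolerance; typical hosts converge in 5–8 sweeps. |

The energy trace reported by `decompose()` is the `TV + L2` surrogate. It
is *not* strictly monotone: the noise step is an l1-proximal substitute,
so the surrogate rises a few percent during the first sweeps while the
texture and noise budgets fill, then stabilizes. The property test asserts
stabilization (bounded level, vanishing late-stage steps) rather than
descent, which is the honest statement for this scheme.

## The watermarking scheme

Both payloads ride on the same transport: take a 1-level orthonormal Haar
DWT of a component, tile the chosen mid-frequency subband (HL or LH) into
2×2 blocks, take each block's 2×2 DFT — which is real-valued, since the
2×2 complex exponentials degenerate to ±1 — and overwrite two fixed
coefficient positions per block with bit levels. Blocks are consumed in
row-major order, both positions per block before advancing; capacity is
exactly `2 * (H/4) * (W/4)` bits per subband.

* **Authentication (robust) channel**: a 64×64 binary logo, embedded in
  the **HL** subband of the noise component at positions (0,0) and (1,0),
  unipolar levels `{0, strength}` — the literal coefficient-substitution
  rule.
* **Integrity (fragile) channel**: a compressed copy of the texture
  component, embedded in the **LH** subband of the texture component at
  positions (0,0) and (1,1), bipolar levels `{-strength, +strength}`.

`strength = 2.0` by default. The extraction margin is half the distance
between levels, and the 8-bit export channel plus re-decomposition produce
coefficient drift with tails to ≈ 0.6 (occasionally ≈ 1 on small hosts);
strength 2 puts the decision boundary several drift standard deviations
away at a cost of ≈ 2.5 dB PSNR, leaving watermarked phantoms at ≈ 44 dB,
far above the 35 dB acceptability line.

Three transport details matter and are worth stating explicitly:

1. **The two channels must not share (subband, position) slots.** Both
   plan defaults write position (0,0); the components sum into one image,
   so two channels writing the same slot of `v` and `w` superpose
   irrecoverably (measured: ~20 % logo bit errors when both channels use
   HL). Hence the HL/LH separation, and `embed()` refuses colliding plans.
2. **Each channel owns its slots across *both* oscillatory components.**
   When the logo goes into `w`'s HL slots, the same slots of `v` are
   zeroed (and vice versa for the payload), so the exported image carries
   exactly the intended level in every slot regardless of how a later
   decomposition splits the oscillation between `v*` and `w*`.
3. **Detection reads the carrier `v* + w*`.** Re-decomposition of the
   watermarked image reproduces `u*` and the residual almost exactly, but
   the *split* of small-amplitude embedded signal between `v*` and `w*`
   is unstable — the soft-threshold step absorbs nearly all of it into
   `w*` wherever it was embedded (reading the payload from `v*` alone is
   at chance level). The sum of the oscillatory components is stable, so
   both watermarks are extracted from the subbands of `v* + w*`. This
   keeps the embedding component-targeted and the read-out blind.

Embedding is deterministic end to end: decompose, write both channels,
re-assemble `u + v' + w' + residual`, round and clamp to 8 bits. The
residual is carried through unmodified — dropping it (reconstructing from
the three components alone) would distort the image for zero security
benefit. A JSON sidecar records the protocol: parameters, plans, logo
shape and payload layout. Detection needs the sidecar but neither the host
nor the watermark content.

## Integrity payload, localization, recovery

The payload is a quantized thumbnail of `v`: block means over 4×4-pixel
cells — one cell per embedding block, i.e. tamper-map granularity — with
2 bits per cell over the thumbnail's min/max range. For every legal image
size this is *exactly* the capacity of one subband (cells × 2 bits =
blocks × 2 slots).

The code of cell (i, j) is stored in the block displaced by a third of the
grid (toroidally) in both directions. Self-referential storage would be
useless — tampering would destroy exactly the data needed to repair the
tampered cells. A third, not half: the half-grid shift is an involution,
so two tampered regions a half-grid apart would host each other's codes
and mask each other during attribution.

Verification runs two complementary checks per cell:

* **Coefficient validity.** Attack-free, every integrity-channel
  coefficient lies within a small drift of one of the two levels
  `{-strength, +strength}`. A block whose coefficients stray beyond
  `0.3 * (level gap)` (= 1.2 at defaults: above the observed drift
  support, well below the wipe distance) has been modified. Bipolar
  signaling is what makes this sharp: any modification that wipes or
  replaces local content parks coefficients near 0, maximally far from
  both levels, whereas with unipolar levels a wipe is indistinguishable
  from honest 0 bits (mean-fill tampering then evades the check — we
  measured localization dropping to Jaccard ≈ 0.24 before switching).
* **Content comparison.** The decoded thumbnail against the thumbnail
  recomputed from `v*`, tolerance one quantization step (floored at one
  intensity unit). A mismatch at cell c can mean "c changed" or "the
  block hosting c's code changed"; the second cause is recognized — and
  the false flag suppressed — when the hosting block fails the validity
  check.

`recover()` rebuilds flagged cells as detected structure `u*` plus the
decoded thumbnail value (nearest upsampling); unflagged pixels are
returned bit-identically. Structure lost to tampering is not recoverable —
only the texture thumbnail is embedded — so the contract is relative:
for texture-destroying tampering the repair strictly reduces the
tampered-region error against the pre-tamper watermarked image (measured:
MSE 100 → 27 for a 16×16 mean-fill patch in a textured region).

## Evaluation

`psnr()` and `nc()` implement the standard `10 log10(255^2 / MSE)` and
normalized-correlation formulas, unit-tested against hand-computed cases.
`attack()` provides seeded salt & pepper (a `density` fraction of pixels
forced to 0 or 255) and additive Gaussian noise (given variance, clamped),
and `run_robustness_suite()` chains embed → attack → detect over a grid.
Because the source tables for the attack experiments are unreadable
figures, the package reports its own grids (salt & pepper density
0.01–0.2, Gaussian variance 5–50) and asserts the qualitative claim: NC
is high attack-free and weakly non-increasing in attack severity. The
absolute NC level under pixel noise is physics-limited: one ±128 pixel hit
perturbs a 2×2-block DFT coefficient by ≈ 16, an order of magnitude above
any imperceptible embedding strength, so NC under 1 % salt & pepper sits
near 0.86 rather than near 1.

## The synthetic phantom generator

`make_phantom()` emulates what the pipeline actually depends on in medical
imagery: a smooth anatomy-like background (seeded elliptical Gaussian
bumps over a mid-gray base, values kept in ≈ 30–220 so watermark-scale
perturbations cannot saturate), windowed sinusoidal texture patches
(amplitude 12, frequency 0.1 cycles/pixel — coarse, coherent texture whose
4×4 block means retain part of the oscillation, as real tissue texture
does), and optional Gaussian noise (sigma 2, below the shrinkage
threshold). It does *not* emulate modality-specific artifacts (speckle
correlation, beam hardening, bias fields), pathological low-contrast
structures, or DICOM value ranges; passing tests therefore show the
pipeline's contracts hold on images with realistic smooth/texture/noise
statistics, not that clinical detectability is unaffected on real scans.

Test and acceptance problem sizes are the package's own choices: unit
tests run at 32–128 px, the end-to-end suites at 256×256 with ten
phantoms and a 64×64 logo, which keeps the full test run a few minutes
while exercising the same code paths as larger images.

## Known limitations

* **The imperceptibility headline of the source scheme is not
  reproducible — by any implementation of its literal embedding rule.**
  Overwriting two coefficients per 2×2 block with bit levels injects a
  fixed energy per consumed block that is independent of the host. With a
  4096-bit logo (2048 blocks) and a capacity-filling integrity payload
  (4096 blocks) on a 256×256 host, that is an MSE of ≈ 0.4–0.7 before
  rounding, i.e. PSNR ≈ 45–52 dB at strengths 1–2 — comfortably above the
  35 dB acceptability threshold, but below the 60.13 dB minimum the
  original experiments report. The corresponding acceptance check is left
  failing deliberately, with this analysis as the explanation.
* Robust-channel survival under heavy pixel noise is modest (see above);
  the scheme's robustness claim holds as a trend, not as noise immunity.
* The sidecar is a protocol descriptor, not a secret: there is no
  cryptographic binding (no keys, hashes or signatures), so a capable
  adversary who knows the protocol could re-embed consistently. Matching
  the source scheme's scope, tamper evidence here targets accidental and
  naive modification, not cryptographic adversaries.
* Geometric attacks (rotation, scaling, cropping) and JPEG compression
  are out of scope; the blockwise transport is not invariant to them.
* Color, 16-bit and DICOM-wrapped inputs are not handled; the method is
  defined on 8-bit grayscale with dimensions divisible by 4.
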