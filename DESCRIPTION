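Package: pdemark
Title: Region-Selection-Free Medical Image Watermarking via PDE
    Structure-Texture-Noise Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Blind dual watermarking of 8-bit grayscale medical images
    without manual region-of-interest selection. A host image is split
    into structure, texture and noise components by the Aujol-Chambolle
    total-variation minimization (Chambolle dual projection plus wavelet
    soft thresholding); a robust binary authentication logo is embedded
    in the noise component and a fragile integrity payload (a compressed
    copy of the texture component) in the texture component, both through
    the real-valued 2x2 blockwise DFT coefficients of a 1-level Haar DWT
    subband. Includes blind detection, authenticity verification by
    normalized correlation, blockwise tamper localization, recovery of
    tampered regions from the embedded texture thumbnail, PSNR/NC
    evaluation, seeded salt-and-pepper and Gaussian noise attacks, a
    synthetic medical phantom generator, PGM/PNG image I/O and a small
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
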