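Package: gcxgcfuse
Title: Chromatogram-Level Fusion of FID and MS Channels in GCxGC
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comprehensive two-dimensional gas chromatography
    (GCxGC) with parallel flame-ionization (FID) and mass-spectrometric
    (MS) detection. The package aligns the two detector channels (phase
    estimation, common resampling, global and zonal polynomial retention
    warping), encodes the FID trace as a pseudo mass-spectral channel at
    m/z 0, fuses it losslessly with the MS data stream, and runs 2D peak
    detection, spectrally constrained template matching, reliable-peak
    fingerprinting across chromatogram batches, and calibration-linearity
    quality control on the fused data. A deterministic twin-channel
    simulator provides ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    mzR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
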