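---
title: "Fusing FID and MS channels in GC×GC: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fusing FID and MS channels in GCxGC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gcxgcfuse)
```

## Why fuse at the chromatogram level

A GC×GC separation observed by two detectors in parallel yields two
images of the *same* chemistry: a single-channel FID image whose
intensities are nearly proportional to combusted carbon mass, and an
MS image whose pixels carry fragmentation spectra. Keeping them apart
forces two processing chains and leaves the FID channel — which has no
spectral dimension — without a reliable way to track features across
runs. Fusing the streams into one spectral chromatogram removes both
problems, *provided* the channels are first registered: even modest
second-dimension offsets between detectors duplicate peaks in the
fused image and corrupt both identification and quantification.

The package therefore treats fusion as the easy final step of a
pipeline whose real substance is registration and validation:
alignment, misalignment metrology, polynomial retention correction,
then fusion, detection, matching and QC.

## Data model

A raw acquisition is a `detector_trace`: scan times plus either one
intensity per sample (FID) or one sparse centroided spectrum per scan
(MS). Folding by the modulation period maps sample *i* at time
*t<sub>i</sub>* to modulation column ⌊(*t<sub>i</sub>* − φ)/*P*<sub>M</sub>⌋
and intra-modulation row given by the remainder; the result is a
`spectral_image` storing `(col, row, mz, intensity)` records in long
form. Conventions: first-dimension retention in minutes, second in
seconds; image coordinates 0-based; *m/z* 0 is reserved for the FID
channel and real spectra must start at *m/z* ≥ 1 (acquisitions start
at *m/z* 35–40, so nothing collides).

Fusion itself is set union per pixel:

* `fid_to_pseudo_ms()` rewrites each FID pixel as the single pair
  (*m/z* 0, intensity);
* `fuse()` concatenates the two record sets (optionally scaling the
  FID channel by `fid_scale`; the default 1 preserves FID quantitation
  — any display normalization is a rendering concern, not a data one);
* `extract_fid()` / `extract_ms()` partition the records back. With
  `fid_scale = 1` both round trips are bit-exact, and
  `tic(fused) = tic(ms) + fid_scale · tic(fid)` holds everywhere.

## Channel alignment and registration

**Common clock.** `resample_common()` resamples both traces onto one
uniform clock over their temporal overlap. The default target rate is
the *lower* native rate: FID intensities interpolate linearly without
information loss, but MS spectra are assigned by nearest scan — the
package never fabricates spectra that were not measured.

**Phase.** `estimate_phase_shift()` maximizes the circular
cross-correlation of the two images' row-marginal TIC profiles and
reports the shift in seconds (exact for constructed shifts; tested as
a property over arbitrary circular shifts).

**Misalignment metrology.** For matched peak pairs,
`relative_misalignment()` reports RM = |²t<sub>R,MS</sub> −
²t<sub>R,FID</sub>| · 1000 ms with the FID as reference, and averages
the two channels' widths. RM is treated as *absolute* and in
milliseconds: the bundled three-set-up panel
(`example_misalignment()`) verifies arithmetically under exactly this
reading, with mean RM 45 ms and 31 ms for the two post-column-split
configurations (negligible against mean base widths of 542/649 ms) and
175 ms for the dual-secondary-column one, where the shift is
compound-dependent: severe at low second-dimension retention factor
*k* = (t₂ − t₂,void)/t₂,void, improving as *k* grows, and growing
again for wrap-around peaks whose *k* is ill-defined because their
modulation cycle count is unknown.

**Correction.** `fit_global_transform()` least-squares fits a
bivariate polynomial (degree 2: basis 1, t₁, t₂, t₁², t₁t₂, t₂²)
mapping one channel's retention coordinates onto the other's; fitting
is exact (coefficients recovered to ≤ 1e-9 relative) whenever the
pairs truly come from such a polynomial. `fit_zonal()` refits
independent polynomials inside user-chosen first-dimension zones (a
zone short of points degrades to degree 1, then to the global
fallback, with a message). `apply_transform()` warps an image by
moving every spectral record to its transformed coordinates and
splatting its intensity bilinearly over the four neighbouring pixels,
per *m/z* channel — retained intensity is conserved exactly, and peaks
move by the transform to within half a pixel. Pair correspondence for
fitting should come from match-factor-validated template matches, not
raw nearest neighbours, and wrap-around peaks are best excluded from
fits (their *k*, hence their planted shift, is uncertain); they stay
in misalignment reports, which is why `write_misalignment_report()`
prints both the inclusive mean and the wrap-around-free mean.

## Peak detection and metrology

`detect_peaks()` works on the TIC of any (fused or single-channel)
image: the baseline (median pixel level) is subtracted; noise is
estimated robustly from the dim quartile of pixels as
(median − Q₂₅)/0.6745 — unbiased on Gaussian noise, untouched by peaks,
floored at machine epsilon times the maximum so it is always positive;
the image is smoothed with a separable Gaussian (default σ = 1 px);
local maxima above `snr_min` · noise (default 100, the conventional
reliable-peak threshold) seed blobs grown by steepest-descent
watershed over pixels above 3 · noise, so ridges split adjacent peaks;
the apex is the sub-pixel intensity-weighted centroid of the pixels
within 10% of the blob maximum; volumes are background-corrected blob
sums, additionally gated by a volume-to-noise threshold (`vnr_min`,
default 10). Widths come from a Gaussian least-squares fit
(`minpack.lm::nlsLM`) to the second-dimension profile through the apex
within its own modulation column: ω<sub>h</sub> = 2.3548 σ,
ω<sub>b</sub> = 4 σ, in ms. The ratio ω<sub>b</sub>/ω<sub>h</sub> =
1.699 for any Gaussian peak — a useful internal consistency check that
the bundled panel's mean columns also satisfy (542/319, 649/382,
431/254 ≈ 1.70).

Choices worth stating: the apex spectrum (not a blob average) is used
for matching — simplest and least bias-prone; width profiles never
merge across modulation columns, matching how ω values are
conventionally read; raising `snr_min` can only shrink the peak list
(tested as a monotonicity property).

## Spectral matching and fingerprinting

`match_factor()` compares spectra as weighted vectors on the union of
their channels, weights *m/z*<sup>mz_exp</sup> ·
intensity<sup>int_exp</sup>, and reports DMF = 999 · cos² plus a
reverse factor restricted to the reference's channels (so RMF ≥ DMF
always). The default weighting (0.5, 0) is the plain square-root
cosine; the NIST-style (0.6, 3) is a config option. 999 means
identity, and the conventional acceptance threshold 700 applies on
this scale. The reserved *m/z* 0 channel is excluded by default, so
the embedded FID signal never perturbs identification.

`match_template()` registers a stored peak pattern to a chromatogram
under the dual criterion: candidates within a retention window,
spectral candidates gated by the entry's `dmf_min`, conflicts resolved
by highest DMF then smallest window-scaled distance (a total order —
matching is deterministic), and a degree-2 transform refitted on the
assignments each round (degrading to degree 1 below 6 pairs, to a pure
translation below 3). Entries without reference spectra match on
distance alone — deliberately retained as the single-channel FID
failure mode, which the validation exercises below quantify.

`ut_fingerprint()` builds a combined untargeted (reference
chromatogram's peaks) + targeted template, matches it to every run in
a batch, and calls a feature *reliable* when matched in at least
`ceiling(fraction · n)` of the *n* runs; the default fraction 0.5 is
the most relaxed conventional setting. `reliable_report()` expresses
each stream's reliable count as a percentage of the FID reference
(with counts 96/20/31 this prints 20.8% and 32.3%).

## Calibration QC and retention indexing

`fit_calibration()` regresses normalized volumes on normalized
concentrations by unweighted OLS (a 1/x weighting is available because
calibration residuals are typically heteroscedastic), reports
R² = 1 − SS<sub>res</sub>/SS<sub>tot</sub>, and checks that every
relative residual |ŷ−y|/ŷ stays within ±20% — residuals are taken
against the fitted value, the conservative reading. `classify_r2()`
bands fits into good (R² > 0.995), acceptable (0.990 ≤ R² ≤ 0.995 —
the boundary 0.990 counts as acceptable, not critical) and critical
(R² < 0.990). `linear_retention_index()` is the van den Dool–Kratz
formula on bracketing n-alkanes.

## The simulator and what it does (not) emulate

`simulate_pair()` renders a compound library to both detectors'
native clocks: separable Gaussian 2D peaks (tailing is out of scope),
amplitudes amount · rf · split-fraction · `amp_scale`, a standing FID
baseline so additive Gaussian noise never clips at zero, MS scans
carrying each compound's reference spectrum scaled by the same
envelope, and a second-dimension shift of the MS channel

  Δt₂(k) = a · exp(−b · k) + wrap_extra · [wrapped]

— this package's parameterization of the qualitative behaviour seen in
dual-secondary-column set-ups (severe at low *k*, improving with *k*,
worse again under wrap-around); all three constants are exposed.
`simulate_batch()` adds per-run retention drift (one Gaussian draw per
run and dimension — "slow" drift, constant within a run), independent
compound dropout, and spurious single-channel decoy peaks emulating
the FID's non-specific response; run seeds derive deterministically
from the configuration seed, and all randomness flows through R's
Mersenne-Twister generator, so outputs are identical across platforms
for a given seed.

Defaults mirror a flow-modulated set-up with parallel quadrupole
MS/FID detection: *P*<sub>M</sub> = 2.5 s, 200 Hz FID, 28 Hz MS,
70:30 FID/MS split, no inter-channel misalignment (the
post-column-split situation where offsets are negligible against peak
widths). The second-dimension void time defaults to 0.1 ·
*P*<sub>M</sub> and must be set explicitly when known — it is rarely
reported for a given column set, and every retention factor depends
on it.

What the simulator does *not* emulate: retention thermodynamics,
modulator dynamics, detector saturation, spectral skewing across a
peak, and chemical backgrounds. Tests passing on simulated data
therefore validate the *processing algebra* (registration, fusion
losslessness, detection and metrology accuracy, matching logic), not
instrument-specific artefacts.

## Validation study designs and problem sizes

The test suite validates each stage at sizes chosen to exercise the
mathematics without waste:

* **Registration study** (transform recovery, RM metrology): a
  12-compound panel spread over t₁ = 3–27 min with second-dimension
  retention correlated to elution order (as under temperature
  programming) in t₂ = 1.0–2.6 s, on a dual-secondary-column style
  configuration: *P*<sub>M</sub> = 4 s, 100 Hz FID / 28 Hz MS, 1:1
  split, t₂,void = 0.6 s, shift model a = 400 ms, b = 1 per unit *k*,
  wrap_extra = 800 ms. The realized *k* range (≈ 0.7–3.3) keeps the
  exponential shift curve in the regime where a degree-2 surface
  captures it — the configuration in which a global fit is expected to
  remove ≥ 90% of the mean RM while the early-eluting zone still
  benefits from a zonal refit, the behaviour the workflow is designed
  around. Noiseless acquisitions isolate metrology error from noise:
  detected-vs-planted RM agrees within half a 28 Hz sample interval
  (17.9 ms) for every compound.
* **Fingerprinting study**: 48 compounds, 30 runs, 40% per-run
  dropout, default drift, ~20 decoys per run, three data streams
  (FID-only, MS-only, fused) fingerprinted identically at DMF ≥ 700.
  The MS stream loses weak features to its smaller split fraction and
  higher noise; the fused stream keeps FID coverage while using MS
  spectra wherever they exist, so its reliable count dominates the MS
  count, and spectrally blind FID matching accrues strictly more false
  assignments (assignments contradicting the planted truth) than fused
  matching. Batches run at the peak-table level — the analytic
  S/N of each planted compound decides channel membership — because
  rendering 90 full acquisitions adds cost without adding information
  about the matching logic under test.
* **Detection properties**: 100 replicate small images for the
  planted-recovery/no-false-positive property; random sparse images
  for fusion losslessness (100), TIC oracles and serialization round
  trips.

## Numerical choices and degenerate inputs

* Folding requires `period_s · rate_hz` to be integral (the standard
  acquisition design); trailing partial modulations are dropped and
  retained intensity is conserved exactly.
* Warping uses forward bilinear splatting rather than backward
  interpolation: it conserves intensity by construction and needs no
  inversion of the fitted polynomial.
* The noise floor (machine epsilon × max intensity) keeps S/N finite
  on noiseless images; the quantile noise estimator assumes at least
  half the pixels are background, which holds for realistically sparse
  chromatograms (a caveat for very crowded toy images).
* Gaussian width fits fall back to unset widths (with a message) on
  flat or single-pixel profiles rather than reporting nonsense.
* Tie-breaks in matching are totally ordered (DMF, then scaled
  distance, then indices), so every operation is reproducible
  byte-for-byte; all writers emit fixed-format numbers (17 significant
  digits for lossless CSV round trips, 9 for the pseudo-MS text
  format, whose write∘parse∘write is byte-identical).
* The pseudo-MS text layout (SCAN/RT/pairs blocks) is fixed by this
  package so files are bit-reproducible; it makes no attempt to match
  any vendor's unpublished export dialect.

## Known limitations

Co-eluting peaks are not deconvolved — the watershed splits them at
ridges, biasing volumes of heavily overlapped pairs. First-dimension
width metrology is out of scope. Multi-way fusion of more than two
channels is composed pairwise rather than in one call. mzML is the
only instrument MS format read natively (via mzR); vendor binaries
must be converted upstream. The supported serializations are the
pseudo-MS text format, CSV and JSON; no binary container is written.
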