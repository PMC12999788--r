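#' @title FID/MS chromatogram fusion
#' @name fusion
#' @description
#' Encodes a folded FID image as a pseudo mass-spectral channel (a
#' single virtual fragment at m/z 0 per pixel) and merges it with the
#' MS image into one fused spectral chromatogram. The embedding is
#' lossless: the FID and MS partitions can be extracted back bit-exact,
#' and the fused TIC equals the sum of the two channel TICs.
NULL

#' Fusion configuration
#'
#' @param fid_scale multiplicative factor applied to FID intensities
#'   before embedding. The default 1 performs no rescaling, preserving
#'   FID quantitation; display normalization is a rendering concern.
#' @param require_aligned enforce identical modulation grids.
#' @return a `fusion_config` list.
#' @export
fusion_config <- function(fid_scale = 1.0, require_aligned = TRUE) {
  stopifnot(fid_scale > 0)
  structure(list(fid_scale = fid_scale, require_aligned = isTRUE(require_aligned)),
            class = "fusion_config")
}

#' Convert a folded FID image to a pseudo-MS image
#'
#' Every non-empty pixel holds exactly one spectral pair: the virtual
#' fragment m/z 0 carrying the FID intensity. `tic()` of the result
#' equals the folded FID matrix exactly.
#'
#' @param fid_img single-channel FID [spectral_image()].
#' @return a [spectral_image()] whose only m/z channel is 0.
#' @export
fid_to_pseudo_ms <- function(fid_img) {
  if (nrow(fid_img$data) && any(fid_img$data$mz > 0))
    stop("fid_to_pseudo_ms: input already contains m/z > 0 channels")
  d <- fid_img$data
  d$mz <- rep(0, nrow(d))
  spectral_image(fid_img$grid, d, channel_id = "FID")
}

#' Fuse a pseudo-MS FID image with an MS image
#'
#' Per pixel, the fused spectrum is the union of the MS spectrum and
#' the FID virtual fragment `(0, fid_scale * fid_intensity)`; no MS
#' channel is modified. Both inputs must live on the identical
#' modulation grid, i.e. be aligned first.
#'
#' @param pseudo pseudo-MS FID image (m/z 0 only).
#' @param ms MS image (m/z >= 1 only).
#' @param cfg a [fusion_config()].
#' @return the fused [spectral_image()].
#' @export
fuse <- function(pseudo, ms, cfg = fusion_config()) {
  if (cfg$require_aligned && !grid_equal(pseudo$grid, ms$grid))
    stop("fuse: modulation grids differ; align and resample the channels first")
  if (nrow(pseudo$data) && any(pseudo$data$mz != 0))
    stop("fuse: pseudo-MS input must carry only the m/z 0 channel")
  if (nrow(ms$data) && any(ms$data$mz < 1))
    stop("fuse: MS input must carry only m/z >= 1 channels")
  p <- pseudo$data
  p$intensity <- p$intensity * cfg$fid_scale
  fused <- rbind(ms$data, p)
  spectral_image(ms$grid, fused, channel_id = "FUSED")
}

#' Extract the FID / MS partitions of a fused image
#'
#' `extract_fid` keeps only the m/z 0 channel (dividing by
#' `fid_scale`); `extract_ms` drops it. The two partitions cover every
#' stored intensity exactly once, so fusion followed by extraction is
#' the identity on both inputs (bit-exact at `fid_scale = 1`).
#'
#' @param fused fused [spectral_image()].
#' @param cfg the [fusion_config()] used during fusion.
#' @return a [spectral_image()].
#' @export
extract_fid <- function(fused, cfg = fusion_config()) {
  d <- fused$data[fused$data$mz == 0, , drop = FALSE]
  d$intensity <- d$intensity / cfg$fid_scale
  rownames(d) <- NULL
  spectral_image(fused$grid, d, channel_id = "FID")
}

#' @rdname extract_fid
#' @export
extract_ms <- function(fused, cfg = fusion_config()) {
  d <- fused$data[fused$data$mz != 0, , drop = FALSE]
  rownames(d) <- NULL
  spectral_image(fused$grid, d, channel_id = "MS")
}
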