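#' @title Domain types for twin-channel GCxGC data
#' @name core-model
#' @description
#' In-memory containers shared by every stage of the fusion workflow:
#' raw detector acquisitions ([detector_trace()]), the modulation grid
#' that maps raw time onto the 2D retention plane ([modulation_grid()]),
#' and folded 2D chromatograms whose pixels carry sparse spectra
#' ([spectral_image()]).
#'
#' Conventions used throughout the package:
#' * first-dimension retention `t1` in minutes, second-dimension
#'   retention `t2` in seconds;
#' * image coordinates are `(col, row)` with `col` the 0-based
#'   modulation index and `row` the 0-based intra-modulation sample;
#' * m/z 0 is a reserved channel carrying the FID intensity in fused
#'   data; real spectra must start at m/z >= 1.
NULL

MZ_FID <- 0L

#' Raw 1D detector acquisition
#'
#' A single unfolded acquisition from either detector. An FID trace
#' stores one intensity per sample; an MS trace stores one sparse
#' spectrum (two-column `mz`/`intensity` matrix) per scan.
#'
#' @param channel_id one of `"FID"`, `"MS"`, `"MS_12eV"`, `"MS_70eV"`.
#' @param rate_hz nominal sampling rate in Hz (> 0).
#' @param times numeric vector of scan times in seconds, strictly
#'   increasing.
#' @param intensity numeric vector of FID intensities (FID traces only).
#' @param scans list of two-column matrices `cbind(mz, intensity)`
#'   (MS traces only); within a scan `mz` must be strictly increasing
#'   with all intensities >= 0 and m/z >= 1.
#' @param t0_s acquisition start offset in seconds.
#' @return an object of class `detector_trace`.
#' @export
detector_trace <- function(channel_id, rate_hz, times,
                           intensity = NULL, scans = NULL, t0_s = times[1]) {
  channel_id <- match.arg(channel_id, c("FID", "MS", "MS_12eV", "MS_70eV"))
  stopifnot(is.numeric(rate_hz), length(rate_hz) == 1L, rate_hz > 0)
  times <- as.numeric(times)
  if (length(times) == 0L) stop("detector_trace: empty scan list")
  if (any(diff(times) <= 0)) stop("detector_trace: times must be strictly increasing")
  is_fid <- channel_id == "FID"
  if (is_fid) {
    if (is.null(intensity) || length(intensity) != length(times))
      stop("detector_trace: FID trace needs one intensity per time point")
    intensity <- as.numeric(intensity)
    scans <- NULL
  } else {
    if (is.null(scans) || length(scans) != length(times))
      stop("detector_trace: MS trace needs one spectrum per scan time")
    scans <- lapply(scans, function(s) {
      s <- matrix(as.numeric(s), ncol = 2L, dimnames = list(NULL, c("mz", "intensity")))
      if (nrow(s) > 0L) {
        if (any(diff(s[, 1L]) <= 0)) stop("detector_trace: mz must be strictly increasing within a scan")
        if (any(s[, 2L] < 0)) stop("detector_trace: negative spectral intensity")
        if (any(s[, 1L] < 1)) stop("detector_trace: real spectra must start at m/z >= 1")
      }
      s
    })
    intensity <- NULL
  }
  structure(list(channel_id = channel_id, rate_hz = rate_hz, t0_s = as.numeric(t0_s),
                 times = times, intensity = intensity, scans = scans),
            class = "detector_trace")
}

#' @export
print.detector_trace <- function(x, ...) {
  cat(sprintf("<detector_trace %s: %d scans @ %g Hz, t = [%.3f, %.3f] s>\n",
              x$channel_id, length(x$times), x$rate_hz,
              x$times[1], x$times[length(x$times)]))
  invisible(x)
}

is_fid_trace <- function(trace) trace$channel_id == "FID"

#' Modulation grid of a folded chromatogram
#'
#' Describes how a uniformly resampled 1D signal folds onto the 2D
#' retention plane: `pts_per_mod = round(period_s * rate_hz)` samples
#' per modulation, `n_mod` modulations in total.
#'
#' @param period_s modulation period P_M in seconds (> 0).
#' @param phase_s phase shift subtracted before folding, in
#'   `[0, period_s)` seconds.
#' @param n_mod number of modulations (image columns).
#' @param rate_hz common post-resampling rate in Hz.
#' @return an object of class `modulation_grid`.
#' @export
modulation_grid <- function(period_s, phase_s = 0, n_mod, rate_hz) {
  stopifnot(period_s > 0, rate_hz > 0, n_mod >= 1)
  if (phase_s < 0 || phase_s >= period_s)
    stop("modulation_grid: phase_s must lie in [0, period_s)")
  ppm <- round(period_s * rate_hz)
  if (abs(period_s * rate_hz - ppm) > 1e-6)
    stop("modulation_grid: period_s * rate_hz must be a whole number of samples")
  structure(list(period_s = period_s, phase_s = phase_s,
                 n_mod = as.integer(n_mod), pts_per_mod = as.integer(ppm),
                 rate_hz = rate_hz),
            class = "modulation_grid")
}

grid_equal <- function(a, b) {
  isTRUE(all.equal(a$period_s, b$period_s)) &&
    isTRUE(all.equal(a$phase_s, b$phase_s)) &&
    a$n_mod == b$n_mod && a$pts_per_mod == b$pts_per_mod &&
    isTRUE(all.equal(a$rate_hz, b$rate_hz))
}

#' Folded 2D chromatogram with per-pixel sparse spectra
#'
#' The central container of the workflow. Pixel data are held in long
#' form: one record per `(col, row, mz)` with a positive intensity.
#' A pure-FID image has exactly one m/z value (0) per non-empty pixel;
#' a fused image mixes the reserved m/z 0 channel with real fragments
#' at m/z >= 1.
#'
#' @param grid a [modulation_grid()].
#' @param data data.frame with integer columns `col`, `row` (0-based),
#'   numeric `mz` and `intensity`.
#' @param channel_id label of the originating channel.
#' @return an object of class `spectral_image`.
#' @export
spectral_image <- function(grid, data, channel_id = "MS") {
  stopifnot(inherits(grid, "modulation_grid"))
  data <- as.data.frame(data)
  need <- c("col", "row", "mz", "intensity")
  if (!all(need %in% names(data))) stop("spectral_image: data needs columns col,row,mz,intensity")
  data <- data[, need]
  if (nrow(data)) {
    if (any(data$col < 0L | data$col >= grid$n_mod)) stop("spectral_image: col out of range")
    if (any(data$row < 0L | data$row >= grid$pts_per_mod)) stop("spectral_image: row out of range")
    if (any(data$intensity < 0)) stop("spectral_image: negative intensity")
    if (any(data$mz < 0)) stop("spectral_image: negative mz")
    data <- data[order(data$col, data$row, data$mz), , drop = FALSE]
    key <- paste(data$col, data$row, data$mz)
    if (anyDuplicated(key)) stop("spectral_image: duplicate (col,row,mz) entries")
    rownames(data) <- NULL
  }
  structure(list(grid = grid, channel_id = channel_id, data = data),
            class = "spectral_image")
}

#' @export
print.spectral_image <- function(x, ...) {
  cat(sprintf("<spectral_image %s: %d x %d pixels, %d spectral entries, P_M = %g s>\n",
              x$channel_id, x$grid$n_mod, x$grid$pts_per_mod, nrow(x$data),
              x$grid$period_s))
  invisible(x)
}

#' Total ion current image
#'
#' Sums each pixel's spectral intensities into a dense
#' `n_mod x pts_per_mod` matrix (rows index modulations, columns index
#' intra-modulation samples). Empty pixels are 0. For a pure-FID image
#' this reproduces the folded FID matrix exactly.
#'
#' @param image a [spectral_image()].
#' @return numeric matrix of dimension `n_mod x pts_per_mod`.
#' @export
tic <- function(image) {
  stopifnot(inherits(image, "spectral_image"))
  g <- image$grid
  m <- matrix(0, nrow = g$n_mod, ncol = g$pts_per_mod)
  d <- image$data
  if (nrow(d)) {
    idx <- d$col + 1L + d$row * g$n_mod   # linear index into m
    acc <- rowsum(d$intensity, group = idx)
    m[as.integer(rownames(acc))] <- acc[, 1L]
  }
  m
}

#' Retention coordinates of image pixels
#'
#' Converts (possibly fractional) 0-based pixel coordinates to
#' retention times under the package convention `t1 = (phase + col *
#' period) / 60` minutes and `t2 = row / rate` seconds.
#'
#' @param grid a [modulation_grid()].
#' @param col,row numeric pixel coordinates (0-based, fractional allowed).
#' @return data.frame with columns `t1_min`, `t2_s`.
#' @export
pixel_to_retention <- function(grid, col, row) {
  data.frame(t1_min = (grid$phase_s + col * grid$period_s) / 60,
             t2_s = row / grid$rate_hz)
}

#' @rdname pixel_to_retention
#' @param t1_min,t2_s retention coordinates.
#' @return for `retention_to_pixel`, a data.frame with fractional
#'   `col`, `row`.
#' @export
retention_to_pixel <- function(grid, t1_min, t2_s) {
  data.frame(col = (t1_min * 60 - grid$phase_s) / grid$period_s,
             row = t2_s * grid$rate_hz)
}

#' Empty 2D peak table
#'
#' Detected peaks are plain data.frames with one row per peak and an
#' `apex_spectrum` list-column of two-column `mz`/`intensity` matrices
#' (`NULL` when unavailable). `wrap_count` counts full modulation
#' periods a wrapped-around peak spent beyond its nominal cycle; `k2`
#' is the second-dimension retention factor.
#'
#' @param n number of (empty) rows.
#' @return data.frame with the canonical peak-table columns.
#' @export
peak_table <- function(n = 0L) {
  data.frame(label = character(n),
             t1_min = numeric(n), t2_s = numeric(n),
             volume = numeric(n), snr = numeric(n),
             width_half_ms = rep(NA_real_, n), width_base_ms = rep(NA_real_, n),
             k2 = rep(NA_real_, n), wrap_count = rep(NA_integer_, n),
             apex_col = rep(NA_real_, n), apex_row = rep(NA_real_, n),
             apex_spectrum = I(vector("list", n)),
             stringsAsFactors = FALSE)
}

validate_peak_table <- function(peaks) {
  stopifnot(is.data.frame(peaks))
  if (nrow(peaks)) {
    stopifnot(all(peaks$volume >= 0, na.rm = TRUE), all(peaks$snr >= 0, na.rm = TRUE))
    ok <- is.na(peaks$width_half_ms) | is.na(peaks$width_base_ms) |
      (peaks$width_base_ms >= peaks$width_half_ms & peaks$width_half_ms > 0)
    if (!all(ok)) stop("peak table: width_base_ms must be >= width_half_ms > 0 when set")
  }
  invisible(peaks)
}

#' Serialize core objects to plain lists
#'
#' Lossless conversion of traces, grids and images to JSON-ready lists,
#' and back. Used by the JSON writers and by round-trip tests.
#'
#' @param x object to convert.
#' @return `as_plain_list`: a nested list of atomic vectors.
#' @export
as_plain_list <- function(x) {
  if (inherits(x, "modulation_grid")) {
    c(list(.type = "modulation_grid"), unclass(x))
  } else if (inherits(x, "detector_trace")) {
    out <- list(.type = "detector_trace", channel_id = x$channel_id,
                rate_hz = x$rate_hz, t0_s = x$t0_s, times = x$times)
    if (is_fid_trace(x)) out$intensity <- x$intensity
    else out$scans <- lapply(x$scans, function(s) list(mz = s[, 1L], intensity = s[, 2L]))
    out
  } else if (inherits(x, "spectral_image")) {
    list(.type = "spectral_image", grid = as_plain_list(x$grid),
         channel_id = x$channel_id, data = as.list(x$data))
  } else stop("as_plain_list: unsupported type")
}

#' @rdname as_plain_list
#' @param lst a list produced by `as_plain_list`.
#' @export
from_plain_list <- function(lst) {
  switch(lst$.type,
    modulation_grid = modulation_grid(lst$period_s, lst$phase_s, lst$n_mod, lst$rate_hz),
    detector_trace = if (lst$channel_id == "FID") {
      detector_trace("FID", lst$rate_hz, lst$times, intensity = lst$intensity, t0_s = lst$t0_s)
    } else {
      detector_trace(lst$channel_id, lst$rate_hz, lst$times, t0_s = lst$t0_s,
                     scans = lapply(lst$scans, function(s) cbind(mz = s$mz, intensity = s$intensity)))
    },
    spectral_image = spectral_image(from_plain_list(lst$grid),
                                    as.data.frame(lst$data), lst$channel_id),
    stop("from_plain_list: unknown type ", lst$.type))
}
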