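#' @title 2D peak detection and metrology
#' @name peakdetect
#' @description
#' Peak detection on (fused) 2D chromatograms proceeds as in
#' conventional GCxGC-MS processing: robust noise estimation on the
#' TIC, Gaussian pre-smoothing, local-maximum seeding with an S/N
#' threshold, blob growth by steepest-descent watershed, and apex /
#' volume / width metrology. The reserved m/z 0 channel participates in
#' the TIC like any other channel, so detection on fused images needs
#' no special casing.
NULL

#' Detection configuration
#'
#' @param snr_min minimum apex signal-to-noise ratio (default 100, the
#'   conventional reliable-peak threshold).
#' @param vnr_min minimum blob volume-to-noise ratio.
#' @param smooth_sigma_rows,smooth_sigma_cols Gaussian pre-smoothing
#'   widths in pixels along the intra-modulation (rows) and modulation
#'   (cols) axes.
#' @return a `detection_config` list.
#' @export
detection_config <- function(snr_min = 100, vnr_min = 10,
                             smooth_sigma_rows = 1.0, smooth_sigma_cols = 1.0) {
  stopifnot(snr_min > 0, vnr_min > 0, smooth_sigma_rows >= 0, smooth_sigma_cols >= 0)
  structure(list(snr_min = snr_min, vnr_min = vnr_min,
                 smooth_sigma_rows = smooth_sigma_rows,
                 smooth_sigma_cols = smooth_sigma_cols),
            class = "detection_config")
}

#' Robust noise estimate of a TIC matrix
#'
#' Quantile-based robust scale estimator using only the dim quarter of
#' the image: `(median - Q25) / 0.6745`, i.e. the spread of the
#' lowest-intensity quartile of pixels re-scaled to a Gaussian standard
#' deviation. Peaks only inflate the upper quantiles, so the estimate
#' is insensitive to them; on pure Gaussian noise it is unbiased. The
#' result is floored at machine epsilon times the maximum intensity so
#' it stays strictly positive even for constant images.
#'
#' @param mat numeric matrix (a TIC image).
#' @return noise standard deviation in intensity units.
#' @export
estimate_noise <- function(mat) {
  stopifnot(length(mat) > 0)
  v <- as.numeric(mat)
  q <- stats::quantile(v, c(0.25, 0.5), names = FALSE, type = 7)
  sd_hat <- (q[2] - q[1]) / stats::qnorm(0.75)
  floor_val <- .Machine$double.eps * max(abs(v), 1)
  max(sd_hat, floor_val)
}

# separable Gaussian blur with edge replication
gauss_smooth <- function(mat, sigma_rows, sigma_cols) {
  smooth1 <- function(m, sigma, along_rows) {
    if (sigma <= 0) return(m)
    r <- max(1L, ceiling(3 * sigma))
    k <- stats::dnorm(-r:r, sd = sigma)
    k <- k / sum(k)
    n <- if (along_rows) ncol(m) else nrow(m)
    idx <- outer(seq_len(n), -r:r, `+`)
    idx[idx < 1L] <- 1L; idx[idx > n] <- n
    if (along_rows) {
      out <- matrix(0, nrow(m), ncol(m))
      for (j in seq_len(2 * r + 1L)) out <- out + m[, idx[, j], drop = FALSE] * k[j]
      out
    } else {
      out <- matrix(0, nrow(m), ncol(m))
      for (j in seq_len(2 * r + 1L)) out <- out + m[idx[, j], , drop = FALSE] * k[j]
      out
    }
  }
  smooth1(smooth1(mat, sigma_cols, along_rows = FALSE), sigma_rows, along_rows = TRUE)
}

#' Detect 2D peaks in a spectral image
#'
#' The TIC is Gaussian-smoothed; local maxima above `snr_min * noise`
#' seed blobs that grow by steepest-descent watershed over all pixels
#' above `3 * noise` (each pixel drains to its strongest
#' already-claimed neighbour, so ridges separate adjacent peaks). The
#' apex is the intensity-weighted centroid of the blob pixels within
#' 10% of the blob maximum, giving sub-pixel apex coordinates; the
#' volume is the raw blob intensity sum; blobs failing the
#' volume-to-noise threshold are discarded. The apex spectrum is the
#' pixel spectrum at the (rounded) apex, with the reserved m/z 0
#' channel retained.
#'
#' @param image a [spectral_image()].
#' @param cfg a [detection_config()].
#' The image's baseline (median TIC level) is subtracted before
#' thresholding, so S/N and volumes are background-corrected.
#'
#' @return a [peak_table()] ordered by decreasing volume.
#' @export
detect_peaks <- function(image, cfg = detection_config()) {
  g <- image$grid
  raw0 <- tic(image)
  noise <- estimate_noise(raw0)
  bg <- stats::median(raw0)          # baseline level of the image
  raw <- raw0 - bg
  sm <- gauss_smooth(raw, cfg$smooth_sigma_rows, cfg$smooth_sigma_cols)
  nm <- nrow(sm); pp <- ncol(sm)
  above <- which(sm > 3 * noise)
  if (!length(above)) return(peak_table(0L))
  ord <- above[order(sm[above], decreasing = TRUE)]
  labels <- matrix(0L, nm, pp)
  n_lab <- 0L
  seed_val <- numeric(0)
  ci <- ((ord - 1L) %% nm) + 1L
  ri <- ((ord - 1L) %/% nm) + 1L
  for (k in seq_along(ord)) {
    cc <- ci[k]; rr <- ri[k]
    nc <- c(cc - 1L, cc, cc + 1L, cc - 1L, cc + 1L, cc - 1L, cc, cc + 1L)
    nr <- c(rr - 1L, rr - 1L, rr - 1L, rr, rr, rr + 1L, rr + 1L, rr + 1L)
    ok <- nc >= 1L & nc <= nm & nr >= 1L & nr <= pp
    nidx <- (nr[ok] - 1L) * nm + nc[ok]
    labs <- labels[nidx]
    claimed <- labs > 0L
    if (any(claimed)) {
      # drain to the strongest already-claimed neighbour
      best <- nidx[claimed][which.max(sm[nidx[claimed]])]
      labels[ord[k]] <- labels[best]
    } else {
      n_lab <- n_lab + 1L
      labels[ord[k]] <- n_lab
      seed_val <- c(seed_val, sm[ord[k]])
    }
  }
  keep_lab <- which(seed_val >= cfg$snr_min * noise)
  if (!length(keep_lab)) return(peak_table(0L))
  peaks <- peak_table(0L)
  spec_lookup <- NULL
  for (lab in keep_lab) {
    pix <- which(labels == lab)
    vol <- sum(raw[pix])
    if (vol / noise < cfg$vnr_min) next
    top <- pix[raw[pix] >= 0.90 * max(raw[pix])]   # apex neighbourhood
    w <- raw[top]
    col0 <- ((top - 1L) %% nm)        # 0-based modulation index
    row0 <- ((top - 1L) %/% nm)       # 0-based intra-modulation sample
    apex_col <- sum(w * col0) / sum(w)
    apex_row <- sum(w * row0) / sum(w)
    rt <- pixel_to_retention(g, apex_col, apex_row)
    ic <- as.integer(round(apex_col)); ir <- as.integer(round(apex_row))
    sp <- image$data[image$data$col == ic & image$data$row == ir, c("mz", "intensity")]
    apex_idx <- top[1L]
    row <- peak_table(1L)
    row$label <- ""
    row$t1_min <- rt$t1_min; row$t2_s <- rt$t2_s
    row$volume <- vol
    row$snr <- raw[apex_idx] / noise
    row$apex_col <- apex_col; row$apex_row <- apex_row
    row$apex_spectrum <- I(list(if (nrow(sp)) cbind(mz = sp$mz, intensity = sp$intensity) else NULL))
    peaks <- rbind(peaks, row)
  }
  if (nrow(peaks)) {
    peaks <- peaks[order(peaks$volume, decreasing = TRUE), , drop = FALSE]
    rownames(peaks) <- NULL
    wd <- peak_widths_all(raw, g, peaks)
    peaks$width_half_ms <- wd$width_half_ms
    peaks$width_base_ms <- wd$width_base_ms
  }
  validate_peak_table(peaks)
}

# Gaussian width fit on the 2D profile through one apex (single column)
fit_profile_widths <- function(profile, apex_row, rate_hz) {
  r <- seq_along(profile) - 1L
  a0 <- max(profile)
  if (a0 <= 0) return(c(NA_real_, NA_real_))
  half <- which(profile >= a0 / 2)
  sigma0 <- max(1, (max(half) - min(half)) / 2.3548)
  fit <- tryCatch(suppressWarnings(
    minpack.lm::nlsLM(y ~ A * exp(-(x - mu)^2 / (2 * s^2)),
                      data = data.frame(x = r, y = profile),
                      start = list(A = a0, mu = apex_row, s = sigma0),
                      control = minpack.lm::nls.lm.control(maxiter = 100))),
    error = function(e) NULL)
  if (is.null(fit)) return(c(NA_real_, NA_real_))
  s <- abs(stats::coef(fit)[["s"]])
  if (!is.finite(s) || s <= 0) return(c(NA_real_, NA_real_))
  ms_per_sample <- 1000 / rate_hz
  c(2.3548 * s * ms_per_sample, 4 * s * ms_per_sample)
}

peak_widths_all <- function(raw, grid, peaks) {
  wh <- numeric(nrow(peaks)); wb <- numeric(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    ic <- as.integer(round(peaks$apex_col[i])) + 1L
    prof <- pmax(raw[ic, ], 0)
    w <- fit_profile_widths(prof, peaks$apex_row[i], grid$rate_hz)
    wh[i] <- w[1]; wb[i] <- w[2]
  }
  list(width_half_ms = wh, width_base_ms = wb)
}

#' Second-dimension peak widths
#'
#' Least-squares Gaussian fit to the second-dimension profile through
#' the peak apex (within the apex's modulation column only). The width
#' at half height is `2.3548 * sigma` and the base (tangent) width
#' `4 * sigma`, both in milliseconds. A failed fit (flat profile)
#' leaves the widths unset with a message.
#'
#' @param image a [spectral_image()].
#' @param peak one-row peak table.
#' @return named numeric vector `c(width_half_ms, width_base_ms)`.
#' @export
peak_widths <- function(image, peak) {
  raw <- tic(image)
  raw <- pmax(raw - stats::median(raw), 0)
  ic <- as.integer(round(peak$apex_col[1])) + 1L
  if (is.na(ic) || ic < 1L || ic > nrow(raw)) stop("peak_widths: apex outside image")
  w <- fit_profile_widths(raw[ic, ], peak$apex_row[1], image$grid$rate_hz)
  if (anyNA(w)) message("peak_widths: Gaussian fit failed; widths unset")
  c(width_half_ms = w[1], width_base_ms = w[2])
}

#' Second-dimension retention factor
#'
#' `k2 = (t2 + wrap_count * period_s - t2_void) / t2_void`. For a peak
#' whose wrap-around count is unknown and whose apparent `t2` is close
#' to zero, the estimate is flagged uncertain: the number of modulation
#' cycles the compound spent in the second dimension cannot be reliably
#' determined.
#'
#' @param peak one-row peak table (uses `t2_s` and, when present,
#'   `wrap_count`).
#' @param t2_void_s second-dimension void time in seconds. The void
#'   time is rarely reported for a given set-up; it defaults to
#'   `0.1 * period_s` downstream but should be set from the column
#'   geometry when known.
#' @param period_s modulation period in seconds.
#' @param wrap_count known number of wrap-around cycles (overrides the
#'   peak table column).
#' @return list with `k2`, `wrap_count`, `uncertain`.
#' @export
retention_factor <- function(peak, t2_void_s, period_s, wrap_count = NULL) {
  stopifnot(t2_void_s > 0)
  t2 <- peak$t2_s[1]
  wc <- wrap_count %||% peak$wrap_count[1]
  uncertain <- FALSE
  if (is.null(wc) || is.na(wc)) {
    uncertain <- t2 < 0.25 * period_s   # apparent early elution: may be wrapped
    wc <- 0L
  }
  k2 <- (t2 + wc * period_s - t2_void_s) / t2_void_s
  list(k2 = k2, wrap_count = as.integer(wc), uncertain = uncertain)
}
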