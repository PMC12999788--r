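#' @title Channel alignment and retention registration
#' @name fold-align
#' @description
#' Prepares the two detector channels for fusion: common resampling,
#' folding onto the modulation grid, inter-channel phase estimation,
#' relative-misalignment metrology, and global / zonal polynomial
#' retention transforms that register one channel onto the other.
NULL

#' Resample two traces onto a common clock
#'
#' Both outputs are sampled on an identical uniform clock at
#' `target_hz` over the temporal overlap window. FID intensity is
#' linearly interpolated; MS spectra are assigned by nearest scan (no
#' spectral interpolation, so no scan is ever fabricated).
#'
#' @param fid FID [detector_trace()].
#' @param ms MS [detector_trace()].
#' @param target_hz common output rate; defaults to the lower of the
#'   two native rates.
#' @return list with elements `fid` and `ms`.
#' @export
resample_common <- function(fid, ms, target_hz = min(fid$rate_hz, ms$rate_hz)) {
  stopifnot(is_fid_trace(fid), !is_fid_trace(ms), target_hz > 0)
  t_start <- max(fid$times[1], ms$times[1])
  t_end <- min(fid$times[length(fid$times)], ms$times[length(ms$times)])
  if (t_end <= t_start) stop("resample_common: traces do not overlap in time")
  n <- floor((t_end - t_start) * target_hz) + 1L
  tt <- t_start + (seq_len(n) - 1L) / target_hz
  fid_y <- stats::approx(fid$times, fid$intensity, xout = tt, rule = 2)$y
  nearest <- findInterval(tt, ms$times, all.inside = TRUE)
  up <- pmin(nearest + 1L, length(ms$times))
  pick <- ifelse(tt - ms$times[nearest] <= ms$times[up] - tt, nearest, up)
  list(fid = detector_trace("FID", target_hz, tt, intensity = fid_y),
       ms = detector_trace(ms$channel_id, target_hz, tt, scans = ms$scans[pick]))
}

#' Fold a uniformly sampled trace onto the 2D retention plane
#'
#' Sample `i` at time `t_i` lands in modulation column
#' `floor((t_i - phase_s) / period_s)` at the intra-modulation row
#' given by the remainder. Samples before `phase_s` and any trailing
#' partial modulation are dropped; total placed intensity equals the
#' total input intensity of the retained samples.
#'
#' @param trace uniformly sampled [detector_trace()].
#' @param period_s modulation period in seconds.
#' @param phase_s phase shift in `[0, period_s)`.
#' @return a [spectral_image()] (FID traces yield a pure m/z-0 image).
#' @export
fold <- function(trace, period_s, phase_s = 0) {
  rate <- trace$rate_hz
  g0 <- modulation_grid(period_s, phase_s, n_mod = 1L, rate_hz = rate)
  ppm <- g0$pts_per_mod
  dt <- diff(trace$times)
  if (length(dt) && (max(dt) - min(dt)) > 0.25 / rate)
    stop("fold: trace is not uniformly sampled")
  gidx <- round((trace$times - phase_s) * rate)   # global sample index from phase origin
  keep <- gidx >= 0
  n_mod <- (sum(keep) %/% ppm)
  if (n_mod < 1L) stop("fold: fewer than one full modulation of data")
  keep <- keep & gidx < n_mod * ppm
  gk <- gidx[keep]
  grid <- modulation_grid(period_s, phase_s, n_mod = n_mod, rate_hz = rate)
  col <- gk %/% ppm
  row <- gk %% ppm
  if (is_fid_trace(trace)) {
    y <- trace$intensity[keep]
    nz <- y != 0
    data <- data.frame(col = col[nz], row = row[nz], mz = 0, intensity = y[nz])
  } else {
    scans <- trace$scans[keep]
    counts <- vapply(scans, nrow, 0L)
    data <- data.frame(col = rep(col, counts), row = rep(row, counts),
                       mz = unlist(lapply(scans, function(s) s[, 1L]), use.names = FALSE),
                       intensity = unlist(lapply(scans, function(s) s[, 2L]), use.names = FALSE))
    data <- data[data$intensity != 0, , drop = FALSE]
  }
  spectral_image(grid, data, channel_id = trace$channel_id)
}

#' Estimate the phase shift between two folded channels
#'
#' Returns the circular row shift (in seconds) that maximizes the
#' cross-correlation between the two images' row-marginal TIC profiles.
#' A positive value means `imgB` elutes later within the modulation
#' than `imgA` by that amount.
#'
#' @param imgA,imgB [spectral_image()]s on grids with equal
#'   `pts_per_mod` and `rate_hz`.
#' @return shift in seconds, with `|shift| < period_s`.
#' @export
estimate_phase_shift <- function(imgA, imgB) {
  ga <- imgA$grid; gb <- imgB$grid
  if (ga$pts_per_mod != gb$pts_per_mod || !isTRUE(all.equal(ga$rate_hz, gb$rate_hz)))
    stop("estimate_phase_shift: images must share pts_per_mod and rate")
  pa <- colSums(tic(imgA))
  pb <- colSums(tic(imgB))
  if (all(pa == 0) || all(pb == 0)) stop("estimate_phase_shift: all-zero image")
  ppm <- ga$pts_per_mod
  cc <- vapply(seq_len(ppm) - 1L, function(s)
    sum(pa * pb[((seq_len(ppm) - 1L + s) %% ppm) + 1L]), 0)
  best <- which.max(cc) - 1L
  if (best > ppm / 2) best <- best - ppm   # minimal signed representative
  best / ga$rate_hz
}

#' Relative misalignment between matched peak pairs
#'
#' For each same-compound pair of peaks detected in the FID and MS
#' channels, computes the relative misalignment RM as the absolute
#' second-dimension apex difference in milliseconds (FID as reference),
#' together with peak widths averaged between the two channels.
#'
#' @param fid_peaks,ms_peaks peak tables matched row-by-row (same
#'   compound on the same row).
#' @return data.frame with columns `name`, `rm_ms`, `width_half_ms`,
#'   `width_base_ms` (and `wrapped` when either input carries a
#'   `wrapped` column).
#' @export
relative_misalignment <- function(fid_peaks, ms_peaks) {
  stopifnot(nrow(fid_peaks) == nrow(ms_peaks))
  out <- data.frame(
    name = if (!is.null(fid_peaks$label)) as.character(fid_peaks$label)
           else sprintf("peak_%d", seq_len(nrow(fid_peaks))),
    rm_ms = abs(ms_peaks$t2_s - fid_peaks$t2_s) * 1000,
    width_half_ms = (fid_peaks$width_half_ms + ms_peaks$width_half_ms) / 2,
    width_base_ms = (fid_peaks$width_base_ms + ms_peaks$width_base_ms) / 2,
    stringsAsFactors = FALSE)
  w <- fid_peaks$wrapped %||% ms_peaks$wrapped
  if (!is.null(w)) out$wrapped <- w
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Summarize misalignment records
#'
#' Arithmetic means of the relative misalignment and of the two peak
#' widths, rounded to the nearest millisecond for reporting.
#'
#' @param records data.frame from [relative_misalignment()] (or any
#'   data.frame with `rm_ms`, `width_half_ms`, `width_base_ms`).
#' @return list with integer `rm_ms`, `width_half_ms`, `width_base_ms`.
#' @export
summarize_misalignment <- function(records) {
  if (is.null(records) || nrow(records) == 0L)
    stop("summarize_misalignment: no records")
  list(rm_ms = as.integer(round(mean(records$rm_ms))),
       width_half_ms = as.integer(round(mean(records$width_half_ms))),
       width_base_ms = as.integer(round(mean(records$width_base_ms))))
}

## ---- polynomial retention transforms --------------------------------------

poly_basis <- function(t1, t2, degree) {
  if (degree == 1L) cbind(1, t1, t2)
  else cbind(1, t1, t2, t1^2, t1 * t2, t2^2)
}

#' Degree-1/2 bivariate retention transform
#'
#' Maps `(t1, t2)` to `(t1', t2')` through a bivariate polynomial with
#' coefficient order `(1, t1, t2)` for degree 1 and
#' `(1, t1, t2, t1^2, t1*t2, t2^2)` for degree 2.
#'
#' @param coeff_t1,coeff_t2 coefficient vectors (length 3 or 6).
#' @param degree 1 or 2.
#' @return a `poly_transform` object.
#' @export
poly_transform <- function(coeff_t1, coeff_t2, degree = if (length(coeff_t1) == 3L) 1L else 2L) {
  stopifnot(degree %in% c(1L, 2L))
  nc <- if (degree == 1L) 3L else 6L
  stopifnot(length(coeff_t1) == nc, length(coeff_t2) == nc)
  structure(list(degree = as.integer(degree),
                 coeff_t1 = as.numeric(coeff_t1), coeff_t2 = as.numeric(coeff_t2)),
            class = "poly_transform")
}

#' @rdname poly_transform
#' @export
identity_transform <- function(degree = 2L) {
  nc <- if (degree == 1L) 3L else 6L
  c1 <- numeric(nc); c1[2] <- 1
  c2 <- numeric(nc); c2[3] <- 1
  poly_transform(c1, c2, degree)
}

#' @export
print.poly_transform <- function(x, ...) {
  cat(sprintf("<poly_transform degree %d>\n", x$degree))
  invisible(x)
}

#' Zonal (piecewise) retention transform
#'
#' An ordered list of non-overlapping first-dimension zones, each with
#' its own [poly_transform()], plus a fallback applied outside all
#' zones.
#'
#' @param zones list of `list(t1_range = c(lo, hi), transform = ...)`.
#' @param fallback [poly_transform()] used outside all zones.
#' @return a `zonal_transform` object.
#' @export
zonal_transform <- function(zones, fallback) {
  stopifnot(inherits(fallback, "poly_transform"))
  rng <- t(vapply(zones, function(z) sort(z$t1_range), numeric(2)))
  if (nrow(rng) > 1L) {
    o <- order(rng[, 1L])
    if (any(rng[o, 1L][-1] < rng[o, 2L][-nrow(rng)]))
      stop("zonal_transform: zones overlap")
  }
  structure(list(zones = zones, fallback = fallback), class = "zonal_transform")
}

#' Apply a retention transform to points
#'
#' @param tf a `poly_transform` or `zonal_transform`.
#' @param t1_min,t2_s input retention coordinates.
#' @return data.frame with transformed `t1_min`, `t2_s`.
#' @export
transform_points <- function(tf, t1_min, t2_s) {
  if (inherits(tf, "poly_transform")) {
    X <- poly_basis(t1_min, t2_s, tf$degree)
    data.frame(t1_min = drop(X %*% tf$coeff_t1), t2_s = drop(X %*% tf$coeff_t2))
  } else if (inherits(tf, "zonal_transform")) {
    out <- transform_points(tf$fallback, t1_min, t2_s)
    for (z in tf$zones) {
      in_zone <- t1_min >= z$t1_range[1] & t1_min <= z$t1_range[2]
      if (any(in_zone)) {
        tz <- transform_points(z$transform, t1_min[in_zone], t2_s[in_zone])
        out[in_zone, ] <- tz
      }
    }
    out
  } else stop("transform_points: unsupported transform")
}

#' Fit a global polynomial retention transform
#'
#' Least-squares fit of the bivariate polynomial mapping source
#' retention points onto target points, minimizing the summed squared
#' retention residuals in both dimensions.
#'
#' @param pairs data.frame with columns `t1_from`, `t2_from`, `t1_to`,
#'   `t2_to` (see [retention_pairs()]).
#' @param degree polynomial degree, 1 or 2.
#' @return a `poly_transform` with attribute `residuals`: per-pair
#'   data.frame of `t1` and `t2` residuals (target minus fitted).
#' @export
fit_global_transform <- function(pairs, degree = 2L) {
  nc <- if (degree == 1L) 3L else 6L
  if (nrow(pairs) < nc)
    stop(sprintf("fit_global_transform: need at least %d pairs for degree %d", nc, degree))
  X <- poly_basis(pairs$t1_from, pairs$t2_from, degree)
  qx <- qr(X)
  if (qx$rank < nc)
    stop("fit_global_transform: rank-deficient design (collinear points); try degree 1")
  c1 <- qr.coef(qx, pairs$t1_to)
  c2 <- qr.coef(qx, pairs$t2_to)
  tf <- poly_transform(c1, c2, degree)
  fit <- transform_points(tf, pairs$t1_from, pairs$t2_from)
  attr(tf, "residuals") <- data.frame(t1 = pairs$t1_to - fit$t1_min,
                                      t2 = pairs$t2_to - fit$t2_s)
  tf
}

#' Build a retention-pair table
#'
#' @param from,to data.frames with columns `t1_min`, `t2_s`; row i of
#'   `from` corresponds to row i of `to`.
#' @return data.frame with columns `t1_from`, `t2_from`, `t1_to`, `t2_to`.
#' @export
retention_pairs <- function(from, to) {
  stopifnot(nrow(from) == nrow(to))
  data.frame(t1_from = from$t1_min, t2_from = from$t2_s,
             t1_to = to$t1_min, t2_to = to$t2_s)
}

#' Fit a zonal retention transform
#'
#' Fits an independent polynomial per first-dimension zone using the
#' pairs whose source `t1` lies in the zone; the fallback is the global
#' fit on all pairs. A zone with too few pairs for the requested degree
#' falls back to degree 1, and below 3 pairs to the global fit (with a
#' message).
#'
#' @param pairs as in [fit_global_transform()].
#' @param zones list of `c(lo, hi)` first-dimension intervals (minutes).
#' @param degree per-zone polynomial degree.
#' @return a `zonal_transform`.
#' @export
fit_zonal <- function(pairs, zones, degree = 2L) {
  fallback <- fit_global_transform(pairs, degree = degree)
  fitted_zones <- list()
  for (z in zones) {
    z <- sort(as.numeric(z))
    sel <- pairs$t1_from >= z[1] & pairs$t1_from <= z[2]
    nz <- sum(sel)
    if (nz < 3L) {
      message(sprintf("fit_zonal: zone [%g, %g] has %d pair(s); using global fit", z[1], z[2], nz))
      tf <- fallback
    } else {
      deg <- if (nz >= (if (degree == 1L) 3L else 6L)) degree else 1L
      tf <- tryCatch(fit_global_transform(pairs[sel, , drop = FALSE], degree = deg),
                     error = function(e) fallback)
    }
    fitted_zones[[length(fitted_zones) + 1L]] <- list(t1_range = z, transform = tf)
  }
  zonal_transform(fitted_zones, fallback)
}

#' Warp a spectral image through a retention transform
#'
#' Each spectral entry is moved to its transformed retention
#' coordinates and its intensity distributed over the four neighbouring
#' pixels by bilinear splatting, per m/z channel. Entries mapping
#' outside the grid are dropped; retained intensity is conserved
#' exactly, so smooth images conserve total intensity to well within
#' 1%.
#'
#' @param image a [spectral_image()].
#' @param tf a `poly_transform` or `zonal_transform`.
#' @return the warped [spectral_image()] on the same grid.
#' @export
apply_transform <- function(image, tf) {
  d <- image$data
  g <- image$grid
  if (!nrow(d)) return(image)
  rt <- pixel_to_retention(g, d$col, d$row)
  new <- transform_points(tf, rt$t1_min, rt$t2_s)
  px <- retention_to_pixel(g, new$t1_min, new$t2_s)
  c0 <- floor(px$col); r0 <- floor(px$row)
  fc <- px$col - c0; fr <- px$row - r0
  # 4-way bilinear splat
  cols <- c(c0, c0 + 1, c0, c0 + 1)
  rows <- c(r0, r0, r0 + 1, r0 + 1)
  wts <- c((1 - fc) * (1 - fr), fc * (1 - fr), (1 - fc) * fr, fc * fr)
  mzs <- rep(d$mz, 4L)
  vals <- rep(d$intensity, 4L) * wts
  keep <- cols >= 0 & cols < g$n_mod & rows >= 0 & rows < g$pts_per_mod & vals > 0
  out <- data.frame(col = cols[keep], row = rows[keep], mz = mzs[keep],
                    intensity = vals[keep])
  if (nrow(out)) {
    key <- paste(out$col, out$row, out$mz)
    acc <- rowsum(out$intensity, group = key)
    parts <- do.call(rbind, strsplit(rownames(acc), " ", fixed = TRUE))
    out <- data.frame(col = as.integer(parts[, 1L]), row = as.integer(parts[, 2L]),
                      mz = as.numeric(parts[, 3L]), intensity = acc[, 1L])
  }
  spectral_image(g, out, channel_id = image$channel_id)
}

transform_to_list <- function(tf) {
  if (inherits(tf, "poly_transform")) {
    list(.type = "poly_transform", degree = tf$degree,
         coeff_t1 = tf$coeff_t1, coeff_t2 = tf$coeff_t2)
  } else if (inherits(tf, "zonal_transform")) {
    list(.type = "zonal_transform",
         zones = lapply(tf$zones, function(z)
           list(t1_range = z$t1_range, transform = transform_to_list(z$transform))),
         fallback = transform_to_list(tf$fallback))
  } else stop("transform_to_list: unsupported transform")
}

transform_from_list <- function(lst) {
  if (lst$.type == "poly_transform") {
    poly_transform(unlist(lst$coeff_t1), unlist(lst$coeff_t2), as.integer(lst$degree))
  } else {
    zones <- lapply(lst$zones, function(z)
      list(t1_range = unlist(z$t1_range), transform = transform_from_list(z$transform)))
    zonal_transform(zones, transform_from_list(lst$fallback))
  }
}
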