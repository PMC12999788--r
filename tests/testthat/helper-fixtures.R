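# shared fixture builders: everything is generated in code at test time

# sparse random spectral image on a small grid
random_image <- function(seed, n_mod = 20L, ppm = 30L, n_entries = 150L,
                         mz_pool = c(0, 35:120), channel = "FUSED") {
  set.seed(seed)
  grid <- modulation_grid(period_s = ppm / 100, phase_s = 0,
                          n_mod = n_mod, rate_hz = 100)
  d <- data.frame(col = sample(0:(n_mod - 1L), n_entries, replace = TRUE),
                  row = sample(0:(ppm - 1L), n_entries, replace = TRUE),
                  mz = sample(mz_pool, n_entries, replace = TRUE),
                  intensity = stats::runif(n_entries, 0.1, 100))
  d <- d[!duplicated(d[c("col", "row", "mz")]), ]
  spectral_image(grid, d, channel_id = channel)
}

# random centroided spectrum with a 999 base peak
random_spectrum <- function(seed, n = 12L, mz_range = c(35, 250)) {
  set.seed(seed)
  mz <- sort(sample(seq(mz_range[1], mz_range[2]), n))
  ints <- stats::rexp(n)
  cbind(mz = mz, intensity = ints / max(ints) * 999)
}

# dense FID image holding planted 2D Gaussians on a baseline
# (detectors ride on an offset, so additive noise never clips at zero)
gaussian_image <- function(n_mod, ppm, peaks, noise_sd = 0, seed = 1L,
                           rate_hz = 100, baseline = 10 * noise_sd) {
  set.seed(seed)
  m <- matrix(baseline, n_mod, ppm)
  cols <- matrix(rep(0:(n_mod - 1L), ppm), n_mod, ppm)
  rows <- matrix(rep(0:(ppm - 1L), each = n_mod), n_mod, ppm)
  for (p in peaks)
    m <- m + p$amp * exp(-((cols - p$col)^2) / (2 * p$sc^2) -
                           ((rows - p$row)^2) / (2 * p$sr^2))
  if (noise_sd > 0) m <- m + stats::rnorm(length(m), 0, noise_sd)
  grid <- modulation_grid(ppm / rate_hz, 0, n_mod, rate_hz)
  idx <- which(m != 0, arr.ind = TRUE)
  spectral_image(grid, data.frame(col = idx[, 1L] - 1L, row = idx[, 2L] - 1L,
                                  mz = 0, intensity = pmax(m[idx], 0)),
                 channel_id = "FID")
}

# configuration of the registration validation study: a within-period
# panel on a dual-secondary-column style set-up with compound-dependent
# second-dimension misalignment decaying with retention factor k
registration_config <- function(seed, noiseless = TRUE) {
  sim_config(period_s = 4, fid_rate_hz = 100, ms_rate_hz = 28,
             split_fid_ms = c(0.5, 0.5),
             noise_sd = if (noiseless) c(fid = 0, ms = 0) else c(fid = 2, ms = 4),
             misalign = c(a_ms = 400, b = 1, wrap_extra_ms = 800),
             t2_void_s = 0.6, seed = seed)
}

registration_library <- function(seed, n = 12L) {
  make_library(n, seed = seed, t1_range = c(3, 27), t2_range = c(1.0, 2.6))
}

# pair detected peaks with the planted truth by nearest retention point
pair_with_truth <- function(peaks, t1, t2) {
  vapply(seq_along(t1), function(i)
    which.min(abs(peaks$t1_min - t1[i]) + abs(peaks$t2_s - t2[i])), 0L)
}

# count false assignments of a reliable-set result against simulator truth
count_false_assignments <- function(rs, chroms, reference = 1L) {
  ref_truth <- chroms[[reference]]$truth
  total <- 0L
  for (r in seq_along(chroms)) {
    asg <- rs$matches[[r]]$assignments
    if (!nrow(asg)) next
    ft <- ref_truth[asg$template]           # untargeted features only
    ft[is.na(ft)] <- "targeted"
    pt <- chroms[[r]]$truth[asg$peak]
    total <- total + sum(ft == "decoy" | pt != ft)
  }
  total
}
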