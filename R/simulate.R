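#' @title Synthetic twin-channel GCxGC generator
#' @name simulate
#' @description
#' Deterministic simulator of paired FID/MS acquisitions of the same
#' separation: separable Gaussian 2D peaks sampled at each detector's
#' native rate, a detector split ratio scaling the two channels'
#' intensities, compound-dependent second-dimension misalignment of the
#' MS channel (large at low retention factor k, shrinking with k, and
#' re-growing under wrap-around), additive Gaussian noise, and slow
#' per-run batch drift with feature dropout. Every run comes with a
#' ground-truth table used to validate detection, metrology and
#' registration. All randomness flows through R's Mersenne-Twister
#' generator seeded from the configuration, so identical seeds give
#' identical data on every platform.
NULL

#' Simulator configuration
#'
#' Defaults emulate a flow-modulated GCxGC run with parallel
#' quadrupole-MS/FID detection: 2.5 s modulation period, 200 Hz FID and
#' 28 Hz MS full scans, and a 70:30 FID/MS detector split.
#'
#' @param period_s modulation period in seconds.
#' @param fid_rate_hz,ms_rate_hz native sampling rates.
#' @param split_fid_ms fractions of the effluent routed to FID and MS;
#'   must sum to 1.
#' @param noise_sd named vector `c(fid = ..., ms = ...)` of additive
#'   noise standard deviations in intensity units.
#' @param misalign second-dimension misalignment model of the MS
#'   channel, `c(a_ms, b, wrap_extra_ms)`:
#'   `delta_t2(k) = a_ms * exp(-b * k)` milliseconds, plus
#'   `wrap_extra_ms` for wrap-around peaks. The default is no
#'   misalignment, the post-column-split situation where the offsets
#'   are negligible against peak widths.
#' @param t2_void_s second-dimension void time used for retention
#'   factors; defaults to one tenth of the period.
#' @param drift per-run retention drift standard deviations,
#'   `c(t1_min, t2_s)`.
#' @param amp_scale intensity of a unit amount at unit response factor
#'   before the detector split.
#' @param fid_baseline standing FID baseline offset in intensity units
#'   (the flame's background current), so additive noise never clips
#'   at zero.
#' @param seed integer seed driving all randomness.
#' @return a `sim_config` list.
#' @export
sim_config <- function(period_s = 2.5, fid_rate_hz = 200, ms_rate_hz = 28,
                       split_fid_ms = c(0.7, 0.3),
                       noise_sd = c(fid = 2, ms = 4),
                       misalign = c(a_ms = 0, b = 1, wrap_extra_ms = 0),
                       t2_void_s = 0.1 * period_s,
                       drift = c(t1_min = 0.1, t2_s = 0.02),
                       amp_scale = 1000, fid_baseline = 20, seed = 1L) {
  stopifnot(period_s > 0, fid_rate_hz > 0, ms_rate_hz > 0,
            length(split_fid_ms) == 2L, all(split_fid_ms > 0),
            abs(sum(split_fid_ms) - 1) < 1e-9, t2_void_s > 0)
  structure(list(period_s = period_s, fid_rate_hz = fid_rate_hz,
                 ms_rate_hz = ms_rate_hz, split_fid_ms = split_fid_ms,
                 noise_sd = c(fid = unname(noise_sd[1]), ms = unname(noise_sd[2])),
                 misalign = c(a_ms = unname(misalign[1]), b = unname(misalign[2]),
                              wrap_extra_ms = unname(misalign[3])),
                 t2_void_s = t2_void_s,
                 drift = c(t1_min = unname(drift[1]), t2_s = unname(drift[2])),
                 amp_scale = amp_scale, fid_baseline = fid_baseline,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Reproducible compound library
#'
#' Generates `n` compounds spread over the retention plane with
#' elution-correlated second-dimension retention (volatile,
#' early-eluting species sit at low t2, as under temperature
#' programming), log-spread amounts, and distinct random reference
#' spectra of 8-25 fragments with the base peak normalized to 999.
#' Libraries are fully determined by `(n, seed)`.
#'
#' @param n number of compounds.
#' @param seed RNG seed.
#' @param t1_range first-dimension retention span, minutes.
#' @param t2_range second-dimension retention span, seconds; the
#'   default emulates a panel spread across the usable 2D plane.
#' @param t2_jitter standard deviation of the deviation from the
#'   elution trend, seconds.
#' @param amount_range range of the log-uniform amount distribution.
#' @param sigma1_s,sigma2_ms peak-width ranges sampled uniformly
#'   (first dimension in seconds, second in milliseconds).
#' @param mz_range m/z range of the random spectra.
#' @return data.frame of class `sim_library` with one row per compound
#'   and a `spectrum` list-column.
#' @export
make_library <- function(n, seed = 1L, t1_range = c(3, 27),
                         t2_range = c(0.3, 4.5),
                         t2_jitter = 0.07 * diff(t2_range),
                         amount_range = c(0.1, 3),
                         sigma1_s = c(2.5, 5), sigma2_ms = c(90, 150),
                         mz_range = c(35, 250)) {
  stopifnot(n >= 1)
  withr_seed(seed, {
    t1 <- sort(seq(t1_range[1], t1_range[2], length.out = n) +
                 stats::rnorm(n, 0, 0.02 * diff(t1_range)))
    frac <- if (n > 1) (t1 - min(t1)) / (max(t1) - min(t1)) else 0.5
    t2 <- t2_range[1] + diff(t2_range) * frac + stats::rnorm(n, 0, t2_jitter)
    t2 <- pmin(pmax(t2, t2_range[1]), t2_range[2])
    amount <- exp(stats::runif(n, log(amount_range[1]), log(amount_range[2])))
    lib <- data.frame(
      name = sprintf("cmp%03d", seq_len(n)),
      t1_min = t1, t2_s = t2,
      sigma1_s = stats::runif(n, sigma1_s[1], sigma1_s[2]),
      sigma2_ms = stats::runif(n, sigma2_ms[1], sigma2_ms[2]),
      amount = amount,
      rf = stats::runif(n, 0.8, 1.2),
      stringsAsFactors = FALSE)
    lib$spectrum <- lapply(seq_len(n), function(i) {
      nf <- sample(8:25, 1L)
      mz <- sort(sample(seq(mz_range[1], mz_range[2]), nf))
      ints <- stats::rexp(nf)^1.5
      ints <- ints / max(ints) * 999
      cbind(mz = mz, intensity = ints)
    })
    class(lib) <- c("sim_library", "data.frame")
    lib
  })
}

# run code under a temporary RNG state
withr_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

# misalignment of the MS channel for one compound, in seconds
ms_shift_s <- function(cfg, k2, wrapped) {
  (cfg$misalign[["a_ms"]] * exp(-cfg$misalign[["b"]] * pmax(k2, 0)) +
     cfg$misalign[["wrap_extra_ms"]] * as.numeric(wrapped)) / 1000
}

# ground-truth table for one run
truth_table <- function(lib, cfg) {
  k2 <- (lib$t2_s - cfg$t2_void_s) / cfg$t2_void_s
  wrapped <- lib$t2_s > cfg$period_s
  shift <- ms_shift_s(cfg, k2, wrapped)
  amp_fid <- lib$amount * lib$rf * cfg$split_fid_ms[1] * cfg$amp_scale
  amp_ms <- lib$amount * lib$rf * cfg$split_fid_ms[2] * cfg$amp_scale
  data.frame(name = lib$name, t1_min = lib$t1_min,
             t2_s = lib$t2_s, t2_ms_s = lib$t2_s + shift,
             delta_t2_ms = shift * 1000, k2 = k2, wrapped = wrapped,
             sigma1_s = lib$sigma1_s, sigma2_ms = lib$sigma2_ms,
             amount = lib$amount,
             amp_fid = amp_fid, amp_ms = amp_ms,
             vol_fid = lib$amount * lib$rf * cfg$split_fid_ms[1],
             vol_ms = lib$amount * lib$rf * cfg$split_fid_ms[2],
             snr_fid = amp_fid / cfg$noise_sd[["fid"]],
             snr_ms = amp_ms / cfg$noise_sd[["ms"]],
             stringsAsFactors = FALSE)
}

# modulated 2D Gaussian envelope evaluated at raw acquisition times
envelope_at <- function(times, period_s, t1_min, t2_s, sigma1_s, sigma2_s) {
  cols <- floor(times / period_s)
  t2l <- times - cols * period_s
  out <- numeric(length(times))
  for (m in 0:2) {   # allow wrap-around into later cycles
    g1 <- exp(-(((cols - m) * period_s) - t1_min * 60)^2 / (2 * sigma1_s^2))
    g2 <- exp(-((t2l + m * period_s) - t2_s)^2 / (2 * sigma2_s^2))
    out <- out + g1 * g2
  }
  out
}

#' Simulate one paired FID/MS acquisition
#'
#' Samples the separation on both detectors' native clocks. The FID
#' intensity is the sum of the compounds' modulated Gaussian envelopes
#' scaled by `amount * rf * split_fid`; MS scans carry each compound's
#' reference spectrum scaled by `amount * rf * split_ms` times the envelope,
#' with the second-dimension retention shifted by the compound's
#' misalignment `delta_t2(k)`. Gaussian noise is added per FID sample
#' and per MS fragment.
#'
#' @param lib a [make_library()] table (possibly modified per run).
#' @param cfg a [sim_config()].
#' @param run_end_s run length; defaults to covering the last compound
#'   plus a margin.
#' @return list with `fid` and `ms` [detector_trace()]s and `truth`,
#'   the planted ground-truth table (retentions, widths, shifts,
#'   retention factors, wrap flags, amplitudes and analytic S/N).
#' @export
simulate_pair <- function(lib, cfg = sim_config(), run_end_s = NULL) {
  truth <- truth_table(lib, cfg)
  if (is.null(run_end_s))
    run_end_s <- ceiling((max(lib$t1_min) * 60 + 4 * max(lib$sigma1_s) +
                            cfg$period_s * 2) / cfg$period_s) * cfg$period_s
  if (any(lib$t1_min * 60 > run_end_s))
    stop("simulate_pair: compound elutes outside the run window")
  withr_seed(cfg$seed, {
    # FID channel
    nf <- floor(run_end_s * cfg$fid_rate_hz)
    t_fid <- (seq_len(nf) - 1L) / cfg$fid_rate_hz
    y <- rep(cfg$fid_baseline, nf)
    for (i in seq_len(nrow(lib))) {
      y <- y + truth$amp_fid[i] *
        envelope_at(t_fid, cfg$period_s, lib$t1_min[i], lib$t2_s[i],
                    lib$sigma1_s[i], lib$sigma2_ms[i] / 1000)
    }
    if (cfg$noise_sd[["fid"]] > 0)
      y <- y + stats::rnorm(nf, 0, cfg$noise_sd[["fid"]])
    fid <- detector_trace("FID", cfg$fid_rate_hz, t_fid, intensity = y)
    # MS channel
    nm <- floor(run_end_s * cfg$ms_rate_hz)
    t_ms <- (seq_len(nm) - 1L) / cfg$ms_rate_hz
    frag <- vector("list", nrow(lib))
    for (i in seq_len(nrow(lib))) {
      env <- truth$amp_ms[i] *
        envelope_at(t_ms, cfg$period_s, lib$t1_min[i], truth$t2_ms_s[i],
                    lib$sigma1_s[i], lib$sigma2_ms[i] / 1000)
      frag[[i]] <- list(scan = which(env > 1e-9), env = env[env > 1e-9],
                        spec = lib$spectrum[[i]])
    }
    scans <- vector("list", nm)
    for (i in seq_len(nrow(lib))) {
      f <- frag[[i]]
      rel <- f$spec[, 2L] / sum(f$spec[, 2L])   # TIC of a scan equals the envelope
      for (j in seq_along(f$scan)) {
        s <- f$scan[j]
        add <- cbind(mz = f$spec[, 1L], intensity = f$env[j] * rel)
        scans[[s]] <- if (is.null(scans[[s]])) add else rbind(scans[[s]], add)
      }
    }
    sd_ms <- cfg$noise_sd[["ms"]]
    scans <- lapply(scans, function(s) {
      if (is.null(s)) s <- cbind(mz = numeric(0), intensity = numeric(0))
      else if (anyDuplicated(s[, 1L])) {
        acc <- rowsum(s[, 2L], group = s[, 1L])
        s <- cbind(mz = as.numeric(rownames(acc)), intensity = acc[, 1L])
      }
      if (sd_ms > 0 && nrow(s)) {
        s[, 2L] <- pmax(s[, 2L] + stats::rnorm(nrow(s), 0, sd_ms), 0)
        s <- s[s[, 2L] > 0, , drop = FALSE]
      }
      s[order(s[, 1L]), , drop = FALSE]
    })
    ms <- detector_trace("MS", cfg$ms_rate_hz, t_ms, scans = scans)
    list(fid = fid, ms = ms, truth = truth)
  })
}

#' Simulate a batch of runs with drift and dropout
#'
#' Applies a smooth per-run retention drift (one draw per run and
#' dimension), drops each compound independently with probability
#' `dropout_prob` per run, and derives each run's seed deterministically
#' from `cfg$seed` and the run index. With `traces = TRUE` every run is
#' rendered to full detector traces via [simulate_pair()]; the default
#' peak-level mode instead returns, per run, detected-peak tables for
#' the three data streams (FID, MS, fused) built from the planted
#' truth:
#' \itemize{
#'   \item a compound enters a channel's table when its analytic S/N in
#'     that channel reaches `snr_min` (the MS channel, receiving the
#'     smaller split fraction, loses the weak features);
#'   \item apex positions carry measurement jitter of half a sample
#'     interval; volumes carry multiplicative noise;
#'   \item MS and fused peaks carry noisy copies of the reference
#'     spectrum; fused peaks lacking MS confirmation carry only the
#'     virtual m/z 0 channel;
#'   \item `decoys_per_run` spurious single-channel peaks (uniform over
#'     the plane, empty spectra) are appended to the FID and fused
#'     tables, emulating the FID's non-specific response.
#' }
#' The hidden `truth` column of every peak table names the planted
#' compound (decoys are `"decoy"`); matching never reads it.
#'
#' @param lib compound library.
#' @param cfg a [sim_config()].
#' @param n_runs number of runs (>= 2).
#' @param dropout_prob per-run, per-compound absence probability.
#' @param traces render full detector traces instead of peak tables.
#' @param snr_min analytic detection threshold for peak-level mode.
#' @param decoys_per_run expected number of spurious FID peaks per run.
#' @param spec_noise relative intensity jitter of measured spectra.
#' @return list of per-run lists; peak-level mode gives `fid`, `ms`,
#'   `fused` peak tables plus `truth`, trace mode gives
#'   [simulate_pair()] output.
#' @export
simulate_batch <- function(lib, cfg = sim_config(), n_runs = 30L,
                           dropout_prob = 0.0, traces = FALSE,
                           snr_min = 100, decoys_per_run = 20,
                           spec_noise = 0.05) {
  stopifnot(n_runs >= 2L)
  run_seeds <- (as.numeric(cfg$seed) * 7919 + 104729 * seq_len(n_runs)) %% 2147483647
  out <- vector("list", n_runs)
  for (r in seq_len(n_runs)) {
    rs <- as.integer(run_seeds[r])
    out[[r]] <- withr_seed(rs, {
      drift1 <- stats::rnorm(1, 0, cfg$drift[["t1_min"]])
      drift2 <- stats::rnorm(1, 0, cfg$drift[["t2_s"]])
      present <- stats::runif(nrow(lib)) >= dropout_prob
      lib_r <- lib[present, , drop = FALSE]
      lib_r$t1_min <- lib_r$t1_min + drift1
      lib_r$t2_s <- pmax(lib_r$t2_s + drift2, 0.05)
      if (traces) {
        cfg_r <- cfg; cfg_r$seed <- rs
        simulate_pair(lib_r, cfg_r)
      } else {
        simulate_run_peaks(lib_r, cfg, snr_min, decoys_per_run, spec_noise)
      }
    })
  }
  out
}

# peak-level rendering of one run (RNG state managed by the caller)
simulate_run_peaks <- function(lib_r, cfg, snr_min, decoys_per_run, spec_noise) {
  truth <- truth_table(lib_r, cfg)
  jit1 <- cfg$period_s / 60 / 2          # half a modulation in t1
  jit2_fid <- 0.5 / cfg$fid_rate_hz
  jit2_ms <- 0.5 / cfg$ms_rate_hz
  n <- nrow(truth)
  noisy_spec <- function(sp) {
    ints <- sp[, 2L] * (1 + stats::rnorm(nrow(sp), 0, spec_noise))
    keep <- ints > 0
    cbind(mz = sp[keep, 1L], intensity = ints[keep])
  }
  mk <- function(sel, t2, jit2, with_spec, channel) {
    m <- sum(sel)
    pk <- peak_table(m)
    if (m) {
      idx <- which(sel)
      pk$label <- truth$name[idx]
      pk$t1_min <- truth$t1_min[idx] + stats::rnorm(m, 0, jit1 / 3)
      pk$t2_s <- t2[idx] + stats::rnorm(m, 0, jit2 / 3)
      pk$volume <- (if (channel == "ms") truth$vol_ms[idx] else truth$vol_fid[idx]) *
        exp(stats::rnorm(m, 0, 0.05))
      pk$snr <- if (channel == "ms") truth$snr_ms[idx] else truth$snr_fid[idx]
      pk$apex_spectrum <- I(lapply(idx, function(i) {
        if (!with_spec[i]) {
          if (channel == "fid") NULL else cbind(mz = 0, intensity = truth$amp_fid[i])
        } else if (channel == "fused") {
          rbind(cbind(mz = 0, intensity = truth$amp_fid[i]),
                noisy_spec(lib_r$spectrum[[match(truth$name[i], lib_r$name)]]))
        } else {
          noisy_spec(lib_r$spectrum[[match(truth$name[i], lib_r$name)]])
        }
      }))
    }
    pk$truth <- pk$label
    pk
  }
  ms_ok <- truth$snr_ms >= snr_min
  fid_ok <- truth$snr_fid >= snr_min
  fused_ok <- (truth$amp_fid + truth$amp_ms) /
    sqrt(cfg$noise_sd[["fid"]]^2 + cfg$noise_sd[["ms"]]^2) >= snr_min
  fid_pk <- mk(fid_ok, truth$t2_s, jit2_fid, rep(FALSE, n), "fid")
  ms_pk <- mk(ms_ok, truth$t2_ms_s, jit2_ms, rep(TRUE, n), "ms")
  fused_pk <- mk(fused_ok, truth$t2_s, jit2_fid, ms_ok, "fused")
  n_decoy <- stats::rpois(1, decoys_per_run)
  if (n_decoy > 0) {
    dk <- peak_table(n_decoy)
    dk$label <- sprintf("decoy%02d", seq_len(n_decoy))
    dk$t1_min <- stats::runif(n_decoy, min(lib_r$t1_min), max(lib_r$t1_min))
    dk$t2_s <- stats::runif(n_decoy, 0.1, cfg$period_s * 0.95)
    dk$volume <- stats::runif(n_decoy, 0.01, 0.2)
    dk$snr <- stats::runif(n_decoy, snr_min, 3 * snr_min)
    dk$apex_spectrum <- I(lapply(seq_len(n_decoy), function(i) NULL))
    dk$truth <- rep("decoy", n_decoy)
    dk_fused <- dk
    dk_fused$apex_spectrum <- I(lapply(seq_len(n_decoy), function(i)
      cbind(mz = 0, intensity = 100)))
    fid_pk <- rbind(fid_pk, dk)
    fused_pk <- rbind(fused_pk, dk_fused)
  }
  list(fid = fid_pk, ms = ms_pk, fused = fused_pk, truth = truth)
}

#' Write one simulated run to disk
#'
#' FID as CSV, MS as mzML (when \pkg{mzR} is available, otherwise as a
#' pseudo-MS scan-block text file), and the ground-truth table as CSV.
#'
#' @param run output of [simulate_pair()].
#' @param dir output directory (created if needed).
#' @param stem file-name stem.
#' @return named character vector of the files written.
#' @export
write_run <- function(run, dir, stem = "run") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fid_path <- file.path(dir, paste0(stem, "_fid.csv"))
  write_fid_csv(run$fid, fid_path)
  if (requireNamespace("mzR", quietly = TRUE)) {
    ms_path <- file.path(dir, paste0(stem, "_ms.mzML"))
    write_ms_mzml(run$ms, ms_path)
  } else {
    ms_path <- file.path(dir, paste0(stem, "_ms.txt"))
    write_scan_text(run$ms, ms_path)
  }
  truth_path <- file.path(dir, paste0(stem, "_truth.csv"))
  utils::write.csv(run$truth, truth_path, row.names = FALSE)
  c(fid = fid_path, ms = ms_path, truth = truth_path)
}

# scan-block text fallback for MS traces (same block format as pseudo-MS)
write_scan_text <- function(trace, path) {
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  writeLines(c(paste0("CHANNEL=", trace$channel_id),
               paste0("RATE_HZ=", fmt_sig9(trace$rate_hz)),
               "PERIOD_S=NA", "PHASE_S=NA", ""), con, sep = "\n")
  for (i in seq_along(trace$times)) {
    s <- trace$scans[[i]]
    writeLines(c(sprintf("SCAN=%d", i - 1L),
                 sprintf("RT=%.6f", trace$times[i]),
                 if (nrow(s)) sprintf("%d %s", as.integer(round(s[, 1L])), fmt_sig9(s[, 2L])),
                 ""), con, sep = "\n")
  }
  invisible(path)
}

#' Read a scan-block text MS file
#'
#' Inverse of the scan-block writer used by [write_run()] when mzML
#' output is unavailable.
#'
#' @param path file to read.
#' @param channel_id channel label.
#' @return an MS [detector_trace()].
#' @export
read_scan_text <- function(path, channel_id = "MS") {
  doc <- parse_pseudo_ms(path)
  rate <- doc$header$rate_hz
  if (is.na(rate)) rate <- 1 / stats::median(diff(doc$scans$time_s))
  detector_trace(channel_id, rate, doc$scans$time_s, scans = doc$scans$pairs)
}
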