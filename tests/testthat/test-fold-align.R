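test_that("resample_common is the identity on the target clock and interpolates linearly", {
  tt <- (0:99) / 28
  fid <- detector_trace("FID", 28, tt, intensity = sin(tt))
  ms <- detector_trace("MS", 28, tt, scans = lapply(seq_along(tt), function(i)
    cbind(mz = 50, intensity = i)))
  rs <- resample_common(fid, ms, target_hz = 28)
  expect_equal(rs$fid$intensity, fid$intensity)
  expect_equal(rs$ms$scans, ms$scans)

  # ramp 0 -> 1 at 100 Hz resampled to 50 Hz: exact midpoint interpolation
  t100 <- (0:100) / 100
  ramp <- detector_trace("FID", 100, t100, intensity = t100)
  ms2 <- detector_trace("MS", 50, (0:50) / 50,
                        scans = rep(list(cbind(mz = 50, intensity = 1)), 51))
  rs2 <- resample_common(ramp, ms2, target_hz = 50)
  expect_equal(rs2$fid$intensity, rs2$fid$times)   # closed-form: y(t) = t

  # default target is the lower native rate
  rs3 <- resample_common(ramp, ms2)
  expect_equal(rs3$fid$rate_hz, 50)

  late <- detector_trace("FID", 100, 10 + t100, intensity = t100)
  expect_error(resample_common(late, ms2), "overlap")
})

test_that("fold places samples arithmetically and conserves intensity", {
  P <- 2.5; rate <- 200
  tt <- (0:(10 * P * rate - 1)) / rate
  const <- detector_trace("FID", rate, tt, intensity = rep(3, length(tt)))
  m <- tic(fold(const, P, 0))
  expect_true(all(m == 3))

  # single Gaussian at t = 3 P + 0.4 P: apex at column 3, row ~ 0.4 * pts_per_mod
  y <- exp(-((tt - 3.4 * P)^2) / (2 * 0.05^2))
  img <- fold(detector_trace("FID", rate, tt, intensity = y), P, 0)
  m <- tic(img)
  apex <- which(m == max(m), arr.ind = TRUE)
  expect_equal(apex[1] - 1L, 3L, ignore_attr = TRUE)
  expect_equal(apex[2] - 1L, round(0.4 * img$grid$pts_per_mod), tolerance = 1,
               ignore_attr = TRUE)
  expect_equal(sum(m), sum(y))   # exact conservation of retained samples

  # a 4 s period configuration folds cleanly too
  img4 <- fold(detector_trace("FID", 100, (0:1599) / 100, intensity = rep(1, 1600)), 4, 0)
  expect_equal(img4$grid$pts_per_mod, 400L)
  expect_equal(img4$grid$n_mod, 4L)

  short <- detector_trace("FID", rate, tt[1:100], intensity = y[1:100])
  expect_error(fold(short, P, 0), "full modulation")
})

test_that("estimate_phase_shift recovers constructed circular shifts", {
  img <- gaussian_image(12, 40, list(list(col = 5, row = 18, sc = 1.2, sr = 3, amp = 100)))
  expect_equal(estimate_phase_shift(img, img), 0)
  ppm <- img$grid$pts_per_mod
  for (s in c(1L, 7L, 19L, ppm - 3L)) {   # ppm - 3 wraps to a negative shift
    d <- img$data
    d$row <- (d$row + s) %% ppm
    shifted <- spectral_image(img$grid, d, "FID")
    want <- if (s > ppm / 2) (s - ppm) else s
    expect_equal(estimate_phase_shift(img, shifted) * img$grid$rate_hz, want)
  }
  empty <- spectral_image(img$grid, img$data[0, ], "FID")
  expect_error(estimate_phase_shift(img, empty), "all-zero")
})

test_that("relative misalignment is the absolute 2D apex difference in ms", {
  a <- peak_table(2L); b <- peak_table(2L)
  a$label <- b$label <- c("x", "benzyl benzoate")
  a$t2_s <- c(1.5, 2.000); b$t2_s <- c(1.5, 2.003)
  a$width_half_ms <- c(300, 310); b$width_half_ms <- c(320, 330)
  a$width_base_ms <- c(500, 520); b$width_base_ms <- c(540, 560)
  rec <- relative_misalignment(a, b)
  expect_equal(rec$rm_ms, c(0, 3))
  expect_equal(rec$width_half_ms, c(310, 320))   # mean of the two channels
  expect_equal(rec$width_base_ms, c(520, 540))
})

test_that("misalignment summaries reproduce the bundled three-set-up panel means", {
  a <- example_misalignment("A")
  expect_equal(summarize_misalignment(a),
               list(rm_ms = 45L, width_half_ms = 319L, width_base_ms = 542L))
  b <- example_misalignment("B")
  expect_equal(summarize_misalignment(b),
               list(rm_ms = 31L, width_half_ms = 382L, width_base_ms = 649L))
  cc <- example_misalignment("C")
  s <- summarize_misalignment(cc)
  expect_equal(s$rm_ms, 175L)   # wrap-around compound included
  expect_equal(s$width_half_ms, 254L)
  expect_equal(s$width_base_ms, 431L)
  # excluding the wrap-around peak the panel mean drops sharply
  s2 <- summarize_misalignment(cc[!cc$wrapped, ])
  expect_lt(s2$rm_ms, 100L)
  one <- summarize_misalignment(cc[1, ])
  expect_equal(one$rm_ms, as.integer(round(cc$rm_ms[1])))
  expect_error(summarize_misalignment(cc[0, ]), "no records")
})

test_that("global transform fitting is exact on identity and known quadratic maps", {
  set.seed(501)
  pts <- data.frame(t1_min = runif(15, 3, 27), t2_s = runif(15, 0.5, 3.5))
  id_fit <- fit_global_transform(retention_pairs(pts, pts), degree = 2)
  expect_equal(id_fit$coeff_t1, c(0, 1, 0, 0, 0, 0), tolerance = 1e-10)
  expect_equal(id_fit$coeff_t2, c(0, 0, 1, 0, 0, 0), tolerance = 1e-10)
  expect_lt(max(abs(unlist(attr(id_fit, "residuals")))), 1e-10)

  for (seed in 1:5) {
    set.seed(seed)
    c1 <- c(0.05, 1 + rnorm(1, 0, 0.01), rnorm(1, 0, 0.01),
            rnorm(1, 0, 1e-4), rnorm(1, 0, 1e-4), rnorm(1, 0, 1e-3))
    c2 <- c(-0.02, rnorm(1, 0, 0.01), 1 + rnorm(1, 0, 0.01),
            rnorm(1, 0, 1e-4), rnorm(1, 0, 1e-4), rnorm(1, 0, 1e-3))
    truth_tf <- poly_transform(c1, c2)
    from <- data.frame(t1_min = runif(25, 3, 27), t2_s = runif(25, 0.5, 3.5))
    to <- transform_points(truth_tf, from$t1_min, from$t2_s)
    fit <- fit_global_transform(retention_pairs(from, to), degree = 2)
    expect_lt(max(abs(fit$coeff_t1 - c1) / pmax(abs(c1), 1e-9)), 1e-9)
    expect_lt(max(abs(fit$coeff_t2 - c2) / pmax(abs(c2), 1e-9)), 1e-9)
  }

  degenerate <- data.frame(t1_from = 1:10, t2_from = rep(2, 10),
                           t1_to = 1:10, t2_to = rep(2, 10))
  expect_error(fit_global_transform(degenerate, degree = 2), "degree 1")
  expect_error(fit_global_transform(degenerate[1:4, ], degree = 2), "at least 6")
})

test_that("apply_transform warps images as expected", {
  img <- gaussian_image(15, 80, list(list(col = 7, row = 30, sc = 1.5, sr = 5, amp = 100)))
  same <- apply_transform(img, identity_transform())
  expect_equal(sum(tic(same)), sum(tic(img)), tolerance = 1e-12)
  expect_equal(tic(same), tic(img), tolerance = 1e-9)

  # +0.2 s translation in t2 moves the apex by 0.2 s
  shift_tf <- poly_transform(c(0, 1, 0, 0, 0, 0), c(0.2, 0, 1, 0, 0, 0))
  moved <- apply_transform(img, shift_tf)
  cfg <- detection_config(snr_min = 5, vnr_min = 1)
  p0 <- detect_peaks(img, cfg); p1 <- detect_peaks(moved, cfg)
  expect_equal(p1$t2_s[1] - p0$t2_s[1], 0.2, tolerance = 0.01)
  expect_equal(p1$t1_min[1], p0$t1_min[1], tolerance = 0.01)
  # smooth image: intensity conserved well within 1%
  expect_equal(sum(tic(moved)), sum(tic(img)), tolerance = 0.01)

  # a zonal transform only alters peaks inside its zone
  two <- gaussian_image(30, 60, list(list(col = 6, row = 20, sc = 1.2, sr = 4, amp = 100),
                                     list(col = 22, row = 40, sc = 1.2, sr = 4, amp = 100)))
  mid <- pixel_to_retention(two$grid, 14, 0)$t1_min
  zone_lo <- zonal_transform(list(list(t1_range = c(0, mid), transform = shift_tf)),
                             fallback = identity_transform())
  warped <- apply_transform(two, zone_lo)
  pw <- detect_peaks(warped, cfg); p2 <- detect_peaks(two, cfg)
  pw <- pw[order(pw$t1_min), ]; p2 <- p2[order(p2$t1_min), ]
  expect_equal(pw$t2_s[1] - p2$t2_s[1], 0.2, tolerance = 0.01)   # early peak moved
  expect_equal(pw$t2_s[2], p2$t2_s[2], tolerance = 1e-6)         # late peak untouched
})

test_that("zonal fitting reduces to the global fit and recovers two-zone maps", {
  set.seed(502)
  from <- data.frame(t1_min = runif(30, 0, 30), t2_s = runif(30, 0.5, 3.5))
  tf_a <- poly_transform(c(0.02, 1.001, 0, 1e-5, 0, 0), c(0.1, 0, 1.01, 0, 1e-4, 1e-3))
  to <- transform_points(tf_a, from$t1_min, from$t2_s)
  pairs <- retention_pairs(from, to)
  zt <- fit_zonal(pairs, zones = list(c(0, 30)), degree = 2)
  glob <- fit_global_transform(pairs, degree = 2)
  expect_equal(zt$zones[[1]]$transform$coeff_t2, glob$coeff_t2, tolerance = 1e-9)

  # two different local quadratics, recovered zone by zone
  tf_b <- poly_transform(c(-0.1, 0.999, 0.002, -1e-5, 0, 0), c(-0.2, 0.001, 0.98, 0, -1e-4, 0.002))
  early <- from$t1_min < 15
  to2 <- to
  to2[early, ] <- transform_points(tf_b, from$t1_min[early], from$t2_s[early])
  pairs2 <- retention_pairs(from, to2)
  zt2 <- fit_zonal(pairs2, zones = list(c(0, 15), c(15, 30)), degree = 2)
  expect_equal(zt2$zones[[1]]$transform$coeff_t2, tf_b$coeff_t2, tolerance = 1e-6)
  expect_equal(zt2$zones[[2]]$transform$coeff_t2, tf_a$coeff_t2, tolerance = 1e-6)

  expect_message(fit_zonal(pairs, zones = list(c(40, 50)), degree = 2), "using global fit")
})
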