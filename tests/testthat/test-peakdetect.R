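test_that("noise estimation recovers a known sigma and floors constant images", {
  set.seed(801)
  sigma <- 3.7
  m <- matrix(rnorm(10000, 0, sigma), 100, 100)
  expect_lt(abs(estimate_noise(m) - sigma) / sigma, 0.15)

  const <- matrix(5, 20, 20)
  expect_equal(estimate_noise(const), .Machine$double.eps * 5)
})

test_that("a blank noisy image yields no peaks", {
  set.seed(802)
  grid <- modulation_grid(0.5, 0, 40L, 100)
  d <- expand.grid(col = 0:39, row = 0:49)
  d$mz <- 0; d$intensity <- abs(rnorm(nrow(d), 10, 2))
  img <- spectral_image(grid, d, "FID")
  expect_equal(nrow(detect_peaks(img, detection_config())), 0L)
})

test_that("the S/N threshold separates strong from weak peaks", {
  # planted apex S/N 500 and 50 against noise sd 1: only the strong peak survives
  img <- gaussian_image(40, 60,
                        list(list(col = 10, row = 20, sc = 1.5, sr = 4, amp = 500),
                             list(col = 28, row = 40, sc = 1.5, sr = 4, amp = 50)),
                        noise_sd = 1, seed = 803)
  pk <- detect_peaks(img, detection_config(snr_min = 100))
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$apex_col, 10, tolerance = 0.5)
  expect_equal(pk$apex_row, 20, tolerance = 0.5)
  # lowering the bar recovers both, with the ~10:1 volume ordering
  pk2 <- detect_peaks(img, detection_config(snr_min = 20))
  expect_equal(nrow(pk2), 2L)
  expect_equal(pk2$volume[1] / pk2$volume[2], 10, tolerance = 0.2)
})

test_that("raising snr_min never increases the peak count", {
  img <- gaussian_image(40, 60,
                        list(list(col = 8, row = 15, sc = 1.2, sr = 3, amp = 400),
                             list(col = 20, row = 30, sc = 1.2, sr = 3, amp = 150),
                             list(col = 32, row = 45, sc = 1.2, sr = 3, amp = 60)),
                        noise_sd = 1, seed = 804)
  counts <- vapply(c(10, 50, 100, 200, 500),
                   function(s) nrow(detect_peaks(img, detection_config(snr_min = s))), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("detection is equivariant under whole-pixel translations", {
  peaks0 <- list(list(col = 10, row = 20, sc = 1.3, sr = 3.5, amp = 300),
                 list(col = 22, row = 38, sc = 1.3, sr = 3.5, amp = 200))
  img0 <- gaussian_image(40, 70, peaks0, noise_sd = 0.5, seed = 805)
  shifted <- lapply(peaks0, function(p) { p$col <- p$col + 4; p$row <- p$row + 6; p })
  img1 <- gaussian_image(40, 70, shifted, noise_sd = 0.5, seed = 805)
  p0 <- detect_peaks(img0); p1 <- detect_peaks(img1)
  expect_equal(nrow(p0), 2L)
  expect_equal(nrow(p1), 2L)
  o0 <- order(p0$apex_col); o1 <- order(p1$apex_col)
  expect_equal(p1$apex_col[o1] - p0$apex_col[o0], c(4, 4), tolerance = 0.15)
  expect_equal(p1$apex_row[o1] - p0$apex_row[o0], c(6, 6), tolerance = 0.15)
})

test_that("planted peaks are recovered and pure noise never fakes one", {
  # strong peaks (S/N >= 2 * snr_min) must be found within a pixel;
  # weak bumps (S/N < snr_min / 2) must never be reported
  hits <- 0L; total <- 0L; false_pos <- 0L
  for (rep in 1:100) {
    set.seed(900 + rep)
    truth <- list(list(col = sample(8:15, 1), row = sample(12:25, 1),
                       sc = 1.2, sr = 3, amp = 200),
                  list(col = sample(25:34, 1), row = sample(35:48, 1),
                       sc = 1.2, sr = 3, amp = 40))
    img <- gaussian_image(42, 60, truth, noise_sd = 1, seed = 900 + rep)
    pk <- detect_peaks(img, detection_config(snr_min = 100))
    total <- total + 1L
    strong <- truth[[1]]
    ok <- any(abs(pk$apex_col - strong$col) <= 1 & abs(pk$apex_row - strong$row) <= 1)
    hits <- hits + as.integer(ok)
    weak <- truth[[2]]
    false_pos <- false_pos +
      sum(abs(pk$apex_col - weak$col) <= 2 & abs(pk$apex_row - weak$row) <= 2)
  }
  expect_gte(hits / total, 0.95)
  expect_equal(false_pos, 0L)
})

test_that("width metrology matches the closed-form Gaussian", {
  # sigma = 100 ms at 100 Hz -> 10 samples
  img <- gaussian_image(20, 120, list(list(col = 9, row = 60, sc = 1.5, sr = 10, amp = 500)),
                        rate_hz = 100)
  pk <- detect_peaks(img, detection_config(snr_min = 5, vnr_min = 1))
  w <- peak_widths(img, pk[1, ])
  expect_equal(unname(w["width_half_ms"]), 235.48, tolerance = 0.02)
  expect_equal(unname(w["width_base_ms"]), 400, tolerance = 0.02)
  # the base/half ratio of any Gaussian peak is 4 / 2.3548
  expect_equal(unname(w["width_base_ms"] / w["width_half_ms"]), 1.699, tolerance = 1e-3)
  expect_equal(pk$width_half_ms[1], 235.48, tolerance = 0.02)

  flat <- spectral_image(img$grid,
                         data.frame(col = 0:19, row = 5, mz = 0, intensity = 1), "FID")
  fake <- pk[1, ]; fake$apex_col <- 0; fake$apex_row <- 5
  expect_message(wf <- peak_widths(flat, fake), "fit failed")
  expect_true(all(is.na(wf)))
})

test_that("retention factors follow the void-time arithmetic and flag wrap-around", {
  pk <- peak_table(1L)
  pk$t2_s <- 0.25
  expect_equal(retention_factor(pk, t2_void_s = 0.25, period_s = 2.5, wrap_count = 0)$k2, 0)
  pk$t2_s <- 0.75
  expect_equal(retention_factor(pk, 0.25, 2.5, wrap_count = 0)$k2, 2)
  # known wrap count: one extra period enters the numerator
  expect_equal(retention_factor(pk, 0.25, 2.5, wrap_count = 1)$k2, (0.75 + 2.5 - 0.25) / 0.25)
  # unknown wrap count near t2 = 0: uncertain, like a wrapped-around lactone
  pk$t2_s <- 0.1
  rf <- retention_factor(pk, 0.25, 2.5)
  expect_true(rf$uncertain)
  pk$t2_s <- 2.0
  expect_false(retention_factor(pk, 0.25, 2.5)$uncertain)
})
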