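test_that("match factors agree with a brute-force cosine oracle", {
  sp <- random_spectrum(1001)
  mf <- match_factor(sp, sp)
  expect_equal(mf$dmf, 999)
  expect_equal(mf$rmf, 999)

  a <- cbind(mz = c(41, 55, 70), intensity = c(999, 300, 100))
  b <- cbind(mz = c(43, 57, 91), intensity = c(999, 500, 200))
  expect_equal(match_factor(a, b)$dmf, 0)

  # independent oracle: explicit union loop with sqrt weighting
  for (seed in 1:10) {
    qa <- random_spectrum(2000 + seed, n = 15L)
    qb <- random_spectrum(3000 + seed, n = 10L)
    mzs <- sort(union(qa[, 1], qb[, 1]))
    va <- vb <- numeric(length(mzs))
    for (i in seq_along(mzs)) {
      ia <- which(qa[, 1] == mzs[i]); ib <- which(qb[, 1] == mzs[i])
      if (length(ia)) va[i] <- sqrt(qa[ia, 2])
      if (length(ib)) vb[i] <- sqrt(qb[ib, 2])
    }
    oracle <- 999 * (sum(va * vb)^2 / (sum(va^2) * sum(vb^2)))
    got <- match_factor(qa, qb)
    expect_equal(got$dmf, oracle, tolerance = 1e-9)
    expect_equal(match_factor(qb, qa)$dmf, got$dmf)   # dmf is symmetric
    expect_gte(got$rmf, got$dmf - 1e-9)               # reverse restricts to reference
  }
})

test_that("match factors ignore overall intensity scale and the reserved m/z 0", {
  a <- random_spectrum(1003)
  b <- random_spectrum(1004)
  base <- match_factor(a, b)$dmf
  a2 <- a; a2[, 2] <- a2[, 2] * 37.5
  expect_equal(match_factor(a2, b)$dmf, base, tolerance = 1e-12)

  # a dominant FID channel at m/z 0 must not disturb spectral scoring
  fused <- rbind(cbind(mz = 0, intensity = 1e6), a)
  expect_equal(match_factor(fused, b)$dmf, base, tolerance = 1e-12)

  only_fid <- cbind(mz = 0, intensity = 1e6)
  expect_error(match_factor(only_fid, b), "empty after")
})

make_peaks <- function(lib, t1, t2, spectra = TRUE, jitter = 0, seed = 1) {
  set.seed(seed)
  pk <- peak_table(nrow(lib))
  pk$label <- lib$name
  pk$t1_min <- t1 + rnorm(nrow(lib), 0, jitter)
  pk$t2_s <- t2 + rnorm(nrow(lib), 0, jitter / 10)
  pk$volume <- lib$amount
  pk$snr <- 500
  pk$apex_spectrum <- I(if (spectra) lib$spectrum else vector("list", nrow(lib)))
  pk
}

test_that("a template matches itself with the identity registration", {
  lib <- make_library(10, seed = 1005)
  pk <- make_peaks(lib, lib$t1_min, lib$t2_s)
  tpl <- template(lapply(seq_len(nrow(lib)), function(i)
    template_peak(lib$name[i], lib$t1_min[i], lib$t2_s[i], lib$spectrum[[i]])))
  mr <- match_template(tpl, pk, window = c(0.5, 0.2))
  expect_equal(nrow(mr$assignments), 10L)
  expect_equal(mr$assignments$name, pk$label[mr$assignments$peak])
  expect_length(mr$unmatched_template, 0L)
  fit <- transform_points(mr$transform, lib$t1_min, lib$t2_s)
  expect_equal(fit$t1_min, lib$t1_min, tolerance = 1e-8)
  expect_equal(fit$t2_s, lib$t2_s, tolerance = 1e-8)
})

test_that("spectral constraints rescue matching under a known quadratic shift", {
  lib <- make_library(20, seed = 1006)
  tf <- poly_transform(c(0.3, 1.002, 0, 1e-4, 0, 0), c(0.12, 0, 1.01, 0, 5e-4, 1e-3))
  moved <- transform_points(tf, lib$t1_min, lib$t2_s)
  correct <- false_spectral <- false_blind <- 0L
  for (seed in 1:3) {
    pk <- make_peaks(lib, moved$t1_min, moved$t2_s, jitter = 0.01, seed = seed)
    # decoy peaks carrying unrelated spectra, scattered near the panel
    set.seed(7000 + seed)
    nd <- 25L
    dk <- peak_table(nd)
    dk$label <- rep("decoy", nd)
    dk$t1_min <- runif(nd, min(moved$t1_min), max(moved$t1_min))
    dk$t2_s <- runif(nd, min(moved$t2_s), max(moved$t2_s))
    dk$volume <- 1; dk$snr <- 300
    dk$apex_spectrum <- I(lapply(1:nd, function(i) random_spectrum(8000 + 100 * seed + i)))
    all_pk <- rbind(pk, dk)
    tpl_s <- template(lapply(seq_len(nrow(lib)), function(i)
      template_peak(lib$name[i], lib$t1_min[i], lib$t2_s[i], lib$spectrum[[i]])))
    tpl_b <- template(lapply(seq_len(nrow(lib)), function(i)
      template_peak(lib$name[i], lib$t1_min[i], lib$t2_s[i])))
    mr_s <- match_template(tpl_s, all_pk, window = c(0.6, 0.25))
    mr_b <- match_template(tpl_b, all_pk, window = c(0.6, 0.25))
    correct <- correct + sum(mr_s$assignments$name == all_pk$label[mr_s$assignments$peak])
    false_spectral <- false_spectral +
      sum(mr_s$assignments$name != all_pk$label[mr_s$assignments$peak])
    false_blind <- false_blind +
      sum(mr_b$assignments$name != all_pk$label[mr_b$assignments$peak])
  }
  expect_gte(correct / (3 * nrow(lib)), 0.98)
  expect_gt(false_blind, false_spectral)   # FID-only mode mismatches more
})

test_that("reliable-set thresholds follow the ceil(fraction * n) rule", {
  lib <- make_library(6, seed = 1007)
  base <- make_peaks(lib, lib$t1_min, lib$t2_s)
  # two identical chromatograms: everything reliable
  rs <- ut_fingerprint(list(base, base), window = c(0.3, 0.1))
  expect_true(all(rs$features$reliable))

  # a feature present in exactly m of 30 chromatograms is reliable iff m >= 15
  for (m in c(14L, 15L)) {
    chroms <- lapply(1:30, function(r)
      if (r <= m) base else base[-1, , drop = FALSE])
    rs <- ut_fingerprint(chroms, window = c(0.3, 0.1))
    expect_equal(rs$features$reliable[1], m >= 15L)
    expect_equal(rs$features$match_count[1], m)
    expect_true(all(rs$features$reliable[-1]))
  }
})

test_that("tightening thresholds never grows the reliable set", {
  lib <- make_library(12, seed = 1008)
  set.seed(1008)
  chroms <- lapply(1:8, function(r) {
    keep <- stats::runif(12) > 0.3
    make_peaks(lib[keep, , drop = FALSE], lib$t1_min[keep], lib$t2_s[keep],
               jitter = 0.01, seed = r)
  })
  n_rel <- vapply(c(0.3, 0.5, 0.8, 1.0), function(fr)
    sum(ut_fingerprint(chroms, fraction_required = fr)$features$reliable), 0L)
  expect_true(all(diff(n_rel) <= 0))

  counts <- vapply(c(500, 700, 900, 990), function(d) {
    rs <- ut_fingerprint(chroms, dmf_min = d)
    sum(rs$features$match_count)
  }, 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("reliable-peak percentages are reported against the FID reference", {
  out <- reliable_report(96, c(MS = 20, fused = 31))
  expect_equal(unname(out["MS"]), 20.8)
  expect_equal(unname(out["fused"]), 32.3)
  expect_equal(unname(out["FID"]), 100.0)
  expect_equal(unname(reliable_report(50, c(MS = 50))["MS"]), 100.0)
})
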