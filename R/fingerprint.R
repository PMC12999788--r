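#' @title Spectral match factors and template fingerprinting
#' @name fingerprint
#' @description
#' Spectral similarity scoring (direct and reverse match factors on the
#' conventional 0-999 scale), template matching under a dual
#' chromatographic + spectral criterion, and reliable-peak UT
#' (untargeted + targeted) fingerprinting across chromatogram batches.
#' The reserved m/z 0 channel of fused data is excluded from spectral
#' scoring by default, so the embedded FID signal never interferes with
#' spectral inspection.
NULL

spectrum_weights <- function(spec, int_exp, mz_exp) {
  (spec[, 1L]^mz_exp) * (spec[, 2L]^int_exp)
}

#' Direct and reverse spectral match factors
#'
#' Spectra are compared as weighted vectors on the union of their m/z
#' channels (after removing `exclude`), with weights
#' `mz^mz_exp * intensity^int_exp`. The direct match factor is
#' `999 * cos^2` of the angle between the vectors; the reverse match
#' factor is computed identically but restricted to the channels
#' present in the reference spectrum `b`, so `rmf >= dmf` always.
#'
#' The default weighting (`int_exp = 0.5`, `mz_exp = 0`) is the plain
#' square-root cosine; the NIST-style weighting is available as
#' `int_exp = 0.6`, `mz_exp = 3`.
#'
#' @param a query spectrum, two-column `mz`/`intensity` matrix.
#' @param b reference spectrum.
#' @param exclude m/z values removed before comparison (default the
#'   reserved FID channel 0).
#' @param int_exp,mz_exp weighting exponents.
#' @return list with `dmf` and `rmf`, both in `[0, 999]`.
#' @export
match_factor <- function(a, b, exclude = 0, int_exp = 0.5, mz_exp = 0) {
  drop_excluded <- function(s) s[!(s[, 1L] %in% exclude), , drop = FALSE]
  a <- drop_excluded(a); b <- drop_excluded(b)
  if (!nrow(a) || !nrow(b))
    stop("match_factor: spectrum empty after m/z exclusion")
  mz_union <- sort(unique(c(a[, 1L], b[, 1L])))
  va <- numeric(length(mz_union)); vb <- numeric(length(mz_union))
  va[match(a[, 1L], mz_union)] <- spectrum_weights(a, int_exp, mz_exp)
  vb[match(b[, 1L], mz_union)] <- spectrum_weights(b, int_exp, mz_exp)
  cos2 <- function(x, y) {
    nx <- sum(x^2); ny <- sum(y^2)
    if (nx == 0 || ny == 0) return(0)
    sum(x * y)^2 / (nx * ny)
  }
  dmf <- 999 * cos2(va, vb)
  in_ref <- vb > 0
  rmf <- 999 * cos2(va[in_ref], vb[in_ref])
  list(dmf = dmf, rmf = rmf)
}

scaled_distance <- function(dt1, dt2, window) {
  sqrt((dt1 / window[1])^2 + (dt2 / window[2])^2)
}

#' Match a template against a detected peak list
#'
#' Iterative template registration under the dual criterion combining
#' chromatographic and spectral agreement:
#' \enumerate{
#'   \item candidate pairs are the peaks within the search window of
#'     each (transformed) template position;
#'   \item where the template entry carries a reference spectrum and
#'     the peak an apex spectrum, candidates must reach the entry's
#'     `dmf_min`; entries without a reference spectrum match on
#'     distance alone (the failure-prone single-channel FID mode);
#'   \item conflicts are resolved by highest direct match factor, then
#'     smallest window-scaled distance (a total order, so matching is
#'     deterministic);
#'   \item a degree-2 retention transform is refitted on the current
#'     assignments and the template re-projected; iteration stops when
#'     assignments stabilize or after `max_iter` rounds.
#' }
#' With fewer than 6 assignments the transform falls back to degree 1,
#' and below 3 to a pure translation.
#'
#' @param tpl a [template()].
#' @param peaks a peak table with an `apex_spectrum` list-column.
#' @param window search window `c(dt1_min, dt2_s)`.
#' @param degree transform degree refitted during matching.
#' @param max_iter maximum number of refinement rounds.
#' @param exclude m/z channels excluded from match factors.
#' @return a `match_result`: list with `assignments` (data.frame of
#'   template index/name, peak index, dmf, rmf, distance), `transform`,
#'   `unmatched_template`, `unmatched_peaks`.
#' @export
match_template <- function(tpl, peaks, window = c(0.5, 0.2), degree = 2L,
                           max_iter = 5L, exclude = 0) {
  stopifnot(inherits(tpl, "gc_template"), length(tpl) >= 1L)
  tf <- identity_transform(2L)
  t1_tpl <- vapply(tpl, `[[`, 0, "t1_min")
  t2_tpl <- vapply(tpl, `[[`, 0, "t2_s")
  prev_key <- ""
  assignments <- NULL
  for (iter in seq_len(max_iter)) {
    proj <- transform_points(tf, t1_tpl, t2_tpl)
    cand <- NULL
    for (i in seq_along(tpl)) {
      dt1 <- peaks$t1_min - proj$t1_min[i]
      dt2 <- peaks$t2_s - proj$t2_s[i]
      sel <- which(abs(dt1) <= window[1] & abs(dt2) <= window[2])
      if (!length(sel)) next
      ref <- tpl[[i]]$ref_spectrum
      for (j in sel) {
        dmf <- NA_real_; rmf <- NA_real_
        if (!is.null(ref)) {
          sp <- peaks$apex_spectrum[[j]]
          if (is.null(sp)) next   # spectral constraint unsatisfiable
          mf <- tryCatch(match_factor(sp, ref, exclude = exclude),
                         error = function(e) list(dmf = 0, rmf = 0))
          if (mf$dmf < tpl[[i]]$dmf_min) next
          dmf <- mf$dmf; rmf <- mf$rmf
        }
        cand <- rbind(cand, data.frame(
          template = i, peak = j, dmf = dmf, rmf = rmf,
          distance = scaled_distance(dt1[j], dt2[j], window)))
      }
    }
    assignments <- resolve_assignments(cand)
    key <- if (is.null(assignments)) "" else
      paste(assignments$template, assignments$peak, collapse = ";")
    if (!is.null(assignments) && nrow(assignments) >= 1L) {
      src <- data.frame(t1_min = t1_tpl[assignments$template],
                        t2_s = t2_tpl[assignments$template])
      dst <- data.frame(t1_min = peaks$t1_min[assignments$peak],
                        t2_s = peaks$t2_s[assignments$peak])
      tf <- fit_registration(retention_pairs(src, dst), degree)
    }
    if (key == prev_key) break
    prev_key <- key
  }
  asg <- if (is.null(assignments)) {
    data.frame(template = integer(0), peak = integer(0), dmf = numeric(0),
               rmf = numeric(0), distance = numeric(0), name = character(0))
  } else {
    assignments$name <- vapply(tpl[assignments$template], `[[`, "", "name")
    assignments
  }
  structure(list(assignments = asg, transform = tf,
                 unmatched_template = setdiff(seq_along(tpl), asg$template),
                 unmatched_peaks = setdiff(seq_len(nrow(peaks)), asg$peak)),
            class = "match_result")
}

# greedy one-to-one resolution: best dmf first, then smallest distance;
# spectral matches outrank distance-only ones
resolve_assignments <- function(cand) {
  if (is.null(cand) || !nrow(cand)) return(NULL)
  dmf_key <- ifelse(is.na(cand$dmf), -1, cand$dmf)
  ord <- order(-dmf_key, cand$distance, cand$template, cand$peak)
  cand <- cand[ord, , drop = FALSE]
  used_t <- logical(max(cand$template)); used_p <- logical(max(cand$peak))
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    ti <- cand$template[k]; pj <- cand$peak[k]
    if (!used_t[ti] && !used_p[pj]) {
      keep[k] <- TRUE; used_t[ti] <- TRUE; used_p[pj] <- TRUE
    }
  }
  out <- cand[keep, , drop = FALSE]
  out[order(out$template), , drop = FALSE]
}

# transform refit with graceful degradation
fit_registration <- function(pairs, degree) {
  n <- nrow(pairs)
  if (degree >= 2L && n >= 6L) {
    tf <- tryCatch(fit_global_transform(pairs, 2L), error = function(e) NULL)
    if (!is.null(tf)) return(tf)
  }
  if (n >= 3L) {
    tf <- tryCatch(fit_global_transform(pairs, 1L), error = function(e) NULL)
    if (!is.null(tf)) return(tf)
  }
  # pure translation
  message("match_template: too few assignments for a polynomial fit; using translation")
  dt1 <- mean(pairs$t1_to - pairs$t1_from)
  dt2 <- mean(pairs$t2_to - pairs$t2_from)
  poly_transform(c(dt1, 1, 0), c(dt2, 0, 1), 1L)
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("<match_result: %d assigned, %d template entries unmatched, %d peaks unmatched>\n",
              nrow(x$assignments), length(x$unmatched_template), length(x$unmatched_peaks)))
  invisible(x)
}

#' Reliable-peak UT fingerprinting across a batch
#'
#' Builds the feature set from the reference chromatogram's peaks
#' (untargeted) plus optional targeted entries, matches the resulting
#' template to every chromatogram in the batch with [match_template()],
#' and flags a feature as reliable when it is matched in at least
#' `fraction_required` of the chromatograms (`ceil(fraction * n)`; the
#' default 0.5 is the most relaxed conventional setting).
#'
#' @param chromatograms list of >= 2 peak tables (with `apex_spectrum`
#'   list-columns where spectra are available).
#' @param reference index of the chromatogram whose peaks seed the
#'   untargeted features.
#' @param targeted optional [template()] of targeted entries appended
#'   to the untargeted feature set.
#' @param fraction_required fraction of chromatograms a feature must be
#'   matched in.
#' @param window,dmf_min,degree,max_iter matching parameters passed to
#'   [match_template()]; `dmf_min` applies to untargeted features that
#'   carry a spectrum.
#' @param use_spectra build untargeted features with reference spectra
#'   (set `FALSE` to emulate single-channel FID matching).
#' @return a `reliable_set`: list with `n_chroms`, `fraction_required`,
#'   `features` (data.frame: `feature`, `match_count`, `reliable`) and
#'   `matches` (per-chromatogram `match_result`s).
#' @export
ut_fingerprint <- function(chromatograms, reference = 1L, targeted = NULL,
                           fraction_required = 0.5, window = c(0.5, 0.2),
                           dmf_min = 700, degree = 2L, max_iter = 5L,
                           use_spectra = TRUE) {
  stopifnot(length(chromatograms) >= 2L)
  ref_peaks <- chromatograms[[reference]]
  entries <- lapply(seq_len(nrow(ref_peaks)), function(i) {
    sp <- if (use_spectra) ref_peaks$apex_spectrum[[i]] else NULL
    if (!is.null(sp)) {
      sp <- sp[sp[, 1L] >= 1, , drop = FALSE]   # drop reserved FID channel
      if (!nrow(sp)) sp <- NULL
    }
    nm <- if (nzchar(ref_peaks$label[i])) ref_peaks$label[i] else sprintf("U%03d", i)
    template_peak(nm, ref_peaks$t1_min[i], ref_peaks$t2_s[i],
                  ref_spectrum = sp, dmf_min = dmf_min)
  })
  if (!is.null(targeted)) entries <- c(entries, unclass(targeted))
  tpl <- template(entries)
  n <- length(chromatograms)
  counts <- integer(length(tpl))
  matches <- vector("list", n)
  for (r in seq_len(n)) {
    mr <- match_template(tpl, chromatograms[[r]], window = window,
                         degree = degree, max_iter = max_iter)
    matches[[r]] <- mr
    counts[mr$assignments$template] <- counts[mr$assignments$template] + 1L
  }
  need <- ceiling(fraction_required * n)
  features <- data.frame(feature = vapply(tpl, `[[`, "", "name"),
                         match_count = counts,
                         reliable = counts >= need,
                         stringsAsFactors = FALSE)
  structure(list(n_chroms = n, fraction_required = fraction_required,
                 features = features, matches = matches, template = tpl),
            class = "reliable_set")
}

#' @export
print.reliable_set <- function(x, ...) {
  cat(sprintf("<reliable_set: %d features over %d chromatograms, %d reliable (>= %d matches)>\n",
              nrow(x$features), x$n_chroms, sum(x$features$reliable),
              ceiling(x$fraction_required * x$n_chroms)))
  invisible(x)
}

#' Reliable-peak percentages relative to the FID reference
#'
#' Expresses each channel's reliable-peak count as a percentage of the
#' FID reference count, rounded to one decimal.
#'
#' @param fid_count reliable-peak count of the FID reference channel
#'   (> 0).
#' @param other_counts named numeric vector of counts for the other
#'   channels.
#' @return named numeric vector of percentages (the reference itself
#'   reports 100).
#' @export
reliable_report <- function(fid_count, other_counts) {
  stopifnot(fid_count > 0)
  out <- round(100 * other_counts / fid_count, 1)
  c(FID = 100.0, out)
}
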