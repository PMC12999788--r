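#' @title On-disk formats
#' @name io-formats
#' @description
#' Readers and writers for every on-disk representation used by the
#' workflow: FID traces as two-column CSV, MS runs as mzML (via mzR) or
#' plain scan-block text, the pseudo-MS text format that carries an FID
#' signal (or a fused image) as mass-spectral scans, peak tables as
#' CSV, and templates / transforms as JSON. All writers are
#' deterministic: identical input produces byte-identical output.
NULL

fmt_num <- function(x) sprintf("%.17g", x)          # lossless double round trip
fmt_sig9 <- function(x) formatC(x, digits = 9L, format = "g", flag = "#")

#' Read an FID trace from CSV
#'
#' Expects two numeric columns: time in seconds (or a 0-based sample
#' index) and intensity. A header line is optional. When the first
#' column is an index, times are reconstructed as `t0_s + i / rate_hz`.
#'
#' @param path file to read.
#' @param rate_hz sampling rate in Hz.
#' @param t0_s acquisition start offset in seconds.
#' @return a [detector_trace()] with `channel_id = "FID"`.
#' @export
read_fid_csv <- function(path, rate_hz, t0_s = 0) {
  lines <- readLines(path)
  if (!length(lines)) stop("read_fid_csv: empty file: ", path)
  first <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  skip <- if (suppressWarnings(anyNA(as.numeric(first)))) 1L else 0L
  body <- lines[seq.int(skip + 1L, length(lines))]
  body <- body[nzchar(body)]
  parts <- strsplit(body, ",", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) stop("read_fid_csv: malformed row at line ", bad[1] + skip)
  t <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  y <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  if (anyNA(t) || anyNA(y))
    stop("read_fid_csv: non-numeric value at line ",
         which(is.na(t) | is.na(y))[1] + skip)
  # index column: non-negative integers starting at 0
  if (length(t) > 1L && all(t == round(t)) && t[1] == 0 && all(diff(t) == 1))
    t <- t0_s + t / rate_hz
  if (any(diff(t) <= 0)) stop("read_fid_csv: times not strictly increasing")
  detector_trace("FID", rate_hz, t, intensity = y, t0_s = t[1])
}

#' @rdname read_fid_csv
#' @param trace FID [detector_trace()] to write.
#' @export
write_fid_csv <- function(trace, path) {
  stopifnot(is_fid_trace(trace))
  writeLines(c("time_s,intensity",
               paste(fmt_num(trace$times), fmt_num(trace$intensity), sep = ",")),
             path)
  invisible(path)
}

#' Read an MS run from mzML
#'
#' Reads MS1 scans through \pkg{mzR}. Profile spectra are kept as-is
#' (no centroiding); scans are returned in retention-time order.
#'
#' @param path mzML file.
#' @param channel_id channel label to attach (default `"MS"`).
#' @param rate_hz nominal scan rate; when `NULL` it is estimated as the
#'   reciprocal median scan spacing.
#' @return a [detector_trace()].
#' @export
read_ms_mzml <- function(path, channel_id = "MS", rate_hz = NULL) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("read_ms_mzml: the mzR package is required to read mzML")
  handle <- mzR::openMSfile(path)
  on.exit(mzR::close(handle), add = TRUE)
  hdr <- mzR::header(handle)
  if (nrow(hdr) == 0L) stop("read_ms_mzml: no scans in ", path)
  if (anyNA(hdr$retentionTime)) stop("read_ms_mzml: scan without retention time")
  ord <- order(hdr$retentionTime)
  pk <- mzR::peaks(handle)
  if (is.matrix(pk)) pk <- list(pk)
  pk <- pk[ord]
  times <- hdr$retentionTime[ord]
  if (is.null(rate_hz)) rate_hz <- 1 / stats::median(diff(times))
  scans <- lapply(pk, function(s)
    matrix(as.numeric(s), ncol = 2L, dimnames = list(NULL, c("mz", "intensity"))))
  detector_trace(channel_id, rate_hz, times, scans = scans, t0_s = times[1])
}

#' Write an MS run to mzML
#'
#' Thin wrapper over `mzR::writeMSData` used mainly by the simulator.
#'
#' @param trace MS [detector_trace()].
#' @param path output mzML file.
#' @export
write_ms_mzml <- function(trace, path) {
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("write_ms_mzml: the mzR package is required to write mzML")
  stopifnot(!is_fid_trace(trace))
  n <- length(trace$times)
  counts <- vapply(trace$scans, nrow, 0L)
  bp <- vapply(trace$scans, function(s)
    if (nrow(s)) s[which.max(s[, 2L]), 1L] else NA_real_, 0)
  bpi <- vapply(trace$scans, function(s) if (nrow(s)) max(s[, 2L]) else 0, 0)
  lo <- vapply(trace$scans, function(s) if (nrow(s)) min(s[, 1L]) else NA_real_, 0)
  hi <- vapply(trace$scans, function(s) if (nrow(s)) max(s[, 1L]) else NA_real_, 0)
  hdr <- data.frame(
    seqNum = seq_len(n), acquisitionNum = seq_len(n), msLevel = 1L,
    polarity = 1L, peaksCount = counts,
    totIonCurrent = vapply(trace$scans, function(s) sum(s[, 2L]), 0),
    retentionTime = trace$times, basePeakMZ = bp, basePeakIntensity = bpi,
    collisionEnergy = NA_real_, ionisationEnergy = 70,
    lowMZ = lo, highMZ = hi,
    precursorScanNum = NA_integer_, precursorMZ = NA_real_,
    precursorCharge = NA_integer_, precursorIntensity = NA_real_,
    mergedScan = NA_integer_, mergedResultScanNum = NA_integer_,
    mergedResultStartScanNum = NA_integer_, mergedResultEndScanNum = NA_integer_,
    injectionTime = 0, filterString = NA_character_,
    spectrumId = paste0("scan=", seq_len(n)), centroided = TRUE,
    ionMobilityDriftTime = NA_real_,
    isolationWindowTargetMZ = NA_real_, isolationWindowLowerOffset = NA_real_,
    isolationWindowUpperOffset = NA_real_,
    scanWindowLowerLimit = min(lo, na.rm = TRUE),
    scanWindowUpperLimit = max(hi, na.rm = TRUE))
  mzR::writeMSData(unname(trace$scans), path, header = hdr)
  invisible(path)
}

## ---- pseudo-MS text format -------------------------------------------------
## Block format, one block per scan:
##   SCAN=<i>
##   RT=<seconds, 6 decimals>
##   <mz, integer> <intensity, 9 significant digits>   (one line per pair)
##   <blank line>
## An optional 4-line header (CHANNEL/RATE_HZ/PERIOD_S/PHASE_S) precedes
## the first block. write %then% parse %then% write is byte-identical.

#' Write a trace or image as a pseudo-MS text file
#'
#' Represents an FID signal (or any folded spectral image, including a
#' fused one) as mass-spectral scans in a simple block-structured text
#' format. For FID input every emitted scan carries exactly one pair
#' with the virtual fragment m/z 0, making the file loadable by
#' MS-oriented tooling.
#'
#' @param x an FID [detector_trace()] or a [spectral_image()].
#' @param path output file.
#' @param period_s,phase_s header metadata (taken from the grid when
#'   `x` is an image).
#' @export
write_pseudo_ms <- function(x, path, period_s = NA_real_, phase_s = NA_real_) {
  if (inherits(x, "detector_trace")) {
    if (!is_fid_trace(x)) stop("write_pseudo_ms: trace input must be FID (single channel)")
    times <- x$times
    spectra <- lapply(x$intensity, function(v) cbind(mz = 0, intensity = v))
    channel <- x$channel_id
    rate <- x$rate_hz
  } else if (inherits(x, "spectral_image")) {
    g <- x$grid
    n_scan <- g$n_mod * g$pts_per_mod
    times <- g$phase_s + (seq_len(n_scan) - 1L) / g$rate_hz
    spectra <- rep(list(NULL), n_scan)
    d <- x$data
    if (nrow(d)) {
      scan_of <- d$col * g$pts_per_mod + d$row
      sp <- split(seq_len(nrow(d)), scan_of)
      for (k in seq_along(sp)) {
        i <- sp[[k]]
        spectra[[as.integer(names(sp)[k]) + 1L]] <-
          cbind(mz = d$mz[i], intensity = d$intensity[i])
      }
    }
    channel <- x$channel_id
    rate <- g$rate_hz
    period_s <- g$period_s
    phase_s <- g$phase_s
  } else stop("write_pseudo_ms: unsupported input")
  con <- file(path, open = "wb")   # fixed \n endings for byte determinism
  on.exit(close(con), add = TRUE)
  hdr <- c(paste0("CHANNEL=", channel),
           paste0("RATE_HZ=", fmt_sig9(rate)),
           paste0("PERIOD_S=", if (is.na(period_s)) "NA" else sprintf("%.6f", period_s)),
           paste0("PHASE_S=", if (is.na(phase_s)) "NA" else sprintf("%.6f", phase_s)),
           "")
  writeLines(hdr, con, sep = "\n")
  for (i in seq_along(times)) {
    s <- spectra[[i]]
    block <- c(sprintf("SCAN=%d", i - 1L),
               sprintf("RT=%.6f", times[i]),
               if (!is.null(s) && nrow(s))
                 sprintf("%d %s", as.integer(round(s[, 1L])), fmt_sig9(s[, 2L])),
               "")
    writeLines(block, con, sep = "\n")
  }
  invisible(path)
}

#' @rdname write_pseudo_ms
#' @return `parse_pseudo_ms` returns a `pseudo_ms_document`: a list
#'   with `header` (channel_id, rate_hz, period_s, phase_s) and `scans`
#'   (data.frame `index`, `time_s` plus a `pairs` list-column).
#' @export
parse_pseudo_ms <- function(path) {
  lines <- readLines(path)
  pos <- 1L
  header <- list(channel_id = NA_character_, rate_hz = NA_real_,
                 period_s = NA_real_, phase_s = NA_real_)
  if (length(lines) && startsWith(lines[1], "CHANNEL=")) {
    kv <- function(l) sub("^[A-Z_]+=", "", l)
    header$channel_id <- kv(lines[1])
    header$rate_hz <- as.numeric(kv(lines[2]))
    header$period_s <- suppressWarnings(as.numeric(kv(lines[3])))
    header$phase_s <- suppressWarnings(as.numeric(kv(lines[4])))
    if (lines[5] != "") stop("parse_pseudo_ms: malformed header")
    pos <- 6L
  }
  idx <- integer(0); tm <- numeric(0); pairs <- list()
  want <- 0L
  while (pos <= length(lines)) {
    if (!startsWith(lines[pos], "SCAN="))
      stop("parse_pseudo_ms: expected SCAN= at scan index ", want)
    i <- as.integer(sub("SCAN=", "", lines[pos], fixed = TRUE))
    if (is.na(i) || i != want)
      stop("parse_pseudo_ms: non-contiguous scan index at scan ", want)
    if (pos + 1L > length(lines) || !startsWith(lines[pos + 1L], "RT="))
      stop("parse_pseudo_ms: missing RT line at scan ", i)
    t <- as.numeric(sub("RT=", "", lines[pos + 1L], fixed = TRUE))
    if (is.na(t)) stop("parse_pseudo_ms: bad RT at scan ", i)
    pos <- pos + 2L
    mzv <- numeric(0); iv <- numeric(0)
    while (pos <= length(lines) && nzchar(lines[pos])) {
      tok <- strsplit(lines[pos], " ", fixed = TRUE)[[1]]
      if (length(tok) != 2L) stop("parse_pseudo_ms: malformed pair at scan ", i)
      mzv <- c(mzv, as.numeric(tok[1])); iv <- c(iv, as.numeric(tok[2]))
      if (anyNA(mzv) || anyNA(iv)) stop("parse_pseudo_ms: non-numeric pair at scan ", i)
      pos <- pos + 1L
    }
    if (pos > length(lines)) stop("parse_pseudo_ms: missing blank line after scan ", i)
    pos <- pos + 1L   # blank separator
    idx <- c(idx, i); tm <- c(tm, t); pairs[[length(pairs) + 1L]] <- cbind(mz = mzv, intensity = iv)
    want <- want + 1L
  }
  scans <- data.frame(index = idx, time_s = tm)
  scans$pairs <- pairs
  structure(list(header = header, scans = scans), class = "pseudo_ms_document")
}

#' Write a pseudo-MS document back to disk
#'
#' Exact inverse of [parse_pseudo_ms()]; parse-then-write is
#' byte-identical to the original file.
#'
#' @param doc a `pseudo_ms_document`.
#' @param path output file.
#' @export
write_pseudo_ms_document <- function(doc, path) {
  stopifnot(inherits(doc, "pseudo_ms_document"))
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  h <- doc$header
  writeLines(c(paste0("CHANNEL=", h$channel_id),
               paste0("RATE_HZ=", fmt_sig9(h$rate_hz)),
               paste0("PERIOD_S=", if (is.na(h$period_s)) "NA" else sprintf("%.6f", h$period_s)),
               paste0("PHASE_S=", if (is.na(h$phase_s)) "NA" else sprintf("%.6f", h$phase_s)),
               ""), con, sep = "\n")
  for (r in seq_len(nrow(doc$scans))) {
    s <- doc$scans$pairs[[r]]
    writeLines(c(sprintf("SCAN=%d", doc$scans$index[r]),
                 sprintf("RT=%.6f", doc$scans$time_s[r]),
                 if (!is.null(s) && nrow(s))
                   sprintf("%d %s", as.integer(round(s[, 1L])), fmt_sig9(s[, 2L])),
                 ""), con, sep = "\n")
  }
  invisible(path)
}

## ---- peak tables and templates --------------------------------------------

PEAK_CSV_COLS <- c("label", "t1_min", "t2_s", "volume", "snr",
                   "width_half_ms", "width_base_ms")

#' Write / read a peak table as CSV
#'
#' The CSV carries the canonical scalar columns (label, retentions,
#' volume, S/N, widths); apex spectra are not serialized. Reading
#' ignores unknown columns with a warning and errors on a missing
#' mandatory column.
#'
#' @param peaks peak table (see [peak_table()]).
#' @param path file path.
#' @export
write_peak_table <- function(peaks, path) {
  df <- as.data.frame(peaks)[, intersect(PEAK_CSV_COLS, names(peaks)), drop = FALSE]
  for (col in setdiff(PEAK_CSV_COLS, names(df))) df[[col]] <- NA_real_
  df <- df[, PEAK_CSV_COLS, drop = FALSE]
  num <- vapply(df, is.numeric, TRUE)
  out <- df
  out[num] <- lapply(df[num], function(x) ifelse(is.na(x), "NA", fmt_num(x)))
  lines <- c(paste(PEAK_CSV_COLS, collapse = ","),
             do.call(paste, c(unname(out), sep = ",")))
  if (nrow(df) == 0L) lines <- lines[1]
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_peak_table
#' @export
read_peak_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  extra <- setdiff(names(df), PEAK_CSV_COLS)
  if (length(extra))
    warning("read_peak_table: ignoring unknown column(s): ", paste(extra, collapse = ", "))
  missing <- setdiff(PEAK_CSV_COLS, names(df))
  if (length(missing))
    stop("read_peak_table: missing mandatory column(s): ", paste(missing, collapse = ", "))
  out <- peak_table(nrow(df))
  for (col in setdiff(PEAK_CSV_COLS, "label")) out[[col]] <- as.numeric(df[[col]])
  out$label <- as.character(df$label)
  out
}

#' Templates of expected peaks
#'
#' A template is a list of expected peaks, each with a name, an
#' expected retention point, an optional reference spectrum and a
#' direct-match-factor threshold used during spectrally constrained
#' matching.
#'
#' @param name compound / feature name.
#' @param t1_min,t2_s expected retention.
#' @param ref_spectrum optional two-column `mz`/`intensity` matrix.
#' @param dmf_min minimum direct match factor (0-999 scale) for a
#'   spectral match to be accepted; default 700.
#' @return `template_peak`: a single template entry;
#'   `template`: a `gc_template` object (list of entries).
#' @export
template_peak <- function(name, t1_min, t2_s, ref_spectrum = NULL, dmf_min = 700) {
  if (!is.null(ref_spectrum)) {
    ref_spectrum <- matrix(as.numeric(ref_spectrum), ncol = 2L,
                           dimnames = list(NULL, c("mz", "intensity")))
    if (!nrow(ref_spectrum)) ref_spectrum <- NULL
  }
  structure(list(name = as.character(name), t1_min = as.numeric(t1_min),
                 t2_s = as.numeric(t2_s), ref_spectrum = ref_spectrum,
                 dmf_min = as.numeric(dmf_min)),
            class = "template_peak")
}

#' @rdname template_peak
#' @param ... `template_peak` entries (or a single list of them).
#' @export
template <- function(...) {
  entries <- list(...)
  if (length(entries) == 1L && !inherits(entries[[1]], "template_peak"))
    entries <- entries[[1]]
  stopifnot(all(vapply(entries, inherits, TRUE, "template_peak")))
  structure(entries, class = "gc_template")
}

#' @export
print.gc_template <- function(x, ...) {
  cat(sprintf("<gc_template: %d entries, %d with reference spectra>\n",
              length(x), sum(!vapply(x, function(e) is.null(e$ref_spectrum), TRUE))))
  invisible(x)
}

#' Read / write templates as JSON
#'
#' @param tpl a `gc_template`.
#' @param path file path.
#' @export
write_template <- function(tpl, path) {
  stopifnot(inherits(tpl, "gc_template"))
  lst <- lapply(tpl, function(e) {
    out <- list(name = e$name, t1_min = e$t1_min, t2_s = e$t2_s, dmf_min = e$dmf_min)
    if (!is.null(e$ref_spectrum))
      out$ref_spectrum <- list(mz = e$ref_spectrum[, 1L],
                               intensity = e$ref_spectrum[, 2L])
    out
  })
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_template
#' @export
read_template <- function(path) {
  lst <- jsonlite::read_json(path, simplifyVector = FALSE)
  template(lapply(lst, function(e) {
    rs <- if (!is.null(e$ref_spectrum))
      cbind(mz = unlist(e$ref_spectrum$mz), intensity = unlist(e$ref_spectrum$intensity))
    template_peak(e$name, e$t1_min, e$t2_s, ref_spectrum = rs,
                  dmf_min = if (is.null(e$dmf_min)) 700 else e$dmf_min)
  }))
}

#' Serialize retention transforms to JSON
#'
#' @param tf a `poly_transform` or `zonal_transform`.
#' @param path file path.
#' @export
write_transform <- function(tf, path) {
  jsonlite::write_json(transform_to_list(tf), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  transform_from_list(jsonlite::read_json(path, simplifyVector = FALSE))
}

#' Misalignment report CSV
#'
#' Writes per-compound relative-misalignment records (name, RM in ms,
#' mean peak widths) plus summary rows: the mean over all compounds and,
#' when a `wrapped` column is present, the mean excluding wrap-around
#' peaks.
#'
#' @param records data.frame from [relative_misalignment()].
#' @param path file path.
#' @export
write_misalignment_report <- function(records, path) {
  df <- records
  df$rm_ms <- fmt_num(df$rm_ms)
  df$width_half_ms <- fmt_num(df$width_half_ms)
  df$width_base_ms <- fmt_num(df$width_base_ms)
  s <- summarize_misalignment(records)
  lines <- c("name,rm_ms,width_half_ms,width_base_ms",
             paste(df$name, df$rm_ms, df$width_half_ms, df$width_base_ms, sep = ","),
             sprintf("Mean,%d,%d,%d", s$rm_ms, s$width_half_ms, s$width_base_ms))
  if (!is.null(records$wrapped) && any(records$wrapped)) {
    s2 <- summarize_misalignment(records[!records$wrapped, , drop = FALSE])
    lines <- c(lines, sprintf("Mean (excl. wrap-around),%d,%d,%d",
                              s2$rm_ms, s2$width_half_ms, s2$width_base_ms))
  }
  writeLines(lines, path)
  invisible(path)
}
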