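#' @title Calibration linearity QC and retention indices
#' @name calibration
#' @description
#' Ordinary least-squares calibration fits of normalized 2D peak
#' volumes against normalized concentrations, the coefficient of
#' determination as the linearity quality parameter, a +/-20% relative
#' residual rule, banding of R-squared values into good / acceptable /
#' critical classes, and van den Dool-Kratz linear retention indices.
NULL

#' Build a calibration series
#'
#' @param analyte analyte name.
#' @param x normalized concentrations (one per measurement; replicates
#'   per level allowed). At least 3 distinct levels, all >= 0.
#' @param y normalized 2D volumes (responses).
#' @return a `calibration_series` list.
#' @export
calibration_series <- function(analyte, x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) == length(y), all(x >= 0))
  if (length(unique(x)) < 3L)
    stop("calibration_series: need at least 3 distinct concentration levels")
  structure(list(analyte = as.character(analyte), x = x, y = y),
            class = "calibration_series")
}

#' Fit a calibration line and score its linearity
#'
#' Fits `y = a * x + b` by unweighted ordinary least squares (a `1/x`
#' weighting is available since calibration residuals are typically
#' heteroscedastic), computes `R^2 = 1 - SS_res / SS_tot`, checks that
#' every relative residual `|y_hat - y| / y_hat` stays within +/-20%,
#' and classifies the fit with [classify_r2()].
#'
#' @param series a [calibration_series()].
#' @param weighting `"none"` (default) or `"1/x"`.
#' @return a `calibration_fit`: list with `analyte`, `slope`,
#'   `intercept`, `r2`, `residuals_ok`, `r2_class`.
#' @export
fit_calibration <- function(series, weighting = c("none", "1/x")) {
  weighting <- match.arg(weighting)
  if (stats::var(series$x) == 0) stop("fit_calibration: zero variance in x")
  w <- if (weighting == "1/x") 1 / pmax(series$x, min(series$x[series$x > 0])) else NULL
  fit <- stats::lm(y ~ x, data = data.frame(x = series$x, y = series$y), weights = w)
  yhat <- stats::fitted(fit)
  ss_res <- sum((series$y - yhat)^2)
  ss_tot <- sum((series$y - mean(series$y))^2)
  r2 <- 1 - ss_res / ss_tot
  rel <- abs(yhat - series$y) / abs(yhat)
  structure(list(analyte = series$analyte,
                 slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r2 = r2,
                 residuals_ok = all(rel <= 0.20),
                 r2_class = classify_r2(r2)),
            class = "calibration_fit")
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("<calibration_fit %s: y = %.4g x + %.4g, R2 = %.4f (%s)%s>\n",
              x$analyte, x$slope, x$intercept, x$r2, x$r2_class,
              if (x$residuals_ok) "" else ", residuals outside +/-20%"))
  invisible(x)
}

#' Classify a coefficient of determination
#'
#' Bands used for calibration-linearity QC: `"good"` for R2 > 0.995,
#' `"acceptable"` for 0.990 <= R2 <= 0.995, `"critical"` for
#' R2 < 0.990.
#'
#' @param r2 coefficient of determination in `[0, 1]`.
#' @return one of `"good"`, `"acceptable"`, `"critical"`.
#' @export
classify_r2 <- function(r2) {
  stopifnot(all(r2 >= 0 & r2 <= 1))
  ifelse(r2 > 0.995, "good", ifelse(r2 < 0.990, "critical", "acceptable"))
}

#' Class distribution of calibration fits
#'
#' @param fits list of `calibration_fit`s (or a character vector of
#'   classes).
#' @return named numeric vector of percentages per class (one decimal),
#'   always covering all three classes.
#' @export
class_distribution <- function(fits) {
  classes <- if (is.character(fits)) fits
             else vapply(fits, `[[`, "", "r2_class")
  if (!length(classes)) stop("class_distribution: no fits")
  lv <- c("good", "acceptable", "critical")
  counts <- table(factor(classes, levels = lv))
  round(100 * as.numeric(counts) / length(classes), 1) |>
    stats::setNames(lv)
}

#' Van den Dool-Kratz linear retention index
#'
#' `I_T = 100 * (n + (t - t_n) / (t_{n+1} - t_n))` using the n-alkanes
#' bracketing the observed first-dimension retention under temperature
#' programming.
#'
#' @param t1_min observed first-dimension retention, minutes.
#' @param alkane_times data.frame with columns `n` (carbon number) and
#'   `t1_min`, covering the bracket.
#' @return the linear retention index.
#' @export
linear_retention_index <- function(t1_min, alkane_times) {
  at <- alkane_times[order(alkane_times$t1_min), , drop = FALSE]
  if (t1_min < min(at$t1_min) || t1_min > max(at$t1_min))
    stop("linear_retention_index: retention outside the alkane bracket")
  i <- findInterval(t1_min, at$t1_min, rightmost.closed = TRUE)
  n <- at$n[i]
  100 * (n + (t1_min - at$t1_min[i]) / (at$t1_min[i + 1L] - at$t1_min[i]) *
           (at$n[i + 1L] - n))
}

#' Read a calibration table from CSV
#'
#' Expects columns `analyte`, `level`, `x`, `y`; returns one
#' [calibration_series()] per analyte.
#'
#' @param path CSV file.
#' @return named list of `calibration_series`.
#' @export
read_calibration_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("analyte", "x", "y")
  if (!all(need %in% names(df)))
    stop("read_calibration_csv: missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  out <- lapply(split(df, df$analyte), function(d)
    calibration_series(d$analyte[1], d$x, d$y))
  out[unique(df$analyte)]
}

#' Write a calibration report as CSV
#'
#' One row per fit: analyte, slope, intercept, R2, residual flag and
#' class.
#'
#' @param fits list of `calibration_fit`s.
#' @param path output CSV.
#' @export
write_calibration_report <- function(fits, path) {
  lines <- c("analyte,slope,intercept,r2,residuals_ok,r2_class",
             vapply(fits, function(f)
               sprintf("%s,%s,%s,%s,%s,%s", f$analyte, fmt_num(f$slope),
                       fmt_num(f$intercept), fmt_num(f$r2),
                       f$residuals_ok, f$r2_class), ""))
  writeLines(lines, path)
  invisible(path)
}
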