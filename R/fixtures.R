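#' Bundled example tables
#'
#' Small report-format tables shipped with the package: a per-compound
#' relative-misalignment panel (12 fragrance allergens measured under
#' three instrumental set-ups A, B and C) and the matching
#' calibration-linearity R-squared panel. They are used in examples and
#' as inputs to the reporting functions.
#'
#' @param setup one of `"A"`, `"B"`, `"C"` (set-up C is the
#'   dual-secondary-column configuration with compound-dependent
#'   misalignment and one wrap-around peak).
#' @return `example_misalignment`: a data.frame of misalignment
#'   records (`name`, `rm_ms`, `width_half_ms`, `width_base_ms`,
#'   `wrapped`) ready for [summarize_misalignment()].
#' @export
example_misalignment <- function(setup = c("A", "B", "C")) {
  setup <- match.arg(setup)
  df <- utils::read.csv(system.file("extdata", "allergen_panel_misalignment.csv",
                                    package = "gcxgcfuse"),
                        stringsAsFactors = FALSE)
  out <- data.frame(name = df$name,
                    rm_ms = df[[paste0("rm_ms_", setup)]],
                    width_half_ms = df[[paste0("width_half_ms_", setup)]],
                    width_base_ms = df[[paste0("width_base_ms_", setup)]],
                    wrapped = if (setup == "C") df$wrapped_C else FALSE,
                    stringsAsFactors = FALSE)
  out
}

#' @rdname example_misalignment
#' @return `example_r2_panel`: a data.frame of R-squared values per
#'   analyte and detector channel across the three set-ups.
#' @export
example_r2_panel <- function() {
  utils::read.csv(system.file("extdata", "allergen_panel_r2.csv", package = "gcxgcfuse"),
                  stringsAsFactors = FALSE)
}
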