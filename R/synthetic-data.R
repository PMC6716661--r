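#' Synthetic hospital length-of-stay fixtures
#'
#' Generates GG-distributed stand-ins for the three male traumatic-brain-
#' injury hospital-stay data sets used as the package's motivating
#' application: `"D1"` (total days in hospital, n = 19), `"D2"` (days in
#' the Neurology Inpatient Department, n = 19) and `"D3"` (days on
#' mechanical ventilation, n = 16).  The default parameter triples are the
#' published PML point estimates for those variables, so the fixtures mimic
#' the real data's scale and shape; they are synthetic draws, not patient
#' data.
#'
#' The real stays are recorded as whole days with minima of 4, 2 and 1
#' day, so the default rounding is *ceiling* to whole days (a stay of 0.3
#' days is recorded as 1), which keeps every value a positive integer and
#' introduces genuine ties — useful for exercising the tie handling of the
#' spacings estimator.
#'
#' @param dataset `"D1"`, `"D2"`, `"D3"` or `"custom"`.
#' @param params Parameter triple `c(phi, mu, alpha)`; required for
#'   `"custom"`, defaulting to the published estimates otherwise.
#' @param n Sample size; defaults to the real data set's size.
#' @param rounding `"ceiling"` (whole days, default) or `"none"`.
#' @param seed Integer seed for reproducibility.
#' @param file Optional path; when given, the sample is also written as a
#'   one-column CSV with header `days`.
#' @return A tibble with column `days`.
#' @examples
#' make_tbi_sample("D3", seed = 42)
#' @export
make_tbi_sample <- function(dataset = c("D1", "D2", "D3", "custom"),
                            params = NULL, n = NULL,
                            rounding = c("ceiling", "none"),
                            seed = NULL, file = NULL) {
  dataset <- match.arg(dataset)
  rounding <- match.arg(rounding)
  defaults <- list(
    D1 = list(params = c(0.410, 0.025, 3.040), n = 19L),
    D2 = list(params = c(0.268, 0.045, 4.658), n = 19L),
    D3 = list(params = c(0.148, 0.053, 6.065), n = 16L)
  )
  if (dataset == "custom") {
    if (is.null(params) || is.null(n)) {
      abort("`params` and `n` are required for dataset = \"custom\".",
            class = "ggfit_error_input")
    }
  } else {
    params <- params %||% defaults[[dataset]]$params
    n <- n %||% defaults[[dataset]]$n
  }
  check_gg_params(params[1], params[2], params[3])
  if (!is.null(seed)) set.seed(seed)
  days <- rgengam(n, params[1], params[2], params[3])
  if (rounding == "ceiling") days <- ceiling(days)
  out <- tibble(days = days)
  if (!is.null(file)) write.csv(out, file, row.names = FALSE)
  out
}

#' Convert a spreadsheet of stay durations to the canonical CSV layout
#'
#' Helper for users who have the original hospital-stay spreadsheet (XLS):
#' reads the requested sheet/column with the readxl package (if installed)
#' and writes a one-column CSV with header `days` that every ggfit command
#' accepts.
#'
#' @param xls_path Path to the spreadsheet.
#' @param csv_path Output CSV path.
#' @param sheet Sheet name or index.
#' @param column Column name or index holding the durations.
#' @return `csv_path`, invisibly.
#' @export
convert_stay_xls <- function(xls_path, csv_path, sheet = 1, column = 1) {
  if (!requireNamespace("readxl", quietly = TRUE)) {
    abort("The readxl package is required to read XLS files.",
          class = "ggfit_error_input")
  }
  raw <- readxl::read_excel(xls_path, sheet = sheet)
  days <- if (is.numeric(column)) raw[[column]] else raw[[as.character(column)]]
  days <- as.numeric(days)
  days <- days[is.finite(days)]
  validate_lifetimes(days)
  write.csv(tibble(days = days), csv_path, row.names = FALSE)
  invisible(csv_path)
}
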