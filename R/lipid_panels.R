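#' Validate a cohort of standard lipid panels
#'
#' Checks one-record-per-participant lipid panel data for physiological
#' validity and attaches the derived non-HDL cholesterol column. All
#' concentrations are in mg/dL throughout the package; no mmol/L conversion
#' is offered.
#'
#' Required columns are `tc` (total cholesterol), `hdl` (HDL cholesterol) and
#' `tg` (triglycerides). A record is valid when `tc > 0`, `hdl > 0`,
#' `tg >= 0` and `hdl < tc`. An optional `ldl_measured` column carries the
#' directly measured LDL-C reference value.
#'
#' @param data A data frame with columns `tc`, `hdl`, `tg` and optionally
#'   `ldl_measured`, all in mg/dL.
#' @return The input as a tibble with a `non_hdl` column (`tc - hdl`),
#'   recomputed so the identity holds exactly.
#' @examples
#' validate_lipid_panels(data.frame(tc = 200, hdl = 50, tg = 100))
#' @export
validate_lipid_panels <- function(data) {
  data <- as_tibble(data)
  assert_columns(data, c("tc", "hdl", "tg"), "lipid panel data")
  for (col in c("tc", "hdl", "tg")) {
    if (!is.numeric(data[[col]])) {
      abort(sprintf("column `%s` must be numeric (mg/dL)", col),
            class = "ldlbench_validation_error")
    }
  }
  bad_field <- function(flag, field, rule) {
    if (any(flag, na.rm = TRUE) || anyNA(flag)) {
      i <- which(flag | is.na(flag))[1]
      abort(sprintf("invalid lipid panel: field `%s` violates %s (first offending record: row %d)",
                    field, rule, i),
            class = "ldlbench_validation_error")
    }
  }
  bad_field(data$tc <= 0, "tc", "tc > 0")
  bad_field(data$hdl <= 0, "hdl", "hdl > 0")
  bad_field(data$tg < 0, "tg", "tg >= 0")
  bad_field(data$hdl >= data$tc, "hdl", "hdl < tc")
  mutate(data, non_hdl = .data$tc - .data$hdl)
}

#' Read and write cohort files
#'
#' Cohorts are exchanged as delimited text (comma by default) with one row
#' per participant and header columns `tc`, `hdl`, `tg` and optionally
#' `ldl_measured` plus any covariates; missing values are empty fields.
#'
#' @param path File path.
#' @param data Cohort data frame.
#' @param delim Single-character field delimiter.
#' @return `read_cohort()` returns a tibble; `write_cohort()` returns `path`
#'   invisibly.
#' @export
read_cohort <- function(path, delim = ",") {
  readr::read_delim(path, delim = delim, show_col_types = FALSE,
                    na = c("", "NA"), progress = FALSE)
}

#' @rdname read_cohort
#' @export
write_cohort <- function(data, path, delim = ",") {
  readr::write_delim(data, path, delim = delim, na = "")
  invisible(path)
}
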