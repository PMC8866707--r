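#' Closed-form LDL-C estimators from the standard lipid panel
#'
#' `estimate_friedewald()` applies the Friedewald equation
#' \deqn{LDL = TC - HDL - TG/5,} which assumes a fixed 5:1
#' triglyceride-to-VLDL-cholesterol ratio and is regarded as inapplicable at
#' TG >= 400 mg/dL: such records are flagged in `friedewald_valid` but the
#' estimate is still returned so whole-range comparisons can include them.
#'
#' `estimate_sampson_nih()` applies the NIH equation developed by Sampson and
#' colleagues for hypertriglyceridemia and low LDL-C:
#' \deqn{LDL = TC/0.948 - HDL/0.971 - (TG/8.56 + TG \cdot nonHDL/2140 -
#'   TG^2/16100) - 9.44.}
#'
#' `estimate_martin()` applies the Martin-style adjustable-factor method
#' \deqn{LDL = TC - HDL - TG/f,} where the divisor `f` is a strata-specific
#' median VLDL-C:TG ratio looked up in a two-dimensional table indexed by TG
#' and non-HDL-C (see [derive_strata_table()]). Strata are left-closed,
#' right-open; values outside all strata clamp to the nearest edge stratum.
#'
#' @param data A data frame of lipid panels (columns `tc`, `hdl`, `tg`, in
#'   mg/dL); validated with [validate_lipid_panels()].
#' @param table A `strata_table` object for the Martin method.
#' @return The input tibble with an added estimate column
#'   (`ldl_friedewald`, `ldl_sampson` or `ldl_martin`); Friedewald also adds
#'   the logical `friedewald_valid` (TRUE when TG < 400 mg/dL).
#' @examples
#' panels <- data.frame(tc = 200, hdl = 50, tg = 100)
#' estimate_friedewald(panels)$ldl_friedewald  # 130
#' estimate_sampson_nih(panels)$ldl_sampson
#' @name ldl_equations
NULL

#' @rdname ldl_equations
#' @export
estimate_friedewald <- function(data) {
  data <- validate_lipid_panels(data)
  mutate(data,
         ldl_friedewald = .data$tc - .data$hdl - .data$tg / 5,
         friedewald_valid = .data$tg < 400)
}

#' @rdname ldl_equations
#' @export
estimate_sampson_nih <- function(data) {
  data <- validate_lipid_panels(data)
  mutate(data,
         ldl_sampson = .data$tc / 0.948 - .data$hdl / 0.971 -
           (.data$tg / 8.56 + .data$tg * .data$non_hdl / 2140 -
              .data$tg^2 / 16100) - 9.44)
}

#' @rdname ldl_equations
#' @export
estimate_martin <- function(data, table) {
  data <- validate_lipid_panels(data)
  f <- lookup_factor(table, data$tg, data$non_hdl)
  mutate(data, ldl_martin = .data$tc - .data$hdl - .data$tg / f)
}
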