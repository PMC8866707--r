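#' Pooled-cohort-equation coefficient sets
#'
#' Ten-year atherosclerotic cardiovascular disease (ASCVD) risk is computed
#' from a pluggable coefficient file rather than hard-coded constants: the
#' model form, per-sex term lists (covariate, transform, optional
#' interaction, coefficient) and baseline constants all live in a
#' human-readable YAML file that is schema-validated on load.
#'
#' Allowed transforms are `identity`, `log`, `square` and products with a
#' second covariate (`interact_with`). Supported model forms are
#' `revised-logistic` (linear predictor through an inverse-logit link) and
#' `original-cox-style` (risk `1 - s0^exp(lp - lp_mean)` with per-sex
#' baseline survival `s0` and mean linear predictor `lp_mean`).
#'
#' The file shipped at
#' `system.file("extdata", "pce_coefficients_synthetic.yaml", package =
#' "ldlbench")` is a synthetic, NOT-CLINICAL placeholder with a plausible
#' sign structure, suitable only for exercising the pipeline; validation of
#' this module is structural and monotonic, not coefficient-exact. A race
#' term is omitted by default.
#'
#' @param path Path to a coefficient YAML file.
#' @return A `pce_coefficients` object.
#' @export
read_pce_coefficients <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("coefficient file not found: %s", path),
          class = "ldlbench_config_error")
  }
  raw <- yaml::read_yaml(path)
  form <- raw$model_form
  if (is.null(form) || !form %in% c("revised-logistic", "original-cox-style")) {
    abort("coefficient file: `model_form` must be 'revised-logistic' or 'original-cox-style'",
          class = "ldlbench_config_error")
  }
  sexes <- raw$sexes
  if (is.null(sexes) || !all(c("male", "female") %in% names(sexes))) {
    abort("coefficient file: `sexes` must provide both 'male' and 'female' blocks",
          class = "ldlbench_config_error")
  }
  allowed <- c("identity", "log", "square")
  for (sx in c("male", "female")) {
    blk <- sexes[[sx]]
    if (form == "revised-logistic" && is.null(blk$intercept)) {
      abort(sprintf("coefficient file: sex '%s' needs an `intercept`", sx),
            class = "ldlbench_config_error")
    }
    if (form == "original-cox-style" &&
        (is.null(blk$baseline_survival) || is.null(blk$mean_lp))) {
      abort(sprintf("coefficient file: sex '%s' needs `baseline_survival` and `mean_lp`", sx),
            class = "ldlbench_config_error")
    }
    if (is.null(blk$terms) || length(blk$terms) == 0) {
      abort(sprintf("coefficient file: sex '%s' has no terms", sx),
            class = "ldlbench_config_error")
    }
    for (tm in blk$terms) {
      if (is.null(tm$covariate) || is.null(tm$transform) || is.null(tm$coefficient)) {
        abort(sprintf("coefficient file: every term needs covariate/transform/coefficient (sex '%s')", sx),
              class = "ldlbench_config_error")
      }
      if (!tm$transform %in% allowed) {
        abort(sprintf("coefficient file: unknown transform '%s' (allowed: %s, plus `interact_with` products)",
                      tm$transform, paste(allowed, collapse = ", ")),
              class = "ldlbench_config_error")
      }
      if (!is.numeric(tm$coefficient)) {
        abort("coefficient file: coefficients must be numeric",
              class = "ldlbench_config_error")
      }
    }
  }
  structure(list(model_form = form, sexes = sexes,
                 label = raw$label %||% basename(path),
                 clinical_use = isTRUE(raw$clinical_use)),
            class = "pce_coefficients")
}

#' @export
print.pce_coefficients <- function(x, ...) {
  cat(sprintf("<pce_coefficients: %s, form = %s%s>\n", x$label, x$model_form,
              if (!x$clinical_use) ", NOT for clinical use" else ""))
  invisible(x)
}

pce_required_covariates <- function() {
  c("age", "sex", "systolic_bp", "bp_treated", "diabetes", "smoker",
    "tc", "hdl")
}

eval_pce_term <- function(term, data) {
  cov <- term$covariate
  if (!cov %in% names(data)) {
    abort(sprintf("pce_risk: missing covariate `%s`", cov),
          class = "ldlbench_validation_error")
  }
  v <- as.numeric(data[[cov]])
  v <- switch(term$transform,
              identity = v,
              log = log(v),
              square = v^2,
              abort(sprintf("pce_risk: unknown term transform '%s'", term$transform),
                    class = "ldlbench_config_error"))
  if (!is.null(term$interact_with)) {
    iw <- term$interact_with
    if (!iw %in% names(data)) {
      abort(sprintf("pce_risk: missing covariate `%s` (interaction)", iw),
            class = "ldlbench_validation_error")
    }
    v <- v * as.numeric(data[[iw]])
  }
  term$coefficient * v
}

#' Compute 10-year ASCVD risk
#'
#' Builds the sex-specific linear predictor from the coefficient term list
#' and maps it through the model form's link. The computation is
#' deterministic, row-wise, and uses only the risk covariates (age, sex,
#' systolic blood pressure, treatment status, diabetes, smoking, TC and
#' HDL-C) — never any estimated LDL value.
#'
#' @param data Cohort with the covariates above. `sex` is `"male"`/
#'   `"female"` (or 1/0); `bp_treated`, `diabetes` and `smoker` are
#'   logical/0-1. The derived indicator `bp_untreated` is provided
#'   automatically.
#' @param coefs A [read_pce_coefficients()] object.
#' @return The input tibble with a `pce_risk` probability column.
#' @export
pce_risk <- function(data, coefs) {
  if (!inherits(coefs, "pce_coefficients")) {
    abort("`coefs` must be a pce_coefficients object",
          class = "ldlbench_config_error")
  }
  data <- as_tibble(data)
  assert_columns(data, pce_required_covariates(), "risk cohort")
  if (anyNA(data[pce_required_covariates()])) {
    abort("pce_risk: risk covariates contain missing values",
          class = "ldlbench_validation_error")
  }
  sex <- data$sex
  if (is.numeric(sex)) sex <- ifelse(sex == 1, "male", "female")
  sex <- tolower(as.character(sex))
  if (!all(sex %in% c("male", "female"))) {
    abort("pce_risk: `sex` must be 'male'/'female' (or 1/0)",
          class = "ldlbench_validation_error")
  }
  work <- mutate(data,
                 bp_treated = as.numeric(.data$bp_treated),
                 bp_untreated = 1 - as.numeric(.data$bp_treated),
                 diabetes = as.numeric(.data$diabetes),
                 smoker = as.numeric(.data$smoker))
  risk <- rep(NA_real_, nrow(work))
  for (sx in c("male", "female")) {
    idx <- sex == sx
    if (!any(idx)) next
    blk <- coefs$sexes[[sx]]
    sub <- work[idx, , drop = FALSE]
    lp <- rep(0, nrow(sub))
    for (tm in blk$terms) lp <- lp + eval_pce_term(tm, sub)
    risk[idx] <- if (coefs$model_form == "revised-logistic") {
      plogis(blk$intercept + lp)
    } else {
      1 - blk$baseline_survival^exp(lp - blk$mean_lp)
    }
  }
  mutate(data, pce_risk = pmin(pmax(risk, 0), 1))
}

#' Equal-frequency quantile bins
#'
#' Ranks the values and cuts them into `n_bins` equal-frequency groups
#' ("vigintiles" at the default 20). Bin sizes differ by at most one (the
#' first `n %% n_bins` bins take the extra record); ties are assigned by
#' stable record order, so the same input always yields the same labels.
#'
#' @param x Numeric vector (e.g. PCE risk scores).
#' @param n_bins Number of bins (default 20).
#' @return Integer vector of bin labels in `1..n_bins`.
#' @export
quantile_bins <- function(x, n_bins = 20) {
  assert_numeric_vector(x, "x")
  n <- length(x)
  if (n < n_bins) {
    abort(sprintf("cannot form %d bins from %d records; use fewer bins",
                  n_bins, n),
          class = "ldlbench_validation_error")
  }
  base <- n %/% n_bins
  rem <- n %% n_bins
  sizes <- rep(base, n_bins) + c(rep(1L, rem), rep(0L, n_bins - rem))
  labels_sorted <- rep.int(seq_len(n_bins), sizes)
  out <- integer(n)
  out[order(x)] <- labels_sorted   # order() is stable: ties keep record order
  out
}

#' @rdname quantile_bins
#' @param data Cohort containing `risk_col`.
#' @param risk_col Column holding the risk score.
#' @return `add_risk_bins()`: the input tibble with an integer `risk_bin`
#'   column.
#' @export
add_risk_bins <- function(data, risk_col = "pce_risk", n_bins = 20) {
  data <- as_tibble(data)
  assert_columns(data, risk_col, "risk cohort")
  mutate(data, risk_bin = quantile_bins(data[[risk_col]], n_bins))
}

#' @rdname read_pce_coefficients
#' @export
default_pce_path <- function() {
  system.file("extdata", "pce_coefficients_synthetic.yaml",
              package = "ldlbench", mustWork = TRUE)
}
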