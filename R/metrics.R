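#' Method-comparison accuracy indices
#'
#' The four indices used throughout this package to compare an LDL-C
#' estimator against directly measured LDL-C:
#'
#' * **bias** — the mean per-record error (estimate − measured), with a
#'   one-sample t-test of the mean error against zero;
#' * **RMSE** — the square root of the mean squared error;
#' * **Pn accuracy** — the fraction of records whose estimate falls within
#'   ±n% of that record's measured value (boundary counts as inside);
#' * **concordance** — within each clinical category, the fraction of
#'   records whose estimate lands in the same category as the measurement.
#'
#' @param estimates,measured Equal-length numeric vectors (mg/dL).
#' @name accuracy_indices
NULL

#' @rdname accuracy_indices
#' @return `ldl_bias()`: a one-row tibble with `n`, `bias_mean`, `bias_t`
#'   and two-sided `bias_p`. When the errors have zero variance and zero
#'   mean, the t statistic is defined as 0.
#' @examples
#' ldl_bias(c(101, 102, 103, 104, 105), c(100, 100, 100, 100, 100))
#' ldl_rmse(c(103, 104), c(100, 100))  # sqrt(12.5)
#' @export
ldl_bias <- function(estimates, measured) {
  assert_paired(estimates, measured)
  n <- length(estimates)
  if (n < 2) {
    abort("bias test needs at least two paired records",
          class = "ldlbench_validation_error")
  }
  err <- estimates - measured
  m <- mean(err)
  s <- sd(err)
  if (s == 0) {
    t_stat <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
  } else {
    t_stat <- m / (s / sqrt(n))
    p <- 2 * pt(-abs(t_stat), df = n - 1)
  }
  tibble(n = n, bias_mean = m, bias_t = t_stat, bias_p = p)
}

#' @rdname accuracy_indices
#' @return `ldl_rmse()`: a single non-negative number (mg/dL).
#' @export
ldl_rmse <- function(estimates, measured) {
  assert_paired(estimates, measured)
  if (length(estimates) == 0) {
    abort("rmse needs at least one paired record",
          class = "ldlbench_validation_error")
  }
  sqrt(mean((estimates - measured)^2))
}

#' @rdname accuracy_indices
#' @param n_percent Tolerance half-width as a percentage of the measured
#'   value (10, 15 or 20 in the standard report).
#' @return `pn_accuracy()`: a proportion in `[0, 1]`.
#' @export
pn_accuracy <- function(estimates, measured, n_percent) {
  assert_paired(estimates, measured)
  if (any(measured <= 0)) {
    abort("pn_accuracy requires measured > 0 for every record",
          class = "ldlbench_validation_error")
  }
  mean(abs(estimates - measured) <= (n_percent / 100) * measured)
}

#' Clinical category schemes
#'
#' A category scheme is a set of left-closed, right-open bins defined by
#' strictly increasing breakpoints, the last bin open-ended. The default
#' LDL-C scheme has five bins: `[0,100)`, `[100,130)`, `[130,160)`,
#' `[160,190)` and `[190, Inf)` mg/dL, following the dyslipidemia-guideline
#' cutpoints with everything below 100 mg/dL pooled into the lowest bin.
#' TG and non-HDL-C schemes default to 50 mg/dL-wide bins and are
#' configurable. Values below the first breakpoint (possible for estimates,
#' e.g. Friedewald at extreme TG) are absorbed into the lowest bin, matching
#' the clamping convention used for strata lookup.
#'
#' @param name Scheme name.
#' @param breaks Strictly increasing bin lower bounds; the first value is
#'   the lower bound of the lowest bin.
#' @return A `category_scheme` object.
#' @export
category_scheme <- function(name, breaks) {
  breaks <- as.numeric(breaks)
  if (length(breaks) < 1 || is.unsorted(breaks, strictly = TRUE)) {
    abort("`breaks` must be strictly increasing",
          class = "ldlbench_config_error")
  }
  upper <- c(breaks[-1], Inf)
  labels <- ifelse(is.finite(upper),
                   sprintf("[%g,%g)", breaks, upper),
                   sprintf(">=%g", breaks))
  structure(list(name = name, breaks = breaks, labels = labels),
            class = "category_scheme")
}

#' @rdname category_scheme
#' @export
ldl_scheme <- function() category_scheme("ldl", c(0, 100, 130, 160, 190))

#' @rdname category_scheme
#' @export
tg_scheme <- function() {
  category_scheme("tg", seq(0, 400, by = 50))
}

#' @rdname category_scheme
#' @export
nonhdl_scheme <- function() {
  category_scheme("non_hdl", c(0, 40, 90, 140, 190, 240))
}

#' @rdname category_scheme
#' @param x Numeric vector to categorise.
#' @param scheme A `category_scheme`.
#' @return `categorize()`: a factor with one level per bin.
#' @export
categorize <- function(x, scheme) {
  if (!inherits(scheme, "category_scheme")) {
    abort("`scheme` must be a category_scheme", class = "ldlbench_config_error")
  }
  i <- findInterval(x, scheme$breaks, left.open = FALSE)
  i <- pmin(pmax(i, 1L), length(scheme$breaks))
  factor(scheme$labels[i], levels = scheme$labels)
}

#' @rdname accuracy_indices
#' @param scheme A [category_scheme()] defining the clinical bins.
#' @return `concordance()`: a tibble with one row per category —
#'   `category`, `n_measured`, `n_agree`, `concordance` — plus attribute
#'   `overall`. Categories with no measured records have `concordance = NA`
#'   (undefined, deliberately distinct from 0).
#' @export
concordance <- function(estimates, measured, scheme = ldl_scheme()) {
  assert_paired(estimates, measured)
  cm <- categorize(measured, scheme)
  ce <- categorize(estimates, scheme)
  agree <- cm == ce
  out <- tibble(category = factor(scheme$labels, levels = scheme$labels)) %>%
    left_join(tibble(category = cm, agree = agree) %>%
                group_by(.data$category) %>%
                summarise(n_measured = dplyr::n(),
                          n_agree = sum(.data$agree), .groups = "drop"),
              by = "category") %>%
    mutate(n_measured = ifelse(is.na(.data$n_measured), 0L, .data$n_measured),
           n_agree = ifelse(is.na(.data$n_agree), 0L, .data$n_agree),
           concordance = ifelse(.data$n_measured > 0,
                                .data$n_agree / .data$n_measured, NA_real_))
  attr(out, "overall") <- mean(agree)
  out
}

#' Grouped RMSE
#'
#' RMSE computed within each level of a grouping label (TG category,
#' non-HDL-C category, risk vigintile, ...). Groups are ordered by label;
#' empty groups are omitted with a log message. The size-weighted pooled
#' mean of the squared group RMSEs recovers the global squared RMSE.
#'
#' @inheritParams accuracy_indices
#' @param group_labels Vector of group labels aligned with the pairs.
#' @return A tibble with columns `group`, `n`, `rmse`.
#' @export
grouped_rmse <- function(estimates, measured, group_labels) {
  assert_paired(estimates, measured)
  if (length(group_labels) != length(estimates)) {
    abort("`group_labels` must align with the paired vectors",
          class = "ldlbench_validation_error")
  }
  if (is.factor(group_labels)) {
    empty <- setdiff(levels(group_labels), as.character(unique(group_labels)))
    if (length(empty) > 0) {
      inform(sprintf("grouped_rmse: omitting %d empty group(s): %s",
                     length(empty), paste(empty, collapse = ", ")))
    }
  }
  tibble(group = group_labels,
         err2 = (estimates - measured)^2) %>%
    group_by(.data$group) %>%
    summarise(n = dplyr::n(), rmse = sqrt(mean(.data$err2)), .groups = "drop") %>%
    arrange(.data$group)
}

#' Full metric report for one or more estimators
#'
#' Computes the complete index set — bias (mean, t, p), RMSE, P10/P15/P20
#' and category concordance — for each estimate column against the measured
#' column, one row per method.
#'
#' @param data Cohort data frame containing the estimate and measured
#'   columns.
#' @param estimate_cols Named or unnamed character vector of estimate
#'   columns (names become method labels).
#' @param measured_col Column holding directly measured LDL-C.
#' @param scheme Category scheme for concordance (default [ldl_scheme()]).
#' @return A tibble of class `metric_report`: one row per method with
#'   columns `method`, `n`, `bias_mean`, `bias_t`, `bias_p`, `rmse`, `p10`,
#'   `p15`, `p20`, `concordance_overall` and a `concordance` list column of
#'   per-category tibbles.
#' @export
metric_report <- function(data, estimate_cols,
                          measured_col = "ldl_measured",
                          scheme = ldl_scheme()) {
  data <- as_tibble(data)
  assert_columns(data, c(estimate_cols, measured_col), "evaluation cohort")
  labels <- names(estimate_cols) %||% estimate_cols
  labels[labels == ""] <- estimate_cols[labels == ""]
  measured <- data[[measured_col]]
  rows <- purrr::map2(estimate_cols, labels, function(col, lab) {
    est <- data[[col]]
    b <- ldl_bias(est, measured)
    conc <- concordance(est, measured, scheme)
    tibble(method = lab,
           n = b$n,
           bias_mean = b$bias_mean, bias_t = b$bias_t, bias_p = b$bias_p,
           rmse = ldl_rmse(est, measured),
           p10 = pn_accuracy(est, measured, 10),
           p15 = pn_accuracy(est, measured, 15),
           p20 = pn_accuracy(est, measured, 20),
           concordance_overall = attr(conc, "overall"),
           concordance = list(conc))
  })
  out <- bind_rows(rows)
  class(out) <- c("metric_report", class(out))
  out
}

#' @export
print.metric_report <- function(x, ...) {
  cat("<metric_report>\n")
  print(as_tibble(x)[, setdiff(names(x), "concordance")], ...)
  invisible(x)
}

#' Serialise metric reports and grouped tables
#'
#' Writes delimited text with a stable column order (the nested per-category
#' concordance is flattened to one `concordance_<category>` column per bin).
#'
#' @param report A [metric_report()] tibble.
#' @param path File path.
#' @param delim Field delimiter.
#' @return `path`, invisibly.
#' @export
write_metric_report <- function(report, path, delim = ",") {
  flat <- as_tibble(report)
  if ("concordance" %in% names(flat)) {
    conc_wide <- purrr::map(flat$concordance, function(tb) {
      stats::setNames(as.list(tb$concordance),
                      paste0("concordance_", tb$category))
    })
    flat <- bind_cols(flat[setdiff(names(flat), "concordance")],
                      bind_rows(purrr::map(conc_wide, as_tibble)))
  }
  readr::write_delim(flat, path, delim = delim, na = "")
  invisible(path)
}

#' Fig-style grouped RMSE plot
#'
#' Line plot of per-group RMSE for several estimators (grouped by TG,
#' non-HDL-C or risk stratum).
#'
#' @param tbl A tibble with columns `method`, `group`, `rmse` (e.g. from
#'   binding [grouped_rmse()] results per method).
#' @return A ggplot object.
#' @export
plot_grouped_rmse <- function(tbl) {
  ggplot2::ggplot(tbl, ggplot2::aes(.data$group, .data$rmse,
                                    colour = .data$method,
                                    group = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "stratum", y = "RMSE (mg/dL)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
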