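#' Configuration for a full estimator-comparison run
#'
#' Bundles every knob of the end-to-end pipeline: the synthetic derivation
#' and external populations, the split, the network search space and
#' training budget, the metric schemes and the risk-coefficient file. The
#' report bundle produced by [run_comparison()] is a pure function of this
#' configuration.
#'
#' @param seed Master seed; every stage derives its own stream from it.
#' @param derivation_params [cohort_params()] for the derivation-population
#'   cohort (split 70/30 into derivation and internal validation by
#'   default).
#' @param external_params [cohort_params()]/[koica_params()] for the
#'   external validation cohort.
#' @param split Derivation/internal fractions.
#' @param depths,node_grid,per_depth_caps Candidate search space (see
#'   [enumerate_candidates()]).
#' @param k_folds Cross-validation folds.
#' @param control [mlp_control()] training settings for the cross-validation
#'   stage (a reduced budget: candidate ranking stabilises well before full
#'   convergence).
#' @param final_control [mlp_control()] training settings for the tournament
#'   refits on the full derivation set: a converged budget (annealed
#'   learning rate, decoupled weight decay, no effective early stop) —
#'   final accuracy targets sit well below what the early-stopping holdout
#'   can resolve.
#' @param features Model input features.
#' @param tg_breaks,nonhdl_breaks Grouping schemes for the grouped-RMSE
#'   tables.
#' @param pce_path Path to a PCE coefficient file, or `NULL` to skip the
#'   risk-stratified table.
#' @param risk_bins Number of equal-frequency risk strata.
#' @return A `comparison_config` list.
#' @export
comparison_config <- function(seed = 1,
                              derivation_params = cohort_params(n = 50000),
                              external_params = koica_params(n = 20000),
                              split = c(0.7, 0.3),
                              depths = c(2, 4, 6),
                              node_grid = c(10, 20, 30),
                              per_depth_caps = c("2" = 30, "4" = 20, "6" = 10),
                              k_folds = 10,
                              control = mlp_control(max_epochs = 30,
                                                    batch_size = 2048,
                                                    learning_rate = 0.006,
                                                    patience = 4),
                              final_control = mlp_control(max_epochs = 300,
                                                          batch_size = 512,
                                                          learning_rate = 0.003,
                                                          patience = 300,
                                                          lr_decay = 0.05,
                                                          weight_decay = 0.4),
                              features = c("tc", "hdl", "tg"),
                              tg_breaks = seq(0, 400, by = 50),
                              nonhdl_breaks = c(0, 40, 90, 140, 190, 240),
                              pce_path = default_pce_path(),
                              risk_bins = 20) {
  structure(as.list(environment()), class = "comparison_config")
}

config_hash <- function(config) {
  rlang::hash(config[sort(names(config))])
}

#' Run the full estimator comparison
#'
#' Executes the complete pipeline on synthetic data: simulate the
#' derivation-population and external cohorts, apply the study-flow
#' exclusions, split derivation/internal, derive the adjustable-factor
#' strata table on the derivation set, select the network estimator
#' (candidate enumeration, k-fold cross-validation, tournament on the
#' internal set), then evaluate all four estimators on the internal and
#' external validation sets; finally produce grouped-RMSE tables by TG and
#' non-HDL category and by risk vigintile (external set).
#'
#' The external validation set is generated up front but read only at the
#' final evaluation stage; the stage log records n in/out and the seed of
#' every stage.
#'
#' @param config A [comparison_config()].
#' @return An `ldl_comparison` object: `metrics` (a [metric_report()] per
#'   validation set), `grouped_tg`, `grouped_nonhdl`, `risk_rmse`,
#'   `strata_table`, `model`, `stage_log`, `config_hash` and `seed`.
#' @export
run_comparison <- function(config = comparison_config()) {
  if (!inherits(config, "comparison_config")) {
    abort("`config` must be a comparison_config object",
          class = "ldlbench_config_error")
  }
  seed <- config$seed
  log <- list()
  stage <- function(name, n_in, n_out, stage_seed) {
    log[[length(log) + 1L]] <<- tibble(stage = name, n_in = n_in,
                                       n_out = n_out, seed = stage_seed)
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage `%s` failed: %s", name,
                    conditionMessage(e)),
            class = "ldlbench_runtime_error")
    })
  }

  # -- simulate -------------------------------------------------------------
  s_sim <- derive_seed(seed, 101L)
  gshc <- run_stage("simulate", generate_cohort(config$derivation_params,
                                                seed = s_sim))
  s_ext <- derive_seed(seed, 102L)
  external <- run_stage("simulate",
                        generate_cohort(config$external_params, seed = s_ext))
  stage("simulate_derivation_population", config$derivation_params$n,
        nrow(gshc), s_sim)
  stage("simulate_external_population", config$external_params$n,
        nrow(external), s_ext)

  # -- exclude --------------------------------------------------------------
  excl <- run_stage("exclude", apply_exclusions(gshc))
  gshc <- excl$cohort
  excl_ext <- run_stage("exclude", apply_exclusions(external))
  external <- excl_ext$cohort
  stage("exclusions_derivation_population", excl$n_input, nrow(gshc), NA)
  stage("exclusions_external_population", excl_ext$n_input, nrow(external), NA)

  # -- split ----------------------------------------------------------------
  s_split <- derive_seed(seed, 103L)
  gshc <- run_stage("split", split_cohort(gshc, config$split, seed = s_split))
  derivation <- filter(gshc, .data$partition == "derivation")
  internal <- filter(gshc, .data$partition == "internal")
  stage("split", nrow(gshc), nrow(derivation), s_split)

  # -- derive strata table --------------------------------------------------
  table <- run_stage("derive_table",
                     suppressMessages(derive_strata_table(derivation)))
  stage("derive_table", nrow(derivation), table$cell_count, NA)

  # -- train/select network -------------------------------------------------
  s_cv <- derive_seed(seed, 104L)
  candidates <- run_stage("train",
                          enumerate_candidates(config$depths, config$node_grid,
                                               config$per_depth_caps))
  cv <- run_stage("train",
                  crossval_select(derivation, candidates,
                                  features = config$features,
                                  k = config$k_folds, seed = s_cv,
                                  control = config$control))
  model <- run_stage("train",
                     tournament_final(cv, derivation, internal,
                                      seed = derive_seed(seed, 105L),
                                      control = config$final_control))
  stage("train_select", nrow(derivation), nrow(candidates), s_cv)

  # -- evaluate -------------------------------------------------------------
  methods <- c(Friedewald = "ldl_friedewald", Martin = "ldl_martin",
               NIH = "ldl_sampson", DNN = "ldl_dnn")
  evaluate_set <- function(dat) {
    dat %>%
      estimate_friedewald() %>%
      estimate_sampson_nih() %>%
      estimate_martin(table) %>%
      estimate_dnn(model)
  }
  internal_est <- run_stage("evaluate", evaluate_set(internal))
  external_est <- run_stage("evaluate", evaluate_set(external))
  metrics <- list(
    internal = metric_report(internal_est, methods),
    external = metric_report(external_est, methods))
  stage("evaluate", nrow(internal) + nrow(external), length(methods) * 2L, NA)

  grouped_by <- function(dat, values, scheme_breaks, var) {
    labels <- categorize(dat[[var]], category_scheme(var, scheme_breaks))
    bind_rows(purrr::imap(values, function(col, m) {
      mutate(grouped_rmse(dat[[col]], dat$ldl_measured, labels), method = m)
    }))
  }
  grouped_tg <- run_stage("evaluate",
                          suppressMessages(grouped_by(external_est, methods,
                                                      config$tg_breaks, "tg")))
  grouped_nonhdl <- run_stage("evaluate",
                              suppressMessages(
                                grouped_by(external_est, methods,
                                           config$nonhdl_breaks, "non_hdl")))

  # -- risk stratification --------------------------------------------------
  risk_rmse <- NULL
  if (is.null(config$pce_path)) {
    inform("run_comparison: no PCE coefficient file configured; skipping the risk-stratified RMSE table")
    stage("risk_stratify", nrow(external_est), 0L, NA)
  } else {
    coefs <- run_stage("risk_stratify", read_pce_coefficients(config$pce_path))
    ext_risk <- run_stage("risk_stratify",
                          external_est %>%
                            pce_risk(coefs) %>%
                            add_risk_bins(n_bins = config$risk_bins))
    risk_rmse <- bind_rows(purrr::imap(methods, function(col, m) {
      mutate(grouped_rmse(ext_risk[[col]], ext_risk$ldl_measured,
                          ext_risk$risk_bin), method = m)
    }))
    stage("risk_stratify", nrow(ext_risk), config$risk_bins, NA)
  }

  structure(list(metrics = metrics,
                 grouped_tg = grouped_tg,
                 grouped_nonhdl = grouped_nonhdl,
                 risk_rmse = risk_rmse,
                 strata_table = table,
                 model = model,
                 exclusions = list(derivation_population = excl$counts,
                                   external_population = excl_ext$counts),
                 stage_log = bind_rows(log),
                 config_hash = config_hash(config),
                 seed = seed),
            class = "ldl_comparison")
}

#' @export
print.ldl_comparison <- function(x, ...) {
  cat(sprintf("<ldl_comparison: seed %d, config %s>\n", x$seed, x$config_hash))
  cat(sprintf("  final network: %s (%d layers)\n", x$model$label, x$model$depth))
  cat("  external metrics:\n")
  print(as_tibble(x$metrics$external)[, c("method", "n", "bias_mean", "rmse",
                                          "p10", "p15", "p20")])
  invisible(x)
}

#' @rdname run_comparison
#' @param x,object An `ldl_comparison`.
#' @param ... Unused.
#' @return `tidy()`: the per-method metric rows of both validation sets;
#'   `glance()`: a one-row summary.
#' @method tidy ldl_comparison
#' @export
tidy.ldl_comparison <- function(x, ...) {
  bind_rows(purrr::imap(x$metrics, function(rep, set) {
    mutate(as_tibble(rep)[, setdiff(names(rep), "concordance")],
           validation_set = set)
  }))
}

#' @rdname run_comparison
#' @method glance ldl_comparison
#' @export
glance.ldl_comparison <- function(x, ...) {
  ext <- x$metrics$external
  tibble(model = x$model$label,
         best_method = ext$method[which.min(ext$rmse)],
         external_rmse_dnn = ext$rmse[ext$method == "DNN"],
         external_rmse_friedewald = ext$rmse[ext$method == "Friedewald"],
         config_hash = x$config_hash,
         seed = x$seed)
}

#' @method autoplot ldl_comparison
#' @export
autoplot.ldl_comparison <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$method, .data$rmse,
                                   fill = .data$validation_set)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "RMSE (mg/dL)",
                  title = "LDL-C estimator comparison") +
    ggplot2::theme_minimal()
}

#' Write a comparison report bundle
#'
#' Serialises every table of an [run_comparison()] result as delimited text
#' in `dir`, each file stamped (in a header comment line) with the config
#' hash and master seed. Output is byte-identical across runs with the same
#' configuration.
#'
#' @param result An `ldl_comparison`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(result, dir) {
  if (!inherits(result, "ldl_comparison")) {
    abort("`result` must be an ldl_comparison object",
          class = "ldlbench_config_error")
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- sprintf("# config %s seed %d", result$config_hash, result$seed)
  emit <- function(tbl, name) {
    path <- file.path(dir, name)
    con <- file(path, "w")
    writeLines(stamp, con)
    close(con)
    readr::write_delim(tbl, path, delim = ",", na = "", append = TRUE,
                       col_names = TRUE)
    path
  }
  for (set in names(result$metrics)) {
    flat <- as_tibble(result$metrics[[set]])
    flat <- flat[, setdiff(names(flat), "concordance")]
    emit(flat, sprintf("metrics_%s.csv", set))
    conc <- bind_rows(purrr::map2(result$metrics[[set]]$concordance,
                                  result$metrics[[set]]$method,
                                  ~ mutate(.x, method = .y)))
    emit(conc, sprintf("concordance_%s.csv", set))
  }
  emit(result$grouped_tg, "grouped_rmse_tg.csv")
  emit(result$grouped_nonhdl, "grouped_rmse_nonhdl.csv")
  if (!is.null(result$risk_rmse)) {
    emit(result$risk_rmse, "grouped_rmse_risk.csv")
  }
  emit(result$stage_log, "stage_log.csv")
  write_strata_table(result$strata_table, file.path(dir, "strata_table.csv"))
  write_dnn(result$model, file.path(dir, "dnn_model.json"))
  invisible(dir)
}
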