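#' Enumerate pyramid network candidates
#'
#' Candidate architectures are non-increasing hidden-layer width sequences
#' ("pyramids": each layer no wider than the one before it) drawn from a node
#' grid, for each requested depth. The default search space mirrors the
#' selection procedure this package implements: depths 2, 4 and 6 over the
#' grid \{10, 20, 30\}. `per_depth_caps` optionally caps the widths available
#' to each depth (e.g. `c("6" = 10, "4" = 20, "2" = 30)`), honouring the
#' alternative reading in which deeper candidates only use narrower layers.
#'
#' Candidates are deduplicated and returned in deterministic order: by depth,
#' then lexicographically by the width tuple.
#'
#' @param depths Integer vector of hidden-layer counts.
#' @param node_grid Integer vector of admissible layer widths.
#' @param per_depth_caps Optional named numeric vector mapping depth to the
#'   maximum width allowed at that depth.
#' @return A tibble with columns `depth`, `widths` (list column) and `label`.
#' @examples
#' enumerate_candidates(depths = 2, node_grid = c(10, 20, 30))
#' @export
enumerate_candidates <- function(depths = c(2, 4, 6),
                                 node_grid = c(10, 20, 30),
                                 per_depth_caps = NULL) {
  if (length(node_grid) == 0 || any(node_grid < 1)) {
    abort("`node_grid` must be a non-empty set of positive widths",
          class = "ldlbench_config_error")
  }
  if (length(depths) == 0 || any(depths < 1)) {
    abort("`depths` must be a non-empty set of positive layer counts",
          class = "ldlbench_config_error")
  }
  node_grid <- sort(unique(as.integer(node_grid)))
  depths <- sort(unique(as.integer(depths)))
  out <- purrr::map(depths, function(k) {
    grid <- node_grid
    if (!is.null(per_depth_caps)) {
      cap <- per_depth_caps[as.character(k)]
      if (!is.na(cap)) grid <- grid[grid <= cap]
    }
    if (length(grid) == 0) return(NULL)
    combos <- as.matrix(do.call(expand.grid, rep(list(grid), k)))
    keep <- apply(combos, 1, function(w) all(diff(w) <= 0))
    combos <- combos[keep, , drop = FALSE]
    ord <- do.call(order, as.data.frame(combos))
    combos <- combos[ord, , drop = FALSE]
    tibble(depth = k,
           widths = lapply(seq_len(nrow(combos)),
                           function(i) as.integer(combos[i, ])))
  })
  out <- bind_rows(out)
  if (nrow(out) == 0) {
    abort("candidate enumeration produced no architectures (caps too tight?)",
          class = "ldlbench_config_error")
  }
  mutate(out, label = purrr::map_chr(.data$widths,
                                     ~ paste(.x, collapse = "-")))
}

#' Seeded k-fold partition
#'
#' Assigns every record to exactly one of `k` folds by a seeded random
#' permutation; fold sizes differ by at most one and the same seed always
#' yields the same partition (so all candidates in a cross-validated search
#' see identical folds).
#'
#' @param n Number of records.
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return Integer vector of fold labels in 1..k.
#' @export
cv_folds <- function(n, k = 10, seed = 1) {
  if (k < 2) abort("`k` must be >= 2", class = "ldlbench_config_error")
  if (n < k) abort("need at least one record per fold",
                   class = "ldlbench_validation_error")
  withr::with_seed(seed, rep_len(seq_len(k), n)[sample.int(n)])
}

#' Cross-validated candidate selection
#'
#' Trains every candidate architecture on each of `k` training folds of the
#' derivation data and scores mean squared error on the held-out fold; the
#' candidate with the lowest fold-averaged MSE within each depth class is the
#' depth winner. The fold partition is identical across candidates.
#'
#' @param data Derivation cohort (data frame).
#' @param candidates Candidate tibble from [enumerate_candidates()].
#' @param target Response column (directly measured LDL-C by default).
#' @param features Input feature columns; defaults to the standard lipid
#'   panel `c("tc", "hdl", "tg")`.
#' @param k Number of folds.
#' @param seed Integer seed driving the fold partition and per-fit
#'   initialisation.
#' @param control [mlp_control()] training settings.
#' @return A tibble (class `ldl_cv`) with one row per candidate: `depth`,
#'   `widths`, `label`, `cv_mse` and logical `winner`; the fold labels are
#'   kept in attribute `folds`.
#' @export
crossval_select <- function(data, candidates,
                            target = "ldl_measured",
                            features = c("tc", "hdl", "tg"),
                            k = 10, seed = 1,
                            control = mlp_control()) {
  data <- as_tibble(data)
  assert_columns(data, c(features, target), "derivation cohort")
  y <- data[[target]]
  x <- as.matrix(data[features])
  n <- nrow(data)
  folds <- cv_folds(n, k, derive_seed(seed, 17L))
  if (isTRUE(sd(y) == 0)) {
    warn("target has zero variance; selection proceeds on MSE")
  }
  res <- candidates
  res$cv_mse <- vapply(seq_len(nrow(candidates)), function(ci) {
    w <- candidates$widths[[ci]]
    fold_mse <- vapply(seq_len(k), function(f) {
      tr <- folds != f
      fit <- mlp_fit(x[tr, , drop = FALSE], y[tr], w,
                     seed = derive_seed(seed, ci * 1000L + f),
                     control = control)
      mean((mlp_predict(fit, x[!tr, , drop = FALSE]) - y[!tr])^2)
    }, numeric(1))
    mean(fold_mse)
  }, numeric(1))
  res <- res %>%
    group_by(.data$depth) %>%
    mutate(winner = seq_len(dplyr::n()) ==
             order(.data$cv_mse,
                   purrr::map_dbl(.data$widths, ~ mlp_n_params(.x, length(features))))[1]) %>%
    ungroup()
  attr(res, "folds") <- folds
  attr(res, "features") <- features
  attr(res, "target") <- target
  class(res) <- c("ldl_cv", class(res))
  res
}

#' Tournament final selection
#'
#' Refits each depth winner on the full derivation set and scores mean
#' squared error on the internal validation set; the lowest-MSE finalist is
#' the final model. Ties break toward fewer total parameters, then fewer
#' layers.
#'
#' @param cv_result Output of [crossval_select()] (all rows or only the
#'   winner rows; non-winners are dropped).
#' @param derivation Derivation cohort used for refitting.
#' @param internal_validation Held-out internal validation cohort (must be
#'   disjoint from the derivation set; never used for training).
#' @param seed Integer seed for the refits.
#' @param control [mlp_control()] training settings.
#' @return An `ldl_dnn` fitted estimator; see [predict.ldl_dnn()],
#'   [tidy.ldl_dnn()] and [glance.ldl_dnn()].
#' @export
tournament_final <- function(cv_result, derivation, internal_validation,
                             seed = 1, control = mlp_control()) {
  features <- attr(cv_result, "features") %||% c("tc", "hdl", "tg")
  target <- attr(cv_result, "target") %||% "ldl_measured"
  finalists <- cv_result[cv_result$winner %||% rep(TRUE, nrow(cv_result)), , drop = FALSE]
  finalists <- as_tibble(finalists)
  if (nrow(finalists) == 0) {
    abort("no finalists to enter the tournament", class = "ldlbench_config_error")
  }
  internal_validation <- as_tibble(internal_validation)
  if (nrow(internal_validation) == 0) {
    abort("internal validation set is empty", class = "ldlbench_validation_error")
  }
  derivation <- as_tibble(derivation)
  assert_columns(derivation, c(features, target), "derivation cohort")
  assert_columns(internal_validation, c(features, target), "internal validation cohort")

  xd <- as.matrix(derivation[features]); yd <- derivation[[target]]
  xv <- as.matrix(internal_validation[features]); yv <- internal_validation[[target]]
  fits <- vector("list", nrow(finalists))
  val_mse <- numeric(nrow(finalists))
  for (i in seq_len(nrow(finalists))) {
    fits[[i]] <- mlp_fit(xd, yd, finalists$widths[[i]],
                         seed = derive_seed(seed, 9000L + i),
                         control = control)
    val_mse[i] <- mean((mlp_predict(fits[[i]], xv) - yv)^2)
  }
  finalists$val_mse <- val_mse
  n_par <- purrr::map_dbl(finalists$widths, ~ mlp_n_params(.x, length(features)))
  pick <- order(val_mse, n_par, finalists$depth)[1]

  structure(list(fit = fits[[pick]],
                 widths = finalists$widths[[pick]],
                 label = finalists$label[[pick]],
                 depth = finalists$depth[[pick]],
                 features = features,
                 target = target,
                 cv_mse = finalists$cv_mse[[pick]],
                 val_mse = val_mse[pick],
                 finalists = finalists[c("depth", "label", "cv_mse", "val_mse")],
                 seed = as.integer(seed)),
            class = "ldl_dnn")
}

#' Fit a single network estimator directly
#'
#' Convenience wrapper around the internal trainer for a known architecture
#' (no selection): useful for capacity checks and as a building block.
#'
#' @inheritParams crossval_select
#' @param widths Hidden-layer width sequence.
#' @return An `ldl_dnn` object.
#' @export
fit_dnn <- function(data, widths, target = "ldl_measured",
                    features = c("tc", "hdl", "tg"),
                    seed = 1, control = mlp_control()) {
  data <- as_tibble(data)
  assert_columns(data, c(features, target), "training cohort")
  fit <- mlp_fit(as.matrix(data[features]), data[[target]],
                 widths, seed = seed, control = control)
  structure(list(fit = fit, widths = as.integer(widths),
                 label = paste(widths, collapse = "-"),
                 depth = length(widths), features = features,
                 target = target, cv_mse = NA_real_,
                 val_mse = NA_real_,
                 finalists = tibble(depth = integer(), label = character(),
                                    cv_mse = numeric(), val_mse = numeric()),
                 seed = as.integer(seed)),
            class = "ldl_dnn")
}

#' Predict LDL-C with a fitted network estimator
#'
#' Applies the stored per-feature standardisation then the network; the same
#' input always yields bit-identical output.
#'
#' @param object An `ldl_dnn` model.
#' @param newdata Data frame providing all of the model's input features.
#' @param ... Unused.
#' @return Numeric vector of LDL-C estimates (mg/dL).
#' @export
predict.ldl_dnn <- function(object, newdata, ...) {
  newdata <- as_tibble(newdata)
  missing <- setdiff(object$features, names(newdata))
  if (length(missing) > 0) {
    abort(sprintf("newdata is missing model feature(s): %s",
                  paste(missing, collapse = ", ")),
          class = "ldlbench_validation_error")
  }
  mlp_predict(object$fit, as.matrix(newdata[object$features]))
}

#' @rdname ldl_equations
#' @param model A fitted `ldl_dnn` estimator.
#' @export
estimate_dnn <- function(data, model) {
  data <- as_tibble(data)
  mutate(data, ldl_dnn = predict(model, data))
}

#' @export
print.ldl_dnn <- function(x, ...) {
  cat(sprintf("<ldl_dnn: %d hidden layers (%s), features: %s>\n",
              x$depth, x$label, paste(x$features, collapse = ", ")))
  if (is.finite(x$val_mse)) {
    cat(sprintf("  cv_mse = %.4f, internal validation mse = %.4f\n",
                x$cv_mse, x$val_mse))
  }
  invisible(x)
}

#' @rdname tournament_final
#' @param x,object An `ldl_dnn` model.
#' @param ... Unused.
#' @method tidy ldl_dnn
#' @export
tidy.ldl_dnn <- function(x, ...) {
  x$finalists
}

#' @rdname tournament_final
#' @method glance ldl_dnn
#' @export
glance.ldl_dnn <- function(x, ...) {
  tibble(label = x$label, depth = x$depth,
         n_params = mlp_n_params(x$widths, length(x$features)),
         cv_mse = x$cv_mse, val_mse = x$val_mse,
         epochs_run = x$fit$epochs_run)
}

#' Serialise a fitted network estimator
#'
#' Writes a self-describing JSON file holding the architecture, feature
#' names, standardisation constants, weights and seeds. Numeric values are
#' stored with full round-trip precision, so a loaded model predicts
#' bit-identically to the model that was saved.
#'
#' @param model An `ldl_dnn` model.
#' @param path File path.
#' @return `write_dnn()` returns `path` invisibly; `read_dnn()` returns the
#'   restored `ldl_dnn`.
#' @export
write_dnn <- function(model, path) {
  if (!inherits(model, "ldl_dnn")) {
    abort("`model` must be an ldl_dnn object", class = "ldlbench_config_error")
  }
  fit <- model$fit
  payload <- list(
    type = "ldl_dnn",
    widths = fit$widths,
    features = model$features,
    target = model$target,
    label = model$label,
    seed = model$seed,
    fit_seed = fit$seed,
    cv_mse = fmt_dbl(model$cv_mse),
    val_mse = fmt_dbl(model$val_mse),
    x_center = fmt_dbl(fit$x_center),
    x_scale = fmt_dbl(fit$x_scale),
    y_center = fmt_dbl(fit$y_center),
    y_scale = fmt_dbl(fit$y_scale),
    W = lapply(fit$W, function(w) list(dim = dim(w), values = fmt_dbl(as.numeric(w)))),
    b = lapply(fit$b, fmt_dbl)
  )
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE), path)
  invisible(path)
}

#' @rdname write_dnn
#' @export
read_dnn <- function(path) {
  p <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(p$type, "ldl_dnn")) {
    abort("not an ldl_dnn model file", class = "ldlbench_config_error")
  }
  chr <- function(x) unlist(lapply(x, as.character))
  W <- lapply(p$W, function(w) {
    d <- unlist(w$dim)
    matrix(parse_dbl(chr(w$values)), d[1], d[2])
  })
  b <- lapply(p$b, function(v) parse_dbl(chr(v)))
  features <- chr(p$features)
  fit <- structure(list(widths = as.integer(unlist(p$widths)),
                        W = W, b = b,
                        x_center = stats::setNames(parse_dbl(chr(p$x_center)), features),
                        x_scale = stats::setNames(parse_dbl(chr(p$x_scale)), features),
                        y_center = parse_dbl(p$y_center),
                        y_scale = parse_dbl(p$y_scale),
                        seed = as.integer(p$fit_seed),
                        epochs_run = NA_integer_,
                        holdout_mse = NA_real_,
                        control = NULL),
                   class = "mlp_fit")
  structure(list(fit = fit, widths = as.integer(unlist(p$widths)),
                 label = p$label, depth = length(unlist(p$widths)),
                 features = features, target = p$target,
                 cv_mse = parse_dbl(p$cv_mse), val_mse = parse_dbl(p$val_mse),
                 finalists = tibble(depth = integer(), label = character(),
                                    cv_mse = numeric(), val_mse = numeric()),
                 seed = as.integer(p$seed)),
            class = "ldl_dnn")
}
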