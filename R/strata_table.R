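#' Adjustable-factor strata tables
#'
#' A `strata_table` holds the grid of adjustable VLDL-C:TG divisors used by
#' the Martin-style LDL-C estimator: a matrix of positive factors indexed by
#' triglyceride stratum (rows) and non-HDL-C stratum (columns). Strata are
#' left-closed, right-open intervals defined by ascending edge vectors whose
#' first and last entries are the outer bounds (typically 0 and `Inf`), so
#' every non-negative value falls in exactly one stratum and out-of-range
#' values clamp to the edge strata.
#'
#' The default geometry is 30 TG strata by 6 non-HDL strata = 180 cells.
#' The exact default edges are a package configuration, not a literature
#' fact: the published factor table belongs to its original authors and is
#' deliberately not reproduced here — use [derive_strata_table()] to fit a
#' table to data with directly measured LDL-C.
#'
#' @param tg_edges Ascending numeric vector of TG stratum boundaries
#'   (mg/dL), length `nrow(factors) + 1`.
#' @param nonhdl_edges Ascending numeric vector of non-HDL-C stratum
#'   boundaries (mg/dL), length `ncol(factors) + 1`.
#' @param factors Numeric matrix of positive adjustable factors,
#'   TG strata in rows, non-HDL strata in columns.
#' @return A `strata_table` object.
#' @seealso [derive_strata_table()], [estimate_martin()]
#' @export
strata_table <- function(tg_edges, nonhdl_edges, factors) {
  factors <- as.matrix(factors)
  if (length(tg_edges) < 2 || length(nonhdl_edges) < 2) {
    abort("strata edges need at least two boundaries per axis",
          class = "ldlbench_config_error")
  }
  if (is.unsorted(tg_edges, strictly = TRUE) ||
      is.unsorted(nonhdl_edges, strictly = TRUE)) {
    abort("strata edges must be strictly ascending",
          class = "ldlbench_config_error")
  }
  if (nrow(factors) != length(tg_edges) - 1L ||
      ncol(factors) != length(nonhdl_edges) - 1L) {
    abort("factor matrix dimensions must match (tg strata x non-HDL strata)",
          class = "ldlbench_config_error")
  }
  if (length(factors) == 0) {
    abort("strata table must have at least one cell",
          class = "ldlbench_config_error")
  }
  if (any(!is.finite(factors)) || any(factors <= 0)) {
    abort("all adjustable factors must be positive and finite",
          class = "ldlbench_config_error")
  }
  structure(
    list(tg_edges = as.numeric(tg_edges),
         nonhdl_edges = as.numeric(nonhdl_edges),
         factors = factors,
         cell_count = length(factors)),
    class = "strata_table")
}

#' @export
print.strata_table <- function(x, ...) {
  cat(sprintf("<strata_table: %d TG x %d non-HDL strata = %d cells>\n",
              nrow(x$factors), ncol(x$factors), x$cell_count))
  cat(sprintf("  factor range: %.3f - %.3f\n",
              min(x$factors), max(x$factors)))
  invisible(x)
}

#' @rdname strata_table
#' @export
default_tg_edges <- function() {
  c(0, seq(40, 240, by = 10), seq(260, 400, by = 20), Inf)
}

#' @rdname strata_table
#' @export
default_nonhdl_edges <- function() {
  c(0, 100, 130, 160, 190, 220, Inf)
}

# Left-closed right-open stratum index with clamping to the edge strata.
stratum_index <- function(x, edges) {
  i <- findInterval(x, edges, left.open = FALSE, rightmost.closed = FALSE)
  pmin(pmax(i, 1L), length(edges) - 1L)
}

# Vectorised factor lookup for the Martin estimator.
lookup_factor <- function(table, tg, nonhdl) {
  if (!inherits(table, "strata_table")) {
    abort("`table` must be a strata_table object",
          class = "ldlbench_config_error")
  }
  ti <- stratum_index(tg, table$tg_edges)
  ni <- stratum_index(nonhdl, table$nonhdl_edges)
  table$factors[cbind(ti, ni)]
}

#' Derive an adjustable-factor table from directly measured LDL-C
#'
#' Each cell's factor is the median, over the records falling in that
#' (TG, non-HDL) cell, of the individual ratio
#' `tg / (tc - hdl - ldl_measured)`, i.e. the TG:VLDL-C ratio implied by the
#' lipid panel identity. Records whose implied VLDL-C (`tc - hdl -
#' ldl_measured`) is not strictly positive are dropped with a logged count.
#' Empty cells are filled from the nearest non-empty cell — first along the
#' same TG row, then along the same non-HDL column, then by overall grid
#' distance — and every fill event is logged.
#'
#' The median is the standard definition (mean of the two central order
#' statistics for even counts).
#'
#' @param data Cohort with columns `tc`, `hdl`, `tg`, `ldl_measured` (mg/dL).
#' @param tg_edges,nonhdl_edges Stratum boundaries; defaults give the
#'   180-cell geometry.
#' @return A [strata_table] with attributes `n_dropped` (records with
#'   non-positive implied VLDL) and `fills` (tibble of filled cells).
#' @export
derive_strata_table <- function(data,
                                tg_edges = default_tg_edges(),
                                nonhdl_edges = default_nonhdl_edges()) {
  data <- validate_lipid_panels(data)
  assert_columns(data, "ldl_measured", "cohort for table derivation")
  vldl <- data$tc - data$hdl - data$ldl_measured
  keep <- is.finite(vldl) & vldl > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    inform(sprintf("derive_strata_table: dropped %d record(s) with non-positive implied VLDL-C",
                   n_dropped))
  }
  data <- data[keep, , drop = FALSE]
  vldl <- vldl[keep]
  if (nrow(data) == 0) {
    abort("no usable records: every cell of the strata table is empty",
          class = "ldlbench_config_error")
  }
  n_tg <- length(tg_edges) - 1L
  n_nh <- length(nonhdl_edges) - 1L
  ti <- stratum_index(data$tg, tg_edges)
  ni <- stratum_index(data$non_hdl, nonhdl_edges)
  ratio <- data$tg / vldl
  fac <- matrix(NA_real_, n_tg, n_nh)
  cell <- (ni - 1L) * n_tg + ti
  med <- tapply(ratio, cell, median)
  fac[as.integer(names(med))] <- as.numeric(med)
  occupied <- !is.na(fac)
  if (!any(occupied)) {
    abort("no usable records: every cell of the strata table is empty",
          class = "ldlbench_config_error")
  }
  if (any(fac[occupied] <= 0)) {
    abort("derived a non-positive median factor; check the input cohort",
          class = "ldlbench_config_error")
  }

  fills <- list()
  occ_idx <- which(occupied, arr.ind = TRUE)
  for (j in seq_len(n_nh)) {
    for (i in seq_len(n_tg)) {
      if (occupied[i, j]) next
      # row-first: nearest occupied cell in the same TG row
      row_occ <- which(occupied[i, ])
      if (length(row_occ) > 0) {
        src_j <- row_occ[which.min(abs(row_occ - j))]
        fac[i, j] <- fac[i, src_j]
        fills[[length(fills) + 1L]] <- c(i, j, i, src_j)
        next
      }
      # then column: nearest occupied cell in the same non-HDL column
      col_occ <- which(occupied[, j])
      if (length(col_occ) > 0) {
        src_i <- col_occ[which.min(abs(col_occ - i))]
        fac[i, j] <- fac[src_i, j]
        fills[[length(fills) + 1L]] <- c(i, j, src_i, j)
        next
      }
      # finally: nearest occupied cell anywhere (Manhattan distance)
      d <- abs(occ_idx[, 1] - i) + abs(occ_idx[, 2] - j)
      src <- occ_idx[which.min(d), ]
      fac[i, j] <- fac[src[1], src[2]]
      fills[[length(fills) + 1L]] <- c(i, j, src[1], src[2])
    }
  }
  if (length(fills) > 0) {
    inform(sprintf("derive_strata_table: filled %d empty cell(s) from nearest neighbours",
                   length(fills)))
  }
  out <- strata_table(tg_edges, nonhdl_edges, fac)
  attr(out, "n_dropped") <- n_dropped
  attr(out, "fills") <- if (length(fills) > 0) {
    m <- do.call(rbind, fills)
    tibble(tg_stratum = m[, 1], nonhdl_stratum = m[, 2],
           source_tg = m[, 3], source_nonhdl = m[, 4])
  } else {
    tibble(tg_stratum = integer(), nonhdl_stratum = integer(),
           source_tg = integer(), source_nonhdl = integer())
  }
  out
}

#' Serialise a strata table as delimited text
#'
#' The format is two header lines (`tg_edges`, `nonhdl_edges`) followed by
#' the factor matrix, one TG stratum per row, comma-delimited. Values are
#' written with round-trip precision so `read_strata_table(write_strata_table(x))`
#' is bit-identical to `x`.
#'
#' @param table A `strata_table`.
#' @param path File path.
#' @return `write_strata_table()` returns `path` invisibly;
#'   `read_strata_table()` returns a `strata_table`.
#' @export
write_strata_table <- function(table, path) {
  if (!inherits(table, "strata_table")) {
    abort("`table` must be a strata_table object",
          class = "ldlbench_config_error")
  }
  lines <- c(
    paste(c("tg_edges", fmt_dbl(table$tg_edges)), collapse = ","),
    paste(c("nonhdl_edges", fmt_dbl(table$nonhdl_edges)), collapse = ","),
    apply(table$factors, 1, function(r) paste(fmt_dbl(r), collapse = ","))
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_strata_table
#' @export
read_strata_table <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 3) {
    abort("malformed strata table file", class = "ldlbench_config_error")
  }
  hdr1 <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  hdr2 <- strsplit(lines[2], ",", fixed = TRUE)[[1]]
  if (hdr1[1] != "tg_edges" || hdr2[1] != "nonhdl_edges") {
    abort("malformed strata table header", class = "ldlbench_config_error")
  }
  tg_edges <- parse_dbl(hdr1[-1])
  nonhdl_edges <- parse_dbl(hdr2[-1])
  fac <- do.call(rbind, lapply(lines[-(1:2)], function(l) {
    parse_dbl(strsplit(l, ",", fixed = TRUE)[[1]])
  }))
  strata_table(tg_edges, nonhdl_edges, fac)
}

#' @method autoplot strata_table
#' @export
autoplot.strata_table <- function(object, ...) {
  df <- tidyr::expand_grid(
    tg_stratum = seq_len(nrow(object$factors)),
    nonhdl_stratum = seq_len(ncol(object$factors)))
  df$factor <- object$factors[cbind(df$tg_stratum, df$nonhdl_stratum)]
  ggplot2::ggplot(df, ggplot2::aes(.data$nonhdl_stratum, .data$tg_stratum,
                                   fill = .data$factor)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "TG:VLDL-C\nfactor") +
    ggplot2::labs(x = "non-HDL-C stratum", y = "TG stratum",
                  title = "Adjustable-factor strata table") +
    ggplot2::theme_minimal()
}
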