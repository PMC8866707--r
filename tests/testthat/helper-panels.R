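# Shared fixtures: random but always-valid lipid panels and strata tables,
# generated in code under fixed seeds.

random_panels <- function(n, seed = 1) {
  withr::with_seed(seed, {
    hdl <- runif(n, 25, 85)
    tc <- hdl + runif(n, 40, 220)
    tg <- runif(n, 0, 600)
    tibble::tibble(tc = tc, hdl = hdl, tg = tg)
  })
}

random_strata_table <- function(seed = 1, n_tg = 5, n_nh = 3) {
  withr::with_seed(seed, {
    tg_edges <- c(0, sort(runif(n_tg - 1, 20, 400)), Inf)
    nonhdl_edges <- c(0, sort(runif(n_nh - 1, 60, 220)), Inf)
    factors <- matrix(runif(n_tg * n_nh, 3, 12), n_tg, n_nh)
    strata_table(tg_edges, nonhdl_edges, factors)
  })
}

# Explicit per-record linear-scan lookup: the independent oracle for the
# Martin cell lookup (left-closed right-open strata, clamp to edge strata).
oracle_martin <- function(panels, table) {
  vapply(seq_len(nrow(panels)), function(i) {
    tg <- panels$tg[i]; nonhdl <- panels$tc[i] - panels$hdl[i]
    find_bin <- function(x, edges) {
      k <- length(edges) - 1
      for (b in seq_len(k)) {
        if (x >= edges[b] && x < edges[b + 1]) return(b)
      }
      if (x < edges[1]) 1 else k
    }
    ti <- find_bin(tg, table$tg_edges)
    ni <- find_bin(nonhdl, table$nonhdl_edges)
    panels$tc[i] - panels$hdl[i] - tg / table$factors[ti, ni]
  }, numeric(1))
}
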