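# Shared fixtures (built once per test run) and independent brute-force
# oracles used to cross-check the package implementations.

fix_env <- new.env(parent = emptyenv())

# Small two-chromosome synthetic world with one interphase-strength map.
small_sim <- function() {
  if (is.null(fix_env$small)) {
    cfg <- sim_config(chrom_lengths = c(chrA = 10e6, chrB = 10e6),
                      read_depth = 5e5, n_prdm9_peaks = 400,
                      n_crossovers = 200, seed = 101)
    fix_env$small <- list(cfg = cfg, sim = simulate_all(cfg, stages = "ES"))
  }
  fix_env$small
}

# Dense random symmetric toy contact matrix wrapped as contact_matrix.
toy_cm <- function(n = 60, seed = 42, lambda = 5, trans_lambda = 20) {
  set.seed(seed)
  m <- matrix(rpois(n * n, lambda), n, n)
  m <- m + t(m)
  diag(m) <- 0
  bins <- make_bins(c(chrT = n * 5000), 5000)
  list(m = m, bins = bins,
       cm = contact_matrix(bins, list(chrT = m),
                           trans = rpois(n, trans_lambda)))
}

# --- independent oracles (deliberately naive implementations) ----------

oracle_cis_total <- function(m, trans) {
  vapply(seq_len(nrow(m)), function(i) {
    cis <- sum(m[i, ])
    cis / (cis + trans[i])
  }, numeric(1))
}

oracle_insulation <- function(m, w) {
  n <- nrow(m)
  mean_b <- rep(NA_real_, n)
  for (b in seq_len(n)) {
    if (b - w >= 1 && b + w <= n) {
      mean_b[b] <- mean(m[(b - w):(b - 1), (b + 1):(b + w)])
    }
  }
  log2(mean_b / mean(mean_b, na.rm = TRUE))
}

oracle_coverage <- function(bed, bins) {
  vapply(seq_len(nrow(bins)), function(k) {
    lo <- bins$start[k]
    hi <- bins$end[k]
    covered <- logical(hi - lo)
    for (r in seq_len(nrow(bed))) {
      if (bed$chrom[r] != bins$chrom[k]) next
      a <- max(bed$start[r], lo)
      b <- min(bed$end[r], hi)
      if (b > a) covered[(a - lo + 1):(b - lo)] <- TRUE
    }
    sum(covered) / (hi - lo)
  }, numeric(1))
}

oracle_xo_map <- function(crossovers, bins) {
  raw <- numeric(nrow(bins))
  for (r in seq_len(nrow(crossovers))) {
    hit <- which(bins$chrom == crossovers$chrom[r] &
                   bins$start < crossovers$end[r] &
                   bins$end > crossovers$start[r])
    raw[hit] <- raw[hit] + 1 / length(hit)
  }
  raw
}
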