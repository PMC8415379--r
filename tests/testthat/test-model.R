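# Feature matrix construction, PCA and forward-selection OLS.

mk_sites <- function(bin_ids, bins) {
  row <- bin_ids + 1L
  structure(data.frame(bin_id = bin_ids, chrom = bins$chrom[row],
                       start = bins$start[row], end = bins$end[row],
                       position = bins$start[row] /
                         attr(bins, "chromsizes")[bins$chrom[row]]),
            class = c("site_set", "data.frame"))
}

test_that("feature columns are standardized and windows hand-computable", {
  nb <- 400
  bins <- make_bins(c(cT = nb * 5000), 5000)
  set.seed(1)
  v <- rnorm(nb)
  delta <- numeric(nb)
  delta[201] <- 1  # bin_id 200
  sites <- mk_sites(as.integer(seq(60, 340, by = 20)), bins)
  expect_warning(
    fm <- build_feature_matrix(
      sites, list(x = binned_track(v, "x"),
                  d = binned_track(delta, "d"),
                  flat = binned_track(rep(2, nb), "flat")),
      bins),
    "zero-variance")
  expect_false(any(grepl("flat", colnames(fm))))
  expect_true(all(abs(colMeans(fm)) < 1e-9))
  expect_true(all(abs(apply(fm, 2, sd) - 1) < 1e-9))

  # delta track pre-scaling: local = 1 only at the delta site; the 101-bin
  # window mean is 1/101 at sites centered there
  raw_local <- delta[sites$bin_id + 1]
  raw_win <- vapply(sites$bin_id, function(b) {
    mean(delta[(b - 50):(b + 50) + 1])
  }, numeric(1))
  k <- which(sites$bin_id == 200)
  expect_equal(raw_local[k], 1)
  expect_equal(raw_win[k], 1 / 101)
  # standardization preserves the ordering of the hand-computed values
  expect_equal(order(fm[, "d_win"]), order(raw_win))
})

test_that("window means clip at chromosome ends and rows with NAs drop", {
  bins <- make_bins(c(cT = 100 * 5000), 5000)
  v <- rep(1, 100)
  v[50] <- NA
  sites <- mk_sites(c(0L, 49L, 80L), bins)
  fm <- suppressWarnings(
    build_feature_matrix(sites, list(x = binned_track(v, "x")), bins,
                         window_bins = 10))
  # site at bin 49 has a missing local value -> dropped
  expect_equal(attr(fm, "dropped_rows"), 1L)
  expect_equal(nrow(fm), 2L)
})

test_that("scaling is idempotent", {
  set.seed(2)
  X <- scale(matrix(rnorm(200), 50, 4))
  X2 <- scale(X)
  expect_lt(max(abs(X2 - X)), 1e-12)
})

test_that("joint sites contain both parents' sites", {
  sm <- small_sim()
  ps <- define_sites(sm$sim$peaks$prdm9_peaks, sm$sim$bins, label = "PRDM9")
  ds <- define_sites(sm$sim$peaks$dmc1_peaks, sm$sim$bins, label = "DSB")
  js <- union_sites(ps, ds)
  expect_gte(nrow(js), max(nrow(ps), nrow(ds)))
  expect_setequal(js$bin_id, union(ps$bin_id, ds$bin_id))
  expect_true(all(js$is_prdm9 | js$is_dsb))
})

test_that("PCA matches the 2x2 closed form and is orthonormal", {
  set.seed(3)
  n <- 800
  x1 <- rnorm(n)
  for (r in c(0.3, 0.7, 0.95)) {
    x2 <- r * x1 + sqrt(1 - r^2) * rnorm(n)
    X <- scale(cbind(a = x1, b = x2))
    pc <- run_pca(X, 2)
    emp <- abs(cor(X[, 1], X[, 2]))
    expect_equal(pc$explained_var[1], (1 + emp) / 2, tolerance = 1e-10)
  }
  # two perfectly correlated columns: PC1 carries everything
  Xp <- scale(cbind(a = x1, b = 2 * x1 + 3))
  pcp <- run_pca(Xp, 2)
  expect_equal(pcp$explained_var[1], 1, tolerance = 1e-12)

  # orthonormal loadings, deterministic sign, full reconstruction
  set.seed(4)
  M <- scale(matrix(rnorm(60 * 6), 60, 6))
  colnames(M) <- paste0("v", 1:6)
  pc <- run_pca(M, 6)
  expect_lt(max(abs(crossprod(pc$loadings) - diag(6))), 1e-9)
  expect_true(all(apply(pc$loadings, 2,
                        function(l) l[which.max(abs(l))] > 0)))
  expect_lt(max(abs(pc$scores %*% t(pc$loadings) - M)), 1e-8)
  expect_true(all(diff(pc$explained_var) <= 1e-12))
  expect_error(run_pca(M[1, , drop = FALSE]), "at least 2 rows")
})

test_that("forward selection recovers a planted predictor and stays null-calibrated", {
  n <- 2000
  hits <- 0L
  coefs <- numeric(0)
  nulls <- 0L
  reps <- 25L
  for (i in seq_len(reps)) {
    set.seed(1000 + i)
    X <- matrix(rnorm(n * 10), n, 10,
                dimnames = list(NULL, paste0("x", 1:10)))
    y <- 2 * X[, "x1"] + rnorm(n)
    fit <- forward_select_ols(y, X)
    if (identical(fit$selected, "x1")) {
      hits <- hits + 1L
      coefs <- c(coefs, fit$coef[["x1"]])
    }
    ynull <- rnorm(n)
    fit0 <- forward_select_ols(ynull, X)
    if (length(fit0$selected) == 0L) nulls <- nulls + 1L
  }
  expect_gte(hits, ceiling(0.95 * reps))
  expect_equal(mean(coefs), 2, tolerance = 0.05)
  expect_gte(nulls, floor(0.96 * reps))
})

test_that("forward selection contracts: exactness, monotone R2, order, ties", {
  set.seed(7)
  n <- 300
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("x", 1:5)))
  y <- X[, "x3"]
  fit <- forward_select_ols(y, X)
  expect_equal(fit$selected[1], "x3")
  expect_equal(fit$r2, 1, tolerance = 1e-12)

  y2 <- X[, "x1"] + 0.5 * X[, "x2"] + rnorm(n, sd = 0.5)
  f1 <- forward_select_ols(y2, X)
  expect_true(all(diff(c(0, f1$r2_path)) >= -1e-12))
  # selection is independent of candidate column order
  f2 <- forward_select_ols(y2, X[, c(4, 2, 5, 1, 3)])
  expect_identical(f1$selected, f2$selected)
  # a duplicated candidate is skipped as collinear once its twin is in
  Xd <- cbind(X, x1b = X[, "x1"])
  expect_warning(f3 <- forward_select_ols(y2, Xd), "collinear")
  expect_false(all(c("x1", "x1b") %in% f3$selected))
  # naive baseline never exceeds the full model when nested
  f4 <- forward_select_ols(y2, X, naive = "x1")
  expect_gte(f4$r2, f4$naive_r2)
})

test_that("the three recombination models recover the injected structure", {
  # lower crossover saturation (600 of 3000 hotspots) keeps the positional
  # ramp visible in which hotspots become crossovers
  cfg <- sim_config(n_crossovers = 600, seed = 1)
  g <- simulate_genome(cfg)
  pk <- simulate_peaks_and_tracks(g, g$truth, cfg)
  xo <- simulate_crossovers(g$truth, pk$dmc1_peaks, cfg, g$bins)
  xot <- crossover_score_map(xo, g$bins)
  cmE <- simulate_contacts(g, g$truth, cfg, "ES")
  states <- chromhmm_overlap_tracks(g$chromhmm, g$bins)
  ref <- binned_track(states[, "promoter"] + states[, "prom_enh"] +
                        states[, "enh_gene_body"] + states[, "gene_body"],
                      "ref")
  vars <- list(cis_total = cis_total_ratio(cmE),
               compartment = fine_grain_compartment(cmE, ref),
               fire = fire_score(cmE),
               rnapii = pk$tracks$rnapii,
               state_gene_body = binned_track(states[, "gene_body"], "gb",
                                              "coverage"),
               state_unmarked = binned_track(states[, "unmarked"], "um",
                                             "coverage"))
  st <- list(prdm9_score = pk$tracks$prdm9, dmc1_score = pk$tracks$dmc1,
             crossover_score = xot)
  js <- union_sites(define_sites(pk$prdm9_peaks, g$bins, st, "PRDM9"),
                    define_sites(pk$dmc1_peaks, g$bins, st, "DSB"))
  fm <- build_feature_matrix(js, vars, g$bins)
  pca <- run_pca(fm, 4)
  mods <- fit_recombination_models(pca, fm)

  # DSB model: PRDM9 binding strength enters positively, and the implied
  # association with the compartment score is positive (A-biased DSBs)
  expect_true("prdm9_score" %in% mods$dsb$selected)
  expect_gt(mods$dsb$coef[["prdm9_score"]], 0)
  sel_pcs <- intersect(mods$dsb$selected, colnames(pca$scores))
  implied_comp <- sum(vapply(sel_pcs, function(pc) {
    mods$dsb$coef[[pc]] * pca$loadings["compartment_local", pc]
  }, numeric(1)))
  expect_gt(implied_comp, 0)
  expect_gt(mods$dsb$r2, mods$dsb$naive_r2)

  # crossover model: position enters positively (pericentromeric
  # depletion), and the implied gene-body association is negative
  expect_true("position" %in% mods$crossover$selected)
  expect_gt(mods$crossover$coef[["position"]], 0)
  xo_pcs <- intersect(mods$crossover$selected, colnames(pca$scores))
  implied_gb <- sum(vapply(xo_pcs, function(pc) {
    mods$crossover$coef[[pc]] * pca$loadings["state_gene_body_local", pc]
  }, numeric(1)))
  expect_lt(implied_gb, 0)
  expect_gt(mods$crossover$r2, mods$crossover$naive_r2)

  # shuffling the response destroys all selections
  meta <- attr(fm, "row_meta")
  set.seed(2)
  yshuf <- sample(meta$dmc1_score[meta$is_prdm9])
  cand <- cbind(pca$scores[meta$is_prdm9, ],
                prdm9_score = scale(meta$prdm9_score[meta$is_prdm9])[, 1],
                position = scale(meta$position[meta$is_prdm9])[, 1])
  fshuf <- forward_select_ols(yshuf, cand)
  expect_length(fshuf$selected, 0L)
})
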