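# Hi-C score derivations against brute-force oracles and their invariances.

test_that("cis/total matches the brute-force oracle exactly", {
  tc <- toy_cm(80, seed = 7)
  ct <- as.numeric(cis_total_ratio(tc$cm))
  expect_equal(ct, oracle_cis_total(tc$m, tc$cm$trans), tolerance = 1e-12)
  expect_true(all(ct >= 0 & ct <= 1))
})

test_that("cis/total handles trivial and pooled cases", {
  n <- 20
  bins <- make_bins(c(cT = n * 5000), 5000)
  m <- matrix(1, n, n); diag(m) <- 0
  cm0 <- contact_matrix(bins, list(cT = m))  # trans all zero
  expect_true(all(as.numeric(cis_total_ratio(cm0)) == 1))

  m2 <- matrix(0, 2, 2); m2[1, 2] <- m2[2, 1] <- 30
  b2 <- make_bins(c(cT = 10000), 5000)
  cm2 <- contact_matrix(b2, list(cT = m2), trans = c(70, 70))
  expect_equal(as.numeric(cis_total_ratio(cm2)), c(0.30, 0.30))

  # pooling: a 3-bin centered window pools the raw sums
  tc <- toy_cm(30, seed = 2)
  agg <- as.numeric(cis_total_ratio(tc$cm, aggregation_bp = 15000))
  i <- 10
  cis3 <- sum(tc$m[(i - 1):(i + 1), ])
  tr3 <- sum(tc$cm$trans[(i - 1):(i + 1)])
  expect_equal(agg[i], cis3 / (cis3 + tr3), tolerance = 1e-12)
})

test_that("compartment eigenvector resolves an exact two-block checkerboard", {
  n <- 80
  blk <- rep(c(1, -1), each = n / 2)
  m <- 5 + 2 * outer(blk, blk)  # 7 within blocks, 3 across
  diag(m) <- 0
  bins <- make_bins(c(cT = n * 5000), 5000)
  cm <- contact_matrix(bins, list(cT = m))
  ref <- binned_track(blk, "ref")
  sc <- as.numeric(fine_grain_compartment(cm, ref, chunk_bp = n * 5000,
                                          min_valid = 10))
  # the O/E step leaves mild distance texture inside blocks, so recovery
  # of the block structure is near-exact rather than exact
  expect_gt(cor(sc, blk), 0.97)  # oriented along the reference
  expect_true(all(sign(sc[1:(n / 2)]) == 1))
  expect_true(all(sign(sc[(n / 2 + 1):n]) == -1))

  # negating the reference flips the sign exactly
  sc_neg <- as.numeric(fine_grain_compartment(cm, binned_track(-blk, "ref"),
                                              chunk_bp = n * 5000,
                                              min_valid = 10))
  expect_equal(sc_neg, -sc, tolerance = 1e-8)

  # invariant to multiplying the matrix by a positive scalar
  cm2 <- contact_matrix(bins, list(cT = 3.7 * m))
  sc2 <- as.numeric(fine_grain_compartment(cm2, ref, chunk_bp = n * 5000,
                                           min_valid = 10))
  expect_equal(sc2, sc, tolerance = 1e-6)
})

test_that("compartment scores recover the injected labels on synthetic maps", {
  sm <- small_sim()
  states <- chromhmm_overlap_tracks(sm$sim$chromhmm, sm$sim$bins)
  ref <- binned_track(states[, "promoter"] + states[, "prom_enh"] +
                        states[, "enh_gene_body"] + states[, "gene_body"],
                      "activity")
  sc <- as.numeric(fine_grain_compartment(sm$sim$contacts$ES, ref))
  truth <- ifelse(sm$sim$truth$compartment == "A", 1, -1)
  expect_gt(cor(sc, truth, use = "complete.obs"), 0.85)
})

test_that("insulation matches the diamond-window oracle and its invariances", {
  tc <- toy_cm(60, seed = 11)
  w <- 4L
  ins <- as.numeric(insulation_score(tc$cm, window_bp = 20000))
  orc <- oracle_insulation(tc$m, w)
  expect_equal(ins, orc, tolerance = 1e-12)

  # Toeplitz matrix: all interior scores equal
  n <- 40
  tm <- outer(1:n, 1:n, function(i, j) 10 / (1 + abs(i - j)))
  diag(tm) <- 0
  bins <- make_bins(c(cT = n * 5000), 5000)
  cmt <- contact_matrix(bins, list(cT = tm))
  ti <- as.numeric(insulation_score(cmt, 20000))
  interior <- ti[!is.na(ti)]
  expect_lt(diff(range(interior)), 1e-9)

  # all-equal matrix: score 0 everywhere defined
  me <- matrix(3, n, n); diag(me) <- 0
  # keep the diagonal consistent with a constant diamond: the diamond
  # window never touches the diagonal, so zeroing it is irrelevant
  cme <- contact_matrix(bins, list(cT = me))
  se <- as.numeric(insulation_score(cme, 20000))
  expect_lt(max(abs(se), na.rm = TRUE), 1e-12)

  # two dense blocks with sparse inter-block contacts: minimum at boundary
  blk <- matrix(0.1, n, n)
  half <- n / 2
  blk[1:half, 1:half] <- 5
  blk[(half + 1):n, (half + 1):n] <- 5
  diag(blk) <- 0
  cmb <- contact_matrix(bins, list(cT = blk))
  sb <- as.numeric(insulation_score(cmb, 20000))
  # the two bins flanking the block boundary tie for the global minimum
  expect_true(which.min(sb) %in% c(half, half + 1L))
  expect_lt(sb[half], min(sb[-c(half, half + 1L)], na.rm = TRUE))

  # scaling invariance (ratio-of-means construction)
  cms <- contact_matrix(bins, list(cT = 11 * blk))
  expect_equal(as.numeric(insulation_score(cms, 20000)), sb,
               tolerance = 1e-12)

  # window larger than the chromosome: all missing
  tiny <- contact_matrix(make_bins(c(cT = 20000), 5000),
                         list(cT = matrix(1, 4, 4) - diag(4)))
  expect_true(all(is.na(as.numeric(insulation_score(tiny, 10000)))))
  expect_error(insulation_score(tc$cm, 7777), "multiple")
})

test_that("FIRE scores flag locally enriched bins and ignore global shifts", {
  n <- 60
  bins <- make_bins(c(cT = n * 5000), 5000)
  base <- matrix(2, n, n); diag(base) <- 0
  cm0 <- contact_matrix(bins, list(cT = base))
  expect_lt(max(abs(as.numeric(fire_score(cm0)))), 1e-9)

  # doubling one bin's near-band contacts makes it the chromosome maximum
  hot <- base
  tgt <- 30
  nb <- setdiff(which(abs(seq_len(n) - tgt) >= 3 & abs(seq_len(n) - tgt) <= 40),
                tgt)
  hot[tgt, nb] <- hot[nb, tgt] <- 4
  cmh <- contact_matrix(bins, list(cT = hot))
  fh <- as.numeric(fire_score(cmh))
  expect_equal(which.max(fh), tgt)

  # adding a constant to every entry leaves the ranking unchanged
  cmc <- contact_matrix(bins, list(cT = hot + 1 - diag(n)))
  fc <- as.numeric(fire_score(cmc))
  expect_equal(order(fc), order(fh))
  expect_error(fire_score(cmh, near_lo = 5e4, near_hi = 2e4), "smaller")
})
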