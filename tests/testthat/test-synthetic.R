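# The synthetic-genome generator: label partitions, determinism, and the
# statistical structure the downstream modules are meant to recover.

test_that("simulate_genome partitions every bin exactly once", {
  cfg <- sim_config(chrom_lengths = c(c1 = 10e6), seed = 3)
  g <- simulate_genome(cfg)
  expect_equal(nrow(g$bins), 2000L)
  expect_equal(length(g$truth$compartment), 2000L)
  expect_true(all(g$truth$compartment %in% c("A", "B")))
  expect_true(all(g$truth$state %in% chromhmm_states()))
  # the BED4 segmentation covers the genome without gaps or overlaps
  ov <- chromhmm_overlap_tracks(g$chromhmm, g$bins)
  expect_true(all(abs(rowSums(ov) - 1) < 1e-12))
})

test_that("the generator is byte-identical under a fixed seed", {
  cfg <- sim_config(chrom_lengths = c(c1 = 5e6), read_depth = 5e4,
                    n_prdm9_peaks = 60, n_crossovers = 30, seed = 12)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(simulate_all(cfg, stages = "ES"), d1)
  write_simulation(simulate_all(cfg, stages = "ES"), d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7),
                     label = paste("bytes of", f))
  }
})

test_that("gene-body chromatin concentrates in the A compartment", {
  sm <- small_sim()
  tr <- sm$sim$truth
  frac_A <- mean(tr$state[tr$compartment == "A"] == "gene_body")
  frac_B <- mean(tr$state[tr$compartment == "B"] == "gene_body")
  expect_gt(frac_A, frac_B)
})

test_that("expected matrix is symmetric and homogeneous without structure", {
  cfg <- sim_config(chrom_lengths = c(c1 = 5e6), shoulder_amp = 0,
                    compartment_strength = c(ES = 0), seed = 5)
  g <- simulate_genome(cfg)
  E <- expected_contact_matrix(g, g$truth, cfg, "ES")$c1
  expect_equal(max(abs(E - t(E))), 0)
  # with no compartment or shoulder structure, bins with mirrored distance
  # coverage have identical column sums
  cs <- colSums(E)
  expect_lt(max(abs(cs - rev(cs))), 1e-9)
})

test_that("sampled maps show lower cis/total in A than in B", {
  sm <- small_sim()
  ct <- as.numeric(cis_total_ratio(sm$sim$contacts$ES))
  lab <- sm$sim$truth$compartment
  expect_lt(mean(ct[lab == "A"], na.rm = TRUE),
            mean(ct[lab == "B"], na.rm = TRUE))
})

test_that("simulate_contacts validates stage and depth", {
  sm <- small_sim()
  expect_error(simulate_contacts(sm$sim, sm$sim$truth, sm$cfg, "mitosis"),
               "unknown stage")
  bad <- sm$cfg
  bad$read_depth <- 0
  expect_error(check_stage(bad, "ES"), "read_depth")
})

test_that("DMC1 equals PRDM9 when bias and noise are off", {
  cfg <- sim_config(chrom_lengths = c(c1 = 5e6), dsb_bias_A = 1,
                    dmc1_noise_sd = 0, n_prdm9_peaks = 100, seed = 8)
  g <- simulate_genome(cfg)
  pk <- simulate_peaks_and_tracks(g, g$truth, cfg)
  expect_equal(pk$dmc1_peaks$score, pk$prdm9_peaks$score)
})

test_that("peaks are valid intervals inside their chromosome", {
  sm <- small_sim()
  pk <- sm$sim$peaks$prdm9_peaks
  sz <- sm$sim$chromsizes
  expect_true(all(pk$end > pk$start))
  expect_true(all(pk$start >= 0 & pk$end <= sz[pk$chrom]))
  # default placement skews A over B
  lab <- sm$sim$truth$compartment[pk$bin_id + 1]
  expect_gt(mean(lab == "A"), 0.5)
  # and A peaks carry higher median DMC1 scores (dsb_bias_A > 1)
  dm <- sm$sim$peaks$dmc1_peaks
  labd <- sm$sim$truth$compartment[dm$bin_id + 1]
  expect_gt(median(dm$score[labd == "A"]), median(dm$score[labd == "B"]))
})

test_that("crossover generation conserves counts and respects weights", {
  sm <- small_sim()
  xo <- sm$sim$crossovers
  expect_equal(nrow(xo), sm$cfg$n_crossovers)
  expect_true(all(xo$end > xo$start))
  expect_true(all(xo$start >= 0 & xo$end <= sm$sim$chromsizes[xo$chrom]))
  # sources are depleted in gene-body state relative to the DSB peak pool
  st <- sm$sim$truth$state
  src_gb <- mean(st[xo$source_bin + 1] == "gene_body")
  pool_gb <- mean(st[sm$sim$peaks$dmc1_peaks$bin_id + 1] == "gene_body")
  expect_lt(src_gb, pool_gb)
})

test_that("gene_body_penalty = 0 forbids gene-body sources; n = 0 is empty", {
  cfg <- sim_config(chrom_lengths = c(c1 = 10e6), gene_body_penalty = 0,
                    n_prdm9_peaks = 300, n_crossovers = 50, seed = 21)
  g <- simulate_genome(cfg)
  pk <- simulate_peaks_and_tracks(g, g$truth, cfg)
  xo <- simulate_crossovers(g$truth, pk$dmc1_peaks, cfg, g$bins)
  expect_false(any(g$truth$state[xo$source_bin + 1] == "gene_body"))

  cfg0 <- sim_config(chrom_lengths = c(c1 = 10e6), n_crossovers = 0, seed = 21)
  xo0 <- simulate_crossovers(g$truth, pk$dmc1_peaks, cfg0, g$bins)
  expect_equal(nrow(xo0), 0L)
  # an empty crossover BED still carries its header line
  path <- withr::local_tempfile(fileext = ".bed")
  write_bed(xo0, path)
  expect_match(readLines(path)[1], "^#chrom")
  expect_equal(length(readLines(path)), 1L)
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(cis_fraction_base = 1.2), "cis_fraction_base")
  expect_error(sim_config(cis_fraction_base = 0.99, cis_offset = 0.05),
               "cis_offset")
  expect_error(sim_config(chrom_lengths = c(a = 1000), bin_size = 5000),
               "at least one bin")
  sm <- small_sim()
  cfgN <- sm$cfg
  cfgN$n_prdm9_peaks <- nrow(sm$sim$bins) + 1
  expect_error(
    simulate_peaks_and_tracks(sm$sim, sm$sim$truth, cfgN),
    "exceeds")
  cfgX <- sm$cfg
  cfgX$n_crossovers <- nrow(sm$sim$peaks$dmc1_peaks) + 1
  expect_error(
    simulate_crossovers(sm$sim$truth, sm$sim$peaks$dmc1_peaks, cfgX,
                        sm$sim$bins),
    "exceeds")
})
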