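# Crossover-score map, site definition, quartile partitioning and
# enrichment statistics.

test_that("crossover mass is split over intersected bins and normalized", {
  bins <- make_bins(c(cT = 500000), 5000)
  # crossover A inside one bin, crossover B spanning four bins
  xo <- data.frame(chrom = "cT", start = c(1000, 50000), end = c(2000, 70000))
  trk <- crossover_score_map(xo, bins)
  raw <- attr(trk, "raw")
  expect_equal(sort(raw[raw > 0]), c(0.25, 0.25, 0.25, 0.25, 1))
  expect_equal(sum(raw), nrow(xo))           # unit mass per crossover
  expect_equal(sort(unique(as.numeric(trk)[raw > 0])), c(1, 4))
  expect_equal(median(as.numeric(trk)[raw > 0]), 1)  # median-normalized

  expect_warning(z <- crossover_score_map(xo[0, ], bins), "no crossovers")
  expect_true(all(as.numeric(z) == 0))
})

test_that("crossover map equals the naive oracle and conserves mass", {
  sm <- small_sim()
  trk <- crossover_score_map(sm$sim$crossovers, sm$sim$bins)
  raw <- attr(trk, "raw")
  expect_equal(raw, oracle_xo_map(sm$sim$crossovers, sm$sim$bins),
               tolerance = 1e-12)
  expect_equal(sum(raw), nrow(sm$sim$crossovers), tolerance = 1e-9)
  expect_equal(median(as.numeric(trk)[raw > 0]), 1, tolerance = 1e-12)
})

test_that("sites sit in the bin containing the peak center", {
  bins <- make_bins(c(cT = 50000), 5000)
  s1 <- define_sites(data.frame(chrom = "cT", start = 6000, end = 9000), bins)
  expect_equal(s1$bin_id, 1L)        # center 7500 -> [5000,10000)
  s2 <- define_sites(data.frame(chrom = "cT", start = 4000, end = 6000), bins)
  expect_equal(s2$bin_id, 1L)        # center exactly 5000: half-open bin
  # two peaks with centers in one bin collapse to one site
  s3 <- define_sites(data.frame(chrom = "cT", start = c(6000, 6200),
                                end = c(9000, 9400)), bins)
  expect_equal(nrow(s3), 1L)
  # summit offset takes precedence over the midpoint
  s4 <- define_sites(data.frame(chrom = "cT", start = 6000, end = 9000,
                                summit = 4500), bins)
  expect_equal(s4$bin_id, 2L)        # 6000 + 4500 = 10500 -> bin 2
  # scores attach from tracks, position is fractional
  trk <- binned_track(c(10, 20, 30, 40, 50, 60, 70, 80, 90, 100), "x")
  s5 <- define_sites(data.frame(chrom = "cT", start = 6000, end = 9000),
                     make_bins(c(cT = 50000), 5000),
                     score_tracks = list(x = trk))
  expect_equal(s5$x, 20)
  expect_equal(s5$position, 5000 / 50000)
})

test_that("quartile partitioning follows floor(n/4) with coordinate ties", {
  mk <- function(sc) {
    n <- length(sc)
    structure(data.frame(bin_id = 0:(n - 1), chrom = "cT",
                         start = (0:(n - 1)) * 5000, end = (1:n) * 5000,
                         position = 0, sc = sc),
              class = c("site_set", "data.frame"))
  }
  p8 <- partition_quartiles(mk(1:8), "sc")
  expect_equal(sort(p8$top), c(6L, 7L))      # scores 7, 8
  expect_equal(sort(p8$bottom), c(0L, 1L))   # scores 1, 2
  p9 <- partition_quartiles(mk(1:9), "sc")
  expect_equal(length(p9$top), 2L)
  expect_equal(length(p9$bottom), 2L)
  # all-equal scores: purely coordinate tie-break, still disjoint
  pt <- partition_quartiles(mk(rep(5, 12)), "sc")
  expect_length(intersect(pt$top, pt$bottom), 0L)
  expect_equal(pt$top, 0:2)
  # untied scores: min(top) >= max(bottom)
  set.seed(4)
  sc <- sample(100, 40)
  pu <- partition_quartiles(mk(sc), "sc")
  expect_gte(min(sc[pu$top + 1]), max(sc[pu$bottom + 1]))
  expect_error(partition_quartiles(mk(c(1, 2, 3)), "sc"), "fewer than 8")
})

test_that("enrichment summary is zero at the median and Bonferroni-adjusted", {
  bins <- make_bins(c(cT = 100 * 5000), 5000)
  v <- rep(2, 100)
  sites <- structure(data.frame(bin_id = 0:39, chrom = "cT",
                                start = (0:39) * 5000, end = (1:40) * 5000,
                                position = 0, sc = rnorm(40)),
                     class = c("site_set", "data.frame"))
  part <- partition_quartiles(sites, "sc")
  es <- enrichment_summary(part, sites, list(flat = binned_track(v, "flat")))
  expect_equal(es$log2fc_all, 0)
  expect_equal(es$log2fc_top, 0)
  # Bonferroni: adjusted p = min(1, m * p)
  set.seed(1)
  vars <- lapply(1:5, function(i) binned_track(rnorm(100), paste0("v", i)))
  names(vars) <- paste0("v", 1:5)
  es5 <- enrichment_summary(part, sites, vars)
  expect_equal(es5$p_adj, pmin(1, 5 * es5$p))
})

test_that("enrichment flags a strong shift but stays calibrated under the null", {
  set.seed(99)
  nb <- 1000
  bins <- make_bins(c(cT = nb * 5000), 5000)
  mk_part <- function() {
    list(top = 0:199, bottom = 200:399)
  }
  sites <- structure(data.frame(bin_id = 0:399, chrom = "cT",
                                start = (0:399) * 5000,
                                end = (1:400) * 5000, position = 0),
                     class = c("site_set", "data.frame"))
  part <- structure(c(mk_part(), list(ranking = "x", n_used = 400)),
                    class = "site_partition")
  # power: top shifted by +3 SD with n = 200 per group
  v <- rnorm(nb)
  v[1:200] <- v[1:200] + 3
  es <- enrichment_summary(part, sites, list(x = binned_track(v, "x")))
  expect_true(es$significant)
  # null calibration on 300 quick replicates (full 1000 in acceptance)
  flags <- vapply(1:300, function(i) {
    vn <- rnorm(nb)
    enrichment_summary(part, sites,
                       list(x = binned_track(vn, "x")))$significant
  }, logical(1))
  expect_lte(mean(flags), 0.03)
})

test_that("state-conditioned scores group every site exactly once", {
  bins <- make_bins(c(cT = 10 * 5000), 5000)
  ov <- matrix(0, 10, 7, dimnames = list(NULL, chromhmm_states()))
  ov[1:4, "gene_body"] <- 1
  ov[5:7, "unmarked"] <- 1
  ov[8, c("promoter", "unmarked")] <- 0.5  # tie -> first declared state
  ov[9:10, "repressed"] <- 1
  class(ov) <- c("state_overlap", class(ov))
  # scores boosted threefold in the gene-body state
  base <- c(2, 2, 2, 2, 1, 1, 1, 1, 1, 1)
  sc <- base * ifelse(seq_len(10) <= 4, 3, 1)
  sites <- structure(data.frame(bin_id = 0:9, chrom = "cT",
                                start = (0:9) * 5000, end = (1:10) * 5000,
                                position = 0, dmc1 = sc),
                     class = c("site_set", "data.frame"))
  out <- state_conditioned_scores(sites, ov, "dmc1")
  expect_equal(sum(unlist(out$n)), nrow(sites))
  expect_equal(names(which.max(out$medians)), "gene_body")
  expect_true("promoter" %in% names(out$scores))  # the tie went to promoter
  expect_equal(out$n[["promoter"]], 1L)
})
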