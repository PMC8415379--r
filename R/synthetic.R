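# Synthetic meiotic genome generator: compartment blocks, a seven-state
# segmentation, Hi-C contacts with compartment-specific loop shoulders,
# recombination peak sets and crossover intervals — all with known ground
# truth and bit-for-bit seed determinism.

#' Configuration for the synthetic genome
#'
#' Defaults define the reference study conditions used throughout the test
#' suite: three 60-Mb chromosomes at 5-kb bins, alternating A/B compartment
#' blocks of mean length 2 Mb, a power-law contact decay with exponent -1
#' carrying compartment-specific loop shoulders at 0.7 Mb (A) and 2.1 Mb
#' (B) — a threefold difference — and roughly 5e6 cis contacts per
#' chromosome.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths (bp).
#' @param bin_size Bin width (bp).
#' @param compartment_block_mean Mean alternating A/B block length (bp);
#'   block lengths are exponential.
#' @param ps_exponent Power-law exponent of contact decay.
#' @param loop_size_A,loop_size_B Mean loop shoulder scale (bp) per
#'   compartment; the P(s) derivative maximum of the noise-free model sits
#'   at these distances.
#' @param shoulder_amp Amplitude of the multiplicative log-normal loop
#'   shoulder (0 disables it).
#' @param shoulder_sigma Width of the shoulder in log10 units.
#' @param compartment_strength Named non-negative vector, one entry per
#'   stage: multiplicative enrichment of same-compartment contacts.
#' @param cis_fraction_base Baseline expected cis/total ratio, in (0, 1).
#' @param cis_offset Compartment offset of the expected cis/total ratio
#'   (added in B bins, subtracted in A bins).
#' @param read_depth Expected cis contacts per chromosome.
#' @param n_prdm9_peaks Number of PRDM9 peaks genome-wide.
#' @param prdm9_frac_A Fraction of PRDM9 peaks placed in A compartment.
#' @param dsb_bias_A Multiplicative DSB-score bias in the A compartment.
#' @param dmc1_noise_sd Log-normal noise sd on DMC1 scores (0 disables).
#' @param n_crossovers Number of crossover intervals.
#' @param gene_body_penalty Multiplicative crossover-source weight in the
#'   gene-body state.
#' @param zygo_dip Optional extra local cis/total dip at PRDM9 bins in
#'   zygonema (magnitude of the ratio decrease; default 0 = off, since no
#'   quantitative magnitude is established).
#' @param seed Integer seed fixing all outputs bit-for-bit.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(chrom_lengths = c(chr1 = 60e6, chr2 = 60e6, chr3 = 60e6),
                       bin_size = 5000,
                       compartment_block_mean = 2e6,
                       ps_exponent = -1.0,
                       loop_size_A = 0.7e6,
                       loop_size_B = 2.1e6,
                       shoulder_amp = 0.6,
                       shoulder_sigma = 0.35,
                       compartment_strength = c(ES = 1.0, zygonema = 0.6,
                                                pachynema = 0.8),
                       cis_fraction_base = 0.8,
                       cis_offset = 0.05,
                       read_depth = 5e6,
                       n_prdm9_peaks = 3000,
                       prdm9_frac_A = 0.57,
                       dsb_bias_A = 2.0,
                       dmc1_noise_sd = 0.5,
                       n_crossovers = 2000,
                       gene_body_penalty = 0.2,
                       zygo_dip = 0,
                       seed = 1L) {
  # tolerate YAML-style named lists for the vector-valued fields
  if (is.list(chrom_lengths)) chrom_lengths <- unlist(chrom_lengths)
  if (is.list(compartment_strength)) {
    compartment_strength <- unlist(compartment_strength)
  }
  cfg <- list(chrom_lengths = chrom_lengths, bin_size = bin_size,
              compartment_block_mean = compartment_block_mean,
              ps_exponent = ps_exponent, loop_size_A = loop_size_A,
              loop_size_B = loop_size_B, shoulder_amp = shoulder_amp,
              shoulder_sigma = shoulder_sigma,
              compartment_strength = compartment_strength,
              cis_fraction_base = cis_fraction_base, cis_offset = cis_offset,
              read_depth = read_depth, n_prdm9_peaks = n_prdm9_peaks,
              prdm9_frac_A = prdm9_frac_A, dsb_bias_A = dsb_bias_A,
              dmc1_noise_sd = dmc1_noise_sd, n_crossovers = n_crossovers,
              gene_body_penalty = gene_body_penalty, zygo_dip = zygo_dip,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (is.null(names(chrom_lengths)) || any(chrom_lengths <= 0)) {
      stop("chrom_lengths must be a named vector of positive lengths")
    }
    if (bin_size <= 0) stop("bin_size must be positive")
    if (any(chrom_lengths < bin_size)) {
      stop("every chromosome must hold at least one bin")
    }
    if (cis_fraction_base <= 0 || cis_fraction_base >= 1) {
      stop("cis_fraction_base must lie in (0, 1)")
    }
    lo <- cis_fraction_base - cis_offset
    hi <- cis_fraction_base + cis_offset
    if (lo <= 0 || hi >= 1) stop("cis_offset pushes cis fraction outside (0, 1)")
    if (any(compartment_strength < 0)) stop("compartment_strength must be >= 0")
    if (is.null(names(compartment_strength))) {
      stop("compartment_strength must be named by stage")
    }
    if (loop_size_A <= 0 || loop_size_B <= 0 || shoulder_sigma <= 0) {
      stop("loop sizes and shoulder_sigma must be positive")
    }
    if (gene_body_penalty < 0) stop("gene_body_penalty must be >= 0")
    if (n_prdm9_peaks < 1 || n_crossovers < 0) stop("invalid peak/crossover counts")
  })
  invisible(cfg)
}

# State frequencies per compartment: active states concentrate in A,
# unmarked/repressed chromatin in B.
state_probs <- function() {
  states <- chromhmm_states()
  rbind(A = stats::setNames(c(0.06, 0.05, 0.08, 0.09, 0.22, 0.38, 0.12), states),
        B = stats::setNames(c(0.015, 0.015, 0.03, 0.035, 0.07, 0.64, 0.195),
                            states))
}

# Draw consecutive block lengths (in bins) covering n bins; exponential
# lengths with the given mean, at least one bin each.
draw_blocks <- function(n_bins, mean_bins) {
  lens <- integer(0)
  total <- 0L
  while (total < n_bins) {
    l <- max(1L, as.integer(round(rexp(1L, rate = 1 / mean_bins))))
    lens <- c(lens, l)
    total <- total + l
  }
  lens[length(lens)] <- lens[length(lens)] - (total - n_bins)
  lens[lens > 0L]
}

#' Simulate the synthetic genome skeleton
#'
#' Generates the bin table, alternating A/B compartment blocks
#' (exponentially distributed lengths), and a seven-state segmentation in
#' which promoter/enhancer/gene-body states concentrate in A blocks and
#' unmarked/repressed chromatin in B blocks.
#'
#' @param config A [sim_config()].
#' @return List with elements `bins`, `truth` (per-bin `compartment` and
#'   `state`, loop sizes), `chromhmm` (BED4 data.frame) and `chromsizes`.
#' @export
simulate_genome <- function(config) {
  validate_sim_config(config)
  bins <- make_bins(config$chrom_lengths, config$bin_size)
  nb <- chrom_nbins(bins)
  states <- chromhmm_states()
  sp <- state_probs()
  with_seed(derive_seed(config$seed, "genome"), {
    comp <- character(0)
    state <- character(0)
    for (ch in names(nb)) {
      n <- nb[[ch]]
      lens <- draw_blocks(n, config$compartment_block_mean / config$bin_size)
      lab0 <- sample(c("A", "B"), 1L)
      labs <- rep(c(lab0, setdiff(c("A", "B"), lab0)),
                  length.out = length(lens))
      comp_ch <- rep(labs, lens)
      seg_lens <- draw_blocks(n, 25000 / config$bin_size)
      seg_start <- cumsum(c(1L, seg_lens[-length(seg_lens)]))
      seg_state <- vapply(seq_along(seg_lens), function(k) {
        sample(states, 1L, prob = sp[comp_ch[seg_start[k]], ])
      }, character(1L))
      comp <- c(comp, comp_ch)
      state <- c(state, rep(seg_state, seg_lens))
    }
  })
  chromhmm <- segments_from_states(bins, state)
  truth <- list(compartment = comp, state = state,
                true_loop_sizes = c(A = config$loop_size_A,
                                    B = config$loop_size_B))
  list(bins = bins, truth = truth, chromhmm = chromhmm,
       chromsizes = chromsizes_of(bins))
}

# Merge consecutive same-state bins into BED4 segments.
segments_from_states <- function(bins, state) {
  brk <- c(TRUE, state[-1L] != state[-length(state)] |
                 bins$chrom[-1L] != bins$chrom[-nrow(bins)])
  grp <- cumsum(brk)
  first <- !duplicated(grp)
  last <- !duplicated(grp, fromLast = TRUE)
  data.frame(chrom = bins$chrom[first], start = bins$start[first],
             end = bins$end[last], state = state[first],
             stringsAsFactors = FALSE)
}

# Shoulder-center calibration: for the multiplicative log-normal bump
# g(x) = amp * exp(-(x - m)^2 / (2 sigma^2)) on log10 P(s), the maximum of
# d log(1 + g) / dx sits u* sigma below the center, with u* depending on
# the amplitude. Solving for u* and placing the center at
# log10(L) + u* sigma puts the noise-free P(s) derivative maximum exactly
# at L, which is what "loop size" means for a derivative-maximum estimator.
shoulder_ustar <- function(amp, sigma) {
  if (amp <= 0) return(0)
  f <- function(u) {
    g <- amp * exp(-u^2 / 2)
    u * g / (1 + g)
  }
  stats::optimize(f, interval = c(0, 6), maximum = TRUE)$maximum
}

# Per-separation class weights (AA, BB, mixed) of the generative contact
# model, for separations d = 1..n-1 in bins. Returns a 3 x (n-1) matrix.
class_weights_by_sep <- function(n, config, stage) {
  strength <- config$compartment_strength[[stage]]
  d <- seq_len(n - 1L)
  s <- d * config$bin_size
  base <- s ^ config$ps_exponent
  ustar <- shoulder_ustar(config$shoulder_amp, config$shoulder_sigma)
  bump <- function(L) {
    m <- log10(L) + ustar * config$shoulder_sigma
    config$shoulder_amp * exp(-(log10(s) - m)^2 / (2 * config$shoulder_sigma^2))
  }
  Lmix <- sqrt(config$loop_size_A * config$loop_size_B)
  rbind(AA = base * (1 + bump(config$loop_size_A)) * (1 + strength),
        BB = base * (1 + bump(config$loop_size_B)) * (1 + strength),
        Mix = base * (1 + bump(Lmix)))
}

#' Expected (pre-sampling) cis contact matrix for small genomes
#'
#' Dense evaluation of the generative model, scaled so each chromosome's
#' expected total equals `read_depth`. Intended for small test genomes.
#'
#' @inheritParams simulate_contacts
#' @return Named list of dense symmetric matrices, one per chromosome.
#' @export
expected_contact_matrix <- function(genome, truth, config, stage) {
  check_stage(config, stage)
  nb <- chrom_nbins(genome$bins)
  if (sum(nb) > 8000) stop("expected_contact_matrix is for small genomes")
  off <- chrom_offsets(genome$bins)
  out <- lapply(names(nb), function(ch) {
    n <- nb[[ch]]
    lab <- truth$compartment[off[[ch]] + seq_len(n)]
    w <- class_weights_by_sep(n, config, stage)
    M <- matrix(0, n, n)
    for (d in seq_len(n - 1L)) {
      i <- seq_len(n - d)
      same <- lab[i] == lab[i + d]
      cls <- ifelse(same, ifelse(lab[i] == "A", 1L, 2L), 3L)
      v <- w[cbind(cls, d)]
      M[cbind(i, i + d)] <- v
      M[cbind(i + d, i)] <- v
    }
    M * (config$read_depth / (sum(M) / 2))
  })
  names(out) <- names(nb)
  out
}

check_stage <- function(config, stage) {
  if (!stage %in% names(config$compartment_strength)) {
    stop("unknown stage '", stage, "'; configured stages: ",
         paste(names(config$compartment_strength), collapse = ", "))
  }
  if (config$read_depth <= 0) stop("read_depth must be positive")
  invisible(TRUE)
}

#' Simulate a Hi-C contact matrix for one stage
#'
#' Expected cis contact between bins at separation s is proportional to
#' `s^ps_exponent * (1 + shoulder(s; L)) * (1 + strength[stage])` for
#' same-compartment pairs (geometric-mean loop size for mixed pairs,
#' without the compartment factor). Contacts are Poisson-sampled at
#' `read_depth` per chromosome; per-bin trans totals are drawn so the
#' expected cis/total ratio is `cis_fraction_base` plus `cis_offset` in B
#' bins and minus `cis_offset` in A bins. Bins with zero sampled coverage
#' are masked.
#'
#' @param genome,truth Output of [simulate_genome()].
#' @param config The [sim_config()].
#' @param stage Stage name (must be in `names(config$compartment_strength)`).
#' @param dip_bins Optional global bin ids receiving an extra cis/total dip
#'   of magnitude `config$zygo_dip` (zygonema-specific accessibility shift).
#' @return A [contact_matrix()].
#' @export
simulate_contacts <- function(genome, truth, config, stage,
                              dip_bins = NULL) {
  check_stage(config, stage)
  bins <- genome$bins
  nb <- chrom_nbins(bins)
  off <- chrom_offsets(bins)
  mats <- vector("list", length(nb))
  names(mats) <- names(nb)
  with_seed(derive_seed(config$seed, paste0("contacts:", stage)), {
    for (ch in names(nb)) {
      n <- nb[[ch]]
      lab <- truth$compartment[off[[ch]] + seq_len(n)]
      a <- lab == "A"
      nAA <- pair_counts_by_sep(a)
      nBB <- pair_counts_by_sep(!a)
      nMix <- (n - seq_len(n - 1L)) - nAA - nBB
      w <- class_weights_by_sep(n, config, stage)
      Tm <- w * rbind(nAA, nBB, nMix)  # expected mass per (class, sep) cell
      p <- as.numeric(Tm) / sum(Tm)
      Ntot <- rpois(1L, config$read_depth)
      counts <- matrix(drop(rmultinom(1L, Ntot, p)), nrow = 3L)
      ii <- integer(0); jj <- integer(0)
      for (cls in 1:3) {
        ks <- which(counts[cls, ] > 0L)
        if (!length(ks)) next
        dvec <- rep(ks, counts[cls, ks])
        res <- sample_class_pairs(dvec, a, cls)
        ii <- c(ii, res$i); jj <- c(jj, res$j)
      }
      U <- Matrix::sparseMatrix(i = ii, j = jj, x = rep(1, length(ii)),
                                dims = c(n, n))
      mats[[ch]] <- Matrix::forceSymmetric(U, uplo = "U")
    }
    cm <- contact_matrix(bins, mats, stage = stage)
    isB <- truth$compartment == "B"
    r <- config$cis_fraction_base + ifelse(isB, config$cis_offset,
                                           -config$cis_offset)
    if (!is.null(dip_bins) && config$zygo_dip > 0) {
      r[dip_bins + 1L] <- pmax(r[dip_bins + 1L] - config$zygo_dip, 0.05)
    }
    lam <- ifelse(cm$valid, cm$cis * (1 - r) / r, 0)
    cm$trans <- as.numeric(rpois(length(lam), lam))
  })
  cm
}

# Rejection-sample positions i for contacts at separations dvec, keeping
# pairs (i, i + d) whose compartment labels match the class (1 = AA,
# 2 = BB, 3 = mixed). Vectorized over all pending contacts per round.
sample_class_pairs <- function(dvec, a, cls) {
  n <- length(a)
  out_i <- integer(length(dvec))
  out_j <- integer(length(dvec))
  filled <- 0L
  pend <- dvec
  guard <- 0L
  while (length(pend)) {
    guard <- guard + 1L
    if (guard > 10000L) stop("contact sampling failed to converge")
    i <- 1L + as.integer(floor(runif(length(pend)) * (n - pend)))
    j <- i + pend
    ok <- switch(cls, a[i] & a[j], (!a[i]) & (!a[j]), xor(a[i], a[j]))
    k <- sum(ok)
    if (k) {
      out_i[filled + seq_len(k)] <- i[ok]
      out_j[filled + seq_len(k)] <- j[ok]
      filled <- filled + k
    }
    pend <- pend[!ok]
  }
  list(i = out_i, j = out_j)
}

#' Simulate recombination peak sets and chromatin signal tracks
#'
#' PRDM9 peaks are placed `prdm9_frac_A` / `1 - prdm9_frac_A` in A/B bins
#' with log-normal binding scores; DMC1 (DSB) peaks sit at the same loci
#' with score `PRDM9 * dsb_bias_A^(A) * noise`. Per-bin bedGraph-style
#' signal tracks are produced for PRDM9, DMC1, RNAPII (elevated in
#' promoter/gene-body states), CTCF and cohesin.
#'
#' @inheritParams simulate_contacts
#' @return List with `prdm9_peaks`, `dmc1_peaks` (data.frames with `chrom`,
#'   `start`, `end`, `score`, `bin_id`) and `tracks` (named list of
#'   `binned_track`s).
#' @export
simulate_peaks_and_tracks <- function(genome, truth, config) {
  bins <- genome$bins
  nbin <- nrow(bins)
  if (config$n_prdm9_peaks > nbin) {
    stop("n_prdm9_peaks exceeds the number of bins")
  }
  st <- truth$state
  comp <- truth$compartment
  sz <- chromsizes_of(bins)
  with_seed(derive_seed(config$seed, "peaks"), {
    idxA <- which(comp == "A")
    idxB <- which(comp == "B")
    nA <- min(round(config$n_prdm9_peaks * config$prdm9_frac_A), length(idxA))
    nB <- min(config$n_prdm9_peaks - nA, length(idxB))
    peak_bins <- sort(c(sample(idxA, nA), sample(idxB, nB)))
    np <- length(peak_bins)
    width <- as.integer(round(runif(np, 800, 2400)))
    bw <- bins$end[peak_bins] - bins$start[peak_bins]
    center <- bins$start[peak_bins] +
      as.integer(floor(runif(np) * bw))
    chrom <- bins$chrom[peak_bins]
    pstart <- pmax(center - width %/% 2L, 0L)
    pend <- pmin(pstart + width, sz[chrom])
    prdm9_score <- rlnorm(np, meanlog = 0, sdlog = 1)
    isA <- comp[peak_bins] == "A"
    noise <- if (config$dmc1_noise_sd > 0) {
      rlnorm(np, meanlog = 0, sdlog = config$dmc1_noise_sd)
    } else rep(1, np)
    dmc1_score <- prdm9_score * config$dsb_bias_A ^ as.numeric(isA) * noise
    peaks <- data.frame(chrom = chrom, start = as.integer(pstart),
                        end = as.integer(pend), score = prdm9_score,
                        bin_id = bins$bin_id[peak_bins],
                        stringsAsFactors = FALSE)
    dmc1 <- peaks
    dmc1$score <- dmc1_score

    promoterish <- st %in% c("promoter", "prom_enh")
    genic <- st %in% c("gene_body", "enh_gene_body")
    bg <- function(base) base * rlnorm(nbin, 0, 0.2)
    rnapii <- bg(0.5) + 2.5 * promoterish + 1.8 * genic
    ctcf <- bg(0.5) + 2.0 * promoterish
    cohesin <- bg(0.5) + 2.0 * promoterish + 0.4 * (comp == "A")
    prdm9_sig <- bg(0.05)
    prdm9_sig[peak_bins] <- pmax(prdm9_sig[peak_bins], prdm9_score)
    dmc1_sig <- bg(0.05)
    dmc1_sig[peak_bins] <- pmax(dmc1_sig[peak_bins], dmc1_score)
  })
  tracks <- list(
    prdm9 = binned_track(prdm9_sig, "prdm9", "signal_max"),
    dmc1 = binned_track(dmc1_sig, "dmc1", "signal_max"),
    rnapii = binned_track(rnapii, "rnapii", "signal_max"),
    ctcf = binned_track(ctcf, "ctcf", "signal_max"),
    cohesin = binned_track(cohesin, "cohesin", "signal_max"))
  list(prdm9_peaks = peaks, dmc1_peaks = dmc1, tracks = tracks)
}

#' Simulate crossover resolution intervals
#'
#' Crossover source sites are drawn without replacement from the DSB peaks
#' with weight `DMC1 score * gene_body_penalty^(gene-body state) * ramp`,
#' where the ramp rises linearly from 0.5 at the chromosome start to 1.5
#' at the end (acrocentric pericentromeric depletion). Each crossover is
#' reported as an interval of log-uniform length in [5 kb, 200 kb]
#' containing its source site.
#'
#' @param truth Ground truth from [simulate_genome()].
#' @param dsb_peaks DMC1 peak table from [simulate_peaks_and_tracks()].
#' @param config The [sim_config()].
#' @param bins Bin table from [simulate_genome()].
#' @return data.frame `chrom`, `start`, `end`, `source_bin`, sorted.
#' @export
simulate_crossovers <- function(truth, dsb_peaks, config, bins) {
  k <- config$n_crossovers
  if (k > nrow(dsb_peaks)) stop("n_crossovers exceeds the number of DSB peaks")
  empty <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), source_bin = integer(0))
  if (k == 0L) return(empty)
  sz <- chromsizes_of(bins)
  pb <- dsb_peaks$bin_id + 1L
  in_gb <- truth$state[pb] == "gene_body"
  pos_frac <- bins$start[pb] / sz[dsb_peaks$chrom]
  wts <- dsb_peaks$score *
    ifelse(in_gb, config$gene_body_penalty, 1) * (0.5 + pos_frac)
  if (all(wts == 0)) stop("all crossover source weights are zero")
  with_seed(derive_seed(config$seed, "crossovers"), {
    pick <- sample(nrow(dsb_peaks), k, prob = wts)
    src <- as.integer((dsb_peaks$start[pick] + dsb_peaks$end[pick]) %/% 2L)
    chrom <- dsb_peaks$chrom[pick]
    len <- as.integer(round(exp(runif(k, log(5e3), log(2e5)))))
    lo <- pmax(src - len + 1L, 0L)
    hi <- pmin(src, sz[chrom] - len)
    hi <- pmax(hi, lo)
    start <- lo + as.integer(floor(runif(k) * (hi - lo + 1L)))
    end <- pmin(start + len, sz[chrom])
  })
  out <- data.frame(chrom = chrom, start = as.integer(start),
                    end = as.integer(end),
                    source_bin = dsb_peaks$bin_id[pick],
                    stringsAsFactors = FALSE)
  out[order(match(out$chrom, names(sz)), out$start), , drop = FALSE]
}

#' Run the whole generator
#'
#' @param config A [sim_config()].
#' @param stages Stage names to simulate contact maps for (default: all
#'   configured stages).
#' @return List with `bins`, `truth`, `chromhmm`, `chromsizes`, `peaks`
#'   (PRDM9 + DMC1 + tracks), `crossovers`, and `contacts` (named list of
#'   `contact_matrix`, one per stage).
#' @export
simulate_all <- function(config = sim_config(),
                         stages = names(config$compartment_strength)) {
  genome <- simulate_genome(config)
  peaks <- simulate_peaks_and_tracks(genome, genome$truth, config)
  crossovers <- simulate_crossovers(genome$truth, peaks$dmc1_peaks, config,
                                    genome$bins)
  contacts <- lapply(stages, function(stg) {
    dip <- if (stg == "zygonema" && config$zygo_dip > 0) {
      peaks$prdm9_peaks$bin_id
    } else NULL
    simulate_contacts(genome, genome$truth, config, stg, dip_bins = dip)
  })
  names(contacts) <- stages
  c(genome, list(peaks = peaks, crossovers = crossovers, contacts = contacts))
}

#' Write a simulation to disk in plain-text formats
#'
#' Emits chrom.sizes, the ChromHMM BED4 segmentation, peak BEDs, per-bin
#' bedGraph signal tracks, the crossover BED and per-stage contact triplet
#' plus trans-total TSVs. Outputs are byte-identical across runs with the
#' same config.
#'
#' @param sim Output of [simulate_all()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_chromsizes(sim$chromsizes, file.path(dir, "chrom.sizes"))
  write_bed(sim$chromhmm, file.path(dir, "chromhmm.bed"))
  write_bed(sim$peaks$prdm9_peaks[, c("chrom", "start", "end", "score")],
            file.path(dir, "prdm9_peaks.bed"))
  write_bed(sim$peaks$dmc1_peaks[, c("chrom", "start", "end", "score")],
            file.path(dir, "dmc1_peaks.bed"))
  write_bed(sim$crossovers, file.path(dir, "crossovers.bed"))
  for (nm in names(sim$peaks$tracks)) {
    write_bedgraph(sim$peaks$tracks[[nm]], sim$bins,
                   file.path(dir, paste0(nm, ".bedgraph")))
  }
  for (stg in names(sim$contacts)) {
    write_contacts(sim$contacts[[stg]],
                   file.path(dir, paste0("contacts_", stg, ".tsv")),
                   file.path(dir, paste0("trans_", stg, ".tsv")))
  }
  invisible(dir)
}
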