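# Symmetric-averaged site-centered profiles and observed/expected contact
# pileups, with seeded bootstrap confidence intervals.

# Per-site window matrix (rows = sites, cols = offsets -F..F) for a
# per-bin track; sites closer than `flank` bins to a chromosome end are
# dropped and counted.
site_windows <- function(track, sites, bins, flank_bins) {
  v <- as.numeric(track)
  stopifnot(length(v) == nrow(bins))
  off <- chrom_offsets(bins)
  nb <- chrom_nbins(bins)
  loc <- sites$bin_id - off[sites$chrom] + 1L
  ok <- loc - flank_bins >= 1L & loc + flank_bins <= nb[sites$chrom]
  idx0 <- sites$bin_id[ok] + 1L
  offs <- -flank_bins:flank_bins
  W <- outer(idx0, offs, "+")
  W[] <- v[W]
  list(W = W, n_dropped = sum(!ok), bin_id = sites$bin_id[ok])
}

# Seeded percentile bootstrap of column means of a window matrix (NAs
# ignored); returns a 2 x ncol matrix of lower/upper bounds.
bootstrap_colmeans_ci <- function(W, n_boot, seed, conf = 0.95) {
  ns <- nrow(W)
  W0 <- W
  W0[is.na(W0)] <- 0
  nonNA <- 1 * !is.na(W)
  cnt <- matrix(0, n_boot, ns)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      cnt[b, ] <- tabulate(sample.int(ns, ns, replace = TRUE), nbins = ns)
    }
  })
  bm <- (cnt %*% W0) / (cnt %*% nonNA)
  a <- (1 - conf) / 2
  apply(bm, 2L, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE,
        names = FALSE)
}

#' Symmetric-averaged track profile around sites
#'
#' Stacks per-site windows of a per-bin track, averages each window with
#' its reverse (per-site symmetrization: sites are unoriented), then
#' averages over sites per offset ignoring missing values. 95% confidence
#' intervals come from a seeded percentile bootstrap over sites.
#'
#' @param track Per-bin `binned_track` (or numeric vector).
#' @param sites A [define_sites()] site set.
#' @param bins Bin table.
#' @param flank_bins Flank in bins on each side of the site (sites nearer
#'   than this to a chromosome end are dropped and counted).
#' @param n_boot Bootstrap resamples (default 1000; 0 disables CIs).
#' @param seed Bootstrap seed (default 0).
#' @param conf Confidence level (default 0.95).
#' @return data.frame of class `site_profile` with columns `offset_bp`,
#'   `mean`, `lo`, `hi`, `n`; the per-site symmetrized windows are kept in
#'   attribute `windows` for downstream comparison.
#' @export
pileup_track <- function(track, sites, bins, flank_bins, n_boot = 1000L,
                         seed = 0L, conf = 0.95) {
  sw <- site_windows(track, sites, bins, flank_bins)
  if (nrow(sw$W) == 0L) stop("no sites retained after flank filtering")
  W <- (sw$W + sw$W[, rev(seq_len(ncol(sw$W))), drop = FALSE]) / 2
  mu <- colMeans(W, na.rm = TRUE)
  nper <- colSums(!is.na(W))
  ci <- if (n_boot > 0L) {
    bootstrap_colmeans_ci(W, n_boot, seed, conf)
  } else {
    rbind(rep(NA_real_, length(mu)), rep(NA_real_, length(mu)))
  }
  bs <- bin_size_of(bins)
  out <- data.frame(offset_bp = (-flank_bins:flank_bins) * bs,
                    mean = mu, lo = ci[1L, ], hi = ci[2L, ], n = nper)
  rownames(out) <- NULL
  attr(out, "windows") <- W
  attr(out, "flank_bins") <- flank_bins
  attr(out, "n_sites") <- nrow(W)
  attr(out, "n_dropped") <- sw$n_dropped
  attr(out, "track") <- if (inherits(track, "binned_track")) {
    track_name(track)
  } else "track"
  class(out) <- c("site_profile", "data.frame")
  out
}

#' Observed/expected contact pileup around sites
#'
#' For each retained site, the `(2F+1)^2` cis submatrix centered on the
#' site bin is divided by the chromosome's expected-by-distance profile
#' (observed/expected), symmetrized by averaging with its center
#' reflection, and averaged over sites ignoring masked cells. Sites on
#' masked bins or too close to a chromosome end are skipped and counted.
#'
#' @param cm A [contact_matrix()].
#' @param sites Site set.
#' @param flank_bins Flank in bins.
#' @return List of class `pileup_matrix`: `mat` (mean O/E), `n`
#'   (contributing sites per cell), `flank_bins`, `n_sites`, `n_skipped`.
#' @export
pileup_matrix <- function(cm, sites, flank_bins) {
  bins <- cm$bins
  off <- chrom_offsets(bins)
  nb <- chrom_nbins(bins)
  F <- as.integer(flank_bins)
  k <- 2L * F + 1L
  sepmat <- abs(.row(c(k, k)) - .col(c(k, k)))
  acc <- matrix(0, k, k)
  cntm <- matrix(0, k, k)
  n_used <- 0L
  n_skipped <- 0L
  for (ch in unique(sites$chrom)) {
    if (!ch %in% names(cm$mats)) next
    n <- nb[[ch]]
    e_d <- expected_by_sep(cm, ch)
    Emat <- matrix(e_d[sepmat + 1L], k, k)
    Emat[!is.finite(Emat) | Emat <= 0] <- NA_real_
    M <- as(cm$mats[[ch]], "CsparseMatrix")
    sl_valid <- cm$valid[off[[ch]] + seq_len(n)]
    sub_sites <- sites[sites$chrom == ch, , drop = FALSE]
    for (r in seq_len(nrow(sub_sites))) {
      b <- sub_sites$bin_id[r] - off[[ch]] + 1L
      if (b - F < 1L || b + F > n || !sl_valid[b]) {
        n_skipped <- n_skipped + 1L
        next
      }
      loc <- (b - F):(b + F)
      sub <- as.matrix(M[loc, loc, drop = FALSE])
      oe <- sub / Emat
      bad <- !sl_valid[loc]
      oe[bad, ] <- NA_real_
      oe[, bad] <- NA_real_
      oe <- (oe + oe[k:1, k:1]) / 2
      fin <- is.finite(oe)
      oe[!fin] <- 0
      acc <- acc + oe
      cntm <- cntm + fin
      n_used <- n_used + 1L
    }
  }
  if (n_used == 0L) stop("no usable sites for contact pileup")
  structure(list(mat = ifelse(cntm > 0, acc / cntm, NA_real_), n = cntm,
                 flank_bins = F, n_sites = n_used, n_skipped = n_skipped),
            class = "pileup_matrix")
}

#' Compare two site-profile groups
#'
#' Per-offset difference of means (first minus second) with a seeded
#' bootstrap confidence interval of the difference (both groups resampled
#' independently), plus a global summary: the difference at offset 0 and
#' averaged over `|offset| <= summary_bins`.
#'
#' @param profile_top,profile_bottom [pileup_track()] outputs over the
#'   same track and flank.
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Seed (default 0).
#' @param conf Confidence level (default 0.95).
#' @param summary_bins Half-width (bins) of the central averaging window
#'   for the global summary (default 10).
#' @return List with `profile` (offset_bp, diff, lo, hi) and `summary`
#'   (diff at offset 0, central mean difference).
#' @export
compare_profiles <- function(profile_top, profile_bottom, n_boot = 1000L,
                             seed = 0L, conf = 0.95, summary_bins = 10L) {
  f1 <- attr(profile_top, "flank_bins")
  f2 <- attr(profile_bottom, "flank_bins")
  if (is.null(f1) || is.null(f2) || f1 != f2) {
    stop("profiles have mismatched flanks")
  }
  W1 <- attr(profile_top, "windows")
  W2 <- attr(profile_bottom, "windows")
  d <- profile_top$mean - profile_bottom$mean
  nc <- ncol(W1)
  lo <- hi <- rep(NA_real_, nc)
  if (n_boot > 0L) {
    boot1 <- bootstrap_group_means(W1, n_boot, derive_seed(seed, "top"))
    boot2 <- bootstrap_group_means(W2, n_boot, derive_seed(seed, "bottom"))
    dd <- boot1 - boot2
    a <- (1 - conf) / 2
    qs <- apply(dd, 2L, stats::quantile, probs = c(a, 1 - a), na.rm = TRUE,
                names = FALSE)
    lo <- qs[1L, ]
    hi <- qs[2L, ]
  }
  center <- f1 + 1L
  ctr_idx <- (center - summary_bins):(center + summary_bins)
  ctr_idx <- ctr_idx[ctr_idx >= 1L & ctr_idx <= nc]
  list(profile = data.frame(offset_bp = profile_top$offset_bp, diff = d,
                            lo = lo, hi = hi),
       summary = c(diff_at_center = d[center],
                   diff_central_mean = mean(d[ctr_idx], na.rm = TRUE)))
}

bootstrap_group_means <- function(W, n_boot, seed) {
  ns <- nrow(W)
  W0 <- W
  W0[is.na(W0)] <- 0
  nonNA <- 1 * !is.na(W)
  cnt <- matrix(0, n_boot, ns)
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      cnt[b, ] <- tabulate(sample.int(ns, ns, replace = TRUE), nbins = ns)
    }
  })
  (cnt %*% W0) / (cnt %*% nonNA)
}
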