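# Per-bin Hi-C scores: cis/total ratio, fine-grain compartment eigenvector,
# insulation, and FIRE-style near-cis interaction z-scores.

#' Cis/total contact ratio per bin
#'
#' Fraction of each bin's contacts that are intra-chromosomal,
#' `cis / (cis + trans)`; low values indicate high spatial accessibility.
#' Optionally the raw sums are pooled over a sliding coarse window before
#' taking the ratio.
#'
#' @param cm A [contact_matrix()].
#' @param aggregation_bp Optional coarse window width (bp) for pooling the
#'   raw sums (centered sliding window, truncated at chromosome ends).
#' @return A `binned_track` (values in `[0, 1]`, masked bins missing).
#' @export
cis_total_ratio <- function(cm, aggregation_bp = NULL) {
  bins <- cm$bins
  cis <- ifelse(cm$valid, cm$cis, 0)
  trans <- ifelse(cm$valid, cm$trans, 0)
  if (!is.null(aggregation_bp)) {
    k <- max(1L, as.integer(round(aggregation_bp / bin_size_of(bins))))
    nb <- chrom_nbins(bins)
    off <- chrom_offsets(bins)
    for (ch in names(nb)) {
      idx <- off[[ch]] + seq_len(nb[[ch]])
      cis[idx] <- roll_sum(cis[idx], k)
      trans[idx] <- roll_sum(trans[idx], k)
    }
  }
  tot <- cis + trans
  ratio <- ifelse(tot > 0, cis / tot, NA_real_)
  ratio[!cm$valid] <- NA_real_
  if (any(cm$valid & tot == 0)) {
    warning(sum(cm$valid & tot == 0),
            " valid bin(s) with zero cis+trans set to missing")
  }
  binned_track(ratio, "cis_total", "score")
}

#' Fine-grain A/B compartment score
#'
#' Compartment calling on 10-Mb diagonal chunks of the contact map, for
#' maps whose long-range signal decays too fast for whole-chromosome
#' eigendecomposition. Each chunk is observed/expected-normalized (every
#' diagonal divided by its mean over valid pairs), the leading eigenvector
#' of the resulting column-correlation matrix is extracted, scaled to unit
#' variance and sign-oriented so that its correlation with the activity
#' reference track is non-negative, then chunks are concatenated. Chunks
#' shorter than 2 Mb are merged into the previous chunk.
#'
#' @param cm A [contact_matrix()].
#' @param reference Activity reference `binned_track` (e.g. promoter +
#'   gene-body state coverage) used only for sign orientation.
#' @param chunk_bp Chunk size in bp (default 10 Mb).
#' @param min_valid Chunks with fewer valid bins get missing values
#'   (default 20), with a warning.
#' @param oe_clip Upper quantile at which observed/expected values are
#'   clipped before correlation (guards sparse long-range count spikes).
#' @param oe_smooth_bins Width (bins) of the separable box smoothing
#'   applied to the O/E chunk before the correlation step (default 5,
#'   i.e. +/- 2 bins). Long-range O/E entries of shallow maps are
#'   individually very noisy; light smoothing trades a 2-bin blurring of
#'   compartment boundaries for a large per-entry variance reduction.
#'   Set 1 to disable.
#' @return A `binned_track` of compartment scores (positive = A-like).
#' @export
fine_grain_compartment <- function(cm, reference, chunk_bp = 1e7,
                                   min_valid = 20L, oe_clip = 0.999,
                                   oe_smooth_bins = 5L) {
  bins <- cm$bins
  bs <- bin_size_of(bins)
  nb <- chrom_nbins(bins)
  off <- chrom_offsets(bins)
  ref <- as.numeric(reference)
  stopifnot(length(ref) == nrow(bins))
  out <- rep(NA_real_, nrow(bins))
  cb <- max(1L, as.integer(round(chunk_bp / bs)))
  min_bins <- as.integer(ceiling(2e6 / bs))
  for (ch in names(cm$mats)) {
    n <- nb[[ch]]
    starts <- seq.int(1L, n, by = cb)
    ends <- pmin(starts + cb - 1L, n)
    if (length(starts) > 1L && (ends[length(ends)] - starts[length(starts)] +
                                1L) < min_bins) {
      starts <- starts[-length(starts)]
      ends[length(starts)] <- n
      ends <- ends[seq_along(starts)]
    }
    for (k in seq_along(starts)) {
      loc <- starts[k]:ends[k]
      glob <- off[[ch]] + loc
      v <- chunk_eigenvector(cm$mats[[ch]][loc, loc, drop = FALSE],
                             cm$valid[glob], min_valid, oe_clip,
                             oe_smooth_bins)
      if (is.null(v)) {
        warning(sprintf("chunk %s:%d-%d has fewer than %d valid bins",
                        ch, (loc[1L] - 1L) * bs, loc[length(loc)] * bs,
                        min_valid))
        next
      }
      r <- suppressWarnings(stats::cor(v, ref[glob],
                                       use = "pairwise.complete.obs"))
      if (is.finite(r) && r < 0) v <- -v
      s <- stats::sd(v, na.rm = TRUE)
      if (is.finite(s) && s > 0) v <- v / s
      out[glob] <- v
    }
  }
  binned_track(out, "compartment", "score")
}

# Leading eigenvector of the correlation matrix of an O/E-normalized chunk.
# Returns a vector over all chunk bins (NA at invalid/degenerate bins), or
# NULL when too few bins are valid.
chunk_eigenvector <- function(M, valid, min_valid, oe_clip,
                              oe_smooth_bins = 5L) {
  m <- nrow(M)
  if (sum(valid) < min_valid) return(NULL)
  X <- as.matrix(M)
  Tm <- as(M, "TsparseMatrix")
  ti <- pmin(Tm@i, Tm@j) + 1L
  tj <- pmax(Tm@i, Tm@j) + 1L
  keep <- valid[ti] & valid[tj]
  sums <- numeric(m)
  if (any(keep)) {
    agg <- rowsum(Tm@x[keep], group = tj[keep] - ti[keep])
    sums[as.integer(rownames(agg)) + 1L] <- agg
  }
  cnt <- c(sum(valid), pair_counts_by_sep(valid))
  mean_d <- ifelse(cnt > 0, sums / cnt, NA_real_)
  sep <- abs(.row(c(m, m)) - .col(c(m, m)))
  E <- matrix(mean_d[sep + 1L], m, m)
  OE <- ifelse(is.finite(E) & E > 0, X / E, 0)
  OE[!valid, ] <- NA_real_
  OE[, !valid] <- NA_real_
  sub <- OE[valid, valid, drop = FALSE]
  if (is.finite(oe_clip) && oe_clip < 1) {
    cap <- stats::quantile(sub, oe_clip, na.rm = TRUE)
    if (is.finite(cap) && cap > 0) sub[sub > cap] <- cap
  }
  sub <- box_smooth_matrix(sub, oe_smooth_bins)
  col_sds <- function(A) {
    nr <- nrow(A)
    sqrt(pmax(colMeans(A^2) - colMeans(A)^2, 0) * nr / max(nr - 1L, 1L))
  }
  ok <- {
    s0 <- col_sds(sub)
    is.finite(s0) & s0 > 0
  }
  if (sum(ok) < min_valid) return(NULL)
  # restrict rows to the same bins so the correlation matrix is symmetric
  Z0 <- sub[ok, ok, drop = FALSE]
  sds <- col_sds(Z0)
  sds[!is.finite(sds) | sds == 0] <- 1
  Z <- sweep(sweep(Z0, 2L, colMeans(Z0), "-"), 2L, sds, "/")
  v <- power_iteration(Z)
  out <- rep(NA_real_, m)
  out[which(valid)[ok]] <- v
  out
}

# Leading eigenvector of C = Z'Z/(n-1) (the column correlation matrix for
# standardized Z) without forming C, via power iteration. Deterministic
# ramp initialization; tolerance on the direction.
power_iteration <- function(Z, max_iter = 500L, tol = 1e-8) {
  m <- ncol(Z)
  nr <- nrow(Z)
  v <- seq_len(m) - (m + 1) / 2
  v <- v + sin(seq_len(m))          # break symmetric-profile orthogonality
  v <- v / sqrt(sum(v^2))
  Z0 <- Z
  Z0[!is.finite(Z0)] <- 0
  for (it in seq_len(max_iter)) {
    w <- drop(crossprod(Z0, Z0 %*% v)) / max(nr - 1L, 1L)
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(rep(0, m))
    w <- w / nw
    if (max(abs(w - v)) < tol || max(abs(w + v)) < tol) {
      v <- w
      break
    }
    v <- w
  }
  v
}

#' Insulation score
#'
#' For each bin, the mean contact frequency in the `window x window`
#' square spanning its diagonal position (pairs `(i, j)` with
#' `i` in `[b-w, b-1]`, `j` in `[b+1, b+w]`), expressed as log2 of its
#' ratio to the chromosome-wide mean of the same statistic. Minima mark
#' domain boundaries. Bins within a window of a chromosome end are
#' missing; a window larger than the chromosome leaves that chromosome
#' entirely missing.
#'
#' @param cm A [contact_matrix()].
#' @param window_bp Window size in bp; must be a multiple of the bin size
#'   (default 100 kb).
#' @return A `binned_track`.
#' @export
insulation_score <- function(cm, window_bp = 1e5) {
  bins <- cm$bins
  bs <- bin_size_of(bins)
  if (window_bp %% bs != 0) stop("window_bp must be a multiple of the bin size")
  w <- as.integer(window_bp / bs)
  if (w < 1L) stop("window too small")
  nb <- chrom_nbins(bins)
  off <- chrom_offsets(bins)
  out <- rep(NA_real_, nrow(bins))
  for (ch in names(cm$mats)) {
    n <- nb[[ch]]
    if (2L * w + 1L > n) next  # window larger than chromosome: all missing
    sl <- chrom_slice(cm, ch)
    tp <- upper_triplets(cm, ch)
    sep <- tp$j - tp$i
    keep <- sep >= 2L & sep <= 2L * w
    num <- range_accumulate(pmax(tp$i[keep] + 1L, tp$j[keep] - w),
                            pmin(tp$j[keep] - 1L, tp$i[keep] + w),
                            tp$x[keep], n)
    lo_all <- integer(0); hi_all <- integer(0)
    for (d in 2:(2L * w)) {
      i <- which(sl$valid[seq_len(n - d)] & sl$valid[(1L + d):n])
      if (!length(i)) next
      lo_all <- c(lo_all, pmax(i + 1L, i + d - w))
      hi_all <- c(hi_all, pmin(i + d - 1L, i + w))
    }
    cells <- range_accumulate(lo_all, hi_all, rep(1, length(lo_all)), n)
    b <- seq_len(n)
    defined <- b > w & b <= n - w & sl$valid & cells > 0
    mean_b <- ifelse(defined, num / cells, NA_real_)
    chrom_mean <- mean(mean_b[defined])
    sc <- rep(NA_real_, n)
    if (is.finite(chrom_mean) && chrom_mean > 0) {
      sc[defined] <- log2(mean_b[defined] / chrom_mean)
    }
    out[sl$idx] <- sc
  }
  binned_track(out, "insulation", "score")
}

#' FIRE-style near-cis interaction score
#'
#' Total cis contacts with bins at separations in `[near_lo, near_hi]`,
#' divided by the number of valid partner bins in that band (regressing
#' out bin effectiveness), then z-scored per chromosome. High scores mark
#' frequently interacting regions.
#'
#' @param cm A [contact_matrix()].
#' @param near_lo,near_hi Separation band in bp (defaults 15 kb-200 kb).
#' @return A `binned_track` of z-scores.
#' @export
fire_score <- function(cm, near_lo = 15e3, near_hi = 2e5) {
  if (near_lo >= near_hi) stop("near_lo must be smaller than near_hi")
  bins <- cm$bins
  bs <- bin_size_of(bins)
  lo <- max(1L, as.integer(ceiling(near_lo / bs)))
  hi <- as.integer(floor(near_hi / bs))
  out <- rep(NA_real_, nrow(bins))
  for (ch in names(cm$mats)) {
    sl <- chrom_slice(cm, ch)
    n <- sl$n
    tp <- upper_triplets(cm, ch)
    sep <- tp$j - tp$i
    keep <- sep >= lo & sep <= hi & sl$valid[tp$i] & sl$valid[tp$j]
    st <- numeric(n)
    if (any(keep)) {
      acc <- rowsum(c(tp$x[keep], tp$x[keep]),
                    group = c(tp$i[keep], tp$j[keep]))
      st[as.integer(rownames(acc))] <- acc
    }
    cs <- cumsum(as.numeric(sl$valid))
    csum <- function(a, b) {  # number of valid bins with index in [a, b]
      a2 <- pmax(a, 1L)
      b2 <- pmin(b, n)
      res <- numeric(length(a))
      ok <- b2 >= a2
      if (any(ok)) {
        res[ok] <- cs[b2[ok]] - cs[a2[ok]] + as.numeric(sl$valid[a2[ok]])
      }
      res
    }
    i <- seq_len(n)
    partners <- csum(i + lo, i + hi) + csum(i - hi, i - lo)
    rate <- ifelse(sl$valid & partners > 0, st / partners, NA_real_)
    mu <- mean(rate, na.rm = TRUE)
    sdv <- stats::sd(rate, na.rm = TRUE)
    z <- if (!is.finite(sdv) || sdv < 1e-12) {
      ifelse(is.na(rate), NA_real_, 0)
    } else {
      (rate - mu) / sdv
    }
    out[sl$idx] <- z
  }
  binned_track(out, "fire", "score")
}
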