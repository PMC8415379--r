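# Crossover-score genetic map, hotspot site sets, quartile partitioning and
# enrichment/significance summaries.

#' Crossover-score map
#'
#' Each crossover resolution interval distributes unit mass over the bins
#' it intersects: a bin's raw score is the sum over intersecting
#' crossovers of `1/k_c`, where `k_c` is the number of bins the crossover
#' intersects (sharply localized crossovers therefore gain prominence).
#' The final score is the raw score normalized by its median over bins
#' with nonzero raw score (the median including zero bins would be zero,
#' crossovers being sparse). With `weight = "bp"` an alternative inverse
#' bp-length weighting is used instead (mass not conserved).
#'
#' @param crossovers data.frame with `chrom`, `start`, `end` (0-based
#'   half-open resolution intervals).
#' @param bins Bin table.
#' @param weight `"bins"` (default, `1/k_c`) or `"bp"` (`1/length_bp`).
#' @return A `binned_track` of normalized scores, with the raw per-bin
#'   scores in attribute `raw`.
#' @export
crossover_score_map <- function(crossovers, bins, weight = c("bins", "bp")) {
  weight <- match.arg(weight)
  raw <- numeric(nrow(bins))
  if (nrow(crossovers) == 0L) {
    warning("no crossovers; returning all-zero track (normalization skipped)")
    out <- binned_track(raw, "crossover_score", "score")
    attr(out, "raw") <- raw
    return(out)
  }
  check_intervals(crossovers, bins, "crossover")
  gr <- GenomicRanges::GRanges(crossovers$chrom,
                               IRanges::IRanges(crossovers$start + 1L,
                                                crossovers$end))
  hits <- GenomicRanges::findOverlaps(gr, bins_gr(bins))
  q <- S4Vectors::queryHits(hits)
  b <- S4Vectors::subjectHits(hits)
  w_per <- if (weight == "bins") {
    1 / tabulate(q, nbins = nrow(crossovers))
  } else {
    1 / (crossovers$end - crossovers$start)
  }
  acc <- rowsum(w_per[q], group = b)
  raw[as.integer(rownames(acc))] <- acc
  med <- stats::median(raw[raw > 0])
  norm <- if (is.finite(med) && med > 0) raw / med else raw
  out <- binned_track(norm, "crossover_score", "score")
  attr(out, "raw") <- raw
  out
}

#' Define hotspot sites from peak calls
#'
#' A site is the genomic bin containing a peak's center: the summit
#' (narrowPeak offset column) when present, else the interval midpoint
#' `floor((start + end) / 2)`. Peaks whose centers fall in the same bin
#' collapse to one site. Per-site scores are attached by evaluating the
#' supplied tracks at the site bin, and the fractional chromosomal
#' position (`bin start / chromosome length`, a centromere-distance proxy
#' for acrocentric chromosomes) is attached as `position`.
#'
#' @param peaks data.frame with `chrom`, `start`, `end` and optionally
#'   `summit` (offset from `start`).
#' @param bins Bin table.
#' @param score_tracks Named list of per-bin tracks whose site values
#'   become columns.
#' @param label Site-set label (e.g. "PRDM9", "DSB", "joint").
#' @return data.frame of class `site_set`: `bin_id`, `chrom`, `start`,
#'   `end`, `position`, one column per score track.
#' @export
define_sites <- function(peaks, bins, score_tracks = list(),
                         label = "sites") {
  stopifnot(all(c("chrom", "start", "end") %in% names(peaks)))
  check_intervals(peaks, bins, "peak")
  center <- if ("summit" %in% names(peaks) && !all(is.na(peaks$summit))) {
    as.integer(peaks$start + peaks$summit)
  } else {
    as.integer((peaks$start + peaks$end) %/% 2L)
  }
  bin_id <- bin_at(bins, peaks$chrom, center)
  keep <- !duplicated(bin_id)
  bin_id <- sort(bin_id[keep])
  row <- bin_id + 1L
  sz <- chromsizes_of(bins)
  out <- data.frame(bin_id = bin_id, chrom = bins$chrom[row],
                    start = bins$start[row], end = bins$end[row],
                    position = bins$start[row] / sz[bins$chrom[row]],
                    stringsAsFactors = FALSE)
  for (nm in names(score_tracks)) {
    out[[nm]] <- as.numeric(score_tracks[[nm]])[row]
  }
  rownames(out) <- NULL
  attr(out, "label") <- label
  class(out) <- c("site_set", "data.frame")
  out
}

#' Partition sites into top and bottom quartiles
#'
#' Sites are ranked descending by the chosen score (sites with a missing
#' score are excluded first; ties break by ascending chromosome then
#' start); the first and last `floor(n/4)` become the top and bottom
#' quartiles.
#'
#' @param sites A [define_sites()] site set.
#' @param ranking Name of the score column to rank by.
#' @return List of class `site_partition` with `top` and `bottom` bin-id
#'   vectors, `ranking`, `n_used`.
#' @export
partition_quartiles <- function(sites, ranking) {
  if (!ranking %in% names(sites)) stop("no score column '", ranking, "'")
  sc <- sites[[ranking]]
  keep <- which(!is.na(sc))
  if (length(keep) < 8L) stop("fewer than 8 scored sites; cannot partition")
  ord <- keep[order(-sc[keep],
                    match(sites$chrom[keep],
                          unique(sites$chrom)),
                    sites$start[keep])]
  q <- length(ord) %/% 4L
  structure(list(top = sites$bin_id[ord[seq_len(q)]],
                 bottom = sites$bin_id[ord[length(ord) - q + seq_len(q)]],
                 ranking = ranking, n_used = length(ord)),
            class = "site_partition")
}

#' Enrichment and significance summary over a partition
#'
#' For each variable, log2 fold enrichment of the group mean over the
#' genome-wide median across valid bins, for all sites and the top and
#' bottom quartiles, plus a two-sided Wilcoxon rank-sum test between top
#' and bottom with Bonferroni adjustment (`p_adj = min(1, m * p)` over the
#' m variables tested) flagged at adjusted p < 0.01. A variable whose
#' genome median is zero is referenced against the genome mean instead
#' and flagged in `ref_stat`.
#'
#' @param partition A [partition_quartiles()] result.
#' @param sites The site set the partition was computed from.
#' @param variables Named list of genome-wide per-bin tracks.
#' @param valid Logical per-bin mask defining the genome background
#'   (default: all bins).
#' @param alpha Significance level on the adjusted p-value (default 0.01).
#' @return data.frame with one row per variable.
#' @export
enrichment_summary <- function(partition, sites, variables, valid = NULL,
                               alpha = 0.01) {
  stopifnot(length(variables) > 0, !is.null(names(variables)))
  m <- length(variables)
  rows <- lapply(names(variables), function(nm) {
    v <- as.numeric(variables[[nm]])
    ok <- if (is.null(valid)) !is.na(v) else valid & !is.na(v)
    g_med <- stats::median(v[ok])
    use_mean <- !is.finite(g_med) || g_med == 0
    ref <- if (use_mean) mean(v[ok]) else g_med
    grp <- function(ids) v[ids + 1L]
    # log2 fold enrichment is undefined for non-positive group means of
    # signed variables (e.g. compartment or insulation scores); those
    # entries come back NA rather than warn.
    lfc <- function(x) {
      val <- suppressWarnings(log2(mean(x, na.rm = TRUE) / ref))
      if (is.nan(val)) NA_real_ else val
    }
    x_top <- grp(partition$top)
    x_bot <- grp(partition$bottom)
    p <- tryCatch(
      suppressWarnings(stats::wilcox.test(x_top, x_bot,
                                          exact = FALSE)$p.value),
      error = function(e) NA_real_)
    p_adj <- if (is.na(p)) NA_real_ else min(1, m * p)
    data.frame(variable = nm,
               ref_stat = if (use_mean) "mean" else "median",
               log2fc_all = lfc(grp(sites$bin_id)),
               log2fc_top = lfc(x_top),
               log2fc_bottom = lfc(x_bot),
               p = p, p_adj = p_adj,
               significant = !is.na(p_adj) & p_adj < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Score distributions conditioned on chromatin state
#'
#' Each site is assigned its plurality state (largest overlap fraction at
#' the site bin; ties resolve to the state listed first in the declared
#' label order; sites with fully missing segmentation go to
#' "unassigned"), and the chosen score is grouped by assigned state.
#'
#' @param sites A site set.
#' @param state_overlaps `state_overlap` matrix from
#'   [chromhmm_overlap_tracks()].
#' @param score Name of the score column in `sites`.
#' @return List with `scores` (named list of score vectors per state),
#'   `medians`, `n`.
#' @export
state_conditioned_scores <- function(sites, state_overlaps, score) {
  stopifnot(score %in% names(sites))
  ov <- unclass(state_overlaps)[sites$bin_id + 1L, , drop = FALSE]
  tot <- rowSums(ov, na.rm = TRUE)
  assigned <- ifelse(tot > 0, colnames(ov)[max.col(replace(ov, is.na(ov), -Inf),
                                                   ties.method = "first")],
                     "unassigned")
  groups <- split(sites[[score]], assigned)
  list(scores = groups,
       medians = vapply(groups, stats::median, numeric(1L), na.rm = TRUE),
       n = vapply(groups, length, integer(1L)))
}
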