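# Per-bin tracks: interval-to-bin mapping and bedGraph/BED readers/writers.

#' Construct a binned track
#'
#' A binned track holds one value per genomic bin for a named variable.
#' Missing values stay missing (they are never imputed as 0), except for
#' coverage tracks whose natural default is 0.
#'
#' @param values Numeric vector, one value per bin.
#' @param name Variable name.
#' @param kind One of `"signal_max"`, `"coverage"`, `"score"`,
#'   `"state_overlap"`.
#' @return Numeric vector of class `binned_track` with `name`/`kind`
#'   attributes.
#' @export
binned_track <- function(values, name, kind = c("score", "signal_max",
                                                "coverage", "state_overlap")) {
  kind <- match.arg(kind)
  values <- as.numeric(values)
  if (kind == "coverage" && any(values < -1e-9 | values > 1 + 1e-9, na.rm = TRUE)) {
    stop("coverage values must lie in [0, 1]")
  }
  structure(values, name = name, kind = kind, class = "binned_track")
}

track_name <- function(x) attr(x, "name")

#' Map a bedGraph signal to bins (maximum score per bin)
#'
#' Each bin receives the maximum score over all intersecting intervals;
#' bins intersecting no interval are missing. Intervals are 0-based
#' half-open, so an interval crossing a bin edge contributes to both bins.
#'
#' @param bg data.frame with columns `chrom`, `start`, `end`, `score`
#'   (e.g. from [read_bedgraph()]).
#' @param bins Bin table from [make_bins()].
#' @param name Track name (default "signal").
#' @return A `binned_track` of kind `signal_max`.
#' @export
map_bedgraph_to_bins <- function(bg, bins, name = "signal") {
  stopifnot(all(c("chrom", "start", "end", "score") %in% names(bg)))
  if (nrow(bg) == 0L) {
    return(binned_track(rep(NA_real_, nrow(bins)), name, "signal_max"))
  }
  check_intervals(bg, bins, "bedGraph interval")
  gr <- GenomicRanges::GRanges(bg$chrom,
                               IRanges::IRanges(bg$start + 1L, bg$end))
  hits <- GenomicRanges::findOverlaps(gr, bins_gr(bins))
  vals <- rep(NA_real_, nrow(bins))
  if (length(hits)) {
    dt <- data.table::data.table(
      bin = S4Vectors::subjectHits(hits),
      score = bg$score[S4Vectors::queryHits(hits)])
    mx <- dt[, list(v = max(score)), by = "bin"]
    vals[mx$bin] <- mx$v
  }
  binned_track(vals, name, "signal_max")
}

#' Map BED features to bins (covered fraction per bin)
#'
#' Overlapping features are merged before computing coverage, so duplicated
#' features do not inflate the value. Bins with no feature get 0.
#'
#' @param bed data.frame with columns `chrom`, `start`, `end`.
#' @inheritParams map_bedgraph_to_bins
#' @return A `binned_track` of kind `coverage` (values in `[0, 1]`).
#' @export
map_bed_coverage_to_bins <- function(bed, bins, name = "coverage") {
  stopifnot(all(c("chrom", "start", "end") %in% names(bed)))
  vals <- numeric(nrow(bins))
  if (nrow(bed)) {
    check_intervals(bed, bins, "BED feature")
    gr <- GenomicRanges::reduce(
      GenomicRanges::GRanges(bed$chrom, IRanges::IRanges(bed$start + 1L, bed$end)))
    bgr <- bins_gr(bins)
    hits <- GenomicRanges::findOverlaps(gr, bgr)
    if (length(hits)) {
      ov <- GenomicRanges::pintersect(gr[S4Vectors::queryHits(hits)],
                                      bgr[S4Vectors::subjectHits(hits)])
      dt <- data.table::data.table(bin = S4Vectors::subjectHits(hits),
                                   w = GenomicRanges::width(ov))
      cov <- dt[, list(v = sum(w)), by = "bin"]
      vals[cov$bin] <- cov$v / (bins$end[cov$bin] - bins$start[cov$bin])
    }
  }
  binned_track(pmin(vals, 1), name, "coverage")
}

#' Declared seven-state chromatin segmentation labels
#'
#' Label order is the tie-break order used when a site's plurality state is
#' ambiguous. The states follow the histone-mark combinations of a
#' seven-state testis segmentation: promoters, promoter/enhancers,
#' enhancers, enhancer/gene-body transitions, gene bodies (H3K36me3),
#' unmarked chromatin and Polycomb-repressed chromatin.
#'
#' @return Character vector of the seven state labels.
#' @export
chromhmm_states <- function() {
  c("promoter", "prom_enh", "enhancer", "enh_gene_body",
    "gene_body", "unmarked", "repressed")
}

#' Per-state overlap fraction tracks from a segmentation
#'
#' @param seg data.frame with columns `chrom`, `start`, `end`, `state`
#'   (BED4; segments must not overlap).
#' @param bins Bin table.
#' @param states Declared label set (default [chromhmm_states()]); an
#'   unknown label in `seg` is an error.
#' @return Numeric matrix `n_bins x n_states` (class `state_overlap`) of
#'   covered fractions; rows sum to the segmented fraction of each bin.
#' @export
chromhmm_overlap_tracks <- function(seg, bins, states = chromhmm_states()) {
  stopifnot(all(c("chrom", "start", "end", "state") %in% names(seg)))
  bad <- setdiff(unique(seg$state), states)
  if (length(bad)) stop("unknown state label: ", paste(bad, collapse = ", "))
  out <- matrix(0, nrow(bins), length(states),
                dimnames = list(NULL, states))
  for (st in states) {
    sub <- seg[seg$state == st, , drop = FALSE]
    out[, st] <- as.numeric(map_bed_coverage_to_bins(sub, bins, name = st))
  }
  class(out) <- c("state_overlap", class(out))
  out
}

#' Read a bedGraph file
#' @param path Four-column TSV (chrom, start, end, score), no header.
#' @param aliases Optional chromosome alias map as in [read_chromsizes()].
#' @return data.frame with columns `chrom`, `start`, `end`, `score`.
#' @export
read_bedgraph <- function(path, aliases = NULL) {
  df <- data.table::fread(path, header = FALSE, sep = "\t", data.table = FALSE,
                          col.names = c("chrom", "start", "end", "score"))
  df$chrom <- apply_aliases(df$chrom, aliases)
  df
}

#' Read a BED file (3+ columns)
#'
#' Column 4 is taken as `name`, column 5 as `score` and column 10 (the
#' narrowPeak summit offset) as `summit` when present.
#'
#' @inheritParams read_bedgraph
#' @return data.frame with `chrom`, `start`, `end` and any of `name`,
#'   `score`, `summit`.
#' @export
read_bed <- function(path, aliases = NULL) {
  df <- data.table::fread(path, header = FALSE, sep = "\t",
                          skip = n_comment_lines(path), data.table = FALSE)
  nm <- c("chrom", "start", "end", "name", "score", "strand",
          "signalValue", "pValue", "qValue", "summit")
  names(df) <- nm[seq_len(min(ncol(df), length(nm)))]
  df$chrom <- apply_aliases(as.character(df$chrom), aliases)
  df
}

#' Read a BED4 chromatin-state segmentation
#' @inheritParams read_bedgraph
#' @return data.frame with columns `chrom`, `start`, `end`, `state`.
#' @export
read_segmentation <- function(path, aliases = NULL) {
  df <- data.table::fread(path, header = FALSE, sep = "\t", data.table = FALSE,
                          skip = n_comment_lines(path),
                          col.names = c("chrom", "start", "end", "state"))
  df$chrom <- apply_aliases(df$chrom, aliases)
  df
}

# Count leading comment/track lines so readers can skip them.
n_comment_lines <- function(path, max_check = 10L) {
  head_lines <- readLines(path, n = max_check)
  n <- 0L
  for (l in head_lines) {
    if (startsWith(l, "#") || startsWith(l, "track")) n <- n + 1L else break
  }
  n
}

apply_aliases <- function(chrom, aliases) {
  chrom <- as.character(chrom)
  if (!is.null(aliases)) {
    hit <- chrom %in% names(aliases)
    chrom[hit] <- aliases[chrom[hit]]
  }
  chrom
}

#' Write a binned track as bedGraph
#'
#' Bins with missing values are omitted, which round-trips exactly through
#' [read_bedgraph()] + [map_bedgraph_to_bins()] for bin-aligned data.
#'
#' @param track A `binned_track` (or plain numeric per-bin vector).
#' @param bins Bin table.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, bins, path) {
  v <- as.numeric(track)
  keep <- !is.na(v)
  data.table::fwrite(
    data.frame(chrom = bins$chrom[keep], start = bins$start[keep],
               end = bins$end[keep], score = v[keep]),
    path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write intervals as BED (3 + optional extra columns)
#' @param df data.frame with at least `chrom`, `start`, `end`.
#' @param path Output path.
#' @param header Write a commented header line naming the columns.
#' @export
write_bed <- function(df, path, header = TRUE) {
  cols <- names(df)
  con <- file(path, "w")
  if (header) writeLines(paste0("#", paste(cols, collapse = "\t")), con)
  close(con)
  data.table::fwrite(df, path, sep = "\t", col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Read a BED written by [write_bed()] (commented header tolerated)
#' @param path File path.
#' @return data.frame.
#' @export
read_bed_headered <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) && startsWith(first, "#")) {
    cols <- strsplit(sub("^#", "", first), "\t")[[1L]]
    if (length(readLines(path, n = 2L)) < 2L) {
      out <- as.data.frame(matrix(nrow = 0, ncol = length(cols)))
      names(out) <- cols
      return(out)
    }
    df <- data.table::fread(path, header = FALSE, sep = "\t", skip = 1L,
                            data.table = FALSE)
    names(df) <- cols[seq_len(ncol(df))]
    df
  } else {
    read_bed(path)
  }
}
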