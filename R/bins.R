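# Genome tiling into fixed-width bins and chromosome-size I/O.

#' Tile a genome into fixed-width bins
#'
#' Tiles each chromosome into `ceil(length / bin_size)` half-open bins
#' `[start, end)`; the last bin is truncated at the chromosome end. Bin ids
#' are global, consecutive and 0-based, in chromosome-table order.
#'
#' @param chromsizes Named numeric vector of chromosome lengths (bp), or a
#'   two-column data.frame `(chrom, length)` as read by [read_chromsizes()].
#' @param bin_size Bin width in bp (default 5000).
#' @return A data.frame with columns `chrom`, `start`, `end`, `bin_id`,
#'   `valid`, carrying attributes `bin_size`, `chromsizes` and
#'   `chrom_order`.
#' @examples
#' make_bins(c(chrTest = 12001), bin_size = 5000)
#' @export
make_bins <- function(chromsizes, bin_size = 5000) {
  if (is.data.frame(chromsizes)) {
    stopifnot(ncol(chromsizes) >= 2L)
    sz <- stats::setNames(as.numeric(chromsizes[[2L]]),
                          as.character(chromsizes[[1L]]))
  } else {
    sz <- chromsizes
  }
  if (is.null(names(sz)) || any(!nzchar(names(sz)))) {
    stop("chromosome sizes must be named")
  }
  if (anyDuplicated(names(sz))) {
    stop("duplicate chromosome names: ",
         paste(unique(names(sz)[duplicated(names(sz))]), collapse = ", "))
  }
  if (any(!is.finite(sz)) || any(sz <= 0)) stop("chromosome sizes must be positive")
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size <= 0) {
    stop("bin_size must be a positive number")
  }
  bin_size <- as.integer(bin_size)
  per <- lapply(names(sz), function(ch) {
    len <- sz[[ch]]
    start <- seq.int(0, len - 1, by = bin_size)
    data.frame(chrom = ch, start = start,
               end = pmin(start + bin_size, len),
               stringsAsFactors = FALSE)
  })
  bins <- do.call(rbind, per)
  bins$bin_id <- seq_len(nrow(bins)) - 1L
  bins$valid <- TRUE
  attr(bins, "bin_size") <- bin_size
  attr(bins, "chromsizes") <- sz
  attr(bins, "chrom_order") <- names(sz)
  class(bins) <- c("meiorec_bins", "data.frame")
  bins
}

bin_size_of <- function(bins) attr(bins, "bin_size")

chromsizes_of <- function(bins) attr(bins, "chromsizes")

# Named integer vector: 0-based global bin_id of the first bin per chromosome.
chrom_offsets <- function(bins) {
  first <- !duplicated(bins$chrom)
  stats::setNames(bins$bin_id[first], bins$chrom[first])
}

# Number of bins per chromosome, in chromosome order.
chrom_nbins <- function(bins) {
  tab <- table(factor(bins$chrom, levels = attr(bins, "chrom_order")))
  stats::setNames(as.integer(tab), names(tab))
}

# Global 0-based bin_id containing position `pos` (0-based bp) on `chrom`.
bin_at <- function(bins, chrom, pos) {
  off <- chrom_offsets(bins)
  sz <- chromsizes_of(bins)
  bs <- bin_size_of(bins)
  if (any(!(chrom %in% names(off)))) {
    stop("unknown chromosome: ",
         paste(unique(chrom[!(chrom %in% names(off))]), collapse = ", "))
  }
  bad <- pos < 0 | pos >= sz[chrom]
  if (any(bad)) {
    k <- which(bad)[1L]
    stop(sprintf("position %s:%d outside chromosome bounds", chrom[k], pos[k]))
  }
  as.integer(off[chrom] + pos %/% bs)
}

#' Read a chromosome-sizes table
#'
#' @param path Two-column TSV `(name, length)`, no header.
#' @param aliases Optional named character vector mapping file names to
#'   canonical names (e.g. `c("1" = "chr1")`).
#' @return Named numeric vector of lengths.
#' @export
read_chromsizes <- function(path, aliases = NULL) {
  df <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "length"),
                          data.table = FALSE)
  nm <- as.character(df$chrom)
  if (!is.null(aliases)) {
    hit <- nm %in% names(aliases)
    nm[hit] <- aliases[nm[hit]]
  }
  stats::setNames(as.numeric(df$length), nm)
}

#' Write a chromosome-sizes table
#' @param chromsizes Named numeric vector.
#' @param path Output TSV path.
#' @export
write_chromsizes <- function(chromsizes, path) {
  data.table::fwrite(
    data.frame(chrom = names(chromsizes), length = as.integer(chromsizes)),
    path, sep = "\t", col.names = FALSE)
  invisible(path)
}

# Bins as GRanges (1-based closed intervals, the Bioconductor convention).
bins_gr <- function(bins) {
  GenomicRanges::GRanges(
    seqnames = bins$chrom,
    ranges = IRanges::IRanges(start = bins$start + 1L, end = bins$end))
}

# Validate 0-based half-open intervals against chromosome bounds; the error
# message carries the first offending coordinates.
check_intervals <- function(df, bins, what = "interval") {
  sz <- chromsizes_of(bins)
  unknown <- !(df$chrom %in% names(sz))
  if (any(unknown)) {
    k <- which(unknown)[1L]
    stop(sprintf("%s on unknown chromosome %s", what, df$chrom[k]))
  }
  bad <- df$start < 0 | df$end > sz[df$chrom] | df$end <= df$start
  if (any(bad)) {
    k <- which(bad)[1L]
    stop(sprintf("%s %s:%d-%d outside chromosome bounds (length %d)",
                 what, df$chrom[k], df$start[k], df$end[k],
                 as.integer(sz[df$chrom[k]])))
  }
  invisible(TRUE)
}
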