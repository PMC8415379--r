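# Contact-matrix container: per-chromosome symmetric cis matrices stored
# sparse, plus per-bin raw cis/trans totals and a valid-bin mask.

#' Construct a contact-matrix object
#'
#' @param bins Bin table from [make_bins()].
#' @param matrices Named list (one element per chromosome, names matching
#'   the bin table) of symmetric cis matrices over that chromosome's bins;
#'   base matrices or any Matrix class are accepted and stored as symmetric
#'   sparse.
#' @param trans Optional per-bin raw trans contact totals (global bin
#'   order); defaults to 0.
#' @param stage Optional stage label (e.g. "zygonema").
#' @param mask_zero Mask bins with zero cis coverage (default TRUE).
#' @return An object of class `contact_matrix`: a list with elements
#'   `bins`, `mats`, `cis`, `trans`, `valid`, `stage`.
#' @export
contact_matrix <- function(bins, matrices, trans = NULL, stage = NULL,
                           mask_zero = TRUE) {
  nb <- chrom_nbins(bins)
  stopifnot(is.list(matrices), !is.null(names(matrices)))
  if (!all(names(matrices) %in% names(nb))) {
    stop("matrix for unknown chromosome: ",
         paste(setdiff(names(matrices), names(nb)), collapse = ", "))
  }
  mats <- lapply(names(matrices), function(ch) {
    m <- matrices[[ch]]
    if (is.matrix(m)) {
      if (!isSymmetric(unname(m), tol = 1e-8)) {
        stop("cis matrix for ", ch, " is not symmetric")
      }
      m <- Matrix::Matrix(m, sparse = TRUE)
    }
    if (nrow(m) != nb[[ch]] || ncol(m) != nb[[ch]]) {
      stop(sprintf("matrix for %s is %dx%d, expected %d bins",
                   ch, nrow(m), ncol(m), nb[[ch]]))
    }
    as(Matrix::forceSymmetric(as(m, "CsparseMatrix"), uplo = "U"),
       "CsparseMatrix")
  })
  names(mats) <- names(matrices)
  cis <- numeric(nrow(bins))
  off <- chrom_offsets(bins)
  for (ch in names(mats)) {
    idx <- off[[ch]] + seq_len(nb[[ch]])
    cis[idx] <- Matrix::rowSums(mats[[ch]])
  }
  if (is.null(trans)) trans <- numeric(nrow(bins))
  stopifnot(length(trans) == nrow(bins))
  if (any(cis < 0) || any(trans < 0, na.rm = TRUE)) {
    stop("raw contact sums must be non-negative")
  }
  valid <- bins$valid
  if (mask_zero) valid <- valid & cis > 0
  structure(list(bins = bins, mats = mats, cis = cis,
                 trans = as.numeric(trans), valid = valid, stage = stage),
            class = "contact_matrix")
}

#' @export
print.contact_matrix <- function(x, ...) {
  cat(sprintf("contact_matrix: %d chromosome(s), %d bins (%d valid)%s\n",
              length(x$mats), nrow(x$bins), sum(x$valid),
              if (!is.null(x$stage)) paste0(", stage ", x$stage) else ""))
  invisible(x)
}

# Upper-triangle triplets (1-based local i <= j) for one chromosome.
upper_triplets <- function(cm, chrom) {
  Tm <- as(cm$mats[[chrom]], "TsparseMatrix")
  i <- Tm@i + 1L
  j <- Tm@j + 1L
  if (methods::is(Tm, "symmetricMatrix")) {
    data.frame(i = pmin(i, j), j = pmax(i, j), x = Tm@x)
  } else {
    keep <- i <= j
    data.frame(i = i[keep], j = j[keep], x = Tm@x[keep])
  }
}

# Local (1-based) indices and validity for one chromosome.
chrom_slice <- function(cm, chrom) {
  nb <- chrom_nbins(cm$bins)
  off <- chrom_offsets(cm$bins)
  idx <- off[[chrom]] + seq_len(nb[[chrom]])
  list(idx = idx, valid = cm$valid[idx], n = nb[[chrom]])
}

# Expected contact by separation for one chromosome: mean over valid bin
# pairs per separation d = 0..n-1 (NA where no valid pairs).
expected_by_sep <- function(cm, chrom) {
  sl <- chrom_slice(cm, chrom)
  tp <- upper_triplets(cm, chrom)
  keep <- sl$valid[tp$i] & sl$valid[tp$j]
  sums <- numeric(sl$n)
  if (any(keep)) {
    agg <- rowsum(tp$x[keep], group = tp$j[keep] - tp$i[keep])
    sums[as.integer(rownames(agg)) + 1L] <- agg
  }
  cnt <- c(sum(sl$valid), pair_counts_by_sep(sl$valid))
  ifelse(cnt > 0, sums / cnt, NA_real_)
}

#' Write cis matrices as bin-pair triplet TSV
#'
#' Columns `bin1_id`, `bin2_id`, `count` with global 0-based ids and
#' `bin1_id <= bin2_id`; the companion trans file holds per-bin totals.
#'
#' @param cm A `contact_matrix`.
#' @param path Output triplet TSV path.
#' @param trans_path Optional output path for per-bin trans totals
#'   (`bin_id`, `trans`).
#' @export
write_contacts <- function(cm, path, trans_path = NULL) {
  off <- chrom_offsets(cm$bins)
  parts <- lapply(names(cm$mats), function(ch) {
    tp <- upper_triplets(cm, ch)
    data.frame(bin1_id = off[[ch]] + tp$i - 1L,
               bin2_id = off[[ch]] + tp$j - 1L,
               count = tp$x)
  })
  all_tp <- do.call(rbind, parts)
  all_tp <- all_tp[order(all_tp$bin1_id, all_tp$bin2_id), , drop = FALSE]
  data.table::fwrite(all_tp, path, sep = "\t")
  if (!is.null(trans_path)) {
    data.table::fwrite(
      data.frame(bin_id = cm$bins$bin_id, trans = cm$trans),
      trans_path, sep = "\t")
  }
  invisible(path)
}

#' Read cis matrices from a bin-pair triplet TSV
#'
#' Cross-chromosome pairs, if present, are folded into the per-bin trans
#' totals of both bins instead of a cis matrix.
#'
#' @param path Triplet TSV (`bin1_id`, `bin2_id`, `count`; header optional).
#' @param bins Bin table the ids refer to.
#' @param trans_path Optional per-bin trans totals TSV (`bin_id`, `trans`).
#' @param balance Apply the iterative-proportional balancing fallback to
#'   each cis matrix (default FALSE: input assumed balanced).
#' @param stage Optional stage label.
#' @return A `contact_matrix`.
#' @export
read_contacts <- function(path, bins, trans_path = NULL, balance = FALSE,
                          stage = NULL) {
  tp <- data.table::fread(path, data.table = FALSE)
  names(tp)[1:3] <- c("bin1_id", "bin2_id", "count")
  if (any(tp$bin1_id < 0 | tp$bin2_id >= nrow(bins))) {
    stop("triplet bin id outside bin table")
  }
  ch1 <- bins$chrom[tp$bin1_id + 1L]
  ch2 <- bins$chrom[tp$bin2_id + 1L]
  cis_tp <- tp[ch1 == ch2, , drop = FALSE]
  trans <- numeric(nrow(bins))
  if (any(ch1 != ch2)) {
    tt <- tp[ch1 != ch2, , drop = FALSE]
    acc <- rowsum(c(tt$count, tt$count), group = c(tt$bin1_id, tt$bin2_id))
    trans[as.integer(rownames(acc)) + 1L] <- acc
  }
  if (!is.null(trans_path)) {
    td <- data.table::fread(trans_path, data.table = FALSE)
    trans[td[[1L]] + 1L] <- trans[td[[1L]] + 1L] + td[[2L]]
  }
  off <- chrom_offsets(bins)
  nb <- chrom_nbins(bins)
  cis_ch <- bins$chrom[cis_tp$bin1_id + 1L]
  mats <- lapply(names(nb), function(ch) {
    sub <- cis_tp[cis_ch == ch, , drop = FALSE]
    i <- sub$bin1_id - off[[ch]] + 1L
    j <- sub$bin2_id - off[[ch]] + 1L
    U <- Matrix::sparseMatrix(i = pmin(i, j), j = pmax(i, j), x = sub$count,
                              dims = c(nb[[ch]], nb[[ch]]))
    m <- Matrix::forceSymmetric(U, uplo = "U")
    if (balance) m <- balance_matrix(m)$mat
    m
  })
  names(mats) <- names(nb)
  contact_matrix(bins, mats, trans = trans, stage = stage)
}

#' Iterative-proportional (ICE-style) balancing fallback
#'
#' Scales a raw symmetric cis matrix so row marginals over unmasked bins
#' equalize. Bins with low coverage (below `mad_frac` times the nonzero
#' median marginal) are masked first; masked bins come back as zero
#' rows/columns and should stay masked downstream.
#'
#' @param m Symmetric matrix (base or Matrix).
#' @param max_iter Maximum iterations (default 50).
#' @param tol Convergence tolerance on the variance of the scaled
#'   marginals (default 1e-5).
#' @param mad_frac Coverage cutoff as a fraction of the nonzero median
#'   (default 0.1).
#' @return List with `mat` (balanced, symmetric sparse), `bias` (per-bin
#'   multiplier, NA for masked), `masked` (logical), `converged`.
#' @export
balance_matrix <- function(m, max_iter = 50L, tol = 1e-5, mad_frac = 0.1) {
  m <- as(Matrix::forceSymmetric(as(Matrix::Matrix(m, sparse = TRUE),
                                    "CsparseMatrix"), uplo = "U"),
          "CsparseMatrix")
  n <- nrow(m)
  cov0 <- Matrix::rowSums(m)
  med <- stats::median(cov0[cov0 > 0])
  masked <- cov0 <= 0 | (is.finite(med) & cov0 < mad_frac * med)
  bias <- rep(1, n)
  bias[masked] <- NA_real_
  bm <- m
  if (any(masked)) {
    Z <- Matrix::Diagonal(x = as.numeric(!masked))
    bm <- as(Matrix::forceSymmetric(as(Z %*% bm %*% Z, "CsparseMatrix"),
                                    uplo = "U"), "CsparseMatrix")
  }
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    s <- Matrix::rowSums(bm)
    sv <- s[!masked]
    if (!length(sv) || mean(sv) == 0) break
    r <- sv / mean(sv)
    if (stats::var(r) < tol) { converged <- TRUE; break }
    d <- rep(1, n)
    d[!masked] <- 1 / sqrt(r)
    bm <- Matrix::Diagonal(x = d) %*% bm %*% Matrix::Diagonal(x = d)
    bm <- as(Matrix::forceSymmetric(as(bm, "CsparseMatrix"), uplo = "U"),
             "CsparseMatrix")
    bias[!masked] <- bias[!masked] * d[!masked]
  }
  list(mat = bm, bias = bias, masked = masked, converged = converged)
}
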