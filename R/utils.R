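# Internal numerical helpers shared across modules.

# data.table is used via :: throughout; declare awareness so [.data.table
# dispatches correctly inside the package namespace.
.datatable.aware <- TRUE

#' Derive a deterministic child seed from a base seed and a stage tag
#'
#' Stage-level substream derivation: every stochastic step of the pipeline
#' draws its own seed from the single user-facing seed plus a short tag, so
#' stages are reproducible in isolation. Arithmetic stays below 2^53 so the
#' hash is exact in double precision; results are in `[0, 2^31 - 2]`.
#'
#' @param seed Integer base seed.
#' @param tag Character scalar naming the consumer (e.g. "contacts:zygonema").
#' @return An integer seed.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- abs(as.double(seed)) %% 2147483647
  for (ch in utf8ToInt(tag)) h <- (h * 31 + ch) %% 2147483647
  as.integer((h * 7919 + 12345) %% 2147483647)
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# Number of pairs (i, i + d) with keep[i] and keep[i + d], for d = 1..n-1,
# via FFT autocorrelation. Exact for logical input (counts are integers).
pair_counts_by_sep <- function(keep) {
  n <- length(keep)
  if (n < 2L) return(integer(0))
  m <- nextn(2L * n)
  f <- fft(c(as.numeric(keep), numeric(m - n)))
  ac <- Re(fft(f * Conj(f), inverse = TRUE)) / m
  as.integer(round(ac[2:n]))
}

# Sum of weights w over all ranges [lo, hi] covering each position 1..n
# (difference-array accumulation; empty ranges lo > hi are dropped).
range_accumulate <- function(lo, hi, w, n) {
  keep <- hi >= lo
  if (!any(keep)) return(numeric(n))
  lo <- lo[keep]; hi <- hi[keep]; w <- w[keep]
  acc <- numeric(n + 1L)
  add <- rowsum(c(w, -w), group = c(lo, hi + 1L))
  idx <- as.integer(rownames(add))
  ok <- idx >= 1L & idx <= n + 1L
  acc[idx[ok]] <- add[ok]
  cumsum(acc)[seq_len(n)]
}

# Centered moving average ignoring NAs (window k, truncated at the ends).
ma_smooth <- function(x, k = 5L) {
  n <- length(x)
  h <- k %/% 2L
  out <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    xs <- x[max(1L, i - h):min(n, i + h)]
    if (any(is.finite(xs))) out[i] <- mean(xs[is.finite(xs)])
  }
  out
}

# Rolling sum over a centered window of k bins, truncated at vector ends.
# NAs contribute 0; use the companion count to renormalize if needed.
roll_sum <- function(x, k) {
  n <- length(x)
  h <- k %/% 2L
  x0 <- ifelse(is.na(x), 0, x)
  cs <- cumsum(x0)
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  cs[hi] - cs[lo] + x0[lo]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Separable k x k box smoothing of a matrix, ignoring non-finite entries
# (cells with no finite neighbors stay NA). Linear, hence transparent to
# scalar rescaling and sign flips.
box_smooth_matrix <- function(X, k) {
  if (k <= 1L) return(X)
  sm1 <- function(M) {
    n <- nrow(M)
    h <- k %/% 2L
    M0 <- M
    M0[!is.finite(M0)] <- 0
    W <- 1 * is.finite(M)
    cs <- rbind(0, apply(M0, 2L, cumsum))
    cw <- rbind(0, apply(W, 2L, cumsum))
    lo <- pmax(seq_len(n) - h, 1L)
    hi <- pmin(seq_len(n) + h, n)
    num <- cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]
    den <- cw[hi + 1L, , drop = FALSE] - cw[lo, , drop = FALSE]
    out <- num / den
    out[den == 0] <- NA_real_
    out
  }
  t(sm1(t(sm1(X))))
}
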