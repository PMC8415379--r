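# Joint-site feature matrix, PCA, and forward-selection linear models of
# DSB and crossover likelihood.

#' Build the standardized site-by-feature matrix
#'
#' Two columns per chromatin variable: the local value at the site bin and
#' the mean over a centered window of `2 * window_bins + 1` bins (the
#' "500-kb average" for 5-kb bins and the default 50), computed ignoring
#' missing values and clipped at chromosome ends. Rows with any missing
#' feature are dropped (counted); zero-variance columns are dropped with
#' a warning; the remaining columns are standardized to mean 0, sd 1.
#'
#' @param sites Site set (rows become observations; its columns are kept
#'   as row metadata).
#' @param variables Named list of genome-wide per-bin tracks.
#' @param bins Bin table.
#' @param window_bins Window half-width in bins (default 50, i.e. a
#'   101-bin window).
#' @return Standardized numeric matrix of class `feature_matrix` with
#'   attributes `row_meta` (the retained site rows), `dropped_rows`,
#'   `dropped_cols`.
#' @export
build_feature_matrix <- function(sites, variables, bins, window_bins = 50L) {
  stopifnot(length(variables) > 0, !is.null(names(variables)))
  nb <- chrom_nbins(bins)
  off <- chrom_offsets(bins)
  row <- sites$bin_id + 1L
  cols <- list()
  for (nm in names(variables)) {
    v <- as.numeric(variables[[nm]])
    stopifnot(length(v) == nrow(bins))
    wm <- numeric(length(v))
    for (ch in names(nb)) {
      idx <- off[[ch]] + seq_len(nb[[ch]])
      x <- v[idx]
      s <- roll_sum(x, 2L * window_bins + 1L)
      cnt <- roll_sum(as.numeric(!is.na(x)), 2L * window_bins + 1L)
      wm[idx] <- ifelse(cnt > 0, s / cnt, NA_real_)
    }
    cols[[paste0(nm, "_local")]] <- v[row]
    cols[[paste0(nm, "_win")]] <- wm[row]
  }
  X <- do.call(cbind, cols)
  keep_row <- stats::complete.cases(X)
  X <- X[keep_row, , drop = FALSE]
  if (nrow(X) == 0L) stop("all rows dropped: no site has complete features")
  sds <- apply(X, 2L, stats::sd)
  zero <- !is.finite(sds) | sds < 1e-12
  dropped_cols <- colnames(X)[zero]
  if (any(zero)) {
    warning("dropping zero-variance feature column(s): ",
            paste(dropped_cols, collapse = ", "))
    X <- X[, !zero, drop = FALSE]
  }
  Xs <- scale(X)
  attr(Xs, "scaled:center") <- NULL
  attr(Xs, "scaled:scale") <- NULL
  attr(Xs, "row_meta") <- as.data.frame(sites)[keep_row, , drop = FALSE]
  attr(Xs, "dropped_rows") <- sum(!keep_row)
  attr(Xs, "dropped_cols") <- dropped_cols
  class(Xs) <- c("feature_matrix", class(Xs))
  Xs
}

#' Principal component analysis of a feature matrix
#'
#' SVD-based PCA of the (already standardized) matrix, with a
#' deterministic sign convention: each loading vector is oriented so its
#' largest-magnitude element is positive. Explained-variance fractions
#' are reported over the full rank.
#'
#' @param fm A [build_feature_matrix()] matrix (or any numeric matrix
#'   whose columns are standardized).
#' @param n_components Components to retain (default 4).
#' @return List of class `pca_result`: `loadings` (columns x components),
#'   `scores` (rows x components), `explained_var` (full fraction
#'   vector), `n_components`.
#' @export
run_pca <- function(fm, n_components = 4L) {
  X <- unclass(fm)
  if (nrow(X) < 2L) stop("PCA needs at least 2 rows")
  if (nrow(X) < ncol(X)) {
    warning("fewer rows than columns; trailing components are degenerate")
  }
  p <- stats::prcomp(X, center = FALSE, scale. = FALSE)
  evf <- p$sdev^2 / sum(p$sdev^2)
  k <- min(n_components, ncol(p$rotation))
  load <- p$rotation[, seq_len(k), drop = FALSE]
  scores <- p$x[, seq_len(k), drop = FALSE]
  for (c in seq_len(k)) {
    j <- which.max(abs(load[, c]))
    if (load[j, c] < 0) {
      load[, c] <- -load[, c]
      scores[, c] <- -scores[, c]
    }
  }
  colnames(load) <- colnames(scores) <- paste0("PC", seq_len(k))
  structure(list(loadings = load, scores = scores, explained_var = evf,
                 n_components = k),
            class = "pca_result")
}

#' Forward-selection ordinary least squares
#'
#' Starts from the intercept-only model and adds, at each step, the
#' remaining candidate with the smallest entry p-value, provided it
#' passes the Bonferroni threshold `alpha_base / n` for the `n`
#' candidates supplied; stops otherwise. Collinear candidates (rank
#' deficiency on entry) are skipped with a warning. Ties in p-value
#' resolve to the lexicographically first candidate name.
#'
#' @param response Numeric response vector.
#' @param candidates Numeric matrix of candidate predictors with column
#'   names.
#' @param alpha_base Base significance level (default 0.001).
#' @param naive Character vector of candidate names forming the naive
#'   baseline model whose R-squared is reported alongside (default none:
#'   baseline is the intercept-only model, R-squared 0).
#' @return List of class `model_fit`: `selected` (in selection order),
#'   `coef`, `t`, `p`, `r2`, `naive_r2`, `threshold`, `n_obs`,
#'   `r2_path`.
#' @export
forward_select_ols <- function(response, candidates, alpha_base = 0.001,
                               naive = character(0)) {
  y <- as.numeric(response)
  X <- as.matrix(candidates)
  stopifnot(!is.null(colnames(X)), nrow(X) == length(y))
  ok <- is.finite(y) & stats::complete.cases(X)
  y <- y[ok]
  X <- X[ok, , drop = FALSE]
  n <- length(y)
  ncand <- ncol(X)
  thr <- alpha_base / ncand
  selected <- character(0)
  r2_path <- numeric(0)
  remaining <- sort(colnames(X))
  repeat {
    if (!length(remaining)) break
    ps <- rep(NA_real_, length(remaining))
    names(ps) <- remaining
    for (nm in remaining) {
      fit <- entry_pvalue(y, X[, selected, drop = FALSE], X[, nm])
      if (is.null(fit)) {
        warning("skipping collinear candidate '", nm, "'")
        remaining <- setdiff(remaining, nm)
        next
      }
      ps[nm] <- fit
    }
    ps <- ps[!is.na(ps)]
    if (!length(ps)) break
    best <- names(ps)[which.min(ps)]  # ties: lexicographic (sorted names)
    if (ps[best] >= thr) break
    selected <- c(selected, best)
    remaining <- setdiff(remaining, best)
    r2_path <- c(r2_path, ols_r2(y, X[, selected, drop = FALSE]))
  }
  final <- ols_summary(y, X[, selected, drop = FALSE])
  naive_r2 <- if (length(naive)) {
    ols_r2(y, X[, intersect(naive, colnames(X)), drop = FALSE])
  } else 0
  structure(list(selected = selected, coef = final$coef, t = final$t,
                 p = final$p, r2 = final$r2, naive_r2 = naive_r2,
                 threshold = thr, n_obs = n, r2_path = r2_path),
            class = "model_fit")
}

# p-value of the newly entered predictor in OLS of y on [1, Xsel, xnew];
# NULL if the design is rank deficient (collinear entry).
entry_pvalue <- function(y, Xsel, xnew) {
  M <- cbind(`(Intercept)` = 1, Xsel, new = xnew)
  fit <- stats::lm.fit(M, y)
  if (fit$rank < ncol(M)) return(NULL)
  rss <- sum(fit$residuals^2)
  df <- length(y) - fit$rank
  if (df <= 0) return(NULL)
  sigma2 <- rss / df
  R <- qr.R(fit$qr)
  XtXinv <- chol2inv(R)
  se <- sqrt(sigma2 * XtXinv[ncol(M), ncol(M)])
  if (!is.finite(se) || se == 0) return(NULL)
  tval <- fit$coefficients[ncol(M)] / se
  2 * stats::pt(-abs(tval), df)
}

ols_r2 <- function(y, X) {
  if (ncol(X) == 0L) return(0)
  fit <- stats::lm.fit(cbind(1, X), y)
  1 - sum(fit$residuals^2) / sum((y - mean(y))^2)
}

ols_summary <- function(y, X) {
  M <- cbind(`(Intercept)` = 1, X)
  fit <- stats::lm.fit(M, y)
  rss <- sum(fit$residuals^2)
  df <- length(y) - fit$rank
  sigma2 <- if (df > 0) rss / df else NA_real_
  XtXinv <- tryCatch(chol2inv(qr.R(fit$qr)), error = function(e) NULL)
  se <- if (!is.null(XtXinv)) sqrt(sigma2 * diag(XtXinv)) else
    rep(NA_real_, ncol(M))
  tval <- fit$coefficients / se
  pval <- 2 * stats::pt(-abs(tval), df)
  list(coef = fit$coefficients, t = tval, p = pval,
       r2 = 1 - rss / sum((y - mean(y))^2))
}

#' Fit the three recombination models
#'
#' Forward-selection OLS of (1) DSB activity (DMC1 score) at PRDM9 sites,
#' (2) crossover likelihood at DSB sites, and (3) crossover likelihood at
#' PRDM9 sites, each on the principal-component scores plus the
#' adjustment covariates (binding score of the upstream stage and
#' fractional chromosomal position), all competing in selection. Naive
#' baselines: PRDM9 score only for the DSB model; DMC1 score plus
#' position for the crossover model; PRDM9 score plus position for the
#' PRDM9-to-crossover model.
#'
#' @param pca [run_pca()] result computed on the joint-site feature
#'   matrix.
#' @param fm The [build_feature_matrix()] the PCA was computed on; its
#'   `row_meta` must carry `is_prdm9`, `is_dsb`, `prdm9_score`,
#'   `dmc1_score`, `crossover_score`, `position`.
#' @param alpha_base Base significance level (default 0.001).
#' @return List of class `recombination_models` with elements `dsb`,
#'   `crossover`, `prdm9_to_crossover` (each a `model_fit`).
#' @export
fit_recombination_models <- function(pca, fm, alpha_base = 0.001) {
  meta <- attr(fm, "row_meta")
  need <- c("is_prdm9", "is_dsb", "prdm9_score", "dmc1_score",
            "crossover_score", "position")
  stopifnot(all(need %in% names(meta)))
  zs <- function(x) {
    s <- stats::sd(x, na.rm = TRUE)
    if (!is.finite(s) || s == 0) s <- 1
    (x - mean(x, na.rm = TRUE)) / s
  }
  pcs <- pca$scores
  one <- function(rows, response, covars, naive) {
    cand <- cbind(pcs[rows, , drop = FALSE],
                  vapply(covars, function(nm) zs(meta[[nm]][rows]),
                         numeric(sum(rows))))
    colnames(cand) <- c(colnames(pcs), names(covars))
    forward_select_ols(response[rows], cand, alpha_base, naive = naive)
  }
  covs_p <- c(prdm9_score = "prdm9_score", position = "position")
  covs_d <- c(dmc1_score = "dmc1_score", position = "position")
  list_out <- list(
    dsb = one(meta$is_prdm9, meta$dmc1_score, covs_p,
              naive = "prdm9_score"),
    crossover = one(meta$is_dsb, meta$crossover_score, covs_d,
                    naive = c("dmc1_score", "position")),
    prdm9_to_crossover = one(meta$is_prdm9, meta$crossover_score, covs_p,
                             naive = c("prdm9_score", "position")))
  structure(list_out, class = "recombination_models")
}

#' @export
print.model_fit <- function(x, ...) {
  cat(sprintf("model_fit: %d obs, R2 = %.4f (naive %.4f), threshold %.2g\n",
              x$n_obs, x$r2, x$naive_r2, x$threshold))
  if (length(x$selected)) {
    cat("selected:", paste(x$selected, collapse = ", "), "\n")
  } else {
    cat("selected: (none)\n")
  }
  invisible(x)
}
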