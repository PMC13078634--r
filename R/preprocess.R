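#' Filter cells by number of detected genes
#'
#' Removes cells detecting fewer than `min_genes` genes (a gene is detected
#' when its count is > 0), leaving the gene set untouched. The adult-heart
#' pipeline uses a cutoff of 400 genes per cell; the circulating-cell
#' reference pipeline requires more than 200.
#'
#' @param counts cells-by-genes raw count matrix (base matrix or
#'   [Matrix::Matrix]) with cell/gene ids as dimnames, or a counts-stage
#'   [expr_matrix()].
#' @param min_genes minimum number of detected genes for a cell to be kept.
#' @return A filtered count matrix of the same type.
#' @export
qc_filter <- function(counts, min_genes = 400) {
  stopifnot(min_genes >= 0)
  m <- if (inherits(counts, "expr_matrix")) counts$values else counts
  detected <- Matrix::rowSums(m > 0)
  keep <- detected >= min_genes
  if (!any(keep)) {
    warn(sprintf("qc_filter: no cell detects >= %d genes; returning 0 cells.", min_genes))
  }
  out <- m[keep, , drop = FALSE]
  if (inherits(counts, "expr_matrix")) {
    counts$values <- out
    counts$params$min_genes <- min_genes
    return(counts)
  }
  out
}

#' Library-size normalization and log transform
#'
#' Scales each cell so its counts sum to `target_sum` (default 1e4), then
#' applies the natural-log `log1p` transform, x -> ln(1 + x).
#'
#' @param counts raw count matrix (cells x genes) or counts-stage
#'   [expr_matrix()]; every cell must have a positive total (run
#'   [qc_filter()] first).
#' @param target_sum per-cell total after normalization.
#' @return A log-stage [expr_matrix()].
#' @export
normalize_log <- function(counts, target_sum = 1e4) {
  m <- if (inherits(counts, "expr_matrix")) counts$values else counts
  totals <- Matrix::rowSums(m)
  if (any(totals <= 0)) {
    bad <- rownames(m)[totals <= 0]
    abort(sprintf("normalize_log: cell(s) with zero total counts: %s. Filter them first.",
                  paste(head(bad, 5), collapse = ", ")))
  }
  scaled <- Matrix::Diagonal(x = target_sum / totals) %*% m
  dimnames(scaled) <- dimnames(m)
  out <- log1p(scaled)
  expr_matrix(out, stage = "log", params = list(target_sum = target_sum))
}

#' Regress technical covariates out of expression values
#'
#' Per gene, replaces expression by the ordinary-least-squares residual of
#' expression on the given per-cell covariates (with intercept). The default
#' covariate in the pipeline is the per-cell total count.
#'
#' @param expr log-stage [expr_matrix()].
#' @param covariates data frame or matrix of per-cell covariates, rows
#'   aligned with (or named by) the cells of `expr`.
#' @return A residual-stage [expr_matrix()]. Residuals are orthogonal to the
#'   covariates and mean zero per gene.
#' @export
regress_covariates <- function(expr, covariates) {
  assert_stage(expr, c("log", "normalized"), "regress_covariates")
  v <- as_dense(expr)
  cv <- as.matrix(covariates)
  if (nrow(cv) != nrow(v)) {
    abort("regress_covariates: covariate rows must align with cells.")
  }
  if (!is.null(rownames(cv)) && !identical(rownames(cv), rownames(v))) {
    cv <- cv[rownames(v), , drop = FALSE]
  }
  X <- cbind(`(Intercept)` = 1, cv)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    abort("regress_covariates: covariates are rank deficient (collinear).")
  }
  res <- as.matrix(stats::lm.fit(x = X, y = v)$residuals)
  dimnames(res) <- dimnames(v)
  expr_matrix(res, stage = "residual",
              params = c(expr$params, list(covariates = colnames(cv) %||% "covariate")))
}

#' Scale genes to unit variance and clip
#'
#' Centers each gene to mean zero, divides by its standard deviation, and
#' truncates values above `clip_max` (default 10) at `clip_max`. Genes with
#' zero variance are mapped to all zeros rather than dropped. The standard
#' deviation uses the population denominator n by default (`ddof = 0`);
#' set `ddof = 1` for the sample denominator.
#'
#' @param expr log- or residual-stage [expr_matrix()].
#' @param clip_max upper clip for scaled values.
#' @param ddof degrees-of-freedom correction for the SD denominator (n - ddof).
#' @return A scaled-stage [expr_matrix()] (dense).
#' @export
scale_clip <- function(expr, clip_max = 10, ddof = 0) {
  assert_stage(expr, c("log", "residual"), "scale_clip")
  v <- as_dense(expr)
  n <- nrow(v)
  mu <- colMeans(v)
  ss <- colSums(v^2) - n * mu^2
  ss[ss < 0] <- 0
  sdv <- sqrt(ss / (n - ddof))
  z <- sweep(v, 2, mu, "-")
  nz <- sdv > 1e-12
  z[, nz] <- sweep(z[, nz, drop = FALSE], 2, sdv[nz], "/")
  z[, !nz] <- 0
  z[z > clip_max] <- clip_max
  expr_matrix(z, stage = "scaled",
              params = c(expr$params, list(clip_max = clip_max, ddof = ddof)))
}

#' Select highly variable genes
#'
#' Mean-binned dispersion ranking: per gene, the dispersion var/mean is
#' computed on the normalized (de-logged) values, genes are binned into
#' `n_bins` quantile bins of mean expression, dispersions are z-scored
#' within each bin, and genes are ranked by normalized dispersion. Ties are
#' broken by gene id in lexicographic order, making the list deterministic.
#'
#' @param expr log-stage [expr_matrix()].
#' @param n_top number of genes to return (capped at the number of genes).
#' @param n_bins number of mean-expression bins.
#' @return Character vector of gene ids, highest dispersion first.
#' @export
select_hvg <- function(expr, n_top = 2000, n_bins = 20) {
  assert_stage(expr, "log", "select_hvg")
  v <- as_dense(expr)
  x <- expm1(v)
  mu <- colMeans(x)
  vr <- apply(x, 2, var)
  disp <- ifelse(mu > 0, vr / mu, 0)
  bins <- cut(rank(mu, ties.method = "first"),
              breaks = min(n_bins, max(1, ncol(v) %/% 2)), labels = FALSE)
  zd <- disp
  for (b in unique(bins)) {
    idx <- bins == b
    s <- sd(disp[idx])
    zd[idx] <- if (is.na(s) || s < 1e-12) 0 else (disp[idx] - mean(disp[idx])) / s
  }
  ord <- order(-zd, colnames(v))
  head(colnames(v)[ord], min(n_top, ncol(v)))
}
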