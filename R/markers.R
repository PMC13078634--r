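#' One-vs-rest Wilcoxon rank-sum marker ranking
#'
#' For every cluster with at least two cells, tests each gene with a
#' two-sided Wilcoxon rank-sum test of the cluster's cells against all other
#' cells, adjusts p-values with Benjamini-Hochberg within the cluster, and
#' ranks genes by p (ties by descending log fold-change). Small untied
#' samples use the exact null distribution; larger or tied samples the
#' normal approximation with continuity correction (the [wilcox.test()]
#' rules).
#'
#' @param expr log-stage [expr_matrix()].
#' @param labels `cluster_labels` (or data frame with `cell_id`, `cluster`).
#' @param genes genes to test; default all.
#' @return Tibble: `cluster`, `gene`, `statistic` (rank-sum W for the
#'   cluster's cells), `p`, `q`, `logfc` (log2 ratio of de-logged means),
#'   `rank`.
#' @export
rank_markers <- function(expr, labels, genes = NULL) {
  assert_stage(expr, c("log", "normalized"), "rank_markers")
  v <- as_dense(expr)[labels$cell_id, , drop = FALSE]
  genes <- genes %||% colnames(v)
  cl <- sort(unique(labels$cluster))
  if (length(cl) < 2) abort("rank_markers: at least 2 clusters are required.")
  res <- purrr::map(cl, function(k) {
    in_k <- labels$cluster == k
    if (sum(in_k) < 2) {
      warn(sprintf("rank_markers: cluster %s has < 2 cells; skipped.", k))
      return(NULL)
    }
    stats_g <- purrr::map(genes, function(g) {
      x <- v[in_k, g]
      y <- v[!in_k, g]
      wt <- suppressWarnings(wilcox.test(x, y, alternative = "two.sided"))
      eps <- 1e-9
      tibble::tibble(gene = g,
                     statistic = unname(wt$statistic),
                     p = wt$p.value,
                     logfc = log2((mean(expm1(x)) + eps) / (mean(expm1(y)) + eps)))
    })
    out <- dplyr::bind_rows(stats_g)
    out$p[is.na(out$p)] <- 1
    out$q <- p.adjust(out$p, method = "BH")
    out <- dplyr::arrange(out, .data$p, dplyr::desc(.data$logfc))
    out$rank <- seq_len(nrow(out))
    out$cluster <- k
    out
  })
  dplyr::bind_rows(res) |>
    dplyr::select("cluster", "gene", "statistic", "p", "q", "logfc", "rank")
}

#' Panel z-score matrix for curated gene lists
#'
#' Computes the matrix of per-cluster mean expression for a curated gene
#' panel and z-scores each gene across *all* clusters (population SD).
#' Masking the display to a subset of clusters never changes the values: the
#' z-scores are always derived from the full cluster set.
#'
#' @param expr log-stage [expr_matrix()].
#' @param labels cluster labels.
#' @param genes curated gene panel; all must be present.
#' @return Matrix clusters x genes of z-scores (constant genes give 0), with
#'   attribute `cluster_means` carrying the raw mean matrix.
#' @export
panel_zscores <- function(expr, labels, genes) {
  assert_stage(expr, c("log", "normalized"), "panel_zscores")
  missing_g <- setdiff(genes, gene_ids(expr))
  if (length(missing_g)) {
    abort(sprintf("panel_zscores: genes not in matrix: %s",
                  paste(missing_g, collapse = ", ")))
  }
  v <- as_dense(expr)[labels$cell_id, genes, drop = FALSE]
  cl <- sort(unique(labels$cluster))
  means <- t(vapply(cl, function(k) colMeans(v[labels$cluster == k, , drop = FALSE]),
                    numeric(length(genes))))
  rownames(means) <- as.character(cl)
  colnames(means) <- genes
  mu <- colMeans(means)
  sdp <- sqrt(colMeans(sweep(means, 2, mu, "-")^2)) # population SD across clusters
  z <- sweep(means, 2, mu, "-")
  nz <- sdp > 1e-12
  z[, nz] <- sweep(z[, nz, drop = FALSE], 2, sdp[nz], "/")
  z[, !nz] <- 0
  attr(z, "cluster_means") <- means
  z
}

#' Top expressed genes per cluster with specificity scores
#'
#' Ranks genes within each cluster by mean expression and reports a
#' specificity score (mean in cluster / mean in all other clusters' cells)
#' to support manual curation. Cluster-exclusive genes (zero expression
#' elsewhere) get specificity `Inf`.
#'
#' @param expr log-stage [expr_matrix()].
#' @param labels cluster labels.
#' @param k top genes to keep per cluster.
#' @return Tibble: `cluster`, `gene`, `mean_expr`, `specificity`, `rank`.
#' @export
top_expressed <- function(expr, labels, k = 10) {
  stopifnot(k >= 1)
  assert_stage(expr, c("log", "normalized"), "top_expressed")
  v <- as_dense(expr)[labels$cell_id, , drop = FALSE]
  cl <- sort(unique(labels$cluster))
  res <- purrr::map(cl, function(kk) {
    in_k <- labels$cluster == kk
    m_in <- colMeans(v[in_k, , drop = FALSE])
    m_out <- if (any(!in_k)) colMeans(v[!in_k, , drop = FALSE]) else rep(0, ncol(v))
    spec <- ifelse(m_out > 0, m_in / m_out, ifelse(m_in > 0, Inf, NA_real_))
    ord <- order(-m_in, colnames(v))
    tibble::tibble(cluster = kk,
                   gene = colnames(v)[ord],
                   mean_expr = m_in[ord],
                   specificity = spec[ord],
                   rank = seq_along(ord)) |>
      dplyr::slice_head(n = k)
  })
  dplyr::bind_rows(res)
}
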