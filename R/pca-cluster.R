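#' Truncated principal component analysis
#'
#' Computes the top `n_components` principal components of a scaled
#' expression matrix with the implicitly-restarted Lanczos solver
#' ([irlba::irlba()]), the same family of ARPACK-style truncated
#' eigensolvers standard single-cell toolkits use. Variance ratios are each
#' component's variance over the total variance of the input.
#'
#' @param expr scaled-stage [expr_matrix()].
#' @param n_components number of components; must be < min(cells, genes).
#' @param seed integer seed for the solver's random initialization.
#' @return An `embedding` object: list with `scores` (cells x k, rownames =
#'   cell ids), `loadings` (genes x k), `variance_ratio`, and `params`.
#' @export
run_pca <- function(expr, n_components = 50, seed = 0) {
  assert_stage(expr, "scaled", "run_pca")
  v <- as_dense(expr)
  if (n_components >= min(dim(v))) {
    abort("run_pca: n_components must be smaller than min(n_cells, n_genes).")
  }
  v_c <- sweep(v, 2, colMeans(v), "-")
  total_var <- sum(colSums(v_c^2)) / (nrow(v) - 1)
  set.seed(seed)
  if (n_components <= min(dim(v)) / 3) {
    sv <- irlba::irlba(v_c, nv = n_components)
  } else {
    # truncated solvers need a large spectral gap to the requested rank;
    # fall back to the dense SVD when most components are wanted
    sv_full <- svd(v_c, nu = n_components, nv = n_components)
    sv <- list(d = sv_full$d[seq_len(n_components)], u = sv_full$u, v = sv_full$v)
  }
  # fix sign for reproducibility: largest-|loading| entry positive
  flip <- vapply(seq_len(n_components), function(j) {
    l <- sv$v[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(v_c %*% sv$v, 2, flip, "*")
  loadings <- sweep(sv$v, 2, flip, "*")
  comp_var <- sv$d^2 / (nrow(v) - 1)
  rownames(scores) <- rownames(v)
  rownames(loadings) <- colnames(v)
  colnames(scores) <- colnames(loadings) <- paste0("PC", seq_len(n_components))
  structure(list(scores = scores,
                 loadings = loadings,
                 variance_ratio = comp_var / total_var,
                 params = list(n_components = n_components, seed = seed)),
            class = "embedding")
}

#' @export
print.embedding <- function(x, ...) {
  cat(sprintf("<embedding> %d cells, %d components; leading variance ratios: %s\n",
              nrow(x$scores), ncol(x$scores),
              paste(signif(head(x$variance_ratio, 5), 3), collapse = ", ")))
  invisible(x)
}

#' Choose the number of informative principal components
#'
#' Formalizes picking components from the log variance-ratio curve: the knee
#' is located at the largest discrete second difference of ln(variance
#' ratio) — the point where the curve flattens — and all components before
#' the flattening are kept. The result is bounded to `[min_pcs, max_pcs]`
#' and can be overridden outright.
#'
#' @param variance_ratios non-increasing positive variance ratios.
#' @param min_pcs,max_pcs bounds on the returned count.
#' @param override if non-NULL, returned as-is.
#' @return Integer number of components.
#' @export
choose_n_pcs <- function(variance_ratios, min_pcs = 2,
                         max_pcs = length(variance_ratios), override = NULL) {
  if (!is.null(override)) return(as.integer(override))
  n <- length(variance_ratios)
  if (n < 4) return(n)
  if (any(variance_ratios <= 0)) abort("choose_n_pcs: variance ratios must be positive.")
  l <- log(variance_ratios)
  # centered second difference at i = 2..n-1; knee = flattening point
  d2 <- l[1:(n - 2)] - 2 * l[2:(n - 1)] + l[3:n]
  knee <- which.max(d2) + 1L # index into 2..n-1
  k <- knee - 1L
  as.integer(min(max(k, min_pcs), max_pcs))
}

# Shared kNN-graph Louvain step. Edges are weighted by the Jaccard overlap
# of the two cells' neighbor sets (shared-nearest-neighbor weighting), which
# keeps coherent groups together at moderate resolutions.
louvain_on_scores <- function(scores, n_neighbors, resolution, seed) {
  n <- nrow(scores)
  if (resolution <= 0) abort("resolution must be > 0.")
  if (n == 1) return(setNames(0L, rownames(scores)))
  k <- min(n_neighbors, n - 1)
  nn <- FNN::get.knn(scores, k = k)$nn.index
  # incidence of (cell, neighborhood incl. self)
  A <- Matrix::sparseMatrix(i = rep(seq_len(n), k + 1),
                            j = c(as.vector(nn), seq_len(n)),
                            x = 1, dims = c(n, n))
  shared <- Matrix::tcrossprod(A) # counts of shared neighbors
  sh <- methods::as(methods::as(shared, "generalMatrix"), "TsparseMatrix")
  keep <- sh@i < sh@j
  i <- sh@i[keep] + 1L
  j <- sh@j[keep] + 1L
  w <- sh@x[keep] / (2 * (k + 1) - sh@x[keep]) # Jaccard
  ok <- w >= 1 / 15
  g <- igraph::graph_from_edgelist(cbind(i[ok], j[ok]), directed = FALSE)
  igraph::E(g)$weight <- w[ok]
  g <- igraph::simplify(g, edge.attr.comb = "max")
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  set.seed(seed)
  comm <- igraph::cluster_louvain(g, resolution = resolution)
  memb <- igraph::membership(comm)
  # relabel contiguous from 0, largest cluster first
  sizes <- sort(table(memb), decreasing = TRUE)
  relab <- setNames(seq_along(sizes) - 1L, names(sizes))
  setNames(as.integer(relab[as.character(memb)]), rownames(scores))
}

#' Louvain clustering on the neighbor graph
#'
#' Builds a k-nearest-neighbor graph on the chosen principal components
#' (Euclidean distance) and partitions it with Louvain community detection.
#'
#' @param embedding an `embedding` from [run_pca()].
#' @param n_neighbors neighbors per cell in the kNN graph.
#' @param resolution Louvain resolution; > 0.
#' @param n_pcs number of leading components to use; default
#'   [choose_n_pcs()] on the embedding's variance ratios.
#' @param seed integer seed (Louvain is stochastic).
#' @return A `cluster_labels` tibble: `cell_id`, `cluster` (integer, 0-based,
#'   contiguous), with attributes `resolution` and `parent`.
#' @export
cluster_cells <- function(embedding, n_neighbors = 15, resolution = 1.0,
                          n_pcs = NULL, seed = 0) {
  n_pcs <- n_pcs %||% choose_n_pcs(embedding$variance_ratio)
  n_pcs <- min(n_pcs, ncol(embedding$scores))
  memb <- louvain_on_scores(embedding$scores[, seq_len(n_pcs), drop = FALSE],
                            n_neighbors, resolution, seed)
  new_cluster_labels(tibble::tibble(cell_id = names(memb), cluster = unname(memb)),
                     resolution = resolution, parent = NA_integer_, n_pcs = n_pcs)
}

new_cluster_labels <- function(tbl, resolution, parent, n_pcs = NA_integer_) {
  structure(tbl, class = c("cluster_labels", class(tbl)),
            resolution = resolution, parent = parent, n_pcs = n_pcs)
}

#' Sub-cluster one cluster on the preserved parent embedding
#'
#' Re-runs Louvain on the cells of a single parent cluster, reusing the rows
#' of the parent PCA scores (no recomputation of PCA), so the sub-structure
#' is resolved inside the parent's coordinate system. The default resolution
#' is 0.83.
#'
#' @param embedding the parent `embedding` (from [run_pca()]).
#' @param labels the parent `cluster_labels`.
#' @param cluster_id the parent cluster to split.
#' @param resolution Louvain resolution for the sub-clustering.
#' @param n_neighbors neighbors in the sub-graph; the target cluster must
#'   have more cells than this.
#' @param n_pcs components to use; defaults to the parent clustering's.
#' @param seed integer seed.
#' @return A `cluster_labels` tibble restricted to the target cluster's
#'   cells, with `parent` set to `cluster_id`.
#' @export
subcluster <- function(embedding, labels, cluster_id, resolution = 0.83,
                       n_neighbors = 15, n_pcs = NULL, seed = 0) {
  cells <- labels$cell_id[labels$cluster == cluster_id]
  if (length(cells) == 0) abort(sprintf("Cluster %s does not exist.", cluster_id))
  if (length(cells) <= n_neighbors) {
    abort(sprintf(paste0("Cluster %s has %d cells, too few for n_neighbors = %d; ",
                         "use a smaller n_neighbors."),
                  cluster_id, length(cells), n_neighbors))
  }
  n_pcs <- n_pcs %||% attr(labels, "n_pcs") %||% ncol(embedding$scores)
  if (is.na(n_pcs)) n_pcs <- ncol(embedding$scores)
  sub_scores <- embedding$scores[cells, seq_len(n_pcs), drop = FALSE]
  memb <- louvain_on_scores(sub_scores, n_neighbors, resolution, seed)
  new_cluster_labels(tibble::tibble(cell_id = names(memb), cluster = unname(memb)),
                     resolution = resolution, parent = cluster_id, n_pcs = n_pcs)
}
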