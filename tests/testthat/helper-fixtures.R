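# Small fixtures built in code, shared across test files.

# tiny raw count matrix with dimnames
tiny_counts <- function(values, n_cells = NULL, n_genes = NULL) {
  if (is.matrix(values)) {
    m <- values
  } else {
    m <- matrix(values, nrow = n_cells, ncol = n_genes)
  }
  rownames(m) <- sprintf("cell%02d", seq_len(nrow(m)))
  colnames(m) <- sprintf("g%03d", seq_len(ncol(m)))
  m
}

# log-stage expr_matrix straight from a dense value matrix (bypasses
# normalization when a test wants exact hand-picked log values)
as_log_expr <- function(values) {
  expr_matrix(tiny_counts(values), stage = "log")
}

as_dense_values <- function(e) as.matrix(e$values)

# cluster labels tibble from an integer vector aligned with matrix rows
labels_for <- function(m, clusters) {
  tibble::tibble(cell_id = rownames(m), cluster = as.integer(clusters))
}

# hand-built cluster_profiles from a centroid matrix + cell counts
profiles_from <- function(centroids, n_cells) {
  rownames(centroids) <- as.character(seq_len(nrow(centroids)) - 1L)
  structure(list(centroids = centroids,
                 info = tibble::tibble(cluster = seq_len(nrow(centroids)) - 1L,
                                       n_cells = as.integer(n_cells),
                                       abundance = n_cells / sum(n_cells)),
                 hvg = colnames(centroids) %||%
                   sprintf("g%03d", seq_len(ncol(centroids)))),
            class = "cluster_profiles")
}

`%||%` <- rlang::`%||%`

# F1 of a predicted cell set against a truth cell set
f1_cells <- function(pred, truth) {
  tp <- length(intersect(pred, truth))
  fp <- length(setdiff(pred, truth))
  fn <- length(setdiff(truth, pred))
  if (2 * tp + fp + fn == 0) return(1)
  2 * tp / (2 * tp + fp + fn)
}

# run the full match pipeline on a generated pair; returns cell-level F1
pipeline_f1 <- function(seed, cfg = NULL, pcfg = NULL) {
  cfg <- cfg %||% sc_sim_config(seed = seed)
  pair <- generate_sc_pair(cfg)
  pcfg <- pcfg %||% pipeline_config(min_genes = 5, n_components = 20, seed = seed)
  res <- run_pipeline(pair$query$counts, pair$reference$counts, pcfg)
  dec <- res$decisions
  lab <- res$query$labels
  pred <- lab$cell_id[lab$cluster %in% dec$query_cluster[dec$verdict == "contaminant"]]
  truth <- names(pair$truth$query_contaminant)[pair$truth$query_contaminant]
  f1_cells(pred, truth)
}
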