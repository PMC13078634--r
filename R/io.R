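#' Read / write a count matrix in Matrix Market layout
#'
#' The on-disk layout follows the common droplet convention: `matrix.mtx`
#' (genes implicitly columns of the transposed store are handled here as
#' cells x genes directly), `genes.tsv` (one gene id per line) and
#' `barcodes.tsv` (one cell id per line) inside a directory.
#'
#' @param path directory containing (or to contain) `matrix.mtx`,
#'   `genes.tsv`, `barcodes.tsv`.
#' @return `read_count_matrix`: a sparse cells x genes count matrix with
#'   dimnames. `write_count_matrix`: the path, invisibly.
#' @export
read_count_matrix <- function(path) {
  mtx <- file.path(path, "matrix.mtx")
  gf <- file.path(path, "genes.tsv")
  bf <- file.path(path, "barcodes.tsv")
  for (f in c(mtx, gf, bf)) {
    if (!file.exists(f)) abort(sprintf("read_count_matrix: missing file %s", f))
  }
  m <- tryCatch(Matrix::readMM(mtx),
                error = function(e) abort(sprintf("read_count_matrix: malformed %s: %s",
                                                  mtx, conditionMessage(e))))
  genes <- readLines(gf)
  barcodes <- readLines(bf)
  if (nrow(m) != length(barcodes) || ncol(m) != length(genes)) {
    abort(sprintf(paste0("read_count_matrix: dimension mismatch: matrix is %dx%d ",
                         "but %d barcodes and %d genes listed."),
                  nrow(m), ncol(m), length(barcodes), length(genes)))
  }
  m <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
  dimnames(m) <- list(barcodes, genes)
  m
}

#' @rdname read_count_matrix
#' @param counts sparse or dense cells x genes count matrix with dimnames.
#' @export
write_count_matrix <- function(counts, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  m <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                               "CsparseMatrix"), "generalMatrix")
  Matrix::writeMM(m, file.path(path, "matrix.mtx"))
  writeLines(colnames(counts), file.path(path, "genes.tsv"))
  writeLines(rownames(counts), file.path(path, "barcodes.tsv"))
  invisible(path)
}

pipeline_defaults <- function() {
  list(min_genes = 400, target_sum = 1e4, clip_max = 10, ddof = 0,
       n_top_hvg = 2000, n_components = 50, n_pcs = NULL, n_neighbors = 15,
       resolution = 1.0, subcluster_resolution = 0.83,
       match_threshold = 0.5, match_band = 0.01, match_ratio_limit = 10,
       seed = 0)
}

#' Pipeline configuration
#'
#' Collects every tunable stage parameter with its default. Unknown keys
#' are rejected so a config file cannot silently misspell a parameter.
#' `read_pipeline_config()` loads a YAML file; `write_pipeline_config()`
#' round-trips it losslessly.
#'
#' @param ... overrides of the default parameters (see
#'   [pipeline_defaults] in the source for the full key list: `min_genes`,
#'   `target_sum`, `clip_max`, `ddof`, `n_top_hvg`, `n_components`, `n_pcs`,
#'   `n_neighbors`, `resolution`, `subcluster_resolution`,
#'   `match_threshold`, `match_band`, `match_ratio_limit`, `seed`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  over <- list(...)
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown)) {
    abort(sprintf("pipeline_config: unknown key(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, over, keep.null = TRUE)
  structure(cfg, class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param path YAML file path.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' @rdname pipeline_config
#' @param config a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the full contaminant-elimination pipeline on a dataset pair
#'
#' Binds the stages end to end: QC filter, normalize + log, HVG selection,
#' scale + clip, PCA, Louvain clustering for query and reference, centroid
#' profiling on log-stage values over the common HVG set, correlation
#' matching, and contaminant decisions. Returns all intermediate state plus
#' a run manifest (config echo, seed, package version).
#'
#' @param query,reference raw count matrices (cells x genes, dimnames set),
#'   e.g. from [generate_sc_pair()] or [read_count_matrix()].
#' @param config a [pipeline_config()].
#' @return List: `query`, `reference` (each with `expr_log`, `embedding`,
#'   `labels`, `profiles`), `hvg`, `match`, `decisions`, `manifest`.
#' @export
run_pipeline <- function(query, reference, config = pipeline_config()) {
  process_one <- function(counts, what) {
    counts <- qc_filter(counts, min_genes = config$min_genes)
    expr_log <- normalize_log(counts, target_sum = config$target_sum)
    total_counts <- Matrix::rowSums(counts)
    expr_res <- regress_covariates(expr_log, data.frame(total_counts = total_counts))
    expr_sc <- scale_clip(expr_res, clip_max = config$clip_max, ddof = config$ddof)
    n_comp <- min(config$n_components, min(dim(counts)) - 1)
    emb <- run_pca(expr_sc, n_components = n_comp,
                   seed = stage_seed(config$seed, paste0("pca_", what)))
    labels <- cluster_cells(emb, n_neighbors = config$n_neighbors,
                            resolution = config$resolution, n_pcs = config$n_pcs,
                            seed = stage_seed(config$seed, paste0("louvain_", what)))
    list(counts = counts, expr_log = expr_log, embedding = emb, labels = labels)
  }
  q <- process_one(query, "query")
  r <- process_one(reference, "reference")
  hvg <- intersect(select_hvg(q$expr_log, n_top = config$n_top_hvg),
                   select_hvg(r$expr_log, n_top = config$n_top_hvg))
  if (length(hvg) < 2) abort("run_pipeline: fewer than 2 common HVGs.")
  q$profiles <- cluster_profiles(q$expr_log, q$labels, hvg)
  r$profiles <- cluster_profiles(r$expr_log, r$labels, hvg)
  match <- profile_correlation(q$profiles, r$profiles)
  decisions <- assign_contaminants(match, match_config(
    threshold = config$match_threshold, band = config$match_band,
    ratio_limit = config$match_ratio_limit))
  manifest <- list(
    config = unclass(config),
    config_hash = rlang::hash(unclass(config)),
    seed = config$seed,
    package_version = as.character(utils::packageVersion("ulheart")),
    n_cells = c(query = nrow(q$counts), reference = nrow(r$counts)),
    n_hvg = length(hvg))
  list(query = q, reference = r, hvg = hvg, match = match,
       decisions = decisions, manifest = manifest)
}

#' Write a run manifest as JSON
#'
#' @param manifest the `manifest` element of a [run_pipeline()] result.
#' @param path output JSON file.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
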