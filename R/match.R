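#' Per-cluster centroid profiles
#'
#' For each cluster, the centroid is the mean log-transformed expression
#' over the supplied highly-variable-gene set, and the abundance is the
#' cluster's fraction of its dataset's cells. Centroids are computed on
#' log-normalized (pre-scaling) values.
#'
#' @param expr log-stage [expr_matrix()].
#' @param labels `cluster_labels` (or a data frame with `cell_id`, `cluster`).
#' @param hvg character vector of gene ids to profile over.
#' @return A `cluster_profiles` object: list with `centroids` (clusters x
#'   HVGs matrix, rownames = cluster ids) and `info` tibble (`cluster`,
#'   `n_cells`, `abundance`).
#' @export
cluster_profiles <- function(expr, labels, hvg) {
  assert_stage(expr, "log", "cluster_profiles")
  missing_g <- setdiff(hvg, gene_ids(expr))
  if (length(missing_g)) {
    abort(sprintf("cluster_profiles: genes absent from matrix: %s",
                  paste(head(missing_g, 5), collapse = ", ")))
  }
  v <- as_dense(expr)[labels$cell_id, hvg, drop = FALSE]
  cl <- sort(unique(labels$cluster))
  cent <- t(vapply(cl, function(k) {
    colMeans(v[labels$cluster == k, , drop = FALSE])
  }, numeric(length(hvg))))
  rownames(cent) <- as.character(cl)
  colnames(cent) <- hvg
  n_cells <- as.integer(table(factor(labels$cluster, levels = cl)))
  structure(list(centroids = cent,
                 info = tibble::tibble(cluster = cl, n_cells = n_cells,
                                       abundance = n_cells / sum(n_cells)),
                 hvg = hvg),
            class = "cluster_profiles")
}

#' @export
print.cluster_profiles <- function(x, ...) {
  cat(sprintf("<cluster_profiles> %d clusters over %d genes\n",
              nrow(x$centroids), length(x$hvg)))
  print(x$info)
  invisible(x)
}

#' Pairwise Pearson correlation of cluster centroids
#'
#' Correlates every (query cluster, reference cluster) centroid pair over
#' the common HVG set. Zero-variance centroids yield an undefined
#' correlation, recorded as `NA` with a warning.
#'
#' @param query,reference `cluster_profiles` built over the same HVG set
#'   (same genes, same order).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return A `match_matrix`: correlation matrix (query clusters x reference
#'   clusters) with the profile objects attached.
#' @export
profile_correlation <- function(query, reference, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!identical(query$hvg, reference$hvg)) {
    abort("profile_correlation: profiles must share an identical HVG set and order.")
  }
  degen <- c(apply(query$centroids, 1, sd), apply(reference$centroids, 1, sd)) < 1e-12
  if (any(degen)) warn("profile_correlation: zero-variance centroid(s); correlations set to NA.")
  r <- suppressWarnings(cor(t(query$centroids), t(reference$centroids), method = method))
  structure(list(r = r, query = query, reference = reference, method = method),
            class = "match_matrix")
}

#' @export
print.match_matrix <- function(x, ...) {
  cat(sprintf("<match_matrix> %d query x %d reference clusters (%s)\n",
              nrow(x$r), ncol(x$r), x$method))
  print(round(x$r, 3))
  invisible(x)
}

#' @rdname profile_correlation
#' @param x a `match_matrix`.
#' @param ... unused.
#' @method tidy match_matrix
#' @export
tidy.match_matrix <- function(x, ...) {
  tibble::as_tibble(as.table(x$r), .name_repair = "minimal") |>
    setNames(c("query_cluster", "reference_cluster", "r")) |>
    tibble::as_tibble()
}

#' Calibrate the matching threshold on reference replicates
#'
#' Re-runs the centroid-matching analysis between biological replicates of
#' the reference dataset and picks the decision threshold as the largest
#' grid value at which every cluster of each replicate still has a match in
#' every other replicate (all shared states cross-match in both directions).
#' The full grid curve is returned for inspection.
#'
#' @param replicate_profiles list of >= 2 `cluster_profiles`, one per
#'   replicate, built over a common HVG set.
#' @param grid candidate thresholds.
#' @return A list with `threshold` (a grid member) and `curve`, a tibble of
#'   (`threshold`, `all_cross_matched`, `frac_matched`).
#' @export
calibrate_threshold <- function(replicate_profiles, grid = seq(0.1, 0.9, by = 0.05)) {
  if (length(replicate_profiles) < 2) {
    abort("calibrate_threshold: at least 2 replicate profiles are required.")
  }
  pairs <- utils::combn(length(replicate_profiles), 2, simplify = FALSE)
  best_r <- unlist(lapply(pairs, function(p) {
    r <- profile_correlation(replicate_profiles[[p[1]]], replicate_profiles[[p[2]]])$r
    c(apply(r, 1, max, na.rm = TRUE), apply(r, 2, max, na.rm = TRUE))
  }))
  curve <- tibble::tibble(
    threshold = grid,
    frac_matched = vapply(grid, function(t) mean(best_r >= t), numeric(1)),
    all_cross_matched = vapply(grid, function(t) all(best_r >= t), logical(1))
  )
  ok <- curve$threshold[curve$all_cross_matched]
  if (!length(ok)) {
    warn("calibrate_threshold: no grid threshold keeps all replicate clusters matched; returning grid minimum.")
    ok <- min(grid)
  }
  list(threshold = max(ok), curve = curve)
}

#' Matching configuration
#'
#' @param threshold correlation above which a query cluster is labeled a
#'   contaminant (default 0.5).
#' @param band width of the near-threshold review band below `threshold`;
#'   pairs with `threshold - band <= r < threshold` are flagged for review.
#' @param ratio_limit abundance-ratio veto: when the summed abundance of the
#'   query clusters matched to one reference cluster exceeds that reference
#'   cluster's abundance by more than this factor, the match is vetoed.
#' @param overrides named list mapping query cluster id (as character) to a
#'   forced verdict (`"contaminant"` or `"retained"`).
#' @export
match_config <- function(threshold = 0.5, band = 0.01, ratio_limit = 10,
                         overrides = list()) {
  stopifnot(threshold > 0, threshold < 1, band >= 0, ratio_limit > 0)
  structure(list(threshold = threshold, band = band, ratio_limit = ratio_limit,
                 overrides = overrides), class = "match_config")
}

#' Decide which query clusters are contaminants
#'
#' Applies the decision ladder to a [profile_correlation()] result: a query
#' cluster whose best reference correlation reaches the threshold is labeled
#' `contaminant`, unless the abundance veto fires; a best correlation just
#' under the threshold (within the review band) yields `needs_review`;
#' everything else is `retained`. The abundance veto compares each reference
#' cluster's abundance with the summed abundance of all query clusters whose
#' best match it is — a tiny reference state cannot absolve a large slab of
#' query cells. Manual overrides are applied last and recorded.
#'
#' @param match a `match_matrix` from [profile_correlation()].
#' @param config a [match_config()].
#' @return Tibble of decisions: `query_cluster`, `best_reference`, `best_r`,
#'   `verdict` (`contaminant` / `retained` / `needs_review`), `rules`
#'   (comma-joined triggered rules).
#' @export
assign_contaminants <- function(match, config = match_config()) {
  r <- match$r
  qinfo <- match$query$info
  rinfo <- match$reference$info
  best_j <- apply(r, 1, function(row) {
    if (all(is.na(row))) NA_integer_ else which.max(row)
  })
  best_r <- vapply(seq_len(nrow(r)), function(i) {
    if (is.na(best_j[i])) NA_real_ else r[i, best_j[i]]
  }, numeric(1))
  best_ref <- rinfo$cluster[best_j]
  # summed query abundance claimed by each reference cluster (threshold-free,
  # so raising the threshold can only shrink the contaminant set)
  claimed <- tapply(qinfo$abundance, factor(best_ref, levels = rinfo$cluster),
                    sum, default = 0)
  ref_abund <- setNames(rinfo$abundance, rinfo$cluster)
  decisions <- purrr::map(seq_len(nrow(r)), function(i) {
    rules <- character(0)
    if (is.na(best_r[i])) {
      verdict <- "retained"
      rules <- "undefined_correlation"
    } else if (best_r[i] >= config$threshold) {
      ratio <- claimed[as.character(best_ref[i])] / ref_abund[as.character(best_ref[i])]
      if (is.finite(ratio) && ratio > config$ratio_limit) {
        verdict <- "retained"
        rules <- "abundance_discrepancy"
      } else {
        verdict <- "contaminant"
      }
    } else if (best_r[i] >= config$threshold - config$band) {
      verdict <- "needs_review"
      rules <- "near_threshold"
    } else {
      verdict <- "retained"
    }
    ov <- config$overrides[[as.character(qinfo$cluster[i])]]
    if (!is.null(ov)) {
      verdict <- ov
      rules <- c(rules, "manual_override")
    }
    tibble::tibble(query_cluster = qinfo$cluster[i],
                   best_reference = best_ref[i],
                   best_r = best_r[i],
                   verdict = verdict,
                   rules = paste(rules, collapse = ","))
  })
  dplyr::bind_rows(decisions)
}
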