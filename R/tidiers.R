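#' Tidy a test result
#'
#' One row per test with the statistic, p-value and context fields.
#'
#' @param x an `ul_test`.
#' @param ... unused.
#' @return A one-row tibble.
#' @method tidy ul_test
#' @export
tidy.ul_test <- function(x, ...) {
  tibble::tibble(
    test = x$test,
    statistic = x$statistic,
    p = x$p,
    p_adj = x$p_adj %||% NA_real_,
    gate = x$gate %||% NA_character_,
    exact = x$exact %||% NA,
    n_perm = x$n_perm %||% NA_integer_)
}

#' @rdname tidy.ul_test
#' @method glance ul_test
#' @export
glance.ul_test <- function(x, ...) tidy.ul_test(x)

#' Tidy cluster labels
#'
#' @param x a `cluster_labels` object.
#' @param ... unused.
#' @return Tibble with `cell_id`, `cluster`, `resolution`, `parent`.
#' @method tidy cluster_labels
#' @export
tidy.cluster_labels <- function(x, ...) {
  tibble::tibble(cell_id = x$cell_id, cluster = x$cluster,
                 resolution = attr(x, "resolution"),
                 parent = attr(x, "parent"))
}

#' Tidy a cluster-profiles object
#'
#' @param x a `cluster_profiles` object.
#' @param ... unused.
#' @return Long tibble `cluster`, `gene`, `mean_log_expr` joined with
#'   abundances.
#' @method tidy cluster_profiles
#' @export
tidy.cluster_profiles <- function(x, ...) {
  long <- tibble::as_tibble(x$centroids, rownames = "cluster") |>
    tidyr::pivot_longer(-"cluster", names_to = "gene",
                        values_to = "mean_log_expr") |>
    dplyr::mutate(cluster = as.integer(.data$cluster))
  dplyr::left_join(long, x$info, by = "cluster")
}
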