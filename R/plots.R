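#' Heatmap of the query-reference match matrix
#'
#' Tile plot of centroid correlations with the decision threshold band
#' marked in the fill scale midpoint.
#'
#' @param match a `match_matrix` from [profile_correlation()].
#' @param threshold decision threshold drawn at the fill midpoint.
#' @return A ggplot object.
#' @export
plot_match_matrix <- function(match, threshold = 0.5) {
  df <- tidy.match_matrix(match)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$reference_cluster,
                                   y = .data$query_cluster, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)), size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white", high = "#B2182B",
                                  midpoint = threshold, limits = c(-1, 1)) +
    ggplot2::labs(x = "reference cluster", y = "query cluster",
                  fill = "Pearson r") +
    ggplot2::theme_minimal()
}

#' Threshold-calibration curve
#'
#' @param calibration result of [calibrate_threshold()].
#' @return A ggplot object: fraction of replicate clusters still
#'   cross-matched against the candidate threshold, with the chosen
#'   threshold marked.
#' @export
plot_calibration_curve <- function(calibration) {
  ggplot2::ggplot(calibration$curve,
                  ggplot2::aes(x = .data$threshold, y = .data$frac_matched)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(color = .data$all_cross_matched)) +
    ggplot2::geom_vline(xintercept = calibration$threshold, linetype = 2) +
    ggplot2::labs(x = "candidate threshold",
                  y = "fraction of replicate clusters matched",
                  color = "all matched") +
    ggplot2::theme_minimal()
}

#' Bar plot of the EdU+ count distribution
#'
#' @param dist result of [edu_count_distribution()].
#' @return A ggplot object of percent of animals per count bin, dodged by
#'   condition when present.
#' @export
plot_edu_distribution <- function(dist) {
  p <- ggplot2::ggplot(dist, ggplot2::aes(x = .data$bin, y = .data$percent))
  if ("condition" %in% names(dist)) {
    p <- p + ggplot2::geom_col(ggplot2::aes(fill = .data$condition),
                               position = "dodge")
  } else {
    p <- p + ggplot2::geom_col()
  }
  p + ggplot2::labs(x = "EdU+ cells per animal", y = "% of animals") +
    ggplot2::theme_minimal()
}

#' Histogram of frameshift-deletion offsets relative to the PAM
#'
#' @param offsets result of [deletion_offsets()].
#' @param locus the [locus_spec()] used (window drawn as dashed lines).
#' @return A ggplot object.
#' @export
plot_deletion_offsets <- function(offsets, locus = locus_spec()) {
  df <- tibble::tibble(offset = offsets$offsets)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$offset)) +
    ggplot2::geom_bar() +
    ggplot2::geom_vline(xintercept = c(-locus$window, locus$window), linetype = 2) +
    ggplot2::labs(x = "deletion start offset from PAM (bp)", y = "deletions") +
    ggplot2::theme_minimal()
}
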