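#' Expression matrix with a processing-stage tag
#'
#' A thin S3 wrapper around a cells-by-genes matrix (dense or sparse
#' [Matrix::Matrix]) that records which preprocessing stage produced it
#' (`"counts"`, `"normalized"`, `"log"`, `"residual"`, `"scaled"`) and the
#' parameters applied along the way. The tag lets downstream operations
#' assert that they receive data at the stage their definition expects
#' (e.g. cluster centroids are means of *log*-stage values, PCA runs on
#' *scaled* values).
#'
#' @param values cells-by-genes numeric matrix with cell ids as rownames and
#'   gene ids as colnames.
#' @param stage processing-stage tag.
#' @param params named list of parameters applied so far.
#' @return An `expr_matrix` object.
#' @export
expr_matrix <- function(values,
                        stage = c("counts", "normalized", "log", "residual", "scaled"),
                        params = list()) {
  stage <- match.arg(stage)
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must have cell ids as rownames and gene ids as colnames.")
  }
  if (anyDuplicated(rownames(values)) || anyDuplicated(colnames(values))) {
    abort("Duplicate cell or gene ids are not allowed.")
  }
  structure(list(values = values, stage = stage, params = params),
            class = "expr_matrix")
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' @export
dimnames.expr_matrix <- function(x) dimnames(x$values)

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d cells x %d genes, stage: %s\n",
              nrow(x$values), ncol(x$values), x$stage))
  if (length(x$params)) {
    cat("  params:", paste(names(x$params),
                           vapply(x$params, function(p) paste(format(p), collapse = ","), ""),
                           sep = "=", collapse = "; "), "\n")
  }
  invisible(x)
}

cell_ids <- function(x) rownames(if (inherits(x, "expr_matrix")) x$values else x)
gene_ids <- function(x) colnames(if (inherits(x, "expr_matrix")) x$values else x)

as_dense <- function(x) {
  v <- if (inherits(x, "expr_matrix")) x$values else x
  as.matrix(v)
}

assert_stage <- function(x, stages, op) {
  if (!inherits(x, "expr_matrix")) {
    abort(sprintf("`%s` expects an expr_matrix (see `expr_matrix()`).", op))
  }
  if (!x$stage %in% stages) {
    abort(sprintf("`%s` expects data at stage %s, got '%s'.",
                  op, paste(sQuote(stages), collapse = " or "), x$stage))
  }
  invisible(x)
}
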