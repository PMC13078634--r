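#' Configuration for the paired single-cell simulator
#'
#' Describes a query (heart-like) and reference (circulating-cell-like)
#' dataset pair sharing a subset of cell states. Each state has its own
#' negative-binomial mean profile over genes; states shared between
#' datasets reuse the same profile, so their cluster centroids correlate
#' strongly, while distinct states draw independent profiles and correlate
#' weakly. Contaminant states are shared states whose query cells represent
#' reference-type (blood) cells caught in the query tissue.
#'
#' @param n_states number of true cell states overall.
#' @param shared_states integer ids of states present in both datasets.
#' @param contaminant_states ids of query states that are reference-type
#'   contaminants; must be a subset of `shared_states`.
#' @param n_genes number of genes.
#' @param cells_per_state_query,cells_per_state_reference cells per state in
#'   each dataset: a single count or a vector named by state id, allowing
#'   rare states (e.g. an abundance fraction of 0.0017).
#' @param nb_mean optional states x genes matrix of negative-binomial means;
#'   by default drawn per state from a gamma distribution (so state profiles
#'   are independent).
#' @param nb_dispersion negative-binomial size parameter (must be > 0);
#'   smaller = more overdispersed.
#' @param n_replicates_reference biological replicates of the reference
#'   (>= 2); replicates differ only by sampling noise unless
#'   `batch_factor_sd > 0`, which applies a per-replicate multiplicative
#'   gene-wise batch factor exp(N(0, sd)).
#' @param batch_factor_sd log-normal SD of the optional replicate batch
#'   effect (default 0, no batch effect).
#' @param seed integer seed.
#' @export
sc_sim_config <- function(n_states = 6,
                          shared_states = 1:3,
                          contaminant_states = 1:3,
                          n_genes = 300,
                          cells_per_state_query = 80,
                          cells_per_state_reference = 100,
                          nb_mean = NULL,
                          nb_dispersion = 2,
                          n_replicates_reference = 2,
                          batch_factor_sd = 0,
                          seed = 1) {
  if (!all(contaminant_states %in% shared_states)) {
    abort("sc_sim_config: contaminant_states must be a subset of shared_states.")
  }
  if (!all(shared_states %in% seq_len(n_states))) {
    abort("sc_sim_config: shared_states out of range.")
  }
  if (nb_dispersion <= 0) abort("sc_sim_config: nb_dispersion must be > 0.")
  if (n_replicates_reference < 2) {
    abort("sc_sim_config: at least 2 reference replicates are required.")
  }
  structure(list(n_states = n_states, shared_states = shared_states,
                 contaminant_states = contaminant_states, n_genes = n_genes,
                 cells_per_state_query = cells_per_state_query,
                 cells_per_state_reference = cells_per_state_reference,
                 nb_mean = nb_mean, nb_dispersion = nb_dispersion,
                 n_replicates_reference = n_replicates_reference,
                 batch_factor_sd = batch_factor_sd, seed = seed),
            class = "sc_sim_config")
}

expand_cells_per_state <- function(x, states) {
  if (length(x) == 1) return(setNames(rep(as.integer(x), length(states)),
                                      as.character(states)))
  out <- x[as.character(states)]
  if (any(is.na(out))) abort("cells_per_state must cover every state (named vector).")
  setNames(as.integer(out), as.character(states))
}

nb_draw <- function(n_cells, mu_profile, size) {
  m <- matrix(rnbinom(n_cells * length(mu_profile),
                      mu = rep(mu_profile, each = n_cells), size = size),
              nrow = n_cells)
  m
}

#' Generate a paired query/reference single-cell dataset
#'
#' Draws raw counts per cell from the per-state negative-binomial model of a
#' [sc_sim_config()]. The query dataset holds all query states (including
#' the contaminant states); the reference holds the shared states only,
#' replicated `n_replicates_reference` times. The ground truth records every
#' cell's true state and which query cells are contaminants.
#'
#' @param config a [sc_sim_config()].
#' @return List with `query` (list: `counts` sparse cells x genes, `cells`
#'   tibble of `cell_id`, `state`), `reference` (same plus `replicate`), and
#'   `truth` (list: `query_states`, `contaminant_states`,
#'   `query_contaminant` logical vector, `nb_mean`).
#' @export
generate_sc_pair <- function(config = sc_sim_config()) {
  stopifnot(inherits(config, "sc_sim_config"))
  set.seed(stage_seed(config$seed, "sc_pair"))
  genes <- sprintf("g%04d", seq_len(config$n_genes))
  states <- seq_len(config$n_states)
  mu <- config$nb_mean
  if (is.null(mu)) {
    # independent gamma mean profiles per state: sparse-ish, overdispersed
    mu <- matrix(stats::rgamma(config$n_states * config$n_genes,
                               shape = 0.35, rate = 0.12),
                 nrow = config$n_states)
    mu[mu < 0.05] <- 0
  }
  if (any(dim(mu) != c(config$n_states, config$n_genes))) {
    abort("generate_sc_pair: nb_mean must be n_states x n_genes.")
  }
  rownames(mu) <- as.character(states)
  colnames(mu) <- genes

  draw_dataset <- function(states_here, cells_per_state, prefix, rep_id = NULL,
                           batch = NULL) {
    n_per <- expand_cells_per_state(cells_per_state, states_here)
    blocks <- lapply(states_here, function(s) {
      prof <- mu[as.character(s), ]
      if (!is.null(batch)) prof <- prof * batch
      nb_draw(n_per[as.character(s)], prof, config$nb_dispersion)
    })
    m <- do.call(rbind, blocks)
    state_vec <- rep(states_here, n_per[as.character(states_here)])
    ids <- sprintf("%s_c%05d", prefix, seq_len(nrow(m)))
    dimnames(m) <- list(ids, genes)
    cells <- tibble::tibble(cell_id = ids, state = state_vec)
    if (!is.null(rep_id)) cells$replicate <- rep_id
    list(counts = methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix"),
         cells = cells)
  }

  query <- draw_dataset(states, config$cells_per_state_query, "q")
  refs <- lapply(seq_len(config$n_replicates_reference), function(r) {
    batch <- if (config$batch_factor_sd > 0) {
      exp(rnorm(config$n_genes, 0, config$batch_factor_sd))
    } else NULL
    draw_dataset(config$shared_states, config$cells_per_state_reference,
                 sprintf("r%d", r), rep_id = r, batch = batch)
  })
  reference <- list(
    counts = do.call(rbind, lapply(refs, `[[`, "counts")),
    cells = dplyr::bind_rows(lapply(refs, `[[`, "cells"))
  )
  truth <- list(
    query_states = setNames(query$cells$state, query$cells$cell_id),
    contaminant_states = config$contaminant_states,
    query_contaminant = setNames(query$cells$state %in% config$contaminant_states,
                                 query$cells$cell_id),
    nb_mean = mu
  )
  list(query = query, reference = reference, truth = truth)
}
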