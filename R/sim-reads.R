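#' Configuration for the amplicon read-set simulator
#'
#' Emulates a table of unique amplicon reads from a CRISPR targeting assay:
#' a fraction of reads carries a prevalent naturally occurring IN/DEL; among
#' the remainder, Cas9-induced deletions occur at `edit_rate`, with start
#' offsets concentrated near the PAM (a discretized, truncated distribution
#' with a configurable mode, by default 3 bp upstream) and lengths mostly
#' producing frameshifts.
#'
#' @param n_reads number of unique reads.
#' @param natural_indel_prevalence fraction of reads carrying the natural
#'   IN/DEL.
#' @param edit_rate fraction of non-IN/DEL reads carrying a Cas9 edit.
#' @param pam_position PAM coordinate within the amplicon.
#' @param amplicon_length amplicon length (bp); `pam_position` must lie
#'   inside.
#' @param offset_mode modal deletion start offset relative to the PAM
#'   (negative = upstream).
#' @param offset_window deletions fall within +/- this many bp of the PAM.
#' @param max_multiplicity read multiplicities are drawn uniformly from
#'   1..this.
#' @param seed integer seed.
#' @export
read_set_config <- function(n_reads = 1500,
                            natural_indel_prevalence = 0.67,
                            edit_rate = 0.17,
                            pam_position = 150,
                            amplicon_length = 400,
                            offset_mode = -3,
                            offset_window = 60,
                            max_multiplicity = 5,
                            seed = 1) {
  if (natural_indel_prevalence < 0 || natural_indel_prevalence > 1 ||
      edit_rate < 0 || edit_rate > 1) {
    abort("read_set_config: fractions must be in [0, 1].")
  }
  if (pam_position < 1 || pam_position > amplicon_length) {
    abort("read_set_config: pam_position lies outside the amplicon.")
  }
  if (abs(offset_mode) > offset_window) {
    abort("read_set_config: offset_mode must be inside the offset window.")
  }
  structure(list(n_reads = n_reads,
                 natural_indel_prevalence = natural_indel_prevalence,
                 edit_rate = edit_rate, pam_position = pam_position,
                 amplicon_length = amplicon_length, offset_mode = offset_mode,
                 offset_window = offset_window,
                 max_multiplicity = max_multiplicity, seed = seed),
            class = "read_set_config")
}

#' Generate a synthetic unique-read table with edits
#'
#' @param config a [read_set_config()].
#' @return List with `reads` (tibble `read_id`, `count`, `natural_indel`),
#'   `edits` (tibble `read_id`, `type`, `offset`, `length`, `frameshift`;
#'   one deletion per edited read), and `truth` (the configured rates).
#' @export
generate_read_set <- function(config = read_set_config()) {
  stopifnot(inherits(config, "read_set_config"))
  set.seed(stage_seed(config$seed, "reads"))
  n <- config$n_reads
  reads <- tibble::tibble(
    read_id = sprintf("read%05d", seq_len(n)),
    count = sample.int(config$max_multiplicity, n, replace = TRUE),
    natural_indel = runif(n) < config$natural_indel_prevalence)
  edited <- !reads$natural_indel & runif(n) < config$edit_rate
  n_ed <- sum(edited)
  edits <- if (n_ed > 0) {
    # discretized double-geometric around the mode, truncated to the window
    support <- seq(-config$offset_window, config$offset_window)
    wts <- 0.65^abs(support - config$offset_mode)
    offs <- sample(support, n_ed, replace = TRUE, prob = wts)
    lens <- sample(c(1L, 2L, 4L, 5L, 7L, 3L, 6L), n_ed, replace = TRUE,
                   prob = c(0.25, 0.2, 0.15, 0.15, 0.1, 0.1, 0.05))
    tibble::tibble(read_id = reads$read_id[edited],
                   type = "deletion",
                   offset = as.integer(offs),
                   length = lens,
                   frameshift = lens %% 3 != 0)
  } else {
    tibble::tibble(read_id = character(0), type = character(0),
                   offset = integer(0), length = integer(0),
                   frameshift = logical(0))
  }
  list(reads = reads, edits = edits,
       truth = list(natural_indel_prevalence = config$natural_indel_prevalence,
                    edit_rate = config$edit_rate,
                    offset_mode = config$offset_mode,
                    offset_window = config$offset_window))
}
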