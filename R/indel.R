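#' Locus specification for amplicon indel analysis
#'
#' @param sgrna_id identifier of the guide.
#' @param pam_position PAM coordinate within the amplicon (bp); edit offsets
#'   are signed distances from the PAM-proximal base (negative = upstream).
#' @param window half-width (bp) of the "at the target locus" window around
#'   the PAM.
#' @export
locus_spec <- function(sgrna_id = "sgRNA", pam_position = 0, window = 60) {
  stopifnot(window > 0)
  structure(list(sgrna_id = sgrna_id, pam_position = pam_position,
                 window = window), class = "locus_spec")
}

weight_of <- function(reads, weighting) {
  if (weighting == "multiplicity") reads$count else rep(1, nrow(reads))
}

#' Partition unique reads by a prevalent natural IN/DEL
#'
#' Splits a unique-read table by the presence of a naturally occurring
#' insertion/deletion variant near the target locus (a population
#' polymorphism that must be separated from Cas9-induced edits). Reads are
#' classified either by a pre-annotated `natural_indel` logical column or by
#' matching an explicit signature (type + offset + length) against the edit
#' table. Prevalence is the multiplicity-weighted fraction of reads carrying
#' the variant (set `weighting = "unique"` to count each unique read once).
#'
#' @param reads tibble with `read_id`, `count`, and (unless a signature is
#'   given) logical `natural_indel`.
#' @param edits optional edit table (`read_id`, `type`, `offset`, `length`,
#'   `frameshift`) used when classifying by `signature`.
#' @param signature optional list(type, offset, length) identifying the
#'   natural IN/DEL in `edits`.
#' @param weighting `"multiplicity"` (default) or `"unique"`.
#' @return List with `with`, `without` (read tibbles) and `prevalence`.
#' @export
classify_natural_indel <- function(reads, edits = NULL, signature = NULL,
                                   weighting = c("multiplicity", "unique")) {
  weighting <- match.arg(weighting)
  if (!is.null(signature)) {
    if (is.null(edits)) abort("classify_natural_indel: `signature` needs an `edits` table.")
    hit_ids <- edits$read_id[edits$type == signature$type &
                               edits$offset == signature$offset &
                               edits$length == signature$length]
    flag <- reads$read_id %in% hit_ids
  } else if ("natural_indel" %in% names(reads)) {
    flag <- reads$natural_indel
  } else {
    abort("classify_natural_indel: no `natural_indel` column and no signature rule given.")
  }
  w <- weight_of(reads, weighting)
  list(with = reads[flag, , drop = FALSE],
       without = reads[!flag, , drop = FALSE],
       prevalence = sum(w[flag]) / sum(w))
}

#' Mutagenesis incidence among reads without the natural IN/DEL
#'
#' Fraction of reads (multiplicity-weighted by default) carrying at least
#' one edit whose start offset lies within the locus window around the PAM
#' (|offset| <= window). Edits strictly outside the window do not count.
#'
#' @param reads read tibble (typically the `without` partition of
#'   [classify_natural_indel()]).
#' @param edits edit table with `read_id`, `offset`.
#' @param locus a [locus_spec()].
#' @param weighting `"multiplicity"` or `"unique"`.
#' @return Fraction in \[0, 1\].
#' @export
mutagenesis_incidence <- function(reads, edits, locus = locus_spec(),
                                  weighting = c("multiplicity", "unique")) {
  weighting <- match.arg(weighting)
  if (nrow(reads) == 0) abort("mutagenesis_incidence: empty read set.")
  in_window <- edits[abs(edits$offset) <= locus$window, , drop = FALSE]
  edited <- reads$read_id %in% in_window$read_id
  w <- weight_of(reads, weighting)
  sum(w[edited]) / sum(w)
}

#' Frameshift-deletion offsets relative to the PAM
#'
#' Collects the start offsets of deletions that can cause a frameshift
#' (length not divisible by 3) and summarises their position relative to
#' the PAM: modal offset, maximum absolute offset, and whether all fall
#' within the locus window.
#'
#' @param edits edit table (`read_id`, `type`, `offset`, `length`,
#'   `frameshift`).
#' @param locus a [locus_spec()].
#' @param frameshift_only keep only frameshift deletions (default TRUE).
#' @return List with `offsets` (integer vector, possibly empty) and
#'   `summary` tibble (`n`, `mode_offset`, `max_abs_offset`,
#'   `all_within_window`).
#' @export
deletion_offsets <- function(edits, locus = locus_spec(), frameshift_only = TRUE) {
  del <- edits[edits$type == "deletion", , drop = FALSE]
  if (frameshift_only && nrow(del)) del <- del[del$length %% 3 != 0, , drop = FALSE]
  offs <- del$offset
  if (length(offs) == 0) {
    return(list(offsets = integer(0),
                summary = tibble::tibble(n = 0L, mode_offset = NA_integer_,
                                         max_abs_offset = NA_integer_,
                                         all_within_window = TRUE)))
  }
  tab <- sort(table(offs), decreasing = TRUE)
  list(offsets = as.integer(offs),
       summary = tibble::tibble(
         n = length(offs),
         mode_offset = as.integer(names(tab)[1]),
         max_abs_offset = max(abs(offs)),
         all_within_window = all(abs(offs) <= locus$window)))
}
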