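# Coverage scores: covered nucleotides per kilo-nucleotide of coding
# sequence, for single exons and exon sets. Only the coding part of an exon
# ever enters the numerator or denominator, and overlapping hits of one term
# are unioned before measuring, so a score always lies in [0, 1000].

#' Coverage score of one term on one exon
#'
#' `score = 1000 * covered_nt / coding_len`, where `covered_nt` is the union
#' length of the term's hit intervals within the exon's coding part.
#'
#' @param store An `exont_store`.
#' @param exon A one-row data frame from `models$exons` (needs `exon_id`
#'   and `coding_len`).
#' @param term_id Term id.
#' @return Numeric score in `[0, 1000]`.
#' @export
exon_score <- function(store, exon, term_id) {
  stopifnot(inherits(store, "exont_store"), nrow(exon) == 1L)
  if (exon$coding_len < 1L) stop("exon ", exon$exon_id, " has no coding part")
  cv <- store$coverage
  i <- which(cv$exon_id == exon$exon_id & cv$term_id == term_id)
  covered <- if (length(i)) cv$covered_nt[i] else 0L
  1000 * covered / exon$coding_len
}

#' Coverage score of one term on an exon set
#'
#' `score = 1000 * sum(covered_nt) / sum(coding_len)` over the member
#' exons, i.e. the coding-length-weighted mean of per-exon scores.
#'
#' @param store An `exont_store`.
#' @param exons Data frame of exon records (needs `exon_id`, `coding_len`);
#'   duplicate exon ids are an error.
#' @param term_id Term id.
#' @return Numeric score in `[0, 1000]`.
#' @export
set_score <- function(store, exons, term_id) {
  stopifnot(inherits(store, "exont_store"))
  if (!nrow(exons)) stop("empty exon set")
  if (anyDuplicated(exons$exon_id)) stop("duplicate exon ids in set")
  total <- sum(exons$coding_len)
  if (total < 1L) stop("exon set has no coding sequence")
  cv <- store$coverage
  sel <- cv$term_id == term_id & cv$exon_id %in% exons$exon_id
  1000 * sum(cv$covered_nt[sel]) / total
}

#' Score table over all terms for an exon set
#'
#' @inheritParams set_score
#' @param terms Terms to report; defaults to every term in the store.
#' @return Data frame (`term_id`, `covered_nt`, `total_nt`, `score`).
#' @export
score_table <- function(store, exons, terms = NULL) {
  stopifnot(inherits(store, "exont_store"))
  if (!nrow(exons)) stop("empty exon set")
  if (anyDuplicated(exons$exon_id)) stop("duplicate exon ids in set")
  if (is.null(terms)) terms <- store$terms
  total <- sum(exons$coding_len)
  cv <- store$coverage[store$coverage$exon_id %in% exons$exon_id, ,
                       drop = FALSE]
  covered <- tapply(cv$covered_nt, factor(cv$term_id, levels = terms), sum,
                    default = 0L)
  data.frame(
    term_id = terms,
    covered_nt = as.integer(covered),
    total_nt = total,
    score = 1000 * as.numeric(covered) / total,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
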