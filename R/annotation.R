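# Projection of protein-coordinate features onto genomic exons, regex
# scanning of localization motifs, and the (exon, term) -> interval store.

#' Map an amino-acid interval to genomic coordinates
#'
#' Amino acid `i` of a protein occupies coding nucleotides `3(i-1)+1 .. 3i`
#' of its transcript's CDS; these are mapped through the ordered CDS
#' segments, respecting strand, and the result is split at CDS-segment
#' boundaries. The total mapped length is always `3 * (aa_end - aa_start + 1)`
#' nucleotides.
#'
#' @param transcript A transcript model (an element of
#'   `exont_models$transcripts`).
#' @param aa_start,aa_end 1-based inclusive amino-acid coordinates.
#' @return Data frame (`chrom`, `start`, `end`, `strand`) of genomic
#'   intervals in coding (5'->3') order.
#' @export
map_feature_to_genome <- function(transcript, aa_start, aa_end) {
  if (is.null(transcript$cds) || !nrow(transcript$cds)) {
    stop("transcript ", transcript$transcript_id, " has no CDS")
  }
  stopifnot(aa_start >= 1L, aa_end >= aa_start)
  cds <- transcript$cds                      # already in coding order
  w <- cds$end - cds$start + 1L
  total <- sum(w)
  if (3L * aa_end > total) {
    stop("amino acids ", aa_start, "-", aa_end, " exceed the CDS of ",
         transcript$transcript_id, " (", total %/% 3L, " codons)")
  }
  nt <- (3L * (aa_start - 1L) + 1L):(3L * aa_end)   # coding-nt positions
  cum <- cumsum(w)
  seg <- findInterval(nt - 1L, cum) + 1L
  off <- nt - c(0L, cum)[seg]                        # 1-based within segment
  g <- if (transcript$strand == "+") {
    cds$start[seg] + off - 1L
  } else {
    cds$end[seg] - off + 1L
  }
  runs <- unique(seg)
  data.frame(
    chrom = transcript$chrom,
    start = vapply(runs, function(s) min(g[seg == s]), integer(1)),
    end = vapply(runs, function(s) max(g[seg == s]), integer(1)),
    strand = transcript$strand,
    stringsAsFactors = FALSE
  )
}

#' Intersect genomic intervals with the coding parts of overlapping exons
#'
#' Each interval is clipped to the coding sub-interval of every model exon
#' it overlaps (a feature partially overlapping an exon contributes only the
#' overlapping region). Intervals overlapping no coding exon are dropped
#' with a message.
#'
#' @param intervals Data frame (`chrom`, `start`, `end`, `strand`) as
#'   returned by [map_feature_to_genome()].
#' @param models An `exont_models` object.
#' @param term_id Term id recorded on the resulting hits.
#' @return Data frame (`exon_id`, `term_id`, `start`, `end`); one row per
#'   (interval, overlapped exon) clip.
#' @export
project_to_exons <- function(intervals, models, term_id = NA_character_) {
  stopifnot(inherits(models, "exont_models"))
  ex <- models$exons
  rows <- vector("list", nrow(intervals))
  dropped <- 0L
  for (k in seq_len(nrow(intervals))) {
    cand <- which(ex$chrom == intervals$chrom[k] &
                    ex$strand == intervals$strand[k] &
                    ex$coding_start <= intervals$end[k] &
                    ex$coding_end >= intervals$start[k])
    if (!length(cand)) {
      dropped <- dropped + 1L
      next
    }
    rows[[k]] <- data.frame(
      exon_id = ex$exon_id[cand],
      term_id = term_id,
      start = pmax(ex$coding_start[cand], intervals$start[k]),
      end = pmin(ex$coding_end[cand], intervals$end[k]),
      stringsAsFactors = FALSE
    )
  }
  if (dropped) {
    message("project_to_exons: ", dropped,
            " interval(s) overlapped no coding exon and were dropped")
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(exon_id = character(0), term_id = character(0),
                      start = integer(0), end = integer(0))
  }
  out
}

#' Scan protein sequences for localization motifs
#'
#' Applies each configured regular expression to each protein and emits one
#' feature per leftmost non-overlapping match (the semantics of a global
#' regex scan; anchors may be used for terminal signals such as PTS1). Scan
#' order is deterministic: proteins in input order, patterns in config
#' order, matches left to right.
#'
#' @param proteins Named character vector of protein sequences, an
#'   `AAStringSet`, or a path to a protein FASTA file. Names must be
#'   transcript ids.
#' @param patterns Data frame (`term_id`, `regex`) or path to a two-column
#'   TSV. Invalid regular expressions are a configuration error.
#' @return Data frame of features (`transcript_id`, `term_id`, `aa_start`,
#'   `aa_end`, `evidence = "motif_scan"`).
#' @export
scan_localization_motifs <- function(proteins, patterns) {
  if (is.character(proteins) && length(proteins) == 1L &&
      file.exists(proteins) && is.null(names(proteins))) {
    proteins <- Biostrings::readAAStringSet(proteins)
  }
  if (methods::is(proteins, "AAStringSet")) {
    proteins <- stats::setNames(as.character(proteins),
                                sub("\\s.*$", "", names(proteins)))
  }
  if (is.character(patterns) && length(patterns) == 1L) {
    patterns <- read_motif_config(patterns)
  }
  for (i in seq_len(nrow(patterns))) {
    ok <- tryCatch({
      suppressWarnings(grepl(patterns$regex[i], "", perl = TRUE))
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) {
      stop("invalid regular expression for term ", patterns$term_id[i],
           ": ", patterns$regex[i])
    }
  }
  rows <- list()
  for (pid in names(proteins)) {
    seq <- proteins[[pid]]
    for (i in seq_len(nrow(patterns))) {
      m <- gregexpr(patterns$regex[i], seq, perl = TRUE)[[1L]]
      if (m[1L] == -1L) next
      len <- attr(m, "match.length")
      rows[[length(rows) + 1L]] <- data.frame(
        transcript_id = pid,
        term_id = patterns$term_id[i],
        aa_start = as.integer(m),
        aa_end = as.integer(m) + len - 1L,
        evidence = "motif_scan",
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(transcript_id = character(0), term_id = character(0),
                      aa_start = integer(0), aa_end = integer(0),
                      evidence = character(0))
  }
  rownames(out) <- NULL
  out
}

#' Read a localization-motif configuration
#'
#' @param path Two-column TSV (`term_id <TAB> regex`, `#` comments allowed).
#'   The default set shipped with the package
#'   (`system.file("extdata", "motifs.tsv", package = "exont")`) covers a
#'   monopartite NLS, a bipartite NLS, a CRM1-type NES, and the C-terminal
#'   PTS1 peroxisomal signal; patterns are data and freely editable.
#' @return Data frame (`term_id`, `regex`).
#' @export
read_motif_config <- function(path) {
  utils::read.table(path, sep = "\t", header = FALSE, comment.char = "#",
                    quote = "", stringsAsFactors = FALSE,
                    col.names = c("term_id", "regex"))
}

#' Build the exon/term annotation store
#'
#' Projects every protein feature through its transcript onto the coding
#' parts of overlapping exons and merges the resulting intervals per
#' (exon, term): a nucleotide covered by two features of the same term
#' counts once. With `propagate = TRUE` every hit is also recorded for all
#' ancestor terms, so parent coverage is the interval union over the
#' subtree.
#'
#' @param features Data frame (`transcript_id`, `term_id`, `aa_start`,
#'   `aa_end`, optional `evidence`) or path to such a TSV (with header).
#' @param models An `exont_models` object.
#' @param tree An `exont_ontology`, required when `propagate = TRUE`; when
#'   supplied, features with unknown terms are skipped with a warning.
#' @param propagate Record hits for ancestor terms as well (default `TRUE`,
#'   the setting used for enrichment; per-exon annotation reports are
#'   clearer with `FALSE`).
#' @return An `exont_store` object: list with `hits` (data frame of
#'   disjoint, normalized intervals per exon and term), `coverage`
#'   (data frame `exon_id`, `term_id`, `covered_nt`), `terms` and
#'   `propagated`.
#' @export
annotate_exons <- function(features, models, tree = NULL, propagate = TRUE) {
  stopifnot(inherits(models, "exont_models"))
  if (is.character(features) && length(features) == 1L) {
    features <- utils::read.table(features, sep = "\t", header = TRUE,
                                  comment.char = "#", quote = "",
                                  stringsAsFactors = FALSE)
  }
  if (propagate && is.null(tree)) {
    stop("propagate = TRUE requires an ontology")
  }
  if (!is.null(tree)) {
    bad <- !features$term_id %in% tree$terms$term_id
    if (any(bad)) {
      warning("skipped ", sum(bad),
              " feature(s) with unknown term id(s): ",
              paste(unique(features$term_id[bad]), collapse = ", "))
      features <- features[!bad, , drop = FALSE]
    }
  }
  bad <- !features$transcript_id %in% names(models$transcripts)
  if (any(bad)) {
    warning("skipped ", sum(bad),
            " feature(s) with unknown transcript id(s): ",
            paste(unique(features$transcript_id[bad]), collapse = ", "))
    features <- features[!bad, , drop = FALSE]
  }

  # Bulk path: enumerate every coding nucleotide of every feature through
  # its transcript's CDS, then overlap all positions against exon coding
  # intervals at once. Equivalent to mapping and projecting feature by
  # feature (map_feature_to_genome / project_to_exons), which tests verify.
  g_all <- integer(0); fidx_all <- integer(0)
  for (tid in unique(features$transcript_id)) {
    tx <- models$transcripts[[tid]]
    rows <- which(features$transcript_id == tid)
    if (is.null(tx$cds) || !nrow(tx$cds)) {
      stop("transcript ", tid, " has no CDS")
    }
    w <- tx$cds$end - tx$cds$start + 1L
    cum <- cumsum(w)
    over <- 3L * features$aa_end[rows] > sum(w)
    if (any(over)) {
      stop("feature(s) exceed the CDS of transcript ", tid, " (",
           sum(w) %/% 3L, " codons): aa_end ",
           paste(features$aa_end[rows][over], collapse = ", "))
    }
    s3 <- 3L * (features$aa_start[rows] - 1L) + 1L
    lens <- 3L * features$aa_end[rows] - s3 + 1L
    nt <- sequence(lens, from = s3)
    seg <- findInterval(nt - 1L, cum) + 1L
    off <- nt - c(0L, cum)[seg]
    g <- if (tx$strand == "+") tx$cds$start[seg] + off - 1L
         else tx$cds$end[seg] - off + 1L
    g_all <- c(g_all, g)
    fidx_all <- c(fidx_all, rep(rows, lens))
  }
  ex <- models$exons
  tx_meta <- models$transcripts[features$transcript_id]
  f_chrom <- vapply(tx_meta, `[[`, character(1), "chrom")
  f_strand <- vapply(tx_meta, `[[`, character(1), "strand")
  hit_rows <- list()
  for (grp in unique(paste(f_chrom, f_strand))) {
    sel <- which(paste(f_chrom[fidx_all], f_strand[fidx_all]) == grp)
    if (!length(sel)) next
    esel <- which(paste(ex$chrom, ex$strand) == grp)
    if (!length(esel)) next
    ov <- IRanges::findOverlaps(
      IRanges::IRanges(g_all[sel], g_all[sel]),
      IRanges::IRanges(ex$coding_start[esel], ex$coding_end[esel]))
    if (!length(ov)) next
    hit_rows[[grp]] <- data.frame(
      exon_id = ex$exon_id[esel[S4Vectors::subjectHits(ov)]],
      term_id = features$term_id[fidx_all[sel[S4Vectors::queryHits(ov)]]],
      start = g_all[sel[S4Vectors::queryHits(ov)]],
      end = g_all[sel[S4Vectors::queryHits(ov)]],
      stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, hit_rows)
  annotation_store(hits, tree = tree, propagate = propagate)
}

#' Construct an annotation store from raw hit intervals
#'
#' Lower-level constructor used by [annotate_exons()] and available for
#' building stores directly (e.g. from a saved annotation dump). Intervals
#' are assumed to lie within their exon's coding part; per (exon, term) they
#' are merged into disjoint runs.
#'
#' @param hits Data frame (`exon_id`, `term_id`, `start`, `end`) or `NULL`.
#' @inheritParams annotate_exons
#' @return An `exont_store` object.
#' @export
annotation_store <- function(hits, tree = NULL, propagate = FALSE) {
  if (is.null(hits) || !nrow(hits)) {
    hits <- data.frame(exon_id = character(0), term_id = character(0),
                       start = integer(0), end = integer(0))
  }
  if (propagate) {
    if (is.null(tree)) stop("propagate = TRUE requires an ontology")
    anc <- lapply(stats::setNames(nm = unique(hits$term_id)),
                  function(t) c(t, ancestors(tree, t)))
    reps <- lengths(anc)[hits$term_id]
    hits <- data.frame(
      exon_id = rep(hits$exon_id, reps),
      term_id = unlist(anc[hits$term_id], use.names = FALSE),
      start = rep(hits$start, reps),
      end = rep(hits$end, reps),
      stringsAsFactors = FALSE
    )
  }
  if (nrow(hits)) {
    key <- paste(hits$exon_id, hits$term_id, sep = "\r")
    ir <- IRanges::IRanges(hits$start, hits$end)
    red <- IRanges::reduce(S4Vectors::split(ir, factor(key, unique(key))))
    n <- S4Vectors::elementNROWS(red)
    ks <- strsplit(rep(names(red), n), "\r", fixed = TRUE)
    flat <- unlist(red, use.names = FALSE)
    hits <- data.frame(
      exon_id = vapply(ks, `[`, character(1), 1L),
      term_id = vapply(ks, `[`, character(1), 2L),
      start = IRanges::start(flat),
      end = IRanges::end(flat),
      stringsAsFactors = FALSE
    )
    cov_nt <- sum(IRanges::width(red))   # per-element sums over the List
    kc <- strsplit(names(red), "\r", fixed = TRUE)
    coverage <- data.frame(
      exon_id = vapply(kc, `[`, character(1), 1L),
      term_id = vapply(kc, `[`, character(1), 2L),
      covered_nt = as.integer(cov_nt),
      stringsAsFactors = FALSE
    )
  } else {
    coverage <- data.frame(exon_id = character(0), term_id = character(0),
                           covered_nt = integer(0))
  }
  ord <- order(hits$exon_id, hits$term_id, hits$start)
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  ord <- order(coverage$exon_id, coverage$term_id)
  coverage <- coverage[ord, , drop = FALSE]
  rownames(coverage) <- NULL
  structure(list(hits = hits, coverage = coverage,
                 terms = sort(unique(coverage$term_id)),
                 propagated = propagate),
            class = "exont_store")
}

#' Fraction of a universe's exons annotated with each term
#'
#' @param store An `exont_store`.
#' @param universe Data frame of exons (needs `exon_id`) or a character
#'   vector of exon ids; the denominator of every fraction.
#' @param terms Terms to report; defaults to all terms in the store. Terms
#'   with no hit in the universe get frequency 0.
#' @return Named numeric vector of fractions in `[0, 1]`.
#' @export
term_frequency <- function(store, universe, terms = NULL) {
  stopifnot(inherits(store, "exont_store"))
  uid <- if (is.data.frame(universe)) universe$exon_id else universe
  if (!length(uid)) stop("empty universe")
  if (is.null(terms)) terms <- store$terms
  cv <- store$coverage[store$coverage$exon_id %in% uid &
                         store$coverage$term_id %in% terms, , drop = FALSE]
  counts <- table(factor(cv$term_id, levels = terms))
  stats::setNames(as.numeric(counts) / length(uid), terms)
}

#' @export
print.exont_store <- function(x, ...) {
  cat("exont_store:", length(unique(x$coverage$exon_id)), "exons,",
      length(x$terms), "terms,", nrow(x$hits), "merged intervals",
      if (x$propagated) "(ancestor-propagated)" else "(primary terms only)",
      "\n")
  invisible(x)
}
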