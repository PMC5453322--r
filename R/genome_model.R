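# Gene models: coding exons, their coding sub-intervals, and the exon
# categories used as control pools (first / internal / last coding exon;
# constitutive / alternative).
#
# Coordinates are 1-based inclusive throughout the package (the GFF3 and
# IRanges convention); BED input/output is converted at the boundary.

#' Read gene models from GFF3
#'
#' Parses gene / mRNA / exon / CDS records (via `rtracklayer`) into
#' transcript models and the universe of coding exons. An exon belongs to
#' the coding universe if it overlaps a CDS segment of any transcript of its
#' gene; its coding sub-interval is the span of those intersections. Exon
#' identity within a gene is the exact `(chrom, start, end, strand)` tuple,
#' shared across transcripts.
#'
#' @param path Path to a GFF3 file with `Parent` attributes linking
#'   CDS/exon -> mRNA -> gene.
#' @return An `exont_models` object: list with `genes` (data frame),
#'   `transcripts` (named list; each has `transcript_id`, `gene_id`,
#'   `chrom`, `strand`, `cds` ordered 5'->3' in coding order, `exons`,
#'   `cds_len`) and `exons` (data frame of coding exons with columns
#'   `exon_id`, `gene_id`, `chrom`, `strand`, `start`, `end`,
#'   `coding_start`, `coding_end`, `coding_len`, `position_category`,
#'   `splice_class`; the last two are filled by [categorize_exons()]).
#' @details Records whose `Parent` is missing are skipped with a warning; a
#'   CDS segment not contained in any exon of its transcript is a hard
#'   error. A transcript CDS length not divisible by 3 raises a warning
#'   only, since real annotations (e.g. partial models) violate it.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  typ <- as.character(gr$type)
  get_parent <- function(g) {
    p <- g$Parent
    vapply(seq_along(g), function(i) {
      pi <- p[[i]]
      if (length(pi)) as.character(pi[1L]) else NA_character_
    }, character(1))
  }
  feat_tbl <- function(g, what) {
    par <- get_parent(g)
    drop <- is.na(par)
    if (any(drop)) {
      warning(sum(drop), " ", what, " record(s) without Parent skipped")
      g <- g[!drop]
      par <- par[!drop]
    }
    data.frame(
      parent = par,
      chrom = as.character(GenomicRanges::seqnames(g)),
      start = GenomicRanges::start(g),
      end = GenomicRanges::end(g),
      strand = as.character(GenomicRanges::strand(g)),
      stringsAsFactors = FALSE
    )
  }
  tx_gr <- gr[typ %in% c("mRNA", "transcript")]
  tx_tbl <- data.frame(
    transcript_id = as.character(tx_gr$ID),
    gene_id = get_parent(tx_gr),
    stringsAsFactors = FALSE
  )
  no_gene <- is.na(tx_tbl$gene_id)
  if (any(no_gene)) {
    warning(sum(no_gene), " transcript(s) without Parent gene skipped")
    tx_tbl <- tx_tbl[!no_gene, , drop = FALSE]
  }
  assemble_models(tx_tbl,
                  feat_tbl(gr[typ == "exon"], "exon"),
                  feat_tbl(gr[typ == "CDS"], "CDS"))
}

# Build an exont_models object from parsed feature tables. Shared by the
# GFF3 reader and the synthetic generator so both paths produce identical
# structures.
assemble_models <- function(tx_tbl, exon_tbl, cds_tbl) {
  transcripts <- vector("list", nrow(tx_tbl))
  names(transcripts) <- tx_tbl$transcript_id
  for (i in seq_len(nrow(tx_tbl))) {
    tid <- tx_tbl$transcript_id[i]
    ex <- exon_tbl[exon_tbl$parent == tid, , drop = FALSE]
    cd <- cds_tbl[cds_tbl$parent == tid, , drop = FALSE]
    if (!nrow(ex)) next
    strand <- ex$strand[1L]
    chrom <- ex$chrom[1L]
    ex <- ex[order(ex$start), , drop = FALSE]
    cd <- cd[order(cd$start), , drop = FALSE]
    if (nrow(cd)) {
      inside <- vapply(seq_len(nrow(cd)), function(k) {
        any(cd$start[k] >= ex$start & cd$end[k] <= ex$end)
      }, logical(1))
      if (!all(inside)) {
        stop("CDS segment(s) outside parent exon in transcript ", tid, ": ",
             paste(sprintf("%d-%d", cd$start[!inside], cd$end[!inside]),
                   collapse = ", "))
      }
      cds_len <- sum(cd$end - cd$start + 1L)
      if (cds_len %% 3L != 0L) {
        warning("CDS length of transcript ", tid, " (", cds_len,
                ") is not divisible by 3")
      }
      if (strand == "-") cd <- cd[rev(seq_len(nrow(cd))), , drop = FALSE]
    } else {
      cds_len <- 0L
    }
    transcripts[[tid]] <- list(
      transcript_id = tid, gene_id = tx_tbl$gene_id[i],
      chrom = chrom, strand = strand,
      exons = data.frame(start = ex$start, end = ex$end),
      cds = data.frame(start = cd$start, end = cd$end),
      cds_len = cds_len
    )
  }
  transcripts <- Filter(Negate(is.null), transcripts)

  gene_ids <- unique(vapply(transcripts, `[[`, character(1), "gene_id"))
  exon_rows <- vector("list", length(gene_ids))
  for (gi in seq_along(gene_ids)) {
    gid <- gene_ids[gi]
    txs <- Filter(function(t) t$gene_id == gid, transcripts)
    ex_all <- unique(do.call(rbind, lapply(txs, function(t) {
      cbind(t$exons, chrom = t$chrom, strand = t$strand)
    })))
    cds_all <- do.call(rbind, lapply(txs, `[[`, "cds"))
    if (is.null(cds_all) || !nrow(cds_all)) next
    cs <- ce <- integer(nrow(ex_all))
    keep <- logical(nrow(ex_all))
    for (k in seq_len(nrow(ex_all))) {
      os <- pmax(cds_all$start, ex_all$start[k])
      oe <- pmin(cds_all$end, ex_all$end[k])
      hit <- os <= oe
      if (any(hit)) {
        keep[k] <- TRUE
        cs[k] <- min(os[hit])
        ce[k] <- max(oe[hit])
      }
    }
    ex <- ex_all[keep, , drop = FALSE]
    if (!nrow(ex)) next
    exon_rows[[gi]] <- data.frame(
      exon_id = sprintf("%s:%s:%d-%d:%s", gid, ex$chrom, ex$start, ex$end,
                        ex$strand),
      gene_id = gid, chrom = ex$chrom, strand = ex$strand,
      start = ex$start, end = ex$end,
      coding_start = cs[keep], coding_end = ce[keep],
      coding_len = ce[keep] - cs[keep] + 1L,
      position_category = NA_character_,
      splice_class = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  exons <- do.call(rbind, exon_rows)
  exons <- exons[order(exons$chrom, exons$start, exons$end, exons$gene_id), ,
                 drop = FALSE]
  rownames(exons) <- NULL
  genes <- unique(exons[, c("gene_id", "chrom", "strand")])
  rownames(genes) <- NULL
  structure(list(genes = genes, transcripts = transcripts, exons = exons),
            class = "exont_models")
}

#' Assign position categories and splice classes to coding exons
#'
#' Position categories (`first_coding`, `internal_coding`, `last_coding`)
#' are computed per gene on the union of its coding exons in transcription
#' order (strand-aware: the first coding exon of a minus-strand gene is the
#' rightmost). An exon is `constitutive` when its exact genomic coordinates
#' occur in every transcript of its gene, `alternative` otherwise. The
#' single exon of a one-coding-exon gene is both first and last; it is
#' recorded as `first_coding` and reported, so it never enters internal
#' pools.
#'
#' @param models An `exont_models` object.
#' @return The `exont_models` object with `position_category` and
#'   `splice_class` filled in `models$exons`.
#' @export
categorize_exons <- function(models) {
  stopifnot(inherits(models, "exont_models"))
  ex <- models$exons
  n_tx_gene <- table(vapply(models$transcripts, `[[`, character(1), "gene_id"))
  singles <- character(0)
  for (gid in unique(ex$gene_id)) {
    rows <- which(ex$gene_id == gid)
    ord <- rows[order(ex$start[rows])]
    if (ex$strand[ord[1L]] == "-") ord <- rev(ord)
    n <- length(ord)
    cat_ <- rep("internal_coding", n)
    cat_[1L] <- "first_coding"
    if (n > 1L) cat_[n] <- "last_coding" else singles <- c(singles, gid)
    ex$position_category[ord] <- cat_

    txs <- Filter(function(t) t$gene_id == gid, models$transcripts)
    for (r in rows) {
      present <- vapply(txs, function(t) {
        any(t$exons$start == ex$start[r] & t$exons$end == ex$end[r])
      }, logical(1))
      ex$splice_class[r] <-
        if (all(present)) "constitutive" else "alternative"
    }
  }
  if (length(singles)) {
    message("categorize_exons: ", length(singles),
            " single-coding-exon gene(s); their exon is both first and ",
            "last, recorded as first_coding and kept out of internal pools")
  }
  models$exons <- ex
  models
}

#' Extract a control pool of exons
#'
#' Returns the deterministic, coordinate-sorted exon universe used to draw
#' size-matched random sets for the enrichment null distribution.
#'
#' @param models A categorized `exont_models` object.
#' @param which One of `"all_coding"`, `"first"`, `"internal"`, `"last"`,
#'   `"internal_constitutive"`, `"internal_alternative"`.
#' @return A data frame of exon records (subset of `models$exons`).
#' @export
control_pool <- function(models,
                         which = c("all_coding", "first", "internal", "last",
                                   "internal_constitutive",
                                   "internal_alternative")) {
  stopifnot(inherits(models, "exont_models"))
  which <- match.arg(which)
  ex <- models$exons
  if (anyNA(ex$position_category)) {
    stop("exons are not categorized; run categorize_exons() first")
  }
  sel <- switch(which,
    all_coding = rep(TRUE, nrow(ex)),
    first = ex$position_category == "first_coding",
    internal = ex$position_category == "internal_coding",
    last = ex$position_category == "last_coding",
    internal_constitutive = ex$position_category == "internal_coding" &
      ex$splice_class == "constitutive",
    internal_alternative = ex$position_category == "internal_coding" &
      ex$splice_class == "alternative"
  )
  pool <- ex[sel, , drop = FALSE]
  if (!nrow(pool)) stop("empty control pool: ", which)
  pool <- pool[order(pool$chrom, pool$start, pool$end, pool$exon_id), ,
               drop = FALSE]
  rownames(pool) <- NULL
  pool
}

#' Resolve a user exon list against gene models
#'
#' Reads a test list either as BED (>= 3 columns; 0-based half-open, strand
#' honoured when present) or as a two-column TSV `gene_id <TAB> exon_number`
#' (1-based rank of the coding exon in transcription order). Coordinates are
#' matched to model exons exactly first; unmatched records fall back to the
#' model exon with >= 90% reciprocal overlap (with a warning). Records that
#' still match nothing are dropped with a warning.
#'
#' @param path Path to the exon list.
#' @param models A categorized `exont_models` object.
#' @return Data frame of matched exon records.
#' @export
read_exon_list <- function(path, models) {
  stopifnot(inherits(models, "exont_models"))
  first <- readLines(path, n = 50L, warn = FALSE)
  first <- first[!startsWith(first, "#") & nzchar(first)]
  if (!length(first)) stop("empty exon list: ", path)
  f1 <- strsplit(first[1L], "\t| +")[[1L]]
  is_bed <- length(f1) >= 3L && !is.na(suppressWarnings(as.integer(f1[2L]))) &&
    !is.na(suppressWarnings(as.integer(f1[3L])))
  ex <- models$exons
  if (is_bed) {
    bed <- rtracklayer::import(path, format = "bed")
    q <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(bed)),
      start = GenomicRanges::start(bed),  # rtracklayer converts to 1-based
      end = GenomicRanges::end(bed),
      strand = as.character(GenomicRanges::strand(bed)),
      stringsAsFactors = FALSE
    )
    hits <- integer(0)
    fallback <- 0L
    unmatched <- 0L
    for (k in seq_len(nrow(q))) {
      m <- which(ex$chrom == q$chrom[k] & ex$start == q$start[k] &
                   ex$end == q$end[k] &
                   (q$strand[k] == "*" | ex$strand == q$strand[k]))
      if (!length(m)) {
        ov_s <- pmax(ex$start, q$start[k])
        ov_e <- pmin(ex$end, q$end[k])
        ov <- pmax(0L, ov_e - ov_s + 1L)
        recip <- ov / (ex$end - ex$start + 1L) >= 0.9 &
          ov / (q$end[k] - q$start[k] + 1L) >= 0.9 &
          ex$chrom == q$chrom[k] &
          (q$strand[k] == "*" | ex$strand == q$strand[k])
        m <- which(recip)
        if (length(m)) {
          m <- m[which.max(ov[m])]
          fallback <- fallback + 1L
        }
      }
      if (!length(m)) unmatched <- unmatched + 1L else hits <- c(hits, m[1L])
    }
    if (fallback) {
      warning(fallback, " exon(s) matched by >=90% reciprocal overlap, ",
              "not exact coordinates")
    }
    if (unmatched) {
      warning(unmatched, " exon(s) in ", path,
              " matched no model exon and were dropped")
    }
    out <- ex[unique(hits), , drop = FALSE]
  } else {
    tab <- utils::read.table(path, sep = "\t", header = FALSE,
                             comment.char = "#", stringsAsFactors = FALSE,
                             col.names = c("gene_id", "exon_number"))
    ids <- character(0)
    for (k in seq_len(nrow(tab))) {
      rows <- which(ex$gene_id == tab$gene_id[k])
      if (!length(rows)) {
        warning("gene not found: ", tab$gene_id[k])
        next
      }
      ord <- rows[order(ex$start[rows])]
      if (ex$strand[ord[1L]] == "-") ord <- rev(ord)
      n <- tab$exon_number[k]
      if (n < 1L || n > length(ord)) {
        warning("gene ", tab$gene_id[k], " has no coding exon #", n)
        next
      }
      ids <- c(ids, ex$exon_id[ord[n]])
    }
    out <- ex[ex$exon_id %in% ids, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' @export
print.exont_models <- function(x, ...) {
  cat("exont_models:", nrow(x$genes), "genes,", length(x$transcripts),
      "transcripts,", nrow(x$exons), "coding exons\n")
  if (!anyNA(x$exons$position_category)) {
    tab <- table(x$exons$position_category)
    cat("  ", paste(names(tab), as.integer(tab), collapse = ", "), "\n")
  }
  invisible(x)
}
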