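# Brute-force oracles and tiny fixture builders, implemented independently
# of the package's interval arithmetic (per-nucleotide marking, boolean
# matrix closure), so tests compare two genuinely different computations.

# transitive closure by boolean matrix powers
oracle_closure_matrix <- function(parents) {
  ids <- names(parents)
  A <- matrix(FALSE, length(ids), length(ids), dimnames = list(ids, ids))
  for (x in ids) A[x, parents[[x]]] <- TRUE
  R <- A
  repeat {
    R2 <- R | ((R %*% A) > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  R
}

oracle_ancestors <- function(parents, id) {
  R <- oracle_closure_matrix(parents)
  sort(names(which(R[id, ])))
}

# genomic positions of a transcript's CDS, one per nucleotide, coding order
oracle_cds_positions <- function(cds, strand) {
  unlist(lapply(seq_len(nrow(cds)), function(i) {
    seg <- cds$start[i]:cds$end[i]
    if (strand == "-") rev(seg) else seg
  }), use.names = FALSE)
}

# per-nucleotide mark-and-count coverage: data frame (exon_id, term_id,
# covered_nt) from marking every covered genomic position per exon and term
oracle_coverage <- function(features, models, tree = NULL,
                            propagate = FALSE) {
  ex <- models$exons
  if (propagate) {
    R <- oracle_closure_matrix(tree$parents)
  }
  marks <- new.env(parent = emptyenv())
  pos_cache <- new.env(parent = emptyenv())
  for (k in seq_len(nrow(features))) {
    tid <- features$transcript_id[k]
    tx <- models$transcripts[[tid]]
    pos_all <- get0(tid, envir = pos_cache)
    if (is.null(pos_all)) {
      pos_all <- oracle_cds_positions(tx$cds, tx$strand)
      assign(tid, pos_all, envir = pos_cache)
    }
    pos <- pos_all[(3L * (features$aa_start[k] - 1L) + 1L):
                     (3L * features$aa_end[k])]
    terms <- features$term_id[k]
    if (propagate) terms <- c(terms, names(which(R[terms, ])))
    for (r in which(ex$gene_id == tx$gene_id)) {
      inside <- pos[pos >= ex$coding_start[r] & pos <= ex$coding_end[r]]
      if (!length(inside)) next
      for (t in terms) {
        key <- paste(ex$exon_id[r], t, sep = "\r")
        old <- get0(key, envir = marks, ifnotfound = integer(0))
        assign(key, union(old, inside), envir = marks)
      }
    }
  }
  keys <- ls(marks)
  if (!length(keys)) {
    return(data.frame(exon_id = character(0), term_id = character(0),
                      covered_nt = integer(0)))
  }
  parts <- strsplit(keys, "\r", fixed = TRUE)
  out <- data.frame(
    exon_id = vapply(parts, `[`, character(1), 1L),
    term_id = vapply(parts, `[`, character(1), 2L),
    covered_nt = vapply(keys, function(k) length(get(k, envir = marks)),
                        integer(1)),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$exon_id, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

oracle_set_score <- function(cov, exons, term) {
  sel <- cov$term_id == term & cov$exon_id %in% exons$exon_id
  1000 * sum(cov$covered_nt[sel]) / sum(exons$coding_len)
}

# -- tiny builders -----------------------------------------------------------

write_gff <- function(lines) {
  tf <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", lines), tf)
  tf
}

gff_row <- function(chrom, type, start, end, strand, attrs, phase = ".") {
  sprintf("%s\ttest\t%s\t%d\t%d\t.\t%s\t%s\t%s", chrom, type, start, end,
          strand, phase, attrs)
}

# a bare transcript model for map_feature_to_genome (cds in coding order)
mk_tx <- function(id, chrom, strand, cds_starts, cds_ends, gene = "G1") {
  list(transcript_id = id, gene_id = gene, chrom = chrom, strand = strand,
       exons = data.frame(start = sort(cds_starts), end = sort(cds_ends)),
       cds = data.frame(start = cds_starts, end = cds_ends),
       cds_len = sum(cds_ends - cds_starts + 1L))
}

# minimal ontology files from a parents list; roots (no parents) are mapped
# round-robin onto the eight classes unless a named `classes` map is given
write_ontology <- function(parents, classes = NULL) {
  obo <- tempfile(fileext = ".obo")
  lines <- "format-version: 1.2"
  for (id in names(parents)) {
    lines <- c(lines, "", "[Term]", paste0("id: ", id),
               paste0("name: ", id),
               paste0("is_a: ", parents[[id]]))
  }
  writeLines(lines, obo)
  map <- tempfile(fileext = ".tsv")
  if (is.null(classes)) {
    roots <- names(parents)[lengths(parents) == 0L]
    classes <- stats::setNames(
      rep(exont::exont_classes(), length.out = length(roots)), roots)
  }
  writeLines(paste(names(classes), classes, sep = "\t"), map)
  list(obo = obo, map = map)
}

# random DAG: edges only point to earlier nodes, hence acyclic
random_dag_parents <- function(n, max_parents = 3L) {
  ids <- sprintf("T%03d", seq_len(n))
  parents <- stats::setNames(vector("list", n), ids)
  for (i in seq_len(n)) parents[[i]] <- character(0)
  for (i in seq_len(n)[-1L]) {
    k <- sample(0:min(max_parents, i - 1L), 1L)
    if (k > 0L) parents[[i]] <- sample(ids[seq_len(i - 1L)], k)
  }
  parents
}

# a three-exon plus-strand gene used across genome-model tests
simple_gene_gff <- function() {
  write_gff(c(
    gff_row("chr1", "gene", 100, 1000, "+", "ID=G1"),
    gff_row("chr1", "mRNA", 100, 1000, "+", "ID=G1.t1;Parent=G1"),
    gff_row("chr1", "exon", 100, 199, "+", "ID=e1;Parent=G1.t1"),
    gff_row("chr1", "exon", 300, 499, "+", "ID=e2;Parent=G1.t1"),
    gff_row("chr1", "exon", 700, 1000, "+", "ID=e3;Parent=G1.t1"),
    gff_row("chr1", "CDS", 100, 199, "+", "Parent=G1.t1", 0),
    gff_row("chr1", "CDS", 300, 499, "+", "Parent=G1.t1", 2),
    gff_row("chr1", "CDS", 700, 999, "+", "Parent=G1.t1", 0)
  ))
}
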