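# Deterministic file emitters for synthetic fixtures. All files are plain
# text with LF line endings; the same simulation always writes identical
# bytes.

write_fixture_files <- function(sim, onto_tbl, out_dir, config, seed) {
  paths <- c(
    models = file.path(out_dir, "models.gff3"),
    features = file.path(out_dir, "features.tsv"),
    proteins = file.path(out_dir, "proteins.fa"),
    ontology = file.path(out_dir, "ontology.obo"),
    root_map = file.path(out_dir, "root_classes.tsv"),
    motifs = file.path(out_dir, "motifs.tsv"),
    test = file.path(out_dir, "test_exons.bed"),
    mitab = file.path(out_dir, "interactions.mitab"),
    idmap = file.path(out_dir, "idmap.tsv")
  )
  writeLines(fixture_gff3_lines(sim$models), paths[["models"]])
  write_tsv_meta(sim$features, paths[["features"]])
  writeLines(fasta_lines(sim$proteins), paths[["proteins"]])
  writeLines(obo_lines(onto_tbl), paths[["ontology"]])
  roots <- onto_tbl[!is.na(onto_tbl$class), , drop = FALSE]
  writeLines(paste(roots$term_id, roots$class, sep = "\t"),
             paths[["root_map"]])
  mt <- synth_motif_tbl()
  writeLines(paste(mt$term_id, mt$regex, sep = "\t"), paths[["motifs"]])
  te <- sim$test_exons
  writeLines(sprintf("%s\t%s\t%s\t%s\t0\t%s", te$chrom,
                     fmt_int(te$start - 1L), fmt_int(te$end), te$exon_id,
                     te$strand),
             paths[["test"]])
  writeLines(mitab_lines(sim$edges), paths[["mitab"]])
  gids <- sort(unique(c(sim$edges$gene_a, sim$edges$gene_b)))
  writeLines(paste(gids, gids, sep = "\t"), paths[["idmap"]])
  paths
}

fixture_gff3_lines <- function(models) {
  out <- "##gff-version 3"
  gff <- function(chrom, type, start, end, strand, phase, attrs) {
    sprintf("%s\texont\t%s\t%s\t%s\t.\t%s\t%s\t%s", chrom, type,
            fmt_int(start), fmt_int(end), strand, phase, attrs)
  }
  for (gid in models$genes$gene_id) {
    txs <- Filter(function(t) t$gene_id == gid, models$transcripts)
    g_start <- min(vapply(txs, function(t) min(t$exons$start), integer(1)))
    g_end <- max(vapply(txs, function(t) max(t$exons$end), integer(1)))
    chrom <- txs[[1L]]$chrom
    strand <- txs[[1L]]$strand
    out <- c(out, gff(chrom, "gene", g_start, g_end, strand, ".",
                      sprintf("ID=%s;Name=%s", gid, gid)))
    for (tx in txs) {
      tid <- tx$transcript_id
      out <- c(out, gff(chrom, "mRNA", min(tx$exons$start),
                        max(tx$exons$end), strand, ".",
                        sprintf("ID=%s;Parent=%s", tid, gid)))
      for (i in seq_len(nrow(tx$exons))) {
        out <- c(out, gff(chrom, "exon", tx$exons$start[i], tx$exons$end[i],
                          strand, ".",
                          sprintf("ID=%s.e%d;Parent=%s", tid, i, tid)))
      }
      # phase from cumulative CDS length in coding order
      w <- tx$cds$end - tx$cds$start + 1L
      phase <- c(0L, (3L - cumsum(w) %% 3L) %% 3L)[seq_len(nrow(tx$cds))]
      ord <- order(tx$cds$start)           # rows ascending, phase per segment
      for (i in ord) {
        out <- c(out, gff(chrom, "CDS", tx$cds$start[i], tx$cds$end[i],
                          strand, phase[i],
                          sprintf("ID=%s.cds;Parent=%s", tid, tid)))
      }
    }
  }
  out
}

fasta_lines <- function(seqs, width = 60L) {
  unlist(lapply(names(seqs), function(nm) {
    s <- seqs[[nm]]
    c(paste0(">", nm),
      substring(s, seq(1L, nchar(s), width),
                pmin(nchar(s), seq(1L, nchar(s), width) + width - 1L)))
  }), use.names = FALSE)
}

obo_lines <- function(onto_tbl) {
  out <- c("format-version: 1.2", "")
  for (i in seq_len(nrow(onto_tbl))) {
    out <- c(out, "[Term]",
             paste0("id: ", onto_tbl$term_id[i]),
             paste0("name: ", onto_tbl$name[i]))
    parents <- strsplit(onto_tbl$parents[i], ",", fixed = TRUE)[[1L]]
    parents <- parents[nzchar(parents)]
    for (p in parents) out <- c(out, paste0("is_a: ", p))
    out <- c(out, "")
  }
  out
}

mitab_lines <- function(edges) {
  rows <- sprintf("synthdb:%s\tsynthdb:%s%s\t%s%s",
                  edges$gene_a, edges$gene_b,
                  strrep("\t-", 10L), "psi-mi:synthdb", strrep("\t-", 2L))
  # duplicate the first two edges in reversed order: readers must
  # canonicalize and deduplicate
  dup <- utils::head(sprintf("synthdb:%s\tsynthdb:%s%s\t%s%s",
                             edges$gene_b, edges$gene_a,
                             strrep("\t-", 10L), "psi-mi:synthdb",
                             strrep("\t-", 2L)), 2L)
  c(rows, dup)
}
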