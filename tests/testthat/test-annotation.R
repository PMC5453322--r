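test_that("amino-acid intervals map through CDS segments per the 3 nt/aa rule", {
  # single CDS segment, plus strand: aa 1-2 occupy the first 6 nt
  tx <- mk_tx("t+", "chr1", "+", 101L, 130L)
  iv <- map_feature_to_genome(tx, 1L, 2L)
  expect_equal(iv[, c("start", "end")], data.frame(start = 101L, end = 106L))

  # split CDS, plus strand: aa 2 = coding nt 4-6 -> {104-105, 201-201}
  tx <- mk_tx("t2", "chr1", "+", c(101L, 201L), c(105L, 210L))
  iv <- map_feature_to_genome(tx, 2L, 2L)
  expect_equal(iv$start, c(104L, 201L))
  expect_equal(iv$end, c(105L, 201L))

  # minus strand, coding order 291-300 then 271-280: aa 1 -> genomic 298-300
  tx <- mk_tx("t-", "chr1", "-", c(291L, 271L), c(300L, 280L))
  iv <- map_feature_to_genome(tx, 1L, 1L)
  expect_equal(iv[, c("start", "end")], data.frame(start = 298L, end = 300L))

  # error contracts
  expect_error(map_feature_to_genome(tx, 1L, 10L), "exceed")
  notx <- mk_tx("t0", "chr1", "+", integer(0), integer(0))
  expect_error(map_feature_to_genome(notx, 1L, 1L), "no CDS")
})

test_that("mapping is exhaustively invertible and conserves 3 nt per aa", {
  set.seed(77)
  for (rep in 1:30) {
    n_seg <- sample(1:3, 1L)
    strand <- sample(c("+", "-"), 1L)
    seg_len <- sample(3:60, n_seg)
    total <- sum(seg_len)
    n_aa <- total %/% 3L
    if (n_aa < 1L) next
    gaps <- sample(50:500, n_seg)
    starts <- 1000L + cumsum(gaps) + cumsum(c(0L, seg_len[-n_seg]))
    ends <- starts + seg_len - 1L
    if (strand == "-") {           # coding order: descending coordinates
      ord <- rev(seq_len(n_seg))
      starts <- starts[ord]; ends <- ends[ord]
    }
    tx <- mk_tx("tx", "chrR", strand, starts, ends)
    pos_oracle <- oracle_cds_positions(tx$cds, strand)
    usable_aa <- tx$cds_len %/% 3L
    for (aa in seq_len(usable_aa)) {
      iv <- map_feature_to_genome(tx, aa, aa)
      g <- unlist(Map(seq, iv$start, iv$end))
      expect_length(g, 3L)                         # conservation
      idx <- match(g, pos_oracle)                  # round trip
      expect_false(anyNA(idx))
      expect_true(all(ceiling(idx / 3) == aa))
    }
  }
})

make_two_exon_models <- function() {
  # one gene, two coding exons with an intron; CDS covers both fully
  gff <- write_gff(c(
    gff_row("chr1", "gene", 1001, 1400, "+", "ID=GA"),
    gff_row("chr1", "mRNA", 1001, 1400, "+", "ID=GA.t1;Parent=GA"),
    gff_row("chr1", "exon", 1001, 1091, "+", "Parent=GA.t1"),
    gff_row("chr1", "exon", 1201, 1400, "+", "Parent=GA.t1"),
    gff_row("chr1", "CDS", 1001, 1091, "+", "Parent=GA.t1"),
    gff_row("chr1", "CDS", 1201, 1400, "+", "Parent=GA.t1")
  ))
  suppressWarnings(categorize_exons(read_gene_models(gff)))
}

test_that("projection clips to exon coding parts and unions same-term overlaps", {
  models <- make_two_exon_models()
  tx <- models$transcripts[["GA.t1"]]

  # wholly inside exon 1: one hit of length 3*aa
  iv <- map_feature_to_genome(tx, 2L, 11L)
  hits <- project_to_exons(iv, models, "T1")
  expect_equal(nrow(hits), 1L)
  expect_equal(sum(hits$end - hits$start + 1L), 30L)

  # junction-spanning: two hits whose lengths sum to 3*aa
  iv <- map_feature_to_genome(tx, 28L, 33L)
  hits <- project_to_exons(iv, models, "T1")
  expect_equal(nrow(hits), 2L)
  expect_equal(sum(hits$end - hits$start + 1L), 18L)

  # intervals overlapping no exon are dropped with a message
  orphan <- data.frame(chrom = "chr1", start = 5000L, end = 5002L,
                       strand = "+")
  expect_message(out <- project_to_exons(orphan, models, "T1"), "dropped")
  expect_equal(nrow(out), 0L)

  # two overlapping features of one term: union < sum, equal to the oracle
  feats <- data.frame(transcript_id = "GA.t1", term_id = "T1",
                      aa_start = c(3L, 8L), aa_end = c(12L, 17L),
                      evidence = "x")
  store <- annotate_exons(feats, models, propagate = FALSE)
  cov <- store$coverage$covered_nt
  expect_lt(sum(cov), 2L * 30L)
  orc <- oracle_coverage(feats, models)
  expect_equal(store$coverage[, c("exon_id", "term_id", "covered_nt")], orc)

  # union idempotence: duplicating a feature changes no coverage
  store2 <- annotate_exons(rbind(feats, feats), models, propagate = FALSE)
  expect_identical(store$coverage, store2$coverage)
})

test_that("ancestor propagation copies hit intervals up the term DAG", {
  models <- make_two_exon_models()
  o <- write_ontology(list(root = character(0), parent = "root",
                           child = "parent"),
                      classes = c(root = "binding"))
  tree <- load_ontology(o$obo, o$map)
  feats <- data.frame(transcript_id = "GA.t1", term_id = "child",
                      aa_start = 2L, aa_end = 6L, evidence = "x")
  on_ <- annotate_exons(feats, models, tree, propagate = TRUE)
  off <- annotate_exons(feats, models, tree, propagate = FALSE)
  expect_setequal(on_$terms, c("child", "parent", "root"))
  expect_identical(off$terms, "child")
  by_term <- split(on_$hits[, c("start", "end")], on_$hits$term_id)
  expect_equal(by_term$child, by_term$parent, ignore_attr = TRUE)
  expect_equal(unname(unlist(lapply(by_term, nrow))), rep(1L, 3L))

  # features with unknown terms are skipped with a warning, the rest kept
  feats2 <- rbind(feats, data.frame(transcript_id = "GA.t1",
                                    term_id = "ghost", aa_start = 1L,
                                    aa_end = 2L, evidence = "x"))
  expect_warning(st <- annotate_exons(feats2, models, tree), "unknown term")
  expect_setequal(st$terms, c("child", "parent", "root"))
})

test_that("parent coverage and frequency dominate children on random fixtures", {
  fix <- generate_fixture(synth_config(n_genes = 12L), seed = 17L)
  store <- annotate_exons(fix$features, fix$models, fix$ontology,
                          propagate = TRUE)
  tree <- fix$ontology
  cov <- store$coverage
  freq <- term_frequency(store, fix$models$exons)
  for (child in intersect(store$terms, tree$terms$term_id)) {
    for (parent in ancestors(tree, child)) {
      merged <- merge(cov[cov$term_id == child, c("exon_id", "covered_nt")],
                      cov[cov$term_id == parent, c("exon_id", "covered_nt")],
                      by = "exon_id")
      expect_true(all(merged$covered_nt.y >= merged$covered_nt.x))
      expect_gte(freq[[parent]], freq[[child]])
    }
  }
})

test_that("term frequencies are counts of annotated exons over the universe", {
  hits <- data.frame(exon_id = sprintf("e%02d", 1:5), term_id = "T1",
                     start = 1L, end = 10L)
  store <- annotation_store(hits)
  universe <- sprintf("e%02d", 1:100)
  freq <- term_frequency(store, universe, terms = c("T1", "T2"))
  expect_equal(unname(freq), c(0.05, 0))
  expect_error(term_frequency(store, character(0)), "empty")
})

test_that("motif scanning finds leftmost non-overlapping matches deterministically", {
  pats <- data.frame(term_id = c("NLS", "PTS1"),
                     regex = c("K[KR].[KR]", "[SAC][KRH][LM]$"))
  hits <- scan_localization_motifs(c(p1 = "AKKAKR"), pats)
  expect_equal(nrow(hits), 1L)
  expect_equal(c(hits$aa_start, hits$aa_end), c(2L, 5L))

  hits <- scan_localization_motifs(c(p2 = "MDDQAGSKL"), pats)
  expect_identical(hits$term_id, "PTS1")
  expect_equal(c(hits$aa_start, hits$aa_end), c(7L, 9L))

  expect_equal(nrow(scan_localization_motifs(c(p3 = "AAAA"), pats)), 0L)
  expect_error(
    scan_localization_motifs(c(p = "AA"),
                             data.frame(term_id = "X", regex = "[")),
    "invalid regular expression")

  # cross-engine check: PCRE scan agrees with the TRE engine on random
  # sequences for the default motif set
  set.seed(99)
  motifs <- read_motif_config(system.file("extdata", "motifs.tsv",
                                          package = "exont"))
  for (rep in 1:20) {
    s <- paste(sample(c(LETTERS[1:26 %in% c(1,3,4,5,6,7,9,11,12,13,18,19)]),
                      200, replace = TRUE), collapse = "")
    got <- scan_localization_motifs(stats::setNames(s, "p"), motifs)
    for (i in seq_len(nrow(motifs))) {
      m <- gregexpr(motifs$regex[i], s)[[1L]]   # default TRE engine
      starts <- if (m[1L] == -1L) integer(0) else as.integer(m)
      expect_equal(got$aa_start[got$term_id == motifs$term_id[i]], starts)
    }
  }
})
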