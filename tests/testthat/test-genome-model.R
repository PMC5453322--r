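test_that("a simple plus-strand gene yields ordered coding exon categories", {
  models <- categorize_exons(read_gene_models(simple_gene_gff()))
  ex <- models$exons
  expect_equal(nrow(ex), 3L)
  expect_identical(ex$position_category[order(ex$start)],
                   c("first_coding", "internal_coding", "last_coding"))
  # third exon is only partially coding
  e3 <- ex[ex$start == 700L, ]
  expect_equal(c(e3$coding_start, e3$coding_end), c(700L, 999L))
  expect_equal(e3$coding_len, 300L)
  expect_identical(unique(ex$splice_class), "constitutive")
})

test_that("minus-strand first coding exon is the rightmost genomic exon", {
  gff <- write_gff(c(
    gff_row("chr2", "gene", 100, 900, "-", "ID=G2"),
    gff_row("chr2", "mRNA", 100, 900, "-", "ID=G2.t1;Parent=G2"),
    gff_row("chr2", "exon", 100, 199, "-", "ID=x1;Parent=G2.t1"),
    gff_row("chr2", "exon", 400, 499, "-", "ID=x2;Parent=G2.t1"),
    gff_row("chr2", "exon", 800, 900, "-", "ID=x3;Parent=G2.t1"),
    gff_row("chr2", "CDS", 100, 199, "-", "Parent=G2.t1"),
    gff_row("chr2", "CDS", 400, 499, "-", "Parent=G2.t1"),
    gff_row("chr2", "CDS", 800, 900, "-", "Parent=G2.t1")
  ))
  models <- categorize_exons(suppressWarnings(read_gene_models(gff)))
  ex <- models$exons
  expect_identical(ex$position_category[which.max(ex$start)], "first_coding")
  expect_identical(ex$position_category[which.min(ex$start)], "last_coding")
  # CDS segments of the transcript are stored in coding order: descending
  cds <- models$transcripts[["G2.t1"]]$cds
  expect_true(all(diff(cds$start) < 0))
})

test_that("exons without CDS overlap are excluded from the coding universe", {
  gff <- write_gff(c(
    gff_row("chr1", "gene", 100, 999, "+", "ID=G3"),
    gff_row("chr1", "mRNA", 100, 999, "+", "ID=G3.t1;Parent=G3"),
    gff_row("chr1", "exon", 100, 199, "+", "Parent=G3.t1"),   # 5' UTR only
    gff_row("chr1", "exon", 300, 599, "+", "Parent=G3.t1"),
    gff_row("chr1", "exon", 700, 999, "+", "Parent=G3.t1"),
    gff_row("chr1", "CDS", 300, 599, "+", "Parent=G3.t1"),
    gff_row("chr1", "CDS", 700, 999, "+", "Parent=G3.t1")
  ))
  models <- read_gene_models(gff)
  expect_equal(nrow(models$exons), 2L)
  expect_false(any(models$exons$start == 100L))
})

test_that("constitutive vs alternative splice classes follow transcript membership", {
  gff <- write_gff(c(
    gff_row("chr1", "gene", 100, 999, "+", "ID=G4"),
    gff_row("chr1", "mRNA", 100, 999, "+", "ID=G4.t1;Parent=G4"),
    gff_row("chr1", "exon", 100, 198, "+", "Parent=G4.t1"),
    gff_row("chr1", "exon", 300, 401, "+", "Parent=G4.t1"),
    gff_row("chr1", "exon", 700, 999, "+", "Parent=G4.t1"),
    gff_row("chr1", "CDS", 100, 198, "+", "Parent=G4.t1"),
    gff_row("chr1", "CDS", 300, 401, "+", "Parent=G4.t1"),
    gff_row("chr1", "CDS", 700, 999, "+", "Parent=G4.t1"),
    gff_row("chr1", "mRNA", 100, 999, "+", "ID=G4.t2;Parent=G4"),
    gff_row("chr1", "exon", 100, 198, "+", "Parent=G4.t2"),
    gff_row("chr1", "exon", 700, 999, "+", "Parent=G4.t2"),
    gff_row("chr1", "CDS", 100, 198, "+", "Parent=G4.t2"),
    gff_row("chr1", "CDS", 700, 999, "+", "Parent=G4.t2")
  ))
  models <- categorize_exons(suppressWarnings(read_gene_models(gff)))
  ex <- models$exons
  expect_identical(ex$splice_class[ex$start == 300L], "alternative")
  expect_identical(ex$splice_class[ex$start == 100L], "constitutive")
  expect_identical(ex$splice_class[ex$start == 700L], "constitutive")
})

test_that("control pools partition all coding exons on generated fixtures", {
  for (seed in c(5L, 6L)) {
    models <- generate_fixture(synth_config(), seed = seed)$models
    n_first <- nrow(control_pool(models, "first"))
    n_internal <- nrow(control_pool(models, "internal"))
    n_last <- nrow(control_pool(models, "last"))
    expect_equal(n_first + n_internal + n_last,
                 nrow(control_pool(models, "all_coding")))
    n_ic <- nrow(control_pool(models, "internal_constitutive"))
    n_ia <- nrow(control_pool(models, "internal_alternative"))
    expect_equal(n_ic + n_ia, n_internal)
    # a 5-exon single-transcript gene has exactly 1 first, 3 internal, 1 last
    tab <- table(models$exons$gene_id, models$exons$position_category)
    five <- rownames(tab)[rowSums(tab) == 5L]
    if (length(five)) {
      expect_true(all(tab[five, "first_coding"] == 1L))
      expect_true(all(tab[five, "internal_coding"] == 3L))
      expect_true(all(tab[five, "last_coding"] == 1L))
    }
  }
})

test_that("categories are invariant under transcript order in the file", {
  fix <- generate_fixture(synth_config(n_genes = 6L), seed = 9L,
                          out_dir = tempfile("reorder_"))
  lines <- readLines(fix$paths[["models"]])
  # move every t2 mRNA block (mRNA+exon+CDS rows) before its t1 block
  is_t2 <- grepl("\\.t2", lines)
  reordered <- c(lines[1L], lines[-1L][order(!is_t2[-1L])])
  # reordering rows globally keeps gene lines first removed; instead swap
  # transcript blocks within the file by sorting feature rows per gene
  tf <- tempfile(fileext = ".gff3")
  writeLines(reordered, tf)
  m1 <- categorize_exons(read_gene_models(fix$paths[["models"]]))
  m2 <- categorize_exons(read_gene_models(tf))
  k1 <- m1$exons[order(m1$exons$exon_id), ]
  k2 <- m2$exons[order(m2$exons$exon_id), ]
  expect_identical(k1$position_category, k2$position_category)
  expect_identical(k1$splice_class, k2$splice_class)
})

test_that("mirroring the genome (strand flip) preserves categories and coding lengths", {
  fix <- generate_fixture(synth_config(n_genes = 8L), seed = 13L,
                          out_dir = tempfile("mirror_"))
  lines <- readLines(fix$paths[["models"]])
  body <- lines[-1L]
  f <- strsplit(body, "\t", fixed = TRUE)
  C <- 10000000L
  mirrored <- vapply(f, function(x) {
    s <- as.integer(x[4L]); e <- as.integer(x[5L])
    x[4L] <- as.character(C - e)
    x[5L] <- as.character(C - s)
    x[7L] <- if (x[7L] == "+") "-" else "+"
    paste(x, collapse = "\t")
  }, character(1))
  tf <- tempfile(fileext = ".gff3")
  writeLines(c(lines[1L], mirrored), tf)
  m1 <- categorize_exons(read_gene_models(fix$paths[["models"]]))
  m2 <- categorize_exons(read_gene_models(tf))
  # match exons across mirrors by gene and mirrored coordinates
  key1 <- paste(m1$exons$gene_id, m1$exons$start, m1$exons$end)
  key2 <- paste(m2$exons$gene_id, C - m2$exons$end, C - m2$exons$start)
  expect_setequal(key1, key2)
  ord <- match(key1, key2)
  expect_identical(m1$exons$position_category,
                   m2$exons$position_category[ord])
  expect_identical(m1$exons$splice_class, m2$exons$splice_class[ord])
  expect_identical(m1$exons$coding_len, m2$exons$coding_len[ord])
})

test_that("single-coding-exon genes are first_coding and kept out of internal pools", {
  gff <- write_gff(c(
    gff_row("chr1", "gene", 100, 400, "+", "ID=G5"),
    gff_row("chr1", "mRNA", 100, 400, "+", "ID=G5.t1;Parent=G5"),
    gff_row("chr1", "exon", 100, 400, "+", "Parent=G5.t1"),
    gff_row("chr1", "CDS", 101, 400, "+", "Parent=G5.t1")
  ))
  expect_message(models <- categorize_exons(read_gene_models(gff)),
                 "single-coding-exon")
  expect_identical(models$exons$position_category, "first_coding")
  expect_error(control_pool(models, "internal"), "empty")
})

test_that("CDS outside its transcript's exons is a hard error; missing Parent is skipped", {
  gff <- write_gff(c(
    gff_row("chr1", "gene", 100, 400, "+", "ID=G6"),
    gff_row("chr1", "mRNA", 100, 400, "+", "ID=G6.t1;Parent=G6"),
    gff_row("chr1", "exon", 100, 250, "+", "Parent=G6.t1"),
    gff_row("chr1", "CDS", 100, 300, "+", "Parent=G6.t1")
  ))
  expect_error(suppressWarnings(read_gene_models(gff)), "outside parent exon")

  gff <- write_gff(c(
    gff_row("chr1", "gene", 100, 400, "+", "ID=G7"),
    gff_row("chr1", "mRNA", 100, 400, "+", "ID=G7.t1;Parent=G7"),
    gff_row("chr1", "exon", 100, 399, "+", "Parent=G7.t1"),
    gff_row("chr1", "exon", 500, 599, "+", "ID=orphan"),
    gff_row("chr1", "CDS", 100, 399, "+", "Parent=G7.t1")
  ))
  expect_warning(models <- read_gene_models(gff), "without Parent")
  expect_equal(nrow(models$exons), 1L)
})

test_that("exon lists resolve by exact coordinates, overlap fallback, and gene/rank", {
  models <- categorize_exons(read_gene_models(simple_gene_gff()))
  bed <- tempfile(fileext = ".bed")
  # exact (0-based starts), then a slightly shifted record (>=90% overlap)
  writeLines(c("chr1\t99\t199\te1\t0\t+",
               "chr1\t300\t499\tshifted\t0\t+"), bed)
  expect_warning(hits <- read_exon_list(bed, models), "reciprocal overlap")
  expect_setequal(hits$start, c(100L, 300L))

  writeLines("chr1\t5000\t5100\tnowhere\t0\t+", bed)
  expect_warning(none <- read_exon_list(bed, models), "dropped")
  expect_equal(nrow(none), 0L)

  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("G1\t1", "G1\t3"), tsv)
  byrank <- read_exon_list(tsv, models)
  expect_setequal(byrank$start, c(100L, 700L))
})
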