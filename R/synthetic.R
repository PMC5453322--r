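# Ground-truthed synthetic fixtures: gene models, protein features,
# proteins with inserted localization motifs, a small term DAG with the
# eight root classes, a test exon list, and an interaction table. Every
# planted quantity is recomputable from the emitted files; the truth record
# carries term frequencies recomputed by independent per-nucleotide marking.

#' Default synthetic fixture configuration
#'
#' Defaults emulate compact vertebrate-like coding genes: exon lengths are
#' log-normal (median ~130 nt, clipped to 30-2000 nt), genes carry 3-8
#' coding exons on either strand, and most genes have a second transcript
#' skipping one internal exon, which makes that exon alternative. Term
#' coverage is placed as randomly positioned intervals (geometric lengths,
#' mean ~30 nt) until a target density is reached, so hits overlap and
#' exercise interval-union logic.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A config list with entries: `n_genes`, `exons_per_gene` (range),
#'   `exon_len_meanlog`, `exon_len_sdlog`, `exon_len_range`,
#'   `intron_len_range`, `p_two_transcripts`, `term_exon_prob_range`
#'   (per-term probability that an exon carries the term),
#'   `coverage_density` (target covered fraction within an annotated exon),
#'   `hit_len_mean_nt`, `ptm_density`, `n_test_exons`, `n_motif_sites`
#'   (named counts per motif term), `n_edges`, and `spike`
#'   (`term_id`, `exons` = `"test"` or exon ids, `multiplier`).
#' @export
synth_config <- function(...) {
  cfg <- list(
    n_genes = 40L,
    exons_per_gene = c(3L, 8L),
    exon_len_meanlog = log(130),
    exon_len_sdlog = 0.6,
    exon_len_range = c(30L, 2000L),
    intron_len_range = c(100L, 2000L),
    p_two_transcripts = 0.7,
    term_exon_prob_range = c(0.15, 0.40),
    coverage_density = 0.25,
    hit_len_mean_nt = 30,
    ptm_density = 0.03,
    n_test_exons = 25L,
    n_motif_sites = c(nls_monopartite = 4L, nls_bipartite = 3L,
                      nes = 3L, pts1 = 3L),
    n_edges = 40L,
    spike = list(term_id = NULL, exons = "test", multiplier = 1)
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

# The fixed fixture ontology: a small DAG under the eight root classes,
# including one multi-parent node so tests exercise true DAG closure.
synth_ontology_tbl <- function() {
  tbl <- function(id, name, parents, class = NA_character_) {
    data.frame(term_id = id, name = name, parents = parents, class = class,
               stringsAsFactors = FALSE)
  }
  rbind(
    tbl("EX:0001", "catalytic activity region", "", "catalytic"),
    tbl("EX:0002", "binding region", "", "binding"),
    tbl("EX:0003", "receptor region", "", "receptor"),
    tbl("EX:0004", "transporter region", "", "transporter"),
    tbl("EX:0005", "localization signal", "", "localization"),
    tbl("EX:0006", "structural region", "", "structure"),
    tbl("EX:0007", "modified residue", "", "PTM"),
    tbl("EX:0008", "other feature", "", "other"),
    tbl("EX:0101", "kinase domain", "EX:0001"),
    tbl("EX:0102", "protease domain", "EX:0001"),
    tbl("EX:0201", "protein binding region", "EX:0002"),
    tbl("EX:0202", "nucleic acid binding region", "EX:0002"),
    tbl("EX:0203", "RNA recognition motif", "EX:0202"),
    tbl("EX:0204", "phosphopeptide binding region", "EX:0201,EX:0002"),
    tbl("EX:0301", "GPCR domain", "EX:0003"),
    tbl("EX:0401", "ion channel domain", "EX:0004"),
    tbl("EX:0501", "monopartite NLS", "EX:0005"),
    tbl("EX:0502", "bipartite NLS", "EX:0005"),
    tbl("EX:0503", "nuclear export signal", "EX:0005"),
    tbl("EX:0504", "peroxisomal targeting signal 1", "EX:0005"),
    tbl("EX:0601", "intrinsically unstructured region", "EX:0006"),
    tbl("EX:0602", "transmembrane region", "EX:0006"),
    tbl("EX:0603", "coiled coil", "EX:0006"),
    tbl("EX:0701", "phosphorylation site", "EX:0007"),
    tbl("EX:0702", "phosphoserine", "EX:0701"),
    tbl("EX:0703", "acetylation site", "EX:0007"),
    tbl("EX:0801", "low complexity region", "EX:0008")
  )
}

# Terms planted as interval coverage vs single-residue sites.
synth_interval_terms <- function() {
  c("EX:0101", "EX:0102", "EX:0201", "EX:0203", "EX:0301", "EX:0401",
    "EX:0601", "EX:0602", "EX:0603", "EX:0801")
}
synth_residue_terms <- function() c("EX:0702", "EX:0703")

# Default localization-motif patterns (also shipped in inst/extdata).
synth_motif_tbl <- function() {
  data.frame(
    term_id = c("EX:0501", "EX:0502", "EX:0503", "EX:0504"),
    regex = c("K[KR].[KR]",
              "[KR][KR].{10,12}[KR]{3}",
              "L.{2,3}[LIVFM].{2,3}L.[LI]",
              "[SAC][KRH][LM]$"),
    stringsAsFactors = FALSE
  )
}
# Literal strings inserted into proteins; each matches its pattern exactly
# once and, against the reduced background alphabet (no K, R, L, H), cannot
# arise or extend by chance.
synth_motif_strings <- function() {
  c(nls_monopartite = "KKAK", nls_bipartite = "KRAAAAAAAAAAKKK",
    nes = "LAAMAALAL", pts1 = "SKL")
}
synth_motif_terms <- function() {
  c(nls_monopartite = "EX:0501", nls_bipartite = "EX:0502",
    nes = "EX:0503", pts1 = "EX:0504")
}
synth_protein_alphabet <- function() {
  c("A", "C", "D", "E", "F", "G", "I", "M", "N", "P", "Q", "S", "T", "V",
    "W", "Y")
}

# Sub-seed for per-(term, exon) interval placement; independent of the main
# stream so spiking one (term, exon) pair leaves all others byte-identical.
placement_seed <- function(seed, term_idx, exon_idx) {
  (as.numeric(seed) * 7919 + term_idx * 104729 + exon_idx * 131) %% 2147483647
}

# Draw intervals (aa coordinates) until `density` of [a_lo, a_hi] is
# covered. A larger target with the same sub-seed extends the same draw
# sequence, so spiked placements are supersets of unspiked ones.
place_term_intervals <- function(a_lo, a_hi, density, mean_len_aa, subseed,
                                 single_residue = FALSE) {
  n_aa <- a_hi - a_lo + 1L
  empty <- list(aa_start = integer(0), aa_end = integer(0))
  if (n_aa < 1L || density <= 0) return(empty)
  target <- max(1L, ceiling(density * n_aa))
  starts <- ends <- integer(0)
  with_seed(subseed, {
    covered <- logical(n_aa)
    it <- 0L
    while (sum(covered) < target && it < 500L) {
      it <- it + 1L
      s <- sample.int(n_aa, 1L)
      len <- if (single_residue) 1L else {
        1L + stats::rgeom(1L, min(1, 1 / mean_len_aa))
      }
      e <- min(n_aa, s + len - 1L)
      starts <- c(starts, a_lo + s - 1L)
      ends <- c(ends, a_lo + e - 1L)
      covered[s:e] <- TRUE
    }
  })
  list(aa_start = starts, aa_end = ends)
}

#' Generate a complete ground-truthed fixture
#'
#' Simulates gene models (multi-transcript genes on both strands, so
#' constitutive and alternative exons exist), per-term protein-feature
#' coverage, proteins with localization motifs inserted at recorded
#' positions, the fixture ontology, a test exon list, and an interaction
#' table. With `out_dir` set, all files are written (GFF3, feature TSV,
#' protein FASTA, OBO subset + root-class map, motif config, BED test list,
#' MITAB, id map, truth JSON); the same config and seed always produce
#' byte-identical files.
#'
#' @param config Configuration from [synth_config()].
#' @param seed Integer seed driving every random choice.
#' @param out_dir Optional output directory (created if needed).
#' @return A list of class `exont_fixture`: `models` (categorized
#'   `exont_models`), `features` (data frame), `proteins` (named character
#'   vector), `ontology` (`exont_ontology`), `motifs` (pattern table),
#'   `test_exons` (exon record data frame), `edges`, `truth`, `paths`
#'   (named file paths, or `NULL`), `config`, `seed`.
#' @export
generate_fixture <- function(config = synth_config(), seed = 1L,
                             out_dir = NULL) {
  validate_synth_config(config)
  sim <- with_seed(seed, simulate_fixture(config, seed))
  onto_tbl <- synth_ontology_tbl()
  paths <- NULL
  obo_dir <- out_dir %||% tempfile("exont_fixture_")
  dir.create(obo_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- write_fixture_files(sim, onto_tbl, obo_dir, config, seed)
  ontology <- load_ontology(paths[["ontology"]], paths[["root_map"]])
  truth <- c(sim$truth, list(
    term_frequency = as.list(brute_term_frequency(
      sim$features, sim$models, ontology))
  ))
  if (!is.null(out_dir)) {
    json <- jsonlite::toJSON(truth, pretty = TRUE, auto_unbox = TRUE,
                             digits = 10)
    writeLines(json, file.path(out_dir, "truth.json"))
    paths[["truth"]] <- file.path(out_dir, "truth.json")
  }
  structure(list(models = sim$models, features = sim$features,
                 proteins = sim$proteins, ontology = ontology,
                 motifs = synth_motif_tbl(), test_exons = sim$test_exons,
                 edges = sim$edges, truth = truth,
                 paths = if (is.null(out_dir)) NULL else paths,
                 config = config, seed = seed),
            class = "exont_fixture")
}

validate_synth_config <- function(config) {
  with_ <- function(x, lo, hi) x >= lo && x <= hi
  if (!with_(config$coverage_density, 0, 1) ||
      !with_(config$ptm_density, 0, 1)) {
    stop("coverage densities must lie in [0, 1]")
  }
  sp <- config$spike
  if (!is.null(sp$term_id)) {
    if (sp$multiplier < 1) stop("spike multiplier must be >= 1")
    base <- if (sp$term_id %in% synth_residue_terms()) {
      config$ptm_density
    } else {
      config$coverage_density
    }
    if (sp$multiplier * base > 1) {
      stop("infeasible config: spiked density ", sp$multiplier * base, " > 1")
    }
  }
  invisible(config)
}

# Runs entirely inside with_seed(seed); the draw order is fixed (genes,
# test list, term placement, proteins, interactions) so spiking never
# perturbs unrelated draws.
simulate_fixture <- function(config, seed) {
  n_genes <- config$n_genes
  tx_rows <- list(); exon_rows <- list(); cds_rows <- list()
  cursor <- c(chr1 = 10000L, chr2 = 10000L)
  gene_meta <- list()
  for (g in seq_len(n_genes)) {
    gid <- sprintf("G%03d", g)
    chrom <- sample(c("chr1", "chr2"), 1L)
    strand <- sample(c("+", "-"), 1L)
    n_ex <- sample(seq(config$exons_per_gene[1L], config$exons_per_gene[2L]),
                   1L)
    lens <- as.integer(pmin(pmax(
      round(stats::rlnorm(n_ex, config$exon_len_meanlog,
                          config$exon_len_sdlog)),
      config$exon_len_range[1L]), config$exon_len_range[2L]))
    two_tx <- n_ex >= 3L && stats::runif(1L) < config$p_two_transcripts
    skip_idx <- if (two_tx) sample(seq(2L, n_ex - 1L), 1L) else NA_integer_
    if (two_tx) {   # skipped exon kept in frame so both CDS are mod-3
      lens[skip_idx] <- lens[skip_idx] + (3L - lens[skip_idx] %% 3L) %% 3L
    }
    lens[n_ex] <- lens[n_ex] + (3L - sum(lens) %% 3L) %% 3L
    introns <- as.integer(round(stats::runif(n_ex - 1L,
                                             config$intron_len_range[1L],
                                             config$intron_len_range[2L])))
    starts <- cursor[[chrom]] + cumsum(c(0L, lens[-n_ex] + introns))
    ends <- starts + lens - 1L
    cursor[[chrom]] <- ends[n_ex] + 5000L +
      as.integer(round(stats::runif(1L, 0, 5000)))
    t1 <- paste0(gid, ".t1")
    tx_rows[[length(tx_rows) + 1L]] <-
      data.frame(transcript_id = t1, gene_id = gid)
    exon_rows[[length(exon_rows) + 1L]] <-
      data.frame(parent = t1, chrom = chrom, start = starts, end = ends,
                 strand = strand)
    cds_rows[[length(cds_rows) + 1L]] <-
      data.frame(parent = t1, chrom = chrom, start = starts, end = ends,
                 strand = strand)
    if (two_tx) {
      t2 <- paste0(gid, ".t2")
      keep <- setdiff(seq_len(n_ex), skip_idx)
      tx_rows[[length(tx_rows) + 1L]] <-
        data.frame(transcript_id = t2, gene_id = gid)
      exon_rows[[length(exon_rows) + 1L]] <-
        data.frame(parent = t2, chrom = chrom, start = starts[keep],
                   end = ends[keep], strand = strand)
      cds_rows[[length(cds_rows) + 1L]] <-
        data.frame(parent = t2, chrom = chrom, start = starts[keep],
                   end = ends[keep], strand = strand)
    }
    gene_meta[[gid]] <- list(gid = gid, chrom = chrom, strand = strand,
                             starts = starts, ends = ends, t1 = t1)
  }
  tx_tbl <- do.call(rbind, tx_rows)
  exon_tbl <- do.call(rbind, exon_rows)
  cds_tbl <- do.call(rbind, cds_rows)
  models <- categorize_exons(assemble_models(tx_tbl, exon_tbl, cds_tbl))
  ex <- models$exons

  # amino-acid span of each exon within its gene's full-length transcript
  aa_span <- exon_aa_spans(models)

  # -- test list ------------------------------------------------------------
  internal <- ex$exon_id[ex$position_category == "internal_coding"]
  n_test <- min(config$n_test_exons, length(internal))
  test_ids <- sort(sample(internal, n_test))
  spike <- config$spike
  spike_ids <- character(0)
  if (!is.null(spike$term_id)) {
    spike_ids <- if (identical(spike$exons, "test")) test_ids else spike$exons
    unknown <- setdiff(spike_ids, ex$exon_id)
    if (length(unknown)) {
      stop("spike exon(s) not in fixture: ", paste(unknown, collapse = ", "))
    }
  }

  # -- per-term coverage ----------------------------------------------------
  all_terms <- c(synth_interval_terms(), synth_residue_terms())
  probs <- stats::runif(length(all_terms), config$term_exon_prob_range[1L],
                        config$term_exon_prob_range[2L])
  f_tx <- f_term <- character(0)
  f_s <- f_e <- integer(0)
  for (ti in seq_along(all_terms)) {
    term <- all_terms[ti]
    residue <- term %in% synth_residue_terms()
    base_d <- if (residue) config$ptm_density else config$coverage_density
    for (ei in seq_len(nrow(ex))) {
      include <- stats::runif(1L) < probs[ti]     # main stream, spike-blind
      d <- base_d
      spiked <- !is.null(spike$term_id) && term == spike$term_id &&
        ex$exon_id[ei] %in% spike_ids
      if (spiked) {
        include <- TRUE
        d <- base_d * spike$multiplier
      }
      if (!include) next
      span <- aa_span[[ex$exon_id[ei]]]
      iv <- place_term_intervals(span$aa_lo, span$aa_hi, d,
                                 config$hit_len_mean_nt / 3,
                                 placement_seed(seed, ti, ei),
                                 single_residue = residue)
      n_iv <- length(iv$aa_start)
      if (n_iv) {
        f_tx <- c(f_tx, rep(span$transcript_id, n_iv))
        f_term <- c(f_term, rep(term, n_iv))
        f_s <- c(f_s, iv$aa_start)
        f_e <- c(f_e, iv$aa_end)
      }
    }
  }
  features <- data.frame(transcript_id = f_tx, term_id = f_term,
                         aa_start = f_s, aa_end = f_e,
                         evidence = "synthetic", stringsAsFactors = FALSE)

  # -- proteins and motif insertions ---------------------------------------
  alpha <- synth_protein_alphabet()
  prot_ids <- names(models$transcripts)
  proteins <- vapply(prot_ids, function(tid) {
    L <- models$transcripts[[tid]]$cds_len %/% 3L
    paste(sample(alpha, L, replace = TRUE), collapse = "")
  }, character(1))
  motif_strings <- synth_motif_strings()
  motif_terms <- synth_motif_terms()
  eligible <- prot_ids[nchar(proteins) >= 40L]
  slots <- rep(names(config$n_motif_sites), config$n_motif_sites)
  chosen <- sample(eligible, min(length(slots), length(eligible)))
  slots <- slots[seq_along(chosen)]
  site_rows <- list()
  for (k in seq_along(chosen)) {
    pid <- chosen[k]
    motif <- slots[k]
    s <- motif_strings[[motif]]
    L <- nchar(proteins[[pid]])
    if (motif == "pts1") {
      pos <- L - nchar(s) + 1L
    } else {
      pos <- sample(seq(5L, L - nchar(s) - 4L), 1L)
    }
    substr(proteins[[pid]], pos, pos + nchar(s) - 1L) <- s
    site_rows[[k]] <- data.frame(
      transcript_id = pid, term_id = motif_terms[[motif]],
      aa_start = pos, aa_end = pos + nchar(s) - 1L,
      stringsAsFactors = FALSE)
  }
  motif_sites <- do.call(rbind, site_rows)
  if (!is.null(motif_sites)) {
    motif_sites <- motif_sites[order(motif_sites$transcript_id,
                                     motif_sites$aa_start), , drop = FALSE]
    rownames(motif_sites) <- NULL
  }

  # -- interactions ---------------------------------------------------------
  gids <- models$genes$gene_id
  pairs <- unique(t(replicate(config$n_edges, sort(sample(gids, 2L)))))
  edges <- data.frame(gene_a = pairs[, 1L], gene_b = pairs[, 2L],
                      source = "synthdb", stringsAsFactors = FALSE)

  test_exons <- ex[match(test_ids, ex$exon_id), , drop = FALSE]
  rownames(test_exons) <- NULL
  truth <- list(
    seed = seed,
    n_genes = nrow(models$genes),
    n_coding_exons = nrow(ex),
    test_exons = test_ids,
    spike = list(term_id = spike$term_id, exons = spike_ids,
                 multiplier = spike$multiplier),
    expected_direction = if (!is.null(spike$term_id) && spike$multiplier > 1) {
      stats::setNames(list("enriched"), spike$term_id)
    } else {
      stats::setNames(list(), character(0))
    },
    motif_sites = motif_sites
  )
  list(models = models, features = features, proteins = proteins,
       test_exons = test_exons, edges = edges, truth = truth,
       gene_meta = gene_meta)
}

# aa interval of each exon fully inside it, on its gene's full transcript
exon_aa_spans <- function(models) {
  spans <- list()
  for (tid in names(models$transcripts)) {
    if (!endsWith(tid, ".t1")) next
    tx <- models$transcripts[[tid]]
    w <- tx$cds$end - tx$cds$start + 1L
    cum <- cumsum(w)
    for (i in seq_len(nrow(tx$cds))) {
      cs <- c(0L, cum)[i] + 1L
      ce <- cum[i]
      eid <- models$exons$exon_id[
        models$exons$gene_id == tx$gene_id &
          models$exons$start == tx$cds$start[i] &
          models$exons$end == tx$cds$end[i]]
      if (length(eid) != 1L) next
      spans[[eid]] <- list(transcript_id = tid,
                           aa_lo = as.integer(ceiling((cs + 2L) / 3)),
                           aa_hi = as.integer(floor(ce / 3)))
    }
  }
  spans
}

#' Raise a term's coverage density on selected exons
#'
#' Regenerates the fixture with the term's target density multiplied on the
#' listed exons and unchanged everywhere else (per-exon placement streams
#' are independently seeded, so unspiked placements are byte-identical and
#' spiked placements are supersets of the originals). An empty exon list is
#' a no-op and reproduces identical files.
#'
#' @param fixture An `exont_fixture` from [generate_fixture()].
#' @param term_id Term to spike.
#' @param exons Character vector of exon ids (must exist in the fixture).
#' @param multiplier Density multiplier (>= 1; the spiked density must stay
#'   <= 1).
#' @return A new `exont_fixture` with the modified feature table (files
#'   rewritten in place when the fixture was written to disk).
#' @export
spike_in <- function(fixture, term_id, exons, multiplier) {
  stopifnot(inherits(fixture, "exont_fixture"))
  cfg <- fixture$config
  if (length(exons)) {
    unknown <- setdiff(exons, fixture$models$exons$exon_id)
    if (length(unknown)) {
      stop("unknown exon(s): ", paste(unknown, collapse = ", "))
    }
    cfg$spike <- list(term_id = term_id, exons = exons,
                      multiplier = multiplier)
  }
  out_dir <- if (is.null(fixture$paths)) NULL else {
    dirname(fixture$paths[["models"]])
  }
  generate_fixture(cfg, fixture$seed, out_dir = out_dir)
}

# Per-nucleotide truth oracle: marks every genomic nucleotide touched by
# every feature (ancestors included) by full CDS enumeration, then counts
# annotated exons per term. Deliberately a different computation path from
# the interval-union store.
brute_term_frequency <- function(features, models, ontology) {
  ex <- models$exons
  cds_positions <- lapply(models$transcripts, function(tx) {
    unlist(lapply(seq_len(nrow(tx$cds)), function(i) {
      if (tx$strand == "+") tx$cds$start[i]:tx$cds$end[i]
      else tx$cds$end[i]:tx$cds$start[i]
    }), use.names = FALSE)
  })
  anc <- lapply(stats::setNames(nm = unique(features$term_id)),
                function(t) ancestors(ontology, t))
  terms <- sort(unique(c(names(anc), unlist(anc, use.names = FALSE))))
  hit <- matrix(FALSE, nrow = nrow(ex), ncol = length(terms),
                dimnames = list(ex$exon_id, terms))
  for (k in seq_len(nrow(features))) {
    tx <- models$transcripts[[features$transcript_id[k]]]
    pos <- cds_positions[[features$transcript_id[k]]][
      (3L * (features$aa_start[k] - 1L) + 1L):(3L * features$aa_end[k])]
    cand <- which(ex$gene_id == tx$gene_id)
    rows <- cand[vapply(cand, function(r) {
      any(pos >= ex$coding_start[r] & pos <= ex$coding_end[r])
    }, logical(1))]
    if (!length(rows)) next
    tset <- c(features$term_id[k], anc[[features$term_id[k]]])
    hit[rows, tset] <- TRUE
  }
  colSums(hit) / nrow(ex)
}

#' @export
print.exont_fixture <- function(x, ...) {
  cat("exont_fixture (seed ", x$seed, "): ", nrow(x$models$genes), " genes, ",
      nrow(x$models$exons), " coding exons, ", nrow(x$features),
      " features, ", length(x$test_exons$exon_id), " test exons\n", sep = "")
  invisible(x)
}
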