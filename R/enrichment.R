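# Enrichment of terms in a test exon set against size-matched random sets
# drawn from a control pool. Scores are compared on the log scale (they are
# approximately log-normal across random sets), giving a Z-score, a normal
# or empirical p-value, and a Benjamini-Hochberg FDR per term.

#' Draw one size-matched random exon set from a control pool
#'
#' Exons are drawn uniformly without replacement; drawing stops at the
#' first exon that brings the cumulative coding length to at least
#' `target_size_nt`, so the realized size overshoots the target by less
#' than one exon. Uses the current RNG stream (seed upstream, e.g. via
#' the `seed` arguments of [build_null()] / [enrich()]).
#'
#' @param pool Data frame of exon records (needs `exon_id`, `coding_len`).
#' @param target_size_nt Target total coding length in nucleotides.
#' @return Data frame of sampled exon records, with attribute
#'   `realized_size_nt`.
#' @export
sample_control_set <- function(pool, target_size_nt) {
  len <- pool$coding_len
  if (sum(len) < target_size_nt) {
    stop("control pool (", sum(len), " nt) smaller than target (",
         target_size_nt, " nt)")
  }
  idx <- sample.int(nrow(pool))
  k <- which(cumsum(len[idx]) >= target_size_nt)[1L]
  sel <- idx[seq_len(k)]
  out <- pool[sel, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "realized_size_nt") <- sum(len[sel])
  out
}

# covered-nt matrix, exons x terms, used to score many random sets cheaply.
coverage_matrix <- function(store, exon_ids, terms) {
  M <- matrix(0, nrow = length(exon_ids), ncol = length(terms),
              dimnames = list(exon_ids, terms))
  cv <- store$coverage[store$coverage$exon_id %in% exon_ids &
                         store$coverage$term_id %in% terms, , drop = FALSE]
  if (nrow(cv)) {
    M[cbind(match(cv$exon_id, exon_ids), match(cv$term_id, terms))] <-
      cv$covered_nt
  }
  M
}

# Zero scores are floored at the score of a single covered nucleotide over
# the set's total size, keeping the log finite and order-preserving.
floor_log_score <- function(score, total_nt) {
  log(ifelse(score <= 0, 1000 / total_nt, score))
}

#' Build null score distributions from a control pool
#'
#' Draws `n_sets` size-matched random exon sets (see
#' [sample_control_set()]) and computes every term's set score on each,
#' yielding the per-term mean and standard deviation of log scores that the
#' Z-score is measured against. A zero score is replaced by the score of a
#' single covered nucleotide over the set's size before taking logs.
#'
#' @param store An `exont_store`.
#' @param pool Control pool data frame (from [control_pool()]).
#' @param target_size_nt Target total coding length of each random set.
#' @param terms Terms to build distributions for.
#' @param n_sets Number of random sets (default 1000; at least 100 is
#'   required for inference).
#' @param seed Optional integer seed (RNG state is restored afterwards).
#' @return An `exont_null` object: list with `terms`, `mu`, `sigma`
#'   (named, log scale), `log_scores` (`n_sets` x terms matrix), `sizes`
#'   (realized set sizes), `target_size_nt`, `n_sets`. Terms with zero
#'   variance are flagged in `untestable`.
#' @export
build_null <- function(store, pool, target_size_nt, terms, n_sets = 1000L,
                       seed = NULL) {
  stopifnot(inherits(store, "exont_store"), length(terms) >= 1L)
  if (n_sets < 100L) {
    warning("n_sets < 100 is too few for inference")
  }
  M <- coverage_matrix(store, pool$exon_id, terms)
  len <- pool$coding_len
  logs <- matrix(NA_real_, nrow = n_sets, ncol = length(terms),
                 dimnames = list(NULL, terms))
  sizes <- numeric(n_sets)
  with_seed(seed, {
    perm_scores <- function(b) {
      idx <- sample.int(nrow(pool))
      k <- which(cumsum(len[idx]) >= target_size_nt)[1L]
      sel <- idx[seq_len(k)]
      size <- sum(len[sel])
      s <- 1000 * colSums(M[sel, , drop = FALSE]) / size
      sizes[b] <<- size
      logs[b, ] <<- floor_log_score(s, size)
    }
    for (b in seq_len(n_sets)) perm_scores(b)
  })
  mu <- colMeans(logs)
  sigma <- apply(logs, 2L, stats::sd)
  structure(list(terms = terms, mu = mu, sigma = sigma, log_scores = logs,
                 sizes = sizes, target_size_nt = target_size_nt,
                 n_sets = n_sets, untestable = terms[sigma <= 0]),
            class = "exont_null")
}

#' Test term enrichment in an exon set against a control pool
#'
#' For every term annotated on at least `min_freq` of the control pool's
#' exons, compares the test set's score with the distribution of scores of
#' `n_sets` size-matched random sets from the pool. Scores are log
#' transformed (they are approximately log-normal across random sets), and
#' `z = (log s_obs - mu) / sigma`. The parametric p-value is the two-sided
#' normal tail of `z`; the empirical p-value is
#' `2 * min(count_above + 1, count_below + 1) / (n_sets + 1)`, capped at 1.
#' Benjamini-Hochberg q-values are computed over all testable terms.
#'
#' Test exons are not removed from the pool by default (the usual designs
#' compare disjoint categories); set `exclude_test = TRUE` for overlapping
#' designs.
#'
#' @param test Data frame of test exon records.
#' @param pool Control pool data frame (from [control_pool()]).
#' @param store An `exont_store` (ancestor-propagated for the usual usage).
#' @param tree Optional `exont_ontology`; adds term names and root classes
#'   to the result.
#' @param n_sets Number of random control sets (default 1000).
#' @param seed Optional integer seed; with a fixed seed the result table is
#'   fully reproducible.
#' @param min_freq Minimum fraction of pool exons a term must annotate to
#'   be tested (default 0.04).
#' @param mode `"parametric"` (normal tail) or `"empirical"` (rank-based).
#' @param exclude_test Drop test exons from the pool before sampling
#'   (default `FALSE`).
#' @return Data frame of class `exont_enrichment`, one row per tested term:
#'   `term_id`, `name`, `root_class`, `covered_nt`, `total_nt`, `score`,
#'   `null_mu_log`, `null_sigma_log`, `z`, `p`, `q`, `direction`, sorted by
#'   `q`, then decreasing `|z|`, then `term_id`. Terms with a degenerate
#'   (zero-variance) null get `NA` z/p/q and direction `"untestable"`, and
#'   are excluded from the FDR.
#' @export
enrich <- function(test, pool, store, tree = NULL, n_sets = 1000L,
                   seed = NULL, min_freq = 0.04,
                   mode = c("parametric", "empirical"),
                   exclude_test = FALSE) {
  mode <- match.arg(mode)
  stopifnot(inherits(store, "exont_store"))
  if (!nrow(test)) stop("empty test set")
  if (exclude_test) {
    pool <- pool[!pool$exon_id %in% test$exon_id, , drop = FALSE]
    if (!nrow(pool)) stop("control pool empty after excluding test exons")
  }
  freq <- term_frequency(store, pool)
  terms <- names(freq)[freq >= min_freq]
  if (!length(terms)) {
    warning("no term passes the frequency filter (min_freq = ", min_freq, ")")
    return(empty_enrichment())
  }
  terms <- sort(terms)

  obs <- score_table(store, test, terms)
  total_nt <- sum(test$coding_len)
  log_obs <- floor_log_score(obs$score, total_nt)

  null <- build_null(store, pool, total_nt, terms, n_sets = n_sets,
                     seed = seed)
  testable <- null$sigma > 0
  z <- ifelse(testable, (log_obs - null$mu) / null$sigma, NA_real_)
  p <- rep(NA_real_, length(terms))
  if (mode == "parametric") {
    p[testable] <- 2 * stats::pnorm(-abs(z[testable]))
  } else {
    for (j in which(testable)) {
      above <- sum(null$log_scores[, j] >= log_obs[j])
      below <- sum(null$log_scores[, j] <= log_obs[j])
      p[j] <- min(1, 2 * min(above + 1L, below + 1L) / (n_sets + 1L))
    }
  }
  q <- rep(NA_real_, length(terms))
  q[testable] <- bh_fdr(p[testable])

  res <- data.frame(
    term_id = terms,
    name = if (!is.null(tree)) {
      tree$terms$name[match(terms, tree$terms$term_id)]
    } else NA_character_,
    root_class = if (!is.null(tree)) {
      tree$terms$root_class[match(terms, tree$terms$term_id)]
    } else NA_character_,
    covered_nt = obs$covered_nt,
    total_nt = total_nt,
    score = obs$score,
    null_mu_log = unname(null$mu),
    null_sigma_log = unname(null$sigma),
    z = z,
    p = p,
    q = q,
    direction = ifelse(!testable, "untestable",
                       ifelse(z > 0, "enriched",
                              ifelse(z < 0, "depleted", "none"))),
    stringsAsFactors = FALSE
  )
  ord <- order(res$q, -abs(res$z), res$term_id, na.last = TRUE)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_sets") <- n_sets
  attr(res, "seed") <- seed
  attr(res, "mode") <- mode
  attr(res, "target_size_nt") <- total_nt
  class(res) <- c("exont_enrichment", "data.frame")
  res
}

empty_enrichment <- function() {
  res <- data.frame(term_id = character(0), name = character(0),
                    root_class = character(0), covered_nt = integer(0),
                    total_nt = integer(0), score = numeric(0),
                    null_mu_log = numeric(0), null_sigma_log = numeric(0),
                    z = numeric(0), p = numeric(0), q = numeric(0),
                    direction = character(0), stringsAsFactors = FALSE)
  class(res) <- c("exont_enrichment", "data.frame")
  res
}

#' Benjamini-Hochberg step-up false discovery rates
#'
#' `q_i = min_{j : p_(j) >= p_i over ranks >= rank(i)} p_(j) * m / j`,
#' capped at 1; the input order is preserved in the output.
#'
#' @param pvals Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(pvals) {
  if (!is.numeric(pvals)) stop("p-values must be numeric")
  if (!length(pvals)) return(numeric(0))
  if (anyNA(pvals) || any(pvals < 0 | pvals > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(pvals)
  o <- order(pvals)
  q_sorted <- pvals[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))   # step-up: min over larger ranks
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}
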