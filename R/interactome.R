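# Protein-protein interaction overlay: read a PSI-MITAB 2.5 table as an
# undirected edge list and look up partners of the genes carrying tested
# exons, including partners shared by several query genes.

#' Read a PSI-MITAB 2.5 interaction file
#'
#' Consumes only the two interactor identifier columns (1-2) and the source
#' database column (13); confidence scores and the remaining columns are
#' ignored, since the interactome is used as a partner list, not a weighted
#' network. Identifiers of the form `db:value` are resolved through the
#' optional `id_map` (value -> gene id); rows whose identifiers cannot be
#' resolved, and malformed rows, are skipped and counted in a message.
#' Edges are stored canonically (lexicographic order), deduplicated;
#' self-edges are kept and flagged.
#'
#' @param path Path to the MITAB file (header lines starting with `#` are
#'   skipped).
#' @param id_map Optional data frame (`id`, `gene`) mapping identifier
#'   values to gene ids, or path to such a TSV (no header).
#' @return Data frame (`gene_a`, `gene_b`, `source`, `self`).
#' @export
read_mitab <- function(path, id_map = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!is.null(id_map) && is.character(id_map) && length(id_map) == 1L) {
    id_map <- utils::read.table(id_map, sep = "\t", header = FALSE,
                                quote = "", stringsAsFactors = FALSE,
                                col.names = c("id", "gene"))
  }
  strip_db <- function(x) sub("^[^:]*:", "", sub("\\(.*$", "", x))
  resolve <- function(v) {
    if (is.null(id_map)) return(v)
    out <- id_map$gene[match(v, id_map$id)]
    out
  }
  skipped_malformed <- 0L
  skipped_unresolved <- 0L
  rows <- vector("list", length(lines))
  for (k in seq_along(lines)) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 13L) {
      skipped_malformed <- skipped_malformed + 1L
      next
    }
    ra <- strip_db(f[1L])
    rb <- strip_db(f[2L])
    if (ra %in% c("", "-") || rb %in% c("", "-")) {
      skipped_malformed <- skipped_malformed + 1L
      next
    }
    a <- resolve(ra)
    b <- resolve(rb)
    if (is.na(a) || is.na(b)) {
      skipped_unresolved <- skipped_unresolved + 1L
      next
    }
    rows[[k]] <- c(min(a, b), max(a, b), strip_db(f[13L]))
  }
  if (skipped_malformed) {
    message("read_mitab: skipped ", skipped_malformed, " malformed row(s)")
  }
  if (skipped_unresolved) {
    message("read_mitab: skipped ", skipped_unresolved,
            " row(s) with unresolvable identifier(s)")
  }
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      source = character(0), self = logical(0)))
  }
  edges <- data.frame(gene_a = rows[, 1L], gene_b = rows[, 2L],
                      source = rows[, 3L], stringsAsFactors = FALSE)
  edges <- edges[!duplicated(edges[, c("gene_a", "gene_b")]), , drop = FALSE]
  edges$self <- edges$gene_a == edges$gene_b
  if (any(edges$self)) {
    message("read_mitab: ", sum(edges$self), " self-edge(s) kept, flagged")
  }
  rownames(edges) <- NULL
  edges
}

#' Interaction partners of a set of query genes
#'
#' @param edges Edge data frame from [read_mitab()].
#' @param genes Non-empty character vector of query gene ids.
#' @return List with `partners` (named list: query gene -> sorted character
#'   vector of partners, the query gene itself excluded unless it has a
#'   self-edge) and `shared` (named list: partner -> the query genes that
#'   touch it, restricted to partners hit by at least two query genes).
#' @export
partners_of <- function(edges, genes) {
  if (!length(genes)) stop("empty query gene set")
  genes <- unique(genes)
  partners <- lapply(stats::setNames(nm = genes), function(g) {
    p <- c(edges$gene_b[edges$gene_a == g], edges$gene_a[edges$gene_b == g])
    p <- unique(p)
    if (!any(edges$self & edges$gene_a == g)) p <- setdiff(p, g)
    sort(p)
  })
  all_partners <- sort(unique(unlist(partners, use.names = FALSE)))
  shared <- lapply(stats::setNames(nm = all_partners), function(x) {
    sort(genes[vapply(partners[genes], function(p) x %in% p, logical(1))])
  })
  shared <- shared[lengths(shared) >= 2L]
  list(partners = partners, shared = shared)
}
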