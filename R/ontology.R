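# Ontology of protein-feature terms: a DAG of is_a links whose roots are the
# eight height classes of protein features used throughout the suite.

#' The eight root classes of protein features
#'
#' Every term in a valid ontology resolves, through its `is_a` ancestors, to
#' exactly one of these classes: catalytic activity, molecular binding,
#' receptor, transporter, subcellular localization, structural state,
#' post-translational modification, or other.
#'
#' @return Character vector of the eight class labels.
#' @export
exont_classes <- function() {
  c("catalytic", "binding", "receptor", "transporter",
    "localization", "structure", "PTM", "other")
}

#' Load a protein-feature term ontology
#'
#' Reads a minimal OBO subset (`[Term]` stanzas with `id:`, `name:` and
#' `is_a:` tags; all other tags and stanza types are ignored) together with a
#' sidecar two-column TSV mapping root term ids of the source ontologies to
#' the eight protein-feature classes (see [exont_classes()]). The merged term
#' graph must be a DAG; cycles and `is_a` references to missing terms are
#' hard errors. Each term is assigned the class of its nearest mapped root;
#' terms reachable from more than one class are flagged
#' (`multi_root = TRUE`) and terms from which no mapped root is reachable are
#' reported and labelled `"unresolved"`.
#'
#' @param obo_path Path to the OBO-subset file.
#' @param root_map_path Path to the root-class mapping TSV
#'   (`term_id <TAB> class`, no header, `#` comments allowed).
#' @return An object of class `exont_ontology`: a list with
#'   `terms` (data frame: `term_id`, `name`, `root_class`, `multi_root`),
#'   `parents` (named list of parent id vectors) and
#'   `roots` (named character vector, term id -> class).
#' @examples
#' obo <- tempfile(fileext = ".obo")
#' writeLines(c("[Term]", "id: X:1", "name: root", "",
#'              "[Term]", "id: X:2", "name: child", "is_a: X:1 ! root"), obo)
#' map <- tempfile(fileext = ".tsv")
#' writeLines("X:1\tlocalization", map)
#' onto <- load_ontology(obo, map)
#' ancestors(onto, "X:2")
#' @export
load_ontology <- function(obo_path, root_map_path) {
  stanzas <- parse_obo_terms(obo_path)
  ids <- vapply(stanzas, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate term ids in ontology: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  parents <- lapply(stanzas, `[[`, "is_a")
  names(parents) <- ids
  dangling <- setdiff(unlist(parents, use.names = FALSE), ids)
  if (length(dangling)) {
    stop("is_a reference to missing term(s): ",
         paste(sort(dangling), collapse = ", "))
  }
  cyc <- find_cycle(parents)
  if (!is.null(cyc)) {
    stop("cycle detected in ontology: ", paste(cyc, collapse = " -> "))
  }

  root_map <- utils::read.table(root_map_path, sep = "\t", header = FALSE,
                                comment.char = "#", quote = "",
                                stringsAsFactors = FALSE,
                                col.names = c("term_id", "class"))
  bad_class <- setdiff(root_map$class, exont_classes())
  if (length(bad_class)) {
    stop("unknown root class(es) in mapping: ",
         paste(bad_class, collapse = ", "))
  }
  missing_root <- setdiff(root_map$term_id, ids)
  if (length(missing_root)) {
    stop("root-class mapping names unknown term(s): ",
         paste(missing_root, collapse = ", "))
  }
  roots <- stats::setNames(root_map$class, root_map$term_id)

  res <- resolve_root_classes(parents, roots)
  unresolved <- ids[res$class == "unresolved"]
  if (length(unresolved)) {
    message("ontology: ", length(unresolved),
            " term(s) not reachable from any mapped root class: ",
            paste(utils::head(unresolved, 10L), collapse = ", "),
            if (length(unresolved) > 10L) ", ..." else "")
  }
  multi <- ids[res$multi]
  if (length(multi)) {
    message("ontology: ", length(multi),
            " term(s) reachable from more than one root class were ",
            "assigned their nearest root's class: ",
            paste(utils::head(multi, 10L), collapse = ", "),
            if (length(multi) > 10L) ", ..." else "")
  }

  terms <- data.frame(
    term_id = ids,
    name = vapply(stanzas, `[[`, character(1), "name"),
    root_class = res$class,
    multi_root = res$multi,
    stringsAsFactors = FALSE
  )
  rownames(terms) <- NULL
  structure(list(terms = terms, parents = parents, roots = roots),
            class = "exont_ontology")
}

#' Transitive is_a closure of a term
#'
#' @param tree An `exont_ontology` from [load_ontology()].
#' @param term_id A term id present in the ontology.
#' @return Character vector of all ancestor term ids (the term itself
#'   excluded); empty for root terms.
#' @export
ancestors <- function(tree, term_id) {
  stopifnot(inherits(tree, "exont_ontology"))
  if (!term_id %in% names(tree$parents)) {
    stop("unknown term: ", term_id)
  }
  seen <- character(0)
  frontier <- tree$parents[[term_id]]
  while (length(frontier)) {
    frontier <- setdiff(frontier, seen)
    seen <- c(seen, frontier)
    frontier <- unique(unlist(tree$parents[frontier], use.names = FALSE))
  }
  sort(seen)
}

#' Root class of a term
#'
#' @inheritParams ancestors
#' @return One of [exont_classes()] or `"unresolved"`.
#' @export
root_class_of <- function(tree, term_id) {
  stopifnot(inherits(tree, "exont_ontology"))
  i <- match(term_id, tree$terms$term_id)
  if (is.na(i)) stop("unknown term: ", term_id)
  tree$terms$root_class[i]
}

#' @export
print.exont_ontology <- function(x, ...) {
  cat("exont_ontology with", nrow(x$terms), "terms,",
      length(x$roots), "mapped roots\n")
  tab <- table(x$terms$root_class)
  cat(paste0("  ", names(tab), ": ", as.integer(tab), collapse = "\n"), "\n")
  invisible(x)
}

# -- internals ---------------------------------------------------------------

parse_obo_terms <- function(path) {
  lines <- readLines(path, warn = FALSE)
  trimmed <- trimws(lines)
  starts <- which(trimmed == "[Term]")
  if (!length(starts)) stop("no [Term] stanzas found in ", path)
  headers <- which(startsWith(trimmed, "["))
  lapply(starts, function(s) {
    nxt <- headers[headers > s]
    e <- if (length(nxt)) nxt[1L] - 1L else length(lines)
    body <- trimmed[seq(s + 1L, e)]
    id <- sub("^id:\\s*", "", grep("^id:", body, value = TRUE))
    nm <- sub("^name:\\s*", "", grep("^name:", body, value = TRUE))
    isa <- sub("^is_a:\\s*", "", grep("^is_a:", body, value = TRUE))
    isa <- trimws(sub("\\s*!.*$", "", isa))          # strip trailing comment
    if (length(id) != 1L || !nzchar(id)) {
      stop("term stanza without a single id near line ", s, " of ", path)
    }
    list(id = id,
         name = if (length(nm)) nm[1L] else id,
         is_a = isa[nzchar(isa)])
  })
}

# Depth-first search for a cycle in the parent graph; returns the cycle as a
# vector of term ids (first == last) or NULL.
find_cycle <- function(parents) {
  state <- stats::setNames(integer(length(parents)), names(parents))
  path <- character(0)
  found <- NULL
  visit <- function(id) {
    if (!is.null(found)) return()
    if (state[[id]] == 1L) {
      i <- match(id, path)
      found <<- c(path[seq(i, length(path))], id)
      return()
    }
    if (state[[id]] == 2L) return()
    state[[id]] <<- 1L
    path <<- c(path, id)
    for (p in parents[[id]]) visit(p)
    path <<- path[-length(path)]
    state[[id]] <<- 2L
  }
  for (id in names(parents)) {
    visit(id)
    if (!is.null(found)) break
  }
  found
}

# Breadth-first walk up the DAG assigning each term the class of its nearest
# mapped root; ties at equal depth take the lexicographically first class.
resolve_root_classes <- function(parents, roots) {
  ids <- names(parents)
  cls <- character(length(ids))
  multi <- logical(length(ids))
  for (k in seq_along(ids)) {
    id <- ids[k]
    level <- id
    seen <- character(0)
    reached <- character(0)     # classes of all reachable mapped roots
    nearest <- NA_character_
    while (length(level)) {
      hit <- intersect(level, names(roots))
      if (length(hit)) {
        if (is.na(nearest)) nearest <- sort(unique(unname(roots[hit])))[1L]
        reached <- union(reached, unname(roots[hit]))
      }
      seen <- union(seen, level)
      level <- setdiff(unique(unlist(parents[level], use.names = FALSE)), seen)
    }
    cls[k] <- if (is.na(nearest)) "unresolved" else nearest
    multi[k] <- length(reached) > 1L
  }
  list(class = cls, multi = multi)
}
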