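#' Construct an ontology from terms and parent relations
#'
#' An ontology is a directed acyclic graph of terms with child-to-parent
#' edges. Flat vocabularies (pathway or domain term sets with no hierarchy)
#' are ontologies with zero edges: every term is a root.
#'
#' @param terms Character vector of term identifiers.
#' @param edges Data frame with columns `child`, `parent` and optionally
#'   `relation` (defaults to `"is_a"`). Both ends must appear in `terms`.
#' @return A `pl_ontology` object: list with elements `terms`, `edges`,
#'   `parents` (named list), `children`, `roots`, and `ancestors` (named
#'   list of all ancestors per term, excluding the term itself).
#' @examples
#' ont <- ontology(c("a", "b", "c"),
#'                 data.frame(child = c("b", "c"), parent = c("a", "b")))
#' ontology_ancestors(ont, "c")
#' @export
ontology <- function(terms, edges = NULL) {
  terms <- as.character(terms)
  if (anyDuplicated(terms)) abort("duplicate term identifiers")
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- tibble(child = character(), parent = character(),
                    relation = character())
  } else {
    edges <- as_tibble(edges)
    if (!"relation" %in% names(edges)) edges$relation <- "is_a"
    edges <- distinct(edges[, c("child", "parent", "relation")])
    edges$child <- as.character(edges$child)
    edges$parent <- as.character(edges$parent)
    bad <- setdiff(c(edges$child, edges$parent), terms)
    if (length(bad) > 0) {
      abort(sprintf("edge references unknown term(s): %s",
                    paste(head(bad, 5), collapse = ", ")))
    }
  }

  parents <- split(edges$parent, factor(edges$child, levels = terms))
  children <- split(edges$child, factor(edges$parent, levels = terms))

  ord <- topological_order(terms, parents)   # errors on a cycle, naming it
  ancestors <- vector("list", length(terms))
  names(ancestors) <- terms
  for (t in ord) {                           # parents before children
    ps <- parents[[t]]
    ancestors[[t]] <- unique(c(ps, unlist(ancestors[ps], use.names = FALSE)))
  }

  structure(
    list(terms = terms, edges = edges, parents = parents,
         children = children,
         roots = terms[lengths(parents) == 0L],
         ancestors = ancestors),
    class = "pl_ontology"
  )
}

# Kahn's algorithm over child->parent edges; emits parents before children.
topological_order <- function(terms, parents) {
  n_unresolved <- lengths(parents)
  names(n_unresolved) <- terms
  children_of <- new.env(parent = emptyenv())
  for (t in terms) {
    for (p in parents[[t]]) {
      children_of[[p]] <- c(children_of[[p]], t)
    }
  }
  queue <- terms[n_unresolved == 0L]
  out <- character(0)
  while (length(queue) > 0) {
    t <- queue[[1]]
    queue <- queue[-1]
    out <- c(out, t)
    for (ch in children_of[[t]]) {
      n_unresolved[[ch]] <- n_unresolved[[ch]] - 1L
      if (n_unresolved[[ch]] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < length(terms)) {
    cyc <- find_cycle(terms[!terms %in% out], parents)
    abort(sprintf("ontology graph is cyclic: %s", paste(cyc, collapse = " -> ")))
  }
  out
}

# Walk parent pointers from an unresolved term until a repeat is seen.
find_cycle <- function(candidates, parents) {
  start <- candidates[[1]]
  path <- start
  cur <- start
  repeat {
    nxt <- intersect(parents[[cur]], candidates)[1]
    if (is.na(nxt)) return(path)
    if (nxt %in% path) {
      i <- match(nxt, path)
      return(c(path[i:length(path)], nxt))
    }
    path <- c(path, nxt)
    cur <- nxt
  }
}

#' @export
print.pl_ontology <- function(x, ...) {
  cat(sprintf("# Ontology: %d terms, %d edges, %d root(s)\n",
              length(x$terms), nrow(x$edges), length(x$roots)))
  invisible(x)
}

#' All ancestors of a term
#'
#' @param ont A `pl_ontology`.
#' @param term A term identifier.
#' @param include_self Include the term itself (a term is conventionally its
#'   own ancestor in common-ancestor computations)? Default `FALSE`.
#' @return Character vector of ancestor term IDs.
#' @export
ontology_ancestors <- function(ont, term, include_self = FALSE) {
  if (!term %in% ont$terms) abort(sprintf("unknown term '%s'", term))
  anc <- ont$ancestors[[term]]
  if (include_self) unique(c(term, anc)) else anc
}

#' Read an OBO 1.2 flat file
#'
#' Parses `[Term]` stanzas. Obsolete terms are excluded. Only the configured
#' relation types become edges (default `is_a` and `part_of`); all other
#' relationships are ignored. A parent reference to an unknown term or a
#' cyclic graph is a hard error.
#'
#' @param path Path to an OBO file.
#' @param relations Relation types to keep as child-to-parent edges.
#' @return A [ontology()] object.
#' @export
read_obo <- function(path, relations = c("is_a", "part_of")) {
  lines <- readLines(path, warn = FALSE)
  in_term <- FALSE
  cur <- NULL
  terms <- character(0)
  obsolete <- character(0)
  edge_child <- character(0)
  edge_parent <- character(0)
  edge_rel <- character(0)

  flush_term <- function() {
    if (is.null(cur) || is.null(cur$id)) return()
    if (isTRUE(cur$obsolete)) {
      obsolete <<- c(obsolete, cur$id)
      return()
    }
    terms <<- c(terms, cur$id)
    if (length(cur$parents) > 0) {
      edge_child <<- c(edge_child, rep(cur$id, length(cur$parents)))
      edge_parent <<- c(edge_parent, cur$parents)
      edge_rel <<- c(edge_rel, cur$relations)
    }
  }

  for (raw in lines) {
    line <- sub("!.*$", "", raw)          # strip trailing OBO comments
    line <- trimws(line)
    if (line == "") next
    if (startsWith(line, "[")) {
      flush_term()
      in_term <- identical(line, "[Term]")
      cur <- if (in_term) list(parents = character(0), relations = character(0))
      next
    }
    if (!in_term) next
    if (startsWith(line, "id:")) {
      cur$id <- trimws(sub("^id:", "", line))
    } else if (startsWith(line, "is_obsolete:")) {
      cur$obsolete <- grepl("true", line, fixed = TRUE)
    } else if (startsWith(line, "is_a:")) {
      if ("is_a" %in% relations) {
        cur$parents <- c(cur$parents, trimws(sub("^is_a:", "", line)))
        cur$relations <- c(cur$relations, "is_a")
      }
    } else if (startsWith(line, "relationship:")) {
      parts <- strsplit(trimws(sub("^relationship:", "", line)), "[[:space:]]+")[[1]]
      if (length(parts) >= 2 && parts[[1]] %in% relations) {
        cur$parents <- c(cur$parents, parts[[2]])
        cur$relations <- c(cur$relations, parts[[1]])
      }
    }
  }
  flush_term()

  # Drop edges pointing at obsolete parents, then validate the remainder.
  keep <- !edge_parent %in% obsolete
  edge_child <- edge_child[keep]
  edge_parent <- edge_parent[keep]
  edge_rel <- edge_rel[keep]
  unknown <- setdiff(edge_parent, terms)
  if (length(unknown) > 0) {
    abort(sprintf("OBO file references unknown parent term(s): %s",
                  paste(head(unknown, 5), collapse = ", ")))
  }
  ontology(terms, tibble(child = edge_child, parent = edge_parent,
                         relation = edge_rel))
}
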