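# Independent oracles and small generators shared across tests.

# Random DAG: term i >= 2 draws 1-3 parents among terms 1..(i-1), so every
# term reaches a root by construction and the graph is acyclic.
random_dag <- function(n_terms, max_parents = 3) {
  terms <- sprintf("t%02d", seq_len(n_terms))
  child <- character(0)
  parent <- character(0)
  for (i in 2:n_terms) {
    np <- sample.int(min(i - 1, max_parents), 1)
    ps <- sample.int(i - 1, np)
    child <- c(child, rep(terms[[i]], np))
    parent <- c(parent, terms[ps])
  }
  ontology(terms, data.frame(child = child, parent = parent))
}

# Random annotations: each gene gets 1-3 random terms.
random_annotations <- function(ont, n_genes) {
  genes <- sprintf("G%02d", seq_len(n_genes))
  rows <- lapply(genes, function(g) sample(ont$terms, sample.int(3, 1)))
  dplyr::distinct(tibble::tibble(gene = rep(genes, lengths(rows)),
                                 term = unlist(rows)))
}

# Exhaustive enumeration of every directed path (node sequences, both
# endpoints included) from `from` up to `to`.
all_paths <- function(ont, from, to) {
  if (from == to) return(list(from))
  out <- list()
  for (p in ont$parents[[from]]) {
    for (tail in all_paths(ont, p, to)) {
      out[[length(out) + 1]] <- c(from, tail)
    }
  }
  out
}

# Brute-force disjunctive common ancestors: greedy decreasing-IC acceptance,
# but the path-avoidance check enumerates every path explicitly instead of
# searching the reduced graph.
oracle_dca <- function(t1, t2, ont, ic) {
  anc1 <- unique(c(t1, ont$ancestors[[t1]]))
  anc2 <- unique(c(t2, ont$ancestors[[t2]]))
  ca <- intersect(anc1, anc2)
  if (length(ca) == 0) return(character(0))
  icv <- stats::setNames(ic$ic, ic$term)
  vals <- icv[ca]
  vals[is.na(vals)] <- 0
  ca <- ca[order(-vals, ca, method = "radix")]
  accepted <- character(0)
  for (a in ca) {
    ok <- length(accepted) == 0 ||
      (any(vapply(all_paths(ont, t1, a),
                  function(p) !any(p %in% accepted), TRUE)) &&
       any(vapply(all_paths(ont, t2, a),
                  function(p) !any(p %in% accepted), TRUE)))
    if (ok) accepted <- c(accepted, a)
  }
  accepted
}

oracle_resnik <- function(t1, t2, ont, ic) {
  dca <- oracle_dca(t1, t2, ont, ic)
  icv <- stats::setNames(ic$ic, ic$term)
  vals <- icv[dca]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) 0 else mean(vals)
}

# A tiny deterministic ontology + IC table used by several similarity tests:
# root r with children a, b (IC crafted by hand where tests need exact
# values).
toy_diamond <- function() {
  ontology(c("a", "b", "c", "x", "y"),
           data.frame(child = c("b", "c", "x", "x", "y", "y"),
                      parent = c("a", "a", "b", "c", "b", "c")))
}
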