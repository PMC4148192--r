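# Resnik similarity over disjunctive common ancestors (the GraSM refinement):
# rather than scoring a term pair by the IC of its single most informative
# common ancestor, the non-redundant "interpretations" of the pair are
# collected and their ICs averaged. Ancestors are visited in decreasing IC
# order; an ancestor is accepted iff, from each query term, some directed
# path to it avoids every already-accepted ancestor (it represents shared
# meaning not already captured). The most informative common ancestor is
# always accepted. IC ties are broken lexicographically by term ID so the
# procedure is deterministic.

#' Disjunctive common ancestors of two terms
#'
#' @param t1,t2 Term identifiers (a term counts as its own ancestor).
#' @param ont A [ontology()].
#' @param ic IC table from [information_content()]. Terms without an IC entry
#'   rank lowest (IC treated as 0) in the acceptance order.
#' @return Character vector of accepted ancestor terms; empty if the terms
#'   share no ancestor.
#' @export
disjunctive_common_ancestors <- function(t1, t2, ont, ic) {
  ca <- intersect(ontology_ancestors(ont, t1, include_self = TRUE),
                  ontology_ancestors(ont, t2, include_self = TRUE))
  if (length(ca) == 0) return(character(0))
  icv <- ic_vector(ic)
  ca_ic <- icv[ca]
  ca_ic[is.na(ca_ic)] <- 0
  ca <- ca[order(-ca_ic, ca, method = "radix")]

  accepted <- character(0)
  for (a in ca) {
    if (length(accepted) == 0 ||
        (path_avoiding(ont, t1, a, accepted) &&
         path_avoiding(ont, t2, a, accepted))) {
      accepted <- c(accepted, a)
    }
  }
  accepted
}

# Is there a directed path from `from` up to `to` whose nodes (including
# both endpoints) all avoid `blocked`? Depth-first search over parent edges
# with blocked nodes removed.
path_avoiding <- function(ont, from, to, blocked) {
  if (from %in% blocked) return(FALSE)
  if (from == to) return(TRUE)
  stack <- from
  seen <- from
  while (length(stack) > 0) {
    cur <- stack[[length(stack)]]
    stack <- stack[-length(stack)]
    for (p in ont$parents[[cur]]) {
      if (p %in% blocked || p %in% seen) next
      if (p == to) return(TRUE)
      seen <- c(seen, p)
      stack <- c(stack, p)
    }
  }
  FALSE
}

#' Resnik term similarity with disjunctive common ancestors
#'
#' The similarity of two ontology terms is the mean IC of their disjunctive
#' common ancestors. Ancestors without an IC entry are dropped from the
#' average; if no ancestor with an IC remains (or the terms share no
#' ancestor) the similarity is 0. `resnik_grasm(t, t)` equals `IC(t)`.
#'
#' @inheritParams disjunctive_common_ancestors
#' @return A non-negative number on the IC scale.
#' @export
resnik_grasm <- function(t1, t2, ont, ic) {
  dca <- disjunctive_common_ancestors(t1, t2, ont, ic)
  if (length(dca) == 0) return(0)
  icv <- ic_vector(ic)
  vals <- icv[dca]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) return(0)
  mean(vals)
}

#' Pairwise term-similarity matrix
#'
#' @param terms Terms to score (defaults to all IC-bearing terms).
#' @inheritParams disjunctive_common_ancestors
#' @return A symmetric numeric matrix with `terms` as dimnames.
#' @export
term_similarity_matrix <- function(ont, ic, terms = ic$term) {
  terms <- unique(terms)
  k <- length(terms)
  m <- matrix(0, k, k, dimnames = list(terms, terms))
  for (i in seq_len(k)) {
    for (j in i:k) {
      s <- resnik_grasm(terms[[i]], terms[[j]], ont, ic)
      m[i, j] <- s
      m[j, i] <- s
    }
  }
  m
}

#' Semantic similarity of two genes from their annotation term sets
#'
#' Compares the term sets `T1`, `T2` annotated to the two genes. `max` takes
#' the largest pairwise term similarity over `T1 x T2`. `bma` (best match
#' average) takes, for each term, the best match in the other gene's set and
#' averages all those best matches with equal weight per term (pooled over
#' both directions, so `|T1| + |T2|` values enter the mean).
#'
#' A gene with no annotation has *undefined* similarity: the result is `NA`,
#' never 0, so unannotated genes can be excluded from benchmarks rather than
#' deflating them.
#'
#' @param g1,g2 Gene identifiers.
#' @param ann Annotation tibble (`gene`, `term`).
#' @param ont A [ontology()].
#' @param ic IC table from [information_content()].
#' @param method `"bma"` or `"max"`.
#' @return A non-negative number, or `NA` if either gene is unannotated.
#' @export
gene_similarity <- function(g1, g2, ann, ont, ic, method = c("bma", "max")) {
  method <- match.arg(method)
  out <- gene_pair_similarity(tibble(gene_a = g1, gene_b = g2),
                              ann, ont, ic, method = method)
  out$sim[[1]]
}

#' Direct-match similarity for flat vocabularies
#'
#' For annotation vocabularies without a deep hierarchy (pathway or domain
#' term sets), only exact shared terms count: the similarity is the maximum
#' IC over terms annotated to both genes, 0 if they share none, and `NA` if
#' either gene is unannotated.
#'
#' @inheritParams gene_similarity
#' @param ic IC table computed with `information_content(ann, ont = NULL)`.
#' @return A non-negative number or `NA`.
#' @export
gene_similarity_flat <- function(g1, g2, ann, ic) {
  out <- gene_pair_similarity(tibble(gene_a = g1, gene_b = g2),
                              ann, ont = NULL, ic, method = "flat")
  out$sim[[1]]
}

#' Vectorised gene-pair semantic similarity
#'
#' Scores many gene pairs at once, sharing one term-similarity computation
#' across pairs. This is the workhorse behind [gene_similarity()],
#' [annotation_links()] and benchmark construction.
#'
#' @param pairs Data frame with columns `gene_a`, `gene_b`.
#' @param ann Annotation tibble (`gene`, `term`).
#' @param ont A [ontology()], or `NULL` with `method = "flat"`.
#' @param ic IC table.
#' @param method `"bma"`, `"max"`, or `"flat"` (direct matches only).
#' @return `pairs` as a tibble with an added `sim` column (`NA` where either
#'   gene is unannotated).
#' @export
gene_pair_similarity <- function(pairs, ann, ont, ic,
                                 method = c("bma", "max", "flat")) {
  method <- match.arg(method)
  pairs <- as_tibble(pairs)
  stopifnot(all(c("gene_a", "gene_b") %in% names(pairs)))
  term_sets <- split(ann$term, ann$gene)
  icv <- ic_vector(ic)

  if (method == "flat") {
    sims <- purrr::map2_dbl(pairs$gene_a, pairs$gene_b, function(g1, g2) {
      t1 <- term_sets[[g1]]
      t2 <- term_sets[[g2]]
      if (is.null(t1) || is.null(t2)) return(NA_real_)
      shared <- intersect(t1, t2)
      vals <- icv[shared]
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0) 0 else max(vals)
    })
    pairs$sim <- sims
    return(pairs)
  }

  genes <- unique(c(pairs$gene_a, pairs$gene_b))
  used_terms <- unique(unlist(term_sets[intersect(genes, names(term_sets))],
                              use.names = FALSE))
  tsm <- term_similarity_matrix(ont, ic, terms = used_terms)

  sims <- purrr::map2_dbl(pairs$gene_a, pairs$gene_b, function(g1, g2) {
    t1 <- term_sets[[g1]]
    t2 <- term_sets[[g2]]
    if (is.null(t1) || is.null(t2)) return(NA_real_)
    s <- tsm[t1, t2, drop = FALSE]
    if (method == "max") {
      max(s)
    } else {
      mean(c(apply(s, 1, max), apply(s, 2, max)))
    }
  })
  pairs$sim <- sims
  pairs
}
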