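# Link derivation: turn raw evidence (expression matrices, interaction
# tables, annotation vocabularies, pre-scored pair lists) into scored,
# unordered gene-pair link sets.

#' Co-expression links from an expression matrix
#'
#' Scores every gene pair by the Pearson correlation of their expression
#' profiles over exactly the samples in which *both* genes are expressed
#' (non-missing and above `floor`), requiring at least `min_shared` such
#' samples -- pairs with fewer shared expressed samples are absent. Pairs
#' whose shared profile has zero variance are skipped and counted in the
#' `n_skipped` attribute.
#'
#' @param expr Gene-by-sample matrix with rownames, or a data frame whose
#'   first column holds gene IDs.
#' @param min_shared Minimum number of samples where both genes are
#'   expressed; the default 10 mirrors requiring at least ten tissues.
#' @param floor Expression presence threshold: a gene is expressed in a
#'   sample when its value is non-missing and strictly greater than `floor`.
#' @param source Source label for the resulting link set.
#' @return A raw-scored [links()] set; scores lie in `[-1, 1]`.
#' @export
coexpression_links <- function(expr, min_shared = 10, floor = 0,
                               source = "coexpression") {
  if (min_shared < 2) abort("min_shared must be at least 2")
  if (is.data.frame(expr)) {
    m <- as.matrix(expr[, -1, drop = FALSE])
    rownames(m) <- as.character(expr[[1]])
  } else {
    m <- as.matrix(expr)
  }
  if (is.null(rownames(m))) abort("expression matrix needs gene IDs as rownames")
  if (anyDuplicated(rownames(m))) abort("duplicate gene IDs in expression matrix")
  if (ncol(m) < 2) abort("expression matrix needs at least 2 samples")
  storage.mode(m) <- "double"

  masked <- m
  masked[!(is.finite(m) & m > floor)] <- NA   # below-floor values don't count

  expressed <- !is.na(masked)
  shared <- tcrossprod(expressed * 1)         # pairwise shared-sample counts
  suppressWarnings(
    r <- stats::cor(t(masked), use = "pairwise.complete.obs")
  )

  idx <- which(upper.tri(shared) & shared >= min_shared, arr.ind = TRUE)
  score <- r[idx]
  ok <- is.finite(score)                      # NA = zero-variance profile
  n_skipped <- sum(!ok)
  if (n_skipped > 0) {
    inform(sprintf("coexpression_links: skipped %d pair(s) with zero-variance shared profile",
                   n_skipped))
  }
  g <- rownames(m)
  new_links(tibble(gene_a = g[idx[ok, 1]], gene_b = g[idx[ok, 2]],
                   score = score[ok]),
            source, "raw", extra_attrs = list(n_skipped = n_skipped))
}

#' Direct physical-interaction links, scored by benchmark assay medians
#'
#' Physical interactions are binary evidence: every pair from one assay type
#' receives the same score, namely the median benchmark semantic similarity
#' over the assay's pairs for which both genes are benchmarked. Because this
#' score is already on the benchmark-similarity scale, the returned link
#' sets are marked `rescored` and skip the regression rescoring step. Assay
#' types with fewer than `min_benchmarked` benchmarked pairs are dropped
#' with a warning.
#'
#' @param interactions Data frame with columns `gene_a`, `gene_b`, `assay`.
#' @param bench_sim Pair-similarity tibble (`gene_a`, `gene_b`, `sim`) from
#'   [gene_pair_similarity()] on the benchmark annotations; pairs with `NA`
#'   similarity do not count as benchmarked.
#' @param min_benchmarked Minimum benchmarked pairs per assay.
#' @param source Prefix for the per-assay source labels.
#' @return A named list of [links()] sets, one per retained assay. A pair
#'   occurring in several assays keeps each assay's score until integration.
#' @export
ppi_direct_links <- function(interactions, bench_sim, min_benchmarked = 100,
                             source = "ppi") {
  tab <- as_tibble(interactions)
  stopifnot(all(c("gene_a", "gene_b", "assay") %in% names(tab)))
  tab <- canonicalise_pairs(mutate(tab, gene_a = as.character(.data$gene_a),
                                   gene_b = as.character(.data$gene_b)))
  tab <- filter(tab, .data$gene_a != .data$gene_b)
  bench <- filter(as_pair_sims(bench_sim), !is.na(.data$sim))

  out <- list()
  for (a in unique(tab$assay)) {
    pairs_a <- distinct(filter(tab, .data$assay == a)[, c("gene_a", "gene_b")])
    scored <- dplyr::inner_join(pairs_a, bench, by = c("gene_a", "gene_b"))
    if (nrow(scored) < min_benchmarked) {
      warn(sprintf("ppi_direct_links: assay '%s' dropped (%d benchmarked pair(s) < %d)",
                   a, nrow(scored), min_benchmarked))
      next
    }
    med <- median(scored$sim)
    out[[a]] <- new_links(mutate(pairs_a, score = med),
                          paste0(source, ":", a), "rescored",
                          extra_attrs = list(assay = a,
                                             n_benchmarked = nrow(scored)))
  }
  out
}

#' Indirect interaction links from shared partners
#'
#' For gene pairs that do not interact directly, the raw score is the
#' Jaccard index of their interaction-partner sets. Pairs with fewer than
#' `min_shared_partners` shared partners are absent. The output is raw
#' evidence and must pass through benchmark evaluation and rescoring like
#' any other source.
#'
#' @param interactions Data frame with columns `gene_a`, `gene_b` (an
#'   `assay` column, if present, is ignored: partners pool over assays).
#' @param min_shared_partners Minimum number of shared partners.
#' @param source Source label.
#' @return A raw-scored [links()] set with scores in `[0, 1]`.
#' @export
ppi_indirect_links <- function(interactions, min_shared_partners = 1,
                               source = "ppi_indirect") {
  tab <- as_tibble(interactions)
  stopifnot(all(c("gene_a", "gene_b") %in% names(tab)))
  tab <- canonicalise_pairs(mutate(tab, gene_a = as.character(.data$gene_a),
                                   gene_b = as.character(.data$gene_b)))
  tab <- distinct(filter(tab, .data$gene_a != .data$gene_b)[, c("gene_a", "gene_b")])

  nbr <- split(c(tab$gene_b, tab$gene_a), c(tab$gene_a, tab$gene_b))
  nbr <- lapply(nbr, unique)

  # Candidate pairs: co-members of some partner's neighbourhood.
  cand <- purrr::map(nbr, function(v) {
    if (length(v) < 2) return(NULL)
    v <- sort(v)
    idx <- utils::combn(length(v), 2)
    tibble(gene_a = v[idx[1, ]], gene_b = v[idx[2, ]])
  })
  cand <- distinct(bind_rows(cand))
  if (nrow(cand) == 0) {
    return(new_links(tibble(gene_a = character(), gene_b = character(),
                            score = numeric()), source, "raw"))
  }
  # Direct interactors are excluded: these are *indirect* links.
  cand <- dplyr::anti_join(cand, tab, by = c("gene_a", "gene_b"))

  jac <- purrr::map2_dbl(cand$gene_a, cand$gene_b, function(g1, g2) {
    n1 <- nbr[[g1]]
    n2 <- nbr[[g2]]
    ns <- length(intersect(n1, n2))
    if (ns < min_shared_partners) return(NA_real_)
    ns / length(union(n1, n2))
  })
  keep <- !is.na(jac)
  new_links(tibble(gene_a = cand$gene_a[keep], gene_b = cand$gene_b[keep],
                   score = jac[keep]), source, "raw")
}

#' Links from annotation semantic similarity
#'
#' Scores all pairs of annotated genes by their semantic similarity
#' ([gene_pair_similarity()]), keeping pairs with defined similarity above
#' `floor`. An annotation vocabulary must not be scored against itself as
#' benchmark: passing the benchmark's source name errors unless explicitly
#' overridden.
#'
#' @param ann Annotation tibble (`gene`, `term`).
#' @param ont A [ontology()] (`NULL` for flat vocabularies).
#' @param ic IC table for `ann` (computed if missing).
#' @param method `"bma"`, `"max"`, or `"flat"`.
#' @param source Source label for this vocabulary.
#' @param benchmark_source Name of the benchmark annotation source, if any.
#' @param allow_self_benchmark Override the self-benchmarking guard.
#' @param floor Keep pairs with similarity strictly greater than this.
#' @return A raw-scored [links()] set.
#' @export
annotation_links <- function(ann, ont = NULL, ic = NULL,
                             method = c("bma", "max", "flat"),
                             source = "annotation",
                             benchmark_source = NULL,
                             allow_self_benchmark = FALSE,
                             floor = 0) {
  method <- match.arg(method)
  if (!is.null(benchmark_source) && identical(source, benchmark_source) &&
      !allow_self_benchmark) {
    abort(sprintf("source '%s' is the benchmark annotation source; refusing to self-benchmark (set allow_self_benchmark = TRUE to override)",
                  source))
  }
  if (is.null(ic)) ic <- information_content(ann, ont)
  genes <- sort(unique(ann$gene))
  if (length(genes) < 2) abort("need at least 2 annotated genes")
  idx <- utils::combn(length(genes), 2)
  pairs <- tibble(gene_a = genes[idx[1, ]], gene_b = genes[idx[2, ]])
  scored <- gene_pair_similarity(pairs, ann, ont, ic, method = method)
  keep <- !is.na(scored$sim) & scored$sim > floor
  new_links(tibble(gene_a = scored$gene_a[keep], gene_b = scored$gene_b[keep],
                   score = scored$sim[keep]), source, "raw")
}

#' Map gene identifiers through an ortholog table
#'
#' Applies a two-column mapping (`from`, `to`) to the genes of a pair table
#' before link derivation or evaluation. Pairs with an unmapped gene are
#' dropped and counted in a message; pairs that become self-pairs after
#' mapping are dropped too.
#'
#' @param pairs A [links()] set or any pair tibble.
#' @param map Data frame whose first two columns are source and target IDs.
#' @return The mapped object (same class as the input links, duplicate pairs
#'   collapsed keeping the maximum score).
#' @export
apply_orthologs <- function(pairs, map) {
  map <- as_tibble(map)
  from <- as.character(map[[1]])
  to <- as.character(map[[2]])
  lut <- to[!duplicated(from)]
  names(lut) <- from[!duplicated(from)]
  df <- as_pair_scores(pairs)
  a <- unname(lut[df$gene_a])
  b <- unname(lut[df$gene_b])
  ok <- !is.na(a) & !is.na(b)
  if (any(!ok)) {
    inform(sprintf("apply_orthologs: dropped %d pair(s) with unmapped gene(s)",
                   sum(!ok)))
  }
  new_links(tibble(gene_a = a[ok], gene_b = b[ok], score = df$score[ok]),
            link_source(pairs), score_kind(pairs))
}

# Normalise a benchmark similarity table to canonical pair order.
as_pair_sims <- function(x) {
  df <- as_tibble(x)
  stopifnot(all(c("gene_a", "gene_b", "sim") %in% names(df)))
  canonicalise_pairs(df[, c("gene_a", "gene_b", "sim")])
}
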