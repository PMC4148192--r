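# Gene-set clustering test. The statistic is the sum of integrated link
# weights among the genes of a set; significance comes from comparing it to
# the same statistic over randomized gene sets. Because long genes both
# accumulate more de novo mutations and sit in denser network neighbourhoods,
# a uniform null is anti-conservative for mutation-derived gene sets; the
# matched nulls draw, for each study gene, one gene from a pre-assigned list
# of candidates with the same or most similar CDS length (or node degree),
# removing that confounding.

#' Sum of link weights within a gene set
#'
#' @param net A `pl_network` (or pair tibble with `weight`).
#' @param genes Character vector of gene IDs (duplicates removed). Genes
#'   absent from the network are allowed and contribute nothing.
#' @return The summed weight over all within-set network edges.
#' @export
link_weight_sum <- function(net, genes) {
  genes <- unique(as.character(genes))
  if (length(genes) < 2) abort("gene set must contain at least 2 distinct genes")
  df <- as_tibble(net)
  w <- if ("weight" %in% names(df)) df$weight else df$score
  sum(w[df$gene_a %in% genes & df$gene_b %in% genes])
}

#' CDS-length-matched candidate list for one gene
#'
#' Returns the `k` genes whose longest-CDS length is the same as or most
#' similar to the query gene's, excluding the query itself. Distance ties
#' are broken by lexicographic gene ID, so the list is deterministic.
#'
#' @param lengths Tibble (`gene`, `cds_length`), longest CDS per gene.
#' @param gene Query gene ID.
#' @param k List size (default 100).
#' @return Character vector of `k` gene IDs, nearest first.
#' @export
cds_matched_candidates <- function(lengths, gene, k = 100) {
  i <- match(gene, lengths$gene)
  if (is.na(i)) abort(sprintf("gene absent from length table: %s", gene))
  if (nrow(lengths) - 1 < k) {
    abort(sprintf("k = %d exceeds the %d other genes in the length table",
                  k, nrow(lengths) - 1))
  }
  d <- abs(lengths$cds_length - lengths$cds_length[[i]])
  ord <- order(d, lengths$gene, method = "radix")   # C-locale, deterministic
  out <- lengths$gene[ord]
  out <- out[out != gene]
  out[seq_len(k)]
}

#' Degree-matched candidate list for one gene
#'
#' All genes whose network degree lies within `tolerance` of the query
#' gene's degree, excluding the query. An empty shell widens automatically
#' to the nearest non-empty one, with a warning.
#'
#' @param net A `pl_network`.
#' @param gene Query gene ID (must be in the network).
#' @param tolerance Allowed absolute degree difference (default 0).
#' @return Character vector of gene IDs, ordered by degree distance then ID.
#' @export
degree_matched_candidates <- function(net, gene, tolerance = 0) {
  deg <- if (inherits(net, "pl_adjacency")) net$degrees else node_degrees(net)
  i <- match(gene, deg$gene)
  if (is.na(i)) abort(sprintf("gene absent from network: %s", gene))
  d0 <- deg$degree[[i]]
  dist <- abs(deg$degree - d0)
  dist[i] <- NA   # exclude the query
  tol <- tolerance
  repeat {
    sel <- which(!is.na(dist) & dist <= tol)
    if (length(sel) > 0) break
    tol <- min(dist, na.rm = TRUE)   # nearest non-empty shell
  }
  if (tol > tolerance) {
    warn(sprintf("degree_matched_candidates: no gene within tolerance %d of degree %d for '%s'; widened to %d",
                 tolerance, d0, gene, tol))
  }
  sel <- sel[order(dist[sel], deg$gene[sel], method = "radix")]
  deg$gene[sel]
}

#' Draw one randomized gene set from candidate lists
#'
#' Selects one gene uniformly from each candidate list. If the draw contains
#' duplicates, the colliding positions are redrawn up to `max_retries`
#' times; a still-colliding draw is accepted with a warning and returned
#' de-duplicated.
#'
#' @param candidate_lists List of character vectors, one per study gene.
#' @param seed Optional RNG seed for a reproducible draw.
#' @param max_retries Bounded redraw attempts for duplicate resolution.
#' @return A character vector (a set: no duplicates).
#' @export
sample_null_set <- function(candidate_lists, seed = NULL, max_retries = 10) {
  draw <- function() {
    g <- vapply(candidate_lists,
                function(v) v[[sample.int(length(v), 1)]], "")
    for (r in seq_len(max_retries)) {
      dup <- which(duplicated(g))
      if (length(dup) == 0) return(g)
      for (j in dup) {
        v <- candidate_lists[[j]]
        g[[j]] <- v[[sample.int(length(v), 1)]]
      }
    }
    if (anyDuplicated(g)) {
      warn("sample_null_set: duplicates remained after bounded retries; returning de-duplicated set")
    }
    g
  }
  g <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  unique(g)
}

#' Permutation test for functional clustering of a gene set
#'
#' Computes the observed sum of link weights `S` among the study genes and
#' compares it to `n_rand` randomized gene sets. `null_kind` selects how the
#' random sets are assembled:
#' \describe{
#'   \item{`"cds"`}{for each study gene, a list of `k` genes with the same
#'     or most similar CDS length is assembled, and each random set picks
#'     one gene per list -- matching the confounding effect of
#'     coding-sequence length on both mutation rate and connectivity.}
#'   \item{`"degree"`}{as above with node-degree-matched lists.}
#'   \item{`"uniform"`}{size-matched uniform draws from the network's genes.}
#' }
#' The empirical p-value uses the add-one estimator
#' `p = (1 + #\{null >= S\}) / (1 + n_rand)` (ties count against the study
#' set), so it is never 0; the fold change is `S / median(null)`.
#'
#' @param net A `pl_network`, or a prebuilt [network_adjacency()] when many
#'   tests run against the same network.
#' @param genes Study gene set (duplicates removed; genes missing from the
#'   network contribute 0 to `S`).
#' @param null_kind `"cds"`, `"degree"`, or `"uniform"`.
#' @param n_rand Number of random sets (default 100000).
#' @param lengths CDS-length tibble, required for `null_kind = "cds"`; must
#'   cover every study gene.
#' @param k Candidate-list size for the cds null (default 100).
#' @param tolerance Degree tolerance for the degree null.
#' @param seed Optional RNG seed.
#' @param max_retries Bounded redraws for duplicate genes within one random
#'   set; unresolved draws are kept and scored on their distinct genes.
#' @param keep_null Keep the full null vector in the result?
#' @return A `pl_cluster_test` object; `glance()` gives the one-row summary
#'   (statistic, p_value, fold_change, ...), `tidy()` the null-distribution
#'   quantiles.
#' @export
cluster_test <- function(net, genes,
                         null_kind = c("cds", "degree", "uniform"),
                         n_rand = 100000, lengths = NULL, k = 100,
                         tolerance = 0, seed = NULL, max_retries = 10,
                         keep_null = TRUE) {
  null_kind <- match.arg(null_kind)
  genes <- unique(as.character(genes))
  if (length(genes) < 2) abort("gene set must contain at least 2 distinct genes")
  if (n_rand < 1) abort("n_rand must be positive")

  adj <- if (inherits(net, "pl_adjacency")) net else network_adjacency(net)
  S <- set_stat(adj, match(genes, adj$nodes))

  cand <- NULL
  if (null_kind == "cds") {
    if (is.null(lengths)) abort("null_kind = 'cds' requires a length table")
    missing <- setdiff(genes, lengths$gene)
    if (length(missing) > 0) {
      abort(sprintf("missing CDS length for gene(s): %s",
                    paste(missing, collapse = ", ")))
    }
    cand <- lapply(genes, function(g) cds_matched_candidates(lengths, g, k))
  } else if (null_kind == "degree") {
    missing <- setdiff(genes, adj$nodes)
    if (length(missing) > 0) {
      abort(sprintf("gene(s) absent from network for degree matching: %s",
                    paste(missing, collapse = ", ")))
    }
    cand <- lapply(genes, function(g) degree_matched_candidates(adj, g, tolerance))
  }

  run <- function() {
    if (null_kind == "uniform") {
      draw_uniform_null(adj, length(genes), n_rand)
    } else {
      draw_matched_null(adj, cand, n_rand, max_retries)
    }
  }
  res <- if (is.null(seed)) run() else withr::with_seed(seed, run())

  null_stats <- res$stats
  p <- (1 + sum(null_stats >= S)) / (1 + n_rand)
  null_median <- median(null_stats)

  structure(
    list(statistic = S,
         p_value = p,
         fold_change = S / null_median,
         null_kind = null_kind,
         n_rand = n_rand,
         set_size = length(genes),
         n_in_network = sum(genes %in% adj$nodes),
         null_median = null_median,
         null_quantiles = quantile(null_stats, c(0.025, 0.25, 0.5, 0.75, 0.975)),
         n_dup_accepted = res$n_dup_accepted,
         seed = seed,
         genes = genes,
         null = if (keep_null) null_stats),
    class = "pl_cluster_test"
  )
}

# --- internal machinery -----------------------------------------------------

#' Precompute a reusable adjacency structure for cluster tests
#'
#' [cluster_test()] accepts the result in place of the network, which
#' avoids rebuilding the adjacency when many gene sets are tested against
#' the same network.
#'
#' @param net A `pl_network` (or pair tibble with `weight`).
#' @param dense_limit Use a dense matrix up to this many nodes, neighbour
#'   lists beyond.
#' @return A `pl_adjacency` object.
#' @export
network_adjacency <- function(net, dense_limit = 4000) {
  df <- as_tibble(net)
  w <- if ("weight" %in% names(df)) df$weight else df$score
  nodes <- sort(unique(c(df$gene_a, df$gene_b)))
  n <- length(nodes)
  ia <- match(df$gene_a, nodes)
  ib <- match(df$gene_b, nodes)
  deg <- tabulate(c(ia, ib), nbins = n)
  degrees <- tibble(gene = nodes, degree = deg)
  out <- if (n <= dense_limit) {
    A <- matrix(0, n + 1L, n + 1L)
    A[cbind(ia, ib)] <- w
    A[cbind(ib, ia)] <- w
    list(kind = "dense", nodes = nodes, pad = n + 1L, A = A,
         degrees = degrees)
  } else {
    nbr <- vector("list", n + 1L)
    wts <- vector("list", n + 1L)
    ord <- order(c(ia, ib))
    from <- c(ia, ib)[ord]
    to <- c(ib, ia)[ord]
    ww <- c(w, w)[ord]
    split_to <- split(to, from)
    split_w <- split(ww, from)
    idx <- as.integer(names(split_to))
    nbr[idx] <- split_to
    wts[idx] <- split_w
    list(kind = "list", nodes = nodes, pad = n + 1L, nbr = nbr, wts = wts,
         degrees = degrees)
  }
  structure(out, class = "pl_adjacency")
}

# Sum of within-set weights; idx may contain NA (genes outside the network)
# and duplicates (ignored).
set_stat <- function(adj, idx) {
  idx[is.na(idx)] <- adj$pad
  u <- unique(idx)
  if (adj$kind == "dense") {
    sum(adj$A[u, u]) / 2
  } else {
    member <- logical(adj$pad)
    member[u] <- TRUE
    s <- 0
    for (g in u) {
      nb <- adj$nbr[[g]]
      if (length(nb) > 0) s <- s + sum(adj$wts[[g]][member[nb]])
    }
    s / 2
  }
}

draw_uniform_null <- function(adj, m, n_rand) {
  n <- length(adj$nodes)
  if (m > n) abort("set size exceeds number of network genes")
  stats <- numeric(n_rand)
  for (i in seq_len(n_rand)) {
    stats[[i]] <- set_stat(adj, sample.int(n, m))
  }
  list(stats = stats, n_dup_accepted = 0L)
}

draw_matched_null <- function(adj, cand, n_rand, max_retries) {
  m <- length(cand)
  # universe ids for duplicate detection (candidate genes need not be in the
  # network); adjacency index per universe id, pad for absentees
  universe <- unique(unlist(cand, use.names = FALSE))
  cand_uid <- lapply(cand, function(v) match(v, universe))
  uid_adj <- match(universe, adj$nodes)
  uid_adj[is.na(uid_adj)] <- adj$pad

  G <- matrix(0L, n_rand, m)
  for (j in seq_len(m)) {
    v <- cand_uid[[j]]
    G[, j] <- v[sample.int(length(v), n_rand, replace = TRUE)]
  }

  n_dup_accepted <- 0L
  stats <- numeric(n_rand)
  for (i in seq_len(n_rand)) {
    u <- G[i, ]
    if (anyDuplicated(u)) {
      for (r in seq_len(max_retries)) {
        dup <- which(duplicated(u))
        if (length(dup) == 0) break
        for (j in dup) {
          v <- cand_uid[[j]]
          u[[j]] <- v[[sample.int(length(v), 1)]]
        }
      }
      if (anyDuplicated(u)) n_dup_accepted <- n_dup_accepted + 1L
    }
    stats[[i]] <- set_stat(adj, uid_adj[unique(u)])
  }
  if (n_dup_accepted > 0) {
    warn(sprintf("cluster_test: %d null set(s) kept duplicate genes after bounded retries (scored on distinct genes)",
                 n_dup_accepted))
  }
  list(stats = stats, n_dup_accepted = n_dup_accepted)
}

#' @export
print.pl_cluster_test <- function(x, ...) {
  cat(sprintf("# Gene-set clustering test (%s null, %d randomizations)\n",
              x$null_kind, x$n_rand))
  cat(sprintf("#   set: %d genes (%d in network)\n", x$set_size, x$n_in_network))
  cat(sprintf("#   S = %.4g, null median = %.4g, fold change = %.3g\n",
              x$statistic, x$null_median, x$fold_change))
  cat(sprintf("#   empirical p = %.4g\n", x$p_value))
  invisible(x)
}

#' Tidy and glance methods for cluster tests
#'
#' `glance()` returns the one-row test summary; `tidy()` the null
#' distribution quantiles.
#'
#' @param x A `pl_cluster_test`.
#' @param ... Unused.
#' @return A tibble.
#' @export
glance.pl_cluster_test <- function(x, ...) {
  tibble(set_size = x$set_size, n_in_network = x$n_in_network,
         statistic = x$statistic, null_median = x$null_median,
         fold_change = x$fold_change, p_value = x$p_value,
         null_kind = x$null_kind, n_rand = x$n_rand,
         seed = x$seed %||% NA_integer_)
}

#' @rdname glance.pl_cluster_test
#' @export
tidy.pl_cluster_test <- function(x, ...) {
  tibble(quantile = names(x$null_quantiles),
         null_statistic = unname(x$null_quantiles))
}

#' Plot a cluster-test null distribution
#'
#' Histogram of the null statistics with the observed sum of link weights
#' marked.
#'
#' @param object A `pl_cluster_test` computed with `keep_null = TRUE`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pl_cluster_test <- function(object, ...) {
  if (is.null(object$null)) {
    abort("autoplot needs the null vector; rerun cluster_test(keep_null = TRUE)")
  }
  ggplot2::ggplot(tibble(null = object$null), ggplot2::aes(x = .data$null)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey60") +
    ggplot2::geom_vline(xintercept = object$statistic, colour = "red") +
    ggplot2::labs(
      x = "sum of link weights (null sets)", y = "count",
      title = sprintf("%s null: S = %.3g, p = %.3g, fold = %.2f",
                      object$null_kind, object$statistic, object$p_value,
                      object$fold_change)
    ) +
    ggplot2::theme_minimal()
}
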