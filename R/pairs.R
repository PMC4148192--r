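# Unordered gene pairs are stored canonically with gene_a < gene_b
# (lexicographic), one row per pair. Every link-producing function funnels
# through new_links() so the invariants (no self pairs, unique pairs,
# deterministic row order) hold everywhere.

canonicalise_pairs <- function(df) {
  swap <- df$gene_a > df$gene_b
  if (any(swap)) {
    tmp <- df$gene_a[swap]
    df$gene_a[swap] <- df$gene_b[swap]
    df$gene_b[swap] <- tmp
  }
  df
}

#' Construct a link set
#'
#' A link set is a tibble of scored, unordered gene pairs from one evidence
#' source. Pairs are canonicalised (`gene_a < gene_b`), self pairs are
#' dropped, and duplicate pairs are collapsed keeping the maximum score --
#' the most confident record wins within a source.
#'
#' @param pairs A data frame with columns `gene_a`, `gene_b`, `score`.
#' @param source Name of the evidence source.
#' @param score_kind `"raw"` (data-specific scale) or `"rescored"`
#'   (benchmark semantic-similarity scale; must be non-negative).
#' @return A `pl_links` tibble with attributes `source` and `score_kind`.
#' @examples
#' links(data.frame(gene_a = c("b", "a"), gene_b = c("a", "b"),
#'                  score = c(1, 2)), source = "demo")
#' @export
links <- function(pairs, source = "unknown", score_kind = c("raw", "rescored")) {
  score_kind <- match.arg(score_kind)
  new_links(pairs, source, score_kind)
}

new_links <- function(pairs, source, score_kind, extra_attrs = list()) {
  stopifnot(all(c("gene_a", "gene_b", "score") %in% names(pairs)))
  df <- as_tibble(pairs)[, c("gene_a", "gene_b", "score")]
  df$gene_a <- as.character(df$gene_a)
  df$gene_b <- as.character(df$gene_b)
  df$score <- as.numeric(df$score)

  n_self <- sum(df$gene_a == df$gene_b)
  if (n_self > 0) {
    inform(sprintf("links(%s): dropped %d self pair(s)", source, n_self))
    df <- df[df$gene_a != df$gene_b, ]
  }
  df <- canonicalise_pairs(df)
  if (anyDuplicated(df[c("gene_a", "gene_b")])) {
    df <- df |>
      group_by(.data$gene_a, .data$gene_b) |>
      summarise(score = max(.data$score), .groups = "drop")
  }
  if (score_kind == "rescored" && nrow(df) > 0 && any(df$score < 0)) {
    abort("rescored link sets must have non-negative scores")
  }
  df <- arrange(df, .data$gene_a, .data$gene_b)
  attr(df, "source") <- source
  attr(df, "score_kind") <- score_kind
  for (nm in names(extra_attrs)) attr(df, nm) <- extra_attrs[[nm]]
  class(df) <- c("pl_links", class(tibble()))
  df
}

#' @export
print.pl_links <- function(x, ...) {
  cat(sprintf("# Link set '%s' (%s scores): %d pairs\n",
              link_source(x), score_kind(x), nrow(x)))
  NextMethod()
}

#' Source name and score kind of a link set
#' @param x A `pl_links` object.
#' @return A length-one character vector.
#' @export
link_source <- function(x) attr(x, "source") %||% "unknown"

#' @rdname link_source
#' @export
score_kind <- function(x) attr(x, "score_kind") %||% "raw"

# Coerce any pair-shaped table (links, network, plain tibble) to a canonical
# pair tibble with a `score` column; networks contribute their edge weight.
as_pair_scores <- function(x) {
  df <- as_tibble(x)
  if (!"score" %in% names(df) && "weight" %in% names(df)) {
    df <- rename(df, score = "weight")
  }
  stopifnot(all(c("gene_a", "gene_b", "score") %in% names(df)))
  canonicalise_pairs(df[, c("gene_a", "gene_b", "score")])
}
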