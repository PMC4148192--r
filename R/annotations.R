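#' Read a gene-to-term annotation table
#'
#' Expects a TSV with two columns, `gene<TAB>term`, one direct annotation per
#' line; lines starting with `#` are comments. Annotations are stored
#' unpropagated; ancestor propagation happens when information content is
#' computed.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `gene` and `term`, one row per direct
#'   annotation, duplicates removed.
#' @export
read_annotations <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) return(tibble(gene = character(), term = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (identical(parts[[1]][1:2], c("gene", "term"))) parts <- parts[-1]
  if (length(parts) == 0) {
    return(tibble(gene = character(), term = character()))
  }
  bad <- which(lengths(parts) < 2)
  if (length(bad) > 0) {
    abort(sprintf("malformed annotation line %d: expected gene<TAB>term", bad[[1]]))
  }
  distinct(tibble(gene = vapply(parts, `[[`, "", 1),
                  term = vapply(parts, `[[`, "", 2)))
}

#' Read annotations from a GAF 2.x file
#'
#' Convenience reader for Gene Association Format: takes the gene symbol
#' (column 2... configurable) and term ID (column 5), keeping only rows whose
#' evidence code (column 7) is in `evidence`. Rows with a `NOT` qualifier are
#' dropped.
#'
#' @param path Path to a GAF file (uncompressed).
#' @param evidence Evidence codes to keep; defaults to the experimentally
#'   grounded set IDA, IMP, TAS, IC.
#' @param gene_column Column holding the gene identifier (2 = DB object ID,
#'   3 = symbol).
#' @return A tibble with columns `gene` and `term`.
#' @export
read_gaf <- function(path, evidence = c("IDA", "IMP", "TAS", "IC"),
                     gene_column = 2) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^!", lines) & nzchar(lines)]
  if (length(lines) == 0) return(tibble(gene = character(), term = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(parts) >= 7
  parts <- parts[ok]
  qualifier <- vapply(parts, `[[`, "", 4)
  code <- vapply(parts, `[[`, "", 7)
  keep <- code %in% evidence & !grepl("\\bNOT\\b", qualifier)
  distinct(tibble(gene = vapply(parts[keep], `[[`, "", gene_column),
                  term = vapply(parts[keep], `[[`, "", 5)))
}

#' Information content of annotation terms
#'
#' The information content of a term `a` is `-log p(a)`, where `p(a)` is the
#' proportion of genes annotated with `a` *or any of its descendant terms*
#' among all genes carrying at least one annotation. Terms that annotate no
#' gene (directly or via descendants) get no entry. For a flat vocabulary
#' (ontology with no edges, or `ont = NULL`) propagation is a no-op and
#' `p(a)` is the fraction of genes directly annotated with `a`.
#'
#' @param ann Annotation tibble with columns `gene`, `term`.
#' @param ont A [ontology()], or `NULL` for a flat vocabulary.
#' @param log_base Base of the logarithm; the default natural log yields IC
#'   in nats, and every downstream similarity inherits this scale.
#' @return A tibble with columns `term`, `n_genes` (genes covered by the term
#'   or its descendants), and `ic`.
#' @examples
#' ann <- tibble::tibble(gene = letters[1:8], term = c("t1", rep("t2", 7)))
#' information_content(ann)   # IC(t1) = -log(1/8)
#' @export
information_content <- function(ann, ont = NULL, log_base = exp(1)) {
  stopifnot(all(c("gene", "term") %in% names(ann)))
  ann <- distinct(as_tibble(ann)[, c("gene", "term")])
  if (nrow(ann) == 0) abort("empty annotation universe: no annotated genes")
  if (!is.null(ont)) {
    unknown <- setdiff(ann$term, ont$terms)
    if (length(unknown) > 0) {
      abort(sprintf("annotation uses term(s) absent from the ontology: %s",
                    paste(head(unknown, 5), collapse = ", ")))
    }
  }
  n_universe <- length(unique(ann$gene))

  if (is.null(ont) || nrow(ont$edges) == 0) {
    closed <- ann
  } else {
    anc <- ont$ancestors[ann$term]
    closed <- tibble(
      gene = rep(ann$gene, lengths(anc) + 1L),
      term = unlist(purrr::map2(ann$term, anc, c), use.names = FALSE)
    )
    closed <- distinct(closed)
  }

  counts <- closed |>
    group_by(.data$term) |>
    summarise(n_genes = dplyr::n_distinct(.data$gene), .groups = "drop")
  counts |>
    mutate(ic = -log(.data$n_genes / n_universe) / log(log_base)) |>
    arrange(.data$term)
}

# Named IC vector for fast lookup.
ic_vector <- function(ic) {
  v <- ic$ic
  names(v) <- ic$term
  v
}
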