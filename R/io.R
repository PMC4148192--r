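# TSV round-tripping for every table the pipeline exchanges. All writers
# prepend `#`-comment headers recording provenance (source, parameters) so
# result files are auditable; all readers skip them.

#' Read a pre-scored gene-pair edge list
#'
#' Expects TSV lines `gene_a<TAB>gene_b<TAB>score`. Duplicate unordered
#' pairs collapse to their maximum score; self pairs are dropped with a
#' count. A malformed line is a hard error naming the line number. An empty
#' file yields an empty link set.
#'
#' @param path Path to the TSV file.
#' @param source Source label (defaults to the file name).
#' @param score_kind `"raw"` unless the file header says otherwise.
#' @return A [links()] set.
#' @export
read_scored_pairs <- function(path, source = NULL, score_kind = NULL) {
  lines <- readLines(path, warn = FALSE)
  header <- parse_comment_header(lines)
  lines_idx <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  source <- source %||% header[["source"]] %||% basename(path)
  score_kind <- score_kind %||% header[["score_kind"]] %||% "raw"
  if (length(lines_idx) == 0) {
    return(new_links(tibble(gene_a = character(), gene_b = character(),
                            score = numeric()), source, score_kind))
  }
  parts <- strsplit(lines[lines_idx], "\t", fixed = TRUE)
  if (identical(parts[[1]], c("gene_a", "gene_b", "score"))) {
    parts <- parts[-1]
    lines_idx <- lines_idx[-1]
    if (length(parts) == 0) {
      return(new_links(tibble(gene_a = character(), gene_b = character(),
                              score = numeric()), source, score_kind))
    }
  }
  bad <- which(lengths(parts) != 3)
  if (length(bad) > 0) {
    abort(sprintf("%s: malformed line %d (expected gene_a<TAB>gene_b<TAB>score)",
                  path, lines_idx[bad[[1]]]))
  }
  score <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3)))
  bad <- which(is.na(score))
  if (length(bad) > 0) {
    abort(sprintf("%s: non-numeric score on line %d", path, lines_idx[bad[[1]]]))
  }
  new_links(tibble(gene_a = vapply(parts, `[[`, "", 1),
                   gene_b = vapply(parts, `[[`, "", 2),
                   score = score),
            source, score_kind)
}

#' Write a link set (or network) as edge-list TSV
#'
#' @param x A [links()] set or [integrate_links()] network.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_links <- function(x, path) {
  hdr <- c(source = link_source(x), score_kind = score_kind(x))
  resc <- attr(x, "rescoring")
  if (!is.null(resc)) {
    hdr <- c(hdr, slope = format(resc$slope, digits = 15),
             intercept = format(resc$intercept, digits = 15),
             include = tolower(as.character(resc$include)))
  }
  df <- as_pair_scores(x)
  write_tsv_commented(df, path, hdr)
}

#' Write / read an integrated network as edge-list TSV
#'
#' The writer records the integration parameters (`D`, kernel, sources) in
#' the comment header; the reader restores them.
#'
#' @param net A network from [integrate_links()].
#' @param path File path.
#' @return `write_network`: `path`, invisibly. `read_network`: a
#'   `pl_network` tibble.
#' @export
write_network <- function(net, path) {
  hdr <- c(type = "pl_network",
           D = format(attr(net, "D") %||% NA),
           kernel = attr(net, "kernel") %||% "harmonic",
           sources = paste(attr(net, "sources") %||% character(0),
                           collapse = ","))
  df <- as_tibble(net)[, c("gene_a", "gene_b", "weight")]
  write_tsv_commented(df, path, hdr)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  lines <- readLines(path, warn = FALSE)
  header <- parse_comment_header(lines)
  df <- read_tsv_body(lines, c("gene_a", "gene_b", "weight"), path,
                      numeric_cols = "weight")
  new_network(df,
              D = suppressWarnings(as.numeric(header[["D"]] %||% NA)),
              kernel = header[["kernel"]] %||% "harmonic",
              sources = strsplit(header[["sources"]] %||% "", ",")[[1]])
}

#' Read a gene CDS-length table
#'
#' TSV `gene<TAB>length` with the longest CDS per gene, in base pairs.
#' Lengths must be positive integers; duplicate genes are an error.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `gene`, `cds_length`.
#' @export
read_lengths <- function(path) {
  lines <- readLines(path, warn = FALSE)
  df <- read_tsv_body(lines, c("gene", "cds_length"), path,
                      numeric_cols = "cds_length")
  if (anyDuplicated(df$gene)) {
    abort(sprintf("%s: duplicate gene in length table: %s", path,
                  df$gene[duplicated(df$gene)][[1]]))
  }
  if (any(df$cds_length <= 0)) abort(sprintf("%s: non-positive CDS length", path))
  df
}

#' @rdname read_lengths
#' @param lengths Tibble with columns `gene`, `cds_length`.
#' @export
write_lengths <- function(lengths, path) {
  write_tsv_commented(lengths[, c("gene", "cds_length")], path,
                      c(type = "cds_lengths"))
}

#' Read / write a gene set (one gene ID per line)
#'
#' @param path File path.
#' @return `read_gene_set`: character vector of unique gene IDs.
#' @export
read_gene_set <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  unique(lines[nzchar(lines) & !startsWith(lines, "#")])
}

#' @rdname read_gene_set
#' @param genes Character vector of gene IDs.
#' @export
write_gene_set <- function(genes, path) {
  writeLines(unique(as.character(genes)), path)
  invisible(path)
}

#' Read an expression matrix TSV
#'
#' First row: sample IDs (header); first column: gene IDs.
#'
#' @param path File path.
#' @return A numeric matrix, genes in rows.
#' @export
read_expression <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  storage.mode(m) <- "double"
  m
}

#' Read an interaction table TSV (`gene_a<TAB>gene_b<TAB>assay`)
#'
#' @param path File path.
#' @return A tibble with columns `gene_a`, `gene_b`, `assay`.
#' @export
read_interactions <- function(path) {
  lines <- readLines(path, warn = FALSE)
  read_tsv_body(lines, c("gene_a", "gene_b", "assay"), path)
}

# --- shared helpers ---------------------------------------------------------

parse_comment_header <- function(lines) {
  meta <- grep("^#\\s*[A-Za-z_.]+\\s*=", lines, value = TRUE)
  if (length(meta) == 0) return(list())
  kv <- sub("^#\\s*", "", meta)
  keys <- sub("\\s*=.*$", "", kv)
  vals <- sub("^[^=]*=\\s*", "", kv)
  stats::setNames(as.list(trimws(vals)), trimws(keys))
}

write_tsv_commented <- function(df, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header) > 0) {
    writeLines(sprintf("# %s = %s", names(header), unname(header)), con)
  }
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df) > 0) {
    cols <- lapply(df, function(col) {
      if (is.numeric(col)) format(col, digits = 15, trim = TRUE,
                                  scientific = FALSE) else as.character(col)
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

read_tsv_body <- function(lines, expected_cols, path, numeric_cols = character(0)) {
  idx <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(idx) == 0) {
    abort(sprintf("%s: empty file (no header row)", path))
  }
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  header <- parts[[1]]
  has_header <- all(expected_cols %in% header)
  if (has_header) {
    col_idx <- match(expected_cols, header)
    parts <- parts[-1]
    idx <- idx[-1]
  } else {
    if (length(header) < length(expected_cols)) {
      abort(sprintf("%s: expected columns %s", path,
                    paste(expected_cols, collapse = ", ")))
    }
    col_idx <- seq_along(expected_cols)
  }
  bad <- which(lengths(parts) < max(col_idx))
  if (length(bad) > 0) {
    abort(sprintf("%s: malformed line %d", path, idx[bad[[1]]]))
  }
  out <- lapply(seq_along(expected_cols), function(j) {
    vapply(parts, `[[`, "", col_idx[[j]])
  })
  names(out) <- expected_cols
  df <- as_tibble(out)
  for (nc in numeric_cols) {
    v <- suppressWarnings(as.numeric(df[[nc]]))
    bad <- which(is.na(v) & !is.na(df[[nc]]))
    if (length(bad) > 0) {
      abort(sprintf("%s: non-numeric value in column '%s', line %d",
                    path, nc, idx[bad[[1]]]))
    }
    df[[nc]] <- v
  }
  df
}
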