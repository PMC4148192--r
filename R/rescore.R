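# Benchmark evaluation and rescoring. An evidence source earns its place in
# the integrated network by demonstrating that its strongest links connect
# genes with similar benchmark phenotypes: pairs are ordered by raw score,
# cut into bins, and the bin-median benchmark similarity must rise with the
# bin-median raw score. Included sources are then mapped onto the benchmark
# similarity scale with an ordinary least-squares fit through the bin
# medians, so that every source's weights are commensurable.

#' Evaluate an evidence source against a phenotype benchmark
#'
#' Restricts the link set to pairs where both genes carry benchmark
#' annotations (pairs with undefined similarity are excluded, not scored 0),
#' orders pairs by raw score from largest to smallest (ties broken by pair
#' ID for determinism), cuts them into consecutive bins of `bin_size`, and
#' computes per-bin medians of raw score and benchmark similarity. The
#' source is included when the rank correlation between the two bin medians
#' is positive with one-sided p below `alpha`. The partial final bin is kept
#' in the bin table, flagged, and excluded from both the correlation and the
#' regression fit.
#'
#' @param ls A [links()] set (raw scores).
#' @param bench_sim Benchmark pair similarities: a tibble (`gene_a`,
#'   `gene_b`, `sim`) as produced by [gene_pair_similarity()] on the
#'   benchmark annotation set; `NA` similarities mark unbenchmarked pairs.
#' @param bin_size Pairs per bin (default 1000).
#' @param alpha One-sided significance level for inclusion.
#' @return A `pl_evaluation` object; see [tidy.pl_evaluation()] for the bin
#'   table and [glance.pl_evaluation()] for the one-row report (rank
#'   correlation `rho`, `p_value`, `include`, fitted `slope` and
#'   `intercept`).
#' @export
evaluate_links <- function(ls, bench_sim, bin_size = 1000, alpha = 0.05) {
  if (bin_size < 2) abort("bin_size must be at least 2")
  df <- as_pair_scores(ls)
  bench <- filter(as_pair_sims(bench_sim), !is.na(.data$sim))
  df <- dplyr::inner_join(df, bench, by = c("gene_a", "gene_b"))

  n_full <- nrow(df) %/% bin_size
  if (n_full < 2) {
    abort(sprintf("insufficient benchmark overlap: %d benchmarked pair(s) give %d full bin(s) of %d (need >= 2)",
                  nrow(df), n_full, bin_size))
  }

  df <- arrange(df, desc(.data$score), .data$gene_a, .data$gene_b)
  df$bin <- (seq_len(nrow(df)) - 1L) %/% bin_size + 1L

  bins <- df |>
    group_by(.data$bin) |>
    summarise(n = n(),
              score_median = median(.data$score),
              sim_median = median(.data$sim),
              .groups = "drop") |>
    mutate(full = .data$n == bin_size)

  fullb <- filter(bins, .data$full)
  ct <- suppressWarnings(
    cor.test(fullb$score_median, fullb$sim_median,
             method = "spearman", alternative = "greater", exact = FALSE)
  )
  rho <- unname(ct$estimate)
  p <- ct$p.value
  include <- is.finite(rho) && rho > 0 && p < alpha

  fit <- tryCatch(fit_rescoring(bins), error = function(e) NULL)

  structure(
    list(bins = bins,
         source = link_source(ls),
         n_pairs = nrow(as_tibble(ls)),
         n_benchmarked = nrow(df),
         bin_size = bin_size,
         alpha = alpha,
         rho = rho,
         p_value = p,
         include = include,
         slope = if (is.null(fit)) NA_real_ else fit[["slope"]],
         intercept = if (is.null(fit)) NA_real_ else fit[["intercept"]]),
    class = "pl_evaluation"
  )
}

#' Fit the linear rescoring map from a bin table
#'
#' Ordinary least squares of bin-median benchmark similarity on bin-median
#' raw score, over full bins only.
#'
#' @param bins A bin table (from [evaluate_links()], its `$bins`, or any
#'   tibble with `score_median`, `sim_median` and optionally `full`).
#' @return A `pl_rescoring` object: named list with `slope` and `intercept`.
#' @export
fit_rescoring <- function(bins) {
  if (inherits(bins, "pl_evaluation")) bins <- bins$bins
  bins <- as_tibble(bins)
  if ("full" %in% names(bins)) bins <- filter(bins, .data$full)
  if (nrow(bins) < 2) abort("need at least 2 full bins to fit a rescoring map")
  if (sd(bins$score_median) == 0) {
    abort("zero variance of bin score medians: cannot fit a rescoring map")
  }
  fit <- lm(sim_median ~ score_median, data = bins)
  structure(list(slope = unname(coef(fit)[[2]]),
                 intercept = unname(coef(fit)[[1]])),
            class = "pl_rescoring")
}

#' Rescore a link set onto the benchmark similarity scale
#'
#' Applies the fitted linear map to every pair in the source -- benchmarked
#' or not. Negative fitted values clamp to 0 and the pair is dropped: it
#' carries no evidence weight. An evaluation with `include = FALSE` refuses
#' to rescore (excluded sources must not reach integration) unless `force`.
#'
#' @param ls The raw [links()] set (same source as the evaluation).
#' @param map A `pl_evaluation` or `pl_rescoring` object, or a numeric
#'   vector `c(slope, intercept)`.
#' @param force Rescore even if the evaluation excluded the source.
#' @return A rescored [links()] set carrying a `rescoring` attribute
#'   (slope, intercept, include).
#' @export
rescore_links <- function(ls, map, force = FALSE) {
  include <- TRUE
  if (inherits(map, "pl_evaluation")) {
    include <- map$include
    if (!include && !force) {
      abort(sprintf("source '%s' was excluded by the benchmark evaluation (rho = %.3f, p = %.3g); not rescoring (use force = TRUE to override)",
                    map$source, map$rho, map$p_value))
    }
    map <- list(slope = map$slope, intercept = map$intercept)
  } else if (is.numeric(map)) {
    map <- list(slope = map[[1]], intercept = map[[2]])
  }
  if (!is.finite(map$slope) || !is.finite(map$intercept)) {
    abort("rescoring map has no finite slope/intercept")
  }
  df <- as_pair_scores(ls)
  df$score <- pmax(0, map$slope * df$score + map$intercept)
  df <- filter(df, .data$score > 0)
  new_links(df, link_source(ls), "rescored",
            extra_attrs = list(rescoring = list(slope = map$slope,
                                                intercept = map$intercept,
                                                include = include)))
}

#' @export
print.pl_evaluation <- function(x, ...) {
  cat(sprintf("# Benchmark evaluation of '%s'\n", x$source))
  cat(sprintf("#   %d pairs, %d benchmarked, %d bin(s) of %d\n",
              x$n_pairs, x$n_benchmarked, nrow(x$bins), x$bin_size))
  cat(sprintf("#   rank correlation rho = %.3f, one-sided p = %.3g -> %s\n",
              x$rho, x$p_value,
              if (x$include) "INCLUDE" else "exclude"))
  cat(sprintf("#   rescoring map: sim = %.4g * score + %.4g\n",
              x$slope, x$intercept))
  invisible(x)
}

#' Tidy and glance methods for benchmark evaluations
#'
#' `tidy()` returns the bin table (one row per bin: `bin`, `n`,
#' `score_median`, `sim_median`, `full`); `glance()` returns the one-row
#' evaluation report.
#'
#' @param x A `pl_evaluation` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pl_evaluation <- function(x, ...) x$bins

#' @rdname tidy.pl_evaluation
#' @export
glance.pl_evaluation <- function(x, ...) {
  tibble(source = x$source, n_pairs = x$n_pairs,
         n_benchmarked = x$n_benchmarked, bin_size = x$bin_size,
         n_bins = nrow(x$bins), rho = x$rho, p_value = x$p_value,
         include = x$include, slope = x$slope, intercept = x$intercept)
}

#' Plot a benchmark evaluation
#'
#' Bin-median benchmark similarity against bin-median raw score, with the
#' fitted rescoring line; the partial bin (if any) is hollow.
#'
#' @param object A `pl_evaluation` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pl_evaluation <- function(object, ...) {
  b <- object$bins
  ggplot2::ggplot(b, ggplot2::aes(x = .data$score_median,
                                  y = .data$sim_median)) +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         linetype = 2, colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(shape = .data$full), size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                guide = "none") +
    ggplot2::labs(
      x = "bin median raw score",
      y = "bin median benchmark similarity",
      title = sprintf("%s: rho = %.3f, p = %.2g (%s)", object$source,
                      object$rho, object$p_value,
                      if (object$include) "included" else "excluded")
    ) +
    ggplot2::theme_minimal()
}
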