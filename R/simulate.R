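# Synthetic data with the statistical structure the method assumes: a
# layered DAG ontology with module-structured annotations, noisy monotone
# evidence scores, log-normal CDS lengths optionally coupled to network
# connectivity, and study gene sets that are either length-biased (pure
# mutability confounding, no function) or drawn from a planted module.

#' Simulation configuration
#'
#' Bundles the knobs of the synthetic-data generators. Defaults describe the
#' regime the package's calibration experiments run in: a human-coding-
#' genome-scale universe of 18000 genes, log-normal CDS lengths around
#' 1.8 kb, a length-connectivity coupling `beta` of 0.5, a mean network
#' degree of 50 (full integrated functional networks are dense; top-N link
#' selections are a reporting-time thinning), a depth-5 branching-3
#' ontology with 20 annotation modules, and planted functional modules with
#' a complex-like internal edge density of 0.25.
#'
#' @param n_genes Number of genes in the universe.
#' @param n_modules Number of functional modules the annotated genes
#'   partition into ([simulate_ontology()]).
#' @param depth Ontology depth (number of layers, root included).
#' @param branching Ontology branching factor per layer.
#' @param noise_sd Gaussian noise sd added to evidence scores.
#' @param coverage Fraction of truth pairs an evidence source observes.
#' @param length_meanlog,length_sdlog Log-normal CDS-length parameters
#'   (natural-log scale; the defaults give a median near 1.8 kb).
#' @param beta Length-connectivity coupling: edge probability scales as
#'   `exp(beta * (z_i + z_j))` with `z` the standardized log CDS length.
#'   `beta = 0` decouples them.
#' @param effect_size Planted-module effect size: the absolute within-module
#'   edge probability (background edges this dense or denser are untouched).
#' @param mean_degree Target mean node degree of the simulated network.
#' @param weight_meanlog,weight_sdlog Log-normal parameters for edge weights.
#' @return A `pl_sim_config` list.
#' @export
sim_config <- function(n_genes = 18000, n_modules = 20, depth = 5,
                       branching = 3, noise_sd = 0.3, coverage = 1,
                       length_meanlog = 7.5, length_sdlog = 0.8,
                       beta = 0.5, effect_size = 0.25, mean_degree = 50,
                       weight_meanlog = log(0.5), weight_sdlog = 0.4) {
  stopifnot(n_genes >= 2, n_modules >= 1, depth >= 2, branching >= 2,
            noise_sd >= 0, mean_degree > 0)
  if (coverage < 0 || coverage > 1) abort("coverage must lie in [0, 1]")
  if (beta < 0) abort("beta must be >= 0")
  if (effect_size <= 0 || effect_size > 1) {
    abort("effect_size is a within-module edge probability; need 0 < effect_size <= 1")
  }
  structure(as.list(environment()), class = "pl_sim_config")
}

#' Simulate a layered ontology with module-structured annotations
#'
#' Builds a DAG of `depth` layers (layer 1 is the single root; layer `l` has
#' `branching^(l-1)` terms), each term with one backbone parent and, with
#' probability 0.3, a second random parent in the layer above. Genes are
#' partitioned into modules; genes of a module share its deep, high-IC leaf
#' terms and additionally carry one or two random shallow terms, so
#' same-module pairs have systematically higher semantic similarity.
#'
#' @param cfg A [sim_config()].
#' @param seed Optional RNG seed (fixed seed, identical output).
#' @return A list: `ontology` ([ontology()]), `annotations` (tibble `gene`,
#'   `term`), `modules` (tibble `gene`, `module`), `ic` (IC table).
#' @export
simulate_ontology <- function(cfg = sim_config(), seed = NULL) {
  run <- function() {
    layer_sizes <- cfg$branching^(seq_len(cfg$depth) - 1)
    total <- sum(layer_sizes)
    terms <- sprintf("T%04d", seq_len(total))
    layer_of <- rep(seq_len(cfg$depth), layer_sizes)
    offset <- cumsum(c(0, layer_sizes))

    child <- character(0)
    parent <- character(0)
    for (l in 2:cfg$depth) {
      ids <- offset[[l]] + seq_len(layer_sizes[[l]])
      above <- offset[[l - 1]] + seq_len(layer_sizes[[l - 1]])
      backbone <- above[((seq_along(ids) - 1) %/% cfg$branching) + 1]
      child <- c(child, terms[ids])
      parent <- c(parent, terms[backbone])
      # occasional multiple inheritance: a second parent in the layer above
      if (length(above) > 1) {
        extra <- which(runif(length(ids)) < 0.3)
        for (e in extra) {
          alt <- sample(setdiff(above, backbone[[e]]), 1)
          child <- c(child, terms[ids[[e]]])
          parent <- c(parent, terms[alt])
        }
      }
    }
    ont <- ontology(terms, tibble(child = child, parent = parent))

    genes <- sprintf("g%04d", seq_len(cfg$n_genes))
    module <- ((seq_len(cfg$n_genes) - 1) %% cfg$n_modules) + 1
    leaves <- terms[layer_of == cfg$depth]
    mids <- terms[layer_of >= 2 & layer_of < cfg$depth]
    # contiguous leaf pool per module (recycled if modules outnumber leaves)
    pool <- split(leaves, ((seq_along(leaves) - 1) %% cfg$n_modules) + 1)

    rows <- lapply(seq_len(cfg$n_genes), function(i) {
      p <- pool[[((module[[i]] - 1) %% length(pool)) + 1]]
      t_deep <- p[[1]]
      if (length(p) > 1 && runif(1) < 0.5) {
        t_deep <- c(t_deep, sample(p[-1], 1))
      }
      n_shallow <- sample(1:2, 1)
      c(t_deep, sample(mids, min(n_shallow, length(mids))))
    })
    ann <- distinct(tibble(gene = rep(genes, lengths(rows)),
                           term = unlist(rows, use.names = FALSE)))
    list(ontology = ont, annotations = ann,
         modules = tibble(gene = genes, module = module),
         ic = information_content(ann, ont))
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a noisy evidence source from true pair similarities
#'
#' Observes a random `coverage` fraction of the truth pairs and reports
#' `score = scale * sim + noise`, a noisy monotone transform on a hidden,
#' source-specific scale -- what a real data source provides before
#' benchmark evaluation recalibrates it.
#'
#' @param truth Tibble (`gene_a`, `gene_b`, `sim`) of true similarities.
#' @param cfg A [sim_config()] supplying `noise_sd` and `coverage`.
#' @param scale Hidden multiplicative scale; drawn from `U(0.5, 2)` if
#'   `NULL`.
#' @param source Source label.
#' @param seed Optional RNG seed.
#' @return A raw-scored [links()] set.
#' @export
simulate_evidence <- function(truth, cfg = sim_config(), scale = NULL,
                              source = "synthetic_evidence", seed = NULL) {
  truth <- as_pair_sims(truth)
  run <- function() {
    a <- scale %||% runif(1, 0.5, 2)
    keep <- runif(nrow(truth)) < cfg$coverage
    df <- truth[keep, ]
    new_links(tibble(gene_a = df$gene_a, gene_b = df$gene_b,
                     score = a * df$sim + rnorm(nrow(df), 0, cfg$noise_sd)),
              source, "raw")
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate CDS lengths and a length-coupled gene network
#'
#' CDS lengths are log-normal. An edge between genes `i` and `j` appears
#' with probability proportional to
#' `exp(beta * (z_i + z_j) - beta * (z_i - z_j)^2 / 2)` (with `z` the
#' standardized log length), scaled to hit the target mean degree. The first
#' factor makes long genes sit in denser neighbourhoods (length-degree
#' coupling); the second makes connected genes resemble each other in
#' length (length assortativity, the median-neighbour-length signature) --
#' a purely factorized kernel cannot produce assortativity because every
#' gene would draw neighbours from the same distribution. Both confounding
#' signatures vanish at `beta = 0`. Edge weights are log-normal and
#' independent of length.
#'
#' If `modules` are supplied, pairs of genes in the same module get edge
#' probability at least `effect_size` (an absolute, complex-like internal
#' density): planted functional structure. The modules table may cover only
#' a subset of the universe; uncovered genes carry no planted signal.
#'
#' Edges are sampled in blocks over the first pair index, so genome-scale
#' universes do not materialise all gene pairs at once.
#'
#' @param cfg A [sim_config()].
#' @param genes Gene identifiers of the universe; defaults to
#'   `sprintf("g%05d", 1:cfg$n_genes)`. Pass `modules$gene` (plus any extra
#'   genes) to align with a simulated ontology.
#' @param modules Optional tibble (`gene`, `module`).
#' @param seed Optional RNG seed.
#' @return A list: `lengths` (tibble `gene`, `cds_length`) and `network`
#'   (`pl_network`).
#' @export
simulate_lengths_and_network <- function(cfg = sim_config(), genes = NULL,
                                         modules = NULL, seed = NULL) {
  run <- function() {
    genes <- genes %||% sprintf("g%05d", seq_len(cfg$n_genes))
    n <- length(genes)
    len <- pmax(30, round(rlnorm(n, cfg$length_meanlog, cfg$length_sdlog)))
    z <- as.numeric(scale(log(len)))
    mod <- if (!is.null(modules)) {
      modules$module[match(genes, modules$gene)]
    }

    kernel_row <- function(i) {
      j <- seq.int(i + 1, n)
      exp(cfg$beta * ((z[[i]] + z[j]) - (z[[i]] - z[j])^2 / 2))
    }
    # first pass: normalisation for the target mean degree
    pair_sum <- 0
    for (i in seq_len(n - 1)) pair_sum <- pair_sum + sum(kernel_row(i))
    base_rate <- (n * cfg$mean_degree / 2) / pair_sum

    # second pass: sample the edges
    ei <- vector("list", n - 1)
    ej <- vector("list", n - 1)
    for (i in seq_len(n - 1)) {
      j <- seq.int(i + 1, n)
      p <- base_rate * kernel_row(i)
      if (!is.null(mod) && !is.na(mod[[i]])) {
        same <- !is.na(mod[j]) & mod[j] == mod[[i]]
        if (any(same)) p[same] <- pmax(p[same], cfg$effect_size)
      }
      hit <- which(runif(length(j)) < pmin(1, p))
      if (length(hit) > 0) {
        ei[[i]] <- rep.int(i, length(hit))
        ej[[i]] <- j[hit]
      }
    }
    i <- unlist(ei, use.names = FALSE)
    j <- unlist(ej, use.names = FALSE)
    w <- rlnorm(length(i), cfg$weight_meanlog, cfg$weight_sdlog)

    net <- new_network(tibble(gene_a = genes[i], gene_b = genes[j],
                              weight = w),
                       kernel = "synthetic", sources = "synthetic")
    list(lengths = tibble(gene = genes, cds_length = as.numeric(len)),
         network = net)
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Simulate a study gene set
#'
#' `length_biased_null` samples genes with probability proportional to CDS
#' length and no functional structure -- the mutability confound in pure
#' form, mimicking how passive de novo mutation targets long genes.
#' `planted_module` samples genes from one functional module, a set with
#' genuine internal clustering.
#'
#' @param lengths Tibble (`gene`, `cds_length`).
#' @param size Number of study genes.
#' @param mode `"length_biased_null"` or `"planted_module"`.
#' @param modules Required for `planted_module`: tibble (`gene`, `module`).
#' @param module Which module to sample from (default: the first).
#' @param seed Optional RNG seed.
#' @return Character vector of study gene IDs.
#' @export
simulate_study_genes <- function(lengths, size,
                                 mode = c("length_biased_null", "planted_module"),
                                 modules = NULL, module = NULL, seed = NULL) {
  mode <- match.arg(mode)
  run <- function() {
    if (mode == "length_biased_null") {
      sample(lengths$gene, size, prob = lengths$cds_length)
    } else {
      if (is.null(modules)) abort("planted_module mode requires a modules table")
      module <- module %||% modules$module[[1]]
      pool <- modules$gene[modules$module == module]
      if (length(pool) < size) {
        abort(sprintf("module %s has only %d gene(s), need %d",
                      format(module), length(pool), size))
      }
      sample(pool, size)
    }
  }
  if (is.null(seed)) run() else withr::with_seed(seed, run())
}

#' Write an ontology as an OBO 1.2 file
#'
#' @param ont A [ontology()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(ont, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (t in ont$terms) {
    writeLines(c("[Term]", paste0("id: ", t)), con)
    ps <- ont$parents[[t]]
    rels <- ont$edges$relation[ont$edges$child == t][match(ps, ont$edges$parent[ont$edges$child == t])]
    for (k in seq_along(ps)) {
      if (identical(rels[[k]], "is_a") || is.na(rels[[k]])) {
        writeLines(paste0("is_a: ", ps[[k]]), con)
      } else {
        writeLines(paste0("relationship: ", rels[[k]], " ", ps[[k]]), con)
      }
    }
    writeLines("", con)
  }
  invisible(path)
}

#' @rdname read_annotations
#' @param ann Annotation tibble (`gene`, `term`).
#' @export
write_annotations <- function(ann, path) {
  write_tsv_commented(ann[, c("gene", "term")], path, c(type = "annotations"))
}

#' Materialize a small demonstration workspace
#'
#' Generates a compact, fully self-consistent set of input files (ontology
#' OBO, annotation TSV, evidence edge lists, CDS lengths, network, study
#' gene set) that exercise the whole pipeline, and writes them to `dir`.
#'
#' @param dir Output directory (created if needed).
#' @param cfg A [sim_config()]; the default is scaled down for speed.
#' @param seed RNG seed (default 1).
#' @return Invisibly, a named list of the written file paths.
#' @export
write_fixtures <- function(dir,
                           cfg = sim_config(n_genes = 150, n_modules = 6,
                                            depth = 4, branching = 3,
                                            mean_degree = 8),
                           seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_ontology(cfg, seed = seed)
  lw <- simulate_lengths_and_network(cfg, genes = sim$modules$gene,
                                     modules = sim$modules, seed = seed + 1)
  genes <- sort(unique(sim$annotations$gene))
  idx <- utils::combn(length(genes), 2)
  truth <- gene_pair_similarity(
    tibble(gene_a = genes[idx[1, ]], gene_b = genes[idx[2, ]]),
    sim$annotations, sim$ontology, sim$ic, method = "bma")
  ev1 <- simulate_evidence(truth, sim_config(noise_sd = 0.3, coverage = 0.8),
                           source = "evidence_a", seed = seed + 2)
  ev2 <- simulate_evidence(truth, sim_config(noise_sd = 0.6, coverage = 0.6),
                           source = "evidence_b", seed = seed + 3)
  study <- simulate_study_genes(lw$lengths, 15, "planted_module",
                                modules = sim$modules, seed = seed + 4)

  paths <- list(
    ontology = file.path(dir, "ontology.obo"),
    annotations = file.path(dir, "annotations.tsv"),
    evidence_a = file.path(dir, "evidence_a.tsv"),
    evidence_b = file.path(dir, "evidence_b.tsv"),
    lengths = file.path(dir, "lengths.tsv"),
    network = file.path(dir, "network.tsv"),
    study_genes = file.path(dir, "study_genes.txt")
  )
  write_obo(sim$ontology, paths$ontology)
  write_annotations(sim$annotations, paths$annotations)
  write_links(ev1, paths$evidence_a)
  write_links(ev2, paths$evidence_b)
  write_lengths(lw$lengths, paths$lengths)
  write_network(lw$network, paths$network)
  write_gene_set(study, paths$study_genes)
  invisible(paths)
}
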