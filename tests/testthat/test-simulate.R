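small_cfg <- function(...) {
  sim_config(n_genes = 120, n_modules = 6, depth = 4, branching = 3,
             mean_degree = 8, ...)
}

test_that("simulated ontologies are layered with the requested shape", {
  tiny <- simulate_ontology(sim_config(n_genes = 10, n_modules = 2,
                                       depth = 2, branching = 2), seed = 1)
  expect_equal(length(tiny$ontology$terms), 3)   # 1 root + 2 leaves
  expect_equal(length(tiny$ontology$roots), 1)

  sim <- simulate_ontology(small_cfg(), seed = 2)
  expect_equal(length(sim$ontology$terms), 1 + 3 + 9 + 27)
  # IC spectrum spans >= 3 nats
  expect_gte(max(sim$ic$ic), 3)
  expect_equal(min(sim$ic$ic), 0)
})

test_that("same-module gene pairs are more similar than cross-module pairs", {
  sim <- simulate_ontology(small_cfg(), seed = 3)
  mods <- sim$modules
  withr::local_seed(4)
  pick_pair <- function(same) {
    repeat {
      g <- sample(mods$gene, 2)
      m <- mods$module[match(g, mods$gene)]
      if ((m[1] == m[2]) == same) return(g)
    }
  }
  n <- 100
  pairs <- rbind(
    t(replicate(n, pick_pair(TRUE))),
    t(replicate(n, pick_pair(FALSE)))
  )
  sims <- gene_pair_similarity(
    tibble::tibble(gene_a = pairs[, 1], gene_b = pairs[, 2]),
    sim$annotations, sim$ontology, sim$ic, method = "bma")$sim
  expect_gt(mean(sims[1:n]), mean(sims[(n + 1):(2 * n)]))
})

test_that("generators are deterministic under a fixed seed", {
  a <- simulate_ontology(small_cfg(), seed = 5)
  b <- simulate_ontology(small_cfg(), seed = 5)
  expect_equal(a$ontology$edges, b$ontology$edges)
  expect_equal(a$annotations, b$annotations)

  la <- simulate_lengths_and_network(small_cfg(), seed = 6)
  lb <- simulate_lengths_and_network(small_cfg(), seed = 6)
  expect_equal(la$lengths, lb$lengths)
  expect_equal(as.data.frame(la$network), as.data.frame(lb$network))
})

test_that("evidence sources observe a binomial share of the truth", {
  truth <- tibble::tibble(gene_a = sprintf("a%04d", 1:1000),
                          gene_b = sprintf("b%04d", 1:1000),
                          sim = stats::rexp(1000))
  ev <- simulate_evidence(truth, sim_config(coverage = 0.5, noise_sd = 0.1),
                          seed = 7)
  expect_gt(nrow(ev), 500 - 3 * sqrt(250))
  expect_lt(nrow(ev), 500 + 3 * sqrt(250))
  # vanishing noise: scores are an affine transform of the truth
  ev0 <- simulate_evidence(truth, sim_config(coverage = 1, noise_sd = 1e-9),
                           seed = 8)
  j <- dplyr::inner_join(as_tibble(ev0), truth, by = c("gene_a", "gene_b"))
  expect_gt(stats::cor(j$score, j$sim), 0.9999)
})

test_that("length-connectivity coupling appears iff beta > 0", {
  uncoupled <- simulate_lengths_and_network(
    sim_config(n_genes = 2000, beta = 0, mean_degree = 50), seed = 9)
  deg <- dplyr::left_join(node_degrees(uncoupled$network), uncoupled$lengths,
                          by = "gene")
  rho0 <- stats::cor(deg$degree, deg$cds_length, method = "spearman")
  expect_lt(abs(rho0), 0.05)

  coupled <- simulate_lengths_and_network(
    sim_config(n_genes = 2000, beta = 0.5, mean_degree = 50), seed = 10)
  degc <- dplyr::left_join(node_degrees(coupled$network), coupled$lengths,
                           by = "gene")
  rhoc <- stats::cor(degc$degree, degc$cds_length, method = "spearman")
  expect_gt(rhoc, 0.2)

  # length assortativity: a gene's length correlates with the median length
  # of its network neighbours
  len <- stats::setNames(coupled$lengths$cds_length, coupled$lengths$gene)
  edges <- as_tibble(coupled$network)
  nbr_len <- tibble::tibble(gene = c(edges$gene_a, edges$gene_b),
                            other = c(len[edges$gene_b], len[edges$gene_a])) |>
    dplyr::group_by(gene) |>
    dplyr::summarise(med = median(other), .groups = "drop")
  rho_assort <- stats::cor(len[nbr_len$gene], nbr_len$med, method = "spearman")
  expect_gt(rho_assort, 0.2)
})

test_that("planted modules are denser than background", {
  mods <- tibble::tibble(gene = sprintf("g%05d", 1:40),
                         module = rep(1:2, each = 20))
  lw <- simulate_lengths_and_network(
    sim_config(n_genes = 400, mean_degree = 10, effect_size = 0.3),
    modules = mods, seed = 11)
  S_mod <- link_weight_sum(lw$network, mods$gene[mods$module == 1])
  # uniform null median for 20-gene sets
  withr::local_seed(12)
  null <- replicate(200, link_weight_sum(lw$network,
                                         sample(lw$lengths$gene, 20)))
  expect_gt(S_mod, median(null))
})

test_that("length-biased study sets are longer than the universe", {
  lw <- simulate_lengths_and_network(sim_config(n_genes = 2000), seed = 13)
  study <- simulate_study_genes(lw$lengths, 50, "length_biased_null",
                                seed = 14)
  wt <- stats::wilcox.test(
    lw$lengths$cds_length[lw$lengths$gene %in% study],
    lw$lengths$cds_length, alternative = "greater")
  expect_lt(wt$p.value, 0.01)

  # equal lengths degenerate to uniform sampling (and still work)
  flat <- tibble::tibble(gene = sprintf("g%03d", 1:100), cds_length = 500)
  s <- simulate_study_genes(flat, 10, "length_biased_null", seed = 15)
  expect_equal(length(s), 10)
})

test_that("degenerate configurations surface the pipeline's error paths", {
  sim <- simulate_ontology(small_cfg(), seed = 16)
  # unannotated gene -> undefined similarity
  expect_true(is.na(gene_similarity("not_a_gene", sim$modules$gene[[1]],
                                    sim$annotations, sim$ontology, sim$ic)))
  # missing lengths -> cluster_test error listing the gene
  lw <- simulate_lengths_and_network(small_cfg(), seed = 17)
  short_lengths <- lw$lengths[-1, ]
  expect_error(
    cluster_test(lw$network, c(lw$lengths$gene[[1]], lw$lengths$gene[[2]],
                               lw$lengths$gene[[3]]),
                 "cds", n_rand = 10, lengths = short_lengths, k = 10),
    lw$lengths$gene[[1]]
  )
  # insufficient benchmark overlap -> evaluate error
  truth <- tibble::tibble(gene_a = "x", gene_b = "y", sim = 1)
  tiny_ls <- links(data.frame(gene_a = "x", gene_b = "y", score = 1), "s")
  expect_error(evaluate_links(tiny_ls, truth, bin_size = 1000),
               "insufficient")
})
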