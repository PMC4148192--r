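test_that("link sets canonicalise pairs, drop self pairs, collapse duplicates", {
  suppressMessages(
    ls <- links(data.frame(gene_a = c("b", "a", "c", "c"),
                           gene_b = c("a", "b", "c", "d"),
                           score = c(1, 2, 3, 4)), source = "demo")
  )
  expect_equal(nrow(ls), 2)                       # (a,b) collapsed, (c,c) out
  expect_equal(ls$score[ls$gene_a == "a"], 2)     # max kept
  expect_true(all(ls$gene_a < ls$gene_b))
})

test_that("deriving links from shuffled input yields an identical link set", {
  withr::local_seed(3)
  df <- data.frame(gene_a = sample(letters, 50, TRUE),
                   gene_b = sample(LETTERS, 50, TRUE),
                   score = runif(50))
  a <- links(df, "s")
  b <- links(df[sample(nrow(df)), ], "s")
  expect_equal(as.data.frame(a), as.data.frame(b))
})

test_that("co-expression uses shared expressed samples with a minimum of ten", {
  withr::local_seed(1)
  m <- rbind(
    g1 = c(1:12),
    g2 = c(1:12) * 2,                         # identical profile shape
    g3 = c(1:9, NA, NA, NA),                  # only 9 shared with anyone
    g4 = c(2 * (1:12) + rnorm(12, 0, 0.01))   # nearly linear in g1
  )
  rownames(m) <- c("g1", "g2", "g3", "g4")
  ls <- coexpression_links(m)
  df <- as.data.frame(ls)
  expect_equal(df$score[df$gene_a == "g1" & df$gene_b == "g2"], 1.0)
  expect_false(any(df$gene_a == "g3" | df$gene_b == "g3"))
  expect_gt(df$score[df$gene_a == "g1" & df$gene_b == "g4"], 0.99)
  expect_true(all(df$score >= -1 & df$score <= 1))
})

test_that("below-floor values do not count as expressed", {
  m <- rbind(g1 = c(rep(5, 9), 0, 0, 0),   # only 9 samples above floor 0
             g2 = rep(3, 12))
  ls <- suppressMessages(coexpression_links(m, min_shared = 10))
  expect_equal(nrow(ls), 0)
})

test_that("zero-variance shared profiles are skipped and counted", {
  m <- rbind(g1 = rep(5, 12), g2 = 1:12)
  expect_message(ls <- coexpression_links(m, min_shared = 10),
                 "zero-variance")
  expect_equal(nrow(ls), 0)
  expect_equal(attr(ls, "n_skipped"), 1)
})

test_that("direct PPI links take the per-assay benchmark median", {
  tab <- tibble::tibble(
    gene_a = c("a", "b", "c", "p", "q", "p"),
    gene_b = c("b", "c", "d", "q", "r", "r"),
    assay = c(rep("y2h", 3), rep("coip", 3))
  )
  bench <- tibble::tibble(gene_a = c("a", "b", "c", "p", "q", "p"),
                          gene_b = c("b", "c", "d", "q", "r", "r"),
                          sim = c(0, 1, 2, 3, 5, 4))
  out <- ppi_direct_links(tab, bench, min_benchmarked = 3)
  expect_named(out, c("y2h", "coip"))
  expect_true(all(out$y2h$score == 1))   # median of 0,1,2
  expect_true(all(out$coip$score == 4))  # median of 3,4,5
  expect_equal(score_kind(out$y2h), "rescored")
  # a pair in two assays keeps both candidate scores until integration
  tab2 <- dplyr::bind_rows(tab, tibble::tibble(gene_a = "a", gene_b = "b",
                                               assay = "coip"))
  out2 <- ppi_direct_links(tab2, bench, min_benchmarked = 3)
  s <- c(out2$y2h$score[out2$y2h$gene_a == "a"],
         out2$coip$score[out2$coip$gene_a == "a"])
  expect_equal(sort(s), c(1, 3.5))
})

test_that("assays below the benchmark-coverage floor are dropped with a warning", {
  tab <- tibble::tibble(gene_a = c("a", "x"), gene_b = c("b", "y"),
                        assay = c("big", "tiny"))
  bench <- tibble::tibble(gene_a = "a", gene_b = "b", sim = 1)
  expect_warning(out <- ppi_direct_links(tab, bench, min_benchmarked = 1),
                 "tiny")
  expect_named(out, "big")
})

test_that("indirect PPI links score shared partners by Jaccard", {
  # g1 and g2 both interact with a and b (and not each other)
  tab <- tibble::tibble(
    gene_a = c("g1", "g1", "g2", "g2", "g3", "g4"),
    gene_b = c("a", "b", "a", "b", "c", "d"),
    assay = "y2h"
  )
  ls <- ppi_indirect_links(tab)
  df <- as.data.frame(ls)
  expect_equal(df$score[df$gene_a == "g1" & df$gene_b == "g2"], 1.0)
  expect_false(any(df$gene_a == "g3" & df$gene_b == "g4"))  # disjoint partners
  expect_true(all(df$score > 0 & df$score <= 1))
  expect_equal(score_kind(ls), "raw")
})

test_that("indirect PPI Jaccard arithmetic: {a,b,c} vs {b,c,d} -> 0.5", {
  tab <- tibble::tibble(
    gene_a = c("g1", "g1", "g1", "g2", "g2", "g2"),
    gene_b = c("a", "b", "c", "b", "c", "d")
  )
  df <- as.data.frame(ppi_indirect_links(tab))
  expect_equal(df$score[df$gene_a == "g1" & df$gene_b == "g2"], 0.5)
})

test_that("annotation links refuse to self-benchmark and score shared terms", {
  ann <- tibble::tibble(gene = c("g1", "g2", "g3"),
                        term = c("k1", "k1", "k2"))
  expect_error(
    annotation_links(ann, method = "flat", source = "mouse_phenotypes",
                     benchmark_source = "mouse_phenotypes"),
    "self-benchmark"
  )
  ls <- annotation_links(ann, method = "flat", source = "pathways",
                         benchmark_source = "mouse_phenotypes")
  df <- as.data.frame(ls)
  # only g1-g2 share the (rare) term k1: IC = -log(2/3)
  expect_equal(nrow(df), 1)
  expect_equal(df$score, -log(2 / 3))
})

test_that("annotation links match a hand-computed flat similarity matrix", {
  ann <- tibble::tibble(
    gene = c("g1", "g1", "g2", "g2", "g3", "g4", "g4"),
    term = c("k1", "k2", "k2", "k3", "k3", "k1", "k3")
  )
  ic <- information_content(ann)           # N = 4 genes
  icv <- stats::setNames(ic$ic, ic$term)
  ls <- annotation_links(ann, ic = ic, method = "flat", source = "v")
  df <- as.data.frame(ls)
  get <- function(a, b) {
    r <- df[df$gene_a == a & df$gene_b == b, "score"]
    if (length(r) == 0) 0 else r
  }
  expect_equal(get("g1", "g2"), icv[["k2"]])
  expect_equal(get("g2", "g3"), icv[["k3"]])
  expect_equal(get("g1", "g4"), icv[["k1"]])
  expect_equal(get("g2", "g4"), icv[["k3"]])
  expect_equal(get("g1", "g3"), 0)   # disjoint -> absent
})

test_that("ortholog mapping renames genes and drops unmapped pairs", {
  ls <- links(data.frame(gene_a = c("h1", "h2"), gene_b = c("h2", "h3"),
                         score = c(1, 2)), "s")
  map <- data.frame(human = c("h1", "h2"), mouse = c("m1", "m2"))
  suppressMessages(out <- apply_orthologs(ls, map))
  expect_equal(nrow(out), 1)
  expect_equal(out$gene_a, "m1")
  expect_equal(out$gene_b, "m2")
})
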