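---
title: "Phenotypic-linkage networks and confounder-matched clustering tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotypic-linkage networks and confounder-matched clustering tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plnet)
library(dplyr)
```

## The problem

Gene sets derived from sequencing studies — for instance genes hit by de
novo variants in affected children — are routinely tested for *functional
clustering*: do these genes sit closer together in a functional gene
network than random genes would? Two methodological gaps undermine naive
versions of this test.

First, the functional network itself. Heterogeneous evidence sources
(co-expression, physical interactions, annotation similarity, literature
scores) arrive on incomparable scales and with very different reliability.
Summing or averaging them naively lets noisy sources dilute reliable ones.

Second, the null model. The chance that a gene acquires a de novo mutation
grows roughly in proportion to its coding-sequence (CDS) length, and long
genes are also better studied and better connected in functional networks.
A study gene set assembled from mutations is therefore length-biased, and a
uniform random null compares it against shorter, less connected genes — the
test rejects even when the study set carries no functional signal at all.

`plnet` implements both halves of the remedy: evidence integration
calibrated against a phenotype-ontology benchmark, and permutation nulls
matched on the confounder (CDS length or node degree).

## Semantic similarity as the common currency

All annotation evidence is expressed as *semantic similarity* between
genes. Each ontology term `a` has an information content

$$\mathrm{IC}(a) = -\log p(a),$$

where `p(a)` is the proportion of genes annotated with `a` *or any of its
descendant terms* among all genes that have at least one annotation. Direct
annotations are stored unpropagated; propagation happens when IC is
computed. IC is reported in nats by default (`log_base` switches the base;
every downstream score inherits it).

Term-to-term similarity is Resnik's measure refined by disjunctive common
ancestors: rather than only the single most informative common ancestor,
the similarity of `t1` and `t2` is the *mean* IC of their disjunct common
ancestors — the common ancestors representing non-redundant routes of
shared meaning. Operationally, common ancestors are visited in decreasing
IC order and one is accepted iff, from each query term, some directed path
to it avoids every already-accepted ancestor; the most informative common
ancestor is always accepted. Ties in IC are broken lexicographically by
term ID, so the procedure is deterministic. The exact selection rule has
room for interpretation; the package's greedy operationalization is
validated, in the test suite and the acceptance script, against a
brute-force oracle that enumerates every directed path explicitly, on
hundreds of random DAGs.

Gene-to-gene similarity aggregates over the genes' term sets: `max` takes
the best term pair; `bma` (best-match average) pools, for each term in
either set, its best match in the other set, and averages all of them with
equal weight per term (so for sets of size 1 and 2 the average runs over 3
best matches). When the sets differ in size this pooled form differs from
averaging the two directional means; the pooled form is the package
default. Genes without annotations have *undefined* (`NA`) similarity,
never zero — otherwise unannotated genes would drag benchmark medians down.

Flat vocabularies (pathway or domain memberships without a deep hierarchy)
use direct matches only: the similarity is the maximum IC over terms
annotated to both genes.

## From raw evidence to one network

Each evidence source becomes a set of scored, unordered gene pairs:

* **Co-expression** — Pearson correlation over exactly the samples in which
  both genes are expressed (non-missing and above an expression floor,
  default 0), requiring at least ten such samples. The paper-scale default
  of ten shared tissues is kept; pairs below it are absent rather than
  scored 0.
* **Physical interactions** — binary evidence. All pairs from one assay
  type receive that assay's median benchmark similarity (computed over its
  benchmarked pairs), which puts them directly on the benchmark scale.
  Assays with fewer than 100 benchmarked pairs are dropped.
  Indirect links between non-interacting genes with shared partners are
  scored by the Jaccard index of their partner sets — any monotone score
  works here because benchmark rescoring recalibrates it; Jaccard is
  bounded and parameter-free.
* **Annotation vocabularies** — pairwise gene similarity (`bma`, `max`, or
  flat direct-match), excluding the benchmark vocabulary itself: a source
  must not certify itself.
* **Pre-scored pairs** — read as-is; duplicate records collapse to their
  maximum, self-pairs are dropped.

**Evaluation and rescoring.** A source earns inclusion by demonstrating
that stronger links mean more similar phenotypes: its pairs (restricted to
benchmark-annotated genes) are ordered by score, cut into bins of 1000, and
the bin-median benchmark similarity must correlate positively (one-sided
Spearman, $\alpha = 0.05$) with the bin-median raw score. Score ties are
broken by pair ID so binning is deterministic. The partial final bin is
reported but excluded from both the correlation and the fit — using the
same rows for the inclusion decision and the regression keeps the two
consistent. Included sources are mapped onto the benchmark scale by
ordinary least squares of bin-median similarity on bin-median raw score,
and *every* pair — benchmarked or not — is rescored through that line.
Negative fitted values clamp to zero and the pair is dropped: it carries no
evidence. Excluded sources cannot be rescored (without an explicit
override) and therefore can never reach integration.

**Integration.** When several sources support the same pair, the rescored
weights, sorted decreasingly as $L_0 \ge L_1 \ge \dots$, combine as

$$WS = L_0 + \sum_{i\ge1} \frac{L_i}{D\,i} \qquad\text{(harmonic, default)}$$

or $WS = L_0 + \sum_i L_i / D^i$ (geometric), with $D = 5$ by default. The
displayed form of this weighted sum in the source literature admits both
readings of the denominator; both are implemented, the harmonic form —
matching the prose description of a linear index $i$ — is the default, and
the choice is a single `kernel` argument. Each source contributes at most
one weight per pair (its maximum), so duplicated records cannot
double-count. $WS$ never falls below the best single-source weight, and a
single source passes through unchanged. $D$ is a configuration input; no
optimization procedure for it is implemented.

## The clustering test and its nulls

The statistic for a gene set is the sum of integrated link weights over
within-set edges; genes absent from the network stay in the set and
contribute zero (dropping them would quietly shrink the set). Significance
comes from `n_rand` randomized sets (default 100,000):

* `uniform` — size-matched uniform draws from the network's genes;
* `cds` — for each study gene, a list of the `k = 100` genes with the same
  or most similar longest-CDS length is assembled (query excluded,
  distance ties broken lexicographically), and each random set takes one
  uniform draw per list;
* `degree` — as `cds` with node-degree shells, auto-widened to the nearest
  non-empty shell when a degree is unique.

The empirical p-value uses the add-one estimator
$p = (1 + \#\{S_{null} \ge S\}) / (1 + n_{rand})$ — never zero, ties
counted against the study set (conservative). The fold change is
$S / \mathrm{median}(S_{null})$, so a typical null draw sits near 1.
Duplicate genes inside one random draw are redrawn a bounded number of
times; a draw that still collides is kept, scored on its distinct genes,
and counted in a warning. Seeds make every test reproducible.

Two deliberate conservatisms: study genes are excluded from their own
candidate lists, and genes missing from the network still receive matched
counterparts (who may be connected), which biases the null upward rather
than downward.

## What the synthetic data emulates

The generators produce data with the statistical structure the method
assumes, so every stage can be exercised and calibrated offline:

* **Ontology and annotations** — a layered DAG (default depth 5, branching
  3; each term one backbone parent plus an occasional second parent), genes
  partitioned into 20 modules sharing deep, high-IC leaf terms plus random
  shallow terms. Same-module pairs are systematically more similar, and the
  IC spectrum spans more than 3 nats.
* **Evidence** — a hidden affine transform of true pair similarity plus
  Gaussian noise (sd 0.3 by default) on a random coverage subset; exactly
  what benchmark evaluation is designed to see through.
* **Lengths and network** — CDS lengths log-normal (meanlog 7.5, sdlog 0.8
  on the natural scale, median ≈ 1.8 kb); the universe defaults to 18,000
  genes, the scale of the human coding genome. This scale matters: the
  quality of 100-nearest-length matching depends on how densely the length
  axis is populated, and a much smaller universe would degrade the matched
  null in the log-normal tail in a way the real gene universe does not.
  Edge probability is proportional to
  $\exp\!\big(\beta[(z_i + z_j) - (z_i - z_j)^2/2]\big)$ with $z$ the
  standardized log length, normalized to a mean degree of 50 — full
  integrated functional networks are dense; "strongest-100,000-links"
  views of them are reporting-time thinnings. The first kernel factor
  couples length to degree; the difference penalty makes connected genes
  resemble each other in length (a purely factorized kernel gives every
  gene the same neighbour distribution and hence *no* length
  assortativity, which is why the penalty exists). At $\beta = 0.5$ the
  generator reproduces both observed signatures of the confound — long
  genes are hubs, and a gene's neighbours resemble it in length. Edge
  weights are log-normal and independent of length.
* **Planted modules** — a module's internal pairs get an absolute edge
  probability of 0.25 (complex-like density). An absolute density rather
  than a background multiplier: against a genome-scale background
  (density ~3·10⁻⁴) no plausible multiplier yields a genuinely clustered
  20-gene module.
* **Study sets** — either sampled with probability proportional to CDS
  length with *no* functional structure (the mutability confound in pure
  form), or taken from a planted module (genuine signal).

What the generators do **not** emulate: realistic expression matrices
beyond what correlation scoring needs, annotation biases that correlate
with study ascertainment, ortholog-mapping noise, or dependence between
evidence sources beyond their shared truth. Calibration results on
synthetic data therefore certify the machinery — not the realism of any
particular database.

## Calibration experiments and problem sizes

The package's tests and `scripts/acceptance.R` run these experiments at the
following sizes, chosen to keep each meaningful while fitting comfortably
in a routine test run:

* GraSM oracle sweep: 200 random DAGs (≤ 30 terms, ≤ 12 genes), exact
  agreement of ancestor sets and similarities.
* Inclusion calibration: a 200-gene benchmark; 100 pure-noise sources must
  be included at most 10% of the time at $\alpha = 0.05$ (measured ≈ 4%),
  100 planted monotone sources must all be included.
* Rescoring recovery: a planted map $sim = 0.5 \cdot score + 0.2$ with
  noise sd 0.05 over 100,000 pairs; the fitted slope lands within
  [0.45, 0.55].
* Bias reproduction and cure: 18,000 genes, $\beta = 0.5$, 50
  length-proportional study genes with no signal, 500 replicate tests at
  `n_rand` 999. The uniform null rejects ≈ 50% of the time at
  $\alpha = 0.05$; the CDS-matched null stays at ≈ 5%.
* Power: 200 planted 20-gene modules at density 0.25; the CDS-null test
  detects essentially all of them at $p \le 0.05$.
* Null uniformity: 500 uniform gene sets under the uniform null pass a KS
  test against U(0,1).
* Integration dominance: four sources of varying noise and coverage; the
  integrated network's binned benchmark-similarity curve is at least each
  source's curve, bin for bin, at matched coverage.

## Numerical choices and degenerate inputs

* IC uses natural logarithms by default; terms annotating no gene get no
  IC entry and are treated as IC 0 when ordering candidate ancestors.
* All pair containers canonicalise `gene_a < gene_b`, drop self-pairs, and
  collapse within-source duplicates to the maximum score, so results are
  invariant to input row order.
* Spearman p-values for the inclusion test use the asymptotic
  approximation (bin medians are continuous; exactness is immaterial at
  the bin counts involved).
* `evaluate_links()` refuses to run with fewer than two full bins
  ("insufficient benchmark overlap"); `fit_rescoring()` refuses
  zero-variance bin scores; `cluster_test()` refuses sets smaller than
  two, missing CDS lengths (naming the genes), and degree-matching of
  genes absent from the network.
* Zero-variance expression profiles are skipped and counted rather than
  scored; an empty evidence file is an empty link set, not an error.
* Gene identifiers are opaque strings; ortholog mapping is an explicit
  input table applied before derivation, with unmapped pairs dropped and
  counted.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_genes = 300, n_modules = 10, mean_degree = 20)
sim <- simulate_ontology(cfg, seed = 1)
lw  <- simulate_lengths_and_network(cfg, genes = sim$modules$gene,
                                    modules = sim$modules, seed = 2)

# benchmark: phenotype similarity for all pairs
genes <- sort(unique(sim$annotations$gene))
pairs <- t(utils::combn(genes, 2))
truth <- gene_pair_similarity(
  tibble::tibble(gene_a = pairs[, 1], gene_b = pairs[, 2]),
  sim$annotations, sim$ontology, sim$ic, method = "bma")

# one noisy evidence source: evaluate, rescore, integrate
ev  <- simulate_evidence(truth, cfg, source = "expression_like", seed = 3)
eva <- evaluate_links(ev, truth, bin_size = 1000)
glance(eva)
net <- integrate_links(list(rescore_links(ev, eva)))

# is a planted module more interlinked than length-matched random sets?
study <- simulate_study_genes(lw$lengths, 20, "planted_module",
                              modules = sim$modules, seed = 4)
ct <- cluster_test(lw$network, study, null_kind = "cds", n_rand = 9999,
                   lengths = lw$lengths, k = 50, seed = 5)
glance(ct)
autoplot(ct)
```

## Known limitations

* The disjunctive-ancestor rule is a greedy operationalization; it is
  oracle-validated on random DAGs up to 30 terms, not formally proven
  equivalent to every published reading of the approach.
* Rescoring is strictly linear. Sources whose score-to-similarity
  relationship is monotone but strongly curved keep a monotone rescoring
  (slope times score), but their relative weighting across the score range
  is only first-order correct. The evaluation report and its `autoplot()`
  make curvature visible; a non-linear fit would slot in at
  `fit_rescoring()`.
* The degree-matched null conditions on the realized network, so it cannot
  separate "long genes are hubs because they are long" from "long genes
  are hubs because they are important"; the CDS null is the primary
  control, the degree null a robustness check.
* Database-specific parsers, ortholog inference, and any optimization of
  `D` are out of scope; `D` is an input with default 5.
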