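# Expression analysis: TPM, DEG calling, bi-clustering, GSEA,
# over-representation.

# independent running-sum enumeration used as the GSEA oracle: walks the
# ranked list position by position, maintaining hit/miss cumulative fractions
gsea_enumerate <- function(in_set, weights, p) {
  N <- length(in_set)
  k <- sum(in_set)
  w <- abs(weights)^p
  wsum <- sum(w[in_set])
  phit <- 0
  pmiss <- 0
  dev <- numeric(N)
  for (i in seq_len(N)) {
    if (in_set[i]) phit <- phit + (if (wsum > 0) w[i] / wsum else 1 / k)
    else pmiss <- pmiss + 1 / (N - k)
    dev[i] <- phit - pmiss
  }
  dev[which.max(abs(dev))]
}

test_that("TPM columns sum to one million and respect length scaling", {
  counts <- matrix(c(10, 10), nrow = 2,
                   dimnames = list(c("g1", "g2"), "s1"))
  tpm <- tpm_normalize(counts, c(g1 = 1000, g2 = 2000))
  # equal counts, lengths 1:2 -> TPM ratio 2:1
  expect_equal(tpm["g1", 1] / tpm["g2", 1], 2)
  expect_equal(colSums(tpm), c(s1 = 1e6))

  single <- matrix(5, 1, 1, dimnames = list("g1", "s1"))
  expect_equal(tpm_normalize(single, c(g1 = 500))[1, 1], 1e6)

  set.seed(2)
  m <- matrix(rpois(200, 50), 20,
              dimnames = list(sprintf("g%d", 1:20), sprintf("s%d", 1:10)))
  tpm_r <- tpm_normalize(m, setNames(sample(500:2000, 20), rownames(m)))
  expect_true(all(abs(colSums(tpm_r) - 1e6) < 1e-6 * 1e6))
  expect_error(tpm_normalize(m, c(g1 = 100)), "missing gene length")
})

test_that("DEG calling recovers planted genes and respects call semantics", {
  cfg <- sim_config(seed = 201, n_genes = 400, de_fraction = 0.1,
                    de_log2fc = 2, nb_dispersion = 0.05, pathway_size = 0)
  sim <- generate_counts(cfg)
  tpm <- tpm_normalize(sim$counts, sim$gene_lengths)
  degs <- call_degs(tpm, sim$groups)

  up_planted <- sim$truth$gene_id[sim$truth$log2fc > 0]
  recall <- mean(degs$call[match(up_planted, degs$gene_id)] == "up")
  expect_gt(recall, 0.8)
  # call invariants
  expect_true(all((degs$call == "up") ==
                    (degs$log2fc > 1 & degs$p < 0.05)))
  expect_true(all((degs$call == "down") ==
                    (degs$log2fc < -1 & degs$p < 0.05)))
  # BH invariants
  expect_true(all(degs$fdr >= degs$p - 1e-12))
  expect_true(!is.unsorted(degs$fdr[order(degs$p)]))
})

test_that("identical groups produce no calls and constant genes get p = 1", {
  set.seed(7)
  m <- matrix(rpois(100 * 8, 60), 100,
              dimnames = list(sprintf("g%d", 1:100), sprintf("s%d", 1:8)))
  m <- cbind(m, m)  # treated duplicates control exactly
  colnames(m) <- sprintf("s%d", 1:16)
  groups <- factor(rep(c("control", "treated"), each = 8),
                   levels = c("control", "treated"))
  degs <- call_degs(tpm_normalize(m, setNames(rep(1000, 100), rownames(m))),
                    groups)
  expect_true(all(degs$call == "ns"))
  expect_true(all(degs$log2fc == 0))

  const <- matrix(5, 3, 6, dimnames = list(c("a", "b", "c"),
                                           sprintf("s%d", 1:6)))
  dc <- call_degs(tpm_normalize(const, c(a = 1, b = 1, c = 1) * 1000),
                  factor(rep(c("control", "treated"), each = 3)))
  expect_true(all(dc$p == 1))
  expect_error(call_degs(const, factor(c("a", "a", "a", "a", "a", "b"))),
               "2 samples")
})

test_that("bi-clustering merges identical samples first and separates groups", {
  cfg <- sim_config(seed = 202, n_genes = 200, de_fraction = 0.3,
                    de_log2fc = 3, nb_dispersion = 0.05)
  sim <- generate_counts(cfg)
  tpm <- tpm_normalize(sim$counts, sim$gene_lengths)

  dup <- cbind(tpm, dup_of_1 = tpm[, 1])
  bc <- hierarchical_bicluster(dup)
  first_merge <- bc$col_dendrogram$merge[1, ]
  merged <- colnames(dup)[-first_merge]
  expect_setequal(merged, c(colnames(tpm)[1], "dup_of_1"))

  # strong planted signal: the root split separates the two groups
  bc2 <- hierarchical_bicluster(tpm)
  groups <- sub("_.*", "", bc2$col_order)
  expect_identical(length(rle(groups)$values), 2L)

  # permuting input rows leaves the column tree heights unchanged
  bc3 <- hierarchical_bicluster(tpm[sample(nrow(tpm)), ])
  expect_equal(bc3$col_dendrogram$height, bc2$col_dendrogram$height)
  expect_error(hierarchical_bicluster(matrix(c(1, NA, 2, 3), 2)), "NA")
})

test_that("GSEA ES matches the running-sum enumeration oracle", {
  set.seed(11)
  genes <- sprintf("g%d", 1:10)
  stats <- sort(rnorm(10), decreasing = TRUE)
  top3 <- genes[1:3]

  # unweighted: set at the top of the list
  res <- gsea_es(genes, stats, top3, p = 0, n_perm = 0)
  expect_equal(res$es,
               gsea_enumerate(genes %in% top3, stats, 0))
  expect_identical(res$overlap_k, 3L)

  # weighted: random sets, several sizes
  for (k in c(2, 4, 7)) {
    set <- sample(genes, k)
    res1 <- gsea_es(genes, stats, set, p = 1, n_perm = 0)
    expect_equal(res1$es, gsea_enumerate(genes %in% set, stats, 1))
    expect_gte(res1$es, -1)
    expect_lte(res1$es, 1)
  }
})

test_that("reversing the ranking negates the unweighted ES", {
  set.seed(12)
  genes <- sprintf("g%d", 1:50)
  stats <- sort(rnorm(50), decreasing = TRUE)
  set <- sample(genes, 8)
  fwd <- gsea_es(genes, stats, set, p = 0, n_perm = 0)
  rev_ <- gsea_es(rev(genes), rev(stats), set, p = 0, n_perm = 0)
  expect_equal(rev_$es, -fwd$es)
})

test_that("GSEA flags degenerate sets and detects a planted suppressed pathway", {
  genes <- sprintf("g%d", 1:10)
  expect_error(gsea_es(genes, NULL, c("x1", "x2"), n_perm = 0), "no overlap")
  expect_error(gsea_es(genes, NULL, genes, n_perm = 0), "N - k")

  cfg <- sim_config(seed = 203, n_genes = 500, de_fraction = 0.05,
                    pathway_size = 40, pathway_shift = 1.5)
  sim <- generate_counts(cfg)
  degs <- call_degs(tpm_normalize(sim$counts, sim$gene_lengths), sim$groups)
  ranked <- degs[order(-degs$log2fc), ]
  enr <- gsea_es(ranked$gene_id, ranked$log2fc, sim$pathway$PI3K_AKT_LIKE,
                 n_perm = 500, seed = 203)
  expect_lt(enr$es, 0)
  expect_lt(enr$p_perm, 0.05)
  # seeded permutations are reproducible
  enr2 <- gsea_es(ranked$gene_id, ranked$log2fc, sim$pathway$PI3K_AKT_LIKE,
                  n_perm = 500, seed = 203)
  expect_identical(enr$p_perm, enr2$p_perm)
})

test_that("GSEA ES agrees with fgsea on a moderate example", {
  skip_if_not_installed("fgsea")
  set.seed(13)
  genes <- sprintf("g%d", 1:200)
  stats <- setNames(sort(rnorm(200), decreasing = TRUE), genes)
  set <- sample(genes, 20)
  ours <- gsea_es(genes, unname(stats), set, p = 1, n_perm = 0)
  ref <- suppressWarnings(
    fgsea::calcGseaStat(stats, selectedStats = which(genes %in% set),
                        gseaParam = 1))
  expect_equal(ours$es, ref, tolerance = 1e-8)
})

test_that("hypergeometric tail equals brute-force enumeration", {
  # exact combinatorial check on small universes
  enum_tail <- function(N, K, n, k) {
    # P(overlap >= k) by enumerating the hypergeometric pmf directly
    sum(vapply(k:min(K, n), function(x) {
      choose(K, x) * choose(N - K, n - x) / choose(N, n)
    }, 0))
  }
  universe <- sprintf("u%d", 1:20)
  res <- hypergeom_ora(universe[1:5], list(s = universe[1:5]), universe)
  expect_equal(res$p_hyper, 1 / choose(20, 5))
  expect_equal(res$p_hyper, enum_tail(20, 5, 5, 5))

  set.seed(14)
  for (i in 1:10) {
    N <- sample(10:25, 1)
    K <- sample(2:6, 1)
    n <- sample(2:8, 1)
    uni <- sprintf("u%d", seq_len(N))
    set <- sample(uni, K)
    sel <- sample(uni, n)
    k <- length(intersect(set, sel))
    res <- hypergeom_ora(sel, list(s = set), uni)
    expect_equal(res$p_hyper, enum_tail(N, K, n, k), info = i)
  }

  # zero overlap has tail probability 1
  res0 <- hypergeom_ora(universe[6:10], list(s = universe[1:3]), universe)
  expect_equal(res0$p_hyper, enum_tail(20, 3, 5, 0))
  # selected = universe forces full overlap and p = 1
  resf <- hypergeom_ora(universe, list(s = universe[1:4]), universe)
  expect_identical(resf$overlap_k, 4L)
  expect_equal(resf$p_hyper, 1)
  expect_error(hypergeom_ora("u1", list(s = "u1"), character(0)), "universe")
})
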