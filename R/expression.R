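# Knockdown characterisation: TPM, per-gene Welch tests, hierarchical
# bi-clustering, GSEA running-sum enrichment, hypergeometric
# over-representation.

#' TPM-normalise a count matrix
#'
#' Transcripts per million: counts are divided by gene length (kb) and each
#' sample column rescaled to sum to one million.
#'
#' @param counts Genes x samples numeric matrix with rownames.
#' @param gene_lengths Named vector of gene lengths (nt) covering all genes.
#' @return TPM matrix, same dimensions; each column sums to 1e6.
#' @export
tpm_normalize <- function(counts, gene_lengths) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  missing <- setdiff(rownames(counts), names(gene_lengths))
  if (length(missing)) {
    stop("missing gene length for: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  len <- gene_lengths[rownames(counts)]
  if (any(len <= 0)) stop("gene lengths must be > 0", call. = FALSE)
  rate <- counts / (len / 1000)
  sweep(rate, 2, colSums(rate), "/") * 1e6
}

#' Call differentially expressed genes
#'
#' Per-gene log2 fold change on group mean TPM (with a pseudocount) and a
#' two-tailed Welch t-test on `log2(TPM + pseudocount)`. Fold change is
#' `log2((mean treated + pc) / (mean control + pc))`, i.e. negative for
#' knocked-down genes. Benjamini-Hochberg FDR is reported alongside; calls
#' (`up`/`down`/`ns`) use the raw p-value, mirroring common practice of
#' filtering on unadjusted p at a fold-change cutoff.
#'
#' Genes constant across all samples get `p = 1` by convention (no evidence
#' either way) and are counted in the FDR correction.
#'
#' @param tpm Genes x samples TPM matrix.
#' @param groups Factor of length `ncol(tpm)` with levels
#'   `c(control, treated)` (first level = control/reference).
#' @param log2fc_thresh Absolute log2 fold-change threshold for calls.
#' @param alpha Raw p-value threshold for calls.
#' @param pseudocount Added to TPM before logs and ratios.
#' @return Data.frame of `DEGRecord`s: `gene_id`, `mean_treated`,
#'   `mean_control`, `log2fc`, `p`, `fdr`, `call`.
#' @export
call_degs <- function(tpm, groups, log2fc_thresh = 1, alpha = 0.05,
                      pseudocount = 1) {
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2L, length(groups) == ncol(tpm))
  if (min(table(groups)) < 2L) {
    stop("need at least 2 samples per group", call. = FALSE)
  }
  ctrl <- tpm[, groups == levels(groups)[1], drop = FALSE]
  trt <- tpm[, groups == levels(groups)[2], drop = FALSE]
  lx_c <- log2(ctrl + pseudocount)
  lx_t <- log2(trt + pseudocount)

  mean_c <- rowMeans(ctrl)
  mean_t <- rowMeans(trt)
  log2fc <- log2((mean_t + pseudocount) / (mean_c + pseudocount))

  p <- vapply(seq_len(nrow(tpm)), function(g) {
    a <- lx_t[g, ]
    b <- lx_c[g, ]
    if (stats::sd(c(a, b)) == 0) return(1)  # constant gene convention
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      return(if (mean(a) == mean(b)) 1 else 0)
    }
    stats::t.test(a, b, var.equal = FALSE)$p.value
  }, 0)
  fdr <- stats::p.adjust(p, "BH")
  call <- ifelse(log2fc > log2fc_thresh & p < alpha, "up",
                 ifelse(log2fc < -log2fc_thresh & p < alpha, "down", "ns"))
  data.frame(gene_id = rownames(tpm), mean_treated = mean_t,
             mean_control = mean_c, log2fc = log2fc, p = p, fdr = fdr,
             call = call, row.names = NULL, stringsAsFactors = FALSE)
}

#' Hierarchical bi-clustering of an expression matrix
#'
#' Complete-linkage hierarchical clustering of genes and samples on Euclidean
#' distances of `log2(TPM + pseudocount)`. `hclust` is deterministic for a
#' given input ordering; distance ties resolve to the earlier-merged cluster.
#'
#' @param tpm Genes x samples matrix (>= 2 rows and columns), no NAs.
#' @param pseudocount Added before the log transform.
#' @return A list with `row_order`, `col_order` (leaf orders), and the
#'   `hclust` objects `row_dendrogram`, `col_dendrogram`. Serializable to
#'   JSON via [write_cluster_json()].
#' @export
hierarchical_bicluster <- function(tpm, pseudocount = 1) {
  stopifnot(nrow(tpm) >= 2L, ncol(tpm) >= 2L)
  if (anyNA(tpm)) stop("matrix contains NA", call. = FALSE)
  lx <- log2(tpm + pseudocount)
  hr <- stats::hclust(stats::dist(lx), method = "complete")
  hc <- stats::hclust(stats::dist(t(lx)), method = "complete")
  list(row_order = rownames(tpm)[hr$order], col_order = colnames(tpm)[hc$order],
       row_dendrogram = hr, col_dendrogram = hc)
}

#' Serialise bi-clustering orderings to JSON
#'
#' @param bicluster Output of [hierarchical_bicluster()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cluster_json <- function(bicluster, path) {
  jsonlite::write_json(list(
    row_order = bicluster$row_order,
    col_order = bicluster$col_order,
    row_merge = bicluster$row_dendrogram$merge,
    col_merge = bicluster$col_dendrogram$merge,
    row_height = bicluster$row_dendrogram$height,
    col_height = bicluster$col_dendrogram$height
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# Running-sum enrichment score of a gene set in a ranked list.
# stats must be ordered (decreasing ranking statistic); p is the hit weight
# exponent. Classic weighted Kolmogorov-Smirnov statistic: hits step up by
# |stat|^p (normalised), misses step down by 1/(N - k); ES is the running
# sum's maximum deviation from zero, signed.
.gsea_running_es <- function(in_set, stats_abs_p, N, k) {
  hit_w <- stats_abs_p * in_set
  denom <- sum(hit_w)
  if (denom == 0) {
    # all hit weights zero (p > 0 with zero statistics): fall back to equal
    hit_w <- in_set / k
  } else {
    hit_w <- hit_w / denom
  }
  run <- cumsum(hit_w - (!in_set) / (N - k))
  run[which.max(abs(run))]
}

#' Gene-set enrichment score (weighted Kolmogorov-Smirnov running sum)
#'
#' Classic GSEA enrichment statistic on a ranked gene list: walking down the
#' ranking, genes in the set increment the running sum by their weight
#' `|statistic|^p` (normalised over the set) and genes outside decrement it
#' by `1/(N - k)`; the ES is the maximum deviation from zero, signed. A
#' permutation p-value is obtained by permuting gene labels (seeded), with a
#' +1 pseudo-observation, counting permutations at least as extreme in the
#' same direction as the observed ES.
#'
#' @param ranked_genes Character vector of gene ids ordered by decreasing
#'   ranking statistic.
#' @param stats Ranking statistic aligned with `ranked_genes` (used for
#'   weights; ignored when `p = 0`).
#' @param gene_set Character vector of gene ids.
#' @param p Weight exponent (1 = classic weighted GSEA, 0 = unweighted KS).
#' @param n_perm Number of gene-label permutations (0 skips the p-value).
#' @param seed Seed for the permutation stream.
#' @return A list: `set_id`, `es`, `nes` (ES over mean |permuted ES| of the
#'   same sign; NA when `n_perm = 0`), `p_perm`, `overlap_k`, `set_size`,
#'   `universe`.
#' @export
gsea_es <- function(ranked_genes, stats = NULL, gene_set, p = 1,
                    n_perm = 1000L, seed = 1L) {
  N <- length(ranked_genes)
  stopifnot(N >= 2L, anyDuplicated(ranked_genes) == 0L)
  if (is.null(stats)) stats <- rep(0, N)
  stopifnot(length(stats) == N)
  in_set <- ranked_genes %in% gene_set
  k <- sum(in_set)
  if (k == 0L) stop("gene set has no overlap with the ranked list", call. = FALSE)
  if (k == N) stop("gene set covers the whole ranked list (N - k = 0)", call. = FALSE)
  w <- abs(stats)^p
  es <- .gsea_running_es(in_set, w, N, k)

  p_perm <- NA_real_
  nes <- NA_real_
  if (n_perm > 0) {
    set.seed(derive_seed(seed, "gsea_perm"))
    perm_es <- vapply(seq_len(n_perm), function(b) {
      .gsea_running_es(sample(in_set), w, N, k)
    }, 0)
    same_sign <- if (es >= 0) perm_es >= es else perm_es <= es
    p_perm <- (1 + sum(same_sign)) / (n_perm + 1)
    side <- perm_es[sign(perm_es) == sign(es)]
    if (length(side)) nes <- es / mean(abs(side))
  }
  list(set_id = "gene_set", es = es, nes = nes, p_perm = p_perm,
       overlap_k = k, set_size = length(unique(gene_set)), universe = N)
}

#' Hypergeometric over-representation of gene sets
#'
#' Exact upper-tail hypergeometric test of the overlap between a selected
#' gene list (e.g. significant DEGs) and each gene set, with
#' Benjamini-Hochberg correction across sets. `P(X >= k)` where X is the
#' overlap under random draws of `|selected|` genes from the universe.
#'
#' @param selected Character vector of selected genes (subset of universe).
#' @param gene_sets Named list of gene sets, or a single character vector.
#' @param universe Character vector of all genes considered.
#' @return Data.frame: `set_id`, `overlap_k`, `set_size`, `selected`,
#'   `universe`, `p_hyper`, `fdr`.
#' @export
hypergeom_ora <- function(selected, gene_sets, universe) {
  if (!is.list(gene_sets)) gene_sets <- list(gene_set = gene_sets)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  if (!all(selected %in% universe)) {
    stop("selected genes must be a subset of the universe", call. = FALSE)
  }
  n_sel <- length(unique(selected))
  res <- lapply(names(gene_sets), function(nm) {
    set <- intersect(unique(gene_sets[[nm]]), universe)
    k <- length(intersect(set, selected))
    # P(X >= k), X ~ Hypergeometric(|set| white, N - |set| black, n_sel draws)
    p <- stats::phyper(k - 1, length(set), length(universe) - length(set),
                       n_sel, lower.tail = FALSE)
    data.frame(set_id = nm, overlap_k = k, set_size = length(set),
               selected = n_sel, universe = length(universe), p_hyper = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$fdr <- stats::p.adjust(out$p_hyper, "BH")
  out
}
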