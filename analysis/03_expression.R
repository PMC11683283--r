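#!/usr/bin/env Rscript

# Stage 3: knockdown characterisation on the simulated count matrix.
#
# TPM-normalises the counts, calls differential genes (|log2FC| > 1, p <
# 0.05, Welch t on log2 TPM), bi-clusters samples and genes, and scores the
# planted pathway by GSEA (gene-label permutations) and hypergeometric
# over-representation. The planted pathway is expected to come out negatively
# enriched (suppressed).

suppressPackageStartupMessages(library(trfscreen))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L
data_dir <- "results/data"
counts_tab <- read.delim(file.path(data_dir, "counts.tsv"), check.names = FALSE)
counts <- as.matrix(counts_tab[, -1])
rownames(counts) <- counts_tab$gene_id
lengths_tab <- read.delim(file.path(data_dir, "gene_lengths.tsv"))
gene_lengths <- setNames(lengths_tab$length_nt, lengths_tab$gene_id)
pathway <- read_gmt(file.path(data_dir, "pathway.gmt"))
groups <- factor(sub("_.*", "", colnames(counts)),
                 levels = c("ctrl", "trt"), labels = c("control", "treated"))

tpm <- tpm_normalize(counts, gene_lengths)
degs <- call_degs(tpm, groups, log2fc_thresh = 1, alpha = 0.05)
write.table(degs, "results/degs.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

bc <- hierarchical_bicluster(tpm)
write_cluster_json(bc, "results/bicluster.json")

ranked <- degs[order(-degs$log2fc), ]
enr <- gsea_es(ranked$gene_id, ranked$log2fc, pathway[[1]],
               n_perm = 1000, seed = seed)
ora <- hypergeom_ora(degs$gene_id[degs$call == "down"], pathway,
                     degs$gene_id)
write.table(
  data.frame(set_id = names(pathway), es = enr$es, nes = enr$nes,
             p_perm = enr$p_perm, overlap_k = ora$overlap_k,
             p_hyper = ora$p_hyper),
  "results/enrichment.tsv", sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf(
  "DEG analysis: %d up, %d down, %d unchanged of %d genes (|log2FC| > 1, p < 0.05)\n",
  sum(degs$call == "up"), sum(degs$call == "down"),
  sum(degs$call == "ns"), nrow(degs)))
grp_order <- sub("_.*", "", bc$col_order)
cat(sprintf("  bi-clustering %s the two groups at the root\n",
            if (length(rle(grp_order)$values) == 2) "separates" else "does not separate"))
cat(sprintf(
  "  %s: GSEA ES %.3f (perm p %.4f), over-representation of down calls p %.2e\n",
  names(pathway)[1], enr$es, enr$p_perm, ora$p_hyper))
cat("  tables -> results/degs.tsv, results/enrichment.tsv, results/bicluster.json\n")
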