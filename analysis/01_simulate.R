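#!/usr/bin/env Rscript

# Stage 1: simulate every input the pipeline consumes.
#
# Builds the synthetic study materials: a tRNA library, a 3'UTR carrying a
# planted binding site for the 22-nt 5' fragment of the first tRNA, a
# two-group RNA-seq count matrix with planted differential genes and a
# down-shifted "PI3K-Akt-like" pathway, plus dose-response, qPCR, wound and
# caliper tables. Everything is a pure function of the seed.

suppressPackageStartupMessages(library(trfscreen))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = seed)

trnas <- generate_trna_library(cfg)
write_rna_fasta(trnas, file.path(out, "trna_library.fa"))

planted_trf <- substr(trnas$sequence[cfg$planted_site$trf_index], 1,
                      cfg$frag_len)
site <- plant_target_site(cfg, planted_trf)
write_rna_fasta(site$utr, file.path(out, "utr.fa"))

sim <- generate_counts(cfg)
write.table(data.frame(gene_id = rownames(sim$counts), sim$counts,
                       check.names = FALSE),
            file.path(out, "counts.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(gene_id = names(sim$gene_lengths),
                       length_nt = sim$gene_lengths),
            file.path(out, "gene_lengths.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(sim$truth, file.path(out, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_gmt(sim$pathway, file.path(out, "pathway.gmt"))

for (preset in c("hct8_trf36", "lovo_trf36", "hct8_taxol", "lovo_taxol",
                 "hcoepic_taxol", "hct8t_trf36", "hct8t_taxol")) {
  write.table(generate_dose_response(preset, cfg),
              file.path(out, paste0("dose_", preset, ".tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
write.table(generate_qpcr_ct(cfg, ddct = 2), file.path(out, "qpcr_ct.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(generate_wound_areas(cfg), file.path(out, "wound_areas.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(generate_tumor_growth(cfg), file.path(out, "tumor_caliper.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)

cat(sprintf(
  "simulated with seed %d:\n  %d tRNAs (%d-%d nt), planted site at %d-%d on a %d-nt UTR\n  %d x %d count matrix, %d planted DE genes, pathway of %d genes shifted -%.1f log2\n  7 dose-response tables, qPCR/wound/caliper tables -> %s\n",
  seed, nrow(trnas), min(nchar(trnas$sequence)), max(nchar(trnas$sequence)),
  site$site_start, site$site_end, cfg$utr_len,
  nrow(sim$counts), ncol(sim$counts), sum(sim$truth$class == "de"),
  cfg$pathway_size, abs(cfg$pathway_shift), out))
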