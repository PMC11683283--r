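# End-to-end rehearsal on synthetic data, plus YAML config validation.

.config_schema <- list(
  seed = list(type = "integer", default = 1L),
  n_trnas = list(type = "integer", default = 50L),
  frag_len = list(type = "integer", default = 22L),
  utr_len = list(type = "integer", default = 300L),
  mfe_max = list(type = "numeric", default = -20),
  comp_min = list(type = "numeric", default = 72),
  log2fc_thresh = list(type = "numeric", default = 1),
  alpha = list(type = "numeric", default = 0.05),
  outdir = list(type = "character", default = "trfscreen_out"),
  verbosity = list(type = "integer", default = 1L)
)

#' Validate a YAML run configuration
#'
#' Schema-checks a YAML file of run settings: unknown keys are rejected,
#' missing keys filled with defaults, and type violations reported by key
#' name. The returned config re-validates unchanged (round-trip safe).
#'
#' @param path Path to a YAML file, or a named list already in memory.
#' @return A named list with every schema key present.
#' @export
validate_config <- function(path) {
  cfg <- if (is.character(path)) yaml::read_yaml(path) else path
  if (is.null(cfg)) cfg <- list()
  stopifnot(is.list(cfg))
  unknown <- setdiff(names(cfg), names(.config_schema))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  out <- list()
  for (key in names(.config_schema)) {
    spec <- .config_schema[[key]]
    val <- if (key %in% names(cfg)) cfg[[key]] else spec$default
    ok <- switch(spec$type,
                 integer = is.numeric(val) && length(val) == 1L &&
                   val == round(val),
                 numeric = is.numeric(val) && length(val) == 1L,
                 character = is.character(val) && length(val) == 1L)
    if (!ok) {
      stop("configuration key '", key, "' must be a scalar ", spec$type,
           call. = FALSE)
    }
    if (spec$type == "integer") val <- as.integer(val)
    out[[key]] <- val
  }
  out
}

#' Run the end-to-end synthetic demo workflow
#'
#' Stitches every stage together on synthetic data: simulate a tRNA library
#' and a UTR with a planted binding site, build 22-nt 5' fragments, screen
#' them against the UTR (the planted tRF must rank first), simulate counts,
#' call DEGs, score the planted pathway by GSEA (negative enrichment
#' expected) and over-representation, and recover a preset IC50 by 4PL
#' fitting. Each stage has a built-in check; any failure raises an error
#' naming the stage unless `strict = FALSE`.
#'
#' @param seed Master seed.
#' @param outdir Optional output directory; when given, FASTA/TSV/JSON
#'   artifacts of every stage are written there.
#' @param strict Stop on the first failed stage check.
#' @param n_perm Permutations for the GSEA p-value.
#' @return A list of stage results with a logical `checks` vector; invisibly
#'   `TRUE` checks mean the pipeline behaved as constructed.
#' @export
run_demo <- function(seed = 1L, outdir = NULL, strict = TRUE, n_perm = 500L) {
  cfg <- sim_config(seed = seed)
  model <- energy_model()
  checks <- c()
  fail <- function(stage, ok) {
    checks[[stage]] <<- ok
    if (!ok && strict) stop("demo stage check failed: ", stage, call. = FALSE)
    ok
  }

  # simulate library + planted site
  trnas <- generate_trna_library(cfg)
  planted_trf <- substr(trnas$sequence[cfg$planted_site$trf_index], 1,
                        cfg$frag_len)
  site <- plant_target_site(cfg, planted_trf)
  frags <- make_fragments(trnas, lengths = cfg$frag_len, ends = "five_prime")

  # screen: planted tRF must rank 1
  hits <- run_screen(frags, site$utr, model)
  planted_id <- frags$id[frags$parent_id ==
                           trnas$id[cfg$planted_site$trf_index]]
  fail("screen_planted_rank1",
       nrow(hits) >= 1L && hits$trf_id[1] == planted_id)

  # counts -> DEG -> enrichment
  sim <- generate_counts(cfg)
  tpm <- tpm_normalize(sim$counts, sim$gene_lengths)
  degs <- call_degs(tpm, sim$groups)
  planted_down <- sim$truth$gene_id[sim$truth$log2fc < 0 &
                                      sim$truth$class == "de"]
  recall_down <- mean(degs$call[match(planted_down, degs$gene_id)] == "down")
  fail("deg_recall", recall_down > 0.8)

  ranked <- degs[order(-degs$log2fc), ]
  enr <- gsea_es(ranked$gene_id, ranked$log2fc, sim$pathway$PI3K_AKT_LIKE,
                 n_perm = n_perm, seed = seed)
  fail("gsea_pathway_suppressed", enr$es < 0 && enr$p_perm < 0.05)
  ora <- hypergeom_ora(degs$gene_id[degs$call != "ns"], sim$pathway,
                       degs$gene_id)

  # dose-response recovery
  dr <- generate_dose_response("hct8_trf36", cfg)
  fit <- fit_4pl(dr$dose_nM, dr$viability_pct, n_boot = 0, seed = seed)
  preset_ic50 <- cfg$dose_presets$hct8_trf36$ic50
  fail("ic50_recovery",
       fit$converged && abs(fit$ic50 - preset_ic50) / preset_ic50 < 0.15)

  # quantification formulas on synthetic assay tables
  ct <- generate_qpcr_ct(cfg, ddct = 2, sd = 0)
  qpcr <- ddct_fold_table(ct)
  growth <- growth_summary(generate_tumor_growth(cfg))

  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_rna_fasta(trnas, file.path(outdir, "trna_library.fa"))
    write_rna_fasta(site$utr, file.path(outdir, "utr.fa"))
    write_fragments_fasta(frags, file.path(outdir, "fragments.fa"))
    write_screen_report(hits, file.path(outdir, "screen_hits.tsv"),
                        quiet = TRUE)
    utils::write.table(degs, file.path(outdir, "degs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_gmt(sim$pathway, file.path(outdir, "pathway.gmt"))
    jsonlite::write_json(list(seed = seed, checks = as.list(checks)),
                         file.path(outdir, "demo_report.json"),
                         auto_unbox = TRUE)
  }

  invisible(list(trnas = trnas, site = site, hits = hits, degs = degs,
                 gsea = enr, ora = ora, ic50_fit = fit, qpcr = qpcr,
                 growth = growth, checks = unlist(checks)))
}
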