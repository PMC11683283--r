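# Seeded generators for every input the pipeline consumes: tRNA libraries,
# UTRs with planted binding sites, count matrices with planted DE genes and a
# down-shifted pathway, dose-response readouts, qPCR CT tables, tumor growth.

# One global seed governs all substreams: each generator re-seeds R's RNG
# with derive_seed(seed, <stream name>), a deterministic 31-bit hash, so
# generators are order-independent and individually reproducible.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

.isotypes <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His",
               "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp",
               "Tyr", "Val")

.default_dose_presets <- function() {
  # dose grids are chosen to span each preset's transition (about two
  # decades either side of the IC50), as a plate layout would be designed
  mk <- function(ic50, lo = 0.1, hi = 1000) {
    list(ic50 = ic50, hill = 1, top = 100, bottom = 0, cv = 0.05,
         doses = signif(10^seq(log10(lo), log10(hi), length.out = 8), 4),
         replicates = 3L)
  }
  list(
    hct8_trf36    = mk(10.0),    # tRF mimic, parental colorectal line
    lovo_trf36    = mk(27.54),
    hct8_taxol    = mk(216.5, 1, 10000),
    lovo_taxol    = mk(103.8, 1, 10000),
    hcoepic_taxol = mk(167.0, 1, 10000),  # normal colon epithelium, taxol
    hct8t_trf36   = mk(9.49),    # taxol-resistant line, tRF mimic
    hct8t_taxol   = mk(1550, 10, 100000)  # taxol-resistant, taxol (1.55 uM)
  )
}

#' Simulation configuration
#'
#' Bundles every parameter of the synthetic-data generators. A fixed seed
#' makes every generator byte-identical across calls.
#'
#' @param seed Integer master seed; all generator substreams derive from it.
#' @param n_trnas Number of synthetic tRNAs in the library.
#' @param trna_len_range Integer pair, min/max tRNA length (nt).
#' @param frag_len tRF length in nt (default 22, the canonical 5'-tRF length).
#' @param gc_bias Probability mass on G/C when drawing tRNA bases.
#' @param planted_site List: `trf_index` (which tRNA's 5' fragment gets a
#'   planted site), `mismatches`, `gu_wobbles`, `utr_offset` (1-based start
#'   of the planted site in the UTR).
#' @param utr_len UTR length (nt).
#' @param n_genes,n_samples_per_group Count-matrix dimensions.
#' @param de_fraction Proportion of genes planted as differential.
#' @param de_log2fc Planted absolute log2 fold change (treated vs control).
#' @param nb_dispersion Negative-binomial dispersion (1/size).
#' @param pathway_size Number of genes in the planted down-shifted set.
#' @param pathway_shift Downward log2 shift applied to the planted pathway in
#'   the treated group (positive value = suppression).
#' @param dose_presets Named list of dose-response presets; each has `ic50`
#'   (nM), `hill`, `top`/`bottom` (percent viability), `cv`, `doses` (nM) and
#'   `replicates`. Defaults cover the assay conditions the package's worked
#'   examples use (tRF mimic and taxol on parental, resistant and normal
#'   colon lines).
#' @return A list of class `trf_sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_trnas = 50L,
                       trna_len_range = c(70L, 90L),
                       frag_len = 22L,
                       gc_bias = 0.55,
                       planted_site = list(trf_index = 1L, mismatches = 0L,
                                           gu_wobbles = 0L, utr_offset = 151L),
                       utr_len = 300L,
                       n_genes = 2000L,
                       n_samples_per_group = 6L,
                       de_fraction = 0.1,
                       de_log2fc = 2,
                       nb_dispersion = 0.1,
                       pathway_size = 50L,
                       pathway_shift = 1,
                       dose_presets = .default_dose_presets()) {
  cfg <- list(seed = as.integer(seed), n_trnas = as.integer(n_trnas),
              trna_len_range = as.integer(trna_len_range),
              frag_len = as.integer(frag_len), gc_bias = gc_bias,
              planted_site = planted_site, utr_len = as.integer(utr_len),
              n_genes = as.integer(n_genes),
              n_samples_per_group = as.integer(n_samples_per_group),
              de_fraction = de_fraction, de_log2fc = de_log2fc,
              nb_dispersion = nb_dispersion,
              pathway_size = as.integer(pathway_size),
              pathway_shift = pathway_shift,
              dose_presets = dose_presets)
  if (length(cfg$trna_len_range) != 2L ||
      cfg$trna_len_range[1] > cfg$trna_len_range[2] ||
      cfg$trna_len_range[1] < 1L) {
    stop("invalid trna_len_range", call. = FALSE)
  }
  if (cfg$frag_len > cfg$trna_len_range[1]) {
    stop("frag_len exceeds the minimum tRNA length", call. = FALSE)
  }
  if (cfg$de_fraction < 0 || cfg$de_fraction >= 1) {
    stop("de_fraction must be in [0, 1)", call. = FALSE)
  }
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be > 0", call. = FALSE)
  for (p in cfg$dose_presets) {
    if (any(p$doses <= 0) || p$ic50 <= 0) {
      stop("all concentrations must be > 0", call. = FALSE)
    }
  }
  class(cfg) <- "trf_sim_config"
  cfg
}

#' Generate a synthetic tRNA library
#'
#' Draws `n_trnas` random RNA sequences with the configured GC bias and
#' lengths uniform in `trna_len_range`, labelled with isotype-like ids
#' (`tRNA-Asn-GUU-like-007` style). Only the pairing structure of the
#' sequences matters downstream; no cloverleaf folding is emulated.
#'
#' @param cfg A [sim_config()].
#' @return A data.frame (`id`, `sequence`) writable with [write_rna_fasta()].
#' @export
generate_trna_library <- function(cfg) {
  stopifnot(inherits(cfg, "trf_sim_config"))
  set.seed(derive_seed(cfg$seed, "trna_library"))
  pg <- cfg$gc_bias / 2
  pa <- (1 - cfg$gc_bias) / 2
  lens <- sample(cfg$trna_len_range[1]:cfg$trna_len_range[2],
                 cfg$n_trnas, replace = TRUE)
  iso <- sample(.isotypes, cfg$n_trnas, replace = TRUE)
  seqs <- vapply(lens, function(L) {
    paste(sample(.BASES, L, replace = TRUE, prob = c(pa, pg, pg, pa)),
          collapse = "")
  }, "")
  anticodon <- vapply(seq_len(cfg$n_trnas), function(i) {
    paste(sample(.BASES, 3, replace = TRUE), collapse = "")
  }, "")
  data.frame(
    id = sprintf("tRNA-%s-%s-like-%03d", iso, anticodon, seq_len(cfg$n_trnas)),
    sequence = seqs, stringsAsFactors = FALSE)
}

#' Plant a tRF binding site into a synthetic 3'UTR
#'
#' Builds a random UTR of `cfg$utr_len` and embeds, at
#' `cfg$planted_site$utr_offset`, the reverse complement of `trf_sequence`
#' with exactly `mismatches` non-pairing substitutions and `gu_wobbles`
#' positions converted to G.U pairs. Wobbles are only placed where the tRF
#' has a G or U (the site base is changed C->U or A->G respectively);
#' mismatch and wobble positions are disjoint and drawn from the seeded
#' stream.
#'
#' @param cfg A [sim_config()].
#' @param trf_sequence RNA string of length `cfg$frag_len`.
#' @return A list: `utr` (data.frame `id`, `sequence`), `site_start`,
#'   `site_end` (1-based inclusive), `mismatch_trf_pos`, `wobble_trf_pos`
#'   (1-based positions on the tRF).
#' @export
plant_target_site <- function(cfg, trf_sequence) {
  stopifnot(inherits(cfg, "trf_sim_config"))
  ps <- cfg$planted_site
  trf <- .as_rna_chars(trf_sequence, "trf")
  L <- length(trf)
  if (L != cfg$frag_len) stop("trf length must equal cfg$frag_len", call. = FALSE)
  n_mm <- as.integer(ps$mismatches)
  n_gu <- as.integer(ps$gu_wobbles)
  if (n_mm + n_gu >= L) {
    stop("mismatches + gu_wobbles must be < tRF length", call. = FALSE)
  }
  offset <- as.integer(ps$utr_offset)
  if (offset < 1L || offset + L - 1L > cfg$utr_len) {
    stop("planted site does not fit in the UTR", call. = FALSE)
  }
  set.seed(derive_seed(cfg$seed, "plant_target_site"))
  utr <- sample(.BASES, cfg$utr_len, replace = TRUE)
  site <- strsplit(.revcomp_rna(paste(trf, collapse = "")), "")[[1]]

  # site position pairing tRF position i is L - i + 1 (antiparallel)
  wobble_eligible <- which(trf %in% c("G", "U"))
  if (n_gu > length(wobble_eligible)) {
    stop("not enough G/U positions on the tRF for the requested wobbles",
         call. = FALSE)
  }
  wob <- if (n_gu > 0) sort(sample(wobble_eligible, n_gu)) else integer(0)
  mm_pool <- setdiff(seq_len(L), wob)
  mm <- if (n_mm > 0) sort(sample(mm_pool, n_mm)) else integer(0)

  comp <- c(A = "U", C = "G", G = "C", U = "A")
  for (i in wob) {
    j <- L - i + 1L
    site[j] <- if (trf[i] == "G") "U" else "G"  # C->U or A->G
  }
  for (i in mm) {
    j <- L - i + 1L
    nonpairing <- .BASES[!vapply(.BASES, function(b) pair_allowed(trf[i], b), TRUE)]
    site[j] <- sample(nonpairing, 1L)
  }
  utr[offset:(offset + L - 1L)] <- site
  list(
    utr = data.frame(id = "synthetic_utr",
                     sequence = paste(utr, collapse = ""),
                     stringsAsFactors = FALSE),
    site_start = offset, site_end = offset + L - 1L,
    mismatch_trf_pos = mm, wobble_trf_pos = wob)
}

#' Generate a two-group RNA-seq count matrix with planted signal
#'
#' Negative-binomial counts for `n_genes` genes in two groups of
#' `n_samples_per_group` samples. A `de_fraction` of genes is shifted by
#' `± de_log2fc` in the treated group (half up, half down), and one designated
#' gene set of `pathway_size` genes (disjoint from the DE set; the
#' "PI3K-Akt-like" pathway) is shifted downward by `pathway_shift` log2
#' units. Gene lengths for TPM normalisation are drawn uniform 500-3000 nt.
#'
#' @param cfg A [sim_config()].
#' @return A list: `counts` (genes x samples integer matrix, columns
#'   `ctrl_*`/`trt_*`), `gene_lengths` (named, nt), `truth` (data.frame of
#'   every planted gene: `gene_id`, `log2fc` (treated vs control),
#'   `class` in `de`/`pathway`), `pathway` (named list of one gene set,
#'   GMT-writable), `groups` (factor of sample conditions).
#' @export
generate_counts <- function(cfg) {
  stopifnot(inherits(cfg, "trf_sim_config"))
  n <- cfg$n_samples_per_group
  if (n < 2L) stop("need at least 2 samples per group", call. = FALSE)
  set.seed(derive_seed(cfg$seed, "counts"))
  G <- cfg$n_genes
  gene_ids <- sprintf("gene%05d", seq_len(G))
  base_mu <- exp(stats::rnorm(G, mean = log(100), sd = 1.2))
  gene_lengths <- stats::setNames(sample(500:3000, G, replace = TRUE), gene_ids)

  n_de <- round(cfg$de_fraction * G)
  de_genes <- if (n_de > 0) sample(G, n_de) else integer(0)
  de_sign <- rep(c(1, -1), length.out = n_de)
  pool <- setdiff(seq_len(G), de_genes)
  pw_genes <- sort(sample(pool, min(cfg$pathway_size, length(pool))))

  lfc <- numeric(G)
  lfc[de_genes] <- de_sign * cfg$de_log2fc
  lfc[pw_genes] <- -abs(cfg$pathway_shift)

  mu_ctrl <- base_mu
  mu_trt <- base_mu * 2^lfc
  size <- 1 / cfg$nb_dispersion
  draw <- function(mu) {
    matrix(stats::rnbinom(G * n, mu = rep(mu, n), size = size), nrow = G)
  }
  counts <- cbind(draw(mu_ctrl), draw(mu_trt))
  dimnames(counts) <- list(gene_ids,
                           c(sprintf("ctrl_%d", seq_len(n)),
                             sprintf("trt_%d", seq_len(n))))
  truth <- data.frame(
    gene_id = gene_ids[c(de_genes, pw_genes)],
    log2fc = lfc[c(de_genes, pw_genes)],
    class = c(rep("de", n_de), rep("pathway", length(pw_genes))),
    stringsAsFactors = FALSE)
  list(counts = counts, gene_lengths = gene_lengths, truth = truth,
       pathway = list(PI3K_AKT_LIKE = gene_ids[pw_genes]),
       groups = factor(rep(c("control", "treated"), each = n),
                       levels = c("control", "treated")))
}

#' Generate synthetic dose-response (viability) data
#'
#' Draws viability from the four-parameter logistic curve of a named preset
#' with multiplicative log-normal noise of the preset's CV.
#'
#' @param preset Name of a preset in `cfg$dose_presets` (e.g. `hct8_trf36`).
#' @param cfg A [sim_config()].
#' @return A data.frame: `dose_nM`, `replicate`, `viability_pct`.
#' @export
generate_dose_response <- function(preset, cfg = sim_config()) {
  stopifnot(inherits(cfg, "trf_sim_config"))
  if (!preset %in% names(cfg$dose_presets)) {
    stop("unknown dose-response preset: ", preset, call. = FALSE)
  }
  p <- cfg$dose_presets[[preset]]
  set.seed(derive_seed(cfg$seed, paste0("dose_response/", preset)))
  tab <- expand.grid(replicate = seq_len(p$replicates), dose_nM = p$doses,
                     KEEP.OUT.ATTRS = FALSE)[, 2:1]
  mu <- four_pl(tab$dose_nM, top = p$top, bottom = p$bottom,
                ic50 = p$ic50, hill = p$hill)
  noise <- if (p$cv > 0) {
    sdlog <- sqrt(log(1 + p$cv^2))
    exp(stats::rnorm(nrow(tab), -sdlog^2 / 2, sdlog))
  } else rep(1, nrow(tab))
  tab$viability_pct <- mu * noise
  tab[order(tab$dose_nM, tab$replicate), ]
}

#' Generate a synthetic qPCR CT table
#'
#' Target and reference CT values in control and treated conditions with a
#' planted ddCt (so the planted downstream fold change is `2^-ddct`).
#' Gaussian noise of `sd` on every CT.
#'
#' @param cfg A [sim_config()].
#' @param ddct Planted delta-delta-CT (CT units).
#' @param ct_target_control,ct_ref Baseline CTs for target and reference.
#' @param sd Gaussian CT noise (0.15 by default; 0 gives exact tables).
#' @param replicates Technical replicates per condition.
#' @return Data.frame: `condition`, `gene` (`target`/`reference`),
#'   `replicate`, `ct`.
#' @export
generate_qpcr_ct <- function(cfg = sim_config(), ddct = 2,
                             ct_target_control = 24, ct_ref = 18,
                             sd = 0.15, replicates = 3L) {
  stopifnot(inherits(cfg, "trf_sim_config"))
  set.seed(derive_seed(cfg$seed, "qpcr_ct"))
  grid <- expand.grid(replicate = seq_len(replicates),
                      gene = c("target", "reference"),
                      condition = c("control", "treated"),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)[, 3:1]
  mu <- ifelse(grid$gene == "reference", ct_ref,
               ifelse(grid$condition == "control",
                      ct_target_control, ct_target_control + ddct))
  grid$ct <- mu + stats::rnorm(nrow(grid), 0, sd)
  grid
}

#' Generate synthetic caliper measurements of tumor growth
#'
#' Exponential tumor growth from a common starting volume, with a treatment
#' multiplier applied smoothly so that the expected final treated/control
#' volume ratio equals `multiplier`. Volumes get multiplicative log-normal
#' noise and are converted to width/length via a fixed elongation factor
#' (length = 1.3 x width, `volume = width^2 * length / 2`).
#'
#' @param cfg A [sim_config()].
#' @param n_per_group Mice per group.
#' @param days Measurement days (day 0 = treatment start).
#' @param v0 Starting volume, mm^3.
#' @param growth_rate Control exponential growth rate per day.
#' @param multiplier Expected final treated/control volume ratio.
#' @param cv Coefficient of variation of the volume noise.
#' @return Data.frame: `group`, `mouse`, `day`, `width_mm`, `length_mm`.
#' @export
generate_tumor_growth <- function(cfg = sim_config(), n_per_group = 6L,
                                  days = seq(0, 21, by = 3), v0 = 50,
                                  growth_rate = 0.15, multiplier = 0.5,
                                  cv = 0.1) {
  stopifnot(inherits(cfg, "trf_sim_config"))
  if (v0 <= 0 || any(days < 0)) stop("negative dimensions", call. = FALSE)
  set.seed(derive_seed(cfg$seed, "tumor_growth"))
  Tend <- max(days)
  shape <- 1.3  # length/width elongation
  out <- list()
  for (grp in c("control", "treated")) {
    rate <- growth_rate + if (grp == "treated") log(multiplier) / Tend else 0
    for (mouse in seq_len(n_per_group)) {
      vol <- v0 * exp(rate * days)
      if (cv > 0) {
        sdlog <- sqrt(log(1 + cv^2))
        vol <- vol * exp(stats::rnorm(length(days), -sdlog^2 / 2, sdlog))
      }
      width <- (2 * vol / shape)^(1 / 3)
      out[[length(out) + 1L]] <- data.frame(
        group = grp, mouse = sprintf("%s_%d", grp, mouse), day = days,
        width_mm = width, length_mm = shape * width, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate synthetic wound areas at a target healing rate
#'
#' Convenience generator for scratch-assay tables: areas at time 0 and at the
#' endpoint such that the expected wound healing rate equals `whr_pct`.
#'
#' @param cfg A [sim_config()].
#' @param whr_pct Named numeric vector of target healing rates (percent),
#'   one entry per condition.
#' @param area_t0 Baseline wound area (arbitrary units).
#' @param sd Gaussian noise on the endpoint area.
#' @param replicates Replicates per condition.
#' @return Data.frame: `condition`, `replicate`, `area_t0`, `area_t`.
#' @export
generate_wound_areas <- function(cfg = sim_config(),
                                 whr_pct = c(control = 63.5, treated = 13.7),
                                 area_t0 = 100, sd = 2, replicates = 3L) {
  stopifnot(inherits(cfg, "trf_sim_config"), area_t0 > 0)
  set.seed(derive_seed(cfg$seed, "wound_areas"))
  grid <- expand.grid(replicate = seq_len(replicates),
                      condition = names(whr_pct),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)[, 2:1]
  target <- area_t0 * (1 - whr_pct[grid$condition] / 100)
  grid$area_t0 <- area_t0
  grid$area_t <- pmax(0, target + stats::rnorm(nrow(grid), 0, sd))
  grid
}

#' Write a gene-set list to a GMT file
#'
#' @param sets Named list of character vectors of gene ids.
#' @param path Output path.
#' @param description Optional per-set description (recycled).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, description = "synthetic") {
  stopifnot(is.list(sets), !is.null(names(sets)))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, description, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' @param path Path to a GMT file (one set per line: name, description, then
#'   gene ids, tab-separated).
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  stats::setNames(lapply(parts, function(p) p[-(1:2)]),
                  vapply(parts, `[`, "", 1L))
}
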