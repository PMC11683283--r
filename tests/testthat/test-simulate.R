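# Seeded generators: determinism, contracts, planted-signal fidelity.

test_that("configuration invariants are enforced", {
  expect_error(sim_config(trna_len_range = c(90, 70)), "trna_len_range")
  expect_error(sim_config(frag_len = 80), "frag_len")
  expect_error(sim_config(de_fraction = 1.2), "de_fraction")
  expect_error(sim_config(nb_dispersion = 0), "nb_dispersion")
  expect_silent(sim_config(frag_len = 22, trna_len_range = c(70, 90)))
})

test_that("tRNA library generation is byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 11, n_trnas = 50)
  lib1 <- generate_trna_library(cfg)
  lib2 <- generate_trna_library(cfg)
  expect_identical(lib1, lib2)
  expect_identical(nrow(lib1), 50L)
  expect_true(all(nchar(lib1$sequence) >= 70 & nchar(lib1$sequence) <= 90))
  expect_true(all(grepl("^[ACGU]+$", lib1$sequence)))

  f1 <- withr::local_tempfile(fileext = ".fa")
  f2 <- withr::local_tempfile(fileext = ".fa")
  write_rna_fasta(lib1, f1)
  write_rna_fasta(generate_trna_library(cfg), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("planted sites carry the requested mismatches and wobbles", {
  cfg <- sim_config(seed = 21)
  trf <- substr(generate_trna_library(cfg)$sequence[1], 1, 22)

  perfect <- plant_target_site(cfg, trf)
  site_seq <- substr(perfect$utr$sequence, perfect$site_start, perfect$site_end)
  d <- duplex_mfe(trf, site_seq, tm)
  expect_identical(d$comp_rate, 100)

  # 6 mismatches on a 22-nt tRF: at most 16/22 positions pairable
  cfg6 <- sim_config(seed = 21, planted_site = list(
    trf_index = 1, mismatches = 6, gu_wobbles = 0, utr_offset = 151))
  site6 <- plant_target_site(cfg6, trf)
  s6 <- strsplit(substr(site6$utr$sequence, site6$site_start, site6$site_end),
                 "")[[1]]
  tchars <- strsplit(trf, "")[[1]]
  pairable <- vapply(seq_len(22), function(i) {
    pair_allowed(tchars[i], s6[22 - i + 1])
  }, TRUE)
  expect_identical(sum(pairable), 16L)
  expect_lte(complementarity_rate(sum(pairable), 22), 72.7)
  expect_identical(which(!pairable), site6$mismatch_trf_pos)

  # wobbles remain paired but are G.U
  cfgw <- sim_config(seed = 21, planted_site = list(
    trf_index = 1, mismatches = 2, gu_wobbles = 3, utr_offset = 151))
  sitew <- plant_target_site(cfgw, trf)
  sw <- strsplit(substr(sitew$utr$sequence, sitew$site_start, sitew$site_end),
                 "")[[1]]
  for (i in sitew$wobble_trf_pos) {
    b <- sw[22 - i + 1]
    expect_true(pair_allowed(tchars[i], b))
    expect_true(paste0(sort(c(tchars[i], b)), collapse = "") == "GU")
  }
  for (i in sitew$mismatch_trf_pos) {
    expect_false(pair_allowed(tchars[i], sw[22 - i + 1]))
  }
  # all other positions reverse-complement-match the tRF
  untouched <- setdiff(seq_len(22), c(sitew$wobble_trf_pos,
                                      sitew$mismatch_trf_pos))
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  for (i in untouched) {
    expect_identical(sw[22 - i + 1], unname(comp[tchars[i]]))
  }
})

test_that("planted site bounds and argument contracts are checked", {
  cfg <- sim_config(seed = 1, planted_site = list(
    trf_index = 1, mismatches = 0, gu_wobbles = 0, utr_offset = 290))
  trf <- substr(generate_trna_library(cfg)$sequence[1], 1, 22)
  expect_error(plant_target_site(cfg, trf), "does not fit")
  expect_error(plant_target_site(sim_config(seed = 1), substr(trf, 1, 10)),
               "frag_len")
  cfg_bad <- sim_config(seed = 1, planted_site = list(
    trf_index = 1, mismatches = 20, gu_wobbles = 3, utr_offset = 100))
  expect_error(plant_target_site(cfg_bad, trf), "< tRF length")
})

test_that("count generation is reproducible and honours de_fraction", {
  cfg0 <- sim_config(seed = 31, de_fraction = 0, pathway_size = 0)
  sim0 <- generate_counts(cfg0)
  expect_identical(nrow(sim0$truth), 0L)

  cfg <- sim_config(seed = 31)
  s1 <- generate_counts(cfg)
  s2 <- generate_counts(cfg)
  expect_identical(s1$counts, s2$counts)
  expect_identical(dim(s1$counts), c(2000L, 12L))
  expect_identical(levels(s1$groups), c("control", "treated"))
  # planted pathway genes are all planted downward and disjoint from DE set
  expect_true(all(s1$truth$log2fc[s1$truth$class == "pathway"] < 0))
  expect_identical(anyDuplicated(s1$truth$gene_id), 0L)
})

test_that("planted log2 fold changes are recovered empirically at n = 20", {
  cfg <- sim_config(seed = 32, n_genes = 300, n_samples_per_group = 20,
                    de_fraction = 0.2, de_log2fc = 2)
  sim <- generate_counts(cfg)
  ctrl <- sim$counts[, sim$groups == "control"]
  trt <- sim$counts[, sim$groups == "treated"]
  obs <- log2((rowMeans(trt) + 0.5) / (rowMeans(ctrl) + 0.5))
  de <- sim$truth[sim$truth$class == "de", ]
  err <- obs[match(de$gene_id, rownames(sim$counts))] - de$log2fc
  expect_lt(max(abs(err)), 0.8)      # every planted gene individually close
  expect_lt(abs(mean(err)), 0.3)     # no systematic bias
})

test_that("dose-response draws lie on the 4PL curve when noise is off", {
  presets <- .default_preset_noise_free()
  cfg <- sim_config(seed = 41, dose_presets = presets)
  tab <- generate_dose_response("hct8_trf36", cfg)
  p <- presets$hct8_trf36
  expect_equal(tab$viability_pct,
               four_pl(tab$dose_nM, p$top, p$bottom, p$ic50, p$hill),
               tolerance = 1e-12)
  # midpoint: viability at the IC50 dose equals (top+bottom)/2
  presets$hct8_trf36$doses <- c(0.1, 1, p$ic50, 100, 1000)
  cfg2 <- sim_config(seed = 41, dose_presets = presets)
  tab2 <- generate_dose_response("hct8_trf36", cfg2)
  expect_equal(unique(tab2$viability_pct[tab2$dose_nM == p$ic50]),
               (p$top + p$bottom) / 2, tolerance = 1e-12)
  expect_error(generate_dose_response("nope", cfg), "unknown")
  # same seed, same bytes
  cfg3 <- sim_config(seed = 41)
  expect_identical(generate_dose_response("lovo_trf36", cfg3),
                   generate_dose_response("lovo_trf36", cfg3))
})

test_that("qPCR tables plant the intended ddCt exactly at zero noise", {
  cfg <- sim_config(seed = 51)
  ct <- generate_qpcr_ct(cfg, ddct = 1, sd = 0)
  res <- ddct_fold_table(ct)
  expect_identical(res$ddct, 1)
  expect_identical(res$fold, 0.5)
  expect_identical(generate_qpcr_ct(cfg), generate_qpcr_ct(cfg))
})

test_that("tumor growth reaches the planted final volume ratio on average", {
  ratios <- vapply(1:15, function(s) {
    cal <- generate_tumor_growth(sim_config(seed = 600 + s),
                                 n_per_group = 8, multiplier = 0.5)
    growth_summary(cal)$final_volume_ratio
  }, 0)
  expect_lt(abs(mean(ratios) - 0.5), 0.08)
  cfg <- sim_config(seed = 61)
  expect_identical(generate_tumor_growth(cfg), generate_tumor_growth(cfg))
  expect_error(generate_tumor_growth(cfg, v0 = -5), "negative")
})

test_that("wound-area tables hit the requested healing rates", {
  cfg <- sim_config(seed = 71)
  wa <- generate_wound_areas(cfg, whr_pct = c(control = 63.5, treated = 13.7),
                             sd = 0)
  whr <- wound_healing_rate(wa$area_t0, wa$area_t)
  expect_equal(unique(whr[wa$condition == "control"]), 63.5)
  expect_equal(unique(whr[wa$condition == "treated"]), 13.7)
})

test_that("GMT files round-trip gene sets", {
  sets <- list(SET_A = c("g1", "g2", "g3"), SET_B = c("g9"))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  expect_identical(read_gmt(path), sets)
})
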