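# Shared fixtures: one energy model per test run, small RNA helpers.

tm <- energy_model()

rand_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGU", "UGCA", seq), "")[[1]]), collapse = "")
}

# score an explicit duplex pair set (1-based trf/site positions) under the
# model's energy terms; used to verify that reported structures attain the MFE
score_pairs <- function(trf, site, pairs, model = tm) {
  if (!nrow(pairs)) return(Inf)
  ta <- strsplit(trf, "")[[1]]
  sa <- strsplit(site, "")[[1]]
  ord <- order(pairs$trf_pos)
  tp <- pairs$trf_pos[ord]
  sp <- pairs$site_pos[ord]
  stopifnot(all(diff(tp) > 0), all(diff(sp) < 0) || length(sp) == 1)
  ptype <- function(i, j) paste0(ta[i], sa[j])
  is_wob <- function(p) p %in% c("AU", "UA", "GU", "UG")
  e <- model$duplex_init
  e <- e + if (is_wob(ptype(tp[1], sp[1]))) model$terminal_au_gu else 0L
  n <- length(tp)
  e <- e + if (is_wob(ptype(tp[n], sp[n]))) model$terminal_au_gu else 0L
  if (n > 1) {
    for (x in seq_len(n - 1)) {
      a <- tp[x + 1] - tp[x] - 1L
      b <- sp[x] - sp[x + 1] - 1L
      e <- e + if (a == 0 && b == 0) {
        model$stack[ptype(tp[x], sp[x]), ptype(tp[x + 1], sp[x + 1])]
      } else if (a == 0 || b == 0) model$bulge[a + b]
      else model$internal[a + b]
    }
  }
  e / 100
}

# default dose-response presets with the noise switched off
.default_preset_noise_free <- function() {
  lapply(sim_config()$dose_presets, function(x) {
    x$cv <- 0
    x
  })
}
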