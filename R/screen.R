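# Screening: every tRF against a target 3'UTR, thresholded and ranked.

#' Screen a tRF library against a target 3'UTR
#'
#' Scans each fragment over the UTR with [scan_utr()], keeps its best site
#' (lowest MFE; `all_sites = TRUE` retains every merged site), and filters by
#' the free-energy and complementarity thresholds. Hits are sorted by
#' (MFE ascending, complementarity descending, trf_id) with a dense rank on
#' the (MFE, complementarity) key.
#'
#' @param frags Fragment records from [make_fragments()] (columns `id`,
#'   `sequence`), or any data.frame with those columns.
#' @param utr UTR record (list or one-row data.frame with `id`, `sequence`).
#' @param model Energy model from [energy_model()].
#' @param mfe_max Retain hits with MFE <= this value (kcal/mol). The default
#'   (-20) admits strong 22-nt sites with margin; both thresholds are
#'   screening policy, not physics, and should be tuned to the application.
#' @param comp_min Retain hits with complementarity rate >= this value (%).
#' @param window,step Passed to [scan_utr()].
#' @param all_sites Keep all non-overlapping sites per tRF instead of the
#'   single best.
#' @return A data.frame of hits: `rank`, `trf_id`, `utr_id`, `site_start`,
#'   `site_end`, `mfe`, `comp_rate`. Attribute `report` carries a summary
#'   (library size, thresholds, hit count).
#' @export
run_screen <- function(frags, utr, model = energy_model(),
                       mfe_max = -20, comp_min = 72,
                       window = 40L, step = 5L, all_sites = FALSE) {
  stopifnot(is.finite(mfe_max) || mfe_max == Inf,
            is.finite(comp_min) || comp_min == -Inf)
  if (!is.data.frame(frags) || nrow(frags) == 0L) {
    warning("empty tRF library: screen returns no hits")
    hits <- data.frame(rank = integer(0), trf_id = character(0),
                       utr_id = character(0), site_start = integer(0),
                       site_end = integer(0), mfe = numeric(0),
                       comp_rate = numeric(0), stringsAsFactors = FALSE)
    attr(hits, "report") <- list(library_size = 0L, mfe_max = mfe_max,
                                 comp_min = comp_min, n_hits = 0L)
    return(hits)
  }
  rows <- list()
  for (r in seq_len(nrow(frags))) {
    sites <- scan_utr(frags[r, , drop = FALSE], utr, model,
                      window = window, step = step)
    if (nrow(sites) == 0L) next
    if (!all_sites) sites <- sites[1L, , drop = FALSE]  # already MFE-sorted
    rows[[length(rows) + 1L]] <- sites
  }
  tab <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(tab)) {
    tab <- tab[tab$mfe <= mfe_max & tab$comp_rate >= comp_min, , drop = FALSE]
  }
  if (is.null(tab) || nrow(tab) == 0L) {
    hits <- data.frame(rank = integer(0), trf_id = character(0),
                       utr_id = character(0), site_start = integer(0),
                       site_end = integer(0), mfe = numeric(0),
                       comp_rate = numeric(0), stringsAsFactors = FALSE)
  } else {
    tab <- tab[order(tab$mfe, -tab$comp_rate, tab$trf_id), , drop = FALSE]
    key <- paste(tab$mfe, tab$comp_rate)
    hits <- data.frame(rank = as.integer(match(key, unique(key))),
                       tab[, c("trf_id", "utr_id", "site_start", "site_end",
                               "mfe", "comp_rate")],
                       stringsAsFactors = FALSE)
    rownames(hits) <- NULL
  }
  attr(hits, "report") <- list(library_size = nrow(frags), mfe_max = mfe_max,
                               comp_min = comp_min, n_hits = nrow(hits))
  hits
}

#' Write a screen report
#'
#' Writes the hit table as TSV and prints a short human-readable summary to
#' the console (library size, thresholds, hit count).
#'
#' @param hits Output of [run_screen()].
#' @param path Output TSV path.
#' @param quiet Suppress the summary.
#' @return `path`, invisibly.
#' @export
write_screen_report <- function(hits, path, quiet = FALSE) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  rep <- attr(hits, "report")
  if (!quiet && !is.null(rep)) {
    message(sprintf(
      "screen: %d fragments, thresholds MFE <= %.2f kcal/mol, comp >= %.1f %% -> %d hit(s)",
      rep$library_size, rep$mfe_max, rep$comp_min, rep$n_hits))
  }
  invisible(path)
}

#' Read back a screen report TSV
#'
#' @param path TSV written by [write_screen_report()].
#' @return The hit table as a data.frame.
#' @export
read_screen_report <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
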