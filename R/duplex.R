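# Duplex scoring: DP front-end, enumeration oracle, complementarity rate,
# UTR scanning.

.as_rna_chars <- function(seq, what = "sequence") {
  if (length(seq) != 1L || !is.character(seq) || !nzchar(seq)) {
    stop(what, " must be a non-empty character scalar", call. = FALSE)
  }
  x <- strsplit(toupper(seq), "")[[1]]
  x[x == "T"] <- "U"
  bad <- setdiff(unique(x), .BASES)
  if (length(bad)) {
    stop(what, " contains non-RNA characters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  x
}

.revcomp_rna <- function(seq) {
  x <- .as_rna_chars(seq)
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  paste(rev(unname(comp[x])), collapse = "")
}

#' Minimum free energy of an intermolecular RNA:RNA duplex
#'
#' Computes the hybridisation minimum free energy of a small RNA (tRF) bound
#' to a target site by nearest-neighbor dynamic programming. Only
#' intermolecular pairs are formed (the two strands are assumed unstructured),
#' as in standard small-RNA target-site scoring. The optimal structure is a
#' chain of Watson-Crick / G.U pairs, strictly increasing along the tRF and
#' strictly decreasing along the site, interrupted by bulges and internal
#' loops up to `model$max_loop` unpaired bases per strand.
#'
#' @param trf RNA sequence of the small RNA, 5'->3' (character; T accepted and
#'   read as U).
#' @param site RNA sequence of the target site, 5'->3', at most 60 nt.
#' @param model An energy model from [energy_model()].
#' @return An object of class `trf_duplex_result`: list with `mfe` (kcal/mol;
#'   `Inf` when no pair can form), `pairs` (data.frame of 1-based `trf_pos`,
#'   `site_pos`; `trf_pos` increasing, `site_pos` decreasing), `comp_rate`
#'   (percent of tRF positions paired, 1 decimal), and `structure` (two-line
#'   dot-bracket annotation, tRF then site).
#' @examples
#' m <- energy_model()
#' duplex_mfe("GGGGG", "CCCCC", m)$mfe  # -8.95
#' @export
duplex_mfe <- function(trf, site, model = energy_model()) {
  qc <- .as_rna_chars(trf, "trf")
  sc <- .as_rna_chars(site, "site")
  if (length(sc) > 60L) {
    stop("site longer than 60 nt; scan longer sequences with scan_utr()",
         call. = FALSE)
  }
  mp <- .model_for_dp(model)
  res <- .duplex_dp_cpp(.base_code(qc), .base_code(rev(sc)), mp$stack,
                        mp$bulge, mp$internal, mp$init, mp$term,
                        mp$max_loop, mp$big)
  n <- length(qc)
  m <- length(sc)
  if (is.na(res$mfe_cents)) {
    pairs <- data.frame(trf_pos = integer(0), site_pos = integer(0))
    mfe <- Inf
  } else {
    pairs <- data.frame(trf_pos = res$pairs_q,
                        site_pos = m - res$pairs_t + 1L)
    mfe <- res$mfe_cents / 100
  }
  trf_line <- rep(".", n)
  site_line <- rep(".", m)
  trf_line[pairs$trf_pos] <- "("
  site_line[pairs$site_pos] <- ")"
  structure(list(
    mfe = mfe,
    pairs = pairs,
    comp_rate = complementarity_rate(nrow(pairs), n),
    structure = c(trf = paste(trf_line, collapse = ""),
                  site = paste(site_line, collapse = "")),
    trf = paste(qc, collapse = ""),
    site = paste(sc, collapse = "")
  ), class = "trf_duplex_result")
}

#' @export
print.trf_duplex_result <- function(x, ...) {
  cat("RNA:RNA duplex: MFE ",
      if (is.finite(x$mfe)) sprintf("%.2f kcal/mol", x$mfe) else "none (no pair possible)",
      ", ", nrow(x$pairs), " pairs, complementarity ", x$comp_rate, " %\n",
      sep = "")
  cat("  tRF  5'-", x$trf, "-3'  ", x$structure[["trf"]], "\n", sep = "")
  cat("  site 5'-", x$site, "-3'  ", x$structure[["site"]], "\n", sep = "")
  invisible(x)
}

#' Complementarity rate of a duplex
#'
#' Percentage of tRF positions that are paired (Watson-Crick or G.U) in the
#' optimal duplex, reported to one decimal. G.U wobbles count as paired.
#'
#' @param result A `trf_duplex_result`, or directly the number of pairs.
#' @param trf_len Length of the tRF in nucleotides.
#' @return Percentage in `[0, 100]`, rounded to 1 decimal.
#' @examples
#' complementarity_rate(16, 22)  # 72.7
#' @export
complementarity_rate <- function(result, trf_len) {
  n_pairs <- if (inherits(result, "trf_duplex_result")) nrow(result$pairs)
             else as.numeric(result)
  stopifnot(trf_len >= 1)
  round(100 * n_pairs / trf_len, 1)
}

#' Brute-force duplex MFE by structure enumeration
#'
#' Reference implementation used to validate [duplex_mfe()]: enumerates every
#' legal duplex structure (every non-empty chain of allowed pairs, monotone
#' on both strands, with loop sizes within `model$max_loop`) and scores each
#' with the same integer energy terms. Exponential in sequence length; only
#' usable for short sequences (both about 10 nt or fewer).
#'
#' @inheritParams duplex_mfe
#' @return Minimum free energy in kcal/mol (`Inf` when no pair can form).
#' @export
duplex_mfe_brute <- function(trf, site, model = energy_model()) {
  qc <- .base_code(.as_rna_chars(trf, "trf"))
  tc <- .base_code(rev(.as_rna_chars(site, "site")))
  n <- length(qc)
  m <- length(tc)
  mp <- .model_for_dp(model)
  pt <- outer(seq_len(n), seq_len(m),
              function(i, k) .pair_type(.BASES[qc[i] + 1L], .BASES[tc[k] + 1L]))
  term_pen <- ifelse(pt %in% c(0L, 1L, 4L, 5L), mp$term, 0L)
  dim(term_pen) <- dim(pt)
  big <- mp$big
  best <- big

  loop_cost <- function(a, b, p_prev, p_next) {
    if (a == 0L && b == 0L) return(mp$stack[p_prev + 1L, p_next + 1L])
    if (a > mp$max_loop || b > mp$max_loop) return(NA_integer_)
    cost <- if (a == 0L || b == 0L) mp$bulge[a + b] else mp$internal[a + b]
    if (cost >= big) NA_integer_ else cost
  }

  dfs <- function(i, k, e) {
    total <- e + term_pen[i, k] + mp$init
    if (total < best) best <<- total
    if (i == n || k == m) return(invisible())
    for (i2 in (i + 1L):min(n, i + 1L + mp$max_loop)) {
      for (k2 in (k + 1L):min(m, k + 1L + mp$max_loop)) {
        if (pt[i2, k2] < 0L) next
        cost <- loop_cost(i2 - i - 1L, k2 - k - 1L, pt[i, k], pt[i2, k2])
        if (is.na(cost)) next
        dfs(i2, k2, e + cost)
      }
    }
  }

  for (i in seq_len(n)) {
    for (k in seq_len(m)) {
      if (pt[i, k] >= 0L) dfs(i, k, term_pen[i, k])
    }
  }
  if (best >= big) Inf else best / 100
}

#' Scan a 3'UTR for tRF binding sites
#'
#' Slides a window along the UTR, scores the duplex of the tRF with every
#' window via [duplex_mfe()], and merges overlapping hits keeping the
#' lowest-MFE representative (ties broken by leftmost coordinate). UTRs
#' shorter than the window are scored as a single whole-UTR window.
#'
#' @param trf A tRF: either a sequence string or a one-row fragment record
#'   from [make_fragments()] (fields `id`, `sequence`).
#' @param utr The UTR: a sequence string, or a list/one-row data.frame with
#'   fields `id` and `sequence`.
#' @param model Energy model from [energy_model()].
#' @param window Window width in nt (must be >= the tRF length).
#' @param step Step between window starts in nt.
#' @return A data.frame of hits sorted by MFE: `trf_id`, `utr_id`,
#'   `site_start`, `site_end` (1-based inclusive on the UTR sense strand),
#'   `mfe`, `comp_rate`, `n_pairs`. Attribute `duplexes` holds the
#'   corresponding `trf_duplex_result` objects.
#' @export
scan_utr <- function(trf, utr, model = energy_model(), window = 40L, step = 5L) {
  if (is.data.frame(trf)) {
    stopifnot(nrow(trf) == 1L)
    trf_id <- trf$id
    trf_seq <- trf$sequence
  } else {
    trf_id <- "trf"
    trf_seq <- trf
  }
  if (is.data.frame(utr)) {
    stopifnot(nrow(utr) == 1L)
    utr <- as.list(utr)
  }
  if (is.list(utr)) {
    utr_id <- utr$id
    utr_seq <- utr$sequence
  } else {
    utr_id <- "utr"
    utr_seq <- utr
  }
  utr_chars <- .as_rna_chars(utr_seq, "utr")
  L <- length(utr_chars)
  window <- as.integer(window)
  if (window < nchar(trf_seq)) stop("window smaller than the tRF", call. = FALSE)
  if (L <= window) {
    starts <- 1L
    window <- min(window, L)
  } else {
    starts <- unique(c(seq(1L, L - window + 1L, by = as.integer(step)),
                       L - window + 1L))
  }

  hits <- list()
  duplexes <- list()
  for (s in starts) {
    win <- paste(utr_chars[s:(s + window - 1L)], collapse = "")
    d <- duplex_mfe(trf_seq, win, model)
    if (!is.finite(d$mfe)) next
    site_abs <- s + d$pairs$site_pos - 1L
    hits[[length(hits) + 1L]] <- data.frame(
      trf_id = trf_id, utr_id = utr_id,
      site_start = min(site_abs), site_end = max(site_abs),
      mfe = d$mfe, comp_rate = d$comp_rate, n_pairs = nrow(d$pairs),
      stringsAsFactors = FALSE)
    duplexes[[length(hits)]] <- d
  }
  if (!length(hits)) {
    out <- data.frame(trf_id = character(0), utr_id = character(0),
                      site_start = integer(0), site_end = integer(0),
                      mfe = numeric(0), comp_rate = numeric(0),
                      n_pairs = integer(0), stringsAsFactors = FALSE)
    attr(out, "duplexes") <- list()
    return(out)
  }
  tab <- do.call(rbind, hits)
  ord <- order(tab$mfe, tab$site_start)
  tab <- tab[ord, , drop = FALSE]
  duplexes <- duplexes[ord]

  # greedy merge: keep lowest-MFE representative of overlapping hits
  keep <- logical(nrow(tab))
  occupied <- matrix(numeric(0), ncol = 2)
  for (r in seq_len(nrow(tab))) {
    s1 <- tab$site_start[r]; e1 <- tab$site_end[r]
    overlaps <- nrow(occupied) > 0 &&
      any(s1 <= occupied[, 2] & e1 >= occupied[, 1])
    if (!overlaps) {
      keep[r] <- TRUE
      occupied <- rbind(occupied, c(s1, e1))
    }
  }
  out <- tab[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "duplexes") <- duplexes[keep]
  out
}
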