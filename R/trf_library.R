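# tRF library construction: FASTA IO and terminal-fragment slicing.

#' Read RNA sequences from a FASTA file
#'
#' Reads a FASTA file through Biostrings, normalises T to U, and validates
#' the alphabet. Duplicate ids are disambiguated with a numeric suffix
#' (with a warning); empty files, empty records and non-nucleotide letters
#' are errors naming the offending record.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id` and `sequence` (RNA, uppercase),
#'   in file order.
#' @export
read_rna_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- sub("\\s.*$", "", names(set))
  seqs <- toupper(as.character(set))
  seqs <- gsub("T", "U", seqs, fixed = TRUE)
  for (i in seq_along(seqs)) {
    if (!nzchar(seqs[i])) {
      stop("record '", ids[i], "' has an empty sequence", call. = FALSE)
    }
    bad <- setdiff(unique(strsplit(seqs[i], "")[[1]]), .BASES)
    if (length(bad)) {
      stop("record '", ids[i], "' contains non-nucleotide characters: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  if (anyDuplicated(ids)) {
    warning("duplicate FASTA ids disambiguated with numeric suffixes")
    ids <- make.unique(ids, sep = "_")
  }
  data.frame(id = ids, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Write RNA sequences to a FASTA file
#'
#' @param records A data.frame with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rna_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Build candidate tRF records from tRNA sequences
#'
#' Slices terminal fragments (the fragment classes generated by nucleolytic
#' cleavage at tRNA ends): 5' fragments start at the tRNA 5' terminus, 3'
#' fragments end at the 3' terminus. Internal fragments are not produced.
#' tRNAs shorter than a requested length are skipped for that length with a
#' warning.
#'
#' @param trnas A data.frame of tRNA records (`id`, `sequence`), e.g. from
#'   [read_rna_fasta()] or [generate_trna_library()].
#' @param lengths Integer vector of fragment lengths in nt. The default
#'   covers the usual tRF size range, 18-34 nt; 22 nt is the canonical
#'   5'-tRF length used throughout this package's examples.
#' @param ends Character subset of `c("five_prime", "three_prime")`.
#' @return A data.frame of fragment records: `id` (scheme
#'   `{parent}_{5p|3p}_{length}`), `parent_id`, `end`, `offset` (0-based
#'   start in the parent), `length`, `sequence`.
#' @examples
#' lib <- data.frame(id = "trna1", sequence = strrep("ACGU", 19))
#' make_fragments(lib, lengths = 22, ends = "five_prime")
#' @export
make_fragments <- function(trnas, lengths = 18:34,
                           ends = c("five_prime", "three_prime")) {
  stopifnot(is.data.frame(trnas), nrow(trnas) >= 1L)
  if (length(lengths) == 0L) stop("no fragment lengths requested", call. = FALSE)
  lengths <- as.integer(lengths)
  stopifnot(all(lengths >= 1L))
  ends <- match.arg(ends, c("five_prime", "three_prime"), several.ok = TRUE)

  out <- list()
  skipped <- character(0)
  for (r in seq_len(nrow(trnas))) {
    parent <- trnas$id[r]
    seq <- trnas$sequence[r]
    plen <- nchar(seq)
    for (len in lengths) {
      if (len > plen) {
        skipped <- c(skipped, sprintf("%s (len %d < %d)", parent, plen, len))
        next
      }
      for (end in ends) {
        offset <- if (end == "five_prime") 0L else plen - len
        out[[length(out) + 1L]] <- data.frame(
          id = sprintf("%s_%s_%d", parent,
                       if (end == "five_prime") "5p" else "3p", len),
          parent_id = parent, end = end, offset = offset, length = len,
          sequence = substr(seq, offset + 1L, offset + len),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(skipped)) {
    warning("skipped fragments for short parents: ",
            paste(unique(skipped), collapse = "; "))
  }
  frags <- do.call(rbind, out)
  rownames(frags) <- NULL
  frags
}

#' Write tRF fragments to FASTA
#'
#' The id scheme `{parent}_{5p|3p}_{length}` round-trips through
#' [read_rna_fasta()] and [parse_fragment_ids()].
#'
#' @param frags Fragment records from [make_fragments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments_fasta <- function(frags, path) {
  write_rna_fasta(frags, path)
}

#' Recover (parent, end, length) from fragment ids
#'
#' @param ids Character vector of ids in the [make_fragments()] scheme.
#' @return A data.frame with `parent_id`, `end`, `length`.
#' @export
parse_fragment_ids <- function(ids) {
  m <- regmatches(ids, regexec("^(.*)_(5p|3p)_(\\d+)$", ids))
  bad <- vapply(m, length, 1L) != 4L
  if (any(bad)) {
    stop("ids not in the {parent}_{5p|3p}_{length} scheme: ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  data.frame(
    parent_id = vapply(m, `[`, "", 2L),
    end = ifelse(vapply(m, `[`, "", 3L) == "5p", "five_prime", "three_prime"),
    length = as.integer(vapply(m, `[`, "", 4L)),
    stringsAsFactors = FALSE)
}
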