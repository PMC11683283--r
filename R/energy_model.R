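#' @useDynLib trfscreen, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Pair-type codes shared with the C++ dynamic program.
# 0 AU, 1 UA, 2 CG, 3 GC, 4 GU, 5 UG; -1 = not pairable.
.PAIR_TYPES <- c("AU", "UA", "CG", "GC", "GU", "UG")
.BASES <- c("A", "C", "G", "U")

# md5 of the shipped stack table; guards against silent edits of the
# thermodynamic resource.
.STACKS_MD5 <- "3a60b97972bb8ee2cb665c0b8b2c241f"

.base_code <- function(x) {
  code <- match(x, .BASES) - 1L
  if (anyNA(code)) {
    stop("sequence contains non-RNA characters: ",
         paste(unique(x[is.na(code)]), collapse = ", "), call. = FALSE)
  }
  code
}

.pair_type <- function(x, y) {
  key <- paste0(x, y)
  pt <- match(key, .PAIR_TYPES) - 1L
  ifelse(is.na(pt), -1L, pt)
}

#' Is an RNA base pair allowed in a duplex?
#'
#' Watson-Crick (A-U, C-G) and wobble (G-U) pairs are allowed; all other
#' combinations are not.
#'
#' @param x,y Single RNA bases, characters in `A`, `C`, `G`, `U`.
#' @return Logical scalar (vectorised over `x`/`y`).
#' @examples
#' pair_allowed("G", "C")  # TRUE
#' pair_allowed("G", "U")  # TRUE (wobble)
#' pair_allowed("A", "G")  # FALSE
#' @export
pair_allowed <- function(x, y) {
  stopifnot(all(x %in% .BASES), all(y %in% .BASES))
  .pair_type(x, y) >= 0L
}

#' Nearest-neighbor energy model for intermolecular RNA:RNA duplexes
#'
#' Loads the Turner 2004 dG37 stacking parameters (Watson-Crick and G.U
#' entries) and loop-initiation tables shipped with the package, and combines
#' them with the duplex-initiation and terminal-pair penalties into the model
#' used by [duplex_mfe()]. Energies are held internally in integer
#' centi-kcal/mol so that sums are exact and independent of summation order.
#'
#' The model scores a duplex as the sum of adjacent base-pair stack energies,
#' bulge/internal-loop size penalties (Jacobson-Stockmayer extrapolation
#' `dG(6) + lxc * log(n/6)` above size 6), a duplex-initiation term, and a
#' penalty for each duplex end closed by an A.U or G.U pair. Dangling ends
#' and coaxial stacking are not modelled.
#'
#' @param duplex_init Duplex initiation free energy, kcal/mol.
#' @param terminal_au_gu Penalty per helix end closed by A.U or G.U, kcal/mol.
#' @param lxc Jacobson-Stockmayer extrapolation coefficient, kcal/mol.
#' @param max_loop Maximum number of unpaired bases allowed on either strand
#'   between two consecutive pairs.
#' @return An object of class `trf_energy_model`: list with the 6x6 stack
#'   matrix (centi-kcal, rows/cols in order AU, UA, CG, GC, GU, UG), loop
#'   penalty vectors, and the scalar terms.
#' @export
energy_model <- function(duplex_init = 4.09, terminal_au_gu = 0.45,
                         lxc = 1.079, max_loop = 15L) {
  stopifnot(max_loop >= 1L)
  path <- system.file("extdata", "turner2004_stacks.tsv", package = "trfscreen")
  md5 <- unname(tools::md5sum(path))
  if (!identical(md5, .STACKS_MD5)) {
    stop("stack parameter table checksum mismatch (", md5,
         "); the shipped thermodynamic resource has been altered", call. = FALSE)
  }
  stacks <- utils::read.delim(path, stringsAsFactors = FALSE)
  loops <- utils::read.delim(
    system.file("extdata", "turner2004_loops.tsv", package = "trfscreen"),
    stringsAsFactors = FALSE)

  stack_e <- matrix(NA_integer_, 6, 6, dimnames = list(.PAIR_TYPES, .PAIR_TYPES))
  put <- function(x, y, w, z, cents) {
    p1 <- .pair_type(x, w)
    p2 <- .pair_type(y, z)
    stopifnot(p1 >= 0L, p2 >= 0L)
    stack_e[p1 + 1L, p2 + 1L] <<- cents
  }
  for (r in seq_len(nrow(stacks))) {
    top <- strsplit(stacks$top5p3p[r], "")[[1]]     # 5'-XY-3'
    bot <- strsplit(stacks$bottom3p5p[r], "")[[1]]  # 3'-WZ-5'
    cents <- as.integer(round(stacks$dg37_kcal_mol[r] * 100))
    put(top[1], top[2], bot[1], bot[2], cents)
    # 180-degree rotation: 5'-ZW-3'/3'-YX-5' is the same physical stack
    put(bot[2], bot[1], top[2], top[1], cents)
  }
  if (anyNA(stack_e)) stop("incomplete stack table", call. = FALSE)

  loop_cents <- function(type) {
    tab <- loops[loops$loop_type == type, ]
    base <- integer(max_loop * 2L)
    known <- as.integer(round(tab$dg37_kcal_mol * 100))
    top_size <- max(tab$size)
    g6 <- tab$dg37_kcal_mol[tab$size == top_size]
    for (n in seq_along(base)) {
      if (n %in% tab$size) {
        base[n] <- known[match(n, tab$size)]
      } else if (n > top_size) {
        base[n] <- as.integer(round(100 * (g6 + lxc * log(n / top_size))))
      } else {
        base[n] <- NA_integer_  # size not in table and not extrapolable
      }
    }
    base
  }
  bulge <- loop_cents("bulge")
  internal <- loop_cents("internal")
  internal[1] <- NA_integer_  # internal loop needs >= 1 unpaired base per side

  structure(list(
    stack = stack_e,
    bulge = bulge,
    internal = internal,
    duplex_init = as.integer(round(duplex_init * 100)),
    terminal_au_gu = as.integer(round(terminal_au_gu * 100)),
    lxc = lxc,
    max_loop = as.integer(max_loop)
  ), class = "trf_energy_model")
}

#' @export
print.trf_energy_model <- function(x, ...) {
  cat("Nearest-neighbor RNA:RNA duplex energy model (dG37, kcal/mol)\n")
  cat("  duplex initiation: ", x$duplex_init / 100, "\n", sep = "")
  cat("  terminal A.U/G.U penalty: ", x$terminal_au_gu / 100, "\n", sep = "")
  cat("  max loop size per strand: ", x$max_loop, "\n", sep = "")
  cat("  stack energies (kcal/mol):\n")
  print(x$stack / 100)
  invisible(x)
}

# Convert an energy model to the flat integer form the C++ core consumes.
.model_for_dp <- function(model) {
  stopifnot(inherits(model, "trf_energy_model"))
  big <- .Machine$integer.max %/% 4L
  bulge <- model$bulge
  internal <- model$internal
  bulge[is.na(bulge)] <- big
  internal[is.na(internal)] <- big
  list(stack = model$stack, bulge = bulge, internal = internal,
       init = model$duplex_init, term = model$terminal_au_gu,
       max_loop = model$max_loop, big = big)
}
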