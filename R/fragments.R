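# Monoisotopic residue masses (Da), standard 20 amino acids.
# Sources: IUPAC atomic masses; values as tabulated in every proteomics tool.
RESIDUE_MASS <- c(
  G =  57.02146, A =  71.03711, S =  87.03203, P =  97.05276,
  V =  99.06841, T = 101.04768, C = 103.00919, L = 113.08406,
  I = 113.08406, N = 114.04293, D = 115.02694, Q = 128.05858,
  K = 128.09496, E = 129.04259, M = 131.04049, H = 137.05891,
  F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931
)

PROTON_MASS <- 1.007276466
WATER_MASS  <- 18.010565

#' Construct a peptide
#'
#' A peptide is a sequence over the 20 standard residues plus positioned
#' monoisotopic mass modifications and a precursor charge. Modifications use
#' 1-based residue positions; position 0 denotes the N-terminus and
#' `nchar(sequence) + 1` the C-terminus.
#'
#' @param sequence Character scalar, uppercase one-letter residue codes,
#'   length >= 2.
#' @param modifications Either `NULL`, a `data.frame` with columns `position`
#'   (integer) and `delta` (Da), or a compact string `"pos:delta;pos:delta"`
#'   as used in PSM tables.
#' @param charge Positive integer precursor charge.
#' @return An object of class `"peptide"`.
#' @examples
#' peptide("PEPTIDE", "4:79.96633", charge = 2)
#' @export
peptide <- function(sequence, modifications = NULL, charge = 2L) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L < 2L)
    stop("peptide sequence must have length >= 2, got '", sequence, "'")
  res <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(res, names(RESIDUE_MASS))
  if (length(bad))
    stop("unknown residue letter(s) in '", sequence, "': ",
         paste(unique(bad), collapse = ", "))
  mods <- parse_modifications(modifications)
  if (nrow(mods) && any(mods$position < 0L | mods$position > L + 1L))
    stop("modification position out of range for peptide of length ", L)
  charge <- as.integer(charge)
  stopifnot(length(charge) == 1L, !is.na(charge), charge >= 1L)
  structure(list(sequence = sequence, residues = res,
                 modifications = mods, charge = charge),
            class = "peptide")
}

#' Parse a compact modification string
#'
#' The PSM-table dialect is `"pos:delta"` pairs separated by semicolons,
#' e.g. `"0:42.010565;4:79.96633"`. Position 0 is the N-terminus and
#' L+1 the C-terminus. Empty or `NA` input yields zero modifications.
#'
#' @param x `NULL`, `NA`, a compact string, or a data.frame with columns
#'   `position` and `delta` (passed through).
#' @return data.frame with integer `position` and numeric `delta`.
#' @export
parse_modifications <- function(x) {
  empty <- data.frame(position = integer(), delta = numeric())
  if (is.null(x)) return(empty)
  if (is.data.frame(x)) {
    stopifnot(all(c("position", "delta") %in% names(x)))
    if (!nrow(x)) return(empty)
    out <- data.frame(position = as.integer(x$position),
                      delta = as.numeric(x$delta))
    return(out[order(out$position), , drop = FALSE])
  }
  stopifnot(is.character(x), length(x) == 1L)
  if (is.na(x) || !nzchar(trimws(x))) return(empty)
  toks <- strsplit(trimws(x), ";", fixed = TRUE)[[1L]]
  toks <- toks[nzchar(toks)]
  parts <- strsplit(toks, ":", fixed = TRUE)
  ok <- vapply(parts, length, 1L) == 2L
  if (!all(ok))
    stop("bad modification token(s): ", paste(toks[!ok], collapse = ", "))
  pos <- suppressWarnings(as.integer(vapply(parts, `[[`, "", 1L)))
  delta <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(pos) || anyNA(delta))
    stop("unparseable modification string: '", x, "'")
  out <- data.frame(position = pos, delta = delta)
  out[order(out$position), , drop = FALSE]
}

#' @export
print.peptide <- function(x, ...) {
  cat("<peptide> ", x$sequence, " (", x$charge, "+)", sep = "")
  if (nrow(x$modifications))
    cat("  mods: ", paste0(x$modifications$position, ":",
                           sprintf("%+.5f", x$modifications$delta),
                           collapse = "; "), sep = "")
  cat("\n")
  invisible(x)
}

as_peptide <- function(x, modifications = NULL, charge = 2L) {
  if (inherits(x, "peptide")) x else peptide(x, modifications, charge)
}

#' Monoisotopic peptide mass
#'
#' Sum of residue monoisotopic masses plus one water plus all modification
#' deltas (neutral, uncharged mass).
#'
#' @param p A [peptide()] or a plain sequence string.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptide_monoisotopic_mass("GG")  # 132.0535
#' @export
peptide_monoisotopic_mass <- function(p) {
  p <- as_peptide(p)
  sum(RESIDUE_MASS[p$residues]) + WATER_MASS + sum(p$modifications$delta)
}

#' Theoretical singly charged b- and y-ions
#'
#' Computes the m/z of all singly protonated b- and y-ions with ordinals
#' 1..L-1 for a (possibly modified) peptide. Only the b/y series at charge
#' 1+ is produced: for high-resolution HCD spectra these carry nearly all
#' identifiable backbone information, and multiply charged product ions are
#' handled, if at all, by deconvolution upstream. A modification at residue
#' position k shifts b_i for i >= k and y_j for j >= L-k+1; N-terminal
#' modifications (position 0) shift every b-ion, C-terminal (L+1) every
#' y-ion.
#'
#' @param p A [peptide()] or sequence string.
#' @return data.frame with columns `series` ("b"/"y"), `ordinal` (1..L-1)
#'   and `mz` (Th, singly protonated).
#' @examples
#' theoretical_by_ions("PE")
#' @export
theoretical_by_ions <- function(p) {
  p <- as_peptide(p)
  L <- length(p$residues)
  masses <- unname(RESIDUE_MASS[p$residues])
  # distribute modification deltas onto residue slots:
  # N-term -> residue 1, C-term -> residue L
  modv <- numeric(L)
  if (nrow(p$modifications)) {
    pos <- pmin(pmax(p$modifications$position, 1L), L)
    for (i in seq_len(nrow(p$modifications)))
      modv[pos[i]] <- modv[pos[i]] + p$modifications$delta[i]
  }
  # N-term mod must stay on b-side, C-term on y-side, which the clamping
  # above guarantees (position 0 -> residue 1, L+1 -> residue L).
  total <- masses + modv
  ord <- seq_len(L - 1L)
  b_mz <- cumsum(total)[ord] + PROTON_MASS
  y_mz <- cumsum(rev(total))[ord] + WATER_MASS + PROTON_MASS
  data.frame(series = rep(c("b", "y"), each = L - 1L),
             ordinal = c(ord, ord),
             mz = c(b_mz, y_mz))
}
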