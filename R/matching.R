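#' Annotate a spectrum with a peptide's theoretical ions
#'
#' Each theoretical b/y ion is matched to at most one peak: the nearest in
#' ppm within `tol_ppm` (equidistant peaks resolve to the lower m/z). One
#' observed peak may annotate several theoretical ions. The matched
#' intensity fraction is computed over the deduplicated set of annotated
#' peaks, relative to the total intensity of the (filtered) spectrum handed
#' in — the matcher never sees the unfiltered peak list.
#'
#' @param spec A [spectrum()] with peaks sorted ascending (any `spectrum`
#'   object satisfies this).
#' @param ions data.frame from [theoretical_by_ions()].
#' @param tol_ppm Fragment mass tolerance in ppm (default 20, a common
#'   Orbitrap HCD setting).
#' @return Object of class `"match_result"`: `matched_ions` (data.frame with
#'   series, ordinal, theoretical_mz, peak_index, mass_error_ppm),
#'   `matched_sites` (integer cleavage-site indices; site i is evidenced by
#'   b_i and/or y_{L-i}), `annotated_peak_indices`, `n_b`, `n_y`,
#'   `n_unmatched`, `matched_intensity_fraction` and `peptide_length`.
#' @export
match_peaks <- function(spec, ions, tol_ppm = 20) {
  stopifnot(inherits(spec, "spectrum"), tol_ppm > 0)
  L <- max(ions$ordinal) + 1L
  pk_mz <- spec$peaks$mz
  pk_int <- spec$peaks$intensity
  empty <- data.frame(series = character(), ordinal = integer(),
                      theoretical_mz = numeric(), peak_index = integer(),
                      mass_error_ppm = numeric())
  if (!length(pk_mz)) {
    return(structure(list(matched_ions = empty, matched_sites = integer(),
                          annotated_peak_indices = integer(),
                          matched_intensity_fraction = 0,
                          n_b = 0L, n_y = 0L, n_unmatched = nrow(ions),
                          peptide_length = L),
                     class = "match_result"))
  }
  tmz <- ions$mz
  pos <- findInterval(tmz, pk_mz)
  lo <- pmax(pos, 1L)
  hi <- pmin(pos + 1L, length(pk_mz))
  d_lo <- abs(pk_mz[lo] - tmz)
  d_hi <- abs(pk_mz[hi] - tmz)
  d_lo[pos < 1L] <- Inf
  d_hi[pos + 1L > length(pk_mz)] <- Inf
  # equidistant -> lower mz wins
  pick <- ifelse(d_lo <= d_hi, lo, hi)
  err <- (pk_mz[pick] - tmz) / tmz * 1e6
  hit <- abs(err) <= tol_ppm
  mi <- data.frame(series = ions$series[hit],
                   ordinal = ions$ordinal[hit],
                   theoretical_mz = tmz[hit],
                   peak_index = pick[hit],
                   mass_error_ppm = err[hit])
  site <- ifelse(mi$series == "b", mi$ordinal, L - mi$ordinal)
  annotated <- sort(unique(mi$peak_index))
  frac <- if (sum(pk_int) > 0) sum(pk_int[annotated]) / sum(pk_int) else 0
  structure(list(matched_ions = mi,
                 matched_sites = sort(unique(as.integer(site))),
                 annotated_peak_indices = annotated,
                 matched_intensity_fraction = frac,
                 n_b = sum(mi$series == "b"),
                 n_y = sum(mi$series == "y"),
                 n_unmatched = nrow(ions) - nrow(mi),
                 peptide_length = L),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf(
    "<match_result> L=%d  b=%d y=%d unmatched=%d  sites=%d  intensity %.3f\n",
    x$peptide_length, x$n_b, x$n_y, x$n_unmatched,
    length(x$matched_sites), x$matched_intensity_fraction))
  invisible(x)
}

#' Count residues flanked on both sides by matched ions
#'
#' The matched sequence stretch counts residues (not runs) whose two
#' adjacent cleavage sites are both evidenced by matched product ions.
#' Terminal residues have only one internal neighbour site, so under the
#' strict both-sides reading they never count; `count_terminal_residues`
#' exists for sensitivity analysis and treats the peptide termini as
#' always-evidenced boundaries.
#'
#' @param matched_sites Integer vector of cleavage-site indices in 1..L-1.
#' @param L Peptide length.
#' @param count_terminal_residues Logical, default `FALSE`.
#' @return Integer stretch-residue count.
#' @examples
#' stretch_residue_count(c(1, 2, 3), 7)  # residues 2 and 3 -> 2
#' @export
stretch_residue_count <- function(matched_sites, L,
                                  count_terminal_residues = FALSE) {
  matched_sites <- as.integer(matched_sites)
  if (length(matched_sites) &&
      (min(matched_sites) < 1L || max(matched_sites) > L - 1L))
    stop("matched_sites must lie in 1..L-1")
  if (L < 2L) return(0L)
  evid <- logical(L + 1L)          # boundaries 0..L; index shift +1
  evid[matched_sites + 1L] <- TRUE
  if (count_terminal_residues) evid[c(1L, L + 1L)] <- TRUE
  res <- seq_len(L)
  sum(evid[res] & evid[res + 1L])  # residue i flanked by sites i-1 and i
}
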