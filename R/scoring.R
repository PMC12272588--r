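#' The canonical rescoring value
#'
#' The score of a peptide-spectrum match is the plain unweighted sum of the
#' number of matched b-ions, matched y-ions and stretch residues (residues
#' flanked on both sides by matched ions). It is an integer between 0 and
#' 3L-4: a fully matched length-L peptide has 2(L-1) ions and L-2 stretch
#' residues.
#'
#' @param m A [match_peaks()] result.
#' @param L Peptide length; defaults to the length recorded in `m`.
#' @return Integer score.
#' @export
uniscore <- function(m, L = m$peptide_length) {
  stopifnot(inherits(m, "match_result"))
  as.integer(m$n_b + m$n_y + stretch_residue_count(m$matched_sites, L))
}

#' Score weights for the parameterised site/stretch variant
#'
#' Cleavage sites evidenced by exactly one ion series weigh `w_single`,
#' sites evidenced by both b and y weigh `w_double`, and the stretch term
#' enters as `w_stretch * stretch^stretch_exponent`. With weights
#' (0.5, 1, 1) and exponent 1 the variant ranks PSMs identically to
#' 0.5*(n_b + n_y) + stretch, i.e. to the canonical unweighted ion sum —
#' which is why the plain sum is the default and this variant exists only
#' to reproduce the weighting ablation.
#'
#' @param w_single,w_double,w_stretch Non-negative weights.
#' @param stretch_exponent 1 or 2.
#' @export
score_weights <- function(w_single = 0.5, w_double = 1, w_stretch = 1,
                          stretch_exponent = 1L) {
  if (any(c(w_single, w_double, w_stretch) < 0))
    stop("score weights must be non-negative")
  stopifnot(stretch_exponent %in% c(1L, 2L))
  structure(list(w_single = w_single, w_double = w_double,
                 w_stretch = w_stretch,
                 stretch_exponent = as.integer(stretch_exponent)),
            class = "score_weights")
}

#' Weighted site/stretch score variant
#'
#' @param m A [match_peaks()] result.
#' @param L Peptide length; defaults to the length recorded in `m`.
#' @param w A [score_weights()].
#' @return Numeric score.
#' @export
weighted_site_score <- function(m, L = m$peptide_length, w = score_weights()) {
  stopifnot(inherits(m, "match_result"), inherits(w, "score_weights"))
  mi <- m$matched_ions
  if (nrow(mi)) {
    site <- ifelse(mi$series == "b", mi$ordinal, L - mi$ordinal)
    bs <- unique(site[mi$series == "b"])
    ys <- unique(site[mi$series == "y"])
    n_double <- length(intersect(bs, ys))
    n_single <- length(union(bs, ys)) - n_double
  } else {
    n_single <- n_double <- 0L
  }
  stretch <- stretch_residue_count(m$matched_sites, L)
  w$w_single * n_single + w$w_double * n_double +
    w$w_stretch * stretch^w$stretch_exponent
}

#' Morpheus-style comparison score
#'
#' Number of matched product ions plus the fraction of spectrum intensity
#' assigned to them; the fractional part is always < 1, so the integer part
#' is the ion count.
#'
#' @param m A [match_peaks()] result.
#' @return Numeric score >= 0.
#' @export
morpheus_score <- function(m) {
  stopifnot(inherits(m, "match_result"))
  (m$n_b + m$n_y) + m$matched_intensity_fraction
}

#' Generic-style comparison score (pluggable)
#'
#' A scorer over exactly four components: peptide length, total fragment
#' hits, b-ion hits and the matched intensity ratio. The published formula
#' behind the name is not restated here; the shipped default,
#' `(hits + 0.5 * n_b + intensity_fraction) / log2(L)`, is NON-CANONICAL —
#' a documented stand-in that is monotone non-decreasing in total hits at
#' fixed other components. Supply `fn` to plug in any other formula over
#' `(length, hits, b_hits, intensity_fraction)`. Never used by the default
#' pipeline.
#'
#' @param m A [match_peaks()] result.
#' @param L Peptide length; defaults to the length recorded in `m`.
#' @param fn Optional replacement `function(length, hits, b_hits, frac)`.
#' @return Numeric score >= 0.
#' @export
generic_score <- function(m, L = m$peptide_length, fn = NULL) {
  stopifnot(inherits(m, "match_result"))
  hits <- m$n_b + m$n_y
  if (is.null(fn))
    fn <- function(length, hits, b_hits, frac)
      (hits + 0.5 * b_hits + frac) / log2(pmax(length, 2))
  fn(L, hits, m$n_b, m$matched_intensity_fraction)
}

#' Sum of the canonical score and the Generic-style score
#'
#' Provided for the score-comparison narrative; intensity-fraction terms
#' penalise chimeric spectra, so this combination is not used by the
#' default pipeline.
#'
#' @inheritParams generic_score
#' @return Numeric score.
#' @export
uniscore_plus_generic <- function(m, L = m$peptide_length, fn = NULL) {
  uniscore(m, L) + generic_score(m, L, fn)
}

#' Component tuple of a match, for feature export
#'
#' @param m A [match_peaks()] result.
#' @param L Peptide length; defaults to the length recorded in `m`.
#' @return Named numeric vector: n_b, n_y, n_single_sites, n_double_sites,
#'   n_stretch, n_stretch_sq, n_unmatched, peptide_length,
#'   length_minus_stretch, matched_intensity_fraction, uniscore.
#' @export
score_components <- function(m, L = m$peptide_length) {
  stopifnot(inherits(m, "match_result"))
  mi <- m$matched_ions
  if (nrow(mi)) {
    site <- ifelse(mi$series == "b", mi$ordinal, L - mi$ordinal)
    bs <- unique(site[mi$series == "b"])
    ys <- unique(site[mi$series == "y"])
    n_double <- length(intersect(bs, ys))
    n_single <- length(union(bs, ys)) - n_double
  } else n_single <- n_double <- 0L
  stretch <- stretch_residue_count(m$matched_sites, L)
  c(n_b = m$n_b, n_y = m$n_y,
    n_single_sites = n_single, n_double_sites = n_double,
    n_stretch = stretch, n_stretch_sq = stretch^2,
    n_unmatched = m$n_unmatched, peptide_length = L,
    length_minus_stretch = L - stretch,
    matched_intensity_fraction = m$matched_intensity_fraction,
    uniscore = m$n_b + m$n_y + stretch)
}
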