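#' Rescore candidate PSMs against their spectra
#'
#' The full pipeline: spectra are (optionally) deisotoped, filtered to the
#' top-N peaks per m/z bin, and every merged candidate is annotated with
#' its theoretical b/y ions and scored by the unweighted ion + stretch sum.
#' Per spectrum, co-isolated candidates are accepted by the chimera rule
#' (rejected when more than half of their annotated peaks are already
#' claimed). Target-decoy q-values are then computed at the PSM level, at
#' the peptide level (bare sequence only), and — when a protein database is
#' supplied — at the protein-group level via parsimonious inference.
#'
#' @param spectra List of [spectrum()] objects or a path to an MGF file.
#' @param psm_tables Named list (name = engine) of [load_psm_table()]
#'   results or of TSV paths.
#' @param fasta Optional `AAStringSet` or FASTA path (targets + decoys +
#'   optional entrapment) enabling protein-group inference.
#' @param filter_cfg A [peak_filter_config()]; default 12 peaks / 100 Th.
#' @param tol_ppm Fragment match tolerance (ppm).
#' @param chimera_cfg A [chimera_config()]; default rejects > 50% shared.
#' @param alpha FDR level applied at every level; default 0.01.
#' @param estimator "DT" or "DTD", see [fdr_curve()].
#' @param deisotope Apply [deisotope_and_deconvolute()] before filtering.
#' @param il_equate Equate I/L at the peptide-collapse stage.
#' @param entrapment_prefix,decoy_prefix Accession prefixes.
#' @return Object of class `"uniscore_run"`; see [summary.uniscore_run()].
#' @export
rescore <- function(spectra, psm_tables, fasta = NULL,
                    filter_cfg = peak_filter_config(), tol_ppm = 20,
                    chimera_cfg = chimera_config(), alpha = 0.01,
                    estimator = c("DT", "DTD"), deisotope = FALSE,
                    il_equate = FALSE, entrapment_prefix = "ENTRAP_",
                    decoy_prefix = "rev_") {
  estimator <- match.arg(estimator)
  if (is.character(spectra)) spectra <- read_mgf(spectra)
  if (length(psm_tables) && is.character(psm_tables[[1L]])) {
    stopifnot(!is.null(names(psm_tables)))
    psm_tables <- lapply(names(psm_tables), function(nm)
      load_psm_table(psm_tables[[nm]], nm))
  }
  merged <- label_entrapment(merge_engines(psm_tables), entrapment_prefix)
  spec_ids <- vapply(spectra, `[[`, "", "spectrum_id")
  if (anyDuplicated(spec_ids)) stop("duplicate spectrum ids in input")
  prepped <- lapply(spectra, function(s) {
    if (deisotope) s <- deisotope_and_deconvolute(s)
    filter_top_n_per_bin(s, filter_cfg)
  })
  names(prepped) <- spec_ids

  known <- merged$spectrum_id %in% spec_ids
  n_skipped <- sum(!known)
  if (n_skipped)
    warning(n_skipped, " candidate(s) reference spectra absent from the ",
            "peak list; skipped")
  merged <- merged[known, , drop = FALSE]

  # score every candidate
  n <- nrow(merged)
  match_results <- vector("list", n)
  uniscores <- integer(n)
  comp <- matrix(0, n, 11L)
  ion_cache <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    key <- paste0(merged$sequence[i], "\x01", merged$mod_key[i])
    ions <- ion_cache[[key]]
    if (is.null(ions)) {
      ions <- theoretical_by_ions(
        peptide(merged$sequence[i], merged$modifications[i],
                merged$charge[i]))
      ion_cache[[key]] <- ions
    }
    m <- match_peaks(prepped[[merged$spectrum_id[i]]], ions, tol_ppm)
    match_results[[i]] <- m
    uniscores[i] <- uniscore(m)
    comp[i, ] <- score_components(m)
  }
  colnames(comp) <- c("n_b", "n_y", "n_single_sites", "n_double_sites",
                      "n_stretch", "n_stretch_sq", "n_unmatched",
                      "peptide_length", "length_minus_stretch",
                      "matched_intensity_fraction", "uniscore")
  merged$uniscore <- uniscores
  merged$record_id <- paste(merged$spectrum_id, merged$sequence,
                            merged$mod_key, merged$charge, sep = "/")

  # chimera resolution per spectrum
  sp_groups <- split(seq_len(n), merged$spectrum_id)
  accepted <- lapply(sp_groups, function(ix)
    resolve_chimera(merged[ix, , drop = FALSE], match_results[ix],
                    chimera_cfg))
  accepted <- do.call(rbind, accepted)
  if (is.null(accepted)) accepted <- cbind(merged[0, ], rank = integer(),
                                           shared_fraction = numeric(),
                                           is_chimera_mate = logical())
  rownames(accepted) <- NULL
  comp_accepted <- comp[match(accepted$record_id, merged$record_id), ,
                        drop = FALSE]

  # PSM-level FDR
  psm_records <- data.frame(record_id = accepted$record_id,
                            score = accepted$uniscore,
                            label = accepted$label,
                            sequence = accepted$sequence,
                            spectrum_id = accepted$spectrum_id)
  psm_fdr <- fdr_curve(psm_records, estimator)
  psm_accepted <- filter_at_fdr(psm_fdr, alpha)

  # peptide level: collapse all chimera-accepted PSMs, then the same curve
  pep_records <- collapse_to_peptides(psm_records, il_equate)
  pep_fdr <- fdr_curve(pep_records, estimator)
  pep_accepted <- filter_at_fdr(pep_fdr, alpha)

  groups <- group_fdr <- group_accepted <- NULL
  if (!is.null(fasta)) {
    pep_in <- data.frame(sequence = pep_accepted$sequence,
                         score = pep_accepted$score,
                         label = pep_accepted$label)
    groups <- infer_protein_groups(pep_in, fasta, decoy_prefix,
                                   entrapment_prefix)
    if (nrow(groups)) {
      rec <- data.frame(record_id = groups$group_id,
                        score = groups$group_score, label = groups$label)
      group_fdr <- fdr_curve(rec, estimator)
      group_accepted <- filter_at_fdr(group_fdr, alpha)
    }
  }

  counts <- c(candidates = n,
              chimera_accepted = nrow(accepted),
              chimera_rejected = n - nrow(accepted),
              skipped = n_skipped,
              psms_at_alpha = sum(psm_accepted$label != "decoy"),
              peptides_at_alpha = sum(pep_accepted$label != "decoy"),
              protein_groups_at_alpha = if (is.null(group_accepted)) NA_integer_
                else sum(group_accepted$label != "decoy"))

  structure(list(accepted = accepted, components = comp_accepted,
                 psm_fdr = psm_fdr, psm_accepted = psm_accepted,
                 peptide_fdr = pep_fdr, peptide_accepted = pep_accepted,
                 protein_groups = groups, group_fdr = group_fdr,
                 group_accepted = group_accepted,
                 chimera = chimera_statistics(accepted),
                 counts = counts,
                 settings = list(filter_cfg = filter_cfg, tol_ppm = tol_ppm,
                                 chimera_cfg = chimera_cfg, alpha = alpha,
                                 estimator = estimator,
                                 deisotope = deisotope,
                                 il_equate = il_equate)),
            class = "uniscore_run")
}

#' @export
print.uniscore_run <- function(x, ...) {
  cat("Peptide-spectrum match rescoring run\n")
  cat(sprintf("  candidates scored : %d\n", x$counts[["candidates"]]))
  cat(sprintf("  accepted at FDR %g%%: %d PSMs, %d peptides",
              100 * x$settings$alpha, x$counts[["psms_at_alpha"]],
              x$counts[["peptides_at_alpha"]]))
  if (!is.na(x$counts[["protein_groups_at_alpha"]]))
    cat(sprintf(", %d protein groups", x$counts[["protein_groups_at_alpha"]]))
  cat("\n")
  cat(sprintf("  chimeric spectra  : %.1f%%\n", 100 * x$chimera$chimera_fraction))
  invisible(x)
}

#' Summarise a rescoring run
#'
#' @param object A [rescore()] result.
#' @param ... Unused.
#' @return The `counts` vector plus chimera statistics, invisibly printed.
#' @method summary uniscore_run
#' @export
summary.uniscore_run <- function(object, ...) {
  print(object)
  cat("\nPSMs per spectrum:\n")
  print(object$chimera$psms_per_spectrum)
  cat(sprintf("\nscore range %d..%d; decoys among accepted PSMs: %d\n",
              min(object$accepted$uniscore), max(object$accepted$uniscore),
              sum(object$psm_accepted$label == "decoy")))
  invisible(object$counts)
}

#' Diagnostic plots for a rescoring run
#'
#' Left: score distributions of target vs decoy candidates (the separation
#' that drives the FDR). Right: accepted-PSM count as a function of the
#' q-value threshold.
#'
#' @param x A [rescore()] result.
#' @param ... Passed to [graphics::hist()].
#' @method plot uniscore_run
#' @export
plot.uniscore_run <- function(x, ...) {
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  tg <- x$accepted$uniscore[x$accepted$label != "decoy"]
  dc <- x$accepted$uniscore[x$accepted$label == "decoy"]
  brk <- seq(-0.5, max(x$accepted$uniscore) + 0.5)
  graphics::hist(tg, breaks = brk, col = grDevices::adjustcolor("steelblue", 0.6),
                 main = "score distributions", xlab = "score", ...)
  if (length(dc))
    graphics::hist(dc, breaks = brk,
                   col = grDevices::adjustcolor("firebrick", 0.6), add = TRUE)
  graphics::legend("topright", fill = c("steelblue", "firebrick"),
                   legend = c("target", "decoy"), bty = "n")
  tab <- x$psm_fdr
  q <- sort(unique(tab$q_value))
  nacc <- vapply(q, function(a) sum(tab$q_value <= a & tab$label != "decoy"),
                 0L)
  graphics::plot(q, nacc, type = "s", xlab = "q-value threshold",
                 ylab = "accepted target PSMs", main = "identification curve",
                 xlim = c(0, min(max(q), 0.2)))
  graphics::abline(v = x$settings$alpha, lty = 2)
  invisible(x)
}

#' Export scored PSMs as a Percolator feature (PIN) file
#'
#' One row per chimera-accepted PSM (targets and decoys alike — the
#' semi-supervised learner needs both). The feature columns are exactly
#' the candidate component set: sites matched by one ion series, sites
#' matched by both, stretch and stretch squared, unmatched-ion count,
#' peptide length minus stretch, plus the canonical score itself.
#'
#' @param run A [rescore()] result.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
export_percolator_features <- function(run, path) {
  stopifnot(inherits(run, "uniscore_run"))
  acc <- run$accepted
  comp <- run$components
  scannr <- match(acc$spectrum_id, unique(acc$spectrum_id))
  df <- data.frame(
    SpecId = acc$record_id,
    Label = ifelse(acc$label == "decoy", -1L, 1L),
    ScanNr = scannr,
    n_single_sites = comp[, "n_single_sites"],
    n_double_sites = comp[, "n_double_sites"],
    n_stretch = comp[, "n_stretch"],
    n_stretch_sq = comp[, "n_stretch_sq"],
    n_unmatched = comp[, "n_unmatched"],
    length_minus_stretch = comp[, "length_minus_stretch"],
    uniscore = comp[, "uniscore"],
    Peptide = paste0("-.", acc$sequence, ".-"),
    Proteins = acc$protein_ids)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Tabular summary of a run
#'
#' @param run A [rescore()] result.
#' @param alphas FDR levels to tabulate.
#' @return data.frame with accepted counts per level and alpha, plus
#'   chimera fraction and per-engine contributions as attributes.
#' @export
report_summary <- function(run, alphas = c(0.01, 0.05)) {
  stopifnot(inherits(run, "uniscore_run"))
  count_at <- function(tab, a)
    if (is.null(tab)) NA_integer_ else
      sum(tab$q_value <= a & tab$label != "decoy")
  out <- do.call(rbind, lapply(alphas, function(a)
    data.frame(alpha = a,
               psms = count_at(run$psm_fdr, a),
               peptides = count_at(run$peptide_fdr, a),
               protein_groups = count_at(run$group_fdr, a))))
  engines <- sort(unique(unlist(strsplit(run$accepted$engines, ";",
                                         fixed = TRUE))))
  contrib <- vapply(engines, function(e)
    sum(grepl(e, run$accepted$engines, fixed = TRUE)), 0L)
  attr(out, "chimera_fraction") <- run$chimera$chimera_fraction
  attr(out, "engine_contributions") <- contrib
  out
}

#' Export annotated matched ions as TSV
#'
#' @param spec A filtered [spectrum()].
#' @param pep A [peptide()].
#' @param m The corresponding [match_peaks()] result.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
export_annotated_ions <- function(spec, pep, m, path) {
  mi <- m$matched_ions
  df <- data.frame(spectrum_id = spec$spectrum_id, peptide = pep$sequence,
                   series = mi$series, ordinal = mi$ordinal,
                   theoretical_mz = mi$theoretical_mz,
                   observed_mz = spec$peaks$mz[mi$peak_index],
                   error_ppm = mi$mass_error_ppm,
                   intensity = spec$peaks$intensity[mi$peak_index])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
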