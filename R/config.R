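#' Run configuration
#'
#' A flat key-value description of one rescoring run: input paths, spectrum
#' filter, match tolerance, chimera rule, FDR settings and flags. Defaults
#' mirror the canonical settings (12 peaks per 100 Th, unweighted score,
#' 50% chimera threshold, 1% FDR). The object round-trips losslessly
#' through its YAML file form.
#'
#' @param mgf Path to the MGF peak list.
#' @param psm_tables Named character vector: engine name -> TSV path.
#' @param fasta Optional FASTA path (protein grouping).
#' @param bin_width,top_n Peak filter parameters (Th, count).
#' @param tol_ppm Fragment match tolerance.
#' @param max_shared_fraction Chimera rejection threshold.
#' @param alpha FDR level for all levels.
#' @param estimator "DT" or "DTD".
#' @param deisotope,il_equate Logical flags.
#' @param decoy_prefix,entrapment_prefix Accession prefixes.
#' @param seed Seed recorded for provenance (the rescoring pipeline itself
#'   is deterministic; the seed drives simulation commands only).
#' @return Object of class `"run_config"`.
#' @export
run_config <- function(mgf = NULL, psm_tables = character(), fasta = NULL,
                       bin_width = 100, top_n = 12L, tol_ppm = 20,
                       max_shared_fraction = 0.5, alpha = 0.01,
                       estimator = "DT", deisotope = FALSE,
                       il_equate = FALSE, decoy_prefix = "rev_",
                       entrapment_prefix = "ENTRAP_", seed = 1L) {
  stopifnot(estimator %in% c("DT", "DTD"))
  structure(list(mgf = mgf, psm_tables = psm_tables, fasta = fasta,
                 bin_width = as.numeric(bin_width), top_n = as.integer(top_n),
                 tol_ppm = as.numeric(tol_ppm),
                 max_shared_fraction = as.numeric(max_shared_fraction),
                 alpha = as.numeric(alpha), estimator = estimator,
                 deisotope = isTRUE(deisotope), il_equate = isTRUE(il_equate),
                 decoy_prefix = decoy_prefix,
                 entrapment_prefix = entrapment_prefix,
                 seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  x <- unclass(cfg)
  x$psm_tables <- as.list(x$psm_tables)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  cfg <- run_config()
  known <- names(unclass(cfg))
  bad <- setdiff(names(x), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  x$psm_tables <- unlist(x$psm_tables)
  if (is.null(x$psm_tables)) x$psm_tables <- character()
  do.call(run_config, x)
}

#' Run the pipeline from a configuration
#'
#' @param cfg A [run_config()] (or path to one).
#' @param out_dir Optional directory; when given, result tables are written
#'   via [write_results()].
#' @return The [rescore()] run object.
#' @export
rescore_from_config <- function(cfg, out_dir = NULL) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  run <- rescore(cfg$mgf, as.list(cfg$psm_tables), fasta = cfg$fasta,
                 filter_cfg = peak_filter_config(cfg$bin_width, cfg$top_n),
                 tol_ppm = cfg$tol_ppm,
                 chimera_cfg = chimera_config(cfg$max_shared_fraction),
                 alpha = cfg$alpha, estimator = cfg$estimator,
                 deisotope = cfg$deisotope, il_equate = cfg$il_equate,
                 entrapment_prefix = cfg$entrapment_prefix,
                 decoy_prefix = cfg$decoy_prefix)
  if (!is.null(out_dir)) write_results(run, out_dir)
  run
}

#' Write a run's result tables
#'
#' Accepted-PSM, peptide-level and protein-group TSVs plus a compact FDR
#' report (one row per level and threshold). Deterministic: identical runs
#' produce byte-identical files.
#'
#' @param run A [rescore()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written paths.
#' @export
write_results <- function(run, dir) {
  stopifnot(inherits(run, "uniscore_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths <- c(
    w(run$accepted, "psms_accepted.tsv"),
    w(run$psm_accepted, "psms_fdr_accepted.tsv"),
    w(run$peptide_accepted, "peptides_accepted.tsv"))
  if (!is.null(run$group_accepted))
    paths <- c(paths, w(run$group_accepted, "protein_groups_accepted.tsv"))
  rep <- report_summary(run, alphas = unique(c(run$settings$alpha, 0.05)))
  paths <- c(paths, w(rep, "fdr_report.tsv"))
  invisible(paths)
}
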