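# Independent brute-force oracles used across tests. These deliberately
# avoid the implementation's code paths.

# per-bin sort oracle for the top-N intensity filter
bf_filter <- function(mz, intensity, bin_width, top_n) {
  bin <- floor(mz / bin_width)
  keep <- unlist(lapply(split(seq_along(mz), bin), function(ix) {
    o <- ix[order(-intensity[ix], mz[ix])]
    o[seq_len(min(top_n, length(o)))]
  }))
  sort(keep)
}

# exhaustive nearest-within-tolerance ion matching
bf_match <- function(peak_mz, ion_mz, tol_ppm) {
  vapply(ion_mz, function(t) {
    err <- (peak_mz - t) / t * 1e6
    ok <- which(abs(err) <= tol_ppm)
    if (!length(ok)) return(NA_integer_)
    best <- ok[abs(err[ok]) == min(abs(err[ok]))]
    min(best)  # equidistant -> lower mz
  }, 1L)
}

# residue scan for the stretch count
bf_stretch <- function(sites, L) {
  n <- 0L
  for (i in seq_len(L)) {
    left <- (i - 1L) %in% sites
    right <- i %in% sites
    if (i > 1L && i < L && left && right) n <- n + 1L
  }
  n
}

# O(n^2) recount of the target-decoy curve
bf_fdr <- function(records, estimator = "DT") {
  n <- nrow(records)
  raw <- numeric(n)
  for (i in seq_len(n)) {
    up <- records$score >= records$score[i]
    d <- sum(up & records$label == "decoy")
    t <- sum(up & records$label != "decoy")
    raw[i] <- if (estimator == "DT") {
      if (t > 0) d / t else if (d > 0) Inf else 0
    } else d / (t + d)
  }
  q <- numeric(n)
  for (i in seq_len(n)) {
    down <- records$score <= records$score[i]
    q[i] <- min(raw[down])
  }
  data.frame(record_id = records$record_id, raw_fdr = raw, q_value = q)
}

# tiny spectrum straight from a set of m/z values
peaks_spectrum <- function(mz, intensity = rep(100, length(mz)),
                           id = "t1", pmz = 500, z = 2L)
  spectrum(id, pmz, z, mz, intensity)

# write a PSM table data.frame to a temp TSV and load it back
load_psm_df <- function(df, engine) {
  f <- tempfile(fileext = ".tsv")
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  load_psm_table(f, engine)
}

psm_row <- function(spectrum_id, peptide, charge = 2L, is_decoy = 0L,
                    modifications = "", protein_ids = "P1",
                    engine_score = 10) {
  data.frame(spectrum_id = spectrum_id, peptide = peptide,
             modifications = modifications, charge = charge,
             is_decoy = is_decoy, protein_ids = protein_ids,
             engine_score = engine_score)
}

# loaded PSM tables of a simulated dataset, named by persona
dataset_tables <- function(ds)
  stats::setNames(lapply(names(ds$psm_tables), function(n)
    load_psm_df(ds$psm_tables[[n]], n)), names(ds$psm_tables))
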