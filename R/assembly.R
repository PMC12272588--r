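PSM_TABLE_COLUMNS <- c("spectrum_id", "peptide", "modifications", "charge",
                       "is_decoy", "protein_ids", "engine_score")

#' Load one search engine's candidate PSM table
#'
#' The input is a TSV with header columns `spectrum_id`, `peptide`,
#' `modifications` (compact `"pos:delta;..."` dialect, empty for none),
#' `charge`, `is_decoy` (0/1), `protein_ids` (";"-separated accessions)
#' and `engine_score`. Entrapment records arrive labelled `target` and are
#' relabelled later by accession prefix (see [label_entrapment()]).
#'
#' @param path TSV file path.
#' @param engine Engine name recorded as provenance.
#' @return data.frame of candidate PSMs with columns `spectrum_id`,
#'   `sequence`, `modifications`, `mod_key` (canonical rounded form used
#'   for merging), `charge`, `label`, `engines`, `engine_score`,
#'   `protein_ids`.
#' @export
load_psm_table <- function(path, engine) {
  tab <- utils::read.delim(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  missing <- setdiff(PSM_TABLE_COLUMNS, names(tab))
  if (length(missing))
    stop("PSM table ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  mod_key <- character(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    mods <- tryCatch(parse_modifications(tab$modifications[i]),
                     error = function(e)
                       stop("row ", i, " of ", path, ": ",
                            conditionMessage(e), call. = FALSE))
    mod_key[i] <- canonical_mod_key(mods)
  }
  data.frame(spectrum_id = tab$spectrum_id,
             sequence = toupper(tab$peptide),
             modifications = tab$modifications,
             mod_key = mod_key,
             charge = as.integer(tab$charge),
             label = ifelse(tab$is_decoy %in% c("1", "TRUE", "true"),
                            "decoy", "target"),
             engines = engine,
             engine_score = as.numeric(tab$engine_score),
             protein_ids = tab$protein_ids)
}

# total modification mass per position, rounded to 3 decimals: engines that
# disagree on modification naming still merge when the deltas agree
canonical_mod_key <- function(mods) {
  if (!nrow(mods)) return("")
  agg <- tapply(mods$delta, mods$position, sum)
  paste(sprintf("%s:%.3f", names(agg), agg), collapse = ";")
}

#' Relabel PSMs hitting entrapment proteins
#'
#' A candidate whose accessions all carry the entrapment prefix is an
#' entrapment hit; decoy labels are never overwritten.
#'
#' @param psms A [load_psm_table()]-shaped data.frame.
#' @param prefix Accession prefix, default `"ENTRAP_"`.
#' @export
label_entrapment <- function(psms, prefix = "ENTRAP_") {
  if (!nrow(psms)) return(psms)
  accs <- strsplit(psms$protein_ids, ";", fixed = TRUE)
  all_ent <- vapply(accs, function(a) length(a) > 0 &&
                      all(startsWith(a, prefix)), TRUE)
  psms$label[all_ent & psms$label != "decoy"] <- "entrapment"
  psms
}

#' Merge candidate tables from several search engines
#'
#' Candidates identical in (spectrum, bare sequence, canonical modification
#' key, charge) are unified into one record whose `engines` field is the
#' union and whose `engine_score` keeps each engine's value
#' (`"engine:score"` pairs). Distinct sequences proposed for one spectrum
#' all survive — they are the raw material for chimera resolution. The
#' same key carrying both a target and a decoy label means the engines
#' searched different databases and is a hard error.
#'
#' @param tables List of [load_psm_table()] results.
#' @return data.frame ordered by (spectrum_id, sequence, mod_key, charge).
#' @export
merge_engines <- function(tables) {
  all <- do.call(rbind, tables)
  if (is.null(all) || !nrow(all)) {
    return(data.frame(spectrum_id = character(), sequence = character(),
                      modifications = character(), mod_key = character(),
                      charge = integer(), label = character(),
                      engines = character(), engine_score = character(),
                      protein_ids = character()))
  }
  key <- paste(all$spectrum_id, all$sequence, all$mod_key, all$charge,
               sep = "\x01")
  sp <- split(seq_len(nrow(all)), key)
  rows <- lapply(sp, function(ix) {
    r <- all[ix[1L], , drop = FALSE]
    labs <- unique(all$label[ix])
    if (all(c("target", "decoy") %in% labs))
      stop("candidate ", all$sequence[ix[1L]], " for spectrum ",
           all$spectrum_id[ix[1L]],
           " is target in one engine and decoy in another: database mismatch")
    eng <- all$engines[ix]
    o <- order(eng)
    r$engines <- paste(eng[o], collapse = ";")
    r$engine_score <- paste(sprintf("%s:%g", eng[o], all$engine_score[ix][o]),
                            collapse = ";")
    r$protein_ids <- paste(sort(unique(unlist(
      strsplit(all$protein_ids[ix], ";", fixed = TRUE)))), collapse = ";")
    r
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$spectrum_id, out$sequence, out$mod_key, out$charge), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Chimera configuration
#'
#' @param max_shared_fraction A later-ranked candidate is rejected when more
#'   than this fraction of its annotated peaks is already claimed by
#'   accepted candidates; default 0.5.
#' @param max_psms_per_spectrum Optional cap (default unlimited).
#' @export
chimera_config <- function(max_shared_fraction = 0.5,
                           max_psms_per_spectrum = Inf) {
  stopifnot(max_shared_fraction >= 0, max_shared_fraction <= 1)
  structure(list(max_shared_fraction = max_shared_fraction,
                 max_psms_per_spectrum = max_psms_per_spectrum),
            class = "chimera_config")
}

#' Accept co-isolated candidates for one spectrum
#'
#' Different sequences assigned to a single spectrum usually reflect
#' co-isolated precursors (a chimeric spectrum), so each is scored in its
#' own right — except when it mostly re-explains peaks already claimed.
#' Candidates are ranked by descending score (ties: target before decoy,
#' then lexicographic sequence). The best candidate is accepted as rank 1;
#' each subsequent candidate is accepted iff the fraction of *its own*
#' annotated peaks already present in the union of accepted candidates'
#' peaks is <= `max_shared_fraction` (a later candidate with zero annotated
#' peaks is rejected). Accepted candidates receive ranks 2, 3, ...
#'
#' @param candidates data.frame of scored candidates for one spectrum;
#'   must carry a `uniscore` column and `label`, `sequence`.
#' @param match_results List of [match_peaks()] results, parallel to
#'   `candidates` rows.
#' @param cfg A [chimera_config()].
#' @return The accepted rows with columns `rank`, `shared_fraction` and
#'   `is_chimera_mate` (rank > 1) appended.
#' @export
resolve_chimera <- function(candidates, match_results, cfg = chimera_config()) {
  stopifnot(nrow(candidates) == length(match_results),
            "uniscore" %in% names(candidates))
  if (!nrow(candidates)) return(cbind(candidates, rank = integer()))
  lab_ord <- match(candidates$label, c("target", "entrapment", "decoy"))
  o <- order(-candidates$uniscore, lab_ord, candidates$sequence)
  cand <- candidates[o, , drop = FALSE]
  mrs <- match_results[o]
  claimed <- integer(0)
  acc <- integer(0)
  shared <- numeric(0)
  for (k in seq_len(nrow(cand))) {
    pk <- mrs[[k]]$annotated_peak_indices
    if (!length(acc)) {
      acc <- k; shared <- 0; claimed <- pk
      next
    }
    if (length(acc) >= cfg$max_psms_per_spectrum) break
    if (!length(pk)) next
    fr <- length(intersect(pk, claimed)) / length(pk)
    if (fr <= cfg$max_shared_fraction) {
      acc <- c(acc, k)
      shared <- c(shared, fr)
      claimed <- union(claimed, pk)
    }
  }
  out <- cand[acc, , drop = FALSE]
  out$rank <- seq_along(acc)
  out$shared_fraction <- shared
  out$is_chimera_mate <- out$rank > 1L
  rownames(out) <- NULL
  out
}

#' Summaries of chimeric-spectrum structure
#'
#' @param accepted data.frame of accepted PSMs across spectra, carrying
#'   `spectrum_id`, `rank` and `shared_fraction`.
#' @return List: `psms_per_spectrum` (named count histogram),
#'   `chimera_fraction` (spectra with >= 2 accepted PSMs), and
#'   `overlap_distribution` (shared annotated-peak fractions of
#'   rank > 1 PSMs).
#' @export
chimera_statistics <- function(accepted) {
  if (!nrow(accepted))
    return(list(psms_per_spectrum = table(integer()),
                chimera_fraction = NaN,
                overlap_distribution = numeric()))
  per <- table(table(accepted$spectrum_id))
  n_spec <- length(unique(accepted$spectrum_id))
  n_chim <- sum(table(accepted$spectrum_id) >= 2L)
  list(psms_per_spectrum = per,
       chimera_fraction = n_chim / n_spec,
       overlap_distribution = accepted$shared_fraction[accepted$rank > 1L])
}
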