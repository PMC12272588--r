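# run code under a fixed seed without disturbing the caller's RNG stream
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647L))
  force(code)
}

# fixed per-stage seed offsets keep the stages independent yet reproducible
sub_seed <- function(seed, k) (as.numeric(seed) * 131 + k * 7919) %% 2147483647

# background residue frequencies with lysine/arginine tuned so tryptic
# peptides average ~10 residues (K+R ~ 10% of residues)
SIM_AA_FREQ <- c(
  A = 0.080, C = 0.012, D = 0.052, E = 0.062, F = 0.040, G = 0.070,
  H = 0.022, I = 0.050, K = 0.055, L = 0.090, M = 0.021, N = 0.042,
  P = 0.047, Q = 0.040, R = 0.048, S = 0.068, T = 0.053, V = 0.062,
  W = 0.011, Y = 0.030)

#' Configuration of the synthetic-data generator
#'
#' Defaults emulate a high-resolution Orbitrap DDA experiment on a toy
#' proteome: ~70% of b/y fragments detected, 5 ppm mass jitter, 30 noise
#' peaks per spectrum, and a 0.14 co-isolation (chimera) probability — the
#' reported precursor ion fraction of standard DDA. Entrapment follows the
#' shuffled-foreign-proteome design: each foreign protein is shuffled
#' `n_entrapment_shuffles` (default 100) times.
#'
#' @param seed Integer; fully determines every generated byte.
#' @param n_proteins,protein_length Target proteome size and length range.
#' @param missed_cleavages Maximum missed cleavages in the digest.
#' @param peptide_length Detectable tryptic peptide length range.
#' @param n_spectra Number of simulated MS/MS spectra.
#' @param charges Precursor charges sampled uniformly.
#' @param ion_detection_prob Probability each theoretical 1+ b/y ion is
#'   observed.
#' @param mz_jitter_ppm Gaussian m/z error (s.d., ppm) on fragments and
#'   precursors.
#' @param signal_intensity,noise_intensity `c(meanlog, sdlog)` of the
#'   log-normal intensity draws for fragment and noise peaks.
#' @param n_noise_peaks Uniform-random noise peaks per spectrum over
#'   `[100, 1.1 * max fragment m/z]`.
#' @param chimera_rate Probability a spectrum co-isolates a second peptide.
#' @param isolation_width Th window within which a chimera mate's precursor
#'   must fall.
#' @param n_entrapment_proteins Foreign stand-in proteins (0 = no
#'   entrapment database).
#' @param n_entrapment_shuffles Shuffled copies per foreign protein.
#' @param personas List of engine personas, each
#'   `list(name =, precursor_tol_ppm =, frag_tol_ppm =, top_k =)`; an
#'   optional `precursor_window_th` widens the candidate window to a fixed
#'   Th range (a chimera-aware persona mimicking engines that search the
#'   whole isolation window for co-isolated precursors).
#' @return Object of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1L,
                       n_proteins = 40L, protein_length = c(150L, 350L),
                       missed_cleavages = 0L, peptide_length = c(7L, 30L),
                       n_spectra = 300L, charges = 2:3,
                       ion_detection_prob = 0.7, mz_jitter_ppm = 5,
                       signal_intensity = c(4, 0.5),
                       noise_intensity = c(2, 1), n_noise_peaks = 30L,
                       chimera_rate = 0.14, isolation_width = 2.0,
                       n_entrapment_proteins = 0L,
                       n_entrapment_shuffles = 100L,
                       personas = list(
                         list(name = "engineA", precursor_tol_ppm = 10,
                              frag_tol_ppm = 20, top_k = 3L),
                         list(name = "engineB", precursor_tol_ppm = 15,
                              frag_tol_ppm = 30, top_k = 5L,
                              precursor_window_th = 2.0),
                         list(name = "engineC", precursor_tol_ppm = 8,
                              frag_tol_ppm = 15, top_k = 2L))) {
  stopifnot(ion_detection_prob >= 0, ion_detection_prob <= 1,
            chimera_rate >= 0, chimera_rate <= 1,
            n_entrapment_shuffles >= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Generate a random target proteome
#'
#' Random sequences over the 20 residues with lysine/arginine frequency
#' tuned so the tryptic digest lands mostly in the detectable length range.
#' Accessions are `TGT_0001`, ... Deterministic under the config seed.
#'
#' @param cfg A [sim_config()].
#' @return A `Biostrings::AAStringSet`.
#' @export
generate_proteome <- function(cfg) {
  with_seed(sub_seed(cfg$seed, 1L), {
    lens <- sample(cfg$protein_length[1L]:cfg$protein_length[2L],
                   cfg$n_proteins, replace = TRUE)
    seqs <- vapply(lens, function(n)
      paste(sample(names(SIM_AA_FREQ), n, replace = TRUE,
                   prob = SIM_AA_FREQ), collapse = ""), "")
    names(seqs) <- sprintf("TGT_%04d", seq_len(cfg$n_proteins))
    Biostrings::AAStringSet(seqs)
  })
}

#' In-silico tryptic digest
#'
#' Cleaves after K or R except when the next residue is P; includes up to
#' `max_missed` missed cleavages.
#'
#' @param sequence Protein sequence string.
#' @param max_missed Maximum missed cleavages.
#' @return data.frame with `peptide`, `start`, `end`, `missed`; unique
#'   peptides (first occurrence kept).
#' @export
tryptic_digest <- function(sequence, max_missed = 0L) {
  res <- strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
  n <- length(res)
  cut <- which(res %in% c("K", "R"))
  cut <- cut[cut < n & res[pmin(cut + 1L, n)] != "P"]
  bounds <- c(0L, cut, n)                 # segment i = (bounds[i]+1)..bounds[i+1]
  nseg <- length(bounds) - 1L
  out <- list()
  for (i in seq_len(nseg)) {
    for (m in 0:min(max_missed, nseg - i)) {
      s <- bounds[i] + 1L
      e <- bounds[i + 1L + m]
      out[[length(out) + 1L]] <-
        data.frame(peptide = paste(res[s:e], collapse = ""),
                   start = s, end = e, missed = m)
    }
  }
  out <- do.call(rbind, out)
  out[!duplicated(out$peptide), , drop = FALSE]
}

#' Pseudo-reversed decoy database
#'
#' Each tryptic segment of each protein is reversed with its C-terminal
#' residue held in place, preserving tryptic termini and therefore the
#' precursor-mass distribution of the digest. Accessions gain the
#' `rev_` prefix.
#'
#' @param fasta Target `AAStringSet`.
#' @param prefix Decoy accession prefix.
#' @return `AAStringSet` of equal length.
#' @export
make_decoys <- function(fasta, prefix = "rev_") {
  seqs <- as.character(fasta)
  dec <- vapply(seqs, function(sq) {
    res <- strsplit(sq, "", fixed = TRUE)[[1L]]
    n <- length(res)
    cut <- which(res %in% c("K", "R"))
    cut <- cut[cut < n & res[pmin(cut + 1L, n)] != "P"]
    bounds <- c(0L, cut, n)
    segs <- character(length(bounds) - 1L)
    for (i in seq_len(length(bounds) - 1L)) {
      s <- bounds[i] + 1L; e <- bounds[i + 1L]
      seg <- res[s:e]
      if (length(seg) > 1L && seg[length(seg)] %in% c("K", "R"))
        seg <- c(rev(seg[-length(seg)]), seg[length(seg)])
      else
        seg <- rev(seg)
      segs[i] <- paste(seg, collapse = "")
    }
    paste(segs, collapse = "")
  }, "", USE.NAMES = FALSE)
  out <- Biostrings::AAStringSet(dec)
  names(out) <- paste0(prefix, names(fasta))
  out
}

#' Shuffled entrapment database
#'
#' Each input sequence is residue-shuffled `k` times independently;
#' composition and length are preserved exactly. Accessions become
#' `ENTRAP_<i>_<original>`.
#'
#' @param fasta Foreign proteome (or generated stand-in) `AAStringSet`.
#' @param k Number of shuffles per sequence.
#' @param seed Seed for the shuffles.
#' @param prefix Entrapment accession prefix.
#' @return `AAStringSet` with `k * length(fasta)` records.
#' @export
make_entrapment <- function(fasta, k = 100L, seed = 1L, prefix = "ENTRAP_") {
  stopifnot(k >= 1L)
  with_seed(sub_seed(seed, 3L), {
    seqs <- as.character(fasta)
    out <- character(k * length(seqs))
    nm <- character(k * length(seqs))
    idx <- 0L
    for (i in seq_len(k)) {
      for (j in seq_along(seqs)) {
        idx <- idx + 1L
        res <- strsplit(seqs[[j]], "", fixed = TRUE)[[1L]]
        out[idx] <- paste(sample(res), collapse = "")
        nm[idx] <- paste0(prefix, i, "_", names(seqs)[j])
      }
    }
    res <- Biostrings::AAStringSet(out)
    names(res) <- nm
    res
  })
}

#' Simulate one noisy MS/MS spectrum for a peptide
#'
#' Every theoretical 1+ b/y ion is observed with probability
#' `ion_detection_prob` at its true m/z perturbed by Gaussian ppm jitter,
#' with log-normal intensity; uniform-random noise peaks are added. Uses
#' the current RNG stream — seed at the call site (dataset-level functions
#' do this for you).
#'
#' @param p A [peptide()].
#' @param cfg A [sim_config()].
#' @param spectrum_id Id for the resulting spectrum.
#' @return A [spectrum()]; its precursor m/z carries the same ppm jitter.
#' @export
simulate_spectrum <- function(p, cfg, spectrum_id = "sim.1") {
  ions <- theoretical_by_ions(p)
  det <- stats::runif(nrow(ions)) < cfg$ion_detection_prob
  mz <- ions$mz[det]
  mz <- mz * (1 + stats::rnorm(length(mz), 0, cfg$mz_jitter_ppm) * 1e-6)
  inten <- stats::rlnorm(length(mz), cfg$signal_intensity[1L],
                         cfg$signal_intensity[2L])
  if (cfg$n_noise_peaks > 0L) {
    hi <- 1.1 * max(ions$mz)
    nmz <- stats::runif(cfg$n_noise_peaks, 100, hi)
    nint <- stats::rlnorm(cfg$n_noise_peaks, cfg$noise_intensity[1L],
                          cfg$noise_intensity[2L])
    mz <- c(mz, nmz); inten <- c(inten, nint)
  }
  pmass <- peptide_monoisotopic_mass(p)
  pmz <- (pmass + p$charge * PROTON_MASS) / p$charge
  pmz <- pmz * (1 + stats::rnorm(1, 0, cfg$mz_jitter_ppm) * 1e-6)
  spectrum(spectrum_id, pmz, p$charge, mz, inten)
}

#' Digest a target/decoy/entrapment database into an indexed peptide table
#'
#' Applies the tryptic digest to every protein, keeps peptides within the
#' configured detectable length range, records provenance (accessions,
#' label) and returns the table sorted by neutral monoisotopic mass — the
#' index [emulate_search()] consumes.
#'
#' @param targets,decoys,entrapment `AAStringSet`s (the latter two may be
#'   `NULL`).
#' @param cfg A [sim_config()] (length range, missed cleavages).
#' @return data.frame with `sequence`, `accession` (";"-joined), `label`,
#'   `mass`, ordered by mass.
#' @export
digest_database <- function(targets, decoys = NULL, entrapment = NULL,
                            cfg = sim_config()) {
  one <- function(fasta, label) {
    if (is.null(fasta) || !length(fasta)) return(NULL)
    seqs <- as.character(fasta)
    rows <- lapply(seq_along(seqs), function(i) {
      d <- tryptic_digest(seqs[[i]], cfg$missed_cleavages)
      len <- nchar(d$peptide)
      d <- d[len >= cfg$peptide_length[1L] & len <= cfg$peptide_length[2L], ,
             drop = FALSE]
      if (!nrow(d)) return(NULL)
      data.frame(sequence = d$peptide, accession = names(seqs)[i],
                 label = label)
    })
    do.call(rbind, rows)
  }
  db <- rbind(one(targets, "target"), one(decoys, "decoy"),
              one(entrapment, "entrapment"))
  # a peptide present in several proteins of one class keeps all accessions
  key <- paste(db$sequence, db$label)
  acc <- tapply(db$accession, key, function(a)
    paste(sort(unique(a)), collapse = ";"))
  db <- db[!duplicated(key), , drop = FALSE]
  db$accession <- as.character(acc[paste(db$sequence, db$label)])
  db$mass <- vapply(db$sequence, peptide_monoisotopic_mass, 0)
  rownames(db) <- NULL
  db[order(db$mass), , drop = FALSE]
}

#' Emulate a search engine over simulated spectra
#'
#' A crude engine persona: for each spectrum, every database peptide
#' (target, decoy, entrapment alike) whose precursor mass lies within the
#' persona's tolerance at the spectrum's charge becomes a candidate; each
#' candidate is scored by its matched b/y ion count at the persona's
#' fragment tolerance, and the `top_k` highest-scoring candidates are
#' emitted in the standard PSM-table schema. Persona diversity (different
#' tolerances, different `top_k`) mimics the disagreement between real
#' engines.
#'
#' @param spectra List of [spectrum()] objects.
#' @param db A `digest_database()`-shaped data.frame sorted by mass.
#' @param persona `list(name, precursor_tol_ppm, frag_tol_ppm, top_k)`.
#' @return data.frame in the [load_psm_table()] input schema.
#' @export
emulate_search <- function(spectra, db, persona) {
  ion_cache <- new.env(parent = emptyenv())
  ions_of <- function(sq) {
    v <- ion_cache[[sq]]
    if (is.null(v)) {
      v <- theoretical_by_ions(peptide(sq))
      ion_cache[[sq]] <- v
    }
    v
  }
  rows <- vector("list", length(spectra))
  for (si in seq_along(spectra)) {
    sp <- spectra[[si]]
    neutral <- (sp$precursor_mz - PROTON_MASS) * sp$precursor_charge
    tol <- if (!is.null(persona$precursor_window_th))
      persona$precursor_window_th / 2 * sp$precursor_charge
    else neutral * persona$precursor_tol_ppm * 1e-6
    lo <- findInterval(neutral - tol, db$mass) + 1L
    hi <- findInterval(neutral + tol, db$mass)
    if (hi < lo) next
    cand <- db[lo:hi, , drop = FALSE]
    sc <- vapply(cand$sequence, function(sq) {
      m <- match_peaks(sp, ions_of(sq), persona$frag_tol_ppm)
      m$n_b + m$n_y
    }, 0L)
    o <- order(-sc, cand$sequence)[seq_len(min(persona$top_k, nrow(cand)))]
    rows[[si]] <- data.frame(
      spectrum_id = sp$spectrum_id,
      peptide = cand$sequence[o],
      modifications = "",
      charge = sp$precursor_charge,
      is_decoy = as.integer(cand$label[o] == "decoy"),
      protein_ids = cand$accession[o],
      engine_score = as.numeric(sc[o]))
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(spectrum_id = character(), peptide = character(),
                      modifications = character(), charge = integer(),
                      is_decoy = integer(), protein_ids = character(),
                      engine_score = numeric())
  rownames(out) <- NULL
  out
}

#' Generate a complete labelled synthetic dataset
#'
#' Produces the full study bundle: target proteome, pseudo-reversed decoys,
#' optional shuffled entrapment database, simulated (possibly chimeric)
#' spectra with ground-truth labels, and one candidate PSM table per engine
#' persona. Everything is a deterministic function of `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List with `targets`, `decoys`, `entrapment` (AAStringSets or
#'   NULL), `db` (digested database), `spectra` (list of [spectrum()]),
#'   `truth` (data.frame spectrum_id -> true peptide(s)), and `psm_tables`
#'   (named list of per-persona data.frames).
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  targets <- generate_proteome(cfg)
  decoys <- make_decoys(targets)
  entrapment <- NULL
  if (cfg$n_entrapment_proteins > 0L) {
    foreign_cfg <- cfg
    foreign_cfg$n_proteins <- cfg$n_entrapment_proteins
    foreign_cfg$seed <- sub_seed(cfg$seed, 2L)
    foreign <- generate_proteome(foreign_cfg)
    names(foreign) <- sprintf("FOR_%04d", seq_along(foreign))
    entrapment <- make_entrapment(foreign, cfg$n_entrapment_shuffles,
                                  seed = cfg$seed)
  }
  db <- digest_database(targets, decoys, entrapment, cfg)
  tgt_pep <- db[db$label == "target", , drop = FALSE]
  with_seed(sub_seed(cfg$seed, 4L), {
    pick <- sample(nrow(tgt_pep), cfg$n_spectra, replace = TRUE)
    chg <- sample(cfg$charges, cfg$n_spectra, replace = TRUE)
    spectra <- vector("list", cfg$n_spectra)
    truth <- vector("list", cfg$n_spectra)
    for (i in seq_len(cfg$n_spectra)) {
      sq <- tgt_pep$sequence[pick[i]]
      p <- peptide(sq, charge = chg[i])
      id <- sprintf("sim.%05d", i)
      sp <- simulate_spectrum(p, cfg, id)
      mates <- sq
      if (stats::runif(1) < cfg$chimera_rate) {
        pmz <- (tgt_pep$mass + chg[i] * PROTON_MASS) / chg[i]
        near <- which(abs(pmz - sp$precursor_mz) <= cfg$isolation_width / 2 &
                        tgt_pep$sequence != sq)
        if (length(near)) {
          mate_sq <- tgt_pep$sequence[near[sample.int(length(near), 1L)]]
          mate <- simulate_spectrum(peptide(mate_sq, charge = chg[i]), cfg,
                                    id)
          sp <- spectrum(id, sp$precursor_mz, chg[i],
                         c(sp$peaks$mz, mate$peaks$mz),
                         c(sp$peaks$intensity, mate$peaks$intensity))
          mates <- c(sq, mate_sq)
        }
      }
      spectra[[i]] <- sp
      truth[[i]] <- data.frame(spectrum_id = id,
                               true_peptide = mates,
                               charge = chg[i])
    }
    truth <- do.call(rbind, truth)
  })
  psm_tables <- lapply(cfg$personas, function(per) emulate_search(
    spectra, db, per))
  names(psm_tables) <- vapply(cfg$personas, `[[`, "", "name")
  list(targets = targets, decoys = decoys, entrapment = entrapment,
       db = db, spectra = spectra, truth = truth, psm_tables = psm_tables,
       config = cfg)
}

#' Write a simulated dataset to disk
#'
#' FASTA databases, an MGF peak-list file, per-engine candidate TSVs and a
#' ground-truth TSV, all plain text and byte-deterministic under the
#' config seed.
#'
#' @param ds A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of written paths.
#' @export
write_simulated_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  fa <- ds$targets
  fa <- c(fa, ds$decoys)
  if (!is.null(ds$entrapment)) fa <- c(fa, ds$entrapment)
  p <- file.path(dir, "database.fasta")
  Biostrings::writeXStringSet(fa, p)
  paths <- c(paths, p)
  p <- file.path(dir, "spectra.mgf")
  write_mgf(ds$spectra, p)
  paths <- c(paths, p)
  for (nm in names(ds$psm_tables)) {
    p <- file.path(dir, paste0("psms_", nm, ".tsv"))
    df <- ds$psm_tables[[nm]]
    names(df)[names(df) == "peptide"] <- "peptide"
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "truth.tsv")
  utils::write.table(ds$truth, p, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, p)
  invisible(paths)
}

#' Simulate scored candidates for FDR-calibration studies
#'
#' For each replicate unit one spectrum is simulated from a random target
#' peptide and matched (i) against its true peptide — a correct target
#' candidate — and, for the false set, (ii) against a mass-matched decoy
#' peptide drawn from the pseudo-reversed database — an incorrect target
#' candidate — and (iii) against a second, independent decoy peptide — a
#' decoy candidate. Incorrect-target and decoy scores are draws from the
#' same null, which is exactly the premise of target-decoy FDR; the truth
#' column enables exact false discovery proportion computation. When `db`
#' contains entrapment peptides (shuffled foreign sequences), each false
#' unit additionally draws a mass-matched entrapment candidate, so the
#' decoy-estimated FDR can be compared with the entrapment-measured FDP on
#' the same records.
#'
#' @param cfg A [sim_config()].
#' @param n_true,n_false Numbers of correct and incorrect target
#'   candidates (an equal number of decoy candidates is generated).
#' @param seed Seed for this replicate.
#' @param db Optional pre-digested database (from several replicates over
#'   one proteome, rebuild once and pass it in).
#' @return data.frame: `record_id`, `score`, `label`, `is_correct`.
#' @export
simulate_calibration_set <- function(cfg = sim_config(), n_true = 2000L,
                                     n_false = 2000L, seed = 1L, db = NULL) {
  if (is.null(db)) {
    targets <- generate_proteome(cfg)
    decoys <- make_decoys(targets)
    db <- digest_database(targets, decoys, NULL, cfg)
  }
  tgt <- db[db$label == "target", , drop = FALSE]
  dec <- db[db$label == "decoy", , drop = FALSE]
  ent <- db[db$label == "entrapment", , drop = FALSE]
  ion_cache <- new.env(parent = emptyenv())
  ions_of <- function(sq) {
    v <- ion_cache[[sq]]
    if (is.null(v)) { v <- theoretical_by_ions(peptide(sq)); ion_cache[[sq]] <- v }
    v
  }
  # nearest-in-mass draw, randomised among the w nearest for variety
  near_mass <- function(pool, mass, w = 25L) {
    i <- findInterval(mass, pool$mass)
    lo <- max(1L, i - w %/% 2L); hi <- min(nrow(pool), lo + w - 1L)
    lo + sample.int(hi - lo + 1L, 1L) - 1L
  }
  with_seed(sub_seed(seed, 5L), {
    n <- max(n_true, n_false)
    pick <- sample(nrow(tgt), n, replace = TRUE)
    ids <- character(0); scores <- integer(0)
    labels <- character(0); correct <- logical(0)
    for (i in seq_len(n)) {
      sq <- tgt$sequence[pick[i]]
      sp <- simulate_spectrum(peptide(sq), cfg, sprintf("cal.%05d", i))
      spf <- filter_top_n_per_bin(sp)
      if (i <= n_true) {
        m <- match_peaks(spf, ions_of(sq))
        ids <- c(ids, sprintf("true.%05d", i))
        scores <- c(scores, uniscore(m))
        labels <- c(labels, "target"); correct <- c(correct, TRUE)
      }
      if (i <= n_false) {
        wrong <- dec$sequence[near_mass(dec, tgt$mass[pick[i]])]
        wrong2 <- dec$sequence[near_mass(dec, tgt$mass[pick[i]])]
        m <- match_peaks(spf, ions_of(wrong))
        m2 <- match_peaks(spf, ions_of(wrong2))
        ids <- c(ids, sprintf("false.%05d", i), sprintf("decoy.%05d", i))
        scores <- c(scores, uniscore(m), uniscore(m2))
        labels <- c(labels, "target", "decoy")
        correct <- c(correct, FALSE, FALSE)
        if (nrow(ent)) {
          esq <- ent$sequence[near_mass(ent, tgt$mass[pick[i]])]
          me <- match_peaks(spf, ions_of(esq))
          ids <- c(ids, sprintf("entrap.%05d", i))
          scores <- c(scores, uniscore(me))
          labels <- c(labels, "entrapment")
          correct <- c(correct, FALSE)
        }
      }
    }
    data.frame(record_id = ids, score = scores, label = labels,
               is_correct = correct)
  })
}
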