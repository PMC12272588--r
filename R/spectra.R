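#' Construct an MS/MS spectrum
#'
#' @param spectrum_id Unique text key.
#' @param precursor_mz Precursor mass-to-charge (Th).
#' @param precursor_charge Positive integer; DDA precursors are mostly 2+/3+.
#' @param mz,intensity Numeric vectors of equal length; peaks are stored
#'   sorted ascending by m/z.
#' @param retention_time Seconds, or `NA`.
#' @return Object of class `"spectrum"` with a `peaks` data.frame.
#' @export
spectrum <- function(spectrum_id, precursor_mz, precursor_charge = 2L,
                     mz = numeric(), intensity = numeric(),
                     retention_time = NA_real_) {
  stopifnot(length(mz) == length(intensity))
  if (length(mz)) {
    stopifnot(all(mz > 0), all(intensity >= 0))
    o <- order(mz)
    mz <- mz[o]; intensity <- intensity[o]
  }
  precursor_charge <- as.integer(precursor_charge)
  stopifnot(precursor_charge >= 1L)
  structure(list(spectrum_id = as.character(spectrum_id),
                 precursor_mz = as.numeric(precursor_mz),
                 precursor_charge = precursor_charge,
                 retention_time = as.numeric(retention_time),
                 peaks = data.frame(mz = as.numeric(mz),
                                    intensity = as.numeric(intensity))),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s  precursor %.4f Th (%d+)  %d peaks\n",
              x$spectrum_id, x$precursor_mz, x$precursor_charge,
              nrow(x$peaks)))
  invisible(x)
}

#' Peak filter configuration
#'
#' Top-N most intense peaks are retained per fixed m/z bin. The default,
#' 12 peaks per 100 Th, is the setting that maximises identifications for
#' high-resolution HCD spectra; 4 per 30 Th and 6 per 50 Th are equivalent
#' tighter alternatives.
#'
#' @param bin_width Bin width in Th (> 0).
#' @param top_n Maximum peaks kept per bin (>= 1).
#' @export
peak_filter_config <- function(bin_width = 100, top_n = 12L) {
  stopifnot(bin_width > 0, top_n >= 1)
  structure(list(bin_width = as.numeric(bin_width), top_n = as.integer(top_n)),
            class = "peak_filter_config")
}

#' Keep the top-N most intense peaks per m/z bin
#'
#' Bins are fixed half-open windows `[k*bin_width, (k+1)*bin_width)` anchored
#' at m/z 0. Within each bin at most `top_n` peaks survive, chosen by
#' descending intensity with intensity ties broken in favour of the lower
#' m/z. The operation is idempotent and never alters retained peak values.
#'
#' @param spec A [spectrum()].
#' @param cfg A [peak_filter_config()].
#' @return A new filtered [spectrum()]; the input is not modified.
#' @export
filter_top_n_per_bin <- function(spec, cfg = peak_filter_config()) {
  stopifnot(inherits(spec, "spectrum"))
  pk <- spec$peaks
  if (!nrow(pk)) return(spec)
  bin <- floor(pk$mz / cfg$bin_width)
  # rank within bin: descending intensity, ties by ascending mz
  o <- order(bin, -pk$intensity, pk$mz)
  rank_in_bin <- stats::ave(seq_along(o), bin[o], FUN = seq_along)
  keep_sorted <- o[rank_in_bin <= cfg$top_n]
  keep <- sort(keep_sorted)
  out <- spec
  out$peaks <- pk[keep, , drop = FALSE]
  rownames(out$peaks) <- NULL
  out
}

#' Collapse isotope envelopes and deconvolute multiply charged peaks
#'
#' A best-effort substitute for vendor-grade preprocessing: peak series
#' spaced by 1.00335/z Th (within `iso_tol_ppm`) whose intensities decrease
#' monotonically after the envelope apex are collapsed onto their
#' monoisotopic member, intensities summed; members attributed charge z > 1
#' are re-expressed at the singly protonated mass `m*z - (z-1)*proton`.
#' Charges are tried from `max_charge` down to 2, then 1 (which only
#' declusters, never moves peaks). With `max_charge = 0` the function is the
#' identity. The canonical pipeline assumes already-preprocessed peak lists;
#' this step is off by default.
#'
#' @param spec A [spectrum()].
#' @param max_charge Highest fragment charge considered; 0 disables.
#' @param iso_tol_ppm Tolerance for the isotope spacing, in ppm.
#' @return A new [spectrum()] with collapsed peak list sorted by m/z.
#' @export
deisotope_and_deconvolute <- function(spec, max_charge = 2L, iso_tol_ppm = 10) {
  stopifnot(inherits(spec, "spectrum"))
  if (max_charge < 1L || !nrow(spec$peaks)) return(spec)
  mz <- spec$peaks$mz
  inten <- spec$peaks$intensity
  n <- length(mz)
  used <- logical(n)
  out_mz <- numeric(0)
  out_int <- numeric(0)
  iso <- 1.00335
  for (z in seq(as.integer(max_charge), 1L)) {
    spacing <- iso / z
    for (i in seq_len(n)) {
      if (used[i]) next
      chain <- i
      cur <- i
      apex_passed <- FALSE
      repeat {
        expect <- mz[cur] + spacing
        tol <- expect * iso_tol_ppm * 1e-6
        cand <- which(!used & abs(mz - expect) <= tol)
        cand <- setdiff(cand, chain)
        if (!length(cand)) break
        nxt <- cand[which.min(abs(mz[cand] - expect))]
        if (inten[nxt] <= inten[cur]) {
          apex_passed <- TRUE
        } else if (apex_passed) {
          break  # intensities must keep decreasing after the apex
        }
        chain <- c(chain, nxt)
        cur <- nxt
      }
      if (length(chain) >= 2L) {
        used[chain] <- TRUE
        mono <- mz[chain[1L]]
        newmz <- if (z > 1L) mono * z - (z - 1L) * PROTON_MASS else mono
        out_mz <- c(out_mz, newmz)
        out_int <- c(out_int, sum(inten[chain]))
      }
    }
  }
  # untouched peaks pass through unchanged
  out_mz <- c(out_mz, mz[!used])
  out_int <- c(out_int, inten[!used])
  o <- order(out_mz)
  out <- spec
  out$peaks <- data.frame(mz = out_mz[o], intensity = out_int[o])
  out
}

#' Read a Mascot Generic Format peak list
#'
#' Parses BEGIN IONS/END IONS blocks with PEPMASS, optional CHARGE,
#' TITLE and RTINSECONDS headers. A block without CHARGE is assigned 2+
#' (the most common DDA precursor charge) with a warning; a block without
#' TITLE gets `"<file stem>.<index>"` as its id. Blocks without peaks are
#' kept (flagged with zero peaks). Malformed blocks raise an error carrying
#' the offending line number.
#'
#' @param path Path to an MGF file.
#' @return List of [spectrum()] objects (empty list for an empty file).
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  stem <- tools::file_path_sans_ext(basename(path))
  spectra <- list()
  i <- 1L
  n <- length(lines)
  idx <- 0L
  missing_charge <- 0L
  while (i <= n) {
    ln <- trimws(lines[[i]])
    if (ln != "BEGIN IONS") { i <- i + 1L; next }
    idx <- idx + 1L
    hdr <- list(TITLE = NULL, PEPMASS = NULL, CHARGE = NULL, RTINSECONDS = NULL)
    mzv <- numeric(0); intv <- numeric(0)
    i <- i + 1L
    start_line <- i
    while (i <= n) {
      ln <- trimws(lines[[i]])
      if (ln == "END IONS") break
      if (!nzchar(ln)) { i <- i + 1L; next }
      if (grepl("=", ln, fixed = TRUE)) {
        key <- toupper(sub("=.*$", "", ln))
        val <- sub("^[^=]*=", "", ln)
        hdr[[key]] <- val
      } else {
        flds <- strsplit(ln, "[ \t]+")[[1L]]
        pm <- suppressWarnings(as.numeric(flds[1:2]))
        if (length(flds) < 2L || anyNA(pm))
          stop("unparseable peak line ", i, " in ", path, ": '", ln, "'")
        mzv <- c(mzv, pm[1L]); intv <- c(intv, pm[2L])
      }
      i <- i + 1L
    }
    if (i > n) stop("unterminated BEGIN IONS block starting near line ",
                    start_line, " in ", path)
    if (is.null(hdr$PEPMASS))
      stop("block ending at line ", i, " in ", path, " has no PEPMASS")
    pepmass <- suppressWarnings(
      as.numeric(strsplit(trimws(hdr$PEPMASS), "[ \t]+")[[1L]][1L]))
    if (is.na(pepmass))
      stop("unparseable PEPMASS in block ending at line ", i, " in ", path)
    if (is.null(hdr$CHARGE)) {
      chg <- 2L
      missing_charge <- missing_charge + 1L
    } else {
      chg <- suppressWarnings(as.integer(gsub("[+ ]", "", hdr$CHARGE)))
      if (is.na(chg)) chg <- 2L
    }
    rt <- if (is.null(hdr$RTINSECONDS)) NA_real_ else
      suppressWarnings(as.numeric(hdr$RTINSECONDS))
    id <- if (is.null(hdr$TITLE) || !nzchar(hdr$TITLE))
      sprintf("%s.%d", stem, idx) else hdr$TITLE
    spectra[[length(spectra) + 1L]] <-
      spectrum(id, pepmass, chg, mzv, intv, rt)
    i <- i + 1L
  }
  if (missing_charge)
    warning(missing_charge, " MGF block(s) without CHARGE assumed 2+")
  spectra
}

#' Write spectra to Mascot Generic Format
#'
#' m/z values are printed with 5 decimals (re-reading reproduces them to at
#' least 4), intensities with 4 significant-digit precision. Output order
#' follows the input list, so writing is deterministic.
#'
#' @param spectra List of [spectrum()] objects.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (s in spectra) {
    stopifnot(inherits(s, "spectrum"))
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", s$spectrum_id), con)
    writeLines(sprintf("PEPMASS=%.5f", s$precursor_mz), con)
    writeLines(sprintf("CHARGE=%d+", s$precursor_charge), con)
    if (!is.na(s$retention_time))
      writeLines(sprintf("RTINSECONDS=%.3f", s$retention_time), con)
    if (nrow(s$peaks))
      writeLines(sprintf("%.5f %.6g", s$peaks$mz, s$peaks$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}
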