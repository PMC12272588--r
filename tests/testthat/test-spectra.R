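test_that("MGF blocks parse into spectra", {
  f <- tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=scan1", "PEPMASS=400.7", "CHARGE=2+",
               "100.1 10", "200.2 20", "300.3 30", "END IONS",
               "BEGIN IONS", "TITLE=empty", "PEPMASS=500.1", "CHARGE=3+",
               "END IONS"), f)
  sp <- read_mgf(f)
  expect_length(sp, 2L)
  expect_equal(sp[[1]]$spectrum_id, "scan1")
  expect_equal(sp[[1]]$precursor_charge, 2L)
  expect_equal(nrow(sp[[1]]$peaks), 3L)
  expect_equal(nrow(sp[[2]]$peaks), 0L)  # kept, just empty
})

test_that("MGF edge cases: missing charge, malformed blocks, empty file", {
  f <- tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "PEPMASS=400.7", "100.0 1", "END IONS"), f)
  expect_warning(sp <- read_mgf(f), "CHARGE")
  expect_equal(sp[[1]]$precursor_charge, 2L)
  expect_match(sp[[1]]$spectrum_id, "^.*\\.1$")  # file stem + index

  writeLines(c("BEGIN IONS", "CHARGE=2+", "100.0 1", "END IONS"), f)
  expect_error(read_mgf(f), "PEPMASS")
  writeLines(c("BEGIN IONS", "PEPMASS=400.7", "CHARGE=2+", "100.0 oops",
               "END IONS"), f)
  expect_error(read_mgf(f), "line 4")
  writeLines(character(), f)
  expect_length(read_mgf(f), 0L)
})

test_that("MGF write/read round-trips to 4 decimals", {
  set.seed(7)
  orig <- lapply(1:10, function(i) {
    n <- sample(0:40, 1)
    spectrum(sprintf("rt.%d", i), runif(1, 300, 1200), sample(1:4, 1),
             sort(runif(n, 100, 1800)), runif(n, 1, 1e5),
             retention_time = runif(1, 0, 3600))
  })
  f <- tempfile(fileext = ".mgf")
  write_mgf(orig, f)
  back <- read_mgf(f)
  expect_length(back, length(orig))
  for (i in seq_along(orig)) {
    expect_equal(back[[i]]$spectrum_id, orig[[i]]$spectrum_id)
    expect_equal(back[[i]]$precursor_charge, orig[[i]]$precursor_charge)
    expect_equal(back[[i]]$peaks$mz, orig[[i]]$peaks$mz, tolerance = 1e-4)
  }
  # a second write of the re-read file is byte-identical
  f2 <- tempfile(fileext = ".mgf")
  write_mgf(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("top-N filter keeps the most intense peaks per bin", {
  set.seed(1)
  mz <- runif(14, 10, 95)          # all in bin [0, 100)
  inten <- sample(1:1000, 14)
  sp <- peaks_spectrum(mz, inten)
  out <- filter_top_n_per_bin(sp, peak_filter_config(100, 12))
  expect_equal(nrow(out$peaks), 12L)
  expect_setequal(out$peaks$intensity, sort(inten, decreasing = TRUE)[1:12])
  # under capacity: untouched
  sp5 <- peaks_spectrum(mz[1:5], inten[1:5])
  expect_equal(filter_top_n_per_bin(sp5, peak_filter_config(100, 12))$peaks,
               sp5$peaks)
})

test_that("filter agrees with the per-bin sort oracle and is idempotent", {
  set.seed(99)
  for (cfg in list(c(30, 4), c(50, 6), c(100, 12))) {
    pf <- peak_filter_config(cfg[1], cfg[2])
    for (r in 1:20) {
      n <- 500
      sp <- peaks_spectrum(runif(n, 100, 1700), rlnorm(n, 5, 2))
      out <- filter_top_n_per_bin(sp, pf)
      keep <- bf_filter(sp$peaks$mz, sp$peaks$intensity, cfg[1], cfg[2])
      expect_equal(out$peaks$mz, sp$peaks$mz[keep])
      expect_equal(out$peaks$intensity, sp$peaks$intensity[keep])
      twice <- filter_top_n_per_bin(out, pf)
      expect_identical(twice$peaks, out$peaks)
    }
  }
})

test_that("bin membership is half-open at exact bin boundaries", {
  # 13 peaks at exactly 100.0 (bin 1) with one stronger peak at 99.99 (bin 0)
  mz <- c(99.99, seq(100, 100.0012, by = 1e-4))
  inten <- c(1, 13:1)
  out <- filter_top_n_per_bin(peaks_spectrum(mz, inten),
                              peak_filter_config(100, 12))
  expect_true(99.99 %in% out$peaks$mz)         # alone in its bin, survives
  expect_equal(sum(out$peaks$mz >= 100), 12L)  # boundary peak counts in bin 1
  expect_false(1 %in% out$peaks$intensity[out$peaks$mz >= 100])
})

test_that("deisotoping collapses a 2+ envelope onto the 1+ mass", {
  sp <- peaks_spectrum(c(500.000, 500.502, 501.004), c(100, 60, 25))
  out <- deisotope_and_deconvolute(sp, max_charge = 2, iso_tol_ppm = 20)
  expect_equal(nrow(out$peaks), 1L)
  expect_equal(out$peaks$mz, 998.9927, tolerance = 1e-3)
  expect_equal(out$peaks$intensity, 185)
})

test_that("deisotoping leaves isolated 1+ peaks untouched and 0 disables", {
  sp <- peaks_spectrum(c(200.0, 450.3, 801.7), c(5, 9, 2))
  expect_equal(deisotope_and_deconvolute(sp, 2)$peaks, sp$peaks)
  sp2 <- peaks_spectrum(c(500.000, 500.502), c(10, 8))
  expect_identical(deisotope_and_deconvolute(sp2, 0)$peaks, sp2$peaks)
})

test_that("deconvolution recovers 1+ matches for 2+ fragment spectra", {
  # build a spectrum whose fragments are all 2+ versions of the b/y ions
  p <- peptide("SAMPLEKPEPTIDER")
  ions <- theoretical_by_ions(p)
  proton <- 1.007276466
  mz2 <- (ions$mz + proton) / 2
  mz <- c(rbind(mz2, mz2 + 1.00335 / 2))       # envelopes of two peaks
  inten <- c(rbind(rep(100, nrow(ions)), rep(55, nrow(ions))))
  sp <- peaks_spectrum(mz, inten)
  before <- match_peaks(sp, ions, 20)
  after <- match_peaks(deisotope_and_deconvolute(sp, 2), ions, 20)
  expect_gte(after$n_b + after$n_y, before$n_b + before$n_y)
  expect_equal(after$n_b + after$n_y, nrow(ions))
})
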