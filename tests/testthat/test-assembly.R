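test_that("PSM tables load with labels, mods and provenance", {
  df <- rbind(psm_row("s1", "PEPTIDEK"),
              psm_row("s1", "KEDITPEP", is_decoy = 1, protein_ids = "rev_P1"),
              psm_row("s2", "SAMPLER", modifications = "3:79.96633"))
  tab <- load_psm_df(df, "comet")
  expect_equal(nrow(tab), 3L)
  expect_true(all(tab$engines == "comet"))
  expect_equal(tab$label, c("target", "decoy", "target"))
  mods <- parse_modifications(tab$modifications[3])
  expect_equal(mods$position, 3L)
  expect_equal(mods$delta, 79.96633)
  expect_equal(tab$mod_key[3], "3:79.966")
})

test_that("schema violations are reported by column and row", {
  f <- tempfile()
  writeLines(c("spectrum_id\tpeptide\tcharge", "s1\tPEP\t2"), f)
  expect_error(load_psm_table(f, "x"), "modifications")
  df <- psm_row("s1", "PEPTIDEK", modifications = "4:oops")
  f2 <- tempfile()
  write.table(df, f2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_psm_table(f2, "x"), "row 1")
})

test_that("entrapment relabelling follows the accession prefix", {
  df <- rbind(psm_row("s1", "PEPTIDEK", protein_ids = "ENTRAP_1_F1"),
              psm_row("s1", "SAMPLER", protein_ids = "ENTRAP_1_F1;TGT_01"),
              psm_row("s2", "TIDEPEPK", is_decoy = 1,
                      protein_ids = "ENTRAP_2_F9"))
  tab <- label_entrapment(load_psm_df(df, "x"))
  expect_equal(tab$label, c("entrapment", "target", "decoy"))
})

test_that("identical candidates merge across engines; distinct ones survive", {
  t1 <- load_psm_df(psm_row("s1", "PEPTIDEK", engine_score = 5), "comet")
  t2 <- load_psm_df(psm_row("s1", "PEPTIDEK", engine_score = 9), "tandem")
  t3 <- load_psm_df(psm_row("s1", "PEPTIDEK", engine_score = 2), "mq")
  m <- merge_engines(list(t1, t2, t3))
  expect_equal(nrow(m), 1L)
  expect_equal(m$engines, "comet;mq;tandem")
  expect_match(m$engine_score, "comet:5.*mq:2.*tandem:9")

  t4 <- load_psm_df(psm_row("s1", "SAMPLER"), "tandem")
  m2 <- merge_engines(list(t1, t4))
  expect_equal(nrow(m2), 2L)
  expect_equal(nrow(merge_engines(list())), 0L)
})

test_that("modification or charge differences prevent merging", {
  t1 <- load_psm_df(psm_row("s1", "PEPTIDEK"), "a")
  t2 <- load_psm_df(psm_row("s1", "PEPTIDEK", modifications = "4:79.96633"),
                    "b")
  t3 <- load_psm_df(psm_row("s1", "PEPTIDEK", charge = 3), "c")
  expect_equal(nrow(merge_engines(list(t1, t2, t3))), 3L)
  # same delta written with extra precision still merges (3-decimal key)
  t4 <- load_psm_df(psm_row("s1", "PEPTIDEK", modifications = "4:79.9663"),
                    "d")
  expect_equal(nrow(merge_engines(list(t2, t4))), 1L)
})

test_that("conflicting target/decoy labels for one candidate are fatal", {
  t1 <- load_psm_df(psm_row("s1", "PEPTIDEK"), "a")
  t2 <- load_psm_df(psm_row("s1", "PEPTIDEK", is_decoy = 1), "b")
  expect_error(merge_engines(list(t1, t2)), "database mismatch")
})

# helpers building scored candidates with controlled annotated peaks
fake_match <- function(peaks) structure(
  list(matched_ions = data.frame(), matched_sites = integer(),
       annotated_peak_indices = peaks, matched_intensity_fraction = 0.5,
       n_b = length(peaks), n_y = 0L, n_unmatched = 0L, peptide_length = 8L),
  class = "match_result")

cand_df <- function(seqs, scores, labels = "target") {
  data.frame(spectrum_id = "s1", sequence = seqs, uniscore = scores,
             label = labels)
}

test_that("chimera rule accepts disjoint mates and rejects >50% overlap", {
  cands <- cand_df(c("AAAAAAAK", "CCCCCCCK"), c(12, 9))
  both <- resolve_chimera(cands, list(fake_match(1:6), fake_match(7:12)))
  expect_equal(both$rank, 1:2)
  expect_equal(both$is_chimera_mate, c(FALSE, TRUE))

  # second candidate shares 3/5 = 60% of its annotated peaks
  shared <- resolve_chimera(cands, list(fake_match(1:6),
                                        fake_match(c(1, 2, 3, 7, 8))))
  expect_equal(nrow(shared), 1L)
  expect_equal(shared$sequence, "AAAAAAAK")

  # exactly 50% shared is allowed (the rule rejects strictly more)
  half <- resolve_chimera(cands, list(fake_match(1:6),
                                      fake_match(c(1, 2, 3, 7, 8, 9))))
  expect_equal(nrow(half), 2L)
})

test_that("single candidates and degenerate configs behave", {
  one <- resolve_chimera(cand_df("AAAAAAAK", 5), list(fake_match(integer())),
                         chimera_config(0))
  expect_equal(one$rank, 1L)  # top candidate accepted regardless
  cands <- cand_df(c("AAAAAAAK", "CCCCCCCK", "DDDDDDDK"), c(9, 8, 7))
  mrs <- list(fake_match(1:4), fake_match(1:4), fake_match(1:2))
  all_in <- resolve_chimera(cands, mrs, chimera_config(1))
  expect_equal(nrow(all_in), 3L)
  strict <- resolve_chimera(cands, mrs, chimera_config(0))
  expect_equal(nrow(strict), 1L)
  # a later candidate with no annotated peaks is rejected
  none <- resolve_chimera(cand_df(c("AAAAAAAK", "CCCCCCCK"), c(9, 8)),
                          list(fake_match(1:4), fake_match(integer())))
  expect_equal(nrow(none), 1L)
})

test_that("acceptance is invariant to candidate input order", {
  cands <- cand_df(c("AAAAAAAK", "CCCCCCCK", "DDDDDDDK"), c(9, 8, 7),
                   c("target", "decoy", "target"))
  mrs <- list(fake_match(1:6), fake_match(7:12), fake_match(c(1, 13)))
  ref <- resolve_chimera(cands, mrs)
  for (o in list(c(2, 1, 3), c(3, 2, 1), c(2, 3, 1))) {
    alt <- resolve_chimera(cands[o, ], mrs[o])
    expect_equal(alt$sequence, ref$sequence)
    expect_equal(alt$rank, ref$rank)
  }
  # ranking is descending in score with deterministic tie-breaks
  expect_true(all(diff(ref$uniscore) <= 0))
})

test_that("tied scores rank target before decoy, then by sequence", {
  cands <- cand_df(c("CCCCCCCK", "AAAAAAAK", "BBBBBBBK"), c(5, 5, 5),
                   c("decoy", "target", "target"))
  mrs <- list(fake_match(1:2), fake_match(3:4), fake_match(5:6))
  out <- resolve_chimera(cands, mrs)
  expect_equal(out$sequence[1], "AAAAAAAK")
  expect_equal(out$label[3], "decoy")
})

test_that("chimera statistics count spectra and overlaps", {
  acc <- data.frame(
    spectrum_id = c(paste0("s", 1:8), "s9", "s9", "s10", "s10"),
    rank = c(rep(1L, 8), 1L, 2L, 1L, 2L),
    shared_fraction = c(rep(0, 8), 0, 0.25, 0, 0.5))
  st <- chimera_statistics(acc)
  expect_equal(st$chimera_fraction, 0.2)
  expect_equal(as.integer(st$psms_per_spectrum[c("1", "2")]), c(8L, 2L))
  expect_equal(st$overlap_distribution, c(0.25, 0.5))
  empty <- chimera_statistics(acc[0, ])
  expect_true(is.nan(empty$chimera_fraction))
})
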