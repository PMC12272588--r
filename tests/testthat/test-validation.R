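rec_df <- function(scores, labels, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("r%02d", seq_along(scores))
  data.frame(record_id = ids, score = scores, label = labels)
}

test_that("the decoy occurrence rate is counted down the sorted list", {
  # labels in score order T,T,D,T,D: at the first decoy T=2, D=1 -> 0.5
  tab <- fdr_curve(rec_df(c(10, 9, 8, 7, 6),
                          c("target", "target", "decoy", "target", "decoy")))
  expect_equal(tab$raw_fdr[3], 0.5)
  expect_equal(tab$cum_targets, c(1, 2, 2, 3, 3))
  expect_equal(tab$cum_decoys, c(0, 0, 1, 1, 2))
  # q-values: bottom-up running minimum (the T,T,D,T prefix has raw 1/3)
  expect_equal(tab$q_value, c(0, 0, 1 / 3, 1 / 3, 2 / 3))
  no_dec <- fdr_curve(rec_df(5:1, rep("target", 5)))
  expect_true(all(no_dec$raw_fdr == 0) && all(no_dec$q_value == 0))
  expect_equal(nrow(fdr_curve(rec_df(numeric(), character()))), 0L)
})

test_that("both estimators agree with the O(n^2) recount oracle", {
  set.seed(61)
  for (r in 1:25) {
    n <- sample(c(20, 100, 1000), 1)
    # integer scores force plenty of ties
    rec <- rec_df(sample(0:30, n, replace = TRUE),
                  sample(c("target", "decoy"), n, TRUE, prob = c(0.6, 0.4)))
    for (est in c("DT", "DTD")) {
      tab <- fdr_curve(rec, est)
      oracle <- bf_fdr(rec, est)
      ix <- match(tab$record_id, oracle$record_id)
      expect_equal(tab$raw_fdr, oracle$raw_fdr[ix])
      expect_equal(tab$q_value, oracle$q_value[ix])
    }
  }
})

test_that("q-values are monotone and acceptance sets nest", {
  set.seed(62)
  rec <- rec_df(sample(0:25, 400, replace = TRUE),
                sample(c("target", "decoy"), 400, TRUE, c(0.7, 0.3)))
  tab <- fdr_curve(rec)
  expect_true(all(diff(tab$q_value) >= 0))  # non-decreasing as score drops
  a1 <- filter_at_fdr(tab, 0.01)$record_id
  a5 <- filter_at_fdr(tab, 0.05)$record_id
  expect_true(all(a1 %in% a5))
  expect_equal(nrow(filter_at_fdr(tab, 1)), 400L)
  expect_error(filter_at_fdr(tab, 0), "alpha")
})

test_that("a target and decoy tied at the threshold are both kept", {
  # last accepted score group holds one target and one decoy
  rec <- rec_df(c(rep(10, 98), 5, 5, 4, 3),
                c(rep("target", 98), "target", "decoy", "target", "target"))
  tab <- fdr_curve(rec)
  q_at_5 <- unique(tab$q_value[tab$score == 5])
  acc <- filter_at_fdr(tab, q_at_5)
  expect_true(all(c("target", "decoy") %in% acc$label[acc$score == 5]))
})

test_that("peptide collapse keeps the best PSM per bare sequence", {
  psms <- data.frame(
    record_id = sprintf("p%d", 1:5),
    sequence = c("PEPTIDEK", "PEPTIDEK", "PEPTIDEK", "SAMPLER", "SAMPLER"),
    score = c(10, 14, 11, 7, 7),
    label = c("target", "target", "target", "target", "decoy"))
  # charges 2/3 and a phospho form all collapse to one record at score 14
  out <- collapse_to_peptides(psms)
  expect_equal(nrow(out), 2L)
  expect_equal(out$score[out$sequence == "PEPTIDEK"], 14)
  # all-unique sequences: identity
  uniq <- data.frame(record_id = c("a", "b"), sequence = c("AK", "CK"),
                     score = 1:2, label = "target")
  expect_equal(nrow(collapse_to_peptides(uniq)), 2L)
  # I/L equating merges XLX and XIX only when asked
  il <- data.frame(record_id = c("a", "b"), sequence = c("ALK", "AIK"),
                   score = c(3, 9), label = "target")
  expect_equal(nrow(collapse_to_peptides(il)), 2L)
  merged <- collapse_to_peptides(il, il_equate = TRUE)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$score, 9)
})

test_that("protein grouping merges, absorbs and razors deterministically", {
  fa <- Biostrings::AAStringSet(c(
    A = "MKPEPTIDEKSAMPLERTT",      # PEPTIDEK, SAMPLER
    B = "GGPEPTIDEKGG",             # PEPTIDEK (proper subset of A)
    C = "MKPEPTIDEKSAMPLERGG",      # identical peptide set to A
    D = "QQQELVISHKQQ"))            # disjoint: ELVISHK
  peps <- data.frame(sequence = c("PEPTIDEK", "SAMPLER", "ELVISHK"),
                     score = c(12, 9, 7), label = "target")
  g <- infer_protein_groups(peps, fa)
  expect_equal(nrow(g), 2L)
  big <- g[g$n_peptides == 2, ]
  expect_equal(big$members, "A;B;C")   # C merged (identical), B absorbed
  expect_equal(big$group_score, 12)
  expect_equal(g$members[g$n_peptides == 1], "D")
})

test_that("razor peptides go to the group with more evidence", {
  fa <- Biostrings::AAStringSet(c(
    A = "MKPEPTIDEKSAMPLERK",       # PEPTIDEK, SAMPLER
    B = "GGSAMPLERKELVISHK"))       # SAMPLER, ELVISHK -> tie broken by accession
  peps <- data.frame(sequence = c("PEPTIDEK", "SAMPLER", "ELVISHK"),
                     score = c(5, 8, 2), label = "target")
  g <- infer_protein_groups(peps, fa)
  expect_equal(nrow(g), 2L)
  # both groups have 2 candidate peptides; SAMPLER is shared and goes to A
  expect_equal(g$n_peptides[g$group_id == "A"], 2L)
  expect_equal(g$n_peptides[g$group_id == "B"], 1L)
})

test_that("orphan peptides are dropped with a warning", {
  fa <- Biostrings::AAStringSet(c(A = "MKPEPTIDEK"))
  peps <- data.frame(sequence = c("PEPTIDEK", "NOTINDBK"),
                     score = c(5, 4), label = "target")
  expect_warning(g <- infer_protein_groups(peps, fa), "no database protein")
  expect_equal(nrow(g), 1L)
})

test_that("protein-group FDR follows the same counting rules", {
  g <- data.frame(group_id = sprintf("G%02d", 1:10),
                  members = "x", peptides = "y", n_peptides = 1L,
                  group_score = 10:1,
                  label = c("decoy", rep("target", 9)))
  # one decoy above nine targets: raw FDR infinite at the top, never <= 1%
  acc <- protein_group_fdr(g, alpha = 0.01)
  expect_equal(nrow(acc), 0L)
  g2 <- g; g2$label <- "target"
  expect_equal(nrow(protein_group_fdr(g2, alpha = 0.01)), 10L)
})

test_that("entrapment FDP estimators compute the stated arithmetic", {
  acc <- data.frame(label = c(rep("target", 200), rep("entrapment", 2)))
  expect_equal(as.numeric(entrapment_fdp(acc)), 2 / 202)
  expect_equal(as.numeric(entrapment_fdp(
    data.frame(label = rep("target", 50)))), 0)
  sc <- entrapment_fdp(acc, db_sizes = c(target = 1000, entrapment = 4000),
                       scaled = TRUE)
  expect_equal(as.numeric(sc), 2 * 1.25 / 202)
  expect_equal(attr(sc, "estimator"), "scaled")
  expect_warning(v <- entrapment_fdp(data.frame(label = character())),
                 "undefined")
  expect_true(is.nan(v))
})

test_that("decoys are excluded from the FDP denominator", {
  acc <- data.frame(label = c(rep("target", 97), rep("decoy", 10),
                              rep("entrapment", 3)))
  expect_equal(as.numeric(entrapment_fdp(acc)), 3 / 100)
})
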