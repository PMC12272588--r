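#' Target-decoy FDR curve
#'
#' Records are ordered by descending score; at each row the raw FDR is
#' computed from the cumulative decoy and target counts up to (and
#' including) that score. Tied scores form one group sharing the
#' cumulative counts at the group's end. q-values are the running minimum
#' of the raw FDR taken from the worst score upward, which makes
#' thresholding at any level well-defined between decoy events. Entrapment
#' records count as targets here; they matter only for the empirical FDP.
#'
#' @param records data.frame with columns `record_id`, `score` and `label`
#'   (one of "target", "decoy", "entrapment"). Extra columns are carried
#'   through.
#' @param estimator "DT" for decoys/targets (default, the classical
#'   target-decoy estimate) or "DTD" for decoys/(targets + decoys).
#' @return data.frame of class `"fdr_table"` ordered by descending score
#'   with columns `cum_targets`, `cum_decoys`, `raw_fdr`, `q_value`
#'   appended. Empty input gives an empty table.
#' @export
fdr_curve <- function(records, estimator = c("DT", "DTD")) {
  estimator <- match.arg(estimator)
  stopifnot(all(c("record_id", "score", "label") %in% names(records)))
  if (!nrow(records)) {
    out <- records
    out$cum_targets <- integer(); out$cum_decoys <- integer()
    out$raw_fdr <- numeric(); out$q_value <- numeric()
    class(out) <- c("fdr_table", class(out))
    attr(out, "estimator") <- estimator
    return(out)
  }
  stopifnot(all(records$label %in% c("target", "decoy", "entrapment")))
  o <- order(-records$score, records$label, records$record_id)
  out <- records[o, , drop = FALSE]
  rownames(out) <- NULL
  is_decoy <- out$label == "decoy"
  cum_d <- cumsum(is_decoy)
  cum_t <- cumsum(!is_decoy)
  # tied scores share the cumulative counts at the end of the tie group
  grp <- cumsum(!duplicated(out$score))
  last_of_grp <- cumsum(tabulate(grp))     # index of last row in each group
  cum_d <- cum_d[last_of_grp][grp]
  cum_t <- cum_t[last_of_grp][grp]
  raw <- if (estimator == "DT") {
    ifelse(cum_t > 0, cum_d / cum_t, ifelse(cum_d > 0, Inf, 0))
  } else {
    cum_d / (cum_t + cum_d)
  }
  q <- rev(cummin(rev(raw)))
  out$cum_targets <- cum_t
  out$cum_decoys <- cum_d
  out$raw_fdr <- raw
  out$q_value <- q
  class(out) <- c("fdr_table", class(out))
  attr(out, "estimator") <- estimator
  out
}

#' Threshold an FDR table
#'
#' Accepts every record with q-value <= `alpha`. Because tied scores share
#' one q-value, a target and a decoy tied exactly at the threshold score
#' are both retained — neither is arbitrarily rejected in favour of the
#' other.
#'
#' @param table An [fdr_curve()] result.
#' @param alpha FDR level in (0, 1]; default 0.01.
#' @return The accepted rows (targets, decoys and entrapment records alike;
#'   split on `label` as needed).
#' @export
filter_at_fdr <- function(table, alpha = 0.01) {
  stopifnot(inherits(table, "fdr_table"))
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]")
  table[table$q_value <= alpha, , drop = FALSE]
}

#' Collapse scored PSMs to the peptide level
#'
#' One record per bare sequence — modifications and charge are ignored;
#' isoleucine and leucine are equated only when `il_equate = TRUE`. Each
#' sequence keeps the score of its best PSM and inherits that PSM's label.
#' The FDR machinery then applies unchanged.
#'
#' @param psms data.frame with columns `record_id`, `sequence`, `score`,
#'   `label`.
#' @param il_equate Treat I and L as the same letter for sequence identity.
#' @return data.frame with one row per collapsed sequence.
#' @export
collapse_to_peptides <- function(psms, il_equate = FALSE) {
  stopifnot(all(c("record_id", "sequence", "score", "label") %in% names(psms)))
  if (!nrow(psms)) return(psms)
  key <- if (il_equate) chartr("I", "L", psms$sequence) else psms$sequence
  o <- order(key, -psms$score, psms$label, psms$record_id)
  s <- psms[o, , drop = FALSE]
  k <- key[o]
  best <- !duplicated(k)
  out <- s[best, , drop = FALSE]
  out$record_id <- if (il_equate) k[best] else out$sequence
  rownames(out) <- NULL
  out
}

#' Map peptides onto proteins and build parsimonious protein groups
#'
#' Peptides are located in the database by exact substring match (decoy
#' peptides therefore land on decoy accessions). Grouping is classical
#' parsimony: proteins with identical peptide sets are merged into one
#' group; proteins whose peptide set is a proper subset of another's are
#' absorbed; remaining shared peptides are assigned to the group with the
#' larger peptide set (razor rule, ties by accession order). The group
#' score is the best member-peptide score by default (`group_score_fn =
#' max`); the group label comes from its accessions' prefixes.
#'
#' @param peptides data.frame with columns `sequence`, `score`, `label`
#'   (e.g. accepted peptide records).
#' @param fasta An `AAStringSet` (targets + decoys + optional entrapment)
#'   or path to a FASTA file.
#' @param decoy_prefix,entrapment_prefix Accession prefixes marking decoy
#'   and entrapment database entries.
#' @param group_score_fn Order statistic combining member-peptide scores.
#' @return data.frame of protein groups: `group_id`, `members`
#'   (";"-joined accessions), `peptides` (";"-joined), `n_peptides`,
#'   `group_score`, `label`. Peptides matching no protein are dropped with
#'   a warning (orphan bucket, excluded from FDR).
#' @export
infer_protein_groups <- function(peptides, fasta,
                                 decoy_prefix = "rev_",
                                 entrapment_prefix = "ENTRAP_",
                                 group_score_fn = max) {
  if (is.character(fasta)) fasta <- Biostrings::readAAStringSet(fasta)
  acc <- sub("\\s.*$", "", names(fasta))
  seqs <- as.character(fasta)
  pep <- unique(peptides$sequence)
  hits <- lapply(pep, function(p) acc[grepl(p, seqs, fixed = TRUE)])
  orphan <- lengths(hits) == 0L
  if (any(orphan))
    warning(sum(orphan), " peptide(s) matched no database protein; excluded")
  pep <- pep[!orphan]; hits <- hits[!orphan]
  if (!length(pep))
    return(data.frame(group_id = character(), members = character(),
                      peptides = character(), n_peptides = integer(),
                      group_score = numeric(), label = character()))
  # protein -> peptide set
  prot <- sort(unique(unlist(hits)))
  pset <- lapply(prot, function(a)
    sort(pep[vapply(hits, function(h) a %in% h, TRUE)]))
  names(pset) <- prot
  # 1) merge proteins with identical peptide sets
  sig <- vapply(pset, paste, "", collapse = "\x01")
  grp_members <- split(prot, sig)
  grp_peps <- lapply(split(pset, sig), `[[`, 1L)
  # deterministic order: by first accession of each group
  ord <- order(vapply(grp_members, `[[`, "", 1L))
  grp_members <- grp_members[ord]; grp_peps <- grp_peps[ord]
  # 2) absorb proper subsets into the (first) superset group
  n <- length(grp_peps)
  absorbed <- rep(NA_integer_, n)
  size <- lengths(grp_peps)
  for (i in order(size)) {
    for (j in order(-size)) {
      if (i == j || size[j] <= size[i] || !is.na(absorbed[j])) next
      if (all(grp_peps[[i]] %in% grp_peps[[j]])) { absorbed[i] <- j; break }
    }
  }
  root <- function(i) { while (!is.na(absorbed[i])) i <- absorbed[i]; i }
  keep <- which(is.na(absorbed))
  roots <- vapply(seq_len(n), root, 1L)
  members <- lapply(keep, function(i)
    sort(unlist(grp_members[roots == i], use.names = FALSE)))
  peps <- grp_peps[keep]
  # 3) razor: assign each shared peptide to the group with the larger set
  owner <- integer(length(pep)); names(owner) <- pep
  gsize <- lengths(peps)
  first_acc <- vapply(members, `[[`, "", 1L)
  for (k in seq_along(pep)) {
    cand <- which(vapply(peps, function(ps) pep[k] %in% ps, TRUE))
    if (length(cand) > 1L)
      cand <- cand[order(-gsize[cand], first_acc[cand])][1L]
    owner[k] <- cand
  }
  pscore <- peptides$score[match(pep, peptides$sequence)]
  out <- do.call(rbind, lapply(seq_along(peps), function(g) {
    mine <- pep[owner == g]
    if (!length(mine)) return(NULL)   # all its peptides razored away
    accs <- members[[g]]
    lab <- if (all(startsWith(accs, decoy_prefix))) "decoy"
           else if (all(startsWith(accs, entrapment_prefix))) "entrapment"
           else "target"
    data.frame(group_id = accs[1L],
               members = paste(accs, collapse = ";"),
               peptides = paste(sort(mine), collapse = ";"),
               n_peptides = length(mine),
               group_score = group_score_fn(pscore[match(mine, pep)]),
               label = lab)
  }))
  rownames(out) <- NULL
  out[order(out$group_id), , drop = FALSE]
}

#' Protein-group level FDR
#'
#' Applies the same target-decoy curve and threshold to group scores.
#'
#' @param groups An [infer_protein_groups()] result.
#' @param alpha FDR level.
#' @param estimator Passed to [fdr_curve()].
#' @return Accepted groups (an [fdr_curve()] subset).
#' @export
protein_group_fdr <- function(groups, alpha = 0.01,
                              estimator = c("DT", "DTD")) {
  rec <- data.frame(record_id = groups$group_id, score = groups$group_score,
                    label = groups$label)
  rec <- cbind(rec, groups[setdiff(names(groups),
                                   c("group_id", "group_score", "label"))])
  filter_at_fdr(fdr_curve(rec, match.arg(estimator)), alpha)
}

#' Entrapment false discovery proportion
#'
#' Empirical FDP of an accepted set from entrapment hits: foreign (shuffled)
#' sequences cannot be genuinely present, so their acceptance rate bounds
#' the true error. Decoys are excluded from the set under evaluation. The
#' default lower-bound estimator is `N_entrapment / N_accepted`; the scaled
#' variant multiplies `N_entrapment` by `1 + |target db| / |entrapment db|`
#' (residue counts) to account for false hits landing in the target portion.
#'
#' @param accepted data.frame with a `label` column.
#' @param db_sizes Optional named numeric `c(target =, entrapment =)`
#'   residue counts, required for `scaled = TRUE`.
#' @param scaled Use the scaled estimator.
#' @return FDP in [0, 1] (or above for the scaled variant), with attribute
#'   `"estimator"`. `NaN` with a warning when nothing is accepted.
#' @export
entrapment_fdp <- function(accepted, db_sizes = NULL, scaled = FALSE) {
  keep <- accepted[accepted$label != "decoy", , drop = FALSE]
  n <- nrow(keep)
  if (!n) {
    warning("no accepted records; FDP undefined")
    return(structure(NaN, estimator = if (scaled) "scaled" else "lower_bound"))
  }
  n_ent <- sum(keep$label == "entrapment")
  if (scaled) {
    stopifnot(!is.null(db_sizes), all(c("target", "entrapment") %in%
                                        names(db_sizes)))
    n_ent <- n_ent * (1 + db_sizes[["target"]] / db_sizes[["entrapment"]])
  }
  structure(n_ent / n, estimator = if (scaled) "scaled" else "lower_bound")
}
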