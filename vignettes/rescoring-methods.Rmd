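---
title: "Rescoring peptide-spectrum matches with a matched-ion count score"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rescoring peptide-spectrum matches with a matched-ion count score}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uniscore)
```

## The problem

In bottom-up proteomics, a data-dependent acquisition (DDA) run produces
tens of thousands of MS/MS spectra, and each search engine assigns
candidate peptides to them with its own score. Different engines disagree:
their scores are not comparable, so their results cannot simply be pooled.
A *rescoring* measure that depends only on the spectrum and the candidate
sequence — not on which engine proposed it — makes the candidates from any
number of engines directly comparable, and lets a single target-decoy FDR
analysis be run over the union.

This package implements such a measure and everything required to use it:
spectrum preprocessing, theoretical fragment generation, peak annotation,
chimeric-spectrum handling, multi-engine merging, and FDR control at the
PSM, peptide and protein-group levels, validated against ground truth and
entrapment databases on synthetic data.

## The score

For a candidate peptide of length $L$, the theoretical singly charged
b- and y-ions have ordinals $1 \dots L-1$. After peak filtering, each
theoretical ion is matched to the nearest peak within a ppm tolerance.
Writing $N_b$ and $N_y$ for the matched b- and y-ion counts and $N_s$ for
the number of residues whose two adjacent cleavage sites are both
evidenced by matched ions (the *matched sequence stretch*, counted in
residues, not runs), the score is the plain unweighted sum

$$ S = N_b + N_y + N_s. $$

It is an integer in $[0,\, 3L-4]$: a fully matched peptide yields
$2(L-1)$ ions plus $L-2$ flanked residues. Cleavage site $i$ is evidenced
by $b_i$ and/or $y_{L-i}$; the site set is deduplicated, while $N_b$ and
$N_y$ count ions individually. That convention is what makes the
site-weighted variant with weights 0.5 (one series) : 1 (both series)
rank candidates identically to the plain ion sum — the reason the
unweighted sum is the canonical choice. A `score_weights()` object exposes
the weighting and stretch-exponent ablations; `morpheus_score()`,
`generic_score()` and `uniscore_plus_generic()` provide comparison
scorers. Intensity-fraction terms in the latter two penalise chimeric
spectra (a co-isolated mate claims part of the total intensity), so none
of them are used by the default pipeline. The exact published formula
behind the Generic score is not restated anywhere in this package; the
shipped default is explicitly documented as a non-canonical stand-in over
the same four components and is pluggable.

Only singly charged b/y ions are generated. For high-resolution HCD data
the information lost is small, and multiply charged fragments can be
folded in beforehand by `deisotope_and_deconvolute()` — a simple
best-effort envelope collapser that is off by default, because the
canonical pipeline assumes vendor-grade preprocessed peak lists.

### Terminal residues

A residue counts toward the stretch only when *both* adjacent cleavage
sites are matched. The first and last residues have only one internal
neighbouring site, so they can never count under the strict reading; the
flag `count_terminal_residues` exists for sensitivity analysis and treats
the peptide termini as always-evidenced boundaries. The strict reading is
the default.

## Spectrum preprocessing

`filter_top_n_per_bin()` keeps the `top_n` most intense peaks per fixed
half-open m/z window `[k*bin_width, (k+1)*bin_width)`. The default is 12
peaks per 100 Th; 4 per 30 Th and 6 per 50 Th are the corresponding
settings at narrower windows. Bins are anchored at m/z 0 rather than
sliding — the simplest deterministic reading of per-window filtering — and
intensity ties break toward the lower m/z so the operation is a pure
function of the peak list. When deisotoping is enabled it runs before
filtering; the order is our choice, flagged, not a claim about any
upstream convention.

The matched-intensity fraction (used by the comparison scorers) is
computed against the *filtered* spectrum: the matcher never sees the
unfiltered peak list, so the filtered total is the only well-defined
denominator.

## Chimeric spectra

DDA isolation windows frequently contain more than one precursor (a
co-isolation fraction of 0.14 is a standard literature figure), so two or
more engines proposing *different* sequences for one spectrum is expected
rather than pathological. All distinct candidates survive merging; per
spectrum they are ranked by descending score and each later candidate is
accepted only if at most 50% of *its own* annotated peaks are already
claimed by previously accepted candidates. The denominator choice (the
candidate's own annotated-peak count, not the union) penalises candidates
that merely re-explain claimed peaks, which is the rule's motive; the
threshold is `chimera_config(max_shared_fraction = 0.5)`. Score ties rank
targets before decoys, then lexicographically — a determinism device only;
FDR tie handling happens downstream and is label-symmetric.

## FDR estimation

`fdr_curve()` sorts records by descending score and, walking down the
list, computes the decoy occurrence rate from the cumulative counts —
decoys/targets by default (`"DT"`), decoys/(targets+decoys) (`"DTD"`)
optionally. Tied scores form one group sharing the group-end counts.
q-values are the running minimum of the raw rate taken from the worst
score upward; the monotonisation is not part of the counting rule itself
but is required for thresholds between decoy events to be well defined.
When a target and a decoy are tied exactly at the threshold score, both
are retained — neither is arbitrarily dropped. With no targets above a
leading decoy the D/T ratio is undefined; we report `Inf` there and let
the running minimum define the q-values, which keeps thresholding
conservative at the top of the list.

Peptide-level FDR collapses PSMs to bare sequences — modifications and
charge are ignored, I/L only on request (`il_equate`) — keeping each
sequence's best score and that PSM's label, then applies the identical
curve. Protein groups are built by classical parsimony: proteins with
identical peptide sets merge; proper-subset proteins are absorbed
(transitively); remaining shared peptides go to the group with the larger
peptide set, ties by accession order (razor assignment). The group score
is the best member-peptide score by default (`group_score_fn = max`; sum
is available) and the same curve applies once more. The parsimony recipe
is our interpretation of standard practice, recorded as such.

`entrapment_fdp()` measures the empirical error of an accepted set from
entrapment hits. The default estimator `N_ent / N_accepted` is a lower
bound: entrapment sequences are pure noise, while real false candidates
can share fragments with the spectrum's true peptide (e.g. the
pseudo-reversed twin of the true peptide conserves its C-terminal
residue, hence y1, and occasionally more), so foreign shuffles
under-count slightly. The scaled variant multiplies the entrapment count
by $1 + |T|/|E|$ (database residue counts), accounting for false hits
that land in the target portion of the database; with an entrapment
database several times the target size both variants nearly coincide.

## The synthetic-data generator

`sim_config()` fixes the study conditions; every generated byte is a
deterministic function of its seed. Defaults, chosen once to emulate a
high-resolution Orbitrap DDA experiment at desk scale:

| parameter | default | rationale |
|---|---|---|
| `n_proteins`, `protein_length` | 40, 150–350 aa | toy proteome, ~1,000 detectable tryptic peptides |
| `peptide_length` | 7–30 | usual detectable tryptic range |
| `ion_detection_prob` | 0.7 | typical HCD b/y coverage |
| `mz_jitter_ppm` | 5 | Orbitrap-like mass error |
| `n_noise_peaks` | 30 | uniform over [100, 1.1 × max fragment m/z] |
| `chimera_rate` | 0.14 | the reported DDA co-isolation fraction |
| `isolation_width` | 2 Th | common quadrupole isolation setting |
| `n_entrapment_shuffles` | 100 | standard entrapment design (k shuffles per foreign protein) |

Decoys are pseudo-reversed (each tryptic segment reversed with its
C-terminal residue fixed) so decoy precursor masses and termini remain
realistic. Three engine personas emulate multi-engine diversity: two
narrow ppm-window engines with different fragment tolerances and
candidate depths, and one chimera-aware persona that searches the whole
isolation window in Th — without such an engine no candidate list could
ever contain a co-isolated mate, because the mate's precursor mass
differs from the recorded one by up to half the isolation width. The
crude persona score is the matched-ion count at the persona's tolerance;
rescoring replaces it.

What the generator does *not* emulate: realistic fragment intensity
patterns (mobile-proton chemistry, collision-energy dependence),
retention-time structure, modified peptides in the emulated searches, and
homology between proteins. Tests passing on this generator therefore
demonstrate the correctness and calibration of the *procedure* — counting,
ranking, thresholds, estimators — not identification performance on real
instrument data.

For FDR-calibration studies, `simulate_calibration_set()` produces, per
simulated spectrum, one correct target candidate plus mass-matched
incorrect-target, decoy and (optionally) entrapment candidates. Incorrect
targets and decoys are drawn from the same pseudo-reversed pool, making
them exchangeable — exactly the premise of target-decoy estimation — while
the ground-truth column permits exact false-discovery-proportion
computation.

## Numerical choices

* Monoisotopic residue masses, proton 1.007276466 Da and water
  18.010565 Da are hard-coded from standard tables; b/y complementarity
  holds to < 1e-6 Da.
* Fragment match tolerance defaults to 20 ppm (config-exposed; no single
  canonical value exists for high-resolution HCD annotation). Nearest
  peak in ppm wins; an equidistant pair resolves to the lower m/z. One
  peak may annotate several theoretical ions; the annotated-peak set is
  deduplicated before intensity summation.
* Candidates merge across engines on (spectrum, sequence, per-position
  modification mass rounded to 3 decimals, charge), so engines that name
  the same modification differently still unify.
* Full-length $b_L$/$y_L$ ions are excluded; I and L are distinct letters
  everywhere except the optional peptide-collapse equating.
* Missing MGF `CHARGE` defaults to 2+ with a warning (the most common DDA
  precursor charge); empty peak blocks are kept.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script exercise: 300-spectrum datasets
for end-to-end runs; 10 seeds of 150-spectrum datasets for the
multi-engine comparison; 20 replicates of 2,000 correct + 2,000 incorrect
candidates (plus matched decoys and entrapment draws) for calibration;
1,000 random spectra for the filter contract; 10,000 random modified
peptides for mass conservation. These sizes were chosen as the smallest
at which the stochastic properties stabilise well inside their asserted
bands.

## Limitations

* The deisotoping step is a labelled best-effort heuristic, not a
  replacement for vendor or established preprocessing; m/z recalibration
  against pre-search results is out of scope entirely.
* Native engine output formats (pepXML, mzIdentML, `msms.txt`) are not
  parsed; a documented seven-column TSV is the exchange schema.
* Percolator itself is not run; `export_percolator_features()` writes the
  feature file only.
* The score favours longer peptides by construction (its ceiling is
  $3L-4$); this mirrors probability-based scores, which also rise with
  length, and is controlled by the FDR machinery rather than corrected
  away.
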