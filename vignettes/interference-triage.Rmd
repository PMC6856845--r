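---
title: "Triage of assay-technology interference: models, scores and protocol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triage of assay-technology interference: models, scores and protocol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Single-concentration high-throughput screens (HTS) report many actives that
never turn into chemistry. A substantial fraction are not inhibiting the
target at all: they interfere with the *detection technology* —
luminescence or fluorescence readouts such as AlphaScreen, FRET and
TR-FRET — via quenching, singlet-oxygen scavenging, auto-fluorescence,
redox cycling and similar mechanisms. The operational definition used
here: a compound active in a primary assay is a **CIAT** (Compound
Interfering with an Assay Technology) when it is also active in the
technology's **artefact assay** — the counter-screen run with every assay
component except the target — and an **NCIAT** when the artefact assay is
clean. `hitsieve` implements the three triage instruments that compete for
this call, and the protocol that compares them fairly.

## Curation model

Raw HTS records carry several datapoints per (compound, assay): flags
derived from a plate-normalized percent effect and flags derived from a
Z-score. Reconciliation (`reconcile_primary_flags()`) applies three rules,
in order:

1. Z-score flags take precedence whenever present; percent-effect flags
   are a fallback.
2. Within the considered flags, active + inactive at the same conditions
   (same assay; concentration metadata is not modeled, as these are
   single-concentration screens) resolves to **active**.
3. Compounds left with only inconclusive readouts are dropped.

`derive_technology_labels()` then labels every compound active in at least
one artefact-linked primary assay of a technology: CIAT if active in *any*
artefact assay of the technology, NCIAT if inactive in all, excluded
without conclusive artefact data. Only primary assays with a linked
artefact assay contribute; compounds labeled in several technologies are
kept independently per technology, since interference is
technology-specific. Labeling is idempotent and order-independent, which
the test suite checks by permuting input rows.

## The three instruments

**Random forest on structure.** Every labeled compound is encoded as a
1024-bit ECFP4 fingerprint (Morgan circular fingerprint, radius 2). A
random forest (`ranger`) is trained per technology; hyperparameters come
from a seeded random search scored by mean MCC over a stratified 3-fold
cross-validation (`tune_hyperparameters()`). The published account of the
original search grid is not available, so the default space is the
standard forest space — trees 100–1000, depth unlimited/10/20, minimum
node size 1–10, `mtry` sqrt or log2 of the feature count — and it is fully
configurable. Class assignment uses probability ≥ 0.5; classes are left
unweighted (observed prevalences sit at 20–45 %, not extreme). Chemistry
primitives are delegated to RDKit through a bundled Python helper
(`inst/python/chem_backend.py`); the test suite cross-checks substructure
matching against OpenBabel, an independent engine.

**Binomial Survivor Function.** For a compound tested in `N` screens and
active in `A` of them, under pooled hit rate `h`,

  pBSF = −log10 P(X ≥ A | N, h),  X ~ Binomial(N, h).

A score ≥ 2 — a 1 % chance that the activity pattern is random — flags a
promiscuous compound. Two numerical points deserve note. First, the
score's common printed form ("−10 log") conflicts with the cutoff's stated
meaning (2 ↔ 1 % requires −log10); the cutoff semantics are operationally
binding, so `pbsf()` uses −log10 and offers the literal ten-fold variant
behind `scale = "ten_log10"`. Second, the tail is evaluated in log space
(`pbinom(..., log.p = TRUE)`), never by naive powers, so small hit rates
and large `N` cannot underflow; agreement with exact term-by-term
summation is verified to 1e-9 relative for N ≤ 50 (with an absolute floor
where the score vanishes — there the term-by-term oracle itself loses
digits to cancellation). Replicates within one assay collapse to a single
tested/active pair before counting, and `h` is pooled across the
considered assays (a single-`h` score; per-assay hit rates are out of
scope).

**PAINS filters.** The published 480 pan-assay interference substructures,
in their standard SMARTS transcription as distributed with RDKit (entry
names like `quinone_A(370)`), applied as an any-match binary predictor.
The A/B/C families are treated as one filter set. A user-supplied SMARTS
catalog is accepted as well.

## The comparison protocol

`loao_run()` implements leave-one-assay-out evaluation: for each
artefact-linked primary assay of a technology, training labels are rebuilt
from the remaining assays only, and the held-out assay's actives are
scored by all three instruments. Held-out compounds split into **Set A**
(also found — active — in ≥ 1 training assay, hence present in the
training table) and **Set B** (found only in the held-out assay — novel
structures from the model's point of view). Occurrence is read in the
screening sense, "found", rather than "tested": a compound screened
elsewhere without ever reproducing is as unknown to the trained model as
a never-screened one, and only the found-based split makes Set A the
previously-learned stratum its near-perfect recovery is meant to certify.
Protocol details that matter:

- Assays with ≤ 5 CIATs among their actives are excluded (strictly more
  than five required), as are assays with an empty Set B; both appear in
  the report flagged with a reason, never silently dropped.
- Comparison rows are restricted to the compounds predictable by *every*
  requested method. The BSF cannot score a compound with no prior
  screening record (`N = 0`); such compounds are marked unpredictable.
- The BSF's screening record is the technology's own primary assays
  (linked and historic), not the cross-technology pool.
- MCC with any zero denominator factor is defined as 0; ROC AUC uses the
  midrank tie convention (forest probabilities tie, and a binary PAINS
  score is nothing but ties); nearest-neighbor ties at equal Tanimoto
  similarity break by compound id, for determinism.
- Per-technology summaries are unweighted per-assay means.

Two controls guard against self-deception: stratified 10-fold
cross-validation of the training table (`crossval_10fold()`), and the same
cross-validation after a seeded label permutation (`randomize_labels()`),
which must fall back to chance AUC. `nn_analysis()` supports the error
analysis: for each true-positive and false-negative CIAT, the mean
Tanimoto similarity to its five nearest training CIATs and NCIATs.

`bsf_scaling_experiment()` measures how the BSF's standing changes with
the size of the screening record: the artefact-linked assays form the base
panel and seeded random fractions of the remaining screens are added, with
the forest's LOAO performance as a constant baseline and the mean number
of tests per scored compound recorded, so "how often must a compound be
tested before the promiscuity score catches up" can be read off the curve.

## What the synthetic campaigns emulate

Real interference data of this kind is proprietary, so the package ships a
generator (`simulate_campaign()`) whose defaults define the conditions all
end-to-end claims are tested under:

- **Structures.** Libraries are enumerated from hand-written scaffold
  templates × substituent fragments — guaranteed parseable, duplicate-free
  (canonical-SMILES deduplication), and with exact control over motif
  content. Per technology, 8 % of the library carries one of two planted
  interference chemotypes: one overlapping the PAINS space (quinone for
  AlphaScreen, rhodanine for FRET, catechol for TR-FRET — all documented
  interference chemotypes for these readouts) and one deliberately outside
  it (an N-sulfonylpiperidine, quinoxaline, benzothiazole), so substructure
  alerts can capture part but not all of the structural signal, as they do
  in practice.
- **Ground truth.** A compound is a true interferer with probability 0.8
  given the technology's motif and 0.015 otherwise — structure drives
  interference but imperfectly, in both directions.
- **Readouts.** A true interferer's interference manifests in any given
  primary screen with penetrance 0.5; genuine activity occurs at a base
  hit rate calibrated (by solving the expected-prevalence equation) so
  that interferers make up 22.4 % of primary actives, the composition
  reported for large curated AlphaScreen collections. Artefact readouts
  contradict ground truth with probability 0.05 (a free parameter; no
  published estimate exists), and small fractions of duplicate
  percent-effect flags and inconclusive readouts exercise the
  reconciliation rules. With penetrance 1 a single historic observation
  would be a perfect oracle and a promiscuity score could never be beaten
  by a model on tested compounds — contradicting everything reported about
  these methods; 0.5 makes one observation evidence, not proof.
- **Design.** Each compound is tested in 1–4 of the 8 artefact-linked
  primary assays per technology (half the compounds once, so Set B is well
  populated), plus 6 "historic" screens per technology without artefact
  data, each covering 15 % of the library. Historic screens feed only the
  BSF's screening record and its scaling experiment; coverage is sparse
  because novel compounds having essentially *no* record is precisely the
  regime the Set A/Set B contrast exists to probe.
- **Determinism.** One master seed fans out into named substreams
  (library, truth, assignment, noise), so the same configuration is
  byte-identical and stages are independently reproducible.

What the generator does **not** emulate — and what passing tests therefore
do not establish about real data: dose–response and plate effects
(readouts are binary flags; Z-score computation is upstream of this
package), target-family polypharmacology (a promiscuity score's false
friends in kinase panels), chemistry beyond the enumerated fragment space,
and technology-specific interference mechanisms beyond a planted
structure→interference association. The protocol's *relative* statements
(memorization on Set A; structure beating sparse screening history on
Set B; label permutation collapsing to chance; BSF improving with record
size) are the transferable content, not the absolute metric values.

## Problem sizes and numerical choices

End-to-end acceptance checks run one technology at the full study scale —
20 000 compounds, 8 linked primary assays — where forests train on roughly
5 000 labeled compounds; unit tests exercise all three technologies at
2 500 compounds. Forest fits in the large runs use 200 trees (`mtry` =
sqrt, unlimited depth), sizes at which seeded refits are stable to well
under the margins being tested. The BSF scaling experiment averages over
12 seeds at 6 000 compounds. Degenerate inputs are defined, not guessed:
Tanimoto similarity of two empty fingerprints is 0 (logged as
pathological), `pbsf(0, N, h) = 0` for every N and h, a hit rate of 0 or 1
is rejected whenever A > 0, and single-class training sets are an error.

## Known limitations

- CIAT/NCIAT labels inherit every bias of the artefact assays themselves;
  the package treats artefact flags as given and models nothing about
  their error structure beyond one flip probability.
- The PAINS catalog is applied as published; no attempt is made to
  re-derive or re-weight the alerts.
- `ingest_pubchem()` implements the counter-screen curation rules
  (inconclusive discarded, cross-assay conflicts discarded) for standard
  BioAssay CSV exports; it is exercised on a synthetic fixture, as the
  real exports require network access.
- The forest's decision threshold is fixed at 0.5; cost-sensitive triage
  (precision/recall trade-offs per project) is left to the caller, who has
  the full probability output.
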