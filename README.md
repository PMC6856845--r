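# hitsieve

Triage of assay-technology interference compounds in high-throughput
screening.

A large share of primary HTS actives are false positives that do not touch
the target: they interfere with the detection technology itself
(AlphaScreen, FRET, TR-FRET) through quenching, auto-fluorescence, redox
cycling and related mechanisms. The operational label comes from the
**artefact assay** — the counter-screen run with all assay components
except the target: a primary active that also fires there is a **CIAT**
(Compound Interfering with an Assay Technology); one that is clean there
is an **NCIAT**. `hitsieve` is for screening informaticians who need to
make, and audit, that call at collection scale.

The package implements and compares three instruments:

- **Random forest classifier** on 1024-bit ECFP4 fingerprints (Morgan,
  radius 2), trained per technology on curated CIAT/NCIAT labels, with a
  seeded random hyperparameter search scored by mean MCC over 3-fold
  cross-validation.
- **Binomial Survivor Function (BSF)**, a screening-history promiscuity
  score: for a compound tested in *N* screens, active in *A*, under pooled
  hit rate *h*,

      pBSF = −log10 P(X ≥ A | N, h),   X ~ Binomial(N, h),

  computed in log space; pBSF ≥ 2 (a 1 % survivor chance) flags a CIAT.
- **PAINS filters**: the published 480 pan-assay interference
  substructures (SMARTS), applied as an any-match predictor.

Around them sits the full evaluation protocol: flag reconciliation
(Z-score precedence, active-wins, inconclusive discarded), per-technology
label derivation, leave-one-assay-out evaluation with **Set A**
(previously tested) / **Set B** (novel) splits restricted to the common
predictable subset, the strict >5-CIAT assay filter, MCC / recall /
precision / ROC AUC (midrank ties), label-randomization controls, 10-fold
cross-validation, nearest-neighbor Tanimoto error analysis, and a BSF
assay-subsampling experiment against the forest baseline. A seeded
synthetic-campaign generator with planted interference chemotypes makes
everything testable without proprietary data; PubChem BioAssay
counter-screen exports can be ingested with the standard curation rules.

Chemistry primitives (SMILES parsing, fingerprints, PAINS matching) are
delegated to RDKit through a bundled Python helper; `python` with RDKit
must be on the PATH.

## Worked example

```r
library(hitsieve)

cfg <- generator_config(n_compounds = 2500, n_primary_assays = 4, seed = 11)
cmp <- simulate_campaign(cfg)
cmp
#> Synthetic HTS campaign
#>   compounds:  2500
#>   technologies:  AlphaScreen, FRET, TR-FRET
#>   assays: 42 (30 primary, 12 artefact)
#>   results:  23599
#>   base hit rate used:  0.117
#>   CIAT prevalence among primary actives: AlphaScreen 20.4%, FRET 22.4%, TR-FRET 19.4%
```

The generator calibrated the base hit rate so that interferers make up
about 22.4 % of primary actives — the composition reported for large
curated AlphaScreen collections — and the three realized per-technology
prevalences sit within the sampling band around it. Curation turns the raw
flags into a training table:

```r
ds <- curate_campaign(cmp, technologies = "AlphaScreen")[["AlphaScreen"]]
ds
#> Technology dataset: AlphaScreen
#>   582 compounds: 153 CIAT (26.3 %), 429 NCIAT (73.7 %)
```

582 compounds were active in at least one artefact-linked AlphaScreen
primary assay; 153 also fired in the artefact assay (CIATs). Score a
screening history and check a structure against the PAINS catalog:

```r
pbsf(A = 3, N = 20, h = 0.05)
#> [1] 1.122          # tail chance ~7.5 %: below the cutoff
classify_bsf(pbsf(3, 20, 0.05))
#> [1] "NCIAT"

match_pains("CC1=CC(=O)C=CC1=O")   # a methyl-benzoquinone
#> $s1
#> [1] "quinone_A(370)"
```

Three active results in twenty screens at a 5 % hit rate is unremarkable
(pBSF 1.12 < 2), but the quinone substructure is a named PAINS alert. The
full three-method comparison on a technology:

```r
fp  <- fingerprint_matrix(cmp$compounds$smiles, ids = cmp$compounds$compound_id)
rep <- loao_run(cmp, "AlphaScreen", fingerprints = fp, seed = 1)
compare_report(rep)$summary
plot_method_comparison(rep)
```

which reports, per held-out assay and per Set A/Set B, how the forest, the
BSF and PAINS rank the held-out actives — with all three measured on the
identical, commonly-predictable compound set.

A thin command-line wrapper covers the same stages
(`inst/scripts/hitsieve simulate|curate|pains|bsf|evaluate`).

## Package layout

- `R/synthetic.R` — seeded campaign generator with planted chemotypes
- `R/chem.R` — fingerprints, Tanimoto, PAINS catalog and matching
- `R/curation.R` — flag reconciliation, labels, datasets, PubChem ingest
- `R/rfc.R` — forest training, tuning, label randomization
- `R/bsf.R` — pBSF score, histories, LOAO scoring, assay subsampling
- `R/evaluation.R` — LOAO protocol, metrics rows, CV, NN analysis, scaling
- `R/metrics.R`, `R/io.R` — metric primitives; CSV/JSON persistence
- `vignettes/interference-triage.Rmd` — models, assumptions, design choices
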