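# hergdb

Integration and consensus classification of hERG bioactivity data.

Blockade of the hERG potassium channel is closely tied to drug-induced
QT-interval prolongation and arrhythmia, which makes hERG liability one of
the standard counter-screens of drug discovery. Activity data for hERG are
scattered across literature, patent, phenotypic-screening and HTS
collections that disagree in measure types (IC50, EC50, Ki, Kd, percent
inhibition, qualitative comments), units, assay protocols and structure
conventions. `hergdb` is an R package for building an integrated,
consistently labeled hERG dataset from such heterogeneous sources, for
anyone assembling training data for cardiotoxicity models or auditing the
consistency of multi-source SAR collections.

## What it does

* **Harmonize** raw activity records: measure taxonomy (IC50-type vs
  inhibition-type vs qualitative), exact unit conversion to nM
  (pIC50 x becomes 10^(9−x) nM), remaining-activity → percent-inhibition
  conversion, concentration recovery from assay descriptions, source
  validity filters, and activator/inconclusive exclusion — every record
  either harmonized or excluded with a recorded reason.
* **Standardize and merge structures**: desalt → neutralize → canonical
  tautomer (standard-InChI round trip) → canonical SMILES key;
  drug-likeness filter (metals, MW outside [150, 700], fewer than 10 heavy
  atoms, isotopes); records merged per canonical parent.
* **Classify by staged consensus**: a compound is an inhibitor when
  IC50 ≤ 10 μM or inhibition ≥ 50% at 10 μM. Votes are resolved by
  unanimity, then single-pass removal of values ≥ 10-fold from the
  compound's geometric-mean IC50, then a ≥ 2/3 majority; IC50-type
  evidence overrides single-concentration evidence, and HTS-scale sources
  (> 200 compounds of single-concentration data) vote with the stricter
  > 70% / < 30% thresholds. Near-even splits are inconclusive.
* **Characterize** the integrated set: Murcko-framework scaffold counts
  per class, chemical-space coverage against a reference framework
  universe, cumulative per-year growth, per-scaffold IC50 spread, the
  12-descriptor physicochemical profile (MW, AlogP, logD, HBA, HBD,
  N_Cations, N_Anions, MSA, MPSA, N_Rot, pKa_base, pKa_acid), and
  binding-vs-patch-clamp concordance (R², RMSD of per-compound mean
  pIC50).
* **Validate** on synthetic multi-source data with known ground truth,
  generated by the package itself (`generateSynthData()`).

## Worked example

```r
library(hergdb)

# a small synthetic multi-source dataset with known ground truth
g <- generateSynthData(synthSpec(scale = 0.02, seed = 3))
nrow(g$records)
#> [1] 310

out <- runPipeline(g$records)
out$result
#> ClassifiedSet with 177 compounds and 308 records
#>   filter: 177 pass / 0 fail
#>   labels: inactive=129, inconclusive=5, inhibitor=43

out$funnel$n_excluded_records      # records excluded, each with a reason
coverage(79806, 438551)            # chemical-space coverage, percent
#> [1] 18.2
```

`runPipeline()` returns the classified compound set (an S4 `ClassifiedSet`
with accessors `compoundData()`, `recordData()`, `compoundLabels()`), the
harmonized record table, and a funnel report whose stage counts reconcile
exactly. `makeTable1()` tabulates compounds and unique Murcko frameworks
per source and class; `concordance()` and `deviationStats()` produce the
assay-agreement and value-deviation statistics; `summarizeProperties()`
the class-wise descriptor table. A thin command-line wrapper ships in
`inst/scripts/hergdb` (`simulate` and `run` subcommands).

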