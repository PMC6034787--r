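---
title: "Integrating heterogeneous hERG bioactivity data: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating heterogeneous hERG bioactivity data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hergdb)
```

## The problem

Blockade of the hERG potassium channel is a principal cause of drug-induced
QT-interval prolongation, and screening compounds for hERG liability is a
routine step in lead optimization. Public and commercial databases together
hold hundreds of thousands of hERG activity records, but they disagree in
measure types (IC50, EC50, Ki, Kd, percent inhibition at a single
concentration, qualitative comments), units, assay protocols, structure
representations and curation conventions. `hergdb` implements a complete,
reproducible integration pipeline: it harmonizes raw records, merges them
by standardized chemical structure, assigns a consensus inhibitor /
inactive / inconclusive label per compound, and characterizes the
integrated set by scaffold diversity, physicochemical profiles and
assay-protocol agreement.

## Harmonization

Records are first split by *value kind*. Point-potency measures (IC50,
EC50, ED50, Ki, Kd and their log forms such as pIC50) are treated as one
"IC50-type" family and converted exactly to nanomolar; a log-form value
$x$ becomes $10^{9-x}$ nM. Percent-remaining-activity values are converted
to percent inhibition as $100 - x$. Single-concentration measurements keep
their test concentration in micromolar, recovered from the assay
description text ("at 10 uM") when the concentration field is empty.
Measures that cannot be compared across sources -- non-50% threshold
concentrations such as IC70 or IC30, raw currents, QT ratios -- are
excluded with a recorded reason, as are records flagged by source-side
validity comments, records whose outcome comment marks the curve fit
"Inconclusive", and hERG *activator* entries (an activation record carries
no information about inhibition). Every input record ends up either
harmonized or excluded-with-reason; the funnel report reconciles counts
exactly at every stage.

Text-driven steps (measure taxonomy, assay-class assignment, qualitative
"no activity" detection) use editable keyword dictionaries with
case-insensitive substring matching
(`defaultKeywordDictionaries()`). A dictionary is the reproducible
analogue of the manual text curation that produced the original data:
every decision it makes can be inspected and overridden.

## Structure standardization

Records are merged by compound, where compound identity is the canonical
parent structure. The standardization chain is: desalting (keep the
largest organic fragment; ties break deterministically), neutralization of
protonation states where chemically valid (permanent cations such as
quaternary ammonium survive), canonical tautomer selection, and canonical
SMILES serialization. Tautomer canonicalization is implemented as a
standard-InChI round trip: the InChI model pools mobile hydrogens, so 1H-
and 3H-imidazole forms, for example, collapse to a single parent. The
choice of canonicalizer is recorded in the output metadata;
cross-toolkit key equality is not promised, only within-run consistency.
Stereochemistry is preserved: enantiomers remain distinct compounds,
because collapsing them would destroy information while keeping them is
lossless.

The drug-likeness filter removes metal-containing molecules (any element
outside H, B, C, N, O, F, Si, P, S, Cl, Se, Br, I), molecular weights
below 150 or above 700 g/mol (bounds inclusive: exactly 150 passes),
fewer than 10 heavy atoms (10 passes), and isotope-labeled molecules.
"Fewer than 10 atoms" is read as heavy atoms because hydrogen counts
depend on representation; the bound is a config knob
(`min_heavy_atoms`).

## Consensus classification

A compound is a hERG inhibitor when its evidence shows IC50 at or below
10 uM or at least 50% inhibition at 10 uM; an inactive when the evidence
shows the opposite. Because multi-source records frequently contradict
each other, labels are assigned by a staged procedure rather than by
averaging:

1. **IC50 stage.** If the compound has informative IC50-type votes (after
   discarding implausible values below 1 pM or above 1 mM, which are
   typically unit-registration errors), unanimity decides immediately.
   Otherwise one pass of outlier removal drops every exact value at least
   10-fold above or below the compound's geometric mean, votes are
   recomputed, and a two-thirds majority decides; an even split is
   inconclusive. Inhibition-type and qualitative records are ignored
   whenever usable IC50 evidence exists, because an IC50 derives from a
   full concentration series while a percent inhibition reflects a single
   concentration.
2. **Inhibition stage.** Compounds without usable IC50 evidence are voted
   on by their percent-inhibition records (at least 50% at a
   concentration at or below 10 uM is positive; below 50% at a
   concentration at or above 10 uM is negative), together with
   qualitative "no activity" comments counted as negative votes.
3. Compounds with no informative votes stay unclassified; near-even
   splits are inconclusive and are excluded from all class-wise analyses.

Sources that contribute single-concentration data for more than 200
distinct compounds are treated as HTS-scale: their percent-inhibition
votes use the stricter thresholds (strictly above 70% for positive,
strictly below 30% for negative), because single-concentration HTS
readouts are unreliable near the 50% threshold. The rule is applied by
counting, not by source name, so a literature source that crosses the
200-compound mark is treated identically -- the criterion is the amount of
single-concentration data, which is what drives the reliability concern.

Design choices that the procedure statement leaves open, and how this
package resolves them:

* **The 10-fold outlier mean is geometric** (arithmetic mean of
  log-potency). IC50 values span orders of magnitude; with an arithmetic
  mean a single large outlier shields itself (for values 100, 120, 90,
  5000 nM the arithmetic mean is 1327.5, so 5000 < 13275 would survive
  while the three consistent values fall below mean/10 and would be
  removed). The config exposes `outlier_mean = "arithmetic"` for
  sensitivity analysis.
* **The two-thirds majority is inclusive** (fraction >= 2/3, so 2 votes
  of 3 decide). A strict reading would make the common 2-of-3 case
  inconclusive, defeating the purpose of the majority stage. A
  `majority_strict` switch provides the strict variant.
* **Outlier removal is a single pass**, not iterated: iteration can
  cascade on small sets, and the procedure describes one removal step.
* **Qualified values ("<", ">") vote only when decisive** (an upper bound
  at or below threshold is positive; a lower bound at or above it is
  negative) and never enter the outlier mean, since bounds are not point
  estimates.
* **A compound whose only IC50-type records are undecidable bounds falls
  through to the inhibition stage**: such records carry no usable IC50
  information, and compounds "without IC50 information" are classified
  from percent-inhibition data.
* **Qualitative "no activity" comments vote at the inhibition stage
  only**, as negative votes: IC50 priority implies they cannot override a
  measured IC50.

The staged rules are verified in two independent ways: exhaustively
against a brute-force reimplementation over all positive/negative vote
multisets up to size 8 plus randomized potency multisets spanning
outliers and extreme values, and end-to-end by ground-truth recovery on
synthetic data (below).

## Scaffold diversity and chemical-space coverage

Structural diversity is measured by Murcko frameworks: the union of a
molecule's ring systems and the acyclic linker atoms connecting them,
side chains removed. The implementation prunes terminal atoms iteratively
on the bond graph, then restores atoms attached to the remaining core by
a double or triple bond (the common convention for exocyclic carbonyls
and the default; `framework_keep_exocyclic = FALSE` strips them). The
framework keeps elements and bond orders -- it is a framework, not a
carbon-skeleton graph framework -- and is canonically serialized, so the
framework of a framework is itself. Acyclic molecules yield no framework
and are excluded from framework counts but not compound counts. The
implementation is tested against an independent reference scaffold
implementation on a fixture set.

Coverage of chemical space is the percentage of a reference framework
universe (for example, the frameworks of a whole bioactivity database)
hit by the integrated set. Time series use each compound's earliest
record year; compounds lacking a year are excluded from the series and
counted. Per-scaffold potency spread summarizes compounds by their mean
pIC50 (arithmetic mean in log space, back-converted) and reports max/min
fold ranges for scaffolds with more than 10 members.

## Physicochemical profiles

Twelve descriptors are computed per compound: MW, AlogP
(atomic-contribution logP of the neutral form), logD at pH 7.4, HBA, HBD,
N_Cations and N_Anions at pH 7.4, MSA, MPSA (topological polar surface
area), N_Rot (non-ring single bonds between non-terminal heavy atoms,
amides excluded), pKa_base and pKa_acid. The ionization-dependent
descriptors are served by a pluggable rule predictor: a SMARTS table of
ionizable groups with typical aqueous pKa values (aliphatic amines ~10,
amidines/guanidines ~12.5, pyridines ~5.2, anilines ~4.6, carboxylic
acids ~4.2, phenols ~10, sulfonamide N-H ~10, tetrazoles ~4.9, thiols
~8.3), combined with Henderson-Hasselbalch at pH 7.4;
logD = AlogP $- \log_{10}(1 + 10^{\mathrm{p}K_a^{base} - 7.4})
- \log_{10}(1 + 10^{7.4 - \mathrm{p}K_a^{acid}})$ over the terms present.
MSA is an approximate molecular surface: per-atom van der Waals spheres
(implicit hydrogens included) minus the spherical caps buried in bonded
neighbours at ideal covalent distances, an isolated-pair approximation
labeled approximate in the metadata. Exact numerical reproduction of
closed commercial predictors is out of reach by construction; the
contract, enforced by tests, is directional fidelity -- inhibitor-like
chemistry (basic, lipophilic, aromatic-rich) scores higher AlogP, more
cations, lower polar surface than inactive-like chemistry.

Class summaries report the mean and population standard deviation per
descriptor over drug-likeness-passing compounds with definite labels;
compounds lacking a pKa are excluded descriptor-wise.

## Assay-protocol concordance and value deviation

Assay descriptions are classified into *binding* (radioligand
displacement) and *electrostatic* (patch clamp and other current/voltage
measurements) protocols by keyword dictionary; descriptions matching
neither or both are unknown and excluded from the comparison. For
compounds with valid exact IC50 values from both classes, per-compound
mean pIC50s per class give a squared Pearson correlation and a root mean
squared deviation in log units, plus the count of compounds more potent
by electrophysiology. Per-compound deviation statistics (max/min fold and
75th/25th percentile fold, linear interpolation between closest ranks)
are computed for compounds with more than three valid values -- read
strictly, so at least four -- with extreme values pre-dropped; the
percentile method is fixed and documented because the fold bins depend on
it.

## The synthetic data generator

Because the real source databases are licensed or offline, validation
runs on synthetic data with known ground truth. The generator emulates
the statistical structure of the real landscape:

* two literature-like sources (1,500 and 1,200 compounds by default) with
  a 1:1 inhibitor:inactive balance and 1-5 records per compound, mixed
  measures (IC50/Ki/Kd/pIC50 in nM, uM, mM or log units), occasional
  percent-inhibition and remaining-activity records at 10 uM, censored
  bounds, and qualitative "no activity" comments;
* a phenotype-annotated source (500 compounds, about 1:6) with one EC50
  record per compound, Inhibitor/Inactive phenotypes, extra Activator
  compounds, and a fraction of "Inconclusive" outcome flags;
* an HTS-like source (6,500 compounds, 1:64) with exactly one
  percent-inhibition record per compound at 10 uM.

True potencies are log-normal around class medians of 1 uM (inhibitors)
and 50 uM (inactives) with 0.5 log units of spread -- chosen to straddle
the 10 uM threshold with a controllable borderline mass -- truncated to
the 1 pM - 1 mM plausibility window (the extreme-value filter exists for
curation errors, not biology). Records measure the true potency under
multiplicative log-normal noise (0.3 log units by default); percent
inhibition follows a Hill response with coefficient 1, the simplest
monotone link consistent with sigmoid curve fitting,
$\mathrm{pct} = 100\,C/(C + \mathrm{IC50})$. Structures come from a
deterministic library of ring-system cores crossed with substituent
pairs; inhibitor-flavoured parents carry basic, lipophilic substituents
(the classic hERG pharmacophore of a protonatable amine with aromatic
bulk) and inactive parents carry polar or acidic ones, so the
physicochemical class differences have known sign. Salt forms, exact
cross-source duplicate structures and 100-fold outlier values are
injected at configurable rates. Outliers are injected only into compounds
with at least three exact unqualified IC50 records and capped at one
third of them, so that single-pass removal around the geometric mean can
always separate them (with at most $m \le k/3$ outliers among $k$
values, an outlier sits at least $2 - 2m/k \ge 4/3$ log units from the
mean while inliers sit at most $2m/k \le 2/3$ away).

Ground truth labels every parent from its realized true potency against
the 10 uM threshold, and flags two kinds of structurally unrecoverable
parents: *borderline* (within 2-fold of the threshold) and
*percent-only-ambiguous* (parents whose only usable evidence is
single-concentration data and whose noise-free 10 uM response falls in
the strict 70%/30% no-vote band -- the deliberate price of removing
low-confidence near-threshold HTS readouts, mirrored in the real
integration by the drop of near-50% entries). The recovery properties are
asserted over the remaining parents: with noise and outliers switched
off the pipeline recovers 100% of their labels, and with 100-fold
outliers injected as a per-compound minority it still recovers 100%.

What the generator does *not* emulate: realistic SAR landscapes,
medicinal-chemistry series correlation between structure and potency, the
real databases' scaffold distributions, free-text assay descriptions
beyond the dictionary vocabulary, and curation pathologies other than
unit-scale outliers. A pass on synthetic data therefore demonstrates the
pipeline's rule logic and bookkeeping, not its robustness to every
real-world curation artifact.

## Numerical choices and degenerate inputs

* All potencies are stored in nM and concentrations in uM; unit
  conversion happens exactly once, at harmonization.
* Percent values outside [0, 100] are retained as measured (HTS data
  contains them; clipping would distort vote boundaries) and logged.
* The extreme-value window and the drug-likeness bounds are inclusive at
  their endpoints; the HTS vote thresholds are strict, the standard ones
  inclusive, each following its defining phrase.
* Outlier removal with fewer than two values is a pass-through; removal
  at exactly 10-fold from the mean triggers (inclusive), with the caveat
  that a two-value set exactly 100-fold apart is a floating-point
  knife-edge -- both values sit exactly at the boundary -- which the
  generator's eligibility rule avoids creating.
* Classification is invariant to record order, and the empty record set
  classifies to unclassified.
* Desalting ties (equal heavy-atom counts) break by string length then
  lexicographically; purely inorganic entries keep their largest
  fragment.

## Problem sizes

The shipped validation uses the default study conditions: about 9,700
ground-truth parents and 15,000 records per synthetic run for the
end-to-end recovery checks, the full vote-multiset enumeration to size 8
plus 500 randomized multisets for oracle equivalence, and fixture-scale
inputs (3-5 compounds) for the closed-form statistics oracles. These
sizes keep a complete validation run in minutes on one CPU while leaving
every rule branch exercised.

## Worked example

```{r example, eval = FALSE}
library(hergdb)

spec <- synthSpec(scale = 0.1, seed = 42)
g <- generateSynthData(spec)
out <- runPipeline(g$records)

out$funnel$labels
makeTable1(out$result)
countFrameworks(out$result, "inhibitor")$n_frameworks
concordance(out$result)$r_squared
```

## Known limitations

* Tautomer pooling is the InChI mobile-H model; tautomers that InChI does
  not regard as mobile (e.g. keto/enol pairs) remain distinct compounds.
* The pKa/logD rule table is coarse by design; descriptor *values* are
  comparison references, only their class-wise directions are contracts.
* The MSA approximation ignores multi-body sphere overlaps and ring
  geometry.
* Assay-class assignment sees only the description text; records whose
  descriptions match neither dictionary are excluded from the
  binding-vs-electrostatic comparison rather than guessed.
* Column mappings for real database exports are configuration, not code:
  the reader accepts a mapping table, and adapters for specific dumps are
  left to the user.
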