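---
title: "Methods and design of crosslinkR"
author: "crosslinkR authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of crosslinkR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crosslinkR)
```

# Scope

crosslinkR implements the computational stages of an in-cell
photo-crosslinking mass spectrometry (XL-MS) study of a large protein
assembly: quantitative AP-MS enrichment analysis, hierarchical
target-decoy FDR control for crosslink identifications, mapping of
crosslink-derived distance restraints onto structural ensembles, and
crosslink-based validation of predicted complex models. Spectrum-level
search and quantification engines are out of scope; the package starts
from their exports (candidate residue-pair tables, LFQ matrices,
per-model confidence scores) and from structures in PDB/mmCIF.

# The crosslinker model

SDA (succinimidyl 4,4'-azipentanoate) is a heterobifunctional
photo-crosslinker: an NHS-ester end acylates lysines, serines,
threonines, tyrosines and protein N-termini, while the UV-activated
diazirine end inserts promiscuously (A, C, D, E, G, H, I, K, L, P, S,
T, V, Y and protein termini). Its short spacer constrains the
Calpha-Calpha distance of bridged residues to roughly 27 Angstrom.

Two conventions follow from this and are used throughout:

* **Satisfaction is inclusive**: a restraint is satisfied when the
  minimal Calpha-Calpha distance is less than or equal to the threshold
  (default 27 A). The strict-versus-inclusive choice only matters for
  distances exactly at the boundary; the threshold is configurable
  (`xlConfig(sda_max_ca_distance = )`).
* **Banded coloring** for visual triage splits distances at 21.5 and
  28.5 A (short / mid / long); the middle band includes both edges.

# Restraint mapping

Crosslink tables address residues by 1-based positions in the canonical
full-length sequence; structures use arbitrary author numbering and may
contain several copies of a protein. `buildChainMaps()` aligns each
chain's observed one-letter sequence to the canonical sequence
(Needleman-Wunsch, chain-global/canonical-local, BLOSUM62) and derives
a canonical-position-to-author-number map. Maps with aligned-position
identity below 0.95 are rejected: empirically, unrelated sequences
align far below this, while engineered constructs and point variants
stay above it.

`measureCrosslink()` evaluates every chain-copy combination that
resolves both endpoints and reports the **minimum** distance: a
crosslink evidences proximity somewhere in the particle, so in
multi-copy assemblies (e.g. doubly-capped particles) the most favorable
placement is the conservative interpretation for restraint violation
calls. Per-copy distances are retained for ambiguity reporting.
Self-links on multi-copy proteins are minimized over intra-chain and
inter-copy placements alike.

`ensembleSatisfaction()` applies this over a set of structural states
and reports, per crosslink, whether any state satisfies it; the summary
is the fraction of mappable crosslinks satisfied in at least one state.
Restraints that cannot be mapped (endpoint in an unresolved region, no
qualifying chain) are excluded from the denominator rather than counted
as violations.

Clusters of violated crosslinks between one protein pair suggest an
unmodeled conformational state. The operational rule in
`detectViolationClusters()` — same unordered protein pair, both
endpoint positions within a 10-residue window, connected components of
size at least 3 — is our concretization of a qualitative idea; all
three knobs are configurable and the defaults were chosen to group
contiguous interface patches without bridging distant epitopes.

# Hierarchical target-decoy FDR

Candidate matches are first prefiltered on fragment evidence (more than
two fragments carrying non-cleaved crosslinker, and at least five
matched fragments per peptide), then collapsed to unique residue pairs
(best score, provenance unioned).

FDR is estimated from reversed-sequence decoy counts as
max(0, TD − DD)/TT, where TD and DD are target-decoy and decoy-decoy
matches above the score threshold; the DD subtraction corrects the
double counting of random matches inherent in TD counts. The
residue-pair threshold is the most permissive one whose estimate stays
at or below the target (default 2%); survivors are aggregated to
protein-pair (PPI) edges — summed member scores by default; max and
top-n alternatives are provided — and a second threshold enforces the
PPI-level target (default 5%). "Boosting for PPIs" grid-searches the
residue-pair cutoff to maximize accepted target PPIs subject to both
constraints; we restrict the search to one dimension (the residue-pair
score), coarsening grids beyond 64 candidate thresholds while always
retaining the unboosted threshold, so the boosted solution can never be
worse. Self-links are excluded from edges but kept in residue-pair
output. Merged datasets are unioned by canonical residue pair and the
combined PPI FDR is re-estimated from pooled decoy edge counts rather
than averaged.

Two calibration properties deserve note, both visible in the test
suite's Monte-Carlo experiments:

* Selecting the *largest* acceptable set induces a winner's-curse bias:
  conditional on the noisy estimate dipping below the target, the true
  FDR tends to sit slightly above it. At the set sizes typical of real
  crosslink datasets (thousands of residue pairs, as simulated by the
  generator defaults) the residual bias is a few hundredths of a
  percentage point; at very small set sizes (hundreds) it can reach
  nearly a percentage point. This is a property of threshold-selection
  target-decoy control itself, not of the estimator.
* The clamp at zero makes the estimator conservative when decoy counts
  fluctuate high.

The AP-MS-based network filter removes crosslink PPI edges whose
non-core partners were not independently enriched in the matching
crosslinked pulldown; edges between canonical core subunits are exempt,
since false matches concentrate among candidate interactors rather than
within the well-characterized core.

# Quantitative enrichment analysis

The AP-MS stage follows the standard label-free workflow: proteins
quantified in at least 80% of replicates of some group are retained;
intensities are log2-transformed and median-centered per sample
(default) or glog-transformed (a variance-stabilizing alternative:
per-sample moment-matched scaling, offset from the pooled lower decile,
`normalizeQuant(method = "glog")`) — the exact VSN fit of upstream
tools is not reproduced, which we document as a deviation; missing
values are imputed by the mixed rule; Welch's t-test with
Benjamini-Hochberg correction yields calls at |log2FC| >= 2 and
adjusted p < 0.05 (strict).

The mixed imputation rule classifies a missing cell as MAR when the
protein has at least one observed replicate in that cell's group
(imputed by the group mean), and as MNAR otherwise (drawn from
Normal(m − 1.8 s, (0.3 s)^2), with m and s the mean and SD of the
cell's *sample*). Per-sample rather than global down-shift statistics
follow the down-shifted-Gaussian convention; draws are consumed in a
fixed protein-major order so a seed fully determines the imputed
matrix regardless of input ordering.

## Small-sample behavior of the Welch test

Two properties of Welch's t at triplicate scale matter for interpreting
the calibration experiments:

* The test is *conservative* at n = 3 per group: the true type-I rate
  at nominal 0.05 is near 0.03 because the Welch-Satterthwaite
  reference distribution is an approximation that degrades at tiny
  degrees of freedom. The type-I calibration experiment therefore uses
  10 replicates per group, where the approximation is accurate (true
  size ~0.048); at n = 3 the same experiment would flag the test's own
  conservatism rather than an implementation fault.
* Power at n = 3 is bounded by variance-estimation noise: even a
  7-sigma planted effect (log2 effect 3 with replicate SD 0.5) yields
  p-values in the 1e-3 range, not the 1e-13 a z-test would give.
  Against a Benjamini-Hochberg threshold over 2000 proteins this caps
  recall well below 1 for any realistic planted fraction, and
  one-sided planting additionally shifts sample medians so that global
  normalization erodes fold changes. The recovery experiment plants
  300 of 2000 proteins (a realistic specific-interactor share for an
  efficient pulldown) and reports recall and empirical FDR as
  measured; empirical FDR control is tight, while recall reflects this
  fundamental power limit of triplicate designs.

# Predicted-model confidence and crosslink validation

Per-model confidence is 0.8 ipTM + 0.2 pTM; a prediction is high
confidence when the mean over its models (typically five) strictly
exceeds 0.65. There is no best-model shortcut: the mean over all
supplied models is used. Crosslink validation delegates to the
restraint-mapping stage on the predicted coordinates; crosslinks with
an unresolved endpoint (e.g. trimmed disordered regions) are excluded
from the satisfaction denominator and reported separately, since the
headline satisfied/mappable ratio should not penalize residues the
model does not contain. Interfaces are ranked by (high-confidence flag,
mean confidence, crosslink satisfaction fraction), ties broken by pair
id for determinism.

# The synthetic-data generators

Every stage is testable at desk scale against known ground truth:

* `generateToyComplex()` builds multi-chain Calpha traces as 3D
  self-avoiding random walks with exact 3.8 A consecutive spacing
  (minimum non-consecutive separation 3.5 A), chains seeded 8 A from an
  existing residue so every chain shares an interface (minimal
  inter-chain distance <= 10 A), plus random sequences.
* `simulateCrosslinks()` draws true links uniformly from
  chemistry-eligible residue pairs within the threshold and false links
  from eligible pairs strictly beyond threshold + 5 A (the buffer
  removes boundary ambiguity from truth labels). Scores follow a
  right-skewed Gumbel null (location 4, scale 1) for false links and
  decoys and a shifted Gaussian N(9, 1.5^2) for true links — chosen
  only to produce realistic overlap, not fitted to data. Decoy records
  relabel accessions with the decoy prefix.
* `simulateCandidateScores()` builds candidate sets for FDR
  calibration: defaults of 3000 true and 300 false targets mirror the
  set sizes of real crosslink datasets, with TD:DD populated at the
  2:1 reversed-decoy expectation and decoy counts matched so that
  E[TD − DD] equals the planted false-target count — the identity that
  makes the estimator unbiased at a fixed threshold.
* `simulateQuantMatrix()` draws per-protein log2 baselines from
  Normal(25, 2) with replicate noise, plants one-sided effects in the
  test group, applies MNAR missingness to the lowest-intensity
  quantile of cells and MAR missingness uniformly at random.

What the generators do **not** emulate: peptide-level effects
(shared peptides, missed cleavages, modification localization),
intensity-dependent MS detectability, correlated replicate noise,
structure coordinate error, or decoy score distributions that deviate
from the target null. Passing calibration on synthetic data therefore
demonstrates correctness of the implemented procedures under their own
model assumptions, not robustness to every pathology of real data.

All generators are bit-reproducible from a seed, and all randomness in
the pipeline flows from the configured seed.

# Numerical choices and degenerate inputs

* Distances are exact Euclidean norms; equality tests against the
  exhaustive oracle allow 1e-12 relative tolerance for
  summation-order effects.
* Zero intensities on the raw scale are missing (LFQ convention);
  non-positive values entering a log transform are recoded missing
  with a message.
* A protein with zero variance in both groups gets t = 0, p = 1 when
  means agree and infinite t with p = 0 otherwise.
* FDR with no targets above threshold is undefined (NA), not zero.
* An empty enriched set in the network filter retains only core-core
  edges, with a warning.
* Alternate locations resolve to highest occupancy, then file order;
  only the first model block of a multi-model file is read.
* Interface ranking and pseudobond output have deterministic order; a
  rerun with identical inputs and seed is byte-identical.

# Problem sizes in the test suite

The packaged experiments are sized to run on one CPU in minutes: 100
toy complexes (2-4 chains x 40 residues) for the distance oracle, a
100-link two-conformer ensemble experiment, 200 Monte-Carlo seeds of
paper-scale candidate sets for FDR calibration, one 2000-protein
recovery and one null matrix for the enrichment stage, and 1e5 draws
for the imputation moment check.

# Known limitations

* Solvent-accessible surface distances are not computed; restraints are
  Euclidean Calpha-Calpha only.
* The glog option approximates variance stabilization by moment
  matching; it is not the maximum-likelihood VSN fit.
* Ambiguous residue localizations are treated as single positions; an
  ambiguity expansion is not yet implemented.
* PPI boosting searches one dimension (the residue-pair score cutoff),
  not the multi-dimensional filter space of dedicated FDR tools.
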