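---
title: "Planar pi-pi contacts: detection, survey statistics and the PScore"
author: "PiPiContacts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Planar pi-pi contacts: detection, survey statistics and the PScore}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

## What counts as a planar pi-pi contact

Delocalized pi systems in proteins live on sp²-hybridized atom groups: the
aromatic rings of Trp, Phe, Tyr and His, the guanidinium of Arg, the amides
of Gln and Asn, the carboxyls of Glu, Asp and the C terminus, and — by far
the most numerous — the backbone peptide bond spanning residues *i* and
*i*+1. Two such groups are counted as a face-to-face planar contact when
three conditions hold simultaneously, all thresholds inclusive:

1. **van der Waals contact**: at least `minAtomPairs = 2` distinct pairs of
   heavy atoms (C, N, O), one atom from each group, within
   `vdwCutoff = 4.9` Å. The generous cutoff avoids imposing an energetic
   interpretation on atom positions whose reliability varies with data
   resolution; requiring two pairs suppresses glancing single-atom
   approaches.
2. **elevated-surface proximity**: for every atom of a group, points are
   constructed `elevation = 1.7` Å (a carbon VDW radius) above and below
   the group plane along its unit normal; the minimum distance between any
   elevated point of one group and any of the other, over both normal
   signs, must be at most `surfaceCutoff = 1.5` Å. This is what restricts
   contacts to geometries that bring the pi clouds, not just the atoms,
   into proximity.
3. **plane alignment**: the absolute dot product of the two unit plane
   normals must be at least `minAbsDot = 0.8`, i.e. an inter-plane angle of
   about 37° or less.

These live in a `ContactCriteria` object so every threshold can be varied.
The elevated-surface construction is applied per atom and over both normal
signs, which makes it symmetric in the two groups and free of any sign
convention for the normals; the normals themselves come from the cross
product of three atoms bracketing the central sp² atom, so their sign is
arbitrary but deterministic.

Group membership is a plain-text table
(`system.file("extdata", "sp2_definitions.tsv")`) so alternative atom
memberships are directly testable. Choices worth noting: the Trp ring
system is treated as one nine-atom plane rather than two fused rings; the
Tyr hydroxyl oxygen is excluded (it is not part of the pi system); the
peptide unit includes both flanking CA atoms (CA(i), C(i), O(i), N(i+1),
CA(i+1)), giving it a carbon count of 3; Arg contributes only the
guanidinium (NE, CZ, NH1, NH2). Incomplete groups — any expected heavy atom
missing — are never instantiated; they are counted and reported. Peptide
units require C(i)–N(i+1) ≤ 1.8 Å, which tolerates refinement noise but
refuses chain breaks. Pairs that share an atom (adjacent peptide units
share a CA) or are directly bonded (a C-terminal carboxyl against its
preceding peptide unit) are never contact candidates; a sidechain may
stack on its own flanking peptide unit.

## Structure handling

Structures are parsed through bio3d (PDB and mmCIF). Normalization keeps
the *first-encountered* altloc variant of each atom (not the highest
occupancy — deterministic in file order), maps MSE to MET, drops other
non-standard residues with a message, flags waters and hydrogens, and
assigns a contiguous per-chain residue index (insertion codes are distinct
residues in file order) used for all sequence-separation arithmetic.
Crystal symmetry operators are taken from REMARK 290 (orthogonal frame) or
from mmCIF operator strings (fractional, converted through the cell
orthogonalization matrix); symmetry expansion enumerates every operator
combined with lattice translations of ±1 cell along each axis and keeps
copies with any atom within the query radius (8 Å by default). Contacts to
symmetry copies are measured but flagged `symmetry` and excluded from
frequency statistics by default, since symmetry contact sets contain a
small population of extreme clashes (reported as atom pairs under 1 Å).

Detection uses a centroid-distance prefilter (candidate pairs must have
centroids within the cutoff plus both bounding radii — a strict superset of
pairs with any atom pair in range), so results are identical to exhaustive
search; the test suite asserts this equivalence against a brute-force
all-pairs oracle on a thousand random group fields.

## Survey statistics

*Involvement* is the fraction of residues contributing any atom to at least
one planar contact; a backbone contact involves both flanking residues.
Rates per 100 residues count group participations (two per contact) and
partition by aromaticity class; a per-contact variant exists for
sensitivity. Resolution binning sorts PDB entries by exact resolution and
rolls bins under 100 entries into the next bin within 0.25 Å (a bin that
cannot reach 100 within the window is kept); trend lines are least squares
on bin means weighted by bin size. Standard errors come from a block
bootstrap that resamples whole PDB entries with replacement (default
10,000 iterations, seeded). The solvation profile conditions involvement
on the number of water oxygens within the VDW cutoff of each residue,
restricted to structures averaging more than one water per residue. The
secondary-structure profile places each residue on a signed axis — negative
inside H/G/E (distance to the nearest loop/turn), positive in loops
(distance to the nearest H/G/E), pooled beyond ±7 — using DSSP one-letter
assignments read from DSSP output files (assignments are consumed, never
recomputed). Interface breakdowns classify residues by whether any
sidechain atom is within the VDW cutoff of another chain (same asymmetric
unit) or of a symmetry copy, and split each sidechain type's contact
frequency into local (≤4), non-local intrachain, and interchain parts.

## Stage 1: contact frequencies from sequence

The predictor rests on an empirical table keyed by (group sequence
identity, partner residue type, separation class, contacted category).
Identities are the nine sp² sidechain letters plus the 400 ordered
backbone dipeptides; separation is short (≤4) versus long (>4);
contacted category is the partner's sidechain versus backbone. One
canonical *opportunity* enumeration backs everything: unordered pairs of
groups with anchor offsets 1–40 (the ±40-residue context window), adjacent
backbone units excluded. Each observed contact is counted once in each
direction, and each opportunity contributes one directed opportunity per
direction, making every cell a proper conditional rate. Restricting
opportunities to the context window keeps the table and the context
averages on a single scale.

Raw cell rates at survey scale are tiny (order 10⁻³–10⁻⁴ per opportunity),
so smoothing must never inject pseudocounts comparable to the rates.
`tableFrequencies()` therefore uses a hierarchical Gamma-Poisson scheme
within each (separation, category) slice: a guarded global rate, a
partner-type effect pooled over all identities, an anchor-residue pool for
the 400 dipeptide identities, an identity residual, and finally the cell
itself, each level shrunk toward its parent with a prior worth
`priorContacts = 10` pseudo-contacts *at the parent rate*. Denominating
the prior in contacts makes the scheme self-scaling: a cell is trusted
once it has seen enough contacts for its rate to be measurable, and at
full-survey data volumes the shrinkage weights approach one and the table
reproduces the empirical rates.

The *raw context expectation* of a group is the mean table rate over its
opportunities, split into four channels ({short, long} × {sidechain,
backbone partner}). Raw expectations are then *calibrated*: within groups
of the same sequence identity (pooled per category when an identity has
fewer than `minPerIdentity = 2000` training groups — percentile maps fit
on small samples at these event rates memorize noise), the raw value is
mapped to its percentile among training raw values (20 equal-population
bins) and replaced by the mean observed rate in that bin, monotonized by
isotonic regression. Relative channels subtract the identity's mean
observed rate (identities need ≥ 50 training groups for their own mean).
Calibration outcomes are taken from training chains *disjoint* from the
chains that built the table (`trainContactPredictor()` uses a 2/3 table /
1/3 calibration split of the training chains): reusing the table's own
chains correlates the outcomes with the table's sampling noise and
produces reliability slopes near 1 on the training side but far below 1 on
held-out data. With the honest split, held-out percentile-binned predicted
versus realized rates for the per-group total contact rate (each channel
weighted by its share of opportunities) have slope statistically
indistinguishable from one; the acceptance suite asserts slope ∈ [0.8, 1.2].

The full profile is one 8-vector per sp² group: four calibrated absolute
rates plus four relative differences.

## Stage 2: the PScore

Each profile channel becomes a per-residue track: sidechain groups attach
their value to their own residue, backbone units to both flanking
residues, overlapping attachments averaged; an optional per-component flag
multiplies group values by the group's carbon count (Phe 6, Trp 8, peptide
unit 3, ...) before attachment. A model has one component per channel with
a signed weight, a window length (10–140 residues), and an aggregation
mode: the maximum contiguous-window mean, or the mean over the union of
the top-60 residues expanded by ±5 positions. The raw score is the
weighted sum of the aggregates; the PScore is its z-score against the
background reference set (PScore = (raw − background mean)/background SD).
Scoring refuses sequences under 140 residues explicitly — never a silent
zero — because shorter sequences were outside the score's design range.

Training is seeded hill climbing: proposals perturb one component's weight
(Gaussian, SD 0.3), move its window within a fixed ladder, toggle its
mode, or toggle its carbon flag; a proposal is accepted only if it
strictly improves the objective, the background-normalized z difference
between the lowest-scoring training positive and the mean of the
top-scoring 1% of the background. Background moments are recomputed at
every evaluation, so the objective is always in current z units; the
accepted-step trace is non-decreasing by construction. Training stops
after `plateau = 2000` consecutive rejected proposals (hard cap 20,000).
Weights start at zero except a unit weight on the long-range backbone
absolute channel — the unoptimized predictor — which is also the channel
retrospective analysis singles out as carrying most of the discriminative
power. With a fixed seed, training is bit-reproducible.

## Evaluation

ROC curves are empirical step functions; the AUC is computed directly via
the rank formulation, which handles ties with the Mann-Whitney ½
convention (the suite asserts exact equality with the normalized
Mann-Whitney U). AUC errors use a plain bootstrap over both score sets.
Sequence-similarity controls use 400-cell dipeptide-profile L1 distances
(minimum over a reference set) and Shannon entropy of the amino-acid
profile in bits.

# Synthetic study conditions

All tests and the acceptance script run on seeded generators; nothing is
downloaded.

* **Geometry fixtures** place ideal groups (hexagonal rings with C–C
  1.39 Å, planar amide with C–N 1.33 Å, guanidinium with C–N 1.33 Å) at
  exact gap/offset/tilt; random fields scatter them uniformly in a box
  with uniform random orientations.
* **The contact-annotation corpus** draws contact events over the
  canonical opportunity enumeration with a stated probability: per-pair
  rate = base(separation) × category factors × partner-type multipliers ×
  (1 + γ·mean context flexibility) for long range, with γ = 2, aromatic
  partners ×1.8, the sp² amide/carboxyl/guanidinium sidechains ×1.3, and
  the backbone-exposing residues Gly/Ser/Thr/Pro ×1.5. Base rates
  (0.002 short, 0.0002 long per opportunity) put realized involvement
  near one residue in five and backbone unit rates at a few percent — the
  regime reported for folded high-resolution structures — and were fixed
  from those survey anchors, not tuned on test outcomes. Chain sequences
  are drawn from UniProt-average composition. The shared test corpus uses
  400 chains of 150–300 residues, sized so the held-out reliability slope
  estimator has adequate power at these event rates.
* **The residue-level statistics corpus** simulates involvement directly
  from stated coefficients (a constant base, a per-water slope, an
  order/disorder sigmoid running from 9.5% deep in secondary structure to
  16% deep in loops, interface intra→inter exchange, a resolution trend)
  and pairs involved residues into contact records, so each survey
  statistic can be checked against its generating parameter.
* **Sequence sets** build positives from Pro-Gly, Phe-Gly, Ser-Arg,
  Tyr-Gly and Arg-Gly dipeptide repeats with 10% composition noise, and
  background sequences from the folded-composition model, all ≥140
  residues.

What passing these tests shows: the geometry criterion is implemented
exactly (oracle equivalence, boundary behavior, rigid-motion invariance);
the statistics recover stated generating parameters; the predictor's
calibration is honest on held-out data drawn from the same process; and
the score separates sequences whose generative contact propensity is
elevated. What it does not show: performance on real PDB structures or
real phase-separation benchmarks, which depend on downloading a current
non-redundant structure set and on literature-curated sequence sets; the
generators emulate rate structure, not real packing geometry, homology
structure, crystallographic error, or the full covariance of amino-acid
composition in natural proteins.

# Numerical choices and degenerate inputs

* Plane normals require a cross-product norm ≥ 10⁻⁶ (collinear triples are
  degenerate; the group is skipped).
* All criterion thresholds are inclusive; boundary behavior is tested with
  exactly representable geometry.
* The surface distance is only evaluated once the cheaper VDW-pair and
  alignment criteria pass; the decision is unchanged.
* Contacts are stored once, with the two groups ordered by (chain, residue
  index, category).
* Frequency denominators guard empty cells; an all-zero-contact table
  yields strictly positive rates bounded by the guarded global floor.
* Equal-population calibration bins deduplicate quantile breaks under
  ties and fall back to fewer bins when an identity has few groups;
  models and calibrations serialize to text at 17 significant digits so
  round trips are bit-exact.
* Resampling (bootstraps, splits, training) runs inside a private seeded
  RNG stream that restores the caller's stream.
* A stats corpus chain with an odd number of involved residues drops one
  involvement (at most one residue per chain) when pairing contacts.

# Problem sizes

The default test run uses the 400-chain shared corpus, 1000 random
geometry fields of 6–24 groups (plus three 200-group fields), 100 rigid
motions, PScore training with an 11-positive / 150-background set at
plateau 2000, and bootstrap sizes of 200–10,000 depending on the
statistic. `scripts/acceptance.R` regenerates everything from its `--seed`
and reports involvement, per-100 rates, the solvation slope, the
secondary-structure endpoints, the resolution trend, the held-out
calibration slope, the training objective, the held-out AUC and the
threshold captures.

# Known limitations

* The exact published predictor weights and table are not reproduced; the
  training *procedure* is, and models carry their provenance (seed,
  trace, background moments).
* Ligand and nucleic-acid pi systems, NMR ensembles beyond the first
  model, hydrogen-bond coupling, and energy estimates are out of scope.
* Face-to-edge and parallel-displaced aromatic geometries are not
  classified; the criterion is face-to-face by construction.
* DSSP assignments are consumed, not computed; supply DSSP output files.
* The contiguous internal residue index treats gaps in author numbering
  as adjacent positions (the convention used for separation arithmetic);
  author numbering is preserved alongside.
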