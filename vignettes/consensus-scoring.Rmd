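---
title: "Consensus contact scoring and selection of docking models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus contact scoring and selection of docking models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consrankr)
```

## The scoring problem

Protein–protein docking produces large ensembles of candidate complex
structures ("decoys"), of which only a few — sometimes none — resemble the
real complex. Scoring is the task of ranking such an ensemble so that
correct models surface at the top. `consrankr` implements a *pure consensus*
approach: no physical energies are evaluated; a model is good insofar as its
inter-residue contacts are frequent in the ensemble it belongs to. The
rationale is statistical: when many independent docking protocols converge
on the same interface, that interface is likely right, and enrichment of
even a modest fraction of near-correct poses concentrates contact frequency
on the true interface.

## The model

Two residues on different chains are **in contact** when any pair of their
heavy atoms lies closer than 5 Å (strict inequality; hydrogens and
heteroatoms are ignored throughout). For an ensemble of $n$ models, the
**conservation rate** $CR_{kl}$ of the contact between residues $k$ and $l$
is the fraction of models containing it. Each model $i$ with contact set of
size $M_i$ receives the raw score

$$S_i = \sum^{M_i} CR_{kl},$$

the sum of the conservation rates of its own contacts, and the normalized
score

$$\bar S_i = S_i / M_i,$$

its *mean* contact conservation. Models are ranked by $\bar S_i$,
descending. The normalized score of the top model, the **Maxscore**, is a
proxy for how sharp the ensemble consensus is, and it drives the selection
strategy below.

Ties in $\bar S_i$ are broken by $M_i$ descending (a richer interface is
preferred), then by model identifier; the ranking is therefore total and
independent of input order. Contacts scored against a fixed ensemble but
absent from its rates table contribute 0 to $S_i$ while still counting in
$M_i$.

### Contact-fingerprint clustering

Because a pure consensus ranking is intentionally redundant (top models all
share the consensus interface), a complementary clustering step diversifies
selections when the consensus is weak. The distance between two models is
the **Hamming distance** between their contact sets — the number of
contacts present in exactly one of the two — arranged in a condensed
$n(n-1)/2$ vector. Agglomeration is **complete linkage** (farthest point:
the distance between clusters is the maximum member-pair distance), and
flat clusters are extracted with the **maxclust** criterion: the smallest
cut height producing at most $t$ clusters, with $t = \lfloor n/10 \rfloor$
(minimum 1) so the granularity does not depend on ensemble size. Clusters
are numbered 0, 1, 2, … by decreasing population. Within each of the most
populated clusters, the consensus ranking is recomputed *locally* (the
cluster's own size is the consensus $n$), which lets minority binding modes
produce their own top models.

Determinism required two tie rules the clustering literature leaves open:
equal-height merge candidates are resolved by the smallest member label,
and equal-population clusters by the smallest contained model identifier.
Both rules are label-based rather than index-based, so the full clustering
— tree, cut, and numbering — is invariant under permutation of the input.

### Interface analysis and final selection

The final ranking of the models chosen for submission is based not on the
consensus score but on the *extent* of the interface, computed for a
candidate pool only (defaults: the top 30 consensus-ranked models plus the
top 2 models of each of the 15 most populated clusters, deduplicated — of
the order of 50–60 models):

* `n_contacts` — the model's inter-residue contact count at 5 Å;
* `interface_area` — solvent-accessible surface buried on complex
  formation, $(A_1 + A_2 - A_{12})/2$, from Shrake–Rupley areas of each
  partner alone and of the complex; the mean-of-partners convention is the
  default, with the summed convention available by flag;
* `n_clashes` — inter-chain heavy-atom pairs closer than 3 Å.

Models with more than 25 clashes are excluded outright. The survivors are
ordered by contact count, then interface area, then normalized score, all
descending. Contact count precedes area deliberately: it is cutoff-exact,
whereas the area carries quadrature noise.

The *composition* of the submission depends on the consensus sharpness:

* **strong consensus** (Maxscore ≥ 0.1): all 10 submitted models come from
  the global consensus ranking, reordered by interface extent;
* **weak consensus** (Maxscore < 0.1): the top consensus model takes
  position 1 and the remaining 9 positions are filled from distinct
  clusters in population order — one model per cluster before any second
  pick — then ordered by interface extent.

The 0.1 threshold encodes the empirical observation that ensembles whose
top model exceeds a mean contact conservation of about 10% essentially
always carry a correct consensus; the boundary value is assigned to the
strong regime. Only the two regimes are implemented; no intermediate blends
are invented.

### Quality assessment

For validation against a known reference structure the package provides the
standard CAPRI metrics: `fnat` (fraction of reference contacts reproduced,
5 Å atom-pair definition), `L_rms` (backbone RMSD of the ligand — the
smaller partner — after least-squares superposition of the receptor) and
`I_rms` (backbone RMSD over reference interface residues, defined at 10 Å,
after their own superposition). Backbone means N, CA, C, O. The tier table
(editable via `capri_thresholds()`) follows the standard criteria: *high*
requires fnat ≥ 0.5 and L-rms ≤ 1 Å or I-rms ≤ 1 Å; *medium* fnat ≥ 0.3
with L-rms ≤ 5 or I-rms ≤ 2; *acceptable* fnat ≥ 0.1 with L-rms ≤ 10 or
I-rms ≤ 4; anything else is *incorrect*. Tiers are evaluated best-first,
which makes the classification monotone in each metric. Clash-penalty
sub-rules of the full CAPRI protocol are not implemented. For homodimers
the chain assignment of a decoy is arbitrary, so both assignments are
evaluated and the better (lower L-rms) one is used.

## Tunable parameters

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| `contact_cutoff` | 5.0 | Å | heavy-atom contact definition |
| `clash_cutoff` | 3.0 | Å | heavy-atom clash definition |
| `clash_max` | 25 | pairs | exclusion threshold |
| `maxscore_threshold` | 0.1 | – | strong/weak regime boundary |
| `top_consrank_pool` | 30 | models | consensus route of the pool |
| `top_clusters` | 15 | clusters | cluster route of the pool |
| `per_cluster` | 2 | models | picks per cluster |
| `n_submit` | 10 | models | submission size |
| `seq_identity_min` | 0.90 | – | chain-to-target identity floor |
| `coverage_min` | 0.70 | – | chain-to-target coverage floor |
| `sasa_probe` | 1.4 | Å | solvent probe radius |
| `sasa_points` | 960 | points | Shrake–Rupley quadrature |

All cutoffs compare with strict `<`; boundary hits are measure-zero in
real coordinates.

## Input handling

Decoy sets arrive as one PDB file per model with arbitrary, inconsistent
numbering. Before any consensus can be computed, models are filtered and
renumbered:

1. empty or unparseable files are recorded (reasons `empty`/`unreadable`);
2. models with a single chain identifier are discarded;
3. each chain is aligned to each target sequence (end-gap-free global
   alignment, identity matrix, gap open 10 / extend 0.5) and chains are
   assigned to target labels greedily by identity; a model whose chains
   cannot all be matched at ≥ 90% identity **and** ≥ 70% coverage is
   discarded (`sequence_mismatch`) — either failure alone makes reliable
   renumbering impossible, hence the conjunctive reading;
4. residues are renumbered to aligned target positions (insertion codes
   flattened; unaligned residues keep their coordinates but are excluded
   from contact consideration); alternate locations resolve to the
   highest-occupancy conformer;
5. models with zero intermolecular contacts are discarded.

The filter report reconciles exactly: every input model is either kept or
attributed to one discard reason. For ensembles of two identical target
sequences (homodimers) contact keys drop the chain labels, so a pose and
its chain-relabelled mirror produce identical contact fingerprints —
without this, the arbitrary A/B labelling of decoys from different
predictors would split the consensus.

## The synthetic decoy generator

`generate_ensemble()` emulates the structure of a blind scoring set with
known ground truth: a reference homodimer of two idealized poly-alanine
helices (backbone + Cβ, C2 symmetric, docked at the closest strictly
clash-free separation, which carries ≥ 10 interface contacts), from which
it derives

* **near-native** poses — the planted fraction; the ligand chain receives a
  small rigid-body perturbation (rotation s.d. 2°, translation s.d. 0.5 Å
  per component), calibrated so that such poses assess as high/medium;
* **random** poses — uniformly random ligand orientation and approach
  direction, packed against the receptor until a genuine contact patch of
  at least 5 residue contacts forms while keeping at most 25 clashes.
  Packing matters: incorrect poses from real docking programs bury real
  interfaces; grazing single-contact placements would be trivially
  distinguishable yet would dominate the *normalized* consensus score
  whenever their lone contact happens to be a hot one;
* optional **swapped-monomer** poses built on an alternative monomer fold
  (a tighter, faster-twisting helix), which carry a distinct contact
  fingerprint and therefore their own cluster — emulating ensembles whose
  monomer conformation itself varies;
* optional **clash-injected** poses (a near-native pushed into the receptor
  past 25 clashes) to exercise the exclusion rule.

File names are shuffled and anonymized; a single RNG stream seeded from the
spec drives everything, so generation is exactly reproducible.

What the generator does *not* emulate: real side-chain packing and
rotamers, flexible backbones, the energy-ranked redundancy structure of
individual docking programs, sequence errors, or multi-interface
higher-order assemblies. Passing tests on these ensembles therefore
demonstrates the correctness and calibration of the scoring machinery — not
docking accuracy on real proteins.

## Numerical choices

* **Neighbor search.** Contacts and clashes are exact: a bounding-box
  prefilter discards atoms that cannot be within the cutoff of the other
  chain, and surviving pairs are evaluated in vectorized blocks. Oracle
  tests compare against the full quadratic brute force.
* **SASA.** Shrake–Rupley with 960 deterministic golden-spiral sphere
  points per atom (configurable), probe 1.4 Å, Bondi heavy-atom radii
  (C 1.70, N 1.55, O 1.52, S 1.80 Å); unknown elements fall back on carbon
  with a warning. Occlusion is evaluated as a half-space test on the unit
  sphere, processing nearest neighbours first and dropping buried points
  early. Translation leaves areas bit-identical; rotations re-sample the
  fixed point directions, so areas are rotation invariant only to
  quadrature accuracy (≲ 1%), one reason the exact contact count outranks
  area in the final ordering.
* **Superposition.** Kabsch via SVD with determinant correction; validated
  against an independent fitting implementation to 10⁻⁶ Å.
* **Clustering ties.** See above; heights additionally pass through a
  running maximum before the maxclust cut to guard against floating-point
  inversions (complete linkage is monotone in exact arithmetic).
* **Degenerate inputs.** A consensus of fewer than two models is an error;
  a single-member cluster ranks its member with normalized score 1; zero
  contact maps are rejected at scoring time (they are filtered upstream);
  if fewer than `n_submit` candidates survive the clash rule, all survivors
  are returned with a warning.

## Problem sizes

The test-suite and the acceptance script work at desk scale, chosen to make
the statistical properties measurable while keeping runs comfortable on a
single CPU: ensembles of 100 models of a 2 × 30-residue dimer, 20
replicate seeds for stochastic properties, a 10-point enrichment grid, and
oracle cross-checks at n ≤ 50 for clustering and ≤ 200 maps for scoring.

## Known limitations

* Designated chain-pair scoring only: higher-order oligomers are scored on
  a chosen bipartition of chains; symmetry-aware enumeration of multiple
  interfaces is out of scope.
* Protein chains only; no mmCIF input; no gap filling or side-chain
  rebuilding.
* The interface-area convention (mean of the two partners' buried
  surfaces) matches the magnitudes reported by the interface-analysis
  tools this pipeline descends from, but published areas do not always
  state their convention; the summed convention is available by flag.
* The weak-consensus quota (1 consensus pick + cluster picks in population
  order) codifies the published practice; the original protocol left room
  for case-by-case judgement (e.g. skipping clusters on interface-feature
  grounds), which is deliberately not automated.
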