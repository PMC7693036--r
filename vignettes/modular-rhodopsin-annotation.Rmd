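---
title: "Annotating modular microbial rhodopsins: methods and design"
author: "modrhod"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating modular microbial rhodopsins: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(modrhod)
```

## The problem

Microbial (type I) rhodopsins are seven-transmembrane photoreceptors that
bind retinal through a conserved lysine in the seventh helix. Most act as
light-driven ion pumps, light-gated channels, or photosensors. *Modular*
rhodopsins additionally carry effector domains — histidine kinases, response
regulators, cyclases, transposases and others — fused in the same open
reading frame, making them attractive optogenetic raw material. Because
almost none of them have been characterised experimentally, their likely
function must be read off their sequence: a small number of residue
positions, long studied in bacteriorhodopsin (BR), channelrhodopsin-2
(ChR2) and proteorhodopsin (PR), determine whether the photocycle can pump,
gate a channel, or merely signal, and what colour of light the pigment
prefers.

`modrhod` implements that residue-level annotation as a reusable, tested
pipeline:

1. **Topology** — is the protein plausibly a rhodopsin at all? Seven
   transmembrane helices by hydropathy segmentation, plus a lysine in the
   seventh helix.
2. **Reference mapping** — where are the diagnostic positions in *this*
   sequence? Global pairwise alignment against a reference scaffold
   projects, e.g., "BR position 85" onto the query.
3. **Classification** — rule evaluation on the extracted residue
   fingerprint: functional class, spectral-tuning class, cyclase-domain
   activity, and conservation tallies across a set of entries.
4. **Phylogeny** — p-distances, neighbor-joining, bootstrap support.

Curated residue tables for the known modular rhodopsins ship with the
package (`loadFixture()`), so every published tally can be recomputed
offline.

## The rule model

Each *reference scheme* names a set of key positions with mechanistic roles
and expected residues.

**Ion pumping (BR numbering).** Asp85 accepts the Schiff-base proton during
deprotonation, Asp96 re-protonates it, Asp212 is part of the counterion,
and Lys216 binds retinal. The pump gate is therefore

> acceptor (85) ∈ {D, E} ∧ donor (96) = D ∧ counterion (212) = D ∧
> attachment (216) = K.

Thr89 (stabilises the acceptor), Thr90 (binding pocket) and the
proton-release pair Glu194/Glu204 are recorded as evidence but do not gate
the call: a minimal pump can release protons by other routes, and gating on
them would contradict the observed uniqueness of the one pump-competent
modular entry, which carries Gly at the 194-equivalent. An entry without
the attachment lysine cannot form the retinal Schiff base and is called
non-retinylidene; one with the lysine but a failed gate is called
sensory/atypical.

**Channel competence (ChR2 numbering).** Asp253 (acceptor), Asp156 (donor),
Cys128 (the DC-gate cysteine hydrogen-bonded to the donor), Arg120
(stabilises the acceptor and lines the extracellular gate) and Lys257
(attachment) must all match; the acceptor admits D or E because glutamate
serves as acceptor in ChR2 itself.

**Spectral tuning (PR numbering).** The residue at the PR-105-equivalent
position switches green- versus blue-absorbing proteorhodopsins: nonpolar →
green, polar-uncharged → blue. Charged residues fall outside the published
two-way rule and return `UNKNOWN`; gaps and missing cells return
`UNSCORED`. The full partition (nonpolar {A,V,L,I,M,F,W,P,G,C},
polar-uncharged {S,T,N,Q,Y}, charged {D,E,H,K,R}) extends the published
examples (L/I/M → green, Q → blue, D → unknown) to the whole alphabet and
is overridable per call.

**Cyclase activity.** A class III cyclase needs two metal-binding
aspartates, a substrate-specifying residue (Glu for GTP, Lys for ATP) and
the transition-state stabilising Asn/Arg pair. Any substituted or absent
catalytic residue yields `DEGENERATE`. The published source for the
modular-rhodopsin cyclase domains is an alignment figure without a printed
residue table or numbering, so the packaged cyclase rows
(`loadFixture("cyclase")`) are a *synthetic* transcription of its
qualitative content — an intact canonical row and intact Cop6 versus
Cop5/Vop5 rows lacking the catalytic set — and the scheme's coordinates are
defined relative to that canonical row, not to any published numbering.

## Curated tables and the grouped-row convention

The packaged pump-scheme table prints one row per rhodopsin *or* per group
of rhodopsins sharing identical key residues: a trailing `2/3` or `9-10`
(as in GtRh2/3, Cop9-10, BgRh1/2) denotes several proteins on one row.
`loadFixture("table2B")` expands such rows to one entry per protein, giving
46 modular entries next to the 7 non-modular reference proteins (BR, HR,
KR2, ASR1, SR2, RhoGC, RhoPDE); the published conservation tallies (14
Asp/Glu and 17 Gln at 85, 6 Asn at 212, 25 Glu at 204) are reproduced
exactly on the expanded set, and the retinal-attachment lysine is present
in all 46. The accompanying prose states 47 modular rhodopsins, one more
than the printed table expands to; the package follows the printed table,
and only tallies the table itself supports are asserted anywhere.

A printed `-` cell (three entries have no residue at the 204-equivalent)
loads as *missing*: it never counts towards a conservation numerator but
stays in the denominator. The spectral table lists GpRh3 twice with
different residues; the transcription keeps the assignment consistent with
the pump table's grouping (methionine, in the Cop5-7/GpRh3-5 row), flags
the isoleucine-row duplicate, and `loadFixture("table3")` drops the flagged
row while reporting it in the `"duplicates"` attribute. Both printed rows
call the same colour, so no downstream result depends on the choice.

## Topology: hydropathy segmentation

Hydropathy uses the Kyte–Doolittle scale (X scores 0) smoothed with a
19-residue window, the community default for transmembrane detection;
positions within half a window of a terminus are scored with shrunken
windows rather than left undefined. Candidate helices are maximal runs of
smoothed score ≥ 1.6; runs separated by at most 3 sub-threshold residues
merge (the gap residues joining the helix); merged runs shorter than 15
residues are discarded. All four parameters are exposed
(`segmentHelices()`), and raising the threshold can only shrink total helix
coverage — a property the tests assert.

The published analysis states that candidates required the conserved seven
helices and the seventh-helix retinal lysine but not how helix boundaries
were delimited, so the segmentation parameters are this package's own
(canonical) choices, not claims from the source analysis.
`validateRhodopsin()` demands exactly 7 detected helices and at least one K
inside the last one; with any other helix count the lysine check is not
attempted and the verdict lists each failed criterion.

## Reference mapping

Queries are aligned to a scheme scaffold by global Needleman–Wunsch with
affine gaps (BLOSUM62, gap open 10, gap extend 0.5 — the de-facto protein
defaults; the alignment engine is `Biostrings::pairwiseAlignment`, whose
traceback is deterministic, and no result here depends on which co-optimal
alignment is returned because scores, not paths, are asserted). The
original analysis used a progressive multiple alignment; this package
deliberately re-interprets position transfer as independent *pairwise*
projection of each query onto the reference, which preserves the
"numbered with respect to BR" semantics while removing the dependence on
an external multiple-alignment tool and on the unstated parameters of that
step. For each key position the alignment column holding the reference
residue is located; a query-side gap leaves the role unmapped, otherwise
the query residue and its 1-based position are recorded. Mapped positions
are strictly increasing in reference order whenever all roles map.

The package does not redistribute the real BR/ChR2/PR sequences: for real
use the reference FASTA is supplied by the user, and for testing the
synthetic scaffolds below serve as references with known coordinates.

## Synthetic data: what it emulates, what it does not

`makeScaffold()` builds rhodopsin-like proteins with known ground truth:
7 hydrophobic helices (default 36 residues) separated by hydrophilic loops
(default 14), with the scheme's expected residues planted at fixed
helix-interior slots and the scheme re-based to scaffold coordinates.
Helices draw from {A,V,L,I,F,M} weighted towards the strongly hydrophobic
residues, as real transmembrane helices are; loops draw uniformly from
{D,E,N,Q,K,R,S,T,G,H}. Three placement rules keep detection and planting
orthogonal: key slots sit well inside helices (an edge dent in the smoothed
profile shortens the detected run irrecoverably, while an interior dent is
bridged by the gap-merging rule); when a helix hosts two key slots they sit
a full smoothing window apart, so no window ever contains two planted polar
residues; and the attachment role always occupies the centre of the last
helix. The helix length, 36, is longer than a typical 20–25-residue
transmembrane helix; it buys a smoothed-profile plateau wide enough that
segmentation at the canonical parameters stays reliable under the 5%
background mutation used in the closure experiments.

`makeVariant()` plants an arbitrary role → residue fingerprint and applies
background substitutions (uniform over the other 19 residues) outside the
key positions at a caller-chosen rate, attaching the planted truth to the
result. `evolveFamily()` evolves the scaffold along a given tree under a
uniform replacement model (site changes with probability
1 − exp(−rate·branch length), new residue uniform over the other 19).

None of this emulates real evolutionary processes: there is no empirical
exchangeability matrix, no rate heterogeneity, no indels (beyond the fixed
insertions used in mapping tests), and loop/helix composition is idealised.
Passing the closure tests therefore shows that the pipeline's stages
compose correctly and that alignment-based projection is robust to moderate
divergence on topology-clean inputs — not that the pipeline is robust to
everything real sequences do (signal peptides, long insertions in loops,
marginal hydrophobicity). Every generator takes an explicit seed and
restores the global RNG state, so results are pure functions of
(parameters, seed).

## Phylogeny

Distances are p-distances (mismatches over pairwise non-gap columns; zero
comparable columns is an error), with an optional Poisson correction
−ln(1−p); a saturated pair (p ≥ 1) is an error rather than an infinite
distance, on the view that silently infinite distances corrupt
neighbor-joining. The source analysis names only the tree method, not its
distance, so p-distance is this package's default.

Neighbor-joining follows the Saitou–Nei agglomeration: minimise
Q(i,j) = (n−2)·d(i,j) − r(i) − r(j), ties broken by the lowest index pair
(for determinism), standard branch-length formulas, final three lineages
resolved in closed form. Negative branch lengths are clamped to zero with
the excess moved to the sister branch, preserving the path length through
the joined pair. On additive matrices the output reproduces the input
path-length matrix to numerical precision (asserted at 1e-9 over random
4–8-taxon trees); on noisy matrices the topology agrees with the
independent `ape::nj` implementation, which the tests use as a
cross-check, never as the implementation.

Bootstrap support resamples alignment columns with replacement, rebuilds
the tree per replicate, and annotates each internal bipartition of the
full-data tree with its replicate frequency × 100, matched by bipartition
identity. The basal node of the unrooted tree carries an empty label — its
bipartition is trivial. The published tree itself is not reproduced:
it depends on full-length sequences retrievable only from database
accessions, which the package deliberately does not fetch; the
neighbor-joining stage is instead validated by the property-based
experiments above.

## Numerical and degenerate-input choices

* Missing (`NA`) versus gap (`-`) are distinct everywhere: missing means
  the curated table printed no residue, gap means the aligned query had
  none. Both are excluded from conservation numerators and spectrally
  `UNSCORED`; only a non-K attachment (including gap/missing) makes an
  entry non-retinylidene.
* An empty helix list, an empty batch, and an empty annotation report are
  valid results, not errors.
* Q-minimisation and traceback ties are resolved deterministically, and all
  TSV/JSON outputs have stable column and key order, so identical inputs
  and seeds give byte-identical outputs.
* X (unknown residue) is tolerated in sequences (hydropathy 0) and yields
  `UNKNOWN` spectrally; it never satisfies a rule expecting a specific
  residue.

## Problem sizes in the shipped experiments

The test-suite and acceptance-script experiment sizes are the package's
standard validation settings: 100 random additive matrices on 4–8 taxa for
NJ consistency; 30 seeded short pairs (combined length ≤ 12) for exhaustive
alignment-score equivalence; 50 simulated 8-taxon families (rate 1.0,
~360-residue scaffold) for ≥90% topology recovery; 200 planted variants at
5% background mutation for ≥99% pipeline class recovery; 200 scaffolds for
the ≥95% topology-validation rate. These sizes give stable pass/fail
behaviour across seeds while keeping a full run in tens of seconds.

## Known limitations

* Helix boundaries from first-principles hydropathy are approximate;
  marginally hydrophobic helices (as in some real channelrhodopsins) may
  fall below the canonical threshold, and no machine-learned predictor is
  included by design.
* Pairwise projection can misplace positions when the query is highly
  diverged or has long insertions near a key column; the multiple-alignment
  context the original analysis had is deliberately out of scope.
* The functional rules are necessary-condition fingerprints, not
  predictors: an entry can satisfy the pump gate yet be a sensor, and the
  sensory/atypical class is a catch-all for "retinal-binding but not
  obviously pump- or channel-like".
* The cyclase fixture is synthetic (see above); only its qualitative
  pattern, not its coordinates, reflects the published figure.
* The uniform replacement model makes simulated families easier for
  distance methods than real protein families are.
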