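---
title: "Detecting and classifying Binder of Sperm superfamily proteins"
author: "bsptools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and classifying Binder of Sperm superfamily proteins}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsptools)
```

## The biological problem

Binder of Sperm (BSP) proteins are seminal-plasma proteins that coat the
sperm plasma membrane, bind choline phospholipids, and modulate capacitation.
The superfamily comprises three families — BSP and its homologs BSPH1 and
BSPH2 — and the BSP family further splits into four subfamilies (BSP1, BSP2,
BSP3, BSP5). All members share one structural signature: two tandem
fibronectin type II (FN2) domains, each stabilized by two conserved disulfide
bonds, each contributing an aromatic phosphorylcholine (PC) binding pocket
whose floor is a strictly conserved tryptophan.

Database annotations for this superfamily are noisy: several sequences are
deposited as BSPH1 although their sequence features are those of a BSPH2,
and gene symbols differ between resources. `bsptools` operationalizes the
sequence-level evidence — conserved blocks, family fingerprints, phylogeny
and gene context — into a reproducible pipeline that can call families,
flag misannotations, and be validated end to end on synthetic data.

## The conserved-block model

The tandem-FN2 region is modelled as an 87-position core frame anchored at
the first conserved cysteine. Nine conserved blocks tile this frame: Blocks
I–IV form the N-terminal domain (1FN2, core positions 1–38), Block V is the
inter-domain linker (40–42), and Blocks VI–IX form the C-terminal domain
(2FN2, 46–87). Each block is a degenerate consensus over the aligned
superfamily: fixed residues, alternative sets (`[VA]`), wildcards (`x`) and
a hydrophobic class (`h`).

```{r blocks}
block_definitions()[, c("block_id", "domain", "pattern",
                        "canonical_start", "canonical_length")]
```

Two arithmetic facts of this table recur throughout the package's checks:
the C-terminal domain is 4 residues longer than the N-terminal one (42 vs
38), and its third and fourth blocks are each 2 residues longer than their
1FN2 homologs (VIII vs III, IX vs IV).

The hydrophobic class defaults to `{A, V, L, I, M, F, W, Y}`. The source
consensus notation only states "hydrophobic", so the set is an argument of
every function that interprets `h`.

### Scanning and assembly

`scan_blocks()` is an exhaustive per-position matcher: every window whose
mismatch count is at most the tolerance is reported. The default tolerance
of 1 mismatch per block is deliberate: even the cloned ram protein RSVP20
deviates from the Block IV aromatic consensus at one position, so exact
matching would reject genuine members. Exact mode (`tolerance = 0`) is
available.

`assemble_architecture()` reduces the raw match list to the best mutually
consistent chain by dynamic programming. Two matches are compatible when
ordered, non-overlapping, and their start offset deviates from the
canonical offset by at most `gap_slack` (default 2) residues per block
step. Chains are ranked lexicographically: more blocks, then fewer total
mismatches, then leftmost starts — a total order, which is what makes the
assembly deterministic and permutation-invariant.

### Disulfide topology

Each FN2 domain carries two disulfide bonds with 1–3/2–4 connectivity. In
1FN2 all four cysteines are housed by blocks (I, II, III, IV). In 2FN2 the
first and third are in Blocks VI and VIII and the fourth in Block IX, but
the second is expected in the gap between Blocks VI and VII, which no block
covers. `check_disulfides()` therefore searches that gap; absence of the
gap cysteine downgrades the pair to `incomplete` (a warning) rather than a
violation, because the consensus model does not pin its exact position. The
synthetic generator and `canonical_core()` place this cysteine at core
position 56 so that noise-free synthetic members display the full
four-bond topology the family is described with.

## Family classification

BSPH1 and BSPH2 carry diagnostic exact versions ("fingerprints") of
particular blocks; BSP carries none:

```{r fingerprints}
family_fingerprints()
```

`classify_family()` scores each family as the fraction of its fingerprint
components present. A component is read both from the chained block match
and from its canonical core-frame coordinates, and the better view is kept:
this matters for the BSPH2 linker fingerprint `DPP`, which itself violates
the linker consensus `xxD`, so the best-scoring chain can legitimately
place Block V one position away from the fingerprint.

A component matches when (i) every *diagnostic* position — a position where
the fingerprint is strictly narrower than the superfamily consensus, e.g.
the H and K of `HKWCSLN` or the W of `ChFPFWY` — is satisfied, and (ii) at
most one scaffold position deviates. A plain "at most one mismatch
anywhere" rule was tried first and rejected: most fingerprint positions are
shared with the consensus, so under that rule a consensus-only BSP sequence
matches the Block VI BSPH1 fingerprint with probability ≈ 0.26 and roughly
1 in 100 synthetic BSP groups is miscalled BSPH1. Anchoring the decision on
the diagnostic positions removes those false calls without giving up the
single-substitution tolerance real variants need.

The decision rule: with `theta = 2/3` (fraction of components required), a
complete architecture is BSPH1 or BSPH2 when that family's score reaches
`theta` and exceeds the other's, `unclassified` on a tie at or above
`theta`, and BSP when both scores fall below `theta`. Incomplete
architectures are `not_BSP_superfamily`. Both `theta` and the scaffold
tolerance are exposed configuration.

### Subfamilies

No printed motif separates BSP1/BSP2/BSP3/BSP5 — they are defined as tree
clades. `assign_subfamily()` therefore uses nearest labelled reference:
highest pairwise-deletion identity over the 87-position core against a
reference panel, with a floor (default 0.40) below which no subfamily is
assigned, and alphabetical tie-breaking with an ambiguity flag.

### Annotation reconciliation

`reconcile_annotation()` compares the family token extracted from a
database symbol (after an editable synonym table; `ELSPBP1` is explicitly
excluded because it contains the letters BSP) with a sequence-based call:
`consistent`, `misannotated`, `novel` (no existing symbol) or `unresolved`.
Applied to the bundled nomenclature table, it reproduces the four
family-level renames (all BSPH1 → BSPH2: accessions M3XZ70, G3VIB3,
H0Y1M6, I3N753).

## Phylogeny

Distances are computed from pairwise comparisons with pairwise deletion:
per pair, only columns gapped in that pair are excluded. Three models are
available: the raw proportion `p`, the Poisson correction `-ln(1 - p)`,
and the default Dayhoff PAM distance — the time `t` (substitutions/site)
at which the Dayhoff-1978 replacement model's expected residue identity
equals `1 - p`, found by a monotone root search. The exchangeabilities and
equilibrium frequencies of the Dayhoff model are taken from phangorn's
amino-acid model set; the inversion is validated in the tests against an
independent dense matrix-exponential bisection. The "Dayhoff model" of
popular tree programs is not operationally documented, so this
expected-identity inversion is our stated approximation; `p` and `poisson`
remain as fallbacks. Distances beyond the model's invertible range are
flagged saturated.

`nj_tree()` is a from-scratch Saitou–Nei implementation: minimize
`Q(i,j) = (r-2)d(i,j) - R(i) - R(j)`, closed-form branch lengths, negative
lengths clamped to zero (counted in an attribute), ties broken toward the
smallest index pair. Its consistency on additive matrices and agreement
with an independent NJ implementation are property-tested.
`bootstrap_supports()` resamples alignment columns with replacement,
rebuilds distances and the tree per replicate, and reports for every
non-trivial split of the full-data tree the percentage of replicates
containing it; replicates with undefined distances are dropped, counted
and warned about. Trees serialize to Newick through ape, with supports as
internal node labels.

The pipeline aligns synthetic panels trivially: every generated core is
exactly 87 columns, so no multiple-alignment engine is needed or included.
Real data must arrive pre-aligned.

## Gene context

Three synteny patterns are encoded: BSP loci flanked by the CD177/TEX101
cluster on one side and LYPD3/PHLDB3/ETHE1/ZNF575 on the other;
BSPH1/BSPH2 loci adjacent to C19orf68/LIG1/CABP5/ELSPBP1 and SULT2A1/CRX;
and a BSPH1/BSPH2 context without ELSPBP1 where PLA2G4C appears instead.
`match_pattern()` scores the fraction of pattern anchors found within 10
genes of the outermost BSP-superfamily core gene, orientation-agnostic
(reversing the record changes nothing), with a 0.5 threshold; the
without-ELSPBP1 pattern additionally requires PLA2G4C present and forbids
ELSPBP1. The 10-gene window and 0.5 threshold reflect that gene inventories
differ between databases, so exact adjacency cannot be required.

`cross_check()` reports every gene whose symbol-derived family conflicts
with its sequence-based call, with the matched pattern as context. The
bundled ferret-style fixture — a BSPH1-labelled gene carrying a BSPH2
sequence call inside an ELSPBP1-context neighborhood — yields exactly one
such report. (We place the ferret fixture in the ELSPBP1-containing
context, which is where the original misannotation was described.)

## The synthetic-data generator

`generate_panel()` emulates the superfamily's generative structure, not
its evolutionary history. Each family/subfamily group draws one ancestor
core: consensus-fixed residues kept, alternatives sampled, wildcards drawn
from a background (uniform by default; Dayhoff frequencies optional),
hydrophobic positions from the hydrophobic set, family fingerprints
overwritten for BSPH1/BSPH2, and the `SP` dipeptide appended after the
core for BSPH2. Members are the ancestor plus i.i.d. per-position
substitutions at rate `epsilon`, wrapped in a signal-peptide-like
hydrophobic prefix (15–25 residues, cosmetic) and a short random tail.
Ancestors are drawn from sub-seeds derived from `(seed, group)`, so
`generate_reference_panel()` reproduces exactly the ancestors a same-seed
panel was mutated from — that is what makes generator truth labels
recoverable by nearest-reference assignment. Decoys (single-domain and
residue-shuffled sequences) are available for specificity checks.

What the generator does *not* emulate: indels (beyond nothing — linker
length variation is handled by `gap_slack` at match time, not simulated),
rate heterogeneity across sites, tree-like divergence within a group, and
real signal peptides. Passing tests therefore demonstrate that the
pipeline's logic is correct under its own model — block recovery,
fingerprint classification, clade recovery, misannotation flagging — not
that real database sequences will behave identically.

`generate_neighborhoods()` emits one gene-order record per requested
synteny pattern, from the published gene lists, optionally with filler
genes inserted, with truth labels attached.

A deterministic synthetic stand-in for the RSVP20 precursor
(`synthetic_rsvp20_like_precursor()`) pins every published residue
landmark of that protein (core anchor C63, pocket tryptophans W86 and
W133, the Block IV I99 deviation, and the rest); all unpinned positions
are inventions. It exists to test coordinate arithmetic against published
precursor numbering without bundling any database sequence.

## Numerical and reproducibility choices

* Coordinates are 1-based inclusive everywhere, matching residue
  numbering conventions.
* All randomness flows through explicit integer seeds; generation and
  bootstrap use `withr::with_seed`, so library calls never perturb the
  caller's RNG state. Identical config + seed reproduce byte-identical
  pipeline artifacts, and every tabular output carries a header with
  package version, seed and an md5 hash of the analysis parameters.
* Degenerate inputs: empty match lists assemble to an (incomplete)
  empty architecture; all-gap pairs get an `undefined` distance flag;
  saturated distances are flagged rather than clamped; bootstrap
  replicates with undefined distances are dropped and counted.
* Problem sizes in the tests and acceptance script — panels of 18
  sequences (3 per group), 87-column cores, bootstrap with tens of
  replicates, property tests on trees of up to 12 taxa — were chosen as
  the smallest sizes at which every behaviour of interest (clade
  recovery, support saturation, tie handling) is actually exercised.

## Known limitations

* The Dayhoff distance is an expected-identity inversion, not a
  maximum-likelihood distance; for deep divergences it will differ from
  ML estimates.
* Fingerprint thresholds (`theta`, the scaffold tolerance) are design
  choices; the original authors' implicit criteria are not recoverable
  from the printed consensus alone.
* Subfamily assignment is only as good as the reference panel; with real
  data, references should be curated sequences, not synthetic ancestors.
* The gene-context module reasons over gene order only — no genomic
  coordinates, no strand-aware logic beyond orientation-agnostic
  matching.
* No signal-peptide prediction: the N-terminal region upstream of the
  core frame is simply ignored.
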