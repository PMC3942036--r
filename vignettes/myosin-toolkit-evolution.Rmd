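---
title: "Reconstructing the evolution of the eukaryotic myosin toolkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing the evolution of the eukaryotic myosin toolkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(myoevo)
```

## The problem

Myosins are the actin-based motor proteins of eukaryotes. All of them share
one domain — the motor ("head") domain, Pfam accession PF00063 — flanked by
a remarkable diversity of N- and C-terminal cargo-binding domains. The
family is organised into *classes* (paralog groups such as myosin II or
myosin V), some of which split into *subclasses*, and classes cluster into
deeper *types* (ancestral paralogs such as the "V-like" assembly that
unites opisthokont myosin V, plant myosin XI and several protist classes).
Because domain architectures are re-shuffled, convergently re-invented and
repeatedly lost, class membership must be defined by phylogenetic affinity
— clades in a gene tree — rather than by architecture similarity.

`myoevo` implements the computational core of such an analysis:

1. **annotation parsing** — reading per-proteome domain scans, extracting
   every protein that carries the motor domain, resolving clan-redundant
   overlapping hits, and canonicalising domain architectures;
2. **classification** — assigning sequences to classes by clade membership
   in a support-annotated gene tree, and tabulating presence/absence per
   lineage;
3. **ancestral reconstruction** — Dollo parsimony over a rooted species
   tree, yielding the myosin complement of named ancestors (LECA, LBikCA,
   LACA, LOCA, LHolCA) and its sensitivity to the rooting;
4. **diversity and convergence** — concurrent-domain repertoires, Venn
   partitions between lineages, and detection of convergently acquired
   architecture signatures;
5. **simulation** — a seeded generator of gain/loss histories, evolving
   architectures and gene trees, used to validate every stage end to end.

## The Dollo model

Each classification unit (class, subclass or type) is treated as a binary
character on a rooted species tree. Under Dollo parsimony a unit arises
exactly **once** and can afterwards only be **lost** — the right model for
paralog families that are *defined* as clades, since a second independent
origin of the same clade is excluded by construction.

For a unit observed in the leaf set $P$:

* the gain is placed on the branch above $\mathrm{MRCA}(P)$ (a unit seen on
  both sides of the root is reported as gained at `ROOT`);
* every node on a path from the MRCA to a leaf of $P$ is inferred present;
* every maximal subtree under the MRCA that contains no leaf of $P$
  contributes exactly one loss, on its root branch.

This loss set is the unique minimum for the observed pattern, which the
test suite verifies against an exhaustive search over all
(gain node, loss subset) histories on small trees. One property worth
spelling out: adding a presence leaf can increase the minimal loss count by
*more* than one (the new leaf can drag the gain rootward past many empty
side branches), but never moves the gain tipward; the tests assert exactly
this.

The ancestral complement of a node is simply the set of units inferred
present there:

```{r}
rec <- fixture_reconstruction(granularity = "type")
ancestor_complement(rec, "LECA")
```

## The packaged census

The package ships a curated census of the family across 62 genomes in 14
lineage groups: 31 classes (class I with five subclasses, class II with a
striated and a smooth subclass), their canonical architectures, a
lineage-level presence matrix at the finest unit granularity, and a species
tree with the five named ancestors under the unikont–bikont rooting plus
two alternative rootings (opisthokont stem, excavate stem).

Three caveats define what this fixture is and is not:

* Presence cells and taxon identities that the published record pins down
  explicitly are transcribed; the remaining cells are best-effort
  reconstructions chosen for internal consistency. Quantities asserted in
  the tests (the class census, the six-type ancestral complement, the
  complete losses in metamonads and rhodophytes, the holozoan-stem origin
  of striated muscle myosin II) rest only on the pinned-down facts.
* The species tree keeps the relationships among unicellular holozoans
  unresolved (a multifurcation at the holozoan ancestor). This matters:
  with presence in Metazoa and *Ministeria vibrans* only, the multifurcate
  topology is what places the striated myosin II gain on the holozoan stem
  with independent losses in ichthyosporeans, choanoflagellates and
  *Capsaspora owczarzaki* — the parsimony-consistent reading of that
  history.
* Domain names are normalised to underscore form (`Cyt_b5`), because `-`
  separates tokens in canonical architecture strings and names containing
  it would not round-trip.

## Tunable parameters

* **Support thresholds** (`min_bs = 50`, `min_bpp = 0.95`): a clade
  assignment is *clear* when its host clade meets either the bootstrap
  percentage or the posterior probability threshold. Either suffices
  because well-supported Bayesian clades with mediocre bootstrap are
  routinely accepted as classes; both are arguments of
  `assign_by_clade()`.
* **Unclear policy** (`as_absent` by default): cells supported only by
  sub-threshold orthologs are treated conservatively as absent before
  reconstruction; `as_present` gives the sensitivity direction, and the
  pipeline can emit both bundles.
* **Comparison mode** (`repeat_insensitive` by default): copy counts such
  as `IQ(x2)` are recorded but ignored when comparing architectures, since
  repeat numbers vary freely within classes ("0 to 2 IQ repeats").
* **Overlap policy** (`clan_best_evalue`): among same-clan overlapping
  hits only the lowest-E-value hit survives. How the original scans
  resolved clan overlaps is not documented; this mirrors the scanning
  tool's default behaviour and is switchable to `keep_all`.
* **Convergence evidence**: independence of gains is topological (neither
  gain branch ancestral to the other) — decidable without branch lengths.
  When gains are nested, an optional class-level tree allows the
  complementary evidence route: non-orthologous (non-sister) classes
  bearing the same signature, which is how the fungal class XVII and the
  annelid/mollusc members of class XVI are both associated with a
  chitin-synthase domain. Motif matching is ordered-subsequence rather
  than contiguous, so `MyTH4–FERM` matches a `MyTH4–SH3–FERM` tail.

## What the simulator emulates

`simulate_repertoire()` draws, per unit, a gain branch uniformly over all
branches (including the notional root branch) and then loses the unit on
each branch below the gain independently with probability `loss_prob`
(subtrees below a loss are skipped — under Dollo nothing re-appears).
This is the simplest generative process whose maximum-parsimony solution
is the Dollo reconstruction being tested. `simulate_architectures()` gives
each unit a root architecture (motor domain plus 0–4 flanking domains) and
evolves it by per-branch token deletion, duplication and insertion, with
the motor domain immune to both deletion and duplication, so each emitted
protein has exactly one head. `simulate_gene_tree()` arranges each unit's
surviving leaves as a clade mirroring the pruned species tree, joined on a
random backbone, with high within-clade supports (90–100) and low joining
supports (0–50). All randomness flows from one integer seed and reruns are
bit-identical.

What the simulator does **not** emulate: branch-length heterogeneity, rate
variation across units, gene conversion, horizontal transfer, annotation
error, and incomplete proteomes. Passing recovery tests therefore show
correctness of the reconstruction machinery under the Dollo generative
model, not robustness of the biology to those confounders.

### Recovery calibration

On a balanced 32-leaf tree with per-branch loss probability 0.05, the
probability that the reconstruction recovers a unit's true gain branch has
a closed form, computed by dynamic programming in
`expected_gain_recovery()`: per child branch, the probability $q$ of
leaving no surviving leaf satisfies $q = p + (1-p)\prod_c q_c$, and a gain
is recovered exactly when survivors remain in at least two child subtrees.

```{r}
expected_gain_recovery(balanced_tree(32), 0.05)
```

The expectation among reconstructable units (~95.2%) sits close to the 95%
bar used in the tests, so a single 200-unit draw is noisy at that margin;
the acceptance test therefore aggregates 50 seeded replicates (10,000
units), whose standard error (~0.2 percentage points) makes the comparison
stable. Recovery is scored over units with at least one surviving leaf —
a unit lost everywhere leaves no signal and no reconstruction could place
its gain.

## Numerical and design choices

* Branches are identified by the label of their child node; unlabelled
  internal nodes get stable auto-names (`N<id>`), and the root-spanning
  gain is the distinguished branch `ROOT`.
* Multifurcations are first-class: MRCA, path-marking and loss placement
  operate on the topology as given, never on an arbitrary binary
  resolution.
* Hits are sorted by envelope start, ties broken by envelope end and then
  accession, so canonical architectures are order-stable.
* Overlap means any shared position under 1-based inclusive envelope
  coordinates.
* In gene trees, internal-node "labels" are supports (`85`, `0.99` or
  `79/0.99`), not identities; values at most 1 are read as posteriors.
  The N- versus C-terminal placement of a domain is captured purely by
  token order relative to the motor domain.
* Empty inputs degrade gracefully: an empty annotation stream yields an
  empty hit table, a unit absent everywhere has no gain and no events, and
  species without assignments yield all-absent matrix rows.

## Problem sizes used in validation

The oracle-equivalence suite samples random rooted topologies of 4–8
leaves (200 random presence patterns per leaf count against an
independently coded path-marking oracle, plus full loss-subset enumeration
on trees of up to 6 leaves); the recovery suite uses the balanced 32-leaf
tree with 200 units per replicate and 50 replicates. These sizes make the
checks exhaustive where exhaustiveness is tractable and tightly
concentrated where they are stochastic.

## Limitations

* Class definitions enter as *seeds* on a gene tree; the package does not
  infer gene trees, alignments, or supports.
* Dollo parsimony has no rate model: it cannot distinguish one loss from
  several consecutive ones on a path with no sampled taxa, and it will
  interpret a horizontally transferred gene as an ancient gain plus
  many losses.
* The census fixture is a transcription at lineage granularity; per-species
  gene counts and figure-level domain lists of the original study depend on
  the underlying proteomes and are outside what the fixture can reproduce.
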