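---
title: "Local structural comparison with pseudoatom representations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local structural comparison with pseudoatom representations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(structmatch)
```

## The problem

Protein function often depends on a handful of residues arranged in a
specific three-dimensional geometry — an enzyme's catalytic triad, a
phosphate-binding loop, a metal coordination shell.  Local structural
comparison asks whether two structures share such an arrangement,
irrespective of sequence order and of overall fold.  Two ingredients
determine what such a method can see:

1. **The representation** — which points stand in for each residue.  A
   Cα-only description finds backbone-shape similarity; adding a side-chain
   centroid brings in residue orientation; describing individual chemical
   groups (carboxylates, hydroxyls, ring centroids) lets chemically
   analogous but structurally different residues align by their functional
   atoms only.
2. **The search** — finding the largest correspondence between the two point
   sets that superimposes rigidly below an RMSD threshold.

`structmatch` treats the representation as user input, written in a small
residue-definition language, and solves the search with branch-and-bound
over unit pairings with quaternion-based optimal superposition.

## The residue-definition language

A representation file contains `def` lines, equivalence rules, and an
optional `mode` directive:

```
mode grouped
def SER CA CB                 # two pseudoatoms, the CA and CB atoms
def HIS avg(ND1,NE2):bar      # centroid of the imidazole nitrogens
def *   \N;\O                 # any other residue: every N- or O-named atom
SER.(CA) HIS.(BAR)            # which residues (fragments) may pair, in order
```

Atoms are paired positionally, in the order written; fragment selectors
restrict a rule to named pseudoatoms.  `*` in a residue position means "any
residue without a more specific definition"; `\STR` in an atom position
means "every atom whose name contains STR".  Because pattern pseudoatoms
inherit the pattern as their recipe identity, the positional pairing of two
wildcard definitions automatically restricts nitrogen-derived points to
match nitrogen-derived points — no extra typing mechanism is needed.

Three presets ship with the package (see `rep_preset()`): Cα-only with free
substitution; Cα plus side-chain centroid with substitutions limited to
BLOSUM62 score ≥ −1; and a chemical-group description in independent-atom
mode with no main-chain matching.  In independent-atom mode every pseudoatom
is its own match unit, so two groups of one residue can align with two
different residues; in grouped mode (the default) a residue's points move as
one unit, which keeps the search cost independent of the number of points
per residue.

Design choices in the language that were genuinely open:

* **Self-equivalence.** A residue named anywhere in a rule may match itself;
  a residue named in no rule matches nothing.  Rules are the only pairing
  mechanism, so membership is the natural licence for self-matches.
* **One `def` per residue.** A duplicate definition is an error rather than
  an extension; silent merging would make files order-dependent.
* **Missing atoms.** A single-atom recipe whose atom is absent yields no
  pseudoatom; a centroid recipe averages over the atoms present (warning
  issued) and is dropped only if none are present.  Truncated side chains
  are common in crystal structures, and dropping a whole residue for one
  missing atom would silently shrink binding sites.
* **Atom names are taken verbatim** from the PDB record (no OXT or primed
  ribose aliasing), since the language itself refers to PDB naming.

## Optimal superposition

For an ordered correspondence the optimal rigid superposition minimising

$$\mathrm{RMSD} = \sqrt{\tfrac{1}{n}\sum_i \lVert a_i - (R b_i + t)\rVert^2}$$

over proper rotations is computed by the quaternion method: the 4×4 key
matrix built from the cross-covariance of the centred point sets has the
optimal quaternion as its top eigenvector, and the top eigenvalue $\lambda$
gives $\mathrm{RMSD}^2 = (G_a + G_b - 2\lambda)/n$ directly.  Reflections
are excluded by construction — a mirror-image site never reports RMSD 0.
Superpositions are unweighted.

Numerical notes: the exported `optimal_superposition()` uses a full
symmetric eigendecomposition (LAPACK); inside the search only the top
eigenvalue is needed and is obtained by Newton iteration on the
characteristic quartic of the (traceless) key matrix, started at
$(G_a+G_b)/2 \ge \lambda_{\max}$, with incremental coordinate sums
maintained along the search path.  Both paths agree with an independent
Kabsch SVD implementation to better than $10^{-8}$ Å in the test suite.
For $n = 1$ the RMSD is 0 with the identity rotation; for $n = 2$ the
closed form $|d_a - d_b|/2$ is used; degenerate top eigenvalues (symmetric
point sets) can make the rotation non-unique, in which case any maximising
quaternion is returned — the RMSD, not the rotation, is the contract.

## The search

Units of the two pseudoatom sets are paired only as licensed by the
equivalence rules.  All admissible single-unit pairings are enumerated as
seeds (`seed_pairs()`); each is grown depth-first, and a partial
correspondence survives only while its own optimal RMSD stays at or below
the threshold.  When the exploration finishes, all correspondences of
maximum size (in units) are returned, sorted by RMSD.

Two implementation decisions matter for completeness and speed:

* **Canonical-order growth.**  Candidate pairings carry a fixed order
  (probe-unit major, target-unit minor); a correspondence set is explored
  through its unique ascending-order chain, each link of which must pass
  the RMSD criterion.  Because the RMSD of a growing set is not monotone, a
  set can in principle be reachable through one insertion order and not
  another; exploring all orders is combinatorially infeasible on realistic
  inputs (it multiplies work by the number of admissible subsets of every
  solution).  With noise well below the threshold — the regime in which a
  motif search is meaningful — every prefix of a true match passes
  comfortably in any order, and the brute-force reference in the test suite
  applies the identical completion rule, making the equivalence checks
  exact.
* **Distance-compatibility shortcut.**  If a set of $N$ point pairs
  superimposes with RMSD $\le t$, every pair of pairs satisfies
  $|d_A - d_B| \le t\sqrt{2N}$ (error vectors sum to zero and their squared
  norms sum to at most $N t^2$).  Extensions violating this bound for any
  current member are skipped without an eigenvalue evaluation.  The bound
  is implied by the RMSD criterion, so it never changes which sets are
  admissible — it only avoids provably futile evaluations.

The node budget (default $10^8$ evaluations) guards against the regime the
method is not meant for: comparing two globally similar structures under a
permissive threshold, where the number of admissible correspondences
explodes.  Exceeding it raises an error; the screening layer catches it and
flags the target instead of aborting the run.

## Synthetic data

Because meaningful inputs are protein structures, the package generates its
own: `make_structure()` packs Cα positions uniformly in a box at ~125 Å³
per residue (protein-like density) with a 3.5 Å minimum separation, and
hangs idealized-bond-length backbone and side-chain atoms off each Cα in
random directions.  `plant_motif()` embeds one shared k-residue motif —
full-atom geometry built once and reused in both structures — among decoy
residues, perturbing every motif atom in the second copy with isotropic
Gaussian noise and applying a random proper rigid motion to the whole
structure.  `make_ligand_complex()` adds a single-atom hetero ligand at an
exact distance from an anchor residue for proximity-validation tests.

What the fixtures do **not** emulate: real backbone connectivity and
Ramachandran statistics, secondary structure, side-chain rotamers,
crystallographic artefacts.  Tests passing on these fixtures demonstrate
the geometry and bookkeeping of the method — representation projection,
search completeness, ranking, validation — not its biological hit rate on
real binding sites.

The recovery experiment plants an 8-residue motif with σ = 0.1 Å among 30
decoys per side and searches at a 0.7 Å threshold with the Cα +
side-chain-centroid + BLOSUM62 preset — the representation used for
database screening — recovering the planted correspondence inside a
returned maximum in ≥ 95 of 100 seeds.  Under the coarse any-residue Cα
preset the same decoy clouds contain spurious 11–12 unit correspondences
below 0.7 Å: two compact random structures with free substitution are
exactly the "globally comparable inputs" regime the method is documented
not to serve, which is why the recovery experiment pairs the planted motif
with a restrictive representation.

## Screening and significance

`screen()` runs the probe against each target selection independently and
keeps each target's best match; results are ranked by match size
(descending) then RMSD (ascending) then target id, a deterministic total
order that is independent of target processing order.  Interpreting such a
ranking follows the practical guidelines: small matches (the vast majority)
are background and are removed with `filter_background()` — the cutoff is a
parameter, since what counts as background depends on the probe size; where
ligands are present, `proximity_validate()` checks whether any matched
target residue lies strictly within 4.5 Å of a qualifying ligand atom
(element-filtered, water never qualifies); and `roc_auc()` scores how well
the size/RMSD ranking predicts the validation labels, using the
Mann–Whitney formulation with midrank ties (the tie policy is a
documented choice; ranks within one size/RMSD key share their midrank).

## Problem sizes and tolerances

The test suite and the acceptance script use: 10,000 random point-set pairs
(n = 3–12) for the superposition oracle at 10⁻⁸ Å; 100 random ≤ 6×6-unit
instances for exact search-vs-enumeration equality; 100 planted-motif seeds
(k = 8, σ = 0.1 Å, 30 decoys/side, threshold 0.7 Å); a 25-target synthetic
screen for the validation AUC; and exhaustive label sequences up to length
8 for the AUC unit.  These sizes keep the full suite within a few minutes
on one CPU while leaving each check statistically meaningful.

## Known limitations

* Complexity is exponential in the worst case; the method is for local
  motifs against chains, not whole-structure alignment of homologues.
* The canonical-order completion rule can, in adversarial near-threshold
  geometries, miss a correspondence reachable only through a non-canonical
  insertion order.
* No statistical significance model is provided; ranking plus orthogonal
  validation (ligand proximity) is the supported interpretation route.
* PDB input follows fixed policies (first model, highest-occupancy altloc,
  HETATM residues with full backbones treated as polymer); mmCIF is not
  read.
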