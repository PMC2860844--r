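---
title: "Building and analysing pMHC-I complexes with pmhcbuild"
author: "pmhcbuild maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and analysing pMHC-I complexes with pmhcbuild}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmhcbuild)
```

## The scientific problem

Cytotoxic T cells survey the proteome through short peptides (8–12
residues) presented in the binding groove of MHC class I molecules. The
bound peptide's main-chain conformation is not free: peptides presented by
one MHC allele adopt a shared, allele-specific backbone shape imposed by
the groove — its anchor pockets, the conserved bulge-inducing tryptophans
of the α1/α2 helices, and the hydrogen-bond network that clamps the
peptide termini. This observation has a practical consequence: if the
backbone of a new epitope is essentially dictated by the allele, a
peptide:MHC (pMHC) complex for *any* sequence of matching length can be
built by copying a crystallographic template backbone, rebuilding the side
chains, and letting a docking/relaxation protocol settle the details. The
resulting models can then be compared on the features a T-cell receptor
(TCR) actually sees — the solvent-exposed surface, its topology and its
electrostatic potential — to screen candidate epitopes for
cross-reactivity.

`pmhcbuild` implements this programme end to end:

1. **Pattern extraction** — superpose a set of same-allele complexes on
   their receptor Cα traces and summarise the peptide backbone as a
   per-position mean with an RMS dispersion; flag structural outliers.
2. **Construction (D1–EM–D2)** — thread a target sequence onto a template
   backbone, relax the new side chains, dock into a donor receptor,
   energy-minimise the selected complex, separate the partners and dock
   again.
3. **Cross-reactivity analytics** — per-position solvent-accessible
   surface area (ASA) signatures of the bound peptide, and TCR-face
   surface maps (heights above the cleft plane, Coulomb potential in kT/e
   clipped to ±10) with nearest-point comparison between complexes.
4. **Synthetic fixtures** — a deterministic generator of ideal-geometry
   peptides and toy MHC-like clefts, so the whole pipeline can be
   exercised and tested with no external structure files.

## The backbone pattern and its dispersion statistic

`extract_pattern()` fits every member complex onto a frame member using
only the receptor α-chain Cα atoms (matched by residue number), then
averages the peptide backbone (N, CA, C, O) per position. Published
descriptions of allele-specific patterns are qualitative — superposition
imagery; the formal object here adds a dispersion statistic: for position
*p*, the RMS over members and backbone atoms of the distance to the
per-position mean. For members perturbed by independent Gaussian
coordinate noise of standard deviation σ the expected per-atom
displacement is the 3-D χ distribution's RMS, σ√3; the test suite and the
acceptance script verify this closed form at σ = 0.3 Å (≈ 0.52 Å) on
populations of 1000.

`deviation_from_pattern()` flags exceptions. Published analyses flag
outliers (a synthetic peptide bulging out of the groove at p5, divergent
cancer-related peptides) without a numeric rule, so the package commits to
one: a complex is an exception when its overall backbone RMSD to the
pattern mean exceeds 2.0 Å — deliberately just inside the 2.2 Å bound used
to call a reconstruction valid — or when any single position deviates
beyond the member mean plus three member dispersions at that position.
Both thresholds are arguments.

One caveat discovered while formalising the dispersion: "adding an exact
copy of a member never increases dispersion" is *not* a theorem for RMS
dispersion (duplicating an extreme outlier can raise it); duplication is
only guaranteed neutral-or-contracting for members at or below the RMS.
The test suite therefore asserts permutation invariance and the
zero-noise/known-noise cases instead.

## Anchor composition

`composition_at()` counts residues and physicochemical classes at an
absolute position from the N terminus. The class partition is: nonpolar
{A,V,L,I,M,F,W,P,G}, polar {S,T,N,Q,Y,C}, positive {K,R,H}, negative
{D,E}; aromatics {F,Y,W} are reported as an overlay, not a fifth class.
On the packaged H-2Db ligand survey (28 distinct epitopes) this reproduces
the allele's anchor fingerprint: asparagine at p5 in 25 of 28 (the three
exceptions carry nonpolar residues there) and a nonpolar C-terminal
residue in 27 of 28 (one cysteine).

```{r anchors, eval = FALSE}
seqs <- h2db_sequences()
composition_at(seqs, 5)
composition_at_cterm(seqs)
```

## The scoring function

The potential is deliberately simple enough to verify by brute force; its
units are arbitrary "score units" and are **not** calibrated to any
docking engine's kcal/mol.

* **Sterics** — 12-6 Lennard-Jones on per-element σ/ε (C 3.4, N 3.25,
  O 3.0, S 3.6 Å), Lorentz–Berthelot combining, sharp 8 Å cutoff.
* **Electrostatics** — Coulomb on coarse formal charges (Lys +1, Arg +0.5
  ×2, Asp/Glu −0.5 ×2, His +0.05 ×2, termini ±1) with a
  distance-dependent dielectric ε = 4r (a constant-ε mode exists for the
  surface maps).
* **Hydrogen bonds** — a 10-4 well between donor and acceptor heavy atoms
  (depth 2.0, optimum 2.9 Å) weighted by max(0, −cos θ)² of the
  antecedent–donor–acceptor angle, so bonds fade below 90° and peak when
  linear. Crystal structures carry no hydrogens; this is the standard
  heavy-atom criterion, and the same geometry (≤ 3.5 Å, ≥ 90°) defines
  the discrete hydrogen bonds reported by `conserved_contact_report()`.
* **Torsions** — a staple penalty k(1 + cos 3χ) on side-chain χ angles
  (k(1 − cos 2χ) for the aromatic ring-flip torsion), keeping rotamers
  near the canonical −60/60/180 wells.
* **Restraints** — harmonic terms on bonded and 1–3 distances toward a
  reference geometry, used only by the minimiser.

`score_pose()` is intermolecular only; `internal_energy()` adds the
intramolecular terms with 1-2/1-3 exclusions. Every term is pairwise and
the test suite re-derives the totals with a naive double loop.

All parameters live in a packaged JSON file (`default_scoring_params()`),
and analytic gradients for every term (including the dihedral and angular
chain rules) are verified against numeric differentiation.

## Minimisation

`minimize()` is plain steepest descent with an Armijo backtracking line
search. Two numerical choices matter. First, the pair list is frozen at
entry (cutoff + 2 Å margin) and evaluated without cutoff truncation during
the run, so the objective is smooth and accepted-step energies are
non-increasing by construction — the sharp cutoff only applies to reported
scores. Second, convergence is declared at a gradient infinity-norm of
10⁻³ score units/Å, or when no decreasing step exists. Fixed atoms
(receptor backbone, peptide backbone during the protocol) never move.

## The D1–EM–D2 construction protocol

`run_d1_em_d2()` executes: thread → short relaxation of the threaded side
chains (backbone fixed) → first docking (D1) → long relaxation of the
selected complex (all backbones fixed, side chains of both molecules
free) → separation → second docking (D2). The receptor is never moved by
docking; relaxing the complex between the dockings is what lets the
receptor side chains adapt to the new ligand, and across seeds the median
D2 energy of the representative is at or below the median D1 energy.

Each docking runs `n_runs` replicate stochastic local searches from a
common deterministically refined start pose. A proposal perturbs the
current best pose of the run: a rigid-body move of the whole peptide
(≤ 1 Å translation, ≤ 10° rotation) and/or a chi-staple resampling of one
or two side chains with Gaussian jitter (σ = 20°), implemented as
geometry-preserving bond rotations; improving proposals are kept. Each
run's best pose is then refined deterministically — greedy chi-staple
scans (jointly over χ₁/χ₂ to escape single-flip traps, side chains before
rigid moves so clashes are not resolved by dragging the backbone out of
register) interleaved with axis line searches. The frequency analysis
operates on these per-run best conformations: greedy clustering at 1.0 Å
all-heavy-atom RMSD, largest cluster wins, ties and the within-cluster
choice resolved by energy and then by index. An energy-first switch
exists. The full pooled population is recorded in the result for
inspection.

Determinism: one master seed; each run draws from a stream derived by a
fixed offset, so results are bit-reproducible and adding runs does not
reshuffle earlier ones.

Defaults follow the published protocol scale: 20 runs × 50 retained
poses (a thousand-conformer population), short/long relaxations of
100/1000 steps. The test and acceptance runs use a scaled search — 3 runs
× 10 poses × 60 iterations with 50/100-step relaxations on a ~330-atom
toy complex — chosen as the smallest setting at which the planted-truth
recovery statistics are stable.

## What the synthetic fixtures emulate — and what they do not

`make_toy_cleft()` builds a rigid scaffold of GLY-like three-atom
pseudo-residues: a floor under an ideal-geometry peptide, two flanking
walls, closed groove ends (class I grooves are closed at both ends),
terminal anchors (a carboxylate coordinating the charged peptide
N terminus and an ammonium coordinating the C-terminal carboxylate — the
toy analog of the conserved A/F-pocket hydrogen-bond network that fixes
the bound register), and occluding anchor-pocket cages, by default at p5
and the C-terminal position as in H-2Db. Options add mid-cleft bulge
blockers that force the peptide to arc over them (the Trp73/Trp147-like
constriction) and a serine-like hydrogen-bond donor planted as receptor
residue 73 next to a chosen peptide position.

The planted peptide is settled into the scaffold's *ground state* by a
generous fixed-seed conformer search before the complex is returned. This
matters: a crystal structure sits in the minimum of the true physical
potential, and a planted-truth fixture is only meaningful if its pose is
likewise the minimum of the package potential. Without the terminal
anchors and pockets, a smooth groove supports near-degenerate minima
displaced along its axis and no docking method could single out the
planted pose.

What passing the planted-truth test shows: the protocol finds and selects
the global basin of its own potential from a threaded start, reproducibly
across seeds. What it does not show: that the potential ranks real
peptide poses the way nature does. The fixtures have no solvation, no
receptor flexibility beyond side chains, poly-glycine walls instead of a
real fold, and formal rather than partial charges. Validation against
real structures goes through `reproduce_crystal()`, which runs the
identical protocol on user-supplied PDB files and reports the
fit-receptor-Cα epitope RMSD against the 2.2 Å validity bound.

## Surface analytics

`shrake_rupley()` samples 960 deterministic golden-spiral points per atom
on the solvent sphere (Chothia-style radii, 1.4 Å probe); the isolated
atom reproduces 4πR² to machine precision of the sampling and two-sphere
overlaps match the spherical-cap closed form within 1%. `asa_signature()`
sums whole-residue atom areas per peptide position with the receptor
present; `burial_profile()` divides side-chain ASA by the free-residue
reference (the same residue in an extended Ala-X-Ala tripeptide; glycine
uses its CA as surrogate) and classifies buried < 0.1 < intermediate
< 0.4 < exposed.

`surface_potential()` keeps unoccluded sphere points facing "up" relative
to the cleft reference plane — a least-squares plane through the receptor
Cα atoms, oriented toward the peptide — within 12 Å of the peptide, and
evaluates the formal-charge Coulomb potential at each point in kT/e
(332.06 kcal·Å/(mol·e²), kT = 0.593 kcal/mol), clipped to ±10. The
clipping follows the published ±10 display scale (whose "kiloteslas" unit
label we read as kT/e; teslas measure magnetic flux density) and bounds
the potential-RMS comparison. `compare_surfaces()` matches nearest points
within 1.5 Å between two maps in a common frame and reports topology RMS
(heights), potential RMS and the matched fraction.

## Degenerate inputs and tie-breaks

* Superposition refuses fewer than 3 points and collinear sets (the
  rotation is underdetermined); reflections are corrected so det(R) = +1.
* Splitting a structure refuses zero or multiple 8–12-residue chains and
  peptides with incomplete backbones (mirroring the curation rule that
  excludes incomplete epitopes).
* Threading refuses length mismatches and non-canonical residues on
  either side; the packaged survey marks such entries so they are
  filterable upstream.
* Clustering visits conformers by increasing energy, so the medoid set is
  deterministic; all remaining ties fall back to the lower index.
* Alternate locations keep blank or 'A'; insertion codes sort after their
  base residue number in file order.

## Known limitations

The potential is desk-scale, with no solvation or polarisation; energies
are comparative, never binding free energies. Backbone flexibility is
limited to what the relaxations allow (none, under the default fixed
backbones) — by design, since the premise is that the allele pattern
fixes the backbone. Receptor pseudo-atom fixtures cannot detect
force-field pathologies that only a real fold would expose. The
rotamer library is a minimal staple set, not a backbone-dependent
library; aromatic ring flips are handled, but rare non-staple rotamers
are reachable only through the jitter.
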