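---
title: "Covalent screening at an anchor cysteine: models, parameters and design choices"
author: "cyslock"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Covalent screening at an anchor cysteine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyslock)
```

This vignette is the package's own account of the science it implements: the
covalent-docking model and its assumptions, the tunable parameters and why
their defaults are what they are, what the synthetic generators emulate, and
the numerical and design choices made where the problem left them open.

## The covalent-docking model

A Michael acceptor reacts with a cysteine thiol by conjugate addition: the
thiolate attacks the terminal (beta) carbon of an electron-poor C=C, the
alpha carbon picks up the thiol proton, and the entire ligand ends up bonded
to S-gamma with no leaving group. `applyMichaelAddition()` encodes exactly
that transform on the molecular graph, which has two consequences the rest of
the package relies on:

* the adduct's mass shift equals the neutral monoisotopic mass of the intact
  parent compound (`massDelta()`), which is what an LC-MS/MS experiment
  observes on the modified tryptic peptide; and
* the pose search is a search over conformations of a *tethered* molecule:
  the only rigid-body freedom left is rotation about the new S–C bond, so an
  exhaustive torsion scan is feasible where free docking would need a
  stochastic search.

`placeAnchor()` realizes the attachment geometry from internal coordinates
(NeRF chain extension over a breadth-first tree from the beta carbon):
idealized bond lengths by element pair, tetrahedral or trigonal angles by
hybridization, and planar-polygon closure for rings. The S–C(beta) vector
starts anti to the cysteine's S–CB bond — the direction that maximizes
distance from the receptor — and the receptor is held rigid throughout,
including the cysteine chi angles. Kekulized aromatic rings close exactly
under this construction (an equiangular hexagon with alternating sides closes
whenever opposite sides differ equally, which alternating single/double bond
lengths satisfy); fused polycycles are placed by the same rules and are only
approximate, a known limitation.

`enumerateConformers()` drives every rotatable bond through the full circle
in constant increments, lexicographically over the breadth-first bond
ordering, truncating at a cap. A bond is rotatable when single, acyclic and
non-terminal; amide C–N bonds are held planar (a convention, not a
measurement); the anchor S–C bond is always rotatable and always first.
Determinism is bit-for-bit: rotations are pure arithmetic on the built
coordinates.

### Scoring

Poses are scored pocket–ligand only (no intramolecular ligand term) with the
two classical nonbonded terms:

$$E = w_{es}\sum_{ij}\frac{332.0637\,q_iq_j}{\varepsilon_r\,r_{ij}}
    + w_{vdw}\sum_{ij}4\bar\epsilon_{ij}\left[
      \left(\tfrac{\bar\sigma_{ij}}{r_{ij}}\right)^{12}-
      \left(\tfrac{\bar\sigma_{ij}}{r_{ij}}\right)^{6}\right]$$

with Lorentz–Berthelot combining (arithmetic $\bar\sigma$, geometric
$\bar\epsilon$). No separate clash term exists or is needed: the $r^{-12}$
wall makes any overlapping pose strongly positive, and favorable
electrostatic/dispersion contacts make good poses negative, so ranking by the
minimum total per compound is meaningful. The anchor S-gamma and its CB are
excluded from the sums — they are covalently bonded to the ligand and would
otherwise contribute a spurious huge repulsion at bonding distance.

Tunable parameters, defaults, and rationale:

| parameter | default | units | why |
|---|---|---|---|
| dielectric $\varepsilon_r$ | 4 | — | distance-independent screen typical for buried, partly desolvated pockets |
| term weights $w_{es}, w_{vdw}$ | 1, 1 | — | unweighted sum; exposed because the right balance is system-dependent |
| pair cutoff | 12 | Å | beyond this both terms are negligible at these charges |
| pocket radius | 10 | Å | covers the groove lining an anchored fragment can reach without engulfing distal sites |
| S–C bond length | 1.81 | Å | standard thioether C–S distance |
| torsion increment | 30 | ° | 12 states/bond: a 2–3-bond warhead ligand lands in the hundreds of conformers, the intended scan scale |
| conformer cap | 10000 (screens use 1000) | — | bounds worst-case combinatorics deterministically (lexicographic truncation) |
| clash threshold | 1.2 | Å | below any plausible nonbonded contact; removes only self-intersecting poses |

### Parameters and charges

Protein atoms take charges from a packaged united-atom-style table (heavy
atoms only, polar-hydrogen charge folded into the bearing atom, residues sum
to their formal charge exactly) and element-typed Lennard-Jones parameters.
This is a deliberately compact, self-contained set: absolute energies are
*not* comparable to programs using all-atom commercial preparation tools, but
rankings over one fixed pocket — the quantity the screen uses — are
well-defined. The table ships as `inst/extdata/residue_params.tsv` and any
table with the same columns can replace it.

Ligand partial charges come from the iterative partial equalization of
orbital electronegativity (PEOE, the Gasteiger–Marsili scheme): six damped
iterations of charge transfer along bonds driven by electronegativity
differences, run over the implicit-hydrogen-expanded graph and collapsed back
onto heavy atoms. The scheme is deterministic, conserves total formal charge
to machine precision, and its constants are packaged in code.

### The screen

`runScreen()` uses each compound's *first* detected warhead (lowest
beta-carbon index); compounds with none are recorded `no_warhead` and stay
out of the ranking, and any per-compound failure is recorded, never fatal.
The ranking sorts scored compounds by ascending best total with lexicographic
id tie-break, and `selectTopFraction()` takes the first
$\lceil f\,n_{scored}\rceil$ ids — ceiling keeps small libraries non-empty,
and for the canonical 10 % of 120 the count is 12 either way. Raw best totals
are ranked, not size-normalized scores; the alternative (per-atom
normalization) is a one-line change on the records table and was left out to
keep the ranking the plain argmin the model defines.

## Trajectory clustering

`clusterFrames()` partitions evenly extracted C-alpha frames with k-medoids
(PAM) on the pairwise superposed-RMSD matrix — superposition is a Kabsch fit
with the determinant corrected so only proper rotations occur. PAM was
chosen over k-means because the metric is an RMSD matrix (no coordinate
averages exist) and because the medoid *is* the representative structure a
pocket-discovery workflow inspects. The PAM build/swap procedure is
deterministic, so results do not depend on a seed; the `seed` argument exists
for interface stability and is documented as inert. Clusters are renumbered
by descending occupancy with the lower medoid index breaking ties, occupancies
are exact cluster fractions and sum to 1 by construction.

Frames travel as multi-model PDB — desk-scale and dependency-light. The
tests run 100–200 frames of 10–40 residues; the algorithms are quadratic in
frame count, so production-scale inputs (tens of thousands of frames) should
be thinned through `extractEvenFrames()` first.

## Validation computations

Masses are sums of packaged IUPAC atomic masses (monoisotopic and standard
weights); peptide masses add one water to the residue-formula sum, keeping
the two code paths formula-additive and mutually consistent to 1e-9 Da.
Tryptic digestion cleaves C-terminal to K/R except before P. Adduct matching
converts a ppm tolerance to Da on the *unmodified peptide* mass, which is the
scale the instrument's error applies to.

CSP combines the amide shifts as
$\sqrt{\Delta\delta_H^2+(w_N\Delta\delta_N)^2}$ with $w_N = 0.2$, the common
1H/15N scaling convention (conventions between 0.1 and 0.2 circulate; the
weight is an argument). A residue counts as perturbed when CSP strictly
exceeds the 0.05 ppm threshold or its peak is attenuated; "attenuated" is
operationalized as a bound/apo intensity ratio below 0.2 or outright absence
from the bound list, since "the peak disappeared" needs a numeric criterion
to be testable. The strict inequality at the threshold is deliberate and
tested.

## What the synthetic generators emulate — and what they do not

The generators produce inputs with the *shapes and contrasts* of the real
study desk-scaled: a pocket of 8 residues rather than a protein, 120
compounds spanning the five warhead classes on inert tails, 100-frame
two/three-state trajectories rather than 20000-frame ensembles, 180-residue
peak lists with designed perturbed segments (64–78 and 90–113 by default).
Within-state noise is Gaussian and isotropic; states are independent random
coils redrawn until their pairwise RMSD exceeds the separation, so a 10:1
separation-to-noise ratio *guarantees* perfect cluster recovery. Passing
tests on these fixtures therefore demonstrates algorithmic correctness —
energy sums match naive references, enumeration counts match the torsion
product, partitions match generation labels — not predictive accuracy on
real proteins: real trajectories have overlapping states, real peak lists
have missing assignments and peak overlap, and real ligand geometries are
not ideal-valence constructions.

## Numerical choices and degenerate inputs

* Coordinates parse and write at 0.001 Å (PDB precision); round-trips are
  exact at that resolution.
* Alternate locations other than blank/'A' are dropped; insertion codes are
  rejected with a structure error rather than silently renumbered.
* Half-way values in even frame extraction round up (`floor(x + 0.5)`), so
  the kept-model indices are platform-independent.
* Conformer and cluster indices are 1-based throughout, as is idiomatic in R.
* Collinear NeRF reference frames (the S–CB–C-beta start is collinear by
  construction) fall back to a fixed perpendicular; the torsional freedom
  this absorbs is exactly the anchor-bond rotation the scan explores anyway.
* A zero interatomic distance in the Lennard-Jones term is a singular-geometry
  error, not an Inf that would silently poison a ranking.
* Ties: `bestScore()` takes the lowest conformer index; rankings break score
  ties lexicographically by compound id; cluster renumbering breaks occupancy
  ties by medoid index. Every tie-break is deterministic and tested.

## Known limitations

* The scoring function has no solvation, hydrogen-bond, torsional-strain or
  entropy terms, and its absolute values are tied to the packaged parameter
  set; it ranks tethered poses in one pocket, nothing more.
* The receptor is rigid; cysteine chi angles are not sampled.
* Geometry is idealized (no energy minimization); fused-ring systems are
  approximate.
* One warhead per compound per screen (the first by beta-carbon order);
  covalent chemistries other than Michael addition — SN2 displacement,
  disulfide exchange — are out of scope.
* The conservation screen reads one alignment column; it does not build
  alignments or assess structural equivalence of the column.

## Problem sizes used by the tests

The shipped test-and-acceptance runs use: 120-compound screens at 30°
increments with a 1000-conformer cap against an 8-residue pocket (about half
a minute), 100-frame trajectories of 40 residues for clustering, and
180-residue peak lists — sizes chosen so the full suite exercises every
pipeline end to end in a couple of minutes on one core while keeping the
combinatorial quantities (conformer counts, occupancies, segment bounds)
exactly checkable.
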