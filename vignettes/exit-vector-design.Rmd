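---
title: "Exit-vector design of bifunctional cyclopropane building blocks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exit-vector design of bifunctional cyclopropane building blocks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The design problem

Fragment-based drug discovery grows small, mostly flat (2-D) fragment hits
into lead-like molecules by adding chemical matter along spatial vectors.
The bottleneck is synthetic: elaboration in three dimensions, from sp3
carbons, is rarely worked out in advance. One answer is a fixed repertoire
of rigid *bifunctional* linker scaffolds, each presenting two orthogonal
attachment points - a cyclopropane carbon (C1) that receives the aryl
fragment and a ring nitrogen (N2) that receives a capping group - so that
every scaffold displays the two substituents along a characteristic pair of
exit vectors.

This package implements the computational half of that strategy:

1. **Enumerate** every distinct scaffold combining a small cyclic amine
   (azetidine, pyrrolidine, piperidine) with a fused or spirocyclic
   cyclopropane bearing a substitutable handle carbon.
2. **Elaborate** each scaffold virtually: an aryl fragment bonded at C1
   (the in-silico surrogate of a Suzuki-Miyaura coupling of a boron
   handle) and a cap bonded at N2 (sulfonylation, acylation, alkylation or
   arylation).
3. **Embed** each product in 3D and keep its lowest-energy conformer.
4. **Measure** the exit-vector parameters and assemble the r-vs-theta
   plot table.
5. **Profile** lead-likeness and select diverse subsets.

## The exit-vector parameters

For the four tracked atoms - cap attachment atom ("red"), N2 ("orange"),
C1 ("green"), fragment attachment atom ("blue") - the geometry of the
elaborated compound is summarized by

* **r**: the through-space Euclidean distance C1...N2 in Angstrom, and
* **theta**: the dihedral angle between the plane containing the N2 exit
  vector and the C1-N2 axis and the plane containing the C1 exit vector
  and that axis; computed as the four-point torsion red-orange-green-blue
  and reported unsigned in [0, 180] degrees.

theta is reported unsigned because compounds are racemic or meso and only
one enantiomeric series belongs on the plot; a signed torsion would split
each racemate into two mirror points. A `fold = "90"` option additionally
folds obtuse angles back, for users who prefer axis-agnostic comparisons;
the default is the unsigned [0, 180] convention.

Degenerate inputs (coincident C1/N2, collinear atom triples) raise errors
rather than returning NaN, because a silent NaN would drop points from the
plot table unnoticed.

## Enumeration universe and stereochemical conventions

The enumeration is brute force by construction: every C-C edge of the
amine ring as a fusion bond, every ring carbon as a spiro centre, every
substitutable cyclopropane carbon as the handle position, and every
realizable relative configuration - followed by deduplication on a
canonical identity. Identity is the InChI of a bromine-probe form (a Br
atom bonded at C1 so the handle orientation is stereogenic) with the
absolute-stereo layers (/m, /s) stripped: diastereomers stay distinct,
enantiomeric pairs collapse to one representative. Deduplication therefore
also absorbs the ring-symmetry duplicates (e.g. fusing at the 2,3- and
4,5-bonds of pyrrolidine gives the same scaffold).

Three chemical conventions shape the stereo enumeration; all three are
encoded as written parities in the SMILES templates and are validated
against embedded 3D geometry in the test-suite:

* **cis fusion only.** A cyclopropane trans-fused to a 4-6-membered ring
  is prohibitively strained; junction parities are fixed cis, and a
  substituent replacing a junction hydrogen inherits the single
  orientation the cis fusion allows.
* **apex substituents exo by default.** On a fused bicycle the
  cyclopropane apex has two faces; the endo face points back over the
  amine ring and is both strained and synthetically inaccessible (the
  debromination chemistry that installs apex handles is exo-selective).
  `apex_stereo = "both"` enumerates the endo series as well (adding the
  five endo diastereomers).
* **spiro faces both enumerated.** A handle on a spiro cyclopropane
  methylene can sit syn or anti to the ring nitrogen; both faces are
  accessible and are kept whenever the spiro pattern makes them distinct
  diastereomers (at symmetric spiro positions the two faces are
  equivalent and collapse).

Under these defaults the count is 26 (fused: 3 azetidine + 5 pyrrolidine +
6 piperidine; spiro: 3 + 4 + 5), matching the theoretical set the nine
packaged building blocks were selected from, and `augment_with_tropane()`
appends the one tropane-based scaffold (a piperidine carrying an ethano
bridge, cyclopropane spiro at the carbon para to nitrogen, anti to the
bridge) for 27. The convention choice is genuinely open - counting the
endo apex series *instead of* the spiro faces also lands on 26 - but only
the defaults are consistent with the packaged blocks: the two spiro
pyrrolidine diastereomers (1d/1e) are distinct registry entries, and the
apex-handle blocks (1g-1i) are exo. `enumeration_cells()` exposes the
per-cell counts so a convention disagreement is localized rather than
hidden.

Two registry conventions are package choices where the source material is
silent: the syn/anti labels of the 1d/1e spiro diastereomer pair, and the
exo orientation of the boron-bearing carbon of the tropane block (the
anti-to-bridge face of its cyclopropane is fixed by the documented
carbene selectivity; the substituent orientation on that carbon is chosen
as the lower-energy exo form). Neither choice affects counts, matching,
or the span of r.

## Attachment-point bookkeeping

Structures are annotated SMILES: atom map 1 marks C1, map 2 marks N2, and
after elaboration map 3 marks the fragment atom bonded to C1 and map 4 the
cap atom bonded to N2. Where the handle carbon is a stereocentre its
replaceable hydrogen is written as an explicit `([H])` branch directly
after the atom's ring-closure digits; substitution then splices the new
bond into exactly that neighbour slot, so the written tetrahedral parity
is preserved without any re-perception. Caps are stored as complete
substituents bonded through their attachment atom (methanesulfonyl through
sulfur, acetyl through the carbonyl carbon), hydrogen-completed so every
registry entry is a valid molecule; elaboration therefore obeys strict
mass balance (product MW = sum of parts minus one H2 per bond formed).

## Conformers

`embed_and_minimize()` runs, per compound:

1. up to `n_confs = 200` seeded distance-geometry embeddings (ETKDG),
   pruned at 0.5 Angstrom heavy-atom RMSD (rigid bicyclics typically
   retain well under 30 distinct conformers);
2. MMFF94 minimization of every conformer (500 step cap), with UFF as the
   fallback for atoms MMFF94 cannot parameterize;
3. energy scoring and selection of the minimum (ties break to the lowest
   index). No Boltzmann weighting: downstream geometry uses the single
   lowest-energy conformer.

The embedding runs through the system RDKit as a subprocess because it is
the only seedable distance-geometry engine available on this stack; the
OpenBabel builder draws unseedable random numbers, which would break the
package's reproducibility contract (identical seed, identical energy
list, byte-identical pipeline reruns). When no python/RDKit is present
the OpenBabel builder plus a systematic rotor walk is used instead, with
a warning that results are then not reproducible bit-for-bit.

Crystallographic or other externally determined coordinates enter the
same analysis via `load_coordinates()`; multi-model files yield one
conformer per model and *all* models are measured (a crystal's asymmetric
unit can hold several distinct conformations, each a legitimate point on
the plot), whereas computed ensembles contribute only their lowest-energy
member.

Reproducibility across *different* force fields or embedding engines is
only claimed at the level of the measured geometry (about +-0.2 Angstrom
in r, +-15 degrees in theta), never at the coordinate level.

## Properties and filters

* MW uses standard average atomic weights of the neutral parent.
* clogP is an open atom-contribution (Crippen-type) estimate. Different
  estimators disagree by a few tenths; cross-method comparisons should
  allow about +-0.5. With this estimator the tropane scaffold sits at
  2.01, a hair over the Rule-of-Two bound that proprietary calculators
  place it under.
* Fsp3 is the fraction of carbons engaged only in single bonds.
* Filters follow the printed inequalities verbatim: Rule-of-Two strict
  (MW < 200 and clogP < 2); lead-like with inclusive mass bounds and
  strict lipophilicity bounds (200 <= MW <= 350, -1 < clogP < 3).

## Diversity selection

`diversity_select()` picks k compounds spread in normalized (r, theta)
space (r scaled by its observed range, theta by 180). The objective is
maximin - maximize the smallest pairwise distance in the selected subset.
Small instances are solved exactly by exhaustive search (so, e.g., three
collinear points at k = 2 always return the two extremes); larger ones
use the standard greedy construction seeded at the point closest to the
centroid. A pure greedy cannot satisfy the extreme-point behaviour (its
centroid seed is the middle point), which is why the exact route is the
primary one. All ties break deterministically on compound ids.

## What the fixture generator emulates - and what it does not

`generate_fixtures()` decorates random enumerated scaffolds with random
small substituents (methyl, fluoro, amino, methoxy, cyano, phenyl,
hydroxymethyl) at both variation points, seeded and byte-reproducible. It
stresses the elaboration, conformer and profiling machinery with
chemically valid but arbitrary molecules. It does not emulate real
medicinal-chemistry substituent distributions, tautomerism, ionization
states, or synthetic accessibility - so green tests on fixtures certify
the machinery, not the drug-likeness of any particular virtual compound.

## Problem sizes

The full design run used throughout the documentation is 27 scaffolds x 1
fragment (pyrimidin-5-yl) x 4 caps = 108 products; the focused series is
the nine building blocks x pyrimidin-5-yl x methanesulfonyl (the
crystallographically characterized sulfonamide series), which completes -
enumeration, elaboration, 200-embedding conformer generation and vector
measurement - in well under a minute on one CPU. The test-suite uses the
nine-compound series plus ring-size-restricted pipeline runs.

A note on the published library size: 27 scaffolds x 4 caps is 108 by
plain arithmetic, while the source study reports 112 virtual compounds
from the same grid; the extra four presumably stem from a
diastereomer-handling convention documented only in that study's
supporting information. The package reports its own count together with
the per-cell scaffold table and does not force the published number.

## Known limitations

* Conformers come from a force-field protocol; no solvation, no crystal
  packing. Crystal-structure geometries can differ from the computed
  lowest-energy conformer (that is why supplied coordinates are
  first-class inputs).
* clogP is estimator-dependent; filter outcomes within ~0.5 of a bound
  should not be over-interpreted.
* The enumeration universe is exactly the stated one: rings 4-6, one
  cyclopropane, fused or spiro, plus the fixed tropane augmentation.
  Larger rings, difluorocyclopropanes and alternative boron handles are
  out of scope.
* Stereo bookkeeping relies on the package's own SMILES templates; user
  registries must follow the same annotation conventions (documented in
  `load_registry()`).
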