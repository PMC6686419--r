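---
title: "Torsion parameter refitting and conformer recovery: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Torsion parameter refitting and conformer recovery: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(torsionforge)
```

## The model

The torsional energy of an atom quadruple *i-j-k-l* is the three-term
cosine series

$$E_T(\varphi) = \tfrac12\left(V_1(1+\cos\varphi) + V_2(1-\cos 2\varphi)
  + V_3(1+\cos 3\varphi)\right)$$

with barrier heights in kcal/mol. Two analytic anchors follow directly and
are used throughout the tests: $E(0) = V_1 + V_3$ and $E(180) = 0$. A
positive twofold term $V_2$ therefore *stabilizes* the planar arrangements
(0° and 180°) and penalizes the perpendicular ones — this is how a large
$V_2$ on the aryl–amide quadruple forces N-aryl amides planar, and why
lowering it (6.0 → 2.7 for the wildcard entry) flattens the barrier. A
negative $V_1$ breaks the cis/trans degeneracy toward the 0° conformation,
which is how the amidothiophene S···O chalcogen preference is emulated
without anisotropic electrostatics.

Parameter records are keyed by (torsion type, quadruple) with the torsion
type treated as an opaque integer: its perception from bond orders belongs
to the calling force-field engine, not to the parameter table. Records are
stored in a canonical orientation ($j<k$, or $j=k$ and $i\le l$); lookups
canonicalize the query and resolve in three stages (exact; one-end
wildcard; both-end wildcard), which reproduces the use of the `0-10-37-0`
wildcard for phenyl amides while remaining deterministic. The internal
energy unit is kcal/mol; kJ/mol is a presentation unit with the conversion
fixed at exactly 4.184.

## TorsionID

A TorsionID is a canonical string for the local environment of a rotatable
bond. Assignability is the conjunction of four conditions: single bond,
non-aromatic, not a member of a ring of five or fewer atoms, and a
definable dihedral (at least two neighbours on each endpoint). Taken
literally, this admits bonds inside 6- and 7-membered non-aromatic rings;
such torsions are not driven by the conformer generator (ring
conformations are never altered), but they do receive identifiers. We kept
the literal rule rather than silently tightening it.

The encoded fragment is the central bond plus every directly bonded atom,
hydrogens included; when the bond belongs to a consecutive chain of
sp-hybridized linear atoms, the whole linear run plus both chain-end atoms
and their substituent shells is included. Each atom contributes its
element, formal charge, aromaticity, sp²-nitrogen flag, and its
hydrogen-inclusive neighbour count in the *parent* molecule; each bond its
order, with delocalized bonds flagged. The rendered grammar is linear and
reversible:

```
side [ center ] side          side   := atom ( sub , sub , ... )
sub  := bondtok atom          atom   := El[charge][^a][^2]:nK
bondtok := - = # ~            center := bondtok (atom bondtok)*
```

with `~` marking delocalized bonds and `{p-b-q}` suffixes for the rare
induced bonds not on the written tree (e.g. cyclopropyl substituents).
Canonicalization sorts substituents lexicographically and takes the
smaller of the two central-bond directions, so the string is independent
of atom input order. `decodeTorsionId()` inverts the grammar exactly;
`encodeTorsionId(decodeTorsionId(s)) == s` for canonical strings.

Stereochemistry: the descriptor is restricted to E/Z on double bonds
inside the fragment, since only bond-local stereochemistry can affect a
torsion environment at this radius. At radius one, however, a fragment
double bond never carries reference neighbours on both ends *inside* the
fragment, and sp-chain axial arrangements are atom-axis chirality, which
is out of scope — so no stereo token ever applies and the grammar omits
them. This is a property of the chosen fragment radius, not a parser
limitation.

Perception rules feeding the descriptor:

* **Aromaticity** is decided per simple ring of at most 7 atoms using
  Hückel's 4n+2 count (ring atoms with a ring double bond contribute one
  electron; saturated N/P and O/S/Se contribute a lone pair; an atom whose
  only multiple bond is exocyclic contributes zero; a saturated neutral
  carbon blocks the ring). Larger rings — cyclooctatetraene is the test
  case — are never aromatic.
* **Delocalized bonds** are the bonds of 6-membered aromatic rings; the
  bonds of 5-membered heteroaromatics are deliberately not flagged, so a
  pyrrole ring encodes with explicit orders while benzene encodes with
  `~`.
* **sp² nitrogens** are aromatic N, amide N, enamine N, and N bonded to an
  aromatic ring atom. The resonance condition is suppressed when both
  ortho ring positions of the attachment atom carry non-hydrogen
  substituents — a topological proxy for steric inhibition of planarity,
  chosen because no geometric test is available on a graph. The enamine
  and amide conditions require a non-aromatic carbon, otherwise every
  Kekulé structure of an aniline would fire the enamine rule.

## Symmetry-corrected deviations

Each end of a rotatable bond is classified topologically: D3 when its
three non-central branches are pairwise equivalent, D2 when a planar-type
end (aromatic, sp²-N, or multiply bonded) carries two equivalent branches,
D1 when the branch pattern admits a mirror that makes the torsion profile
even (a single branch; an equivalent pair on a non-planar end; an
equivalent pair among three branches), and C1 otherwise. Branch
equivalence is decided exactly, by graph automorphisms that fix the
central bond, with vertex colours from element and charge and edge colours
from bond order — aromatic bonds share one colour so that Kekulé
alternation cannot break a ring flip. D3 collapses to D1 for pair
classification, giving six pair classes.

Raw deviations $\varphi \in [-180, 180]$ are mapped by the literal
piecewise functions per class ($\varphi+360$ below zero for C1C1/C1D1;
$\varphi+180$ below zero for C1D2; $|\varphi|$ for D1D1; for D1D2/D2D2
$\varphi+180$ below zero and $180-\varphi$ above 90, with the undocumented
0–90 branch taken as the identity — the unique choice that closes the
[0, 90] fundamental domain of a twofold-plus-mirror symmetry). Because the
literal C1C1 map sends a −10° deviation to 350°, threshold tests use the
*effective* deviation instead: the distance from the reference angle to
the nearest symmetry image of the predicted angle, with fold periods
360/360/180/180/90/90 for the six classes and mirror images included for
classes containing a D1 end (D1 *is* the mirror symmetry; D2 contributes
pure rotations, which is what makes a 170° deviation fold to 10° for a
D2D2 biaryl). Both values are exposed; the 30° wrongness test uses the
effective one. The effective deviation is a pseudometric bounded by half
the fold period, verified against explicit image enumeration in the test
suite.

## Conformer pipeline

Rotatable bonds for generation are the assignable acyclic bonds; ring
internal coordinates are never altered. Each bond takes values on the 30°
grid; when the full grid $12^n$ fits under the 1000-conformer cap it is
enumerated exhaustively, otherwise distinct assignment vectors are sampled
without replacement under an explicit seed (distinctness is enforced on
assignment vectors, not on coordinates, since minimization collapses
basins anyway). Driving a dihedral rotates the smaller side of the bond
about its axis; ties go to the side containing the lower atom index. Both
choices are arbitrary but deterministic, which is what reproducibility
requires.

Minimization is delegated to a pluggable engine receiving the schedule
(300 conjugate-gradient then 5000 L-BFGS steps) and the dielectric
constant (4). The shipped torsion-only engine evaluates the cosine series
over every quadruple of every rotatable bond and minimizes over the
rotatable dihedrals only, exploiting that all other internal coordinates
are rigid under torsion driving; it ignores the dielectric (it has no
electrostatics) and never returns a higher energy than its input. Engine
failures downgrade individual conformers to a failed status and are
counted, never raised collectively. Conformers within 10 kcal/mol of the
ensemble minimum are the low-energy pool.

Best RMSD to a reference conformation is heavy-atom only and minimized
over graph automorphisms (element- and normalized-bond-order-coloured), so
a phenyl flip or methyl rotation never inflates the deviation; neither
choice is universal in the literature, so both are stated here rather than
asserted as anyone else's. Superposition is the standard SVD solution with
reflection correction, cross-checked in the tests against an independent
implementation. Recovery tables report the cumulative fraction of
successfully processed molecules under each RMSD threshold plus the
failure rate.

## Parameter fitting

The merit function is the RMSD between the model and reference profiles
after both are shifted to a zero minimum — profiles are relative
energies, so absolute offsets carry no information. References in kJ/mol
are converted on construction. The model profile is linear in
$(V_1, V_2, V_3)$, which the fitting code exploits by precomputing a basis
matrix per reference; repeated quadruple rows (the same environment
occurring several times on one bond, or with angular offsets between the
contributing dihedrals) simply add basis columns.

The systematic mode refits a single quadruple by exhaustive search on a
0.1-step grid over the free components within ±15 kcal/mol — bounds that
cover every refitted magnitude (max |V| = 11.5) with margin. Ties are
broken toward the smaller total magnitude, then lexicographically. The
free set follows the published convention: V₂ alone for most quadruples,
with V₁ added when the cis/trans gap (`cisTransGap()`, $E(0)-E(180)$)
cannot be reproduced otherwise. Whether the published search stepped the
components jointly or one at a time is not stated; we take the Cartesian
product over the declared free set, which subsumes both readings.

The GA mode minimizes the summed merit over several references jointly.
No hyperparameters were published, so the defaults are our own and are
configurable: population 60, 300 generations, tournament selection (k=3),
uniform crossover with probability 0.7, Gaussian mutation with σ = 0.25
kcal/mol clipped to the bounds, 2 elites, and a mandatory explicit seed;
with a fixed seed the result is bit-identical across runs. Elitism makes
the best fitness per generation non-increasing, which the tests assert.

## Synthetic data and what the tests do and do not show

The synthetic PES generator (`synthPes()`) sums the cosine series over
given triples — written out independently of the model evaluator so the
two code paths check each other to 10⁻¹² — optionally adds seeded
Gaussian noise, and min-shifts. It emulates the *shape* of
quantum-chemistry torsion scans but none of their physics: no coupling to
bond/angle relaxation, no nonbonded 1–5 interactions, no basis-set or
correlation error. Parameter-recovery tests on this generator therefore
demonstrate that the fitting machinery inverts its own forward model (to
within grid resolution for the systematic mode, 0.05 kcal/mol for the GA),
not that refitted values would match ab initio scans of real molecules.
Similarly, the end-to-end benchmark property — recovery at 0.5 Å
approaching 1 as the ensemble grows when the engine that generated the
reference conformation also scores the candidates — validates the
pipeline's plumbing, not any force field's accuracy on protein-bound
conformations, which would require the external benchmark dataset and full
force-field engines.

Fixture molecules are analogues of the compound families discussed above
(N-aryl amides with phenyl, pyridyl, thiophene, pyrrole-type rings;
phenylpyrrole and phenylpyrazole; ortho-substituted and N-methylated
variants; toluene and biphenyl as symmetry references). Their 3D
coordinates were embedded once with a standard builder and frozen as SDF
so tests are bit-stable; their ground-truth annotations (assignable bond
counts, end symmetries, key quadruple types) were assigned by hand from
the connection tables.

## Numerical choices and problem sizes

* Dihedral angles in degrees throughout, wrapped to (−180, 180];
  periodicity asserted to 10⁻⁹.
* Minimizer convergence beyond the step counts: L-BFGS `factr` 10⁴ and
  gradient tolerance 10⁻⁸ on the torsion-space objective.
* The test suite runs the symmetry oracle on ~1700 random cases per pair
  class (10,200 total), parameter recovery on 100 random systematic fits
  plus one seeded GA fit, and the end-to-end benchmark on ensembles of 2
  and 80 conformers over four seeds with a shortened minimizer schedule
  (50 CG + 500 L-BFGS steps); these sizes keep the full suite around half
  a minute while exercising every code path. The GA property tests use 60
  generations where convergence history, not accuracy, is under test.

## Known limitations

* The original-parameter table ships only the wildcard triple whose
  numeric values we can state with confidence; the historical entries for
  `0-37-39-0`, `0-63-10-0` and `0-64-10-0` exist in full MMFF94s
  distributions but are not reproduced here, so lookups against the
  original table for those environments raise a missing-parameter error
  rather than guessing.
* Atom typing covers exactly the types used by the shipped tables (3, 10,
  28, 37, 39, 44, 63, 64, 65, 66); everything else is NA, and the
  torsion-only engine treats untyped quadruples as zero-energy by
  default.
* End-symmetry classification is topological. A geometrically pyramidal
  nitrogen that our perception flags planar (or vice versa) would shift a
  D2 to D1; exotic cases of mirror symmetry not visible to branch
  automorphisms are classified C1.
* The TorsionID rendering is one faithful realization of the descriptor
  content; string equality with other implementations of the same idea is
  not claimed.
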