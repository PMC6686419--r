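# torsionforge

Force-field minimization is the workhorse of small-molecule conformer
generation, and the quality of the generated geometries hinges on the
torsion-angle term. `torsionforge` is an R toolkit for analysing and
refitting that term in MMFF94s-style force fields. It grew out of the
observation that the stock MMFF94s systematically mispredicts two
pharmacologically common environments — *N*-aryl amides and
phenylpyrroles — by grossly overestimating the rotation barrier around the
C(aromatic)–N bond, and it packages both the diagnosis machinery and the
refitting machinery behind one API.

The torsional energy of a quadruple *i‑j‑k‑l* is the three-term cosine
series

E<sub>T</sub>(φ) = ½ [ V₁(1 + cos φ) + V₂(1 − cos 2φ) + V₃(1 + cos 3φ) ]

with barrier heights V₁, V₂, V₃ in kcal/mol. Parameters are resolved per
(torsion type, atom quadruple) key with staged wildcard fallback — exact,
single-end wildcard, double wildcard — matching MMFF94 practice.

The package provides:

* **Parameter model** — `torsionEnergy()`, `lookupTorsion()`,
  `computeProfile()`, `barrierHeight()`, plus two shipped tables:
  the original MMFF94s wildcard triple for aryl amides
  (`builtinParams("original")`) and the refitted set for aryl amides,
  5-membered heteroaromatic variants (including the amidothiophene V₁
  correction that mimics the S···O chalcogen contact), and phenylpyrroles
  (`builtinParams("new")`).
* **TorsionID** — a canonical string descriptor of a rotatable bond's
  local environment (element, aromaticity, neighbour count, sp²-nitrogen
  flags, bond orders, delocalization), invariant to atom input order and
  decodable back into a fragment: `torsionIds()`, `encodeTorsionId()`,
  `decodeTorsionId()`.
* **Symmetry-corrected deviations** — topological end-symmetry
  classification (C1/D1/D2/D3) and the piecewise fold mappings for the six
  pair classes, with a fundamental-domain effective deviation used for the
  30° wrong-prediction test: `classifyEnd()`, `foldDeviation()`,
  `deviationExceeds()`.
* **Conformer pipeline** — random dihedral assignment in 30° steps up to
  1000 distinct conformers, pluggable minimization engines (300 CG + 5000
  L-BFGS steps, dielectric 4), a 10 kcal/mol energy window,
  automorphism-aware heavy-atom best RMSD, recovery tables and per-TorsionID
  error aggregation: `enumerateConformers()`, `minimizeEnsemble()`,
  `filterLowEnergy()`, `bestRmsd()`, `recoveryTable()`,
  `diagnoseTorsions()`.
* **Parameter fitting** — RMSD merit between relative energy profiles,
  exhaustive systematic search (step 0.1) for single quadruples, and an
  elitist genetic algorithm with summed-RMSD fitness for joint fits over
  shared quadruples: `systematicFit()`, `gaFit()`, `cisTransGap()`.
* **Fixtures and I/O** — SDF/SMILES input (ChemmineR/ChemmineOB), ten
  frozen analogue molecules with annotated ground truth
  (`builtinFixture()`), synthetic PES generation (`synthPes()`), parameter
  `.par` and PES CSV formats, and a CLI (`exec/torsionforge`).

## Worked example

```r
library(torsionforge)

orig <- builtinParams("original")
newp <- builtinParams("new")

## the phenyl amide quadruple 37-37-10-3 resolves through the wildcard
## entry 0-0-10-37-0 (stage 3)
lookupTorsion(newp, 0, 37, 37, 10, 3)
#>   tt i  j  k l v1  v2 v3 provenance stage
#> 1  0 0 10 37 0  0 2.7  0        new     3

## the refit lowers the aryl-amide rotation barrier from 6.0 to 2.7
barrierHeight(computeProfile(lookupTorsion(orig, 0, 37, 37, 10, 3), seq(-180, 180, 5)))
#> [1] 6
barrierHeight(computeProfile(lookupTorsion(newp, 0, 37, 37, 10, 3), seq(-180, 180, 5)))
#> [1] 2.7

## canonical TorsionIDs for every assignable bond of N-phenylacetamide
torsionIds(builtinFixture("n-phenylacetamide")$graph)
#>   bond a1 a2                                            id
#> 1    1  1  2 C:n3(-N^2:n3,=O:n1)[-]C:n4(-H:n1,-H:n1,-H:n1)
#> 2    6  2  4     C:n3(-C:n4,=O:n1)[-]N^2:n3(-C^a:n3,-H:n1)
#> 3    7  4  5 C^a:n3(~C^a:n3,~C^a:n3)[-]N^2:n3(-C:n3,-H:n1)

## systematic refit of the phenylpyrrole V2 against a reference scan
quad <- data.frame(tt = 1, i = 0, j = 37, k = 39, l = 0)
ref <- ReferencePES("phenylpyrrole",
                    synthPes(c(0, 2.6, 0), seq(-180, 180, 15))$profile, quad)
systematicFit(ref, FitSpec(cbind(quad, comp = "v2")))
#> FitResult (systematic): merit 8.49085e-16 kcal/mol, 301 evaluations
#>   tt i  j  k l v1  v2 v3
#> 1  1 0 37 39 0  0 2.6  0
```

The three TorsionID lines read, in order: the methyl–carbonyl bond, the
amide C–N bond, and the aryl–N bond (aromatic carbons flagged `^a`,
delocalized ring bonds `~`, the sp² amide nitrogen `N^2`). The fit
recovers the generating V₂ = 2.6 kcal/mol exactly because the reference
lies on the 0.1 grid.

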