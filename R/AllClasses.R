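#' @import methods
#' @importFrom stats optim rnorm runif setNames aggregate
#' @importFrom utils read.csv write.csv head tail
NULL

## ---------------------------------------------------------------------------
## Parameter tables
## ---------------------------------------------------------------------------

#' Torsion parameter table
#'
#' Holds torsion parameter records, one per (torsion type, atom quadruple)
#' key. Each record carries a torsion-type index \code{tt}, four numeric
#' MMFF94 atom types \code{i, j, k, l} (0 meaning wildcard), the barrier
#' heights \code{v1, v2, v3} of the onefold, twofold and threefold cosine
#' terms (kcal/mol), and a \code{provenance} tag (\code{"original"} or
#' \code{"new"}). Records are stored in canonical orientation: \code{j < k},
#' or \code{j == k} and \code{i <= l}; the reversed quadruple l-k-j-i
#' denotes the same record.
#'
#' @slot records data.frame with columns tt, i, j, k, l, v1, v2, v3,
#'   provenance.
#' @slot name character(1), free-text table name.
#'
#' @seealso [TorsionParams()], [builtinParams()], [lookupTorsion()]
#' @export
setClass("TorsionParams",
         representation(records = "data.frame", name = "character"))

setValidity("TorsionParams", function(object) {
  rec <- object@records
  need <- c("tt", "i", "j", "k", "l", "v1", "v2", "v3", "provenance")
  if (!all(need %in% names(rec)))
    return(paste("records must have columns:", paste(need, collapse = ", ")))
  if (nrow(rec) > 0) {
    at <- as.matrix(rec[, c("tt", "i", "j", "k", "l")])
    if (any(!is.finite(at)) || any(at < 0) || any(at != round(at)))
      return("tt and atom types must be non-negative integers")
    bad <- rec$j > rec$k | (rec$j == rec$k & rec$i > rec$l)
    if (any(bad))
      return("records must be stored in canonical orientation (j < k, or j == k and i <= l)")
    key <- paste(rec$tt, rec$i, rec$j, rec$k, rec$l)
    if (anyDuplicated(key))
      return("duplicate (tt, i, j, k, l) keys after canonical orientation")
    if (!all(rec$provenance %in% c("original", "new")))
      return("provenance must be 'original' or 'new'")
  }
  if (length(object@name) != 1L) return("name must be character(1)")
  TRUE
})

## ---------------------------------------------------------------------------
## Energy profiles
## ---------------------------------------------------------------------------

#' One-dimensional torsion energy profile
#'
#' A paired angle grid (degrees) and relative-energy vector with an explicit
#' unit tag. Angles must be strictly increasing and lie within
#' [-180, 360] degrees.
#'
#' @slot angles numeric, strictly increasing, degrees.
#' @slot energies numeric, same length as angles.
#' @slot unit character(1), \code{"kcal/mol"} or \code{"kJ/mol"}.
#'
#' @seealso [EnergyProfile()], [computeProfile()], [barrierHeight()],
#'   [convertUnit()]
#' @export
setClass("EnergyProfile",
         representation(angles = "numeric", energies = "numeric",
                        unit = "character"))

setValidity("EnergyProfile", function(object) {
  a <- object@angles
  if (length(a) < 1L) return("profile must contain at least one grid point")
  if (any(!is.finite(a)) || any(!is.finite(object@energies)))
    return("angles and energies must be finite")
  if (length(a) != length(object@energies))
    return("angles and energies must have equal length")
  if (length(a) > 1L && any(diff(a) <= 0))
    return("angles must be strictly increasing")
  if (any(a < -180 - 1e-9) || any(a > 360 + 1e-9))
    return("angles must lie within [-180, 360] degrees")
  if (length(object@unit) != 1L || !object@unit %in% c("kcal/mol", "kJ/mol"))
    return("unit must be 'kcal/mol' or 'kJ/mol'")
  TRUE
})

## ---------------------------------------------------------------------------
## Molecular graphs and torsion fragments
## ---------------------------------------------------------------------------

#' Molecular graph with perception flags
#'
#' A hydrogen-explicit molecular graph: element symbols, formal charges,
#' optional 3D coordinates, and a bond list with integer orders 1-3.
#' Perception (ring finding, aromaticity, delocalized bonds, sp2-nitrogen
#' flags) populates the flag slots; \code{perceived} records whether it has
#' run. Rings are stored as integer atom cycles up to size 7, the maximum
#' size at which aromaticity is considered.
#'
#' @slot name character(1)
#' @slot elements character, element symbol per atom.
#' @slot charges numeric, formal charge per atom.
#' @slot coords numeric matrix, natoms x 3 (0-row if coordinates absent).
#' @slot bonds data.frame with columns a1, a2, order.
#' @slot rings list of integer vectors (simple cycles, size <= 7).
#' @slot aromAtom,sp2N logical per atom.
#' @slot aromBond,delocBond logical per bond.
#' @slot perceived logical(1)
#'
#' @seealso [molecularGraph()], [perceiveAll()], [detectAssignableBonds()]
#' @export
setClass("MolecularGraph",
         representation(name = "character", elements = "character",
                        charges = "numeric", coords = "matrix",
                        bonds = "data.frame", rings = "list",
                        aromAtom = "logical", sp2N = "logical",
                        aromBond = "logical", delocBond = "logical",
                        perceived = "logical"))

setValidity("MolecularGraph", function(object) {
  n <- length(object@elements)
  b <- object@bonds
  if (!all(c("a1", "a2", "order") %in% names(b)))
    return("bonds must have columns a1, a2, order")
  if (length(object@charges) != n) return("charges must match atom count")
  if (nrow(object@coords) > 0 &&
      (nrow(object@coords) != n || ncol(object@coords) != 3))
    return("coords must be an natoms x 3 matrix (or 0-row)")
  if (nrow(b) > 0) {
    if (any(b$a1 < 1 | b$a1 > n | b$a2 < 1 | b$a2 > n))
      return("bond endpoints out of range")
    if (any(b$a1 == b$a2)) return("self-bonds are not allowed")
    if (!all(b$order %in% 1:3)) return("bond orders must be 1, 2 or 3")
  }
  for (fl in c("aromAtom", "sp2N"))
    if (!length(slot(object, fl)) %in% c(0L, n))
      return(paste(fl, "must have length 0 or natoms"))
  for (fl in c("aromBond", "delocBond"))
    if (!length(slot(object, fl)) %in% c(0L, nrow(b)))
      return(paste(fl, "must have length 0 or nbonds"))
  TRUE
})

#' Torsion fragment
#'
#' The local-environment fragment of a rotatable bond: the central bond
#' atoms (or, for sp-atom chains, the whole linear run plus both chain-end
#' atoms) and every atom directly bonded to the central/end atoms,
#' hydrogens included. Atom descriptors carry element, aromaticity,
#' sp2-nitrogen flag, formal charge, and the neighbour count of the atom in
#' the parent molecule (hydrogen-inclusive). Bonds carry order and a
#' delocalized flag.
#'
#' @slot atoms data.frame with columns element, aromatic, sp2n, charge,
#'   degree.
#' @slot bonds data.frame with columns a1, a2, order, deloc (fragment-local
#'   indices).
#' @slot central integer, fragment-local indices of the central unit in
#'   chain order (length 2 for an ordinary bond).
#'
#' @seealso [extractFragment()], [encodeTorsionId()], [decodeTorsionId()]
#' @export
setClass("TorsionFragment",
         representation(atoms = "data.frame", bonds = "data.frame",
                        central = "integer"))

setValidity("TorsionFragment", function(object) {
  a <- object@atoms; b <- object@bonds
  if (!all(c("element", "aromatic", "sp2n", "charge", "degree") %in% names(a)))
    return("atoms must have columns element, aromatic, sp2n, charge, degree")
  if (!all(c("a1", "a2", "order", "deloc") %in% names(b)))
    return("bonds must have columns a1, a2, order, deloc")
  if (length(object@central) < 2L)
    return("central unit must contain at least two atoms")
  if (any(object@central < 1L | object@central > nrow(a)))
    return("central indices out of range")
  ## connectivity of the fragment
  if (nrow(a) > 1L) {
    adj <- lapply(seq_len(nrow(a)), function(i)
      c(b$a2[b$a1 == i], b$a1[b$a2 == i]))
    seen <- logical(nrow(a)); seen[1L] <- TRUE; queue <- 1L
    while (length(queue)) {
      v <- queue[1L]; queue <- queue[-1L]
      nb <- adj[[v]][!seen[adj[[v]]]]
      seen[nb] <- TRUE; queue <- c(queue, nb)
    }
    if (!all(seen)) return("fragment must be connected")
  }
  TRUE
})

## ---------------------------------------------------------------------------
## Energy engine contract and conformer sets
## ---------------------------------------------------------------------------

#' Pluggable energy engine
#'
#' Contract used by the conformer pipeline: \code{energy(coords)} returns a
#' scalar energy in kcal/mol for an natoms x 3 coordinate matrix, and
#' \code{minimize(coords, cgSteps, lbfgsSteps, dielectric)} returns
#' \code{list(coords =, energy =)}. Implementations must never increase the
#' energy during minimization and must be deterministic for fixed inputs.
#'
#' @slot name character(1)
#' @slot energy function(coords) -> numeric(1)
#' @slot minimize function(coords, cgSteps, lbfgsSteps, dielectric) ->
#'   list(coords, energy)
#'
#' @seealso [torsionOnlyEngine()], [quadraticWellEngine()],
#'   [minimizeEnsemble()]
#' @export
setClass("EnergyEngine",
         representation(name = "character", energy = "function",
                        minimize = "function"))

#' Conformer ensemble
#'
#' Conformers generated by random dihedral assignment. \code{assignments}
#' holds one dihedral target (degrees, multiples of the step) per rotatable
#' bond and conformer; \code{coords} the per-conformer coordinate matrices;
#' \code{energies} are set by minimization (NA while status is
#' \code{"raw"} or \code{"failed"}).
#'
#' @slot assignments numeric matrix, nconf x nbonds.
#' @slot coords list of natoms x 3 matrices.
#' @slot energies numeric, kcal/mol.
#' @slot status character: "raw", "ok" or "failed".
#' @slot bondIndex integer, rows of the graph bond table that were driven.
#' @slot dihedralAtoms integer matrix, nbonds x 4 (i, j, k, l per bond).
#'
#' @seealso [enumerateConformers()], [minimizeEnsemble()],
#'   [filterLowEnergy()]
#' @export
setClass("ConformerSet",
         representation(assignments = "matrix", coords = "list",
                        energies = "numeric", status = "character",
                        bondIndex = "integer", dihedralAtoms = "matrix"))

setValidity("ConformerSet", function(object) {
  n <- length(object@coords)
  if (nrow(object@assignments) != n || length(object@energies) != n ||
      length(object@status) != n)
    return("assignments, coords, energies, status must agree in length")
  if (!all(object@status %in% c("raw", "ok", "failed")))
    return("status must be 'raw', 'ok' or 'failed'")
  if (any(!is.na(object@energies) & object@status != "ok"))
    return("energies may be set only for conformers with status 'ok'")
  TRUE
})

#' Recovery benchmark result
#'
#' Cumulative recovery ratios over RMSD thresholds plus the failure count,
#' mirroring the layout of bioactive-conformation recovery tables.
#'
#' @slot rmsd numeric, per-molecule best RMSD in Angstrom (successes only).
#' @slot thresholds numeric, Angstrom.
#' @slot ratios numeric in [0, 1], non-decreasing with threshold.
#' @slot nFailed,nTotal integer.
#' @export
setClass("RecoveryResult",
         representation(rmsd = "numeric", thresholds = "numeric",
                        ratios = "numeric", nFailed = "integer",
                        nTotal = "integer"))

setValidity("RecoveryResult", function(object) {
  if (length(object@ratios) != length(object@thresholds))
    return("one ratio per threshold required")
  if (any(object@ratios < 0 | object@ratios > 1))
    return("ratios must lie in [0, 1]")
  if (is.unsorted(object@ratios)) return("ratios must be non-decreasing")
  TRUE
})

## ---------------------------------------------------------------------------
## Fitting
## ---------------------------------------------------------------------------

#' Reference potential-energy-surface scan
#'
#' One fitting target: a relative energy profile (shifted so that its
#' minimum is zero, converted to kcal/mol on construction) together with
#' the torsion quadruples present on the scanned bond of the molecule.
#' Each quadruple row may carry an angular \code{offset} (degrees) of its
#' dihedral relative to the driven dihedral.
#'
#' @slot molecule character(1) identifier.
#' @slot profile EnergyProfile, relative, kcal/mol.
#' @slot quadruples data.frame with columns tt, i, j, k, l, offset.
#' @seealso [ReferencePES()], [systematicFit()], [gaFit()]
#' @export
setClass("ReferencePES",
         representation(molecule = "character", profile = "EnergyProfile",
                        quadruples = "data.frame"))

setValidity("ReferencePES", function(object) {
  q <- object@quadruples
  if (!all(c("tt", "i", "j", "k", "l", "offset") %in% names(q)))
    return("quadruples must have columns tt, i, j, k, l, offset")
  if (nrow(q) < 1L) return("at least one quadruple required")
  if (length(object@profile@angles) < 2L)
    return("profile must cover at least two distinct angles")
  if (object@profile@unit != "kcal/mol")
    return("reference profiles are stored in kcal/mol")
  if (abs(min(object@profile@energies)) > 1e-9)
    return("reference profile must be relative (minimum zero)")
  TRUE
})

#' Fit specification
#'
#' Which (V1, V2, V3) components are free for which quadruples, the search
#' bounds, the systematic grid step, and genetic-algorithm settings.
#'
#' @slot free data.frame with columns tt, i, j, k, l, comp (comp one of
#'   "v1", "v2", "v3"); one row per free component.
#' @slot fixed data.frame with columns tt, i, j, k, l, v1, v2, v3: starting
#'   values for components that are not free (defaults to all-zero rows).
#' @slot lower,upper numeric(1), bounds in kcal/mol.
#' @slot step numeric(1), systematic grid step.
#' @slot ga list: popSize, generations, mutSigma, crossProb, elites,
#'   tournamentK, seed.
#' @seealso [FitSpec()], [systematicFit()], [gaFit()]
#' @export
setClass("FitSpec",
         representation(free = "data.frame", fixed = "data.frame",
                        lower = "numeric", upper = "numeric",
                        step = "numeric", ga = "list"))

setValidity("FitSpec", function(object) {
  f <- object@free
  if (!all(c("tt", "i", "j", "k", "l", "comp") %in% names(f)))
    return("free must have columns tt, i, j, k, l, comp")
  if (nrow(f) < 1L) return("at least one free component required")
  if (!all(f$comp %in% c("v1", "v2", "v3")))
    return("comp must be 'v1', 'v2' or 'v3'")
  if (anyDuplicated(paste(f$tt, f$i, f$j, f$k, f$l, f$comp)))
    return("duplicate free components")
  if (!is.finite(object@lower) ||
      !is.finite(object@upper) || object@lower >= object@upper)
    return("bounds must be finite with lower < upper")
  if (!is.finite(object@step) || object@step <= 0)
    return("step must be positive")
  TRUE
})

#' Fit result
#'
#' Fitted parameter triples plus the merit value (kcal/mol RMSD between the
#' model and reference profiles; for the GA, summed over references).
#'
#' @slot params data.frame with columns tt, i, j, k, l, v1, v2, v3.
#' @slot merit numeric(1), >= 0.
#' @slot mode character(1): "systematic" or "ga".
#' @slot evaluations integer(1), number of merit evaluations.
#' @slot seed integer(1) (NA for the deterministic systematic mode).
#' @slot history numeric, best fitness per GA generation (empty for
#'   systematic fits).
#' @export
setClass("FitResult",
         representation(params = "data.frame", merit = "numeric",
                        mode = "character", evaluations = "integer",
                        seed = "integer", history = "numeric"))

setValidity("FitResult", function(object) {
  if (object@merit < 0) return("merit must be non-negative")
  if (!object@mode %in% c("systematic", "ga"))
    return("mode must be 'systematic' or 'ga'")
  TRUE
})
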