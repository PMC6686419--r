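## Energy engines implementing the pluggable minimization contract. The
## torsion-only engine sums the three-term cosine potential over all torsion
## quadruples of the rotatable bonds; it carries no bonded or nonbonded
## terms and ignores the dielectric argument (no electrostatics).

#' Construct an energy engine
#'
#' @param name engine name.
#' @param energy function(coords) -> numeric(1), kcal/mol.
#' @param minimize function(coords, cgSteps, lbfgsSteps, dielectric) ->
#'   list(coords =, energy =). Must never increase the energy and must be
#'   deterministic for fixed inputs.
#' @return An [EnergyEngine-class].
#' @export
EnergyEngine <- function(name, energy, minimize) {
  new("EnergyEngine", name = name, energy = energy, minimize = minimize)
}

setMethod("show", "EnergyEngine", function(object)
  cat("EnergyEngine \"", object@name, "\"\n", sep = ""))

## all torsion quadruples around rotatable bond (j, k): one row per (i, l)
## neighbour pair
.bondQuadruples <- function(graph, bondIdx) {
  adj <- .adjacency(graph)
  j <- graph@bonds$a1[bondIdx]; k <- graph@bonds$a2[bondIdx]
  is <- setdiff(adj[[j]], k); ls <- setdiff(adj[[k]], j)
  out <- expand.grid(i = is, l = ls)
  out$j <- j; out$k <- k
  out[, c("i", "j", "k", "l")]
}

#' Torsion-term-only energy engine
#'
#' Energy is the sum of the three-term cosine potential over every torsion
#' quadruple of every rotatable (assignable, acyclic) bond, with parameters
#' resolved through [lookupTorsion()] from the supplied table using the
#' supplied numeric atom types. Quadruples without a matching record
#' contribute zero when \code{missingAction = "zero"} (the default), or
#' raise when \code{"error"}. Minimization runs conjugate gradient then
#' L-BFGS on the rotatable dihedrals (all other internal coordinates are
#' rigid), so it is deterministic and never increases the energy. The
#' dielectric argument of the contract is accepted and ignored.
#'
#' @param graph a perceived [MolecularGraph-class].
#' @param types integer vector of numeric MMFF94 atom types per atom (see
#'   [assignMmffTypes()]).
#' @param params a [TorsionParams-class] table.
#' @param tt torsion-type index per rotatable bond (recycled; default 0).
#'   The index is an opaque key into the table; callers decide it.
#' @param missingAction "zero" or "error".
#' @return An [EnergyEngine-class].
#' @export
torsionOnlyEngine <- function(graph, types, params, tt = 0L,
                              missingAction = c("zero", "error")) {
  stopifnot(is(graph, "MolecularGraph"), is(params, "TorsionParams"))
  missingAction <- match.arg(missingAction)
  bonds <- detectAssignableBonds(graph, acyclicOnly = TRUE)
  tt <- rep_len(as.integer(tt), length(bonds))
  terms <- list()
  for (t in seq_along(bonds)) {
    quads <- .bondQuadruples(graph, bonds[t])
    for (r in seq_len(nrow(quads))) {
      ty <- types[unlist(quads[r, ])]
      if (any(is.na(ty)) || any(ty == 0)) {
        if (missingAction == "error")
          stop("untyped atom in torsion quadruple on bond ", bonds[t])
        next
      }
      rec <- tryCatch(lookupTorsion(params, tt[t], ty[1], ty[2], ty[3], ty[4]),
                      error = function(e) NULL)
      if (is.null(rec)) {
        if (missingAction == "error")
          stop("missing parameter for quadruple on bond ", bonds[t])
        next
      }
      terms[[length(terms) + 1L]] <- list(
        atoms = as.integer(unlist(quads[r, ])), bond = t,
        v = c(rec$v1, rec$v2, rec$v3))
    }
  }
  da <- if (length(bonds))
    t(vapply(bonds, .dihedralAtomsOf, integer(4), graph = graph))
  else matrix(integer(0), 0L, 4L)

  energyFn <- function(coords) {
    e <- 0
    for (tm in terms) {
      phi <- getDihedral(coords, tm$atoms[1], tm$atoms[2], tm$atoms[3],
                         tm$atoms[4])
      e <- e + torsionEnergy(tm$v[1], tm$v[2], tm$v[3], phi)
    }
    e
  }

  minimizeFn <- function(coords, cgSteps = 300L, lbfgsSteps = 5000L,
                         dielectric = 4) {
    e0 <- energyFn(coords)
    if (!length(bonds) || !length(terms))
      return(list(coords = coords, energy = e0))
    theta0 <- vapply(seq_along(bonds), function(t)
      getDihedral(coords, da[t, 1], da[t, 2], da[t, 3], da[t, 4]), numeric(1))
    ## each quadruple's dihedral differs from its bond's driven dihedral by
    ## a fixed offset while only torsions move
    offsets <- vapply(terms, function(tm) {
      phi <- getDihedral(coords, tm$atoms[1], tm$atoms[2], tm$atoms[3],
                         tm$atoms[4])
      phi - theta0[tm$bond]
    }, numeric(1))
    V <- vapply(terms, function(tm) tm$v, numeric(3))
    bondOf <- vapply(terms, function(tm) tm$bond, integer(1))
    obj <- function(th) {
      rad <- (th[bondOf] + offsets) * pi / 180
      sum(0.5 * (V[1, ] * (1 + cos(rad)) + V[2, ] * (1 - cos(2 * rad)) +
                 V[3, ] * (1 + cos(3 * rad))))
    }
    fit <- stats::optim(theta0, obj, method = "CG",
                        control = list(maxit = max(1L, cgSteps)))
    if (lbfgsSteps > 0L)
      fit <- stats::optim(fit$par, obj, method = "L-BFGS-B",
                          control = list(maxit = lbfgsSteps,
                                         factr = 1e4, pgtol = 1e-8))
    if (fit$value > e0)
      return(list(coords = coords, energy = e0))
    cc <- coords
    for (t in seq_along(bonds))
      cc <- setDihedral(graph, cc, da[t, 1], da[t, 2], da[t, 3], da[t, 4],
                        .wrap180(fit$par[t]))
    list(coords = cc, energy = fit$value)
  }

  EnergyEngine("torsion-only", energyFn, minimizeFn)
}

#' Quadratic-well toy engine
#'
#' Convex test engine: energy is \code{k * sum((coords - center)^2)} and
#' minimization jumps straight to the known minimum.
#'
#' @param center natoms x 3 matrix, the well minimum.
#' @param k force constant.
#' @return An [EnergyEngine-class].
#' @export
quadraticWellEngine <- function(center, k = 1) {
  center <- as.matrix(center)
  EnergyEngine(
    "quadratic-well",
    energy = function(coords) k * sum((coords - center)^2),
    minimize = function(coords, cgSteps = 300L, lbfgsSteps = 5000L,
                        dielectric = 4)
      list(coords = center, energy = 0))
}
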