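## Conformer pipeline: dihedral driving, random-assignment enumeration,
## pluggable minimization, energy-window filtering, symmetry-aware best
## RMSD, recovery tables and torsion diagnostics.

#' Measure a dihedral angle
#'
#' @param coords natoms x 3 coordinate matrix.
#' @param i,j,k,l atom indices; the dihedral is the angle between planes
#'   i-j-k and j-k-l, in degrees within (-180, 180].
#' @return numeric(1) degrees.
#' @export
getDihedral <- function(coords, i, j, k, l) {
  b1 <- coords[j, ] - coords[i, ]
  b2 <- coords[k, ] - coords[j, ]
  b3 <- coords[l, ] - coords[k, ]
  n1 <- c(b1[2] * b2[3] - b1[3] * b2[2],
          b1[3] * b2[1] - b1[1] * b2[3],
          b1[1] * b2[2] - b1[2] * b2[1])
  n2 <- c(b2[2] * b3[3] - b2[3] * b3[2],
          b2[3] * b3[1] - b2[1] * b3[3],
          b2[1] * b3[2] - b2[2] * b3[1])
  m1 <- c(n1[2] * b2[3] - n1[3] * b2[2],
          n1[3] * b2[1] - n1[1] * b2[3],
          n1[1] * b2[2] - n1[2] * b2[1])
  nb2 <- sqrt(sum(b2^2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2) / nb2
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

## atoms on the `k` side of bond j-k (reachable from k without crossing the
## bond), as a logical mask
.sideMask <- function(graph, j, k) {
  adj <- .adjacency(graph)
  seen <- logical(length(graph@elements))
  seen[k] <- TRUE
  queue <- k
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    for (nb in adj[[v]]) {
      if (v == k && nb == j) next
      if (nb == j) next  # ring closure through j would rotate everything
      if (!seen[nb]) { seen[nb] <- TRUE; queue <- c(queue, nb) }
    }
  }
  seen
}

.rotateAbout <- function(coords, mask, origin, axis, angleDeg) {
  a <- axis / sqrt(sum(axis^2))
  th <- angleDeg * pi / 180
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              3, 3, byrow = TRUE)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  pts <- sweep(coords[mask, , drop = FALSE], 2, origin)
  coords[mask, ] <- sweep(pts %*% t(R), 2, origin, `+`)
  coords
}

#' Drive a dihedral to a target value
#'
#' Rotates the smaller branch of the bond j-k about the bond axis so that
#' the dihedral i-j-k-l equals \code{target}. The branch choice is
#' deterministic: the side with fewer atoms rotates; on ties, the side
#' containing the lower atom index.
#'
#' @param graph a [MolecularGraph-class] (topology for branch detection).
#' @param coords natoms x 3 coordinate matrix.
#' @param i,j,k,l dihedral atom indices.
#' @param target target angle in degrees.
#' @return the updated coordinate matrix.
#' @export
setDihedral <- function(graph, coords, i, j, k, l, target) {
  current <- getDihedral(coords, i, j, k, l)
  delta <- target - current
  maskK <- .sideMask(graph, j, k)
  maskJ <- .sideMask(graph, k, j)
  nK <- sum(maskK); nJ <- sum(maskJ)
  rotateK <- if (nK != nJ) nK < nJ else min(which(maskK)) < min(which(maskJ))
  if (rotateK) {
    ## rotating the k side by +delta about j->k increases the dihedral
    coords <- .rotateAbout(coords, maskK, coords[k, ],
                           coords[k, ] - coords[j, ], delta)
  } else {
    coords <- .rotateAbout(coords, maskJ, coords[j, ],
                           coords[j, ] - coords[k, ], -delta)
  }
  coords
}

## deterministic reference atoms (i, l) for the dihedral of bond (j, k):
## lowest-index neighbour on each side
.dihedralAtomsOf <- function(graph, bondIdx) {
  adj <- .adjacency(graph)
  j <- graph@bonds$a1[bondIdx]; k <- graph@bonds$a2[bondIdx]
  i <- min(setdiff(adj[[j]], k))
  l <- min(setdiff(adj[[k]], j))
  c(i, j, k, l)
}

#' Enumerate conformers by random dihedral assignment
#'
#' Rotatable bonds are the assignable, acyclic bonds of the molecule (ring
#' internal coordinates are never altered). Each rotatable bond takes
#' values on the step grid (default 0, 30, ..., 330 degrees). When the
#' full grid has at most \code{maxN} points it is enumerated exhaustively;
#' otherwise \code{maxN} distinct assignment vectors are sampled without
#' replacement using \code{seed}. A molecule without rotatable bonds
#' yields a single conformer: the input geometry.
#'
#' @param graph a perceived [MolecularGraph-class] with 3D coordinates.
#' @param maxN maximum number of conformers (default 1000).
#' @param step dihedral step in degrees; must divide 360 (default 30).
#' @param seed integer seed for the sampling branch.
#' @return A [ConformerSet-class].
#' @export
enumerateConformers <- function(graph, maxN = 1000L, step = 30, seed = 1L) {
  stopifnot(is(graph, "MolecularGraph"))
  if (nrow(graph@coords) == 0L)
    stop("molecule has no 3D coordinates")
  if (360 %% step != 0) stop("step must divide 360")
  bonds <- detectAssignableBonds(graph, acyclicOnly = TRUE)
  nb <- length(bonds)
  values <- seq(0, 360 - step, by = step)
  nv <- length(values)
  if (nb == 0L) {
    return(new("ConformerSet",
               assignments = matrix(numeric(0), nrow = 1L, ncol = 0L),
               coords = list(graph@coords), energies = NA_real_,
               status = "raw", bondIndex = integer(0),
               dihedralAtoms = matrix(integer(0), 0L, 4L)))
  }
  total <- nv^nb
  if (total <= maxN) {
    grid <- as.matrix(expand.grid(rep(list(values), nb)))
  } else {
    set.seed(seed)
    seenKeys <- character(0)
    rows <- list()
    while (length(rows) < maxN) {
      draw <- matrix(sample(values, size = nb * (maxN - length(rows)) * 2L,
                            replace = TRUE),
                     ncol = nb)
      for (r in seq_len(nrow(draw))) {
        key <- paste(draw[r, ], collapse = ",")
        if (!key %in% seenKeys) {
          seenKeys <- c(seenKeys, key)
          rows[[length(rows) + 1L]] <- draw[r, ]
          if (length(rows) >= maxN) break
        }
      }
    }
    grid <- do.call(rbind, rows)
  }
  dimnames(grid) <- NULL
  da <- t(vapply(bonds, .dihedralAtomsOf, integer(4), graph = graph))
  coordsList <- vector("list", nrow(grid))
  for (r in seq_len(nrow(grid))) {
    cc <- graph@coords
    for (bi in seq_len(nb))
      cc <- setDihedral(graph, cc, da[bi, 1], da[bi, 2], da[bi, 3], da[bi, 4],
                        grid[r, bi])
    coordsList[[r]] <- cc
  }
  new("ConformerSet", assignments = grid, coords = coordsList,
      energies = rep(NA_real_, nrow(grid)),
      status = rep("raw", nrow(grid)), bondIndex = as.integer(bonds),
      dihedralAtoms = da)
}

#' Minimize a conformer ensemble with a pluggable energy engine
#'
#' Each conformer is minimized with
#' \code{engine@minimize(coords, cgSteps, lbfgsSteps, dielectric)} (default
#' schedule: 300 conjugate-gradient then 5000 L-BFGS steps, dielectric 4).
#' Engine exceptions downgrade the conformer to \code{"failed"}; failures
#' are counted, never raised collectively.
#'
#' @param confs a [ConformerSet-class].
#' @param engine an [EnergyEngine-class].
#' @param cgSteps,lbfgsSteps,dielectric minimization schedule forwarded to
#'   the engine.
#' @return the ConformerSet with energies, coordinates and status updated.
#' @export
minimizeEnsemble <- function(confs, engine, cgSteps = 300L,
                             lbfgsSteps = 5000L, dielectric = 4) {
  stopifnot(is(confs, "ConformerSet"), is(engine, "EnergyEngine"))
  for (r in seq_along(confs@coords)) {
    res <- tryCatch(
      engine@minimize(confs@coords[[r]], cgSteps, lbfgsSteps, dielectric),
      error = function(e) NULL)
    if (is.null(res) || !is.finite(res$energy)) {
      confs@status[r] <- "failed"
      confs@energies[r] <- NA_real_
    } else {
      confs@coords[[r]] <- res$coords
      confs@energies[r] <- res$energy
      confs@status[r] <- "ok"
    }
  }
  confs
}

#' Keep low-energy conformers
#'
#' Retains minimized conformers within \code{window} kcal/mol of the
#' lowest-energy conformer. The minimum-energy conformer is always kept;
#' the selection is invariant to constant energy offsets.
#'
#' @param confs a minimized [ConformerSet-class] with at least one ok
#'   conformer.
#' @param window energy window in kcal/mol (default 10.0).
#' @return the filtered ConformerSet.
#' @export
filterLowEnergy <- function(confs, window = 10.0) {
  stopifnot(is(confs, "ConformerSet"))
  ok <- confs@status == "ok"
  if (!any(ok)) stop("no successfully minimized conformer to filter")
  emin <- min(confs@energies[ok])
  keep <- ok & (confs@energies - emin <= window + 1e-12)
  new("ConformerSet",
      assignments = confs@assignments[keep, , drop = FALSE],
      coords = confs@coords[keep], energies = confs@energies[keep],
      status = confs@status[keep], bondIndex = confs@bondIndex,
      dihedralAtoms = confs@dihedralAtoms)
}

## Kabsch superposition RMSD between two coordinate sets (rows aligned)
.kabschRmsd <- function(P, Q) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  H <- t(Qc) %*% Pc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  diffs <- Pc - Qc %*% t(R)
  sqrt(sum(diffs^2) / nrow(P))
}

#' Optimal-superposition RMSD between two conformations
#'
#' @param P,Q n x 3 coordinate matrices with rows in correspondence.
#' @return numeric(1) RMSD in the coordinate unit after optimal rigid
#'   superposition (rotation + translation, no reflection).
#' @export
kabschRmsd <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  if (!all(dim(P) == dim(Q))) stop("coordinate sets must have equal dimensions")
  .kabschRmsd(P, Q)
}

## graph automorphisms (element/charge vertex colours, bond-order edge
## colours) as a list of permutation vectors; capped for safety
.graphAutomorphisms <- function(graph, cap = 5000L) {
  ci <- .colouredIgraph(graph)
  maps <- igraph::graph.get.isomorphisms.vf2(
    ci$g, ci$g, vertex.color1 = ci$vcol, vertex.color2 = ci$vcol,
    edge.color1 = ci$ecol, edge.color2 = ci$ecol)
  if (length(maps) > cap) maps <- maps[seq_len(cap)]
  lapply(maps, as.integer)
}

#' Best RMSD of an ensemble to a reference conformation
#'
#' Heavy-atom RMSD after optimal rigid superposition, minimized over graph
#' automorphisms (symmetry-equivalent atom relabelings, e.g. phenyl flips)
#' and over all ok conformers.
#'
#' @param confs a [ConformerSet-class] or a list of coordinate matrices.
#' @param reference natoms x 3 reference coordinate matrix.
#' @param graph the molecule (for elements and automorphisms).
#' @param heavyOnly if TRUE (default) hydrogens are excluded.
#' @return numeric(1) minimum RMSD in Angstrom.
#' @export
bestRmsd <- function(confs, reference, graph, heavyOnly = TRUE) {
  coordsList <- if (is(confs, "ConformerSet")) {
    ok <- confs@status %in% c("ok", "raw")
    confs@coords[ok]
  } else confs
  if (!length(coordsList)) stop("no conformers to compare")
  reference <- as.matrix(reference)
  if (nrow(reference) != length(graph@elements))
    stop("atom count mismatch between reference and molecule")
  heavy <- if (heavyOnly) which(graph@elements != "H")
           else seq_along(graph@elements)
  autos <- .graphAutomorphisms(graph)
  ## deduplicate automorphisms by their action on heavy atoms
  autosH <- unique(lapply(autos, function(p) p[heavy]))
  best <- Inf
  for (cc in coordsList) {
    if (nrow(cc) != nrow(reference)) stop("atom count mismatch in ensemble")
    for (perm in autosH) {
      r <- .kabschRmsd(reference[heavy, , drop = FALSE],
                       cc[perm, , drop = FALSE])
      if (r < best) best <- r
    }
  }
  best
}

#' Cumulative recovery table over RMSD thresholds
#'
#' @param rmsds numeric vector of per-molecule best RMSD values (successes
#'   only), Angstrom.
#' @param nFailed number of molecules that could not be processed.
#' @param thresholds RMSD thresholds in Angstrom.
#' @return A [RecoveryResult-class]; ratios are fractions of successfully
#'   processed molecules with best RMSD below each threshold, and the
#'   failure rate is \code{nFailed / (length(rmsds) + nFailed)}.
#' @export
recoveryTable <- function(rmsds, nFailed = 0L,
                          thresholds = c(0.5, 1.0, 1.5, 2.0)) {
  if (!length(rmsds)) stop("empty result list")
  ratios <- vapply(thresholds, function(t) mean(rmsds < t), numeric(1))
  new("RecoveryResult", rmsd = as.numeric(rmsds),
      thresholds = as.numeric(thresholds), ratios = ratios,
      nFailed = as.integer(nFailed),
      nTotal = as.integer(length(rmsds) + nFailed))
}

#' @describeIn recoveryTable failure rate in percent.
#' @param x a RecoveryResult.
#' @export
failureRate <- function(x) {
  stopifnot(is(x, "RecoveryResult"))
  100 * x@nFailed / x@nTotal
}

setMethod("show", "RecoveryResult", function(object) {
  cat("RecoveryResult over", length(object@rmsd), "molecule(s),",
      object@nFailed, "failed\n")
  print(data.frame(threshold = object@thresholds, ratio = object@ratios))
})

#' Torsion-by-torsion diagnostics between two conformations
#'
#' For every assignable bond, reports the TorsionID, the symmetry pair
#' class of the bond ends, the raw and effective dihedral deviation
#' between the reference and predicted conformation, and whether the
#' effective deviation exceeds the threshold (default 30 degrees).
#'
#' @param graph a perceived [MolecularGraph-class].
#' @param refCoords,predCoords natoms x 3 coordinate matrices of the same
#'   molecule.
#' @param threshold wrongness threshold in degrees.
#' @return data.frame with columns bond, id, pair, phiRef, phiPred, raw,
#'   folded, effective, exceeds.
#' @export
diagnoseTorsions <- function(graph, refCoords, predCoords, threshold = 30) {
  stopifnot(is(graph, "MolecularGraph"))
  refCoords <- as.matrix(refCoords); predCoords <- as.matrix(predCoords)
  n <- length(graph@elements)
  if (nrow(refCoords) != n || nrow(predCoords) != n)
    stop("coordinate matrices do not match the molecular graph")
  bonds <- detectAssignableBonds(graph)
  out <- vector("list", length(bonds))
  for (t in seq_along(bonds)) {
    bi <- bonds[t]
    id <- encodeTorsionId(extractFragment(graph, bi))
    s1 <- classifyEnd(graph, bi, graph@bonds$a1[bi])
    s2 <- classifyEnd(graph, bi, graph@bonds$a2[bi])
    pair <- symmetryPairClass(s1, s2)
    da <- .dihedralAtomsOf(graph, bi)
    phiRef <- getDihedral(refCoords, da[1], da[2], da[3], da[4])
    phiPred <- getDihedral(predCoords, da[1], da[2], da[3], da[4])
    dev <- deviationExceeds(phiRef, phiPred, pair, threshold)
    out[[t]] <- cbind(data.frame(bond = bi, id = id,
                                 phiRef = phiRef, phiPred = phiPred), dev)
  }
  if (!length(out))
    return(data.frame(bond = integer(), id = character(), phiRef = numeric(),
                      phiPred = numeric(), pair = character(), raw = numeric(),
                      folded = numeric(), effective = numeric(),
                      exceeds = logical()))
  do.call(rbind, out)
}

#' Aggregate torsion diagnostics across molecules
#'
#' Sums the wrong-prediction flags per TorsionID and sorts the counts in
#' descending order, the bookkeeping used to rank systematically
#' mispredicted torsion environments.
#'
#' @param diagList list of data.frames from [diagnoseTorsions()].
#' @return data.frame with columns id, wrong, total, sorted by wrong
#'   descending.
#' @export
aggregateDiagnostics <- function(diagList) {
  all <- do.call(rbind, diagList)
  if (is.null(all) || !nrow(all))
    return(data.frame(id = character(), wrong = integer(), total = integer()))
  agg <- stats::aggregate(cbind(wrong = all$exceeds, total = rep(1L, nrow(all))),
                          by = list(id = all$id), FUN = sum)
  agg <- agg[order(-agg$wrong, agg$id), ]
  rownames(agg) <- NULL
  agg
}
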