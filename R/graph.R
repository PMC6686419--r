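## Molecular graphs and chemical perception: ring finding (simple cycles up
## to size 7), Hueckel aromaticity on isolated ring systems, delocalized
## bonds, and sp2-nitrogen flags.

#' Construct a molecular graph
#'
#' Hydrogens are explicit atoms. Perception flags start empty; run
#' [perceiveAll()] (or the individual perception steps) before querying
#' aromaticity, delocalization, sp2-nitrogen flags or assignable bonds.
#'
#' @param elements character vector of element symbols.
#' @param bonds data.frame with columns a1, a2, order (1, 2 or 3).
#' @param coords optional natoms x 3 coordinate matrix (Angstrom).
#' @param charges optional numeric formal charges (default 0).
#' @param name molecule name.
#' @return A [MolecularGraph-class].
#' @export
molecularGraph <- function(elements, bonds, coords = NULL, charges = NULL,
                           name = "mol") {
  n <- length(elements)
  if (is.null(coords)) coords <- matrix(numeric(0), nrow = 0, ncol = 3)
  coords <- as.matrix(coords)
  if (nrow(coords) > 0) colnames(coords) <- c("x", "y", "z")
  if (is.null(charges)) charges <- numeric(n)
  bonds <- as.data.frame(bonds)
  bonds$a1 <- as.integer(bonds$a1); bonds$a2 <- as.integer(bonds$a2)
  bonds$order <- as.integer(bonds$order)
  new("MolecularGraph", name = name, elements = as.character(elements),
      charges = as.numeric(charges), coords = coords, bonds = bonds,
      rings = list(), aromAtom = logical(0), sp2N = logical(0),
      aromBond = logical(0), delocBond = logical(0), perceived = FALSE)
}

#' @rdname molecularGraph
#' @param x a MolecularGraph.
#' @export
natoms <- function(x) { stopifnot(is(x, "MolecularGraph")); length(x@elements) }

#' @rdname molecularGraph
#' @export
atomElements <- function(x) { stopifnot(is(x, "MolecularGraph")); x@elements }

#' @rdname molecularGraph
#' @export
atomCoords <- function(x) { stopifnot(is(x, "MolecularGraph")); x@coords }

#' @rdname molecularGraph
#' @export
bondTable <- function(x) { stopifnot(is(x, "MolecularGraph")); x@bonds }

setMethod("show", "MolecularGraph", function(object) {
  cat("MolecularGraph \"", object@name, "\": ", length(object@elements),
      " atoms, ", nrow(object@bonds), " bonds",
      if (object@perceived) " (perceived)" else "", "\n", sep = "")
})

## adjacency list: for each atom, data.frame-free integer neighbours
.adjacency <- function(graph) {
  n <- length(graph@elements)
  adj <- vector("list", n)
  b <- graph@bonds
  for (r in seq_len(nrow(b))) {
    adj[[b$a1[r]]] <- c(adj[[b$a1[r]]], b$a2[r])
    adj[[b$a2[r]]] <- c(adj[[b$a2[r]]], b$a1[r])
  }
  adj
}

.degree <- function(graph) lengths(.adjacency(graph))

## index of the bond between atoms u, v (0 if none)
.bondIndexOf <- function(graph, u, v) {
  b <- graph@bonds
  w <- which((b$a1 == u & b$a2 == v) | (b$a1 == v & b$a2 == u))
  if (length(w)) w[1L] else 0L
}

## all simple cycles of length <= maxSize, deduplicated; each returned as an
## integer vector starting at its smallest atom index
.findRings <- function(graph, maxSize = 7L) {
  adj <- .adjacency(graph)
  n <- length(adj)
  rings <- list()
  recurse <- function(path) {
    last <- path[length(path)]
    for (nb in adj[[last]]) {
      if (nb == path[1L] && length(path) >= 3L) {
        ## fix orientation so each cycle is found once
        if (path[2L] < path[length(path)])
          rings[[length(rings) + 1L]] <<- path
      } else if (nb > path[1L] && !(nb %in% path) && length(path) < maxSize) {
        recurse(c(path, nb))
      }
    }
  }
  for (s in seq_len(n)) if (length(adj[[s]]) >= 2L) recurse(s)
  rings
}

## pi-electron contribution of ring atom a within candidate ring (Hueckel
## counting): atoms with a multiple bond inside the ring give 1; atoms whose
## only multiple bond is exocyclic give 0 (sp2, no electrons in the ring
## system); saturated N/P and O/S/Se donate a lone pair (2); anionic C
## donates 2, cationic C 0; a saturated neutral C breaks aromaticity (NA).
.piContribution <- function(graph, a, ring, adj) {
  b <- graph@bonds
  multi <- which((b$a1 == a | b$a2 == a) & b$order >= 2L)
  if (length(multi)) {
    partners <- ifelse(b$a1[multi] == a, b$a2[multi], b$a1[multi])
    if (any(partners %in% ring)) return(1)
    return(0)
  }
  el <- graph@elements[a]; q <- graph@charges[a]
  if (el %in% c("N", "P")) return(2)
  if (el %in% c("O", "S", "Se")) return(2)
  if (el == "C" && q <= -1) return(2)
  if (el == "C" && q >= 1) return(0)
  NA_real_
}

#' Perceive aromaticity
#'
#' Finds simple rings up to size 7 and flags a ring (atoms and bonds)
#' aromatic when every ring atom can contribute to the pi system and the
#' electron count satisfies the 4n+2 rule. Rings larger than 7 atoms are
#' never considered, so e.g. cyclooctatetraene receives no aromatic flags.
#'
#' @param graph a [MolecularGraph-class].
#' @return the graph with \code{aromAtom}/\code{aromBond} flags and the
#'   ring list populated.
#' @export
perceiveAromaticity <- function(graph) {
  stopifnot(is(graph, "MolecularGraph"))
  n <- length(graph@elements)
  graph@rings <- .findRings(graph, 7L)
  aromAtom <- logical(n)
  aromBond <- logical(nrow(graph@bonds))
  adj <- .adjacency(graph)
  for (ring in graph@rings) {
    contrib <- vapply(ring, .piContribution, numeric(1),
                      graph = graph, ring = ring, adj = adj)
    if (any(is.na(contrib))) next
    total <- sum(contrib)
    if (total >= 2 && (total - 2) %% 4 == 0) {
      aromAtom[ring] <- TRUE
      m <- length(ring)
      for (t in seq_len(m)) {
        bi <- .bondIndexOf(graph, ring[t], ring[t %% m + 1L])
        if (bi > 0L) aromBond[bi] <- TRUE
      }
    }
  }
  graph@aromAtom <- aromAtom
  graph@aromBond <- aromBond
  graph
}

#' Flag delocalized bonds
#'
#' Bonds of 6-membered aromatic rings are flagged delocalized (their
#' Kekule structures are energetically equivalent); bonds of 5-membered
#' heteroaromatic rings are not.
#'
#' @param graph a graph after [perceiveAromaticity()].
#' @return the graph with \code{delocBond} populated.
#' @export
flagDelocalizedBonds <- function(graph) {
  stopifnot(is(graph, "MolecularGraph"))
  if (!length(graph@aromBond))
    stop("run perceiveAromaticity() first")
  deloc <- logical(nrow(graph@bonds))
  for (ring in graph@rings) {
    if (length(ring) != 6L) next
    if (!all(graph@aromAtom[ring])) next
    m <- 6L
    bis <- vapply(seq_len(m), function(t)
      .bondIndexOf(graph, ring[t], ring[t %% m + 1L]), integer(1))
    if (all(bis > 0L) && all(graph@aromBond[bis])) deloc[bis] <- TRUE
  }
  graph@delocBond <- deloc
  graph
}

## TRUE when both ring-ortho positions of aromatic atom ar (relative to the
## attached substituent atom sub) carry non-hydrogen substituents; this is
## the topological proxy for "ortho substituents that prevent planarity"
.orthoBlocked <- function(graph, ar, sub, adj) {
  aromRings <- Filter(function(r) ar %in% r && all(graph@aromAtom[r]),
                      graph@rings)
  if (!length(aromRings)) return(FALSE)
  for (ring in aromRings) {
    ortho <- intersect(adj[[ar]], ring)
    if (length(ortho) < 2L) next
    blockedCount <- 0L
    for (o in ortho) {
      ext <- setdiff(adj[[o]], c(ring, sub))
      if (any(graph@elements[ext] != "H")) blockedCount <- blockedCount + 1L
    }
    if (blockedCount >= 2L) return(TRUE)
  }
  FALSE
}

#' Flag sp2-hybridized nitrogens
#'
#' A nitrogen receives the sp2 flag when it is aromatic, part of an amide
#' (bonded to a carbon that is double-bonded to oxygen), an enamine
#' nitrogen (bonded to a carbon that is double-bonded to carbon), or in
#' resonance with an aromatic ring (bonded to an aromatic ring atom). The
#' resonance condition is suppressed when both ortho ring positions of the
#' attachment atom carry non-hydrogen substituents, the topological stand-in
#' for steric inhibition of planarity.
#'
#' @param graph a graph after [perceiveAromaticity()].
#' @return the graph with \code{sp2N} populated.
#' @export
flagSp2Nitrogens <- function(graph) {
  stopifnot(is(graph, "MolecularGraph"))
  if (!length(graph@aromAtom))
    stop("run perceiveAromaticity() first")
  n <- length(graph@elements)
  adj <- .adjacency(graph)
  b <- graph@bonds
  sp2 <- logical(n)
  for (a in which(graph@elements == "N")) {
    if (graph@aromAtom[a]) { sp2[a] <- TRUE; next }
    flagged <- FALSE
    for (nb in adj[[a]]) {
      bi <- .bondIndexOf(graph, a, nb)
      if (b$order[bi] != 1L) next
      if (graph@elements[nb] == "C" && !graph@aromAtom[nb]) {
        dbl <- which((b$a1 == nb | b$a2 == nb) & b$order == 2L)
        partners <- ifelse(b$a1[dbl] == nb, b$a2[dbl], b$a1[dbl])
        if (any(graph@elements[partners] == "O")) flagged <- TRUE  # amide
        if (any(graph@elements[partners] == "C")) flagged <- TRUE  # enamine
      }
      if (graph@aromAtom[nb] && !.orthoBlocked(graph, nb, a, adj))
        flagged <- TRUE                                            # aryl resonance
    }
    sp2[a] <- flagged
  }
  graph@sp2N <- sp2
  graph
}

#' Run all perception steps
#'
#' Ring finding, aromaticity, delocalized bonds and sp2-nitrogen flags, in
#' order. Idempotent.
#'
#' @param graph a [MolecularGraph-class].
#' @return the fully perceived graph.
#' @export
perceiveAll <- function(graph) {
  graph <- perceiveAromaticity(graph)
  graph <- flagDelocalizedBonds(graph)
  graph <- flagSp2Nitrogens(graph)
  graph@perceived <- TRUE
  graph
}

## is bond row bi part of any stored ring of size <= maxSize?
.bondInSmallRing <- function(graph, bi, maxSize = 5L) {
  u <- graph@bonds$a1[bi]; v <- graph@bonds$a2[bi]
  for (ring in graph@rings) {
    if (length(ring) > maxSize) next
    m <- length(ring)
    for (t in seq_len(m)) {
      p <- ring[t]; q <- ring[t %% m + 1L]
      if ((p == u && q == v) || (p == v && q == u)) return(TRUE)
    }
  }
  FALSE
}

## is the bond part of ANY cycle (of any size)? used to keep ring
## conformations untouched during conformer enumeration
.bondInAnyRing <- function(graph, bi) {
  b <- graph@bonds
  u <- b$a1[bi]; v <- b$a2[bi]
  adj <- .adjacency(graph)
  seen <- logical(length(graph@elements))
  seen[u] <- TRUE; queue <- u
  while (length(queue)) {
    w <- queue[1L]; queue <- queue[-1L]
    for (nb in adj[[w]]) {
      if (w == u && nb == v) next
      if (!seen[nb]) { seen[nb] <- TRUE; queue <- c(queue, nb) }
    }
  }
  seen[v]
}

#' Detect bonds to which a TorsionID can be assigned
#'
#' Assignable bonds are single bonds, non-aromatic, not members of a ring
#' with 5 or fewer atoms, and have at least two neighbours on each
#' endpoint so a dihedral is definable.
#'
#' @param graph a perceived [MolecularGraph-class].
#' @param acyclicOnly if TRUE, additionally exclude bonds lying in any ring
#'   (ring conformations are never driven by the conformer generator).
#' @return integer vector of row indices into \code{bondTable(graph)}.
#' @export
detectAssignableBonds <- function(graph, acyclicOnly = FALSE) {
  stopifnot(is(graph, "MolecularGraph"))
  if (!graph@perceived) stop("run perceiveAll() first")
  b <- graph@bonds
  deg <- .degree(graph)
  out <- integer(0)
  for (bi in seq_len(nrow(b))) {
    if (b$order[bi] != 1L) next
    if (graph@aromBond[bi]) next
    if (.bondInSmallRing(graph, bi, 5L)) next
    if (deg[b$a1[bi]] < 2L || deg[b$a2[bi]] < 2L) next
    if (acyclicOnly && .bondInAnyRing(graph, bi)) next
    out <- c(out, bi)
  }
  out
}
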