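## Local symmetry of rotatable-bond ends and symmetry-corrected dihedral
## deviations.
##
## Each end of a rotatable bond is classified topologically as C1 (no
## symmetry), D1 (a mirror makes the torsion profile even), D2 (planar end
## with two equivalent branches: twofold) or D3 (three pairwise equivalent
## branches: threefold). D3 collapses to D1 for pair classification. The
## pair class determines the piecewise mapping applied to raw deviations
## and the fold period used for the effective (fundamental-domain)
## deviation.

.PAIR_CLASSES <- c("C1C1", "C1D1", "C1D2", "D1D1", "D1D2", "D2D2")

.PAIR_PERIOD <- c(C1C1 = 360, C1D1 = 360, C1D2 = 180, D1D1 = 180,
                  D1D2 = 90, D2D2 = 90)

## mirror images are folded in for pair classes containing a D1 end (D1 is
## the mirror symmetry); D2 contributes pure rotational images only
.PAIR_MIRROR <- c(C1C1 = FALSE, C1D1 = TRUE, C1D2 = FALSE, D1D1 = TRUE,
                  D1D2 = TRUE, D2D2 = FALSE)

#' Combine two end-symmetry labels into a pair class
#'
#' The pair is unordered and D3 is treated as D1.
#'
#' @param s1,s2 character(1) in C1, D1, D2, D3.
#' @return character(1), one of C1C1, C1D1, C1D2, D1D1, D1D2, D2D2.
#' @export
symmetryPairClass <- function(s1, s2) {
  lab <- function(s) {
    if (!s %in% c("C1", "D1", "D2", "D3"))
      stop("symmetry labels must be C1, D1, D2 or D3")
    if (s == "D3") "D1" else s
  }
  p <- sort(c(lab(s1), lab(s2)))
  cls <- paste0(p[1], p[2])
  stopifnot(cls %in% .PAIR_CLASSES)
  cls
}

## igraph representation with element/charge vertex colours and bond-order
## edge colours; two extra unique colours pin the end atom and its central
## partner so enumerated isomorphisms are automorphisms fixing the bond
.colouredIgraph <- function(graph, pin = integer(0)) {
  el <- paste(graph@elements, graph@charges)
  col <- as.integer(factor(el))
  if (length(pin))
    col[pin] <- max(col) + seq_along(pin)
  g <- igraph::graph_from_edgelist(
    as.matrix(graph@bonds[, c("a1", "a2")]), directed = FALSE)
  if (igraph::vcount(g) < length(graph@elements))
    g <- igraph::add_vertices(g, length(graph@elements) - igraph::vcount(g))
  ## aromatic bonds share one colour: Kekule alternation must not break
  ## ring symmetry
  ecol <- graph@bonds$order
  if (length(graph@aromBond) == nrow(graph@bonds))
    ecol[graph@aromBond] <- 4L
  list(g = g, vcol = col, ecol = ecol)
}

## branch equivalence: substituent branches r1, r2 of `end` are equivalent
## iff some automorphism of the molecule fixing both central-bond atoms
## maps r1 to r2
.branchEquivalence <- function(graph, endAtom, centralPartner, roots) {
  ci <- .colouredIgraph(graph, pin = c(endAtom, centralPartner))
  maps <- igraph::graph.get.isomorphisms.vf2(
    ci$g, ci$g, vertex.color1 = ci$vcol, vertex.color2 = ci$vcol,
    edge.color1 = ci$ecol, edge.color2 = ci$ecol)
  k <- length(roots)
  eq <- diag(TRUE, k)
  for (m in maps) {
    mm <- as.integer(m)
    for (p in seq_len(k)) for (q in seq_len(k))
      if (mm[roots[p]] == roots[q]) eq[p, q] <- eq[q, p] <- TRUE
  }
  eq
}

#' Classify the local symmetry of one end of a rotatable bond
#'
#' Classification is topological: branch equivalence is decided by graph
#' automorphisms (element- and bond-order-coloured) that fix the central
#' bond. A methyl carbon (three equivalent hydrogens) is D3; an
#' unsubstituted phenyl ipso carbon (two equivalent ring branches on a
#' planar atom) is D2; an end whose branch pattern admits a mirror (a
#' single branch, or an equivalent branch pair on a non-planar atom, or an
#' equivalent pair among three branches) is D1; anything else is C1.
#'
#' @param graph a perceived [MolecularGraph-class].
#' @param bond assignable bond row index.
#' @param endAtom one of the two atoms of that bond.
#' @return character(1): "C1", "D1", "D2" or "D3".
#' @export
classifyEnd <- function(graph, bond, endAtom) {
  stopifnot(is(graph, "MolecularGraph"))
  b <- graph@bonds
  if (!endAtom %in% c(b$a1[bond], b$a2[bond]))
    stop("endAtom is not part of the bond")
  partner <- if (b$a1[bond] == endAtom) b$a2[bond] else b$a1[bond]
  adj <- .adjacency(graph)
  roots <- setdiff(adj[[endAtom]], partner)
  if (!length(roots))
    stop("terminal end atom: no dihedral is definable")
  k <- length(roots)
  planar <- graph@aromAtom[endAtom] ||
    (graph@elements[endAtom] == "N" && length(graph@sp2N) && graph@sp2N[endAtom]) ||
    any(b$order[(b$a1 == endAtom | b$a2 == endAtom)] >= 2L)
  if (k == 1L) return("D1")
  eq <- .branchEquivalence(graph, endAtom, partner, roots)
  if (k == 3L) {
    if (all(eq)) return("D3")
    if (any(eq[upper.tri(eq)])) return("D1")
    return("C1")
  }
  if (k == 2L) {
    if (eq[1, 2]) return(if (planar) "D2" else "D1")
    return("C1")
  }
  ## higher coordination: a mirror needs at least one equivalent pair
  if (any(eq[upper.tri(eq)])) "D1" else "C1"
}

#' Symmetry mapping of a raw dihedral deviation
#'
#' Literal application of the piecewise mapping functions per pair class:
#' \itemize{
#'   \item C1C1, C1D1: \eqn{\varphi + 360} for \eqn{\varphi < 0}, else
#'     \eqn{\varphi};
#'   \item C1D2: \eqn{\varphi + 180} for \eqn{\varphi < 0}, else
#'     \eqn{\varphi};
#'   \item D1D1: \eqn{|\varphi|};
#'   \item D1D2, D2D2: \eqn{\varphi + 180} for \eqn{\varphi < 0},
#'     \eqn{180 - \varphi} for \eqn{\varphi > 90}, identity on the
#'     remaining 0..90 branch.
#' }
#' The mapped value is the raw symmetry-corrected deviation; the
#' fundamental-domain residue used for threshold tests is computed by
#' [effectiveDeviation()].
#'
#' @param phi numeric deviation(s) in degrees, within [-180, 180].
#' @param pair pair class string (see [symmetryPairClass()]).
#' @return numeric mapped deviation(s) in degrees.
#' @export
foldDeviation <- function(phi, pair) {
  if (!pair %in% .PAIR_CLASSES) stop("unknown pair class: ", pair)
  if (any(!is.finite(phi)) || any(phi < -180 - 1e-9) || any(phi > 180 + 1e-9))
    stop("phi must lie within [-180, 180] degrees")
  switch(pair,
    C1C1 = ,
    C1D1 = ifelse(phi < 0, phi + 360, phi),
    C1D2 = ifelse(phi < 0, phi + 180, phi),
    D1D1 = abs(phi),
    D1D2 = ,
    D2D2 = ifelse(phi < 0, phi + 180, ifelse(phi > 90, 180 - phi, phi)))
}

.wrap180 <- function(x) ((x + 180) %% 360) - 180

#' Effective (fundamental-domain) deviation between two dihedrals
#'
#' Distance from the reference angle to the nearest symmetry image of the
#' predicted angle. Images are the translates by the pair's fold period
#' (360 for C1C1/C1D1, 180 for C1D2/D1D1, 90 for D1D2/D2D2), plus the
#' mirror images for pair classes containing a D1 end.
#'
#' @param phiRef,phiPred numeric dihedral angles in degrees.
#' @param pair pair class string.
#' @return numeric effective deviation(s) in degrees, >= 0.
#' @export
effectiveDeviation <- function(phiRef, phiPred, pair) {
  if (!pair %in% .PAIR_CLASSES) stop("unknown pair class: ", pair)
  if (any(!is.finite(phiRef)) || any(!is.finite(phiPred)))
    stop("angles must be finite")
  P <- .PAIR_PERIOD[[pair]]
  foldP <- function(x) abs(((x + P / 2) %% P) - P / 2)
  d <- foldP(phiRef - phiPred)
  if (.PAIR_MIRROR[[pair]]) d <- pmin(d, foldP(phiRef + phiPred))
  d
}

#' Threshold test on the symmetry-corrected deviation
#'
#' Wraps the raw deviation to [-180, 180], applies the literal mapping of
#' [foldDeviation()], computes the effective deviation of
#' [effectiveDeviation()], and flags torsions whose effective deviation
#' exceeds the threshold (default 30 degrees, the wrong-prediction
#' criterion of the diagnostics pipeline).
#'
#' @param phiRef,phiPred numeric(1) dihedral angles in degrees.
#' @param pair pair class string.
#' @param threshold positive threshold in degrees.
#' @return one-row data.frame with columns pair, raw, folded, effective,
#'   exceeds.
#' @export
deviationExceeds <- function(phiRef, phiPred, pair, threshold = 30) {
  stopifnot(is.finite(phiRef), is.finite(phiPred), threshold > 0)
  raw <- .wrap180(phiPred - phiRef)
  eff <- effectiveDeviation(phiRef, phiPred, pair)
  data.frame(pair = pair, raw = raw, folded = foldDeviation(raw, pair),
             effective = eff, exceeds = eff > threshold)
}
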