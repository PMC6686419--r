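## TorsionID: canonical string identifiers for rotatable-bond environments.
##
## Grammar (linear, reversible):
##   id      := side "[" center "]" side ( extras )?
##   side    := atomtok "(" [ sub ("," sub)* ] ")"
##   sub     := bondtok atomtok
##   center  := bondtok ( atomtok bondtok )*      # inner atoms only for sp chains
##   extras  := ( "{" pos "-" bondtok "-" pos "}" )*
##   atomtok := Element [charge] [ "^a" ] [ "^2" ] ":n" count
##   bondtok := "-" | "=" | "#" | "~"             # "~" flags delocalized bonds
## Atom positions for extras are counted in written order (first end atom,
## its substituents, chain atoms, second end atom, its substituents).
## The canonical form is the lexicographically smallest string over the two
## central-bond directions, with substituents of each side sorted.

.BOND_TOKENS <- c("-", "=", "#")

.bondTok <- function(order, deloc) if (deloc) "~" else .BOND_TOKENS[order]

.chargeTok <- function(q) {
  if (q == 0) return("")
  sign <- if (q > 0) "+" else "-"
  if (abs(q) == 1) sign else paste0(sign, abs(q))
}

.atomTok <- function(element, charge, aromatic, sp2n, degree) {
  paste0(element, .chargeTok(charge),
         if (aromatic) "^a" else "", if (sp2n) "^2" else "",
         ":n", degree)
}

## is atom a an sp-linear chain atom (2 neighbours, triple bond or two
## cumulated double bonds)?
.isSpLinear <- function(graph, a, adj) {
  if (length(adj[[a]]) != 2L) return(FALSE)
  b <- graph@bonds
  orders <- b$order[(b$a1 == a | b$a2 == a)]
  any(orders == 3L) || sum(orders == 2L) == 2L
}

## central unit of an assignable bond: ordinary bonds give c(a1, a2); for
## bonds into consecutive sp-sp chains the whole linear run plus both
## non-linear end atoms is returned, in chain order
.centralUnit <- function(graph, bondIdx, adj) {
  a <- graph@bonds$a1[bondIdx]; b <- graph@bonds$a2[bondIdx]
  extend <- function(from, towards) {
    chain <- c(from, towards)
    while (.isSpLinear(graph, chain[length(chain)], adj)) {
      nxt <- setdiff(adj[[chain[length(chain)]]], chain[length(chain) - 1L])
      if (length(nxt) != 1L) break
      chain <- c(chain, nxt)
    }
    chain
  }
  left <- rev(extend(b, a))    # ends with (..., a, b)
  right <- extend(a, b)        # starts with (a, b, ...)
  c(left[-length(left)], right[-1L])
}

#' Extract the torsion fragment of an assignable bond
#'
#' The fragment contains the central bond atoms and every atom directly
#' bonded to them (hydrogens included). When the central bond belongs to a
#' consecutive chain of sp-hybridized linear atoms, the whole linear run
#' plus both chain-end atoms and their substituent shells are included.
#' All bonds induced among the included atoms are kept.
#'
#' @param graph a perceived [MolecularGraph-class].
#' @param bond row index into \code{bondTable(graph)}; must be assignable
#'   (see [detectAssignableBonds()]).
#' @return A [TorsionFragment-class].
#' @export
extractFragment <- function(graph, bond) {
  stopifnot(is(graph, "MolecularGraph"))
  if (!graph@perceived) stop("run perceiveAll() first")
  if (!bond %in% detectAssignableBonds(graph))
    stop("bond is not assignable; no torsion fragment is defined")
  adj <- .adjacency(graph)
  unit <- .centralUnit(graph, bond, adj)
  ends <- c(unit[1L], unit[length(unit)])
  members <- unique(c(unit, unlist(adj[ends])))
  ## order: stable by original index, central unit first in chain order
  members <- c(unit, setdiff(members, unit))
  local <- match(seq_along(graph@elements), members)
  deg <- .degree(graph)
  atoms <- data.frame(
    element = graph@elements[members],
    aromatic = graph@aromAtom[members],
    sp2n = graph@sp2N[members],
    charge = graph@charges[members],
    degree = deg[members])
  b <- graph@bonds
  keep <- which(!is.na(local[b$a1]) & !is.na(local[b$a2]))
  fb <- data.frame(a1 = local[b$a1[keep]], a2 = local[b$a2[keep]],
                   order = b$order[keep], deloc = graph@delocBond[keep])
  new("TorsionFragment", atoms = atoms, bonds = fb,
      central = match(unit, members))
}

## ---------------------------------------------------------------------------
## Encoding
## ---------------------------------------------------------------------------

.fragAtomTok <- function(atoms, idx) {
  .atomTok(atoms$element[idx], atoms$charge[idx], atoms$aromatic[idx],
           atoms$sp2n[idx], atoms$degree[idx])
}

.fragBondTok <- function(frag, u, v) {
  b <- frag@bonds
  w <- which((b$a1 == u & b$a2 == v) | (b$a1 == v & b$a2 == u))
  if (!length(w)) stop("no bond between fragment atoms ", u, " and ", v)
  .bondTok(b$order[w[1]], b$deloc[w[1]])
}

## encode for one direction of the central unit; subPerm optionally forces
## the substituent order of each side (used to resolve ties with extras)
.encodeDirected <- function(frag, unit) {
  atoms <- frag@atoms
  b <- frag@bonds
  adjOf <- function(v) sort(unique(c(b$a2[b$a1 == v], b$a1[b$a2 == v])))
  end1 <- unit[1L]; end2 <- unit[length(unit)]
  sideOf <- function(end, chainNb) {
    subs <- setdiff(adjOf(end), chainNb)
    toks <- vapply(subs, function(s)
      paste0(.fragBondTok(frag, end, s), .fragAtomTok(atoms, s)), character(1))
    ord <- order(toks, subs)
    list(atoms = subs[ord], str = paste0(
      .fragAtomTok(atoms, end), "(", paste(toks[ord], collapse = ","), ")"))
  }
  s1 <- sideOf(end1, unit[2L])
  s2 <- sideOf(end2, unit[length(unit) - 1L])
  center <- .fragBondTok(frag, unit[1L], unit[2L])
  if (length(unit) > 2L)
    for (t in 2:(length(unit) - 1L))
      center <- paste0(center, .fragAtomTok(atoms, unit[t]),
                       .fragBondTok(frag, unit[t], unit[t + 1L]))
  core <- paste0(s1$str, "[", center, "]", s2$str)
  ## positions in written order
  written <- c(end1, s1$atoms, if (length(unit) > 2L) unit[2:(length(unit) - 1L)],
               end2, s2$atoms)
  pos <- match(seq_len(nrow(atoms)), written)
  ## extras: induced bonds not on the written tree (end-sub, chain) paths
  treePairs <- rbind(
    cbind(end1, s1$atoms), cbind(end2, s2$atoms),
    if (length(unit) >= 2L) cbind(unit[-length(unit)], unit[-1L]))
  treeKey <- apply(treePairs, 1L, function(p) paste(sort(p), collapse = "_"))
  extras <- character(0)
  for (r in seq_len(nrow(b))) {
    key <- paste(sort(c(b$a1[r], b$a2[r])), collapse = "_")
    if (key %in% treeKey) next
    p <- sort(c(pos[b$a1[r]], pos[b$a2[r]]))
    extras <- c(extras, paste0("{", p[1], "-", .bondTok(b$order[r], b$deloc[r]),
                               "-", p[2], "}"))
  }
  paste0(core, paste(sort(extras), collapse = ""))
}

#' Encode a torsion fragment as a canonical TorsionID string
#'
#' The string encodes, for every fragment atom, its element, formal
#' charge, aromaticity, sp2-nitrogen flag and neighbour count in the
#' parent molecule, and for every bond its order with delocalized bonds
#' flagged specially. The result is independent of the atom input order:
#' substituents are sorted and the lexicographically smaller of the two
#' central-bond directions is chosen.
#'
#' @param fragment a [TorsionFragment-class].
#' @return character(1) TorsionID.
#' @seealso [decodeTorsionId()], [torsionIds()]
#' @export
encodeTorsionId <- function(fragment) {
  stopifnot(is(fragment, "TorsionFragment"))
  fwd <- .encodeDirected(fragment, fragment@central)
  rev_ <- .encodeDirected(fragment, rev(fragment@central))
  min(fwd, rev_)
}

## ---------------------------------------------------------------------------
## Decoding (recursive-descent parser; errors report the position of the
## first grammar violation)
## ---------------------------------------------------------------------------

.parseError <- function(pos, what) {
  stop(sprintf("malformed TorsionID at position %d: expected %s", pos, what),
       call. = FALSE)
}

#' Decode a TorsionID string into a torsion fragment
#'
#' Inverse of [encodeTorsionId()]: parses the canonical grammar back into
#' atom descriptors, bonds and the central unit.
#' \code{encodeTorsionId(decodeTorsionId(s))} reproduces a canonical
#' \code{s} exactly; \code{decodeTorsionId(encodeTorsionId(f))} is
#' descriptor-level isomorphic to \code{f}.
#'
#' @param id character(1) TorsionID string.
#' @return A [TorsionFragment-class].
#' @export
decodeTorsionId <- function(id) {
  stopifnot(is.character(id), length(id) == 1L)
  s <- id; pos <- 1L
  n <- nchar(s)
  peek <- function() if (pos <= n) substr(s, pos, pos) else ""
  atoms <- data.frame(element = character(), aromatic = logical(),
                      sp2n = logical(), charge = numeric(), degree = integer())
  bonds <- data.frame(a1 = integer(), a2 = integer(), order = integer(),
                      deloc = logical())
  addBond <- function(u, v, tok) {
    ord <- match(tok, .BOND_TOKENS)
    bonds[nrow(bonds) + 1L, ] <<- list(u, v, if (is.na(ord)) 1L else ord,
                                       is.na(ord))
  }
  parseAtom <- function() {
    m <- regmatches(substr(s, pos, n),
      regexec("^([A-Z][a-z]?)([+-][0-9]*)?(\\^a)?(\\^2)?:n([0-9]+)",
              substr(s, pos, n)))[[1]]
    if (!length(m)) .parseError(pos, "an atom token El[charge][^a][^2]:nK")
    pos <<- pos + nchar(m[1])
    q <- 0
    if (nzchar(m[3])) {
      mag <- if (nchar(m[3]) > 1L) as.numeric(substr(m[3], 2, nchar(m[3]))) else 1
      q <- if (substr(m[3], 1, 1) == "+") mag else -mag
    }
    atoms[nrow(atoms) + 1L, ] <<- list(m[2], nzchar(m[4]), nzchar(m[5]), q,
                                       as.integer(m[6]))
    nrow(atoms)
  }
  parseBondTok <- function() {
    ch <- peek()
    if (!ch %in% c("-", "=", "#", "~")) .parseError(pos, "a bond token -=#~")
    pos <<- pos + 1L
    ch
  }
  expectChar <- function(ch) {
    if (peek() != ch) .parseError(pos, paste0("'", ch, "'"))
    pos <<- pos + 1L
  }
  parseSide <- function() {
    end <- parseAtom()
    expectChar("(")
    subs <- integer(0)
    while (peek() != ")") {
      tok <- parseBondTok()
      a <- parseAtom()
      addBond(end, a, tok)
      subs <- c(subs, a)
      if (peek() == ",") pos <<- pos + 1L
      else if (peek() != ")") .parseError(pos, "',' or ')'")
    }
    expectChar(")")
    list(end = end, subs = subs)
  }
  side1 <- parseSide()
  expectChar("[")
  chain <- side1$end
  tok <- parseBondTok()
  while (peek() != "]") {
    a <- parseAtom()
    addBond(chain[length(chain)], a, tok)
    chain <- c(chain, a)
    tok <- parseBondTok()
  }
  expectChar("]")
  side2 <- parseSide()
  addBond(chain[length(chain)], side2$end, tok)
  chain <- c(chain, side2$end)
  ## extras
  writtenOrder <- seq_len(nrow(atoms))  # atoms were appended in written order
  while (pos <= n) {
    m <- regmatches(substr(s, pos, n),
      regexec("^\\{([0-9]+)-([-=#~])-([0-9]+)\\}", substr(s, pos, n)))[[1]]
    if (!length(m)) .parseError(pos, "an extra-bond term {p-b-q} or end of string")
    pos <- pos + nchar(m[1])
    u <- as.integer(m[2]); v <- as.integer(m[4])
    if (u < 1L || v > nrow(atoms)) .parseError(pos, "valid atom positions")
    addBond(u, v, m[3])
  }
  new("TorsionFragment", atoms = atoms, bonds = bonds, central = chain)
}

#' TorsionIDs of all assignable bonds of a molecule
#'
#' @param graph a perceived [MolecularGraph-class].
#' @return data.frame with columns bond (row index into the bond table),
#'   a1, a2 and id.
#' @export
torsionIds <- function(graph) {
  bonds <- detectAssignableBonds(graph)
  ids <- vapply(bonds, function(bi)
    encodeTorsionId(extractFragment(graph, bi)), character(1))
  data.frame(bond = bonds, a1 = graph@bonds$a1[bonds],
             a2 = graph@bonds$a2[bonds], id = ids)
}

#' Dump a fragment as a MOL block for visualization
#'
#' Coordinates are not part of a fragment descriptor, so the block carries
#' zero coordinates; neighbour counts and flags are appended as a comment
#' line in the properties block of the data section.
#'
#' @param fragment a [TorsionFragment-class].
#' @param name molecule name for the header.
#' @return character vector of MOL-block lines.
#' @export
fragmentToMolBlock <- function(fragment, name = "torsion-fragment") {
  a <- fragment@atoms; b <- fragment@bonds
  lines <- c(name, "  torsionforge", "",
             sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000",
                     nrow(a), nrow(b)))
  for (r in seq_len(nrow(a)))
    lines <- c(lines, sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                              0, 0, 0, a$element[r]))
  for (r in seq_len(nrow(b)))
    lines <- c(lines, sprintf("%3d%3d%3d  0  0  0  0", b$a1[r], b$a2[r], b$order[r]))
  c(lines, "M  END", "$$$$")
}
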