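## Small molecules built in code for perception, symmetry and pipeline
## tests. Coordinates are only attached where geometry is exercised.

mkBonds <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  data.frame(a1 = m[, 1], a2 = m[, 2], order = m[, 3])
}

## benzene (Kekule orders), explicit hydrogens
benzeneGraph <- function() {
  molecularGraph(
    c(rep("C", 6), rep("H", 6)),
    mkBonds(1,2,2, 2,3,1, 3,4,2, 4,5,1, 5,6,2, 6,1,1,
            1,7,1, 2,8,1, 3,9,1, 4,10,1, 5,11,1, 6,12,1),
    name = "benzene")
}

## cyclooctatetraene: alternating ring of size 8
cotGraph <- function() {
  bonds <- data.frame(a1 = 1:8, a2 = c(2:8, 1), order = rep(c(2L, 1L), 4))
  h <- data.frame(a1 = 1:8, a2 = 9:16, order = 1L)
  molecularGraph(c(rep("C", 8), rep("H", 8)), rbind(bonds, h), name = "cot")
}

## pyrrole with N-H
pyrroleGraph <- function() {
  molecularGraph(
    c("N", "C", "C", "C", "C", "H", "H", "H", "H", "H"),
    mkBonds(1,2,1, 2,3,2, 3,4,1, 4,5,2, 5,1,1,
            1,6,1, 2,7,1, 3,8,1, 4,9,1, 5,10,1),
    name = "pyrrole")
}

## s-trans butadiene
butadieneGraph <- function() {
  molecularGraph(
    c("C", "C", "C", "C", rep("H", 6)),
    mkBonds(1,2,2, 2,3,1, 3,4,2,
            1,5,1, 1,6,1, 2,7,1, 3,8,1, 4,9,1, 4,10,1),
    name = "butadiene")
}

cyclopentaneGraph <- function() {
  ring <- data.frame(a1 = 1:5, a2 = c(2:5, 1), order = 1L)
  h <- data.frame(a1 = rep(1:5, each = 2), a2 = 6:15, order = 1L)
  molecularGraph(c(rep("C", 5), rep("H", 10)), rbind(ring, h),
                 name = "cyclopentane")
}

trimethylamineGraph <- function() {
  molecularGraph(
    c("N", "C", "C", "C", rep("H", 9)),
    mkBonds(1,2,1, 1,3,1, 1,4,1,
            2,5,1, 2,6,1, 2,7,1, 3,8,1, 3,9,1, 3,10,1, 4,11,1, 4,12,1, 4,13,1),
    name = "trimethylamine")
}

## N,N-dimethyl-2,6-dimethylaniline: both ortho positions substituted, so
## the aryl-resonance sp2 flag on N must be suppressed
dimethylanilineGraph <- function() {
  ## ring 1..6 (1 = ipso), N 7, N-methyls 8,9, ortho methyls 10 (on 2), 11 (on 6)
  heavy <- mkBonds(1,2,2, 2,3,1, 3,4,2, 4,5,1, 5,6,2, 6,1,1,
                   1,7,1, 7,8,1, 7,9,1, 2,10,1, 6,11,1)
  els <- c(rep("C", 6), "N", rep("C", 4))
  nH <- c(0, 0, 1, 1, 1, 0, 0, 3, 3, 3, 3)
  hb <- NULL; hidx <- 12L
  for (a in seq_along(nH)) if (nH[a] > 0)
    for (t in seq_len(nH[a])) {
      hb <- rbind(hb, data.frame(a1 = a, a2 = hidx, order = 1L))
      hidx <- hidx + 1L
    }
  molecularGraph(c(els, rep("H", hidx - 12L)), rbind(heavy, hb),
                 name = "N,N-dimethyl-2,6-dimethylaniline")
}

## ethane with a staggered 3D geometry
ethaneGraph <- function() {
  coords <- rbind(
    c(0, 0, 0), c(1.54, 0, 0),
    c(-0.5, 0.95, 0), c(-0.5, -0.48, 0.83), c(-0.5, -0.48, -0.83),
    c(2.04, 0.48, 0.83), c(2.04, 0.48, -0.83), c(2.04, -0.95, 0))
  molecularGraph(
    c("C", "C", rep("H", 6)),
    mkBonds(1,2,1, 1,3,1, 1,4,1, 1,5,1, 2,6,1, 2,7,1, 2,8,1),
    coords = coords, name = "ethane")
}

## four-atom carbon chain with a well-defined central dihedral (~60 deg)
chain4Graph <- function() {
  coords <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.0, 1.42, 0),
                  c(1.55, 2.16, 1.23))
  molecularGraph(c("C", "C", "C", "C"),
                 mkBonds(1,2,1, 2,3,1, 3,4,1),
                 coords = coords, name = "chain4")
}

## 1,4-diphenylbutadiyne: phenyl-C#C-C#C-phenyl (sp chain)
diyneGraph <- function() {
  ## phenyl A: 1..6 (1 ipso), sp carbons 7,8,9,10, phenyl B: 11..16 (11 ipso)
  heavy <- mkBonds(1,2,2, 2,3,1, 3,4,2, 4,5,1, 5,6,2, 6,1,1,
                   1,7,1, 7,8,3, 8,9,1, 9,10,3, 10,11,1,
                   11,12,2, 12,13,1, 13,14,2, 14,15,1, 15,16,2, 16,11,1)
  els <- c(rep("C", 16))
  hOn <- c(2:6, 12:16)
  hb <- data.frame(a1 = hOn, a2 = 17:(16 + length(hOn)), order = 1L)
  molecularGraph(c(els, rep("H", length(hOn))), rbind(heavy, hb),
                 name = "diphenylbutadiyne")
}

## synthetic whole-molecule typing for the benchmark engine: every atom gets
## a positive integer type (1 H, 2 sp3 C, 3 N, 4 O, 5 carbonyl C, 6
## aromatic C, 7 S, 8 F)
syntheticTypes <- function(g) {
  el <- atomElements(g)
  ty <- ifelse(el == "H", 1L, ifelse(el == "O", 4L, ifelse(el == "N", 3L,
        ifelse(el == "S", 7L, ifelse(el == "F", 8L,
        ifelse(g@aromAtom, 6L, 2L))))))
  bt <- bondTable(g)
  for (a in which(el == "C")) {
    sel <- bt$a1 == a | bt$a2 == a
    partners <- ifelse(bt$a1[sel] == a, bt$a2[sel], bt$a1[sel])
    if (any(bt$order[sel] == 2L & el[partners] == "O")) ty[a] <- 5L
  }
  ty
}

## full-coverage wildcard table for the synthetic benchmark
syntheticBenchTable <- function() {
  TorsionParams(data.frame(
    tt = 0, i = 0,
    j = c(2, 3, 3, 2), k = c(5, 5, 6, 2), l = 0,
    v1 = 0, v2 = c(0, 6, 2.7, 0), v3 = c(0.4, 0, 0, 0.3)),
    "synthetic benchmark table")
}

## shuffle atom order of a graph (for canonicalization tests)
shuffleGraph <- function(g, seed) {
  set.seed(seed)
  n <- natoms(g)
  perm <- sample.int(n)        # perm[old] = new index
  b <- bondTable(g)
  coords <- if (nrow(atomCoords(g))) {
    cc <- matrix(0, n, 3); cc[perm, ] <- atomCoords(g); cc
  } else NULL
  els <- character(n); els[perm] <- atomElements(g)
  ch <- numeric(n); ch[perm] <- g@charges
  molecularGraph(els,
                 data.frame(a1 = perm[b$a1], a2 = perm[b$a2],
                            order = b$order),
                 coords = coords, charges = ch, name = g@name)
}
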