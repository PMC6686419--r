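test_that("aromaticity perception follows the ring-size-capped Hueckel rule", {
  g <- perceiveAromaticity(benzeneGraph())
  expect_equal(sum(g@aromAtom), 6L)
  expect_equal(sum(g@aromBond), 6L)
  ## ring size 8: never aromatic
  g <- perceiveAromaticity(cotGraph())
  expect_false(any(g@aromAtom))
  ## pyrrole: 6 pi electrons including the N lone pair
  g <- perceiveAromaticity(pyrroleGraph())
  expect_true(all(g@aromAtom[1:5]))
  ## butadiene: no rings at all
  g <- perceiveAromaticity(butadieneGraph())
  expect_false(any(g@aromAtom))
})

test_that("delocalized flags mark 6-ring aromatic bonds only", {
  g <- flagDelocalizedBonds(perceiveAromaticity(benzeneGraph()))
  expect_equal(sum(g@delocBond), 6L)
  g <- flagDelocalizedBonds(perceiveAromaticity(pyrroleGraph()))
  expect_false(any(g@delocBond))
  g <- flagDelocalizedBonds(perceiveAromaticity(butadieneGraph()))
  expect_false(any(g@delocBond))
})

test_that("sp2 flags cover amide, aryl and aromatic nitrogens but respect the ortho block", {
  g <- builtinFixture("n-phenylacetamide")$graph
  amideN <- which(atomElements(g) == "N")
  expect_true(g@sp2N[amideN])
  g <- perceiveAll(trimethylamineGraph())
  expect_false(any(g@sp2N))
  ## both ortho positions substituted: aryl resonance suppressed
  g <- perceiveAll(dimethylanilineGraph())
  expect_false(g@sp2N[7])
  ## aromatic N (pyrrole) is flagged
  g <- perceiveAll(pyrroleGraph())
  expect_true(g@sp2N[1])
})

test_that("assignability is the conjunction of the printed conditions", {
  g <- perceiveAll(benzeneGraph())
  expect_length(detectAssignableBonds(g), 0L)
  g <- perceiveAll(cyclopentaneGraph())
  ab <- detectAssignableBonds(g)
  expect_length(ab, 0L)  # ring bonds in a 5-ring, C-H bonds terminal
  g <- builtinFixture("n-phenylacetamide")$graph
  ab <- detectAssignableBonds(g)
  bt <- bondTable(g)
  els <- function(bi) sort(atomElements(g)[c(bt$a1[bi], bt$a2[bi])])
  pairs <- vapply(ab, function(bi) paste(els(bi), collapse = "-"), "")
  ## aryl-N, N-C(=O) and methyl-C(=O) are all assignable
  expect_equal(sort(pairs), c("C-C", "C-N", "C-N"))
  ## butadiene central C-C single bond is assignable and non-delocalized
  g <- perceiveAll(butadieneGraph())
  ab <- detectAssignableBonds(g)
  expect_equal(unlist(bondTable(g)[ab, c("a1", "a2")], use.names = FALSE),
               c(2L, 3L))
})

test_that("fragments contain the central atoms, their shells, and sp chains", {
  g <- perceiveAll(ethaneGraph())
  f <- extractFragment(g, 1L)
  expect_equal(nrow(f@atoms), 8L)  # 2 C + 6 H
  expect_equal(length(f@central), 2L)
  ## butane C2-C3: central 2 + methyl carbons + 4 central H -> shell rule
  g <- builtinFixture("n-phenylacetamide")$graph
  bt <- bondTable(g)
  arylBond <- detectAssignableBonds(g)
  arylBond <- arylBond[sapply(arylBond, function(bi)
    any(g@aromAtom[c(bt$a1[bi], bt$a2[bi])]))]
  f <- extractFragment(g, arylBond)
  ## ipso + N + 2 ortho C + carbonyl C + amide H = central 2 + shell 4
  expect_equal(nrow(f@atoms), 6L)
  ## sp-chain: diphenylbutadiyne aryl-sp bond spans all four sp carbons
  g <- perceiveAll(diyneGraph())
  ab <- detectAssignableBonds(g)
  f <- extractFragment(g, ab[1])
  expect_equal(length(f@central), 6L)  # ipso, 4 sp carbons, ipso
  ## both ipso shells (2 ring C each) included
  expect_equal(nrow(f@atoms), 10L)
  expect_error(extractFragment(g, which(bondTable(g)$order == 3L)[1]),
               "not assignable")
})

test_that("encoding is canonical under atom-order shuffles and local", {
  for (nm in c("n-phenylacetamide", "1-phenylpyrrole", "toluene",
               "n-thiophen-2-ylacetamide")) {
    g <- builtinFixture(nm)$graph
    ids <- sort(torsionIds(g)$id)
    for (seed in c(7, 23)) {
      gs <- perceiveAll(shuffleGraph(g, seed))
      expect_equal(sort(torsionIds(gs)$id), ids, info = nm)
    }
  }
  ## locality: a substitution outside the fragment shell leaves the ID
  ## unchanged (acetanilide vs its ortho-fluoro analogue share the amide
  ## C-N environment; the fluorine sits beyond the encoded shell)
  g1 <- builtinFixture("n-phenylacetamide")$graph
  g2 <- builtinFixture("ortho-fluoro-n-phenylacetamide")$graph
  amideId <- function(g) {
    bt <- bondTable(g)
    ab <- detectAssignableBonds(g)
    for (bi in ab) {
      e <- atomElements(g)[c(bt$a1[bi], bt$a2[bi])]
      arom <- g@aromAtom[c(bt$a1[bi], bt$a2[bi])]
      if (setequal(e, c("N", "C")) && !any(arom))
        return(encodeTorsionId(extractFragment(g, bi)))
    }
  }
  expect_identical(amideId(g1), amideId(g2))
})

test_that("encode/decode round-trips and malformed strings report positions", {
  n <- 0L
  for (nm in fixtureNames()) {
    g <- builtinFixture(nm)$graph
    for (bi in detectAssignableBonds(g)) {
      f <- extractFragment(g, bi)
      id <- encodeTorsionId(f)
      f2 <- decodeTorsionId(id)
      expect_identical(encodeTorsionId(f2), id)
      ## descriptor-level isomorphism: same atom multiset and bond count
      expect_equal(sort(f2@atoms$element), sort(f@atoms$element))
      expect_equal(nrow(f2@bonds), nrow(f@bonds))
      n <- n + 1L
    }
  }
  expect_gte(n, 20L)
  expect_error(decodeTorsionId("C:n4(-H:n1)"), "position 12")
  expect_error(decodeTorsionId("Xx"), "position 1")
  expect_error(decodeTorsionId("C:n4(-H:n1)[-]C:n4()junk"), "position")
})

test_that("fragment MOL-block dumps are structurally consistent", {
  g <- builtinFixture("toluene")$graph
  f <- extractFragment(g, detectAssignableBonds(g)[1])
  blk <- fragmentToMolBlock(f)
  expect_match(blk[4], "V2000")
  expect_equal(blk[length(blk)], "$$$$")
  expect_equal(length(blk), 4L + nrow(f@atoms) + nrow(f@bonds) + 2L)
})
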