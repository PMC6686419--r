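test_that("fixture registry serves annotated molecules and rejects unknowns", {
  expect_length(fixtureNames(), 10L)
  for (nm in fixtureNames()) {
    fx <- builtinFixture(nm)
    g <- fx$graph
    expect_true(g@perceived)
    expect_equal(length(detectAssignableBonds(g)), fx$truth$nAssignable,
                 info = nm)
    ## chemically reasonable frozen geometries: bonded distances 0.8-1.9 A
    bt <- bondTable(g)
    cc <- atomCoords(g)
    d <- sqrt(rowSums((cc[bt$a1, ] - cc[bt$a2, ])^2))
    expect_true(all(d > 0.8 & d < 1.9), info = nm)
  }
  expect_error(builtinFixture("caffeine"), "toluene")  # lists the registry
})

test_that("fixture ground truth matches perception and symmetry labels", {
  for (nm in fixtureNames()) {
    fx <- builtinFixture(nm)
    g <- fx$graph; bt <- bondTable(g)
    ab <- detectAssignableBonds(g)
    kb <- fx$truth$keyBond
    hit <- NA
    for (bi in ab) {
      e <- c(atomElements(g)[bt$a1[bi]], atomElements(g)[bt$a2[bi]])
      arom <- c(g@aromAtom[bt$a1[bi]], g@aromAtom[bt$a2[bi]])
      if (setequal(e, kb) && any(arom)) { hit <- bi; break }
      if (setequal(e, kb) && is.na(hit)) hit <- bi
    }
    expect_false(is.na(hit), info = nm)
    s1 <- classifyEnd(g, hit, bt$a1[hit])
    s2 <- classifyEnd(g, hit, bt$a2[hit])
    got <- if (atomElements(g)[bt$a1[hit]] == kb[1]) c(s1, s2) else c(s2, s1)
    expect_equal(got, fx$truth$keySymmetry, info = nm)
  }
})

test_that("minimal MMFF typing reproduces the key torsion quadruples", {
  ## phenyl amide: 37-37-10-3 across the aryl-N bond
  fx <- builtinFixture("n-phenylacetamide")
  g <- fx$graph; ty <- assignMmffTypes(g)
  bt <- bondTable(g)
  nAt <- which(atomElements(g) == "N")
  expect_equal(ty[nAt], 10L)
  expect_equal(sum(ty == 37L, na.rm = TRUE), 6L)
  expect_equal(sum(ty == 28L, na.rm = TRUE), 1L)
  expect_equal(sum(ty == 3L, na.rm = TRUE), 1L)
  ## and the quadruple resolves to the 0-10-37-0 wildcard of both tables
  expect_equal(lookupTorsion(builtinParams("original"), 0, 37, 37, 10, 3)$v2,
               6.0)
  expect_equal(lookupTorsion(builtinParams("new"), 0, 37, 37, 10, 3)$v2, 2.7)
  ## thiophene amide: S-C(alpha)-N-C quadruple types 44-63-10-3
  fx <- builtinFixture("n-thiophen-2-ylacetamide")
  g <- fx$graph; ty <- assignMmffTypes(g)
  expect_equal(sort(unique(ty[!is.na(ty)])),
               c(3L, 10L, 28L, 44L, 63L, 64L))
  ## pyrrole nitrogen types 39; phenylpyrrole ring carbons 63/64
  g <- builtinFixture("1-phenylpyrrole")$graph
  ty <- assignMmffTypes(g)
  expect_equal(ty[which(atomElements(g) == "N")], 39L)
  expect_equal(sum(ty == 63L, na.rm = TRUE), 2L)
  expect_equal(sum(ty == 64L, na.rm = TRUE), 2L)
  ## pyrazole: N1 pyrrole-type 39, N2 pyridine-type alpha 65
  g <- builtinFixture("1-phenylpyrazole")$graph
  ty <- assignMmffTypes(g)
  expect_setequal(ty[atomElements(g) == "N"], c(39L, 65L))
})

test_that("fixtures round-trip through SDF write/read", {
  for (nm in c("toluene", "n-thiophen-2-ylacetamide")) {
    g <- builtinFixture(nm)$graph
    f <- tempfile(fileext = ".sdf")
    writeMolecules(g, f)
    g2 <- loadMolecules(f, "sdf")[[1]]
    expect_identical(atomElements(g2), atomElements(g))
    expect_equal(bondTable(g2), bondTable(g))
    expect_equal(atomCoords(g2), atomCoords(g), tolerance = 1e-4)
  }
  ## multi-record files, including repeated names
  g <- builtinFixture("toluene")$graph
  f <- tempfile(fileext = ".sdf")
  writeMolecules(list(g, g), f)
  back <- loadMolecules(f, "sdf")
  expect_length(back, 2L)
  expect_equal(atomCoords(back[[2]]), atomCoords(g), tolerance = 1e-4)
})

test_that("SDF loading skips corrupt records and warns on empty input", {
  src <- system.file("extdata", "fixtures.sdf", package = "torsionforge")
  lines <- readLines(src)
  ends <- grep("^\\$\\$\\$\\$", lines)
  block1 <- lines[1:ends[1]]
  block2 <- lines[(ends[1] + 1):ends[2]]
  corrupt <- c("broken", " bad", "", " garbage counts line", "M  END", "$$$$")
  f <- tempfile(fileext = ".sdf")
  writeLines(c(block1, corrupt, block2), f)
  mols <- suppressWarnings(loadMolecules(f, "sdf"))
  expect_length(mols, 2L)
  expect_length(attr(mols, "skipped"), 1L)
  fEmpty <- tempfile(fileext = ".sdf")
  writeLines(character(0), fEmpty)
  expect_warning(m0 <- loadMolecules(fEmpty, "sdf"), "no records")
  expect_length(m0, 0L)
  expect_error(loadMolecules(tempfile(), "sdf"), "cannot read")
})

test_that("synthetic PES matches the model evaluation and is seed-stable", {
  grid <- seq(0, 180, 15)
  s <- synthPes(c(0, 2.7, 0), grid)
  expect_equal(max(profileEnergies(s$profile)), 2.7)
  expect_equal(profileAngles(s$profile)[which.max(profileEnergies(s$profile))],
               90)
  ## independent summation agrees with computeProfile to 1e-12
  for (v in list(c(0, 2.7, 0), c(-11.5, 6.6, 0), c(1.1, -2.2, 3.3))) {
    a <- profileEnergies(synthPes(v, seq(-180, 180, 5))$profile)
    b <- profileEnergies(computeProfile(v, seq(-180, 180, 5)))
    expect_equal(a, b, tolerance = 1e-12)
  }
  ## noise is reproducible and linearity holds
  n1 <- synthPes(c(0, 2.7, 0), grid, sigma = 0.1, seed = 9)
  n2 <- synthPes(c(0, 2.7, 0), grid, sigma = 0.1, seed = 9)
  expect_identical(profileEnergies(n1$profile), profileEnergies(n2$profile))
  twice <- synthPes(list(c(0, 2.7, 0), c(0, 2.7, 0)), grid)
  expect_equal(profileEnergies(twice$profile),
               2 * profileEnergies(s$profile), tolerance = 1e-12)
  expect_error(synthPes(c(0, 1, 0), grid, sigma = -1), "non-negative")
})
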