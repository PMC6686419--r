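test_that("torsion energy reproduces the analytic worked examples", {
  ## E(90) = V2 when V1 = V3 = 0 (cos 180 = -1)
  expect_equal(torsionEnergy(0.0, 6.0, 0.0, 90), 6.0)
  ## all three terms vanish at 180
  expect_equal(torsionEnergy(3.2, -1.7, 0.9, 180), 0.0)
  ## E(0) = V1 + V3
  expect_equal(torsionEnergy(-11.5, 6.60, 0.0, 0), -11.5)
  expect_equal(torsionEnergy(1, 1, 1, 0), 2.0)
  expect_error(torsionEnergy(NA, 1, 1, 0), "non-finite")
  expect_error(torsionEnergy(0, 1, 1, Inf), "non-finite")
})

test_that("torsion energy is periodic, even, and anchored at 0/180", {
  set.seed(101)
  for (rep in 1:1000) {
    v <- runif(3, -15, 15)
    phi <- runif(1, -720, 720)
    e <- torsionEnergy(v[1], v[2], v[3], phi)
    expect_equal(e, torsionEnergy(v[1], v[2], v[3], phi + 360),
                 tolerance = 1e-9)
    expect_equal(e, torsionEnergy(v[1], v[2], v[3], -phi), tolerance = 1e-9)
  }
  set.seed(102)
  for (rep in 1:50) {
    v <- runif(3, -15, 15)
    expect_equal(torsionEnergy(v[1], v[2], v[3], 0), v[1] + v[3])
    expect_equal(torsionEnergy(v[1], v[2], v[3], 180), 0)
  }
})

test_that("parameter lookup stages resolve exact, single- and double-wildcard keys", {
  tab <- builtinParams("new")
  ## stage 3: phenyl amide quadruple falls through to the 0-0-10-37-0 wildcard
  rec <- lookupTorsion(tab, 0, 3, 10, 37, 37)
  expect_equal(c(rec$v1, rec$v2, rec$v3), c(0.0, 2.7, 0.0))
  expect_equal(rec$stage, 3L)
  ## exact hit
  rec <- lookupTorsion(tab, 0, 28, 10, 64, 66)
  expect_equal(c(rec$v1, rec$v2, rec$v3), c(0.00, 1.29, 0.00))
  expect_equal(rec$stage, 1L)
  ## empty table
  empty <- TorsionParams(data.frame(tt = integer(), i = integer(),
                                    j = integer(), k = integer(),
                                    l = integer(), v1 = numeric(),
                                    v2 = numeric(), v3 = numeric()))
  expect_error(lookupTorsion(empty, 0, 1, 2, 3, 4), "empty")
  ## wildcard queries are rejected, misses name the canonical quadruple
  expect_error(lookupTorsion(tab, 0, 0, 10, 37, 5), "no wildcards")
  expect_error(lookupTorsion(tab, 0, 9, 9, 9, 9), "0-9-9-9-9")
})

test_that("lookup is invariant under quadruple reversal", {
  tab <- builtinParams("new")
  cases <- list(c(0, 3, 10, 64, 66), c(0, 44, 63, 10, 3),
                c(1, 63, 39, 37, 37), c(0, 28, 10, 64, 65))
  for (q in cases) {
    a <- lookupTorsion(tab, q[1], q[2], q[3], q[4], q[5])
    b <- lookupTorsion(tab, q[1], q[5], q[4], q[3], q[2])
    expect_equal(a, b)
  }
})

test_that("profiles evaluate, shift and report barriers correctly", {
  grid <- seq(0, 180, by = 15)
  p <- computeProfile(c(0, 2.7, 0), grid, relative = TRUE)
  expect_equal(max(profileEnergies(p)), 2.7)
  expect_equal(profileEnergies(p)[profileAngles(p) == 90], 2.7)
  expect_equal(profileEnergies(p)[profileAngles(p) %in% c(0, 180)], c(0, 0))
  expect_true(all(profileEnergies(computeProfile(c(0, 0, 0), grid)) == 0))
  expect_error(computeProfile(c(0, 1, 0), c(90, 45)), "increasing")
  expect_error(computeProfile(c(0, 1, 0), numeric(0)), "non-empty")

  expect_equal(barrierHeight(computeProfile(c(0, 7.97, 0), seq(0, 180, 5))),
               7.97)
  expect_equal(barrierHeight(EnergyProfile(c(0, 90), c(1.3, 1.3))), 0)
  ## brute-force oracle over the same grid
  g2 <- seq(-180, 180, by = 1)
  e2 <- torsionEnergy(2.47, -3.26, 0, g2)
  expect_equal(barrierHeight(computeProfile(c(2.47, -3.26, 0), g2)),
               max(e2) - min(e2))
})

test_that("unit conversion round-trips at the fixed 4.184 factor", {
  p <- computeProfile(c(1.2, -0.7, 2.2), seq(-180, 180, 30))
  q <- convertUnit(p, "kJ/mol")
  expect_equal(profileEnergies(q), profileEnergies(p) * 4.184)
  back <- convertUnit(q, "kcal/mol")
  expect_equal(profileEnergies(back), profileEnergies(p), tolerance = 1e-12)
  expect_identical(energyUnit(back), "kcal/mol")
})

test_that("parameter records are canonicalized and duplicate keys rejected", {
  tab <- TorsionParams(data.frame(tt = 0, i = 44, j = 63, k = 10, l = 3,
                                  v1 = -11.5, v2 = 6.6, v3 = 0))
  rec <- paramRecords(tab)
  expect_equal(unlist(rec[1, c("i", "j", "k", "l")], use.names = FALSE),
               c(3, 10, 63, 44))
  expect_error(TorsionParams(data.frame(
    tt = c(0, 0), i = c(44, 3), j = c(63, 10), k = c(10, 63), l = c(3, 44),
    v1 = 0, v2 = 1, v3 = 0)), "duplicate")
  ## j == k tie-break: i <= l after canonicalization
  tb <- TorsionParams(data.frame(tt = 0, i = 9, j = 5, k = 5, l = 2,
                                 v1 = 0, v2 = 1, v3 = 0))
  expect_equal(unlist(paramRecords(tb)[1, c("i", "l")], use.names = FALSE),
               c(2, 9))
})

test_that("parameter files and PES CSVs round-trip", {
  tab <- builtinParams("new")
  f <- tempfile(fileext = ".par")
  writeParamFile(tab, f)
  tab2 <- readParamFile(f)
  expect_equal(paramRecords(tab2)[, 1:8], paramRecords(tab)[, 1:8])
  expect_error(readParamFile({
    ff <- tempfile(); writeLines("0 1 2 3", ff); ff
  }), "8 fields")

  p <- computeProfile(c(0, 2.6, 0), seq(-180, 180, 15))
  f2 <- tempfile(fileext = ".csv")
  writePesCsv(p, f2)
  p2 <- readPesCsv(f2)
  expect_equal(profileAngles(p2), profileAngles(p))
  expect_equal(profileEnergies(p2), profileEnergies(p))
  expect_identical(energyUnit(p2), "kcal/mol")
})

test_that("the shipped tables carry the original and refitted triples", {
  orig <- builtinParams("original")
  rec <- lookupTorsion(orig, 0, 37, 37, 10, 3)  # phenyl amide quadruple
  expect_equal(c(rec$v1, rec$v2, rec$v3), c(0.0, 6.0, 0.0))
  new <- builtinParams("new")
  expect_equal(nrow(paramRecords(new)), 12L)
  ## amidothiophene V1 correction present with its negative onefold term
  rec <- lookupTorsion(new, 0, 44, 63, 10, 3)
  expect_equal(c(rec$v1, rec$v2, rec$v3), c(-11.5, 6.60, 0.0))
})
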