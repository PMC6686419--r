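test_that("dihedral driving reaches targets and preserves rigid geometry", {
  g <- perceiveAll(chain4Graph())
  cc <- atomCoords(g)
  for (target in c(0, 60, -90, 180, 145.5)) {
    c2 <- setDihedral(g, cc, 1, 2, 3, 4, target)
    got <- getDihedral(c2, 1, 2, 3, 4)
    expect_equal(torsionforge:::.wrap180(got - target), 0, tolerance = 1e-9)
    ## bond lengths unchanged
    bt <- bondTable(g)
    d0 <- sqrt(rowSums((cc[bt$a1, ] - cc[bt$a2, ])^2))
    d1 <- sqrt(rowSums((c2[bt$a1, ] - c2[bt$a2, ])^2))
    expect_equal(d1, d0, tolerance = 1e-12)
  }
})

test_that("enumeration is exhaustive below the cap and capped above it", {
  ## one rotatable bond: exactly 12 conformers at 30-degree steps
  g <- builtinFixture("1-phenylpyrrole")$graph
  confs <- enumerateConformers(g)
  expect_equal(length(confs@coords), 12L)
  expect_equal(sort(confs@assignments[, 1]), seq(0, 330, 30))
  ## no rotatable bonds: the input geometry
  ge <- perceiveAll(ethaneGraph())
  ## ethane's C-C bond IS rotatable; strip to a two-atom "molecule" instead
  g0 <- perceiveAll(molecularGraph(c("O", "H"),
                                   data.frame(a1 = 1, a2 = 2, order = 1),
                                   coords = rbind(c(0, 0, 0), c(0.97, 0, 0))))
  confs0 <- enumerateConformers(g0)
  expect_equal(length(confs0@coords), 1L)
  expect_equal(confs0@coords[[1]], atomCoords(g0))
  ## ethane: one bond, exhaustive
  expect_equal(length(enumerateConformers(ge)@coords), 12L)
  ## coordinates are required
  gNo <- perceiveAll(chain4Graph())
  gNo@coords <- matrix(numeric(0), 0, 3)
  expect_error(enumerateConformers(gNo), "coordinates")
})

test_that("sampling without replacement is seed-deterministic", {
  g <- builtinFixture("n-phenylacetamide")$graph  # 3 rotatable bonds
  a <- enumerateConformers(g, maxN = 50, seed = 5)
  b <- enumerateConformers(g, maxN = 50, seed = 5)
  expect_identical(a@assignments, b@assignments)
  c3 <- enumerateConformers(g, maxN = 50, seed = 6)
  expect_false(identical(a@assignments, c3@assignments))
  keys <- apply(a@assignments, 1, paste, collapse = ",")
  expect_false(anyDuplicated(keys) > 0)
  expect_true(all(a@assignments %in% seq(0, 330, 30)))
})

test_that("minimization downgrades failures per conformer and converges convex wells", {
  g <- perceiveAll(ethaneGraph())
  confs <- enumerateConformers(g, maxN = 5, seed = 1)
  well <- quadraticWellEngine(atomCoords(g))
  out <- minimizeEnsemble(confs, well)
  expect_true(all(out@status == "ok"))
  for (cc in out@coords) expect_equal(cc, atomCoords(g))
  expect_true(all(out@energies == 0))
  ## an engine that throws on one conformer fails only that conformer
  k <- 0L
  flaky <- EnergyEngine("flaky",
    energy = function(coords) 0,
    minimize = function(coords, cgSteps, lbfgsSteps, dielectric) {
      k <<- k + 1L
      if (k == 2L) stop("boom")
      list(coords = coords, energy = 1)
    })
  out <- minimizeEnsemble(confs, flaky)
  expect_equal(sum(out@status == "failed"), 1L)
  expect_equal(which(out@status == "failed"), 2L)
  expect_true(is.na(out@energies[2]))
})

test_that("twofold barriers drive a chain dihedral to the analytic minima", {
  g <- perceiveAll(chain4Graph())
  ## positive V2: 0.5 V2 (1 - cos 2 phi) vanishes at 0/180 (planar
  ## preference) and peaks at +/-90
  tab <- TorsionParams(data.frame(tt = 0, i = 0, j = 2, k = 2, l = 0,
                                  v1 = 0, v2 = 2.7, v3 = 0))
  eng <- torsionOnlyEngine(g, c(1L, 2L, 2L, 1L), tab)
  res <- eng@minimize(atomCoords(g), 300, 5000, 4)
  phi <- abs(torsionforge:::.wrap180(getDihedral(res$coords, 1, 2, 3, 4)))
  expect_true(min(abs(phi - c(0, 180))) < 1e-3)
  expect_equal(res$energy, 0, tolerance = 1e-8)
  ## negative V2 inverts the profile: minima move to +/-90
  tabNeg <- TorsionParams(data.frame(tt = 0, i = 0, j = 2, k = 2, l = 0,
                                     v1 = 0, v2 = -2.7, v3 = 0))
  engNeg <- torsionOnlyEngine(g, c(1L, 2L, 2L, 1L), tabNeg)
  resNeg <- engNeg@minimize(atomCoords(g), 300, 5000, 4)
  phiNeg <- abs(torsionforge:::.wrap180(getDihedral(resNeg$coords, 1, 2, 3, 4)))
  expect_equal(phiNeg, 90, tolerance = 1e-3)
  expect_equal(resNeg$energy, -2.7, tolerance = 1e-8)
})

test_that("the energy window keeps the <= 10 kcal/mol subset and the minimum", {
  g <- perceiveAll(ethaneGraph())
  confs <- enumerateConformers(g, maxN = 4, seed = 2)
  confs@status <- rep("ok", 4L)
  confs@energies <- c(0, 5, 9.9, 10.1)
  kept <- filterLowEnergy(confs, 10.0)
  expect_equal(length(kept@coords), 3L)
  expect_equal(kept@energies, c(0, 5, 9.9))
  ## invariance to constant offsets
  confs@energies <- confs@energies + 137.4
  expect_equal(filterLowEnergy(confs, 10.0)@energies - 137.4, c(0, 5, 9.9))
  ## all equal / single conformer
  confs@energies <- rep(3, 4)
  expect_equal(length(filterLowEnergy(confs, 10.0)@coords), 4L)
  expect_error(filterLowEnergy({
    confs@energies <- rep(NA_real_, 4); confs@status <- rep("failed", 4L); confs
  }), "no successfully minimized")
})

test_that("best RMSD is rigid-motion invariant and automorphism-aware", {
  g <- builtinFixture("toluene")$graph
  cc <- atomCoords(g)
  expect_equal(bestRmsd(list(cc), cc, g), 0, tolerance = 1e-9)
  ## rotated + translated copy
  th <- 0.83
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  cc2 <- cc %*% R + matrix(c(3, -1, 2), nrow(cc), 3, byrow = TRUE)
  expect_equal(bestRmsd(list(cc2), cc, g), 0, tolerance = 1e-9)
  ## a 180-degree phenyl flip is symmetry-equivalent: RMSD stays ~0
  da <- torsionforge:::.dihedralAtomsOf(g, detectAssignableBonds(g)[1])
  phi <- getDihedral(cc, da[1], da[2], da[3], da[4])
  ccFlip <- setDihedral(g, cc, da[1], da[2], da[3], da[4], phi + 180)
  expect_lt(bestRmsd(list(ccFlip), cc, g), 0.05)
  expect_error(bestRmsd(list(cc[1:5, ]), cc, g), "mismatch")
})

test_that("kabsch RMSD matches an independent superposition oracle", {
  skip_if_not_installed("bio3d")
  set.seed(33)
  P <- matrix(rnorm(30), 10, 3)
  Q <- P + matrix(rnorm(30, sd = 0.3), 10, 3)
  got <- kabschRmsd(P, Q)
  want <- bio3d::rmsd(as.vector(t(P)), as.vector(t(Q)), fit = TRUE)
  expect_equal(got, want, tolerance = 1e-3)  # bio3d rounds its report
})

test_that("recovery tables count cumulatively and report failures", {
  r <- recoveryTable(rep(0, 5))
  expect_equal(r@ratios, rep(1, 4))
  r <- recoveryTable(c(0.3, 0.7, 1.2, 1.8, 2.5))
  expect_equal(r@ratios, c(0.2, 0.4, 0.6, 0.8))
  expect_false(is.unsorted(r@ratios))
  r <- recoveryTable(runif(9, 0, 2), nFailed = 1L)
  expect_equal(failureRate(r), 10)
  expect_error(recoveryTable(numeric(0)), "empty")
})

test_that("torsion diagnostics flag deviations above 30 degrees and aggregate", {
  g <- builtinFixture("1-phenylpyrrole")$graph
  cc <- atomCoords(g)
  d0 <- diagnoseTorsions(g, cc, cc)
  expect_equal(nrow(d0), 1L)
  expect_false(any(d0$exceeds))
  ## drive the biaryl torsion 40 degrees away: D2D2 folds it to 40 > 30
  da <- torsionforge:::.dihedralAtomsOf(g, detectAssignableBonds(g)[1])
  phi <- getDihedral(cc, da[1], da[2], da[3], da[4])
  cc2 <- setDihedral(g, cc, da[1], da[2], da[3], da[4], phi + 40)
  d1 <- diagnoseTorsions(g, cc, cc2)
  expect_true(d1$exceeds)
  expect_equal(d1$effective, 40, tolerance = 1e-6)
  ## aggregation sums per TorsionID across molecules
  agg <- aggregateDiagnostics(list(d1, d1))
  expect_equal(agg$wrong, 2L)
  expect_equal(agg$id, d1$id)
  expect_error(diagnoseTorsions(g, cc[1:3, ], cc), "do not match")
})
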