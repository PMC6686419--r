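## Torsion parameter fitting: RMSD merit on relative profiles, systematic
## grid search (one quadruple), elitist genetic algorithm with summed-RMSD
## fitness (many references, shared quadruples).

#' Construct a reference PES
#'
#' The profile is converted to kcal/mol and shifted to a zero minimum on
#' construction.
#'
#' @param molecule identifier.
#' @param profile an [EnergyProfile-class] (kcal/mol or kJ/mol).
#' @param quadruples data.frame with columns tt, i, j, k, l and optional
#'   offset (degrees of each quadruple's dihedral relative to the driven
#'   dihedral; default 0). Repeated rows express quadruple multiplicity.
#' @return A [ReferencePES-class].
#' @export
ReferencePES <- function(molecule, profile, quadruples) {
  stopifnot(is(profile, "EnergyProfile"))
  profile <- convertUnit(profile, "kcal/mol")
  profile@energies <- profile@energies - min(profile@energies)
  quadruples <- as.data.frame(quadruples)
  if (is.null(quadruples$offset)) quadruples$offset <- 0
  new("ReferencePES", molecule = as.character(molecule), profile = profile,
      quadruples = quadruples[, c("tt", "i", "j", "k", "l", "offset")])
}

#' Construct a fit specification
#'
#' @param free data.frame with columns tt, i, j, k, l, comp ("v1", "v2" or
#'   "v3"), one row per free component. Convenience: \code{comp} may be a
#'   comma-free string like "v1v2" on a single-row input.
#' @param fixed optional data.frame (tt, i, j, k, l, v1, v2, v3) of
#'   starting values for non-free components; quadruples absent from it
#'   have all components fixed at zero, matching the convention that only
#'   V2 (and sometimes V1) is optimized while the rest stays at zero.
#' @param lower,upper bounds in kcal/mol (default -15, 15, covering every
#'   refitted magnitude with margin).
#' @param step systematic grid step (default 0.1).
#' @param ga list overriding GA settings: popSize (60), generations (300),
#'   mutSigma (0.25 kcal/mol), crossProb (0.7), elites (2), tournamentK
#'   (3), seed (mandatory for [gaFit()]).
#' @return A [FitSpec-class].
#' @export
FitSpec <- function(free, fixed = NULL, lower = -15, upper = 15, step = 0.1,
                    ga = list()) {
  free <- as.data.frame(free)
  if (nrow(free) == 1L && grepl("v[123]v", free$comp[1])) {
    comps <- regmatches(free$comp[1], gregexpr("v[123]", free$comp[1]))[[1]]
    free <- free[rep(1L, length(comps)), ]
    free$comp <- comps
    rownames(free) <- NULL
  }
  gaDefaults <- list(popSize = 60L, generations = 300L, mutSigma = 0.25,
                     crossProb = 0.7, elites = 2L, tournamentK = 3L,
                     seed = NA_integer_)
  gaDefaults[names(ga)] <- ga
  if (is.null(fixed))
    fixed <- data.frame(tt = integer(), i = integer(), j = integer(),
                        k = integer(), l = integer(), v1 = numeric(),
                        v2 = numeric(), v3 = numeric())
  new("FitSpec", free = free, fixed = as.data.frame(fixed),
      lower = lower, upper = upper, step = step, ga = gaDefaults)
}

#' RMSD merit between a force-field profile and a reference profile
#'
#' Both profiles are shifted to a zero minimum (the relative-energy
#' convention: absolute offsets are not meaningful), then the
#' root-mean-square of the pointwise differences is returned. Grids and
#' units must match.
#'
#' @param ffProfile,refProfile [EnergyProfile-class] objects on identical
#'   angle grids and in the same unit.
#' @return numeric(1) RMSD in the shared unit.
#' @export
meritRmsd <- function(ffProfile, refProfile) {
  stopifnot(is(ffProfile, "EnergyProfile"), is(refProfile, "EnergyProfile"))
  if (ffProfile@unit != refProfile@unit)
    stop("profiles must share a unit")
  if (length(ffProfile@angles) != length(refProfile@angles) ||
      any(abs(ffProfile@angles - refProfile@angles) > 1e-9))
    stop("profiles must share an identical angle grid")
  a <- ffProfile@energies - min(ffProfile@energies)
  b <- refProfile@energies - min(refProfile@energies)
  sqrt(mean((a - b)^2))
}

#' Cis/trans energy gap of a profile
#'
#' E(0 deg) - E(180 deg). The sign decides whether a onefold V1 term must
#' join the free set: a pure twofold term cannot reproduce a cis/trans
#' preference (for the amidothiophenes, a negative gap reflects the
#' S-O-contact-driven preference for the in-plane 0-degree conformation).
#'
#' @param profile an [EnergyProfile-class] whose grid contains 0 and 180.
#' @return numeric(1), profile unit.
#' @export
cisTransGap <- function(profile) {
  stopifnot(is(profile, "EnergyProfile"))
  i0 <- which(abs(profile@angles - 0) < 1e-6)
  i180 <- which(abs(profile@angles - 180) < 1e-6)
  if (!length(i0) || !length(i180))
    stop("profile grid must contain 0 and 180 degrees")
  profile@energies[i0[1]] - profile@energies[i180[1]]
}

## ---------------------------------------------------------------------------
## internal: linear basis of the model profile
## ---------------------------------------------------------------------------

## The torsion energy is linear in (V1, V2, V3):
##   E(phi) = 0.5 (1 + cos phi) V1 + 0.5 (1 - cos 2 phi) V2
##            + 0.5 (1 + cos 3 phi) V3.
## For a reference with quadruples q and offsets d_q, the model profile is
## sum_q E_q(phi + d_q); collecting terms gives one basis column per
## (quadruple key, component).

.quadKey <- function(q) paste(q$tt, q$i, q$j, q$k, q$l, sep = "-")

## basis matrix: length(grid) x (3 * nKeys), plus the key list
.modelBasis <- function(ref) {
  grid <- ref@profile@angles
  q <- ref@quadruples
  keys <- unique(.quadKey(q))
  B <- matrix(0, length(grid), 3L * length(keys))
  for (r in seq_len(nrow(q))) {
    ki <- match(.quadKey(q[r, ]), keys)
    phi <- (grid + q$offset[r]) * pi / 180
    B[, 3 * ki - 2] <- B[, 3 * ki - 2] + 0.5 * (1 + cos(phi))
    B[, 3 * ki - 1] <- B[, 3 * ki - 1] + 0.5 * (1 - cos(2 * phi))
    B[, 3 * ki]     <- B[, 3 * ki]     + 0.5 * (1 + cos(3 * phi))
  }
  list(B = B, keys = keys)
}

## fixed component values (v1, v2, v3 stacked per key) from a FitSpec
.fixedVector <- function(spec, keys) {
  v <- numeric(3L * length(keys))
  fx <- spec@fixed
  if (nrow(fx)) {
    for (r in seq_len(nrow(fx))) {
      ki <- match(paste(fx$tt[r], fx$i[r], fx$j[r], fx$k[r], fx$l[r],
                        sep = "-"), keys)
      if (is.na(ki)) next
      v[3 * ki - 2] <- fx$v1[r]; v[3 * ki - 1] <- fx$v2[r]
      v[3 * ki] <- fx$v3[r]
    }
  }
  v
}

## column indices of the free components in the stacked parameter vector
.freeIndices <- function(spec, keys) {
  f <- spec@free
  idx <- integer(nrow(f))
  for (r in seq_len(nrow(f))) {
    ki <- match(paste(f$tt[r], f$i[r], f$j[r], f$k[r], f$l[r], sep = "-"),
                keys)
    if (is.na(ki))
      stop("free quadruple ", paste(f[r, 1:5], collapse = "-"),
           " does not occur in the reference")
    idx[r] <- 3L * ki - 3L + match(f$comp[r], c("v1", "v2", "v3"))
  }
  idx
}

## assemble the fitted parameter data.frame from the stacked vector
.paramsFromVector <- function(keys, v) {
  parts <- do.call(rbind, lapply(strsplit(keys, "-"), as.integer))
  data.frame(tt = parts[, 1], i = parts[, 2], j = parts[, 3],
             k = parts[, 4], l = parts[, 5],
             v1 = v[seq_along(keys) * 3 - 2],
             v2 = v[seq_along(keys) * 3 - 1],
             v3 = v[seq_along(keys) * 3])
}

## ---------------------------------------------------------------------------
## systematic fit
## ---------------------------------------------------------------------------

#' Systematic grid-search fit of one torsion quadruple
#'
#' Exhaustively evaluates the Cartesian grid (step \code{spec@step},
#' default 0.1 kcal/mol) over the free components of a single quadruple
#' and returns the minimum-merit triple. Ties are broken toward the
#' smaller total magnitude \eqn{\sum |V|}, then lexicographically.
#'
#' @param ref a [ReferencePES-class].
#' @param spec a [FitSpec-class] whose free components all belong to one
#'   quadruple.
#' @return A [FitResult-class] with mode "systematic".
#' @export
systematicFit <- function(ref, spec) {
  stopifnot(is(ref, "ReferencePES"), is(spec, "FitSpec"))
  f <- spec@free
  if (length(unique(paste(f$tt, f$i, f$j, f$k, f$l))) != 1L)
    stop("systematic mode refits exactly one quadruple; use gaFit() for joint fits")
  mb <- .modelBasis(ref)
  v0 <- .fixedVector(spec, mb$keys)
  freeIdx <- .freeIndices(spec, mb$keys)
  gridVals <- seq(spec@lower, spec@upper, by = spec@step)
  cand <- as.matrix(expand.grid(rep(list(gridVals), length(freeIdx))))
  ## model energies for all candidates at once: base + Bfree %*% t(cand)
  base <- as.numeric(mb$B %*% v0)
  Bfree <- mb$B[, freeIdx, drop = FALSE]
  E <- matrix(base, nrow(cand), length(base), byrow = TRUE) + cand %*% t(Bfree)
  E <- E - apply(E, 1L, min)
  refE <- ref@profile@energies
  merit <- sqrt(rowMeans((E - matrix(refE, nrow(cand), length(refE),
                                     byrow = TRUE))^2))
  eps <- 1e-12
  bestMerit <- min(merit)
  tied <- which(merit <= bestMerit + eps)
  if (length(tied) > 1L) {
    mag <- rowSums(abs(cand[tied, , drop = FALSE]))
    tied <- tied[mag <= min(mag) + eps]
    if (length(tied) > 1L)
      tied <- tied[do.call(order, as.data.frame(cand[tied, , drop = FALSE]))[1L]]
  }
  best <- tied[1L]
  v <- v0
  v[freeIdx] <- cand[best, ]
  new("FitResult", params = .paramsFromVector(mb$keys, v),
      merit = merit[best], mode = "systematic",
      evaluations = nrow(cand), seed = NA_integer_, history = numeric(0))
}

## ---------------------------------------------------------------------------
## genetic algorithm
## ---------------------------------------------------------------------------

#' Genetic-algorithm fit over multiple reference scans
#'
#' Minimizes the summed RMSD merit over all references, jointly over every
#' free component (quadruples may be shared between references, which adds
#' redundancy to the fit). Elitist generational GA: tournament selection,
#' uniform crossover, Gaussian mutation clipped to the bounds; with a
#' fixed seed the result is bit-identical across runs.
#'
#' @param refs list of [ReferencePES-class] objects (or a single one).
#' @param spec a [FitSpec-class]; \code{spec@ga$seed} must be set.
#' @return A [FitResult-class] with mode "ga"; \code{history} holds the
#'   best fitness per generation (non-increasing).
#' @export
gaFit <- function(refs, spec) {
  if (is(refs, "ReferencePES")) refs <- list(refs)
  if (!length(refs)) stop("empty reference list")
  stopifnot(all(vapply(refs, is, logical(1), "ReferencePES")),
            is(spec, "FitSpec"))
  ga <- spec@ga
  if (is.na(ga$seed)) stop("gaFit requires an explicit seed in spec@ga$seed")
  ## global key set across references
  keys <- unique(unlist(lapply(refs, function(r) .quadKey(r@quadruples))))
  f <- spec@free
  freeKeys <- paste(f$tt, f$i, f$j, f$k, f$l, sep = "-")
  if (!all(freeKeys %in% keys))
    stop("every free quadruple must occur in at least one reference")
  gIdx <- cbind(match(freeKeys, keys) * 3L - 3L +
                match(f$comp, c("v1", "v2", "v3")))
  v0 <- numeric(3L * length(keys))
  fx <- spec@fixed
  if (nrow(fx)) {
    for (r in seq_len(nrow(fx))) {
      ki <- match(paste(fx$tt[r], fx$i[r], fx$j[r], fx$k[r], fx$l[r],
                        sep = "-"), keys)
      if (is.na(ki)) next
      v0[3 * ki - 2] <- fx$v1[r]; v0[3 * ki - 1] <- fx$v2[r]
      v0[3 * ki] <- fx$v3[r]
    }
  }
  ## per-reference basis restricted to the global key order
  pre <- lapply(refs, function(r) {
    mb <- .modelBasis(r)
    map <- match(mb$keys, keys)
    B <- matrix(0, nrow(mb$B), 3L * length(keys))
    for (ki in seq_along(mb$keys))
      B[, 3 * map[ki] - (2:0)] <- mb$B[, 3 * ki - (2:0)]
    list(B = B, refE = r@profile@energies)
  })
  fitness <- function(genome) {
    v <- v0; v[gIdx] <- genome
    s <- 0
    for (p in pre) {
      e <- as.numeric(p$B %*% v)
      e <- e - min(e)
      s <- s + sqrt(mean((e - p$refE)^2))
    }
    s
  }
  nG <- nrow(f)
  set.seed(ga$seed)
  pop <- matrix(stats::runif(ga$popSize * nG, spec@lower, spec@upper),
                ga$popSize, nG)
  fit <- apply(pop, 1L, fitness)
  evals <- ga$popSize
  history <- numeric(ga$generations)
  for (gen in seq_len(ga$generations)) {
    ord <- order(fit)
    newPop <- pop[ord[seq_len(ga$elites)], , drop = FALSE]
    while (nrow(newPop) < ga$popSize) {
      pick <- function() {
        cands <- sample.int(ga$popSize, ga$tournamentK)
        cands[which.min(fit[cands])]
      }
      p1 <- pop[pick(), ]; p2 <- pop[pick(), ]
      child <- p1
      if (stats::runif(1) < ga$crossProb) {
        mask <- stats::runif(nG) < 0.5
        child[mask] <- p2[mask]
      }
      child <- child + stats::rnorm(nG, 0, ga$mutSigma)
      child <- pmin(pmax(child, spec@lower), spec@upper)
      newPop <- rbind(newPop, child)
    }
    pop <- newPop
    fit <- apply(pop, 1L, fitness)
    evals <- evals + ga$popSize
    history[gen] <- min(fit)
  }
  best <- which.min(fit)
  v <- v0; v[gIdx] <- pop[best, ]
  new("FitResult", params = .paramsFromVector(keys, v), merit = fit[best],
      mode = "ga", evaluations = as.integer(evals),
      seed = as.integer(ga$seed), history = cummin(history))
}

setMethod("show", "FitResult", function(object) {
  cat("FitResult (", object@mode, "): merit ",
      format(object@merit, digits = 6), " kcal/mol, ",
      object@evaluations, " evaluations\n", sep = "")
  print(object@params)
})

#' @describeIn gaFit fitted parameter table of a fit result.
#' @param x a FitResult.
#' @export
fitParams <- function(x) { stopifnot(is(x, "FitResult")); x@params }

#' @describeIn gaFit merit value of a fit result.
#' @export
fitMerit <- function(x) { stopifnot(is(x, "FitResult")); x@merit }
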