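## Fixture molecules, file I/O and synthetic PES generation. Fixture 3D
## coordinates were embedded once with a standard 3D builder and frozen
## into extdata as SDF so tests are bit-stable without an embedding step.

## registry: fixture name -> SMILES and ground-truth annotations. The
## annotations mark the key rotatable bond by the elements/types of its
## central atoms, the expected end symmetry labels, and expected MMFF
## numeric types for selected atoms.
.FIXTURES <- list(
  "toluene" = list(
    smiles = "Cc1ccccc1",
    truth = list(nAssignable = 1L, keyBond = c("C", "C"),
                 keySymmetry = c("D3", "D2"))),
  "biphenyl" = list(
    smiles = "c1ccc(-c2ccccc2)cc1",
    truth = list(nAssignable = 1L, keyBond = c("C", "C"),
                 keySymmetry = c("D2", "D2"))),
  "n-phenylacetamide" = list(
    smiles = "CC(=O)Nc1ccccc1",
    truth = list(nAssignable = 3L, keyBond = c("N", "C"),
                 keySymmetry = c("C1", "D2"),
                 keyQuadTypes = c(37, 37, 10, 3))),
  "n-2-pyridylacetamide" = list(
    smiles = "CC(=O)Nc1ccccn1",
    truth = list(nAssignable = 3L, keyBond = c("N", "C"),
                 keySymmetry = c("C1", "C1"))),
  "n-thiophen-2-ylacetamide" = list(
    smiles = "CC(=O)Nc1cccs1",
    truth = list(nAssignable = 3L, keyBond = c("N", "C"),
                 keySymmetry = c("C1", "C1"),
                 keyQuadTypes = c(44, 63, 10, 3))),
  "1-phenylpyrrole" = list(
    smiles = "c1ccc(-n2cccc2)cc1",
    truth = list(nAssignable = 1L, keyBond = c("N", "C"),
                 keySymmetry = c("D2", "D2"),
                 keyQuadTypes = c(63, 39, 37, 37))),
  "1-phenylpyrazole" = list(
    smiles = "c1ccc(-n2cccn2)cc1",
    truth = list(nAssignable = 1L, keyBond = c("N", "C"),
                 keySymmetry = c("C1", "D2"))),
  "ortho-methyl-n-phenylacetamide" = list(
    smiles = "CC(=O)Nc1ccccc1C",
    truth = list(nAssignable = 4L, keyBond = c("N", "C"),
                 keySymmetry = c("C1", "C1"))),
  "n-methyl-n-phenylacetamide" = list(
    smiles = "CC(=O)N(C)c1ccccc1",
    truth = list(nAssignable = 4L, keyBond = c("N", "C"),
                 keySymmetry = c("C1", "D2"))),
  "ortho-fluoro-n-phenylacetamide" = list(
    smiles = "CC(=O)Nc1ccccc1F",
    truth = list(nAssignable = 3L, keyBond = c("N", "C"),
                 keySymmetry = c("C1", "C1"))))

#' Names of the built-in fixture molecules
#' @return character vector.
#' @export
fixtureNames <- function() names(.FIXTURES)

## V2000 charge field codes (column 4 of the atom block)
.V2000_CHARGE <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `5` = -1, `6` = -2,
                   `7` = -3)

## build a MolecularGraph from a ChemmineR SDF object
.graphFromSdf <- function(sdf, name = NULL) {
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  coords <- unname(ab[, 1:3, drop = FALSE])
  chargeCode <- if (ncol(ab) >= 4) as.character(ab[, 4]) else rep("0", nrow(ab))
  charges <- unname(.V2000_CHARGE[chargeCode])
  charges[is.na(charges)] <- 0
  bonds <- data.frame(a1 = as.integer(bb[, 1]), a2 = as.integer(bb[, 2]),
                      order = as.integer(bb[, 3]))
  if (any(!bonds$order %in% 1:3))
    stop("unsupported bond order (aromatic SDF bond type 4 must be kekulized)")
  if (is.null(name)) {
    hdr <- ChemmineR::header(sdf)
    name <- if (length(hdr)) trimws(hdr[[1]]) else "mol"
    if (!nzchar(name)) name <- "mol"
  }
  molecularGraph(elements, bonds, coords = coords, charges = charges,
                 name = name)
}

#' Load molecules from SDF or SMILES
#'
#' SDF records are parsed with ChemmineR; SMILES input is embedded in 3D
#' (with explicit hydrogens) through ChemmineOB. Per-record parse errors
#' are collected and reported as warnings, not raised; an empty file
#' yields an empty list with a warning.
#'
#' @param path input file (SDF: multi-record V2000; SMILES: one per line).
#' @param format "sdf" or "smiles".
#' @param perceive run [perceiveAll()] on each molecule (default TRUE).
#' @return list of [MolecularGraph-class] objects; skipped records are
#'   recorded in the \code{"skipped"} attribute.
#' @export
loadMolecules <- function(path, format = c("sdf", "smiles"),
                          perceive = TRUE) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read file: ", path)
  graphs <- list()
  skipped <- character(0)
  if (format == "sdf") {
    sdfset <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(path)),
                       error = function(e) list())
    if (!length(sdfset)) {
      warning("no records in ", path)
      return(structure(list(), skipped = character(0)))
    }
    valid <- ChemmineR::validSDF(sdfset)
    for (r in seq_along(sdfset)) {
      if (!valid[r]) {
        skipped <- c(skipped, sprintf("record %d: invalid SDF", r))
        next
      }
      g <- tryCatch(.graphFromSdf(sdfset[[r]]), error = function(e)
        conditionMessage(e))
      if (is.character(g)) {
        skipped <- c(skipped, sprintf("record %d: %s", r, g))
        next
      }
      graphs[[length(graphs) + 1L]] <- if (perceive) perceiveAll(g) else g
    }
  } else {
    if (!requireNamespace("ChemmineOB", quietly = TRUE))
      stop("SMILES input requires the ChemmineOB package")
    lines <- trimws(readLines(path, warn = FALSE))
    lines <- lines[nzchar(lines)]
    if (!length(lines)) {
      warning("no records in ", path)
      return(structure(list(), skipped = character(0)))
    }
    for (r in seq_along(lines)) {
      g <- tryCatch({
        sdfTxt <- ChemmineOB::convertFormat(
          "SMI", "SDF", paste0(lines[r], "\n"),
          options = data.frame(names = c("gen3d", "h"), args = c("", "")))
        sdfset <- ChemmineR::read.SDFset(
          ChemmineR::read.SDFstr(strsplit(sdfTxt, "\n")[[1]]))
        .graphFromSdf(sdfset[[1]], name = lines[r])
      }, error = function(e) conditionMessage(e))
      if (is.character(g)) {
        skipped <- c(skipped, sprintf("record %d (%s): %s", r, lines[r], g))
        next
      }
      graphs[[length(graphs) + 1L]] <- if (perceive) perceiveAll(g) else g
    }
  }
  if (length(skipped))
    warning("skipped ", length(skipped), " record(s): ",
            paste(skipped, collapse = "; "))
  structure(graphs, skipped = skipped)
}

#' Write molecules to an SDF file
#'
#' @param graphs a [MolecularGraph-class] or list of them.
#' @param path output file.
#' @param tags optional named character vector of SD data tags applied to
#'   every record.
#' @export
writeMolecules <- function(graphs, path, tags = character(0)) {
  if (is(graphs, "MolecularGraph")) graphs <- list(graphs)
  sdfs <- lapply(graphs, function(g) {
    n <- length(g@elements); nb <- nrow(g@bonds)
    coords <- if (nrow(g@coords)) g@coords else matrix(0, n, 3)
    ab <- cbind(coords, matrix(0, n, 13))
    rownames(ab) <- paste(g@elements, seq_len(n), sep = "_")
    colnames(ab) <- c("C1", "C2", "C3", paste0("C", 5:17))
    bb <- cbind(g@bonds$a1, g@bonds$a2, g@bonds$order,
                matrix(0, nb, 4))
    rownames(bb) <- as.character(seq_len(nb))
    colnames(bb) <- paste0("C", 1:7)
    header <- c(Molecule_Name = g@name, Source = "  torsionforge",
                Comment = "", Counts_Line = sprintf(
                  "%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
    new("SDF", header = header, atomblock = ab, bondblock = bb,
        datablock = tags)
  })
  ## IDs must be unique for record indexing; names travel in the header
  sdfset <- new("SDFset", SDF = sdfs,
                ID = make.unique(vapply(graphs, function(g) g@name,
                                        character(1))))
  ChemmineR::write.SDF(sdfset, file = path)
  invisible(path)
}

#' Built-in fixture molecule with ground-truth annotations
#'
#' Returns one of the frozen analogue molecules (N-aryl amides,
#' phenylpyrrole/pyrazole, toluene, biphenyl) with perception run, plus
#' hand-checked ground truth: the number of assignable bonds, the central
#' elements of the key rotatable bond, the expected end-symmetry labels
#' and (where relevant) the expected MMFF numeric types of the key torsion
#' quadruple.
#'
#' @param name fixture name; see [fixtureNames()].
#' @return list with elements \code{graph} (a perceived
#'   [MolecularGraph-class]), \code{truth} (annotation list) and
#'   \code{smiles}.
#' @export
builtinFixture <- function(name) {
  if (!name %in% names(.FIXTURES))
    stop("unknown fixture \"", name, "\"; available: ",
         paste(names(.FIXTURES), collapse = ", "))
  path <- system.file("extdata", "fixtures.sdf", package = "torsionforge",
                      mustWork = TRUE)
  sdfset <- suppressWarnings(ChemmineR::read.SDFset(path))
  ids <- vapply(seq_along(sdfset), function(r)
    trimws(ChemmineR::header(sdfset[[r]])[[1]]), character(1))
  idx <- match(name, ids)
  if (is.na(idx)) stop("fixture record missing from fixtures.sdf: ", name)
  g <- perceiveAll(.graphFromSdf(sdfset[[idx]], name = name))
  list(graph = g, truth = .FIXTURES[[name]]$truth,
       smiles = .FIXTURES[[name]]$smiles)
}

## ---------------------------------------------------------------------------
## Minimal MMFF numeric typing for the atom types used by the shipped
## parameter tables: 3 (carbonyl carbon), 10 (amide nitrogen), 28 (amide
## hydrogen), 37 (aromatic carbon, 6-ring), 39 (pyrrole-type nitrogen),
## 44 (thiophene sulfur), 63/64 (alpha/beta carbon of 5-membered
## heteroaromatics), 65/66 (alpha/beta pyridine-type nitrogen of the same).
## Atoms outside this set receive NA; a full MMFF typing engine is out of
## scope.
## ---------------------------------------------------------------------------

#' Assign the minimal MMFF94 numeric atom types
#'
#' @param graph a perceived [MolecularGraph-class].
#' @return integer vector (NA for atoms outside the supported set).
#' @export
assignMmffTypes <- function(graph) {
  stopifnot(is(graph, "MolecularGraph"))
  if (!graph@perceived) stop("run perceiveAll() first")
  n <- length(graph@elements)
  adj <- .adjacency(graph)
  b <- graph@bonds
  types <- rep(NA_integer_, n)
  arom5 <- Filter(function(r) length(r) == 5L && all(graph@aromAtom[r]),
                  graph@rings)
  arom6 <- Filter(function(r) length(r) == 6L && all(graph@aromAtom[r]),
                  graph@rings)
  in5 <- logical(n); for (r in arom5) in5[r] <- TRUE
  in6 <- logical(n); for (r in arom6) in6[r] <- TRUE
  ## pivot (2-electron donor) of each aromatic 5-ring and alpha/beta shells
  alpha <- logical(n); beta <- logical(n)
  for (ring in arom5) {
    contrib <- vapply(ring, .piContribution, numeric(1), graph = graph,
                      ring = ring, adj = adj)
    pivot <- ring[which(contrib == 2)[1]]
    if (is.na(pivot)) next
    a <- intersect(adj[[pivot]], ring)
    alpha[a] <- TRUE
    beta[setdiff(ring, c(pivot, a))] <- TRUE
  }
  hasDoubleTo <- function(a, el) {
    dbl <- which((b$a1 == a | b$a2 == a) & b$order == 2L)
    partners <- ifelse(b$a1[dbl] == a, b$a2[dbl], b$a1[dbl])
    any(graph@elements[partners] == el)
  }
  for (a in seq_len(n)) {
    el <- graph@elements[a]
    if (el == "C") {
      if (graph@aromAtom[a] && in6[a]) types[a] <- 37L
      else if (graph@aromAtom[a] && in5[a])
        types[a] <- if (alpha[a]) 63L else 64L
      else if (hasDoubleTo(a, "O")) types[a] <- 3L
    } else if (el == "N") {
      if (graph@aromAtom[a] && in5[a]) {
        pyrrole <- !any(b$order[(b$a1 == a | b$a2 == a)] >= 2L)
        types[a] <- if (pyrrole) 39L else if (alpha[a]) 65L else 66L
      } else if (!graph@aromAtom[a] && length(graph@sp2N) && graph@sp2N[a]) {
        ## amide nitrogen: bonded to a carbonyl carbon
        nbC <- adj[[a]][graph@elements[adj[[a]]] == "C"]
        if (any(vapply(nbC, hasDoubleTo, logical(1), el = "O")))
          types[a] <- 10L
      }
    } else if (el == "S") {
      if (graph@aromAtom[a] && in5[a]) types[a] <- 44L
    } else if (el == "H") {
      nb <- adj[[a]][1]
      if (!is.na(nb) && graph@elements[nb] == "N") types[a] <- 0L  # placeholder
    }
  }
  ## amide hydrogens need the nitrogen types resolved first
  for (a in which(graph@elements == "H")) {
    nb <- adj[[a]][1]
    types[a] <- if (!is.na(nb) && !is.na(types[nb]) && types[nb] == 10L)
      28L else NA_integer_
  }
  types
}

## ---------------------------------------------------------------------------
## Synthetic PES generation (oracle for the fitting engines)
## ---------------------------------------------------------------------------

#' Generate a synthetic reference PES from parameter triples
#'
#' Sums the three-term cosine series over the supplied triples (the
#' summation is written out independently of [torsionEnergy()] so the two
#' code paths can be cross-checked), adds optional Gaussian noise, and
#' shifts the profile to a zero minimum.
#'
#' @param triples list of numeric length-3 vectors c(v1, v2, v3), or a
#'   single such vector.
#' @param grid strictly increasing angle grid in degrees.
#' @param sigma Gaussian noise standard deviation in kcal/mol (>= 0).
#' @param seed integer seed used when sigma > 0.
#' @return list of class "SyntheticPES" with elements profile
#'   ([EnergyProfile-class]), triples, sigma, seed.
#' @export
synthPes <- function(triples, grid, sigma = 0, seed = 1L) {
  if (is.numeric(triples) && length(triples) == 3L) triples <- list(triples)
  if (sigma < 0) stop("sigma must be non-negative")
  if (length(grid) > 1L && any(diff(grid) <= 0))
    stop("grid must be strictly increasing")
  e <- rep(0, length(grid))
  for (v in triples) {
    stopifnot(length(v) == 3L)
    e <- e + 0.5 * v[1] * (1 + cospi(grid / 180)) +
         0.5 * v[2] * (1 - cospi(grid / 90)) +
         0.5 * v[3] * (1 + cospi(grid / 60))
  }
  if (sigma > 0) {
    set.seed(seed)
    e <- e + stats::rnorm(length(e), 0, sigma)
  }
  e <- e - min(e)
  structure(list(profile = EnergyProfile(grid, e, "kcal/mol"),
                 triples = triples, sigma = sigma, seed = seed),
            class = "SyntheticPES")
}

## one JSON line per pipeline stage when options(torsionforge.verbose = TRUE)
.logStage <- function(stage, ...) {
  if (!isTRUE(getOption("torsionforge.verbose"))) return(invisible())
  rec <- c(list(stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
           list(...))
  cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n", file = stderr())
  invisible()
}
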