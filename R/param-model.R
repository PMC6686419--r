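## Torsion energy model: three-term cosine series, parameter tables with
## wildcard fallback, energy profiles.

KCAL_PER_KJ <- 1 / 4.184
KJ_PER_KCAL <- 4.184

#' Torsion energy of the three-term cosine series
#'
#' Evaluates the MMFF94-style torsional energy
#' \deqn{E_T(\varphi) = 0.5\,(V_1 (1 + \cos\varphi) + V_2 (1 - \cos 2\varphi)
#'   + V_3 (1 + \cos 3\varphi))}
#' for barrier heights \eqn{V_1, V_2, V_3} (kcal/mol) at dihedral angle
#' \eqn{\varphi} (degrees). The function is periodic with period 360
#' degrees and even in \eqn{\varphi}; analytically, \eqn{E(0) = V_1 + V_3}
#' and \eqn{E(180) = 0}.
#'
#' @param v1,v2,v3 numeric(1) barrier heights in kcal/mol; negative values
#'   are allowed (several refitted triples carry them).
#' @param phi numeric vector of dihedral angles in degrees.
#' @return numeric vector of energies in kcal/mol.
#' @examples
#' torsionEnergy(0, 6, 0, 90)    # 6: the twofold barrier at 90 degrees
#' torsionEnergy(1, 1, 1, 180)   # 0: all three terms vanish at 180
#' @export
torsionEnergy <- function(v1, v2, v3, phi) {
  stopifnot(length(v1) == 1L, length(v2) == 1L, length(v3) == 1L)
  if (!all(is.finite(c(v1, v2, v3))) || !all(is.finite(phi)))
    stop("torsionEnergy: non-finite input")
  rad <- phi * pi / 180
  0.5 * (v1 * (1 + cos(rad)) + v2 * (1 - cos(2 * rad)) + v3 * (1 + cos(3 * rad)))
}

## canonical orientation of a (tt, i, j, k, l) key: j < k, or j == k and
## i <= l; the reversed quadruple denotes the same torsion.
.canonicalQuad <- function(i, j, k, l) {
  if (j > k || (j == k && i > l)) c(l, k, j, i) else c(i, j, k, l)
}

#' Construct a torsion parameter table
#'
#' Rows are canonicalized (reversed where needed) before storage; duplicate
#' keys after canonicalization are an error.
#'
#' @param records data.frame with columns tt, i, j, k, l, v1, v2, v3 and
#'   optionally provenance (default "new").
#' @param name character(1) table name.
#' @return A [TorsionParams-class] object.
#' @export
TorsionParams <- function(records, name = "unnamed") {
  records <- as.data.frame(records)
  if (is.null(records$provenance))
    records$provenance <- rep("new", nrow(records))
  if (nrow(records) > 0) {
    for (r in seq_len(nrow(records))) {
      q <- .canonicalQuad(records$i[r], records$j[r], records$k[r], records$l[r])
      records$i[r] <- q[1]; records$j[r] <- q[2]
      records$k[r] <- q[3]; records$l[r] <- q[4]
    }
  }
  rownames(records) <- NULL
  new("TorsionParams", records = records, name = name)
}

#' @describeIn TorsionParams Accessor for the record data.frame.
#' @param object,x a TorsionParams object.
#' @export
paramRecords <- function(x) {
  stopifnot(is(x, "TorsionParams"))
  x@records
}

setMethod("show", "TorsionParams", function(object) {
  cat("TorsionParams \"", object@name, "\": ", nrow(object@records),
      " record(s)\n", sep = "")
  if (nrow(object@records) > 0)
    print(utils::head(object@records, 12L))
})

#' Look up a torsion parameter record with wildcard fallback
#'
#' Resolution is staged after canonical orientation of the query: (1) exact
#' (tt, i, j, k, l); (2) single-end wildcards (tt, 0, j, k, l) then
#' (tt, i, j, k, 0); (3) double wildcard (tt, 0, j, k, 0). The first hit
#' wins. The query itself must not contain wildcards.
#'
#' @param table a [TorsionParams-class] table.
#' @param tt torsion-type index (opaque integer key; its perception from
#'   bond orders is the caller's responsibility).
#' @param i,j,k,l numeric MMFF94 atom types, all > 0.
#' @return one-row data.frame (the matching record) with an added
#'   \code{stage} column (1, 2 or 3).
#' @examples
#' tab <- builtinParams("new")
#' lookupTorsion(tab, 0, 3, 10, 37, 37)   # resolves via wildcard 0-0-10-37-0
#' @export
lookupTorsion <- function(table, tt, i, j, k, l) {
  stopifnot(is(table, "TorsionParams"))
  if (nrow(table@records) == 0L)
    stop("missing torsion parameter: table is empty")
  key <- c(tt, i, j, k, l)
  if (any(!is.finite(key)) || any(key < 0) || any(key[-1] == 0))
    stop("query quadruple must contain no wildcards (atom types > 0)")
  q <- .canonicalQuad(i, j, k, l)
  cands <- list(c(q[1], q[2], q[3], q[4]),
                c(0,    q[2], q[3], q[4]),
                c(q[1], q[2], q[3], 0),
                c(0,    q[2], q[3], 0))
  stage <- c(1L, 2L, 2L, 3L)
  rec <- table@records
  for (s in seq_along(cands)) {
    cq <- .canonicalQuad(cands[[s]][1], cands[[s]][2], cands[[s]][3], cands[[s]][4])
    hit <- which(rec$tt == tt & rec$i == cq[1] & rec$j == cq[2] &
                 rec$k == cq[3] & rec$l == cq[4])
    if (length(hit)) {
      out <- rec[hit[1L], , drop = FALSE]
      out$stage <- stage[s]
      rownames(out) <- NULL
      return(out)
    }
  }
  stop(sprintf("missing torsion parameter for canonical quadruple %d-%d-%d-%d-%d",
               tt, q[1], q[2], q[3], q[4]))
}

#' Construct an energy profile
#'
#' @param angles strictly increasing numeric vector of dihedral angles in
#'   degrees within [-180, 360].
#' @param energies numeric vector of the same length.
#' @param unit "kcal/mol" (default) or "kJ/mol".
#' @return An [EnergyProfile-class] object.
#' @export
EnergyProfile <- function(angles, energies, unit = "kcal/mol") {
  new("EnergyProfile", angles = as.numeric(angles),
      energies = as.numeric(energies), unit = unit)
}

#' @rdname EnergyProfile
#' @param x an EnergyProfile.
#' @export
profileAngles <- function(x) { stopifnot(is(x, "EnergyProfile")); x@angles }

#' @rdname EnergyProfile
#' @export
profileEnergies <- function(x) { stopifnot(is(x, "EnergyProfile")); x@energies }

#' @rdname EnergyProfile
#' @export
energyUnit <- function(x) { stopifnot(is(x, "EnergyProfile")); x@unit }

setMethod("show", "EnergyProfile", function(object) {
  cat("EnergyProfile: ", length(object@angles), " points, ",
      min(object@angles), "..", max(object@angles), " deg, unit ",
      object@unit, "\n", sep = "")
})

#' Convert an energy profile between kcal/mol and kJ/mol
#'
#' The conversion factor is fixed at 4.184 kJ per kcal.
#'
#' @param profile an [EnergyProfile-class].
#' @param unit target unit.
#' @return the converted profile.
#' @export
convertUnit <- function(profile, unit = c("kcal/mol", "kJ/mol")) {
  stopifnot(is(profile, "EnergyProfile"))
  unit <- match.arg(unit)
  if (unit == profile@unit) return(profile)
  fac <- if (unit == "kJ/mol") KJ_PER_KCAL else KCAL_PER_KJ
  EnergyProfile(profile@angles, profile@energies * fac, unit)
}

#' Evaluate a parameter triple on an angle grid
#'
#' @param record either a one-row data.frame with columns v1, v2, v3 (as
#'   returned by [lookupTorsion()]) or a numeric length-3 vector
#'   \code{c(v1, v2, v3)}.
#' @param grid strictly increasing numeric vector of angles in degrees.
#' @param relative if TRUE (default) the grid minimum is subtracted so the
#'   profile minimum is zero.
#' @return An [EnergyProfile-class] in kcal/mol.
#' @export
computeProfile <- function(record, grid, relative = TRUE) {
  v <- if (is.data.frame(record)) c(record$v1[1], record$v2[1], record$v3[1])
       else as.numeric(record)
  stopifnot(length(v) == 3L)
  if (length(grid) < 1L) stop("grid must be non-empty")
  if (length(grid) > 1L && any(diff(grid) <= 0))
    stop("grid must be strictly increasing")
  e <- torsionEnergy(v[1], v[2], v[3], grid)
  if (relative) e <- e - min(e)
  EnergyProfile(grid, e, "kcal/mol")
}

#' Barrier height of an energy profile
#'
#' @param profile an [EnergyProfile-class].
#' @return max(energies) - min(energies), in the profile's unit.
#' @export
barrierHeight <- function(profile) {
  stopifnot(is(profile, "EnergyProfile"))
  max(profile@energies) - min(profile@energies)
}

## ---------------------------------------------------------------------------
## Parameter table text format: `TT I J K L V1 V2 V3`, whitespace-separated,
## '#' comments.
## ---------------------------------------------------------------------------

#' Read a torsion parameter file
#'
#' One record per line, `TT I J K L V1 V2 V3`, whitespace separated, `#`
#' starts a comment. Quadruples are canonicalized on load.
#'
#' @param path file path.
#' @param name table name (defaults to the file name).
#' @param provenance provenance tag for all records.
#' @return A [TorsionParams-class] table.
#' @export
readParamFile <- function(path, name = basename(path), provenance = "new") {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    return(TorsionParams(data.frame(tt = integer(), i = integer(),
                                    j = integer(), k = integer(),
                                    l = integer(), v1 = numeric(),
                                    v2 = numeric(), v3 = numeric(),
                                    provenance = character()), name))
  fields <- strsplit(lines, "[[:space:]]+")
  bad <- which(lengths(fields) != 8L)
  if (length(bad))
    stop(sprintf("malformed parameter record at line %d: expected 8 fields", bad[1]))
  m <- do.call(rbind, lapply(fields, as.numeric))
  if (any(!is.finite(m))) stop("non-numeric field in parameter file")
  rec <- data.frame(tt = as.integer(m[, 1]), i = as.integer(m[, 2]),
                    j = as.integer(m[, 3]), k = as.integer(m[, 4]),
                    l = as.integer(m[, 5]), v1 = m[, 6], v2 = m[, 7],
                    v3 = m[, 8], provenance = provenance)
  TorsionParams(rec, name)
}

#' Write a torsion parameter file
#'
#' @param table a [TorsionParams-class].
#' @param path output file.
#' @export
writeParamFile <- function(table, path) {
  stopifnot(is(table, "TorsionParams"))
  rec <- table@records
  lines <- c(sprintf("# %s", table@name), "# TT I J K L V1 V2 V3",
             sprintf("%d %d %d %d %d %.6g %.6g %.6g",
                     rec$tt, rec$i, rec$j, rec$k, rec$l,
                     rec$v1, rec$v2, rec$v3))
  writeLines(lines, path)
  invisible(path)
}

#' Built-in torsion parameter tables
#'
#' \code{"original"} holds the original MMFF94s wildcard triple for the
#' N-aryl amide quadruple 0-10-37-0 (V1 = 0.0, V2 = 6.0, V3 = 0.0);
#' \code{"new"} holds the full refitted set for N-aryl amides (including
#' 5-membered heterocyclic variants and the amidothiophene V1 correction)
#' and phenylpyrroles.
#'
#' @param which "original" or "new".
#' @return A [TorsionParams-class] table.
#' @export
builtinParams <- function(which = c("new", "original")) {
  which <- match.arg(which)
  f <- if (which == "new") "mmff94s_patch_new.par" else "mmff94s_patch_original.par"
  path <- system.file("extdata", f, package = "torsionforge", mustWork = TRUE)
  readParamFile(path, name = paste0("mmff94s_patch_", which),
                provenance = if (which == "new") "new" else "original")
}

## ---------------------------------------------------------------------------
## PES CSV format: header `angle_deg,energy,unit`; one row per grid point,
## the unit column repeating the unit tag.
## ---------------------------------------------------------------------------

#' Read a PES scan from CSV
#'
#' Expects columns \code{angle_deg} and \code{energy}; an optional third
#' column \code{unit} tags the energy unit (default kcal/mol).
#'
#' @param path CSV file.
#' @return An [EnergyProfile-class].
#' @export
readPesCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("angle_deg", "energy") %in% names(df)))
    stop("PES CSV must have columns angle_deg and energy")
  unit <- if ("unit" %in% names(df)) df$unit[1] else "kcal/mol"
  EnergyProfile(df$angle_deg, df$energy, unit)
}

#' Write a PES scan to CSV
#'
#' @param profile an [EnergyProfile-class].
#' @param path output file (or "" for stdout).
#' @export
writePesCsv <- function(profile, path) {
  stopifnot(is(profile, "EnergyProfile"))
  df <- data.frame(angle_deg = profile@angles, energy = profile@energies,
                   unit = profile@unit)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
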