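## File formats: XYZ trajectories, JSON topologies, LAMMPS data export,
## PDB input for SBCG, and YAML run configuration.

#' Write a trajectory in XYZ format
#'
#' Standard multi-frame XYZ: atom count, a comment line carrying the frame
#' index and interval, then `name x y z` records.  Coordinates are written
#' with 6 decimals; a read/write round trip is lossless to that precision.
#'
#' @param trajectory a [Trajectory-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeXYZ <- function(trajectory, path) {
  stopifnot(is(trajectory, "Trajectory"))
  n <- nBeads(trajectory)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(nFrames(trajectory))) {
    m <- frameCoords(trajectory, f)
    writeLines(c(as.character(n),
                 sprintf("frame %d interval %.8g", f,
                         trajectory@frameInterval)), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", trajectory@beadNames,
                       m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' Read an XYZ trajectory
#'
#' Tolerant reader: extra columns after x, y, z are ignored with a warning;
#' malformed counts raise an error naming the offending line; a file with
#' zero frames is rejected.
#'
#' @param path XYZ file.
#' @param frameInterval frame interval to attach (default 1).
#' @param box box to attach (default from the coordinate extent).
#' @return a [Trajectory-class].
#' @export
readXYZ <- function(path, frameInterval = 1, box = NULL) {
  lines <- readLines(path)
  lines <- lines[seq_len(max(which(nzchar(trimws(lines))), 0))]
  if (!length(lines)) stop("no frames in ", path)
  frames <- list()
  nm <- NULL
  i <- 1
  warned <- FALSE
  while (i <= length(lines)) {
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 1)
      stop("parse error at line ", i, ": expected an atom count")
    if (i + 1 + n > length(lines))
      stop("parse error at line ", i, ": truncated frame")
    block <- lines[(i + 2):(i + 1 + n)]
    parts <- strsplit(trimws(block), "\\s+")
    bad <- which(vapply(parts, length, integer(1)) < 4)
    if (length(bad))
      stop("parse error at line ", i + 1 + bad[1],
           ": need 'name x y z'")
    if (any(vapply(parts, length, integer(1)) > 4) && !warned) {
      warning("extra columns ignored")
      warned <- TRUE
    }
    nm0 <- vapply(parts, `[[`, character(1), 1)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (anyNA(xyz))
      stop("parse error near line ", i + 2, ": non-numeric coordinate")
    if (is.null(nm)) nm <- nm0
    frames[[length(frames) + 1L]] <- xyz
    i <- i + 2 + n
  }
  arr <- array(unlist(frames), dim = c(length(nm), 3, length(frames)))
  if (is.null(box))
    box <- apply(arr, 2, max) - pmin(apply(arr, 2, min), 0) + 1
  new("Trajectory", coords = arr, beadNames = nm, box = box,
      frameInterval = frameInterval,
      track = list(), provenance = list(source = path))
}

#' Serialize a system topology to JSON
#'
#' Full round trip of a [DiabodySystem-class] (beads, bonded terms, rigid
#' groups, walls, tether, box) through a JSON file.
#'
#' @param system a [DiabodySystem-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeTopologyJSON <- function(system, path) {
  obj <- list(
    format = "diabodysim-topology", version = 1L,
    units = list(sigmaAngstrom = system@units@sigmaAngstrom,
                 epsilonKelvin = system@units@epsilonKelvin,
                 kTReduced = system@units@kTReduced,
                 timeUnitLabel = system@units@timeUnitLabel),
    beads = system@beads, bonds = system@bonds, angles = system@angles,
    dihedrals = system@dihedrals,
    rigidGroups = lapply(system@rigidGroups, as.integer),
    pairs = system@pairs, exclusions = system@exclusions,
    walls = system@walls, tether = system@tether, box = system@box,
    linkerN = system@linkerN, chain = as.integer(system@chain),
    provenance = system@provenance)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeTopologyJSON
#' @export
readTopologyJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "diabodysim-topology"))
    stop("not a diabodysim topology file: ", path)
  fixdf <- function(d, proto) {
    if (is.null(d) || !length(d)) return(proto)
    as.data.frame(d)
  }
  rg <- lapply(obj$rigidGroups, as.integer)
  new("DiabodySystem",
      units = unitSystem(obj$units$sigmaAngstrom, obj$units$epsilonKelvin,
                         obj$units$kTReduced, obj$units$timeUnitLabel),
      beads = as.data.frame(obj$beads),
      bonds = fixdf(obj$bonds, .emptyBonds()),
      angles = fixdf(obj$angles, .emptyAngles()),
      dihedrals = fixdf(obj$dihedrals, .emptyDihedrals()),
      rigidGroups = rg,
      pairs = fixdf(obj$pairs, data.frame(i = integer(), j = integer(),
                                          eps = numeric(), s = numeric(),
                                          rcut = numeric())),
      exclusions = fixdf(obj$exclusions,
                         data.frame(i = integer(), j = integer())),
      walls = list(lower = as.data.frame(obj$walls$lower),
                   upper = as.data.frame(obj$walls$upper)),
      tether = if (length(obj$tether)) obj$tether else list(),
      box = as.numeric(obj$box), linkerN = as.integer(obj$linkerN),
      chain = as.integer(obj$chain),
      provenance = if (length(obj$provenance)) obj$provenance else list())
}

#' Export a system as a LAMMPS data file
#'
#' Writes the topology in the `atom_style full` dialect (atom-ID molecule-ID
#' type charge x y z) with Masses, Bonds, Angles and Dihedrals sections, for
#' cross-checking the model in an external engine.  Pair and wall styles are
#' not encoded in a data file and must be set in the input script.
#'
#' @param system a [DiabodySystem-class].
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeLammpsData <- function(system, path) {
  b <- beads(system)
  n <- nrow(b)
  types <- factor(paste0(b$group, "_", format(b$diameter)))
  bd <- system@bonds; an <- system@angles; dh <- system@dihedrals
  btype <- if (nrow(bd)) factor(paste(format(bd$k), format(bd$r0))) else factor()
  atype <- if (nrow(an)) factor(paste(format(an$kTheta), format(an$theta0)))
           else factor()
  dtype <- if (nrow(dh)) factor(paste(format(dh$kPhi), format(dh$phi0)))
           else factor()
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("LAMMPS data file generated by diabodysim (reduced LJ units)")
  w("")
  w("%d atoms", n)
  w("%d bonds", nrow(bd))
  w("%d angles", nrow(an))
  w("%d dihedrals", nrow(dh))
  w("")
  w("%d atom types", nlevels(types))
  if (nlevels(btype)) w("%d bond types", nlevels(btype))
  if (nlevels(atype)) w("%d angle types", nlevels(atype))
  if (nlevels(dtype)) w("%d dihedral types", nlevels(dtype))
  w("")
  w("0.0 %.6f xlo xhi", system@box[1])
  w("0.0 %.6f ylo yhi", system@box[2])
  w("0.0 %.6f zlo zhi", system@box[3])
  w("")
  w("Masses")
  w("")
  for (t in seq_len(nlevels(types)))
    w("%d %.6f  # %s", t, b$mass[match(levels(types)[t], types)],
      levels(types)[t])
  w("")
  w("Atoms  # full")
  w("")
  for (i in seq_len(n))
    w("%d 1 %d 0.0 %.6f %.6f %.6f  # %s", i, as.integer(types[i]),
      b$x[i], b$y[i], b$z[i], b$name[i])
  if (nrow(bd)) {
    w(""); w("Bonds"); w("")
    for (q in seq_len(nrow(bd)))
      w("%d %d %d %d", q, as.integer(btype[q]), bd$i[q], bd$j[q])
  }
  if (nrow(an)) {
    w(""); w("Angles"); w("")
    for (q in seq_len(nrow(an)))
      w("%d %d %d %d %d", q, as.integer(atype[q]), an$i[q], an$j[q], an$k[q])
  }
  if (nrow(dh)) {
    w(""); w("Dihedrals"); w("")
    for (q in seq_len(nrow(dh)))
      w("%d %d %d %d %d %d", q, as.integer(dtype[q]), dh$i[q], dh$j[q],
        dh$k[q], dh$l[q])
  }
  invisible(path)
}

#' Read protein coordinates from a PDB file
#'
#' Reads a standard PDB (via the bio3d package), selects CA atoms (default)
#' or all atoms, and returns coordinates converted to sigma units together
#' with masses in Dalton, ready for [buildSbcgNanobody()].
#'
#' @param path PDB file.
#' @param ca use CA atoms only (one point per residue, residue masses) or
#'   all atoms (atomic masses).
#' @param sigmaAngstrom length unit for the conversion.
#' @return list with `coords` (m x 3 matrix, sigma) and `masses` (Dalton).
#' @export
readPdbCoords <- function(path, ca = TRUE, sigmaAngstrom = 3.5) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("readPdbCoords needs the bio3d package")
  pdb <- bio3d::read.pdb(path)
  sel <- if (ca) bio3d::atom.select(pdb, "calpha")
         else bio3d::atom.select(pdb, "protein")
  at <- pdb$atom[sel$atom, ]
  coords <- as.matrix(at[, c("x", "y", "z")]) / sigmaAngstrom
  masses <- if (ca) {
    aa3 <- c(ALA = 71.08, ARG = 156.19, ASN = 114.10, ASP = 115.09,
             CYS = 103.14, GLN = 128.13, GLU = 129.12, GLY = 57.05,
             HIS = 137.14, ILE = 113.16, LEU = 113.16, LYS = 128.17,
             MET = 131.19, PHE = 147.18, PRO = 97.12, SER = 87.08,
             THR = 101.10, TRP = 186.21, TYR = 163.18, VAL = 99.13)
    m <- aa3[at$resid]
    m[is.na(m)] <- 110
    unname(m)
  } else {
    el <- c(C = 12.01, N = 14.01, O = 16.00, S = 32.06, H = 1.008)
    m <- el[substr(trimws(at$elety), 1, 1)]
    m[is.na(m)] <- 12
    unname(m)
  }
  list(coords = coords, masses = masses)
}

.configSchema <- c("model", "N", "wallSet", "kT", "dt", "steps",
                   "sampleEvery", "seed", "outputPrefix", "nsPerTauB",
                   "trackBeads", "z0", "minDuration")

#' Read and validate a run configuration
#'
#' YAML run configuration with a fixed schema (`model`, `N`, `wallSet`,
#' `kT`, `dt`, `steps`, `sampleEvery`, `seed`, `outputPrefix`, optional
#' `nsPerTauB`, `trackBeads`, `z0`, `minDuration`); unknown keys are
#' rejected.
#'
#' @param path YAML file.
#' @return named list.
#' @export
readRunConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  unknown <- setdiff(names(cfg), .configSchema)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  need <- c("model", "N", "wallSet")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("missing configuration key(s): ", paste(miss, collapse = ", "))
  if (!cfg$model %in% c("SPH", "SBCG"))
    stop("model must be SPH or SBCG")
  defaults <- list(kT = 1, dt = 1e-4, steps = 1e5, sampleEvery = 1000,
                   seed = 1, outputPrefix = "run")
  utils::modifyList(defaults, cfg)
}

#' @rdname readRunConfig
#' @param config named list of configuration values.
#' @export
writeRunConfig <- function(config, path) {
  unknown <- setdiff(names(config), .configSchema)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Provenance sidecar for an output artifact
#'
#' Writes a JSON sidecar with the configuration, seed and package version so
#' that any artifact can be regenerated from the sidecar alone.
#'
#' @param path artifact path (sidecar gets `.provenance.json` appended).
#' @param config configuration list.
#' @param seed seed used.
#' @return sidecar path, invisibly.
#' @export
writeProvenance <- function(path, config, seed) {
  side <- paste0(path, ".provenance.json")
  obj <- list(artifact = basename(path), config = config, seed = seed,
              package = "diabodysim",
              version = as.character(utils::packageVersion("diabodysim")),
              configHash = sum(utf8ToInt(paste(deparse(config),
                                               collapse = ""))))
  jsonlite::write_json(obj, side, auto_unbox = TRUE, pretty = TRUE)
  invisible(side)
}
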