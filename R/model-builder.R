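## Builders for SPH and SBCG diabody topologies in reduced LJ units.
##
## Geometry conventions: lengths in sigma (linker monomer diameter), energies
## in kBT, the lower z-wall is the tethering wall at z = 0, the box is
## periodic in x and y.

# Bond force constant: 54 N/m converted to kT/sigma^2 at 300 K in the
# 1/2 k (r - r0)^2 convention.
.kBondDefault <- function() bondConstantFromSI(54)

# Linker bending: the quoted coefficient 1.8 is taken as the LAMMPS-style
# angle coefficient in LJ energy units (epsilon = kBT/3 at room temperature,
# no 1/2), i.e. a bending weight of 0.6 kBT (theta - pi)^2.  In the package's
# 1/2 k convention this is kTheta = 1.2 kT/rad^2, which reproduces the
# linker's persistence length of ~1.5 sigma.
.kThetaDefault <- 1.2

.sphGeometry <- list(nbDiameter = 10, paratopeDiameter = 1.6,
                     connectorDiameter = 1, linkerDiameter = 1,
                     epitopeDiameter = 1.6)

#' Convert a bond spring constant from N/m to reduced units
#'
#' Converts a stretching constant in SI units to \eqn{k_BT/\sigma^2} at the
#' given temperature, for the harmonic convention
#' \eqn{V = \frac12 k (r - r_0)^2}.
#'
#' @param nPerM spring constant in N/m.
#' @param sigmaAngstrom length unit in Angstrom.
#' @param temperatureK temperature in K.
#' @return spring constant in kT/sigma^2.
#' @examples
#' bondConstantFromSI(54)   # ~1.6e3
#' @export
bondConstantFromSI <- function(nPerM, sigmaAngstrom = 3.5,
                               temperatureK = 300) {
  kB <- 1.380649e-23
  nPerM * (sigmaAngstrom * 1e-10)^2 / (kB * temperatureK)
}

#' Wall parameter sets
#'
#' The four lower-wall parameter sets used for the flight/residence
#' simulations: two purely repulsive walls (differing in the repulsive length
#' seen by the tethered nanobody) and two attractive walls with well depths of
#' 1.5 and 2.5 kT.  `sWallNbd1`/`sWallNbd2` apply to the free and tethered
#' nanobody beads of the SPH model; all linker and connector beads always see
#' a repulsive wall with s = 0.8 sigma, and the paratopes are attracted only
#' under the attractive sets.
#'
#' @return data.frame with one row per wall set.
#' @export
wallSetTable <- function() {
  data.frame(
    set = c("repulsive#1", "repulsive#2", "attractive#1", "attractive#2"),
    sWallNbd1 = c(4.5, 4.5, 4.5, 4.5),
    sWallNbd2 = c(3.0, 4.5, 4.5, 4.5),
    sWallOther = 0.8,
    epsWall = c(1, 1, 1.5, 2.5),
    attractive = c(FALSE, FALSE, TRUE, TRUE),
    stringsAsFactors = FALSE)
}

# rcut from kind: repulsive walls are WCA (cut at the minimum), attractive
# walls are cut at 2.5 s.
.wallRcut <- function(s, attractive) ifelse(attractive, 2.5 * s, 2^(1/6) * s)

# per-bead wall tables for a named wall set
.wallSpecs <- function(beadGroup, wallSet, model = c("sph", "sbcg")) {
  model <- match.arg(model)
  ws <- wallSetTable()
  row <- ws[ws$set == wallSet, ]
  if (nrow(row) != 1L) {
    stop("unknown wall_set '", wallSet, "'; one of: ",
         paste(ws$set, collapse = ", "))
  }
  n <- length(beadGroup)
  lower <- data.frame(s = rep(row$sWallOther, n), eps = 1,
                      rcut = 0, active = TRUE)
  if (model == "sph") {
    lower$s[beadGroup == "nanobody1"] <- row$sWallNbd1
    lower$s[beadGroup == "nanobody2"] <- row$sWallNbd2
  }
  attr <- rep(FALSE, n)
  if (row$attractive) {
    attr <- beadGroup %in% c("nanobody1", "nanobody2", "paratope")
    lower$eps[attr] <- row$epsWall
  }
  lower$rcut <- .wallRcut(lower$s, attr)
  lower$active <- beadGroup != "epitope"
  # container wall: always repulsive, s = 0.8 for every bead
  upper <- data.frame(s = rep(0.8, n), eps = 1, rcut = 2^(1/6) * 0.8,
                      active = beadGroup != "epitope")
  list(lower = lower, upper = upper)
}

#' Build the flexible linker
#'
#' N unit-diameter, unit-mass beads joined by stiff harmonic bonds
#' (\eqn{r_0 = 1\sigma}) with harmonic bending terms (\eqn{\theta_0 =
#' 180^\circ}) between consecutive bonds.
#'
#' @param N number of monomers (>= 1).
#' @param kBond bond constant, kT/sigma^2 (1/2 k convention); default is
#'   54 N/m converted to reduced units (~1.6e3), giving bond-length
#'   fluctuations of about 2 percent.
#' @param kTheta bending constant, kT/rad^2 (1/2 k convention); the default
#'   1.2 corresponds to the model's bending weight of 0.6 kT per squared
#'   radian of bending and a persistence length of ~1.5 sigma.
#' @param theta0 equilibrium angle in degrees.
#' @return list with `beads` (data.frame), `bonds`, `angles`; N-1 bonds and
#'   N-2 angles.
#' @examples
#' lk <- buildLinker(10)
#' nrow(lk$bonds)   # 9
#' nrow(lk$angles)  # 8
#' @export
buildLinker <- function(N, kBond = .kBondDefault(), kTheta = .kThetaDefault,
                        theta0 = 180) {
  if (!is.numeric(N) || length(N) != 1L || N < 1 || N != round(N))
    stop("N must be a positive integer")
  beads <- data.frame(name = paste0("L", seq_len(N)), diameter = 1, mass = 1,
                      group = "linker", stringsAsFactors = FALSE)
  bonds <- if (N >= 2) {
    data.frame(i = seq_len(N - 1), j = seq_len(N - 1) + 1L,
               k = kBond, r0 = 1)
  } else data.frame(i = integer(), j = integer(), k = numeric(),
                    r0 = numeric())
  angles <- if (N >= 3) {
    data.frame(i = seq_len(N - 2), j = seq_len(N - 2) + 1L,
               k = seq_len(N - 2) + 2L, kTheta = kTheta, theta0 = theta0)
  } else data.frame(i = integer(), j = integer(), k = integer(),
                    kTheta = numeric(), theta0 = numeric())
  list(beads = beads, bonds = bonds, angles = angles)
}

.emptyBonds <- function() data.frame(i = integer(), j = integer(),
                                     k = numeric(), r0 = numeric())
.emptyAngles <- function() data.frame(i = integer(), j = integer(),
                                      k = integer(), kTheta = numeric(),
                                      theta0 = numeric())
.emptyDihedrals <- function() data.frame(i = integer(), j = integer(),
                                         k = integer(), l = integer(),
                                         kPhi = numeric(), phi0 = numeric())

# nonbonded exclusions: bonded 1-2 pairs, 1-3 pairs (second neighbours of
# the bond network, plus angle-spanning pairs for angles that cross rigid
# units), and all pairs inside a rigid group
.buildExclusions <- function(bonds, angles, rigidGroups, extra = NULL) {
  ex <- list()
  if (nrow(bonds)) {
    ex[[length(ex) + 1L]] <- cbind(bonds$i, bonds$j)
    # 1-3 pairs from bond adjacency
    nmax <- max(bonds$i, bonds$j)
    adj <- vector("list", nmax)
    for (q in seq_len(nrow(bonds))) {
      adj[[bonds$i[q]]] <- c(adj[[bonds$i[q]]], bonds$j[q])
      adj[[bonds$j[q]]] <- c(adj[[bonds$j[q]]], bonds$i[q])
    }
    for (j in seq_len(nmax)) {
      nb <- adj[[j]]
      if (length(nb) >= 2)
        ex[[length(ex) + 1L]] <- t(utils::combn(nb, 2))
    }
  }
  if (nrow(angles)) ex[[length(ex) + 1L]] <- cbind(angles$i, angles$k)
  for (g in rigidGroups)
    if (length(g) >= 2) ex[[length(ex) + 1L]] <- t(utils::combn(g, 2))
  if (!is.null(extra) && nrow(extra)) ex[[length(ex) + 1L]] <- as.matrix(extra)
  if (!length(ex))
    return(data.frame(i = integer(), j = integer()))
  m <- do.call(rbind, ex)
  ij <- cbind(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
  ij <- unique(ij)
  data.frame(i = as.integer(ij[, 1]), j = as.integer(ij[, 2]))
}

#' Build a rigid-sphere (SPH) diabody tethered to the lower wall
#'
#' Constructs the full topology of a polymer-linked two-nanobody molecule in
#' which each nanobody is a rigid sphere of diameter 10 sigma decorated with a
#' connector bead (diameter 1) and a paratope bead (diameter 1.6) at
#' diametrically opposite poles, at tangent contact with the sphere surface.
#' The N-monomer linker joins the two connector beads; the paratope of the
#' tethered nanobody (P2) is attracted to a fixed epitope bead on the lower
#' z-wall.  Angle restraints at \eqn{\theta_0 = 180^\circ} (ten times the
#' linker bending stiffness) keep the linker take-off aligned with each
#' sphere's polar axis.
#'
#' @param N linker length (monomers, >= 1).
#' @param wallSet one of `"repulsive#1"`, `"repulsive#2"`, `"attractive#1"`,
#'   `"attractive#2"`; see [wallSetTable()].
#' @param box optional `c(Lx, Ly, Lz)`; default `Lx = Ly = 5 (N + 12)`,
#'   `Lz = 2 (N + 12)`.
#' @param tethered build with an epitope bead and tether (default) or as a
#'   free molecule.
#' @param tetherEps tether well depth in kT (deep by default so that no
#'   detachment occurs at thermal energies).
#' @param kBond,kTheta linker force-field constants, see [buildLinker()].
#' @return a [DiabodySystem-class]; for a tethered system, `N + 6` diabody
#'   beads plus one epitope bead.
#' @examples
#' sys <- buildSphDiabody(10, "repulsive#2")
#' nBeads(sys)   # 17
#' @export
buildSphDiabody <- function(N, wallSet = "repulsive#2", box = NULL,
                            tethered = TRUE, tetherEps = 20,
                            kBond = .kBondDefault(),
                            kTheta = .kThetaDefault) {
  if (!is.numeric(N) || length(N) != 1L || N < 1 || N != round(N))
    stop("N must be a positive integer")
  N <- as.integer(N)
  g <- .sphGeometry
  if (is.null(box)) box <- c(5 * (N + 12), 5 * (N + 12), 2 * (N + 12))
  cx <- box[1] / 2; cy <- box[2] / 2

  rNB <- g$nbDiameter / 2; rP <- g$paratopeDiameter / 2
  rCB <- g$connectorDiameter / 2; rEpi <- g$epitopeDiameter / 2
  dPN <- rNB + rP     # paratope-sphere centre distance (tangent contact)
  dCN <- rNB + rCB    # connector-sphere centre distance

  # vertical starting structure above the epitope
  zEpi <- rEpi
  zP2 <- zEpi + 2^(1/6) * (rP + rEpi)   # at the tether minimum
  zNB2 <- zP2 + dPN
  zCB2 <- zNB2 + dCN
  zL <- zCB2 + rCB + 0.5 + seq_len(N) - 1      # L1 ... LN
  zCB1 <- zL[N] + 1
  zNB1 <- zCB1 + dCN
  zP1 <- zNB1 + dPN

  lnames <- paste0("L", seq_len(N))
  names <- c("P2", "NB2", "CB2", lnames, "CB1", "NB1", "P1")
  diam <- c(g$paratopeDiameter, g$nbDiameter, g$connectorDiameter,
            rep(g$linkerDiameter, N), g$connectorDiameter, g$nbDiameter,
            g$paratopeDiameter)
  grp <- c("paratope", "nanobody2", "connector", rep("linker", N),
           "connector", "nanobody1", "paratope")
  z <- c(zP2, zNB2, zCB2, zL, zCB1, zNB1, zP1)
  if (tethered) {
    names <- c("EPI", names)
    diam <- c(g$epitopeDiameter, diam)
    grp <- c("epitope", grp)
    z <- c(zEpi, z)
  }
  n <- length(names)
  beads <- data.frame(id = seq_len(n), name = names, diameter = diam,
                      mass = diam^3, group = grp, x = cx, y = cy, z = z,
                      fixed = grp == "epitope", stringsAsFactors = FALSE)

  id <- function(nm) match(nm, beads$name)
  iL <- id(lnames)

  link <- buildLinker(N, kBond = kBond, kTheta = kTheta)
  bonds <- rbind(
    data.frame(i = id("CB2"), j = iL[1], k = kBond, r0 = rCB + 0.5),
    if (N >= 2) data.frame(i = iL[link$bonds$i], j = iL[link$bonds$j],
                           k = link$bonds$k, r0 = link$bonds$r0),
    data.frame(i = iL[N], j = id("CB1"), k = kBond, r0 = rCB + 0.5))

  angles <- .emptyAngles()
  if (N >= 3)
    angles <- data.frame(i = iL[link$angles$i], j = iL[link$angles$j],
                         k = iL[link$angles$k], kTheta = kTheta, theta0 = 180)
  kRestraint <- 10 * kTheta
  restr <- rbind(
    data.frame(i = iL[N], j = id("CB1"), k = id("P1")),      # LN-CB1-P1
    data.frame(i = id("P2"), j = id("CB2"), k = iL[1]),      # P2-CB2-L1
    if (N >= 2) data.frame(i = iL[2], j = iL[1], k = id("CB2")),
    if (N >= 2) data.frame(i = iL[N - 1], j = iL[N], k = id("CB1")))
  angles <- rbind(angles,
                  data.frame(i = restr$i, j = restr$j, k = restr$k,
                             kTheta = kRestraint, theta0 = 180))

  rigidGroups <- list(nbd1 = id(c("NB1", "CB1", "P1")),
                      nbd2 = id(c("NB2", "CB2", "P2")))

  pairs <- data.frame(i = integer(), j = integer(), eps = numeric(),
                      s = numeric(), rcut = numeric())
  tether <- list()
  extraExcl <- NULL
  if (tethered) {
    sT <- rP + rEpi
    pairs <- data.frame(i = id("P2"), j = id("EPI"), eps = tetherEps,
                        s = sT, rcut = 2.5 * sT)
    tether <- list(epitope = id("EPI"), paratope = id("P2"), eps = tetherEps,
                   s = sT, rcut = 2.5 * sT)
    extraExcl <- data.frame(i = id("P2"), j = id("EPI"))
  }

  walls <- .wallSpecs(grp, wallSet, "sph")
  excl <- .buildExclusions(bonds, angles, rigidGroups, extraExcl)

  new("DiabodySystem", units = unitSystem(), beads = beads, bonds = bonds,
      angles = angles, dihedrals = .emptyDihedrals(),
      rigidGroups = rigidGroups, pairs = pairs, exclusions = excl,
      walls = walls, tether = tether, box = box, linkerN = N,
      chain = as.integer(iL),
      provenance = list(builder = "buildSphDiabody", N = N,
                        wallSet = wallSet, tethered = tethered))
}

#' Build a bare linker chain (no nanobodies, no walls)
#'
#' A free N-monomer chain used as the reference system for persistence-length
#' estimation; bending and stretching terms as in the diabody linker, WCA
#' excluded volume, no walls and no tether.
#'
#' @inheritParams buildLinker
#' @param box optional box; default a cube of side `4 N` sigma.
#' @return a [DiabodySystem-class] with `N` beads and inactive walls.
#' @export
buildFreeLinker <- function(N, box = NULL, kBond = .kBondDefault(),
                            kTheta = .kThetaDefault) {
  if (!is.numeric(N) || length(N) != 1L || N < 2 || N != round(N))
    stop("N must be an integer >= 2")
  N <- as.integer(N)
  if (is.null(box)) box <- rep(4 * N, 3)
  link <- buildLinker(N, kBond = kBond, kTheta = kTheta)
  beads <- data.frame(id = seq_len(N), name = link$beads$name, diameter = 1,
                      mass = 1, group = "linker", x = box[1] / 2,
                      y = box[2] / 2,
                      z = box[3] / 2 + seq_len(N) - (N + 1) / 2,
                      fixed = FALSE, stringsAsFactors = FALSE)
  angles <- if (nrow(link$angles)) {
    data.frame(i = link$angles$i, j = link$angles$j, k = link$angles$k,
               kTheta = link$angles$kTheta, theta0 = link$angles$theta0)
  } else .emptyAngles()
  n <- N
  walls <- list(lower = data.frame(s = rep(0.8, n), eps = 1,
                                   rcut = 2^(1/6) * 0.8, active = FALSE),
                upper = data.frame(s = rep(0.8, n), eps = 1,
                                   rcut = 2^(1/6) * 0.8, active = FALSE))
  excl <- .buildExclusions(link$bonds, angles, list())
  new("DiabodySystem", units = unitSystem(), beads = beads,
      bonds = link$bonds, angles = angles, dihedrals = .emptyDihedrals(),
      rigidGroups = list(),
      pairs = data.frame(i = integer(), j = integer(), eps = numeric(),
                         s = numeric(), rcut = numeric()),
      exclusions = excl, walls = walls, tether = list(), box = box,
      linkerN = N, chain = seq_len(N),
      provenance = list(builder = "buildFreeLinker", N = N))
}

#' Assign bead radii from masses
#'
#' Mass-proportional volume rule relative to a reference monomer: a bead of
#' the reference mass has radius 0.5 sigma, and
#' \eqn{r_i = 0.5\,\sigma\,(m_i/m_{ref})^{1/3}} in general, so that total
#' bead volume is conserved in units of the reference-monomer volume.
#'
#' @param masses bead masses (any consistent unit).
#' @param referenceMass mass of the reference monomer (default 44, the PEG
#'   monomer in Dalton).
#' @return radii in sigma.
#' @examples
#' assignBeadRadii(c(44, 352), 44)   # 0.5, 1.0
#' @export
assignBeadRadii <- function(masses, referenceMass = 44) {
  if (any(!is.finite(masses)) || any(masses <= 0))
    stop("masses must be positive")
  if (referenceMass <= 0) stop("referenceMass must be positive")
  0.5 * (masses / referenceMass)^(1/3)
}

#' Shape-based coarse graining of a protein coordinate cloud
#'
#' Maps a point cloud (atoms or residues, with masses) onto `nBeads`
#' coarse-grained beads using a topology-representing neural-gas map: the
#' bead positions are the converged codebook vectors of rank-based
#' competitive learning over the input points, bead masses are the summed
#' masses of the points in each bead's Voronoi domain, and the bead network
#' is wired either from supplied point-level connectivity (preferred: bonds
#' between beads whose domains are joined by an input bond) or from the
#' competitive-Hebbian adjacency (first and second best-matching units).
#'
#' @param coords numeric matrix `m x 3` of input points (in sigma).
#' @param masses point masses (length m); default 1 for all.
#' @param nBeads number of coarse-grained beads.
#' @param seed RNG seed for the map (deterministic given the seed).
#' @param connectivity optional integer matrix of point-index pairs (bonds in
#'   the input system).
#' @param epochs adaptation passes over the data.
#' @param kBond,kTheta force constants for the generated bonds and angles.
#' @param referenceMass reference monomer mass for [assignBeadRadii()] (same
#'   unit as `masses`).
#' @return list with `beads` (data.frame: x, y, z, mass, radius), `bonds`,
#'   `angles`, `assignment` (bead index per input point).
#' @export
buildSbcgNanobody <- function(coords, masses = NULL, nBeads = 40, seed = 1,
                              connectivity = NULL, epochs = 60,
                              kBond = 50, kTheta = 20, referenceMass = 44) {
  coords <- as.matrix(coords)
  if (nrow(coords) == 0) stop("empty input cloud")
  if (ncol(coords) != 3) stop("coords must be m x 3")
  if (is.null(masses)) masses <- rep(1, nrow(coords))
  if (length(masses) != nrow(coords)) stop("masses length mismatch")
  if (any(masses <= 0)) stop("masses must be positive")
  if (nBeads < 1) stop("nBeads must be >= 1")
  if (nBeads > nrow(coords)) stop("nBeads exceeds the number of input points")

  m <- nrow(coords)
  rng <- .seededRNG(seed)
  W <- coords[rng$sampleInt(m, nBeads), , drop = FALSE]

  if (nBeads > 1) {
    tmax <- epochs * m
    lam0 <- nBeads / 2; lamF <- 0.01
    eps0 <- 0.3; epsF <- 0.02
    order <- rng$sampleInt(m, tmax, replace = TRUE)
    for (t in seq_len(tmax)) {
      v <- coords[order[t], ]
      d2 <- (W[, 1] - v[1])^2 + (W[, 2] - v[2])^2 + (W[, 3] - v[3])^2
      rk <- rank(d2, ties.method = "first") - 1
      frac <- (t - 1) / max(tmax - 1, 1)
      lam <- lam0 * (lamF / lam0)^frac
      ep <- eps0 * (epsF / eps0)^frac
      h <- ep * exp(-rk / lam)
      W <- W + h * (matrix(v, nBeads, 3, byrow = TRUE) - W)
    }
  }

  d2all <- outer(rowSums(coords^2), rowSums(W^2), "+") -
    2 * coords %*% t(W)
  assign <- max.col(-d2all)
  # snap any empty bead onto its least-well-represented point
  for (b in which(tabulate(assign, nBeads) == 0)) {
    worst <- which.max(apply(d2all, 1, min))
    assign[worst] <- b
    W[b, ] <- coords[worst, ]
    d2all[worst, ] <- Inf
  }
  beadMass <- as.numeric(tapply(masses, factor(assign, levels = seq_len(nBeads)),
                                sum, default = 0))
  # codebook refined to the mass-weighted centroid of each domain
  for (b in seq_len(nBeads)) {
    sel <- assign == b
    W[b, ] <- colSums(coords[sel, , drop = FALSE] * masses[sel]) /
      sum(masses[sel])
  }

  edges <- matrix(integer(), 0, 2)
  if (nBeads >= 2) {
    if (!is.null(connectivity)) {
      cc <- as.matrix(connectivity)
      ab <- cbind(assign[cc[, 1]], assign[cc[, 2]])
      ab <- ab[ab[, 1] != ab[, 2], , drop = FALSE]
      if (nrow(ab))
        edges <- unique(cbind(pmin(ab[, 1], ab[, 2]), pmax(ab[, 1], ab[, 2])))
    } else {
      # competitive Hebbian rule: connect first and second BMU of each point
      bmu2 <- t(apply(d2all, 1, function(d) order(d)[1:2]))
      edges <- unique(cbind(pmin(bmu2[, 1], bmu2[, 2]),
                            pmax(bmu2[, 1], bmu2[, 2])))
    }
  }

  beadDist <- function(a, b) sqrt(sum((W[a, ] - W[b, ])^2))
  bonds <- if (nrow(edges)) {
    data.frame(i = edges[, 1], j = edges[, 2], k = kBond,
               r0 = mapply(beadDist, edges[, 1], edges[, 2]))
  } else .emptyBonds()

  angles <- .emptyAngles()
  if (nrow(edges)) {
    adj <- lapply(seq_len(nBeads), function(b)
      sort(unique(c(edges[edges[, 1] == b, 2], edges[edges[, 2] == b, 1]))))
    alist <- list()
    for (j in seq_len(nBeads)) {
      nb <- adj[[j]]
      if (length(nb) >= 2) {
        pr <- utils::combn(nb, 2)
        for (q in seq_len(ncol(pr))) {
          i <- pr[1, q]; k <- pr[2, q]
          v1 <- W[i, ] - W[j, ]; v2 <- W[k, ] - W[j, ]
          th <- acos(max(-1, min(1, sum(v1 * v2) /
                                   sqrt(sum(v1^2) * sum(v2^2)))))
          alist[[length(alist) + 1L]] <-
            data.frame(i = i, j = j, k = k, kTheta = kTheta,
                       theta0 = th * 180 / pi)
        }
      }
    }
    if (length(alist)) angles <- do.call(rbind, alist)
  }

  radius <- assignBeadRadii(beadMass, referenceMass)
  list(beads = data.frame(x = W[, 1], y = W[, 2], z = W[, 3],
                          mass = beadMass, radius = radius),
       bonds = bonds, angles = angles, assignment = assign)
}

#' Synthetic nanobody-like point cloud
#'
#' A reproducible stand-in for the residue coordinates of a ~126-residue
#' single-domain antibody: points drawn inside a prolate ellipsoid whose
#' major/minor diameters bracket 10 sigma (the SPH sphere diameter equals the
#' geometric mean of the axes), with residue-like masses.  Synthetic; it
#' reproduces only overall shape and mass, not any real structure.
#'
#' @param nResidues number of points.
#' @param seed RNG seed.
#' @param semiAxes ellipsoid semi-axes in sigma.
#' @return list with `coords` (matrix, sigma) and `masses` (Dalton).
#' @export
syntheticNanobodyCloud <- function(nResidues = 126, seed = 1,
                                   semiAxes = c(5.6, 4.1, 4.1)) {
  rng <- .seededRNG(seed)
  pts <- matrix(0, nResidues, 3)
  got <- 0
  while (got < nResidues) {
    p <- rng$runif(3) * 2 - 1
    if (sum(p^2) <= 1) {
      got <- got + 1
      pts[got, ] <- p * semiAxes
    }
  }
  masses <- 110 + rng$runif(nResidues) * 40   # residue-like masses, Da
  list(coords = pts, masses = masses)
}

#' Build a shape-based (SBCG) diabody tethered to the lower wall
#'
#' Two SBCG nanobodies (flexible bead networks from [buildSbcgNanobody()])
#' joined by an N-monomer linker via connector beads, each decorated with a
#' paratope bead at the pole opposite its connector.  Both nanobodies see the
#' wall with s = 0.8 sigma per bead (the wall resolves their shape, unlike
#' the SPH sphere).  Besides the straightening angle restraints of the SPH
#' model, one harmonic dihedral per nanobody restrains rotation about its
#' long axis.
#'
#' @inheritParams buildSphDiabody
#' @param nanobody output of [buildSbcgNanobody()]; default builds one from
#'   [syntheticNanobodyCloud()] with 40 beads.
#' @param seed seed for the default nanobody map.
#' @return a [DiabodySystem-class].
#' @export
buildSbcgDiabody <- function(N, wallSet = "repulsive#1", nanobody = NULL,
                             box = NULL, seed = 1, tethered = TRUE,
                             tetherEps = 20, kBond = .kBondDefault(),
                             kTheta = .kThetaDefault) {
  if (!is.numeric(N) || length(N) != 1L || N < 2 || N != round(N))
    stop("N must be an integer >= 2")
  N <- as.integer(N)
  if (is.null(nanobody)) {
    cloud <- syntheticNanobodyCloud(seed = seed)
    nanobody <- buildSbcgNanobody(cloud$coords, cloud$masses, nBeads = 40,
                                  seed = seed)
  }
  if (is.null(box)) box <- c(5 * (N + 12), 5 * (N + 12), 2 * (N + 12))
  cx <- box[1] / 2; cy <- box[2] / 2
  g <- .sphGeometry
  rP <- g$paratopeDiameter / 2; rCB <- g$connectorDiameter / 2
  rEpi <- g$epitopeDiameter / 2

  nb <- nanobody$beads
  nbn <- nrow(nb)
  xyz <- as.matrix(nb[, c("x", "y", "z")])
  ctr <- colSums(xyz * nb$mass) / sum(nb$mass)
  xyz <- sweep(xyz, 2, ctr)
  # principal (long) axis -> z
  ev <- eigen(crossprod(xyz) / nbn, symmetric = TRUE)
  axis <- ev$vectors[, 1]
  ref <- if (abs(axis[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * axis) * axis; e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(axis[2] * e1[3] - axis[3] * e1[2],
          axis[3] * e1[1] - axis[1] * e1[3],
          axis[1] * e1[2] - axis[2] * e1[1])
  R <- cbind(e1, e2, axis)            # body -> world, axis along z
  loc <- xyz %*% R                    # coordinates with long axis as 3rd col

  zmin <- min(loc[, 3]); zmax <- max(loc[, 3])
  iBot <- which.min(loc[, 3]); iTop <- which.max(loc[, 3])
  rBot <- nb$radius[iBot]; rTop <- nb$radius[iTop]

  placeNB <- function(zBase, flip) {
    # flip: paratope pole points down (tethered unit)
    l <- loc
    if (flip) l[, 3] <- -l[, 3]
    l[, 3] <- l[, 3] - min(l[, 3]) + zBase
    cbind(cx + l[, 1], cy + l[, 2], l[, 3])
  }

  zEpi <- rEpi
  zP2 <- zEpi + 2^(1/6) * (rP + rEpi)
  # tethered copy is flipped (paratope pole down); in the flipped copy the
  # bead iTop lands at the bottom.  P2/CB2 sit on their pole bead's own
  # vertical so the attachment bonds start at rest length.
  zBase2 <- zP2 + rP + rTop
  pos2 <- placeNB(zBase2, flip = TRUE)
  p2xy <- pos2[iTop, 1:2]
  zP2v <- pos2[iTop, 3] - (rP + rTop)
  cb2xy <- pos2[iBot, 1:2]
  zCB2 <- pos2[iBot, 3] + rCB + rBot
  zL <- zCB2 + 2 * rCB + seq_len(N) - 1
  zCB1 <- zL[N] + 2 * rCB
  zBase1 <- zCB1 + rCB + rBot
  pos1 <- placeNB(zBase1, flip = FALSE)
  # shift the free copy so its connector pole sits right above CB1
  pos1[, 1] <- pos1[, 1] - (pos1[iBot, 1] - cb2xy[1])
  pos1[, 2] <- pos1[, 2] - (pos1[iBot, 2] - cb2xy[2])
  p1xy <- pos1[iTop, 1:2]
  zP1 <- pos1[iTop, 3] + rP + rTop

  lnames <- paste0("L", seq_len(N))
  nb2names <- sprintf("NB2_%02d", seq_len(nbn))
  nb1names <- sprintf("NB1_%02d", seq_len(nbn))
  names <- c("EPI"[tethered], "P2", nb2names, "CB2", lnames, "CB1",
             nb1names, "P1")
  grp <- c("epitope"[tethered], "paratope", rep("nanobody2", nbn),
           "connector", rep("linker", N), "connector",
           rep("nanobody1", nbn), "paratope")
  diam <- c(g$epitopeDiameter[tethered], g$paratopeDiameter,
            2 * nb$radius, g$connectorDiameter, rep(1, N),
            g$connectorDiameter, 2 * nb$radius, g$paratopeDiameter)
  massRed <- nb$mass / 44   # reduced masses relative to the PEG monomer
  mass <- c((rEpi * 2)^3[tethered], g$paratopeDiameter^3, massRed, 1,
            rep(1, N), 1, massRed, g$paratopeDiameter^3)
  xs <- c(p2xy[1][tethered], p2xy[1], pos2[, 1], cb2xy[1], rep(cb2xy[1], N),
          cb2xy[1], pos1[, 1], p1xy[1])
  ys <- c(p2xy[2][tethered], p2xy[2], pos2[, 2], cb2xy[2], rep(cb2xy[2], N),
          cb2xy[2], pos1[, 2], p1xy[2])
  zs <- c(zEpi[tethered], zP2v, pos2[, 3], zCB2, zL, zCB1, pos1[, 3], zP1)

  n <- length(names)
  beads <- data.frame(id = seq_len(n), name = names, diameter = diam,
                      mass = mass, group = grp, x = xs, y = ys, z = zs,
                      fixed = grp == "epitope", stringsAsFactors = FALSE)
  id <- function(nm) match(nm, beads$name)
  iL <- id(lnames)
  i2 <- id(nb2names); i1 <- id(nb1names)

  # pole beads: in the flipped tethered copy iTop is the lower (paratope)
  # pole; in the free copy iBot is the lower (connector) pole
  pole2P <- i2[iTop]; pole2CB <- i2[iBot]
  pole1CB <- i1[iBot]; pole1P <- i1[iTop]

  nbBonds <- nanobody$bonds
  protBond <- function(idx, off) {
    if (!nrow(nbBonds)) return(NULL)
    data.frame(i = idx[nbBonds$i], j = idx[nbBonds$j], k = nbBonds$k,
               r0 = nbBonds$r0)
  }
  attach1 <- function(att, pole, rAtt) {
    data.frame(i = att, j = pole, k = 50,
               r0 = rAtt + nb$radius[ifelse(pole %in% i2, match(pole, i2),
                                            match(pole, i1))])
  }
  bonds <- rbind(
    protBond(i2), protBond(i1),
    attach1(id("P2"), pole2P, rP), attach1(id("CB2"), pole2CB, rCB),
    attach1(id("CB1"), pole1CB, rCB), attach1(id("P1"), pole1P, rP),
    data.frame(i = id("CB2"), j = iL[1], k = kBond, r0 = 2 * rCB),
    if (N >= 2) data.frame(i = iL[seq_len(N - 1)], j = iL[seq_len(N - 1) + 1],
                           k = kBond, r0 = 1),
    data.frame(i = iL[N], j = id("CB1"), k = kBond, r0 = 2 * rCB))

  nbAngles <- nanobody$angles
  protAngle <- function(idx) {
    if (!nrow(nbAngles)) return(NULL)
    data.frame(i = idx[nbAngles$i], j = idx[nbAngles$j], k = idx[nbAngles$k],
               kTheta = nbAngles$kTheta, theta0 = nbAngles$theta0)
  }
  kRestraint <- 10 * kTheta
  angles <- rbind(
    protAngle(i2), protAngle(i1),
    if (N >= 3) data.frame(i = iL[seq_len(N - 2)], j = iL[seq_len(N - 2) + 1],
                           k = iL[seq_len(N - 2) + 2], kTheta = kTheta,
                           theta0 = 180),
    data.frame(i = iL[N], j = id("CB1"), k = id("P1"),
               kTheta = kRestraint, theta0 = 180),
    data.frame(i = id("P2"), j = id("CB2"), k = iL[1],
               kTheta = kRestraint, theta0 = 180),
    data.frame(i = iL[2], j = iL[1], k = id("CB2"),
               kTheta = kRestraint, theta0 = 180),
    data.frame(i = iL[N - 1], j = iL[N], k = id("CB1"),
               kTheta = kRestraint, theta0 = 180))

  # anti-rotation dihedrals: linker bead, connector, and two protein beads
  pickRef <- function(idx, pole) {
    cand <- setdiff(idx, pole)
    cand[order(abs(beads$z[cand] - mean(beads$z[idx])))[1:2]]
  }
  ref2 <- pickRef(i2, pole2CB); ref1 <- pickRef(i1, pole1CB)
  dihedrals <- rbind(
    data.frame(i = iL[1], j = id("CB2"), k = ref2[1], l = ref2[2],
               kPhi = 10, phi0 = NA),
    data.frame(i = iL[N], j = id("CB1"), k = ref1[1], l = ref1[2],
               kPhi = 10, phi0 = NA))

  pairs <- data.frame(i = integer(), j = integer(), eps = numeric(),
                      s = numeric(), rcut = numeric())
  tether <- list()
  extraExcl <- NULL
  if (tethered) {
    sT <- rP + rEpi
    pairs <- data.frame(i = id("P2"), j = id("EPI"), eps = tetherEps,
                        s = sT, rcut = 2.5 * sT)
    tether <- list(epitope = id("EPI"), paratope = id("P2"), eps = tetherEps,
                   s = sT, rcut = 2.5 * sT)
    extraExcl <- data.frame(i = id("P2"), j = id("EPI"))
  }
  excl <- .buildExclusions(bonds, angles, list(), extraExcl)
  walls <- .wallSpecs(grp, wallSet, "sbcg")

  sys <- new("DiabodySystem", units = unitSystem(), beads = beads,
             bonds = bonds, angles = angles, dihedrals = dihedrals,
             rigidGroups = list(), pairs = pairs, exclusions = excl,
             walls = walls, tether = tether, box = box, linkerN = N,
             chain = as.integer(iL),
             provenance = list(builder = "buildSbcgDiabody", N = N,
                               wallSet = wallSet, seed = seed))
  # set dihedral equilibria to the built geometry
  sys@dihedrals$phi0 <- .builtDihedralAngles(sys)
  sys
}

# equilibrium dihedral angles evaluated on the build coordinates (degrees)
.builtDihedralAngles <- function(system) {
  d <- system@dihedrals
  if (!nrow(d)) return(numeric())
  x <- startCoords(system)
  vapply(seq_len(nrow(d)), function(q) {
    b1 <- x[d$j[q], ] - x[d$i[q], ]
    b2 <- x[d$k[q], ] - x[d$j[q], ]
    b3 <- x[d$l[q], ] - x[d$k[q], ]
    n1 <- c(b1[2]*b2[3]-b1[3]*b2[2], b1[3]*b2[1]-b1[1]*b2[3],
            b1[1]*b2[2]-b1[2]*b2[1])
    n2 <- c(b2[2]*b3[3]-b2[3]*b3[2], b2[3]*b3[1]-b2[1]*b3[3],
            b2[1]*b3[2]-b2[2]*b3[1])
    m1 <- c(n1[2]*n2[3]-n1[3]*n2[2], n1[3]*n2[1]-n1[1]*n2[3],
            n1[1]*n2[2]-n1[2]*n2[1])
    atan2(sum(m1 * b2) / sqrt(sum(b2^2)), sum(n1 * n2)) * 180 / pi
  }, numeric(1))
}

#' Beads forming the free nanobody (nbd-1)
#'
#' The bead set whose centre of mass defines the collective variables: the
#' free nanobody (NB1 for SPH, all NB1 beads for SBCG) together with CB1 and
#' P1.
#'
#' @param system a [DiabodySystem-class].
#' @return integer bead ids.
#' @export
nbd1Beads <- function(system) {
  b <- beads(system)
  which(b$group == "nanobody1" | b$name %in% c("CB1", "P1"))
}
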