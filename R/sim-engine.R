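## R-side driver for the compiled sampling kernels: system packing, energy
## and force evaluation, Brownian dynamics, and Metropolis Monte Carlo.

#' @useDynLib diabodysim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# deterministic RNG stream isolated from the user's .Random.seed
.seededRNG <- function(seed) {
  saved <- NULL
  grab <- function() {
    if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
  }
  put <- function(s) {
    if (is.null(s)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", s, globalenv())
  }
  outer <- grab()
  set.seed(seed)
  state <- grab()
  put(outer)
  run <- function(f) {
    outer <- grab()
    put(state)
    res <- f()
    state <<- grab()
    put(outer)
    res
  }
  list(runif = function(n = 1) run(function() stats::runif(n)),
       rnorm = function(n = 1) run(function() stats::rnorm(n)),
       sampleInt = function(n, size, replace = FALSE)
         run(function() sample.int(n, size, replace = replace)))
}

# derive independent integer sub-seeds from one master seed
.subSeeds <- function(seed, n) {
  rng <- .seededRNG(seed)
  rng$sampleInt(.Machine$integer.max - 1L, n, replace = TRUE)
}

# normalize a bias/cv spec: beads can be ids or names; weights default to
# mass fractions
.normalizeCvSpec <- function(system, spec) {
  b <- beads(system)
  idx <- spec$idx
  if (is.character(idx)) idx <- match(idx, b$name)
  if (anyNA(idx)) stop("unknown bead in collective-variable spec")
  w <- spec$w
  if (is.null(w)) w <- b$mass[idx] / sum(b$mass[idx])
  out <- list(type = spec$type, idx = as.integer(idx), w = w)
  if (!is.null(spec$k)) out$k <- spec$k
  if (!is.null(spec$center)) out$center <- spec$center
  if (spec$type == "com_xy") {
    if (is.null(spec$x0)) {
      if (!length(system@tether)) stop("com_xy needs x0/y0 or a tether")
      epi <- system@tether$epitope
      out$x0 <- b$x[epi]; out$y0 <- b$y[epi]
    } else {
      out$x0 <- spec$x0; out$y0 <- spec$y0
    }
  }
  out
}

#' Collective-variable definitions
#'
#' `cvRhoZ()` is the height of the centre of mass of the free nanobody
#' (nbd-1, i.e. NB1 beads + CB1 + P1) above the tethering wall; `cvRhoXY()`
#' is the in-plane distance between that centre of mass and the tethering
#' point.
#'
#' @param system a [DiabodySystem-class].
#' @return a spec list understood by the samplers and [runUmbrella()].
#' @export
cvRhoZ <- function(system) {
  list(type = "com_z", idx = nbd1Beads(system), w = NULL)
}

#' @rdname cvRhoZ
#' @export
cvRhoXY <- function(system) {
  list(type = "com_xy", idx = nbd1Beads(system), w = NULL)
}

# friction models: "stokes" scales bead drag with diameter and rigid-group
# rotational drag with diameter^3; "uniform" gives every bead and rigid
# group unit translational and rotational drag (fast conformational
# sampling for dimensionless kinetics, where no absolute time mapping is
# claimed)
.dragModel <- function(system, drag = c("stokes", "uniform")) {
  drag <- match.arg(drag)
  b <- beads(system)
  groups <- unname(system@rigidGroups)
  if (drag == "stokes") {
    gdiam <- vapply(groups, function(g) max(b$diameter[g]), numeric(1))
    list(gamma = b$diameter, gammaT = gdiam, gammaR = gdiam^3 / 3)
  } else {
    list(gamma = rep(1, nrow(b)), gammaT = rep(1, length(groups)),
         gammaR = rep(1, length(groups)))
  }
}

# full pack consumed by the C++ kernels
.packSystem <- function(system, biases = NULL, cv = NULL, pos = NULL,
                        drag = "stokes") {
  b <- beads(system)
  n <- nrow(b)
  if (is.null(pos)) pos <- startCoords(system)
  radius <- b$diameter / 2

  grp <- integer(n)
  for (gi in seq_along(system@rigidGroups))
    grp[system@rigidGroups[[gi]]] <- gi

  eps <- matrix(1, n, n)
  smat <- outer(radius, radius, "+")
  rcut <- 2^(1/6) * smat
  diag(rcut) <- 0
  ex <- system@exclusions
  if (nrow(ex)) {
    rcut[cbind(ex$i, ex$j)] <- 0
    rcut[cbind(ex$j, ex$i)] <- 0
  }
  sp <- system@pairs
  if (nrow(sp)) {
    for (q in seq_len(nrow(sp))) {
      i <- sp$i[q]; j <- sp$j[q]
      eps[i, j] <- eps[j, i] <- sp$eps[q]
      smat[i, j] <- smat[j, i] <- sp$s[q]
      rcut[i, j] <- rcut[j, i] <- sp$rcut[q]
    }
  }

  wl <- system@walls$lower; wu <- system@walls$upper
  wall <- cbind(wl$s, wl$eps, wl$rcut, as.numeric(wl$active),
                wu$s, wu$eps, wu$rcut, as.numeric(wu$active))

  an <- system@angles
  angles <- if (nrow(an)) {
    cbind(an$i, an$j, an$k, an$kTheta, an$theta0 * pi / 180)
  } else matrix(0, 0, 5)
  dh <- system@dihedrals
  dihedrals <- if (nrow(dh)) {
    cbind(dh$i, dh$j, dh$k, dh$l, dh$kPhi, dh$phi0 * pi / 180)
  } else matrix(0, 0, 6)
  bd <- system@bonds
  bondsM <- if (nrow(bd)) cbind(bd$i, bd$j, bd$k, bd$r0) else matrix(0, 0, 4)

  groups <- unname(system@rigidGroups)
  dm <- .dragModel(system, drag)

  biasList <- lapply(biases, function(bi) .normalizeCvSpec(system, bi))
  cvSpec <- if (is.null(cv)) list() else .normalizeCvSpec(system, cv)

  cm <- .chainMoves(system)

  list(pos = pos, box = system@box, capFactor = 0.3, forceCap = 500,
       radius = radius, mass = b$mass, gamma = dm$gamma,
       fixed = as.integer(b$fixed), grp = as.integer(grp),
       bonds = bondsM, angles = angles, dihedrals = dihedrals,
       pairEps = eps, pairS = smat, pairRcut = rcut,
       wall = wall, wallShifted = TRUE,
       groups = groups, gammaT = dm$gammaT, gammaR = dm$gammaR,
       biases = if (length(biasList)) biasList else list(),
       cv = cvSpec,
       chain = cm$chain, pivotTails = cm$tails, crank = cm$crank,
       tiltPivot = if (length(system@tether))
         as.integer(system@tether$epitope) else 0L,
       tiltSet = which(!b$fixed))
}

# chain bookkeeping for crankshaft and pivot Monte Carlo moves
.chainMoves <- function(system) {
  ch <- system@chain
  N <- length(ch)
  if (!N) return(list(chain = integer(), tails = list(),
                      crank = matrix(0, 0, 3)))
  bd <- system@bonds
  partners <- function(i) c(bd$j[bd$i == i], bd$i[bd$j == i])
  prevA <- setdiff(partners(ch[1]), ch)
  nextA <- setdiff(partners(ch[N]), ch)
  freeSide <- if (length(nextA)) nbd1Beads(system) else integer(0)

  tails <- vector("list", N)
  for (p in seq_len(N)) {
    tl <- if (p < N) ch[(p + 1):N] else integer(0)
    tails[[p]] <- as.integer(c(tl, freeSide))
  }
  keep <- vapply(tails, length, integer(1)) > 0
  crank <- matrix(0L, 0, 3)
  for (p in seq_len(N)) {
    prev <- if (p > 1) ch[p - 1] else if (length(prevA)) prevA[1] else NA
    nxt <- if (p < N) ch[p + 1] else if (length(nextA)) nextA[1] else NA
    if (!is.na(prev) && !is.na(nxt))
      crank <- rbind(crank, c(ch[p], prev, nxt))
  }
  storage.mode(crank) <- "double"
  list(chain = as.integer(ch[keep]), tails = tails[keep], crank = crank)
}

#' Potential energy and analytic forces
#'
#' Evaluates the full potential (bond, angle, dihedral, pair, wall, bias
#' terms) and its exact negative gradient for a configuration of a system.
#'
#' @param system a [DiabodySystem-class].
#' @param pos optional `n x 3` coordinate matrix (default: build coordinates).
#' @param biases optional list of harmonic bias specs (as used by umbrella
#'   sampling): each `list(type = "com_z"|"com_xy", idx =, k =, center =)`.
#' @return list with `forces` (`n x 3`), `energy` (total) and `byTerm`
#'   (named decomposition).
#' @export
computeForces <- function(system, pos = NULL, biases = NULL) {
  pack <- .packSystem(system, biases = biases, pos = pos)
  fr <- cg_forces(pack, pack$pos)
  en <- cg_energy(pack, pack$pos)
  rownames(fr$forces) <- beads(system)$name
  list(forces = fr$forces, energy = en$total,
       byTerm = unlist(en[c("bond", "angle", "dihedral", "pair", "wall",
                            "bias")]))
}

#' @rdname computeForces
#' @export
systemEnergy <- function(system, pos = NULL, biases = NULL) {
  pack <- .packSystem(system, biases = biases, pos = pos)
  unlist(cg_energy(pack, pack$pos))
}

#' Truncated Lennard-Jones wall potential
#'
#' The 12-6 wall term as a function of the bead-wall distance, cut at
#' `rcut`.  With `shifted = FALSE` this is the bare truncated form, whose
#' node sits exactly at `d = s`; the samplers use the shifted form
#' (continuous at the cutoff).
#'
#' @param d distance from the wall (sigma).
#' @param s repulsive length (sigma).
#' @param eps well depth (kT).
#' @param rcut cutoff; `2^(1/6) s` repulsive, `2.5 s` attractive.
#' @param shifted shift the energy to 0 at the cutoff.
#' @return energy in kT.
#' @export
wallPotential <- function(d, s, eps = 1, rcut = 2^(1/6) * s, shifted = TRUE) {
  vapply(d, cg_wall_potential, numeric(1), s = s, eps = eps, rcut = rcut,
         shifted = shifted)
}

.mcDefaults <- function() {
  list(dispBead = 0.06, dispGroup = 0.2, rotGroup = 0.2,
       pivotAngle = 0.5, pivotsPerSweep = 4L,
       tiltAngle = 0.5, tiltsPerSweep = 3L)
}

.trackIdx <- function(system, trackBeads) {
  if (is.null(trackBeads)) return(integer())
  b <- beads(system)
  idx <- if (is.character(trackBeads)) match(trackBeads, b$name)
         else as.integer(trackBeads)
  if (anyNA(idx)) stop("unknown bead in trackBeads")
  idx
}

.makeTrajectory <- function(system, res, frameInterval, trackNames,
                            trackInterval, provenance) {
  track <- list()
  if (length(trackNames)) {
    track <- list(beads = trackNames, interval = trackInterval,
                  z = res$track)
    if (length(res$cv)) track$cv <- as.numeric(res$cv)
  } else if (length(res$cv)) {
    track <- list(beads = character(), interval = trackInterval,
                  z = matrix(numeric(), 0, 0), cv = as.numeric(res$cv))
  }
  new("Trajectory", coords = res$frames, beadNames = beads(system)$name,
      box = system@box, frameInterval = frameInterval, track = track,
      provenance = provenance)
}

#' Overdamped Langevin (Brownian) dynamics
#'
#' Euler--Maruyama integration of the overdamped Langevin equation
#' \eqn{\gamma \dot x = F + \sqrt{2\gamma k_BT}\,\xi(t)} for free beads, with
#' rigid groups translated by their net force and rotated by their net torque
#' (translational drag proportional to the group diameter, rotational drag to
#' its cube).  Times are in Brownian units \eqn{\tau_B = \gamma\sigma^2/k_BT}
#' of a unit-diameter bead.
#'
#' @param system a [DiabodySystem-class].
#' @param nSteps number of time steps.
#' @param dt time step in \eqn{\tau_B}; the default resolves the stiff bond
#'   term.
#' @param sampleEvery store a full frame every this many steps.
#' @param seed integer seed; runs are bitwise reproducible given the seed.
#' @param temperature reduced temperature (kT); 0 gives noiseless descent.
#' @param trackBeads bead names whose z-coordinate is recorded every
#'   `trackEvery` steps (cheap high-frequency series for kinetics).
#' @param trackEvery sampling stride of the z-track, in steps.
#' @param start optional starting coordinates (default: build coordinates).
#' @param biases optional harmonic bias specs (umbrella restraints).
#' @param cv optional collective-variable spec recorded with the track.
#' @param drag friction model: `"stokes"` (bead drag proportional to
#'   diameter, rigid-group rotational drag to diameter cubed) or
#'   `"uniform"` (unit drag everywhere; much faster conformational
#'   exploration for dimensionless kinetics, since the reduced-to-physical
#'   time mapping is a free parameter anyway).
#' @return a [Trajectory-class].
#' @export
runTrajectory <- function(system, nSteps, dt = 1e-4, sampleEvery = 1000,
                          seed = 1, temperature = 1, trackBeads = NULL,
                          trackEvery = 10, start = NULL, biases = NULL,
                          cv = NULL, drag = "stokes") {
  stopifnot(nSteps >= 0, dt > 0)
  if (sampleEvery <= 0) sampleEvery <- max(nSteps, 1)
  pack <- .packSystem(system, biases = biases, cv = cv, pos = start,
                      drag = drag)
  idx <- .trackIdx(system, trackBeads)
  res <- cg_bd_run(pack, pack$pos, as.integer(nSteps), dt,
                   as.integer(sampleEvery), as.integer(seed), temperature,
                   as.integer(idx), as.integer(trackEvery))
  .makeTrajectory(system, res, sampleEvery * dt,
                  beads(system)$name[idx], trackEvery * dt,
                  list(sampler = "brownian", seed = seed, dt = dt,
                       nSteps = nSteps, temperature = temperature))
}

#' Equilibrium Metropolis Monte Carlo
#'
#' Samples the Boltzmann distribution of a system (the stationary measure of
#' the Brownian dynamics) with a move mixture of single-bead displacements,
#' rigid-group translations/rotations, crankshaft rotations of chain beads
#' and pivot rotations of the chain tail.  Time is measured in sweeps; only
#' equilibrium observables are meaningful.
#'
#' @inheritParams runTrajectory
#' @param nSweeps number of Monte Carlo sweeps.
#' @param sampleEvery store a frame every this many sweeps.
#' @param trackEvery z-track stride in sweeps.
#' @param moves move-amplitude overrides, see `diabodysim:::.mcDefaults()`.
#' @return a [Trajectory-class]; acceptance rates in `@provenance$acceptance`.
#' @export
sampleEquilibriumMC <- function(system, nSweeps, sampleEvery = 10, seed = 1,
                                trackBeads = NULL, trackEvery = 1,
                                start = NULL, biases = NULL, cv = NULL,
                                moves = list()) {
  stopifnot(nSweeps >= 0)
  if (sampleEvery <= 0) sampleEvery <- max(nSweeps, 1)
  mp <- utils::modifyList(.mcDefaults(), moves)
  pack <- .packSystem(system, biases = biases, cv = cv, pos = start)
  idx <- .trackIdx(system, trackBeads)
  res <- cg_mc_run(pack, pack$pos, as.integer(nSweeps),
                   as.integer(sampleEvery), as.integer(seed), mp,
                   as.integer(idx), as.integer(trackEvery))
  tr <- .makeTrajectory(system, res, sampleEvery,
                        beads(system)$name[idx], trackEvery,
                        list(sampler = "mc", seed = seed, nSweeps = nSweeps,
                             acceptance = res$accepted /
                               pmax(res$attempted, 1)))
  tr
}

#' Height distribution of a bead above the tethering wall
#'
#' Normalized histogram of the z-coordinate of a named bead over a
#' trajectory, together with its mean and quantiles.
#'
#' @param trajectory a [Trajectory-class].
#' @param bead bead name.
#' @param bins number of histogram bins (or a vector of break points).
#' @param discard fraction of the initial samples dropped as burn-in.
#' @return list with `histogram` (data.frame: z, density), `mean`,
#'   `quantiles` (5, 25, 50, 75, 95 percent).
#' @export
beadHeightDistribution <- function(trajectory, bead, bins = 50,
                                   discard = 0) {
  hs <- beadHeightSeries(trajectory, bead)
  z <- hs$z
  if (discard > 0) z <- z[-seq_len(floor(discard * length(z)))]
  if (length(unique(z)) == 1L) {
    return(list(histogram = data.frame(z = z[1], density = Inf),
                mean = z[1],
                quantiles = stats::setNames(rep(z[1], 5),
                                            c("5%", "25%", "50%", "75%",
                                              "95%"))))
  }
  h <- if (length(bins) > 1) graphics::hist(z, breaks = bins, plot = FALSE)
       else graphics::hist(z, breaks = bins, plot = FALSE)
  list(histogram = data.frame(z = h$mids, density = h$density),
       mean = mean(z),
       quantiles = stats::quantile(z, c(0.05, 0.25, 0.5, 0.75, 0.95)))
}
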