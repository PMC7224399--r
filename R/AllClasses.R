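#' @import methods
#' @importFrom stats setNames
NULL

#' Reduced Lennard-Jones unit system
#'
#' Bookkeeping for the reduced unit system used throughout: lengths in
#' \eqn{\sigma} (one linker monomer, 3.5 Angstrom), energies internally in
#' \eqn{k_BT} (at room temperature \eqn{k_BT = 3\epsilon} with
#' \eqn{\epsilon = 100} K), times in the Brownian unit
#' \eqn{\tau_B = \gamma\sigma^2/k_BT}.
#'
#' @slot sigmaAngstrom length unit in Angstrom.
#' @slot epsilonKelvin energy unit of the underlying LJ system, in Kelvin.
#' @slot kTReduced thermal energy in internal reduced units (1: energies are
#'   expressed in \eqn{k_BT}).
#' @slot timeUnitLabel label of the time unit.
#' @export
setClass("UnitSystem",
  slots = c(sigmaAngstrom = "numeric", epsilonKelvin = "numeric",
            kTReduced = "numeric", timeUnitLabel = "character"))

setValidity("UnitSystem", function(object) {
  if (object@sigmaAngstrom <= 0) return("sigmaAngstrom must be > 0")
  if (object@epsilonKelvin <= 0) return("epsilonKelvin must be > 0")
  if (object@kTReduced <= 0) return("kTReduced must be > 0")
  TRUE
})

#' @describeIn UnitSystem-class constructor with the package defaults.
#' @param sigmaAngstrom,epsilonKelvin,kTReduced,timeUnitLabel slot values.
#' @export
unitSystem <- function(sigmaAngstrom = 3.5, epsilonKelvin = 100,
                       kTReduced = 1, timeUnitLabel = "tau_B") {
  new("UnitSystem", sigmaAngstrom = sigmaAngstrom,
      epsilonKelvin = epsilonKelvin, kTReduced = kTReduced,
      timeUnitLabel = timeUnitLabel)
}

#' Coarse-grained diabody (or bare linker) topology
#'
#' Container for a complete bead system in reduced units: bead table with
#' initial coordinates, bonded terms, rigid groups, wall specifications,
#' tether, and box.  Built by [buildSphDiabody()], [buildSbcgDiabody()] or
#' [buildFreeLinker()] and consumed by the samplers.
#'
#' @slot units a [UnitSystem-class].
#' @slot beads data.frame with columns `id`, `name`, `diameter`, `mass`,
#'   `group` (one of nanobody/connector/paratope/linker/epitope), `x`, `y`,
#'   `z`, `fixed`.
#' @slot bonds data.frame `i`, `j`, `k`, `r0` (harmonic, \eqn{\frac12 k (r-r_0)^2}).
#' @slot angles data.frame `i`, `j`, `k`, `kTheta`, `theta0` (degrees).
#' @slot dihedrals data.frame `i`, `j`, `k`, `l`, `kPhi`, `phi0` (degrees).
#' @slot rigidGroups list of integer vectors of bead ids moved as rigid bodies.
#' @slot pairs data.frame of special (non-WCA) pair interactions
#'   `i`, `j`, `eps`, `s`, `rcut`; the tether lives here.
#' @slot exclusions data.frame `i`, `j` of pairs with no nonbonded term.
#' @slot walls list with elements `lower` and `upper`, each a data.frame with
#'   one row per bead: `s`, `eps`, `rcut`, `active`.
#' @slot tether list describing the paratope--epitope attraction (or empty).
#' @slot box numeric length-3, `c(Lx, Ly, Lz)`; periodic in x and y only.
#' @slot linkerN number of linker monomers.
#' @slot chain integer vector of linker bead ids ordered from the tethered to
#'   the free end (used by chain Monte Carlo moves).
#' @slot provenance free-form list (builder call, seed, wall set).
#' @export
setClass("DiabodySystem",
  slots = c(units = "UnitSystem", beads = "data.frame", bonds = "data.frame",
            angles = "data.frame", dihedrals = "data.frame",
            rigidGroups = "list", pairs = "data.frame",
            exclusions = "data.frame", walls = "list", tether = "list",
            box = "numeric", linkerN = "integer", chain = "integer",
            provenance = "list"))

setValidity("DiabodySystem", function(object) {
  b <- object@beads
  if (anyDuplicated(b$name)) return("bead names must be unique")
  if (any(b$diameter <= 0)) return("bead diameters must be > 0")
  if (any(b$mass <= 0)) return("bead masses must be > 0")
  if (length(object@box) != 3 || any(object@box <= 0))
    return("box must be three positive lengths")
  if (nrow(object@bonds) && any(object@bonds$k < 0))
    return("bond force constants must be >= 0")
  if (nrow(object@angles) &&
      (any(object@angles$kTheta < 0) ||
       any(object@angles$theta0 < 0 | object@angles$theta0 > 180)))
    return("angle constants must be >= 0 and equilibria in [0, 180] degrees")
  nepi <- sum(b$group == "epitope")
  if (length(object@tether) && nepi != 1L)
    return("a tethered system must have exactly one epitope bead")
  for (g in object@rigidGroups)
    if (length(g) < 2) return("rigid groups need at least 2 beads")
  w <- object@walls
  if (!all(c("lower", "upper") %in% names(w)))
    return("walls must have 'lower' and 'upper' entries")
  for (side in w) {
    act <- side$active & side$rcut > 0
    kind <- ifelse(abs(side$rcut - 2^(1/6) * side$s) < 1e-9, "repulsive",
                   ifelse(abs(side$rcut - 2.5 * side$s) < 1e-9, "attractive",
                          "other"))
    if (any(act & kind == "other"))
      return("wall cutoffs must be 2^(1/6)*s (repulsive) or 2.5*s (attractive)")
  }
  TRUE
})

setMethod("show", "DiabodySystem", function(object) {
  b <- object@beads
  cat(sprintf("DiabodySystem: %d beads (%s), N = %d linker monomers\n",
              nrow(b), paste(names(table(b$group)), table(b$group),
                             sep = ":", collapse = ", "),
              object@linkerN))
  cat(sprintf("  %d bonds, %d angles, %d dihedrals, %d rigid groups\n",
              nrow(object@bonds), nrow(object@angles),
              nrow(object@dihedrals), length(object@rigidGroups)))
  cat(sprintf("  box %.1f x %.1f x %.1f sigma (periodic x,y); %s\n",
              object@box[1], object@box[2], object@box[3],
              if (length(object@tether)) "tethered to lower wall"
              else "untethered"))
  invisible(object)
})

#' Bead-coordinate trajectory
#'
#' Time-ordered snapshots of bead coordinates from a Brownian-dynamics or
#' Monte-Carlo run, with optional high-frequency z-tracks of selected beads.
#'
#' @slot coords numeric array `n x 3 x frames`.
#' @slot beadNames character vector of bead names.
#' @slot box numeric length-3 box.
#' @slot frameInterval time (\eqn{\tau_B}) or sweeps between stored frames.
#' @slot track list with `beads`, `interval` and `z` (matrix, one column per
#'   tracked bead), possibly empty.
#' @slot provenance list: sampler, seed, config hash.
#' @export
setClass("Trajectory",
  slots = c(coords = "array", beadNames = "character", box = "numeric",
            frameInterval = "numeric", track = "list", provenance = "list"))

setValidity("Trajectory", function(object) {
  d <- dim(object@coords)
  if (length(d) != 3 || d[2] != 3) return("coords must be n x 3 x frames")
  if (d[3] < 1) return("at least one frame required")
  if (length(object@beadNames) != d[1])
    return("beadNames length must match bead count")
  if (object@frameInterval <= 0) return("frameInterval must be > 0")
  TRUE
})

setMethod("show", "Trajectory", function(object) {
  d <- dim(object@coords)
  cat(sprintf("Trajectory: %d beads, %d frames (interval %.4g)\n",
              d[1], d[3], object@frameInterval))
  if (length(object@track))
    cat(sprintf("  z-track: %s every %.4g\n",
                paste(object@track$beads, collapse = ", "),
                object@track$interval))
  invisible(object)
})

#' Potential of mean force profile
#'
#' A free-energy profile along a collective variable, reconstructed by WHAM
#' from umbrella windows, shifted so its minimum is zero.
#'
#' @slot grid strictly increasing collective-variable grid (bin centres).
#' @slot pmf free energy in kT, min 0.
#' @slot stderr per-bin statistical uncertainty (kT).
#' @slot cv collective-variable label ("rho_z" or "rho_xy").
#' @slot meta WHAM convergence metadata.
#' @export
setClass("PMFProfile",
  slots = c(grid = "numeric", pmf = "numeric", stderr = "numeric",
            cv = "character", meta = "list"))

setValidity("PMFProfile", function(object) {
  if (length(object@grid) != length(object@pmf))
    return("grid and pmf lengths differ")
  if (is.unsorted(object@grid, strictly = TRUE))
    return("grid must be strictly increasing")
  if (abs(min(object@pmf)) > 1e-8) return("pmf minimum must be 0")
  TRUE
})

setMethod("show", "PMFProfile", function(object) {
  cat(sprintf("PMFProfile along %s: %d bins on [%.2f, %.2f] sigma, max %.2f kT\n",
              object@cv, length(object@grid), min(object@grid),
              max(object@grid), max(object@pmf)))
  invisible(object)
})

#' Alternating flight/residence event series
#'
#' Events extracted from a paratope height series against a threshold
#' \eqn{z_0}: "flight" when the bead is at or above the threshold, "residence"
#' below it.  Events touching the trajectory ends are flagged as censored.
#'
#' @slot events data.frame with columns `kind` ("flight"/"residence"),
#'   `duration` (time units) and `censored`.
#' @slot config list: `z0`, `minDuration`, `frameInterval`, source bead.
#' @export
setClass("EventSeries",
  slots = c(events = "data.frame", config = "list"))

setValidity("EventSeries", function(object) {
  e <- object@events
  if (nrow(e)) {
    if (!all(e$kind %in% c("flight", "residence"))) return("unknown event kind")
    if (any(diff(as.integer(factor(e$kind))) == 0))
      return("event kinds must strictly alternate")
    if (any(e$duration < 0)) return("durations must be >= 0")
  }
  TRUE
})

setMethod("show", "EventSeries", function(object) {
  e <- object@events
  cat(sprintf("EventSeries: %d flights, %d residences (z0 = %.2f, min duration %.3g)\n",
              sum(e$kind == "flight"), sum(e$kind == "residence"),
              object@config$z0, object@config$minDuration))
  invisible(object)
})

#' Empirical survival curve of event durations
#'
#' Complementary cumulative distribution \eqn{S(t)} of flight or residence
#' durations; \eqn{S(0) = 1}, non-increasing, with \eqn{\int_0^\infty S\,dt}
#' equal to the mean duration.
#'
#' @slot time time grid (sorted unique durations, starting at 0).
#' @slot S survival values.
#' @slot domain "flight" or "residence".
#' @slot nEvents number of events used.
#' @export
setClass("SurvivalCurve",
  slots = c(time = "numeric", S = "numeric", domain = "character",
            nEvents = "integer"))

setValidity("SurvivalCurve", function(object) {
  if (length(object@time) != length(object@S)) return("time/S length mismatch")
  if (length(object@S)) {
    if (abs(object@S[1] - 1) > 1e-12) return("S(0) must be 1")
    if (any(diff(object@S) > 1e-12)) return("S must be non-increasing")
  }
  TRUE
})

setMethod("show", "SurvivalCurve", function(object) {
  cat(sprintf("SurvivalCurve (%s): %d events, mean duration %.4g\n",
              object@domain, object@nEvents, survivalIntegral(object)))
  invisible(object)
})

#' Tethered Gaussian-chain reference model
#'
#' Analytic model of the free-end height distribution of a Gaussian polymer
#' with `Nk` Kuhn segments of length `b`, tethered at height `zt` above a
#' reflecting wall (image construction); `zt = 0` recovers the simple
#' tethered-end law \eqn{P(z) = (3z/\langle d^2\rangle)
#' \exp(-3z^2/2\langle d^2\rangle)}.
#'
#' @slot Nk Kuhn segment count.
#' @slot b Kuhn length (sigma).
#' @slot zt tether height (sigma).
#' @export
setClass("GaussianChainModel",
  slots = c(Nk = "numeric", b = "numeric", zt = "numeric"))

setValidity("GaussianChainModel", function(object) {
  if (object@Nk <= 0 || object@b <= 0) return("Nk and b must be > 0")
  if (object@zt < 0) return("zt must be >= 0")
  TRUE
})

setMethod("show", "GaussianChainModel", function(object) {
  cat(sprintf("GaussianChainModel: Nk = %.4g, b = %.3g sigma, zt = %.3g sigma, <d^2> = %.4g sigma^2\n",
              object@Nk, object@b, object@zt, object@Nk * object@b^2))
  invisible(object)
})

#' @describeIn GaussianChainModel-class constructor.
#' @param Nk,b,zt slot values.
#' @export
gaussianChainModel <- function(Nk, b, zt = 0) {
  new("GaussianChainModel", Nk = as.numeric(Nk), b = as.numeric(b),
      zt = as.numeric(zt))
}

#' @rdname GaussianChainModel-class
#' @param model a `GaussianChainModel`.
#' @return `meanSquareEndToEnd()`: \eqn{\langle d^2\rangle = N_k b^2}.
#' @export
meanSquareEndToEnd <- function(model) model@Nk * model@b^2
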