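# shared fixtures: tiny systems built in code

# a single free bead in a large box with no walls (for trap tests)
singleBeadSystem <- function(diameter = 1, box = c(40, 40, 40)) {
  beads <- data.frame(id = 1L, name = "B1", diameter = diameter,
                      mass = diameter^3, group = "linker",
                      x = box[1] / 2, y = box[2] / 2, z = box[3] / 2,
                      fixed = FALSE, stringsAsFactors = FALSE)
  off <- data.frame(s = 0.8, eps = 1, rcut = 2^(1/6) * 0.8, active = FALSE)
  new("DiabodySystem", units = unitSystem(), beads = beads,
      bonds = diabodysim:::.emptyBonds(),
      angles = diabodysim:::.emptyAngles(),
      dihedrals = diabodysim:::.emptyDihedrals(), rigidGroups = list(),
      pairs = data.frame(i = integer(), j = integer(), eps = numeric(),
                         s = numeric(), rcut = numeric()),
      exclusions = data.frame(i = integer(), j = integer()),
      walls = list(lower = off, upper = off), tether = list(), box = box,
      linkerN = 0L, chain = integer(), provenance = list())
}

# a free rigid dumbbell (two beads moved as one body), no walls
rigidDumbbellSystem <- function(box = c(40, 40, 40)) {
  beads <- data.frame(id = 1:2, name = c("A", "B"), diameter = c(2, 1),
                      mass = c(8, 1), group = "linker",
                      x = box[1] / 2, y = box[2] / 2,
                      z = box[3] / 2 + c(0, 1.5), fixed = FALSE,
                      stringsAsFactors = FALSE)
  off <- data.frame(s = rep(0.8, 2), eps = 1, rcut = 2^(1/6) * 0.8,
                    active = FALSE)
  new("DiabodySystem", units = unitSystem(), beads = beads,
      bonds = diabodysim:::.emptyBonds(),
      angles = diabodysim:::.emptyAngles(),
      dihedrals = diabodysim:::.emptyDihedrals(),
      rigidGroups = list(body = 1:2),
      pairs = data.frame(i = integer(), j = integer(), eps = numeric(),
                         s = numeric(), rcut = numeric()),
      exclusions = data.frame(i = 1L, j = 2L),
      walls = list(lower = off, upper = off), tether = list(), box = box,
      linkerN = 0L, chain = integer(), provenance = list())
}

# brute-force reference decomposition of a height series into alternating
# runs (no filter), used as the oracle for the event decomposer
referenceRuns <- function(z, z0) {
  state <- z >= z0
  r <- rle(state)
  data.frame(kind = ifelse(r$values, "flight", "residence"),
             frames = r$lengths, stringsAsFactors = FALSE)
}

# small MC sample of a system, returning the trajectory
quickMC <- function(system, nSweeps, seed = 1, ...) {
  sampleEquilibriumMC(system, nSweeps, seed = seed, ...)
}
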