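test_that("analytic forces equal the numerical gradient for every term", {
  # attractive walls + tether + restraint angles all active; jitter breaks
  # symmetry without creating deep overlaps
  s <- buildSphDiabody(6, "attractive#1")
  sb <- buildSbcgDiabody(4, "repulsive#1", seed = 3)   # adds dihedrals
  for (sys in list(s, sb)) {
    set.seed(11)
    # relax residual build overlaps first so no pair sits in the
    # force-capped core, where the capped force is deliberately not the
    # exact gradient
    relaxed <- frameCoords(sampleEquilibriumMC(sys, 300, sampleEvery = 0,
                                               seed = 2))
    pos <- relaxed + matrix(rnorm(3 * nBeads(sys), 0, 0.01), ncol = 3)
    bias <- list(list(type = "com_z", idx = nbd1Beads(sys), k = 2,
                      center = 15),
                 list(type = "com_xy", idx = nbd1Beads(sys), k = 1,
                      center = 3))
    pack <- diabodysim:::.packSystem(sys, biases = bias, pos = pos)
    fr <- diabodysim:::cg_forces(pack, pack$pos)
    h <- 1e-6
    probe <- seq_len(nBeads(sys))
    worst <- 0
    for (i in probe) {
      for (c in 1:3) {
        p1 <- pack$pos; p1[i, c] <- p1[i, c] + h
        p2 <- pack$pos; p2[i, c] <- p2[i, c] - h
        fd <- -(diabodysim:::cg_energy(pack, p1)$total -
                  diabodysim:::cg_energy(pack, p2)$total) / (2 * h)
        worst <- max(worst, abs(fd - fr$forces[i, c]))
      }
    }
    expect_lt(worst, 1e-5)
  }
})

test_that("pair, bond and wall terms vanish at their characteristic points", {
  # two non-bonded WCA beads exactly at the cutoff: zero energy and force
  s2 <- singleBeadSystem()
  sys <- s2
  sys@beads <- rbind(sys@beads,
                     within(sys@beads, {id <- 2L; name <- "B2"}))
  sys@beads$x[2] <- sys@beads$x[1] + 2^(1/6)
  sys@walls <- list(lower = sys@walls$lower[c(1, 1), ],
                    upper = sys@walls$upper[c(1, 1), ])
  pack <- diabodysim:::.packSystem(sys)
  en <- diabodysim:::cg_energy(pack, pack$pos)
  expect_equal(en$pair, 0, tolerance = 1e-12)
  fr <- diabodysim:::cg_forces(pack, pack$pos)
  expect_equal(max(abs(fr$forces)), 0, tolerance = 1e-9)
  # just inside the cutoff the (shifted) WCA energy is positive
  pin <- pack$pos; pin[2, 1] <- pin[1, 1] + 1.05
  expect_gt(diabodysim:::cg_energy(pack, pin)$pair, 0)
  # bond at its rest length: zero bond energy (straight build)
  en2 <- systemEnergy(buildFreeLinker(2))
  expect_equal(en2[["bond"]], 0, tolerance = 1e-12)
  # unshifted wall potential crosses zero at d = s_wall (12-6 node)
  expect_equal(wallPotential(0.8, s = 0.8, eps = 1, shifted = FALSE), 0,
               tolerance = 1e-14)
  expect_equal(wallPotential(2^(1/6) * 0.8, s = 0.8, eps = 1,
                             rcut = 2.5 * 0.8, shifted = FALSE), -1,
               tolerance = 1e-12)
  # shifted form is continuous at the cutoff
  expect_equal(wallPotential(2^(1/6) * 0.8 - 1e-9, s = 0.8), 0,
               tolerance = 1e-6)
})

test_that("energy is invariant under lattice translations in x and y", {
  s <- buildSphDiabody(8, "repulsive#2")
  pos <- startCoords(s)
  e0 <- systemEnergy(s, pos)[["total"]]
  shift <- pos
  shift[, 1] <- shift[, 1] + s@box[1]
  shift[, 2] <- shift[, 2] - 2 * s@box[2]
  e1 <- systemEnergy(s, shift)[["total"]]
  expect_equal(e1, e0, tolerance = 1e-9)
})

test_that("Brownian runs are reproducible and handle edge cases", {
  s <- buildSphDiabody(4, "repulsive#2")
  t1 <- runTrajectory(s, 2000, sampleEvery = 500, seed = 99)
  t2 <- runTrajectory(s, 2000, sampleEvery = 500, seed = 99)
  expect_identical(t1@coords, t2@coords)            # bitwise determinism
  t3 <- runTrajectory(s, 2000, sampleEvery = 500, seed = 100)
  expect_false(identical(t3@coords, t1@coords))
  t0 <- runTrajectory(s, 0, seed = 1)
  expect_equal(nFrames(t0), 1)                      # initial frame only
  expect_error(runTrajectory(s, 100, dt = 0.2, seed = 1), "diverged")
})

test_that("zero-temperature dynamics relaxes to the trap minimum at rate k/gamma", {
  sys <- singleBeadSystem()
  z0 <- sys@box[3] / 2
  bias <- list(list(type = "com_z", idx = 1L, w = 1, k = 2, center = z0 + 5))
  dt <- 1e-3
  tr <- runTrajectory(sys, 4000, dt = dt, sampleEvery = 0, seed = 1,
                      temperature = 0, biases = bias, trackBeads = "B1",
                      trackEvery = 100)
  z <- beadHeightSeries(tr, "B1")$z
  t <- (seq_along(z) - 1) * 100 * dt
  # displacement from target decays as exp(-k t / gamma), gamma = 1
  expect_equal(z0 + 5 - z, 5 * exp(-2 * t), tolerance = 0.01)
})

test_that("Brownian and MC samplers both satisfy equipartition in a trap", {
  sys <- singleBeadSystem()
  bias <- list(list(type = "com_z", idx = 1L, w = 1, k = 1,
                    center = sys@box[3] / 2))
  tr <- runTrajectory(sys, 2e5, dt = 2e-3, sampleEvery = 0, seed = 7,
                      biases = bias, trackBeads = "B1", trackEvery = 20)
  zb <- beadHeightSeries(tr, "B1")$z[-(1:500)]
  expect_equal(var(zb), 1, tolerance = 0.12)        # kT/k = 1 sigma^2
  tm <- sampleEquilibriumMC(sys, 6e4, sampleEvery = 0, seed = 8,
                            biases = bias, trackBeads = "B1",
                            trackEvery = 1, moves = list(dispBead = 1))
  zm <- beadHeightSeries(tm, "B1")$z[-(1:500)]
  expect_equal(var(zm), 1, tolerance = 0.12)
})

test_that("a free rigid body diffuses to an isotropic orientation", {
  sys <- rigidDumbbellSystem()
  tr <- runTrajectory(sys, 4e4, dt = 2e-3, sampleEvery = 40, seed = 5,
                      drag = "uniform")
  nF <- nFrames(tr)
  u <- t(vapply(seq_len(nF), function(f) {
    m <- frameCoords(tr, f)
    v <- m["B", ] - m["A", ]
    v / sqrt(sum(v^2))
  }, numeric(3)))
  u <- u[-(1:(nF %/% 4)), ]
  # Rayleigh test of uniformity on the sphere: 3|sum u|^2 / n ~ chi^2_3
  R2 <- sum(colSums(u)^2)
  stat <- 3 * R2 / nrow(u)
  # orientations are autocorrelated; deflate by the effective sample size
  tauEff <- max(1, diabodysim:::integratedAutocorrelationTime(u[, 3]))
  stat <- stat / tauEff
  expect_lt(stat, qchisq(0.999, df = 3))
  # rigid internal distance preserved to machine precision
  d <- vapply(seq_len(nF), function(f) {
    m <- frameCoords(tr, f)
    sqrt(sum((m["B", ] - m["A", ])^2))
  }, numeric(1))
  expect_lt(max(abs(d - d[1])), 1e-10)
})

test_that("rigid groups of the diabody keep exact internal geometry under MC and BD", {
  s <- buildSphDiabody(6, "repulsive#2")
  for (tr in list(runTrajectory(s, 5000, sampleEvery = 1000, seed = 3),
                  sampleEquilibriumMC(s, 300, sampleEvery = 100, seed = 4))) {
    x0 <- frameCoords(tr, 1)
    xT <- frameCoords(tr, nFrames(tr))
    for (g in rigidGroups(s)) {
      expect_equal(as.numeric(dist(xT[g, ])), as.numeric(dist(x0[g, ])),
                   tolerance = 1e-10)
    }
  }
})

test_that("MC and Brownian dynamics sample the exact stationary trap marginal", {
  # end bead of a free chain held by a harmonic z-bias: by translation
  # invariance of all chain terms, the bead's z-marginal is exactly
  # N(center, kT/k) -- an analytic oracle for both samplers.  Series are
  # decorrelated at three times their estimated autocorrelation time.
  s <- buildFreeLinker(3)
  ctr <- s@box[3] / 2
  bias <- list(list(type = "com_z", idx = 3L, w = 1, k = 2, center = ctr))
  zb <- beadHeightSeries(
    runTrajectory(s, 3e6, dt = 1e-4, sampleEvery = 0, seed = 21,
                  biases = bias, trackBeads = "L3", trackEvery = 50),
    "L3")$z[-(1:500)]
  zm <- beadHeightSeries(
    sampleEquilibriumMC(s, 4e4, sampleEvery = 0, seed = 22, biases = bias,
                        trackBeads = "L3", trackEvery = 1),
    "L3")$z[-(1:500)]
  decor <- function(z) {
    st <- max(1, ceiling(3 * integratedAutocorrelationTime(z)))
    z[seq(1, length(z), by = st)]
  }
  for (z in list(zb, zm)) {
    expect_lt(abs(mean(z) - ctr), 0.2)
    expect_lt(abs(var(z) - 0.5), 0.2)
    ks <- suppressWarnings(stats::ks.test(decor(z), "pnorm", ctr,
                                          sqrt(0.5)))
    expect_gt(ks$p.value, 0.001)
  }
})

test_that("ideal freely-jointed chain statistics: <R^2> = (N-1) b^2", {
  # switch off bending and excluded volume -> ideal chain
  s <- buildFreeLinker(10, kTheta = 0)
  s@exclusions <- unique(rbind(s@exclusions,
                               expand.grid(i = 1:10, j = 1:10)[
                                 expand.grid(i = 1:10, j = 1:10)$i <
                                   expand.grid(i = 1:10, j = 1:10)$j, ]))
  r2 <- unlist(lapply(c(12, 13, 14), function(seed) {
    tm <- sampleEquilibriumMC(s, 10000, sampleEvery = 5, seed = seed)
    v <- vapply(seq_len(nFrames(tm)), function(f) {
      m <- frameCoords(tm, f)
      sum((m[10, ] - m[1, ])^2)
    }, numeric(1))
    v[-(1:200)]
  }))
  expect_equal(mean(r2), 9, tolerance = 0.08)
})

test_that("bead height distributions are normalized with sensible moments", {
  s <- buildSphDiabody(4, "repulsive#2")
  tr <- runTrajectory(s, 4000, sampleEvery = 40, seed = 2)
  bh <- beadHeightDistribution(tr, "P1", bins = 20)
  dz <- diff(bh$histogram$z)[1]
  expect_equal(sum(bh$histogram$density * dz), 1, tolerance = 1e-6)
  expect_error(beadHeightDistribution(tr, "NOPE"), "unknown bead")
  # constant series: delta distribution
  trc <- tr
  trc@track <- list(beads = "P1", interval = 1,
                    z = matrix(5, nrow = 50, ncol = 1))
  bhc <- beadHeightDistribution(trc, "P1")
  expect_equal(bhc$mean, 5)
  # uniform synthetic series
  tru <- tr
  tru@track <- list(beads = "P1", interval = 1,
                    z = matrix(seq(0, 1, length.out = 2001), ncol = 1))
  expect_equal(beadHeightDistribution(tru, "P1")$mean, 0.5, tolerance = 1e-3)
})
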