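test_that("tethered-end density is normalized, vanishes at the wall, and has the right mode", {
  for (pars in list(c(50, 3, 7.5), c(10, 1, 2), c(108, 3, 7.5))) {
    m <- gaussianChainModel(pars[1], pars[2], pars[3])
    expect_equal(tetheredEndPdf(0, m), 0, tolerance = 1e-12)
    nrm <- stats::integrate(function(z) tetheredEndPdf(z, m), 0, Inf,
                            rel.tol = 1e-10)$value
    expect_equal(nrm, 1, tolerance = 1e-8)
  }
  # zero-tether law: mode at sqrt(<d^2>/3)
  m0 <- gaussianChainModel(12, 2, 0)
  d2 <- meanSquareEndToEnd(m0)
  zs <- seq(0.01, 4 * sqrt(d2), by = 1e-3)
  p <- tetheredEndPdf(zs, m0)
  expect_equal(zs[which.max(p)], sqrt(d2 / 3), tolerance = 1e-2)
  nrm0 <- stats::integrate(function(z) tetheredEndPdf(z, m0), 0, Inf)$value
  expect_equal(nrm0, 1, tolerance = 1e-8)
  expect_error(tetheredEndPdf(-1, m0), "z must be")
})

test_that("reflected-wall density reduces to the zero-tether law as zt -> 0", {
  mSmall <- gaussianChainModel(20, 3, 1e-4)
  m0 <- gaussianChainModel(20, 3, 0)
  z <- seq(0.1, 40, by = 0.5)
  rel <- abs(tetheredEndPdf(z, mSmall) - tetheredEndPdf(z, m0)) /
    pmax(tetheredEndPdf(z, m0), 1e-300)
  expect_lt(max(rel[tetheredEndPdf(z, m0) > 1e-12]), 1e-3)
})

test_that("threshold probabilities: analytic values and empirical agreement", {
  m <- gaussianChainModel(25, 2, 0)
  expect_equal(thresholdProbabilities(0, m)$pAbove, 1)
  d2 <- meanSquareEndToEnd(m)
  z0 <- sqrt(2 * d2 / 3)
  tp <- thresholdProbabilities(z0, m)
  expect_equal(tp$pAbove, exp(-1), tolerance = 1e-12)
  expect_equal(tp$pAbove + tp$pBelow, 1)
  # empirical branch on samples drawn from the zero-tether law
  zamp <- fixtureIdealTetheredChain(25, 2, 0, n = 40000, seed = 8)
  h <- graphics::hist(zamp, breaks = 120, plot = FALSE)
  te <- thresholdProbabilities(z0, histogram = data.frame(z = h$mids,
                                                          density = h$density))
  expect_equal(te$pAbove, exp(-1), tolerance = 0.02)
  expect_error(thresholdProbabilities(-1, m), "z0")
})

test_that("run-length laws are geometric and match a simulated frame process", {
  rl <- runLengthDistribution(0.8, 0.2, k = 1:10)
  expect_equal(rl$Pa[-1] / rl$Pa[-10], rep(0.8, 9))   # ratio 1 - P_<
  expect_equal(rl$Pa[1], 0.8 * 0.2)
  # brute-force enumeration over the iid two-state frame process:
  # P(frames 1..k above, frame k+1 below) = P_>^k P_<
  for (k in 1:6) expect_equal(rl$Pa[k], 0.8^k * 0.2, tolerance = 1e-12)
  # concentration at k = 1 when P_< -> 1
  rlc <- runLengthDistribution(1e-6, 1 - 1e-6, k = 1:5)
  expect_gt(rlc$Pa[1] / sum(rlc$Pa), 0.999)
  # chi-square agreement with empirical maximal-run lengths
  above <- fixtureTwoStateChain(pBelow = 0.3, n = 2e5, seed = 12)
  r <- rle(above)
  runs <- r$lengths[r$values][-c(1)]
  runs <- runs[runs <= 8]
  obs <- tabulate(runs, 8)
  pk <- 0.7^(1:8 - 1) * 0.3 / sum(0.7^(0:7) * 0.3)
  chi <- suppressWarnings(stats::chisq.test(obs, p = pk))
  expect_gt(chi$p.value, 0.001)
  expect_error(runLengthDistribution(0.8, 0.2, k = 0), "k must")
})

test_that("tail time constants: exact forms, expansions and scaling", {
  x <- 0.15                                 # 3 z0^2 / 2 <d^2>
  d2 <- 3 * 2^2 / (2 * x)                   # choose z0 = 2
  tc <- tailConstantsTheory(2, d2, 1)
  expect_equal(tc$tauF, 1 / (1 - exp(-0.15)), tolerance = 1e-12)
  expect_equal(tc$tauF, 7.18, tolerance = 0.01)
  expect_equal(tc$tauFApprox, 1 / 0.15, tolerance = 1e-12)
  expect_equal(tc$tauR, exp(0.15), tolerance = 1e-12)
  expect_equal(tc$tauR, 1.1618, tolerance = 1e-3)
  expect_true(tc$expansionValid)
  # tau_f grows linearly with <d^2> at fixed z0 in the expansion regime
  d2s <- seq(100, 400, by = 100)
  tf <- vapply(d2s, function(d) tailConstantsTheory(2, d, 1)$tauFApprox,
               numeric(1))
  expect_equal(tf / tf[1], d2s / d2s[1], tolerance = 1e-12)
})

test_that("persistence length estimator: ideal-chain bias and stiffness ordering", {
  # chains sampled directly from the discrete worm-like measure (oracle
  # sampler, no dynamics): phi from the exact bending Boltzmann weight
  sampleWLC <- function(a, nBonds, nConf, seed) {
    rng <- diabodysim:::.seededRNG(seed)
    lapply(seq_len(nConf), function(cf) {
      u <- matrix(0, nBonds, 3)
      u[1, ] <- c(0, 0, 1)
      for (b in 2:nBonds) {
        # rejection-sample cos(phi) with weight exp(-a phi^2) sin(phi)
        repeat {
          phi <- acos(1 - 2 * rng$runif(1))
          if (rng$runif(1) < exp(-a * phi^2)) break
        }
        psi <- 2 * pi * rng$runif(1)
        prev <- u[b - 1, ]
        ref <- if (abs(prev[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
        e1 <- ref - sum(ref * prev) * prev
        e1 <- e1 / sqrt(sum(e1^2))
        e2 <- c(prev[2] * e1[3] - prev[3] * e1[2],
                prev[3] * e1[1] - prev[1] * e1[3],
                prev[1] * e1[2] - prev[2] * e1[1])
        u[b, ] <- cos(phi) * prev + sin(phi) * (cos(psi) * e1 +
                                                  sin(psi) * e2)
      }
      apply(rbind(c(0, 0, 0), u), 2, cumsum)
    })
  }
  a <- 0.9
  confs <- sampleWLC(a, nBonds = 40, nConf = 120, seed = 30)
  est <- persistenceLength(confs)
  # transfer-matrix truth for this weight
  num <- stats::integrate(function(p) cos(p) * sin(p) * exp(-a * p^2),
                          0, pi)$value
  den <- stats::integrate(function(p) sin(p) * exp(-a * p^2), 0, pi)$value
  lpTrue <- -1 / log(num / den)
  expect_equal(est$lp, lpTrue, tolerance = 0.12 * lpTrue)

  # freely-jointed chain: correlation ~ 0 beyond the first bond, lp < 1
  sFJ <- buildFreeLinker(40, kTheta = 0)
  tmFJ <- sampleEquilibriumMC(sFJ, 4000, sampleEvery = 10, seed = 31)
  estFJ <- persistenceLength(tmFJ@coords[, , -(1:100)])
  expect_lt(estFJ$lp, 1)
  expect_lt(abs(estFJ$correlation$C[5]), 0.1)

  # stiffness ordering: kTheta = 10 beats the default
  sStiff <- buildFreeLinker(40, kTheta = 10)
  tmS <- sampleEquilibriumMC(sStiff, 4000, sampleEvery = 10, seed = 32)
  estS <- persistenceLength(tmS@coords[, , -(1:100)])
  sDef <- buildFreeLinker(40)
  tmD <- sampleEquilibriumMC(sDef, 4000, sampleEvery = 10, seed = 33)
  estD <- persistenceLength(tmD@coords[, , -(1:100)])
  expect_gt(estS$lp, estD$lp)
})

test_that("effective-Kuhn fit recovers a known Nk and reports the naive guess", {
  z <- fixtureIdealTetheredChain(50, b = 3, zt = 7.5, n = 60000, seed = 14)
  h <- graphics::hist(z, breaks = seq(0, max(z) + 1, by = 0.75),
                      plot = FALSE)
  fit <- fitEffectiveNk(data.frame(z = h$mids, density = h$density),
                        b = 3, zt = 7.5, N = 40)
  expect_equal(fit$NkEff, 50, tolerance = 0.06 * 50)
  expect_equal(fit$naiveGuess, (40 + 2 * 5.65) / 3, tolerance = 1e-12)
  # un-normalized input is renormalized with a warning
  expect_warning(
    fitEffectiveNk(data.frame(z = h$mids, density = h$density * 3),
                   b = 3, zt = 7.5), "renormaliz")
})

test_that("theory closes the loop with event kinetics on an uncorrelated frame process", {
  # two-state chain with known P_<: the flight-tail constant matches
  # tau_f = dt_c / P_< from the run-length argument
  pBelow <- 0.25
  above <- fixtureTwoStateChain(pBelow = pBelow, n = 3e5, seed = 19)
  z <- ifelse(above, 5, 1)
  ev <- decomposeEvents(z, z0 = 3.5, minDuration = 0, frameInterval = 1)
  Sf <- survivalCurve(ev, "flight")
  fit <- fitExponentialTail(Sf, tMin = 3)
  theo <- tailConstantsTheory(1, 3 * 1^2 / (2 * (-log(1 - pBelow))), 1)
  # geometric tail: S(t) ~ (1-P_<)^t -> tau = -1/log(1-P_<) ~ 1/P_<
  tauGeom <- -1 / log(1 - pBelow)
  expect_equal(fit$tau, tauGeom, tolerance = 0.1 * tauGeom)
  expect_equal(theo$tauF, 1 / pBelow, tolerance = 1e-12)
})
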