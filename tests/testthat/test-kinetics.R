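test_that("event decomposition matches hand-computed stretch examples", {
  # all-above series: one censored flight, no residences
  ev <- decomposeEvents(c(4, 4, 4, 4), z0 = 3.5, minDuration = 2,
                        frameInterval = 1)
  e <- events(ev)
  expect_equal(nrow(e), 1)
  expect_equal(e$kind, "flight")
  expect_equal(e$duration, 4)
  expect_true(e$censored)

  # clean alternation
  e2 <- events(decomposeEvents(c(4, 4, 1, 1, 1, 4, 4), z0 = 3.5,
                               minDuration = 2, frameInterval = 1))
  expect_equal(e2$kind, c("flight", "residence", "flight"))
  expect_equal(e2$duration, c(2, 3, 2))
  expect_equal(e2$censored, c(TRUE, FALSE, TRUE))

  # one-frame dip below the minimum duration is absorbed
  e3 <- events(decomposeEvents(c(4, 4, 1, 4, 4), z0 = 3.5, minDuration = 2,
                               frameInterval = 1))
  expect_equal(nrow(e3), 1)
  expect_equal(e3$duration, 5)

  expect_error(decomposeEvents(rep(3.5, 10), z0 = 3.5), "degenerate")
  expect_error(decomposeEvents(4, z0 = 3.5), "at least 2")
})

test_that("decomposition invariants hold on random series (fuzz vs reference)", {
  rng <- diabodysim:::.seededRNG(77)
  for (rep in 1:25) {
    n <- 50 + rep * 10
    z <- 3.5 + cumsum(rng$rnorm(n)) * 0.8
    # unfiltered events match the brute-force run decomposition exactly
    ev <- events(decomposeEvents(z, z0 = 3.5, minDuration = 0,
                                 frameInterval = 1))
    ref <- referenceRuns(z, 3.5)
    expect_equal(ev$kind, ref$kind)
    expect_equal(ev$duration, ref$frames)
    # filtered: kinds alternate strictly and total duration is conserved
    evf <- events(decomposeEvents(z, z0 = 3.5, minDuration = 3,
                                  frameInterval = 1))
    if (nrow(evf) > 1)
      expect_true(all(evf$kind[-1] != evf$kind[-nrow(evf)]))
    expect_equal(sum(evf$duration), n)
    # with no filter, time-fraction identity holds exactly
    expect_equal(sum(ev$duration[ev$kind == "flight"]) / n, mean(z >= 3.5))
  }
})

test_that("survival curves are proper complementary cumulatives", {
  S <- survivalCurve(c(2, 2, 2))
  expect_equal(S@S[S@time < 2], rep(1, sum(S@time < 2)))
  expect_equal(S@S[S@time >= 2], rep(0, sum(S@time >= 2)))
  S2 <- survivalCurve(c(1, 2, 3))
  # S(1.5) = 2/3: value held from the previous jump point
  idx <- max(which(S2@time <= 1.5))
  expect_equal(S2@S[idx], 2 / 3)
  expect_equal(S2@S[1], 1)
  expect_true(all(diff(S2@S) <= 0))
  # exponential durations: KS agreement with exp(-t)
  rng <- diabodysim:::.seededRNG(3)
  d <- -log(rng$runif(4000))
  S3 <- survivalCurve(d)
  ks <- suppressWarnings(stats::ks.test(d, "pexp", 1))
  expect_gt(ks$p.value, 0.01)
  expect_equal(survivalIntegral(S3), mean(d), tolerance = 1e-12)
})

test_that("rates are reciprocal mean durations, exactly", {
  Sf <- survivalCurve(c(1, 2, 3))
  Sr <- survivalCurve(c(0.5, 0.5))
  r <- ratesFromSurvival(Sf, Sr, nBoot = 200, seed = 9)
  expect_equal(r$kOn, 0.5)                      # 1 / mean(1,2,3)
  expect_equal(r$kOff, 2)
  # integral of S computed from the curve equals the direct mean to 1e-12
  expect_equal(survivalIntegral(Sf), 2, tolerance = 1e-12)
  expect_true(is.finite(r$kOnSE))
  # closed form: S(t) = exp(-t/tau) has rate 1/tau
  tgrid <- seq(0, 30, by = 1e-4)
  tau <- 2.5
  approxRate <- 1 / sum(exp(-tgrid / tau) * 1e-4)
  expect_equal(approxRate, 1 / tau, tolerance = 1e-3)
  # single event: infinite error flag
  r1 <- ratesFromSurvival(survivalCurve(2), survivalCurve(1), nBoot = 10)
  expect_equal(r1$kOnSE, Inf)
})

test_that("exponential tails are recovered with calibrated uncertainty", {
  rng <- diabodysim:::.seededRNG(15)
  d <- -0.5 * log(rng$runif(3000))              # rate 2 -> tau = 0.5
  S <- survivalCurve(d)
  fit <- fitExponentialTail(S, tMin = 0.2)
  expect_true(fit$ci[1] < 0.5 && 0.5 < fit$ci[2])
  expect_equal(fit$tau, 0.5, tolerance = 0.1)
  # mixture: power-law head + exponential tail; fitting past the crossover
  # recovers the tail constant
  head <- (rng$runif(4000))^(-1/2) * 0.01       # ~ t^{-1/2} head, small t
  tail <- 1 - log(rng$runif(1500))              # exponential rate 1 from t=1
  Sm <- survivalCurve(c(head[head < 0.5], tail))
  fitMix <- fitExponentialTail(Sm, tMin = 2)
  expect_equal(fitMix$tau, 1, tolerance = 0.25)
  expect_error(fitExponentialTail(S, tMin = max(S@time) + 1),
               "insufficient")
})

test_that("short-time power-law exponent: self-consistency and misfit flag", {
  rng <- diabodysim:::.seededRNG(21)
  # durations with S(t) = (t/t0)^(-1/2) on t >= t0 (Pareto alpha = 1/2)
  d <- 0.01 * rng$runif(20000)^(-2)
  S <- survivalCurve(d)
  fit <- fitShorttimePowerlaw(S, c(0.02, 1))
  expect_equal(fit$alpha, 0.5, tolerance = 0.03)
  expect_true(fit$powerLawOK)
  # excursion lengths of an unbiased random walk approach the 1/2 law;
  # reflecting the walk in a wide box keeps it returning to the threshold
  # (the distant boundary cannot affect the short-time window)
  raw <- cumsum(rng$rnorm(1e6))
  m <- (raw + 25) %% 100
  z <- ifelse(m <= 50, m, 100 - m) - 25
  ev <- decomposeEvents(z + 0.5, z0 = 0.5, minDuration = 0,
                        frameInterval = 1)
  Sw <- survivalCurve(ev, "flight")
  fw <- fitShorttimePowerlaw(Sw, c(2, 60))
  expect_equal(fw$alpha, 0.5, tolerance = 0.1)
  # exponential durations are flagged as a poor power law
  de <- -log(rng$runif(5000))
  Se <- survivalCurve(de)
  fe <- fitShorttimePowerlaw(Se, c(0.5, 6))
  expect_false(fe$powerLawOK)
})

test_that("rate gains are element-wise ratios against the eps = 0 baseline", {
  tab <- data.frame(eps = c(0, 0, 1.5, 1.5), N = c(10, 30, 10, 30),
                    kOn = c(1, 0.5, 2, 2), kOff = c(4, 4, 2, 2),
                    kOnSE = 0.05, kOffSE = 0.1)
  g <- rateGainRatios(tab)
  expect_equal(g$kOnGain, c(1, 1, 2, 4))
  expect_equal(g$kOffGain, c(1, 1, 0.5, 0.5))
  expect_true(all(is.finite(g$kOnGainSE)))
  # constructed case: kOn(eps, N) flat in N while kOn(0, N) ~ 1/N gives a
  # gain increasing linearly with N
  tab2 <- data.frame(eps = rep(c(0, 2), each = 3), N = rep(c(10, 20, 30), 2),
                     kOn = c(1 / c(10, 20, 30), rep(0.2, 3)),
                     kOff = 1)
  g2 <- rateGainRatios(tab2)
  gains <- g2$kOnGain[g2$eps == 2]
  expect_equal(gains, 0.2 * c(10, 20, 30))
  expect_error(rateGainRatios(tab[tab$eps > 0, ]), "baseline")
})
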