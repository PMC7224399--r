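test_that("window grids are exact inclusive arithmetic sequences", {
  expect_length(generateWindows(3, 30, 0.5), 55)
  expect_length(generateWindows(3, 40, 0.5), 75)
  expect_length(generateWindows(3, 70, 0.5), 135)
  expect_length(generateWindows(5, 35, 0.5), 61)
  expect_length(generateWindows(5, 55, 0.5), 101)
  expect_equal(generateWindows(3, 3, 0.5), 3)
  expect_error(generateWindows(3, 30, 0), "spacing")
  expect_error(generateWindows(30, 3), "rcMax")
})

test_that("WHAM recovers a known 1D potential from exact biased samples", {
  # master oracle: U(x) = 0.5 x^2; under a harmonic bias k(c) the biased
  # density is Gaussian with precision (1 + k) and mean k c / (1 + k),
  # so windows can be sampled exactly without any dynamics
  set.seed(91)
  k <- 10
  wins <- lapply(seq(-3, 3, by = 0.5), function(c0) {
    list(center = c0, k = k,
         samples = rnorm(6000, mean = k * c0 / (1 + k),
                         sd = sqrt(1 / (1 + k))))
  })
  p <- wham(wins, binWidth = 0.1)
  sel <- abs(p@grid) <= 2
  ref <- 0.5 * p@grid[sel]^2
  err <- max(abs((p@pmf[sel] - min(p@pmf[sel])) - (ref - min(ref))))
  expect_lt(err, 0.1)
  # permuting window order leaves the profile unchanged
  p2 <- wham(wins[sample(length(wins))], binWidth = 0.1)
  expect_equal(p2@pmf, p@pmf, tolerance = 1e-5)
})

test_that("single unbiased window reduces WHAM to -kT log(histogram)", {
  set.seed(13)
  x <- rnorm(20000, sd = 1.2)
  p <- wham(list(list(center = 0, k = 0, samples = x)), binWidth = 0.2)
  h <- graphics::hist(x, breaks = seq(min(x) - 0.1, max(x) + 0.3, by = 0.2),
                      plot = FALSE)
  ref <- -log(h$density[h$density > 0])
  ref <- ref - min(ref)
  sel <- abs(p@grid) < 2
  refAt <- stats::approx(h$mids[h$density > 0], ref, xout = p@grid[sel])$y
  expect_lt(max(abs(p@pmf[sel] - refAt), na.rm = TRUE), 0.05)
})

test_that("WHAM names the gap when windows are disjoint", {
  set.seed(5)
  wins <- list(list(center = -5, k = 50, samples = rnorm(500, -5, 0.1)),
               list(center = 5, k = 50, samples = rnorm(500, 5, 0.1)))
  expect_error(wham(wins, binWidth = 0.2, maxIter = 2000), "gap")
})

test_that("umbrella windows track their centres in the stiff-bias limit", {
  s <- buildFreeLinker(6)
  run <- runUmbrella(s, "rho_z", windows = c(14, 15), springK = 150,
                     sweepsPerWindow = 400, burnin = 100, dragSweeps = 50,
                     seed = 3, cvSpec = list(type = "com_z", idx = 6L, w = 1))
  expect_length(run$windows, 2)
  for (w in run$windows)
    expect_lt(abs(mean(w$samples) - w$center), 0.15)
})

test_that("adjacent windows of a diabody umbrella run share support", {
  s <- buildSphDiabody(6, "repulsive#2")
  run <- runUmbrella(s, "rho_z", windows = seq(10, 12, 0.5), springK = 10,
                     sweepsPerWindow = 500, burnin = 100, dragSweeps = 60,
                     seed = 41)
  for (q in seq_len(length(run$windows) - 1)) {
    a <- run$windows[[q]]$samples
    b <- run$windows[[q + 1]]$samples
    lo <- max(min(a), min(b))
    hi <- min(max(a), max(b))
    overlapA <- mean(a >= lo & a <= hi)
    overlapB <- mean(b >= lo & b <= hi)
    expect_gt(min(overlapA, overlapB), 0.05)
  }
})

test_that("flat-region metric matches closed forms", {
  # identically flat profile on [0, L]
  g <- seq(0, 10, by = 0.25)
  flat <- new("PMFProfile", grid = g, pmf = rep(0, length(g)),
              stderr = numeric(), cv = "rho_xy", meta = list())
  fm <- pmfFlatMetric(flat, threshold = 1, reach = 10)
  expect_equal(fm$meanNorm, 0.5)
  expect_equal(fm$extent, 10.25)       # full range + one bin width
  # V-shaped profile: single-bin flat region
  v <- new("PMFProfile", grid = g, pmf = abs(g - 5) * 10,
           stderr = numeric(), cv = "rho_xy", meta = list())
  fv <- pmfFlatMetric(v, threshold = 1, reach = 10)
  expect_equal(fv$extent, 0.25, tolerance = 1e-9)
  expect_equal(fv$meanNorm, 0.5)
  # harmonic profile: extent of {0.5 k (x-x0)^2 <= 1} is 2 sqrt(2/k)
  k <- 2
  gg <- seq(0, 10, by = 0.01)
  hq <- new("PMFProfile", grid = gg, pmf = 0.5 * k * (gg - 5)^2,
            stderr = numeric(), cv = "rho_xy", meta = list())
  fh <- pmfFlatMetric(hq, threshold = 1)
  expect_equal(fh$extent, 2 * sqrt(2 / k), tolerance = 0.02)
  # empty flat region
  hi <- new("PMFProfile", grid = g, pmf = c(0, rep(10, length(g) - 1)),
            stderr = numeric(), cv = "rho_xy", meta = list())
  expect_equal(pmfFlatMetric(hi, threshold = -1)$empty, TRUE)
})

test_that("PMF gradient uses central differences with one-sided ends", {
  g <- seq(0, 2, by = 0.1)
  lin <- new("PMFProfile", grid = g, pmf = 3 * g, stderr = numeric(),
             cv = "x", meta = list())
  expect_equal(pmfGradient(lin)$dpmf, rep(3, length(g)), tolerance = 1e-10)
  quad <- new("PMFProfile", grid = g, pmf = (g - 1)^2, stderr = numeric(),
              cv = "x", meta = list())
  dq <- pmfGradient(quad)
  expect_equal(dq$dpmf[dq$cv == 1], 0, tolerance = 1e-10)
  # O(h^2) accuracy on a smooth profile
  gs <- seq(0, pi, length.out = 100)
  sinp <- new("PMFProfile", grid = gs, pmf = sin(gs) + 1 - min(sin(gs) + 1),
              stderr = numeric(), cv = "x", meta = list())
  ds <- pmfGradient(sinp)
  mid <- 2:99
  expect_lt(max(abs(ds$dpmf[mid] - cos(gs[mid]))), (gs[2] - gs[1])^2)
})
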