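## Synthetic datasets with documented statistical structure, used to test
## every analysis module without external data.

#' Two-state (Bernoulli) frame process
#'
#' Independent frames that are "below" the threshold with probability
#' `pBelow`; realizes the uncorrelated frame process behind the geometric
#' run-length laws (see [runLengthDistribution()]).
#'
#' @param pBelow per-frame probability of being below the threshold.
#' @param n number of frames.
#' @param seed RNG seed.
#' @return logical vector, `TRUE` = above.
#' @export
fixtureTwoStateChain <- function(pBelow, n, seed = 1) {
  stopifnot(pBelow >= 0, pBelow <= 1, n >= 1)
  rng <- .seededRNG(seed)
  rng$runif(n) >= pBelow
}

#' Ornstein--Uhlenbeck height series
#'
#' Mean-reverting Gaussian series \eqn{dz = -(z - \mu)/\tau\,dt + \sigma
#' \sqrt{2/\tau}\,dW}: a minimal stand-in for a bead height trajectory with
#' tunable correlation time.
#'
#' @param n samples.
#' @param mean stationary mean.
#' @param tau correlation time (in units of `dt`).
#' @param sd stationary standard deviation.
#' @param dt sampling interval.
#' @param seed RNG seed.
#' @return numeric series of length `n`.
#' @export
fixtureOuHeightSeries <- function(n, mean = 5, tau = 10, sd = 2, dt = 1,
                                  seed = 1) {
  stopifnot(n >= 1, tau > 0, sd > 0, dt > 0)
  rng <- .seededRNG(seed)
  a <- exp(-dt / tau)
  noise <- rng$rnorm(n)
  z <- numeric(n)
  z[1] <- mean + sd * noise[1]
  for (i in seq_len(n - 1))
    z[i + 1] <- mean + a * (z[i] - mean) + sd * sqrt(1 - a^2) * noise[i + 1]
  z
}

#' Free-end heights of an ideal tethered Gaussian chain
#'
#' Direct sampling of the reflected-Gaussian end-height density (see
#' [tetheredEndPdf()]) by rejection from the image construction: draw
#' \eqn{z \sim N(z_t, N_k b^2/3)}, keep `z > 0` with probability
#' \eqn{1 - e^{-4 a z z_t}} (with \eqn{a = 3/2N_kb^2}); for `zt = 0` draws
#' from the zero-tether law directly by inversion.
#'
#' @param Nk Kuhn segments.
#' @param b Kuhn length (sigma).
#' @param zt tether height (sigma).
#' @param n samples.
#' @param seed RNG seed.
#' @return numeric vector of heights.
#' @export
fixtureIdealTetheredChain <- function(Nk, b = 3, zt = 7.5, n = 1000,
                                      seed = 1) {
  stopifnot(Nk > 0, b > 0, zt >= 0, n >= 1)
  rng <- .seededRNG(seed)
  d2 <- Nk * b^2
  if (zt == 0) {
    # inversion of P(Z > z) = exp(-3 z^2 / 2 d2)
    u <- rng$runif(n)
    return(sqrt(-2 * d2 * log(u) / 3))
  }
  a <- 3 / (2 * d2)
  sdz <- sqrt(d2 / 3)
  out <- numeric(0)
  while (length(out) < n) {
    m <- max(2L * (n - length(out)), 100L)
    z <- zt + sdz * rng$rnorm(m)
    keep <- z > 0 & rng$runif(m) < (1 - exp(-4 * a * z * zt))
    out <- c(out, z[keep])
  }
  out[seq_len(n)]
}

#' Gaussian cluster cloud
#'
#' Well-separated isotropic Gaussian clusters with per-point masses; the
#' reference input for testing coarse-graining maps against a k-means
#' oracle.
#'
#' @param centers matrix `k x 3` of cluster centres.
#' @param nPer points per cluster.
#' @param sd within-cluster standard deviation.
#' @param mass per-point mass (recycled).
#' @param seed RNG seed.
#' @return list with `coords`, `masses`, `cluster` (true labels).
#' @export
fixtureClusterCloud <- function(centers, nPer = 50, sd = 0.5, mass = 1,
                                seed = 1) {
  centers <- as.matrix(centers)
  k <- nrow(centers)
  rng <- .seededRNG(seed)
  coords <- do.call(rbind, lapply(seq_len(k), function(c1)
    matrix(rng$rnorm(nPer * 3), nPer, 3) * sd +
      matrix(centers[c1, ], nPer, 3, byrow = TRUE)))
  list(coords = coords, masses = rep_len(mass, k * nPer),
       cluster = rep(seq_len(k), each = nPer))
}

#' Generate a named synthetic fixture
#'
#' Dispatcher over the fixture generators; generation is deterministic given
#' the seed.
#'
#' @param name one of `"two_state_chain"`, `"ou_height_series"`,
#'   `"ideal_tethered_chain"`, `"cluster_cloud"`.
#' @param params named list of generator arguments.
#' @param seed RNG seed.
#' @return the generator's value.
#' @export
generateFixture <- function(name, params = list(), seed = 1) {
  gen <- switch(name,
    two_state_chain = fixtureTwoStateChain,
    ou_height_series = fixtureOuHeightSeries,
    ideal_tethered_chain = fixtureIdealTetheredChain,
    cluster_cloud = fixtureClusterCloud,
    stop("unknown fixture generator: ", name))
  do.call(gen, c(params, list(seed = seed)))
}
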