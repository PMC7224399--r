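## Flight/residence decomposition of paratope height trajectories and the
## survival-time estimators of the second-binding kinetic constants.

#' Decompose a height series into flight and residence events
#'
#' Splits the z-series of the free paratope into alternating stretches above
#' (flight) and below (residence) the threshold `z0`.  Stretches shorter
#' than `minDuration` are absorbed into the enclosing event (recrossing
#' filter), shortest first, which preserves alternation and total duration.
#' Events truncated by the trajectory ends are flagged as censored and
#' excluded from rate estimates by default.
#'
#' @param z numeric height series at uniform sampling (sigma), or the result
#'   of [beadHeightSeries()].
#' @param z0 threshold height (sigma); `z >= z0` counts as flight.
#' @param minDuration minimum event duration, in the same time unit as
#'   `frameInterval`.
#' @param frameInterval sampling interval of `z`.
#' @param bead optional source-bead label stored with the result.
#' @return an [EventSeries-class].
#' @examples
#' ev <- decomposeEvents(c(4, 4, 1, 1, 1, 4, 4), z0 = 3.5,
#'                       minDuration = 0, frameInterval = 1)
#' events(ev)
#' @export
decomposeEvents <- function(z, z0 = 3.5, minDuration = 0, frameInterval = 1,
                            bead = NA_character_) {
  if (is.list(z)) {
    frameInterval <- z$interval
    z <- z$z
  }
  if (length(z) < 2) stop("series must have at least 2 samples")
  if (z0 <= 0) stop("z0 must be > 0")
  if (minDuration < 0) stop("minDuration must be >= 0")
  if (all(z == z0)) stop("degenerate series: constant exactly at threshold")

  state <- z >= z0
  r <- rle(state)
  minFrames <- ceiling(minDuration / frameInterval)

  # absorb sub-minimum stretches (shortest first) into their surroundings;
  # the merge preserves alternation and total duration
  m <- cg_merge_runs(r$lengths, r$values, as.integer(minFrames))
  lens <- m$lengths
  vals <- as.logical(m$values)

  dur <- lens * frameInterval
  kind <- ifelse(vals, "flight", "residence")
  censored <- rep(FALSE, length(dur))
  if (length(dur)) {
    censored[1] <- TRUE
    censored[length(dur)] <- TRUE
  }
  ev <- data.frame(kind = kind, duration = dur, censored = censored,
                   stringsAsFactors = FALSE)
  new("EventSeries", events = ev,
      config = list(z0 = z0, minDuration = minDuration,
                    frameInterval = frameInterval, bead = bead))
}

#' Event durations of one kind
#'
#' @param x an [EventSeries-class].
#' @param kind `"flight"` or `"residence"`.
#' @param includeCensored include events truncated by the trajectory ends.
#' @return numeric durations.
#' @export
eventDurations <- function(x, kind = c("flight", "residence"),
                           includeCensored = FALSE) {
  kind <- match.arg(kind)
  e <- events(x)
  sel <- e$kind == kind & (includeCensored | !e$censored)
  e$duration[sel]
}

#' Empirical survival curve of event durations
#'
#' Complementary cumulative distribution \eqn{S(t) = P(T > t)} of the
#' durations of one event kind; \eqn{S(0) = 1} and
#' \eqn{\int_0^\infty S(t)\,dt} equals the mean duration exactly.
#'
#' @param x an [EventSeries-class], or a numeric vector of durations.
#' @param kind `"flight"` or `"residence"` (ignored for a numeric vector).
#' @param includeCensored include censored events.
#' @return a [SurvivalCurve-class].
#' @export
survivalCurve <- function(x, kind = c("flight", "residence"),
                          includeCensored = FALSE) {
  kind <- match.arg(kind)
  d <- if (is.numeric(x)) x else eventDurations(x, kind, includeCensored)
  if (!length(d)) stop("no ", kind, " events")
  ts <- sort(unique(d))
  n <- length(d)
  S <- vapply(ts, function(t) sum(d > t) / n, numeric(1))
  new("SurvivalCurve", time = c(0, ts), S = c(1, S), domain = kind,
      nEvents = as.integer(n))
}

#' Integral of a survival curve
#'
#' Exact integral of the empirical step function \eqn{S(t)}, equal to the
#' mean event duration.
#'
#' @param S a [SurvivalCurve-class].
#' @return \eqn{\int_0^\infty S\,dt}.
#' @export
survivalIntegral <- function(S) {
  # step function: S is constant on [t_i, t_{i+1})
  sum(S@S[-length(S@S)] * diff(S@time)) + 0
}

#' On- and off-rates from flight and residence survival curves
#'
#' \eqn{k_{on} = [\int_0^\infty S_f\,dt]^{-1}} and
#' \eqn{k_{off} = [\int_0^\infty S_r\,dt]^{-1}}: the inverse mean flight and
#' residence times.  Standard errors by bootstrap over events.
#'
#' @param Sf flight [SurvivalCurve-class] (or an [EventSeries-class], from
#'   which both curves are derived).
#' @param Sr residence [SurvivalCurve-class] (ignored when `Sf` is an event
#'   series).
#' @param nBoot bootstrap resamples.
#' @param seed bootstrap seed.
#' @return list with `kOn`, `kOff`, `kOnSE`, `kOffSE`, `meanFlight`,
#'   `meanResidence`; a single event of a kind yields an infinite error flag.
#' @export
ratesFromSurvival <- function(Sf, Sr = NULL, nBoot = 1000, seed = 1) {
  if (is(Sf, "EventSeries")) {
    es <- Sf
    Sf <- survivalCurve(es, "flight")
    Sr <- survivalCurve(es, "residence")
  }
  stopifnot(is(Sf, "SurvivalCurve"), is(Sr, "SurvivalCurve"))
  mf <- survivalIntegral(Sf)
  mr <- survivalIntegral(Sr)
  rng <- .seededRNG(seed)
  bootSE <- function(S) {
    d <- .durationsFromCurve(S)
    if (length(d) < 2) return(Inf)
    means <- vapply(seq_len(nBoot), function(b)
      mean(d[rng$sampleInt(length(d), length(d), replace = TRUE)]),
      numeric(1))
    stats::sd(1 / means)
  }
  list(kOn = 1 / mf, kOff = 1 / mr,
       kOnSE = bootSE(Sf), kOffSE = bootSE(Sr),
       meanFlight = mf, meanResidence = mr)
}

# reconstruct the duration multiset from an empirical survival curve
.durationsFromCurve <- function(S) {
  n <- S@nEvents
  counts <- round(-diff(c(S@S, 0)) * n)
  rep(S@time[-1], counts[-length(counts)])[seq_len(n)] -> d
  # last time point carries S -> 0
  if (length(d) < n) d <- c(d, rep(S@time[length(S@time)], n - length(d)))
  d
}

#' Exponential-tail decay constant of a survival curve
#'
#' Weighted least squares of \eqn{\ln S} against \eqn{t} over
#' `[tMin, max(t))`, weights proportional to the number of surviving events;
#' returns the decay constant \eqn{\tau} and a 95 percent confidence
#' interval.
#'
#' @param S a [SurvivalCurve-class].
#' @param tMin start of the fit window (past the short-time power-law
#'   regime).
#' @param minEvents minimum number of events beyond `tMin`.
#' @return list with `tau`, `ci` (length 2), `window`, `nTail`.
#' @export
fitExponentialTail <- function(S, tMin, minEvents = 10) {
  sel <- S@time >= tMin & S@S > 0 & S@time < max(S@time)
  nTail <- if (any(sel)) round(S@S[which(sel)[1]] * S@nEvents) else 0
  if (sum(sel) < 3 || nTail < minEvents)
    stop("insufficient tail data beyond tMin = ", tMin,
         " (", nTail, " events)")
  t <- S@time[sel]
  y <- log(S@S[sel])
  wts <- S@S[sel] * S@nEvents
  fit <- stats::lm(y ~ t, weights = wts)
  slope <- stats::coef(fit)[["t"]]
  seFit <- summary(fit)$coefficients["t", "Std. Error"]
  tau <- -1 / slope
  # survival-curve points are strongly correlated, so the regression SE is
  # optimistic; the sampling floor is that of a mean of nTail exponentials
  # (relative SE 1/sqrt(nTail))
  relSE <- max(seFit * tau, 1 / sqrt(nTail))
  ci <- tau * exp(c(-1.96, 1.96) * relSE)
  if (slope >= 0) ci <- c(tau / 3, Inf)
  list(tau = tau, ci = ci, window = c(tMin, max(t)), nTail = nTail,
       slopeSE = seFit)
}

#' Short-time power-law exponent of a survival curve
#'
#' Log--log least squares of \eqn{S(t) \sim t^{-\alpha}} over a time window;
#' free three-dimensional diffusion of the paratope gives
#' \eqn{\alpha = 1/2}.  A significant quadratic term in log-log coordinates
#' flags a poor power-law fit (e.g. exponential data).
#'
#' @param S a [SurvivalCurve-class].
#' @param tWindow length-2 fit window `(t1, t2)`.
#' @param minEvents minimum number of events inside the window.
#' @return list with `alpha` (positive convention), `se`, `powerLawOK`
#'   (curvature diagnostic), `window`.
#' @export
fitShorttimePowerlaw <- function(S, tWindow, minEvents = 100) {
  sel <- S@time >= tWindow[1] & S@time <= tWindow[2] & S@S > 0 & S@time > 0
  if (sum(sel) < 4)
    stop("insufficient data in the fit window")
  nIn <- round((max(S@S[sel]) - min(S@S[sel])) * S@nEvents)
  if (nIn < minEvents)
    stop("fewer than ", minEvents, " events resolve the window")
  lt <- log(S@time[sel])
  ls <- log(S@S[sel])
  fit <- stats::lm(ls ~ lt)
  alpha <- -stats::coef(fit)[["lt"]]
  se <- summary(fit)$coefficients["lt", "Std. Error"]
  fit2 <- stats::lm(ls ~ lt + I(lt^2))
  curv <- summary(fit2)$coefficients
  powerLawOK <- !("I(lt^2)" %in% rownames(curv)) ||
    abs(curv["I(lt^2)", "Estimate"]) < 0.1 ||
    curv["I(lt^2)", "Pr(>|t|)"] > 0.01
  list(alpha = alpha, se = se, powerLawOK = powerLawOK, window = tWindow)
}

#' Flight/residence statistics from an ensemble of short replicas
#'
#' Runs independent Brownian-dynamics replicas of a tethered system, each
#' started from its own Monte-Carlo-equilibrated configuration (so the
#' replica ensemble samples the slow global tilt mode through the initial
#' conditions, as a lattice of non-interacting tethered copies would), and
#' decomposes the tracked bead's height series of each replica into events.
#'
#' @param system a [DiabodySystem-class].
#' @param nReplicas number of independent replicas.
#' @param nSteps BD steps per replica.
#' @param dt BD time step.
#' @param seed master seed.
#' @param bead tracked bead (default the free paratope P1).
#' @param z0,minDuration event decomposition settings.
#' @param equilSweeps MC sweeps used to draw each replica's start.
#' @param drag friction model for the BD runs (see [runTrajectory()]).
#' @param trackEvery z-track stride in steps.
#' @return `runReplicaSeries()`: list of height series (each
#'   `list(z, interval)`); `runKineticsReplicas()`: list of
#'   [EventSeries-class], one per replica.
#' @export
runReplicaSeries <- function(system, nReplicas = 8, nSteps = 1e6,
                             dt = 2e-4, seed = 1, bead = "P1",
                             equilSweeps = 8000, drag = "uniform",
                             trackEvery = 2) {
  seeds <- .subSeeds(seed, 2L * nReplicas)
  lapply(seq_len(nReplicas), function(r) {
    tm <- sampleEquilibriumMC(system, equilSweeps, sampleEvery = 0,
                              seed = seeds[r])
    tr <- runTrajectory(system, nSteps, dt = dt, sampleEvery = 0,
                        seed = seeds[nReplicas + r], trackBeads = bead,
                        trackEvery = trackEvery, start = frameCoords(tm),
                        drag = drag)
    beadHeightSeries(tr, bead)
  })
}

#' @rdname runReplicaSeries
#' @export
runKineticsReplicas <- function(system, nReplicas = 8, nSteps = 1e6,
                                dt = 2e-4, seed = 1, bead = "P1", z0 = 3.5,
                                minDuration = 0, equilSweeps = 8000,
                                drag = "uniform", trackEvery = 2) {
  series <- runReplicaSeries(system, nReplicas = nReplicas, nSteps = nSteps,
                             dt = dt, seed = seed, bead = bead,
                             equilSweeps = equilSweeps, drag = drag,
                             trackEvery = trackEvery)
  lapply(series, decomposeEvents, z0 = z0, minDuration = minDuration,
         bead = bead)
}

#' Pool event durations across replicas
#'
#' @param eventsList list of [EventSeries-class] (e.g. from
#'   [runKineticsReplicas()]).
#' @param kind `"flight"` or `"residence"`.
#' @param includeCensored include events truncated by replica ends.
#' @return numeric durations, concatenated.
#' @export
pooledDurations <- function(eventsList, kind = c("flight", "residence"),
                            includeCensored = FALSE) {
  kind <- match.arg(kind)
  unlist(lapply(eventsList, eventDurations, kind = kind,
                includeCensored = includeCensored))
}

#' Rate gain relative to the non-attractive wall
#'
#' Element-wise ratios \eqn{k(\epsilon, N)/k(0, N)} over a table of rates on
#' a (wall attraction, linker length) grid, with first-order error
#' propagation.
#'
#' @param rates data.frame with columns `eps`, `N`, `kOn`, `kOff` and
#'   optionally `kOnSE`, `kOffSE`; must contain the `eps = 0` baseline for
#'   every `N`.
#' @return data.frame with `eps`, `N`, `kOnGain`, `kOffGain` (+ SEs when
#'   available).
#' @export
rateGainRatios <- function(rates) {
  need <- c("eps", "N", "kOn", "kOff")
  if (!all(need %in% names(rates))) stop("missing columns")
  base <- rates[rates$eps == 0, ]
  if (!nrow(base)) stop("no eps = 0 baseline in the rate table")
  m <- match(rates$N, base$N)
  if (anyNA(m)) stop("missing eps = 0 baseline for N = ",
                     paste(unique(rates$N[is.na(m)]), collapse = ", "))
  out <- data.frame(eps = rates$eps, N = rates$N,
                    kOnGain = rates$kOn / base$kOn[m],
                    kOffGain = rates$kOff / base$kOff[m])
  if (all(c("kOnSE", "kOffSE") %in% names(rates))) {
    out$kOnGainSE <- out$kOnGain *
      sqrt((rates$kOnSE / rates$kOn)^2 + (base$kOnSE[m] / base$kOn[m])^2)
    out$kOffGainSE <- out$kOffGain *
      sqrt((rates$kOffSE / rates$kOff)^2 + (base$kOffSE[m] / base$kOff[m])^2)
  }
  out
}
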