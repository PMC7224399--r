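## Umbrella sampling over the collective variables rho_z / rho_xy and WHAM
## reconstruction of potentials of mean force.

#' Umbrella window centres
#'
#' Inclusive arithmetic grid of window centres along the reaction coordinate.
#'
#' @param rcMin,rcMax first and last reaction-coordinate values (sigma).
#' @param spacing gap between windows (sigma), default 0.5.
#' @return numeric vector of `floor((rcMax - rcMin)/spacing) + 1` centres.
#' @examples
#' length(generateWindows(3, 30, 0.5))   # 55
#' length(generateWindows(5, 55, 0.5))   # 101
#' @export
generateWindows <- function(rcMin, rcMax, spacing = 0.5) {
  if (!is.numeric(spacing) || spacing <= 0) stop("spacing must be > 0")
  if (rcMax < rcMin) stop("rcMax must be >= rcMin")
  rcMin + spacing * seq(0, floor((rcMax - rcMin) / spacing + 1e-9))
}

#' Integrated autocorrelation time of a series
#'
#' Initial-positive-sequence estimate of the integrated autocorrelation time,
#' used to decorrelate window samples before WHAM.
#'
#' @param x numeric series.
#' @return estimated autocorrelation time in sampling intervals (>= 1).
#' @export
integratedAutocorrelationTime <- function(x) {
  n <- length(x)
  if (n < 10 || stats::sd(x) == 0) return(1)
  lagMax <- min(n %/% 4, 2000)
  ac <- stats::acf(x, lag.max = lagMax, plot = FALSE)$acf[-1]
  pos <- which(ac <= 0)
  if (length(pos)) ac <- ac[seq_len(pos[1] - 1)]
  max(1, 1 + 2 * sum(ac))
}

#' Run umbrella-sampling windows
#'
#' Generates starting structures by dragging the free nanobody along the
#' reaction coordinate (short equilibration at each window centre, carrying
#' the final configuration forward), then samples each window with the
#' Monte-Carlo sampler under a harmonic bias on the collective variable.
#' For `rho_xy` windows an additional harmonic restraint holds `rho_z` at a
#' fixed height.  Window series are subsampled at the estimated integrated
#' autocorrelation time.  Windows whose sampled mean stays further from the
#' centre than `3 sqrt(kT/k)` (sterically unreachable) are flagged and
#' excluded with a warning.
#'
#' @param system a [DiabodySystem-class].
#' @param cv `"rho_z"` or `"rho_xy"`.
#' @param windows window centres from [generateWindows()].
#' @param springK bias spring constant (kT/sigma^2).
#' @param sweepsPerWindow production MC sweeps per window.
#' @param burnin sweeps discarded at the start of each window.
#' @param dragSweeps equilibration sweeps at each centre during the drag.
#' @param seed master seed (per-window seeds derived from it).
#' @param rhoZRestraint for `rho_xy`: `list(k =, z =)` restraint holding
#'   rho_z (default 50 kT/sigma^2 at 5 sigma).
#' @param cvSpec optional custom collective-variable spec overriding the
#'   default [cvRhoZ()]/[cvRhoXY()] definitions (e.g. a single bead's
#'   height).
#' @return object of class `umbrellaRun`: list of per-window records
#'   (`center`, `k`, `samples`) plus metadata; feed to [wham()].
#' @export
runUmbrella <- function(system, cv = c("rho_z", "rho_xy"), windows,
                        springK = 10, sweepsPerWindow = 2000, burnin = 200,
                        dragSweeps = 100, seed = 1,
                        rhoZRestraint = list(k = 50, z = 5), cvSpec = NULL) {
  cv <- match.arg(cv)
  stopifnot(length(windows) >= 1)
  if (is.null(cvSpec))
    cvSpec <- if (cv == "rho_z") cvRhoZ(system) else cvRhoXY(system)
  extra <- NULL
  if (cv == "rho_xy") {
    extra <- cvRhoZ(system)
    extra$k <- rhoZRestraint$k
    extra$center <- rhoZRestraint$z
  }
  seeds <- .subSeeds(seed, 2L * length(windows))

  biasAt <- function(center, k) {
    bi <- cvSpec
    bi$k <- k
    bi$center <- center
    c(list(bi), if (!is.null(extra)) list(extra))
  }

  # drag to generate starting structures
  pos <- startCoords(system)
  starts <- vector("list", length(windows))
  for (w in seq_along(windows)) {
    tr <- sampleEquilibriumMC(system, nSweeps = dragSweeps, sampleEvery = 0,
                              seed = seeds[w], start = pos,
                              biases = biasAt(windows[w], max(springK, 50)))
    pos <- frameCoords(tr)
    starts[[w]] <- pos
  }

  out <- vector("list", length(windows))
  for (w in seq_along(windows)) {
    tr <- sampleEquilibriumMC(system, nSweeps = burnin + sweepsPerWindow,
                              sampleEvery = 0,
                              seed = seeds[length(windows) + w],
                              start = starts[[w]],
                              biases = biasAt(windows[w], springK),
                              cv = cvSpec, trackEvery = 1)
    s <- tr@track$cv[-seq_len(burnin + 1)]
    tau <- integratedAutocorrelationTime(s)
    s <- s[seq(1, length(s), by = max(1, round(tau)))]
    reachable <- abs(mean(s) - windows[w]) <= 3 * sqrt(1 / springK) + 1
    out[[w]] <- list(center = windows[w], k = springK, samples = s,
                     tau = tau, reachable = reachable)
  }
  bad <- !vapply(out, `[[`, logical(1), "reachable")
  if (any(bad)) {
    warning(sum(bad), " unreachable window(s) at centres ",
            paste(format(windows[bad]), collapse = ", "), " excluded")
    out <- out[!bad]
  }
  structure(list(windows = out, cv = cv,
                 meta = list(springK = springK, seed = seed,
                             sweepsPerWindow = sweepsPerWindow)),
            class = "umbrellaRun")
}

#' Weighted histogram analysis (WHAM)
#'
#' Self-consistent solution of the WHAM equations for one-dimensional
#' umbrella sampling with harmonic biases: iterates the unbiased density and
#' window free energies until the largest change in the window free energies
#' falls below `tol`, then returns the potential of mean force
#' \eqn{-k_BT\ln P} shifted to zero at its minimum.
#'
#' @param run an `umbrellaRun` from [runUmbrella()], or a list of windows,
#'   each `list(center =, k =, samples =)`.
#' @param kT thermal energy (reduced, default 1).
#' @param binWidth histogram bin width (sigma).
#' @param tol convergence tolerance on the window free energies (kT).
#' @param maxIter iteration cap.
#' @return a [PMFProfile-class]; convergence details in `@meta`.
#' @export
wham <- function(run, kT = 1, binWidth = 0.25, tol = 1e-7, maxIter = 50000) {
  wins <- if (inherits(run, "umbrellaRun")) run$windows else run
  cvLab <- if (inherits(run, "umbrellaRun")) run$cv else "cv"
  if (!length(wins)) stop("no umbrella windows supplied")
  wins <- Filter(function(w) length(w$samples) > 0, wins)

  all <- unlist(lapply(wins, `[[`, "samples"))
  lo <- min(all) - binWidth / 2
  breaks <- seq(lo, max(all) + binWidth, by = binWidth)
  mids <- breaks[-1] - binWidth / 2
  nb <- length(mids)
  W <- length(wins)

  counts <- vapply(wins, function(w)
    graphics::hist(w$samples, breaks = breaks, plot = FALSE)$counts,
    numeric(nb))
  counts <- matrix(counts, nrow = nb)
  Ni <- colSums(counts)
  Htot <- rowSums(counts)

  # disjoint windows leave an interior stretch of empty bins; relative
  # window free energies are then undetermined
  occ <- rle(Htot > 0)
  interior <- occ$lengths[!occ$values &
                            seq_along(occ$values) != 1 &
                            seq_along(occ$values) != length(occ$values)]
  if (any(interior >= 3))
    stop("WHAM failed: histogram gap of ", max(interior),
         " bins along the reaction coordinate (disjoint windows around ",
         format(mids[which(Htot == 0)[1]]), ")")

  # bias energy of window i evaluated at each bin centre
  U <- vapply(wins, function(w) 0.5 * w$k * (mids - w$center)^2, numeric(nb))
  U <- matrix(U, nrow = nb)
  expU <- exp(-U / kT)

  f <- rep(0, W)       # window free energies
  iter <- 0
  repeat {
    iter <- iter + 1
    denom <- as.numeric(expU %*% (Ni * exp(f / kT)))
    P <- Htot / pmax(denom, .Machine$double.xmin)
    fNew <- -kT * log(pmax(colSums(P * expU), .Machine$double.xmin))
    fNew <- fNew - fNew[1]
    delta <- max(abs(fNew - f))
    f <- fNew
    if (delta < tol || iter >= maxIter) break
  }
  if (delta >= tol)
    warning("WHAM stopped at maxIter with residual ", format(delta))

  keep <- Htot > 0
  pmf <- -kT * log(P[keep] / max(P[keep]))
  pmf <- pmf - min(pmf)
  # per-bin uncertainty from Poisson counting in the raw histogram
  se <- kT / sqrt(pmax(Htot[keep], 1))
  new("PMFProfile", grid = mids[keep], pmf = pmf, stderr = se, cv = cvLab,
      meta = list(iterations = iter, residual = delta, nWindows = W,
                  binWidth = binWidth))
}

#' Flat-region metric of a PMF profile
#'
#' The flat region is the set of grid points whose PMF lies at or below
#' `threshold` above the minimum.  Returns the average of the normalized
#' coordinate over that region (a measure of in-plane reach when applied to
#' a rho_xy profile normalized by the tether--paratope distance `reach`) and
#' the extent of the region.
#'
#' @param pmf a [PMFProfile-class].
#' @param threshold flatness threshold in kT (default 1).
#' @param reach normalizing length `L` (default: max of the grid).
#' @return list: `meanNorm` (mean of cv/L over the flat region), `extent`
#'   (width of the flat region), `region` (range), `empty`.
#' @export
pmfFlatMetric <- function(pmf, threshold = 1, reach = max(pmf@grid)) {
  sel <- pmf@pmf <= threshold
  if (!any(sel))
    return(list(meanNorm = NA_real_, extent = 0, region = c(NA, NA),
                empty = TRUE))
  g <- pmf@grid[sel]
  bw <- if (length(pmf@grid) > 1) stats::median(diff(pmf@grid)) else 0
  list(meanNorm = mean(g) / reach, extent = diff(range(g)) + bw,
       region = range(g), empty = FALSE)
}

#' Numerical derivative of a PMF profile
#'
#' Central finite differences on the interior grid, one-sided at the ends.
#'
#' @param pmf a [PMFProfile-class] (>= 3 grid points).
#' @return data.frame with `cv` and `dpmf` (kT/sigma).
#' @export
pmfGradient <- function(pmf) {
  g <- pmf@grid; v <- pmf@pmf
  n <- length(g)
  if (n < 3) stop("need at least 3 grid points")
  d <- numeric(n)
  d[1] <- (v[2] - v[1]) / (g[2] - g[1])
  d[n] <- (v[n] - v[n - 1]) / (g[n] - g[n - 1])
  mid <- 2:(n - 1)
  d[mid] <- (v[mid + 1] - v[mid - 1]) / (g[mid + 1] - g[mid - 1])
  data.frame(cv = g, dpmf = d)
}
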