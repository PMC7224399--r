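## Analytic tethered-Gaussian-polymer references, run-length laws for the
## rare-event tails, persistence-length estimation and effective-polymer
## fitting.

#' Height distribution of the free end of a tethered Gaussian polymer
#'
#' For a chain of `Nk` Kuhn segments of length `b` tethered at height `zt`
#' above a reflecting wall, the normalized free-end height density follows
#' from the image construction,
#' \deqn{P(z) = \sqrt{\frac{3}{2\pi N_k b^2}}
#'   \frac{1}{\mathrm{erf}(z_t\sqrt{3/2N_kb^2})}
#'   \left[e^{-3(z-z_t)^2/2N_kb^2} - e^{-3(z+z_t)^2/2N_kb^2}\right],}
#' which in the limit \eqn{z_t \to 0} reduces to
#' \eqn{P(z) = (3z/\langle d^2\rangle) e^{-3z^2/2\langle d^2\rangle}} with
#' \eqn{\langle d^2\rangle = N_k b^2}.
#'
#' @param z heights (sigma), `z >= 0`.
#' @param model a [GaussianChainModel-class].
#' @return density values.
#' @export
tetheredEndPdf <- function(z, model) {
  if (any(z < 0)) stop("z must be >= 0")
  d2 <- meanSquareEndToEnd(model)
  zt <- model@zt
  a <- 3 / (2 * d2)
  if (zt == 0) return(3 * z / d2 * exp(-a * z^2))
  erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
  pref <- sqrt(a / pi) / erf(zt * sqrt(a))
  pref * (exp(-a * (z - zt)^2) - exp(-a * (z + zt)^2))
}

#' Probability of the free end above/below a threshold
#'
#' For the zero-tether Gaussian model,
#' \eqn{P_> = \exp(-3z_0^2/2\langle d^2\rangle)} and \eqn{P_< = 1 - P_>};
#' alternatively integrates a supplied empirical height histogram.
#'
#' @param z0 threshold height (sigma), `z0 >= 0`.
#' @param model a [GaussianChainModel-class] (analytic branch), or `NULL`.
#' @param histogram data.frame with columns `z` and `density` (empirical
#'   branch; renormalized if needed).
#' @param dtc optional frame correlation time stored with the result.
#' @return list with `pAbove`, `pBelow`, `z0`, `dtc`.
#' @export
thresholdProbabilities <- function(z0, model = NULL, histogram = NULL,
                                   dtc = NA_real_) {
  if (z0 < 0) stop("z0 must be >= 0")
  if (!is.null(model)) {
    if (model@zt != 0) {
      # integrate the reflected-Gaussian density directly
      pA <- stats::integrate(function(z) tetheredEndPdf(z, model), z0, Inf,
                             rel.tol = 1e-10)$value
    } else {
      pA <- exp(-3 * z0^2 / (2 * meanSquareEndToEnd(model)))
    }
  } else if (!is.null(histogram)) {
    dz <- diff(histogram$z)
    dz <- c(dz, dz[length(dz)])
    tot <- sum(histogram$density * dz)
    pA <- sum(histogram$density[histogram$z >= z0] *
                dz[histogram$z >= z0]) / tot
  } else stop("supply a model or a histogram")
  list(pAbove = pA, pBelow = 1 - pA, z0 = z0, dtc = dtc)
}

#' Run-length distribution of frames above/below the threshold
#'
#' For uncorrelated frames with occupation probabilities \eqn{P_>} and
#' \eqn{P_<}, the probability of observing `k` consecutive frames above (a)
#' or below (b) the threshold is
#' \deqn{P_a(k) = P_> (1 - P_<)^{k-1} P_<, \qquad
#'       P_b(k) = P_< (1 - P_>)^{k-1} P_>.}
#' With `approximate = TRUE` the small-probability exponential forms
#' \eqn{P_< e^{-P_< k}} and \eqn{P_> e^{-P_> k}} are returned instead.
#'
#' @param pAbove,pBelow occupation probabilities (sum to 1).
#' @param k run lengths (integers >= 1).
#' @param approximate use the exponential approximation.
#' @return data.frame with `k`, `Pa`, `Pb`.
#' @export
runLengthDistribution <- function(pAbove, pBelow, k, approximate = FALSE) {
  if (any(k < 1)) stop("k must be >= 1")
  if (abs(pAbove + pBelow - 1) > 1e-9) stop("pAbove + pBelow must be 1")
  if (approximate) {
    data.frame(k = k, Pa = pBelow * exp(-pBelow * k),
               Pb = pAbove * exp(-pAbove * k))
  } else {
    data.frame(k = k,
               Pa = pAbove * (1 - pBelow)^(k - 1) * pBelow,
               Pb = pBelow * (1 - pAbove)^(k - 1) * pAbove)
  }
}

#' Exponential-tail time constants of the survival probabilities
#'
#' From the run-length laws, the decay constants of the exponential tails of
#' the flight and residence survival probabilities are
#' \eqn{\tau_f = \Delta t_c / P_<} and \eqn{\tau_r = \Delta t_c / P_>}, with
#' the expansions \eqn{\tau_f \simeq \Delta t_c\, 2\langle d^2\rangle/3z_0^2}
#' and \eqn{\tau_r \simeq \Delta t_c (1 + 3z_0^2/2\langle d^2\rangle)} valid
#' when \eqn{z_0^2/\langle d^2\rangle \ll 1}.
#'
#' @param z0 threshold height (sigma).
#' @param d2 mean-square end-to-end distance \eqn{\langle d^2\rangle}
#'   (sigma^2).
#' @param dtc frame correlation time \eqn{\Delta t_c}.
#' @return list with `tauF`, `tauR` (exact), `tauFApprox`, `tauRApprox`,
#'   `expansionValid`.
#' @export
tailConstantsTheory <- function(z0, d2, dtc) {
  stopifnot(z0 > 0, d2 > 0, dtc > 0)
  x <- 3 * z0^2 / (2 * d2)
  pA <- exp(-x)
  list(tauF = dtc / (1 - pA), tauR = dtc / pA,
       tauFApprox = dtc / x, tauRApprox = dtc * (1 + x),
       expansionValid = x < 0.2)
}

# bond unit-vector correlation over contour separation, averaged over
# conformations; conformations: list of n x 3 matrices or an n x 3 x m array
.bondCorrelation <- function(conformations, sMax) {
  if (is.array(conformations) && length(dim(conformations)) == 3) {
    conformations <- lapply(seq_len(dim(conformations)[3]), function(f) {
      m <- conformations[, , f]
      dim(m) <- dim(conformations)[1:2]
      m
    })
  }
  num <- numeric(sMax); den <- numeric(sMax)
  b0sum <- 0; b0n <- 0
  for (x in conformations) {
    u <- diff(x)
    len <- sqrt(rowSums(u^2))
    b0sum <- b0sum + sum(len); b0n <- b0n + length(len)
    u <- u / len
    nb <- nrow(u)
    for (s in seq_len(min(sMax, nb - 1))) {
      num[s] <- num[s] + sum(u[seq_len(nb - s), , drop = FALSE] *
                               u[seq_len(nb - s) + s, , drop = FALSE])
      den[s] <- den[s] + (nb - s)
    }
  }
  list(s = seq_len(sMax), C = num / pmax(den, 1), b0 = b0sum / b0n,
       n = den)
}

#' Persistence length from chain conformations
#'
#' Estimates the persistence length of a bead-spring chain from the decay of
#' the bond-direction correlation
#' \eqn{\langle u_i \cdot u_{i+s}\rangle = e^{-s b_0/\ell_p}} (log-linear
#' weighted fit through the origin).  The persistence length is a local
#' property: for a chain with excluded volume the correlation is exponential
#' only at short contour separations and crosses over to a slower,
#' swelling-dominated decay, so the fit uses only separations with
#' \eqn{C(s) \ge e^{-1}} (at least two, at most `sMax`).  The Kuhn length is
#' \eqn{b = 2\ell_p}.
#'
#' @param conformations list of `n x 3` coordinate matrices (decorrelated
#'   equilibrium snapshots), or an `n x 3 x frames` array, or a
#'   [Trajectory-class].
#' @param sMax largest contour separation considered (bonds).
#' @param cMin correlation level below which points are excluded from the
#'   fit (crossover to the non-exponential regime).
#' @return list with `lp` (sigma), `kuhnLength`, `correlation` (data.frame
#'   `s`, `C`), `b0`, `rigidRod` (TRUE when the correlation does not decay
#'   inside the fit range, in which case `lp` is a lower bound).
#' @export
persistenceLength <- function(conformations, sMax = 15, cMin = exp(-1)) {
  if (is(conformations, "Trajectory")) conformations <- conformations@coords
  bc <- .bondCorrelation(conformations, sMax)
  keep <- bc$C > 0
  if (sum(keep) < 2) stop("bond correlation non-positive; chain too flexible")
  inFit <- keep & bc$C >= cMin
  if (sum(inFit) < 2) inFit <- keep & seq_along(keep) <= 2
  s <- bc$s[inFit]; C <- bc$C[inFit]
  # delta-method weights for log-transformed correlations
  wts <- bc$n[inFit] * C^2
  fit <- stats::lm(log(C) ~ 0 + s, weights = wts)
  slope <- stats::coef(fit)[["s"]]
  rigidRod <- slope >= -1e-4
  if (rigidRod) {
    warning("bond correlation does not decay within the fit range; ",
            "returning the fit range as a lower bound")
    lp <- sMax * bc$b0
  } else lp <- -bc$b0 / slope
  list(lp = lp, kuhnLength = 2 * lp,
       correlation = data.frame(s = bc$s, C = bc$C), b0 = bc$b0,
       rigidRod = rigidRod)
}

#' Fit the effective Kuhn-segment number to a height histogram
#'
#' Least-squares fit of the reflected-Gaussian tethered-end density (see
#' [tetheredEndPdf()]) to an empirical height histogram of the free paratope,
#' with the Kuhn length `b` and tether height `zt` fixed and the Kuhn-segment
#' number free.  The naive geometric guess \eqn{(N + 2r)/b} (linker contour
#' plus the free nanobody's span) is reported for comparison.
#'
#' @param histogram data.frame with columns `z` and `density` (normalized;
#'   renormalized with a warning otherwise).
#' @param b Kuhn length (sigma).
#' @param zt tether height (sigma); `zt = 0` selects the simple tethered-end
#'   law.
#' @param N linker length used for the naive guess (optional).
#' @param r half the paratope--connector span of a nanobody unit for the
#'   naive guess (default 5.65 sigma for the SPH geometry).
#' @return list with `NkEff`, `residual` (sum of squares), `naiveGuess`,
#'   `fit` (data.frame with the fitted curve).
#' @export
fitEffectiveNk <- function(histogram, b = 3, zt = 7.5, N = NULL, r = 5.65) {
  stopifnot(b > 0, zt >= 0)
  z <- histogram$z
  dens <- histogram$density
  dz <- stats::median(diff(z))
  tot <- sum(dens * dz)
  if (abs(tot - 1) > 0.01) {
    warning("histogram not normalized (integral ", format(tot),
            "); renormalizing")
    dens <- dens / tot
  }
  obj <- function(logNk) {
    m <- gaussianChainModel(exp(logNk), b, zt)
    sum((tetheredEndPdf(pmax(z, 0), m) - dens)^2)
  }
  opt <- stats::optimize(obj, interval = log(c(0.1, 1e5)), tol = 1e-10)
  Nk <- exp(opt$minimum)
  model <- gaussianChainModel(Nk, b, zt)
  list(NkEff = Nk, residual = opt$objective,
       naiveGuess = if (!is.null(N)) (N + 2 * r) / b else NA_real_,
       fit = data.frame(z = z, density = tetheredEndPdf(pmax(z, 0), model)),
       model = model)
}
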