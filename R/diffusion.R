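#' Soumpasis recovery curve for a uniformly bleached circular spot
#'
#' Closed-form fluorescence recovery by pure lateral diffusion into a
#' uniformly bleached circular region:
#' \deqn{F(t) = C_{mob}\, e^{-2\tau_D/t}\,[I_0(2\tau_D/t) + I_1(2\tau_D/t)]}
#' where \eqn{I_0, I_1} are modified Bessel functions of the first kind and
#' \eqn{\tau_D = w^2/(4D)} for spot radius \eqn{w}. Evaluation uses
#' exponentially scaled Bessel functions (\code{besselI(..., expon.scaled =
#' TRUE)}) so the product neither overflows nor loses the cancellation for
#' small \code{t} (large argument). \code{F(0)} is defined by its limit, 0.
#'
#' @param t time since bleach end, seconds (non-negative)
#' @param Cmob mobile fraction, in [0, 1]
#' @param tauD characteristic diffusion time, seconds (> 0)
#' @return numeric vector; monotone nondecreasing in t with limit \code{Cmob}
#' @examples
#' soumpasisCurve(c(0.5, 1.75, 20), Cmob = 0.76, tauD = 1.75)
#' @export
soumpasisCurve <- function(t, Cmob, tauD) {
  .assertScalar(Cmob, "Cmob", 0, 1)
  .assertScalar(tauD, "tauD", 0, Inf, openLower = TRUE)
  if (any(t < 0)) mfStop("t must be non-negative", "validation")
  out <- numeric(length(t))
  pos <- t > 0
  x <- 2 * tauD / t[pos]
  out[pos] <- Cmob * (besselI(x, 0, expon.scaled = TRUE) +
                      besselI(x, 1, expon.scaled = TRUE))
  out
}

#' Convert a diffusion time to a diffusion coefficient
#'
#' \eqn{D = w^2 / (4 \tau_D)} for a circular bleach spot of radius \eqn{w}.
#'
#' @param tauD characteristic diffusion time (s)
#' @param w bleach-spot radius (um); note: radius, not diameter
#' @return diffusion coefficient in um^2/s
#' @examples
#' tauToD(1.75, w = 1.03)
#' @export
tauToD <- function(tauD, w) {
  .assertScalar(tauD, "tauD", 0, Inf, openLower = TRUE)
  .assertScalar(w, "w", 0, Inf, openLower = TRUE)
  w^2 / (4 * tauD)
}

#' Effective (population-average) diffusivity
#'
#' \eqn{D^* = C_{mob} D}: the average diffusivity accounting for both mobile
#' and immobile molecules.
#'
#' @param Cmob mobile fraction, in [0, 1]
#' @param D mobile-fraction diffusion coefficient (um^2/s)
#' @return effective diffusivity in um^2/s
#' @export
effectiveDiffusivity <- function(Cmob, D) {
  .assertScalar(Cmob, "Cmob", 0, 1)
  .assertScalar(D, "D", 0, Inf)
  Cmob * D
}

#' Fit the Soumpasis diffusion model to a spot-FRAP trace
#'
#' Bounded nonlinear least squares of \code{\link{soumpasisCurve}} over the
#' post-bleach frames of a normalized trace, excluding the t = 0 frame
#' (whose model value is a limit). Free parameters: mobile fraction
#' \code{Cmob} and diffusion time \code{tauD}; derived:
#' \code{D = w^2/(4 tauD)} and \code{Dstar = Cmob * D}. Initialization is
#' deterministic: \code{Cmob} from the last-decile mean and \code{tauD} from
#' the time at which the trace reaches 0.524 of that plateau (the model's
#' value at \code{t = tauD}). A fitted \code{tauD} below two frame intervals
#' is flagged as undersampled.
#'
#' @param trace a \code{\linkS4class{NormalizedTrace}}
#' @param w bleach-spot radius in um
#' @param nBoot residual-bootstrap replicates (default 1000; 0 disables)
#' @param bootSeed RNG seed for the bootstrap
#' @return a \code{\linkS4class{SoumpasisFit}}
#' @export
fitSoumpasis <- function(trace, w, nBoot = 1000L, bootSeed = 1L) {
  stopifnot(is(trace, "NormalizedTrace"))
  .assertScalar(w, "w", 0, Inf, openLower = TRUE)
  sel <- trace@t > 0
  t <- trace@t[sel]
  f <- trace@f[sel]
  if (length(t) < 4L)
    mfStop("too few post-bleach frames for a 2-parameter fit", "validation")
  dt <- stats::median(diff(t))

  plateau <- mean(utils::tail(f, max(3L, length(f) %/% 10L)))
  cmobInit <- min(max(plateau, 0.05), 1)
  iTau <- which(f >= 0.524 * plateau)[1]
  tauInit <- if (!is.na(iTau) && t[iTau] > 0) t[iTau] else 5 * dt

  model <- function(p, tt) {
    x <- 2 * p[2] / tt
    p[1] * (besselI(x, 0, expon.scaled = TRUE) +
            besselI(x, 1, expon.scaled = TRUE))
  }
  lower <- c(1e-4, 1e-6)
  upper <- c(1, max(t) * 100)
  fitOnce <- function(y, start) {
    res <- minpack.lm::nls.lm(
      par = start, lower = lower, upper = upper,
      fn = function(p) y - model(p, t),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    if (!res$info %in% 1:4)
      mfStop(sprintf("Soumpasis fit did not converge: %s", res$message),
             "computation")
    res
  }
  res <- fitOnce(f, c(cmobInit, tauInit))
  p <- res$par
  fitted <- model(p, t)
  rss <- sum((f - fitted)^2)
  se <- tryCatch({
    s <- summary(res)$coefficients[, "Std. Error"]
    stats::setNames(as.numeric(s), c("Cmob", "tauD"))
  }, error = function(e)
    stats::setNames(rep(NA_real_, 2), c("Cmob", "tauD")))

  flags <- character(0)
  if (p[2] < 2 * dt) flags <- c(flags, "undersampled_tauD")

  parNames <- c("Cmob", "tauD")
  boot <- matrix(numeric(0), 0, 2, dimnames = list(NULL, parNames))
  ci <- matrix(NA_real_, 2, 2, dimnames = list(parNames, c("2.5%", "97.5%")))
  if (nBoot > 0L) {
    r0 <- f - fitted
    boot <- .withSeed(bootSeed, {
      t(vapply(seq_len(nBoot), function(b) {
        yb <- fitted + sample(r0, length(r0), replace = TRUE)
        tryCatch(fitOnce(yb, p)$par, error = function(e) rep(NA_real_, 2))
      }, numeric(2)))
    })
    colnames(boot) <- parNames
    ci <- t(apply(boot, 2, stats::quantile, probs = c(0.025, 0.975),
                  na.rm = TRUE, names = FALSE))
    dimnames(ci) <- list(parNames, c("2.5%", "97.5%"))
  }

  D <- w^2 / (4 * p[2])
  est <- c(Cmob = p[1], tauD = p[2], w = w, D = D, Dstar = p[1] * D)
  new("SoumpasisFit",
      estimates = est, se = se, rss = rss, nPoints = length(t),
      ci95 = ci, boot = boot, flags = flags,
      t = t, f = f, fitted = fitted)
}

#' Compare effective diffusivity between two conditions
#'
#' Effect report for two Soumpasis fits (e.g. control vs. agonist
#' application): differences in mobile fraction and effective diffusivity,
#' the percent change \eqn{100 (D^*_b - D^*_a)/D^*_a}, and a percentile
#' bootstrap interval of the \eqn{D^*} difference obtained by pairing the
#' fits' bootstrap replicates (available when both fits were bootstrapped
#' with the same number of replicates).
#'
#' @param fitA,fitB \code{\linkS4class{SoumpasisFit}} objects (A = reference)
#' @return object of class \code{frapComparison}: a list with elements
#'   \code{dCmob}, \code{dDstar}, \code{percentChange}, \code{ciDiff}
#' @export
compareConditions <- function(fitA, fitB) {
  stopifnot(is(fitA, "SoumpasisFit"), is(fitB, "SoumpasisFit"))
  ea <- fitA@estimates; eb <- fitB@estimates
  if (ea[["Dstar"]] == 0)
    mfStop("reference effective diffusivity is zero", "computation")
  ciDiff <- c(NA_real_, NA_real_)
  if (nrow(fitA@boot) > 0 && nrow(fitA@boot) == nrow(fitB@boot)) {
    dsA <- ea[["w"]]^2 / (4 * fitA@boot[, "tauD"]) * fitA@boot[, "Cmob"]
    dsB <- eb[["w"]]^2 / (4 * fitB@boot[, "tauD"]) * fitB@boot[, "Cmob"]
    ciDiff <- as.numeric(stats::quantile(dsB - dsA, c(0.025, 0.975),
                                         na.rm = TRUE))
  }
  structure(list(
    dCmob = eb[["Cmob"]] - ea[["Cmob"]],
    dDstar = eb[["Dstar"]] - ea[["Dstar"]],
    percentChange = 100 * (eb[["Dstar"]] - ea[["Dstar"]]) / ea[["Dstar"]],
    ciDiff = ciDiff,
    DstarA = ea[["Dstar"]], DstarB = eb[["Dstar"]]),
    class = "frapComparison")
}

#' @export
print.frapComparison <- function(x, ...) {
  cat("Condition comparison (Soumpasis fits)\n")
  cat(sprintf("  D* %.4g -> %.4g um^2/s (%+.1f%%)\n",
              x$DstarA, x$DstarB, x$percentChange))
  cat(sprintf("  dCmob = %+.4g; bootstrap 95%% CI of dD*: [%.4g, %.4g]\n",
              x$dCmob, x$ciDiff[1], x$ciDiff[2]))
  invisible(x)
}
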