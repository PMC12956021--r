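## Decay of acquired resistance during stress-free attached growth.
## Minimal model consistent with a state memory of M generations:
## geometric per-generation loss, f(g) = f0 (1 - kOff)^g without
## re-induction; with re-induction the fraction relaxes geometrically to
## the equilibrium kOn / (kOn + kOff).

#' Resistant fraction along a reversion time course
#'
#' @param f0 initial resistant fraction.
#' @param kOff per-generation R-to-S switching probability.
#' @param g generations of stress-free attached growth (vectorised).
#' @param kOn per-generation S-to-R re-induction probability (default 0:
#'   pure decay).
#' @return Resistant fraction(s) after `g` generations.
#' @examples
#' reversionTrajectory(1, 0.5, 0:3)          # 1, 0.5, 0.25, 0.125
#' reversionTrajectory(0.76, 1/10.5, 10)     # ~0.279
#' @export
reversionTrajectory <- function(f0, kOff, g, kOn = 0) {
  stopifnot(f0 >= 0, kOff >= 0, kOff <= 1, kOn >= 0, kOn <= 1, all(g >= 0))
  if (kOn == 0) return(f0 * (1 - kOff)^g)
  fEq <- kOn / (kOn + kOff)
  fEq + (f0 - fEq) * (1 - kOn - kOff)^g
}

#' Generations until predicted survival falls to a threshold
#'
#' Smallest integer number of stress-free generations after which the
#' predicted suspension survival `f(g) * exp(gamma * T)` is at or below
#' `threshold` (e.g. the parental population's survival). `Inf` with a
#' warning when the trajectory never reaches it (e.g. re-induction holds
#' the fraction at equilibrium above the threshold, or `kOff = 0`).
#'
#' @inheritParams reversionTrajectory
#' @param threshold survival threshold to reach (on the survival scale).
#' @param T assay duration in hours.
#' @param Td resistant-state suspension doubling time in hours (`Inf` for
#'   no assay-phase growth, in which case the threshold is on the
#'   resistant-fraction scale directly).
#' @param maxG search horizon in generations (default 10000).
#' @return Integer number of generations, or `Inf`.
#' @examples
#' generationsToThreshold(1, 0.5, threshold = 0.25, Td = Inf)  # 2
#' @export
generationsToThreshold <- function(f0, kOff, threshold, kOn = 0, T = 24,
                                   Td = Inf, maxG = 10000) {
  gamma <- growthRateFromDoubling(Td)
  boost <- exp(gamma * T)
  if (f0 * boost <= threshold) return(0L)
  limit <- if (kOn + kOff == 0) f0 else kOn / (kOn + kOff)
  if (limit * boost > threshold || kOff == 0) {
    warning("threshold unreachable: trajectory limit exceeds it",
            call. = FALSE)
    return(Inf)
  }
  g <- seq_len(maxG)
  surv <- reversionTrajectory(f0, kOff, g, kOn) * boost
  hit <- which(surv <= threshold)
  if (!length(hit)) {
    warning("threshold not reached within maxG generations", call. = FALSE)
    return(Inf)
  }
  as.integer(hit[1])
}

#' Fit the geometric memory-decay model to a reversion curve
#'
#' Linear least squares of `log(fraction)` on generation recovers the
#' decay law `f(g) = f0 (1 - kOff)^g` exactly on noiseless curves.
#' Non-positive fractions are masked with a warning; a two-point curve is
#' interpolated exactly but flagged as underdetermined.
#'
#' @param curve a [ReversionCurve-class], or a data frame / list with
#'   elements `generation` and `fraction`.
#' @return A list with `kOff`, `f0`, `memory` (= 1/kOff, generations),
#'   and `diagnostics` (n_used, n_masked, r_squared, residual_sd,
#'   underdetermined).
#' @examples
#' cur <- ReversionCurve(0:10, 0.8 * 0.9^(0:10))
#' fitMemory(cur)$kOff  # 0.1
#' @export
fitMemory <- function(curve) {
  if (is(curve, "ReversionCurve")) {
    g <- curve@generation; f <- curve@fraction
  } else {
    g <- curve$generation; f <- curve$fraction
  }
  ok <- is.finite(f) & f > 0
  if (sum(!ok))
    warning(sprintf("masking %d non-positive/missing point(s)", sum(!ok)),
            call. = FALSE)
  g <- g[ok]; f <- f[ok]
  if (length(g) < 2)
    stop("need at least 2 positive points to fit", call. = FALSE)
  fit <- stats::lm(log(f) ~ g)
  co <- stats::coef(fit)
  kOff <- 1 - exp(co[["g"]])
  res <- stats::residuals(fit)
  n <- length(g)
  list(
    kOff = kOff,
    f0 = exp(co[["(Intercept)"]]),
    memory = if (kOff > 0) 1 / kOff else Inf,
    diagnostics = list(
      n_used = n, n_masked = sum(!ok),
      r_squared = if (n > 2) suppressWarnings(summary(fit)$r.squared) else 1,
      residual_sd = if (n > 2) stats::sd(res) else 0,
      underdetermined = n <= 2)
  )
}
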