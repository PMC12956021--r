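## Closed-form relations of the two-state model. The suspension survival
## balance is f * exp(gamma * T) = S_mean, with gamma = ln 2 / T_d the
## growth rate of resistant cells in suspension: after T hours only
## resistant cells remain and they have multiplied by exp(gamma * T), so
## the measured live fraction equals the resistant fraction at plating
## times that factor.

#' Exponential growth rate from a doubling time
#'
#' @param Td doubling time in hours (> 0; `Inf` allowed and gives rate 0).
#' @return Growth rate `log(2) / Td` per hour. Vectorised.
#' @examples
#' growthRateFromDoubling(100)   # 0.00693 per hour
#' growthRateFromDoubling(Inf)   # 0
#' @export
growthRateFromDoubling <- function(Td) {
  if (any(is.na(Td)) || any(Td <= 0))
    stop("Td must be positive (hours); Inf is allowed", call. = FALSE)
  ifelse(is.infinite(Td), 0, log(2) / Td)
}

#' Resistant fraction from mean suspension survival
#'
#' Inverts the survival balance `f * exp(gamma * T) = S`: the fraction of
#' cells in the resistant state at plating that, growing with doubling
#' time `Td` while all sensitive cells die, reproduces mean survival `S`
#' after `T` hours in suspension.
#'
#' @param S mean survival fraction (> 0; may exceed 1 for net growth).
#' @param T assay duration in hours (> 0).
#' @param Td resistant-state suspension doubling time in hours (`Inf`
#'   allowed).
#' @param strict if `TRUE` (default) an infeasible result (f > 1, i.e.
#'   survival higher than pure resistant growth allows) is an error;
#'   if `FALSE` the value is returned with a warning, never clamped.
#' @return The resistant fraction `f = S * 2^(-T / Td)`.
#' @examples
#' resistantFractionFromSurvival(0.9, 24, 100)  # ~0.76
#' resistantFractionFromSurvival(0.9, 24, Inf)  # 0.9
#' @export
resistantFractionFromSurvival <- function(S, T = 24, Td = 100,
                                          strict = TRUE) {
  if (any(S <= 0)) stop("S must be > 0", call. = FALSE)
  if (any(T <= 0)) stop("T must be > 0 (hours)", call. = FALSE)
  gamma <- growthRateFromDoubling(Td)
  f <- S * exp(-gamma * T)
  if (any(f > 1)) {
    msg <- sprintf(
      "infeasible: implied resistant fraction %.4g > 1 (survival %.4g exceeds pure resistant growth e^(gamma T) = %.4g)",
      max(f), S[which.max(f)], exp(gamma * T)[which.max(f)])
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  f
}

#' Switching rates from state memory and equilibrium fraction
#'
#' Maps the mean resistant-state residence time `M` (generations; the
#' "transient heritability" of the resistant state) and the stationary
#' resistant fraction `fEq` to per-division switching probabilities:
#' `kOff = 1 / M` (geometric residence) and
#' `kOn = fEq / (1 - fEq) * kOff`.
#'
#' @param M memory in generations (> 0).
#' @param fEq equilibrium resistant fraction in \[0, 1).
#' @return Named numeric vector `c(kOn = ..., kOff = ...)`.
#' @examples
#' ratesFromMemoryEquilibrium(10.5, 0.76)
#' @seealso [memoryEquilibriumFromRates()] for the inverse map.
#' @export
ratesFromMemoryEquilibrium <- function(M, fEq) {
  if (any(M <= 0)) stop("M must be > 0 generations", call. = FALSE)
  if (any(fEq < 0) || any(fEq >= 1))
    stop("fEq must lie in [0, 1): fEq = 1 leaves no sensitive reservoir",
         call. = FALSE)
  kOff <- 1 / M
  kOn <- fEq / (1 - fEq) * kOff
  if (any(kOn > 1))
    stop(sprintf(
      "infeasible: implied kOn = %.4g > 1; increase M or decrease fEq",
      max(kOn)), call. = FALSE)
  c(kOn = kOn, kOff = kOff)
}

#' Memory and equilibrium fraction from switching rates
#'
#' Inverse of [ratesFromMemoryEquilibrium()].
#'
#' @param kOn,kOff per-division switching probabilities.
#' @return Named numeric vector `c(M = ..., fEq = ...)`.
#' @export
memoryEquilibriumFromRates <- function(kOn, kOff) {
  if (any(kOn < 0) || any(kOff <= 0))
    stop("need kOn >= 0 and kOff > 0", call. = FALSE)
  c(M = 1 / kOff, fEq = kOn / (kOn + kOff))
}

#' Effective growth rate in suspension
#'
#' `log(Nt / N0) / T` per hour over the assay window; negative values mean
#' net death. A clone with no survivors gets `-Inf` so that the all-dead
#' class stays distinguishable (see [growthRateSummary()] for how moments
#' handle it).
#'
#' @param N0 cells at plating (> 0).
#' @param Nt live cells at assay end (>= 0).
#' @param T assay duration in hours (> 0), default 24.
#' @return Growth rate per hour; `-Inf` where `Nt == 0`. Vectorised.
#' @examples
#' effectiveGrowthRate(250000, 225000)       # ln(0.9)/24 ~ -0.0044
#' effectiveGrowthRate(1000, 2000, T = 45)   # ln(2)/45, a 45-h doubler
#' @export
effectiveGrowthRate <- function(N0, Nt, T = 24) {
  if (any(N0 <= 0)) stop("N0 must be > 0", call. = FALSE)
  if (any(Nt < 0)) stop("Nt must be >= 0", call. = FALSE)
  if (any(T <= 0)) stop("T must be > 0 (hours)", call. = FALSE)
  ifelse(Nt == 0, -Inf, log(Nt / N0) / T)
}

#' Classify survival as anoikis sensitive or resistant
#'
#' Populations with below-threshold 24-h suspension viability are anoikis
#' sensitive (AnS); those at or above it (>= 100% by default, i.e. net
#' survival/growth) are anoikis resistant (AnR).
#'
#' @param survival survival fraction(s), >= 0 (1 = 100%).
#' @param threshold classification threshold, default 1.
#' @return Factor with levels `"sensitive"`, `"resistant"`. Vectorised.
#' @examples
#' classifyAnoikis(c(0.361, 1.252, 1))
#' @export
classifyAnoikis <- function(survival, threshold = 1) {
  if (any(survival < 0)) stop("survival must be >= 0", call. = FALSE)
  factor(ifelse(survival >= threshold, "resistant", "sensitive"),
         levels = c("sensitive", "resistant"))
}

## Lineage-state recursion: probability that a generation-(g+1) cell is
## resistant given m_g at generation g. Used by the simulator and by the
## reversion model (same Markov chain viewed per lineage).
.stateRecursion <- function(m, kOn, kOff) m * (1 - kOff) + (1 - m) * kOn

#' Expected resistant fraction after g generations
#'
#' Iterates the per-lineage state recursion
#' `m_{g+1} = m_g (1 - kOff) + (1 - m_g) kOn` from a founder probability.
#'
#' @param model a [SwitchingModel-class].
#' @param g number of generations (vectorised over `0:max(g)` internally).
#' @param m0 founder resistant probability (1 for a resistant founder).
#' @return Expected resistant fraction(s) after `g` generations.
#' @export
expectedResistantFraction <- function(model, g, m0) {
  fEq <- equilibriumFraction(model)
  lambda <- 1 - model@kOn - model@kOff
  if (is.na(fEq)) return(rep(m0, length(g)))  # no switching at all
  fEq + (m0 - fEq) * lambda^g
}
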