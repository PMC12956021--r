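## Synthetic clone-survival data. Two generators:
##  * the two-state switching model (wraps the simulator) — produces the
##    near-zero interclonal fluctuation the model predicts;
##  * a heritable-continuum model — each clone carries a latent suspension
##    growth rate, survival = exp(g T) x lognormal measurement noise —
##    which reproduces the observed fluctuation structure (CV ~ 0.25-0.3,
##    growth-rate mean ~ -0.004 /h with SD ~ 0.012 /h, no inter-passage
##    correlation when the latent value is memoryless across passages).

#' Load a shipped generator preset
#'
#' Named, versioned parameter sets stored as YAML under
#' `inst/extdata/presets/`. `"ov90-clones"` is calibrated to the observed
#' clone cohort (growth-rate mean -0.004/h, SD 0.012/h, measurement CV
#' 0.03, giving total survival CV about 0.30); `"parental"` describes
#' replicate population-level measurements (no clonal heterogeneity,
#' noise CV 0.11).
#'
#' @param name preset name; see `listPresets()`.
#' @return For continuum presets a [ContinuumParams-class]; for the
#'   parental preset a named list.
#' @examples
#' continuumPreset("ov90-clones")
#' @export
continuumPreset <- function(name = "ov90-clones") {
  path <- system.file("extdata", "presets", paste0(name, ".yaml"),
                      package = "cloneFluct")
  if (!nzchar(path))
    stop(sprintf("unknown preset '%s'; available: %s", name,
                 paste(listPresets(), collapse = ", ")), call. = FALSE)
  y <- yaml::read_yaml(path)
  if (identical(y$kind, "continuum")) {
    ContinuumParams(muG = y$mu_g, sigmaG = y$sigma_g, rho = y$rho,
                    measCV = y$meas_cv, nClones = y$n_clones,
                    passages = unlist(y$passages), nPlated = y$n_plated,
                    durationHours = y$duration_hours, name = y$name,
                    version = as.character(y$version))
  } else {
    y
  }
}

#' @rdname continuumPreset
#' @export
listPresets <- function() {
  dir <- system.file("extdata", "presets", package = "cloneFluct")
  sub("\\.yaml$", "", list.files(dir, pattern = "\\.yaml$"))
}

#' Generate a clone-survival table under the heritable continuum model
#'
#' Each clone draws a founder latent suspension growth rate
#' `g_i ~ Normal(muG, sigmaG)`. Across passages the latent value follows
#' a stationary AR(1) step with coefficient `rho` (so `rho = 0` makes
#' passages independent given the cohort distribution, and `rho = 1`
#' freezes each clone's propensity). Measured survival is
#' `exp(g * durationHours)` times multiplicative lognormal noise with
#' coefficient of variation `measCV`; live counts are rounded from the
#' fraction times `nPlated`.
#'
#' @param params a [ContinuumParams-class] (e.g. from [continuumPreset()]).
#' @param seed integer seed (required; output is deterministic given it).
#' @param nClones optional override of `params@nClones`.
#' @return A [CloneSurvivalTable-class] with attribute `"latent"` holding
#'   the clone-by-passage matrix of latent growth rates (provenance for
#'   recovery tests).
#' @examples
#' tab <- generateContinuumTable(continuumPreset("ov90-clones"), seed = 1)
#' cv(survivalFractions(tab, "P1"))
#' @export
generateContinuumTable <- function(params, seed, nClones = NULL) {
  stopifnot(is(params, "ContinuumParams"))
  if (missing(seed) || is.null(seed))
    stop("generateContinuumTable requires an integer seed", call. = FALSE)
  .localSeed(seed)
  nC <- if (is.null(nClones)) params@nClones else nClones
  nP <- length(params@passages)
  lat <- matrix(NA_real_, nC, nP,
                dimnames = list(NULL, params@passages))
  lat[, 1] <- stats::rnorm(nC, params@muG, params@sigmaG)
  if (nP > 1) for (j in 2:nP) {
    # stationary AR(1): same Normal(muG, sigmaG) marginal at every passage
    innov <- stats::rnorm(nC, 0, params@sigmaG * sqrt(1 - params@rho^2))
    lat[, j] <- params@muG + params@rho * (lat[, j - 1] - params@muG) + innov
  }
  sLn <- sqrt(log(1 + params@measCV^2))
  noise <- matrix(stats::rlnorm(nC * nP, -sLn^2 / 2, sLn), nC, nP)
  surv <- exp(lat * params@durationHours) * noise
  nLive <- round(surv * params@nPlated)
  ids <- sprintf("clone_%03d", seq_len(nC))
  tab <- CloneSurvivalTable(
    clone_id = rep(ids, nP),
    passage = rep(params@passages, each = nC),
    n_plated = params@nPlated,
    n_live = as.vector(nLive),
    survival_fraction = as.vector(nLive) / params@nPlated)
  attr(tab, "latent") <- lat
  attr(tab, "params") <- params
  attr(tab, "seed") <- as.integer(seed)
  tab
}

#' Generate replicate parental-population survival measurements
#'
#' Population-level repeats carry technical/biological measurement noise
#' only — no clonal heterogeneity term — so their CV is the fluctuation
#' floor against which interclonal CVs are compared.
#'
#' @param n number of replicates (default 11).
#' @param meanSurvival population mean survival fraction.
#' @param noiseCV coefficient of variation of the replicate noise
#'   (default 0.11).
#' @param seed integer seed.
#' @return Numeric vector of `n` survival fractions.
#' @examples
#' x <- generateParentalReplicates(11, seed = 1)
#' cv(x)
#' @export
generateParentalReplicates <- function(n = 11, meanSurvival = 0.9,
                                       noiseCV = 0.11, seed) {
  stopifnot(n >= 2)
  if (missing(seed) || is.null(seed))
    stop("generateParentalReplicates requires an integer seed", call. = FALSE)
  .localSeed(seed)
  if (noiseCV == 0) return(rep(meanSurvival, n))
  sLn <- sqrt(log(1 + noiseCV^2))
  meanSurvival * stats::rlnorm(n, -sLn^2 / 2, sLn)
}

#' Generate a clone-survival table under the two-state switching model
#'
#' Runs [fluctuationExperiment()] and emits the result in the common
#' table schema. With `passages` beyond the first, each clone's expansion
#' continues attached between assays (`gensPerPassage` generations per
#' passage step, switching ongoing) and a fresh subsample is assayed.
#'
#' @param model a [SwitchingModel-class].
#' @param protocol an [AssayProtocol-class].
#' @param seed integer seed.
#' @param passages passage labels (default `"P1"` only).
#' @param gensPerPassage attached generations between successive passages
#'   (default 3).
#' @param ... passed to [fluctuationExperiment()].
#' @return A [CloneSurvivalTable-class].
#' @examples
#' m <- switchingModelFromMemory(10.5, 0.76)
#' p <- AssayProtocol(expansionGenerations = 10, cellsPlated = 1000,
#'                    nClones = 10)
#' generateTwoStateTable(m, p, seed = 1)
#' @export
generateTwoStateTable <- function(model, protocol, seed, passages = "P1",
                                  gensPerPassage = 3, ...) {
  if (missing(seed) || is.null(seed))
    stop("generateTwoStateTable requires an integer seed", call. = FALSE)
  if (length(passages) == 1) {
    sim <- fluctuationExperiment(model, protocol, seed = seed, ...)
    tab <- as(sim, "CloneSurvivalTable")
    tab@records$passage <- passages
    attr(tab, "seed") <- as.integer(seed)
    return(tab)
  }
  .localSeed(seed)
  nC <- protocol@nClones
  N0 <- protocol@cellsPlated
  G <- protocol@expansionGenerations
  ids <- sprintf("clone_%03d", seq_len(nC))
  # expand to first assay, then keep growing the same clones between assays
  st <- expandClone(model, G, nClones = nC)
  recs <- list()
  tot <- st$n_sensitive + st$n_resistant
  for (i in seq_along(passages)) {
    if (i > 1) {
      r <- st$n_resistant
      for (g in seq_len(gensPerPassage)) {
        s <- tot - r
        r <- stats::rbinom(nC, 2 * s, model@kOn) +
          stats::rbinom(nC, 2 * r, 1 - model@kOff)
        tot <- 2 * tot
        if (max(tot) > 2^30) {  # renormalise to keep counts in range
          keep <- 2^20
          r <- stats::rbinom(nC, keep, r / tot)
          tot <- rep(keep, nC)
        }
      }
      st$n_resistant <- r
      st$n_sensitive <- tot - r
    }
    plR <- stats::rhyper(nC, m = st$n_resistant, n = st$n_sensitive, k = N0)
    live <- .assaySurvivors(model, N0 - plR, plR, protocol@durationHours)
    recs[[i]] <- data.frame(clone_id = ids, passage = passages[i],
                            n_plated = N0, n_live = live,
                            survival_fraction = live / N0)
  }
  tab <- CloneSurvivalTable(do.call(rbind, recs))
  attr(tab, "seed") <- as.integer(seed)
  tab
}
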