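## Stochastic simulation of the fluctuation protocol: single-cell founding,
## attached expansion with switching at division, subsampling, suspension
## assay. Attached growth is deterministic doubling (every cell divides
## once per generation); the stochastic element is daughter-state
## switching. The default "aggregate" engine propagates (n_S, n_R) counts
## with binomial draws, which is distributionally identical to per-cell
## simulation and makes 2^20-cell clones cheap; a literal per-cell engine
## is kept for small instances and cross-checks.

.localSeed <- function(seed) {
  if (is.null(seed)) return(invisible(NULL))
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  # restore the caller's RNG stream when the calling frame exits
  expr <- if (has) {
    bquote(assign(".Random.seed", .(old), envir = globalenv()))
  } else {
    quote(rm(".Random.seed", envir = globalenv()))
  }
  do.call(on.exit, list(expr, add = TRUE), envir = parent.frame())
  invisible(NULL)
}

.founderStates <- function(founder, nClones, fEq) {
  switch(founder,
    sensitive = rep(0L, nClones),
    resistant = rep(1L, nClones),
    equilibrium = {
      if (is.na(fEq))
        stop("equilibrium founder undefined when kOn = kOff = 0",
             call. = FALSE)
      stats::rbinom(nClones, 1L, fEq)
    },
    stop("founder must be 'sensitive', 'resistant' or 'equilibrium'",
         call. = FALSE))
}

#' Expand clones from single founder cells
#'
#' Grows `nClones` clones for `G` generations of attached culture. Every
#' cell divides once per generation; each daughter switches state
#' independently (S daughter resistant with probability `kOn`, R daughter
#' sensitive with probability `kOff`), so after `G` generations every
#' clone holds exactly `2^G` cells.
#'
#' @param model a [SwitchingModel-class].
#' @param G number of expansion generations (0 <= G <= 30).
#' @param founder `"equilibrium"` (founder state drawn from the stationary
#'   distribution), `"sensitive"` or `"resistant"`.
#' @param nClones number of clones to expand.
#' @param mode `"aggregate"` (binomial count propagation, default) or
#'   `"percell"` (explicit per-cell simulation; requires `2^G <= 2^16`).
#' @param seed optional integer seed (the caller's RNG state is restored).
#' @return A data frame with one row per clone: `founder` (`"S"`/`"R"`),
#'   `n_sensitive`, `n_resistant`, `generation`.
#' @examples
#' m <- switchingModelFromMemory(10.5, 0.76)
#' expandClone(m, G = 5, nClones = 3, seed = 1)
#' @export
expandClone <- function(model, G,
                        founder = c("equilibrium", "sensitive", "resistant"),
                        nClones = 1, mode = c("aggregate", "percell"),
                        seed = NULL) {
  founder <- match.arg(founder)
  mode <- match.arg(mode)
  stopifnot(is(model, "SwitchingModel"), G >= 0, G == round(G))
  if (G > 30)
    stop("G > 30 would overflow cell counts; aggregate mode supports G <= 30",
         call. = FALSE)
  if (mode == "percell" && 2^G > 65536)
    stop("percell mode supports at most 2^16 cells per clone; use mode = 'aggregate'",
         call. = FALSE)
  .localSeed(seed)
  f0 <- .founderStates(founder, nClones, equilibriumFraction(model))
  if (mode == "aggregate") {
    r <- as.numeric(f0)
    tot <- 1
    for (g in seq_len(G)) {
      s <- tot - r
      r <- stats::rbinom(nClones, 2 * s, model@kOn) +
        stats::rbinom(nClones, 2 * r, 1 - model@kOff)
      tot <- 2 * tot
    }
  } else {
    tot <- 2^G
    r <- vapply(f0, function(st) {
      cells <- as.logical(st)  # TRUE = resistant
      for (g in seq_len(G)) {
        parents <- rep(cells, each = 2)
        flip <- stats::runif(length(parents)) <
          ifelse(parents, model@kOff, model@kOn)
        cells <- xor(parents, flip)
      }
      sum(cells)
    }, numeric(1))
  }
  data.frame(founder = c("S", "R")[f0 + 1L], n_sensitive = tot - r,
             n_resistant = r, generation = G)
}

## Live cells at assay end given plated (nS, nR); vectorised over clones.
.assaySurvivors <- function(model, nS, nR, T, stochastic = TRUE) {
  gamma <- growthRateFromDoubling(model@TdSusp)
  if (stochastic) {
    # Yule (pure-birth) process: total offspring of nR lineages after time
    # T is nR + NegBinom(size = nR, prob = e^(-gamma T)), mean nR e^(gamma T)
    liveR <- ifelse(nR > 0,
                    nR + if (gamma > 0)
                      stats::rnbinom(length(nR), size = pmax(nR, 1),
                                     prob = exp(-gamma * T)) else 0,
                    0)
    liveS <- switch(model@sensitiveDeath,
      all_dead = rep(0, length(nS)),
      exponential = stats::rbinom(length(nS), nS,
                                  exp(-model@deathRate * T)))
  } else {
    liveR <- nR * exp(gamma * T)
    liveS <- switch(model@sensitiveDeath,
      all_dead = rep(0, length(nS)),
      exponential = nS * exp(-model@deathRate * T))
  }
  liveR + liveS
}

#' Simulate the suspension assay for plated cell mixtures
#'
#' Places `nS` sensitive and `nR` resistant cells in suspension for `T`
#' hours. Sensitive cells die according to the model's `sensitiveDeath`
#' mode (default: none survive); resistant cells proliferate as a Yule
#' pure-birth process with rate `log(2)/TdSusp`, so the expected survival
#' fraction is `nR / (nS + nR) * exp(gamma T)`.
#'
#' @param model a [SwitchingModel-class].
#' @param nS,nR plated sensitive / resistant cell counts (vectorised).
#' @param T assay duration in hours.
#' @param stochastic if `FALSE`, return expected counts instead of draws.
#' @param seed optional integer seed.
#' @return A data frame with columns `n_plated`, `n_live`,
#'   `survival_fraction`.
#' @examples
#' m <- SwitchingModel(0.3, 0.095, TdSusp = 100)
#' suspensionAssay(m, nS = 60000, nR = 190000, seed = 1)
#' @export
suspensionAssay <- function(model, nS, nR, T = 24, stochastic = TRUE,
                            seed = NULL) {
  stopifnot(is(model, "SwitchingModel"))
  n <- max(length(nS), length(nR))
  nS <- rep_len(nS, n); nR <- rep_len(nR, n)
  if (any(nS + nR < 1)) stop("at least one cell must be plated", call. = FALSE)
  .localSeed(seed)
  live <- .assaySurvivors(model, nS, nR, T, stochastic)
  data.frame(n_plated = nS + nR, n_live = live,
             survival_fraction = live / (nS + nR))
}

#' Simulate one full fluctuation experiment
#'
#' For each clone: found a single cell, expand `G` generations attached,
#' subsample the plated cell number from the expanded clone
#' (hypergeometric, i.e. without replacement), and run the suspension
#' assay. Reproducible given the seed.
#'
#' @param model a [SwitchingModel-class].
#' @param protocol an [AssayProtocol-class].
#' @param seed integer seed (required: the experiment is stochastic).
#' @param founder founder-state rule, as in [expandClone()].
#' @param sampling `"auto"` (hypergeometric when the clone is at least as
#'   large as `cellsPlated`, else binomial), `"hypergeometric"` (error if
#'   the clone is smaller than `cellsPlated`), or `"binomial"`.
#' @param plated `"fixed"` (plate `cellsPlated` cells, default) or
#'   `"whole"` (plate the entire expanded clone).
#' @param stochasticAssay if `FALSE` the assay returns expected counts
#'   (useful for isolating expansion/sampling noise).
#' @return A [SimResult-class]; coerce with
#'   `as(result, "CloneSurvivalTable")` for downstream statistics.
#' @examples
#' m <- switchingModelFromMemory(10.5, 0.76, TdSusp = 100)
#' p <- AssayProtocol(expansionGenerations = 10, cellsPlated = 500,
#'                    nClones = 20)
#' res <- fluctuationExperiment(m, p, seed = 1)
#' cv(res@survival)
#' @export
fluctuationExperiment <- function(model, protocol, seed,
                                  founder = c("equilibrium", "sensitive",
                                              "resistant"),
                                  sampling = c("auto", "hypergeometric",
                                               "binomial"),
                                  plated = c("fixed", "whole"),
                                  stochasticAssay = TRUE) {
  founder <- match.arg(founder)
  sampling <- match.arg(sampling)
  plated <- match.arg(plated)
  stopifnot(is(model, "SwitchingModel"), is(protocol, "AssayProtocol"))
  if (missing(seed) || is.null(seed))
    stop("fluctuationExperiment requires an integer seed", call. = FALSE)
  .localSeed(seed)
  nC <- protocol@nClones
  G <- protocol@expansionGenerations
  N0 <- protocol@cellsPlated
  exp_ <- expandClone(model, G, founder = founder, nClones = nC)
  tot <- exp_$n_sensitive + exp_$n_resistant
  if (plated == "whole") {
    plR <- exp_$n_resistant
    plS <- exp_$n_sensitive
  } else {
    if (any(tot < N0) && sampling == "hypergeometric")
      stop(sprintf(
        "expanded clone (%g cells) smaller than cellsPlated (%g); use sampling = 'binomial' (aggregate fallback) or plated = 'whole'",
        min(tot), N0), call. = FALSE)
    useHyper <- sampling != "binomial" & tot >= N0
    plR <- numeric(nC)
    if (any(useHyper))
      plR[useHyper] <- stats::rhyper(sum(useHyper),
                                     m = exp_$n_resistant[useHyper],
                                     n = exp_$n_sensitive[useHyper], k = N0)
    if (any(!useHyper))
      plR[!useHyper] <- stats::rbinom(sum(!useHyper), N0,
                                      exp_$n_resistant[!useHyper] /
                                        tot[!useHyper])
    plS <- N0 - plR
  }
  live <- .assaySurvivors(model, plS, plR, protocol@durationHours,
                          stochastic = stochasticAssay)
  new("SimResult", survival = live / (plS + plR), founders = exp_$founder,
      nPlated = plS + plR, nLive = live, seed = as.integer(seed),
      model = model, protocol = protocol)
}

#' Monte Carlo prediction of the interclonal CV
#'
#' Repeats the full fluctuation experiment `nReps` times and summarises
#' the interclonal coefficient of variation of survival across clones.
#' This is the model's predicted fluctuation level for the protocol.
#'
#' @inheritParams fluctuationExperiment
#' @param nReps number of replicate simulated experiments (>= 2).
#' @return Named numeric vector `c(cv = ..., mc_error = ...)` (mean CV
#'   across replicates and its standard error), with the per-replicate
#'   CVs in attribute `"cvs"`.
#' @examples
#' m <- switchingModelFromMemory(10.5, 0.76, TdSusp = 100)
#' p <- AssayProtocol(expansionGenerations = 8, cellsPlated = 200,
#'                    nClones = 30)
#' predictedCV(m, p, nReps = 20, seed = 1)
#' @export
predictedCV <- function(model, protocol, nReps = 200, seed,
                        founder = "equilibrium", stochasticAssay = TRUE) {
  stopifnot(nReps >= 2)
  if (missing(seed) || is.null(seed))
    stop("predictedCV requires an integer seed", call. = FALSE)
  .localSeed(seed)
  nC <- protocol@nClones
  # one big vectorised run: nReps * nClones clones share the generator
  big <- AssayProtocol(
    durationHours = protocol@durationHours,
    cellsPlated = protocol@cellsPlated,
    expansionGenerations = protocol@expansionGenerations,
    nClones = nReps * nC,
    resistanceThreshold = protocol@resistanceThreshold)
  sim <- fluctuationExperiment(model, big, seed = sample.int(2^31 - 1, 1),
                               founder = founder,
                               stochasticAssay = stochasticAssay)
  surv <- matrix(sim@survival, nrow = nReps, byrow = TRUE)
  if (all(surv == 0))
    stop("all simulated survivals are zero: CV undefined", call. = FALSE)
  cvs <- apply(surv, 1, cv)
  out <- c(cv = mean(cvs), mc_error = stats::sd(cvs) / sqrt(nReps))
  attr(out, "cvs") <- cvs
  out
}

#' Predicted CV over a grid of suspension doubling times
#'
#' For each doubling time, rebuilds the model with the equilibrium
#' resistant fraction implied by the survival balance
#' `f = S * 2^(-T/Td)` (memory held fixed) and computes the Monte Carlo
#' predicted interclonal CV.
#'
#' @param TdGrid doubling times in hours (default 38-200 h, the
#'   biologically relevant range bounded below by attached doubling).
#' @param S mean suspension survival used for the balance (default 0.9).
#' @param M resistant-state memory in generations (default 10.5).
#' @param protocol an [AssayProtocol-class].
#' @param nReps replicate experiments per grid point.
#' @param seed integer seed.
#' @return Data frame with columns `Td`, `f_eq`, `kOn`, `kOff`, `cv`,
#'   `mc_error`.
#' @export
predictedCVGrid <- function(TdGrid = c(38, 50, 75, 100, 150, 200), S = 0.9,
                            M = 10.5, protocol = AssayProtocol(),
                            nReps = 200, seed) {
  if (missing(seed) || is.null(seed))
    stop("predictedCVGrid requires an integer seed", call. = FALSE)
  .localSeed(seed)
  subSeeds <- sample.int(2^31 - 1, length(TdGrid))
  rows <- lapply(seq_along(TdGrid), function(i) {
    Td <- TdGrid[i]
    fEq <- resistantFractionFromSurvival(S, protocol@durationHours, Td)
    model <- switchingModelFromMemory(M, fEq, TdSusp = Td)
    p <- predictedCV(model, protocol, nReps = nReps, seed = subSeeds[i])
    data.frame(Td = Td, f_eq = fEq, kOn = model@kOn, kOff = model@kOff,
               cv = p[["cv"]], mc_error = p[["mc_error"]])
  })
  do.call(rbind, rows)
}
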