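#' @import methods
NULL

## Central parameter and data containers. All survival values are fractions
## (1.0 = 100% of plated cells recovered alive); values > 1 mean net growth
## in suspension and are deliberately never clipped.

#' Two-state phenotype-switching model
#'
#' Parameters of the reversible switch between an anoikis-sensitive (AnS)
#' and an anoikis-resistant (AnR) cell state. Switching happens at cell
#' division: a daughter of a sensitive cell becomes resistant with
#' probability `kOn`, a daughter of a resistant cell becomes sensitive with
#' probability `kOff`. In suspension, resistant cells grow with rate
#' `log(2)/TdSusp` per hour while sensitive cells die according to
#' `sensitiveDeath`.
#'
#' @slot kOn per-division S-to-R switching probability, in \[0, 1\].
#' @slot kOff per-division R-to-S switching probability, in \[0, 1\].
#' @slot TdSusp doubling time (hours) of resistant cells in suspension;
#'   may be `Inf` (no net growth).
#' @slot Td2D doubling time (hours) in attached (2D) culture, used only to
#'   convert generations to hours.
#' @slot sensitiveDeath either `"all_dead"` (no sensitive cell survives the
#'   assay) or `"exponential"` (per-hour death rate `deathRate`).
#' @slot deathRate per-hour death rate of sensitive cells in suspension,
#'   used only when `sensitiveDeath == "exponential"`.
#'
#' @seealso [SwitchingModel()], [switchingModelFromMemory()]
#' @exportClass SwitchingModel
setClass("SwitchingModel",
  representation(
    kOn = "numeric",
    kOff = "numeric",
    TdSusp = "numeric",
    Td2D = "numeric",
    sensitiveDeath = "character",
    deathRate = "numeric"
  ),
  prototype(
    kOn = 0.3016, kOff = 1 / 10.5, TdSusp = 100, Td2D = 38,
    sensitiveDeath = "all_dead", deathRate = NA_real_
  )
)

setValidity("SwitchingModel", function(object) {
  msg <- character(0)
  for (s in c("kOn", "kOff")) {
    v <- slot(object, s)
    if (length(v) != 1 || is.na(v) || v < 0 || v > 1)
      msg <- c(msg, sprintf("%s must be a single probability in [0, 1]", s))
  }
  for (s in c("TdSusp", "Td2D")) {
    v <- slot(object, s)
    if (length(v) != 1 || is.na(v) || v <= 0)
      msg <- c(msg, sprintf("%s must be a single positive number of hours", s))
  }
  if (!object@sensitiveDeath %in% c("all_dead", "exponential"))
    msg <- c(msg, "sensitiveDeath must be 'all_dead' or 'exponential'")
  if (object@sensitiveDeath == "exponential" &&
      (is.na(object@deathRate) || object@deathRate < 0))
    msg <- c(msg, "deathRate must be a non-negative per-hour rate")
  if (length(msg)) msg else TRUE
})

#' Suspension-assay protocol
#'
#' The experimental schedule of the clonal fluctuation protocol: single
#' cells are expanded attached for `expansionGenerations` divisions, then
#' `cellsPlated` cells are placed in suspension for `durationHours` and
#' live cells are counted.
#'
#' @slot durationHours suspension assay duration in hours (default 24).
#' @slot cellsPlated number of cells plated per assay (default 250000).
#' @slot expansionGenerations attached expansion generations before the
#'   first assay (default 20).
#' @slot nClones number of independent single-cell clones (default 60).
#' @slot resistanceThreshold survival fraction at or above which a
#'   population is called anoikis resistant (default 1, i.e. 100%).
#'
#' @seealso [AssayProtocol()]
#' @exportClass AssayProtocol
setClass("AssayProtocol",
  representation(
    durationHours = "numeric",
    cellsPlated = "numeric",
    expansionGenerations = "numeric",
    nClones = "numeric",
    resistanceThreshold = "numeric"
  ),
  prototype(
    durationHours = 24, cellsPlated = 250000, expansionGenerations = 20,
    nClones = 60, resistanceThreshold = 1
  )
)

setValidity("AssayProtocol", function(object) {
  msg <- character(0)
  if (object@durationHours <= 0) msg <- c(msg, "durationHours must be > 0")
  if (object@cellsPlated < 1 || object@cellsPlated != round(object@cellsPlated))
    msg <- c(msg, "cellsPlated must be a positive integer")
  if (object@expansionGenerations < 0 ||
      object@expansionGenerations != round(object@expansionGenerations))
    msg <- c(msg, "expansionGenerations must be a non-negative integer")
  if (object@nClones < 1 || object@nClones != round(object@nClones))
    msg <- c(msg, "nClones must be a positive integer")
  if (object@resistanceThreshold <= 0)
    msg <- c(msg, "resistanceThreshold must be > 0")
  if (length(msg)) msg else TRUE
})

#' Per-clone, per-passage suspension-survival records
#'
#' Thin S4 container around a data frame with the canonical columns
#' `clone_id`, `passage`, `n_plated`, `n_live`, `survival_fraction`.
#' Counts may be `NA` when only a survival fraction was recorded; when both
#' counts are present, `survival_fraction` must equal `n_live / n_plated`.
#'
#' @slot records a `data.frame` with the five canonical columns.
#'
#' @seealso [CloneSurvivalTable()], [readCloneTable()], [analyzeTable()]
#' @exportClass CloneSurvivalTable
setClass("CloneSurvivalTable", representation(records = "data.frame"))

.cloneTableCols <- c("clone_id", "passage", "n_plated", "n_live",
                     "survival_fraction")

setValidity("CloneSurvivalTable", function(object) {
  rec <- object@records
  msg <- character(0)
  missing <- setdiff(.cloneTableCols, names(rec))
  if (length(missing))
    return(sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  if (!is.numeric(rec$survival_fraction))
    msg <- c(msg, "survival_fraction must be numeric")
  if (any(rec$survival_fraction < 0, na.rm = TRUE))
    msg <- c(msg, "survival_fraction must be non-negative")
  both <- !is.na(rec$n_plated) & !is.na(rec$n_live)
  if (any(both)) {
    ratio <- rec$n_live[both] / rec$n_plated[both]
    off <- abs(ratio - rec$survival_fraction[both]) >
      1e-9 * pmax(1, abs(ratio))
    if (any(off))
      msg <- c(msg, sprintf(
        "survival_fraction disagrees with n_live/n_plated in %d row(s)",
        sum(off)))
  }
  dup <- duplicated(rec[, c("clone_id", "passage")])
  if (any(dup))
    msg <- c(msg, "duplicated (clone_id, passage) record(s)")
  if (length(msg)) msg else TRUE
})

#' Fluctuation statistics for one clone-survival table
#'
#' Computed by [analyzeTable()]: per-passage interclonal CV with bootstrap
#' confidence interval, growth-rate summary, inter-passage regressions and
#' (optionally) the fold ratio of observed over model-predicted CV.
#'
#' @slot passageStats data frame with one row per passage: `passage`, `n`,
#'   `mean_survival`, `cv`, `ci_low`, `ci_high`, `half_width`.
#' @slot growthStats list of growth-rate statistics (see
#'   [growthRateSummary()]), or an empty list when counts are absent.
#' @slot passagePairs data frame of pairwise regressions: `passage_a`,
#'   `passage_b`, `n`, `slope`, `intercept`, `r`, `p`.
#' @slot predictedCV model-predicted CV used for comparison (`NA` if none).
#' @slot foldRatio observed/predicted CV fold ratio (`NA` if no prediction).
#' @slot meta list of provenance fields (seed, n_boot, alpha, ...).
#'
#' @exportClass FluctuationSummary
setClass("FluctuationSummary",
  representation(
    passageStats = "data.frame",
    growthStats = "list",
    passagePairs = "data.frame",
    predictedCV = "numeric",
    foldRatio = "numeric",
    meta = "list"
  ),
  prototype(predictedCV = NA_real_, foldRatio = NA_real_, meta = list())
)

setValidity("FluctuationSummary", function(object) {
  ps <- object@passageStats
  msg <- character(0)
  if (nrow(ps)) {
    if (any(ps$half_width < 0, na.rm = TRUE))
      msg <- c(msg, "CI half-widths must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Heritable-continuum generator parameters
#'
#' Parameters of the latent-propensity model used to emulate the observed
#' clone structure: each clone carries a latent suspension growth rate
#' drawn from Normal(`muG`, `sigmaG`); across passages the latent value
#' follows a stationary AR(1) process with coefficient `rho` (memory);
#' measured survival is `exp(g * durationHours)` times multiplicative
#' lognormal measurement noise with coefficient of variation `measCV`.
#'
#' @slot muG mean latent growth rate, per hour.
#' @slot sigmaG SD of latent growth rates across clones, per hour.
#' @slot rho per-passage autocorrelation of the latent value, in \[-1, 1\].
#' @slot measCV coefficient of variation of multiplicative measurement noise.
#' @slot nClones number of clones per table.
#' @slot passages character vector of passage labels (e.g. `c("P1","P3","P6")`).
#' @slot nPlated cells plated per assay (used to emit integer live counts).
#' @slot durationHours suspension assay duration in hours.
#' @slot name preset name ("" for ad hoc parameter sets).
#' @slot version preset version string.
#'
#' @seealso [continuumPreset()], [generateContinuumTable()]
#' @exportClass ContinuumParams
setClass("ContinuumParams",
  representation(
    muG = "numeric", sigmaG = "numeric", rho = "numeric", measCV = "numeric",
    nClones = "numeric", passages = "character", nPlated = "numeric",
    durationHours = "numeric", name = "character", version = "character"
  ),
  prototype(
    muG = -0.004, sigmaG = 0.012, rho = 0, measCV = 0.03, nClones = 60,
    passages = c("P1", "P3", "P6"), nPlated = 250000, durationHours = 24,
    name = "", version = "1"
  )
)

setValidity("ContinuumParams", function(object) {
  msg <- character(0)
  if (object@sigmaG < 0) msg <- c(msg, "sigmaG must be >= 0")
  if (abs(object@rho) > 1) msg <- c(msg, "rho must lie in [-1, 1]")
  if (object@measCV < 0) msg <- c(msg, "measCV must be >= 0")
  if (object@nClones < 1) msg <- c(msg, "nClones must be >= 1")
  if (!length(object@passages)) msg <- c(msg, "at least one passage label")
  if (object@durationHours <= 0) msg <- c(msg, "durationHours must be > 0")
  if (length(msg)) msg else TRUE
})

#' Resistance-reversion curve
#'
#' Survival (or resistant-fraction) measurements of an adapted resistant
#' population re-assayed after increasing numbers of stress-free attached
#' generations.
#'
#' @slot generation strictly increasing generation numbers.
#' @slot fraction non-negative survival or resistant fractions.
#' @slot label cell-line or condition label.
#'
#' @seealso [fitMemory()], [reversionTrajectory()]
#' @exportClass ReversionCurve
setClass("ReversionCurve",
  representation(generation = "numeric", fraction = "numeric",
                 label = "character"),
  prototype(label = "")
)

setValidity("ReversionCurve", function(object) {
  msg <- character(0)
  if (length(object@generation) != length(object@fraction))
    msg <- c(msg, "generation and fraction must have equal length")
  if (length(object@generation) > 1 && any(diff(object@generation) <= 0))
    msg <- c(msg, "generations must be strictly increasing")
  if (any(object@fraction < 0, na.rm = TRUE))
    msg <- c(msg, "fractions must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Result of one simulated fluctuation experiment
#'
#' Per-clone survival fractions from [fluctuationExperiment()], together
#' with founder states, live counts, the seed and the model/protocol that
#' produced them, so the run is fully reproducible.
#'
#' @slot survival per-clone survival fractions.
#' @slot founders founder state per clone, `"S"` or `"R"`.
#' @slot nPlated cells plated per clone.
#' @slot nLive live cells at assay end per clone.
#' @slot seed integer seed of the run.
#' @slot model the [SwitchingModel-class] used.
#' @slot protocol the [AssayProtocol-class] used.
#'
#' @exportClass SimResult
setClass("SimResult",
  representation(
    survival = "numeric", founders = "character", nPlated = "numeric",
    nLive = "numeric", seed = "integer", model = "SwitchingModel",
    protocol = "AssayProtocol"
  )
)

setValidity("SimResult", function(object) {
  n <- length(object@survival)
  if (length(object@founders) != n || length(object@nLive) != n ||
      length(object@nPlated) != n)
    return("survival, founders, nPlated and nLive must have equal length")
  if (any(object@survival < 0)) return("survival fractions must be >= 0")
  TRUE
})
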