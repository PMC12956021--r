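#' Construct a two-state switching model
#'
#' @param kOn per-division probability that a sensitive cell's daughter is
#'   resistant.
#' @param kOff per-division probability that a resistant cell's daughter is
#'   sensitive.
#' @param TdSusp resistant-state doubling time in suspension, hours
#'   (`Inf` allowed: no net growth).
#' @param Td2D attached doubling time, hours.
#' @param sensitiveDeath `"all_dead"` (default; no sensitive cell survives
#'   24 h of suspension) or `"exponential"`.
#' @param deathRate per-hour death rate for `sensitiveDeath = "exponential"`.
#' @return A [SwitchingModel-class] object.
#' @examples
#' m <- SwitchingModel(kOn = 0.3, kOff = 0.095, TdSusp = 100)
#' equilibriumFraction(m)
#' @export
SwitchingModel <- function(kOn, kOff, TdSusp = 100, Td2D = 38,
                           sensitiveDeath = c("all_dead", "exponential"),
                           deathRate = NA_real_) {
  sensitiveDeath <- match.arg(sensitiveDeath)
  new("SwitchingModel", kOn = as.numeric(kOn), kOff = as.numeric(kOff),
      TdSusp = as.numeric(TdSusp), Td2D = as.numeric(Td2D),
      sensitiveDeath = sensitiveDeath, deathRate = as.numeric(deathRate))
}

#' Construct a switching model from memory and equilibrium fraction
#'
#' Convenience wrapper around [ratesFromMemoryEquilibrium()]: builds the
#' model whose resistant state persists `M` generations on average and
#' whose stationary resistant fraction is `fEq`.
#'
#' @param M mean resistant-state residence time, generations (> 0).
#' @param fEq stationary resistant fraction, in \[0, 1).
#' @inheritParams SwitchingModel
#' @return A [SwitchingModel-class] object.
#' @examples
#' switchingModelFromMemory(M = 10.5, fEq = 0.76, TdSusp = 100)
#' @export
switchingModelFromMemory <- function(M, fEq, TdSusp = 100, Td2D = 38,
                                     sensitiveDeath = c("all_dead",
                                                        "exponential"),
                                     deathRate = NA_real_) {
  k <- ratesFromMemoryEquilibrium(M, fEq)
  SwitchingModel(kOn = k[["kOn"]], kOff = k[["kOff"]], TdSusp = TdSusp,
                 Td2D = Td2D, sensitiveDeath = match.arg(sensitiveDeath),
                 deathRate = deathRate)
}

#' Construct an assay protocol
#'
#' Defaults follow the clonal fluctuation protocol: 24-hour suspension
#' assay on low-attachment plates, 250,000 cells plated, clones expanded
#' 20 generations from single cells, 60 clones, and the >= 100% viability
#' rule for calling a population anoikis resistant.
#'
#' @param durationHours suspension assay duration, hours.
#' @param cellsPlated cells plated per assay.
#' @param expansionGenerations attached expansion generations before the
#'   first assay.
#' @param nClones number of single-cell clones.
#' @param resistanceThreshold survival fraction at or above which a
#'   population is classified resistant.
#' @return An [AssayProtocol-class] object.
#' @examples
#' AssayProtocol()
#' @export
AssayProtocol <- function(durationHours = 24, cellsPlated = 250000,
                          expansionGenerations = 20, nClones = 60,
                          resistanceThreshold = 1) {
  new("AssayProtocol", durationHours = as.numeric(durationHours),
      cellsPlated = as.numeric(cellsPlated),
      expansionGenerations = as.numeric(expansionGenerations),
      nClones = as.numeric(nClones),
      resistanceThreshold = as.numeric(resistanceThreshold))
}

#' Construct a clone-survival table
#'
#' Either pass a data frame with the canonical columns, or the columns as
#' vectors. When counts are given but `survival_fraction` is not, the
#' fraction is filled in as `n_live / n_plated`.
#'
#' @param x optional data frame with columns `clone_id`, `passage`,
#'   `n_plated`, `n_live`, `survival_fraction` (the last may be omitted
#'   when both counts are present).
#' @param clone_id,passage,n_plated,n_live,survival_fraction columns as
#'   vectors, used when `x` is `NULL`.
#' @return A [CloneSurvivalTable-class] object.
#' @examples
#' CloneSurvivalTable(clone_id = c("c1", "c2"), passage = "P1",
#'                    n_plated = 1000, n_live = c(900, 800))
#' @export
CloneSurvivalTable <- function(x = NULL, clone_id = character(),
                               passage = character(), n_plated = NA,
                               n_live = NA, survival_fraction = NULL) {
  if (is.null(x)) {
    n <- max(length(clone_id), length(passage))
    x <- data.frame(
      clone_id = as.character(rep_len(clone_id, n)),
      passage = as.character(rep_len(passage, n)),
      n_plated = as.numeric(rep_len(n_plated, n)),
      n_live = as.numeric(rep_len(n_live, n)),
      stringsAsFactors = FALSE
    )
    if (!is.null(survival_fraction))
      x$survival_fraction <- as.numeric(rep_len(survival_fraction, n))
  } else {
    x <- as.data.frame(x, stringsAsFactors = FALSE)
  }
  if (is.null(x$survival_fraction))
    x$survival_fraction <- x$n_live / x$n_plated
  for (col in c("n_plated", "n_live"))
    if (is.null(x[[col]])) x[[col]] <- NA_real_
  x <- x[, .cloneTableCols]
  x$clone_id <- as.character(x$clone_id)
  x$passage <- as.character(x$passage)
  rownames(x) <- NULL
  new("CloneSurvivalTable", records = x)
}

#' Construct a continuum-generator parameter set
#'
#' @param muG mean latent suspension growth rate (per hour).
#' @param sigmaG between-clone SD of the latent growth rate (per hour).
#' @param rho per-passage autocorrelation of the latent value.
#' @param measCV coefficient of variation of multiplicative lognormal
#'   measurement noise.
#' @param nClones clones per table.
#' @param passages passage labels.
#' @param nPlated cells plated per assay.
#' @param durationHours assay duration, hours.
#' @param name,version preset identification.
#' @return A [ContinuumParams-class] object.
#' @seealso [continuumPreset()] for the shipped calibrated presets.
#' @export
ContinuumParams <- function(muG = -0.004, sigmaG = 0.012, rho = 0,
                            measCV = 0.03, nClones = 60,
                            passages = c("P1", "P3", "P6"),
                            nPlated = 250000, durationHours = 24,
                            name = "", version = "1") {
  new("ContinuumParams", muG = as.numeric(muG), sigmaG = as.numeric(sigmaG),
      rho = as.numeric(rho), measCV = as.numeric(measCV),
      nClones = as.numeric(nClones), passages = as.character(passages),
      nPlated = as.numeric(nPlated),
      durationHours = as.numeric(durationHours),
      name = as.character(name), version = as.character(version))
}

#' Construct a reversion curve
#'
#' @param generation strictly increasing generation numbers.
#' @param fraction survival or resistant fractions (>= 0).
#' @param label optional cell-line label.
#' @return A [ReversionCurve-class] object.
#' @export
ReversionCurve <- function(generation, fraction, label = "") {
  new("ReversionCurve", generation = as.numeric(generation),
      fraction = as.numeric(fraction), label = as.character(label))
}
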