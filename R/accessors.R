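#' Accessors for cloneFluct classes
#'
#' `equilibriumFraction` returns the stationary resistant fraction
#' `kOn / (kOn + kOff)`; `memoryGenerations` the mean resistant-state
#' residence time `1 / kOff`; `passages`, `cloneIds`, `survivalFractions`
#' and `records` extract parts of a [CloneSurvivalTable-class];
#' `passageStats`, `growthStats` and `passagePairs` extract parts of a
#' [FluctuationSummary-class].
#'
#' @param object the object to access.
#' @param passage optional passage label to restrict to.
#' @name accessors
#' @aliases equilibriumFraction memoryGenerations
NULL

#' @rdname accessors
setMethod("equilibriumFraction", "SwitchingModel", function(object) {
  if (object@kOn + object@kOff == 0) return(NA_real_)
  object@kOn / (object@kOn + object@kOff)
})

#' @rdname accessors
setMethod("memoryGenerations", "SwitchingModel", function(object) {
  if (object@kOff == 0) return(Inf)
  1 / object@kOff
})

#' @rdname accessors
setMethod("passages", "CloneSurvivalTable", function(object) {
  unique(object@records$passage)
})

#' @rdname accessors
setMethod("cloneIds", "CloneSurvivalTable", function(object) {
  unique(object@records$clone_id)
})

#' @rdname accessors
setMethod("survivalFractions", "CloneSurvivalTable",
  function(object, passage = NULL) {
    rec <- object@records
    if (!is.null(passage)) rec <- rec[rec$passage %in% passage, ]
    stats::setNames(rec$survival_fraction, rec$clone_id)
  })

#' @rdname accessors
setMethod("records", "CloneSurvivalTable", function(object) object@records)

#' @rdname accessors
setMethod("passageStats", "FluctuationSummary",
          function(object) object@passageStats)

#' @rdname accessors
setMethod("growthStats", "FluctuationSummary",
          function(object) object@growthStats)

#' @rdname accessors
setMethod("passagePairs", "FluctuationSummary",
          function(object) object@passagePairs)

#' @describeIn CloneSurvivalTable-class number of distinct clones.
#' @param x a `CloneSurvivalTable`.
#' @export
setMethod("length", "CloneSurvivalTable", function(x) {
  length(unique(x@records$clone_id))
})

#' Coerce a clone-survival table to a data frame
#'
#' @param x a [CloneSurvivalTable-class].
#' @param row.names,optional,... ignored (base signature).
#' @return The underlying records `data.frame`.
#' @export
as.data.frame.CloneSurvivalTable <- function(x, row.names = NULL,
                                             optional = FALSE, ...) {
  x@records
}

setAs("SimResult", "CloneSurvivalTable", function(from) {
  CloneSurvivalTable(
    clone_id = sprintf("clone_%03d", seq_along(from@survival)),
    passage = "P1",
    n_plated = from@nPlated,
    n_live = from@nLive,
    survival_fraction = from@survival
  )
})

setAs("data.frame", "CloneSurvivalTable", function(from) {
  CloneSurvivalTable(from)
})

setMethod("show", "SwitchingModel", function(object) {
  cat("SwitchingModel (two-state AnS/AnR phenotype switch)\n")
  cat(sprintf("  kOn  = %.6g  (S -> R per division)\n", object@kOn))
  cat(sprintf("  kOff = %.6g  (R -> S per division; memory = %.3g generations)\n",
              object@kOff, memoryGenerations(object)))
  cat(sprintf("  equilibrium resistant fraction f_eq = %.4g\n",
              equilibriumFraction(object)))
  cat(sprintf("  T_d suspension = %.4g h; T_d attached = %.4g h\n",
              object@TdSusp, object@Td2D))
  cat(sprintf("  sensitive-cell death in suspension: %s\n",
              if (object@sensitiveDeath == "all_dead") "all dead at assay end"
              else sprintf("exponential, rate %.4g /h", object@deathRate)))
  invisible(NULL)
})

setMethod("show", "AssayProtocol", function(object) {
  cat("AssayProtocol\n")
  cat(sprintf("  %g h suspension assay, %g cells plated\n",
              object@durationHours, object@cellsPlated))
  cat(sprintf("  %g expansion generations, %g clones, resistance threshold %g\n",
              object@expansionGenerations, object@nClones,
              object@resistanceThreshold))
  invisible(NULL)
})

setMethod("show", "CloneSurvivalTable", function(object) {
  rec <- object@records
  cat(sprintf("CloneSurvivalTable: %d clones x %d passage(s) (%d records)\n",
              length(unique(rec$clone_id)), length(unique(rec$passage)),
              nrow(rec)))
  for (p in unique(rec$passage)) {
    s <- rec$survival_fraction[rec$passage == p]
    cat(sprintf("  %s: mean survival %.3f, CV %.3f (n = %d)\n",
                p, mean(s), cv(s), length(s)))
  }
  invisible(NULL)
})

setMethod("show", "ContinuumParams", function(object) {
  cat("ContinuumParams (heritable-continuum generator)")
  if (nzchar(object@name))
    cat(sprintf(" preset '%s' v%s", object@name, object@version))
  cat("\n")
  cat(sprintf("  latent growth rate ~ Normal(%.4g, %.4g) /h; rho = %.3g\n",
              object@muG, object@sigmaG, object@rho))
  cat(sprintf("  measurement CV %.3g; %g clones; passages %s; %g h assay\n",
              object@measCV, object@nClones,
              paste(object@passages, collapse = "/"),
              object@durationHours))
  invisible(NULL)
})

setMethod("show", "FluctuationSummary", function(object) {
  cat("FluctuationSummary\n")
  ps <- object@passageStats
  for (i in seq_len(nrow(ps)))
    cat(sprintf("  %s: n = %d, mean survival %.3f, CV %.3f (95%% CI %.3f-%.3f, +/- %.3f)\n",
                ps$passage[i], ps$n[i], ps$mean_survival[i], ps$cv[i],
                ps$ci_low[i], ps$ci_high[i], ps$half_width[i]))
  if (length(object@growthStats)) {
    g <- object@growthStats
    cat(sprintf("  growth rate: mean %.4g /h, SD %.4g, CV %.3g, %.0f%% negative, %d doubling-class\n",
                g$mean, g$sd, g$cv, 100 * g$frac_negative, g$n_doubling))
  }
  pp <- object@passagePairs
  for (i in seq_len(nrow(pp)))
    cat(sprintf("  %s vs %s: slope %.3f, r %.3f, p %.3g\n",
                pp$passage_a[i], pp$passage_b[i], pp$slope[i], pp$r[i],
                pp$p[i]))
  if (!is.na(object@foldRatio))
    cat(sprintf("  observed/predicted CV fold ratio: %.1f (predicted %.4g)\n",
                object@foldRatio, object@predictedCV))
  invisible(NULL)
})

setMethod("show", "SimResult", function(object) {
  cat(sprintf("SimResult: %d clones (seed %d)\n", length(object@survival),
              object@seed))
  cat(sprintf("  mean survival %.4f, CV %.4g, founders %d R / %d S\n",
              mean(object@survival), cv(object@survival),
              sum(object@founders == "R"), sum(object@founders == "S")))
  invisible(NULL)
})

setMethod("show", "ReversionCurve", function(object) {
  cat(sprintf("ReversionCurve%s: %d points, generations %g-%g\n",
              if (nzchar(object@label)) paste0(" [", object@label, "]") else "",
              length(object@generation), min(object@generation),
              max(object@generation)))
  invisible(NULL)
})
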