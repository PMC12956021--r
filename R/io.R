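## CSV schema: clone_id, passage, n_plated, n_live, survival_fraction
## (header mandatory, UTF-8, '.' decimal). A `percent` flag converts a
## percent-scale survival column to fractions on read.

#' Read a clone-survival table from CSV
#'
#' @param path path to a CSV file with the canonical header
#'   `clone_id, passage, n_plated, n_live, survival_fraction`
#'   (`survival_fraction` may be omitted when both counts are present).
#' @param percent if `TRUE`, the survival column is in percent and is
#'   divided by 100 on read.
#' @return A [CloneSurvivalTable-class].
#' @export
readCloneTable <- function(path, percent = FALSE) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        fileEncoding = "UTF-8")
  need <- setdiff(c("clone_id", "passage"), names(df))
  if (length(need))
    stop(sprintf("%s: missing required column(s): %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  if (is.null(df$survival_fraction) &&
      (is.null(df$n_plated) || is.null(df$n_live)))
    stop(sprintf(
      "%s: need survival_fraction or both n_plated and n_live", path),
      call. = FALSE)
  if (percent && !is.null(df$survival_fraction))
    df$survival_fraction <- df$survival_fraction / 100
  bad <- which(!is.na(df$survival_fraction) & df$survival_fraction < 0)
  if (length(bad))
    stop(sprintf("%s: negative survival_fraction in row(s) %s", path,
                 paste(utils::head(bad, 5), collapse = ", ")),
         call. = FALSE)
  CloneSurvivalTable(df)
}

#' Write a clone-survival table to CSV
#'
#' @param table a [CloneSurvivalTable-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeCloneTable <- function(table, path) {
  stopifnot(is(table, "CloneSurvivalTable"))
  utils::write.csv(table@records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

.modelAsList <- function(model) {
  list(k_on = model@kOn, k_off = model@kOff, Td_susp = model@TdSusp,
       Td_2D = model@Td2D, sensitive_death = model@sensitiveDeath,
       death_rate = model@deathRate,
       f_eq = equilibriumFraction(model),
       memory_generations = memoryGenerations(model))
}

.protocolAsList <- function(protocol) {
  list(duration_hours = protocol@durationHours,
       cells_plated = protocol@cellsPlated,
       expansion_generations = protocol@expansionGenerations,
       n_clones = protocol@nClones,
       resistance_threshold = protocol@resistanceThreshold)
}

#' Write a JSON run record for a simulation
#'
#' Embeds model, protocol and seed so the run can be reproduced exactly.
#'
#' @param sim a [SimResult-class], or a list with `model`, `protocol`,
#'   `seed` elements.
#' @param path output path (`.json`).
#' @return `path`, invisibly.
#' @export
writeRunRecord <- function(sim, path) {
  rec <- if (is(sim, "SimResult")) {
    list(model = .modelAsList(sim@model),
         protocol = .protocolAsList(sim@protocol),
         seed = sim@seed,
         n_clones = length(sim@survival),
         package_version = as.character(utils::packageVersion("cloneFluct")))
  } else sim
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Serialize a fluctuation summary to JSON
#'
#' Stable field names; percent renderings included alongside fractions.
#'
#' @param summary a [FluctuationSummary-class].
#' @param path output path, or `NULL` to return the list.
#' @return The report list (invisibly when written to `path`).
#' @export
writeSummaryJSON <- function(summary, path = NULL) {
  stopifnot(is(summary, "FluctuationSummary"))
  gs <- summary@growthStats
  rep_ <- list(
    schema_version = "1",
    passage_stats = summary@passageStats,
    growth_rates = if (length(gs))
      gs[setdiff(names(gs), "rates")] else NULL,
    passage_pairs = if (nrow(summary@passagePairs))
      summary@passagePairs else NULL,
    predicted_cv = summary@predictedCV,
    fold_ratio = summary@foldRatio,
    meta = c(summary@meta,
             list(package_version =
                    as.character(utils::packageVersion("cloneFluct")),
                  timestamp = format(Sys.time(), tz = "UTC",
                                     "%Y-%m-%dT%H:%M:%SZ")))
  )
  if (is.null(path)) return(rep_)
  jsonlite::write_json(rep_, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, dataframe = "rows", na = "null")
  invisible(rep_)
}
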