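## Interclonal fluctuation statistics. CV uses the sample SD (n - 1
## denominator); survival fractions above 1 (net growth) enter all
## statistics unclipped.

#' Coefficient of variation
#'
#' Sample standard deviation (n - 1 denominator) divided by the mean.
#'
#' @param x numeric vector, length >= 2.
#' @return `sd(x) / mean(x)`; `NA` with a warning when the mean is zero.
#' @examples
#' cv(c(0.8, 0.9, 1.0))  # 0.111
#' @export
cv <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) stop("cv needs at least 2 values", call. = FALSE)
  m <- mean(x)
  if (m == 0) {
    warning("mean is zero: CV undefined", call. = FALSE)
    return(NA_real_)
  }
  stats::sd(x) / m
}

## column-wise sd of a matrix without extra dependencies
.colSds <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  sqrt(pmax(0, (colSums(m^2) - n * mu^2) / (n - 1)))
}

#' Bootstrap confidence interval for the CV
#'
#' Resamples clones with replacement and returns a percentile (default)
#' or BCa interval for the interclonal coefficient of variation. The
#' half-width `(ci_high - ci_low) / 2` matches the "+/-" reporting style
#' used for fluctuation CVs.
#'
#' @param x numeric vector of per-clone survival fractions (length >= 2).
#' @param nBoot number of bootstrap resamples (>= 1000 recommended).
#' @param alpha two-sided error level (default 0.05 for a 95% interval).
#' @param seed integer seed (required for reproducibility).
#' @param method `"percentile"` (default) or `"bca"`
#'   (bias-corrected and accelerated, jackknife acceleration).
#' @return Named numeric vector `c(cv, ci_low, ci_high, half_width)`.
#' @examples
#' set.seed(1); x <- rlnorm(60, log(0.9), 0.28)
#' bootstrapCvCI(x, nBoot = 2000, seed = 7)
#' @export
bootstrapCvCI <- function(x, nBoot = 2000, alpha = 0.05, seed,
                          method = c("percentile", "bca")) {
  method <- match.arg(method)
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) stop("need at least 2 values", call. = FALSE)
  if (missing(seed) || is.null(seed))
    stop("bootstrapCvCI requires an integer seed", call. = FALSE)
  est <- cv(x)
  if (stats::sd(x) == 0) {
    warning("degenerate (constant) data: zero-width interval", call. = FALSE)
    return(c(cv = est, ci_low = est, ci_high = est, half_width = 0))
  }
  .localSeed(seed)
  samp <- matrix(sample(x, n * nBoot, replace = TRUE), nrow = n)
  mu <- colMeans(samp)
  cvs <- .colSds(samp) / mu
  cvs <- cvs[is.finite(cvs)]
  if (method == "percentile") {
    qs <- stats::quantile(cvs, c(alpha / 2, 1 - alpha / 2), names = FALSE,
                          type = 7)
  } else {
    z0 <- stats::qnorm(mean(cvs < est))
    jack <- vapply(seq_len(n), function(i) cv(x[-i]), numeric(1))
    jm <- mean(jack)
    a <- sum((jm - jack)^3) / (6 * sum((jm - jack)^2)^1.5)
    zq <- stats::qnorm(c(alpha / 2, 1 - alpha / 2))
    adj <- stats::pnorm(z0 + (z0 + zq) / (1 - a * (z0 + zq)))
    qs <- stats::quantile(cvs, adj, names = FALSE, type = 7)
  }
  c(cv = est, ci_low = qs[1], ci_high = qs[2],
    half_width = (qs[2] - qs[1]) / 2)
}

#' Inter-passage regression of clonal survival
#'
#' Ordinary least-squares regression of one passage's per-clone survival
#' on another's, with the Pearson correlation and its two-sided p value.
#' A non-significant relation indicates no fixed (heritable over the
#' inter-passage interval) clonal survival propensity.
#'
#' @param survA,survB paired per-clone survival vectors (same clones, same
#'   order), length >= 3.
#' @return Named numeric vector
#'   `c(slope, intercept, r, p, n)`.
#' @examples
#' passageCorrelation(c(0, 1, 0.5), c(1, 0, 0.5))  # r = -1
#' @export
passageCorrelation <- function(survA, survB) {
  keep <- !is.na(survA) & !is.na(survB)
  survA <- survA[keep]; survB <- survB[keep]
  n <- length(survA)
  if (n < 3 || length(survB) != n)
    stop("need >= 3 paired observations", call. = FALSE)
  if (stats::sd(survA) == 0 || stats::sd(survB) == 0) {
    warning("zero variance in one passage: correlation undefined",
            call. = FALSE)
    return(c(slope = NA_real_, intercept = NA_real_, r = NA_real_,
             p = NA_real_, n = n))
  }
  fit <- stats::lm(survB ~ survA)
  ct <- stats::cor.test(survA, survB, method = "pearson",
                        alternative = "two.sided")
  c(slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r = unname(ct$estimate), p = ct$p.value, n = n)
}

#' Growth-rate summary of a clone-survival table
#'
#' Computes the effective suspension growth rate `log(Nt/N0)/T` per clone
#' (from counts when present, else from the survival fraction) and
#' summarises the cohort: mean, SD, CV (|SD/mean|), fractions with
#' negative/positive rates, and the number in the "doubling class"
#' (rate at least `log(2)/doublingHours`). Clones with zero survivors
#' (rate `-Inf`) are excluded from the moments and counted separately.
#'
#' @param table a [CloneSurvivalTable-class] or data frame with the
#'   canonical columns.
#' @param T assay duration in hours (default 24).
#' @param passage optional passage label to restrict to (default: first
#'   passage in the table).
#' @param doublingHours doubling time defining the fast "doubling class"
#'   (default 45 h).
#' @return A list with elements `rates`, `mean`, `sd`, `cv`,
#'   `frac_negative`, `frac_positive`, `frac_zero`, `n_doubling`,
#'   `n_all_dead`, `n`.
#' @examples
#' tab <- CloneSurvivalTable(clone_id = c("a", "b"), passage = "P1",
#'                           n_plated = 1000, n_live = c(500, 2000))
#' growthRateSummary(tab)$mean  # 0: symmetric halving/doubling
#' @export
growthRateSummary <- function(table, T = 24, passage = NULL,
                              doublingHours = 45) {
  rec <- if (is(table, "CloneSurvivalTable")) table@records else
    as.data.frame(table)
  if (is.null(passage)) passage <- rec$passage[1]
  rec <- rec[rec$passage == passage, ]
  s <- rec$survival_fraction
  rates <- ifelse(s == 0, -Inf, log(pmax(s, 0)) / T)
  names(rates) <- rec$clone_id
  finite <- is.finite(rates)
  fr <- rates[finite]
  m <- mean(fr)
  list(rates = rates,
       mean = m,
       sd = stats::sd(fr),
       cv = if (m != 0) abs(stats::sd(fr) / m) else NA_real_,
       frac_negative = mean(fr < 0),
       frac_positive = mean(fr > 0),
       frac_zero = mean(fr == 0),
       n_doubling = sum(fr >= log(2) / doublingHours),
       n_all_dead = sum(!finite),
       n = length(rates))
}

#' Fold ratio of observed to predicted fluctuation
#'
#' @param observedCV observed interclonal CV.
#' @param predictedCV model-predicted CV (> 0; a zero prediction gives an
#'   infinite ratio with a warning).
#' @return `observedCV / predictedCV`.
#' @examples
#' comparePredictedObserved(0.30, 0.01)  # 30
#' @export
comparePredictedObserved <- function(observedCV, predictedCV) {
  if (any(predictedCV < 0)) stop("predictedCV must be >= 0", call. = FALSE)
  if (any(predictedCV == 0))
    warning("predicted CV is zero: fold ratio infinite", call. = FALSE)
  observedCV / predictedCV
}

#' @describeIn analyzeTable full fluctuation summary of a table: per-passage
#'   CV with bootstrap CI, growth-rate statistics (when counts allow),
#'   inter-passage regressions, and the observed/predicted fold ratio when
#'   a model prediction is supplied.
#' @param nBoot bootstrap resamples for the CV confidence intervals.
#' @param alpha two-sided error level of the intervals.
#' @param seed integer seed for the bootstrap.
#' @param T assay duration in hours.
#' @param predictedCV optional model-predicted CV for fold-ratio
#'   comparison (`NA` to skip).
#' @param bootMethod `"percentile"` or `"bca"`.
#' @export
setMethod("analyzeTable", "CloneSurvivalTable",
  function(object, nBoot = 2000, alpha = 0.05, seed = 1, T = 24,
           predictedCV = NA_real_, bootMethod = "percentile") {
    rec <- object@records
    pls <- unique(rec$passage)
    .localSeed(seed)
    bootSeeds <- sample.int(2^31 - 1, length(pls))
    ps <- do.call(rbind, lapply(seq_along(pls), function(i) {
      s <- rec$survival_fraction[rec$passage == pls[i]]
      ci <- suppressWarnings(
        bootstrapCvCI(s, nBoot = nBoot, alpha = alpha, seed = bootSeeds[i],
                      method = bootMethod))
      data.frame(passage = pls[i], n = length(s), mean_survival = mean(s),
                 cv = ci[["cv"]], ci_low = ci[["ci_low"]],
                 ci_high = ci[["ci_high"]], half_width = ci[["half_width"]])
    }))
    gs <- growthRateSummary(object, T = T, passage = pls[1])
    pairs <- data.frame()
    if (length(pls) > 1) {
      first <- pls[1]
      wide <- split(rec, rec$passage)
      for (other in pls[-1]) {
        a <- wide[[first]]; b <- wide[[other]]
        common <- intersect(a$clone_id, b$clone_id)
        if (length(common) >= 3) {
          pc <- suppressWarnings(passageCorrelation(
            a$survival_fraction[match(common, a$clone_id)],
            b$survival_fraction[match(common, b$clone_id)]))
          pairs <- rbind(pairs, data.frame(
            passage_a = first, passage_b = other, n = pc[["n"]],
            slope = pc[["slope"]], intercept = pc[["intercept"]],
            r = pc[["r"]], p = pc[["p"]]))
        }
      }
    }
    fold <- if (is.na(predictedCV)) NA_real_ else
      comparePredictedObserved(ps$cv[1], predictedCV)
    new("FluctuationSummary", passageStats = ps, growthStats = gs,
        passagePairs = pairs, predictedCV = as.numeric(predictedCV),
        foldRatio = fold,
        meta = list(seed = seed, n_boot = nBoot, alpha = alpha,
                    boot_method = bootMethod, T_hours = T))
  })

#' @describeIn analyzeTable data frames are coerced to
#'   [CloneSurvivalTable-class] first.
#' @export
setMethod("analyzeTable", "data.frame", function(object, ...) {
  analyzeTable(CloneSurvivalTable(object), ...)
})
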