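# Shared fixtures: the default study parameterisation and small instances.

defaultModel <- function(Td = 100, S = 0.9, M = 10.5) {
  switchingModelFromMemory(M, resistantFractionFromSurvival(S, 24, Td),
                           TdSusp = Td)
}

smallProtocol <- function(G = 8, N0 = 200, nClones = 30) {
  AssayProtocol(expansionGenerations = G, cellsPlated = N0,
                nClones = nClones)
}

makeTable <- function(surv, passage = "P1", nPlated = 1000) {
  CloneSurvivalTable(
    clone_id = sprintf("c%02d", seq_along(surv)), passage = passage,
    n_plated = nPlated, n_live = round(surv * nPlated),
    survival_fraction = round(surv * nPlated) / nPlated)
}

# closed-form population CV of the continuum generator's survival
continuumTrueCV <- function(params) {
  v <- (params@sigmaG * params@durationHours)^2 + log(1 + params@measCV^2)
  sqrt(exp(v) - 1)
}
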