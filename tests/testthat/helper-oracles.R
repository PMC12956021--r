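# Independent oracles, kept free of the package's simulation code paths.

# Exact distribution of the number of resistant cells after G generations
# of deterministic doubling with independent per-daughter switching,
# starting from one founder that is resistant with probability pR0.
# Returns the pmf over 0:(2^G) resistant cells.
oracleExpansionPmf <- function(kOn, kOff, G, pR0) {
  pmf <- c(1 - pR0, pR0)  # over r = 0, 1 at generation 0
  tot <- 1
  for (g in seq_len(G)) {
    newTot <- 2 * tot
    nxt <- numeric(newTot + 1)
    for (r in 0:tot) {
      if (pmf[r + 1] == 0) next
      # resistant daughters = Binom(2(tot-r), kOn) + Binom(2r, 1-kOff)
      pa <- dbinom(0:(2 * (tot - r)), 2 * (tot - r), kOn)
      pb <- dbinom(0:(2 * r), 2 * r, 1 - kOff)
      conv <- convolve(pa, rev(pb), type = "open")
      nxt[seq_along(conv)] <- nxt[seq_along(conv)] + pmf[r + 1] * conv
    }
    pmf <- nxt
    tot <- newTot
  }
  pmf
}

# Exact population CV of the survival fraction for a small instance with
# hypergeometric subsampling of N0 cells and a deterministic assay
# (sensitive all dead, resistant multiplied by e^(gamma T)).
oracleSurvivalCV <- function(kOn, kOff, G, N0, Td, T = 24,
                             pR0 = kOn / (kOn + kOff)) {
  tot <- 2^G
  stopifnot(N0 <= tot)
  pmfR <- oracleExpansionPmf(kOn, kOff, G, pR0)
  boost <- exp(log(2) / Td * T)
  # P(rr resistant among the N0 plated)
  pRR <- numeric(N0 + 1)
  for (r in 0:tot) {
    if (pmfR[r + 1] == 0) next
    rr <- 0:N0
    pRR <- pRR + pmfR[r + 1] * dhyper(rr, r, tot - r, N0)
  }
  surv <- (0:N0) * boost / N0
  m1 <- sum(pRR * surv)
  m2 <- sum(pRR * surv^2)
  sqrt(max(0, m2 - m1^2)) / m1
}

# Lineage-state Markov recursion, written independently of the package.
oracleResistantProb <- function(kOn, kOff, G, m0) {
  m <- m0
  for (g in seq_len(G)) m <- m * (1 - kOff) + (1 - m) * kOn
  m
}
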