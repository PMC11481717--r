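# small simulated bundle shared across tests
tinyBundle <- function(seed = 1, nSamples = 80, nProbes = 400,
                       nSpikedProbes = 5, spikeDeltaBeta = 0.05,
                       nSpikedRegions = 1, regionNProbes = 5,
                       regionDeltaBeta = 0.08, ...) {
  simulateLifemethBundle(simulationConfig(
    nSamples = nSamples, nProbes = nProbes,
    nSpikedProbes = nSpikedProbes, spikeDeltaBeta = spikeDeltaBeta,
    nSpikedRegions = nSpikedRegions, regionNProbes = regionNProbes,
    regionDeltaBeta = regionDeltaBeta, seed = seed, ...))
}

# quadratic-time Benjamini-Hochberg oracle: q_i = min over p_j >= p_i of
# p_j * m / rank_j
bruteForceBH <- function(p) {
  m <- length(p)
  r <- rank(p, ties.method = "min")
  vapply(seq_len(m), function(i) {
    cand <- vapply(which(p >= p[i]), function(j) {
      rj <- sum(p <= p[j])
      p[j] * m / rj
    }, numeric(1))
    min(1, cand)
  }, numeric(1))
}

# direct normal-equations least squares for one response
normalEquationsFit <- function(X, y) {
  xtx <- solve(t(X) %*% X)
  coefs <- xtx %*% t(X) %*% y
  res <- y - X %*% coefs
  df <- nrow(X) - ncol(X)
  s2 <- sum(res^2) / df
  list(coef = drop(coefs), se = sqrt(diag(xtx) * s2), sigma2 = s2)
}
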