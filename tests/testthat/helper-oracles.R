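# Independent brute-force oracles used to check the statistics layer, and
# small fixture builders shared across test files.

# Exact two-sided Mann-Whitney p by enumeration of all rank assignments.
bruteMannWhitneyP <- function(x, y) {
  nx <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  uObs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(length(pooled), nx)
  us <- apply(combs, 2, function(ii) sum(r[ii]) - nx * (nx + 1) / 2)
  mu <- nx * length(y) / 2
  mean(abs(us - mu) >= abs(uObs - mu) - 1e-12)
}

# Spearman rho via the explicit rank-and-correlate formula.
bruteSpearmanRho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Exact two-sided Spearman p by full permutation enumeration (n <= 7).
bruteSpearmanP <- function(x, y) {
  n <- length(x)
  stopifnot(n <= 7)
  perms <- permuteAll(seq_len(n))
  rhoObs <- bruteSpearmanRho(x, y)
  rhos <- apply(perms, 1, function(p) bruteSpearmanRho(x, y[p]))
  mean(abs(rhos) >= abs(rhoObs) - 1e-12)
}

permuteAll <- function(v) {
  n <- length(v)
  if (n == 1L) return(matrix(v, 1))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- permuteAll(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

# OLS slope/intercept from the closed-form normal equations.
bruteOlsCoef <- function(X, y) {
  X1 <- cbind(1, X)
  solve(t(X1) %*% X1, t(X1) %*% y)[, 1]
}

# A small straight-tube phantom shared by several tests.
straightPhantom <- function(sigmaLevel = 0.1, venc = 1.5, snr = Inf,
                            nTimeframes = 2L, seed = 42L, ...) {
  generatePhantom(phantomSpec("straight", list(length = 60),
                              lumenRadius = 10, sigmaLevel = sigmaLevel,
                              venc = venc, snr = snr,
                              nTimeframes = nTimeframes, seed = seed, ...))
}

# Synthetic straight centerline along +z with given landmark positions.
straightCenterline <- function(length = 600, n = 601L) {
  z <- seq(0, length, length.out = n)
  new("Centerline", points = cbind(0, 0, z), s = z)
}
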