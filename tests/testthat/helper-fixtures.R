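# shared fixtures: small networks, coarse frequency grids and fast settings
# used by the heavier recovery suites

chainSpec <- function() {
  nodes <- data.frame(label = c("A", "B"), x = c(0, 10), y = 0, z = 0,
                      level = c(1L, 2L), stringsAsFactors = FALSE)
  edges <- data.frame(from = c("A", "B"), to = c("B", "A"),
                      type = c("forward", "backward"),
                      stringsAsFactors = FALSE)
  buildNetwork(list(nodes = nodes, edges = edges))
}

# coarse grid for recovery simulations (scaled-down problem size)
fastFreqs <- function() seq(4, 44, by = 4)

chainGain <- function(seed = 7L) randomGain(2, 2, seed)

# quick linear-Gaussian toy problem for engine/PEB oracles
linearToy <- function(n = 12, p = 3, seed = 1, sigma = 0.5) {
  set.seed(seed)
  A <- matrix(rnorm(n * p), n, p)
  theta <- rnorm(p)
  y <- as.numeric(A %*% theta) + rnorm(n, 0, sigma)
  list(A = A, theta = theta, y = y, sigma = sigma)
}

# closed-form Bayesian linear regression posterior and log evidence
conjugateLinear <- function(A, y, mu0, S0, sigma) {
  P0 <- solve(S0)
  prec <- 1 / sigma^2
  P <- prec * crossprod(A) + P0
  C <- solve(P)
  m <- C %*% (prec * crossprod(A, y) + P0 %*% mu0)
  Sy <- sigma^2 * diag(length(y)) + A %*% S0 %*% t(A)
  r <- y - as.numeric(A %*% mu0)
  logev <- -0.5 * (length(y) * log(2 * pi) +
                     determinant(Sy, logarithm = TRUE)$modulus +
                     sum(r * solve(Sy, r)))
  list(mean = as.numeric(m), cov = C, logev = as.numeric(logev))
}

# belief-level synthetic windows: posteriors drawn around X beta* with given
# posterior sd (bypasses the neural-mass inversion for second-level tests)
beliefWindows <- function(betaStar, X, sdPost = 0.1, sdNoise = 0.05,
                          seed = 1) {
  W <- nrow(X)
  B <- nrow(betaStar)
  traj <- X %*% t(betaStar)
  set.seed(seed)
  lapply(seq_len(W), function(w) {
    m <- traj[w, ] + rnorm(B, 0, sdNoise) +
      rnorm(B, 0, sdPost) # estimation error at the stated posterior sd
    gaussianBelief(m, diag(sdPost^2, B))
  })
}
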