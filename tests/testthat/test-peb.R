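test_that("design matrix has orthonormal DCT columns and a decaying column", {
  X <- buildDesign(60)
  M <- designMatrix(X)
  expect_equal(dim(M), c(60, 5))
  expect_equal(X@labels, c("constant", "dct2", "dct3", "dct4", "decay"))
  expect_equal(unname(M[, 1]), rep(1, 60))
  D <- M[, 2:4]
  G <- crossprod(D)
  expect_equal(diag(G), rep(1, 3), tolerance = 1e-12, ignore_attr = TRUE)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-10)
  expect_equal(unname(M[1, 5]), 1) # exp(0)
  expect_true(all(diff(M[, 5]) < 0))
  expect_equal(unname(M[17, 5]), exp(-1)) # n = 16 at the decay constant
  expect_error(buildDesign(1), "at least")
})

test_that("identity reduction returns exactly zero evidence change", {
  post <- gaussianBelief(c(0.3, -0.2), matrix(c(0.02, 0.005, 0.005, 0.03), 2))
  prior <- gaussianBelief(c(0, 0), diag(1 / 16, 2))
  out <- bayesianModelReduction(post, prior, prior)
  expect_identical(out$dF, 0)
  expect_equal(beliefMean(out$posterior), beliefMean(post))
})

test_that("model reduction matches directly computed log evidences", {
  # linear-Gaussian problem: invert under full and reduced priors separately
  # and compare the evidence difference with the analytic reduction
  for (seed in 1:4) {
    toy <- linearToy(n = 10, p = 3, seed = seed, sigma = 0.3)
    full <- conjugateLinear(toy$A, toy$y, rep(0, 3), diag(0.4, 3), toy$sigma)
    rC <- diag(c(0.4, 0.05, 0.4)); rE <- c(0, 0.1, 0)
    red <- conjugateLinear(toy$A, toy$y, rE, rC, toy$sigma)
    got <- bayesianModelReduction(
      gaussianBelief(full$mean, full$cov),
      gaussianBelief(rep(0, 3), diag(0.4, 3)),
      gaussianBelief(rE, rC))
    expect_equal(got$dF, red$logev - full$logev, tolerance = 1e-6)
    expect_equal(beliefMean(got$posterior), red$mean, tolerance = 1e-6)
    expect_equal(beliefCov(got$posterior), red$cov, tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("an infinitely tight reduced prior pins the posterior to its mean", {
  post <- gaussianBelief(c(0.4, -0.3), diag(0.02, 2))
  prior <- gaussianBelief(c(0, 0), diag(1 / 16, 2))
  rC <- diag(c(1e-12, 1 / 16))
  out <- bayesianModelReduction(post, prior, gaussianBelief(c(0, 0), rC))
  expect_lt(abs(beliefMean(out$posterior)[1]), 1e-6)
})

test_that("consensus windows drive the PEB mean to the shared value", {
  # degenerate regime: many precisely estimated identical windows
  B <- 1
  m <- 0.3
  W <- 400
  beliefs <- replicate(W, gaussianBelief(m, diag(1e-6, B)), simplify = FALSE)
  prior <- gaussianBelief(0, diag(1 / 16, B))
  peb <- pebEstimate(beliefs, prior, matrix(1, W, 1), field = 1)
  expect_equal(unname(beliefMean(posterior(peb))), m, tolerance = 1e-3)
})

test_that("PEB matches the stacked joint-Gaussian oracle on a linear toy", {
  # two-level linear model, B = 2, W = 8: direct one-shot inversion of the
  # joint Gaussian at the estimated random-effects precision
  set.seed(31)
  B <- 2; W <- 8; P <- 2
  X <- cbind(1, seq(-1, 1, length.out = W))
  betaStar <- c(0.3, -0.2, 0.5, 0.1) # stacked regressor-major
  Sw <- diag(0.05, B) # random-effects covariance used for generation
  prior <- gaussianBelief(rep(0, B), diag(1 / 16, B))
  theta <- matrix(0, W, B)
  beliefs <- vector("list", W)
  Cq <- diag(0.01, B)
  for (w in seq_len(W)) {
    eta <- as.numeric(kronecker(t(X[w, ]), diag(B)) %*% betaStar)
    theta[w, ] <- eta + rnorm(B, 0, sqrt(0.05))
    beliefs[[w]] <- gaussianBelief(theta[w, ] + rnorm(B, 0, 0.05), Cq)
  }
  peb <- pebEstimate(beliefs, prior, X, field = seq_len(B))
  # oracle: first-level "data" are the window posterior means with effective
  # observation covariance Cq; theta integrated out analytically
  Pg <- peb@Q0 + exp(-peb@gamma) * peb@Q1
  Sg <- solve(Pg)
  Xi <- kronecker(diag(P), beliefCov(prior))
  XB <- kronecker(X, diag(B))
  # window posterior mean m_i ~ N((x_i' x I) beta, Cq_eff + Sg) where the
  # likelihood replaces the first-level prior via the reduction identity
  Pq <- solve(Cq)
  Pp <- solve(beliefCov(prior))
  # likelihood of theta_i from each window: N(mu_i, Ci) with
  # Ci = (Pq - Pp)^-1, mu_i = Ci (Pq m_i - Pp mu0)
  Ci <- solve(Pq - Pp)
  mu <- t(vapply(beliefs, function(b)
    as.numeric(Ci %*% (Pq %*% beliefMean(b))), numeric(B)))
  Sy <- kronecker(diag(W), Ci + Sg)
  H <- solve(Xi) + t(XB) %*% solve(Sy, XB)
  bOracle <- solve(H, t(XB) %*% solve(Sy, as.numeric(t(mu))))
  expect_equal(unname(beliefMean(posterior(peb))), as.numeric(bOracle),
               tolerance = 1e-4)
  expect_equal(unname(beliefCov(posterior(peb))), unname(solve(H)),
               tolerance = 1e-4)
})

test_that("a negative decay effect is recovered in sign across seeds", {
  X <- buildDesign(20)
  ok <- 0
  for (seed in 1:20) {
    betaStar <- matrix(0, 1, 5)
    betaStar[1, 5] <- -0.5
    beliefs <- beliefWindows(betaStar, designMatrix(X), sdPost = 0.1,
                             sdNoise = 0.05, seed = seed)
    prior <- gaussianBelief(0, diag(1 / 16, 1))
    peb <- pebEstimate(beliefs, prior, X, field = 1)
    if (beliefMean(posterior(peb))[5] < 0) ok <- ok + 1
  }
  expect_gte(ok, 18)
})

test_that("the reduced model space enumerates every basis combination", {
  inc <- enumerateReducedModels(4)
  expect_equal(dim(inc), c(16, 4))
  expect_equal(sum(rowSums(inc) == 0), 1)
  expect_equal(unname(which(rowSums(inc) == 0)), 16L)
  expect_equal(unname(inc[1, ]), rep(1L, 4)) # model 1 carries all bases
  expect_false(any(duplicated(inc)))
  expect_equal(nrow(enumerateReducedModels(0)), 1)
})

test_that("fixed-effects pooling and probabilities behave like a softmax", {
  E <- rbind(c(0, 3), c(0, 3))
  ms <- bmcOverSubjects(E)
  expect_equal(pooledLogEvidence(ms), c(0, 6), ignore_attr = TRUE)
  expect_equal(modelProbabilities(ms)[2], 1 / (1 + exp(-6)),
               ignore_attr = TRUE)
  one <- bmcOverSubjects(E[1, , drop = FALSE])
  expect_equal(pooledLogEvidence(one), E[1, ], ignore_attr = TRUE)
  shifted <- bmcOverSubjects(E + c(5, 0)) # constant added to subject 1's row
  expect_equal(modelProbabilities(shifted), modelProbabilities(ms))
  expect_error(bmcOverSubjects(rbind(c(0, Inf))), "finite")
})

test_that("model-space scoring singles out the generating regressor", {
  X <- buildDesign(30)
  betaStar <- matrix(c(0.2, 0, 0, 0, -0.4), 1)
  beliefs <- beliefWindows(betaStar, designMatrix(X), sdPost = 0.08,
                           sdNoise = 0.05, seed = 2)
  prior <- gaussianBelief(0, diag(1 / 16, 1))
  peb <- pebEstimate(beliefs, prior, X, field = 1)
  inc <- enumerateReducedModels(4)
  le <- scoreModelSpace(peb, inc)
  expect_length(le, 16)
  expect_equal(le[1], 0, tolerance = 1e-9) # model 1 is the full model
  # the winner should include the decay regressor
  expect_equal(unname(inc[which.max(le), "decay"]), 1L)
})
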