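# build a group-level PEBResult directly from subject-level beliefs (the
# second-level machinery is exercised end to end elsewhere)
groupPebFromBeliefs <- function(betaStar, nSubjects, sdSubj = 0.05,
                                sdPost = 0.03, seed = 1, priorVar = 1 / 16) {
  d <- length(betaStar)
  set.seed(seed)
  beliefs <- lapply(seq_len(nSubjects), function(s)
    gaussianBelief(betaStar + rnorm(d, 0, sdSubj), diag(sdPost^2, d)))
  prior <- gaussianBelief(rep(0, d), diag(priorVar, d))
  pebEstimate(beliefs, prior, matrix(1, nSubjects, 1), field = seq_len(d))
}

test_that("the final exhaustive sweep averages 2^8 = 256 models", {
  gp <- groupPebFromBeliefs(c(0.4, 0, -0.3, 0, 0.2, 0, 0, 0, 0.1, 0), 10)
  bma <- greedySearchBma(gp, finalSweepSize = 8)
  expect_equal(nrow(bma@models), 256)
  expect_equal(length(bma@modelProbs), 256)
  expect_equal(sum(bma@modelProbs), 1, tolerance = 1e-9)
})

test_that("null parameters are pruned or uncertain; strong effects survive", {
  nullBelow <- 0
  strongAbove <- 0
  signOk <- 0
  for (seed in 1:20) {
    # parameter 2 has no true effect; parameter 1 is overwhelming
    gp <- groupPebFromBeliefs(c(1, 0, 0.3), 12, sdSubj = 0.02,
                              sdPost = 0.02, seed = seed)
    bma <- greedySearchBma(gp, finalSweepSize = 3)
    pp <- posteriorProb(bma)
    if (pp[2] < 0.95) nullBelow <- nullBelow + 1
    if (pp[1] > 0.95) strongAbove <- strongAbove + 1
    if (bma@mean[1] > 0) signOk <- signOk + 1
  }
  expect_gte(nullBelow, 18)
  expect_gte(strongAbove, 18)
  expect_gte(signOk, 18)
})

test_that("parameters pruned from every averaged model have mean zero", {
  gp <- groupPebFromBeliefs(c(0.8, 0, 0, 0, 0, 0, 0, 0, 0, 0.6), 10,
                            sdSubj = 0.02, sdPost = 0.02)
  bma <- greedySearchBma(gp, finalSweepSize = 4)
  off <- colSums(bma@models) == 0
  if (any(off)) expect_true(all(bma@mean[off] == 0))
  expect_true(all(bma@pp >= 0 & bma@pp <= 1))
})

test_that("retention probability is invariant to model-set ordering", {
  gp <- groupPebFromBeliefs(c(0.5, 0.05, -0.2), 8)
  bma <- greedySearchBma(gp, finalSweepSize = 3)
  set.seed(4)
  perm <- sample(nrow(bma@models))
  ppPerm <- colSums(bma@models[perm, ] * bma@modelProbs[perm])
  expect_equal(unname(ppPerm), unname(bma@pp), tolerance = 1e-12)
})

test_that("group PEB pools identical subjects into a tighter posterior", {
  d <- 3
  bel <- gaussianBelief(c(0.3, -0.1, 0.2), diag(0.02^2, d))
  prior <- gaussianBelief(rep(0, d), diag(1 / 16, d))
  subj <- lapply(1:6, function(s) {
    pebEstimate(list(bel, bel, bel, bel), prior,
                matrix(1, 4, 1), field = seq_len(d))
  })
  gp <- groupPeb(subj)
  sMean <- beliefMean(posterior(subj[[1]]))
  gMean <- beliefMean(posterior(gp))
  expect_equal(unname(gMean), unname(sMean), tolerance = 0.05)
  expect_lt(max(diag(beliefCov(posterior(gp)))),
            min(diag(beliefCov(posterior(subj[[1]])))) + 1e-12)
  # single subject: the group mean tracks that subject's pattern (up to the
  # irreducible empirical-Bayes shrinkage of a one-member group)
  g1 <- groupPeb(subj[1])
  gm <- beliefMean(posterior(g1))
  expect_gt(cor(gm, sMean), 0.999)
  expect_true(all(sign(gm) == sign(sMean)))
})

test_that("group recovery separates conserved decay from subject DCT", {
  # 12 subjects share decay -0.4 on the forward connection; DCT effects are
  # subject-specific with zero group mean
  X <- buildDesign(20)
  set.seed(77)
  subj <- lapply(1:12, function(s) {
    betaS <- matrix(0, 1, 5)
    betaS[1, 5] <- -0.4
    betaS[1, 2:4] <- rnorm(3, 0, 0.2)
    beliefs <- beliefWindows(betaS, designMatrix(X), sdPost = 0.08,
                             sdNoise = 0.05, seed = 100 + s)
    pebEstimate(beliefs, gaussianBelief(0, diag(1 / 16, 1)), X, field = 1)
  })
  gp <- groupPeb(subj)
  m <- beliefMean(posterior(gp))
  s <- sqrt(diag(beliefCov(posterior(gp))))
  # decay coefficient: credible interval excludes 0, negative
  expect_lt(m[5] + 1.645 * s[5], 0)
  # after pruning/averaging: decay retained with confidence, DCTs not
  bma <- greedySearchBma(gp, 5)
  pp <- posteriorProb(bma)
  expect_gt(pp[5], 0.95)
  expect_lt(bma@mean[5], 0)
  expect_true(all(pp[2:4] < 0.95))
})

test_that("trajectories and credible bands follow the posterior algebra", {
  X <- buildDesign(30)
  B <- 2; P <- 5
  mu <- rep(0, B * P); mu[1:B] <- c(0.25, -0.1)
  Cb <- diag(0.01, B * P)
  tr <- predictTrajectories(gaussianBelief(mu, Cb), X)
  # constant-only effect: flat at the constant
  expect_equal(tr$trajectory[, 1], rep(0.25, 30), tolerance = 1e-12,
               ignore_attr = TRUE)
  # negative decay with no DCT: strictly increasing trajectory
  mu2 <- rep(0, B * P); mu2[(P - 1) * B + 1] <- -0.5
  tr2 <- predictTrajectories(gaussianBelief(mu2, Cb), X)
  expect_true(all(diff(tr2$trajectory[, 1]) > 0))
  # band half-width equals 1.645 sqrt(x' Sigma x) per window
  set.seed(9)
  A <- matrix(rnorm((B * P)^2), B * P)
  Cb3 <- crossprod(A) / (B * P)
  tr3 <- predictTrajectories(gaussianBelief(mu, Cb3), X)
  Xm <- designMatrix(X)
  for (w in c(1, 11, 30)) {
    i1 <- 1 + B * (0:(P - 1))
    half <- qnorm(0.95) * sqrt(Xm[w, ] %*% Cb3[i1, i1] %*% Xm[w, ])
    expect_equal(tr3$upper[w, 1] - tr3$trajectory[w, 1], as.numeric(half),
                 tolerance = 1e-6)
  }
})
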