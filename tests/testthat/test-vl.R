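test_that("the engine reproduces the conjugate linear-Gaussian posterior", {
  for (seed in 1:5) {
    toy <- linearToy(n = 15, p = 4, seed = seed, sigma = 0.4)
    mu0 <- rep(0.1, 4)
    S0 <- diag(0.5, 4)
    prior <- gaussianBelief(mu0, S0)
    # noise log-precision pinned at its known value by a tight hyperprior
    lam <- log(1 / toy$sigma^2)
    fit <- variationalLaplace(function(th) as.numeric(toy$A %*% th), prior,
                              toy$y,
                              noiseHyperprior = gaussianBelief(lam, 1e-10))
    oracle <- conjugateLinear(toy$A, toy$y, mu0, S0, toy$sigma)
    expect_equal(beliefMean(fit$posterior), oracle$mean, tolerance = 1e-6)
    expect_equal(beliefCov(fit$posterior), oracle$cov, tolerance = 1e-6,
                 ignore_attr = TRUE)
    # Laplace free energy is the exact log evidence for linear models
    expect_equal(fit$F, oracle$logev, tolerance = 1e-4)
    # no information loss: posterior covariance below prior covariance
    ev <- eigen(S0 - beliefCov(fit$posterior), symmetric = TRUE,
                only.values = TRUE)$values
    expect_gt(min(ev), -1e-10)
  }
})

test_that("an uninformative likelihood returns the prior", {
  toy <- linearToy(seed = 9)
  prior <- gaussianBelief(c(0.2, -0.1, 0.4), diag(0.3, 3))
  fit <- variationalLaplace(function(th) as.numeric(toy$A %*% th), prior,
                            toy$y,
                            noiseHyperprior = gaussianBelief(-30, 1e-12))
  expect_equal(beliefMean(fit$posterior), prior@mean, tolerance = 1e-6)
  expect_equal(beliefCov(fit$posterior), prior@cov, tolerance = 1e-5,
               ignore_attr = TRUE)
})

test_that("accepted free energies are non-decreasing, complexity non-negative", {
  # mildly nonlinear forward map with jointly estimated noise precision
  set.seed(21)
  A <- matrix(rnorm(40 * 3), 40, 3)
  fwd <- function(th) as.numeric(A %*% th + 0.2 * (A %*% th)^2)
  truth <- c(0.5, -0.3, 0.2)
  y <- fwd(truth) + rnorm(40, 0, 0.2)
  fit <- variationalLaplace(fwd, gaussianBelief(rep(0, 3), diag(1, 3)), y)
  expect_true(all(diff(fit$trace) >= -1e-6 * max(1, abs(fit$F))))
  expect_gte(fit$complexity, 0)
  expect_equal(fit$F, fit$accuracy - fit$complexity)
})

test_that("the engine fails loudly when the forward map is invalid at start", {
  prior <- gaussianBelief(0, 1)
  expect_error(variationalLaplace(function(th) NaN * th, prior, 1),
               "prior mean")
})

test_that("window inversion explains self-generated noiseless data", {
  ch <- chainSpec()
  tr <- groundTruth(ch, beta = matrix(0, 2, 5), nWindows = 2,
                    freqs = fastFreqs(), windowNoiseSd = 0, obsNoiseFrac = 0,
                    seed = 5)
  sub <- simulateSubject(tr, seed = 5, gain = chainGain())
  dp <- invertWindow(sub$csd[[1]], ch, defaultPriors(ch), chainGain(),
                     modelBand = c(1, 45))
  expect_gt(explainedVar(dp), 99)
  expect_s4_class(dp, "DCMPosterior")
})

test_that("window inversion rejects data outside the modelled band", {
  ch <- chainSpec()
  tr <- groundTruth(ch, nWindows = 2, freqs = fastFreqs(), seed = 2)
  sub <- simulateSubject(tr, seed = 2, gain = chainGain())
  expect_error(invertWindow(sub$csd[[1]], ch, defaultPriors(ch), chainGain(),
                            modelBand = c(1, 30)),
               "outside the modelled band")
})

test_that("credible intervals cover a known gain perturbation", {
  # +0.3 on the forward edge of the 2-node chain; the 90% interval should
  # cover it in at least 80% of seeded replicates
  ch <- chainSpec()
  L <- chainGain()
  prior <- defaultPriors(ch)
  beta <- matrix(0, 2, 5); beta[1, 1] <- 0.3
  covered <- 0
  for (seed in 1:20) {
    tr <- groundTruth(ch, beta = beta, nWindows = 2, freqs = fastFreqs(),
                      windowNoiseSd = 0, obsNoiseFrac = 0.05, seed = seed)
    sub <- simulateSubject(tr, seed = seed, gain = L)
    dp <- invertWindow(sub$csd[[1]], ch, prior, L)
    m <- beliefMean(posterior(dp))[1]
    s <- sqrt(beliefCov(posterior(dp))[1, 1])
    if (abs(m - 0.3) <= 1.645 * s) covered <- covered + 1
  }
  expect_gte(covered, 16)
})

test_that("refined fitting matches the plain inversion for a single window", {
  ch <- chainSpec()
  tr <- groundTruth(ch, nWindows = 2, freqs = fastFreqs(),
                    windowNoiseSd = 0.05, obsNoiseFrac = 0.05, seed = 3)
  sub <- simulateSubject(tr, seed = 3, gain = chainGain())
  prior <- defaultPriors(ch)
  one <- pebFit(sub$csd[1], ch, prior, chainGain())
  ref <- invertWindow(sub$csd[[1]], ch, prior, chainGain())
  expect_equal(beliefMean(posterior(one[[1]])),
               beliefMean(posterior(ref)), tolerance = 1e-8)
})

test_that("empirical shrinkage refinement does not hurt recovery", {
  # paired comparison over seeds: mean absolute error of window log-gains
  # after refinement vs independent inversions
  ch <- chainSpec()
  L <- chainGain()
  prior <- defaultPriors(ch)
  beta <- matrix(0, 2, 5); beta[, 1] <- c(0.35, -0.25)
  wins <- 0; total <- 0
  for (seed in 1:6) {
    tr <- groundTruth(ch, beta = beta, nWindows = 8, freqs = fastFreqs(),
                      windowNoiseSd = 0.05, obsNoiseFrac = 0.1, seed = seed)
    sub <- simulateSubject(tr, seed = seed, gain = L)
    indep <- lapply(sub$csd, invertWindow, spec = ch, prior = prior,
                    gain = L)
    refined <- pebFit(sub$csd, ch, prior, L, maxIter = 3)
    maeI <- mean(abs(t(vapply(indep, function(p)
      beliefMean(posterior(p))[1:2], numeric(2))) - sub$theta))
    maeR <- mean(abs(t(vapply(refined, function(p)
      beliefMean(posterior(p))[1:2], numeric(2))) - sub$theta))
    total <- total + 1
    if (maeR <= maeI + 1e-6) wins <- wins + 1
    expect_true(all(diff(attr(refined, "Ftrace")) >= -1e-6))
  }
  expect_gte(wins, ceiling(total / 2))
})
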