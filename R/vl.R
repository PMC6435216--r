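#' Variational Laplace inversion of a nonlinear Gaussian model
#'
#' Gauss-Newton ascent on the Laplace free energy F = accuracy - complexity
#' for the model y = f(theta) + e, e ~ N(0, exp(-lambda) I), with Gaussian
#' prior over theta and a Gaussian hyperprior over the noise log-precision
#' lambda. Steps are regularized Levenberg-Marquardt style: a proposed step is
#' accepted only if it increases F (evaluated self-consistently at the
#' candidate), otherwise the previous state is restored and damping increased,
#' so the accepted free-energy trace is non-decreasing by construction.
#'
#' @param forward function mapping a parameter vector to a numeric prediction
#'   vector; may signal an error or return `NULL` for invalid (e.g. unstable)
#'   parameters, which is treated as a rejected step.
#' @param prior [GaussianBelief-class] over theta.
#' @param data observed numeric feature vector.
#' @param noiseHyperprior [GaussianBelief-class] of dimension 1 over lambda
#'   (default mean 0, variance 1/16).
#' @param jacobian optional function(theta) returning
#'   `list(f0 = prediction, J = Jacobian, ok = logical)`; defaults to central
#'   finite differences with step `h`.
#' @param maxIter maximum number of proposed iterations (default 64).
#' @param tol convergence: |dF| below `tol` on 4 consecutive accepted steps.
#' @param h finite-difference step per parameter.
#' @return list with `posterior` ([GaussianBelief-class]), `F`, `lambda`,
#'   `lambdaVar`, `trace` (accepted free energies), `accuracy`, `complexity`,
#'   `residual`.
#' @export
variationalLaplace <- function(forward, prior, data,
                               noiseHyperprior = gaussianBelief(0, 1 / 16),
                               jacobian = NULL, maxIter = 64, tol = 0.01,
                               h = 1e-4) {
  y <- as.numeric(data)
  n <- length(y)
  mu0 <- prior@mean
  S0 <- prior@cov
  P0 <- .solveSym(S0)
  ld0 <- .logdet(S0)
  l0 <- noiseHyperprior@mean[1]
  v0 <- noiseHyperprior@cov[1, 1]

  if (is.null(jacobian)) {
    jacobian <- function(theta) {
      f0 <- tryCatch(forward(theta), error = function(e) NULL)
      if (is.null(f0) || any(!is.finite(f0))) return(list(ok = FALSE))
      J <- matrix(0, n, length(theta))
      for (j in seq_along(theta)) {
        tp <- tm <- theta
        tp[j] <- tp[j] + h
        tm[j] <- tm[j] - h
        fp <- tryCatch(forward(tp), error = function(e) NULL)
        fm <- tryCatch(forward(tm), error = function(e) NULL)
        if (is.null(fp) || is.null(fm)) return(list(ok = FALSE))
        J[, j] <- (fp - fm) / (2 * h)
      }
      list(f0 = f0, J = J, ok = TRUE)
    }
  }

  # free energy and sufficient statistics at a given state
  evalState <- function(m, lam) {
    jc <- jacobian(m)
    if (!isTRUE(jc$ok)) return(NULL)
    e <- y - jc$f0
    M <- crossprod(jc$J)
    ee <- sum(e * e)
    # inner Newton updates of the noise log-precision
    for (it in 1:8) {
      p <- exp(lam)
      C <- .solveSym(p * M + P0)
      E2 <- ee + sum(M * C)
      g <- n / 2 - p * E2 / 2 - (lam - l0) / v0
      H <- -p * E2 / 2 - 1 / v0
      d <- max(min(-g / H, 4), -4)
      lam <- lam + d
      if (abs(d) < 1e-6) break
    }
    p <- exp(lam)
    P <- p * M + P0
    C <- .solveSym(P)
    E2 <- ee + sum(M * C)
    vlam <- 1 / (p * E2 / 2 + 1 / v0)
    acc <- -p / 2 * E2 + n / 2 * lam - n / 2 * log(2 * pi)
    compT <- .klGauss(m, C, mu0, P0, ld0)
    compL <- 0.5 * ((lam - l0)^2 / v0 + vlam / v0 - log(vlam / v0) - 1)
    list(m = m, lam = lam, vlam = vlam, C = C, P = P, e = e, J = jc$J,
         M = M, F = acc - compT - compL, acc = acc, comp = compT + compL,
         p = p)
  }

  st <- evalState(mu0, l0)
  if (is.null(st))
    stop("forward map is non-finite or unstable at the prior mean")
  trace <- st$F
  nu <- 0
  consec <- 0L
  anyAccepted <- FALSE
  for (iter in seq_len(maxIter)) {
    g <- st$p * crossprod(st$J, st$e) - P0 %*% (st$m - mu0)
    Pd <- st$P + nu * diag(diag(st$P), nrow(st$P))
    dm <- tryCatch(as.numeric(.solveSym(Pd, g)), error = function(e) NULL)
    cand <- if (is.null(dm)) NULL else evalState(st$m + dm, st$lam)
    if (!is.null(cand) && is.finite(cand$F) &&
        cand$F >= st$F - 1e-8 * max(1, abs(st$F))) {
      dF <- cand$F - st$F
      st <- cand
      trace <- c(trace, st$F)
      anyAccepted <- TRUE
      nu <- max(nu / 8, 0)
      consec <- if (dF < tol) consec + 1L else 0L
      if (consec >= 4L) break
    } else {
      nu <- if (nu == 0) 1e-4 else nu * 10
      if (nu > 1e8) break
    }
  }
  if (!anyAccepted && maxIter > 0)
    stop("variational Laplace failed to take any accepted step")
  post <- gaussianBelief(as.numeric(st$m), .sym(st$C),
                         label = "VL posterior")
  names(post@mean) <- names(mu0)
  list(posterior = post, F = st$F, lambda = st$lam, lambdaVar = st$vlam,
       trace = trace, accuracy = st$acc, complexity = st$comp,
       residual = st$e)
}

#' Invert one window's cross-spectral data
#'
#' Wraps [variationalLaplace()] with the neural-mass forward model: the
#' parameter vector is mapped through [predictCsd()] and stacked into the
#' real feature vector. Features are scaled by the expected noise level (or a
#' tenth of their root-mean-square when unknown) so the noise log-precision
#' hyperprior is centred on the data scale.
#'
#' @param csd a [CrossSpectralData-class].
#' @param spec a [NetworkSpec-class].
#' @param prior [GaussianBelief-class] over the window parameters (see
#'   [defaultPriors()]).
#' @param gain modes x sources gain matrix.
#' @param modelBand frequency band (Hz) the forward model covers; the data
#'   grid must lie inside it.
#' @param maxIter,tol passed to the engine.
#' @param constants see [erpConstants()].
#' @return A [DCMPosterior-class].
#' @export
invertWindow <- function(csd, spec, prior, gain, modelBand = c(1, 45),
                         maxIter = 64, tol = 0.01,
                         constants = erpConstants()) {
  stopifnot(is(csd, "CrossSpectralData"), is(spec, "NetworkSpec"))
  if (any(csd@freqs < modelBand[1] - 1e-9 | csd@freqs > modelBand[2] + 1e-9))
    stop("data frequency grid lies outside the modelled band")
  if (dim(csd@csd)[1] != nrow(gain))
    stop("gain rows must match the number of observed modes")
  ctx <- .modelContext(spec, gain, csd@freqs, constants)
  y <- csdFeatures(csd)
  s0 <- if (csd@noiseSd > 0) csd@noiseSd else sqrt(mean(y^2)) / 10
  ys <- y / s0
  fwd <- function(theta) {
    out <- .cppFeatures(as.numeric(theta), ctx)
    if (!out$ok) return(NULL)
    out$features / s0
  }
  jac <- function(theta) {
    out <- .cppFeatureJacobian(as.numeric(theta), ctx, 1e-4)
    if (!out$ok) return(list(ok = FALSE))
    list(f0 = out$f0 / s0, J = out$J / s0, ok = TRUE)
  }
  fit <- variationalLaplace(fwd, prior, ys, jacobian = jac,
                            maxIter = maxIter, tol = tol)
  ev <- 100 * (1 - sum(fit$residual^2) / sum(ys^2))
  new("DCMPosterior", belief = fit$posterior, F = fit$F, ev = ev,
      trace = fit$trace, prior = prior)
}

#' Iteratively refined window inversions under empirical shrinkage priors
#'
#' Inverts every window, then alternates: (i) a constant-only
#' parametric-empirical-Bayes estimate of the between-window mean, (ii)
#' re-inversion of all windows under the empirical prior centred on that mean
#' (original prior covariance retained). An outer iteration is kept only if
#' the hierarchical free energy (sum of window free energies plus the
#' second-level free energy) improves by at least `tol`; this pulls
#' window-level solutions away from local minima.
#'
#' @param windows list of [CrossSpectralData-class].
#' @param spec,prior,gain,modelBand,maxIterVL,tol,constants as in
#'   [invertWindow()].
#' @param maxIter maximum outer iterations (default 8).
#' @param tolOuter minimum hierarchical free-energy improvement (default 1/8).
#' @return list of [DCMPosterior-class] (final accepted refinement), with
#'   attributes `Ftrace` (accepted hierarchical free energies) and `prior`
#'   (the final empirical prior).
#' @export
pebFit <- function(windows, spec, prior, gain, maxIter = 8, tolOuter = 1 / 8,
                   modelBand = c(1, 45), maxIterVL = 64, tol = 0.01,
                   constants = erpConstants()) {
  stopifnot(length(windows) >= 1)
  run <- function(pr) lapply(windows, invertWindow, spec = spec, prior = pr,
                             gain = gain, modelBand = modelBand,
                             maxIter = maxIterVL, tol = tol,
                             constants = constants)
  posts <- run(prior)
  if (length(windows) == 1L) {
    attr(posts, "Ftrace") <- posts[[1]]@F
    attr(posts, "prior") <- prior
    return(posts)
  }
  ones <- new("DesignMatrix",
              X = matrix(1, length(windows), 1), labels = "constant")
  hierF <- function(ps, pr) {
    peb <- pebEstimate(lapply(ps, posterior), pr, ones, field = "all",
                       spec = spec)
    sum(vapply(ps, freeEnergy, 0)) + freeEnergy(peb)
  }
  curPrior <- prior
  Fh <- hierF(posts, curPrior)
  trace <- Fh
  for (it in seq_len(max(0, maxIter - 1))) {
    peb <- pebEstimate(lapply(posts, posterior), curPrior, ones,
                       field = "all", spec = spec)
    newPrior <- gaussianBelief(beliefMean(posterior(peb)), prior@cov,
                               label = "empirical shrinkage prior")
    names(newPrior@mean) <- names(prior@mean)
    cand <- run(newPrior)
    Fc <- hierF(cand, newPrior)
    if (Fc >= Fh + tolOuter) {
      posts <- cand
      curPrior <- newPrior
      Fh <- Fc
      trace <- c(trace, Fh)
    } else break
  }
  attr(posts, "Ftrace") <- trace
  attr(posts, "prior") <- curPrior
  posts
}
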