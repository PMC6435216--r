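# reduced prior with an arbitrary set of single parameters switched off
.reduceParams <- function(priorBeta, off, tiny = 1e-8) {
  Xi <- priorBeta@cov
  if (length(off)) {
    Xi[off, ] <- 0
    Xi[, off] <- 0
    Xi[cbind(off, off)] <- tiny
  }
  gaussianBelief(priorBeta@mean, Xi, label = "reduced prior")
}

#' Greedy pruning of second-level parameters with Bayesian model averaging
#'
#' Iteratively scores switching off each remaining parameter by Bayesian
#' model reduction and prunes the parameter whose removal most increases
#' (or least decreases, if >= 0) the log evidence, until no single pruning
#' improves it. A final exhaustive sweep enumerates all on/off combinations
#' of the `finalSweepSize` parameters with the smallest absolute evidence
#' contribution (2^8 = 256 models by default); the posterior is averaged over
#' that model set weighted by evidence, and each parameter's posterior
#' probability Pp is the summed probability of the models retaining it.
#'
#' @param peb a [PEBResult-class] (typically the group-level result).
#' @param finalSweepSize number of parameters in the exhaustive final sweep
#'   (default 8).
#' @return A [BMAResult-class].
#' @export
greedySearchBma <- function(peb, finalSweepSize = 8) {
  qE <- peb@beta@mean
  d <- length(qE)
  prior <- peb@priorBeta

  dFoff <- function(off) {
    if (!length(off)) return(0)
    bayesianModelReduction(peb@beta, prior, .reduceParams(prior, off))$dF
  }

  off <- integer(0)
  Fcur <- 0
  repeat {
    on <- setdiff(seq_len(d), off)
    if (!length(on)) break
    sc <- vapply(on, function(k) dFoff(c(off, k)) - Fcur, 0)
    best <- which(sc >= 0)
    if (!length(best)) break
    # deterministic tie-break: largest improvement, then lowest index
    k <- on[best[which.max(sc[best])]]
    off <- c(off, k)
    Fcur <- dFoff(off)
  }

  # evidence contribution of toggling each parameter against the final model
  contrib <- vapply(seq_len(d), function(k) {
    off2 <- if (k %in% off) setdiff(off, k) else c(off, k)
    dFoff(off2) - Fcur
  }, 0)
  s <- min(finalSweepSize, d)
  cand <- order(abs(contrib), seq_len(d))[seq_len(s)]
  fixedOff <- setdiff(off, cand)

  M <- 2L^s
  models <- matrix(1L, M, d)
  if (length(fixedOff)) models[, fixedOff] <- 0L
  Fm <- numeric(M)
  means <- matrix(0, M, d)
  covs <- vector("list", M)
  for (m in seq_len(M)) {
    bits <- as.integer(bitwAnd(M - m, 2L^(seq_len(s) - 1L)) > 0L)
    models[m, cand] <- bits
    offm <- c(fixedOff, cand[bits == 0L])
    if (length(offm)) {
      red <- bayesianModelReduction(peb@beta, prior,
                                    .reduceParams(prior, offm))
      Fm[m] <- red$dF
      means[m, ] <- red$posterior@mean
      covs[[m]] <- red$posterior@cov
    } else {
      Fm[m] <- 0
      means[m, ] <- qE
      covs[[m]] <- peb@beta@cov
    }
  }
  w <- .softmax(Fm)
  mu <- as.numeric(colSums(means * w))
  Cb <- matrix(0, d, d)
  for (m in seq_len(M)) {
    dm <- means[m, ] - mu
    Cb <- Cb + w[m] * (covs[[m]] + dm %o% dm)
  }
  pp <- as.numeric(colSums(models * w))
  alwaysOff <- colSums(models) == 0
  mu[alwaysOff] <- 0
  names(mu) <- names(qE)
  names(pp) <- names(qE)
  new("BMAResult", mean = mu, cov = .sym(Cb), pp = pp, models = models,
      modelProbs = w, modelF = Fm)
}

#' Group-level (third-level) parametric empirical Bayes
#'
#' Models the subjects' second-level posteriors with a constant-only
#' between-subject design, i.e. estimates the between-window effects that are
#' conserved over subjects.
#'
#' @param subjectPebs list of [PEBResult-class], one per subject, sharing the
#'   same design and field.
#' @return A [PEBResult-class] over the group-mean second-level effects.
#' @export
groupPeb <- function(subjectPebs) {
  stopifnot(length(subjectPebs) >= 1)
  ref <- subjectPebs[[1]]
  for (p in subjectPebs) {
    if (!identical(dim(p@design@X), dim(ref@design@X)) ||
        max(abs(p@design@X - ref@design@X)) > 1e-12 ||
        !identical(p@field, ref@field))
      stop("subjects must share one design and field")
  }
  N <- length(subjectPebs)
  beliefs <- lapply(subjectPebs, posterior)
  ones <- new("DesignMatrix", X = matrix(1, N, 1), labels = "constant")
  out <- pebEstimate(beliefs, ref@priorBeta, ones, field = "all")
  out@field <- ref@field
  # carry subject-level names and the subject design for trajectory prediction
  names(out@beta@mean) <- names(ref@beta@mean)
  out@design <- ref@design
  out@nUnits <- as.integer(N)
  out
}

#' Predicted group-level connectivity trajectories with credible bands
#'
#' Trajectory per connection is X beta (log-gain scale); the 90% credible
#' band is +/- 1.645 posterior standard deviations of x_n' beta at each
#' window, propagated through the posterior covariance.
#'
#' @param groupBma a [BMAResult-class] (or [GaussianBelief-class]) over
#'   second-level effects of length B*P, stacked regressor-major.
#' @param design the within-subject [DesignMatrix-class] (W x P).
#' @param level credible level (default 0.90).
#' @return list with `trajectory`, `lower`, `upper` (each W x B matrices) and
#'   `z` (the normal quantile used).
#' @export
predictTrajectories <- function(groupBma, design, level = 0.90) {
  X <- if (is(design, "DesignMatrix")) design@X else as.matrix(design)
  mu <- if (is(groupBma, "BMAResult")) groupBma@mean else beliefMean(groupBma)
  Cb <- if (is(groupBma, "BMAResult")) groupBma@cov else beliefCov(groupBma)
  P <- ncol(X)
  if (length(mu) %% P != 0)
    stop("effect vector length must be a multiple of the regressor count")
  B <- length(mu) %/% P
  z <- stats::qnorm(1 - (1 - level) / 2)
  W <- nrow(X)
  traj <- matrix(0, W, B)
  half <- matrix(0, W, B)
  for (b in seq_len(B)) {
    ib <- b + B * (0:(P - 1))
    traj[, b] <- X %*% mu[ib]
    Sb <- Cb[ib, ib, drop = FALSE]
    half[, b] <- z * sqrt(pmax(rowSums((X %*% Sb) * X), 0))
  }
  cn <- names(mu)[seq_len(B)]
  if (!is.null(cn)) {
    cn <- sub("^[^:]*:", "", cn)
    colnames(traj) <- colnames(half) <- cn
  }
  list(trajectory = traj, lower = traj - half, upper = traj + half, z = z)
}
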