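#' Second-level design matrix of temporal basis functions
#'
#' Column 1 is the constant; columns 2-4 are orthonormal DCT-II basis
#' functions sqrt(2/W) cos((pi/W)(n + 1/2) k) for k = 2..4; the last column
#' is the mono-exponential decay exp(-n/tau), n = 0..W-1.
#'
#' @param W number of windows (>= 2).
#' @param k DCT orders (default 2:4).
#' @param tau decay constant in windows (default 16).
#' @return A [DesignMatrix-class] with labels constant, dct2..dct4, decay.
#' @examples
#' X <- buildDesign(60)
#' dim(designMatrix(X)) # 60 x 5
#' @export
buildDesign <- function(W, k = 2:4, tau = 16) {
  if (W < 2) stop("need at least W = 2 windows")
  if (tau <= 0) stop("decay constant must be positive")
  if (length(k) && max(k) >= W)
    stop("DCT order must be below the window count")
  n <- 0:(W - 1)
  dct <- vapply(k, function(kk) sqrt(2 / W) * cos((pi / W) * (n + 0.5) * kk),
                numeric(W))
  X <- cbind(1, dct, exp(-n / tau))
  labels <- c("constant", if (length(k)) paste0("dct", k), "decay")
  colnames(X) <- labels
  new("DesignMatrix", X = X, labels = labels)
}

# resolve a field selector to indices within the belief dimension
.resolveField <- function(field, spec, B) {
  if (is.numeric(field)) return(as.integer(field))
  if (is.null(spec)) {
    if (identical(field, "all")) return(seq_len(B))
    stop("character field selectors need a NetworkSpec")
  }
  fieldIndices(spec, field)
}

#' Parametric-empirical-Bayes estimation of second-level effects
#'
#' Estimates the Bayesian linear model theta_i = (x_i' (x) I_B) beta + eps
#' over first-level posteriors, where eps has precision Q0 + exp(-gamma) Q1
#' with a single log-precision parameter gamma. For fixed gamma the
#' first-level priors are replaced by the empirical prior via the Bayesian
#' model reduction identity, which makes the conditional posterior over beta
#' exactly Gaussian; gamma itself is optimized with a Laplace approximation
#' under a weakly informative Gaussian hyperprior (mean 0, variance 4: the
#' log-precision must be able to span the plausible random-effects scales,
#' from window-to-window noise of a few hundredths up to between-subject
#' dispersions of a few tenths on the log-gain scale, i.e. roughly +-3 log
#' units around the pC/16 default). Q1 is 16 times the first-level prior
#' precision of the selected field, i.e. at gamma = 0 the random-effects
#' covariance defaults to pC/16 (the conventional between-unit default);
#' Q0 = 1e-4 I is a precision floor, and the beta prior is zero-mean with
#' covariance I_P (x) pC (one first-level prior width per regressor).
#'
#' @param beliefs list of first-level posterior [GaussianBelief-class]
#'   (windows, or subjects at the third level).
#' @param prior the first-level prior [GaussianBelief-class] (shared).
#' @param design a [DesignMatrix-class] (or plain matrix) with one row per
#'   belief.
#' @param field connection-type selector: `"all"`, `"gains"`, `"forward"`,
#'   `"backward"`, `"lateral"`, or explicit indices.
#' @param spec optional [NetworkSpec-class], needed for named fields.
#' @param gammaRange search interval for the log-precision (default
#'   `c(-16, 8)`).
#' @param gammaPrior mean and variance of the Gaussian hyperprior over the
#'   log-precision gamma.
#' @param Ffirst optional vector of first-level free energies to add as a
#'   constant to F.
#' @return A [PEBResult-class].
#' @export
pebEstimate <- function(beliefs, prior, design, field = "all", spec = NULL,
                        gammaRange = c(-16, 8), gammaPrior = c(0, 4),
                        Ffirst = NULL) {
  X <- if (is(design, "DesignMatrix")) design@X else as.matrix(design)
  dm <- if (is(design, "DesignMatrix")) design
        else new("DesignMatrix", X = X,
                 labels = paste0("r", seq_len(ncol(X))))
  W <- length(beliefs)
  if (nrow(X) != W) stop("design must have one row per first-level belief")
  Bfull <- length(prior@mean)
  idx <- .resolveField(field, spec, Bfull)
  B <- length(idx)
  P <- ncol(X)

  mu0 <- prior@mean[idx]
  pC <- prior@cov[idx, idx, drop = FALSE]
  Pp <- .solveSym(pC)
  ldPp <- .logdet(Pp)
  Q1 <- 16 * Pp
  Q0 <- diag(1e-4, B)
  Xi <- kronecker(diag(1, P), pC)
  XiInv <- .solveSym(Xi)
  ldXi <- .logdet(Xi)

  Pq <- vector("list", W)
  kv <- vector("list", W)
  ms <- vector("list", W)
  cstat <- numeric(W) # gamma-independent pieces of the per-window constants
  for (i in seq_len(W)) {
    b <- beliefs[[i]]
    if (length(b@mean) != Bfull) stop("belief dimension mismatch")
    Cq <- b@cov[idx, idx, drop = FALSE]
    Pq[[i]] <- .solveSym(Cq)
    ms[[i]] <- b@mean[idx]
    kv[[i]] <- Pq[[i]] %*% ms[[i]] - Pp %*% mu0
    cstat[i] <- 0.5 * (.logdet(Pq[[i]]) - ldPp) -
      0.5 * (sum(ms[[i]] * (Pq[[i]] %*% ms[[i]])) - sum(mu0 * (Pp %*% mu0)))
  }

  lnZ <- function(gamma) {
    Pg <- Q0 + exp(-gamma) * Q1
    ldPg <- .logdet(Pg)
    H <- XiInv
    g <- numeric(B * P)
    aSum <- 0
    for (i in seq_len(W)) {
      Ps <- .sym(Pq[[i]] + Pg - Pp)
      ch <- tryCatch(chol(Ps), error = function(e) NULL)
      if (is.null(ch)) return(-Inf)
      ldPs <- 2 * sum(log(diag(ch)))
      Psi <- chol2inv(ch)
      aSum <- aSum + cstat[i] + 0.5 * (ldPg - ldPs) +
        0.5 * sum(kv[[i]] * (Psi %*% kv[[i]]))
      Rm <- Pg - Pg %*% Psi %*% Pg
      tv <- Pg %*% Psi %*% kv[[i]]
      H <- H + kronecker(X[i, ] %o% X[i, ], Rm)
      g <- g + kronecker(X[i, ], as.numeric(tv))
    }
    chH <- tryCatch(chol(.sym(H)), error = function(e) NULL)
    if (is.null(chH)) return(-Inf)
    bhat <- backsolve(chH, forwardsolve(t(chH), g))
    val <- aSum - 0.5 * ldXi - 0.5 * (2 * sum(log(diag(chH)))) +
      0.5 * sum(g * bhat)
    attr(val, "bhat") <- bhat
    attr(val, "Cb") <- chol2inv(chH)
    val
  }
  phi <- function(gamma) {
    z <- lnZ(gamma)
    as.numeric(z) - 0.5 * (gamma - gammaPrior[1])^2 / gammaPrior[2] -
      0.5 * log(2 * pi * gammaPrior[2])
  }

  grid <- seq(gammaRange[1], gammaRange[2], by = 0.5)
  vals <- vapply(grid, phi, 0)
  if (all(!is.finite(vals)))
    stop("random-effects precision not positive definite anywhere in range")
  g0 <- grid[which.max(vals)]
  opt <- optimize(phi, lower = max(gammaRange[1], g0 - 0.6),
                  upper = min(gammaRange[2], g0 + 0.6), maximum = TRUE,
                  tol = 1e-6)
  gamma <- opt$maximum
  hstep <- 1e-3
  d2 <- (phi(gamma + hstep) - 2 * opt$objective + phi(gamma - hstep)) /
    hstep^2
  gv <- if (is.finite(d2) && d2 < 0) -1 / d2 else gammaPrior[2]

  z <- lnZ(gamma)
  bhat <- attr(z, "bhat")
  Cb <- .sym(attr(z, "Cb"))
  Fout <- as.numeric(phi(gamma)) + 0.5 * log(2 * pi * gv) +
    if (is.null(Ffirst)) 0 else sum(Ffirst)

  beta <- gaussianBelief(as.numeric(bhat), Cb, label = "second-level effects")
  pn <- names(prior@mean)[idx]
  if (is.null(pn)) pn <- paste0("p", idx)
  names(beta@mean) <- paste(rep(dm@labels, each = B), pn, sep = ":")
  fieldLabel <- if (is.character(field)) field else "custom"
  new("PEBResult", beta = beta, gamma = gamma, gammaVar = gv, F = Fout,
      design = dm, field = fieldLabel, Q0 = Q0, Q1 = Q1,
      priorBeta = gaussianBelief(rep(0, B * P), Xi, label = "beta prior"),
      nUnits = as.integer(W))
}

# Gaussian Bayesian-model-reduction identity on precisions and
# precision-weighted means; returns the change in log evidence and the
# reduced posterior.
.bmr <- function(qE, qC, pE, pC, rE, rC) {
  Pq <- .solveSym(qC)
  Pp <- .solveSym(pC)
  Pr <- .solveSym(rC)
  Ps <- .sym(Pq + Pr - Pp)
  b <- Pq %*% qE + Pr %*% rE - Pp %*% pE
  ch <- chol(Ps)
  sE <- backsolve(ch, forwardsolve(t(ch), b))
  sC <- chol2inv(ch)
  dF <- 0.5 * (.logdet(Pq) + .logdet(Pr) - .logdet(Pp) -
                 2 * sum(log(diag(ch)))) +
    0.5 * (sum(b * sE) -
             (sum(qE * (Pq %*% qE)) + sum(rE * (Pr %*% rE)) -
                sum(pE * (Pp %*% pE))))
  list(dF = as.numeric(dF), mean = as.numeric(sE), cov = .sym(sC))
}

#' Bayesian model reduction
#'
#' Analytic change in log evidence, and the implied reduced posterior, when
#' the prior of an already-inverted model is replaced by a reduced prior
#' (Gaussian identity on precisions and precision-weighted means). Replacing
#' the prior with itself returns exactly zero.
#'
#' @param fullPosterior,fullPrior,reducedPrior [GaussianBelief-class] objects
#'   of equal dimension.
#' @return list with `dF` (log-evidence change) and `posterior` (reduced
#'   [GaussianBelief-class]).
#' @export
bayesianModelReduction <- function(fullPosterior, fullPrior, reducedPrior) {
  d <- length(fullPosterior@mean)
  if (length(fullPrior@mean) != d || length(reducedPrior@mean) != d)
    stop("all beliefs must share one dimension")
  if (isTRUE(all.equal(reducedPrior@mean, fullPrior@mean,
                       check.attributes = FALSE)) &&
      isTRUE(all.equal(reducedPrior@cov, fullPrior@cov)))
    return(list(dF = 0, posterior = fullPosterior))
  out <- .bmr(fullPosterior@mean, fullPosterior@cov, fullPrior@mean,
              fullPrior@cov, reducedPrior@mean, reducedPrior@cov)
  post <- gaussianBelief(out$mean, out$cov, label = "reduced posterior")
  names(post@mean) <- names(fullPosterior@mean)
  list(dF = out$dF, posterior = post)
}

#' Enumerate reduced second-level models
#'
#' All on/off combinations of the optional temporal regressors; the constant
#' is always retained. Model 1 includes every optional regressor; the last
#' model (2^n) is the constant-only null. Reduction is implemented downstream
#' by shrinking the prior variance of switched-off coefficients to zero.
#'
#' @param nOptional number of optional regressors (4 for dct2..dct4 + decay).
#' @param labels optional regressor labels.
#' @return binary models x optional-regressors inclusion matrix.
#' @export
enumerateReducedModels <- function(nOptional,
                                   labels = if (nOptional == 4)
                                     c("dct2", "dct3", "dct4", "decay")
                                   else paste0("r", seq_len(nOptional))) {
  n <- as.integer(nOptional)
  if (n < 0) stop("nOptional must be >= 0")
  M <- 2L^n
  inc <- matrix(0L, M, n)
  for (m in seq_len(M)) {
    bits <- M - m # model 1 = all on, model 2^n = null
    inc[m, ] <- as.integer(bitwAnd(bits, 2L^(seq_len(n) - 1L)) > 0L)
  }
  if (n > 0) colnames(inc) <- labels
  rownames(inc) <- paste0("model", seq_len(M))
  inc
}

# reduced beta prior with switched-off regressor blocks shrunk to ~zero
.reduceBetaPrior <- function(priorBeta, B, labels, on, tiny = 1e-8) {
  Xi <- priorBeta@cov
  for (p in seq_along(labels)) {
    if (!on[p]) {
      rows <- (p - 1L) * B + seq_len(B)
      Xi[rows, ] <- 0
      Xi[, rows] <- 0
      Xi[cbind(rows, rows)] <- tiny
    }
  }
  gaussianBelief(priorBeta@mean, Xi, label = "reduced beta prior")
}

#' Score the reduced second-level model space for one subject
#'
#' Bayesian model reduction of the full second-level posterior against every
#' row of the inclusion matrix (optional regressors switched off by shrinking
#' their prior variance to zero). Log evidences are relative to the full
#' model.
#'
#' @param peb a [PEBResult-class].
#' @param inclusion matrix from [enumerateReducedModels()]; columns must
#'   match the design's optional regressors (all non-constant columns).
#' @return numeric vector of relative log evidences, one per model.
#' @export
scoreModelSpace <- function(peb, inclusion) {
  labels <- peb@design@labels
  opt <- labels[labels != "constant"]
  if (ncol(inclusion) != length(opt))
    stop("inclusion columns must match the optional regressors")
  B <- length(peb@beta@mean) / length(labels)
  vapply(seq_len(nrow(inclusion)), function(m) {
    on <- c(constant = TRUE,
            stats::setNames(as.logical(inclusion[m, ]), opt))[labels]
    rp <- .reduceBetaPrior(peb@priorBeta, B, labels, on)
    bayesianModelReduction(peb@beta, peb@priorBeta, rp)$dF
  }, 0)
}

#' Fixed-effects Bayesian model comparison over subjects
#'
#' Pools per-subject log evidences by summation (fixed effects) and converts
#' them to posterior model probabilities by softmax.
#'
#' @param subjectLogEv subjects x models matrix of (relative) log evidences.
#' @param inclusion optional inclusion matrix describing the models.
#' @return A [ModelSpace-class].
#' @export
bmcOverSubjects <- function(subjectLogEv, inclusion = NULL) {
  E <- as.matrix(subjectLogEv)
  if (any(!is.finite(E))) stop("log evidences must be finite")
  pooled <- colSums(E)
  if (is.null(inclusion))
    inclusion <- matrix(0L, ncol(E), 0)
  new("ModelSpace", inclusion = inclusion, subjectLogEv = E,
      pooledLogEv = pooled, probs = .softmax(pooled))
}
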