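#' Define the ground truth for a synthetic multi-subject study
#'
#' Default trajectory structure: the mono-exponential decay component carries
#' a group-conserved coefficient of -0.4 on every forward connection (0
#' elsewhere); DCT components are subject-specific draws with dispersion 0.2
#' around a zero group mean; window-to-window log-gain noise has sd 0.05;
#' observation noise is added to the stacked cross-spectral features at a
#' tenth of their root-mean-square.
#'
#' @param spec a [NetworkSpec-class].
#' @param beta optional connections x regressors group coefficient matrix
#'   (columns constant, dct2..dct4, decay); built from `decayCoef` if `NULL`.
#' @param decayCoef group decay coefficient applied to forward connections
#'   when `beta` is NULL (default -0.4).
#' @param nWindows windows per subject (default 60, one per second of a
#'   1-minute recording).
#' @param freqs frequency grid (Hz).
#' @param fs nominal sampling rate (Hz).
#' @param windowNoiseSd sd of window-level log-gain noise.
#' @param dctDispersion between-subject sd of DCT coefficients.
#' @param decayDispersion between-subject sd of the decay coefficient (0 =
#'   conserved over subjects).
#' @param constantDispersion between-subject sd of the constant coefficient.
#' @param obsNoiseFrac observation-noise sd as a fraction of the clean
#'   feature root-mean-square.
#' @param nModes observation modes (default: source count).
#' @param seed default master seed.
#' @return A [GroundTruth-class].
#' @export
groundTruth <- function(spec, beta = NULL, decayCoef = -0.4, nWindows = 60,
                        freqs = 1:45, fs = 160, windowNoiseSd = 0.05,
                        dctDispersion = 0.2, decayDispersion = 0,
                        constantDispersion = 0, obsNoiseFrac = 0.1,
                        nModes = NULL, seed = 1L) {
  nE <- nrow(spec@edges)
  labels <- c("constant", "dct2", "dct3", "dct4", "decay")
  if (is.null(beta)) {
    beta <- matrix(0, nE, length(labels),
                   dimnames = list(NULL, labels))
    beta[spec@edges$type == "forward", "decay"] <- decayCoef
  }
  if (is.null(colnames(beta))) colnames(beta) <- labels
  if (!is.null(nModes)) spec@nModes <- as.integer(nModes)
  new("GroundTruth", spec = spec, beta = beta,
      nWindows = as.integer(nWindows), freqs = as.numeric(freqs),
      fs = fs, windowNoiseSd = windowNoiseSd,
      dctDispersion = dctDispersion, decayDispersion = decayDispersion,
      constantDispersion = constantDispersion, obsNoiseFrac = obsNoiseFrac,
      seed = as.integer(seed))
}

#' Noiseless log-gain trajectories implied by second-level coefficients
#'
#' @param beta connections x regressors coefficient matrix.
#' @param design a [DesignMatrix-class] (or W x P matrix) whose columns match
#'   `beta`'s columns.
#' @return windows x connections matrix X beta' (log-gain scale).
#' @export
makeTrajectories <- function(beta, design) {
  X <- if (is(design, "DesignMatrix")) design@X else as.matrix(design)
  beta <- as.matrix(beta)
  if (ncol(X) != ncol(beta))
    stop("beta must have one column per design regressor")
  X %*% t(beta)
}

#' Simulate one subject's windowed cross-spectral data
#'
#' Per window, the extrinsic log-gains are set to the subject trajectory plus
#' zero-mean window noise (redrawn, at most 100 times, if the linearized
#' system is unstable), the sensor CSD is predicted through the forward
#' model, and observation noise is added to the stacked features. Fully
#' deterministic given the seed.
#'
#' @param truth a [GroundTruth-class].
#' @param subjectBeta this subject's connections x regressors coefficients.
#' @param seed integer seed.
#' @param gain optional modes x sources gain matrix (seeded random unit-norm
#'   columns if missing).
#' @return list with `csd` (list of [CrossSpectralData-class]), `theta`
#'   (windows x connections realized log-gains), `beta`, `gain`, `seed`.
#' @export
simulateSubject <- function(truth, subjectBeta = truth@beta, seed = truth@seed,
                            gain = NULL) {
  spec <- truth@spec
  nE <- nrow(spec@edges)
  nS <- nrow(spec@nodes)
  W <- truth@nWindows
  if (is.null(gain)) gain <- randomGain(spec@nModes, nS, seed)
  labels <- colnames(subjectBeta)
  ks <- as.integer(sub("^dct", "", grep("^dct", labels, value = TRUE)))
  drop <- labels[labels %in% paste0("dct", ks[ks >= W])]
  if (length(drop)) {
    if (any(abs(subjectBeta[, drop]) > 0))
      stop("DCT orders ", paste(drop, collapse = ", "),
           " need more than ", W, " windows")
    subjectBeta <- subjectBeta[, setdiff(labels, drop), drop = FALSE]
  }
  X <- buildDesign(W, k = ks[ks < W])
  traj <- makeTrajectories(subjectBeta, X)
  B <- paramDim(spec)
  ctx <- .modelContext(spec, gain, truth@freqs)
  .withSeed(seed, {
    theta <- matrix(0, W, nE)
    feats <- vector("list", W)
    for (w in seq_len(W)) {
      okDraw <- FALSE
      for (a in 1:100) {
        gw <- traj[w, ] + rnorm(nE, 0, truth@windowNoiseSd)
        th <- c(gw, rep(0, B - nE))
        out <- .cppFeatures(th, ctx)
        if (out$ok) { okDraw <- TRUE; break }
      }
      if (!okDraw) stop("instability after 100 rejection attempts (window ",
                        w, ")")
      theta[w, ] <- gw
      feats[[w]] <- out$features
    }
    sig <- truth@obsNoiseFrac * sqrt(mean(unlist(feats)^2))
    m <- spec@nModes
    nf <- length(truth@freqs)
    csd <- vector("list", W)
    for (w in seq_len(W)) {
      fw <- feats[[w]]
      if (sig > 0) fw <- fw + rnorm(length(fw), 0, sig)
      csd[[w]] <- new("CrossSpectralData", window = w,
                      freqs = truth@freqs,
                      csd = .unstackCsdArray(fw, m, nf), fs = truth@fs,
                      noiseSd = sig)
    }
    list(csd = csd, theta = theta, beta = subjectBeta, gain = gain,
         seed = as.integer(seed))
  })
}

#' Simulate a multi-subject synthetic dataset
#'
#' Subject coefficients are the group coefficients plus zero-mean Gaussian
#' deviations (constant, DCT and decay dispersions from the truth; the decay
#' deviation is zero in the default fully-conserved mode); each subject's
#' windows are then simulated with the derived seed
#' `seed + subject * 10^4`. All subjects share one gain matrix.
#'
#' @param truth a [GroundTruth-class].
#' @param nSubjects number of subjects (>= 1).
#' @param seed master seed (default the truth's).
#' @return A [SyntheticDataset-class].
#' @export
simulateGroup <- function(truth, nSubjects, seed = truth@seed) {
  stopifnot(nSubjects >= 1)
  spec <- truth@spec
  nE <- nrow(spec@edges)
  labels <- colnames(truth@beta)
  gain <- randomGain(spec@nModes, nrow(spec@nodes), seed)
  betas <- .withSeed(seed + 1L, {
    lapply(seq_len(nSubjects), function(s) {
      b <- truth@beta
      b[, "constant"] <- b[, "constant"] +
        rnorm(nE, 0, truth@constantDispersion)
      for (lb in grep("^dct", labels, value = TRUE))
        b[, lb] <- b[, lb] + rnorm(nE, 0, truth@dctDispersion)
      b[, "decay"] <- b[, "decay"] + rnorm(nE, 0, truth@decayDispersion)
      b
    })
  })
  subjects <- lapply(seq_len(nSubjects), function(s) {
    simulateSubject(truth, betas[[s]], seed = seed + s * 10000L, gain = gain)
  })
  new("SyntheticDataset", subjects = subjects, truth = truth, gain = gain,
      seed = as.integer(seed))
}
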