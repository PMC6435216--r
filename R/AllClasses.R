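#' @import methods
#' @importFrom stats rnorm optimize sd var cov setNames
#' @importFrom utils head tail
#' @useDynLib dcmpeb, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.isHermitian <- function(S, tol = 1e-8) {
  sc <- max(1, max(Mod(S)))
  max(Mod(S - Conj(t(S)))) <= tol * sc
}

#' Gaussian belief over a parameter vector
#'
#' A mean/covariance pair used throughout the hierarchy as prior or posterior
#' over any parameter vector (window-level DCM parameters, second-level
#' effects, hyperparameters).
#'
#' @slot mean numeric mean vector (optionally named).
#' @slot cov symmetric positive semidefinite covariance matrix.
#' @slot label free-text description.
#' @export
setClass("GaussianBelief",
  representation(mean = "numeric", cov = "matrix", label = "character"),
  prototype(label = ""))

setValidity("GaussianBelief", function(object) {
  m <- object@mean; C <- object@cov
  if (length(m) != nrow(C) || nrow(C) != ncol(C))
    return("mean length must equal covariance dimension")
  if (any(!is.finite(m)) || any(!is.finite(C)))
    return("non-finite mean or covariance")
  if (max(abs(C - t(C))) > 1e-8 * max(1, max(abs(C))))
    return("covariance must be symmetric")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(1, max(ev)))
    return("covariance must be positive semidefinite")
  TRUE
})

#' Construct a GaussianBelief
#'
#' @param mean numeric mean vector.
#' @param cov covariance matrix (a scalar or vector is promoted to a diagonal).
#' @param label optional description.
#' @return A [GaussianBelief-class] object.
#' @export
gaussianBelief <- function(mean, cov, label = "") {
  if (!is.matrix(cov)) {
    cov <- if (length(cov) == 1L) diag(cov, length(mean)) else diag(cov)
  }
  new("GaussianBelief", mean = as.numeric(mean), cov = cov, label = label)
}

#' Network specification: nodes and typed directed edges
#'
#' Sources (with MNI coordinates and hierarchical level) and the extrinsic
#' coupling structure between them. Edge types follow the cortical-hierarchy
#' convention: forward edges ascend, backward edges descend, lateral edges
#' connect sources at the same level. Every forward edge must have the
#' reciprocal backward edge.
#'
#' @slot nodes data.frame with columns label, x, y, z, level.
#' @slot edges data.frame with columns from, to, type.
#' @slot nModes integer count of observation modes (channels after reduction).
#' @export
setClass("NetworkSpec",
  representation(nodes = "data.frame", edges = "data.frame",
                 nModes = "integer"))

setValidity("NetworkSpec", function(object) {
  nd <- object@nodes; ed <- object@edges
  if (!all(c("label", "x", "y", "z", "level") %in% names(nd)))
    return("nodes needs columns label, x, y, z, level")
  if (anyDuplicated(nd$label)) return("duplicate node labels")
  if (nrow(ed)) {
    if (!all(c("from", "to", "type") %in% names(ed)))
      return("edges needs columns from, to, type")
    if (!all(ed$type %in% c("forward", "backward", "lateral")))
      return("edge type must be forward, backward or lateral")
    if (!all(c(ed$from, ed$to) %in% nd$label))
      return("edge references undeclared node")
    if (any(ed$from == ed$to)) return("self-edges are not allowed")
    key <- paste(ed$from, ed$to, ed$type)
    if (anyDuplicated(key)) return("duplicate (source, target, type) edge")
    fw <- ed[ed$type == "forward", , drop = FALSE]
    bw <- ed[ed$type == "backward", , drop = FALSE]
    if (!setequal(paste(fw$from, fw$to), paste(bw$to, bw$from)))
      return("forward and backward edge sets must be mutually reciprocal")
  }
  if (object@nModes < 1L) return("nModes must be >= 1")
  TRUE
})

#' Per-window observed cross-spectral data
#'
#' Complex cross-spectral matrices over a frequency grid for one time window,
#' together with the sampling rate and a scalar descriptor of the feature
#' noise level.
#'
#' @slot window window index (1-based).
#' @slot freqs strictly increasing frequency grid in Hz, within (0, Nyquist).
#' @slot csd complex array modes x modes x frequencies, Hermitian per slice.
#' @slot fs sampling rate in Hz.
#' @slot noiseSd standard deviation of the additive feature noise (0 if
#'   unknown; estimated during inversion either way).
#' @export
setClass("CrossSpectralData",
  representation(window = "integer", freqs = "numeric", csd = "array",
                 fs = "numeric", noiseSd = "numeric"),
  prototype(window = 1L, noiseSd = 0))

setValidity("CrossSpectralData", function(object) {
  f <- object@freqs; S <- object@csd
  if (length(dim(S)) != 3L || dim(S)[1] != dim(S)[2])
    return("csd must be a modes x modes x frequencies array")
  if (dim(S)[3] != length(f)) return("third csd dimension must match freqs")
  if (any(diff(f) <= 0) || any(f <= 0)) return("freqs must be strictly increasing and > 0")
  if (is.finite(object@fs) && any(f >= object@fs / 2))
    return("freqs must lie below the Nyquist frequency")
  for (k in seq_len(dim(S)[3]))
    if (!.isHermitian(S[, , k, drop = TRUE])) return("csd slices must be Hermitian")
  TRUE
})

#' Model-predicted cross-spectral density
#'
#' The forward model's sensor-level prediction, partitioned into the neuronal
#' component (innovations filtered through the network and lead field) and the
#' observation-noise component (white + 1/f channel noise).
#'
#' @slot freqs frequency grid in Hz.
#' @slot total complex array modes x modes x frequencies.
#' @slot neuronal neuronal component of the same shape.
#' @slot noise observation-noise component of the same shape.
#' @export
setClass("CsdPrediction",
  representation(freqs = "numeric", total = "array", neuronal = "array",
                 noise = "array"))

setValidity("CsdPrediction", function(object) {
  d <- dim(object@total)
  if (!identical(d, dim(object@neuronal)) || !identical(d, dim(object@noise)))
    return("component shapes must agree")
  if (d[3] != length(object@freqs)) return("frequency count mismatch")
  sc <- max(1, max(Mod(object@total)))
  if (max(Mod(object@total - object@neuronal - object@noise)) > 1e-8 * sc)
    return("neuronal + noise must sum to total")
  for (k in seq_len(d[3])) {
    S <- object@total[, , k, drop = TRUE]
    if (!.isHermitian(S)) return("total csd slices must be Hermitian")
    if (any(Re(diag(as.matrix(S))) < -1e-10 * sc))
      return("total csd diagonal must be non-negative")
  }
  TRUE
})

#' Second-level design matrix of temporal basis functions
#'
#' W x P regressor matrix over windows: a constant column, orthonormal DCT-II
#' columns (k = 2..4 by default) and a mono-exponential decay column.
#'
#' @slot X the W x P matrix.
#' @slot labels column labels, e.g. constant, dct2, dct3, dct4, decay.
#' @export
setClass("DesignMatrix",
  representation(X = "matrix", labels = "character"))

setValidity("DesignMatrix", function(object) {
  X <- object@X
  if (ncol(X) != length(object@labels)) return("one label per column")
  if (nrow(X) < 1) return("need at least one row")
  if (max(abs(X[, 1] - 1)) > 1e-12) return("first column must be constant 1")
  dct <- grep("^dct", object@labels)
  if (length(dct)) {
    G <- crossprod(X[, dct, drop = FALSE])
    if (max(abs(G - diag(length(dct)))) > 1e-8)
      return("DCT columns must be orthonormal")
  }
  dec <- which(object@labels == "decay")
  if (length(dec) && any(diff(X[, dec]) >= 0))
    return("decay column must be strictly decreasing")
  TRUE
})

#' Posterior over one window's DCM parameters
#'
#' @slot belief posterior [GaussianBelief-class] over the window parameters.
#' @slot F Laplace free energy at convergence.
#' @slot ev explained variance (percent) of the cross-spectral features.
#' @slot trace accepted free-energy trace (non-decreasing).
#' @slot prior the prior belief the inversion was run under.
#' @export
setClass("DCMPosterior",
  representation(belief = "GaussianBelief", F = "numeric", ev = "numeric",
                 trace = "numeric", prior = "GaussianBelief"))

setValidity("DCMPosterior", function(object) {
  if (!is.finite(object@F)) return("free energy must be finite")
  if (length(object@trace) > 1 &&
      any(diff(object@trace) < -1e-6 * max(1, abs(object@F))))
    return("accepted free-energy trace must be non-decreasing")
  TRUE
})

#' Result of a parametric-empirical-Bayes estimation
#'
#' Posterior over the second-level effects beta (length B*P, stacked
#' regressor-major), the estimated log-precision gamma of the random effects,
#' the precision components and the free energy of the hierarchical model.
#'
#' @slot beta posterior [GaussianBelief-class] over second-level effects.
#' @slot gamma posterior mode of the random-effects log-precision parameter.
#' @slot gammaVar posterior variance of gamma.
#' @slot F free energy of the hierarchical model (up to the constant sum of
#'   first-level free energies).
#' @slot design the [DesignMatrix-class] used.
#' @slot field connection-type selector the estimation was run on.
#' @slot Q0 baseline precision component.
#' @slot Q1 modulated precision component (scaled by exp(-gamma)).
#' @slot priorBeta prior belief over beta.
#' @slot nUnits number of first-level units (windows or subjects).
#' @export
setClass("PEBResult",
  representation(beta = "GaussianBelief", gamma = "numeric",
                 gammaVar = "numeric", F = "numeric", design = "DesignMatrix",
                 field = "character", Q0 = "matrix", Q1 = "matrix",
                 priorBeta = "GaussianBelief", nUnits = "integer"))

setValidity("PEBResult", function(object) {
  P <- object@Q0 + exp(-object@gamma) * object@Q1
  ev <- eigen((P + t(P)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) return("random-effects precision must be positive definite")
  TRUE
})

#' Space of reduced second-level models
#'
#' All on/off combinations of the optional temporal regressors (the constant
#' is always retained), per-subject log evidences, their fixed-effects pooled
#' sum and the posterior model probabilities.
#'
#' @slot inclusion binary models x optional-regressors matrix.
#' @slot subjectLogEv subjects x models log-evidence matrix (relative scale).
#' @slot pooledLogEv pooled (summed) log evidence per model.
#' @slot probs posterior model probabilities (softmax of pooled log evidence).
#' @export
setClass("ModelSpace",
  representation(inclusion = "matrix", subjectLogEv = "matrix",
                 pooledLogEv = "numeric", probs = "numeric"))

setValidity("ModelSpace", function(object) {
  if (length(object@probs)) {
    if (any(object@probs < -1e-12)) return("probabilities must be non-negative")
    if (abs(sum(object@probs) - 1) > 1e-6) return("probabilities must sum to 1")
  }
  if (ncol(object@inclusion) > 0 &&
      sum(rowSums(object@inclusion) == 0) != 1L)
    return("exactly one all-zeros (null) model expected")
  TRUE
})

#' Bayesian-model-average over a pruned model set
#'
#' @slot mean model-averaged posterior mean per second-level parameter
#'   (pruned-everywhere parameters are exactly 0).
#' @slot cov model-averaged posterior covariance (between-model spread
#'   included).
#' @slot pp posterior probability that each parameter is retained.
#' @slot models binary model x parameter inclusion matrix of the averaged set.
#' @slot modelProbs posterior probability of each averaged model.
#' @slot modelF relative log evidence of each averaged model.
#' @export
setClass("BMAResult",
  representation(mean = "numeric", cov = "matrix", pp = "numeric",
                 models = "matrix", modelProbs = "numeric",
                 modelF = "numeric"))

setValidity("BMAResult", function(object) {
  if (any(object@pp < -1e-12 | object@pp > 1 + 1e-12))
    return("posterior probabilities must lie in [0, 1]")
  off <- colSums(object@models) == 0
  if (any(abs(object@mean[off]) > 0))
    return("parameters pruned from every model must have mean 0")
  TRUE
})

#' Ground truth for the synthetic-data generator
#'
#' Defines the group-level trajectory structure: a group-conserved
#' mono-exponential decay component, subject-specific DCT components and
#' window-level noise, on the log-gain scale of the extrinsic connections.
#'
#' @slot spec the [NetworkSpec-class] generating the data.
#' @slot beta group-level coefficients, connections x regressors.
#' @slot nWindows windows per subject.
#' @slot freqs frequency grid (Hz).
#' @slot fs nominal sampling rate (Hz).
#' @slot windowNoiseSd sd of window-to-window log-gain noise.
#' @slot dctDispersion between-subject sd of the DCT coefficients.
#' @slot decayDispersion between-subject sd of the decay coefficient
#'   (0 = fully conserved over subjects).
#' @slot constantDispersion between-subject sd of the constant coefficient.
#' @slot obsNoiseFrac observation-noise sd as a fraction of the clean feature
#'   root-mean-square.
#' @slot seed default master seed.
#' @export
setClass("GroundTruth",
  representation(spec = "NetworkSpec", beta = "matrix", nWindows = "integer",
                 freqs = "numeric", fs = "numeric", windowNoiseSd = "numeric",
                 dctDispersion = "numeric", decayDispersion = "numeric",
                 constantDispersion = "numeric", obsNoiseFrac = "numeric",
                 seed = "integer"))

setValidity("GroundTruth", function(object) {
  nE <- nrow(object@spec@edges)
  if (nrow(object@beta) != nE)
    return("beta needs one row per extrinsic connection")
  if (object@nWindows < 2L) return("need at least two windows")
  if (object@windowNoiseSd < 0 || object@dctDispersion < 0 ||
      object@decayDispersion < 0 || object@constantDispersion < 0 ||
      object@obsNoiseFrac < 0)
    return("noise levels must be non-negative")
  TRUE
})

#' Multi-subject synthetic dataset
#'
#' @slot subjects list; per subject a list with elements `csd` (list of
#'   [CrossSpectralData-class]), `theta` (windows x connections realized
#'   log-gain matrix), `beta` (subject coefficients) and `seed`.
#' @slot truth the generating [GroundTruth-class].
#' @slot gain shared modes x sources gain matrix.
#' @slot seed master seed.
#' @export
setClass("SyntheticDataset",
  representation(subjects = "list", truth = "GroundTruth", gain = "matrix",
                 seed = "integer"))
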