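#' @describeIn GaussianBelief-class mean vector accessor
#' @param object,x a package object.
#' @export
setGeneric("beliefMean", function(object) standardGeneric("beliefMean"))
#' @describeIn GaussianBelief-class covariance accessor
#' @export
setGeneric("beliefCov", function(object) standardGeneric("beliefCov"))
#' Free energy accessor
#' @param object a DCMPosterior or PEBResult.
#' @export
setGeneric("freeEnergy", function(object) standardGeneric("freeEnergy"))
#' Posterior belief accessor
#' @param object a DCMPosterior or PEBResult.
#' @export
setGeneric("posterior", function(object) standardGeneric("posterior"))
#' Explained variance accessor (percent)
#' @param object a DCMPosterior.
#' @export
setGeneric("explainedVar", function(object) standardGeneric("explainedVar"))
#' Number of extrinsic edges, optionally by type
#' @param object a NetworkSpec.
#' @export
setGeneric("edgeCounts", function(object) standardGeneric("edgeCounts"))
#' Full parameter dimension B of the window-level model
#' @param object a NetworkSpec.
#' @export
setGeneric("paramDim", function(object) standardGeneric("paramDim"))
#' Window-level parameter names
#' @param object a NetworkSpec.
#' @export
setGeneric("paramNames", function(object) standardGeneric("paramNames"))
#' Design matrix accessor
#' @param object a DesignMatrix or PEBResult.
#' @export
setGeneric("designMatrix", function(object) standardGeneric("designMatrix"))
#' Posterior model probabilities
#' @param object a ModelSpace or BMAResult.
#' @export
setGeneric("modelProbabilities",
           function(object) standardGeneric("modelProbabilities"))
#' Pooled (fixed-effects) log evidence per model
#' @param object a ModelSpace.
#' @export
setGeneric("pooledLogEvidence",
           function(object) standardGeneric("pooledLogEvidence"))
#' Per-parameter posterior retention probability
#' @param object a BMAResult.
#' @export
setGeneric("posteriorProb", function(object) standardGeneric("posteriorProb"))

setMethod("beliefMean", "GaussianBelief", function(object) object@mean)
setMethod("beliefCov", "GaussianBelief", function(object) object@cov)
setMethod("freeEnergy", "DCMPosterior", function(object) object@F)
setMethod("freeEnergy", "PEBResult", function(object) object@F)
setMethod("posterior", "DCMPosterior", function(object) object@belief)
setMethod("posterior", "PEBResult", function(object) object@beta)
setMethod("explainedVar", "DCMPosterior", function(object) object@ev)
setMethod("edgeCounts", "NetworkSpec", function(object) {
  ed <- object@edges
  c(forward = sum(ed$type == "forward"),
    backward = sum(ed$type == "backward"),
    lateral = sum(ed$type == "lateral"))
})
setMethod("designMatrix", "DesignMatrix", function(object) object@X)
setMethod("designMatrix", "PEBResult", function(object) object@design@X)
setMethod("modelProbabilities", "ModelSpace", function(object) object@probs)
setMethod("modelProbabilities", "BMAResult", function(object) object@modelProbs)
setMethod("pooledLogEvidence", "ModelSpace", function(object) object@pooledLogEv)
setMethod("posteriorProb", "BMAResult", function(object) object@pp)

setMethod("show", "GaussianBelief", function(object) {
  cat("GaussianBelief over", length(object@mean), "parameters",
      if (nzchar(object@label)) paste0("(", object@label, ")"), "\n")
  if (length(object@mean) <= 8) {
    cat("  mean:", signif(object@mean, 3), "\n")
    cat("  sd:  ", signif(sqrt(diag(object@cov)), 3), "\n")
  }
})

setMethod("show", "NetworkSpec", function(object) {
  cc <- edgeCounts(object)
  cat("NetworkSpec:", nrow(object@nodes), "sources (",
      paste(object@nodes$label, collapse = ", "), ")\n")
  cat("  edges: forward", cc["forward"], "| backward", cc["backward"],
      "| lateral", cc["lateral"], "\n")
  cat("  modes:", object@nModes, "| parameter dimension B =",
      paramDim(object), "\n")
})

setMethod("show", "CrossSpectralData", function(object) {
  d <- dim(object@csd)
  cat("CrossSpectralData: window", object@window, "|", d[1], "modes |",
      length(object@freqs), "frequencies (", min(object@freqs), "-",
      max(object@freqs), "Hz ) | fs =", object@fs, "Hz\n")
})

setMethod("show", "DesignMatrix", function(object) {
  cat("DesignMatrix:", nrow(object@X), "windows x", ncol(object@X),
      "regressors (", paste(object@labels, collapse = ", "), ")\n")
})

setMethod("show", "DCMPosterior", function(object) {
  cat("DCMPosterior: F =", format(object@F, digits = 6),
      "| explained variance =", sprintf("%.1f%%", object@ev),
      "|", length(object@trace), "accepted iterations\n")
})

setMethod("show", "PEBResult", function(object) {
  cat("PEBResult (", object@field, "): beta dim =",
      length(object@beta@mean), "| gamma =",
      signif(object@gamma, 4), "| F =", format(object@F, digits = 6), "\n")
})

setMethod("show", "ModelSpace", function(object) {
  cat("ModelSpace:", nrow(object@inclusion), "models,",
      nrow(object@subjectLogEv), "subjects\n")
  best <- which.max(object@pooledLogEv)
  cat("  winning model:", best, "( p =", signif(object@probs[best], 3), ")\n")
})

setMethod("show", "BMAResult", function(object) {
  cat("BMAResult over", length(object@mean), "parameters,",
      nrow(object@models), "models averaged;",
      sum(object@pp > 0.95), "parameters with Pp > .95\n")
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@beta), "connections x",
      ncol(object@beta), "regressors |", object@nWindows, "windows |",
      "window noise sd", object@windowNoiseSd, "\n")
})

setMethod("show", "SyntheticDataset", function(object) {
  cat("SyntheticDataset:", length(object@subjects), "subjects x",
      object@truth@nWindows, "windows (seed", object@seed, ")\n")
})
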