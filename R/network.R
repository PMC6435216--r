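#' Build a source network with typed extrinsic connections
#'
#' Constructs a [NetworkSpec-class] either from a named preset or from an
#' explicit node/edge description. Two presets are built in:
#' \describe{
#'   \item{dmn}{default mode network: bilateral lateral parietal sources
#'     (lLP, rLP), precuneus (Prec) and medial prefrontal cortex (mPFC);
#'     5 forward, 5 backward and 2 lateral connections.}
#'   \item{sal}{saliency network: bilateral lateral parietal (lLP, rLP),
#'     bilateral anterior prefrontal (laPFC, raPFC) and dorsal anterior
#'     cingulate (dACC) sources; 6 forward, 6 backward and 4 lateral
#'     connections.}
#' }
#' Forward edges ascend the hierarchy, each with a reciprocal backward edge;
#' lateral edges connect same-level sources in both directions.
#'
#' @param presetOrEdges `"dmn"`, `"sal"`, or a list with elements `nodes`
#'   (data.frame: label, x, y, z, level) and `edges` (data.frame: from, to,
#'   type).
#' @param nModes number of observation modes; defaults to the node count.
#' @return A [NetworkSpec-class].
#' @examples
#' dmn <- buildNetwork("dmn")
#' edgeCounts(dmn)
#' @export
buildNetwork <- function(presetOrEdges, nModes = NULL) {
  if (is.character(presetOrEdges)) {
    preset <- tolower(presetOrEdges)
    def <- switch(preset, dmn = .dmnPreset(), sal = .salPreset(),
                  stop("unknown network preset: ", presetOrEdges))
  } else if (is.list(presetOrEdges) &&
             all(c("nodes", "edges") %in% names(presetOrEdges))) {
    def <- presetOrEdges
  } else {
    stop("presetOrEdges must be a preset name or list(nodes=, edges=)")
  }
  nodes <- as.data.frame(def$nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(def$edges, stringsAsFactors = FALSE)
  if (is.null(nModes)) nModes <- nrow(nodes)
  new("NetworkSpec", nodes = nodes, edges = edges, nModes = as.integer(nModes))
}

.edgeDf <- function(from = character(), to = character(), type = character())
  data.frame(from = from, to = to, type = type, stringsAsFactors = FALSE)

# reciprocal backward edges for a set of forward edges
.withBackward <- function(fw) {
  rbind(fw, .edgeDf(fw$to, fw$from, rep("backward", nrow(fw))))
}

.dmnPreset <- function() {
  nodes <- data.frame(
    label = c("lLP", "rLP", "Prec", "mPFC"),
    x = c(-46, 49, 0, -1), y = c(-66, -63, -58, 54), z = c(30, 33, 0, 27),
    level = c(1L, 1L, 2L, 3L), stringsAsFactors = FALSE)
  fw <- .edgeDf(c("lLP", "rLP", "lLP", "rLP", "Prec"),
                c("Prec", "Prec", "mPFC", "mPFC", "mPFC"),
                rep("forward", 5))
  lat <- .edgeDf(c("lLP", "rLP"), c("rLP", "lLP"), rep("lateral", 2))
  list(nodes = nodes, edges = rbind(.withBackward(fw), lat))
}

.salPreset <- function() {
  nodes <- data.frame(
    label = c("lLP", "rLP", "laPFC", "raPFC", "dACC"),
    x = c(-62, 62, -35, 32, 0), y = c(-45, -45, 45, 45, 21),
    z = c(30, 30, 30, 30, 36),
    level = c(1L, 1L, 2L, 2L, 3L), stringsAsFactors = FALSE)
  fw <- .edgeDf(c("lLP", "rLP", "lLP", "rLP", "laPFC", "raPFC"),
                c("dACC", "dACC", "laPFC", "raPFC", "dACC", "dACC"),
                rep("forward", 6))
  lat <- .edgeDf(c("lLP", "rLP", "laPFC", "raPFC"),
                 c("rLP", "lLP", "raPFC", "laPFC"), rep("lateral", 4))
  list(nodes = nodes, edges = rbind(.withBackward(fw), lat))
}

#' @describeIn buildNetwork parameter dimension B: one log-gain per extrinsic
#'   edge, one innovations log-amplitude per source, a shared 1/f innovations
#'   log-amplitude, and white and 1/f observation-noise log-amplitudes.
#' @param object a NetworkSpec.
#' @export
setMethod("paramDim", "NetworkSpec", function(object) {
  nrow(object@edges) + nrow(object@nodes) + 3L
})

setMethod("paramNames", "NetworkSpec", function(object) {
  ed <- object@edges
  c(if (nrow(ed)) paste0("g_", substr(ed$type, 1, 1), "_", ed$from, ".", ed$to),
    paste0("a0_", object@nodes$label), "a1", "b0", "b1")
})

#' Indices of a parameter field within the window-level parameter vector
#'
#' @param spec a [NetworkSpec-class].
#' @param field one of `"forward"`, `"backward"`, `"lateral"`, `"gains"`
#'   (all extrinsic log-gains) or `"all"`.
#' @return integer indices into the length-B parameter vector.
#' @export
fieldIndices <- function(spec, field = c("all", "gains", "forward",
                                         "backward", "lateral")) {
  field <- match.arg(field)
  B <- paramDim(spec)
  nE <- nrow(spec@edges)
  switch(field,
         all = seq_len(B),
         gains = seq_len(nE),
         which(spec@edges$type == field))
}

#' Default priors over the window-level parameters
#'
#' Zero-mean Gaussian prior; each extrinsic log-gain has variance 1/16 (so at
#' the prior mean every baseline coupling is unscaled, exp(0) = 1). The
#' spectral and observation-noise log-amplitudes carry the tighter
#' conventional variance of 1/128: amplitude parameters trade off against
#' coupling gains in the spectral prediction, and constraining them is what
#' keeps the extrinsic gains identifiable from short windows.
#'
#' @param spec a [NetworkSpec-class].
#' @return A [GaussianBelief-class] of dimension `paramDim(spec)`.
#' @export
defaultPriors <- function(spec) {
  stopifnot(is(spec, "NetworkSpec"))
  B <- paramDim(spec)
  nE <- nrow(spec@edges)
  v <- c(rep(1 / 16, nE), rep(1 / 128, B - nE))
  bel <- gaussianBelief(rep(0, B), v, label = "window-level prior")
  names(bel@mean) <- paramNames(spec)
  bel
}

#' Write a network specification to a plain-text (YAML) file
#'
#' @param spec a [NetworkSpec-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeNetworkSpec <- function(spec, path) {
  obj <- list(
    nModes = spec@nModes,
    nodes = lapply(seq_len(nrow(spec@nodes)), function(i) {
      nd <- spec@nodes[i, ]
      list(label = nd$label, mni = c(nd$x, nd$y, nd$z), level = nd$level)
    }),
    edges = lapply(seq_len(nrow(spec@edges)), function(i) {
      ed <- spec@edges[i, ]
      list(from = ed$from, to = ed$to, type = ed$type)
    }))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a network specification from a YAML file
#'
#' @param path file written by [writeNetworkSpec()].
#' @return A [NetworkSpec-class].
#' @export
readNetworkSpec <- function(path) {
  obj <- yaml::read_yaml(path)
  nodes <- do.call(rbind, lapply(obj$nodes, function(n)
    data.frame(label = n$label, x = n$mni[1], y = n$mni[2], z = n$mni[3],
               level = as.integer(n$level), stringsAsFactors = FALSE)))
  edges <- do.call(rbind, lapply(obj$edges, function(e)
    data.frame(from = e$from, to = e$to, type = e$type,
               stringsAsFactors = FALSE)))
  if (is.null(edges)) edges <- .edgeDf()
  buildNetwork(list(nodes = nodes, edges = edges), nModes = obj$nModes)
}
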