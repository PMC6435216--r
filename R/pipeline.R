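#' Configuration for the end-to-end hierarchical analysis
#'
#' @param network preset name (`"dmn"`, `"sal"`) or a [NetworkSpec-class].
#' @param truth optional [GroundTruth-class] for the synthetic path; if
#'   `NULL`, `edfPaths` must point to recordings.
#' @param nSubjects subjects to simulate (synthetic path).
#' @param seed master seed; every stage derives its randomness from it.
#' @param edfPaths character vector of EDF files (real-data path).
#' @param winS window length in seconds.
#' @param nModes spatial modes retained for real data.
#' @param freqs frequency grid (Hz).
#' @param basisK DCT orders of the second-level design.
#' @param basisTau decay constant of the second-level design (windows).
#' @param fields connection types analysed at the second level.
#' @param refineIters outer iterations of the empirical-shrinkage refinement
#'   ([pebFit()]); 1 = independent window inversions.
#' @param maxIterVL variational-Laplace iteration cap per window.
#' @param finalSweepSize exhaustive-sweep size of the greedy search.
#' @param outputDir optional directory for exported tables and figures.
#' @return validated configuration list.
#' @export
pipelineConfig <- function(network = "dmn", truth = NULL, nSubjects = 8,
                           seed = 1L, edfPaths = NULL, winS = 1,
                           nModes = 8, freqs = 1:45, basisK = 2:4,
                           basisTau = 16, fields = c("forward", "backward",
                                                     "lateral"),
                           refineIters = 1, maxIterVL = 64,
                           finalSweepSize = 8, outputDir = NULL) {
  spec <- if (is(network, "NetworkSpec")) network else buildNetwork(network)
  if (basisTau <= 0) stop("decay constant must be positive")
  if (is.null(truth) && is.null(edfPaths))
    stop("either a GroundTruth or EDF paths must be given")
  if (!is.null(truth)) {
    if (abs(truth@fs * winS - round(truth@fs * winS)) > 1e-9)
      stop("window length times sampling rate must be integral")
  }
  structure(list(spec = spec, truth = truth, nSubjects = nSubjects,
                 seed = as.integer(seed), edfPaths = edfPaths, winS = winS,
                 nModes = nModes, freqs = freqs, basisK = basisK,
                 basisTau = basisTau, fields = fields,
                 refineIters = refineIters, maxIterVL = maxIterVL,
                 finalSweepSize = finalSweepSize, outputDir = outputDir),
            class = "dcmpebConfig")
}

# real-data path: EDF -> spatial modes -> windows -> MAR cross-spectra
.subjectFromEdf <- function(path, config) {
  rec <- readEdf(path)
  if (config$winS * rec$fs > ncol(rec$series))
    stop("window length exceeds recording: ", path)
  pm <- projectModes(rec$series, config$nModes)
  wins <- segmentWindows(pm$modes, rec$fs, config$winS)
  csd <- lapply(seq_along(wins), function(w)
    marCsd(wins[[w]], freqs = config$freqs, fs = rec$fs, windowIndex = w))
  list(csd = csd, projection = pm$projection)
}

#' Run the full three-level analysis
#'
#' Synthetic or real data are taken to per-window cross-spectral features;
#' each subject's windows are inverted (with optional empirical-shrinkage
#' refinement); a second-level PEB over the temporal basis functions is
#' estimated per connection type; all 2^4 reduced second-level models are
#' scored by Bayesian model reduction and compared with fixed-effects pooling
#' over subjects; a constant-only group PEB, greedy pruning with Bayesian
#' model averaging, and trajectory prediction complete the hierarchy.
#'
#' @param config a configuration from [pipelineConfig()].
#' @return a `dcmpebResults` list: per-subject window fits and diagnostics,
#'   per-field subject PEBs, model spaces, group PEBs, BMA results and
#'   predicted trajectories.
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "dcmpebConfig"))
  spec <- config$spec
  prior <- defaultPriors(spec)

  if (!is.null(config$truth)) {
    ds <- simulateGroup(config$truth, config$nSubjects, config$seed)
    subjectCsd <- lapply(ds@subjects, `[[`, "csd")
    gain <- ds@gain
  } else {
    loaded <- lapply(config$edfPaths, .subjectFromEdf, config = config)
    subjectCsd <- lapply(loaded, `[[`, "csd")
    ds <- NULL
    gain <- randomGain(config$nModes, nrow(spec@nodes), config$seed)
  }
  W <- length(subjectCsd[[1]])
  band <- range(config$freqs)

  fits <- lapply(seq_along(subjectCsd), function(s) {
    pebFit(subjectCsd[[s]], spec, prior, gain, maxIter = config$refineIters,
           modelBand = band, maxIterVL = config$maxIterVL)
  })
  diagnostics <- lapply(fits, function(f) vapply(f, explainedVar, 0))

  X <- buildDesign(W, k = config$basisK, tau = config$basisTau)
  inc <- enumerateReducedModels(ncol(X@X) - 1L,
                                labels = X@labels[X@labels != "constant"])
  fields <- config$fields[vapply(config$fields, function(f)
    length(fieldIndices(spec, f)) > 0, TRUE)]

  pebs <- list(); spaces <- list(); groups <- list(); bmas <- list()
  trajectories <- list()
  for (f in fields) {
    sp <- lapply(fits, function(ps) {
      pr <- attr(ps, "prior")
      pebEstimate(lapply(ps, posterior), pr, X, field = f, spec = spec)
    })
    logev <- t(vapply(sp, scoreModelSpace, numeric(nrow(inc)),
                      inclusion = inc))
    ms <- bmcOverSubjects(logev, inc)
    gp <- groupPeb(sp)
    bma <- greedySearchBma(gp, config$finalSweepSize)
    pebs[[f]] <- sp
    spaces[[f]] <- ms
    groups[[f]] <- gp
    bmas[[f]] <- bma
    trajectories[[f]] <- predictTrajectories(bma, X)
  }

  out <- structure(list(config = config, dataset = ds, gain = gain,
                        subjectFits = fits, design = X,
                        subjectPebs = pebs, modelSpaces = spaces,
                        groupPebs = groups, bmas = bmas,
                        trajectories = trajectories,
                        diagnostics = diagnostics),
                   class = "dcmpebResults")
  if (!is.null(config$outputDir)) exportResults(out, config$outputDir)
  out
}

#' @export
print.dcmpebResults <- function(x, ...) {
  cat("dcmpebResults:", length(x$subjectFits), "subjects,",
      nrow(x$design@X), "windows,", "fields:",
      paste(names(x$modelSpaces), collapse = ", "), "\n")
  for (f in names(x$modelSpaces)) {
    best <- which.max(pooledLogEvidence(x$modelSpaces[[f]]))
    cat("  ", f, ": winning second-level model", best, "| group Pp > .95 on",
        sum(posteriorProb(x$bmas[[f]]) > 0.95), "parameters\n")
  }
  invisible(x)
}

#' Split-half robustness check of the group-level analysis
#'
#' Randomly partitions the subjects into two near-equal subgroups (seeded,
#' deterministic) and repeats the pooled model comparison, group PEB, greedy
#' search/BMA and trajectory prediction within each half, re-using the
#' subject-level fits.
#'
#' @param fit a `dcmpebResults` from [runPipeline()].
#' @param seed partition seed.
#' @return list with `half1`, `half2` (each with modelSpaces, groupPebs,
#'   bmas, trajectories, subjects) covering all subjects exactly once.
#' @export
splitHalf <- function(fit, seed = 1L) {
  stopifnot(inherits(fit, "dcmpebResults"))
  n <- length(fit$subjectFits)
  if (n < 2) stop("split-half needs at least 2 subjects")
  perm <- .withSeed(seed, sample.int(n))
  g1 <- sort(perm[seq_len(ceiling(n / 2))])
  g2 <- sort(setdiff(seq_len(n), g1))
  inc <- enumerateReducedModels(ncol(fit$design@X) - 1L,
                                labels = fit$design@labels[
                                  fit$design@labels != "constant"])
  redo <- function(idx) {
    spaces <- list(); groups <- list(); bmas <- list(); traj <- list()
    for (f in names(fit$subjectPebs)) {
      sp <- fit$subjectPebs[[f]][idx]
      logev <- t(vapply(sp, scoreModelSpace, numeric(nrow(inc)),
                        inclusion = inc))
      spaces[[f]] <- bmcOverSubjects(logev, inc)
      groups[[f]] <- groupPeb(sp)
      bmas[[f]] <- greedySearchBma(groups[[f]],
                                   fit$config$finalSweepSize)
      traj[[f]] <- predictTrajectories(bmas[[f]], fit$design)
    }
    list(modelSpaces = spaces, groupPebs = groups, bmas = bmas,
         trajectories = traj)
  }
  h1 <- redo(g1); h1$subjects <- g1
  h2 <- redo(g2); h2$subjects <- g2
  list(half1 = h1, half2 = h2)
}

#' Export model-space, BMA and design tables as delimited text
#'
#' @param fit a `dcmpebResults`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
exportResults <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(cbind(window = seq_len(nrow(fit$design@X)),
                           fit$design@X),
                     file.path(dir, "design.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  for (f in names(fit$modelSpaces)) {
    ms <- fit$modelSpaces[[f]]
    utils::write.table(
      data.frame(model = seq_along(ms@pooledLogEv), ms@inclusion,
                 pooledLogEv = ms@pooledLogEv, prob = ms@probs),
      file.path(dir, paste0("model_space_", f, ".tsv")), sep = "\t",
      row.names = FALSE, quote = FALSE)
    bma <- fit$bmas[[f]]
    utils::write.table(
      data.frame(parameter = names(bma@mean), mean = bma@mean, pp = bma@pp),
      file.path(dir, paste0("bma_", f, ".tsv")), sep = "\t",
      row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}
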