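#' Fixed biophysical constants of the ERP neural mass model
#'
#' Second-order synaptic kernels per population (v'' = H k u - 2k v' - k^2 v)
#' with excitatory/inhibitory gains `He`/`Hi` (mV), rate constants `ke`/`ki`
#' (1/s), intrinsic coupling gains `g1..g4`, a fixed extrinsic baseline gain
#' scaled by exp(log-gain), the linearized sigmoid slope at the operating
#' point, intrinsic/extrinsic conduction delays (s), and the innovations
#' input amplitude `uamp` (sets the neuronal-to-observation-noise scale of
#' the predicted spectra at prior-mean log-amplitudes).
#'
#' @return named list of constants.
#' @export
erpConstants <- function() {
  list(He = 4, Hi = 32, ke = 1 / 0.008, ki = 1 / 0.016,
       g = c(1, 4 / 5, 1 / 4, 1 / 4) * 128,
       baseline = 32, slope = 0.15, di = 0.002, de = 0.016, uamp = 300)
}

# Build the C++ evaluation context: fixed Jacobian part, extrinsic coupling
# triplets, delay matrix, input/output projections, lead field, frequencies.
.modelContext <- function(spec, gain, freqs, constants = erpConstants()) {
  nS <- nrow(spec@nodes)
  nE <- nrow(spec@edges)
  nx <- 8L * nS
  k <- constants
  eff <- k$slope

  idx <- function(s, state) (s - 1L) * 8L + state

  # pyramidal depolarization is v_pyr_e - v_pyr_i (states 3 and 5); couplings
  # reading the pyramidal output therefore enter through both columns
  J0 <- matrix(0, nx, nx)
  D <- matrix(0, nx, nx)
  for (s in seq_len(nS)) {
    i <- function(state) idx(s, state)
    J0[i(1), i(2)] <- 1
    J0[i(2), i(3)] <- k$He * k$ke * k$g[1] * eff
    J0[i(2), i(5)] <- -k$He * k$ke * k$g[1] * eff
    J0[i(2), i(2)] <- -2 * k$ke
    J0[i(2), i(1)] <- -k$ke^2
    J0[i(3), i(4)] <- 1
    J0[i(4), i(1)] <- k$He * k$ke * k$g[2] * eff
    J0[i(4), i(4)] <- -2 * k$ke
    J0[i(4), i(3)] <- -k$ke^2
    J0[i(5), i(6)] <- 1
    J0[i(6), i(7)] <- k$Hi * k$ki * k$g[4] * eff
    J0[i(6), i(6)] <- -2 * k$ki
    J0[i(6), i(5)] <- -k$ki^2
    J0[i(7), i(8)] <- 1
    J0[i(8), i(3)] <- k$He * k$ke * k$g[3] * eff
    J0[i(8), i(5)] <- -k$He * k$ke * k$g[3] * eff
    J0[i(8), i(8)] <- -2 * k$ke
    J0[i(8), i(7)] <- -k$ke^2
    # intrinsic conduction delays on the between-population couplings
    D[i(2), i(3)] <- k$di
    D[i(2), i(5)] <- k$di
    D[i(4), i(1)] <- k$di
    D[i(6), i(7)] <- k$di
    D[i(8), i(3)] <- k$di
    D[i(8), i(5)] <- k$di
  }

  trEdge <- integer(0); trRow <- integer(0); trCol <- integer(0)
  trCoef <- numeric(0)
  lab <- spec@nodes$label
  if (nE > 0) {
    for (e in seq_len(nE)) {
      src <- match(spec@edges$from[e], lab)
      tgt <- match(spec@edges$to[e], lab)
      rows <- switch(spec@edges$type[e],
                     forward = idx(tgt, 2L),
                     backward = c(idx(tgt, 4L), idx(tgt, 8L)),
                     lateral = c(idx(tgt, 2L), idx(tgt, 4L), idx(tgt, 8L)))
      cols <- c(idx(src, 3L), idx(src, 5L))
      sgn <- c(1, -1)
      for (r in rows) for (q in 1:2) {
        trEdge <- c(trEdge, e - 1L)
        trRow <- c(trRow, r - 1L)
        trCol <- c(trCol, cols[q] - 1L)
        trCoef <- c(trCoef, sgn[q] * k$He * k$ke * k$baseline * eff)
        D[r, cols[q]] <- k$de
      }
    }
  }

  Bu <- matrix(0, nx, nS)
  Cx <- matrix(0, nS, nx)
  for (s in seq_len(nS)) {
    Bu[idx(s, 2L), s] <- k$He * k$ke * k$uamp
    Cx[s, idx(s, 3L)] <- 1
    Cx[s, idx(s, 5L)] <- -1
  }

  list(J0 = J0, trEdge = trEdge, trRow = trRow, trCol = trCol,
       trCoef = trCoef, D = D, Bu = Bu, Cx = Cx,
       L = gain, freqs = as.numeric(freqs), nE = nE, nS = nS)
}

.checkTheta <- function(theta, spec) {
  B <- paramDim(spec)
  if (length(theta) != B)
    stop("parameter vector has length ", length(theta), ", expected B = ", B)
  invisible(TRUE)
}

#' Delay-corrected Jacobian of the linearized network
#'
#' Assembles the full system Jacobian at the given parameters (intrinsic
#' dynamics plus exponentiated extrinsic couplings) and folds the conduction
#' delays in by a first-order Taylor correction.
#'
#' @param theta full parameter vector of length `paramDim(spec)` (log-gains
#'   first, in edge order).
#' @param spec a [NetworkSpec-class].
#' @param constants see [erpConstants()].
#' @return the delay-corrected Jacobian (8*sources square matrix).
#' @export
erpJacobian <- function(theta, spec, constants = erpConstants()) {
  .checkTheta(theta, spec)
  ctx <- .modelContext(spec, diag(nrow(spec@nodes)), 10, constants)
  gains <- theta[seq_len(ctx$nE)]
  J <- .cppBuildJ(as.numeric(gains), ctx$J0, as.integer(ctx$trEdge),
                  as.integer(ctx$trRow), as.integer(ctx$trCol), ctx$trCoef)
  .cppDelayCorrect(J, ctx$D)
}

#' Source-level frequency response of the network
#'
#' Frequency response from per-source innovations to pyramidal
#' depolarization: output-projection of the resolvent
#' (i 2 pi f I - J)^-1 of the delay-corrected Jacobian, computed through one
#' eigendecomposition.
#'
#' @param theta full parameter vector (see [erpJacobian()]).
#' @param spec a [NetworkSpec-class].
#' @param f frequency or frequency vector (Hz).
#' @param constants see [erpConstants()].
#' @return complex sources x sources matrix (single `f`), or a 3-d array over
#'   frequencies.
#' @export
transferMatrix <- function(theta, spec, f, constants = erpConstants()) {
  .checkTheta(theta, spec)
  Jd <- erpJacobian(theta, spec, constants)
  ctx <- .modelContext(spec, diag(nrow(spec@nodes)), f, constants)
  out <- .cppTransfer(Jd, ctx$Bu, ctx$Cx, as.numeric(f))
  if (out$maxre >= 0)
    stop("unstable linearized system: max Re(eigenvalue) = ",
         signif(out$maxre, 4))
  Tcube <- out$transfer
  if (length(f) == 1L) Tcube[, , 1] else Tcube
}

#' Predict the sensor-level cross-spectral density
#'
#' Total CSD(f) = L T(f) G_u(f) T(f)^H L^T + G_n(f): innovations with
#' source-specific white plus shared 1/f spectra are filtered through the
#' network transfer function and the gain (lead-field) matrix; channel noise
#' is a white plus 1/f mixture.
#'
#' @param theta full parameter vector; the trailing entries are the spectral
#'   log-amplitudes (a0 per source, shared a1, observation b0, b1).
#' @param spec a [NetworkSpec-class].
#' @param gain modes x sources gain matrix.
#' @param freqs frequency grid (Hz), default 1-45 Hz in 1 Hz steps.
#' @param constants see [erpConstants()].
#' @return A [CsdPrediction-class].
#' @export
predictCsd <- function(theta, spec, gain, freqs = 1:45,
                       constants = erpConstants()) {
  .checkTheta(theta, spec)
  if (!is.matrix(gain) || ncol(gain) != nrow(spec@nodes))
    stop("gain must be a modes x sources matrix with ",
         nrow(spec@nodes), " columns")
  ctx <- .modelContext(spec, gain, freqs, constants)
  out <- .cppCsd(as.numeric(theta), ctx)
  if (!out$ok)
    stop("unstable linearized system: max Re(eigenvalue) = ",
         signif(out$maxre, 4))
  new("CsdPrediction", freqs = as.numeric(freqs), total = out$total,
      neuronal = out$neuronal, noise = out$noise)
}

# stacked real feature vector (must match the C++ stacking order)
.stackCsdArray <- function(S) {
  m <- dim(S)[1]; nf <- dim(S)[3]
  up <- which(upper.tri(matrix(0, m, m)))
  out <- numeric(nf * m * m)
  p <- 0L
  for (k in seq_len(nf)) {
    Sk <- S[, , k, drop = TRUE]
    if (m == 1L) Sk <- matrix(Sk, 1, 1)
    v <- c(Re(diag(Sk)), Re(Sk[up]), Im(Sk[up]))
    out[p + seq_along(v)] <- v
    p <- p + length(v)
  }
  out
}

.unstackCsdArray <- function(feat, m, nf) {
  per <- m * m
  stopifnot(length(feat) == per * nf)
  up <- which(upper.tri(matrix(0, m, m)))
  S <- array(complex(real = 0), dim = c(m, m, nf))
  nu <- length(up)
  for (k in seq_len(nf)) {
    v <- feat[(k - 1L) * per + seq_len(per)]
    Sk <- matrix(complex(real = 0), m, m)
    diag(Sk) <- v[seq_len(m)]
    if (nu) {
      Sk[up] <- complex(real = v[m + seq_len(nu)],
                        imaginary = v[m + nu + seq_len(nu)])
      Sk <- Sk + Conj(t(Sk)) - diag(diag(Re(Sk)), m)
    }
    S[, , k] <- Sk
  }
  S
}

#' Stack a cross-spectral object into the real feature vector
#'
#' Per frequency: real diagonal, real upper triangle, imaginary upper
#' triangle. This is the feature representation the variational inversion
#' operates on; it is bijective with the Hermitian matrices.
#'
#' @param x a [CrossSpectralData-class] or [CsdPrediction-class].
#' @return numeric feature vector of length `frequencies * modes^2`.
#' @export
csdFeatures <- function(x) {
  if (is(x, "CrossSpectralData")) .stackCsdArray(x@csd)
  else if (is(x, "CsdPrediction")) .stackCsdArray(x@total)
  else stop("x must be CrossSpectralData or CsdPrediction")
}

#' Seeded random gain matrix with unit-norm columns
#'
#' Stand-in for an anatomical lead field (head modelling is out of scope):
#' each source projects to the modes through an independent random pattern
#' normalized to unit Euclidean norm.
#'
#' @param nModes number of observation modes.
#' @param nSources number of sources.
#' @param seed integer seed.
#' @return modes x sources matrix.
#' @export
randomGain <- function(nModes, nSources, seed = 1L) {
  .withSeed(seed, {
    L <- matrix(rnorm(nModes * nSources), nModes, nSources)
    sweep(L, 2, sqrt(colSums(L^2)), "/")
  })
}
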