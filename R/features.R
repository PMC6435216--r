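#' Segment a recording into consecutive non-overlapping windows
#'
#' @param series channels x samples numeric matrix.
#' @param fs sampling rate (Hz).
#' @param winS window length in seconds (default 1 s, so a 1-min recording at
#'   160 Hz yields 60 windows of 160 samples).
#' @return ordered list of channels x (fs*winS) matrices; any trailing
#'   remainder shorter than one window is dropped.
#' @export
segmentWindows <- function(series, fs, winS = 1) {
  if (!is.matrix(series) || ncol(series) == 0)
    stop("series must be a non-empty channels x samples matrix")
  n <- round(fs * winS)
  if (n < 2) stop("window must contain at least 2 samples")
  if (n > ncol(series)) stop("window longer than recording")
  W <- ncol(series) %/% n
  lapply(seq_len(W), function(w)
    series[, (w - 1L) * n + seq_len(n), drop = FALSE])
}

#' Project channels onto principal spatial modes
#'
#' Eigendecomposition of the channel covariance of the whole recording; the
#' projection matrix holds the leading m eigenvectors as orthonormal rows, so
#' all windows share one common feature space.
#'
#' @param series channels x samples matrix.
#' @param m number of modes to retain (default 8).
#' @return list with `modes` (m x samples), `projection` (m x channels,
#'   orthonormal rows) and `varianceRetained` (sum of the top-m covariance
#'   eigenvalues).
#' @export
projectModes <- function(series, m = 8) {
  nc <- nrow(series)
  if (m < 1 || m > nc) stop("m must lie in [1, channel count]")
  X <- series - rowMeans(series)
  C <- tcrossprod(X) / (ncol(series) - 1)
  eg <- eigen(.sym(C), symmetric = TRUE)
  P <- t(eg$vectors[, seq_len(m), drop = FALSE])
  list(modes = P %*% series, projection = P,
       varianceRetained = sum(eg$values[seq_len(m)]))
}

#' Cross-spectral density of one window by multivariate autoregression
#'
#' Fits a MAR(p) model by least squares (ridge-regularized only if the
#' regression is numerically singular) and evaluates the parametric spectrum
#' CSD(f) = A(f)^-1 Sigma A(f)^-H with
#' A(f) = I - sum_k A_k exp(-i 2 pi f k / fs).
#'
#' @param window modes x samples matrix.
#' @param order MAR lag count (default 8).
#' @param freqs frequency grid (Hz).
#' @param fs sampling rate (Hz).
#' @param windowIndex stored window index.
#' @return A [CrossSpectralData-class].
#' @export
marCsd <- function(window, order = 8, freqs = 1:45, fs, windowIndex = 1L) {
  m <- nrow(window)
  Tn <- ncol(window)
  if (Tn <= order * m)
    stop("need more than order*modes samples for an identifiable fit")
  X <- t(window - rowMeans(window))         # samples x modes
  Y <- X[(order + 1):Tn, , drop = FALSE]
  Z <- do.call(cbind, lapply(seq_len(order), function(k)
    X[(order + 1 - k):(Tn - k), , drop = FALSE]))
  G <- crossprod(Z)
  rk <- tryCatch(chol(G), error = function(e) NULL)
  if (is.null(rk)) {
    ridge <- 1e-6 * sum(diag(G)) / nrow(G)
    if (ridge <= 0) stop("singular MAR regression")
    G <- G + diag(ridge, nrow(G))
  }
  A <- solve(G, crossprod(Z, Y))            # (m*order) x m
  E <- Y - Z %*% A
  Sig <- crossprod(E) / (nrow(Y) - ncol(Z))
  Ak <- lapply(seq_len(order), function(k)
    t(A[(k - 1L) * m + seq_len(m), , drop = FALSE]))
  S <- array(complex(real = 0), dim = c(m, m, length(freqs)))
  for (j in seq_along(freqs)) {
    z <- exp(-2i * pi * freqs[j] * seq_len(order) / fs)
    Af <- diag(1 + 0i, m)
    for (k in seq_len(order)) Af <- Af - Ak[[k]] * z[k]
    Ai <- solve(Af)
    Sk <- Ai %*% Sig %*% Conj(t(Ai))
    S[, , j] <- (Sk + Conj(t(Sk))) / 2
  }
  new("CrossSpectralData", window = as.integer(windowIndex),
      freqs = as.numeric(freqs), csd = S, fs = fs, noiseSd = 0)
}

#' Explained variance of a cross-spectral prediction (percent)
#'
#' 100 * (1 - SS_res / SS_tot) over the stacked real and imaginary parts of
#' every matrix entry and frequency.
#'
#' @param observed a [CrossSpectralData-class].
#' @param predicted a [CsdPrediction-class] on the same grid and dimensions.
#' @return percent explained variance (can be negative for predictions worse
#'   than zero).
#' @export
explainedVariance <- function(observed, predicted) {
  if (!isTRUE(all.equal(observed@freqs, predicted@freqs)) ||
      !identical(dim(observed@csd), dim(predicted@total)))
    stop("observed and predicted grids/dimensions must match")
  y <- c(Re(observed@csd), Im(observed@csd))
  p <- c(Re(predicted@total), Im(predicted@total))
  100 * (1 - sum((y - p)^2) / sum(y^2))
}

#' Read a (EDF/EDF+) recording
#'
#' Minimal reader for continuous European-Data-Format files: parses the ASCII
#' header and 16-bit integer records and returns physically calibrated
#' signals. Annotation channels are dropped. Only equal-rate ordinary signals
#' are supported.
#'
#' @param path EDF file path.
#' @return list with `series` (channels x samples), `fs` (Hz) and `labels`.
#' @export
readEdf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- rawToChar(readBin(con, "raw", 256))
  nRec <- as.integer(substr(hdr, 237, 244))
  recDur <- as.numeric(substr(hdr, 245, 252))
  ns <- as.integer(substr(hdr, 253, 256))
  fld <- function(w) {
    x <- rawToChar(readBin(con, "raw", w * ns))
    trimws(substring(x, (seq_len(ns) - 1) * w + 1, seq_len(ns) * w))
  }
  labels <- fld(16); fld(80); fld(8)
  physMin <- as.numeric(fld(8)); physMax <- as.numeric(fld(8))
  digMin <- as.numeric(fld(8)); digMax <- as.numeric(fld(8))
  fld(80); nsamp <- as.integer(fld(8)); fld(32)
  keep <- !grepl("annotation", labels, ignore.case = TRUE)
  if (length(unique(nsamp[keep])) != 1)
    stop("signals with differing sampling rates are not supported")
  spr <- nsamp[keep][1]
  fs <- spr / recDur
  out <- matrix(0, sum(keep), nRec * spr)
  scale <- (physMax - physMin) / (digMax - digMin)
  for (r in seq_len(nRec)) {
    row <- 1L
    for (s in seq_len(ns)) {
      v <- readBin(con, "integer", nsamp[s], size = 2, endian = "little")
      if (keep[s]) {
        out[row, (r - 1L) * spr + seq_len(spr)] <-
          physMin[s] + scale[s] * (v - digMin[s])
        row <- row + 1L
      }
    }
  }
  list(series = out, fs = fs, labels = labels[keep])
}
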