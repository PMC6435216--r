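test_that("segmentation yields consecutive non-overlapping windows", {
  set.seed(1)
  x <- matrix(rnorm(2 * 9600), 2) # 60 s at 160 Hz
  w <- segmentWindows(x, fs = 160, winS = 1)
  expect_length(w, 60)
  expect_true(all(vapply(w, ncol, 0L) == 160))
  # 59.5 s: the 80-sample remainder is dropped
  w2 <- segmentWindows(x[, 1:9520], fs = 160, winS = 1)
  expect_length(w2, 59)
  # concatenating windows reproduces the truncated series exactly
  expect_equal(do.call(cbind, w2), x[, 1:9440])
  expect_error(segmentWindows(x[, 1:80], fs = 160, winS = 1),
               "longer than recording")
})

test_that("mode projection is orthonormal and captures top eigenvariance", {
  set.seed(2)
  mix <- matrix(rnorm(6 * 3), 6, 3)
  x <- mix %*% matrix(rnorm(3 * 2000), 3) + 0.1 * matrix(rnorm(6 * 2000), 6)
  pm <- projectModes(x, 3)
  expect_equal(pm$projection %*% t(pm$projection), diag(3), tolerance = 1e-10)
  ev <- eigen(cov(t(x)), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(pm$varianceRetained, sum(ev[1:3]), tolerance = 1e-8)
  # complete basis retains everything
  pall <- projectModes(x, 6)
  expect_equal(pall$varianceRetained, sum(ev), tolerance = 1e-8)
  expect_error(projectModes(x, 7), "channel count")
})

test_that("MAR spectrum matches the closed-form AR(1) spectrum", {
  set.seed(3)
  a <- 0.6; sigma <- 1.5; fs <- 160
  n <- 20000
  x <- as.numeric(stats::filter(rnorm(n, 0, sigma), a, "recursive"))
  fr <- seq(2, 44, by = 6)
  cs <- marCsd(matrix(x, 1), order = 8, freqs = fr, fs = fs)
  got <- Re(cs@csd[1, 1, ])
  oracle <- sigma^2 / Mod(1 - a * exp(-2i * pi * fr / fs))^2
  expect_lt(max(abs(got - oracle) / oracle), 0.10)
})

test_that("white noise gives a flat MAR spectrum", {
  set.seed(4)
  x <- matrix(rnorm(10000), 1)
  cs <- marCsd(x, order = 8, freqs = seq(2, 44, 2), fs = 160)
  s <- Re(cs@csd[1, 1, ])
  expect_lt(max(s) / min(s), 2)
})

test_that("MAR cross-spectra are Hermitian and permutation-equivariant", {
  set.seed(5)
  x <- matrix(rnorm(3 * 4000), 3)
  x[2, ] <- x[2, ] + 0.5 * c(0, x[1, -4000]) # lagged coupling
  fr <- seq(4, 40, 6)
  cs <- marCsd(x, order = 4, freqs = fr, fs = 160)
  for (k in seq_along(fr)) {
    S <- cs@csd[, , k]
    expect_lt(max(Mod(S - Conj(t(S)))), 1e-10 * max(Mod(S)))
  }
  perm <- c(3, 1, 2)
  cs2 <- marCsd(x[perm, ], order = 4, freqs = fr, fs = 160)
  expect_equal(cs2@csd, cs@csd[perm, perm, ], tolerance = 1e-8)
})

test_that("explained variance matches the stacked-residual definition", {
  ch <- chainSpec()
  th <- rep(0, paramDim(ch))
  L <- chainGain()
  fr <- fastFreqs()
  pc <- predictCsd(th, ch, L, fr)
  obs <- new("CrossSpectralData", window = 1L, freqs = fr, csd = pc@total,
             fs = 160, noiseSd = 0)
  expect_equal(explainedVariance(obs, pc), 100)
  zero <- new("CsdPrediction", freqs = fr,
              total = array(0i, dim(pc@total)),
              neuronal = array(0i, dim(pc@total)),
              noise = array(0i, dim(pc@total)))
  expect_equal(explainedVariance(obs, zero), 0)
  # 2x2 single-frequency worked case, stacked real/imaginary arithmetic
  y <- array(c(2 + 0i, 1 - 1i, 1 + 1i, 3 + 0i), dim = c(2, 2, 1))
  p <- array(c(1 + 0i, 1 - 0.5i, 1 + 0.5i, 2 + 0i), dim = c(2, 2, 1))
  o2 <- new("CrossSpectralData", window = 1L, freqs = 10, csd = y, fs = 160)
  p2 <- new("CsdPrediction", freqs = 10, total = p,
            neuronal = p, noise = array(0i, dim(p)))
  ssr <- sum((c(Re(y), Im(y)) - c(Re(p), Im(p)))^2)
  sst <- sum(c(Re(y), Im(y))^2)
  expect_equal(explainedVariance(o2, p2), 100 * (1 - ssr / sst))
  expect_error(explainedVariance(obs, p2), "match")
})

test_that("feature stacking is a bijection with Hermitian matrices", {
  ch <- chainSpec()
  pc <- predictCsd(rep(0, paramDim(ch)), ch, chainGain(), fastFreqs())
  f <- csdFeatures(pc)
  back <- dcmpeb:::.unstackCsdArray(f, 2, length(fastFreqs()))
  expect_equal(back, pc@total, tolerance = 1e-12)
})

test_that("the EDF adapter reads a minimal calibrated recording", {
  # write a 2-channel, 2-record EDF file from scratch
  path <- tempfile(fileext = ".edf")
  con <- file(path, "wb")
  pad <- function(x, w) writeChar(formatC(x, width = -w), con, w, eos = NULL)
  ns <- 2; nRec <- 2; spr <- 16
  pad("0", 8); pad("patient", 80); pad("recording", 80)
  pad("01.01.20", 8); pad("00.00.00", 8)
  pad(as.character(256 + ns * 256), 8); pad("", 44)
  pad(as.character(nRec), 8); pad("0.1", 8); pad(as.character(ns), 4)
  pad("C3", 16); pad("C4", 16)
  pad("", 80); pad("", 80)
  pad("uV", 8); pad("uV", 8)
  pad("-100", 8); pad("-100", 8); pad("100", 8); pad("100", 8)
  pad("-2048", 8); pad("-2048", 8); pad("2047", 8); pad("2047", 8)
  pad("", 80); pad("", 80)
  pad(as.character(spr), 8); pad(as.character(spr), 8)
  pad("", 32); pad("", 32)
  set.seed(6)
  dig <- matrix(sample(-2048:2047, ns * nRec * spr, replace = TRUE),
                nrow = ns)
  for (r in 1:nRec) for (s in 1:ns)
    writeBin(as.integer(dig[s, (r - 1) * spr + 1:spr]), con, size = 2,
             endian = "little")
  close(con)

  rec <- readEdf(path)
  expect_equal(rec$fs, spr / 0.1)
  expect_equal(rec$labels, c("C3", "C4"))
  expect_equal(dim(rec$series), c(2L, nRec * spr))
  # physical calibration: -2048..2047 digital -> -100..100 physical
  expect_equal(rec$series,
               -100 + (200 / 4095) * (dig + 2048), tolerance = 1e-10,
               ignore_attr = TRUE)
  unlink(path)
})
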