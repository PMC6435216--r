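#' Bar plot of the pooled second-level model evidence
#'
#' @param ms a [ModelSpace-class].
#' @param main plot title.
#' @return invisibly, the plotted relative log evidences.
#' @export
plotModelSpace <- function(ms, main = "second-level model comparison") {
  le <- ms@pooledLogEv - max(ms@pooledLogEv)
  graphics::barplot(le, names.arg = seq_along(le),
                    xlab = "model", ylab = "relative log evidence",
                    main = main, col = "steelblue", border = NA)
  invisible(le)
}

#' Bar plot of model-averaged second-level parameters
#'
#' Parameters with posterior probability above `ppStar` are starred.
#'
#' @param bma a [BMAResult-class].
#' @param ppStar star threshold (default 0.95).
#' @param main plot title.
#' @return invisibly, the plotted means.
#' @export
plotBma <- function(bma, ppStar = 0.95, main = "group BMA parameters") {
  mu <- bma@mean
  bp <- graphics::barplot(mu, names.arg = seq_along(mu), las = 2,
                          ylab = "posterior mean (log gain)", main = main,
                          col = ifelse(bma@pp > ppStar, "firebrick", "grey70"),
                          border = NA)
  star <- bma@pp > ppStar
  if (any(star))
    graphics::text(bp[star], mu[star], "*", pos = ifelse(mu[star] >= 0, 3, 1))
  invisible(mu)
}

#' Predicted connectivity trajectories with credible bands
#'
#' @param traj output of [predictTrajectories()].
#' @param main plot title.
#' @return invisibly, the trajectory matrix.
#' @export
plotTrajectories <- function(traj, main = "predicted trajectories") {
  Y <- traj$trajectory
  W <- nrow(Y)
  graphics::matplot(seq_len(W), Y, type = "l", lty = 1, lwd = 2,
                    xlab = "window", ylab = "log gain", main = main,
                    ylim = range(traj$lower, traj$upper))
  for (b in seq_len(ncol(Y)))
    graphics::polygon(c(seq_len(W), rev(seq_len(W))),
                      c(traj$lower[, b], rev(traj$upper[, b])),
                      col = grDevices::adjustcolor(b, alpha.f = 0.15),
                      border = NA)
  invisible(Y)
}
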