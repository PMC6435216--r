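# internal numeric helpers

# evaluate expr under a temporary RNG seed, restoring global RNG state
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed))
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  force(expr)
}

.sym <- function(A) (A + t(A)) / 2

# log-determinant of a symmetric positive definite matrix
.logdet <- function(A) {
  ch <- tryCatch(chol(.sym(A)), error = function(e) NULL)
  if (is.null(ch)) return(NA_real_)
  2 * sum(log(diag(ch)))
}

.solveSym <- function(A, b = NULL) {
  A <- .sym(A)
  if (is.null(b)) b <- diag(nrow(A))
  tryCatch(solve(A, b), error = function(e) {
    solve(A + diag(1e-10 * max(1, max(abs(diag(A)))), nrow(A)), b)
  })
}

.softmax <- function(x) {
  x <- x - max(x)
  e <- exp(x)
  e / sum(e)
}

# KL(N(m1,C1) || N(m0,C0)); P0 = inv(C0) supplied
.klGauss <- function(m1, C1, m0, P0, logdetC0) {
  d <- m1 - m0
  0.5 * (sum(d * (P0 %*% d)) + sum(diag(P0 %*% C1)) -
           (.logdet(C1) - logdetC0) - length(m1))
}
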