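#' @importFrom rlang abort warn inform %||% .data
#' @importFrom stats approx cor median pnorm sd setNames
#' @importFrom utils head tail
NULL

# sin(x)/x with the removable singularity filled in
sinc <- function(x) {
  out <- rep(1, length(x))
  nz <- x != 0
  out[nz] <- sin(x[nz]) / x[nz]
  out
}

# lag-1 autocorrelation of a vector, normalised by its sum of squares
lag1_autocorr <- function(v) {
  n <- length(v)
  if (n < 2L) return(NA_real_)
  ss <- sum(v^2)
  if (ss == 0) return(0)
  sum(v[-1] * v[-n]) / ss
}

# trapezoidal quadrature weights on an arbitrary grid
trapz_weights <- function(x) {
  n <- length(x)
  w <- numeric(n)
  w[1] <- (x[2] - x[1]) / 2
  w[n] <- (x[n] - x[n - 1]) / 2
  if (n > 2) w[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / 2
  w
}

trapz_int <- function(x, y) sum(trapz_weights(x) * y)

# Wald-Wolfowitz runs test on the signs of a residual vector (normal
# approximation); small p-values flag systematic (correlated) residuals.
runs_test_pvalue <- function(resid) {
  sgn <- sign(resid)
  sgn <- sgn[sgn != 0]
  n1 <- sum(sgn > 0)
  n2 <- sum(sgn < 0)
  n <- n1 + n2
  if (n < 2L || n1 == 0L || n2 == 0L) return(0)
  runs <- 1L + sum(sgn[-1] != sgn[-n])
  mu <- 1 + 2 * n1 * n2 / n
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  if (v <= 0) return(1)
  2 * pnorm(-abs((runs - mu) / sqrt(v)))
}

stop_saxsmix <- function(msg, class) {
  abort(msg, class = c(class, "saxsmix_error"))
}

# Lawson-Hanson active-set non-negative least squares:
# min ||A x - b||_2 subject to x >= 0. Written out in full because the
# ALS and IFT solvers need a generous iteration budget on
# ill-conditioned weighted systems.
nnls_solve <- function(A, b, tol = NULL, max_iter = NULL) {
  n <- ncol(A)
  tol <- tol %||% (10 * .Machine$double.eps * norm(A, "F") * max(1, sqrt(n)))
  max_iter <- max_iter %||% (100L * n)
  x <- numeric(n)
  passive <- logical(n)
  w <- crossprod(A, b - A %*% x)
  iter <- 0L
  while (any(!passive & w > tol) && iter < max_iter) {
    iter <- iter + 1L
    j <- which.max(ifelse(passive, -Inf, w))
    passive[j] <- TRUE
    repeat {
      idx <- which(passive)
      z <- numeric(n)
      sol <- tryCatch(
        qr.solve(A[, idx, drop = FALSE], b),
        error = function(e) rep(0, length(idx))
      )
      z[idx] <- sol
      if (all(z[idx] > tol)) {
        x <- z
        break
      }
      neg <- idx[z[idx] <= tol]
      alpha <- min(x[neg] / (x[neg] - z[neg] + .Machine$double.eps))
      x <- x + alpha * (z - x)
      passive[x <= tol] <- FALSE
      x[!passive] <- 0
      if (!any(passive)) {
        x <- numeric(n)
        break
      }
    }
    w <- crossprod(A, b - A %*% x)
  }
  x
}
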