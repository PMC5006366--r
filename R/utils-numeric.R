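# Internal numerical helpers: finite-difference Jacobians and a PSD matrix
# square root. Central differences are used throughout; the models are cheap
# to evaluate and the step is scaled to the magnitude of each coordinate.

fd_step <- function(x) 1e-6 * pmax(1, abs(x))

# Jacobian of vector-valued fn(v) with respect to v (central differences).
fd_jacobian <- function(fn, v) {
  n <- length(v)
  f0 <- fn(v)
  J <- matrix(0, length(f0), n)
  h <- fd_step(v)
  for (i in seq_len(n)) {
    vp <- v; vm <- v
    vp[i] <- vp[i] + h[i]
    vm[i] <- vm[i] - h[i]
    J[, i] <- (fn(vp) - fn(vm)) / (2 * h[i])
  }
  J
}

# Gradient of scalar fn(v) restricted to coordinates `idx` (others fixed).
fd_gradient <- function(fn, v, idx = seq_along(v)) {
  g <- numeric(length(v))
  h <- fd_step(v)
  for (i in idx) {
    vp <- v; vm <- v
    vp[i] <- vp[i] + h[i]
    vm[i] <- vm[i] - h[i]
    g[i] <- (fn(vp) - fn(vm)) / (2 * h[i])
  }
  g
}

# Lower-triangular Cholesky factor of a PSD matrix, with an eigen fallback
# for singular matrices (e.g. a zero covariance).
psd_sqrt <- function(S) {
  S <- (S + t(S)) / 2
  ch <- tryCatch(t(chol(S)), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  e <- eigen(S, symmetric = TRUE)
  if (any(e$values < -1e-10 * max(abs(e$values), 1)))
    stop("matrix is not positive semidefinite")
  e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow = nrow(S))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
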