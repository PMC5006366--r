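#' Radau collocation nodes on the unit interval
#'
#' Right-Radau points for a given polynomial degree: the nodes of the
#' Radau IIA quadrature/collocation scheme, which always include the right
#' endpoint 1. For degree 3 (the default used throughout the package) the
#' nodes are \eqn{(4-\sqrt 6)/10}, \eqn{(4+\sqrt 6)/10} and \eqn{1}.
#'
#' The induced quadrature with [radau_weights()] integrates polynomials up to
#' degree \eqn{2d-2} exactly on \eqn{[0,1]}.
#'
#' @param degree number of collocation nodes per finite element (>= 1).
#' @return numeric vector of `degree` strictly increasing nodes in (0, 1].
#' @export
#' @examples
#' radau_nodes(3)
radau_nodes <- function(degree = 3) {
  if (!is.numeric(degree) || length(degree) != 1 || degree < 1 ||
      degree != round(degree))
    stop("unsupported degree: must be a positive integer")
  d <- as.integer(degree)
  if (d == 1) return(1)
  # Left-Radau nodes on [-1,1] are the roots of P_{d-1}(x) + P_d(x)
  # (including x = -1); right-Radau nodes are their reflection.
  cf <- legendre_coef(d - 1, d + 1) + legendre_coef(d, d + 1)
  r <- polyroot(cf)
  r <- Re(r[abs(Im(r)) < 1e-8])
  tau_left <- sort((r + 1) / 2)
  sort(1 - tau_left)
}

# Coefficients of the Legendre polynomial P_n in the power basis,
# ascending order, zero-padded to length `len`.
legendre_coef <- function(n, len = n + 1) {
  polys <- list(c(1), c(0, 1))
  if (n >= 2) {
    for (k in 2:n) {
      a <- c(0, polys[[k]]) * (2 * k - 1) / k         # x * P_{k-1}
      b <- c(polys[[k - 1]], rep(0, 2)) * (k - 1) / k  # P_{k-2}, padded
      polys[[k + 1]] <- a - b[seq_along(a)]
    }
  }
  p <- polys[[n + 1]]
  c(p, rep(0, len - length(p)))
}

#' Quadrature weights for the Radau nodes
#'
#' Weights of the right-Radau quadrature rule on \eqn{[0,1]} associated with
#' [radau_nodes()]; exact for polynomials up to degree \eqn{2d-2}.
#'
#' @inheritParams radau_nodes
#' @return numeric vector of positive weights summing to 1.
#' @export
radau_weights <- function(degree = 3) {
  tau <- radau_nodes(degree)
  d <- length(tau)
  # integrate the Lagrange basis through the nodes
  V <- outer(tau, 0:(d - 1), `^`)
  moments <- 1 / (1:d)           # integral of t^k over [0,1]
  drop(solve(t(V), moments))
}

# Collocation matrices for one finite element, following the standard
# Lagrange-polynomial construction: interpolation points are the element
# start (tau = 0) plus the `degree` Radau nodes; the interpolating
# polynomial has degree `degree`.
#
# Returns:
#   tau  - all interpolation points c(0, radau nodes)
#   C    - (degree+1) x degree matrix, C[j, r] = dL_j/dtau at radau node r
#   D    - length degree+1, L_j evaluated at tau = 1 (continuity map)
#   B    - quadrature weights at the radau nodes
colloc_matrices <- function(degree = 3) {
  nodes <- radau_nodes(degree)
  tau <- c(0, nodes)
  d1 <- length(tau)
  V <- outer(tau, 0:(d1 - 1), `^`)
  C <- matrix(0, d1, degree)
  D <- numeric(d1)
  for (j in seq_len(d1)) {
    ej <- numeric(d1); ej[j] <- 1
    cj <- solve(V, ej)                       # power-basis coefficients of L_j
    dcj <- cj[-1] * seq_len(d1 - 1)          # derivative coefficients
    C[j, ] <- vapply(nodes, function(x) sum(dcj * x^(0:(d1 - 2))), 0)
    D[j] <- sum(cj)
  }
  list(tau = tau, C = C, D = D, B = radau_weights(degree), degree = degree)
}
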