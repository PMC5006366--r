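#' Parametric uncertainty specification
#'
#' Describes the joint distribution of the uncertain model parameters:
#' a `normal` or `uniform` family with mean `theta_nom` and covariance
#' `Sigma`. The common case of independent parameters with a shared
#' relative standard deviation is expressed with `rel_std`, which generates
#' the diagonal `Sigma = diag((rel_std * theta_nom)^2)`. Uniform marginals
#' are parameterized by mean and standard deviation, i.e. support
#' `theta_nom +/- sqrt(3) * std`.
#'
#' @param family `"normal"` or `"uniform"`.
#' @param theta_nom named nominal parameter vector.
#' @param rel_std scalar relative standard deviation (alternative to
#'   `Sigma`).
#' @param Sigma covariance matrix (parameter^2 units).
#' @return an object of class `uncertainty_spec`.
#' @export
uncertainty_spec <- function(family = c("normal", "uniform"), theta_nom,
                             rel_std = NULL, Sigma = NULL) {
  family <- match.arg(family)
  n <- length(theta_nom)
  if (is.null(Sigma)) {
    if (is.null(rel_std)) stop("supply rel_std or Sigma")
    Sigma <- diag((rel_std * as.numeric(theta_nom))^2, n)
  }
  Sigma <- as.matrix(Sigma)
  if (nrow(Sigma) != n || ncol(Sigma) != n)
    stop("Sigma dimension does not match theta_nom")
  if (max(abs(Sigma - t(Sigma))) > 1e-12) stop("Sigma must be symmetric")
  ev <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1))
    stop("Sigma must be positive semidefinite")
  structure(list(family = family, theta_nom = as.numeric(theta_nom),
                 param_names = names(theta_nom), rel_std = rel_std,
                 Sigma = Sigma, n_theta = n),
            class = "uncertainty_spec")
}

#' @export
print.uncertainty_spec <- function(x, ...) {
  cat("uncertainty_spec:", x$family, "family,", x$n_theta, "parameters\n")
  cat("  mean:", paste(signif(x$theta_nom, 4), collapse = ", "), "\n")
  cat("  std :", paste(signif(sqrt(diag(x$Sigma)), 4), collapse = ", "), "\n")
  invisible(x)
}

#' Sigma points of the unscented transform
#'
#' Builds the `2 n_theta + 1` deterministic sampling points
#' `pi_0 = theta_nom`, `pi_i = theta_nom +/- column_i sqrt((n_theta + kappa)
#' Sigma)` with the scaling `kappa = 3 - n_theta`. The matrix square root is
#' the lower-triangular Cholesky factor (with an eigen fallback for
#' singular covariances). The weighted mean and covariance of the points
#' reproduce `theta_nom` and `Sigma` exactly.
#'
#' @param spec an [uncertainty_spec()].
#' @return an object of class `sigma_point_set` with fields `points`
#'   (one row per point), `kappa` and mean `weights`.
#' @export
generate_sigma_points <- function(spec) {
  n <- spec$n_theta
  kappa <- 3 - n
  root <- psd_sqrt((n + kappa) * spec$Sigma)
  pts <- matrix(spec$theta_nom, 2 * n + 1, n, byrow = TRUE)
  for (i in seq_len(n)) {
    pts[1 + i, ] <- spec$theta_nom + root[, i]
    pts[1 + n + i, ] <- spec$theta_nom - root[, i]
  }
  w <- c(kappa, rep(0.5, 2 * n)) / (n + kappa)
  structure(list(points = pts, kappa = kappa, weights = w, n_theta = n),
            class = "sigma_point_set")
}

#' Moments from sigma-point evaluations
#'
#' Weighted mean and variance of a quantity evaluated at the sigma points,
#' exact for affine functions of the parameters and matching second-order
#' Taylor accuracy otherwise.
#'
#' @param values numeric vector of `2 n_theta + 1` evaluations, ordered as
#'   the rows of [generate_sigma_points()].
#' @param kappa the scaling used to build the points.
#' @return list with elements `E` and `Var`.
#' @export
sigma_point_moments <- function(values, kappa) {
  m <- length(values)
  if (m %% 2 != 1) stop("expected 2*n_theta + 1 values")
  n <- (m - 1) / 2
  E <- (kappa * values[1] + 0.5 * sum(values[-1])) / (n + kappa)
  Var <- (kappa * (values[1] - E)^2 +
            0.5 * sum((values[-1] - E)^2)) / (n + kappa)
  list(E = E, Var = Var)
}

## ---- polynomial chaos expansion -------------------------------------------

# Evaluate the probabilists' Hermite polynomial He_n at x (recurrence).
hermite_eval <- function(n, x) {
  if (n == 0) return(rep(1, length(x)))
  hm1 <- rep(1, length(x)); h <- x
  if (n == 1) return(h)
  for (k in 2:n) {
    hp <- x * h - (k - 1) * hm1
    hm1 <- h; h <- hp
  }
  h
}

# Evaluate the Legendre polynomial P_n at z in [-1,1].
legendre_eval <- function(n, z) {
  if (n == 0) return(rep(1, length(z)))
  pm1 <- rep(1, length(z)); p <- z
  if (n == 1) return(p)
  for (k in 2:n) {
    pp <- ((2 * k - 1) * z * p - (k - 1) * pm1) / k
    pm1 <- p; p <- pp
  }
  p
}

# Univariate basis value in standardized coordinates xi (unit variance):
# normal -> He_n(xi); uniform -> P_n(xi / sqrt(3)).
pce_phi1 <- function(family, n, xi) {
  if (family == "normal") hermite_eval(n, xi) else legendre_eval(n, xi / sqrt(3))
}

pce_norm1 <- function(family, n) {
  if (family == "normal") factorial(n) else 1 / (2 * n + 1)
}

# Roots of the degree-(p+1) univariate orthogonal polynomial in
# standardized coordinates; these are the candidate collocation abscissae.
pce_roots1 <- function(family, p) {
  clean <- function(r) { r[abs(r) < 1e-12] <- 0; r }
  if (family == "normal") {
    # He_{p+1} roots: p=1 -> +/-1; p=2 -> 0, +/-sqrt(3); general: Jacobi matrix
    J <- matrix(0, p + 1, p + 1)
    for (k in seq_len(p)) J[k, k + 1] <- J[k + 1, k] <- sqrt(k)
    clean(sort(eigen(J, symmetric = TRUE, only.values = TRUE)$values))
  } else {
    # Gauss-Legendre abscissae scaled to the uniform(-sqrt(3), sqrt(3)) support
    J <- matrix(0, p + 1, p + 1)
    for (k in seq_len(p)) {
      b <- k / sqrt(4 * k^2 - 1)
      J[k, k + 1] <- J[k + 1, k] <- b
    }
    clean(sqrt(3) * sort(eigen(J, symmetric = TRUE, only.values = TRUE)$values))
  }
}

# Multi-indices of total degree <= p over n variables, ordered by total
# degree then lexicographically; the first index is the constant term.
pce_indices <- function(n, p) {
  g <- as.matrix(expand.grid(rep(list(0:p), n)))[, n:1, drop = FALSE]
  g <- g[rowSums(g) <= p, , drop = FALSE]
  g[order(rowSums(g), apply(g, 1, paste, collapse = "")), , drop = FALSE]
}

#' Build a polynomial chaos basis
#'
#' Constructs the distribution-matched multivariate orthogonal polynomial
#' basis of total degree at most `p`: probabilists' Hermite polynomials for
#' the normal family and Legendre polynomials (after affine standardization
#' of the uniform support) for the uniform family. Parameters are
#' standardized to zero-mean unit-variance coordinates before basis
#' construction. The basis carries its term count
#' `L = (n_theta + p)! / (n_theta! p!)`, the analytic norms `E[Phi_j^2]`,
#' the `n_s = L` regression sampling points selected by
#' [select_sampling_points()], and the regression matrix `Lambda`
#' (basis functions evaluated at the sampling points).
#'
#' @param spec an [uncertainty_spec()].
#' @param p polynomial order (1 and 2 are the exercised orders).
#' @return an object of class `pce_basis`.
#' @export
build_pce_basis <- function(spec, p) {
  if (!spec$family %in% c("normal", "uniform"))
    stop("unsupported family: ", spec$family)
  n <- spec$n_theta
  idx <- pce_indices(n, p)
  L <- nrow(idx)
  norms <- apply(idx, 1, function(a)
    prod(vapply(a, function(k) pce_norm1(spec$family, k), 0)))
  basis <- structure(list(
    family = spec$family, p = p, n_theta = n, indices = idx, L = L,
    n_s = L, norms = norms,
    transform = psd_sqrt(spec$Sigma),  # theta = theta_nom + transform %*% xi_corr
    theta_nom = spec$theta_nom
  ), class = "pce_basis")
  sel <- select_sampling_points(basis, spec)
  basis$points_std <- sel$points_std
  basis$points <- sel$points
  basis$Lambda <- sel$Lambda
  basis$n_s <- nrow(sel$points_std)
  basis$condition <- sel$condition
  basis
}

# Evaluate all basis terms at standardized points (rows). Returns L x n_s.
pce_eval_basis <- function(basis, xi) {
  out <- matrix(0, basis$L, nrow(xi))
  for (i in seq_len(basis$L)) {
    a <- basis$indices[i, ]
    val <- rep(1, nrow(xi))
    for (d in seq_len(ncol(xi)))
      if (a[d] > 0) val <- val * pce_phi1(basis$family, a[d], xi[, d])
    out[i, ] <- val
  }
  out
}

#' Select PCE regression sampling points
#'
#' Probabilistic-collocation point selection: candidate points are the
#' tensor combinations of the roots of the degree-`(p+1)` univariate
#' orthogonal polynomial; they are ranked by joint probability density
#' (ties broken by proximity to the mean, then lexicographically), the
#' nominal parameter vector is always included, and points are added
#' greedily while they increase the rank of the regression matrix until
#' `n_s = L` points are selected. If the greedy pass cannot reach full
#' rank, the `2L` best-ranked candidates are used in a least-squares
#' design. For the normal family with `p = 2` and three parameters the
#' sigma-point set is a subset of the selection.
#'
#' @param basis a [build_pce_basis()] result (the polynomial part is used).
#' @param spec the matching [uncertainty_spec()].
#' @return list with `points_std` (standardized coordinates), `points`
#'   (parameter vectors, one row per point), `Lambda` and the design
#'   `condition` number.
#' @export
select_sampling_points <- function(basis, spec) {
  if (max(abs(spec$Sigma)) == 0)
    stop("degenerate uncertainty (Sigma = 0): sampling points coincide")
  n <- basis$n_theta
  r1 <- pce_roots1(spec$family, basis$p)
  cand <- as.matrix(expand.grid(rep(list(r1), n)))
  colnames(cand) <- NULL
  # always include the mean
  if (!any(rowSums(abs(cand)) < 1e-12)) cand <- rbind(0, cand)
  dens <- if (spec$family == "normal") {
    rowSums(stats::dnorm(cand, log = TRUE))
  } else rep(0, nrow(cand))            # uniform: constant density
  ord <- order(-dens, rowSums(cand != 0), apply(cand, 1, paste, collapse = ","))
  cand <- cand[ord, , drop = FALSE]
  center <- which(rowSums(abs(cand)) < 1e-12)[1]
  sel <- center
  Phi <- pce_eval_basis(basis, cand)
  for (i in seq_len(nrow(cand))) {
    if (length(sel) >= basis$L) break
    if (i %in% sel) next
    trial <- c(sel, i)
    if (qr(Phi[, trial, drop = FALSE])$rank == length(trial)) sel <- trial
  }
  if (length(sel) < basis$L) {
    # least-squares fallback with an over-determined design
    sel <- unique(c(center, seq_len(min(2 * basis$L, nrow(cand)))))
  }
  xi <- cand[sel, , drop = FALSE]
  Lambda <- Phi[, sel, drop = FALSE]
  condition <- kappa(Lambda %*% t(Lambda), exact = TRUE)
  pts <- matrix(basis$theta_nom, nrow(xi), n, byrow = TRUE) +
    xi %*% t(basis$transform)
  list(points_std = xi, points = pts, Lambda = Lambda, condition = condition)
}

#' Moments from PCE regression
#'
#' Least-squares regression of sampled responses on the PCE basis,
#' `a = (Lambda Lambda^T)^{-1} Lambda R`, with the expected value given by
#' the zeroth coefficient and the variance by
#' `sum_j a_j^2 E[Phi_j^2]` over the non-constant terms.
#'
#' @param values responses at the basis sampling points (same order).
#' @param basis a [build_pce_basis()].
#' @return list with `E`, `Var` and the coefficient vector `a`.
#' @export
pce_moments <- function(values, basis) {
  if (length(values) != basis$n_s)
    stop("expected one value per sampling point (", basis$n_s, ")")
  G <- basis$Lambda %*% t(basis$Lambda)
  a <- drop(solve(G, basis$Lambda %*% values))
  list(E = a[1], Var = sum(a[-1]^2 * basis$norms[-1]), a = a)
}

#' @export
print.pce_basis <- function(x, ...) {
  cat("pce_basis: order", x$p, "-", x$family, "family,", x$n_theta,
      "parameters\n")
  cat("  terms L =", x$L, "| sampling points n_s =", x$n_s,
      "| design condition =", signif(x$condition, 3), "\n")
  invisible(x)
}
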