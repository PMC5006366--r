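#' Sample parameter realizations from an uncertainty specification
#'
#' Independent draws of the parameter vector: multivariate normal (via the
#' Cholesky factor of `Sigma`) or independent uniform marginals on
#' `theta_nom +/- sqrt(3) * std`. Normal draws are not truncated to
#' positive values; at the relative standard deviations exercised here the
#' probability of a negative rate constant is negligible (about 3e-7 per
#' draw at 20 %), and `truncate = TRUE` is available when positivity must
#' be enforced.
#'
#' @param spec an [uncertainty_spec()].
#' @param N number of realizations.
#' @param seed RNG seed (an integer; the report is reproducible given the
#'   seed).
#' @param truncate resample negative draws (normal family only).
#' @return N x n_theta matrix, one realization per row.
#' @export
sample_parameters <- function(spec, N, seed = 1L, truncate = FALSE) {
  if (N < 1) stop("N must be at least 1")
  set.seed(seed)
  n <- spec$n_theta
  if (spec$family == "normal") {
    Z <- matrix(stats::rnorm(N * n), N, n)
    th <- matrix(spec$theta_nom, N, n, byrow = TRUE) + Z %*% t(psd_sqrt(spec$Sigma))
    if (truncate) {
      bad <- which(apply(th, 1, function(r) any(r < 0)))
      while (length(bad)) {
        Z <- matrix(stats::rnorm(length(bad) * n), length(bad), n)
        th[bad, ] <- matrix(spec$theta_nom, length(bad), n, byrow = TRUE) +
          Z %*% t(psd_sqrt(spec$Sigma))
        bad <- bad[apply(th[bad, , drop = FALSE], 1, function(r) any(r < 0))]
      }
    }
  } else {
    sd <- sqrt(diag(spec$Sigma))
    th <- vapply(seq_len(n), function(j)
      stats::runif(N, spec$theta_nom[j] - sqrt(3) * sd[j],
                   spec$theta_nom[j] + sqrt(3) * sd[j]), numeric(N))
    th <- matrix(th, N, n)
  }
  colnames(th) <- spec$param_names
  th
}

#' Fixed-step batch simulator
#'
#' Vectorized classical Runge-Kutta integration of the model for a matrix
#' of parameter realizations under one shared piecewise-constant control
#' profile. Used for large Monte-Carlo ensembles where the per-realization
#' implicit integrator would dominate the cost; the bundled models are
#' non-stiff along feasible controls, and the fixed step is chosen per
#' element.
#'
#' @param model a [network_model()].
#' @param controls a [control_profile()].
#' @param theta_matrix N x n_theta matrix of realizations.
#' @param steps_per_element RK4 steps within each control element.
#' @return N x n_x matrix of terminal states.
#' @export
simulate_batch <- function(model, controls, theta_matrix,
                           steps_per_element = 20) {
  if (is.null(model$rhs_batch))
    stop("batch simulation requires a declarative model")
  Tm <- t(as.matrix(theta_matrix))
  N <- ncol(Tm)
  X <- matrix(as.numeric(model$x0), model$n_x, N)
  f <- model$rhs_batch
  for (e in seq_len(nrow(controls$values))) {
    u <- controls$values[e, ]
    h <- (controls$grid[e + 1] - controls$grid[e]) / steps_per_element
    for (s in seq_len(steps_per_element)) {
      k1 <- f(X, u, Tm)
      k2 <- f(X + h / 2 * k1, u, Tm)
      k3 <- f(X + h / 2 * k2, u, Tm)
      k4 <- f(X + h * k3, u, Tm)
      X <- X + h / 6 * (k1 + 2 * k2 + k3 * 2 + k4)
    }
  }
  out <- t(X)
  colnames(out) <- model$state_names
  out
}

#' Monte-Carlo validation of a control profile
#'
#' Simulates every parameter realization with the controls held fixed,
#' counts terminal-constraint violations (strict inequality against the
#' bound) and reports empirical means and standard deviations of the
#' objective and of the constrained quantity.
#'
#' @param model a [network_model()].
#' @param controls the [control_profile()] to assess.
#' @param samples realization matrix from [sample_parameters()], or an
#'   [uncertainty_spec()] (then `N` and `seed` are used to draw one).
#' @param N,seed used when `samples` is a spec.
#' @param objective_state state whose terminal value is the reported
#'   objective (defaults to the model's terminal-state objective).
#' @param integrator `"lsoda"` for the per-realization implicit integrator
#'   or `"rk4"` for the vectorized fixed-step batch simulator.
#' @return an object of class `mc_report`.
#' @export
validate_controls <- function(model, controls, samples, N = 1000,
                              seed = 1L, objective_state = NULL,
                              integrator = c("lsoda", "rk4")) {
  integrator <- match.arg(integrator)
  if (inherits(samples, "uncertainty_spec"))
    samples <- sample_parameters(samples, N, seed)
  samples <- as.matrix(samples)
  N <- nrow(samples)
  tc <- model$terminal_constraints[[1]]
  if (is.null(objective_state))
    objective_state <- default_tracked(model)[
      default_tracked(model) != tc$state][1]
  failures <- 0L
  if (integrator == "rk4") {
    XF <- simulate_batch(model, controls, samples)
    ct <- XF[, tc$state]
    J <- XF[, objective_state]
  } else {
    ct <- J <- rep(NA_real_, N)
    for (i in seq_len(N)) {
      xf <- tryCatch({
        tr <- simulate_model(model, controls, theta = samples[i, ],
                             output_times = controls$t_f)
        tr$states[nrow(tr$states), ]
      }, error = function(e) NULL)
      if (is.null(xf)) { failures <- failures + 1L; next }
      ct[i] <- xf[tc$state]
      J[i] <- xf[objective_state]
    }
  }
  ok <- !is.na(ct)
  viol <- if (tc$direction == "ge") ct[ok] < tc$bound else ct[ok] > tc$bound
  structure(list(
    N = N, seed = seed, failures = failures,
    constraint = ct, objective = J,
    bound = tc$bound, direction = tc$direction,
    constraint_state = tc$state, objective_state = objective_state,
    violations = sum(viol),
    violation_pct = 100 * sum(viol) / sum(ok),
    J_mean = mean(J[ok]), J_sd = stats::sd(J[ok]),
    ct_mean = mean(ct[ok]), ct_sd = stats::sd(ct[ok])
  ), class = "mc_report")
}

#' @export
print.mc_report <- function(x, ...) {
  cat("mc_report: N =", x$N, "(seed", paste0(x$seed, ")"),
      if (x$failures) paste0("[", x$failures, " failed integrations]"), "\n")
  cat(sprintf("  %s: mean %.4f sd %.4f | bound %s %.4g\n",
              x$constraint_state, x$ct_mean, x$ct_sd,
              if (x$direction == "ge") ">=" else "<=", x$bound))
  cat(sprintf("  %s: mean %.4f sd %.4f\n", x$objective_state, x$J_mean,
              x$J_sd))
  cat(sprintf("  violations: %d (%.1f %%)\n", x$violations,
              x$violation_pct))
  invisible(x)
}

#' Write a Monte-Carlo report table
#'
#' One column per assessed control strategy (nominal plus robustified
#' techniques), rows: objective mean/sd, constraint mean/sd, violations.
#'
#' @param reports named list of `mc_report` objects.
#' @param file output CSV path.
#' @export
write_mc_table <- function(reports, file) {
  tab <- data.frame(row.names = c("J_mean", "J_sd", "ct_mean", "ct_sd",
                                  "violations", "violation_pct"))
  for (nm in names(reports)) {
    r <- reports[[nm]]
    tab[[nm]] <- c(r$J_mean, r$J_sd, r$ct_mean, r$ct_sd, r$violations,
                   r$violation_pct)
  }
  utils::write.csv(tab, file)
  invisible(file)
}
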