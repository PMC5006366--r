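#' Forward-sensitivity augmentation of a model
#'
#' Builds the linearization propagation system: the model states are
#' augmented with the forward parametric sensitivities
#' \eqn{\dot S = (\partial f/\partial x) S + \partial f/\partial \theta},
#' \eqn{S(0) = 0}, evaluated along the nominal parameter vector, giving
#' `(n_theta + 1) * n_x` states in total. The augmented state is laid out
#' as `c(x, S[,1], ..., S[,n_theta])` with `S[, j]` the sensitivity of the
#' state vector to parameter `j`. Jacobians are formed by central finite
#' differences of the model right-hand side.
#'
#' @param model a [network_model()].
#' @return an `augmented_model` object whose `rhs(x_aug, u, theta, t)`
#'   integrates states and sensitivities; `theta` defaults to the nominal
#'   parameters around which the system is linearized.
#' @export
build_sensitivity_system <- function(model) {
  n_x <- model$n_x
  n_th <- model$n_theta
  f <- model$rhs
  jac <- build_jac_funs(model)
  rhs <- function(x_aug, u, theta = model$theta_nom, t = 0) {
    x <- x_aug[seq_len(n_x)]
    S <- matrix(x_aug[-seq_len(n_x)], n_x, n_th)
    J <- jac(x, u, theta)
    c(f(x, u, theta, t), as.vector(J$fx %*% S + J$fth))
  }
  # Jacobian of the augmented RHS: the sensitivity block is linear in S with
  # coefficient I (x) fx; the coupling of the sensitivity equations back to
  # the base states is differentiated numerically.
  sens_part <- function(x, u, S, theta) {
    J <- jac(x, u, theta)
    as.vector(J$fx %*% S + J$fth)
  }
  jac_x <- function(x_aug, u, theta = model$theta_nom, t = 0) {
    x <- x_aug[seq_len(n_x)]
    S <- matrix(x_aug[-seq_len(n_x)], n_x, n_th)
    J <- jac(x, u, theta)
    M <- matrix(0, (n_th + 1) * n_x, (n_th + 1) * n_x)
    M[seq_len(n_x), seq_len(n_x)] <- J$fx
    M[-seq_len(n_x), seq_len(n_x)] <-
      fd_jacobian(function(v) sens_part(v, u, S, theta), x)
    for (j in seq_len(n_th)) {
      rows <- j * n_x + seq_len(n_x)
      M[rows, rows] <- J$fx
    }
    M
  }
  jac_u <- function(x_aug, u, theta = model$theta_nom, t = 0) {
    x <- x_aug[seq_len(n_x)]
    S <- matrix(x_aug[-seq_len(n_x)], n_x, n_th)
    J <- jac(x, u, theta)
    rbind(J$fu, fd_jacobian(function(v) sens_part(x, v, S, theta), u))
  }
  structure(list(
    jac_x = jac_x, jac_u = jac_u,
    technique = "linearization", base = model,
    n_states = (n_th + 1) * n_x, n_x = n_x, n_theta = n_th,
    x0 = c(as.numeric(model$x0), rep(0, n_th * n_x)),
    rhs = rhs,
    state_names = c(model$state_names,
                    as.vector(outer(model$state_names, model$param_names,
                                    function(s, p) paste0("d", s, "_d", p)))),
    theta_points = matrix(model$theta_nom, 1, n_th)
  ), class = "augmented_model")
}

# Replicated-dynamics augmentation: one copy of the model per parameter
# vector (sigma points or PCE sampling points), all sharing the controls.
build_replicated_system <- function(model, theta_points, technique) {
  n_x <- model$n_x
  m <- nrow(theta_points)
  f <- model$rhs
  jac <- build_jac_funs(model)
  th_list <- lapply(seq_len(m), function(i) as.numeric(theta_points[i, ]))
  rhs <- function(x_aug, u, theta = NULL, t = 0) {
    dx <- numeric(m * n_x)
    for (i in seq_len(m)) {
      k <- (i - 1) * n_x
      dx[k + seq_len(n_x)] <- f(x_aug[k + seq_len(n_x)], u, th_list[[i]], t)
    }
    dx
  }
  jac_x <- function(x_aug, u, theta = NULL, t = 0) {
    M <- matrix(0, m * n_x, m * n_x)
    for (i in seq_len(m)) {
      k <- (i - 1) * n_x
      M[k + seq_len(n_x), k + seq_len(n_x)] <-
        jac(x_aug[k + seq_len(n_x)], u, th_list[[i]])$fx
    }
    M
  }
  jac_u <- function(x_aug, u, theta = NULL, t = 0) {
    do.call(rbind, lapply(seq_len(m), function(i) {
      k <- (i - 1) * n_x
      jac(x_aug[k + seq_len(n_x)], u, th_list[[i]])$fu
    }))
  }
  structure(list(
    jac_x = jac_x, jac_u = jac_u,
    technique = technique, base = model,
    n_states = m * n_x, n_x = n_x, n_theta = ncol(theta_points),
    n_replicas = m,
    x0 = rep(as.numeric(model$x0), m),
    rhs = rhs,
    state_names = as.vector(vapply(seq_len(m), function(i)
      paste0(model$state_names, "_pt", i - 1), character(n_x))),
    theta_points = theta_points
  ), class = "augmented_model")
}

#' @export
print.augmented_model <- function(x, ...) {
  cat("augmented_model (", x$technique, "): ", x$n_states,
      " states over base model ", x$base$name, "\n", sep = "")
  invisible(x)
}

#' Moments of a terminal functional from linearized sensitivities
#'
#' Given the terminal augmented state of [build_sensitivity_system()], the
#' expected value of a functional `R` of the states is its nominal value and
#' the variance is \eqn{(\partial R/\partial x)\, S \Sigma S^\top
#' (\partial R/\partial x)^\top}.
#'
#' @param x_aug terminal augmented state vector.
#' @param Sigma parameter covariance.
#' @param dR_dx gradient of the functional with respect to the base states
#'   (a unit vector for a single-state functional), or a state index.
#' @param n_x number of base states.
#' @return list with `E` and `Var`.
#' @export
linearized_moments <- function(x_aug, Sigma, dR_dx, n_x) {
  ev <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1)) stop("Sigma must be PSD")
  if (length(dR_dx) == 1 && dR_dx == round(dR_dx) && dR_dx >= 1) {
    g <- numeric(n_x); g[dR_dx] <- 1
  } else g <- dR_dx
  n_th <- nrow(Sigma)
  S <- matrix(x_aug[-seq_len(n_x)], n_x, n_th)
  E <- sum(g * x_aug[seq_len(n_x)])
  s <- drop(g %*% S)
  list(E = E, Var = max(0, drop(s %*% Sigma %*% s)))
}

# Construct the augmented system and the terminal moment extractors for a
# propagation technique. `tracked` is a character vector of base state
# names whose terminal values are the quantities R_k.
build_propagation <- function(model, technique, spec, p = NULL) {
  technique <- match.arg(technique,
                         c("nominal", "linearization", "sigma_points",
                           "pce1", "pce2"))
  n_x <- model$n_x
  if (technique == "nominal") {
    jac <- build_jac_funs(model)
    th0 <- as.numeric(model$theta_nom)
    aug <- structure(list(
      jac_x = function(x, u, theta = th0, t = 0) jac(x, u, theta)$fx,
      jac_u = function(x, u, theta = th0, t = 0) jac(x, u, theta)$fu,
      technique = "nominal", base = model, n_states = n_x, n_x = n_x,
      n_theta = model$n_theta, x0 = as.numeric(model$x0),
      rhs = function(x, u, theta = th0, t = 0) model$rhs(x, u, theta, t),
      state_names = model$state_names,
      theta_points = matrix(model$theta_nom, 1, model$n_theta)
    ), class = "augmented_model")
    moments <- function(x_aug, idx) list(E = x_aug[idx], Var = 0)
    support <- function(idx) idx
  } else if (technique == "linearization") {
    if (spec$family != "normal")
      stop("the linearization technique assumes normally distributed ",
           "parameters; got family '", spec$family, "'")
    aug <- build_sensitivity_system(model)
    Sigma <- spec$Sigma
    moments <- function(x_aug, idx)
      linearized_moments(x_aug, Sigma, idx, n_x)
    support <- function(idx) c(idx, n_x * seq_len(model$n_theta) + idx)
  } else if (technique == "sigma_points") {
    sp <- generate_sigma_points(spec)
    aug <- build_replicated_system(model, sp$points, "sigma_points")
    moments <- function(x_aug, idx)
      sigma_point_moments(x_aug[idx + n_x * (seq_len(nrow(sp$points)) - 1)],
                          sp$kappa)
    support <- function(idx) idx + n_x * (seq_len(nrow(sp$points)) - 1)
  } else {
    p <- if (is.null(p)) as.integer(substring(technique, 4)) else p
    basis <- build_pce_basis(spec, p)
    aug <- build_replicated_system(model, basis$points,
                                   paste0("pce", p))
    aug$pce_basis <- basis
    moments <- function(x_aug, idx) {
      r <- pce_moments(x_aug[idx + n_x * (seq_len(basis$n_s) - 1)], basis)
      list(E = r$E, Var = r$Var)
    }
    support <- function(idx) idx + n_x * (seq_len(basis$n_s) - 1)
  }
  list(technique = technique, aug = aug, moments = moments,
       support = support)
}

#' Propagate parametric uncertainty along fixed controls
#'
#' Simulates the technique's augmented system under a fixed control profile
#' and returns the expected value and variance of the terminal value of
#' each tracked state.
#'
#' @param model a [network_model()].
#' @param controls a [control_profile()].
#' @param spec an [uncertainty_spec()].
#' @param technique one of `"nominal"`, `"linearization"`, `"sigma_points"`,
#'   `"pce1"`, `"pce2"`.
#' @param tracked character vector of state names (defaults to the states in
#'   the model's terminal constraints plus terminal-state objectives).
#' @param rtol,atol integrator tolerances.
#' @return an object of class `propagation_result`: a data frame with one
#'   row per tracked quantity (`quantity`, `E`, `Var`) carrying the
#'   augmented-state count and per-point raw values as attributes.
#' @export
propagate_uncertainty <- function(model, controls, spec,
                                  technique = "sigma_points",
                                  tracked = NULL, rtol = 1e-8, atol = 1e-10) {
  prop <- build_propagation(model, technique, spec)
  if (is.null(tracked)) tracked <- default_tracked(model)
  aug <- prop$aug
  fn <- function(t, y, parms) list(aug$rhs(y, parms$u, t = t))
  x <- aug$x0
  for (e in seq_len(nrow(controls$values))) {
    seg <- c(controls$grid[e], controls$grid[e + 1])
    sol <- deSolve::lsoda(x, seg, fn, parms = list(u = controls$values[e, ]),
                          rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0) stop("augmented integration failed")
    x <- as.numeric(sol[nrow(sol), -1])
  }
  res <- do.call(rbind, lapply(tracked, function(s) {
    idx <- match(s, model$state_names)
    mm <- prop$moments(x, idx)
    data.frame(quantity = s, technique = technique, E = mm$E, Var = mm$Var)
  }))
  raw <- lapply(tracked, function(s) {
    idx <- match(s, model$state_names)
    x[prop$support(idx)]
  })
  names(raw) <- tracked
  structure(res, class = c("propagation_result", "data.frame"),
            n_states = aug$n_states, raw = raw, terminal_state = x)
}

default_tracked <- function(model) {
  unique(c(vapply(model$terminal_constraints, `[[`, "", "state"),
           unlist(lapply(model$objectives, function(o)
             if (o$type == "terminal_state") o$state else NULL))))
}
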