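#' Declare a kinetic network ODE model
#'
#' Builds a `network_model` object from a stoichiometric matrix and a set of
#' tagged rate laws. The integrated state vector consists of the
#' non-buffered (or zero-row buffered) metabolites, the enzyme states when
#' the controls are expression rates, and any auxiliary integrator states
#' (e.g. an accumulated-cost state).
#'
#' Two rate-law families are supported, which cover the bundled case
#' studies:
#' \describe{
#'   \item{mass_action}{\eqn{v_j = k_j \, S \, e}, with `param` the rate
#'     constant, `substrate` the metabolite and `enzyme` the catalysing
#'     enzyme (a control for `control_kind = "direct_concentration"`, a
#'     state for `"expression_rate"`).}
#'   \item{michaelis_menten}{\eqn{v_j = k_{cat} e \, S/(K_M + S)} with
#'     shared or per-reaction `vmax_param` and `km_param`.}
#' }
#' Other kinetics can be attached through the `rhs` escape hatch (a function
#' `f(x, u, theta, t)` returning the full state derivative), at the price of
#' losing the declarative config round-trip.
#'
#' @param name model identifier.
#' @param species metabolite names, one per row of `stoichiometry`.
#' @param stoichiometry integer matrix N (metabolites x reactions).
#' @param rate_laws list with one entry per reaction column; see Details.
#' @param control_names names of the manipulated inputs.
#' @param control_lower,control_upper bounds on each control.
#' @param param_names,theta_nom uncertain parameter names and nominal values.
#' @param control_kind `"direct_concentration"` when the controls are the
#'   enzyme concentrations themselves, `"expression_rate"` when they drive
#'   enzyme synthesis `de/dt = r - lambda e`.
#' @param buffered names of species held at constant concentration.
#' @param buffered_values named concentrations of `"constant"`-mode buffered
#'   species (mM).
#' @param buffered_mode `"zero_row"` keeps a buffered species as a trivially
#'   integrated state (its stoichiometric row must be zero); `"constant"`
#'   removes it from the state vector.
#' @param enzyme_states enzyme state names (expression-rate models).
#' @param decay_param name of the enzyme degradation-rate parameter.
#' @param extra_states list of integrators, each
#'   `list(name=, vars=, coefs=)` integrating `sum(coefs * vars)` where
#'   `vars` are state or control names.
#' @param x0 named initial state vector (mM; integrators mM*s).
#' @param t_f default final time in seconds; `t_f_max` bounds a free final
#'   time.
#' @param control_sum_bound scalar b enforcing `sum(u) <= b` on every
#'   element (NULL for none).
#' @param state_sum_constraint optional `list(states=, bound=)` path
#'   constraint `sum(x[states]) <= bound`.
#' @param terminal_constraints list of
#'   `list(state=, bound=, direction="ge"|"le", robustify=TRUE)`.
#' @param objectives list of `list(type="terminal_state", state=,
#'   robustify=)` or `list(type="final_time")` entries; all are minimized.
#' @param control_t0 optional control values pinned on the first element.
#' @param rhs optional custom right-hand-side function.
#' @return an object of class `network_model`.
#' @seealso [case1_model()], [case2_model()], [simulate_model()]
#' @export
network_model <- function(name, species, stoichiometry, rate_laws,
                          control_names, control_lower, control_upper,
                          param_names, theta_nom,
                          control_kind = c("direct_concentration",
                                           "expression_rate"),
                          buffered = character(),
                          buffered_mode = c("zero_row", "constant"),
                          buffered_values = numeric(),
                          enzyme_states = character(), decay_param = NULL,
                          extra_states = list(), x0 = NULL,
                          t_f = NULL, t_f_max = NULL,
                          control_sum_bound = NULL,
                          state_sum_constraint = NULL,
                          terminal_constraints = list(),
                          objectives = list(), control_t0 = NULL,
                          rhs = NULL) {
  control_kind <- match.arg(control_kind)
  buffered_mode <- match.arg(buffered_mode)
  stoichiometry <- as.matrix(stoichiometry)
  if (nrow(stoichiometry) != length(species))
    stop("stoichiometry must have one row per metabolite")
  if (ncol(stoichiometry) != length(rate_laws))
    stop("stoichiometry must have one column per reaction rate law")
  rownames(stoichiometry) <- species
  if (length(buffered) && buffered_mode == "zero_row") {
    bad <- buffered[rowSums(abs(stoichiometry[buffered, , drop = FALSE])) != 0]
    if (length(bad))
      stop("buffered zero-row species with nonzero stoichiometry: ",
           paste(bad, collapse = ", "))
  }

  integrated_species <-
    if (buffered_mode == "constant") setdiff(species, buffered) else species
  extra_names <- vapply(extra_states, `[[`, "", "name")
  state_names <- c(integrated_species, enzyme_states, extra_names)
  n_x <- length(state_names)
  if (is.null(x0)) x0 <- stats::setNames(numeric(n_x), state_names)
  x0 <- x0[state_names]
  if (anyNA(x0)) stop("x0 must name every integrated state")

  m <- structure(list(
    name = name, species = species, stoichiometry = stoichiometry,
    rate_laws = rate_laws, control_names = control_names,
    control_lower = control_lower, control_upper = control_upper,
    param_names = param_names,
    theta_nom = stats::setNames(theta_nom, param_names),
    control_kind = control_kind, buffered = buffered,
    buffered_mode = buffered_mode, buffered_values = buffered_values,
    enzyme_states = enzyme_states,
    decay_param = decay_param, extra_states = extra_states,
    state_names = state_names, n_x = n_x, n_u = length(control_names),
    n_theta = length(param_names), x0 = x0, t_f = t_f, t_f_max = t_f_max,
    control_sum_bound = control_sum_bound,
    state_sum_constraint = state_sum_constraint,
    terminal_constraints = terminal_constraints, objectives = objectives,
    control_t0 = control_t0, custom_rhs = !is.null(rhs)
  ), class = "network_model")
  m$rhs <- if (!is.null(rhs)) rhs else build_rhs(m)
  m$rhs_batch <- if (is.null(rhs)) build_rhs_batch(m) else NULL
  m
}

# Compile the declarative model description into an index-based RHS closure
# f(x, u, theta, t). Works on plain numeric vectors for speed.
build_rhs <- function(m) {
  plan <- rhs_plan(m)
  function(x, u, theta, t = 0) {
    v <- numeric(plan$n_r)
    for (j in seq_len(plan$n_r)) {
      p <- plan$reactions[[j]]
      S <- if (p$sub_const) p$sub_value else x[p$sub_idx]
      e <- if (p$enz_in_u) u[p$enz_idx] else x[p$enz_idx]
      v[j] <- if (p$kind == "mass_action") {
        theta[p$k_idx] * S * e
      } else {
        den <- theta[p$km_idx] + S
        if (den < 0) stop("negative Michaelis-Menten denominator")
        theta[p$kcat_idx] * e * S / den
      }
    }
    dx <- numeric(plan$n_x)
    dx[plan$species_idx] <- plan$N_int %*% v
    if (plan$has_enz)
      dx[plan$enz_idx] <- u - theta[plan$decay_idx] * x[plan$enz_idx]
    for (ex in plan$extras) {
      val <- sum(ex$coefs_x * x[ex$idx_x])
      if (length(ex$idx_u)) val <- val + sum(ex$coefs_u * u[ex$idx_u])
      dx[ex$target] <- val
    }
    dx
  }
}

# Vectorized variant: x is an n_x x m matrix of states for m parameter
# realizations, theta an n_theta x m matrix; returns the n_x x m derivative.
build_rhs_batch <- function(m) {
  plan <- rhs_plan(m)
  function(x, u, theta, t = 0) {
    nm <- ncol(x)
    v <- matrix(0, plan$n_r, nm)
    for (j in seq_len(plan$n_r)) {
      p <- plan$reactions[[j]]
      S <- if (p$sub_const) rep(p$sub_value, nm) else x[p$sub_idx, ]
      e <- if (p$enz_in_u) rep(u[p$enz_idx], nm) else x[p$enz_idx, ]
      v[j, ] <- if (p$kind == "mass_action") {
        theta[p$k_idx, ] * S * e
      } else {
        theta[p$kcat_idx, ] * e * S / (theta[p$km_idx, ] + S)
      }
    }
    dx <- matrix(0, plan$n_x, nm)
    dx[plan$species_idx, ] <- plan$N_int %*% v
    if (plan$has_enz) {
      ne <- length(plan$enz_idx)
      dx[plan$enz_idx, ] <- u - x[plan$enz_idx, , drop = FALSE] *
        rep(theta[plan$decay_idx, ], each = ne)
    }
    for (ex in plan$extras) {
      val <- colSums(x[ex$idx_x, , drop = FALSE] * ex$coefs_x)
      if (length(ex$idx_u)) val <- val + sum(ex$coefs_u * u[ex$idx_u])
      dx[ex$target, ] <- val
    }
    dx
  }
}

rhs_plan <- function(m) {
  sn <- m$state_names
  integrated_species <- intersect(m$species, sn)
  reactions <- lapply(seq_along(m$rate_laws), function(j) {
    rl <- m$rate_laws[[j]]
    sub_const <- rl$substrate %in% m$buffered && m$buffered_mode == "constant"
    enz_in_u <- rl$enzyme %in% m$control_names
    p <- list(kind = rl$kind, sub_const = sub_const,
              sub_value = if (sub_const) unname(m$buffered_values[rl$substrate]) else NA,
              sub_idx = if (!sub_const) match(rl$substrate, sn) else NA_integer_,
              enz_in_u = enz_in_u,
              enz_idx = if (enz_in_u) match(rl$enzyme, m$control_names)
                        else match(rl$enzyme, sn))
    if (rl$kind == "mass_action") {
      p$k_idx <- match(rl$param, m$param_names)
    } else {
      p$kcat_idx <- match(rl$vmax_param, m$param_names)
      p$km_idx <- match(rl$km_param, m$param_names)
    }
    p
  })
  # constant value of buffered species (stored on the model as buffered_values)
  extras <- lapply(m$extra_states, function(ex) {
    in_x <- ex$vars %in% sn
    list(target = match(ex$name, sn),
         idx_x = match(ex$vars[in_x], sn), coefs_x = ex$coefs[in_x],
         idx_u = match(ex$vars[!in_x], m$control_names),
         coefs_u = ex$coefs[!in_x])
  })
  list(n_r = length(reactions), n_x = m$n_x,
       reactions = reactions,
       species_idx = match(integrated_species, sn),
       N_int = m$stoichiometry[integrated_species, , drop = FALSE],
       has_enz = length(m$enzyme_states) > 0,
       enz_idx = match(m$enzyme_states, sn),
       decay_idx = if (!is.null(m$decay_param))
         match(m$decay_param, m$param_names) else NA_integer_,
       extras = extras)
}

# Analytic Jacobians of the declarative RHS with respect to states,
# controls and parameters. Returns a function (x, u, theta) -> list(fx, fu,
# fth). Models with a custom rhs fall back to finite differences.
build_jac_funs <- function(m) {
  if (isTRUE(m$custom_rhs)) {
    return(function(x, u, theta) list(
      fx = fd_jacobian(function(v) m$rhs(v, u, theta, 0), x),
      fu = fd_jacobian(function(v) m$rhs(x, v, theta, 0), u),
      fth = fd_jacobian(function(v) m$rhs(x, u, v, 0), theta)))
  }
  plan <- rhs_plan(m)
  n_x <- m$n_x; n_u <- m$n_u; n_th <- m$n_theta
  function(x, u, theta) {
    fx <- matrix(0, n_x, n_x)
    fu <- matrix(0, n_x, n_u)
    fth <- matrix(0, n_x, n_th)
    for (j in seq_len(plan$n_r)) {
      p <- plan$reactions[[j]]
      S <- if (p$sub_const) p$sub_value else x[p$sub_idx]
      e <- if (p$enz_in_u) u[p$enz_idx] else x[p$enz_idx]
      col <- plan$N_int[, j]
      if (p$kind == "mass_action") {
        k <- theta[p$k_idx]
        if (!p$sub_const) fx[plan$species_idx, p$sub_idx] <-
            fx[plan$species_idx, p$sub_idx] + col * (k * e)
        de <- k * S
        fth[plan$species_idx, p$k_idx] <-
          fth[plan$species_idx, p$k_idx] + col * (S * e)
      } else {
        kcat <- theta[p$kcat_idx]; km <- theta[p$km_idx]
        den <- km + S
        if (!p$sub_const) fx[plan$species_idx, p$sub_idx] <-
            fx[plan$species_idx, p$sub_idx] + col * (kcat * e * km / den^2)
        de <- kcat * S / den
        fth[plan$species_idx, p$kcat_idx] <-
          fth[plan$species_idx, p$kcat_idx] + col * (e * S / den)
        fth[plan$species_idx, p$km_idx] <-
          fth[plan$species_idx, p$km_idx] - col * (kcat * e * S / den^2)
      }
      if (p$enz_in_u) {
        fu[plan$species_idx, p$enz_idx] <- fu[plan$species_idx, p$enz_idx] +
          col * de
      } else {
        fx[plan$species_idx, p$enz_idx] <- fx[plan$species_idx, p$enz_idx] +
          col * de
      }
    }
    if (plan$has_enz) {
      lam <- theta[plan$decay_idx]
      for (i in seq_along(plan$enz_idx)) {
        fx[plan$enz_idx[i], plan$enz_idx[i]] <-
          fx[plan$enz_idx[i], plan$enz_idx[i]] - lam
        fu[plan$enz_idx[i], i] <- fu[plan$enz_idx[i], i] + 1
        fth[plan$enz_idx[i], plan$decay_idx] <-
          fth[plan$enz_idx[i], plan$decay_idx] - x[plan$enz_idx[i]]
      }
    }
    for (ex in plan$extras) {
      fx[ex$target, ex$idx_x] <- ex$coefs_x
      if (length(ex$idx_u)) fu[ex$target, ex$idx_u] <- ex$coefs_u
    }
    list(fx = fx, fu = fu, fth = fth)
  }
}

#' Evaluate the model right-hand side
#'
#' Computes the state derivative \eqn{\dot x = N v(x,u,\theta)} stacked with
#' the auxiliary integrator derivatives.
#'
#' @param model a [network_model()].
#' @param x state vector (length `model$n_x`).
#' @param u control vector.
#' @param theta parameter vector (defaults to the nominal values).
#' @param t time in seconds (the bundled models are autonomous).
#' @return numeric state-derivative vector.
#' @export
evaluate_rhs <- function(model, x, u, theta = model$theta_nom, t = 0) {
  if (length(x) != model$n_x) stop("state vector has wrong length")
  if (length(u) != model$n_u) stop("control vector has wrong length")
  if (length(theta) != model$n_theta) stop("parameter vector has wrong length")
  stats::setNames(model$rhs(as.numeric(x), as.numeric(u), as.numeric(theta), t),
                  model$state_names)
}

#' Piecewise-constant control profile
#'
#' @param grid strictly increasing element boundaries, from 0 to `t_f`.
#' @param values matrix with one row per element and one column per control.
#' @return an object of class `control_profile`.
#' @export
control_profile <- function(grid, values) {
  values <- as.matrix(values)
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (nrow(values) != length(grid) - 1)
    stop("need one control row per grid element")
  structure(list(grid = grid, values = values, t_f = grid[length(grid)]),
            class = "control_profile")
}

# control value at time t (right-continuous step function)
control_at <- function(profile, t) {
  i <- findInterval(t, profile$grid, rightmost.closed = TRUE,
                    all.inside = TRUE)
  profile$values[i, ]
}

#' Constant control profile helper
#' @param model a [network_model()].
#' @param u control vector held constant.
#' @param t_f final time; defaults to the model's.
#' @param n_elements number of elements of the returned profile grid.
#' @export
constant_controls <- function(model, u, t_f = model$t_f, n_elements = 1) {
  control_profile(seq(0, t_f, length.out = n_elements + 1),
                  matrix(u, n_elements, model$n_u, byrow = TRUE))
}

#' Simulate a kinetic network model
#'
#' Integrates the model IVP under a piecewise-constant control profile with
#' a stiff-capable implicit integrator (`deSolve::lsoda`), restarting at
#' every control discontinuity.
#'
#' @inheritParams evaluate_rhs
#' @param controls a [control_profile()].
#' @param output_times times at which to report the states (within
#'   `[0, t_f]`); defaults to 101 equispaced points.
#' @param rtol,atol integrator tolerances.
#' @return an object of class `trajectory` with fields `times`, `states`
#'   (time x state matrix) and `controls`.
#' @export
simulate_model <- function(model, controls, theta = model$theta_nom,
                           output_times = NULL, rtol = 1e-8, atol = 1e-10) {
  t_f <- controls$t_f
  if (is.null(output_times))
    output_times <- seq(0, t_f, length.out = 101)
  if (any(output_times < 0 | output_times > t_f + 1e-12))
    stop("output_times must lie within [0, t_f]")
  theta <- as.numeric(theta)
  x <- as.numeric(model$x0)
  fn <- function(t, y, parms) list(model$rhs(y, parms$u, theta, t))
  times_out <- numeric(0)
  states_out <- NULL
  record <- function(tt, xx) {
    times_out <<- c(times_out, tt)
    states_out <<- rbind(states_out, xx)
  }
  if (any(abs(output_times) < 1e-12)) record(0, x)
  for (e in seq_len(nrow(controls$values))) {
    a <- controls$grid[e]; b <- controls$grid[e + 1]
    want <- output_times[output_times > a + 1e-12 & output_times <= b + 1e-12]
    seg <- sort(unique(c(a, want, b)))
    sol <- deSolve::lsoda(x, seg, fn, parms = list(u = controls$values[e, ]),
                          rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0)
      stop("integration failed in element ", e,
           " (lsoda istate ", attr(sol, "istate")[1], ")")
    x <- as.numeric(sol[nrow(sol), -1])
    for (tt in want) {
      k <- which.min(abs(seg - tt))
      record(tt, as.numeric(sol[k, -1]))
    }
  }
  states <- matrix(states_out, ncol = model$n_x,
                   dimnames = list(NULL, model$state_names))
  uu <- vapply(times_out, function(tt) control_at(controls, tt),
               numeric(model$n_u))
  uu <- if (model$n_u == 1) matrix(uu, ncol = 1) else t(uu)
  colnames(uu) <- model$control_names
  structure(list(times = times_out, states = states, controls = uu,
                 model = model$name),
            class = "trajectory")
}

#' First crossing time of a species threshold
#'
#' Finds the first time a species trajectory reaches a threshold from below,
#' with linear interpolation between stored time points. Returns `NA` when
#' the threshold is never reached; a trajectory already at or above the
#' threshold at its first time point returns that time.
#'
#' @param traj a `trajectory` from [simulate_model()].
#' @param species state name.
#' @param threshold concentration threshold (mM).
#' @param tol numerical slack: values within `tol` below the threshold
#'   count as reaching it (useful when a terminal constraint is active to
#'   solver tolerance, so the trajectory touches the threshold at the
#'   final time up to integration error).
#' @return time in seconds, or `NA_real_`.
#' @export
threshold_time <- function(traj, species, threshold, tol = 0) {
  if (!species %in% colnames(traj$states))
    stop("unknown species: ", species)
  y <- traj$states[, species]
  tt <- traj$times
  at <- which(y >= threshold - tol)
  if (!length(at)) return(NA_real_)
  i <- at[1]
  if (i == 1) return(tt[1])
  # linear interpolation on the crossing segment (clamped to the segment
  # when the crossing is only attained within `tol`)
  thr <- min(threshold, y[i])
  tt[i - 1] + (thr - y[i - 1]) / (y[i] - y[i - 1]) * (tt[i] - tt[i - 1])
}

#' @export
print.network_model <- function(x, ...) {
  cat("network_model:", x$name, "\n")
  cat("  states  (", x$n_x, "): ", paste(x$state_names, collapse = ", "),
      "\n", sep = "")
  cat("  controls(", x$n_u, "): ", paste(x$control_names, collapse = ", "),
      " [", x$control_kind, "]\n", sep = "")
  cat("  params  (", x$n_theta, "): ",
      paste(sprintf("%s=%g", x$param_names, x$theta_nom), collapse = ", "),
      "\n", sep = "")
  if (length(x$buffered))
    cat("  buffered:", paste(x$buffered, collapse = ", "),
        sprintf("(%s)", x$buffered_mode), "\n")
  invisible(x)
}

#' @export
print.trajectory <- function(x, ...) {
  cat("trajectory of", x$model, "-", length(x$times), "time points,",
      ncol(x$states), "states\n")
  cat("  final state:\n")
  print(round(x$states[nrow(x$states), ], 4))
  invisible(x)
}

#' Trajectory export
#'
#' Writes a trajectory either as a tidy long table (`time, state, value`) or
#' as a wide CSV with one column per state.
#'
#' @param traj a `trajectory`.
#' @param file output path.
#' @param format `"tidy"` or `"wide"`.
#' @export
write_trajectory <- function(traj, file, format = c("tidy", "wide")) {
  format <- match.arg(format)
  if (format == "wide") {
    utils::write.csv(data.frame(time = traj$times, traj$states,
                                check.names = FALSE),
                     file, row.names = FALSE)
  } else {
    long <- data.frame(
      time = rep(traj$times, ncol(traj$states)),
      state = rep(colnames(traj$states), each = length(traj$times)),
      value = as.vector(traj$states))
    utils::write.table(long, file, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  invisible(file)
}
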