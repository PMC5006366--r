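#' Solve a transcribed NLP
#'
#' Augmented-Lagrangian solution of the inequality-constrained reduced NLP
#' produced by [transcribe()]: the bound-constrained subproblems are solved
#' with `L-BFGS-B` using the exact reduced gradients, and the multiplier
#' estimates are updated between outer iterations until the worst
#' constraint violation falls below `ctol` and the solution is stationary
#' to the KKT tolerance.
#'
#' @param nlp a [transcribe()] result.
#' @param w0 initial decision vector (defaults to mid-bounds).
#' @param options list; recognised entries `ctol` (constraint tolerance,
#'   1e-6), `ktol` (KKT/stationarity tolerance, 1e-5), `max_outer` (20),
#'   `maxit_inner` (300), `mu0` (initial penalty, 10) and `verbose`.
#' @return an object of class `nlp_solution` with the decision vector,
#'   objective, constraint values, multipliers and convergence status.
#' @export
solve_nlp <- function(nlp, w0 = NULL, options = list()) {
  opt <- utils::modifyList(list(ctol = 1e-6, ktol = 1e-5, max_outer = 15,
                                maxit_inner = 300, mu0 = 10, verbose = FALSE),
                           options)
  lower <- nlp$lower; upper <- nlp$upper
  if (is.null(w0)) w0 <- (lower + upper) / 2
  w0 <- pmin(pmax(w0, lower), upper)
  g0 <- nlp$eval_g(w0)
  m <- length(g0$value)
  lambda <- rep(0, m)
  mu <- opt$mu0
  w <- w0
  prev_viol <- max(max(0, g0$value), opt$ctol)
  status <- "max_outer_reached"
  f_val <- NA_real_
  f_prev <- Inf
  stall <- 0L
  for (outer in seq_len(opt$max_outer)) {
    al_fn <- function(w) {
      fe <- nlp$eval_f(w)
      ge <- nlp$eval_g(w)
      s <- pmax(0, ge$value + lambda / mu)
      fe$value + sum(mu / 2 * s^2)
    }
    al_gr <- function(w) {
      fe <- nlp$eval_f(w)
      ge <- nlp$eval_g(w)
      s <- pmax(0, ge$value + lambda / mu)
      g <- fe$grad
      act <- which(s > 0)
      if (length(act))
        g <- g + drop(crossprod(ge$jac[act, , drop = FALSE], mu * s[act]))
      g
    }
    res <- stats::optim(w, al_fn, al_gr, method = "L-BFGS-B",
                        lower = lower, upper = upper,
                        control = list(maxit = opt$maxit_inner,
                                       factr = 1e4, pgtol = 1e-9))
    w_trial <- res$par
    ge <- nlp$eval_g(w_trial)
    viol <- max(0, ge$value)
    # Safeguard: if the inner solve wrecked feasibility (e.g. collapsed into
    # a dead state where the constraint gradients vanish), discard the step
    # and retry with a stiffer penalty.
    if (viol > max(2 * prev_viol, 0.05) && outer > 0 && is.finite(prev_viol)) {
      mu <- min(mu * 10, 1e8)
      if (opt$verbose)
        message(sprintf("outer %d: rejected step (viol=%.3g), mu=%g",
                        outer, viol, mu))
      next
    }
    w <- w_trial
    fe <- nlp$eval_f(w)
    f_val <- fe$value
    # stationarity of the Lagrangian projected on the bounds
    lam_new <- pmax(0, lambda + mu * ge$value)
    gl <- fe$grad
    if (m > 0) gl <- gl + drop(crossprod(ge$jac, lam_new))
    proj <- w - pmin(pmax(w - gl, lower), upper)
    kkt <- max(abs(proj))
    if (opt$verbose)
      message(sprintf("outer %d: f=%.6g viol=%.3g kkt=%.3g mu=%g",
                      outer, f_val, viol, kkt, mu))
    if (viol < opt$ctol && kkt < opt$ktol) {
      lambda <- lam_new
      status <- "converged"
      break
    }
    # feasible and no further progress at the inner solver's precision
    stall <- if (viol < opt$ctol &&
                 abs(f_val - f_prev) < 1e-7 * max(1, abs(f_val)))
      stall + 1L else 0L
    if (stall >= 2L) {
      lambda <- lam_new
      status <- "converged"
      break
    }
    f_prev <- f_val
    lambda <- lam_new
    if (viol > 0.25 * prev_viol && viol > opt$ctol) mu <- min(mu * 10, 1e8)
    prev_viol <- max(viol, opt$ctol)
  }
  sim <- nlp$run_sim(w)
  structure(list(
    w = w, objective = f_val, status = status,
    constraints = stats::setNames(ge$value, ge$names),
    multipliers = lambda, kkt = max(abs(ge$value[ge$value > 0]), 0),
    controls = sim$U, t_f = sim$tf, xf = sim$xf,
    n_outer = outer), class = "nlp_solution")
}

#' Solve a robustified optimal-control problem
#'
#' Convenience driver: transcribes the OCP on a uniform collocation grid
#' and solves it, optionally from several structured initial guesses
#' (uniform mid-level controls and a sequential-activation pattern),
#' returning the best feasible solution.
#'
#' @param ocp an [assemble_robust_ocp()] result.
#' @param n_elements finite elements of the control grid.
#' @param t_f horizon (defaults to the model's `t_f`).
#' @param free_tf treat the final time as a decision variable.
#' @param objective index of the model objective to minimize.
#' @param init `"multi"` (default) tries the bundled guesses, `"uniform"`
#'   or `"sequential"` selects a single structured guess; a
#'   `control_profile` or numeric vector warm-starts from it.
#' @param options solver options, see [solve_nlp()].
#' @return an object of class `robust_solution`: the winning
#'   `nlp_solution` augmented with the control profile, the propagated
#'   moments of the tracked quantities and the transcription.
#' @export
solve_ocp <- function(ocp, n_elements = 30, t_f = NULL, free_tf = FALSE,
                      objective = NULL, init = "multi", options = list()) {
  model <- ocp$model
  t_f <- t_f %||% model$t_f
  grid <- collocation_grid(n_elements, t_f)
  nlp <- transcribe(ocp, grid, objective = objective, free_tf = free_tf)
  starts <- initial_guesses(nlp, init)
  best <- NULL
  for (w0 in starts) {
    sol <- solve_nlp(nlp, w0, options)
    feas <- max(0, sol$constraints) < 1e-5
    if (is.null(best) ||
        (feas && !best$feasible) ||
        (feas == best$feasible && sol$objective < best$sol$objective)) {
      best <- list(sol = sol, feasible = feas)
    }
  }
  sol <- best$sol
  sol$feasible <- best$feasible
  sol$profile <- control_profile(sol$t_f * grid$boundaries / grid$t_f,
                                 sol$controls)
  sol$nlp <- nlp
  sol$moments <- solution_moments(ocp, sol)
  class(sol) <- c("robust_solution", class(sol))
  sol
}

# propagated (E, Var) of the tracked quantities at the solution
solution_moments <- function(ocp, sol) {
  tracked <- default_tracked(ocp$model)
  do.call(rbind, lapply(tracked, function(s) {
    idx <- match(s, ocp$model$state_names)
    mm <- ocp$moments(sol$xf, idx)
    data.frame(quantity = s, technique = ocp$technique, E = mm$E,
               Var = mm$Var, sd = sqrt(mm$Var))
  }))
}

initial_guesses <- function(nlp, init) {
  model <- nlp$ocp$model
  if (inherits(init, "control_profile")) init <- profile_to_w(nlp, init)
  if (is.numeric(init)) return(list(pmin(pmax(init, nlp$lower), nlp$upper)))
  n_u <- model$n_u
  n_free <- length(nlp$free_elements)
  cap <- model$control_sum_bound %||% sum(model$control_upper)
  # uniform split of the admissible total
  u_unif <- rep(pmin(model$control_upper, cap / n_u), n_free)
  # sequential activation: one control at a time across the horizon
  seq_u <- numeric(0)
  for (k in seq_len(n_free)) {
    act <- ceiling(k / n_free * n_u)
    u <- numeric(n_u)
    u[act] <- min(model$control_upper[act], cap)
    seq_u <- c(seq_u, u)
  }
  tf0 <- if (nlp$free_tf) (nlp$lower[nlp$tf_col] + nlp$upper[nlp$tf_col]) / 2
  guesses <- list(uniform = c(u_unif, tf0), sequential = c(seq_u, tf0))
  if (is.character(init) && init %in% names(guesses))
    return(guesses[init])
  guesses
}

profile_to_w <- function(nlp, profile) {
  U <- profile$values
  w <- numeric(nlp$n_w)
  for (e in nlp$free_elements) w[nlp$ucol(e)] <- U[min(e, nrow(U)), ]
  if (nlp$free_tf) w[nlp$tf_col] <- profile$t_f
  w
}

#' @export
print.robust_solution <- function(x, ...) {
  cat("robust_solution (", x$status, if (x$feasible) ", feasible" else
    ", INFEASIBLE", ")\n", sep = "")
  cat("  objective:", signif(x$objective, 6), "| t_f:", signif(x$t_f, 6),
      "s\n")
  cat("  propagated moments:\n")
  print(x$moments, row.names = FALSE)
  invisible(x)
}
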